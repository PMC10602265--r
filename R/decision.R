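# Saccadic decision-making: per-target drift rates, the multi-accumulator
# drift-diffusion race, threshold-crossing interpolation, and the linear
# amplitude-duration law for saccades.

#' Drift-diffusion parameters
#'
#' @param theta Decision threshold (> 0).
#' @param s Diffusion noise level (>= 0).
#' @param dt Time step in frames (default 1; the race is updated once per
#'   video frame).
#' @return An object of class `ddm_params`.
#' @export
ddm_params <- function(theta, s, dt = 1) {
  assert_scalar(theta, "theta", 1e-12)
  assert_scalar(s, "s", 0)
  assert_scalar(dt, "dt", 1e-12)
  structure(list(theta = theta, s = s, dt = dt), class = "ddm_params")
}

#' Space-based drift rates
#'
#' Every pixel is a potential saccade target with drift rate
#' `F * S * (1 - I)`: features times sensitivity times remaining
#' (non-inhibited) fraction.
#'
#' @param F,S,I Congruent H x W fields (features, sensitivity, inhibition).
#' @return H x W rate field in \[0, 1\].
#' @export
drift_rates_space <- function(F, S, I) {
  if (!identical(dim(F), dim(S)) || !identical(dim(F), dim(I)))
    stop("field shape mismatch", call. = FALSE)
  F * S * (1 - I)
}

#' Object-based drift rates
#'
#' Sums `F * S * (1 - I)` over each object's mask and scales the object's
#' perceptual size logarithmically: the sum is divided by
#' `|mask| * log(|mask|)` (natural log). Inhibition may be a per-object scalar
#' (pure object-based IOR) or a spatial field (mixed model: the scalar inside
#' the sum is replaced with the space-based inhibition map). Empty masks and
#' masks of at most `min_size` pixels get rate 0; the denominator is floored
#' at 1 so tiny masks can never blow up the rate.
#'
#' @param F,S H x W fields.
#' @param labels H x W integer label field (0 = background; the background is
#'   itself a race target).
#' @param inhibition Either a named numeric vector (names = object ids as
#'   characters, one entry per present id including "0") or an H x W field.
#' @param ids Optional integer vector of target ids to evaluate; defaults to
#'   all ids present in `labels`.
#' @param min_size Masks with at most this many pixels get rate 0 (default 2).
#' @param mask_idx Optional precomputed list of mask pixel indices keyed by id
#'   (as character), to avoid rescanning the label field.
#' @return Named numeric vector of drift rates, one per id.
#' @export
drift_rates_object <- function(F, S, labels, inhibition, ids = NULL,
                               min_size = 2L, mask_idx = NULL) {
  if (!identical(dim(F), dim(S)) || !identical(dim(F), dim(labels)))
    stop("field shape mismatch", call. = FALSE)
  spatial <- is.matrix(inhibition)
  if (spatial && !identical(dim(inhibition), dim(F)))
    stop("field shape mismatch", call. = FALSE)
  if (is.null(ids)) ids <- sort(unique(as.integer(labels)))
  FS <- if (spatial) F * S * (1 - inhibition) else F * S
  out <- numeric(length(ids))
  names(out) <- as.character(ids)
  for (k in seq_along(ids)) {
    idx <- if (!is.null(mask_idx)) mask_idx[[as.character(ids[k])]]
           else which(labels == ids[k])
    n <- length(idx)
    if (n == 0L || n <= min_size) next
    denom <- max(n * log(n), 1)
    total <- sum(FS[idx])
    if (!spatial) total <- total * (1 - inhibition[[as.character(ids[k])]])
    out[k] <- total / denom
  }
  out
}

#' One step of the drift-diffusion race
#'
#' Updates each target's decision variable as
#' `V + nu * (mu * dt + s * eps * sqrt(dt))` with independent standard-normal
#' `eps` per target, where `nu` is the fraction of the step spent foveating:
#' during a saccade (`nu = 0`) no evidence is accumulated and `V` is returned
#' unchanged. The decision variable is not bounded below.
#'
#' @param V Numeric vector or matrix of decision variables.
#' @param rates Drift rates, same shape as `V`.
#' @param nu_fov Fraction of the step spent foveating, in \[0, 1\].
#' @param params A [ddm_params()].
#' @return Updated decision variables, same shape as `V`.
#' @export
ddm_step <- function(V, rates, nu_fov, params) {
  assert_scalar(nu_fov, "nu_fov", 0, 1)
  if (nu_fov == 0) return(V)
  drift <- rates * params$dt
  if (params$s > 0)
    drift <- drift + params$s * sqrt(params$dt) * stats::rnorm(length(V))
  V + nu_fov * drift
}

#' Detect a threshold crossing in the race
#'
#' Among targets whose new decision variable reaches the threshold, the winner
#' is the one with the earliest linearly interpolated crossing fraction
#' `(theta - V_prev) / (V_new - V_prev)` within the step; ties are broken by
#' the larger `V_new`, then by the smaller target id. The degenerate case
#' `V_new == V_prev == theta` crosses at fraction 0.
#'
#' @param V_prev,V_new Decision variables before/after the step (vectors or
#'   matrices over the same targets; names of `V_new` are used as ids when
#'   present, otherwise linear indices).
#' @param theta Decision threshold.
#' @return `NULL` if no target crossed, else a list with `id` (integer target
#'   id), `index` (position in `V_new`), and `fraction` (crossing time within
#'   the step, in \[0, 1\]).
#' @export
detect_crossing <- function(V_prev, V_new, theta) {
  crossed <- which(V_new >= theta)
  if (!length(crossed)) return(NULL)
  dv <- V_new[crossed] - V_prev[crossed]
  frac <- ifelse(dv > 0, (theta - V_prev[crossed]) / dv, 0)
  frac <- pmin(pmax(frac, 0), 1)
  ids <- if (!is.null(names(V_new)))
    suppressWarnings(as.integer(names(V_new)[crossed])) else crossed
  if (anyNA(ids)) ids <- crossed
  ord <- order(frac, -V_new[crossed], ids)
  k <- ord[1]
  list(id = unname(ids[k]), index = unname(crossed[k]), fraction = unname(frac[k]))
}

#' Saccade duration from amplitude
#'
#' Linear main-sequence law: `2.7 ms/dva * amplitude + 23 ms`.
#'
#' @param amplitude_dva Saccade amplitude in dva (>= 0); vectorised.
#' @return Duration in ms.
#' @export
saccade_duration <- function(amplitude_dva) {
  if (any(amplitude_dva < 0)) stop("negative saccade amplitude", call. = FALSE)
  2.7 * amplitude_dva + 23
}
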