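# Scanpath evaluation: event filters, object assignment for position-only
# traces, functional foveation categories, KS distribution distances and the
# fitness they define, and sequential (turning-angle / return) diagnostics.
# Simulated and reference scanpaths share one event-table format, so every
# statistic applies identically to both.

#' Filter an event table
#'
#' Drops foveation events shorter than 33.3 ms (one frame at 30 fps) and
#' saccades with amplitudes below 0.5 dva (treated as microsaccades, i.e. a
#' component of fixational eye movements). Applied identically to simulated
#' and reference tables before any statistic.
#'
#' @param table Event table (see [simulate_scanpath()] for the schema).
#' @param min_fov_ms,min_sac_dva Thresholds (defaults 33.3 ms, 0.5 dva).
#' @return The filtered table.
#' @export
filter_events <- function(table, min_fov_ms = 33.3, min_sac_dva = 0.5) {
  keep <- ifelse(table$event_type == "fov",
                 table$duration_ms >= min_fov_ms,
                 table$amplitude_dva >= min_sac_dva)
  table[keep & !is.na(keep), , drop = FALSE]
}

#' Object id at a gaze position
#'
#' A gaze sample counts as on object `i` when it falls inside the mask of
#' `O_i` dilated by `radius_dva` (to absorb tracking inaccuracies); among
#' several candidates the nearest mask wins, with ties broken by the nearest
#' mask centroid. Farther than `radius_dva` from every mask is background (0).
#'
#' @param bundle A `scene_bundle`.
#' @param frame Frame index.
#' @param x,y Gaze position in px.
#' @param radius_dva Dilation radius in dva (default 1).
#' @return Integer object id (0 = background).
#' @export
object_at_gaze <- function(bundle, frame, x, y, radius_dva = 1) {
  lab <- bundle$objects[, , frame]
  H <- nrow(lab)
  ri <- min(max(round(y), 1L), H); ci <- min(max(round(x), 1L), ncol(lab))
  hit <- lab[ri, ci]
  if (hit > 0L) return(as.integer(hit))
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(0L)
  rad <- radius_dva * bundle$px_per_dva
  best_id <- 0L; best <- c(Inf, Inf)
  for (i in ids) {
    idx <- which(lab == i)
    rr <- ((idx - 1L) %% H) + 1L
    cc <- ((idx - 1L) %/% H) + 1L
    d2 <- min((cc - x)^2 + (rr - y)^2)
    if (sqrt(d2) <= rad) {
      cd2 <- (mean(cc) - x)^2 + (mean(rr) - y)^2
      if (d2 < best[1] - 1e-12 ||
          (abs(d2 - best[1]) <= 1e-12 && cd2 < best[2])) {
        best <- c(d2, cd2); best_id <- i
      }
    }
  }
  as.integer(best_id)
}

#' Assign object ids to foveation events from a gaze trace
#'
#' Per frame the gaze is assigned to an object via [object_at_gaze()]; each
#' foveation event then gets the id holding the majority of its frames (ties
#' to the id with more time, then the smaller id). Used for position-only
#' scanpaths (human reference data and space-selection models); object-mode
#' simulated events keep their known target id instead.
#'
#' @param trace Per-frame trace with columns `frame`, `t_ms`, `x_px`, `y_px`,
#'   `state`.
#' @param bundle A `scene_bundle`.
#' @param events Optional foveation-event rows (`t_start_ms`, `t_end_ms`);
#'   when `NULL`, maximal runs of consecutive `state == "fov"` frames are
#'   treated as the foveation events.
#' @param radius_dva Dilation radius in dva (default 1).
#' @return Integer vector of object ids, one per foveation event.
#' @export
assign_objects <- function(trace, bundle, events = NULL, radius_dva = 1) {
  fd <- 1000 / bundle$fps
  fov_rows <- trace$state == "fov"
  frame_id <- rep(NA_integer_, nrow(trace))
  for (k in which(fov_rows))
    frame_id[k] <- object_at_gaze(bundle, trace$frame[k],
                                  trace$x_px[k], trace$y_px[k], radius_dva)
  if (is.null(events)) {
    r <- rle(trace$state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values == "fov"
    events <- data.frame(t_start_ms = (trace$frame[starts[keep]] - 1) * fd,
                         t_end_ms = trace$frame[ends[keep]] * fd)
  }
  out <- integer(nrow(events))
  for (e in seq_len(nrow(events))) {
    mids <- (trace$frame - 0.5) * fd
    in_ev <- fov_rows & mids >= events$t_start_ms[e] & mids < events$t_end_ms[e]
    ids <- frame_id[in_ev]
    ids <- ids[!is.na(ids)]
    if (!length(ids)) {      # sub-frame foveation: fall back to the onset gaze
      fr <- min(max(floor(events$t_start_ms[e] / fd) + 1, 1), bundle$n_frames)
      out[e] <- object_at_gaze(bundle, fr, events$x_start_px[e] %||% NA,
                               events$y_start_px[e] %||% NA, radius_dva)
      if (is.na(out[e])) out[e] <- 0L
      next
    }
    tab <- sort(table(ids), decreasing = TRUE)
    top <- names(tab)[tab == tab[1]]
    out[e] <- as.integer(min(as.integer(top)))
  }
  out
}

#' Functional foveation categories
#'
#' Classifies each foveation of one scanpath by the function it serves:
#' `Background` (id 0), `Detection` (first foveation of this object in the
#' scanpath), `Inspection` (same object as the immediately preceding
#' foveation, i.e. a within-object saccade), or `Return` (a previously
#' foveated object that is not the immediately preceding one; an intervening
#' background foveation breaks an inspection chain).
#'
#' @param ids Integer vector of foveated object ids, in chronological order
#'   within one scanpath.
#' @return Character vector of categories, same length as `ids`.
#' @export
categorize_foveations <- function(ids) {
  n <- length(ids)
  out <- character(n)
  seen <- integer(0)
  for (k in seq_len(n)) {
    i <- ids[k]
    out[k] <- if (is.na(i) || i == 0L) "Background"
    else if (!i %in% seen) "Detection"
    else if (k > 1L && !is.na(ids[k - 1L]) && ids[k - 1L] == i) "Inspection"
    else "Return"
    if (!is.na(i) && i > 0L) seen <- union(seen, i)
  }
  out
}

#' Add a category column to an event table
#'
#' Applies [categorize_foveations()] per (scene, run) scanpath.
#'
#' @param table Event table with assigned `object_id`s.
#' @return The table with a `category` column (`NA` for saccade rows).
#' @export
categorize_events <- function(table) {
  table$category <- NA_character_
  for (key in unique(paste(table$scene_id, table$run_id))) {
    sel <- paste(table$scene_id, table$run_id) == key & table$event_type == "fov"
    ord <- order(table$t_start_ms[sel])
    cats <- categorize_foveations(table$object_id[sel][ord])
    table$category[which(sel)[ord]] <- cats
  }
  table
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' `D = sup_x |F(x) - G(x)|` of the two empirical CDFs; tie-safe.
#'
#' @param a,b Non-empty numeric samples.
#' @return `D` in \[0, 1\].
#' @export
ks_statistic <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  xs <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(xs) - stats::ecdf(b)(xs)))
}

#' Scanpath fitness against a reference
#'
#' `-(d_SA + d_FD) / 2`, where `d_SA` and `d_FD` are the two-sample KS
#' distances between the saccade-amplitude and foveation-duration samples of
#' the two (already filtered) tables, pooled across all scenes and runs. The
#' maximum 0 is attained iff both distributions match exactly.
#'
#' @param sim_table,ref_table Filtered event tables.
#' @return Numeric scalar in \[-1, 0\], with attributes `d_SA` and `d_FD`.
#' @export
fitness <- function(sim_table, ref_table) {
  d_sa <- ks_statistic(sim_table$amplitude_dva[sim_table$event_type == "sac"],
                       ref_table$amplitude_dva[ref_table$event_type == "sac"])
  d_fd <- ks_statistic(sim_table$duration_ms[sim_table$event_type == "fov"],
                       ref_table$duration_ms[ref_table$event_type == "fov"])
  structure(-(d_sa + d_fd) / 2, d_SA = d_sa, d_FD = d_fd)
}

wrap_angle <- function(deg) {
  out <- (deg + 180) %% 360 - 180
  ifelse(out == -180, 180, out)
}

#' Sequential saccade diagnostics
#'
#' For each pair of consecutive saccades within a scanpath: the relative
#' angle `phi` between their direction vectors (in degrees, in (-180, 180];
#' positive = rotation from +x toward +y, i.e. clockwise on screen with y
#' pointing downward -- only `|phi|` enters the published summaries), the
#' absolute amplitude difference, and the duration of the foveation preceding
#' the second saccade. Summaries: a 12-degree-bin angle histogram, the
#' fraction of pairs with `|phi| > 135` (facilitation-of-return diagnostic),
#' the return-saccade ratio (`|phi| > 178` and amplitude difference
#' < 1.5 dva), and the angle-binned median preceding foveation duration
#' smoothed with a centred circular moving average across 5 bins.
#'
#' @param table Filtered event table.
#' @return List with `pairs` (per-pair data.frame), `angle_hist`
#'   (`bin_mid`, `count`), `frac_gt135`, `return_ratio`, `n_pairs`, and
#'   `binned_fd` (`bin_mid`, `median_fd_ms`, `smoothed_fd_ms`).
#' @export
sequential_stats <- function(table) {
  pairs <- list(); np <- 0L
  for (key in unique(paste(table$scene_id, table$run_id))) {
    sub <- table[paste(table$scene_id, table$run_id) == key, , drop = FALSE]
    sub <- sub[order(sub$t_start_ms), , drop = FALSE]
    sac <- sub[sub$event_type == "sac", , drop = FALSE]
    if (nrow(sac) < 2L) next
    vx <- sac$x_end_px - sac$x_start_px; vy <- sac$y_end_px - sac$y_start_px
    ang <- atan2(vy, vx) * 180 / pi
    fov <- sub[sub$event_type == "fov", , drop = FALSE]
    for (k in seq_len(nrow(sac) - 1L)) {
      prev <- fov$duration_ms[fov$t_start_ms < sac$t_start_ms[k + 1L] &
                              fov$t_start_ms >= sac$t_start_ms[k]]
      np <- np + 1L
      pairs[[np]] <- data.frame(
        scene_id = sac$scene_id[1], run_id = sac$run_id[1],
        phi = wrap_angle(ang[k + 1L] - ang[k]),
        d_amp = abs(sac$amplitude_dva[k + 1L] - sac$amplitude_dva[k]),
        prec_fd_ms = if (length(prev)) prev[length(prev)] else NA_real_)
    }
  }
  pairs <- if (np) do.call(rbind, pairs) else
    data.frame(scene_id = character(), run_id = integer(), phi = numeric(),
               d_amp = numeric(), prec_fd_ms = numeric())
  breaks <- seq(-180, 180, by = 12)
  mids <- breaks[-1] - 6
  bin <- if (np) findInterval(pairs$phi, breaks, rightmost.closed = TRUE,
                              left.open = TRUE) else integer(0)
  counts <- tabulate(bin, nbins = 30L)
  med <- vapply(seq_len(30L), function(b) {
    v <- pairs$prec_fd_ms[bin == b]
    if (all(is.na(v)) || !length(v)) NA_real_ else stats::median(v, na.rm = TRUE)
  }, numeric(1))
  smoothed <- vapply(seq_len(30L), function(b) {
    idx <- ((b - 3L):(b + 1L)) %% 30L + 1L   # centred window of 5 circular bins
    v <- med[idx]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  list(pairs = pairs,
       angle_hist = data.frame(bin_mid = mids, count = counts),
       frac_gt135 = if (np) mean(abs(pairs$phi) > 135) else NA_real_,
       return_ratio = if (np) mean(abs(pairs$phi) > 178 & pairs$d_amp < 1.5)
                      else NA_real_,
       n_pairs = np,
       binned_fd = data.frame(bin_mid = mids, median_fd_ms = med,
                              smoothed_fd_ms = smoothed))
}

table_object_returns <- function(table) {
  times <- numeric(0); n_ret <- 0L; n_sac <- 0L
  for (key in unique(paste(table$scene_id, table$run_id))) {
    sub <- table[paste(table$scene_id, table$run_id) == key, , drop = FALSE]
    sub <- sub[order(sub$t_start_ms), , drop = FALSE]
    n_sac <- n_sac + sum(sub$event_type == "sac")
    fov <- sub[sub$event_type == "fov", , drop = FALSE]
    if (nrow(fov) < 2L) next
    for (k in 2:nrow(fov)) {
      i <- fov$object_id[k]
      if (is.na(i) || i == 0L) next
      if (!is.na(fov$object_id[k - 1L]) && fov$object_id[k - 1L] == i) next
      earlier <- which(fov$object_id[seq_len(k - 1L)] == i)
      if (!length(earlier)) next
      n_ret <- n_ret + 1L
      times <- c(times, fov$t_start_ms[k] - fov$t_end_ms[max(earlier)])
    }
  }
  list(ratio = if (n_sac) n_ret / n_sac else NA_real_,
       median_ms = if (n_ret) stats::median(times) else NA_real_,
       times_ms = times, n_saccades = n_sac)
}

modal_first_detection <- function(table) {
  out <- list()
  for (scene in unique(table$scene_id)) {
    firsts <- integer(0)
    sub <- table[table$scene_id == scene, , drop = FALSE]
    for (run in unique(sub$run_id)) {
      fov <- sub[sub$run_id == run & sub$event_type == "fov", , drop = FALSE]
      fov <- fov[order(fov$t_start_ms), , drop = FALSE]
      hit <- fov$object_id[!is.na(fov$object_id) & fov$object_id > 0L]
      if (length(hit)) firsts <- c(firsts, hit[1])
    }
    out[[scene]] <- if (length(firsts)) {
      tab <- sort(table(firsts), decreasing = TRUE)
      as.integer(min(as.integer(names(tab)[tab == tab[1]])))
    } else NA_integer_
  }
  data.frame(scene_id = names(out), first_object = unlist(out),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Object-centred comparison of two scanpath sets
#'
#' Computes, per table: per-object total dwell time (summed over each run,
#' then averaged across runs per scene), object-return events (saccades
#' landing on an object foveated earlier but not currently, with return time
#' measured from the end of that object's previous foveation to the landing),
#' and the modal first-detected object per scene. Across tables: the
#' least-squares regression of simulated on reference per-object dwell times
#' and the first-detection agreement (fraction of scenes whose modal first
#' object matches).
#'
#' @param sim_table,ref_table Filtered event tables with assigned object ids.
#' @return List with `dwell` (merged per-object dwell table), `m`, `y0`, `r2`
#'   (regression of sim on ref), `sim_returns`, `ref_returns` (see
#'   `ratio` / `median_ms` elements), `first_detection` (per-scene modal first
#'   objects), and `first_detection_agreement`.
#' @export
object_stats <- function(sim_table, ref_table) {
  dwell_of <- function(table) {
    fov <- table[table$event_type == "fov" & !is.na(table$object_id) &
                 table$object_id > 0L, , drop = FALSE]
    if (!nrow(fov))
      return(data.frame(scene_id = character(), object_id = integer(),
                        dwell_ms = numeric()))
    agg <- stats::aggregate(duration_ms ~ scene_id + run_id + object_id,
                            data = fov, FUN = sum)
    n_runs <- stats::aggregate(run_id ~ scene_id,
                               data = unique(table[c("scene_id", "run_id")]),
                               FUN = length)
    tot <- stats::aggregate(duration_ms ~ scene_id + object_id, data = agg, FUN = sum)
    tot$dwell_ms <- tot$duration_ms /
      n_runs$run_id[match(tot$scene_id, n_runs$scene_id)]
    tot[c("scene_id", "object_id", "dwell_ms")]
  }
  ds <- dwell_of(sim_table); dr <- dwell_of(ref_table)
  dwell <- merge(dr, ds, by = c("scene_id", "object_id"), all = TRUE,
                 suffixes = c("_ref", "_sim"))
  dwell$dwell_ms_ref[is.na(dwell$dwell_ms_ref)] <- 0
  dwell$dwell_ms_sim[is.na(dwell$dwell_ms_sim)] <- 0
  if (nrow(dwell) >= 2 && stats::var(dwell$dwell_ms_ref) > 0) {
    fit <- stats::lm(dwell_ms_sim ~ dwell_ms_ref, data = dwell)
    m <- unname(stats::coef(fit)[2]); y0 <- unname(stats::coef(fit)[1])
    r2 <- summary(fit)$r.squared
  } else m <- y0 <- r2 <- NA_real_
  fd_sim <- modal_first_detection(sim_table)
  fd_ref <- modal_first_detection(ref_table)
  fd <- merge(fd_ref, fd_sim, by = "scene_id", suffixes = c("_ref", "_sim"))
  agree <- if (nrow(fd)) mean(fd$first_object_ref == fd$first_object_sim,
                              na.rm = TRUE) else NA_real_
  list(dwell = dwell, m = m, y0 = y0, r2 = r2,
       sim_returns = table_object_returns(sim_table),
       ref_returns = table_object_returns(ref_table),
       first_detection = fd, first_detection_agreement = agree)
}

#' Time course of functional foveation categories
#'
#' For each time bin, the fraction of concurrently ongoing foveation time per
#' category, normalised over foveation time only (time spent in saccades is
#' excluded), so proportions sum to 1 wherever any foveation overlaps the bin.
#'
#' @param table Event table with assigned object ids (categories are computed
#'   via [categorize_events()] when no `category` column is present).
#' @param bin_ms Bin width in ms (default 100).
#' @param t_max_ms Upper end of the binning (default: last event end).
#' @return `data.frame` with `bin_start_ms`, `category`, `proportion`.
#' @export
category_timecourse <- function(table, bin_ms = 100, t_max_ms = NULL) {
  if (is.null(table$category)) table <- categorize_events(table)
  fov <- table[table$event_type == "fov", , drop = FALSE]
  t_max <- t_max_ms %||% max(table$t_end_ms)
  starts <- seq(0, t_max - 1e-9, by = bin_ms)
  cats <- c("Background", "Detection", "Inspection", "Return")
  out <- expand.grid(bin_start_ms = starts, category = cats,
                     stringsAsFactors = FALSE)
  out$proportion <- NA_real_
  for (b in seq_along(starts)) {
    b0 <- starts[b]; b1 <- min(b0 + bin_ms, t_max)
    ov <- pmax(0, pmin(fov$t_end_ms, b1) - pmax(fov$t_start_ms, b0))
    tot <- sum(ov)
    if (tot <= 0) next
    for (cat in cats)
      out$proportion[out$bin_start_ms == b0 & out$category == cat] <-
        sum(ov[fov$category == cat]) / tot
  }
  out
}
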