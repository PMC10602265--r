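---
title: "Mechanistic scanpath simulation on dynamic scenes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic scanpath simulation on dynamic scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanpathsim)
```

## The model

`scanpathsim` simulates where and when a human observer moves their eyes
while free-viewing a dynamic scene. The gaze alternates between *foveation
events* (fixation when the foveated content is static, smooth pursuit when
it moves) and *saccades*. Both the timing and the target of every saccade
emerge from a race of drift-diffusion accumulators, one per potential
target:

$$V_i(t + \Delta t) = V_i(t) + \nu\,\bigl(\mu_i(t)\,\Delta t + s\,\epsilon_i\sqrt{\Delta t}\bigr), \qquad \epsilon_i \sim \mathcal N(0, 1),$$

where $\nu$ is the fraction of the step spent foveating (no evidence is
accumulated mid-saccade), $s$ is the diffusion noise level, and the race is
updated once per video frame ($\Delta t$ = 1 frame). The first accumulator
to reach the threshold $\theta$ wins; the crossing time is interpolated
linearly inside the step so foveation durations have sub-frame resolution.
The winner defines the saccade target, and the saccade's duration follows
the linear main-sequence law $\tau_s = 2.7\,\mathrm{ms/dva}\cdot a_s + 23$ ms.

The drift rate of a target combines three per-frame fields:

* **Features** $F(x,y,t)$: a per-pixel relevance map in $[0,1]$ (any
  precomputed saliency; the package's synthetic scenes place Gaussian
  feature blobs on the objects), normalised per frame by its maximum and
  multiplied with an anisotropic Gaussian **centre bias**
  $\exp(-\tilde x^2/2\sigma_x^2 - \tilde y^2\nu_{cb}/2\sigma_x^2)$ with
  $\sigma_x^2 = 0.22$ and $\nu_{cb} = 0.45$ on axis-normalised coordinates.
* **Sensitivity** $S(x,y,t)$: a unit-peak isotropic Gaussian of spread
  $\sigma_S$ (dva) centred on the gaze, modelling the acuity fall-off with
  eccentricity. Object-based variants additionally set $S = 1$ across the
  currently foveated object's mask (covert attention spreads over the
  attended object); foveating the background sets no such region.
* **Inhibition of return** $I$: *space-based* IOR sums unit-peak Gaussians
  of spread $\sigma_I$ at previous saccade-target locations (allocentric, so
  a moving object can escape its own inhibition), each decaying linearly to
  zero over $1/r$ frames, clipped at 1. *Object-based* IOR inhibits the
  currently foveated object by $\xi \in [0,1]$, resets an object's
  inhibition to 1 the moment the gaze leaves it, and decays it linearly with
  slope $r$; the background is never inhibited.

Space-based selection treats every pixel as a race target with
$\mu = F\,S\,(1-I)$. Object-based selection treats every segmentation mask
(including the background) as one target with

$$\mu_i = \frac{\sum_{x,y} F\,S\,O_i\,(1 - I_i)}{|O_i|\,\log |O_i|},$$

the logarithmic size normalisation keeping large masks from dominating by
area alone. Five variants wire these pieces together: `S.ll`/`S.hl` (space
selection + space IOR with low-/high-level features), `O.ll` (object
selection + object IOR), `O.cb` (`O.ll` without scene features — centre
bias only) and `M.ll` (object selection with space IOR; the spatial
inhibition map replaces the scalar $I_i$ inside the object sum). Between
decisions the gaze pursues the foveated object's centroid (object variants)
or follows the optical flow at the gaze (space variants), with Brownian
fixational jitter of sd $\sigma_D$ per frame on top; saccades land exactly
on the winning pixel, or on a mask pixel sampled with probability
$\propto F\,S$ at decision time.

## Parameters

| Parameter | Meaning | Unit | Default (`O.ll`) |
|---|---|---|---|
| $\sigma_S$ | spread of visual sensitivity | dva | 13.75 |
| $\theta$ | decision threshold | – | 2.128 |
| $s$ | diffusion noise | – | 0.230 |
| $1/r$ | frames until inhibition recovers | frames | 272 |
| $\sigma_I$ / $\xi$ | space-IOR extent / within-object inhibition | dva / – | – / 0.72 |
| $\sigma_D$ | fixational random walk sd | dva/frame | 0.125 (fixed) |

Per-variant defaults are the published best-fitness values of each variant;
$\theta$ mainly sets mean foveation duration, $\sigma_S$ mean saccade
amplitude, $s$ scanpath variability, and $r$, $\sigma_I$/$\xi$ the rate of
within-object and return saccades. The centre-bias constants and $\sigma_D$
are treated as fixed scene-independent quantities, not fitted.

## Synthetic scenes and reference data

Real inputs (video saliency, segmentation-and-tracking masks, optical flow)
come from upstream vision models. The synthetic generator emulates their
joint structure instead: temporally consistent integer label fields for a
handful of ellipse/rectangle objects under constant-velocity motion, feature
blobs riding on the object centroids over a low background level with mild
clipped Gaussian noise, and flow equal to each object's velocity inside its
mask. `demo_scenes()` fixes the package's study conditions: three scenes of
80 × 60 px at 2 px/dva (a 40 × 30 dva display), 300 frames at 30 fps — the
published scene length — with 3–4 objects each. What such scenes do *not*
emulate: cluttered many-object layouts, occlusion and segmentation errors,
deformable or accelerating objects, camera motion, photometric texture
inside objects, and blink/tracker-noise gaps in reference data. Passing
tests therefore validate the mechanics and statistics of the framework, not
gaze prediction on natural video.

Synthetic *reference* scanpaths draw foveation durations from a log-normal
(meanlog 5.735, sdlog 0.838; mean 439.6 ms) and saccade amplitudes from a
Gamma distribution (shape 1.43, scale 6.50), the forms fitted to human
free-viewing event statistics, and tile the video duration with alternating
events (the last foveation absorbs the remainder). Saccades aim at a
uniformly chosen pixel of a random object with probability `p_object = 0.6`
— free-viewing observers spend the majority of their time on foreground
objects — and otherwise fly in a uniform random direction with the drawn
amplitude. Foveations on an object follow its centroid, and object ids are
assigned with the same 1-dva-dilation majority rule used for any
position-only scanpath.

## Evaluation statistics

Simulated and reference scanpaths share one event-table format and one
pipeline: events are filtered (foveations < 33.3 ms, saccades < 0.5 dva
dropped — the latter treated as microsaccades), object ids are assigned
(object-mode simulations keep their known target id; the dilation rule
exists to absorb tracking inaccuracies in position-only traces), and each
foveation is categorised as Background / Detection / Inspection / Return.
Distribution similarity is the two-sample Kolmogorov–Smirnov statistic on
pooled saccade amplitudes ($d_{SA}$) and foveation durations ($d_{FD}$),
combined into the fitness $\mathcal F = -(d_{SA} + d_{FD})/2$. Sequential
diagnostics use the relative angle $\varphi$ between consecutive saccades
(12° bins; positive $\varphi$ = rotation from $+x$ toward $+y$ with $y$
pointing down — only $|\varphi|$ enters summaries), the fraction with
$|\varphi| > 135°$, return saccades ($|\varphi| > 178°$ and amplitude
difference < 1.5 dva), angle-binned median preceding foveation durations
(centred circular moving average over 5 bins), object returns (time from
leaving an object to landing on it again), per-object dwell-time regression,
and modal first-detected objects.

## Fitting

The five free parameters are fitted by an evolutionary strategy: uniform
initial population (64 by default), rank-weighted parent selection, Gaussian
mutation clipped to the box, elitist survival of the best 32, for 50
generations. The published protocol delegates mutation details to an
optimisation library's defaults; here the step size is a fraction of each
parameter's range adapted by a 1/5-success rule (×1.5 when more than 20 % of
offspring beat their parent, ×0.85 otherwise, bounded in [0.02, 0.5]) — a
standard ES choice, documented in code. Objectives use a fixed
per-(scene, run) seed schedule, so all candidates face the same noise
realisations (common random numbers) and the whole search is reproducible.

## Numerical choices and degenerate inputs

* Unit-peak Gaussians are used for sensitivity and space IOR instead of
  density-normalised ones: the object-mode rule "set the foveated mask to 1"
  is only meaningful with a peak ≤ 1, and $1/(2\pi\sigma^2)$ prefactors at
  pixel scale would make inhibition numerically negligible; the fitted
  $\theta$ and $s$ absorb any constant rescaling.
* Pixel coordinates are 1-based with $x$ = column and $y$ = row (origin top
  left); gaze positions are continuous. A single scalar `px_per_dva`
  converts all dva-valued parameters at use.
* Drift rates are evaluated once per frame. Saccades can be shorter than a
  frame (the duration law's floor is 23 ms vs. 33.3 ms frames), so a frame
  may contain several foveation segments; each contributes its own
  $\nu$-scaled race update, and the sensitivity map is re-centred after an
  intra-frame landing.
* An all-zero feature frame stays all-zero (no division by the frame
  maximum); object masks of ≤ 2 px get drift rate 0 and the denominator
  $|O_i|\log|O_i|$ is floored at 1 (avoiding $\log 1 = 0$); an empty mask
  freezes its accumulator; decision variables may go negative (no lower
  clamp). Crossing ties are broken by the earlier interpolated fraction,
  then the larger decision variable, then the smaller id.
* Space-IOR history is unbounded within a scene (old entries decay to
  exactly zero anyway) and stores landing locations at decision time.
* A saccade spanning the video end is truncated at the last frame and
  flagged; time is conserved exactly: foveation plus saccade durations sum
  to the video duration.
* The control transform (time reversal plus double mirroring) negates flow
  for the reversal and flips each component for its mirrored axis — the
  stored components are unchanged while all fields are re-indexed, making
  the transform an involution; the one-frame offset inherent in reversing a
  forward-difference flow field is ignored.

## Problem sizes used in tests and the reproduction script

Unit tests run on 40 × 30 px, 60–120-frame scenes; the recovery and
distributional-fit checks use the three `demo_scenes()` at the full 300
frames with a reduced search budget (initial population 16, ongoing 8, 15
generations, 6 runs per scene — the 2:1 population ratio of the full
protocol), sizes chosen so the whole pipeline, including two evolutionary
fits, completes on a single CPU in minutes. With this budget the recovery
of $\theta$ and $\sigma_S$ against self-generated reference data lands
within 25 % relative error, and the fitted `O.ll` model reaches a fitness
above −0.15 against the synthetic log-normal/Gamma reference
(both KS distances ≤ 0.2); the slope $r$ is known to be poorly constrained
by the distribution-only objective and is not asserted.

## Known limitations

The framework inherits the published model's idealisations: saccades always
land exactly on their target (no landing error), there is no facilitation
of return (so direct return saccades are structurally underrepresented), no
perisaccadic attention shifts, no blink or tracker-noise episodes, and
object masks are assumed fully formed before being attended. The synthetic
scenes are far simpler than natural video, and fitted parameter values on
them are not comparable to values fitted on real scenes.

## A minimal session

```{r example, eval = FALSE}
scenes <- demo_scenes()
spec <- model_spec("O.ll", theta = 1)
sim <- run_batch(scenes, spec, n_runs = 12, base_seed = 1)
ref <- do.call(rbind, lapply(scenes, function(b)
  synth_reference(reference_spec(seed = 11), b)))
f <- fitness(filter_events(sim), filter_events(ref))
c(fitness = as.numeric(f), d_SA = attr(f, "d_SA"), d_FD = attr(f, "d_FD"))
```
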