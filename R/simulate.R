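#' Haemodynamic response parameters
#'
#' Canonical double-gamma shape: a gamma-density peak minus a scaled,
#' delayed gamma-density undershoot.
#'
#' @param peak_delay,peak_dispersion Delay and dispersion of the positive
#'   lobe, seconds.
#' @param undershoot_delay,undershoot_dispersion Delay and dispersion of the
#'   undershoot, seconds.
#' @param undershoot_ratio Relative amplitude of the undershoot.
#' @return A list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6) {
  stopifnot(peak_delay > 0, undershoot_delay > peak_delay,
            peak_dispersion > 0, undershoot_dispersion > 0,
            undershoot_ratio > 0)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio), class = "hrf_params")
}

#' Canonical double-gamma haemodynamic response
#'
#' @param time_grid Nonnegative, increasing time points in seconds.
#' @param params An [hrf_params()].
#' @return Response values, peak-normalised to 1, with response(0) = 0.
#' @export
hrf <- function(time_grid, params = hrf_params()) {
  stopifnot(all(time_grid >= 0), !is.unsorted(time_grid))
  h <- stats::dgamma(time_grid, shape = params$peak_delay / params$peak_dispersion,
                     scale = params$peak_dispersion) -
    params$undershoot_ratio *
    stats::dgamma(time_grid, shape = params$undershoot_delay / params$undershoot_dispersion,
                  scale = params$undershoot_dispersion)
  h / max(h)
}

new_event_design <- function(onsets, durations, n_volumes, tr, condition = NULL) {
  if (is.null(condition)) condition <- factor(rep("task", length(onsets)))
  run <- n_volumes * tr
  stopifnot(!is.unsorted(onsets), all(onsets >= 0), all(durations > 0),
            all(onsets + durations <= run), length(durations) %in% c(1L, length(onsets)))
  if (length(durations) == 1L) durations <- rep(durations, length(onsets))
  structure(list(onsets = onsets, durations = durations,
                 n_volumes = as.integer(n_volumes), tr = tr,
                 condition = condition),
            class = "event_design")
}

#' Periodic event design
#'
#' Events at 0, period, 2*period, ...; the number of events is the number of
#' whole periods in the run, so each event's cycle fits the acquisition.
#'
#' @param period Inter-onset interval, seconds.
#' @param duration Event duration, seconds.
#' @param n_volumes Number of acquired volumes.
#' @param tr Repetition time, seconds.
#' @return An `event_design`.
#' @export
make_periodic_design <- function(period = 10, duration = 1, n_volumes, tr = 2.52) {
  stopifnot(period > duration, n_volumes >= 1)
  run <- n_volumes * tr
  n_ev <- max(1L, floor(run / period))
  onsets <- (seq_len(n_ev) - 1) * period
  keep <- onsets + duration <= run
  new_event_design(onsets[keep], duration, n_volumes, tr)
}

#' Pseudo-randomised event design
#'
#' A fixed number of stimuli separated by inter-stimulus intervals drawn
#' uniformly from a range, reproducible from the seed.
#'
#' @param n_stimuli Number of events.
#' @param isi_range Two-element range of the inter-stimulus interval, seconds.
#' @param stim_duration Event duration, seconds.
#' @param n_volumes,tr Acquisition length.
#' @param seed Integer seed.
#' @return An `event_design`.
#' @export
make_task_design <- function(n_stimuli = 40L, isi_range = c(15, 25),
                             stim_duration = 1.5, n_volumes = 410L, tr = 2.52,
                             seed = 1L) {
  run <- n_volumes * tr
  if (isi_range[1] * (n_stimuli - 1) + stim_duration > run)
    stop("infeasible design: minimum total ISI exceeds the run length", call. = FALSE)
  rng <- local_rng(seed)
  repeat {
    isis <- rng$runif(n_stimuli - 1L, isi_range[1], isi_range[2])
    onsets <- cumsum(c(isi_range[1], isis))
    if (onsets[n_stimuli] + stim_duration <= run) break
  }
  new_event_design(onsets, stim_duration, n_volumes, tr)
}

#' Alternating two-condition design
#'
#' Strictly alternating events for two conditions, one onset every `period`
#' seconds, with the starting condition randomised by the seed.
#'
#' @inheritParams make_periodic_design
#' @param labels Condition labels.
#' @param seed Integer seed for the starting condition.
#' @return An `event_design` with a two-level `condition` factor.
#' @export
make_alternating_design <- function(period = 10, duration = 1, n_volumes, tr = 2.52,
                                    labels = c("A", "B"), seed = 1L) {
  base <- make_periodic_design(period, duration, n_volumes, tr)
  rng <- local_rng(seed)
  start <- rng$sample_int(2L, 1L)
  cond <- labels[1L + (seq_along(base$onsets) + start) %% 2L]
  new_event_design(base$onsets, base$durations, n_volumes, tr,
                   condition = factor(cond, levels = labels))
}

#' Amplitude ramp around a surface location
#'
#' Per-vertex weight 1 at the centre, falling linearly with geodesic distance
#' to 0 at `radius_mm`.
#'
#' @param phantom A `cortical_phantom`.
#' @param center_vertex Vertex index of the ramp centre.
#' @param radius_mm Geodesic radius at which the weight reaches 0.
#' @return Numeric vector of per-vertex weights.
#' @export
make_roi_ramp <- function(phantom, center_vertex, radius_mm = 6) {
  d <- geodesic_from(phantom, center_vertex)
  pmax(0, 1 - d / radius_mm)
}

#' Noise model for the resting-state-like background
#'
#' Temporally AR(1) noise with a linear drift and mild spatial correlation,
#' standing in for resting-state BOLD backgrounds.
#'
#' @param ar_coeff Lag-1 autoregressive coefficient, in [0, 1).
#' @param sigma Per-voxel standard deviation of the noise, signal units.
#' @param drift_amplitude Standard deviation of the per-voxel linear drift
#'   over the run, signal units.
#' @param spatial_fwhm_mm Spatial correlation scale of the noise field
#'   (Gaussian FWHM); 0 gives voxel-independent noise.
#' @param seed Integer seed.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(ar_coeff = 0.3, sigma = 1, drift_amplitude = 0.01,
                        spatial_fwhm_mm = 6, seed = 1L) {
  stopifnot(abs(ar_coeff) < 1, sigma >= 0, drift_amplitude >= 0,
            spatial_fwhm_mm >= 0)
  structure(list(ar_coeff = ar_coeff, sigma = sigma,
                 drift_amplitude = drift_amplitude,
                 spatial_fwhm_mm = spatial_fwhm_mm, seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a resting-state-like background run
#'
#' AR(1)-plus-drift noise in cortex, white-matter and CSF voxels (zeros in
#' the background compartment), optionally spatially correlated, rescaled so
#' the per-voxel standard deviation equals `sigma`.
#'
#' @param phantom A `cortical_phantom`.
#' @param model A [noise_model()].
#' @param n_volumes Number of volumes.
#' @param tr Repetition time, seconds.
#' @return A `subject_ts`: list with 4D `data`, `tr`, `seed`, `phantom`,
#'   and an empty `ground_truth`.
#' @export
simulate_background <- function(phantom, model = noise_model(), n_volumes, tr = 2.52) {
  shape <- phantom$grid_shape
  n_vox <- prod(shape)
  rng <- local_rng(model$seed)
  mask <- phantom$voxel_tissue != "background"
  data <- array(0, dim = c(shape, n_volumes))
  if (model$sigma > 0) {
    a <- model$ar_coeff
    eps <- matrix(rng$rnorm(n_vox * n_volumes), n_vox, n_volumes)
    for (t in seq_len(n_volumes)[-1]) eps[, t] <- a * eps[, t - 1] + eps[, t]
    ar_var <- 1 / (1 - a^2)
    if (model$spatial_fwhm_mm > 0) {
      svar <- spatial_var_factor(shape, model$spatial_fwhm_mm, phantom$voxel_mm)
      noise4 <- smooth_volume(array(eps, c(shape, n_volumes)),
                              model$spatial_fwhm_mm, phantom$voxel_mm)
      eps <- matrix(noise4, n_vox, n_volumes)
    } else svar <- 1
    eps <- eps * (model$sigma / sqrt(ar_var * svar))
    data <- array(eps, c(shape, n_volumes))
  }
  if (model$drift_amplitude > 0) {
    ramp <- seq(-0.5, 0.5, length.out = n_volumes)
    coefs <- rng$rnorm(n_vox, sd = model$drift_amplitude)
    data <- data + array(outer(coefs, ramp), c(shape, n_volumes))
  }
  data <- data * array(as.numeric(mask), dim = c(shape, n_volumes))
  structure(list(data = data, tr = tr, seed = model$seed, phantom = phantom,
                 ground_truth = list(amplitude = array(0, dim = shape),
                                     signals = list())),
            class = "subject_ts")
}

# interior variance-reduction factor of separable Gaussian smoothing of an
# iid field
spatial_var_factor <- function(shape, fwhm_mm, voxel_mm) {
  sig <- fwhm_to_sigma(fwhm_mm) / voxel_mm
  r <- max(1L, ceiling(4 * sig))
  k <- stats::dnorm(-r:r, sd = sig); k <- k / sum(k)
  sum(k^2)^3
}

#' Task regressor: event boxcar convolved with the haemodynamic response
#'
#' @param design An `event_design`.
#' @param params An [hrf_params()].
#' @param dt Resolution of the internal convolution grid, seconds.
#' @param condition Optional condition label; only that condition's events
#'   enter the boxcar.
#' @return Numeric vector of length `design$n_volumes`, the regressor sampled
#'   at volume acquisition times.
#' @export
event_regressor <- function(design, params = hrf_params(), dt = 0.1,
                            condition = NULL) {
  run <- design$n_volumes * design$tr
  tg <- seq(0, run, by = dt)
  u <- numeric(length(tg))
  sel <- if (is.null(condition)) seq_along(design$onsets)
         else which(design$condition == condition)
  for (k in sel) {
    u[tg >= design$onsets[k] & tg < design$onsets[k] + design$durations[k]] <- 1
  }
  h <- hrf(seq(0, 32, by = dt), params)
  conv <- stats::convolve(u, rev(h), type = "open")[seq_along(tg)] * dt
  vol_t <- (seq_len(design$n_volumes) - 1) * design$tr
  conv[round(vol_t / dt) + 1L]
}

#' Add an event-related BOLD response to a background run
#'
#' The added component at each voxel is `amplitude * weight(voxel) *
#' regressor`, where the regressor is the event boxcar convolved with the
#' haemodynamic response and sampled at the repetition time. The injection is
#' purely additive and recorded in the ground truth.
#'
#' @param ts A `subject_ts`.
#' @param design An `event_design`.
#' @param roi_weights Per-vertex weights (length = vertex count; converted to
#'   voxel weights as the mean over each voxel's vertices) or a 3D array of
#'   per-voxel weights on the phantom grid.
#' @param amplitude Peak amplitude of the injected response, signal units.
#' @param params An [hrf_params()].
#' @param condition Optional condition label passed to [event_regressor()].
#' @return The updated `subject_ts`.
#' @export
inject_hrf_signal <- function(ts, design, roi_weights, amplitude,
                              params = hrf_params(), condition = NULL) {
  phantom <- ts$phantom
  w <- if (is.array(roi_weights) && length(dim(roi_weights)) == 3L) roi_weights
       else map_surface_to_volume(roi_weights, phantom)
  if (amplitude == 0) return(ts)
  reg <- event_regressor(design, params, condition = condition)
  nv <- prod(phantom$grid_shape)
  add <- outer(as.numeric(w) * amplitude, reg)
  ts$data <- ts$data + array(add, dim = dim(ts$data))
  ts$ground_truth$amplitude <- ts$ground_truth$amplitude + amplitude * w
  ts$ground_truth$signals <- c(ts$ground_truth$signals,
                               list(list(regressor = reg, amplitude = amplitude,
                                         weights = w,
                                         condition = condition %||% "task")))
  ts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort of task runs with injected responses
#'
#' Each subject receives an independent resting-state-like background run
#' (and, if configured, a rigid anatomical jitter) into which the same event
#' design injects haemodynamic responses under one or more amplitude-ramped
#' regions of interest.
#'
#' @param phantom A `cortical_phantom` (template).
#' @param design An `event_design` shared by the cohort.
#' @param roi_weights A per-vertex weight vector, or a named list of weight
#'   vectors keyed by condition label for multi-condition designs.
#' @param amplitude Peak amplitude of the injected response.
#' @param model A [noise_model()]; its seed is re-derived per subject.
#' @param n_subjects Cohort size.
#' @param params An [hrf_params()].
#' @param seed Master seed.
#' @return A list of class `task_cohort` with `subjects` (each holding `ts`
#'   and the subject's `phantom`), the template `phantom`, `design`,
#'   `hrf_params` and ground-truth ROI weights.
#' @export
simulate_task_cohort <- function(phantom, design, roi_weights, amplitude = 1,
                                 model = noise_model(), n_subjects = 19L,
                                 params = hrf_params(), seed = 1L) {
  if (!is.list(roi_weights)) roi_weights <- list(task = roi_weights)
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    subj_seed <- (seed * 1000L + s * 13L) %% .Machine$integer.max
    ph_s <- apply_subject_jitter(phantom, subj_seed)
    m <- model; m$seed <- subj_seed
    ts <- simulate_background(ph_s, m, design$n_volumes, design$tr)
    for (cn in names(roi_weights)) {
      cond <- if (length(roi_weights) == 1L && !cn %in% levels(design$condition))
        NULL else cn
      ts <- inject_hrf_signal(ts, design, roi_weights[[cn]], amplitude,
                              params, condition = cond)
    }
    subjects[[s]] <- list(ts = ts, phantom = ph_s, seed = subj_seed)
  }
  structure(list(subjects = subjects, phantom = phantom, design = design,
                 hrf_params = params, roi_weights = roi_weights,
                 amplitude = amplitude, seed = seed),
            class = "task_cohort")
}
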