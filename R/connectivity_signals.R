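standardize <- function(x) {
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) stop("cannot standardize a constant series", call. = FALSE)
  x / s
}

# return a standardized series with exact sample correlation `rho` to the
# standardized target, built from the candidate's component orthogonal to the
# target (Gram-Schmidt pinning)
pin_correlation <- function(target, candidate, rho) {
  z <- standardize(target)
  resid <- candidate - mean(candidate) - z * sum(z * (candidate - mean(candidate))) / sum(z^2)
  if (stats::sd(resid) < 1e-12) return(z * sign(rho))
  rho * z + sqrt(1 - rho^2) * standardize(resid)
}

#' Connectivity signal triplet
#'
#' Generates the three pure signals of the connectivity experiment: a
#' postcentral signal `s1` (a 0.05 Hz carrier plus a 20 percent white-noise
#' portion), a precentral signal `s2c` sharing the carrier, and a precentral
#' signal `s2u` built from an independent-phase carrier. When `rho_cc` /
#' `rho_uu` are supplied, `s2c` and `s2u` are correlation-pinned so their
#' sample correlation with `s1` is exactly the designed value; otherwise the
#' raw mixtures are returned.
#'
#' @param n_volumes Number of time points.
#' @param tr Repetition time, seconds.
#' @param f0 Carrier frequency, Hz; must be below the Nyquist frequency.
#' @param noise_fraction Amplitude fraction of the white-noise component.
#' @param seed Integer seed.
#' @param rho_cc,rho_uu Optional designed correlations of `s2c` / `s2u`
#'   with `s1`.
#' @return A list of class `connectivity_signals` with zero-mean, unit-sd
#'   series `s1`, `s2c`, `s2u` and the achieved pure-signal correlations.
#' @export
make_connectivity_signals <- function(n_volumes = 210L, tr = 2.52, f0 = 0.05,
                                      noise_fraction = 0.20, seed = 1L,
                                      rho_cc = NULL, rho_uu = NULL) {
  if (f0 >= 1 / (2 * tr)) stop("f0 must be below the Nyquist frequency", call. = FALSE)
  stopifnot(noise_fraction >= 0, noise_fraction <= 1)
  rng <- local_rng(seed)
  tt <- (seq_len(n_volumes) - 1) * tr
  mix <- function(carrier, noise) {
    if (noise_fraction == 0) return(standardize(carrier))
    if (noise_fraction == 1) return(standardize(noise))
    standardize((1 - noise_fraction) * standardize(carrier) +
                noise_fraction * standardize(noise))
  }
  phase <- rng$runif(1, 0, 2 * pi)
  carrier <- sin(2 * pi * f0 * tt + phase)
  s1 <- mix(carrier, rng$rnorm(n_volumes))
  x_c <- mix(carrier, rng$rnorm(n_volumes))
  phase_u <- rng$runif(1, 0, 2 * pi)
  carrier_u <- sin(2 * pi * f0 * tt + phase_u)
  x_u <- mix(carrier_u, rng$rnorm(n_volumes))
  s2c <- if (is.null(rho_cc)) x_c else pin_correlation(s1, x_c, rho_cc)
  s2u <- if (is.null(rho_uu)) x_u else pin_correlation(s1, x_u, rho_uu)
  structure(list(s1 = s1, s2c = s2c, s2u = s2u, f0 = f0,
                 noise_fraction = noise_fraction, tr = tr,
                 achieved_r_pure_cc = stats::cor(s1, s2c),
                 achieved_r_pure_cu = stats::cor(s1, s2u)),
            class = "connectivity_signals")
}

#' Scale a pure signal into a background series
#'
#' The signal amplitude starts at a variance-matched value and is multiplied
#' by `growth` until the combined series (background plus scaled signal)
#' correlates at least `target_r` with the pure signal; the returned
#' amplitude is the smallest on that schedule achieving the target.
#'
#' @param background_roi_ts Background time course (e.g. an ROI mean).
#' @param pure_signal Pure signal, same length, non-constant.
#' @param target_r Required correlation of combined and pure signal.
#' @param growth Multiplicative step of the amplitude schedule.
#' @param max_steps Cap on the number of schedule steps.
#' @return List with `combined`, `amplitude`, `achieved_r`.
#' @export
scale_and_insert <- function(background_roi_ts, pure_signal, target_r = 0.95,
                             growth = 1.1, max_steps = 200L) {
  stopifnot(length(background_roi_ts) == length(pure_signal))
  if (stats::sd(pure_signal) == 0) stop("pure signal is constant", call. = FALSE)
  if (stats::sd(background_roi_ts) == 0) {
    return(list(combined = background_roi_ts + pure_signal, amplitude = 1,
                achieved_r = 1))
  }
  a <- stats::sd(background_roi_ts) / stats::sd(pure_signal)
  for (k in seq_len(max_steps)) {
    combined <- background_roi_ts + a * pure_signal
    r <- stats::cor(combined, pure_signal)
    if (r >= target_r) {
      return(list(combined = combined, amplitude = a, achieved_r = r))
    }
    a <- a * growth
  }
  stop("scale_and_insert did not reach the target correlation within the amplitude cap",
       call. = FALSE)
}

# vertex disc of given geodesic radius around a centre vertex
surface_disc <- function(phantom, center_vertex, radius_mm) {
  which(geodesic_from(phantom, center_vertex) <= radius_mm)
}

# voxel footprint of a vertex set: linear voxel indices plus the fraction of
# each voxel's vertices that belong to the set
roi_voxels <- function(phantom, vertex_set) {
  lin <- voxel_linear(phantom$vertex_to_voxel[vertex_set, , drop = FALSE],
                      phantom$grid_shape)
  counts <- table(lin)
  all_counts <- lengths(phantom$voxel_to_vertices)
  lin_u <- as.integer(names(counts))
  frac <- as.numeric(counts) / all_counts[as.character(lin_u)]
  list(linear = lin_u, fraction = unname(frac))
}

# precentral patch centres: same cross-section column as seed_motor, offset
# along the sulcus axis
precentral_patch_centers <- function(phantom, offset_mm) {
  n_s <- phantom$mesh_dims["n_s"]
  i_lip <- 1L + (phantom$seed_motor - 1L) %% n_s
  j_seed <- 1L + (phantom$seed_motor - 1L) %/% n_s
  edge <- phantom$config$mesh_edge_mm
  dj <- round(offset_mm / edge)
  n_y <- phantom$mesh_dims["n_y"]
  j1 <- max(1L, j_seed - dj); j2 <- min(n_y, j_seed + dj)
  c((j1 - 1L) * n_s + i_lip, (j2 - 1L) * n_s + i_lip)
}

#' Default regions of interest of the connectivity experiment
#'
#' One postcentral disc at the sensory seed (carrying `s1`) and two
#' precentral discs on the opposite bank, offset in either direction along
#' the sulcus axis (carrying `s2c` and `s2u`).
#'
#' @param phantom A `cortical_phantom`.
#' @param roi_radius_mm Geodesic radius of each disc.
#' @param patch_offset_mm Along-sulcus offset of the precentral patch centres
#'   from the motor seed.
#' @return List of three ROI descriptors (`post`, `pre_c`, `pre_u`), each
#'   with `vertices`, `voxels` (linear indices) and `fraction`.
#' @export
connectivity_rois <- function(phantom, roi_radius_mm = 3, patch_offset_mm = 4) {
  ctrs <- precentral_patch_centers(phantom, patch_offset_mm)
  mk <- function(center) {
    vs <- surface_disc(phantom, center, roi_radius_mm)
    rv <- roi_voxels(phantom, vs)
    list(center = center, vertices = vs, voxels = rv$linear, fraction = rv$fraction)
  }
  list(post = mk(phantom$seed_sensory), pre_c = mk(ctrs[1]), pre_u = mk(ctrs[2]))
}

# add amplitude * weight * signal to a set of voxels of a 4D array
add_signal_to_voxels <- function(data, voxels, weights, signal) {
  n_vox <- prod(dim(data)[1:3])
  mat <- matrix(data, n_vox, dim(data)[4])
  mat[voxels, ] <- mat[voxels, , drop = FALSE] + outer(weights, signal)
  array(mat, dim(data))
}

roi_mean_series <- function(data, voxels) {
  n_vox <- prod(dim(data)[1:3])
  colMeans(matrix(data, n_vox, dim(data)[4])[voxels, , drop = FALSE])
}

#' Simulate the connectivity cohort
#'
#' For each synthetic subject: generate a resting-state-like background run,
#' scale the postcentral signal `s1` into the postcentral ROI until the
#' combined ROI signal correlates at least `target_r` with it, then build
#' `s2c`/`s2u` pinned to the designed correlations (scaled by the achieved
#' combined~pure correlation, so the design refers to the final combined
#' signal) and scale them into the two precentral patches. Subjects whose
#' final combined~s2c correlation leaves `cc_band` or whose absolute
#' combined~s2u correlation leaves `cu_band` are resampled (new signal
#' noise), with a bounded number of retries.
#'
#' @param phantom A `cortical_phantom`.
#' @param n_subjects Cohort size.
#' @param n_volumes,tr Acquisition length.
#' @param f0,noise_fraction Carrier frequency and noise portion of the pure
#'   signals.
#' @param design_r_cc,design_r_uu Designed correlations of the final combined
#'   postcentral signal with `s2c` and `s2u`.
#' @param cc_band,cu_band Acceptance bands for the per-subject achieved
#'   correlations (the `cu` band applies to the absolute value).
#' @param target_r Insertion target correlation of combined vs pure signal.
#' @param model A [noise_model()]; its seed is re-derived per subject.
#' @param roi_radius_mm,patch_offset_mm ROI geometry, see
#'   [connectivity_rois()].
#' @param seed Master seed.
#' @param max_retries Per-subject cap on resampling attempts.
#' @return A list of class `connectivity_cohort` with per-subject entries
#'   (`ts`, `signals`, `achieved`) plus `rois`, `phantom` and parameters.
#' @export
simulate_connectivity_cohort <- function(phantom, n_subjects = 19L,
                                         n_volumes = 210L, tr = 2.52,
                                         f0 = 0.05, noise_fraction = 0.20,
                                         design_r_cc = 0.82, design_r_uu = 0.04,
                                         cc_band = c(0.80, 0.84),
                                         cu_band = c(0.02, 0.06),
                                         target_r = 0.95,
                                         model = noise_model(),
                                         roi_radius_mm = 3, patch_offset_mm = 4,
                                         seed = 1L, max_retries = 100L) {
  rois <- connectivity_rois(phantom, roi_radius_mm, patch_offset_mm)
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    subj_seed <- (seed * 1000L + s * 7L) %% .Machine$integer.max
    ph_s <- apply_subject_jitter(phantom, subj_seed)
    m <- model; m$seed <- subj_seed
    ts <- simulate_background(ph_s, m, n_volumes, tr)
    bg_post <- roi_mean_series(ts$data, rois$post$voxels)
    for (try in seq_len(max_retries)) {
      sig_seed <- (subj_seed + 131L * try) %% .Machine$integer.max
      sig <- make_connectivity_signals(n_volumes, tr, f0, noise_fraction,
                                       seed = sig_seed)
      ins1 <- scale_and_insert(bg_post, sig$s1, target_r)
      r1 <- ins1$achieved_r
      sig <- make_connectivity_signals(n_volumes, tr, f0, noise_fraction,
                                       seed = sig_seed,
                                       rho_cc = min(design_r_cc / r1, 0.999),
                                       rho_uu = min(design_r_uu / r1, 0.999))
      ins1 <- scale_and_insert(bg_post, sig$s1, target_r)
      r_cc <- stats::cor(ins1$combined, sig$s2c)
      r_cu <- stats::cor(ins1$combined, sig$s2u)
      ok <- r_cc >= cc_band[1] && r_cc <= cc_band[2] &&
        abs(r_cu) >= cu_band[1] && abs(r_cu) <= cu_band[2]
      if (ok || try == max_retries) {
        if (!ok) stop("connectivity cohort: subject calibration did not reach the ",
                      "designed correlation bands", call. = FALSE)
        ins_c <- scale_and_insert(roi_mean_series(ts$data, rois$pre_c$voxels),
                                  sig$s2c, target_r)
        ins_u <- scale_and_insert(roi_mean_series(ts$data, rois$pre_u$voxels),
                                  sig$s2u, target_r)
        data <- ts$data
        add_w <- function(roi, amp) amp * roi$fraction / mean(roi$fraction)
        data <- add_signal_to_voxels(data, rois$post$voxels,
                                     add_w(rois$post, ins1$amplitude), sig$s1)
        data <- add_signal_to_voxels(data, rois$pre_c$voxels,
                                     add_w(rois$pre_c, ins_c$amplitude), sig$s2c)
        data <- add_signal_to_voxels(data, rois$pre_u$voxels,
                                     add_w(rois$pre_u, ins_u$amplitude), sig$s2u)
        ts$data <- data
        subjects[[s]] <- list(
          ts = ts, phantom = ph_s, signals = sig,
          achieved = c(r_pure = r1, r_cc = r_cc, r_cu = r_cu,
                       r_pre_c = ins_c$achieved_r, r_pre_u = ins_u$achieved_r),
          amplitudes = c(post = ins1$amplitude, pre_c = ins_c$amplitude,
                         pre_u = ins_u$amplitude),
          seed = subj_seed, retries = try)
        break
      }
    }
  }
  structure(list(subjects = subjects, rois = rois, phantom = phantom,
                 params = list(n_subjects = n_subjects, n_volumes = n_volumes,
                               tr = tr, f0 = f0, noise_fraction = noise_fraction,
                               design_r_cc = design_r_cc, design_r_uu = design_r_uu,
                               cc_band = cc_band, cu_band = cu_band,
                               target_r = target_r, roi_radius_mm = roi_radius_mm,
                               patch_offset_mm = patch_offset_mm),
                 seed = seed),
            class = "connectivity_cohort")
}

#' Per-subject achieved correlations of a connectivity cohort
#'
#' @param cohort A `connectivity_cohort`.
#' @return Data frame with one row per subject: `r_pure` (combined vs pure
#'   s1), `r_cc`, `r_cu` (combined vs pure s2c / s2u).
#' @export
cohort_achieved <- function(cohort) {
  out <- do.call(rbind, lapply(cohort$subjects, function(s) s$achieved))
  as.data.frame(out)
}
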