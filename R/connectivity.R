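#' Band-pass specification for connectivity preprocessing
#'
#' @param low_hz,high_hz Pass band edges in Hz.
#' @param tr Repetition time, seconds.
#' @return A list of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_hz = 0.01, high_hz = 0.1, tr = 2.52) {
  if (!(0 < low_hz && low_hz < high_hz && high_hz < 1 / (2 * tr)))
    stop("band infeasible: need 0 < low < high < Nyquist", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz, tr = tr),
            class = "bandpass_spec")
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain masking with raised-cosine transition edges (two
#' frequency bins wide). The DC component is removed, the pass band has unit
#' gain, and the filter introduces no phase shift.
#'
#' @param ts Numeric vector, or matrix with time in rows (each column
#'   filtered independently).
#' @param spec A [bandpass_spec()].
#' @return Filtered series, same shape.
#' @export
bandpass <- function(ts, spec) {
  x <- if (is.matrix(ts)) ts else matrix(ts, ncol = 1L)
  n <- nrow(x)
  if (n < 16L) stop("need at least 16 time points to band-pass", call. = FALSE)
  freq <- c(0, seq_len(n - 1)) / (n * spec$tr)
  freq <- pmin(freq, 1 / spec$tr - freq)   # two-sided spectrum
  tw <- 2 / (n * spec$tr)                  # transition width: two bins
  ramp_up <- function(f, edge) {
    w <- numeric(length(f))
    w[f >= edge + tw / 2] <- 1
    sel <- f > edge - tw / 2 & f < edge + tw / 2
    w[sel] <- 0.5 * (1 + sin(pi * (f[sel] - edge) / tw))
    w
  }
  gain <- ramp_up(freq, spec$low_hz) * (1 - ramp_up(freq, spec$high_hz))
  gain[freq == 0] <- 0
  out <- Re(stats::mvfft(stats::mvfft(x) * gain, inverse = TRUE)) / n
  if (is.matrix(ts)) out else as.numeric(out)
}

#' Regress a nuisance time course out of data
#'
#' Ordinary least squares on an intercept plus the nuisance series; returns
#' the residuals, which are orthogonal to both.
#'
#' @param ts Numeric vector or matrix with time in rows.
#' @param nuisance Nuisance time course (e.g. the mean CSF signal).
#' @return Residual series, same shape as `ts`.
#' @export
regress_out <- function(ts, nuisance) {
  x <- if (is.matrix(ts)) ts else matrix(ts, ncol = 1L)
  stopifnot(nrow(x) == length(nuisance))
  if (stats::sd(nuisance) == 0) {
    warning("constant nuisance regressor; removing the mean only")
    X <- matrix(1, nrow(x), 1L)
  } else {
    X <- cbind(1, nuisance)
  }
  res <- x - X %*% solve(crossprod(X), crossprod(X, x))
  if (is.matrix(ts)) res else as.numeric(res)
}

#' Mean time course of a region of interest
#'
#' @param ts 4D array (with `roi` as linear voxel indices), or a matrix
#'   elements x time (with `roi` as row indices).
#' @param roi Indices of the ROI elements; must be nonempty.
#' @return Numeric vector, the unweighted mean over ROI elements per time
#'   point.
#' @export
extract_roi <- function(ts, roi) {
  if (length(roi) == 0) stop("empty ROI", call. = FALSE)
  if (is.array(ts) && length(dim(ts)) == 4L) {
    roi_mean_series(ts, roi)
  } else {
    colMeans(ts[roi, , drop = FALSE])
  }
}

clip_r <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)

new_connectivity_result <- function(r_cc, r_cu, pipeline, params, steps) {
  structure(list(r_cc = r_cc, r_cu = r_cu,
                 z_cc = atanh(clip_r(r_cc)), z_cu = atanh(clip_r(r_cu)),
                 pipeline = pipeline,
                 design_r_cc = params$design_r_cc,
                 design_r_uu = params$design_r_uu,
                 steps = steps),
            class = "connectivity_result")
}

#' Volume-based connectivity pipeline
#'
#' Per subject, in this order: (1) normalisation to template space, (2)
#' volumetric smoothing, (3) band-pass filtering, (4) removal of the mean
#' CSF signal by linear regression, (5) extraction of the ROI mean time
#' courses in normalised space. Pearson correlations are computed between
#' the postcentral ROI and each precentral patch, then Fisher-transformed
#' (z = atanh(r)).
#'
#' @param cohort A `connectivity_cohort`.
#' @param fwhm_mm Volumetric smoothing kernel FWHM in mm.
#' @param band A [bandpass_spec()]; defaults to 0.01-0.1 Hz at the cohort TR.
#' @return A `connectivity_result` with per-subject `r_cc`, `r_cu`, `z_cc`,
#'   `z_cu` and the recorded step order.
#' @export
run_vba_connectivity <- function(cohort, fwhm_mm = 9, band = NULL) {
  band <- band %||% bandpass_spec(tr = cohort$params$tr)
  phantom <- cohort$phantom
  rois <- cohort$rois
  csf <- voxels_of_tissue(phantom, "csf")
  steps <- c("normalize", "smooth_volume", "bandpass", "regress_csf",
             "extract_rois")
  res <- vapply(cohort$subjects, function(subj) {
    vol <- normalize_volume(subj$ts$data, subj$phantom)
    vol <- smooth_volume(vol, fwhm_mm, phantom$voxel_mm)
    dm <- dim(vol)
    mat <- t(matrix(vol, prod(dm[1:3]), dm[4]))     # time x voxels
    mat <- bandpass(mat, band)
    mat <- regress_out(mat, rowMeans(mat[, csf, drop = FALSE]))
    post <- rowMeans(mat[, rois$post$voxels, drop = FALSE])
    pre_c <- rowMeans(mat[, rois$pre_c$voxels, drop = FALSE])
    pre_u <- rowMeans(mat[, rois$pre_u$voxels, drop = FALSE])
    c(stats::cor(post, pre_c), stats::cor(post, pre_u))
  }, numeric(2))
  new_connectivity_result(res[1, ], res[2, ], "vba", cohort$params, steps)
}

#' Surface-based connectivity pipeline
#'
#' Per subject, in this order: (1) band-pass filtering in native volume
#' space, (2) removal of the mean CSF signal by linear regression, (3)
#' mapping of the volumes to the subject surface with the Gaussian
#' weighted-mean sampler followed by surface smoothing on the normalised
#' (template) mesh, (4) ROI extraction in surface space. Correlation and
#' Fisher transform as in the volume pipeline.
#'
#' @inheritParams run_vba_connectivity
#' @param fwhm_mm Surface smoothing kernel FWHM in mm.
#' @return A `connectivity_result`.
#' @export
run_sba_connectivity <- function(cohort, fwhm_mm = 9, band = NULL) {
  band <- band %||% bandpass_spec(tr = cohort$params$tr)
  phantom <- cohort$phantom
  rois <- cohort$rois
  steps <- c("bandpass", "regress_csf", "map_to_surface", "smooth_surface",
             "extract_rois")
  res <- vapply(cohort$subjects, function(subj) {
    csf <- voxels_of_tissue(subj$phantom, "csf")
    dm <- dim(subj$ts$data)
    mat <- t(matrix(subj$ts$data, prod(dm[1:3]), dm[4]))  # time x voxels
    mat <- bandpass(mat, band)
    mat <- regress_out(mat, rowMeans(mat[, csf, drop = FALSE]))
    vol <- array(t(mat), dm)
    surf <- map_volume_to_surface(vol, subj$phantom, method = "weighted_mean")
    surf <- smooth_surface(surf, phantom, fwhm_mm)
    post <- colMeans(surf[rois$post$vertices, , drop = FALSE])
    pre_c <- colMeans(surf[rois$pre_c$vertices, , drop = FALSE])
    pre_u <- colMeans(surf[rois$pre_u$vertices, , drop = FALSE])
    c(stats::cor(post, pre_c), stats::cor(post, pre_u))
  }, numeric(2))
  new_connectivity_result(res[1, ], res[2, ], "sba", cohort$params, steps)
}

#' Compare two pipelines' deviation from the designed correlation
#'
#' Per pipeline, the per-subject deviation on the Fisher scale is
#' d_i = z_i - atanh(design_r); the two sets of deviations are compared
#' with a pooled-variance two-sample t test.
#'
#' @param res_a,res_b `connectivity_result`s for the same cohort.
#' @param pair `"cu"` (designed-uncorrelated pair) or `"cc"`.
#' @param design_r Designed correlation; defaults to the value recorded in
#'   the results.
#' @return List with `t`, `dof`, `p`, and the mean deviations `mean_dev_a`,
#'   `mean_dev_b`.
#' @export
group_compare <- function(res_a, res_b, pair = c("cu", "cc"), design_r = NULL) {
  pair <- match.arg(pair)
  za <- if (pair == "cu") res_a$z_cu else res_a$z_cc
  zb <- if (pair == "cu") res_b$z_cu else res_b$z_cc
  if (length(za) != length(zb)) stop("results come from different cohort sizes",
                                     call. = FALSE)
  if (length(za) < 2) stop("need at least two subjects", call. = FALSE)
  design_r <- design_r %||%
    (if (pair == "cu") res_a$design_r_uu else res_a$design_r_cc)
  da <- za - atanh(design_r)
  db <- zb - atanh(design_r)
  n <- length(da)
  sp2 <- (sum((da - mean(da))^2) + sum((db - mean(db))^2)) / (2 * n - 2)
  tval <- if (sp2 == 0) 0 else (mean(da) - mean(db)) / sqrt(sp2 * 2 / n)
  dof <- 2L * n - 2L
  p <- if (sp2 == 0 && mean(da) == mean(db)) 1 else
    2 * stats::pt(-abs(tval), dof)
  list(t = tval, dof = dof, p = p,
       mean_dev_a = mean(da), mean_dev_b = mean(db), design_r = design_r)
}
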