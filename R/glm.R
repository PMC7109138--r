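#' Design matrix for the mass-univariate general linear model
#'
#' One task regressor per condition (event boxcar convolved with the
#' haemodynamic response, sampled at volume times), an intercept, and an
#' optional mean-centred linear drift column.
#'
#' @param design An `event_design`.
#' @param params An [hrf_params()].
#' @param drift Include a linear drift column?
#' @return A list of class `design_matrix` with the matrix `X` and `names`.
#' @export
build_design_matrix <- function(design, params = hrf_params(), drift = FALSE) {
  n <- design$n_volumes
  conds <- levels(droplevels(design$condition))
  cols <- list()
  if (length(design$onsets)) {
    for (cn in conds) cols[[cn]] <- event_regressor(design, params, condition = cn)
  }
  cols[["intercept"]] <- rep(1, n)
  if (drift) {
    d <- seq_len(n) - (n + 1) / 2
    cols[["drift"]] <- d / max(abs(d))
  }
  X <- do.call(cbind, cols)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  structure(list(X = X, names = colnames(X)), class = "design_matrix")
}

#' Ordinary-least-squares fit of a general linear model per element
#'
#' @param Y Data matrix, elements x time points.
#' @param X A `design_matrix` or a plain numeric matrix (time x regressors).
#' @param contrast Contrast weight vector (length = number of regressors).
#' @return List with `effect` (contrast of estimates), `t`, `dof`, and
#'   `flagged` (elements with zero residual variance, whose t is a signed
#'   infinity sentinel).
#' @export
fit_glm <- function(Y, X, contrast) {
  if (inherits(X, "design_matrix")) X <- X$X
  stopifnot(ncol(Y) == nrow(X), length(contrast) == ncol(X))
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, t(Y))        # regressors x elements
  fitted <- X %*% B
  res <- t(Y) - fitted
  dof <- nrow(X) - qr(X)$rank
  sigma2 <- colSums(res^2) / dof
  eff <- as.numeric(crossprod(contrast, B))
  cvar <- as.numeric(crossprod(contrast, XtXi %*% contrast))
  se <- sqrt(sigma2 * cvar)
  flagged <- sigma2 <= 1e-24
  tval <- ifelse(flagged, sign(eff) * Inf, eff / se)
  tval[flagged & eff == 0] <- 0
  list(effect = eff, t = tval, dof = dof, flagged = flagged)
}

#' One-sample group statistic across subjects
#'
#' Elementwise one-sample t test of per-subject effect maps against zero.
#'
#' @param effects Matrix, elements x subjects.
#' @return List with `t`, `mean`, `dof` (subjects - 1) and `flagged`
#'   (zero across-subject variance).
#' @export
group_onesample <- function(effects) {
  n <- ncol(effects)
  stopifnot(n >= 2)
  m <- rowMeans(effects)
  sd <- sqrt(rowSums((effects - m)^2) / (n - 1))
  flagged <- sd <= 1e-24
  tval <- ifelse(flagged, sign(m) * Inf, m / (sd / sqrt(n)))
  tval[flagged & m == 0] <- 0
  list(t = tval, mean = m, dof = n - 1L, flagged = flagged)
}

#' TFCE parameters
#'
#' @param E Extent exponent.
#' @param H Height exponent.
#' @param dh Threshold step; `NULL` means max|value|/`n_steps` per map.
#' @param n_steps Number of threshold steps used when `dh` is `NULL`.
#' @return A list of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2.0, dh = NULL, n_steps = 100L) {
  stopifnot(E > 0, H > 0, is.null(dh) || dh > 0, n_steps >= 1)
  structure(list(E = E, H = H, dh = dh, n_steps = as.integer(n_steps)),
            class = "tfce_params")
}

# CSR (0-based) adjacency from an undirected edge list on n elements
adjacency_csr <- function(edges, n) {
  if (is.null(dim(edges)) || nrow(edges) == 0)
    return(list(ptr = integer(n + 1L), idx = integer(0), n = n))
  i <- c(edges[, 1], edges[, 2])
  j <- c(edges[, 2], edges[, 1])
  o <- order(i, j)
  i <- i[o]; j <- j[o]
  ptr <- c(0L, cumsum(tabulate(i, nbins = n)))
  list(ptr = as.integer(ptr), idx = as.integer(j - 1L), n = n)
}

#' Adjacency of masked voxels on the grid
#'
#' @param mask_linear 1-based linear indices of the voxels in the analysis
#'   mask, in the order the statistical maps use.
#' @param shape Grid dimensions.
#' @param connectivity 6, 18 or 26.
#' @return CSR adjacency usable by [tfce()].
#' @export
volume_adjacency <- function(mask_linear, shape, connectivity = 26L) {
  n <- length(mask_linear)
  rank <- integer(prod(shape))
  rank[mask_linear] <- seq_len(n)
  idx0 <- arrayInd(mask_linear, shape) - 1L
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(off))
  off <- off[ord > 0 & ord <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  pairs <- list()
  for (k in seq_len(nrow(off))) {
    nb <- sweep(idx0, 2, as.integer(off[k, ]), "+")
    ok <- nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0 &
      nb[, 1] < shape[1] & nb[, 2] < shape[2] & nb[, 3] < shape[3]
    lin <- voxel_linear(nb[ok, , drop = FALSE], shape)
    r <- rank[lin]
    hit <- r > 0
    pairs[[k]] <- cbind(which(ok)[hit], r[hit])
  }
  e <- do.call(rbind, pairs)
  e <- e[e[, 1] < e[, 2], , drop = FALSE]
  adjacency_csr(unique(e), n)
}

#' Adjacency of mesh vertices
#'
#' @param phantom A `cortical_phantom` (or any list with `edges` and
#'   `vertices`).
#' @return CSR adjacency usable by [tfce()].
#' @export
surface_adjacency <- function(phantom) {
  adjacency_csr(phantom$edges, nrow(phantom$vertices))
}

#' Threshold-free cluster enhancement
#'
#' For each element v, integrates extent^E * height^H over all thresholds
#' 0 < h <= value(v), where the extent is the size of v's connected
#' suprathreshold component at height h. Negative values are enhanced by
#' applying the same sweep to the negated map; the result carries their sign.
#'
#' @param values Statistic per element.
#' @param adjacency CSR adjacency from [volume_adjacency()] or
#'   [surface_adjacency()].
#' @param params A [tfce_params()].
#' @return Enhanced map, same length as `values`.
#' @export
tfce <- function(values, adjacency, params = tfce_params()) {
  stopifnot(length(values) == adjacency$n)
  vmax <- max(abs(values))
  if (vmax == 0) return(numeric(length(values)))
  dh <- params$dh %||% (vmax / params$n_steps)
  tfce_signed_cpp(as.numeric(values), adjacency$ptr, adjacency$idx,
                  params$E, params$H, dh)
}

#' Sign-flip permutation inference with TFCE and familywise-error control
#'
#' One-sample inference on per-subject effect maps: the observed group t map
#' is TFCE-enhanced, and a null distribution of the maximum absolute TFCE
#' statistic is built by randomly flipping the sign of whole subjects
#' (exchangeable under a symmetric null). Corrected p-values are
#' `(1 + #(null >= observed)) / (n_perm + 1)`. Elements with zero
#' across-subject variance are excluded from the null maximum and reported
#' with p = 1.
#'
#' @param effects Matrix, elements x subjects.
#' @param adjacency CSR adjacency of the elements.
#' @param params A [tfce_params()].
#' @param n_perm Number of sign-flip permutations (>= 100). When `2^subjects`
#'   does not exceed `n_perm`, all distinct flips are enumerated instead
#'   (with a warning).
#' @param alpha Familywise error level.
#' @param seed Integer seed for the random flips.
#' @return List of class `inference_result` with `corrected_p`, `mask`
#'   (suprathreshold at `alpha`), `t`, `tfce`, `alpha`, `n_perm`.
#' @export
permutation_fwe <- function(effects, adjacency, params = tfce_params(),
                            n_perm = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot(n_perm >= 100L)
  n_sub <- ncol(effects)
  n_el <- nrow(effects)
  grp <- group_onesample(effects)
  ok <- !grp$flagged & is.finite(grp$t)
  t_obs <- ifelse(ok, grp$t, 0)
  vmax <- max(abs(t_obs))
  obs_tfce <- if (vmax > 0)
    tfce(t_obs, adjacency, params) else numeric(n_el)

  enumerate <- 2^n_sub <= n_perm
  if (enumerate) {
    warning("requested permutations exceed the 2^n distinct sign flips; enumerating all")
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_sub)))
    S <- t(S)
    n_perm <- ncol(S)
  } else {
    rng <- local_rng(seed)
    S <- matrix(sign(rng$runif(n_sub * n_perm) - 0.5), n_sub, n_perm)
    S[S == 0] <- 1
  }
  E_ok <- effects[ok, , drop = FALSE]
  m <- (E_ok %*% S) / n_sub
  ss <- rowSums(E_ok^2)
  varp <- (ss - n_sub * m^2) / (n_sub - 1)
  varp[varp < 1e-24] <- Inf
  t_perm <- m / sqrt(varp / n_sub)
  t_full <- matrix(0, n_el, n_perm)
  t_full[ok, ] <- t_perm
  null_max <- tfce_max_batch_cpp(t_full, adjacency$ptr, adjacency$idx,
                                 params$E, params$H, params$n_steps)
  obs_abs <- abs(obs_tfce)
  corrected_p <- vapply(obs_abs, function(o)
    (1 + sum(null_max >= o)) / (n_perm + 1), numeric(1))
  corrected_p[!ok] <- 1
  structure(list(corrected_p = corrected_p, mask = corrected_p <= alpha,
                 t = grp$t, tfce = obs_tfce, alpha = alpha,
                 n_perm = n_perm, flagged = !ok),
            class = "inference_result")
}

# elements x time matrix of the masked voxels of a 4D array
masked_matrix <- function(data, mask_linear) {
  dm <- dim(data)
  matrix(data, prod(dm[1:3]), dm[4])[mask_linear, , drop = FALSE]
}

embed_in_grid <- function(values, mask_linear, shape) {
  out <- array(0, dim = shape)
  out[mask_linear] <- values
  out
}

#' Run one analysis approach end to end on a task cohort
#'
#' The three pipelines differ only in where normalisation, smoothing and the
#' general linear model happen:
#' \describe{
#' \item{vba_smooth_first}{normalise the time series to template space,
#'   smooth in the volume, fit the GLM, group inference on voxels.}
#' \item{vba_glm_first}{fit the GLM in native space, normalise and smooth the
#'   effect maps in the volume, group inference on voxels.}
#' \item{sba}{fit the GLM in native space, map the effect maps to the
#'   subject surface (absolute-maximum sampling), smooth along the surface,
#'   group inference on vertices.}
#' }
#' All end in TFCE sign-flip permutation inference.
#'
#' @param cohort A `task_cohort` from [simulate_task_cohort()].
#' @param approach One of `"vba_smooth_first"`, `"vba_glm_first"`, `"sba"`.
#' @param fwhm_mm Smoothing kernel FWHM in mm.
#' @param condition Which condition's contrast to take to the group stage.
#' @param drift Include a drift regressor in the first-level model.
#' @param params,n_perm,alpha,seed Inference settings, see
#'   [permutation_fwe()].
#' @return An `inference_result` with extra fields `space` (`"volume"` or
#'   `"surface"`), `elements` (linear voxel indices or vertex indices) and
#'   `approach`.
#' @export
run_approach <- function(cohort, approach = c("vba_smooth_first",
                                              "vba_glm_first", "sba"),
                         fwhm_mm, condition = NULL, drift = FALSE,
                         params = tfce_params(), n_perm = 1000L,
                         alpha = 0.05, seed = 1L) {
  approach <- match.arg(approach)
  phantom <- cohort$phantom
  X <- build_design_matrix(cohort$design, cohort$hrf_params, drift = drift)
  conds <- setdiff(colnames(X$X), c("intercept", "drift"))
  condition <- condition %||% conds[1]
  contrast <- as.numeric(colnames(X$X) == condition)
  mask <- which(phantom$voxel_tissue != "background")
  shape <- phantom$grid_shape

  effect_of <- function(subj) {
    ts <- subj$ts
    if (approach == "vba_smooth_first") {
      vol <- normalize_volume(ts$data, subj$phantom)
      vol <- smooth_volume(vol, fwhm_mm, phantom$voxel_mm)
      fit_glm(masked_matrix(vol, mask), X, contrast)$effect
    } else if (approach == "vba_glm_first") {
      fit <- fit_glm(masked_matrix(ts$data, mask), X, contrast)
      eff3 <- embed_in_grid(fit$effect, mask, shape)
      eff3 <- normalize_volume(eff3, subj$phantom)
      eff3 <- smooth_volume(eff3, fwhm_mm, phantom$voxel_mm)
      eff3[mask]
    } else {
      fit <- fit_glm(masked_matrix(ts$data, mask), X, contrast)
      eff3 <- embed_in_grid(fit$effect, mask, shape)
      surf <- map_volume_to_surface(eff3, subj$phantom, method = "abs_max")
      smooth_surface(surf, phantom, fwhm_mm)
    }
  }
  effects <- vapply(cohort$subjects, effect_of,
                    numeric(if (approach == "sba") nrow(phantom$vertices)
                            else length(mask)))
  adj <- if (approach == "sba") surface_adjacency(phantom)
         else volume_adjacency(mask, shape)
  res <- permutation_fwe(effects, adj, params, n_perm, alpha, seed)
  res$space <- if (approach == "sba") "surface" else "volume"
  res$elements <- if (approach == "sba") seq_len(nrow(phantom$vertices)) else mask
  res$approach <- approach
  res$fwhm_mm <- fwhm_mm
  res$condition <- condition
  res
}
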