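#' Smoothing specification
#'
#' Couples a smoothing domain with a kernel size. The Gaussian width follows
#' the standard convention fwhm = 2 * sqrt(2 * ln 2) * sigma.
#'
#' @param domain `"volume"` or `"surface"`.
#' @param fwhm_mm Full width at half maximum in mm (>= 0; 0 means identity).
#' @return A list of class `smoothing_spec` with `domain`, `fwhm_mm`, `sigma_mm`.
#' @export
smoothing_spec <- function(domain = c("volume", "surface"), fwhm_mm) {
  domain <- match.arg(domain)
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop("fwhm_mm must be >= 0", call. = FALSE)
  structure(list(domain = domain, fwhm_mm = fwhm_mm,
                 sigma_mm = fwhm_mm / (2 * sqrt(2 * log(2)))),
            class = "smoothing_spec")
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# dense 1D Gaussian smoothing operator with whole-sample reflective
# boundaries; rows sum to 1 so constants are preserved
gaussian_line_operator <- function(n, sigma_vox) {
  S <- matrix(0, n, n)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    j <- ifelse(j < 1L, 2L - j, j)
    j <- ifelse(j > n, 2L * n - j, j)
    j <- pmin(pmax(j, 1L), n)
    for (m in seq_along(j)) S[i, j[m]] <- S[i, j[m]] + k[m]
  }
  S
}

#' Volumetric Gaussian smoothing
#'
#' Separable Gaussian convolution of a 3D scalar field or a 4D time series
#' (time frames smoothed independently) with reflective boundary handling.
#'
#' @param field 3D array or 4D array (x, y, z, time).
#' @param fwhm_mm Kernel full width at half maximum in mm.
#' @param voxel_mm Isotropic voxel size in mm.
#' @return Smoothed array of the same shape.
#' @export
smooth_volume <- function(field, fwhm_mm, voxel_mm) {
  if (inherits(fwhm_mm, "smoothing_spec")) {
    stopifnot(fwhm_mm$domain == "volume")
    fwhm_mm <- fwhm_mm$fwhm_mm
  }
  if (fwhm_mm == 0) return(field)
  dm <- dim(field)
  if (length(dm) == 4L) {
    out <- field
    ops <- lapply(dm[1:3], gaussian_line_operator,
                  sigma_vox = fwhm_to_sigma(fwhm_mm) / voxel_mm)
    for (t in seq_len(dm[4])) {
      out[, , , t] <- smooth_volume_3d(field[, , , t, drop = FALSE][, , , 1], ops)
    }
    return(out)
  }
  if (length(dm) != 3L) stop("field must be a 3D or 4D array", call. = FALSE)
  ops <- lapply(dm, gaussian_line_operator,
                sigma_vox = fwhm_to_sigma(fwhm_mm) / voxel_mm)
  smooth_volume_3d(field, ops)
}

smooth_volume_3d <- function(vol, ops) {
  dm <- dim(vol)
  # axis 1
  x <- ops[[1]] %*% matrix(vol, dm[1])
  # axis 2
  x <- array(x, dm)
  x <- aperm(x, c(2, 1, 3))
  x <- ops[[2]] %*% matrix(x, dm[2])
  x <- aperm(array(x, dm[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  x <- aperm(x, c(3, 1, 2))
  x <- ops[[3]] %*% matrix(x, dm[3])
  aperm(array(x, dm[c(3, 1, 2)]), c(2, 3, 1))
}

# one-ring adjacency of a triangulated mesh: sparse row-stochastic averaging
# operator plus the mean per-step, per-axis kernel variance at full mixing
surface_neighbourhood <- function(mesh) {
  vertices <- mesh$vertices
  if (is.null(mesh$edges)) {
    tri <- mesh$triangles
    ec <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
    ec <- cbind(pmin(ec[, 1], ec[, 2]), pmax(ec[, 1], ec[, 2]))
    key <- paste(ec[, 1], ec[, 2])
    if (any(table(key) > 2))
      stop("non-manifold mesh: an edge borders more than two triangles", call. = FALSE)
    edges <- unique(ec)
  } else edges <- mesh$edges
  n <- nrow(vertices)
  i <- c(edges[, 1], edges[, 2])
  j <- c(edges[, 2], edges[, 1])
  d2 <- rowSums((vertices[edges[, 1], , drop = FALSE] -
                 vertices[edges[, 2], , drop = FALSE])^2)
  d2 <- c(d2, d2)
  deg <- tabulate(i, nbins = n)
  if (any(deg == 0)) stop("mesh has isolated vertices", call. = FALSE)
  W <- Matrix::sparseMatrix(i = i, j = j, x = 1 / deg[i], dims = c(n, n))
  # per-axis variance of one full-mixing step, averaged over vertices
  step_var1 <- mean(tapply(d2, i, mean)) / 2
  list(W = W, step_var1 = step_var1, n = n)
}

#' Geodesic smoothing on a triangulated mesh
#'
#' Iterated one-ring Laplacian averaging whose accumulated kernel variance is
#' calibrated so the equivalent geodesic kernel has the requested full width
#' at half maximum. Each step replaces a vertex value by a convex combination
#' of itself and the mean of its neighbours; the per-step mixing weight and
#' the number of steps are chosen so the per-axis step variances sum exactly
#' to sigma^2. Constant maps are fixed points and values never leave the
#' input range; smoothing cannot cross disconnected mesh components.
#'
#' @param map Numeric vector (one value per vertex) or matrix
#'   (vertices x time) of per-vertex values.
#' @param mesh A `cortical_phantom` or any list with `vertices` and
#'   `triangles` (or precomputed `edges`).
#' @param fwhm_mm Geodesic kernel full width at half maximum in mm.
#' @param lambda_max Stability cap on the per-step mixing weight.
#' @return Smoothed map with the same shape as `map`.
#' @export
smooth_surface <- function(map, mesh, fwhm_mm, lambda_max = 0.5) {
  if (inherits(fwhm_mm, "smoothing_spec")) {
    stopifnot(fwhm_mm$domain == "surface")
    fwhm_mm <- fwhm_mm$fwhm_mm
  }
  if (fwhm_mm == 0) return(map)
  nb <- surface_neighbourhood(mesh)
  sigma2 <- fwhm_to_sigma(fwhm_mm)^2
  n_steps <- max(1L, ceiling(sigma2 / (lambda_max * nb$step_var1)))
  lambda <- sigma2 / (n_steps * nb$step_var1)
  S <- (1 - lambda) * Matrix::Diagonal(nb$n) + lambda * nb$W
  x <- if (is.matrix(map)) map else matrix(map, ncol = 1L)
  if (nrow(x) != nb$n) stop("map length does not match vertex count", call. = FALSE)
  for (k in seq_len(n_steps)) x <- as.matrix(S %*% x)
  if (is.matrix(map)) x else as.numeric(x)
}

# sparse trilinear interpolation operator: rows = sample points, cols =
# linear voxel indices; points outside the centre lattice are clamped
interp_matrix <- function(pts, grid, warn_clamp = TRUE) {
  shape <- grid$shape
  ci <- sweep(sweep(pts, 2, grid$origin), 2, grid$voxel_mm, "/") - 0.5
  clamped <- ci < 0 | sweep(ci, 2, shape - 1) > 0
  if (warn_clamp && any(clamped))
    warning("sampling points outside the grid were clamped to the boundary")
  ci <- pmax(ci, 0)
  ci <- sweep(ci, 2, shape - 1, pmin)
  i0 <- pmin(floor(ci), matrix(shape - 2L, nrow(ci), 3, byrow = TRUE))
  i0 <- pmax(i0, 0)
  f <- ci - i0
  n <- nrow(pts)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    idx <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
    keep <- w > 0
    rows <- c(rows, which(keep))
    cols <- c(cols, voxel_linear(idx[keep, , drop = FALSE], shape))
    vals <- c(vals, w[keep])
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(n, prod(shape)))
}

phantom_grid <- function(phantom) {
  list(origin = phantom$origin, shape = phantom$grid_shape,
       affine = phantom$affine, voxel_mm = phantom$voxel_mm)
}

# sampling offsets along the vertex normal, inward end first
normal_offsets <- function(depth_mm, n_samples) {
  seq(-depth_mm, depth_mm, length.out = n_samples)
}

#' Map a volumetric field onto the phantom surface
#'
#' Samples the volume with trilinear interpolation at points along each
#' vertex normal and reduces them per vertex, either with the sign-preserving
#' absolute maximum (the sample of largest magnitude; ties go to the inmost
#' sample) or with a Gaussian weighted mean whose weight is 1 at the segment
#' centre and 0.5 at the segment ends.
#'
#' @param field 3D array on the phantom grid, or 4D array (frames mapped
#'   independently).
#' @param phantom A `cortical_phantom`.
#' @param method `"abs_max"` or `"weighted_mean"`.
#' @param sampling_depth_mm Half-length of the sampling segment along the
#'   normal, in mm.
#' @param n_samples Number of equidistant samples along the segment.
#' @return Numeric vector (3D input) or matrix vertices x frames (4D input).
#' @export
map_volume_to_surface <- function(field, phantom,
                                  method = c("abs_max", "weighted_mean"),
                                  sampling_depth_mm = 1.5, n_samples = 5L) {
  method <- match.arg(method)
  grid <- phantom_grid(phantom)
  off <- normal_offsets(sampling_depth_mm, n_samples)
  nv <- nrow(phantom$vertices)
  pts <- do.call(rbind, lapply(off, function(o) phantom$vertices + o * phantom$normals))
  A <- interp_matrix(pts, grid)   # (n_samples*nv) x n_vox, vertex-major per offset
  dm <- dim(field)
  is4d <- length(dm) == 4L
  vol_mat <- if (is4d) matrix(field, prod(dm[1:3]), dm[4]) else matrix(as.numeric(field), ncol = 1L)

  if (method == "weighted_mean") {
    g <- exp(-off^2 / (2 * sampling_depth_mm^2 / (2 * log(2))))
    G <- Matrix::sparseMatrix(
      i = rep(seq_len(nv), n_samples),
      j = seq_len(nv * n_samples),
      x = rep(g / sum(g), each = nv),
      dims = c(nv, nv * n_samples))
    M <- G %*% A
    out <- as.matrix(M %*% vol_mat)
  } else {
    out <- matrix(0, nv, ncol(vol_mat))
    for (tt in seq_len(ncol(vol_mat))) {
      smp <- matrix(as.numeric(A %*% vol_mat[, tt]), nv, n_samples)
      pick <- max.col(abs(smp), ties.method = "first")
      out[, tt] <- smp[cbind(seq_len(nv), pick)]
    }
  }
  if (is4d) out else as.numeric(out)
}

#' Map a surface field into the volume
#'
#' Each cortex voxel receives the mean value of the vertices it contains;
#' all other voxels are zero.
#'
#' @param map Numeric vector, one value per vertex.
#' @param phantom A `cortical_phantom`.
#' @return 3D array on the phantom grid.
#' @export
map_surface_to_volume <- function(map, phantom) {
  stopifnot(length(map) == nrow(phantom$vertices))
  out <- array(0, dim = phantom$grid_shape)
  means <- vapply(phantom$voxel_to_vertices, function(vs) mean(map[vs]), numeric(1))
  out[as.integer(names(phantom$voxel_to_vertices))] <- means
  out
}

#' Resample a native-space volume into template space
#'
#' Undoes a subject's rigid transform: each template voxel centre is pushed
#' through the subject's forward transform and the native volume is sampled
#' there with trilinear interpolation. With an identity transform this is the
#' identity (up to interpolation at exact voxel centres, which is exact).
#'
#' @param field 3D or 4D array in native space (phantom grid).
#' @param phantom The jittered `cortical_phantom` carrying the transform.
#' @return Array of the same shape in template space.
#' @export
normalize_volume <- function(field, phantom) {
  tf <- phantom$transform
  if (all(tf$R == diag(3)) && all(tf$t == 0)) return(field)
  grid <- phantom_grid(phantom)
  shape <- grid$shape
  idx <- as.matrix(expand.grid(x = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                               z = 0:(shape[3] - 1)))
  centers <- sweep(idx * grid$voxel_mm, 2, grid$origin + grid$voxel_mm / 2, "+")
  native_pts <- sweep(centers %*% t(tf$R), 2, tf$t, "+")
  A <- interp_matrix(native_pts, grid, warn_clamp = FALSE)
  dm <- dim(field)
  if (length(dm) == 4L) {
    out <- as.matrix(A %*% matrix(field, prod(dm[1:3]), dm[4]))
    array(out, dm)
  } else {
    array(as.numeric(A %*% as.numeric(field)), dm)
  }
}
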