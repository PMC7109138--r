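test_that("volumetric smoothing matches dense direct convolution", {
  set.seed(8)
  vol <- array(0, c(9, 9, 9)); vol[5, 5, 5] <- 1
  expect_equal(smooth_volume(vol, 6, 3), oracle_gauss3(vol, 6, 3),
               tolerance = 1e-10)
  rnd <- array(rnorm(9^3), c(9, 9, 9))
  expect_equal(smooth_volume(rnd, 7, 3), oracle_gauss3(rnd, 7, 3),
               tolerance = 1e-10)
})

test_that("volumetric smoothing preserves constants, identity and mass", {
  vol <- array(rnorm(6^3), c(6, 6, 6))
  expect_identical(smooth_volume(vol, 0, 3), vol)
  cst <- array(3.7, c(6, 6, 6))
  expect_equal(smooth_volume(cst, 9, 3), cst, tolerance = 1e-12)
  # mass is conserved while the kernel stays on interior support
  interior <- array(0, c(15, 15, 15)); interior[8, 8, 8] <- 2.3
  expect_equal(sum(smooth_volume(interior, 6, 3)), 2.3, tolerance = 1e-10)
  # 4D: frames are smoothed independently
  v4 <- array(rnorm(6^3 * 3), c(6, 6, 6, 3))
  s4 <- smooth_volume(v4, 6, 3)
  for (t in 1:3)
    expect_equal(s4[, , , t], smooth_volume(v4[, , , t], 6, 3), tolerance = 1e-12)
})

test_that("surface smoothing of a delta matches the planar Gaussian kernel", {
  mesh <- planar_mesh(41)
  ctr <- 20L * 41L + 21L   # vertex at (20, 20)
  delta <- numeric(41 * 41); delta[ctr] <- 1
  out <- smooth_surface(delta, mesh, 9)
  pk <- out[ctr]
  row <- which(mesh$vertices[, 2] == 20)
  xs <- mesh$vertices[row, 1] - 20
  f <- stats::approxfun(xs[xs >= 0], out[row][xs >= 0])
  half_max_r <- stats::uniroot(function(r) f(r) - pk / 2, c(0.1, 15))$root
  expect_equal(half_max_r, 4.5, tolerance = 0.1)
})

test_that("surface smoothing is a contraction toward the mean", {
  ph <- tiny_phantom()
  set.seed(12)
  x <- rnorm(nrow(ph$vertices))
  expect_identical(smooth_surface(x, ph, 0), x)
  cst <- rep(2.5, nrow(ph$vertices))
  expect_equal(smooth_surface(cst, ph, 9), cst, tolerance = 1e-12)
  sm <- smooth_surface(x, ph, 6)
  expect_gte(min(sm), min(x))
  expect_lte(max(sm), max(x))
  # widening the kernel keeps shrinking the spread
  spread <- vapply(c(3, 9, 30), function(fw)
    diff(range(smooth_surface(x, ph, fw))), numeric(1))
  expect_true(all(diff(spread) < 0))
})

test_that("volume-to-surface sampling reduces along normals as specified", {
  ph <- tiny_phantom()
  shape <- ph$grid_shape
  cst <- array(4.2, shape)
  expect_equal(map_volume_to_surface(cst, ph, "abs_max"),
               rep(4.2, nrow(ph$vertices)), tolerance = 1e-9)
  expect_equal(map_volume_to_surface(cst, ph, "weighted_mean"),
               rep(4.2, nrow(ph$vertices)), tolerance = 1e-9)
  # linear field f = x: trilinear sampling is exact, so both reductions have
  # closed forms computable straight from the sampling geometry
  xs <- ph$origin[1] + (seq_len(shape[1]) - 0.5) * ph$voxel_mm
  linvol <- array(rep(xs, times = prod(shape[2:3])), shape)
  off <- seq(-1.5, 1.5, length.out = 5)
  samples <- vapply(off, function(o)
    ph$vertices[, 1] + o * ph$normals[, 1], numeric(nrow(ph$vertices)))
  # clamp to the sampling lattice like the implementation does
  samples <- pmin(pmax(samples, xs[1]), xs[length(xs)])
  am <- map_volume_to_surface(linvol, ph, "abs_max")
  pick <- max.col(abs(samples), ties.method = "first")
  expect_equal(am, samples[cbind(seq_len(nrow(samples)), pick)],
               tolerance = 1e-9)
  g <- exp(-off^2 / (2 * 1.5^2 / (2 * log(2))))
  wm <- map_volume_to_surface(linvol, ph, "weighted_mean")
  expect_equal(wm, as.numeric(samples %*% g) / sum(g), tolerance = 1e-9)
  # three equidistant samples a, b, c with end weight one half:
  # (0.5 a + b + 0.5 c) / 2
  wm3 <- map_volume_to_surface(linvol, ph, "weighted_mean", n_samples = 3L)
  s3 <- samples[, c(1, 3, 5)]
  expect_equal(wm3, (0.5 * s3[, 1] + s3[, 2] + 0.5 * s3[, 3]) / 2,
               tolerance = 1e-9)
})

test_that("abs_max keeps the sign of the dominant sample", {
  ph <- tiny_phantom()
  # negate the field on one side so the largest-magnitude sample is negative
  shape <- ph$grid_shape
  xs <- ph$origin[1] + (seq_len(shape[1]) - 0.5) * ph$voxel_mm
  vol <- array(rep(-abs(xs) - 1, times = prod(shape[2:3])), shape)
  out <- map_volume_to_surface(vol, ph, "abs_max")
  expect_true(all(out < 0))
})

test_that("surface-to-volume mapping averages vertices per cortex voxel", {
  ph <- tiny_phantom()
  cst <- rep(1.5, nrow(ph$vertices))
  vol <- map_surface_to_volume(cst, ph)
  cortex <- which(ph$voxel_tissue == "cortex")
  expect_true(all(abs(vol[cortex] - 1.5) < 1e-12))
  expect_true(all(vol[-cortex] == 0))
  # hand-checked mean over one voxel's vertex set
  set.seed(3)
  x <- rnorm(nrow(ph$vertices))
  volx <- map_surface_to_volume(x, ph)
  vox <- as.integer(names(ph$voxel_to_vertices)[7])
  expect_equal(volx[vox], mean(x[ph$voxel_to_vertices[[7]]]))
})

test_that("normalisation resamples a translated grid exactly at voxel shifts", {
  ph <- tiny_phantom()
  set.seed(5)
  vol <- array(rnorm(prod(ph$grid_shape)), ph$grid_shape)
  expect_identical(normalize_volume(vol, ph), vol)
  phj <- ph
  phj$transform <- list(R = diag(3), t = c(ph$voxel_mm, 0, 0),
                        R_inv = diag(3), t_inv = c(-ph$voxel_mm, 0, 0))
  out <- normalize_volume(vol, phj)
  # template voxel i reads native voxel i+1 (one whole voxel shift in x)
  n1 <- ph$grid_shape[1]
  expect_equal(out[seq_len(n1 - 1), , ], vol[2:n1, , ], tolerance = 1e-12)
})

test_that("cross-sulcus leakage happens in the volume but not on the surface", {
  ph <- build_phantom(phantom_config())
  # delta on the postcentral bank crown, as a voxel field
  w <- numeric(nrow(ph$vertices)); w[ph$seed_sensory] <- 1
  vol <- map_surface_to_volume(w, ph)
  pre_bank <- which(ph$vertex_region == "precentral" |
                    ph$vertex_region == "central_sulcus_wall_ant")
  peak <- function(x) max(abs(x))
  for (fw in c(6, 9, 12)) {
    sm <- smooth_volume(vol, fw, ph$voxel_mm)
    onto <- map_volume_to_surface(sm, ph, "weighted_mean")
    expect_gt(max(onto[pre_bank]), 0)      # the volume kernel crosses the gap
  }
  surf <- smooth_surface(w, ph, 12)
  expect_lt(max(surf[pre_bank]), 0.01 * peak(surf))  # the surface kernel does not
})
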