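test_that("default phantom reproduces the near-in-3D, far-on-surface geometry", {
  ph <- build_phantom(phantom_config())
  d_e <- sqrt(sum((ph$vertices[ph$seed_motor, ] -
                   ph$vertices[ph$seed_sensory, ])^2))
  expect_equal(d_e, 4, tolerance = 0.5 / 4)
  d_g <- geodesic_distance(ph, ph$seed_motor, ph$seed_sensory)
  expect_gte(d_g, 37)
  expect_lte(d_g, 43)
  expect_identical(as.character(ph$vertex_region[ph$seed_motor]), "precentral")
  expect_identical(as.character(ph$vertex_region[ph$seed_sensory]), "postcentral")
})

test_that("phantom mesh and voxel maps satisfy their structural invariants", {
  ph <- tiny_phantom()
  # regions partition the vertices
  expect_false(anyNA(ph$vertex_region))
  # manifold: each edge borders at most two triangles
  tri <- ph$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_lte(max(table(key)), 2)
  # unit outward normals
  expect_equal(rowSums(ph$normals^2), rep(1, nrow(ph$vertices)), tolerance = 1e-8)
  # every vertex lies in a voxel labelled cortex
  vlin <- ph$vertex_to_voxel
  lin <- 1L + vlin[, 1] + ph$grid_shape[1] * (vlin[, 2] + ph$grid_shape[2] * vlin[, 3])
  expect_true(all(ph$voxel_tissue[lin] == "cortex"))
  # round trip: each cortex voxel's vertex set maps back to that voxel
  for (vox in sample(names(ph$voxel_to_vertices), 20)) {
    vs <- ph$voxel_to_vertices[[vox]]
    expect_true(all(lin[vs] == as.integer(vox)))
  }
  # voxel-centre containment: vertex coordinates fall in the half-open voxel
  lo <- sweep(vlin * ph$voxel_mm, 2, ph$origin, "+")
  expect_true(all(ph$vertices >= lo - 1e-9))
  expect_true(all(ph$vertices < lo + ph$voxel_mm + 1e-9))
})

test_that("graph geodesics match a dense shortest-path oracle on a flat sheet", {
  ph <- build_phantom(phantom_config(fold_depth_mm = 0, bank_gap_mm = 0,
                                     sheet_width_mm = 2, sheet_length_mm = 4))
  D <- oracle_all_pairs(ph$vertices, ph$edges)
  n <- nrow(ph$vertices)
  pairs <- cbind(sample(n, 40, replace = TRUE), sample(n, 40, replace = TRUE))
  for (k in seq_len(nrow(pairs))) {
    expect_equal(geodesic_distance(ph, pairs[k, 1], pairs[k, 2]),
                 D[pairs[k, 1], pairs[k, 2]], tolerance = 1e-10)
  }
})

test_that("geodesic distance is a metric and collapses to Euclidean when flat", {
  ph <- tiny_phantom()
  expect_identical(geodesic_distance(ph, 5, 5), 0)
  # adjacent vertices: distance equals the edge length
  e <- ph$edges[10, ]
  expect_equal(geodesic_distance(ph, e[1], e[2]),
               sqrt(sum((ph$vertices[e[1], ] - ph$vertices[e[2], ])^2)),
               tolerance = 1e-12)
  # triangle inequality on sampled triples
  set.seed(2)
  n <- nrow(ph$vertices)
  for (k in 1:15) {
    v <- sample(n, 3)
    d12 <- geodesic_distance(ph, v[1], v[2])
    d23 <- geodesic_distance(ph, v[2], v[3])
    d13 <- geodesic_distance(ph, v[1], v[3])
    expect_lte(d13, d12 + d23 + 1e-9)
  }
  # unfolded limit: seed separation along the sheet equals straight-line
  phf <- build_phantom(phantom_config(fold_depth_mm = 0, bank_gap_mm = 0,
                                      sheet_width_mm = 8, sheet_length_mm = 6))
  d_g <- geodesic_distance(phf, phf$seed_motor, phf$seed_sensory)
  d_e <- sqrt(sum((phf$vertices[phf$seed_motor, ] -
                   phf$vertices[phf$seed_sensory, ])^2))
  expect_equal(d_g, d_e, tolerance = phf$config$mesh_edge_mm / d_e)
})

test_that("subject jitter is rigid, seeded and exactly undoable", {
  cfg <- phantom_config(sheet_width_mm = 6, sheet_length_mm = 10,
                        jitter = list(translate_mm = 2, rotate_deg = 3))
  ph <- build_phantom(cfg)
  phj <- apply_subject_jitter(ph, 11)
  expect_equal(apply_subject_jitter(ph, 11)$vertices, phj$vertices)
  # rigid: pairwise Euclidean and all edge lengths preserved
  set.seed(4)
  v <- sample(nrow(ph$vertices), 20)
  d0 <- as.matrix(dist(ph$vertices[v, ]))
  d1 <- as.matrix(dist(phj$vertices[v, ]))
  expect_equal(d1, d0, tolerance = 1e-10)
  expect_equal(phj$edge_lengths, ph$edge_lengths, tolerance = 1e-10)
  expect_equal(geodesic_distance(phj, phj$seed_motor, phj$seed_sensory),
               geodesic_distance(ph, ph$seed_motor, ph$seed_sensory),
               tolerance = 1e-10)
  # stored inverse restores template coordinates
  back <- sweep(phj$vertices %*% t(phj$transform$R_inv), 2,
                phj$transform$t_inv, "+")
  expect_equal(unname(back), unname(ph$vertices), tolerance = 1e-10)
  # zero-magnitude jitter leaves the phantom untouched
  cfg0 <- phantom_config(sheet_width_mm = 6, sheet_length_mm = 10,
                         jitter = list(translate_mm = 0, rotate_deg = 0))
  ph0 <- build_phantom(cfg0)
  expect_identical(apply_subject_jitter(ph0, 5), ph0)
})

test_that("infeasible fold geometry is rejected", {
  expect_error(phantom_config(fold_depth_mm = 2, bank_gap_mm = 4), "infeasible")
  expect_error(phantom_config(voxel_mm = 0.5, mesh_edge_mm = 1), "voxel_mm")
  expect_error(phantom_config(fold_depth_mm = 0, bank_gap_mm = 4), "flat sheet")
})
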