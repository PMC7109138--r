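test_that("design matrix has the expected columns and convolved regressor", {
  d <- make_periodic_design(10, 1, 40, 2.52)
  X <- build_design_matrix(d)
  expect_identical(colnames(X$X), c("task", "intercept"))
  Xd <- build_design_matrix(d, drift = TRUE)
  expect_identical(ncol(Xd$X), 3L)
  expect_equal(mean(Xd$X[, "drift"]), 0, tolerance = 1e-12)
  # no events: intercept-only matrix
  d0 <- sulcalsim:::new_event_design(numeric(0), numeric(0), 40, 2.52)
  expect_identical(colnames(build_design_matrix(d0)$X), "intercept")
  # a single early event: the task column is the sampled response itself
  d1 <- sulcalsim:::new_event_design(0, 0.1, 40, 2.52)
  reg <- build_design_matrix(d1)$X[, "task"]
  # one fine-grid boxcar sample: the regressor is the response itself,
  # scaled by dt and read at the nearest fine-grid point per volume
  direct <- 0.1 * hrf(seq(0, 32, by = 0.1))
  idx <- round((0:39) * 2.52 / 0.1) + 1L
  expected <- ifelse(idx <= length(direct), direct[pmin(idx, length(direct))], 0)
  expect_equal(unname(reg), expected, tolerance = 1e-8)
})

test_that("per-element OLS matches the closed-form normal equations", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(6:10, 1)
    p <- sample(2:3, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    Y <- matrix(rnorm(8 * n), 8, n)
    ctr <- c(numeric(p - 1), 1)
    fit <- fit_glm(Y, X, ctr)
    XtXi <- solve(t(X) %*% X)
    for (e in 1:8) {
      beta <- XtXi %*% t(X) %*% Y[e, ]
      res <- Y[e, ] - X %*% beta
      s2 <- sum(res^2) / (n - p)
      expect_equal(fit$effect[e], sum(ctr * beta), tolerance = 1e-8)
      expect_equal(fit$t[e],
                   drop(sum(ctr * beta) / sqrt(s2 * t(ctr) %*% XtXi %*% ctr)),
                   tolerance = 1e-8)
    }
    expect_identical(fit$dof, n - p)
  }
})

test_that("noiseless data are recovered exactly and flagged", {
  X <- cbind(task = c(0, 1, 0, 1, 1, 0), intercept = 1)
  beta <- c(2.5, -1)
  y <- as.numeric(X %*% beta)
  fit <- fit_glm(matrix(y, 1), X, c(1, 0))
  expect_equal(fit$effect, 2.5, tolerance = 1e-10)
  expect_true(fit$flagged)
  expect_identical(fit$t, Inf)
})

test_that("one-sample group statistic matches hand computation", {
  e <- matrix(c(1, 2, 3), 1)
  g <- group_onesample(e)
  expect_equal(g$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_identical(g$dof, 2L)
  expect_equal(group_onesample(-e)$t, -g$t)
})

test_that("TFCE agrees with the brute-force threshold sweep", {
  # 1D toy map (0, 2, 2, 0, 1), chain adjacency, dh = 0.5
  edges <- cbind(1:4, 2:5)
  adj <- edges_to_csr(edges, 5)
  vals <- c(0, 2, 2, 0, 1)
  got <- tfce(vals, adj, tfce_params(E = 0.5, H = 2, dh = 0.5))
  expect_equal(got, oracle_tfce(vals, edges, 0.5, 2, 0.5), tolerance = 1e-10)
  # isolated nonzero element: sum h^H dh -> v^(H+1)/(H+1)
  adj1 <- edges_to_csr(cbind(1, 2), 3)
  v1 <- c(0, 0, 1)
  got1 <- tfce(v1, adj1, tfce_params(E = 0.5, H = 2, dh = 1e-3))
  expect_equal(got1[3], 1 / 3, tolerance = 0.01)
  expect_equal(got1[1:2], c(0, 0))
  # all-zero map
  expect_identical(tfce(numeric(5), adj), numeric(5))
  # random signed maps on random graphs, any adjacency
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(10:40, 1)
    m <- sample(n:(2 * n), 1)
    edges <- unique(cbind(sample(n, m, TRUE), sample(n, m, TRUE)))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    vals <- round(rnorm(n), 1)
    adj <- edges_to_csr(edges, n)
    dh <- max(abs(vals)) / 23
    expect_equal(tfce(vals, adj, tfce_params(dh = dh)),
                 oracle_tfce(vals, edges, 0.5, 2, dh), tolerance = 1e-9)
  }
})

test_that("TFCE is monotone under map scaling", {
  set.seed(30)
  n <- 25
  edges <- cbind(1:(n - 1), 2:n)
  adj <- edges_to_csr(edges, n)
  vals <- abs(rnorm(n))
  a <- tfce(vals, adj)
  b <- tfce(2 * vals, adj)
  expect_true(all(b >= a - 1e-12))
})

test_that("sign-flip inference respects its probability bounds and symmetry", {
  set.seed(40)
  effects <- matrix(rnorm(30 * 10), 30, 10)
  adj <- edges_to_csr(cbind(1:29, 2:30), 30)
  res <- permutation_fwe(effects, adj, n_perm = 200, alpha = 0.05, seed = 2)
  expect_true(all(res$corrected_p >= 1 / 201))
  expect_true(all(res$corrected_p <= 1))
  expect_identical(res$mask, res$corrected_p <= 0.05)
  # global sign flip leaves the corrected p-values unchanged
  res_neg <- permutation_fwe(-effects, adj, n_perm = 200, alpha = 0.05, seed = 2)
  expect_equal(res_neg$corrected_p, res$corrected_p, tolerance = 1e-12)
  # few subjects: all distinct sign patterns are enumerated, with a warning
  expect_warning(
    res_small <- permutation_fwe(effects[, 1:6], adj, n_perm = 100, seed = 2),
    "enumerat")
  expect_identical(res_small$n_perm, 64L)
})

test_that("with no jitter and no smoothing the two volume pipelines coincide", {
  ph <- tiny_phantom()
  design <- make_periodic_design(10, 1, 30, 2.52)
  ramp <- make_roi_ramp(ph, ph$seed_sensory, 6)
  cohort <- simulate_task_cohort(ph, design, ramp, amplitude = 2,
                                 n_subjects = 3, seed = 5)
  r1 <- suppressWarnings(
    run_approach(cohort, "vba_smooth_first", 0, n_perm = 100, seed = 9))
  r2 <- suppressWarnings(
    run_approach(cohort, "vba_glm_first", 0, n_perm = 100, seed = 9))
  expect_equal(r1$t, r2$t, tolerance = 1e-9)
  expect_equal(r1$corrected_p, r2$corrected_p, tolerance = 1e-12)
})
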