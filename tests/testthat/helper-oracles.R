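# Independent brute-force oracles and small fixtures used across the suite.
# These deliberately avoid the package's own algorithms: dense relaxation for
# shortest paths, triple-loop convolution, BFS component labelling for the
# TFCE threshold sweep.

tiny_phantom <- function(...) {
  build_phantom(phantom_config(sheet_width_mm = 6, sheet_length_mm = 10, ...))
}

# flat square grid mesh with alternating quad diagonals, n x n vertices at
# unit spacing in the x-y plane
planar_mesh <- function(n, spacing = 1) {
  g <- expand.grid(x = seq_len(n) - 1, y = seq_len(n) - 1)
  vx <- cbind(x = g$x * spacing, y = g$y * spacing, z = 0)
  idx <- function(i, j) (j - 1L) * n + i
  tris <- list()
  for (j in seq_len(n - 1L)) {
    i <- seq_len(n - 1L)
    a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
    par <- (i + j) %% 2L == 0L
    te <- rbind(cbind(a, b, d), cbind(a, d, c))
    to <- rbind(cbind(a, b, c), cbind(b, d, c))
    sel <- rep(par, 2)
    tris[[j]] <- rbind(te[sel, , drop = FALSE], to[!sel, , drop = FALSE])
  }
  list(vertices = vx, triangles = do.call(rbind, tris))
}

mesh_edge_list <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

# dense all-pairs shortest paths by repeated relaxation (Bellman-Ford style)
oracle_all_pairs <- function(vertices, edges) {
  n <- nrow(vertices)
  w <- sqrt(rowSums((vertices[edges[, 1], , drop = FALSE] -
                     vertices[edges[, 2], , drop = FALSE])^2))
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[cbind(edges[, 1], edges[, 2])] <- w
  D[cbind(edges[, 2], edges[, 1])] <- w
  repeat {
    changed <- FALSE
    for (k in seq_len(n)) {
      cand <- outer(D[, k], D[k, ], `+`)
      better <- cand < D - 1e-12
      if (any(better)) { D[better] <- cand[better]; changed <- TRUE }
    }
    if (!changed) break
  }
  D
}

# direct dense 3D Gaussian convolution with whole-sample reflection
oracle_gauss3 <- function(vol, fwhm, voxel) {
  sig <- fwhm / (2 * sqrt(2 * log(2))) / voxel
  r <- max(1L, ceiling(4 * sig))
  k1 <- stats::dnorm(-r:r, sd = sig); k1 <- k1 / sum(k1)
  n <- dim(vol)
  refl <- function(j, nn) {
    j <- ifelse(j < 1L, 2L - j, j)
    j <- ifelse(j > nn, 2L * nn - j, j)
    pmin(pmax(j, 1L), nn)
  }
  out <- array(0, n)
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (l in seq_len(n[3])) {
    s <- 0
    for (a in -r:r) for (b in -r:r) for (cc in -r:r) {
      s <- s + k1[a + r + 1] * k1[b + r + 1] * k1[cc + r + 1] *
        vol[refl(i + a, n[1]), refl(j + b, n[2]), refl(l + cc, n[3])]
    }
    out[i, j, l] <- s
  }
  out
}

# BFS connected components of a node subset on an undirected edge list
oracle_components <- function(nodes, edges) {
  keep <- edges[edges[, 1] %in% nodes & edges[, 2] %in% nodes, , drop = FALSE]
  adj <- split(c(keep[, 2], keep[, 1]), c(keep[, 1], keep[, 2]))
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[as.character(start)])) next
    cid <- cid + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[as.character(v)])) next
      comp[as.character(v)] <- cid
      nb <- adj[[as.character(v)]]
      queue <- c(queue, nb[is.na(comp[as.character(nb)])])
    }
  }
  comp
}

# literal threshold sweep TFCE on the positive part of a map
oracle_tfce_pos <- function(values, edges, E, H, dh) {
  out <- numeric(length(values))
  vmax <- max(values)
  if (vmax <= 0) return(out)
  for (h in seq(dh, vmax + 1e-12, by = dh)) {
    nodes <- which(values >= h)
    if (!length(nodes)) break
    comp <- oracle_components(nodes, edges)
    sizes <- table(comp)
    for (v in nodes) {
      e <- as.numeric(sizes[as.character(comp[as.character(v)])])
      out[v] <- out[v] + e^E * h^H * dh
    }
  }
  out
}

oracle_tfce <- function(values, edges, E, H, dh) {
  oracle_tfce_pos(pmax(values, 0), edges, E, H, dh) -
    oracle_tfce_pos(pmax(-values, 0), edges, E, H, dh)
}

# CSR adjacency from an edge list (mirrors the exported builders' format)
edges_to_csr <- function(edges, n) {
  i <- c(edges[, 1], edges[, 2]); j <- c(edges[, 2], edges[, 1])
  o <- order(i, j)
  list(ptr = as.integer(c(0L, cumsum(tabulate(i[o], nbins = n)))),
       idx = as.integer(j[o] - 1L), n = n)
}
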