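#' Configuration for the folded-cortex phantom
#'
#' Parameters of the synthetic sulcus: a cortical sheet folded into a "U" so
#' that the crowns of the two banks face each other across a narrow gap. The
#' defaults realise the motivating geometry: two locations roughly 4 mm apart
#' through the volume but roughly 40 mm apart along the cortical sheet.
#'
#' @param fold_depth_mm Depth of the fold from the crown plane to the deepest
#'   point of the fundus (mm). The default 18 mm, together with the 4 mm gap,
#'   puts the along-surface seed separation close to 40 mm.
#' @param bank_gap_mm Euclidean distance between the opposing bank crowns (mm).
#' @param sheet_width_mm Width of each flat gyral crown segment (mm).
#' @param sheet_length_mm Extent of the sheet along the sulcus axis (mm).
#' @param mesh_edge_mm Target mesh edge length (mm).
#' @param voxel_mm Isotropic voxel size of the companion grid (mm).
#' @param jitter Either `NULL` (no inter-subject variability) or a list with
#'   elements `translate_mm` and `rotate_deg` giving the magnitude of the
#'   per-subject rigid perturbation drawn by [apply_subject_jitter()].
#' @param seed Integer seed for any randomness tied to the phantom.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(fold_depth_mm = 18, bank_gap_mm = 4,
                           sheet_width_mm = 12, sheet_length_mm = 30,
                           mesh_edge_mm = 1, voxel_mm = 3,
                           jitter = NULL, seed = 1L) {
  cfg <- list(
    fold_depth_mm = fold_depth_mm, bank_gap_mm = bank_gap_mm,
    sheet_width_mm = sheet_width_mm, sheet_length_mm = sheet_length_mm,
    mesh_edge_mm = mesh_edge_mm, voxel_mm = voxel_mm,
    jitter = jitter, seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  lens <- c(cfg$sheet_width_mm, cfg$sheet_length_mm, cfg$mesh_edge_mm, cfg$voxel_mm)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all phantom lengths must be positive", call. = FALSE)
  if (cfg$fold_depth_mm < 0 || cfg$bank_gap_mm < 0)
    stop("fold_depth_mm and bank_gap_mm must be nonnegative", call. = FALSE)
  if (cfg$voxel_mm < cfg$mesh_edge_mm)
    stop("voxel_mm must be at least mesh_edge_mm", call. = FALSE)
  if (cfg$fold_depth_mm == 0) {
    if (cfg$bank_gap_mm != 0)
      stop("a flat sheet (fold_depth_mm = 0) requires bank_gap_mm = 0", call. = FALSE)
  } else if (cfg$bank_gap_mm >= 2 * cfg$fold_depth_mm) {
    stop("infeasible geometry: bank_gap_mm must be < 2 * fold_depth_mm", call. = FALSE)
  }
  if (!is.null(cfg$jitter)) {
    if (!is.list(cfg$jitter) ||
        is.null(cfg$jitter$translate_mm) || is.null(cfg$jitter$rotate_deg))
      stop("jitter must be NULL or list(translate_mm=, rotate_deg=)", call. = FALSE)
  }
  invisible(cfg)
}

# Cross-section of the fold in the x-z plane, sampled at ~edge spacing.
# Returns x, z, region label and outward (pial) normal per sample point.
# Traversal: precentral crown -> anterior wall -> fundus arc -> posterior
# wall -> postcentral crown -> posterior wall of the next sulcus.
fold_cross_section <- function(cfg) {
  edge <- cfg$mesh_edge_mm
  seg_pts <- function(p0, p1, region) {
    len <- sqrt(sum((p1 - p0)^2))
    n <- max(1L, ceiling(len / edge))
    tt <- seq(0, 1, length.out = n + 1L)
    list(x = p0[1] + tt * (p1[1] - p0[1]),
         z = p0[2] + tt * (p1[2] - p0[2]),
         region = rep(region, n + 1L))
  }
  if (cfg$fold_depth_mm == 0) {
    w <- cfg$sheet_width_mm
    pre <- seg_pts(c(-w, 0), c(0, 0), "precentral")
    post <- seg_pts(c(0, 0), c(w, 0), "postcentral")
    x <- c(pre$x, post$x[-1]); z <- c(pre$z, post$z[-1])
    region <- c(pre$region, post$region[-1])
    region[x == 0] <- "precentral"
    lip_pre <- which.min(abs(x + w / 2))
    lip_post <- which.min(abs(x - w / 2))
  } else {
    r <- cfg$bank_gap_mm / 2
    wall <- cfg$fold_depth_mm - r
    w <- cfg$sheet_width_mm
    pc_depth <- min(cfg$fold_depth_mm / 3, 6)
    segs <- list(
      seg_pts(c(-r - w, 0), c(-r, 0), "precentral"),
      seg_pts(c(-r, 0), c(-r, -wall), "central_sulcus_wall_ant"),
      NULL, # fundus arc filled below
      seg_pts(c(r, -wall), c(r, 0), "central_sulcus_wall_post"),
      seg_pts(c(r, 0), c(r + w, 0), "postcentral"),
      seg_pts(c(r + w, 0), c(r + w, -pc_depth), "postcentral_sulcus_wall")
    )
    arc_len <- pi * r
    n_arc <- max(2L, ceiling(arc_len / edge))
    th <- seq(pi, 2 * pi, length.out = n_arc + 1L)
    segs[[3]] <- list(x = r * cos(th), z = -wall + r * sin(th),
                      region = ifelse(th <= 1.5 * pi,
                                      "central_sulcus_wall_ant",
                                      "central_sulcus_wall_post"))
    x <- segs[[1]]$x; z <- segs[[1]]$z; region <- segs[[1]]$region
    for (s in segs[-1]) {
      x <- c(x, s$x[-1]); z <- c(z, s$z[-1]); region <- c(region, s$region[-1])
    }
    # crown/wall junction points belong to the gyral crowns so the seeds,
    # placed at the sulcal lips, carry gyral labels
    region[abs(x + r) < 1e-9 & abs(z) < 1e-9] <- "precentral"
    region[abs(x - r) < 1e-9 & abs(z) < 1e-9] <- "postcentral"
    region[abs(x - r - w) < 1e-9 & abs(z) < 1e-9] <- "postcentral"
    lip_pre <- which(abs(x + r) < 1e-9 & abs(z) < 1e-9)[1]
    lip_post <- which(abs(x - r) < 1e-9 & abs(z) < 1e-9)[1]
  }
  n <- length(x)
  # outward (pial) normal = tangent rotated by +90 degrees in the x-z plane;
  # central differences along the polyline
  ip <- pmin(n, seq_len(n) + 1L); im <- pmax(1L, seq_len(n) - 1L)
  tx <- x[ip] - x[im]; tz <- z[ip] - z[im]
  tl <- sqrt(tx^2 + tz^2); tl[tl == 0] <- 1
  nx <- -tz / tl; nz <- tx / tl
  list(x = x, z = z, region = region, nx = nx, nz = nz,
       lip_pre = lip_pre, lip_post = lip_post)
}

#' Build the folded-cortex phantom
#'
#' Constructs the triangulated cortical sheet (a "U" fold extruded along the
#' sulcus axis), a companion isotropic voxel grid with tissue labels, the
#' vertex/voxel correspondence maps, outward normals and two designated seed
#' vertices sitting on the opposing sulcal lips: `seed_motor` on the
#' precentral bank and `seed_sensory` on the postcentral bank. The two seeds
#' are `bank_gap_mm` apart in 3D but separated by the whole descent and ascent
#' of the fold along the surface.
#'
#' The voxel grid is aligned so that a voxel boundary coincides with the
#' sulcal midplane; with the default 4 mm gap and 3 mm voxels the opposing
#' banks therefore never share a voxel and every cross-bank effect measured
#' downstream is attributable to smoothing or interpolation, not to label
#' ambiguity.
#'
#' @param config A [phantom_config()].
#' @return An object of class `cortical_phantom`.
#' @export
build_phantom <- function(config = phantom_config()) {
  validate_phantom_config(config)
  cs <- fold_cross_section(config)
  edge <- config$mesh_edge_mm
  n_s <- length(cs$x)
  n_y <- max(2L, ceiling(config$sheet_length_mm / edge) + 1L)
  ys <- seq(0, config$sheet_length_mm, length.out = n_y)

  vertices <- cbind(
    x = rep(cs$x, times = n_y),
    y = rep(ys, each = n_s),
    z = rep(cs$z, times = n_y)
  )
  vertex_region <- factor(rep(cs$region, times = n_y),
                          levels = c("precentral", "central_sulcus_wall_ant",
                                     "central_sulcus_wall_post", "postcentral",
                                     "postcentral_sulcus_wall"))
  normals <- cbind(rep(cs$nx, times = n_y), 0, rep(cs$nz, times = n_y))

  # alternate the quad diagonal by (i+j) parity so the one-ring neighbourhoods
  # are isotropic on average (union-jack triangulation)
  tri <- build_grid_triangles(n_s, n_y)

  # mid-length row index, sulcal lip columns
  j_mid <- ceiling(n_y / 2)
  seed_motor <- (j_mid - 1L) * n_s + cs$lip_pre
  seed_sensory <- (j_mid - 1L) * n_s + cs$lip_post

  grid <- make_grid(vertices, config$voxel_mm)
  maps <- vertex_voxel_maps(vertices, grid)
  tissue <- label_tissue(vertices, normals, grid, maps)

  edges <- mesh_edges(tri)
  elen <- sqrt(rowSums((vertices[edges[, 1], , drop = FALSE] -
                        vertices[edges[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- elen

  ph <- list(
    vertices = vertices, triangles = tri, vertex_region = vertex_region,
    normals = normals, grid_shape = grid$shape, affine = grid$affine,
    origin = grid$origin, voxel_mm = config$voxel_mm,
    voxel_tissue = tissue,
    vertex_to_voxel = maps$vertex_to_voxel,
    voxel_to_vertices = maps$voxel_to_vertices,
    seed_motor = seed_motor, seed_sensory = seed_sensory,
    edges = edges, edge_lengths = elen, graph = g,
    transform = identity_transform(),
    mesh_dims = c(n_s = n_s, n_y = n_y),
    config = config
  )
  class(ph) <- "cortical_phantom"
  ph
}

build_grid_triangles <- function(n_s, n_y) {
  idx <- function(i, j) (j - 1L) * n_s + i
  tris <- vector("list", (n_s - 1L) * (n_y - 1L))
  k <- 0L
  for (j in seq_len(n_y - 1L)) {
    i <- seq_len(n_s - 1L)
    a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
    par <- (i + j) %% 2L == 0L
    # diagonal a-d for even parity, b-c for odd
    tri_even <- rbind(cbind(a, b, d), cbind(a, d, c))
    tri_odd <- rbind(cbind(a, b, c), cbind(b, d, c))
    sel <- rep(par, 2)
    k <- k + 1L
    tris[[k]] <- rbind(tri_even[sel, , drop = FALSE], tri_odd[!sel, , drop = FALSE])
  }
  tri <- do.call(rbind, tris[seq_len(k)])
  dimnames(tri) <- NULL
  tri
}

mesh_edges <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

identity_transform <- function() {
  list(R = diag(3), t = c(0, 0, 0), R_inv = diag(3), t_inv = c(0, 0, 0))
}

# grid aligned to multiples of voxel_mm with a one-voxel margin; half-open
# voxel ownership [lo, hi), 0-based indices, voxel centres at origin+(k+0.5)*v
make_grid <- function(vertices, voxel_mm) {
  lo <- voxel_mm * (floor(apply(vertices, 2, min) / voxel_mm) - 2L)
  hi <- voxel_mm * (ceiling(apply(vertices, 2, max) / voxel_mm) + 2L)
  shape <- as.integer(round((hi - lo) / voxel_mm))
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- lo + voxel_mm / 2
  list(origin = unname(lo), shape = shape, affine = affine, voxel_mm = voxel_mm)
}

voxel_index0 <- function(pts, grid) {
  idx <- floor(sweep(sweep(pts, 2, grid$origin), 2, grid$voxel_mm, "/"))
  storage.mode(idx) <- "integer"
  idx
}

voxel_linear <- function(idx0, shape) {
  1L + idx0[, 1] + shape[1] * (idx0[, 2] + shape[2] * idx0[, 3])
}

vertex_voxel_maps <- function(vertices, grid) {
  idx0 <- voxel_index0(vertices, grid)
  if (any(idx0 < 0) || any(sweep(idx0, 2, grid$shape) >= 0))
    stop("vertex outside the voxel grid; increase the grid margin", call. = FALSE)
  lin <- voxel_linear(idx0, grid$shape)
  list(vertex_to_voxel = idx0,
       vertex_voxel_linear = lin,
       voxel_to_vertices = split(seq_len(nrow(vertices)), lin))
}

label_tissue <- function(vertices, normals, grid, maps) {
  shape <- grid$shape
  tissue <- array("background", dim = shape)
  cortex_lin <- as.integer(names(maps$voxel_to_vertices))
  tissue[cortex_lin] <- "cortex"

  # shell: non-cortex voxels 26-adjacent to cortex get white (inside the
  # sheet) or csf (outside), decided by the outward normal at the nearest
  # vertex to the voxel centre
  cortex_idx <- which(array(tissue == "cortex", dim = shape), arr.ind = TRUE) - 1L
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  cand <- unique(do.call(rbind, lapply(seq_len(nrow(off)), function(k)
    sweep(cortex_idx, 2, as.integer(off[k, ]), "+"))))
  keep <- cand[, 1] >= 0 & cand[, 2] >= 0 & cand[, 3] >= 0 &
    cand[, 1] < shape[1] & cand[, 2] < shape[2] & cand[, 3] < shape[3]
  cand <- cand[keep, , drop = FALSE]
  lin <- voxel_linear(cand, shape)
  new <- lin[tissue[lin] == "background"]
  if (length(new)) {
    cand <- cand[match(new, lin), , drop = FALSE]
    centers <- sweep(cand * grid$voxel_mm, 2, grid$origin + grid$voxel_mm / 2, "+")
    nearest <- nearest_vertex(centers, vertices)
    d <- centers - vertices[nearest, , drop = FALSE]
    side <- rowSums(d * normals[nearest, , drop = FALSE])
    tissue[new] <- ifelse(side > 0, "csf", "white")
  }
  tissue
}

nearest_vertex <- function(pts, vertices, chunk = 512L) {
  n <- nrow(pts)
  out <- integer(n)
  v2 <- rowSums(vertices^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), v2, "+") - 2 * block %*% t(vertices)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' @export
print.cortical_phantom <- function(x, ...) {
  cat("cortical_phantom:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  cat("  grid", paste(x$grid_shape, collapse = " x "),
      sprintf("at %g mm; tissue: %s\n", x$voxel_mm,
              paste(names(table(x$voxel_tissue)), table(x$voxel_tissue),
                    sep = "=", collapse = " ")))
  d_e <- sqrt(sum((x$vertices[x$seed_motor, ] - x$vertices[x$seed_sensory, ])^2))
  cat(sprintf("  seeds: Euclidean %.2f mm, geodesic %.2f mm\n", d_e,
              geodesic_distance(x, x$seed_motor, x$seed_sensory)))
  invisible(x)
}

#' Geodesic distance between two mesh vertices
#'
#' Shortest-path length along the mesh edge graph with Euclidean edge lengths
#' as weights (graph geodesic). At the default 1 mm edge length this
#' overestimates the exact polyhedral geodesic by under 5 percent.
#'
#' @param phantom A `cortical_phantom`.
#' @param v1,v2 Vertex indices.
#' @return Distance in mm.
#' @export
geodesic_distance <- function(phantom, v1, v2) {
  d <- igraph::distances(phantom$graph, v = v1, to = v2)[1, 1]
  if (!is.finite(d)) stop("vertices are not connected on the mesh", call. = FALSE)
  d
}

#' Geodesic distances from one vertex to all vertices
#'
#' @inheritParams geodesic_distance
#' @param v Source vertex index.
#' @return Numeric vector of distances in mm (Inf for disconnected vertices).
#' @export
geodesic_from <- function(phantom, v) {
  as.numeric(igraph::distances(phantom$graph, v = v))
}

#' Apply a per-subject rigid perturbation to the phantom
#'
#' Stand-in for inter-subject anatomical variability: the whole mesh is
#' rigidly rotated and translated (magnitudes set by the `jitter` field of the
#' configuration), the voxel correspondence maps and tissue labels are
#' regenerated on the fixed template grid, and the exact inverse transform is
#' stored so that "normalisation" back to template space is exact.
#'
#' @param phantom A `cortical_phantom` whose configuration has a non-`NULL`
#'   `jitter` field (with `jitter = NULL` the phantom is returned unchanged).
#' @param subject_seed Integer seed controlling the drawn transform.
#' @return A transformed `cortical_phantom`.
#' @export
apply_subject_jitter <- function(phantom, subject_seed) {
  jit <- phantom$config$jitter
  if (is.null(jit) || (jit$translate_mm == 0 && jit$rotate_deg == 0))
    return(phantom)
  rng <- local_rng(subject_seed)
  tr <- rng$runif(3, -jit$translate_mm, jit$translate_mm)
  axis <- rng$rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- rng$runif(1, -jit$rotate_deg, jit$rotate_deg) * pi / 180
  R <- rotation_matrix(axis, ang)
  rigid_transform_phantom(phantom, R, tr)
}

rigid_transform_phantom <- function(phantom, R, tr) {
  ph <- phantom
  ph$vertices <- sweep(phantom$vertices %*% t(R), 2, tr, "+")
  colnames(ph$vertices) <- colnames(phantom$vertices)
  ph$normals <- phantom$normals %*% t(R)
  grid <- list(origin = phantom$origin, shape = phantom$grid_shape,
               affine = phantom$affine, voxel_mm = phantom$voxel_mm)
  maps <- vertex_voxel_maps(ph$vertices, grid)
  ph$vertex_to_voxel <- maps$vertex_to_voxel
  ph$voxel_to_vertices <- maps$voxel_to_vertices
  ph$voxel_tissue <- label_tissue(ph$vertices, ph$normals, grid, maps)
  elen <- sqrt(rowSums((ph$vertices[ph$edges[, 1], , drop = FALSE] -
                        ph$vertices[ph$edges[, 2], , drop = FALSE])^2))
  ph$edge_lengths <- elen
  igraph::E(ph$graph)$weight <- elen
  ph$transform <- list(R = R, t = tr, R_inv = t(R), t_inv = -as.numeric(t(R) %*% tr))
  ph
}

rotation_matrix <- function(axis, angle) {
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# scoped RNG: draws from a private stream without touching the global seed
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({ set.seed(seed); .Random.seed })
  draw <- function(fn) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    fn(...)
  }
  list(runif = draw(stats::runif), rnorm = draw(stats::rnorm),
       sample_int = draw(sample.int))
}

#' Linear voxel indices of all voxels with a given tissue label
#'
#' @param phantom A `cortical_phantom`.
#' @param label One of `"cortex"`, `"white"`, `"csf"`, `"background"`.
#' @return Integer vector of 1-based linear voxel indices.
#' @export
voxels_of_tissue <- function(phantom, label) {
  which(phantom$voxel_tissue == label)
}

# majority-vote region label per cortex voxel (linear index -> label)
voxel_region_labels <- function(phantom) {
  vapply(phantom$voxel_to_vertices, function(vs) {
    tab <- table(phantom$vertex_region[vs])
    names(tab)[which.max(tab)]
  }, character(1))
}
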