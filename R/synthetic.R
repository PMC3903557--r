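# Seeded procedural generator of ground-truthed vascular scenes.
#
# A scene is a set of binary tree-like structures arranged counter-clockwise
# around a central disk (the stand-in for the optic disk), the trunk of each
# tree starting just inside the disk boundary so its terminal becomes a root
# point. Tree complexity is measured by the classic Shreve order of the root
# segment, which for a tree equals its leaf count: LOW targets 2-5 leaves,
# MEDIUM 5-10, HIGH 11-16. The spread angle gamma between adjacent tree axes
# controls how much neighboring trees overlap, hence the crossover density.

.complexity_leaves <- function(complexity, rng_leaf = NULL) {
  rng <- switch(complexity,
                LOW = 2:5, MEDIUM = 5:10, HIGH = 11:16,
                stop("complexity must be LOW, MEDIUM or HIGH"))
  if (length(rng) == 1) rng else sample(rng, 1)
}

# random full binary tree topology with n_leaves leaves; returns nested list
.random_topology <- function(n_leaves) {
  if (n_leaves == 1) return(list(leaf = TRUE))
  left <- sample.int(n_leaves - 1, 1)
  list(leaf = FALSE,
       left = .random_topology(left),
       right = .random_topology(n_leaves - left))
}

# a gently curved branch polyline from `start` along `dir_deg`
.branch_polyline <- function(start, dir_deg, len, jitter) {
  step <- 2.5
  npt <- max(2L, ceiling(len / step))
  pts <- matrix(NA_real_, npt + 1, 2)
  pts[1, ] <- start
  ang <- dir_deg
  for (i in seq_len(npt)) {
    ang <- ang + stats::rnorm(1, 0, jitter)
    u <- c(-sin(deg2rad(ang)), cos(deg2rad(ang)))  # (drow, dcol), CCW angles
    pts[i + 1, ] <- pts[i, ] + step * u
  }
  list(poly = pts, end = pts[npt + 1, ], end_dir = ang)
}

#' Generate one synthetic vessel tree
#'
#' Recursive binary branching from a trunk: at each bifurcation the children
#' deviate to either side of the parent direction by angles drawn from
#' `branch_angle`, branch lengths shrink geometrically with depth, and
#' polylines carry mild curvature jitter. The leaf count (equal to the
#' classic Shreve order of the root segment) is drawn from the complexity
#' class range.
#'
#' @param complexity `"LOW"` (2-5 leaves), `"MEDIUM"` (5-10) or `"HIGH"`
#'   (11-16).
#' @param axis_deg direction of the tree axis in degrees (counter-clockwise,
#'   0 = +column direction).
#' @param origin trunk starting point `c(row, col)`.
#' @param trunk_len trunk length in pixels.
#' @param branch_angle `c(min, max)` child deviation range in degrees.
#' @param length_decay geometric branch-length decay per depth level.
#' @param jitter per-step direction jitter (degrees, sd).
#' @param n_leaves override the drawn leaf count.
#' @return list with `branches` (list of polylines with depth/leaf flags),
#'   `leaf_count`, `complexity`, `axis_deg`.
#' @export
generate_tree <- function(complexity = "MEDIUM", axis_deg = 0,
                          origin = c(0, 0), trunk_len = 60,
                          branch_angle = c(20, 40), length_decay = 0.78,
                          jitter = 1.0, n_leaves = NULL) {
  if (is.null(n_leaves)) n_leaves <- .complexity_leaves(complexity)
  if (n_leaves < 1) stop("n_leaves must be >= 1")
  topo <- .random_topology(n_leaves)
  branches <- list()
  grow <- function(node, start, dir_deg, len, depth) {
    br <- .branch_polyline(start, dir_deg, len, jitter)
    branches[[length(branches) + 1]] <<-
      list(poly = br$poly, depth = depth, leaf = node$leaf,
           id = length(branches) + 1L)
    this_id <- length(branches)
    if (!node$leaf) {
      d1 <- stats::runif(1, branch_angle[1], branch_angle[2])
      d2 <- stats::runif(1, branch_angle[1], branch_angle[2])
      child_len <- len * length_decay
      i1 <- grow(node$left, br$end, br$end_dir + d1, child_len, depth + 1)
      i2 <- grow(node$right, br$end, br$end_dir - d2, child_len, depth + 1)
      branches[[this_id]]$children <<- c(i1, i2)
    } else branches[[this_id]]$children <<- integer(0)
    this_id
  }
  grow(topo, origin, axis_deg, trunk_len, 0)
  list(branches = branches, leaf_count = n_leaves,
       complexity = complexity, axis_deg = axis_deg)
}

#' Compose a synthetic vascular scene
#'
#' Places `n_trees` trees counter-clockwise around a central disk with
#' successive angular separation `gamma`; trunks start just inside the disk
#' boundary. Overlapping strokes of different trees create crossovers; the
#' per-tree pixel truth keeps both identities at crossing pixels.
#'
#' @param n_trees number of trees (>= 1).
#' @param gamma spread angle between adjacent tree axes, degrees; when
#'   `n_trees * gamma > 360` the separation wraps to `360 / n_trees`.
#' @param complexities character vector (recycled) of complexity classes.
#' @param image_size `c(rows, cols)` canvas.
#' @param disk_radius optic-disk stand-in radius, pixels.
#' @param stroke_width rendered vessel width, pixels.
#' @param start_deg axis direction of the first tree.
#' @param seed optional integer; when given the scene is reproducible.
#' @param ... forwarded to [generate_tree()].
#' @return object of class `vessel_scene`: list with `mask` (logical),
#'   `disk` (logical), `tree_pixels` (list of linear pixel index vectors,
#'   one per tree), `truth_raster` (integer matrix, smallest owning tree id
#'   at shared pixels), `trees` (tree records), `n_trees`, `gamma`, `dim`.
#' @export
compose_scene <- function(n_trees = 8, gamma = 30,
                          complexities = c("LOW", "MEDIUM", "HIGH"),
                          image_size = c(512, 512), disk_radius = 40,
                          stroke_width = 3, start_deg = 0, seed = NULL, ...) {
  stopifnot(n_trees >= 1, gamma > 0, gamma <= 360)
  if (!is.null(seed)) set.seed(seed)
  gamma_requested <- gamma
  if (n_trees * gamma > 360) gamma <- 360 / n_trees
  complexities <- rep_len(complexities, n_trees)
  nr <- image_size[1]; nc <- image_size[2]
  center <- c((nr + 1) / 2, (nc + 1) / 2)
  max_reach <- min(nr, nc) / 2 - 6

  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    ax <- (start_deg + (t - 1) * gamma) %% 360
    origin <- center + (disk_radius - 2) *
      c(-sin(deg2rad(ax)), cos(deg2rad(ax)))
    tr <- generate_tree(complexities[t], axis_deg = ax, origin = origin,
                        ...)
    # rescale a tree that would leave the canvas
    reach <- max(vapply(tr$branches, function(b)
      max(sqrt(rowSums((b$poly - matrix(center, nrow(b$poly), 2,
                                        byrow = TRUE))^2))), numeric(1)))
    if (reach > max_reach) {
      f <- (max_reach - disk_radius) / (reach - disk_radius + 1e-9)
      warning("tree ", t, " exceeds canvas; rescaled by ", round(f, 2))
      for (i in seq_along(tr$branches)) {
        p <- tr$branches[[i]]$poly
        tr$branches[[i]]$poly <- matrix(origin, nrow(p), 2, byrow = TRUE) +
          f * (p - matrix(origin, nrow(p), 2, byrow = TRUE))
      }
    }
    trees[[t]] <- tr
  }

  offs <- disc_offsets((stroke_width - 1) / 2)
  mask <- matrix(FALSE, nr, nc)
  tree_pixels <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    tm <- matrix(FALSE, nr, nc)
    for (b in trees[[t]]$branches) {
      px <- rasterize_polyline(b$poly)
      for (q in seq_len(nrow(offs)))
        tm <- stamp_pixels(tm, cbind(px[, 1] + offs[q, 1], px[, 2] + offs[q, 2]))
    }
    tree_pixels[[t]] <- which(tm)
    mask <- mask | tm
  }
  rr <- matrix(seq_len(nr), nr, nc) - center[1]
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]
  disk <- rr^2 + cc^2 <= disk_radius^2
  truth <- matrix(0L, nr, nc)
  for (t in rev(seq_len(n_trees))) truth[tree_pixels[[t]]] <- t
  structure(list(mask = mask, disk = disk, tree_pixels = tree_pixels,
                 truth_raster = truth, trees = trees, n_trees = n_trees,
                 gamma = gamma, gamma_requested = gamma_requested,
                 dim = c(nr, nc)),
            class = "vessel_scene")
}

#' Scene of two straight vessels crossing
#'
#' Two straight vessels meet at `cross_angle` degrees at the canvas center;
#' the root region is a small disc around each vessel's proximal end, so
#' the scene has exactly two roots and a known collinear partition — the
#' canonical crossover benchmark.
#'
#' @param cross_angle angle between the two vessels at the crossing,
#'   degrees.
#' @param image_size canvas `c(rows, cols)`.
#' @param root_radius radius of the per-vessel root disc, pixels.
#' @param stroke_width vessel width, pixels.
#' @param arm half-length of each vessel, pixels.
#' @return a `vessel_scene` with `n_trees = 2`.
#' @export
x_crossing_scene <- function(cross_angle = 90, image_size = c(256, 256),
                             root_radius = 14, stroke_width = 3, arm = 70) {
  nr <- image_size[1]; nc <- image_size[2]
  P <- c((nr + 1) / 2, (nc + 1) / 2)
  half <- cross_angle / 2
  offs <- disc_offsets((stroke_width - 1) / 2)
  mask <- matrix(FALSE, nr, nc)
  disk <- matrix(FALSE, nr, nc)
  tree_pixels <- vector("list", 2)
  dirs <- c(half, -half)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (t in 1:2) {
    u <- c(-sin(deg2rad(dirs[t])), cos(deg2rad(dirs[t])))
    poly <- rbind(P - arm * u, P + arm * u)
    px <- rasterize_polyline(poly)
    tm <- matrix(FALSE, nr, nc)
    for (q in seq_len(nrow(offs)))
      tm <- stamp_pixels(tm, cbind(px[, 1] + offs[q, 1], px[, 2] + offs[q, 2]))
    tree_pixels[[t]] <- which(tm)
    mask <- mask | tm
    # center the root disc a little inward: skeletonization rounds the
    # stroke tip, pulling the terminal a few pixels along the vessel
    E <- P - (arm - 5) * u
    disk <- disk | ((rr - E[1])^2 + (cc - E[2])^2 <= root_radius^2)
  }
  truth <- matrix(0L, nr, nc)
  for (t in 2:1) truth[tree_pixels[[t]]] <- t
  structure(list(mask = mask, disk = disk, tree_pixels = tree_pixels,
                 truth_raster = truth, trees = NULL, n_trees = 2,
                 gamma = NA_real_, dim = c(nr, nc)),
            class = "vessel_scene")
}

#' Abstract segment graph of a generated tree
#'
#' Converts the branch structure of [generate_tree()] directly into a
#' `vessel_graph` (one 3-clique per bifurcation), bypassing rasterization —
#' useful for exercising the ordering rules on exactly known topologies.
#'
#' @param tree a [generate_tree()] result.
#' @return a `vessel_graph`; branch 1 (the trunk) is the root segment.
#' @export
tree_graph <- function(tree) {
  n <- length(tree$branches)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  igraph::V(g)$root <- seq_len(n) == 1L
  igraph::V(g)$leaf <- vapply(tree$branches, `[[`, logical(1), "leaf")
  cliques <- list()
  ei <- integer(0); ej <- integer(0); jn <- character(0)
  jid <- 0L
  for (b in tree$branches) {
    if (!length(b$children)) next
    jid <- jid + 1L
    mem <- sort(c(b$id, b$children))
    pt <- b$poly[nrow(b$poly), ]
    cliques[[jid]] <- list(junction = jid, point = pt, members = mem,
                           size = 3L,
                           rep_points = matrix(pt, 3, 2, byrow = TRUE))
    prs <- utils::combn(mem, 2)
    ei <- c(ei, prs[1, ]); ej <- c(ej, prs[2, ])
    jn <- c(jn, rep(as.character(jid), ncol(prs)))
  }
  if (length(ei)) {
    g <- igraph::add_edges(g, rbind(ei, ej))
    igraph::E(g)$junctions <- jn
  }
  structure(list(g = g, cliques = cliques, pass_throughs = list(),
                 root_ids = 1L, n = n, simplified = FALSE),
            class = "vessel_graph")
}

#' Generate the three controlled benchmark datasets
#'
#' Dataset 1 varies tree complexity over five mixes (all-low, half-low/
#' half-medium, all-medium, half-medium/half-high, all-high) at 8 trees and
#' gamma 30; dataset 2 varies the tree count over {3, 5, 7, 9, 11, 12} with
#' a third of trees per complexity class at gamma 30; dataset 3 varies gamma
#' over {360, 300, 240, 180, 120, 60} at 8 trees, a third per class.
#'
#' @param which dataset number (1, 2 or 3).
#' @param n_per_subset images generated per subset.
#' @param seed integer seed; image `i` of subset `s` uses `seed + 1000*s + i`.
#' @param out_dir optional directory; when given, each image's mask, disk
#'   and truth raster are written as PNG plus a manifest TSV.
#' @param image_size,disk_radius,stroke_width forwarded to [compose_scene()].
#' @return invisible list with `scenes` (list of `vessel_scene`) and
#'   `manifest` (data.frame).
#' @export
generate_benchmark_datasets <- function(which, n_per_subset = 10, seed = 1,
                                        out_dir = NULL,
                                        image_size = c(512, 512),
                                        disk_radius = 40, stroke_width = 3) {
  subsets <- switch(as.character(which),
    "1" = lapply(list(c("LOW"), c("LOW", "MEDIUM"), c("MEDIUM"),
                      c("MEDIUM", "HIGH"), c("HIGH")),
                 function(cx) list(n_trees = 8, gamma = 30, complexities = cx)),
    "2" = lapply(c(3, 5, 7, 9, 11, 12),
                 function(nt) list(n_trees = nt, gamma = 30,
                                   complexities = c("LOW", "MEDIUM", "HIGH"))),
    "3" = lapply(c(360, 300, 240, 180, 120, 60),
                 function(gm) list(n_trees = 8, gamma = gm,
                                   complexities = c("LOW", "MEDIUM", "HIGH"))),
    stop("which must be 1, 2 or 3"))
  scenes <- list(); rows <- list()
  for (s in seq_along(subsets)) {
    sp <- subsets[[s]]
    for (i in seq_len(n_per_subset)) {
      sd <- seed + 1000L * s + i
      sc <- compose_scene(n_trees = sp$n_trees, gamma = sp$gamma,
                          complexities = sp$complexities,
                          image_size = image_size,
                          disk_radius = disk_radius,
                          stroke_width = stroke_width, seed = sd)
      nm <- sprintf("d%d_s%d_i%03d", which, s, i)
      scenes[[nm]] <- sc
      rows[[nm]] <- data.frame(image = nm, subset = s,
                               n_trees = sp$n_trees, gamma = sp$gamma,
                               complexities = paste(sp$complexities,
                                                    collapse = "+"),
                               seed = sd)
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_mask(sc$mask, file.path(out_dir, paste0(nm, "_mask.png")))
        write_mask(sc$disk, file.path(out_dir, paste0(nm, "_disk.png")))
        png::writePNG(sc$truth_raster / 65535,
                      file.path(out_dir, paste0(nm, "_truth.png")))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir))
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(scenes = scenes, manifest = manifest))
}
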