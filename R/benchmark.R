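# Reproducible benchmark harnesses over the synthetic generator. These are
# the package's own controlled experiments: tracing accuracy across the
# tree-count benchmark under ablations (graph simplification on/off,
# affinity sharpness k), exact tracing on scenes of non-touching trees, and
# crossover recovery on straight-vessel crossings.

# rerun the tail of the pipeline (simplification onward) on shared stages
.trace_tail <- function(segs, orient, vg, om, params, simplify) {
  vg_used <- if (simplify) suppressWarnings(simplify_graph(vg, om)) else vg
  wts <- suppressWarnings(assemble_weight_matrix(vg_used, om, orient, segs,
                                                 params))
  S <- normalize_affinity(wts$W)
  Y <- suppressWarnings(propagate_labels(S, initial_labels(vg$n, segs$root_ids),
                                         params))
  labeling <- assign_tree_labels(Y, wts$W, segs$root_ids)
  structure(list(segments = segs, orient = orient, graph = vg_used,
                 graph_full = vg, ordering = om, weights = wts, Y = Y,
                 labeling = labeling, params = params),
            class = "vessel_trace")
}

#' Tracing accuracy benchmark across tree counts and ablations
#'
#' Generates tree-count benchmark scenes (counts from `tree_counts`, a third
#' of trees per complexity class, spread angle 30 degrees), traces each
#' under three configurations — full pipeline at `k = 5`, without graph
#' simplification, and at `k = 1` — and scores segment-label accuracy.
#' Scenes whose skeleton produces an unsupported junction (7 or more
#' segments) are skipped consistently across configurations.
#'
#' @param tree_counts integer vector of trees per scene.
#' @param n_per_subset scenes per tree count.
#' @param seed integer; scene `i` of subset `s` is seeded `seed + 1000*s + i`.
#' @param image_size,disk_radius forwarded to [compose_scene()].
#' @return data.frame with columns `subset`, `n_trees`, `image`, `config`
#'   (`sim_k5` / `nosim_k5` / `sim_k1`), `accuracy`, `crossover_accuracy`.
#' @export
benchmark_simplification <- function(tree_counts = c(3, 5, 7, 9, 11, 12),
                                     n_per_subset = 10, seed = 1,
                                     image_size = c(512, 512),
                                     disk_radius = 40) {
  params5 <- trace_params(k = 5)
  params1 <- trace_params(k = 1)
  rows <- list()
  for (s in seq_along(tree_counts)) {
    for (i in seq_len(n_per_subset)) {
      sc <- suppressWarnings(compose_scene(
        n_trees = tree_counts[s], gamma = 30,
        complexities = c("LOW", "MEDIUM", "HIGH"),
        image_size = image_size, disk_radius = disk_radius,
        seed = seed + 1000L * s + i))
      stages <- tryCatch({
        segs <- remove_spurious_segments(
          extract_segments(skeletonize_mask(sc$mask), disk = sc$disk),
          params5)
        orient <- end_orientations(segs, params = params5)
        vg <- build_graph(segs)
        om <- order_segments(vg, orient)
        list(segs = segs, orient = orient, vg = vg, om = om)
      }, error = function(e) NULL)
      if (is.null(stages)) next
      cfgs <- list(sim_k5 = list(params5, TRUE),
                   nosim_k5 = list(params5, FALSE),
                   sim_k1 = list(params1, TRUE))
      for (cf in names(cfgs)) {
        tr <- .trace_tail(stages$segs, stages$orient, stages$vg, stages$om,
                          cfgs[[cf]][[1]], cfgs[[cf]][[2]])
        ev <- evaluate_labeling(tr, sc)
        rows[[length(rows) + 1]] <-
          data.frame(subset = s, n_trees = tree_counts[s], image = i,
                     config = cf, accuracy = ev$accuracy,
                     crossover_accuracy = ev$crossover_accuracy)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scenes of mutually non-touching trees
#'
#' Draws scenes with few, widely spread trees and keeps only those where the
#' rendered trees share no pixel and every tree contributes exactly one root
#' (the generator's contract for isolated trees); candidate seeds are
#' advanced deterministically until `n` valid scenes are collected.
#'
#' @param n number of scenes.
#' @param seed base integer seed.
#' @param image_size,disk_radius forwarded to [compose_scene()].
#' @return list of `vessel_scene` objects.
#' @export
disjoint_scenes <- function(n = 50, seed = 1, image_size = c(384, 384),
                            disk_radius = 30) {
  out <- list()
  try_seed <- seed
  while (length(out) < n) {
    try_seed <- try_seed + 1L
    nt <- 2L + (try_seed %% 2L)
    sc <- suppressWarnings(compose_scene(
      n_trees = nt, gamma = 360 / nt,
      complexities = c("LOW", "MEDIUM"),
      image_size = image_size, disk_radius = disk_radius, seed = try_seed))
    prs <- utils::combn(nt, 2)
    touching <- any(vapply(seq_len(ncol(prs)), function(q)
      length(intersect(sc$tree_pixels[[prs[1, q]]],
                       sc$tree_pixels[[prs[2, q]]])) > 0, logical(1)))
    if (touching) next
    segs <- tryCatch(
      extract_segments(skeletonize_mask(sc$mask), disk = sc$disk),
      error = function(e) NULL)
    if (is.null(segs) || length(segs$root_ids) != nt) next
    out[[length(out) + 1]] <- sc
  }
  out
}

#' Crossover-recovery experiment on straight-vessel crossings
#'
#' Traces `n` two-vessel crossing scenes with crossing angles drawn
#' uniformly from `angle_range` and reports the fraction recovered with the
#' exact collinear partition (segment accuracy 1).
#'
#' @param n number of scenes.
#' @param seed integer seed.
#' @param angle_range degrees, `c(min, max)`.
#' @return list with `rate` (fraction perfectly recovered), `accuracies`.
#' @export
crossover_experiment <- function(n = 100, seed = 1,
                                 angle_range = c(60, 120)) {
  set.seed(seed)
  angles <- stats::runif(n, angle_range[1], angle_range[2])
  acc <- vapply(angles, function(a) {
    sc <- x_crossing_scene(cross_angle = a)
    tr <- suppressWarnings(trace_vessels(sc$mask, disk = sc$disk))
    evaluate_labeling(tr, sc)$accuracy
  }, numeric(1))
  list(rate = mean(acc == 1), accuracies = acc, angles = angles)
}
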