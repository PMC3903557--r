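# End-to-end tracing pipeline and the segment-level evaluation proxy.

#' Trace vessel trees in a binary mask
#'
#' Runs the full pipeline: skeletonization, spur removal, dual-graph
#' construction, modified Shreve ordering, graph simplification, affinity
#' assembly and label propagation, returning the per-segment tree labeling
#' together with every intermediate object and per-stage counts.
#'
#' @param mask binary vessel mask (logical or 0/1 matrix).
#' @param image optional grayscale image: enables Hessian-based orientations
#'   and, when `disk` is missing, optic-disk detection.
#' @param disk logical matrix marking the root (optic-disk) region; required
#'   unless `image` is supplied.
#' @param params a [trace_params()] list.
#' @param simplify apply graph simplification before weighting.
#' @param spur_removal remove short low-angle connector segments first.
#' @param verbose print per-stage counts.
#' @return object of class `vessel_trace`: list with `segments`, `orient`,
#'   `graph` (simplified when requested), `ordering`, `weights`, `Y`,
#'   `labeling`, `params`, `log`.
#' @export
trace_vessels <- function(mask, image = NULL, disk = NULL,
                          params = trace_params(), simplify = TRUE,
                          spur_removal = TRUE, verbose = FALSE) {
  if (is.null(disk)) {
    if (is.null(image))
      stop("either a disk mask or a grayscale image is required")
    disk <- detect_optic_disk(image)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  skel <- skeletonize_mask(mask)
  segs <- extract_segments(skel, disk = disk)
  say("stage skeletonize: %d skeleton px, %d segments, %d roots",
      sum(skel$skeleton), length(segs$segments), length(segs$root_ids))
  if (spur_removal) {
    n_before <- length(segs$segments)
    segs <- remove_spurious_segments(segs, params, image = image)
    say("stage spur removal: %d -> %d segments", n_before,
        length(segs$segments))
  }
  orient <- end_orientations(segs, image = image, params = params)
  vg <- build_graph(segs)
  csize <- vapply(vg$cliques, `[[`, numeric(1), "size")
  say("stage graph: %d nodes, %d edges, cliques by size: %s",
      vg$n, igraph::ecount(vg$g),
      paste(names(table(csize)), table(csize), sep = ":", collapse = " "))
  om <- order_segments(vg, orient)
  vg_used <- if (simplify) simplify_graph(vg, om) else vg
  wts <- assemble_weight_matrix(vg_used, om, orient, segs, params)
  S <- normalize_affinity(wts$W)
  Y0 <- initial_labels(vg$n, segs$root_ids)
  Y <- propagate_labels(S, Y0, params)
  say("stage propagate: %d iterations, residual %.2g",
      attr(Y, "iterations"), attr(Y, "residual"))
  labeling <- assign_tree_labels(Y, wts$W, segs$root_ids)
  log <- list(n_segments = vg$n, n_edges = igraph::ecount(vg_used$g),
              n_edges_full = igraph::ecount(vg$g),
              cliques_by_size = table(csize),
              iterations = attr(Y, "iterations"),
              residual = attr(Y, "residual"))
  structure(list(segments = segs, orient = orient, graph = vg_used,
                 graph_full = vg, ordering = om, weights = wts, Y = Y,
                 labeling = labeling, params = params, log = log),
            class = "vessel_trace")
}

# majority-overlap truth tree id per segment; crossing pixels count for all
# owners. Returns NA where a segment overlaps no tree.
segment_truth_ids <- function(segs, scene) {
  n <- length(segs$segments)
  nr <- scene$dim[1]
  member <- lapply(scene$tree_pixels, function(px) {
    m <- matrix(FALSE, scene$dim[1], scene$dim[2]); m[px] <- TRUE; m
  })
  out <- rep(NA_integer_, n)
  for (sg in segs$segments) {
    lin <- (sg$pixels[, 2] - 1L) * nr + sg$pixels[, 1]
    ov <- vapply(member, function(m) sum(m[lin]), numeric(1))
    if (max(ov) > 0) out[sg$id] <- which.max(ov)
  }
  out
}

#' Evaluate a tree labeling against scene ground truth
#'
#' Maps each predicted segment to a truth tree by majority pixel overlap,
#' finds the best one-to-one correspondence between predicted tree labels
#' and truth trees (maximum-weight bipartite matching on the agreement
#' matrix), and reports segment-level accuracy, per-tree precision/recall,
#' and the crossover-resolution accuracy of 4/5/6-cliques (the fraction
#' whose favorable pairing / grouping joins segments of the same truth
#' tree).
#'
#' @param trace a `vessel_trace` from [trace_vessels()].
#' @param scene the `vessel_scene` that produced the mask.
#' @return list with `accuracy`, `n_segments`, `per_tree`
#'   (data.frame truth tree / precision / recall), `crossover_accuracy`,
#'   `n_crossover_cliques`, `mapping` (predicted label -> truth tree).
#' @export
evaluate_labeling <- function(trace, scene) {
  segs <- trace$segments
  lab <- trace$labeling$label
  if (all(is.na(lab))) stop("empty prediction: no segment carries a label")
  truth <- segment_truth_ids(segs, scene)
  keep <- !is.na(truth)
  npred <- trace$labeling$n_trees
  ntruth <- scene$n_trees
  C <- matrix(0, npred, ntruth)
  for (i in which(keep & !is.na(lab))) C[lab[i], truth[i]] <- C[lab[i], truth[i]] + 1

  mapping <- .best_assignment(C)
  agree <- sum(vapply(which(keep), function(i) {
    !is.na(lab[i]) && !is.na(mapping[lab[i]]) && mapping[lab[i]] == truth[i]
  }, logical(1)))
  accuracy <- agree / sum(keep)

  per_tree <- data.frame(truth_tree = seq_len(ntruth),
                         precision = NA_real_, recall = NA_real_)
  for (t in seq_len(ntruth)) {
    pl <- which(mapping == t)
    pred_t <- keep & !is.na(lab) & lab %in% pl
    true_t <- keep & truth == t
    per_tree$precision[t] <- if (any(pred_t)) sum(pred_t & true_t) / sum(pred_t) else NA
    per_tree$recall[t] <- if (any(true_t)) sum(pred_t & true_t) / sum(true_t) else NA
  }

  cx <- .crossover_accuracy(trace, truth)
  list(accuracy = accuracy, n_segments = sum(keep), per_tree = per_tree,
       crossover_accuracy = cx$acc, n_crossover_cliques = cx$n,
       mapping = mapping)
}

# maximum-weight one-to-one assignment between rows and columns of C
.best_assignment <- function(C) {
  npred <- nrow(C); ntruth <- ncol(C)
  idx <- which(C > 0, arr.ind = TRUE)
  mapping <- rep(NA_integer_, npred)
  if (!nrow(idx)) return(mapping)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, npred), rep(TRUE, ntruth)),
    edges = as.vector(t(cbind(idx[, 1], npred + idx[, 2]))))
  m <- igraph::max_bipartite_match(g, weights = C[idx])
  mt <- m$matching[seq_len(npred)]
  ok <- !is.na(mt)
  mapping[ok] <- mt[ok] - npred
  mapping
}

.crossover_accuracy <- function(trace, truth) {
  vg <- trace$graph_full
  wts <- trace$weights
  n <- 0L; good <- 0L
  for (cq in vg$cliques) {
    if (cq$size == 4) {
      pr <- wts$pairings[[as.character(cq$junction)]]
      if (is.null(pr)) next
      n <- n + 1L
      ok <- all(vapply(seq_len(nrow(pr)), function(q) {
        a <- truth[pr$i[q]]; b <- truth[pr$j[q]]
        !is.na(a) && !is.na(b) && a == b
      }, logical(1)))
      if (ok) good <- good + 1L
    } else if (cq$size >= 5) {
      gr <- wts$groups[[as.character(cq$junction)]]
      if (is.null(gr)) next
      n <- n + 1L
      ids <- as.integer(names(gr))
      tv <- truth[ids]
      if (!anyNA(tv) &&
          all(tapply(tv, gr, function(x) length(unique(x)) == 1)) &&
          length(unique(tapply(tv, gr, `[`, 1))) == length(unique(gr)))
        good <- good + 1L
    }
  }
  list(acc = if (n > 0) good / n else NA_real_, n = n)
}
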