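# File-format plumbing: masks and radius maps, tabular exports of segments,
# graphs, orderings, weights and labels, SWC trees, and colored overlays.

#' Read / write binary masks
#'
#' Masks travel as single-channel PNG or TIFF with values 0/255 (any value
#' above 0.5 of full scale reads as vessel).
#'
#' @param path file path; format chosen by extension (.png, .tif/.tiff).
#' @param mask logical matrix.
#' @return `read_mask`: logical matrix.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported mask format: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  switch(ext,
         png = png::writePNG(img, path),
         tif = , tiff = tiff::writeTIFF(img, path),
         stop("unsupported mask format: ", ext))
  invisible(path)
}

#' Write a radius map as 32-bit float TIFF
#' @param radius numeric matrix; @param path output .tif path.
#' @export
write_radius_tiff <- function(radius, path) {
  tiff::writeTIFF(radius / max(1, max(radius)), path, bits.per.sample = 32)
  invisible(path)
}

#' Tabular exports
#'
#' `write_segments_tsv` writes one row per segment (id, end types, length,
#' mean radius, run-length encoded pixel chain); `write_graph_tsv` writes
#' the edge list plus a junction table; `write_ordering_tsv` the per-segment
#' order and rule tag; `write_labels_tsv` the final labeling;
#' `write_weights_mtx` the affinity matrix in Matrix Market format with a
#' per-edge TSV companion.
#'
#' @param segs,vg,om,wts,labeling pipeline objects.
#' @param path output path (TSV; for weights, the .mtx path).
#' @name exports
#' @export
write_segments_tsv <- function(segs, path) {
  rows <- lapply(segs$segments, function(sg) {
    data.frame(segment_id = sg$id,
               end1_type = sg$end_type[1], end2_type = sg$end_type[2],
               length = sg$length, mean_radius = mean(sg$radii),
               pixels = paste(sg$pixels[, 1], sg$pixels[, 2],
                              sep = ",", collapse = ";"))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname exports
#' @export
write_graph_tsv <- function(vg, path) {
  el <- graph_edges(vg)
  df <- data.frame(i = el[, 1], j = el[, 2],
                   junctions = igraph::E(vg$g)$junctions,
                   simplified = vg$simplified)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jp <- file.path(dirname(path), sub("\\.tsv$", "_junctions.tsv",
                                     basename(path)))
  jd <- do.call(rbind, lapply(vg$cliques, function(cq)
    data.frame(junction = cq$junction, row = cq$point[1], col = cq$point[2],
               size = cq$size, members = paste(cq$members, collapse = ","))))
  if (!is.null(jd))
    utils::write.table(jd, jp, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname exports
#' @export
write_ordering_tsv <- function(om, path) {
  df <- data.frame(segment_id = seq_along(om$mu), mu = om$mu, rule = om$rule)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname exports
#' @export
write_weights_mtx <- function(wts, path) {
  Matrix::writeMM(methods::as(wts$W, "CsparseMatrix"), path)
  tp <- sub("\\.mtx$", "_edges.tsv", path)
  utils::write.table(wts$edge_table, tp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname exports
#' @export
write_labels_tsv <- function(labeling, path) {
  df <- data.frame(segment_id = seq_along(labeling$label),
                   tree_id = labeling$label, score = labeling$score)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Colored overlay of a labeling
#'
#' @param trace a `vessel_trace`; @param path output PNG.
#' @export
write_overlay_png <- function(trace, path) {
  dm <- trace$segments$dim
  img <- array(0, c(dm[1], dm[2], 3))
  cols <- grDevices::col2rgb(grDevices::rainbow(max(1, trace$labeling$n_trees))) / 255
  for (sg in trace$segments$segments) {
    l <- trace$labeling$label[sg$id]
    rgb <- if (is.na(l)) c(0.4, 0.4, 0.4) else cols[, l]
    for (ch in 1:3) {
      pl <- cbind(sg$pixels, ch)
      img[pl] <- rgb[ch]
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Export traced trees as SWC files
#'
#' One SWC file per traced tree (7 columns: id, type, x, y, z = 0, radius,
#' parent), rooted at the disk-adjacent point, after resolving
#' self-intersections so the structure is a proper tree.
#'
#' @param trace a `vessel_trace`.
#' @param dir output directory; files are named `tree_<k>.swc`.
#' @return invisible character vector of file paths.
#' @export
export_swc <- function(trace, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  segs <- trace$segments
  lab <- trace$labeling$label
  paths <- character(0)
  for (k in seq_len(trace$labeling$n_trees)) {
    ids <- which(lab == k)
    root <- segs$root_ids[k]
    if (!root %in% ids) ids <- c(root, ids)
    rs <- resolve_self_intersections(ids, root, trace$graph, trace$orient)
    lines <- .swc_lines(rs, segs)
    p <- file.path(dir, sprintf("tree_%d.swc", k))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

.swc_lines <- function(rs, segs) {
  parent <- rs$parent
  ids <- as.integer(names(parent))
  lines <- character(0)
  node_id <- 0L
  # last emitted SWC node of each segment, and its attachment side
  seg_tail <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  emit <- function(sid, parent_node) {
    sg <- segs$segments[[sid]]
    chain <- sg$pixels
    # orient the chain away from the attachment (ROOT end first for roots)
    flip <- if (is.na(parent[as.character(sid)])) {
      which(sg$end_type == "ROOT")[1] %in% 2L
    } else {
      pj <- seg_tail[as.character(parent[as.character(sid)])]
      FALSE
    }
    if (isTRUE(flip)) chain <- chain[rev(seq_len(nrow(chain))), , drop = FALSE]
    pn <- parent_node
    for (q in seq_len(nrow(chain))) {
      node_id <<- node_id + 1L
      lines <<- c(lines, sprintf("%d 2 %.1f %.1f 0.0 %.2f %d",
                                 node_id, chain[q, 2], chain[q, 1],
                                 max(0.5, sg$radii[q]), pn))
      pn <- node_id
    }
    seg_tail[as.character(sid)] <<- node_id
  }
  # BFS emit: roots first, then children in parent order
  todo <- ids[is.na(parent)]
  done <- character(0)
  for (r in todo) emit(r, -1L)
  done <- as.character(todo)
  repeat {
    nxt <- ids[!as.character(ids) %in% done &
               as.character(parent[as.character(ids)]) %in% done]
    if (!length(nxt)) break
    for (s in nxt) emit(s, seg_tail[as.character(parent[as.character(s)])])
    done <- c(done, as.character(nxt))
  }
  lines
}
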