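# The dual graph: segments are nodes, a shared junction yields a clique of
# edges among its incident segments. Junctions with 3-6 incident segments are
# the clique taxonomy the affinity rules understand; 2-segment junctions are
# plain pass-through edges; 7 or more incident segments abort.

#' Build the undirected segment graph
#'
#' @param segs a `segment_set`.
#' @return object of class `vessel_graph`: list with `g` (igraph, vertices =
#'   segment ids with `root` attribute), `cliques` (list of junction cliques:
#'   `junction`, `point`, `members` (3-6 segment ids), `size`, `rep_points`
#'   (member end pixels adjacent to the junction)), `pass_throughs`
#'   (2-segment junctions), `root_ids`, `n`, `simplified` flag.
#' @export
build_graph <- function(segs) {
  stopifnot(inherits(segs, "segment_set"))
  n <- length(segs$segments)
  members <- junction_members(segs)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  igraph::V(g)$root <- seq_len(n) %in% segs$root_ids
  igraph::V(g)$leaf <- vapply(segs$segments,
                              function(sg) any(sg$end_type == "END"),
                              logical(1))

  edge_key <- character(0)
  ei <- integer(0); ej <- integer(0); ejunc <- character(0)
  cliques <- list(); pass <- list()
  jt <- segs$junctions
  ord <- order(jt$row, jt$col, jt$id)
  for (j in jt$id[ord]) {
    mem <- members[[j]]
    m <- length(mem)
    if (m == 0 || m == 1) next
    if (m >= 7)
      stop(sprintf("unsupported junction with %d incident segments at (%.1f, %.1f)",
                   m, jt$row[j], jt$col[j]))
    pt <- c(jt$row[j], jt$col[j])
    if (m == 2) {
      pass[[length(pass) + 1]] <- list(junction = j, point = pt, members = mem)
    } else {
      rp <- t(vapply(mem, function(s) .end_pixel_at(segs$segments[[s]], j, pt),
                     numeric(2)))
      cliques[[length(cliques) + 1]] <-
        list(junction = j, point = pt, members = mem, size = m, rep_points = rp)
    }
    prs <- utils::combn(mem, 2)
    for (q in seq_len(ncol(prs))) {
      a <- prs[1, q]; b <- prs[2, q]
      key <- paste(a, b)
      hit <- match(key, edge_key)
      if (is.na(hit)) {
        edge_key <- c(edge_key, key)
        ei <- c(ei, a); ej <- c(ej, b); ejunc <- c(ejunc, as.character(j))
      } else {
        ejunc[hit] <- paste(ejunc[hit], j)  # loop pair seen at two junctions
      }
    }
  }
  if (length(ei)) {
    g <- igraph::add_edges(g, rbind(ei, ej))
    igraph::E(g)$junctions <- ejunc
  }
  structure(list(g = g, cliques = cliques, pass_throughs = pass,
                 root_ids = segs$root_ids, n = n, simplified = FALSE),
            class = "vessel_graph")
}

# the end pixel of a segment adjacent to junction j (fallback: nearest end)
.end_pixel_at <- function(sg, j, jpt) {
  m <- nrow(sg$pixels)
  e <- which(sg$end_junction == j)
  if (!length(e)) {
    d1 <- sum((sg$pixels[1, ] - jpt)^2)
    d2 <- sum((sg$pixels[m, ] - jpt)^2)
    e <- if (d1 <= d2) 1L else 2L
  }
  as.numeric(sg$pixels[if (e[1] == 1L) 1L else m, ])
}

#' Junction cliques of a vessel graph
#'
#' @param vg a `vessel_graph`.
#' @return the list of junction cliques (sizes 3-6), sorted by junction
#'   point for determinism.
#' @export
detect_junction_cliques <- function(vg) {
  stopifnot(inherits(vg, "vessel_graph"))
  vg$cliques
}

# undirected edge list of a vessel graph as a 2-col matrix of segment ids
graph_edges <- function(vg) {
  el <- igraph::as_edgelist(vg$g, names = FALSE)
  if (nrow(el)) t(apply(el, 1, sort)) else matrix(0L, 0, 2)
}

has_edge <- function(vg, a, b) {
  igraph::are_adjacent(vg$g, a, b)
}
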