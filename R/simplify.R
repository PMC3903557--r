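# Per-clique edge pruning. Within each junction clique the nodes attaining
# the maximal Shreve order (V_CH) are hierarchically above the rest (V_CNH);
# only the complete bipartite edge set V_CH x V_CNH survives, removing the
# redundant sibling edges. Edges outside cliques are untouched.

#' Simplify the segment graph using the ordering
#'
#' @param vg a `vessel_graph` whose clique members are all ordered.
#' @param om an `ordering_map` from [order_segments()].
#' @return the simplified `vessel_graph` (`simplified = TRUE`); node set and
#'   junction bookkeeping unchanged.
#' @export
simplify_graph <- function(vg, om) {
  stopifnot(inherits(vg, "vessel_graph"), inherits(om, "ordering_map"))
  drop <- character(0); keep <- character(0)
  for (cq in vg$cliques) {
    mem <- cq$members
    if (anyNA(om$mu[mem]))
      stop("clique at junction ", cq$junction, " has unordered members")
    mx <- max(om$mu[mem])
    vch <- mem[om$mu[mem] == mx]
    vcnh <- setdiff(mem, vch)
    prs <- utils::combn(mem, 2)
    for (q in seq_len(ncol(prs))) {
      a <- prs[1, q]; b <- prs[2, q]
      key <- paste(min(a, b), max(a, b))
      bip <- (a %in% vch) != (b %in% vch)
      if (length(vcnh) == 0) {
        warning("clique at junction ", cq$junction,
                " has all members at equal order; edges kept")
        keep <- c(keep, key)
      } else if (bip) keep <- c(keep, key) else drop <- c(drop, key)
    }
  }
  drop <- setdiff(drop, keep)  # loop-pair edges survive if any junction keeps
  if (length(drop)) {
    el <- igraph::as_edgelist(vg$g, names = FALSE)
    keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    vg$g <- igraph::delete_edges(vg$g, which(keys %in% drop))
  }
  vg$simplified <- TRUE
  vg
}
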