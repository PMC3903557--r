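# Transductive label propagation over the weighted segment graph, and the
# post-processing that turns soft label scores into a tree partition.

#' Symmetrically normalize an affinity matrix
#'
#' `S = D^(-1/2) W D^(-1/2)` with `D` the diagonal of row sums; zero-degree
#' rows (isolated nodes) stay zero. For mixing `alpha < 1` the spectral
#' radius of `alpha * S` is below 1, so propagation converges.
#'
#' @param W symmetric nonnegative matrix (dense or `Matrix`), zero diagonal.
#' @return sparse normalized matrix `S`.
#' @export
normalize_affinity <- function(W) {
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  d <- Matrix::rowSums(W)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Matrix::Diagonal(x = dinv) %*% W %*% Matrix::Diagonal(x = dinv)
}

#' Initial label matrix from root segments
#'
#' @param n number of segments; @param root_ids root segment ids (tree
#'   labels are assigned in this order).
#' @return n x length(root_ids) matrix, one-hot on root rows.
#' @export
initial_labels <- function(n, root_ids) {
  Y0 <- matrix(0, n, length(root_ids))
  for (c in seq_along(root_ids)) Y0[root_ids[c], c] <- 1
  Y0
}

#' Iterative label propagation
#'
#' Iterates `Y <- alpha * S %*% Y + (1 - alpha) * Y0` from `Y0` until the
#' Frobenius norm of the update drops to `epsilon` (or `max_iters`).
#'
#' @param S normalized affinity from [normalize_affinity()].
#' @param Y0 initial label matrix.
#' @param params a [trace_params()] list (`alpha`, `epsilon`, `max_iters`).
#' @return the converged label matrix, with attributes `iterations` and
#'   `residual`.
#' @export
propagate_labels <- function(S, Y0, params = trace_params()) {
  alpha <- params$alpha
  Y <- Y0
  it <- 0L; res <- Inf
  while (it < params$max_iters) {
    Ynew <- as.matrix(alpha * (S %*% Y)) + (1 - alpha) * Y0
    res <- sqrt(sum((Ynew - Y)^2))
    Y <- Ynew
    it <- it + 1L
    if (res <= params$epsilon) break
  }
  if (res > params$epsilon)
    warning(sprintf("propagation hit max_iters (%d); residual %.3g",
                    params$max_iters, res))
  attr(Y, "iterations") <- it
  attr(Y, "residual") <- res
  Y
}

#' Closed-form propagation limit
#'
#' Returns `(1 - alpha) * (I - alpha S)^(-1) Y0`, the fixed point of the
#' iteration, via a sparse linear solve. Serves as the independent check of
#' [propagate_labels()].
#'
#' @param W affinity matrix (unnormalized); @param Y0 initial labels;
#'   @param alpha mixing coefficient in (0, 1).
#' @return dense label matrix.
#' @export
propagate_closed_form <- function(W, Y0, alpha = 0.9) {
  stopifnot(alpha > 0, alpha < 1)
  S <- normalize_affinity(W)
  n <- nrow(S)
  as.matrix(Matrix::solve(Matrix::Diagonal(n) - alpha * S, (1 - alpha) * Y0))
}

#' Harden soft label scores into a tree labeling
#'
#' Per segment the winning column is taken; all-zero rows stay unassigned
#' (components without a root). Ties go to the label of the
#' strongest-affinity neighbor, then to the lowest label id. Root rows are
#' forced to their own tree (with a warning if the argmax disagreed).
#'
#' @param Y propagated label matrix; @param W affinity matrix used (for tie
#'   breaks); @param root_ids root segment ids.
#' @return object of class `tree_labeling`: list with `label` (integer
#'   vector, NA = unassigned), `score` (winning row value), `n_trees`.
#' @export
assign_tree_labels <- function(Y, W, root_ids) {
  n <- nrow(Y)
  lab <- rep(NA_integer_, n)
  score <- rep(0, n)
  W <- as(Matrix::Matrix(W, sparse = TRUE), "CsparseMatrix")
  for (i in seq_len(n)) {
    row <- Y[i, ]
    mx <- max(row)
    if (mx <= 0) next
    win <- which(row >= mx - 1e-12)
    if (length(win) > 1) {
      nb <- which(W[i, ] > 0)
      nb <- nb[order(-W[i, nb])]
      for (j in nb) {
        jl <- which.max(Y[j, ])
        if (Y[j, jl] > 0 && jl %in% win) { win <- jl; break }
      }
      win <- win[1]
    }
    lab[i] <- win
    score[i] <- mx
  }
  for (c in seq_along(root_ids)) {
    r <- root_ids[c]
    if (!is.na(lab[r]) && lab[r] != c)
      warning("root segment ", r, " argmax disagreed with its own tree; forced")
    lab[r] <- c
    score[r] <- max(score[r], Y[r, c])
  }
  structure(list(label = lab, score = score, n_trees = length(root_ids)),
            class = "tree_labeling")
}

#' Resolve self-intersections of one traced tree
#'
#' A traced tree may still contain cycles where its own branches cross. The
#' labeled subgraph is reduced to a proper rooted tree by a maximum-angle
#' spanning tree: every edge carries the junction angle between its two
#' segments and the spanning tree keeps the smoothest continuations, so at a
#' conflicted junction a segment stays attached to the chain forming the
#' larger angle with it. The result is acyclic by construction.
#'
#' @param tree_ids segment ids belonging to one tree (including its root).
#' @param root_id the tree's root segment id.
#' @param vg the (simplified) `vessel_graph`.
#' @param orient `end_orientations`.
#' @return list with `parent` (named integer vector over `tree_ids`; the
#'   root maps to NA) and `root`.
#' @export
resolve_self_intersections <- function(tree_ids, root_id, vg, orient) {
  sub <- igraph::induced_subgraph(vg$g, tree_ids)
  ids <- as.integer(igraph::V(sub)$name)
  el <- igraph::as_edgelist(sub, names = TRUE)
  if (nrow(el)) {
    th <- vapply(seq_len(nrow(el)), function(q) {
      a <- as.integer(el[q, 1]); b <- as.integer(el[q, 2])
      jid <- .shared_junction(vg, a, b)
      if (is.na(jid)) 90 else .clique_angle(orient, a, b, jid)
    }, numeric(1))
    # igraph::mst minimizes: negate to keep large-angle (smooth) edges
    sub <- igraph::mst(sub, weights = -th)
  }
  rv <- which(ids == root_id)
  parent <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  if (length(rv)) {
    bf <- igraph::bfs(sub, root = rv, unreachable = FALSE, father = TRUE)
    fa <- as.integer(bf$father)
    reach <- !is.na(fa) | seq_along(ids) == rv
    parent[reach] <- ifelse(is.na(fa[reach]), NA_integer_, ids[fa[reach]])
  }
  list(parent = parent, root = root_id)
}
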