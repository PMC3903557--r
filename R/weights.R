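# Assembly of the symmetric affinity matrix W over segments.
#
# Each junction clique assigns weights to its (surviving) edges by
# size-specific rules built from the shape functions f1/f2/f3 and the
# junction angles between outward end orientations:
#   3-clique  case A (ordinary branching)     w = exp(-f1(theta))
#             case B/C (termination/artifact) the two connector edges are
#             contrasted: the better-aligned pair exp(-f1), the other
#             exp(+f1)
#   4-clique  the chord pairing that intersects inside the convex hull of
#             the four entry pixels marks the favorable pairs exp(-f2);
#             everything else exp(-f3)
#   5/6-clique the two top-order members seed two groups, remaining members
#             attach to the seed with the larger junction angle; in-group
#             edges exp(-f1), cross-group exp(+f1).

# angle between two members' outward orientations at a clique's junction
.clique_angle <- function(orient, a, b, jid) {
  angle_between(orientation_at(orient, a, jid),
                orientation_at(orient, b, jid))
}

#' Classify a 3-clique
#'
#' A 3-clique that fired by the ordinary ordering rule is an ordinary
#' branching (case A). One that needed the deadlock rule hides either a
#' vessel terminating on another (case B) or a skeletonization artifact of a
#' crossover (case C); the two are told apart by the connector length: a
#' connector of at most `C_critical` pixels is case C.
#'
#' @param cq one clique record from a `vessel_graph`.
#' @param om an `ordering_map`.
#' @param segs the `segment_set`.
#' @param params a [trace_params()] list.
#' @return list with `case` in `"A"/"B"/"C"` and `connector` (segment id or
#'   NA for case A).
#' @export
classify_three_clique <- function(cq, om, segs, params = trace_params()) {
  stopifnot(length(cq$members) == 3)
  fired <- om$clique_rule[cq$junction]
  if (is.na(fired) || fired != "DEADLOCK")
    return(list(case = "A", connector = NA_integer_))
  lens <- vapply(cq$members, function(s) segs$segments[[s]]$length, numeric(1))
  both_branch <- vapply(cq$members, function(s)
    all(segs$segments[[s]]$end_type == "BRANCH"), logical(1))
  short <- which(both_branch & lens <= params$C_critical)
  if (length(short))
    return(list(case = "C", connector = cq$members[short[which.min(lens[short])]]))
  seed <- om$deadlock_seed[cq$junction]
  if (is.na(seed)) seed <- cq$members[which.min(om$mu[cq$members])]
  list(case = "B", connector = seed)
}

#' Weight assignments for a 3-clique
#'
#' @param cq clique record; @param case_info result of
#'   [classify_three_clique()]; @param orient `end_orientations`;
#'   @param params [trace_params()].
#' @return data.frame with columns `i`, `j`, `theta`, `rule`, `w`.
#' @export
weight_three_clique <- function(cq, case_info, orient, params = trace_params()) {
  jid <- cq$junction
  if (case_info$case == "A") {
    prs <- utils::combn(cq$members, 2)
    th <- apply(prs, 2, function(p) .clique_angle(orient, p[1], p[2], jid))
    return(data.frame(i = prs[1, ], j = prs[2, ], theta = th,
                      rule = "C3_A", w = exp(-eval_f1(th, params))))
  }
  cn <- case_info$connector
  others <- sort(setdiff(cq$members, cn))
  i <- others[1]; j <- others[2]
  psi2 <- .clique_angle(orient, i, cn, jid)
  psi1 <- .clique_angle(orient, j, cn, jid)
  if (psi1 >= psi2) {
    data.frame(i = c(j, i), j = c(cn, cn), theta = c(psi1, psi2),
               rule = paste0("C3_", case_info$case, c("_fav", "_unfav")),
               w = c(exp(-eval_f1(psi1, params)), exp(eval_f1(psi2, params))))
  } else {
    data.frame(i = c(i, j), j = c(cn, cn), theta = c(psi2, psi1),
               rule = paste0("C3_", case_info$case, c("_fav", "_unfav")),
               w = c(exp(-eval_f1(psi2, params)), exp(eval_f1(psi1, params))))
  }
}

# strict segment-segment intersection (shared interior point)
.segments_intersect <- function(a, b, c, d) {
  orient3 <- function(p, q, r)
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  o1 <- orient3(a, b, c); o2 <- orient3(a, b, d)
  o3 <- orient3(c, d, a); o4 <- orient3(c, d, b)
  (o1 * o2 < 0) && (o3 * o4 < 0)
}

#' Chord pairing of a 4-clique
#'
#' Among the three ways of pairing the four junction-entry pixels into two
#' chords, returns the one whose chords intersect inside the convex hull of
#' the four points (for points in convex position exactly one does). Falls
#' back to maximizing the sum of junction angles when the geometry is
#' degenerate.
#'
#' @param pts 4 x 2 matrix of entry-pixel coordinates (clique order).
#' @param angles optional function(a, b) giving the junction angle between
#'   members a and b (indices 1..4), used for the degenerate fallback.
#' @return list with `pairs` (2 x 2 matrix of member indices, one row per
#'   favorable pair) and `degenerate` flag.
#' @export
four_clique_pairing <- function(pts, angles = NULL) {
  pairings <- list(rbind(c(1, 2), c(3, 4)),
                   rbind(c(1, 3), c(2, 4)),
                   rbind(c(1, 4), c(2, 3)))
  hit <- vapply(pairings, function(pr)
    .segments_intersect(pts[pr[1, 1], ], pts[pr[1, 2], ],
                        pts[pr[2, 1], ], pts[pr[2, 2], ]), logical(1))
  if (sum(hit) == 1)
    return(list(pairs = pairings[[which(hit)]], degenerate = FALSE))
  if (is.null(angles))
    return(list(pairs = pairings[[2]], degenerate = TRUE))
  sc <- vapply(pairings, function(pr)
    angles(pr[1, 1], pr[1, 2]) + angles(pr[2, 1], pr[2, 2]), numeric(1))
  list(pairs = pairings[[which.max(sc)]], degenerate = TRUE)
}

#' Weight assignments for a 4-clique
#'
#' @param cq clique record (with `rep_points`); @param orient
#'   `end_orientations`; @param params [trace_params()].
#' @return data.frame as in [weight_three_clique()].
#' @export
weight_four_clique <- function(cq, orient, params = trace_params()) {
  jid <- cq$junction
  mem <- cq$members
  ang <- function(a, b) .clique_angle(orient, mem[a], mem[b], jid)
  pairing <- four_clique_pairing(cq$rep_points, angles = ang)
  if (pairing$degenerate)
    warning("degenerate 4-clique geometry at junction ", jid,
            "; using angle-based pairing")
  fav <- pairing$pairs
  fav_key <- paste(pmin(mem[fav[, 1]], mem[fav[, 2]]),
                   pmax(mem[fav[, 1]], mem[fav[, 2]]))
  prs <- utils::combn(mem, 2)
  out <- data.frame(i = prs[1, ], j = prs[2, ], theta = NA_real_,
                    rule = NA_character_, w = NA_real_)
  for (q in seq_len(nrow(out))) {
    th <- .clique_angle(orient, out$i[q], out$j[q], jid)
    out$theta[q] <- th
    if (paste(out$i[q], out$j[q]) %in% fav_key) {
      out$rule[q] <- "C4_fav";   out$w[q] <- exp(-eval_f2(th, params))
    } else {
      out$rule[q] <- "C4_unfav"; out$w[q] <- exp(-eval_f3(th, params))
    }
  }
  out
}

#' Weight assignments for a 5- or 6-clique
#'
#' @param cq clique record; @param om `ordering_map`; @param orient
#'   `end_orientations`; @param params [trace_params()].
#' @return data.frame as in [weight_three_clique()] plus a `group`
#'   attribute: a named vector mapping each member to its group seed.
#' @export
weight_five_six_clique <- function(cq, om, orient, params = trace_params()) {
  jid <- cq$junction
  mem <- cq$members
  mus <- om$mu[mem]
  ord <- order(-mus, mem)
  if (length(unique(mus)) < 2 && length(mem) > 2)
    warning("5/6-clique at junction ", jid,
            " has tied orders; seeding by smallest ids")
  seeds <- mem[ord[1:2]]
  group <- stats::setNames(integer(length(mem)), mem)
  group[as.character(seeds)] <- c(1L, 2L)
  for (s in setdiff(mem, seeds)) {
    th1 <- .clique_angle(orient, s, seeds[1], jid)
    th2 <- .clique_angle(orient, s, seeds[2], jid)
    group[as.character(s)] <- if (th1 >= th2) 1L else 2L
  }
  prs <- utils::combn(mem, 2)
  th <- apply(prs, 2, function(p) .clique_angle(orient, p[1], p[2], jid))
  same <- group[as.character(prs[1, ])] == group[as.character(prs[2, ])]
  out <- data.frame(i = prs[1, ], j = prs[2, ], theta = th,
                    rule = ifelse(same, "C56_in", "C56_cross"),
                    w = ifelse(same, exp(-eval_f1(th, params)),
                               exp(eval_f1(th, params))))
  attr(out, "group") <- group
  out
}

#' Assemble the affinity matrix
#'
#' Applies the per-clique rules and collects weights on the edges of the
#' (usually simplified) graph. Surviving clique edges missed by every rule
#' get the `exp(-f1(theta))` fallback with a warning; pass-through
#' (2-segment junction) edges get the same fallback silently.
#'
#' @param vg a `vessel_graph` (simplified or not).
#' @param om an `ordering_map`.
#' @param orient `end_orientations`.
#' @param segs the `segment_set`.
#' @param params a [trace_params()] list.
#' @return list with `W` (sparse symmetric `Matrix` with zero diagonal,
#'   nonzero exactly on graph edges) and `edge_table` (data.frame `i`, `j`,
#'   `theta`, `rule`, `w`), plus `groups` (per 5/6-clique grouping) and
#'   `pairings` (per 4-clique favorable pairs) for evaluation.
#' @export
assemble_weight_matrix <- function(vg, om, orient, segs,
                                   params = trace_params()) {
  n <- vg$n
  el <- graph_edges(vg)
  ekey <- paste(el[, 1], el[, 2])
  assigned <- stats::setNames(rep(NA_real_, length(ekey)), ekey)
  atheta <- stats::setNames(rep(NA_real_, length(ekey)), ekey)
  arule <- stats::setNames(rep(NA_character_, length(ekey)), ekey)
  groups <- list(); pairings <- list()

  put <- function(df) {
    for (q in seq_len(nrow(df))) {
      key <- paste(min(df$i[q], df$j[q]), max(df$i[q], df$j[q]))
      if (!key %in% ekey) next        # edge removed by simplification
      if (!is.na(assigned[key])) next # loop-pair edge: first junction wins
      assigned[key] <<- df$w[q]
      atheta[key] <<- df$theta[q]
      arule[key] <<- df$rule[q]
    }
  }

  for (cq in vg$cliques) {
    if (cq$size == 3) {
      ci <- classify_three_clique(cq, om, segs, params)
      put(weight_three_clique(cq, ci, orient, params))
    } else if (cq$size == 4) {
      df <- weight_four_clique(cq, orient, params)
      pairings[[as.character(cq$junction)]] <-
        df[df$rule == "C4_fav", c("i", "j")]
      put(df)
    } else {
      df <- weight_five_six_clique(cq, om, orient, params)
      groups[[as.character(cq$junction)]] <- attr(df, "group")
      put(df)
    }
  }

  # fallback for unassigned surviving edges
  miss <- which(is.na(assigned))
  for (q in miss) {
    a <- el[q, 1]; b <- el[q, 2]
    jid <- .shared_junction(vg, a, b)
    th <- if (is.na(jid)) 90 else .clique_angle(orient, a, b, jid)
    from_clique <- any(vapply(vg$cliques, function(cq)
      all(c(a, b) %in% cq$members), logical(1)))
    if (from_clique)
      warning("surviving edge (", a, ", ", b, ") missed by every rule; ",
              "using f1 fallback")
    assigned[q] <- exp(-eval_f1(th, params))
    atheta[q] <- th
    arule[q] <- "fallback"
  }

  W <- Matrix::sparseMatrix(i = c(el[, 1], el[, 2]),
                            j = c(el[, 2], el[, 1]),
                            x = rep(pmax(assigned, 0), 2),
                            dims = c(n, n))
  edge_table <- data.frame(i = el[, 1], j = el[, 2], theta = atheta,
                           rule = arule, w = assigned, row.names = NULL)
  list(W = W, edge_table = edge_table, groups = groups, pairings = pairings)
}

.shared_junction <- function(vg, a, b) {
  eid <- igraph::get_edge_ids(vg$g, c(a, b))
  if (eid == 0) return(NA_integer_)
  as.integer(strsplit(igraph::E(vg$g)$junctions[eid], " ")[[1]][1])
}
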