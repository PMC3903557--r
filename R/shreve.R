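# Modified Shreve ordering over the segment graph.
#
# Leaves (segments with a free END terminal) start at order 1; a k-clique
# fires once exactly k-2 of its non-root members are ordered, giving every
# still-unordered member the sum of the k-2 earliest-ordered incoming
# orders; 2-segment junctions pass the order through unchanged. When no
# clique can fire, the 3-clique deadlock rule resumes propagation: among all
# 3-cliques with a single ordered member of order mu, the one whose two
# unordered members meet at the smallest angle fires first and both get
# mu + 1. Root segments never act as incoming, so propagation stops at roots.

#' Order segments by the modified Shreve scheme
#'
#' @param vg a `vessel_graph`.
#' @param orient optional `end_orientations` (needed to resolve deadlocks by
#'   angle; without it deadlock ties fall back to junction position).
#' @return object of class `ordering_map`: list with `mu` (integer vector
#'   over segment ids), `rule` (per-segment provenance tag in LEAF / CLIQUE2
#'   / CLIQUE3..CLIQUE6 / DEADLOCK), `clique_rule` (per junction id: rule
#'   that fired there, NA if none), `deadlock_seed` (per junction id: the
#'   pre-ordered member when the deadlock rule fired).
#' @export
order_segments <- function(vg, orient = NULL) {
  stopifnot(inherits(vg, "vessel_graph"))
  n <- vg$n
  mu <- rep(NA_real_, n)
  rule <- rep(NA_character_, n)
  tstamp <- rep(NA_integer_, n)
  clock <- 0L
  is_root <- igraph::V(vg$g)$root

  segs_end_free <- .leaf_ids(vg)
  for (s in segs_end_free) {
    mu[s] <- 1; rule[s] <- "LEAF"; clock <- clock + 1L; tstamp[s] <- clock
  }

  njunc <- max(c(0L, vapply(vg$cliques, `[[`, numeric(1), "junction"),
                 vapply(vg$pass_throughs, `[[`, numeric(1), "junction")))
  clique_rule <- rep(NA_character_, njunc)
  deadlock_seed <- rep(NA_integer_, njunc)

  all_cliques <- c(vg$pass_throughs, vg$cliques)
  # deterministic firing order: junction point scan order
  pts <- t(vapply(all_cliques, `[[`, numeric(2), "point"))
  cq_order <- if (length(all_cliques)) order(pts[, 1], pts[, 2]) else integer(0)

  repeat {
    fired <- FALSE
    for (ci in cq_order) {
      cq <- all_cliques[[ci]]
      mem <- cq$members
      k <- length(mem)
      out <- mem[is.na(mu[mem])]
      if (!length(out)) next
      inc <- mem[!is.na(mu[mem]) & !is_root[mem]]
      # incoming arity: 2 of 3, 2 of 4, 3 of 5, 4 of 6 (pass-through: 1 of 2)
      need <- if (k <= 3) k - 1L else k - 2L
      if (length(inc) < need) next
      inc <- inc[order(tstamp[inc])][seq_len(need)]
      val <- if (k == 2) mu[inc] else sum(mu[inc])
      for (s in out) {
        mu[s] <- val
        rule[s] <- paste0("CLIQUE", k)
        clock <- clock + 1L; tstamp[s] <- clock
      }
      if (k >= 3 && is.na(clique_rule[cq$junction]))
        clique_rule[cq$junction] <- paste0("CLIQUE", k)
      fired <- TRUE
    }
    if (fired) next
    if (!anyNA(mu)) break

    # deadlock: 3-cliques with exactly one ordered member
    upd <- .fire_deadlock(all_cliques, cq_order, mu, tstamp, orient)
    if (is.null(upd)) {
      # last resort: any clique with >= 1 ordered member gets max + 1
      upd <- .fire_residual(all_cliques, cq_order, mu)
      if (is.null(upd)) {
        stuck <- which(is.na(mu))
        stop("unorderable residue: segments ",
             paste(utils::head(stuck, 10), collapse = ", "),
             " cannot be reached by any ordering rule")
      }
    }
    cq <- all_cliques[[upd$ci]]
    for (s in upd$targets) {
      mu[s] <- upd$value; rule[s] <- "DEADLOCK"
      clock <- clock + 1L; tstamp[s] <- clock
    }
    clique_rule[cq$junction] <- "DEADLOCK"
    deadlock_seed[cq$junction] <- upd$seed
  }

  structure(list(mu = mu, rule = rule, clique_rule = clique_rule,
                 deadlock_seed = deadlock_seed),
            class = "ordering_map")
}

# segments with at least one free END terminal (leaves of the network)
.leaf_ids <- function(vg) {
  which(igraph::V(vg$g)$leaf)
}

.fire_deadlock <- function(all_cliques, cq_order, mu, tstamp, orient) {
  best <- NULL
  for (ci in cq_order) {
    cq <- all_cliques[[ci]]
    if (length(cq$members) != 3) next
    mem <- cq$members
    done <- mem[!is.na(mu[mem])]
    if (length(done) != 1) next
    un <- setdiff(mem, done)
    ang <- if (!is.null(orient)) {
      angle_between(orientation_at(orient, un[1], cq$junction),
                    orientation_at(orient, un[2], cq$junction))
    } else Inf
    key <- c(ang, cq$point)
    if (is.null(best) || .lex_less(key, best$key))
      best <- list(ci = ci, key = key, targets = un,
                   value = mu[done] + 1, seed = done)
  }
  best
}

.fire_residual <- function(all_cliques, cq_order, mu) {
  for (ci in cq_order) {
    cq <- all_cliques[[ci]]
    mem <- cq$members
    done <- mem[!is.na(mu[mem])]
    un <- mem[is.na(mu[mem])]
    if (length(done) >= 1 && length(un) >= 1)
      return(list(ci = ci, targets = un, value = max(mu[done]) + 1,
                  seed = done[1]))
  }
  NULL
}

.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-9) return(TRUE)
    if (a[i] > b[i] + 1e-9) return(FALSE)
  }
  FALSE
}
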