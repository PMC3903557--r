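p0 <- trace_params()

test_that("normalization handles unit degrees, stars and isolated nodes", {
  W <- matrix(c(0, 1, 1, 0), 2)
  S <- as.matrix(normalize_affinity(W))
  expect_equal(S, W)
  # star with three unit-weight leaves: spokes 1/sqrt(3)
  Ws <- matrix(0, 4, 4)
  Ws[1, 2:4] <- 1; Ws[2:4, 1] <- 1
  Ss <- as.matrix(normalize_affinity(Ws))
  expect_equal(Ss[1, 2:4], rep(1 / sqrt(3), 3))
  # isolated node: zero row and column
  Wi <- rbind(cbind(Ws, 0), 0)
  Si <- as.matrix(normalize_affinity(Wi))
  expect_equal(Si[5, ], rep(0, 5))
  expect_equal(Si[, 5], rep(0, 5))
})

test_that("alpha -> 0 freezes the initial labels after one step", {
  W <- matrix(c(0, 1, 1, 0), 2)
  Y0 <- initial_labels(2, 1)
  p <- trace_params(alpha = 1e-9)
  Y <- propagate_labels(normalize_affinity(W), Y0, p)
  expect_equal(Y, Y0, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("two-node propagation matches the hand-derived closed form", {
  # W = [[0,1],[1,0]], root at node 1, alpha = 0.9:
  # Y_inf = (1-a)(I-aS)^-1 e1 = [1/(1+a), a/(1+a)]
  W <- matrix(c(0, 1, 1, 0), 2)
  Y0 <- initial_labels(2, 1)
  p <- trace_params(alpha = 0.9, epsilon = 1e-9)
  Y <- propagate_labels(normalize_affinity(W), Y0, p)
  expect_equal(as.vector(Y), c(0.5263158, 0.4736842), tolerance = 1e-6)
  expect_lte(attr(Y, "iterations"), 250)
  Yc <- propagate_closed_form(W, Y0, 0.9)
  expect_equal(as.vector(Yc), c(1 / 1.9, 0.9 / 1.9), tolerance = 1e-12)
})

test_that("iterative propagation equals the closed form on random graphs", {
  set.seed(461)
  p <- trace_params(epsilon = 1e-8)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    W <- matrix(0, n, n)
    idx <- which(upper.tri(W) & matrix(stats::runif(n * n), n, n) < 0.25)
    W[idx] <- stats::runif(length(idx))
    W <- W + t(W)
    roots <- sample(n, sample(1:3, 1))
    Y0 <- initial_labels(n, roots)
    Yi <- propagate_labels(normalize_affinity(W), Y0, p)
    Yc <- propagate_closed_form(W, Y0, p$alpha)
    expect_lt(max(abs(Yi - Yc)), 1e-6)
  }
})

test_that("degenerate closed-form cases: zero labels and isolated roots", {
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
  expect_equal(propagate_closed_form(W, matrix(0, 3, 2), 0.9),
               matrix(0, 3, 2))
  Y0 <- initial_labels(3, 3)  # node 3 isolated
  Yc <- propagate_closed_form(W, Y0, 0.9)
  expect_equal(Yc[3, 1], 0.1)
  expect_equal(Yc[1:2, 1], c(0, 0))
})

test_that("a symmetric barbell splits the middle node's scores evenly", {
  # path 1-2-3 with roots at 1 and 3
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- 1
  Y0 <- initial_labels(3, c(1, 3))
  Y <- propagate_labels(normalize_affinity(W), Y0,
                        trace_params(epsilon = 1e-12))
  expect_lt(abs(Y[2, 1] - Y[2, 2]), 1e-9)
})

test_that("residual decay is eventually geometric with ratio <= alpha", {
  set.seed(462)
  n <- 20
  W <- matrix(stats::runif(n * n) < 0.3, n, n) * stats::runif(n * n)
  W <- (W + t(W)) / 2; diag(W) <- 0
  S <- normalize_affinity(W)
  Y0 <- initial_labels(n, c(1, 5))
  Y <- Y0; res <- numeric(0)
  for (t in 1:60) {
    Yn <- as.matrix(0.9 * (S %*% Y)) + 0.1 * Y0
    res <- c(res, sqrt(sum((Yn - Y)^2)))
    Y <- Yn
  }
  ratios <- res[-1] / res[-length(res)]
  expect_true(all(utils::tail(ratios, 30) <= 0.9 + 1e-9))
})

test_that("label assignment: roots forced, rootless components unassigned, ties broken", {
  Y <- rbind(c(0.9, 0.1), c(0.4, 0.4), c(0, 0), c(0.1, 0.8))
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 2; W[2, 4] <- W[4, 2] <- 1
  lab <- assign_tree_labels(Y, W, root_ids = c(1, 4))
  expect_equal(lab$label[1], 1L)
  expect_equal(lab$label[4], 2L)
  expect_equal(lab$label[2], 1L)  # tie resolved toward strongest neighbor
  expect_true(is.na(lab$label[3]))
  expect_equal(lab$n_trees, 2)
})

test_that("two disjoint rooted components label wholly by their own root", {
  y <- y_mask()
  m <- matrix(FALSE, 64, 140); d <- matrix(FALSE, 64, 140)
  m[, 1:64] <- y$mask; m[, 71:134] <- y$mask
  d[, 1:64] <- y$disk; d[, 71:134] <- y$disk
  tr <- trace_vessels(m, disk = d)
  lab <- tr$labeling$label
  comp <- igraph::components(tr$graph$g)$membership
  for (k in 1:2) {
    ids <- which(comp == comp[tr$segments$root_ids[k]])
    expect_true(all(lab[ids] == k))
  }
})

test_that("self-intersection resolution returns an acyclic parent map", {
  set.seed(463)
  # random graphs with cycles: labeled set = all, root = 1
  for (i in 1:100) {
    n <- sample(5:14, 1)
    tr <- generate_tree("LOW", n_leaves = max(2, n %/% 3))
    vg <- tree_graph(tr)
    # inject a cycle: connect two random non-adjacent leaves
    leaves <- which(igraph::V(vg$g)$leaf)
    if (length(leaves) >= 2) {
      pr <- sample(leaves, 2)
      vg$g <- igraph::add_edges(vg$g, pr,
                                attr = list(junctions = "999"))
    }
    orient <- structure(list(dir = array(stats::runif(vg$n * 4), c(vg$n, 2, 2)),
                             end_junction = matrix(NA_integer_, vg$n, 2)),
                        class = "end_orientations")
    rs <- resolve_self_intersections(seq_len(vg$n), 1L, vg, orient)
    parent <- rs$parent
    # walking up from every node terminates at the root without revisits
    for (v in names(parent)) {
      seen <- character(0); cur <- v
      while (!is.na(parent[cur])) {
        expect_false(cur %in% seen)
        seen <- c(seen, cur)
        cur <- as.character(parent[cur])
      }
    }
  }
})

test_that("a tree without self-intersections is returned unchanged", {
  y <- y_mask()
  tr <- trace_vessels(y$mask, disk = y$disk)
  ids <- which(tr$labeling$label == 1)
  rs <- resolve_self_intersections(ids, tr$segments$root_ids[1],
                                   tr$graph, tr$orient)
  # parent edges are exactly the simplified tree edges
  el <- igraph::as_edgelist(tr$graph$g, names = FALSE)
  got <- cbind(as.integer(names(rs$parent)), rs$parent)
  got <- got[!is.na(got[, 2]), , drop = FALSE]
  expect_equal(nrow(got), nrow(el))
})
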