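test_that("Y-tree orders leaves 1 and root 2; X-crossing orders both roots 2", {
  y <- y_mask()
  segs <- extract_segments(skeletonize_mask(y$mask), disk = y$disk)
  vg <- build_graph(segs)
  om <- order_segments(vg, end_orientations(segs))
  expect_equal(sort(om$mu), c(1, 1, 2))
  expect_equal(om$mu[segs$root_ids], 2)

  x <- x_mask()
  segs <- extract_segments(skeletonize_mask(x$mask), disk = x$disk)
  vg <- build_graph(segs)
  om <- order_segments(vg, end_orientations(segs))
  expect_equal(unname(om$mu[segs$root_ids]), c(2, 2))
  leaves <- setdiff(seq_len(vg$n), segs$root_ids)
  expect_equal(unname(om$mu[leaves]), c(1, 1))
  expect_true(all(om$rule[segs$root_ids] == "CLIQUE4"))
})

test_that("root order equals leaf count on random crossover-free trees", {
  set.seed(431)
  for (i in 1:200) {
    nl <- sample(2:16, 1)
    tr <- generate_tree(sample(c("LOW", "MEDIUM", "HIGH"), 1), n_leaves = nl)
    vg <- tree_graph(tr)
    om <- order_segments(vg)
    expect_equal(om$mu[1], nl)  # trunk order = Shreve magnitude = leaf count
    # monotone toward the root along every parent-child pair
    for (b in tr$branches) {
      for (ch in b$children) expect_gt(om$mu[b$id], om$mu[ch])
    }
    expect_true(all(om$mu >= 1))
  }
})

test_that("relabeling segment ids permutes orders consistently", {
  set.seed(432)
  tr <- generate_tree("MEDIUM", n_leaves = 7)
  vg <- tree_graph(tr)
  om <- order_segments(vg)
  # relabel: reverse ids
  n <- vg$n
  perm <- rev(seq_len(n))
  vg2 <- vg
  vg2$g <- igraph::permute(vg$g, perm)
  vg2$cliques <- lapply(vg$cliques, function(cq) {
    cq$members <- sort(perm[cq$members]); cq
  })
  vg2$root_ids <- perm[vg$root_ids]
  om2 <- order_segments(vg2)
  expect_equal(om2$mu[perm], om$mu)
})

test_that("the deadlock rule fires the smallest-angle clique first", {
  # one ordered stem (id 1) feeding junction A whose two unordered branches
  # meet at 40 degrees, versus junction B at 110 degrees on a second stem
  chains <- list(
    ray_chain(c(100, 70), 0, 29),              # 1: stem to A at (100,100)
    ray_chain(c(99, 101), 20, 30),             # 2: A branch
    ray_chain(c(101, 101), -20, 30),           # 3: A branch (40 deg apart)
    ray_chain(c(160, 70), 0, 29),              # 4: stem to B at (160,100)
    ray_chain(c(159, 101), 55, 30),            # 5: B branch
    ray_chain(c(161, 101), -55, 30)            # 6: B branch (110 deg apart)
  )
  segs <- manual_segment_set(
    chains,
    end_types = rep(list(c("END", "BRANCH"), c("BRANCH", "ROOT"),
                         c("BRANCH", "ROOT")), 2),
    end_junctions = rep(list(c(NA, 1L), c(1L, NA), c(NA_integer_, NA)), 2),
    junctions = rbind(c(100, 100), c(160, 100)))
  # fix junction bookkeeping: branches at B use junction 2
  segs$segments[[2]]$end_junction <- c(1L, NA)
  segs$segments[[3]]$end_junction <- c(1L, NA)
  segs$segments[[4]]$end_junction <- c(NA, 2L)
  segs$segments[[5]]$end_junction <- c(2L, NA)
  segs$segments[[6]]$end_junction <- c(2L, NA)
  # stems are ordinary leaves; the four branches run toward the disk, so
  # their far ends are roots and the cliques can only fire by deadlock
  vg <- build_graph(segs)
  om <- order_segments(vg, end_orientations(segs))
  expect_equal(unname(om$mu), c(1, 2, 2, 1, 2, 2))
  expect_equal(unname(om$rule[c(2, 3, 5, 6)]), rep("DEADLOCK", 4))
  # the 40-degree clique fired first: its members got earlier timestamps,
  # observable through the deadlock seed bookkeeping
  expect_equal(unname(om$clique_rule), c("DEADLOCK", "DEADLOCK"))
  expect_equal(unname(om$deadlock_seed), c(1L, 4L))
})

test_that("a single stuck clique fires regardless of angle; ties break by position", {
  chains <- list(ray_chain(c(50, 20), 0, 29),
                 ray_chain(c(49, 51), 60, 30),
                 ray_chain(c(51, 51), -60, 30))
  segs <- manual_segment_set(
    chains,
    end_types = list(c("END", "BRANCH"), c("BRANCH", "ROOT"),
                     c("BRANCH", "ROOT")),
    end_junctions = list(c(NA, 1L), c(1L, NA), c(1L, NA)),
    junctions = rbind(c(50, 50)))
  vg <- build_graph(segs)
  om <- order_segments(vg, end_orientations(segs))
  expect_equal(unname(om$mu), c(1, 2, 2))
})

test_that("rootless, leafless residue raises the unorderable error", {
  # a pure triangle of segments with no terminals at all
  segs <- manual_segment_set(
    chains = list(ray_chain(c(10, 10), 0, 10), ray_chain(c(10, 10), 60, 10),
                  ray_chain(c(20, 20), 120, 10)),
    end_types = rep(list(c("BRANCH", "BRANCH")), 3),
    end_junctions = list(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
    junctions = rbind(c(10, 10), c(10, 21), c(21, 15)))
  vg <- build_graph(segs)
  expect_error(order_segments(vg, end_orientations(segs)), "unorderable")
})
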