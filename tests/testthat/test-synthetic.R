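test_that("leaf counts respect the complexity classes and seeds reproduce", {
  set.seed(471)
  for (i in 1:30) {
    expect_true(generate_tree("LOW")$leaf_count %in% 2:5)
    expect_true(generate_tree("MEDIUM")$leaf_count %in% 5:10)
    expect_gt(generate_tree("HIGH")$leaf_count, 10)
  }
  s1 <- compose_scene(n_trees = 3, gamma = 60, seed = 99,
                      image_size = c(256, 256), disk_radius = 24)
  s2 <- compose_scene(n_trees = 3, gamma = 60, seed = 99,
                      image_size = c(256, 256), disk_radius = 24)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$tree_pixels, s2$tree_pixels)
})

test_that("tracing an isolated rendered tree recovers the generator's leaf count", {
  set.seed(472)
  for (i in 1:10) {
    sc <- compose_scene(n_trees = 1, gamma = 360,
                        complexities = sample(c("LOW", "MEDIUM"), 1),
                        image_size = c(420, 420), disk_radius = 30,
                        seed = 4720 + i)
    segs <- extract_segments(skeletonize_mask(sc$mask), disk = sc$disk)
    segs <- remove_spurious_segments(segs)
    vg <- build_graph(segs)
    om <- order_segments(vg, end_orientations(segs))
    leaves <- sum(vapply(segs$segments, function(sg)
      any(sg$end_type == "END"), logical(1)))
    expect_equal(max(om$mu), leaves)
    expect_equal(unname(om$mu[segs$root_ids[1]]), leaves)
    # rendered faithfully: leaf count matches the generator's bookkeeping
    expect_equal(leaves, sc$trees[[1]]$leaf_count)
  }
})

test_that("scene composition wraps gamma and spaces axes as requested", {
  sc <- suppressWarnings(compose_scene(n_trees = 8, gamma = 360, seed = 5,
                                       image_size = c(256, 256),
                                       disk_radius = 20,
                                       complexities = "LOW"))
  expect_equal(sc$gamma, 45)  # 360/8 wrap
  expect_equal(sc$gamma_requested, 360)
  axes <- vapply(sc$trees, `[[`, numeric(1), "axis_deg")
  expect_equal(diff(axes)[1], 45)
  # no wrap when the fan fits
  sc2 <- suppressWarnings(compose_scene(n_trees = 8, gamma = 30, seed = 5,
                                        image_size = c(256, 256),
                                        disk_radius = 20,
                                        complexities = "LOW"))
  expect_equal(sc2$gamma, 30)
  axes2 <- vapply(sc2$trees, `[[`, numeric(1), "axis_deg")
  expect_equal(max(axes2) - min(axes2), 210)  # 8 trees spanning 210 degrees
})

test_that("two well-separated trees never cross", {
  set.seed(473)
  for (i in 1:5) {
    sc <- compose_scene(n_trees = 2, gamma = 180, complexities = "LOW",
                        image_size = c(360, 360), disk_radius = 28,
                        seed = 4730 + i)
    expect_length(intersect(sc$tree_pixels[[1]], sc$tree_pixels[[2]]), 0)
  }
})

test_that("rendered scenes agree with generator bookkeeping on roots and truth", {
  set.seed(474)
  sc <- suppressWarnings(compose_scene(n_trees = 4, gamma = 80,
                                       image_size = c(360, 360),
                                       disk_radius = 28, seed = 474))
  segs <- extract_segments(skeletonize_mask(sc$mask), disk = sc$disk)
  expect_equal(length(segs$root_ids), 4)
  expect_true(all(sc$mask[sc$truth_raster > 0]))
  expect_true(all(sc$truth_raster[sc$mask] > 0))
})

test_that("benchmark dataset arithmetic and manifests", {
  out <- generate_benchmark_datasets(2, n_per_subset = 1, seed = 3,
                                     image_size = c(192, 192),
                                     disk_radius = 18)
  expect_equal(nrow(out$manifest), 6)
  expect_equal(out$manifest$n_trees, c(3, 5, 7, 9, 11, 12))
  out3 <- generate_benchmark_datasets(3, n_per_subset = 1, seed = 3,
                                      image_size = c(192, 192),
                                      disk_radius = 18)
  expect_equal(out3$manifest$gamma, c(360, 300, 240, 180, 120, 60))
  # dataset 1 subset 4 mixes MEDIUM and HIGH
  out1 <- generate_benchmark_datasets(1, n_per_subset = 1, seed = 3,
                                      image_size = c(192, 192),
                                      disk_radius = 18)
  expect_equal(out1$manifest$complexities[4], "MEDIUM+HIGH")
  expect_equal(nrow(out1$manifest), 5)
})

test_that("crossover density falls as the spread angle grows", {
  set.seed(475)
  n4 <- sapply(c(25, 72), function(gm) {
    counts <- sapply(1:8, function(i) {
      sc <- suppressWarnings(compose_scene(n_trees = 5, gamma = gm,
                                           complexities = "LOW",
                                           image_size = c(300, 300),
                                           disk_radius = 24,
                                           seed = 4750 + 10 * gm + i))
      segs <- remove_spurious_segments(
        extract_segments(skeletonize_mask(sc$mask), disk = sc$disk))
      vg <- tryCatch(build_graph(segs), error = function(e) NULL)
      if (is.null(vg)) return(NA_real_)
      sum(vapply(vg$cliques, `[[`, numeric(1), "size") >= 4)
    })
    mean(counts, na.rm = TRUE)
  })
  expect_gt(n4[1], n4[2])
})
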