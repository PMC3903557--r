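p0 <- trace_params()

test_that("end orientations of straight and diagonal chains are exact", {
  ch_h <- cbind(rep(10, 12), 1:12)
  sg <- list(id = 1, pixels = ch_h, radii = rep(1, 12),
             end_type = c("END", "END"), end_junction = c(NA, NA),
             length = 12)
  segs <- manual_segment_set(list(ch_h), list(c("END", "END")),
                             list(c(NA, NA)), rbind(c(1, 1)))
  d_last <- segment_end_orientation(sg, 2, segs, params = p0)
  expect_equal(d_last, c(0, 1), tolerance = 1e-12)
  d_first <- segment_end_orientation(sg, 1, segs, params = p0)
  expect_equal(d_first, c(0, -1), tolerance = 1e-12)

  ch_d <- cbind(20:8, 1:13)  # 45-degree chain
  sg$pixels <- ch_d; sg$length <- 13
  d <- segment_end_orientation(sg, 2, segs, params = p0)
  expect_equal(d, c(-sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-12)
})

test_that("arc end orientation is within 6 degrees of the analytic tangent", {
  r <- 30
  th <- seq(0, pi / 2, length.out = 300)
  poly <- cbind(100 - r * sin(th), 100 + r * cos(th) - r)
  ch <- vesseltrace:::rasterize_polyline(poly)
  sg <- list(id = 1, pixels = ch, radii = rep(1, nrow(ch)),
             end_type = c("END", "END"), end_junction = c(NA, NA),
             length = nrow(ch))
  segs <- manual_segment_set(list(ch), list(c("END", "END")),
                             list(c(NA, NA)), rbind(c(1, 1)))
  d <- segment_end_orientation(sg, 2, segs, params = p0)
  tangent <- c(-cos(pi / 2), -sin(pi / 2))  # outward at the 90-degree end
  ang <- acos(abs(sum(d * tangent))) * 180 / pi
  expect_lt(ang, 6)
})

test_that("angle folding: continuation caps at 179.999, perpendicular is 90", {
  expect_equal(angle_between(c(0, 1), c(0, -1)), 179.999)
  expect_equal(angle_between(c(0, 1), c(1, 0)), 90)
  expect_equal(angle_between(c(0, 1), c(0, 1)), 0)
})

test_that("f1 is continuous at both breakpoints and behaves at the extremes", {
  expect_equal(eval_f1(0, p0), 0)
  plateau <- -sin(p0$theta_c * pi / 180)^p0$k
  expect_equal(eval_f1(p0$theta_c, p0), plateau, tolerance = 1e-15)
  # both formulas agree at the breakpoints to machine precision
  expect_lt(abs(-sin(p0$theta_c * pi / 180)^p0$k - eval_f1(p0$theta_c, p0)),
            1e-12)
  expect_lt(abs(p0$k * cos(p0$theta_star * pi / 180) -
                eval_f1(p0$theta_star, p0)), 1e-12)
  expect_equal(eval_f1(179.999, p0), p0$k * cos(179.999 * pi / 180))
  expect_error(eval_f1(180, p0), "theta")
  expect_error(eval_f1(-1, p0), "theta")
})

test_that("f2/f3 identities and the favorable/unfavorable dominance hold", {
  expect_equal(eval_f2(90, p0), 0)
  expect_equal(exp(-eval_f2(90, p0)), 1)
  expect_equal(eval_f3(0, p0), p0$k)
  g <- seq(0, 179.9, by = 0.1)
  expect_lte(max(exp(-eval_f3(g, p0))), exp(-p0$k))
  obtuse <- g[g >= 90]
  expect_gte(min(exp(-eval_f2(obtuse, p0))), exp(-p0$k) - 1e-12)
})

test_that("exp(-f1) is non-decreasing over a 0.1-degree grid", {
  g <- seq(0, 179.9, by = 0.1)
  w <- exp(-eval_f1(g, p0))
  expect_true(all(diff(w) >= -1e-12))
})

test_that("case-A 3-clique weights use exp(-f1) on the pair angles", {
  y <- y_mask()
  segs <- extract_segments(skeletonize_mask(y$mask), disk = y$disk)
  orient <- end_orientations(segs)
  vg <- build_graph(segs)
  om <- order_segments(vg, orient)
  cq <- vg$cliques[[1]]
  ci <- classify_three_clique(cq, om, segs)
  expect_equal(ci$case, "A")
  df <- weight_three_clique(cq, ci, orient)
  expect_equal(nrow(df), 3)
  expect_equal(df$w, exp(-eval_f1(df$theta, p0)))
  # child-parent angles near 135 degrees: strongly attractive weights
  expect_true(all(df$w[df$theta > 100] > 1))
})

test_that("case-B weights reward the better-aligned pair and damp the other", {
  # connector (id 3) joins through-segments 1 and 2: psi1 = 170, psi2 = 95
  chains <- list(ray_chain(c(100, 101), -10, 40),
                 ray_chain(c(99, 100), 85, 40),
                 ray_chain(c(100, 99), 180, 40))
  segs <- manual_segment_set(
    chains,
    end_types = list(c("BRANCH", "END"), c("BRANCH", "END"),
                     c("BRANCH", "END")),
    end_junctions = list(c(1L, NA), c(1L, NA), c(1L, NA)),
    junctions = rbind(c(100, 100)))
  orient <- end_orientations(segs)
  vg <- build_graph(segs)
  cq <- vg$cliques[[1]]
  ci <- list(case = "B", connector = 3L)
  df <- weight_three_clique(cq, ci, orient)
  fav <- df[df$rule == "C3_B_fav", ]
  unf <- df[df$rule == "C3_B_unfav", ]
  expect_equal(sort(c(fav$i, fav$j))[2], 3)  # favorable edge touches connector
  expect_gt(fav$theta, unf$theta)
  expect_equal(fav$w, exp(-eval_f1(fav$theta, p0)))
  expect_equal(unf$w, exp(eval_f1(unf$theta, p0)))
  expect_lte(unf$w, 1)
  expect_gt(fav$w, 1)
})

test_that("4-clique pairing matches the brute-force intersection oracle", {
  set.seed(451)
  for (i in 1:1000) {
    pts <- random_convex_quad()
    pairings <- list(rbind(c(1, 2), c(3, 4)), rbind(c(1, 3), c(2, 4)),
                     rbind(c(1, 4), c(2, 3)))
    hits <- vapply(pairings, function(pr)
      oracle_intersects(pts[pr[1, 1], ], pts[pr[1, 2], ],
                        pts[pr[2, 1], ], pts[pr[2, 2], ]), logical(1))
    expect_equal(sum(hits), 1)
    got <- four_clique_pairing(pts)
    expect_false(got$degenerate)
    expect_equal(got$pairs, pairings[[which(hits)]])
  }
})

test_that("a perfect X gets collinear favorable pairs with near-e^k weights", {
  x <- x_mask()
  tr <- trace_vessels(x$mask, disk = x$disk)
  et <- tr$weights$edge_table
  fav <- et[et$rule == "C4_fav", ]
  unf <- et[et$rule == "C4_unfav", ]
  expect_equal(nrow(fav), 2)
  expect_true(all(fav$theta > 680 / 4))  # collinear: theta close to 180
  expect_true(all(fav$w > exp(p0$k) * 0.9))
  expect_true(all(unf$w < 1))
})

test_that("assembled W is symmetric, zero-diagonal, supported on graph edges", {
  set.seed(452)
  sc <- suppressWarnings(compose_scene(n_trees = 5, gamma = 30,
                                       image_size = c(320, 320),
                                       disk_radius = 28, seed = 452))
  tr <- suppressWarnings(trace_vessels(sc$mask, disk = sc$disk))
  W <- tr$weights$W
  expect_equal(max(abs(W - Matrix::t(W))), 0)
  expect_equal(max(abs(Matrix::diag(W))), 0)
  el <- igraph::as_edgelist(tr$graph$g, names = FALSE)
  expect_equal(Matrix::nnzero(W), 2 * nrow(el))
  expect_true(all(W@x > 0))
})

test_that("whole-image rotation and reflection leave W values unchanged", {
  x <- x_mask()
  base <- trace_vessels(x$mask, disk = x$disk)
  w0 <- sort(base$weights$edge_table$w)
  rot <- function(m) t(m)[, nrow(m):1]  # 90-degree rotation
  for (f in list(rot, function(m) m[nrow(m):1, ])) {
    tr <- trace_vessels(f(x$mask), disk = f(x$disk))
    expect_equal(sort(tr$weights$edge_table$w), w0, tolerance = 1e-9)
  }
})
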