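# Segmentation fusion and branch reconnection.
#
# Three binary masks of the same scene — the highest-F1 supervised output,
# the highest-recall supervised output, and an unsupervised output that
# keeps close parallel branches apart — are fused at the skeleton level:
# starting from the highest-F1 skeleton, suspiciously thin segments are
# replaced from the high-recall skeleton (they are usually broken there
# first) and suspiciously thick ones from the unsupervised skeleton (they
# are usually two merged parallel vessels). A separate pass bridges small
# disconnected components by extending a fitted cubic from both ends.

#' Per-segment vessel diameters
#'
#' Skeletonizes the mask, measures the diameter at every skeleton point as
#' twice the Euclidean distance-transform radius, and summarizes each
#' segment by the median of its point diameters. `d_m` is the mean of the
#' segment medians and `d_sd` their standard deviation.
#'
#' @param mask binary vessel mask.
#' @return list with `per_segment` (data.frame segment_id / median_diameter
#'   / length), `d_m`, `d_sd`, `segs` (the `segment_set`), `skel`.
#' @export
segment_diameters <- function(mask) {
  skel <- skeletonize_mask(mask)
  segs <- extract_segments(skel)
  med <- vapply(segs$segments, function(sg) stats::median(2 * sg$radii),
                numeric(1))
  per <- data.frame(segment_id = seq_along(med), median_diameter = med,
                    length = vapply(segs$segments, `[[`, numeric(1), "length"))
  list(per_segment = per, d_m = mean(med),
       d_sd = if (length(med) > 1) stats::sd(med) else 0,
       segs = segs, skel = skel)
}

# number of chain pixels covered by the dilated band of another segment
.band_overlap <- function(sg_px, band) {
  sum(band[sg_px])
}

#' Fuse three segmentations at the skeleton level
#'
#' @param mask_f1 highest-F1 mask (the backbone).
#' @param mask_recall highest-recall mask (donor for thin segments).
#' @param mask_iuwt unsupervised mask (donor for merged thick segments).
#' @param band_tol correspondence tolerance: a donor segment corresponds to
#'   a backbone segment when at least half of it lies within this dilation
#'   band (pixels) of the backbone segment.
#' @param snap_tol pixels; replacement endpoints are connected back to the
#'   nearest retained skeleton pixel within this distance.
#' @return list with `skeleton` (logical matrix), `radius` (numeric matrix),
#'   `replaced_thin`, `replaced_thick` (segment counts).
#' @export
fuse_segmentations <- function(mask_f1, mask_recall, mask_iuwt,
                               band_tol = 2, snap_tol = 3) {
  stopifnot(all(dim(mask_f1) == dim(mask_recall)),
            all(dim(mask_f1) == dim(mask_iuwt)))
  base <- segment_diameters(mask_f1)
  don_r <- segment_diameters(mask_recall)
  don_u <- segment_diameters(mask_iuwt)
  nr <- nrow(mask_f1)
  lin <- function(px) (px[, 2] - 1L) * nr + px[, 1]

  out <- base$skel$skeleton
  rad <- base$skel$radius
  thin_n <- 0L; thick_n <- 0L
  for (sg in base$segs$segments) {
    md <- stats::median(2 * sg$radii)
    donor <- NULL
    if (md < base$d_m) donor <- don_r
    else if (md > base$d_m + base$d_sd) donor <- don_u
    if (is.null(donor)) next
    band <- matrix(FALSE, nrow(out), ncol(out))
    band[lin(sg$pixels)] <- TRUE
    band <- dilate_mask(band, band_tol)
    cands <- Filter(function(d)
      .band_overlap(lin(d$pixels), band) >= min(d$length, sg$length) / 2,
      donor$segs$segments)
    if (!length(cands)) next  # no correspondence: keep the original
    if (md < base$d_m) thin_n <- thin_n + 1L else thick_n <- thick_n + 1L
    out[lin(sg$pixels)] <- FALSE
    for (d in cands) {
      out[lin(d$pixels)] <- TRUE
      rad[lin(d$pixels)] <- donor$skel$radius[lin(d$pixels)]
      # snap replacement endpoints to the retained skeleton
      for (e in c(1L, nrow(d$pixels))) {
        p <- d$pixels[e, ]
        if (sum(neighbor_count_mat(out)[p[1], p[2]]) >= 1) next
        out <- .snap_to_skeleton(out, p, snap_tol)
      }
    }
  }
  rad[!out] <- 0
  list(skeleton = out, radius = rad,
       replaced_thin = thin_n, replaced_thick = thick_n)
}

.snap_to_skeleton <- function(skel, p, tol) {
  offs <- disc_offsets(tol)
  best <- NULL; bd <- Inf
  for (q in seq_len(nrow(offs))) {
    r <- p[1] + offs[q, 1]; c <- p[2] + offs[q, 2]
    if (r < 1 || c < 1 || r > nrow(skel) || c > ncol(skel)) next
    if ((offs[q, 1] != 0 || offs[q, 2] != 0) && skel[r, c]) {
      d <- offs[q, 1]^2 + offs[q, 2]^2
      if (d < bd) { bd <- d; best <- c(r, c) }
    }
  }
  if (!is.null(best))
    skel <- stamp_pixels(skel, rasterize_polyline(rbind(p, best)))
  skel
}

#' Reconnect disconnected skeleton branches
#'
#' Small isolated components are bridged back to the rest of the skeleton:
#' a cubic polynomial is fitted to the component in its principal-axis
#' frame, the curve is extended one pixel at a time from both ends (up to
#' `budget` pixels), and the bridge is kept as soon as it touches another
#' component. Components of fewer than 4 pixels use a straight-line
#' extension (a cubic is underdetermined). Each bridged pixel's radius is
#' the inverse-distance-weighted convex combination of the radii of the two
#' skeleton points it connects. Components that never connect within budget
#' are left unchanged, so the component count never increases.
#'
#' @param skel logical skeleton matrix or a `skeleton_map`.
#' @param radius numeric radius matrix (taken from `skel` when it is a
#'   `skeleton_map`).
#' @param budget maximal extension length, pixels.
#' @param max_component_size only components up to this size are candidates
#'   for reconnection.
#' @return list with `skeleton`, `radius`, `n_bridged`.
#' @export
reconnect_disconnected_branches <- function(skel, radius = NULL, budget = 30,
                                            max_component_size = 200) {
  if (inherits(skel, "skeleton_map")) {
    radius <- skel$radius
    skel <- skel$skeleton
  }
  if (is.null(radius)) radius <- matrix(1, nrow(skel), ncol(skel))
  lab <- label_components(skel)
  ncomp <- max(lab)
  if (ncomp <= 1) return(list(skeleton = skel, radius = radius, n_bridged = 0L))
  sizes <- tabulate(lab[lab > 0], ncomp)
  main <- which.max(sizes)
  n_bridged <- 0L
  for (comp in setdiff(order(sizes), main)) {
    if (sizes[comp] > max_component_size) next
    px <- which(lab == comp, arr.ind = TRUE)
    bridge <- .extend_component(px, skel, lab, comp, budget)
    if (is.null(bridge)) next
    target <- bridge$target  # (row, col) of the contacted skeleton pixel
    src <- bridge$source
    path <- bridge$path
    if (nrow(path)) {
      w_src <- radius[src[1], src[2]]
      w_tgt <- radius[target[1], target[2]]
      d_src <- sqrt(rowSums((path - matrix(src, nrow(path), 2, byrow = TRUE))^2))
      d_tgt <- sqrt(rowSums((path - matrix(target, nrow(path), 2, byrow = TRUE))^2))
      wt <- (1 / pmax(d_src, 0.5)) /
            (1 / pmax(d_src, 0.5) + 1 / pmax(d_tgt, 0.5))
      for (q in seq_len(nrow(path))) {
        skel[path[q, 1], path[q, 2]] <- TRUE
        radius[path[q, 1], path[q, 2]] <- wt[q] * w_src + (1 - wt[q]) * w_tgt
      }
    }
    lab <- label_components(skel)
    n_bridged <- n_bridged + 1L
  }
  list(skeleton = skel, radius = radius, n_bridged = n_bridged)
}

# fit the component in its principal frame and extend from both ends;
# returns NULL when no contact within budget
.extend_component <- function(px, skel, lab, comp, budget) {
  k <- nrow(px)
  ctr <- colMeans(px)
  X <- sweep(px, 2, ctr)
  if (k >= 4) {
    pc <- stats::prcomp(X, center = FALSE)
    R <- pc$rotation
    tu <- X %*% R
    fit <- stats::lm(tu[, 2] ~ poly(tu[, 1], degree = min(3, k - 1),
                                    raw = TRUE))
    curve_at <- function(t) {
      co <- stats::coef(fit)
      co[is.na(co)] <- 0
      u <- sum(co * t^(0:(length(co) - 1)))
      ctr + as.vector(R %*% c(t, u))
    }
    t_range <- range(tu[, 1])
  } else {
    # straight-line extension along the dominant direction
    d <- if (k >= 2) px[which.max(rowSums(X^2)), ] - ctr else c(0, 1)
    d <- d / sqrt(sum(d^2))
    curve_at <- function(t) ctr + t * d
    t_range <- if (k >= 2) range(X %*% d) else c(0, 0)
  }
  for (side in c(1, -1)) {
    t0 <- if (side > 0) t_range[2] else t_range[1]
    src <- round(curve_at(t0))
    path <- matrix(0, 0, 2)
    for (step in seq_len(budget)) {
      p <- round(curve_at(t0 + side * step))
      if (any(p < 1) || p[1] > nrow(skel) || p[2] > ncol(skel)) break
      hit <- .touches_other(lab, p, comp)
      if (!is.null(hit)) {
        if (!skel[p[1], p[2]]) path <- rbind(path, p)
        return(list(path = path, source = .nearest_in_comp(px, p),
                    target = hit))
      }
      if (!skel[p[1], p[2]]) path <- rbind(path, p)
    }
  }
  NULL
}

.touches_other <- function(lab, p, comp) {
  for (j in seq_len(nrow(.N8))) {
    r <- p[1] + .N8[j, 1]; c <- p[2] + .N8[j, 2]
    if (r < 1 || c < 1 || r > nrow(lab) || c > ncol(lab)) next
    if (lab[r, c] > 0 && lab[r, c] != comp) return(c(r, c))
  }
  if (lab[p[1], p[2]] > 0 && lab[p[1], p[2]] != comp) return(p)
  NULL
}

.nearest_in_comp <- function(px, p) {
  d <- rowSums((px - matrix(p, nrow(px), 2, byrow = TRUE))^2)
  px[which.min(d), ]
}
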