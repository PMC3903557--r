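# Skeleton extraction and pixel taxonomy.
#
# A binary vessel mask is thinned to a one-pixel-wide 8-connected skeleton
# (Zhang-Suen thinning followed by a 2x2-block cleanup of simple points), the
# per-pixel radius is taken from the Euclidean distance transform of the
# original mask, and every skeleton pixel is classified by its number of
# skeleton 8-neighbors: 1 (or 0, degenerate isolated pixel) -> TERMINAL,
# 2 -> BODY, >= 3 -> BRANCHING.

PX_NONE <- 0L; PX_TERMINAL <- 1L; PX_BODY <- 2L; PX_BRANCHING <- 3L

# ring neighborhood of a linear index in a column-major matrix with nr rows,
# in Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW
.ring_offsets <- function(nr) c(-1L, nr - 1L, nr, nr + 1L, 1L, 1L - nr, -nr, -nr - 1L)

# Guo-Hall thinning (two-subiteration parallel scheme). Chosen over
# Zhang-Suen because the latter erodes the free ends of near-diagonal
# strokes by many pixels, displacing vessel terminals.
thin_mask <- function(mask) {
  # pad one background ring so index arithmetic never leaves the matrix
  img <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  nr <- nrow(img)
  off <- .ring_offsets(nr)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      idx <- which(img)
      if (!length(idx)) break
      NB <- matrix(FALSE, length(idx), 8)
      for (q in 1:8) NB[, q] <- img[idx + off[q]]
      p2 <- NB[, 1]; p3 <- NB[, 2]; p4 <- NB[, 3]; p5 <- NB[, 4]
      p6 <- NB[, 5]; p7 <- NB[, 6]; p8 <- NB[, 7]; p9 <- NB[, 8]
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
           (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      m <- if (sub == 1) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
      cond <- C == 1 & N >= 2 & N <= 3 & !m
      if (any(cond)) { img[idx[cond]] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  img[2:(nr - 1), 2:(ncol(img) - 1)]
}

# 8-adjacency among the 8 ring positions (N, NE, E, SE, S, SW, W, NW)
.RING <- cbind(c(-1, -1, 0, 1, 1, 1, 0, -1), c(0, 1, 1, 1, 0, -1, -1, -1))
.RING_ADJ <- local({
  a <- matrix(FALSE, 8, 8)
  for (i in 1:8) for (j in 1:8)
    a[i, j] <- i != j && max(abs(.RING[i, ] - .RING[j, ])) <= 1
  a
})

# Redundant-pixel deletion: a pixel with 2-3 skeleton neighbors that are
# mutually one 8-connected blob is a staircase/triangle thickening; deleting
# it keeps the chain connected. True junction centers have neighbors in
# >= 2 blobs and endpoints have a single neighbor, so both are kept.
prune_blocks <- function(img0) {
  img <- rbind(FALSE, cbind(FALSE, img0, FALSE), FALSE)
  nr <- nrow(img)
  off <- .ring_offsets(nr)
  repeat {
    idx <- which(img)
    if (!length(idx)) break
    NB <- matrix(FALSE, length(idx), 8)
    for (q in 1:8) NB[, q] <- img[idx + off[q]]
    B <- rowSums(NB)
    cand <- idx[B >= 2 & B <= 3]
    removed <- FALSE
    for (p in cand) {
      if (!img[p]) next
      v <- img[p + off]
      on <- which(v)
      if (length(on) < 2 || length(on) > 3) next
      adj <- .RING_ADJ[on, on, drop = FALSE]
      connected <- if (length(on) == 2) adj[1, 2] else sum(adj) / 2 >= 2
      if (connected) { img[p] <- FALSE; removed <- TRUE }
    }
    if (!removed) break
  }
  img[2:(nr - 1), 2:(ncol(img) - 1)]
}

classify_skeleton_pixels <- function(skel) {
  nb <- neighbor_count_mat(skel)
  cls <- matrix(PX_NONE, nrow(skel), ncol(skel))
  cls[skel & nb <= 1] <- PX_TERMINAL
  cls[skel & nb == 2] <- PX_BODY
  cls[skel & nb >= 3] <- PX_BRANCHING
  cls
}

#' Skeletonize a binary vessel mask
#'
#' Reduces a binary mask to a one-pixel-wide classified skeleton with
#' per-pixel radii (the medial-axis view of the mask).
#'
#' @param mask logical or 0/1 matrix; `TRUE`/1 marks vessel pixels.
#' @return an object of class `skeleton_map`: list with `skeleton` (logical
#'   matrix), `radius` (numeric matrix, Euclidean distance to the nearest
#'   background pixel, defined on skeleton pixels), and `pixel_class`
#'   (integer matrix, 0 none / 1 terminal / 2 body / 3 branching).
#' @export
skeletonize_mask <- function(mask) {
  if (is.null(dim(mask)) || length(mask) == 0)
    stop("mask must be a nonempty matrix")
  if (!all(mask %in% c(0, 1, TRUE, FALSE)))
    stop("mask values must be exactly {0, 1}")
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!any(mask)) stop("empty skeleton: mask contains no vessel pixels")
  skel <- prune_blocks(thin_mask(mask))
  radius <- as.matrix(EBImage::distmap(mask * 1))
  radius[!skel] <- 0
  structure(list(skeleton = skel, radius = radius,
                 pixel_class = classify_skeleton_pixels(skel)),
            class = "skeleton_map")
}

#' Detect the optic disk in a grayscale fundus image
#'
#' Locates the brightest smoothed blob: Gaussian smoothing, thresholding at a
#' high intensity quantile, largest connected component, then a small
#' dilation. When a disk mask is already available, pass it through
#' `disk_mask` and this detection is bypassed.
#'
#' @param image numeric matrix (grayscale intensities).
#' @param sigma Gaussian smoothing scale in pixels.
#' @param quantile_cut intensity quantile defining "bright".
#' @param dilation pixels of final dilation.
#' @param disk_mask optional logical matrix; returned verbatim if supplied.
#' @return logical matrix marking the optic-disk region.
#' @export
detect_optic_disk <- function(image, sigma = 10, quantile_cut = 0.995,
                              dilation = 5, disk_mask = NULL) {
  if (!is.null(disk_mask)) return(disk_mask)
  stopifnot(is.matrix(image))
  sm <- as.matrix(EBImage::gblur(image, sigma = sigma))
  thr <- stats::quantile(sm, quantile_cut)
  blob <- sm > thr
  if (!any(blob) || diff(range(sm)) < sqrt(.Machine$double.eps))
    stop("no bright blob found; supply an optic-disk mask explicitly")
  lab <- label_components(blob)
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  dilate_mask(keep, dilation)
}
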