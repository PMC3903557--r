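# Low-level raster helpers shared across the pipeline.
# Conventions: rasters are base matrices indexed [row, col], 0-based nowhere —
# all coordinates are 1-based (row, col) integers; connectivity is 8-connected.

# result[r, c] = m[r + dr, c + dc], out-of-range cells filled with `fill`
shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

.N8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
             dc = c(-1,  0,  1, -1, 1, -1, 0, 1))

# number of TRUE 8-neighbors at every cell
neighbor_count_mat <- function(mask) {
  acc <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(.N8)))
    acc <- acc + shift_mat(mask, .N8[i, 1], .N8[i, 2])
  acc
}

# 8-connected component labelling of a logical mask via an igraph over
# foreground pixels; returns an integer matrix (0 = background).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  pos <- integer(length(mask)); pos[idx] <- seq_along(idx)
  # half of the 8 offsets suffices for an undirected graph
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  ei <- integer(0); ej <- integer(0)
  for (o in offs) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    idx2 <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[idx2]
    ei <- c(ei, pos[idx[ok]][hit])
    ej <- c(ej, pos[idx2][hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(ei)) g <- igraph::add_edges(g, rbind(ei, ej))
  memb <- igraph::components(g)$membership
  # renumber components by scan order (smallest linear index first)
  first_idx <- tapply(idx, memb, min)
  rank <- rank(first_idx)
  lab[idx] <- as.integer(rank[memb])
  lab
}

# offsets of a filled disc of given radius (pixels), including the center
disc_offsets <- function(radius) {
  r <- max(0L, as.integer(ceiling(radius)))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

# logical dilation by a disc structuring element
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  offs <- disc_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs)))
    out <- out | shift_mat(mask, offs[i, 1], offs[i, 2])
  out
}

# stamp pixel coordinates (n x 2 matrix, possibly out of canvas) into a mask
stamp_pixels <- function(mask, px) {
  ok <- px[, 1] >= 1 & px[, 1] <= nrow(mask) & px[, 2] >= 1 & px[, 2] <= ncol(mask)
  mask[px[ok, , drop = FALSE]] <- TRUE
  mask
}

# densely sample a polyline (k x 2 real matrix, (row, col)) at ~0.4 px spacing
# and return the integer pixel chain (deduplicated, order preserved)
rasterize_polyline <- function(poly) {
  if (nrow(poly) < 2) return(matrix(round(poly), ncol = 2))
  pts <- list()
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    n <- max(2L, ceiling(sqrt(sum((b - a)^2)) / 0.4))
    t <- seq(0, 1, length.out = n)
    pts[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  px <- round(do.call(rbind, pts))
  keep <- c(TRUE, rowSums(abs(diff(px))) > 0)
  px[keep, , drop = FALSE]
}

# unit-normalize rows of a 2-col matrix (zero rows stay zero)
unit_rows <- function(v) {
  n <- sqrt(rowSums(v^2))
  n[n == 0] <- 1
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a
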