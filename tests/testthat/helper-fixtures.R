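# Fixtures are built in code: small digital shapes with known structure,
# plus independent brute-force oracles used to cross-check the package.

# horizontal disk mask centered at (r, c)
disk_at <- function(nr, nc, r, c, radius) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - r)^2 + (cc - c)^2 <= radius^2
}

# Y-shape: stem from the left (entering a disk), two diagonal branches
y_mask <- function() {
  m <- matrix(FALSE, 64, 64)
  for (c in 8:32) m[32, c] <- TRUE
  for (i in 1:20) { m[32 - i, 32 + i] <- TRUE; m[32 + i, 32 + i] <- TRUE }
  list(mask = m, disk = disk_at(64, 64, 32, 8, 6))
}

# X-shape: two 1-px diagonal strokes crossing at the center; the two left
# tips fall inside the disk
x_mask <- function() {
  m <- matrix(FALSE, 64, 64)
  for (i in -20:20) { m[32 + i, 32 + i] <- TRUE; m[32 - i, 32 + i] <- TRUE }
  list(mask = m, disk = disk_at(64, 64, 32, 12, 22))
}

plus_mask <- function() {
  m <- matrix(FALSE, 20, 20)
  m[10, 6:14] <- TRUE
  m[6:14, 10] <- TRUE
  m
}

# brute-force Euclidean distance to the nearest background pixel
brute_force_edt <- function(mask) {
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (q in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[q, 1])^2 + (bg[, 2] - fg[q, 2])^2
    out[fg[q, 1], fg[q, 2]] <- sqrt(min(d2))
  }
  out
}

# independent proper-intersection test of segments pq and rs (determinant
# formulation, unlike the package's orientation-sign predicate)
oracle_intersects <- function(p, q, r, s) {
  d1 <- q - p; d2 <- s - r
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) return(FALSE)
  t <- ((r[1] - p[1]) * d2[2] - (r[2] - p[2]) * d2[1]) / den
  u <- ((r[1] - p[1]) * d1[2] - (r[2] - p[2]) * d1[1]) / den
  t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
}

# four random points in convex position
random_convex_quad <- function() {
  repeat {
    pts <- matrix(stats::runif(8, 0, 100), 4, 2)
    if (length(grDevices::chull(pts)) == 4) return(pts)
  }
}

# random blob mask (union of random discs) with a background border
random_blob_mask <- function(nr = 40, nc = 40, n_discs = 3) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(n_discs)) {
    m <- m | disk_at(nr, nc, stats::runif(1, 10, nr - 10),
                     stats::runif(1, 10, nc - 10), stats::runif(1, 3, 7))
  }
  m[1, ] <- FALSE; m[nr, ] <- FALSE; m[, 1] <- FALSE; m[, nc] <- FALSE
  m
}

# build a segment_set by hand from straight polyline chains; chains is a
# list of k x 2 matrices; junction table supplied explicitly
manual_segment_set <- function(chains, end_types, end_junctions, junctions,
                               dim = c(200, 200)) {
  segments <- lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    list(id = i, pixels = ch, radii = rep(1, nrow(ch)),
         end_type = end_types[[i]], end_junction = end_junctions[[i]],
         length = nrow(ch))
  })
  structure(list(segments = segments,
                 junctions = data.frame(id = seq_len(nrow(junctions)),
                                        row = junctions[, 1],
                                        col = junctions[, 2]),
                 root_ids = which(vapply(segments, function(sg)
                   any(sg$end_type == "ROOT"), logical(1))),
                 disk = NULL, dim = dim),
            class = "segment_set")
}

# integer chain approximating a straight ray from `from` (excluded end
# handling: includes both endpoints)
ray_chain <- function(from, angle_deg, len, step = 1) {
  u <- c(-sin(angle_deg * pi / 180), cos(angle_deg * pi / 180))
  t <- seq(0, len, by = step)
  px <- unique(round(cbind(from[1] + t * u[1], from[2] + t * u[2])))
  px
}

# spur geometry: a connector at `beta` degrees (acute line angle) to the two
# flanking arms at each of its two junctions
spur_segment_set <- function(beta, C) {
  j1 <- c(100, 100); j2 <- c(100, 100 + C + 1)
  conn <- ray_chain(c(100, 101), 0, C - 1)
  arms1 <- list(ray_chain(j1 + c(-1, -1), 180 - beta, 30),
                ray_chain(j1 + c(1, -1), beta - 180, 30))
  arms2 <- list(ray_chain(j2 + c(-1, 1), beta, 30),
                ray_chain(j2 + c(1, 1), -beta, 30))
  manual_segment_set(
    chains = c(list(conn), arms1, arms2),
    end_types = c(list(c("BRANCH", "BRANCH")),
                  rep(list(c("BRANCH", "END")), 4)),
    end_junctions = list(c(1L, 2L), c(1L, NA), c(1L, NA), c(2L, NA), c(2L, NA)),
    junctions = rbind(j1, j2))
}

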