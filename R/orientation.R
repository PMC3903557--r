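# Segment-end orientations and the three affinity shape functions.
#
# Each segment end carries an outward unit direction (pointing from the
# segment body into the junction / past the terminal). Without an intensity
# image, per-point directions are chain secants; with one, they are the
# Hessian ridge directions (eigenvector of the smallest-magnitude eigenvalue
# of the Gaussian-scale Hessian), sign-aligned with the secant. The end
# orientation averages the last `orientation_window` point directions.

# per-point outward secants toward a given end of a chain; each point uses a
# window centered on it where the chain allows, so curvature does not bias
# the estimate toward the segment interior
.end_secants <- function(chain, end, window, secant_w) {
  m <- nrow(chain)
  h <- max(1L, secant_w %/% 2)
  if (end == 1L) {
    idx <- seq_len(min(m, window))
    d <- chain[pmax(1L, idx - h), , drop = FALSE] -
         chain[pmin(m, idx + h), , drop = FALSE]
  } else {
    idx <- seq(max(1L, m - window + 1L), m)
    d <- chain[pmin(m, idx + h), , drop = FALSE] -
         chain[pmax(1L, idx - h), , drop = FALSE]
  }
  keep <- rowSums(d^2) > 0
  list(idx = idx[keep], d = unit_rows(d[keep, , drop = FALSE]))
}

# Hessian ridge direction field of a smoothed image: returns a function
# (r, c) -> unit tangent (dr, dc), sign-free
.hessian_field <- function(image, sigma) {
  sm <- as.matrix(EBImage::gblur(image, sigma = sigma))
  dr1 <- (shift_mat(sm, 1, 0, 0) - shift_mat(sm, -1, 0, 0)) / 2
  dc1 <- (shift_mat(sm, 0, 1, 0) - shift_mat(sm, 0, -1, 0)) / 2
  drr <- shift_mat(sm, 1, 0, 0) - 2 * sm + shift_mat(sm, -1, 0, 0)
  dcc <- shift_mat(sm, 0, 1, 0) - 2 * sm + shift_mat(sm, 0, -1, 0)
  drc <- (shift_mat(dr1, 0, 1, 0) - shift_mat(dr1, 0, -1, 0)) / 2
  function(r, c) {
    H <- matrix(c(drr[r, c], drc[r, c], drc[r, c], dcc[r, c]), 2)
    e <- eigen(H, symmetric = TRUE)
    e$vectors[, which.min(abs(e$values))]
  }
}

#' Compute outward end orientations for every segment
#'
#' @param segs a `segment_set`.
#' @param image optional numeric matrix; when given, per-point directions use
#'   the Hessian ridge orientation at scale `params$hessian_sigma`,
#'   sign-aligned with the chain secant.
#' @param params a [trace_params()] list.
#' @return object of class `end_orientations`: list with `dir` (n x 2 ends x
#'   2 (dr, dc) array of outward unit vectors) and `end_junction` (n x 2
#'   integer matrix).
#' @export
end_orientations <- function(segs, image = NULL, params = trace_params()) {
  n <- length(segs$segments)
  dir <- array(NA_real_, c(n, 2, 2))
  ej <- matrix(NA_integer_, n, 2)
  hf <- if (!is.null(image)) .hessian_field(image, params$hessian_sigma) else NULL
  for (sg in segs$segments) {
    ej[sg$id, ] <- sg$end_junction
    for (e in 1:2) {
      dir[sg$id, e, ] <- segment_end_orientation(sg, e, segs, hf, params)
    }
  }
  structure(list(dir = dir, end_junction = ej), class = "end_orientations")
}

#' Orientation of one segment end
#'
#' @param seg one segment record from a `segment_set`.
#' @param end 1 (first pixel) or 2 (last pixel).
#' @param segs the owning `segment_set` (junction geometry for 1-pixel
#'   segments).
#' @param hessian_field internal; precomputed ridge-direction closure or NULL.
#' @param params a [trace_params()] list.
#' @return outward unit vector `c(dr, dc)`.
#' @export
segment_end_orientation <- function(seg, end, segs, hessian_field = NULL,
                                    params = trace_params()) {
  chain <- seg$pixels
  m <- nrow(chain)
  if (m == 1) {
    j <- seg$end_junction[end]
    j <- if (is.na(j)) stats::na.omit(seg$end_junction)[1] else j
    if (!is.na(j) && length(j)) {
      v <- c(segs$junctions$row[j], segs$junctions$col[j]) - chain[1, ]
      if (sum(v^2) > 0) return(v / sqrt(sum(v^2)))
    }
    return(c(1, 0))  # isolated single pixel: arbitrary but deterministic
  }
  sc <- .end_secants(chain, end, params$orientation_window, params$secant_window)
  d <- sc$d
  if (!is.null(hessian_field)) {
    for (i in seq_len(nrow(d))) {
      p <- chain[sc$idx[i], ]
      t <- hessian_field(p[1], p[2])
      if (sum(t * d[i, ]) < 0) t <- -t  # sign-align with outward secant
      if (sum(t^2) > 0) d[i, ] <- t
    }
  }
  v <- colMeans(d)
  if (sum(v^2) == 0) v <- d[nrow(d), ]
  v <- v / sqrt(sum(v^2))
  # curvature compensation: on a curved chain the plain mean lags the
  # endpoint tangent by roughly half the window arc; extrapolate the linear
  # trend of the point directions to the end index instead
  if (nrow(d) >= 4) {
    ref <- atan2(v[1], v[2])
    ang <- atan2(d[, 1], d[, 2]) - ref
    ang <- atan2(sin(ang), cos(ang))
    x <- seq_along(ang)
    x_end <- if (end == 1L) 1L else length(ang)
    b <- stats::cov(x, ang) / stats::var(x)
    th <- ref + mean(ang) + b * (x_end - mean(x))
    v <- c(sin(th), cos(th))
  }
  v
}

#' Look up a segment's outward orientation at a junction
#'
#' @param orient an `end_orientations` object.
#' @param sid segment id.
#' @param jid junction id (NA selects a terminal end).
#' @return outward unit vector `c(dr, dc)`.
#' @export
orientation_at <- function(orient, sid, jid) {
  e <- if (is.na(jid)) which(is.na(orient$end_junction[sid, ]))
       else which(orient$end_junction[sid, ] == jid)
  if (!length(e)) e <- 1L
  orient$dir[sid, e[1], ]
}

#' Angle between two segment-end orientations
#'
#' Folds the angle between two outward unit vectors into `[0, 180)` degrees:
#' 180 (capped at 179.999) means a straight continuation through the
#' junction, 0 means doubling back.
#'
#' @param a,b outward unit vectors `c(dr, dc)`.
#' @return angle in degrees in `[0, 180)`.
#' @export
angle_between <- function(a, b) {
  ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  th <- rad2deg(acos(pmin(1, pmax(-1, ct))))
  min(th, 179.999)
}

.check_theta <- function(theta) {
  if (any(theta < 0 | theta >= 180))
    stop("theta must lie in [0, 180) degrees")
}

#' Affinity shape functions
#'
#' `eval_f1` is the piecewise continuation-affinity function:
#' `-sin(theta)^k` on `[0, theta_c)`, the constant plateau `-sin(theta_c)^k`
#' on `[theta_c, theta_star)`, and `k*cos(theta)` on `[theta_star, 180)`,
#' with `theta_star = acos(-sin(theta_c)^k / k)` so both breakpoints are
#' continuous. `eval_f2(theta) = k*cos(theta)` and
#' `eval_f3(theta) = k + k*sin(theta)`. Edge affinities are `exp(-f(theta))`,
#' so `exp(-f1)` is non-decreasing in the junction angle: straighter
#' continuations never get smaller affinity.
#'
#' @param theta angle(s) in degrees, in `[0, 180)`.
#' @param params a [trace_params()] list (`k`, `theta_c`, `theta_star`).
#' @return numeric vector of function values.
#' @export
eval_f1 <- function(theta, params = trace_params()) {
  .check_theta(theta)
  k <- params$k; tc <- params$theta_c; ts <- params$theta_star
  plateau <- -sin(deg2rad(tc))^k
  out <- ifelse(theta < tc, -sin(deg2rad(theta))^k,
                ifelse(theta < ts, plateau, k * cos(deg2rad(theta))))
  out
}

#' @rdname eval_f1
#' @export
eval_f2 <- function(theta, params = trace_params()) {
  .check_theta(theta)
  params$k * cos(deg2rad(theta))
}

#' @rdname eval_f1
#' @export
eval_f3 <- function(theta, params = trace_params()) {
  .check_theta(theta)
  params$k + params$k * sin(deg2rad(theta))
}
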