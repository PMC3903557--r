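# Segment extraction: from a classified skeleton to an ordered set of vessel
# segments bounded by terminal points and (merged) junctions.
#
# Mutually adjacent branching pixels are merged into one junction located at
# their centroid; a segment is a maximal chain of non-branching skeleton
# pixels, recorded in order with its per-pixel radii, the type of each end
# (ROOT / END / BRANCH) and, for BRANCH ends, the id of the bounding junction.

# order the pixels of one path component (each pixel has <= 2 neighbors
# within the component); cycles are opened at the smallest linear index
.trace_chain <- function(px, nr) {
  k <- nrow(px)
  if (k == 1) return(px)
  lin <- (px[, 2] - 1L) * nr + px[, 1]
  lookup <- new.env(hash = TRUE, size = 2L * k)
  for (i in seq_len(k)) assign(as.character(lin[i]), i, envir = lookup)
  nbrs <- function(i) {
    out <- integer(0)
    for (j in seq_len(nrow(.N8))) {
      l2 <- (px[i, 2] + .N8[j, 2] - 1L) * nr + (px[i, 1] + .N8[j, 1])
      hit <- mget(as.character(l2), envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(hit)) out <- c(out, hit)
    }
    out
  }
  deg <- vapply(seq_len(k), function(i) length(nbrs(i)), integer(1))
  ends <- which(deg <= 1L)
  start <- if (length(ends)) ends[which.min(lin[ends])] else which.min(lin)
  ord <- integer(k); visited <- logical(k)
  ord[1] <- start; visited[start] <- TRUE
  for (step in seq_len(k - 1L)) {
    nx <- nbrs(ord[step])
    nx <- nx[!visited[nx]]
    if (!length(nx)) break
    # prefer 4-adjacent continuation for stable digital chains
    if (length(nx) > 1) {
      d4 <- abs(px[nx, 1] - px[ord[step], 1]) + abs(px[nx, 2] - px[ord[step], 2])
      nx <- nx[order(d4, lin[nx])]
    }
    ord[step + 1L] <- nx[1]
    visited[nx[1]] <- TRUE
  }
  ord <- ord[ord > 0]
  px[ord, , drop = FALSE]
}

# junction labels adjacent to a pixel (sorted, unique)
.adjacent_junctions <- function(jlab, r, c) {
  nr <- nrow(jlab); nc <- ncol(jlab)
  out <- integer(0)
  for (j in seq_len(nrow(.N8))) {
    rr <- r + .N8[j, 1]; cc <- c + .N8[j, 2]
    if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && jlab[rr, cc] > 0)
      out <- c(out, jlab[rr, cc])
  }
  sort(unique(out))
}

#' Extract vessel segments from a classified skeleton
#'
#' @param skel a `skeleton_map` from [skeletonize_mask()].
#' @param disk optional logical matrix marking the (removed) optic-disk
#'   region; terminal pixels inside it (after a 2 px tolerance dilation)
#'   become ROOT ends and their segments root segments.
#' @param require_roots error when `disk` is given but no root is found.
#' @return an object of class `segment_set`: list with `segments` (list of
#'   per-segment records: `id`, `pixels` (ordered n x 2 matrix), `radii`,
#'   `end_type` (length-2 character in ROOT/END/BRANCH), `end_junction`
#'   (length-2 integer, NA for terminal ends), `length`), `junctions`
#'   (data.frame id/row/col), `root_ids`, `disk`, `dim`.
#' @export
extract_segments <- function(skel, disk = NULL, require_roots = !is.null(disk)) {
  stopifnot(inherits(skel, "skeleton_map"))
  cls <- skel$pixel_class
  nr <- nrow(cls)
  disk_tol <- if (!is.null(disk)) dilate_mask(disk, 2) else NULL

  jlab <- label_components(cls == PX_BRANCHING)
  njunc <- max(jlab)
  jpts <- matrix(NA_real_, njunc, 2)
  if (njunc > 0) {
    ji <- which(jlab > 0, arr.ind = TRUE)
    jpts[, 1] <- tapply(ji[, 1], jlab[jlab > 0], mean)
    jpts[, 2] <- tapply(ji[, 2], jlab[jlab > 0], mean)
  }

  path_mask <- skel$skeleton & cls != PX_BRANCHING
  plab <- label_components(path_mask)
  nseg <- max(plab)
  segments <- vector("list", nseg)
  for (s in seq_len(nseg)) {
    px <- which(plab == s, arr.ind = TRUE)
    colnames(px) <- NULL
    chain <- .trace_chain(px, nr)
    m <- nrow(chain)
    end_type <- character(2); end_junction <- c(NA_integer_, NA_integer_)
    if (m == 1) {
      ja <- .adjacent_junctions(jlab, chain[1, 1], chain[1, 2])
      if (length(ja) >= 2) {
        end_type <- c("BRANCH", "BRANCH"); end_junction <- ja[1:2]
      } else if (length(ja) == 1) {
        end_junction[1] <- ja[1]; end_type[1] <- "BRANCH"
        if (cls[chain[1, 1], chain[1, 2]] == PX_TERMINAL) {
          end_type[2] <- if (!is.null(disk_tol) && disk_tol[chain[1, 1], chain[1, 2]])
            "ROOT" else "END"
        } else { end_type[2] <- "BRANCH"; end_junction[2] <- ja[1] }
      } else {
        ty <- if (!is.null(disk_tol) && disk_tol[chain[1, 1], chain[1, 2]])
          "ROOT" else "END"
        end_type <- c(ty, ty)
      }
    } else {
      for (e in 1:2) {
        p <- chain[if (e == 1) 1 else m, ]
        ja <- .adjacent_junctions(jlab, p[1], p[2])
        if (length(ja)) {
          end_type[e] <- "BRANCH"; end_junction[e] <- ja[1]
        } else {
          end_type[e] <- if (!is.null(disk_tol) && disk_tol[p[1], p[2]])
            "ROOT" else "END"
        }
      }
    }
    segments[[s]] <- list(id = s, pixels = chain,
                          radii = skel$radius[chain],
                          end_type = end_type, end_junction = end_junction,
                          length = m)
  }

  root_ids <- which(vapply(segments, function(sg) any(sg$end_type == "ROOT"),
                           logical(1)))
  if (require_roots && length(root_ids) == 0)
    stop("no root segments: no terminal point falls inside the disk region")
  junctions <- data.frame(id = seq_len(njunc),
                          row = jpts[, 1], col = jpts[, 2])
  structure(list(segments = segments, junctions = junctions,
                 root_ids = root_ids, disk = disk, dim = dim(cls)),
            class = "segment_set")
}

# segment ids incident to each junction id
junction_members <- function(segs) {
  nj <- nrow(segs$junctions)
  members <- vector("list", nj)
  for (sg in segs$segments) {
    for (j in unique(stats::na.omit(sg$end_junction)))
      members[[j]] <- c(members[[j]], sg$id)
  }
  lapply(members, function(x) sort(unique(x)))
}

#' Remove spurious spur segments
#'
#' A short connector segment bounded by two junctions, lying at a small
#' average angle `beta` to its flanking branches, is a skeletonization
#' artifact of a crossover: it is deleted and its two junctions are merged
#' into one (so two 3-cliques collapse back into one 4-clique). `beta` is the
#' mean over the spur's two junctions of the smallest angle between the
#' spur's outward end orientation and each continuing branch. The pass is
#' iterated to a fixed point, making the operation idempotent.
#'
#' @param segs a `segment_set`.
#' @param params a [trace_params()] list (`beta_critical`, `C_critical`).
#' @param image optional grayscale image for Hessian-based orientations.
#' @return the filtered `segment_set` (segment ids renumbered compactly).
#' @export
remove_spurious_segments <- function(segs, params = trace_params(),
                                     image = NULL) {
  repeat {
    orient <- end_orientations(segs, image = image, params = params)
    members <- junction_members(segs)
    touched <- integer(0)
    victims <- list()
    for (sg in segs$segments) {
      if (!all(sg$end_type == "BRANCH")) next
      j1 <- sg$end_junction[1]; j2 <- sg$end_junction[2]
      if (is.na(j1) || is.na(j2) || j1 == j2) next
      if (sg$length > params$C_critical) next
      # only the two-3-cliques-from-one-4-clique artifact: merging then
      # restores a 4-way junction and can never grow an oversized junction
      if (length(members[[j1]]) != 3 || length(members[[j2]]) != 3) next
      if (j1 %in% touched || j2 %in% touched) next
      betas <- numeric(0)
      for (j in c(j1, j2)) {
        others <- setdiff(members[[j]], sg$id)
        if (!length(others)) next
        os <- orientation_at(orient, sg$id, j)
        th <- vapply(others, function(o)
          angle_between(os, orientation_at(orient, o, j)), numeric(1))
        th <- pmin(th, 180 - th)  # acute line angle spur-vs-branch
        betas <- c(betas, min(th))
      }
      if (!length(betas)) next
      if (mean(betas) <= params$beta_critical) {
        victims[[length(victims) + 1]] <- sg
        touched <- c(touched, j1, j2)
      }
    }
    if (!length(victims)) break
    segs <- .drop_segments_merge_junctions(segs, victims)
  }
  segs
}

# delete the victim segments and merge each one's junction pair; segment and
# junction ids are compacted afterwards
.drop_segments_merge_junctions <- function(segs, victims) {
  drop_ids <- vapply(victims, `[[`, integer(1), "id")
  nj <- nrow(segs$junctions)
  jmap <- seq_len(nj)
  for (v in victims) {
    a <- min(v$end_junction); b <- max(v$end_junction)
    pt <- c(mean(segs$junctions$row[c(a, b)]),
            mean(segs$junctions$col[c(a, b)]))
    segs$junctions[a, c("row", "col")] <- pt
    jmap[jmap == b] <- a
  }
  alive <- sort(unique(jmap))
  jcompact <- match(jmap, alive)
  keep <- segs$segments[!vapply(segs$segments, function(s)
    s$id %in% drop_ids, logical(1))]
  for (i in seq_along(keep)) {
    ej <- keep[[i]]$end_junction
    ok <- !is.na(ej)
    ej[ok] <- jcompact[ej[ok]]
    keep[[i]]$end_junction <- ej
    keep[[i]]$id <- i
  }
  segs$junctions <- segs$junctions[alive, , drop = FALSE]
  segs$junctions$id <- seq_len(nrow(segs$junctions))
  rownames(segs$junctions) <- NULL
  segs$segments <- keep
  segs$root_ids <- which(vapply(keep, function(sg) any(sg$end_type == "ROOT"),
                                logical(1)))
  segs
}
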