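# Cubic Bezier centerlines: the pathway primitive every graft is lofted along.

MIN_SEGMENT_CHORD_MM <- 0.01

as_point3 <- function(x, what = "point") {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x))) {
    stop(sprintf("%s must be a finite numeric 3-vector", what), call. = FALSE)
  }
  x
}

#' Cubic Bezier segment
#'
#' A single cubic Bezier curve defined by two anchor points (interpolated
#' endpoints, the centers of two cross-sections) and two handle points that
#' set the direction and strength of the pathway. All coordinates in mm.
#'
#' @param p0,p3 Anchor points (numeric 3-vectors, mm); the curve passes
#'   through them at `t = 0` and `t = 1`.
#' @param p1,p2 Handle points (numeric 3-vectors, mm).
#' @return An object of class `bezier_segment`.
#' @export
#' @examples
#' seg <- bezier_segment(c(0, 0, 0), c(0, 0, 5), c(0, 0, 15), c(0, 0, 20))
#' bezier_eval(seg, 0.5)
bezier_segment <- function(p0, p1, p2, p3) {
  p0 <- as_point3(p0, "p0"); p1 <- as_point3(p1, "p1")
  p2 <- as_point3(p2, "p2"); p3 <- as_point3(p3, "p3")
  if (sqrt(sum((p3 - p0)^2)) < MIN_SEGMENT_CHORD_MM) {
    stop("degenerate Bezier segment: anchor chord shorter than ",
         MIN_SEGMENT_CHORD_MM, " mm", call. = FALSE)
  }
  structure(list(p0 = p0, p1 = p1, p2 = p2, p3 = p3),
            class = "bezier_segment")
}

#' Evaluate a cubic Bezier segment
#'
#' Standard Bernstein cubic basis:
#' `P(t) = P0 (1-t)^3 + 3 P1 t (1-t)^2 + 3 P2 t^2 (1-t) + P3 t^3`,
#' so the anchors are interpolated exactly at the ends.
#'
#' @param segment A [bezier_segment()].
#' @param t Parameter value(s) in `[0, 1]`.
#' @return A numeric 3-vector for scalar `t`, otherwise a `length(t) x 3`
#'   matrix of points (mm).
#' @export
bezier_eval <- function(segment, t) {
  stopifnot(inherits(segment, "bezier_segment"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1)) {
    stop("t must lie in [0, 1]", call. = FALSE)
  }
  u <- 1 - t
  cp <- rbind(segment$p0, segment$p1, segment$p2, segment$p3)
  w <- cbind(u^3, 3 * t * u^2, 3 * t^2 * u, t^3)
  out <- w %*% cp
  if (length(t) == 1L) as.numeric(out) else unname(out)
}

bezier_tangent <- function(segment, t) {
  u <- 1 - t
  d <- 3 * (u^2 %o% (segment$p1 - segment$p0) +
            (2 * u * t) %o% (segment$p2 - segment$p1) +
            t^2 %o% (segment$p3 - segment$p2))
  if (length(t) == 1L) as.numeric(d) else unname(d)
}

#' Piecewise-cubic Bezier path
#'
#' An ordered chain of [bezier_segment()]s with C0 continuity: each
#' segment's end anchor is the next segment's start anchor. The path also
#' carries a global arc-length-normalized parameter in `[0, 1]`.
#'
#' @param segments A list of `bezier_segment` objects (at least one).
#' @return An object of class `bezier_path`.
#' @export
bezier_path <- function(segments) {
  if (inherits(segments, "bezier_segment")) segments <- list(segments)
  if (length(segments) < 1L ||
      !all(vapply(segments, inherits, logical(1), "bezier_segment"))) {
    stop("segments must be a non-empty list of bezier_segment objects",
         call. = FALSE)
  }
  if (length(segments) > 1L) {
    for (k in seq_len(length(segments) - 1L)) {
      gap <- sqrt(sum((segments[[k]]$p3 - segments[[k + 1L]]$p0)^2))
      if (gap > 1e-9) {
        stop(sprintf("path is not C0-continuous at segment %d (gap %.3g mm)",
                     k, gap), call. = FALSE)
      }
    }
  }
  structure(list(segments = segments), class = "bezier_path")
}

#' @export
print.bezier_path <- function(x, ...) {
  cat(sprintf("<bezier_path> %d segment(s), arc length %.3f mm\n",
              length(x$segments), path_length(x)))
  invisible(x)
}

# Dense arc-length table used for the global parameterization.
path_arclength_table <- function(path, samples_per_segment = 200L) {
  n <- length(path$segments)
  ts <- seq(0, 1, length.out = samples_per_segment)
  pts <- vector("list", n)
  for (k in seq_len(n)) pts[[k]] <- bezier_eval(path$segments[[k]], ts)
  all_pts <- do.call(rbind, pts)
  seg_id <- rep(seq_len(n), each = samples_per_segment)
  loc_t <- rep(ts, n)
  d <- sqrt(rowSums((all_pts[-1L, , drop = FALSE] -
                     all_pts[-nrow(all_pts), , drop = FALSE])^2))
  # joints between segments contribute zero length (C0 continuity)
  s <- c(0, cumsum(d))
  list(points = all_pts, seg = seg_id, t = loc_t, s = s)
}

#' Total arc length of a path (mm)
#' @param path A [bezier_path()].
#' @export
path_length <- function(path) {
  tab <- path_arclength_table(path)
  tab$s[length(tab$s)]
}

#' Evaluate a path at arc-length-normalized positions
#'
#' @param path A [bezier_path()].
#' @param u Global parameter(s) in `[0, 1]`, proportional to arc length.
#' @return Point(s) on the path (mm); matrix for vector `u`.
#' @export
path_eval <- function(path, u) {
  u <- as.numeric(u)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1)) {
    stop("u must lie in [0, 1]", call. = FALSE)
  }
  tab <- path_arclength_table(path)
  total <- tab$s[length(tab$s)]
  if (total <= 0) stop("zero-length path", call. = FALSE)
  idx <- findInterval(u * total, tab$s, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(tab$s) - 1L)
  frac <- (u * total - tab$s[idx]) / pmax(tab$s[idx + 1L] - tab$s[idx], 1e-300)
  out <- matrix(NA_real_, length(u), 3L)
  for (i in seq_along(u)) {
    k <- tab$seg[idx[i]]
    k2 <- tab$seg[idx[i] + 1L]
    if (k == k2) {
      tt <- tab$t[idx[i]] + frac[i] * (tab$t[idx[i] + 1L] - tab$t[idx[i]])
    } else {           # crossing a joint: snap to whichever side
      tt <- if (frac[i] < 0.5) tab$t[idx[i]] else { k <- k2; tab$t[idx[i] + 1L] }
    }
    out[i, ] <- bezier_eval(path$segments[[k]], tt)
  }
  if (length(u) == 1L) as.numeric(out) else out
}

path_tangent_at <- function(path, u) {
  tab <- path_arclength_table(path)
  total <- tab$s[length(tab$s)]
  idx <- findInterval(u * total, tab$s, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(tab$s) - 1L)
  k <- tab$seg[idx]
  tt <- tab$t[idx]
  d <- bezier_tangent(path$segments[[k[1]]], tt[1])
  if (length(u) == 1L) return(d / sqrt(sum(d^2)))
  out <- matrix(NA_real_, length(u), 3L)
  for (i in seq_along(u)) {
    d <- bezier_tangent(path$segments[[k[i]]], tt[i])
    out[i, ] <- d / sqrt(sum(d^2))
  }
  out
}

#' Insert an anchor point into a path
#'
#' Splits one cubic segment into two cubic segments at local parameter
#' `t_split` by de Casteljau subdivision, which is shape-preserving: the
#' traced curve is geometrically unchanged, one more anchor exists, and the
#' two new handles flank the new anchor.
#'
#' @param path A [bezier_path()].
#' @param segment_index Which segment to split (1-based).
#' @param t_split Local parameter in the open interval (0, 1).
#' @return A new `bezier_path` with one additional segment.
#' @export
insert_anchor <- function(path, segment_index, t_split) {
  stopifnot(inherits(path, "bezier_path"))
  n <- length(path$segments)
  if (!is.numeric(segment_index) || segment_index < 1 || segment_index > n) {
    stop("segment_index out of range", call. = FALSE)
  }
  if (!is.numeric(t_split) || t_split <= 0 || t_split >= 1) {
    stop("degenerate split: t_split must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  seg <- path$segments[[segment_index]]
  t <- t_split
  # de Casteljau construction
  q0 <- (1 - t) * seg$p0 + t * seg$p1
  q1 <- (1 - t) * seg$p1 + t * seg$p2
  q2 <- (1 - t) * seg$p2 + t * seg$p3
  r0 <- (1 - t) * q0 + t * q1
  r1 <- (1 - t) * q1 + t * q2
  s0 <- (1 - t) * r0 + t * r1   # the new anchor, on the original curve
  left  <- bezier_segment(seg$p0, q0, r0, s0)
  right <- bezier_segment(s0, r1, q2, seg$p3)
  segs <- append(path$segments[-segment_index], list(left, right),
                 after = segment_index - 1L)
  bezier_path(segs)
}

#' Path anchors
#'
#' @param path A [bezier_path()].
#' @return Matrix of the path's anchor points, one row per anchor
#'   (`n_segments + 1` rows).
#' @export
path_anchors <- function(path) {
  a <- t(vapply(path$segments, function(s) s$p0, numeric(3)))
  unname(rbind(a, path$segments[[length(path$segments)]]$p3))
}
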