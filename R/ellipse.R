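# Anastomosis ellipses and cross-sections.

MIN_RADIUS_MM <- 0.1

vnorm <- function(v) sqrt(sum(v^2))
unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Anastomosis ellipse
#'
#' The elliptical suturing cross-section where a graft joins a vessel,
#' defined by its center and two semi-axis vectors. The second axis is
#' projected onto the orthogonal complement of the first before use, so the
#' stored axes are always perpendicular; if the supplied axes deviate from
#' perpendicular by more than 30 degrees a warning is raised.
#'
#' @param center Ellipse center (numeric 3-vector, mm).
#' @param axis_a First semi-axis vector (mm); its magnitude is `a`.
#' @param axis_b Second semi-axis vector (mm); its magnitude is `b`
#'   (taken after orthogonal projection).
#' @return An object of class `anastomosis_ellipse`.
#' @export
anastomosis_ellipse <- function(center, axis_a, axis_b) {
  center <- as_point3(center, "center")
  axis_a <- as_point3(axis_a, "axis_a")
  axis_b <- as_point3(axis_b, "axis_b")
  a <- vnorm(axis_a)
  if (a < MIN_RADIUS_MM) {
    stop("semi-axis a below the ", MIN_RADIUS_MM, " mm minimum", call. = FALSE)
  }
  ua <- axis_a / a
  cosang <- abs(sum(unitize(axis_b) * ua))
  if (cosang > sin(30 * pi / 180)) {
    warning(sprintf(
      "ellipse axes deviate from perpendicular by %.1f degrees; axis_b projected",
      asin(min(cosang, 1)) * 180 / pi))
  }
  b_perp <- axis_b - sum(axis_b * ua) * ua
  b <- vnorm(b_perp)
  if (b < MIN_RADIUS_MM) {
    stop("semi-axis b below the ", MIN_RADIUS_MM,
         " mm minimum after orthogonalization", call. = FALSE)
  }
  structure(list(center = center, axis_a = axis_a, axis_b = b_perp,
                 a = a, b = b),
            class = "anastomosis_ellipse")
}

#' Polar radius of an ellipse
#'
#' Center-to-boundary distance at polar angle `theta`, measured from the
#' first semi-axis: `r(theta) = a b / sqrt((b cos)^2 + (a sin)^2)`.
#'
#' @param ellipse An [anastomosis_ellipse()].
#' @param theta Polar angle(s), radians.
#' @return Radius (mm), vectorized over `theta`.
#' @export
ellipse_radius <- function(ellipse, theta) {
  stopifnot(inherits(ellipse, "anastomosis_ellipse"))
  a <- ellipse$a; b <- ellipse$b
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

ellipse_normal <- function(ellipse) {
  unitize(cross3(ellipse$axis_a, ellipse$axis_b))
}

#' Sampled cross-section
#'
#' A planar cross-section of a graft: a center, an orthonormal in-plane
#' frame, and one radius per equally spaced polar angle. The boundary point
#' at angle `theta_j = 2*pi*(j-1)/M` is
#' `center + r_j (cos(theta_j) e1 + sin(theta_j) e2)`.
#'
#' @param center Section center (mm).
#' @param e1,e2 In-plane unit axes; `e2` is orthogonalized against `e1`.
#' @param radii Numeric vector of `M >= 8` positive radii (mm), one per
#'   equally spaced angle.
#' @return An object of class `cross_section`.
#' @export
cross_section <- function(center, e1, e2, radii) {
  center <- as_point3(center, "center")
  e1 <- unitize(as_point3(e1, "e1"))
  e2 <- as_point3(e2, "e2")
  e2 <- unitize(e2 - sum(e2 * e1) * e1)
  radii <- as.numeric(radii)
  if (length(radii) < 8L) stop("a cross-section needs at least 8 radii",
                               call. = FALSE)
  if (any(!is.finite(radii)) || any(radii < MIN_RADIUS_MM)) {
    stop("all radii must be finite and at least ", MIN_RADIUS_MM, " mm",
         call. = FALSE)
  }
  structure(list(center = center, e1 = e1, e2 = e2, radii = radii),
            class = "cross_section")
}

#' @rdname cross_section
#' @param normal Plane normal for a circular section.
#' @param radius Circle radius (mm).
#' @param m Number of angular samples.
#' @export
circular_section <- function(center, normal, radius, m = 32L) {
  normal <- unitize(as_point3(normal, "normal"))
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(cross3(ref, normal))
  e2 <- cross3(normal, e1)
  cross_section(center, e1, e2, rep(radius, m))
}

#' Cross-section sampled from an anastomosis ellipse
#'
#' Samples `m` polar radii of the ellipse (measured from `axis_a`) so the
#' section boundary lies exactly on the ellipse.
#'
#' @param ellipse An [anastomosis_ellipse()].
#' @param m Number of angular samples.
#' @return A [cross_section()].
#' @export
section_from_ellipse <- function(ellipse, m = 32L) {
  theta <- 2 * pi * (seq_len(m) - 1L) / m
  cross_section(ellipse$center,
                ellipse$axis_a / ellipse$a,
                ellipse$axis_b / ellipse$b,
                ellipse_radius(ellipse, theta))
}

section_points <- function(cs) {
  m <- length(cs$radii)
  theta <- 2 * pi * (seq_len(m) - 1L) / m
  outer(rep(1, m), cs$center) +
    cs$radii * (cos(theta) %o% cs$e1 + sin(theta) %o% cs$e2)
}

section_normal <- function(cs) cross3(cs$e1, cs$e2)
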