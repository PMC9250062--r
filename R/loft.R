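# Sweep lofting: cross-sections interpolated along a Bezier path.

# Rotation-minimizing frames by the double-reflection method. Given ring
# centers, unit tangents, and an initial in-plane axis, returns per-ring
# orthonormal (e1, e2) with minimal twist.
rm_frames <- function(centers, tangents, e1_0) {
  n <- nrow(centers)
  e1 <- matrix(NA_real_, n, 3L)
  e2 <- matrix(NA_real_, n, 3L)
  t0 <- tangents[1L, ]
  r <- unitize(e1_0 - sum(e1_0 * t0) * t0)
  e1[1L, ] <- r
  e2[1L, ] <- cross3(t0, r)
  for (i in seq_len(n - 1L)) {
    v1 <- centers[i + 1L, ] - centers[i, ]
    c1 <- sum(v1 * v1)
    if (c1 < 1e-24) {            # coincident centers: carry the frame over
      e1[i + 1L, ] <- e1[i, ]; e2[i + 1L, ] <- e2[i, ]
      next
    }
    rL <- e1[i, ] - (2 / c1) * sum(v1 * e1[i, ]) * v1
    tL <- tangents[i, ] - (2 / c1) * sum(v1 * tangents[i, ]) * v1
    v2 <- tangents[i + 1L, ] - tL
    c2 <- sum(v2 * v2)
    r_next <- if (c2 < 1e-24) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    r_next <- unitize(r_next - sum(r_next * tangents[i + 1L, ]) * tangents[i + 1L, ])
    e1[i + 1L, ] <- r_next
    e2[i + 1L, ] <- cross3(tangents[i + 1L, ], r_next)
  }
  list(e1 = e1, e2 = e2)
}

# Signed in-plane angle taking frame (e1,e2) onto target vector v.
inplane_angle <- function(v, e1, e2) atan2(sum(v * e2), sum(v * e1))

# Ring vertices and ring-to-ring triangulation shared by the loft builders.
# Returns the structured grid so the bifurcation builder can cut windows.
loft_grid <- function(path, start_section, end_section, n_rings, m_samples,
                      f = smoothstep) {
  f <- interp_fun(f)
  m0 <- length(start_section$radii)
  if (m0 != length(end_section$radii)) {
    stop("start and end sections must have matching sample counts",
         call. = FALSE)
  }
  if (n_rings < 2L) stop("n_rings must be at least 2", call. = FALSE)
  if (m_samples < 8L) stop("m_samples must be at least 8", call. = FALSE)
  if (m0 != m_samples) {
    stop("sections must be sampled at m_samples angles", call. = FALSE)
  }
  if (path_length(path) < MIN_SEGMENT_CHORD_MM) {
    stop("zero-length path", call. = FALSE)
  }
  u <- seq(0, 1, length.out = n_rings)
  centers <- path_eval(path, u)
  tangents <- path_tangent_at(path, u)
  fr <- rm_frames(centers, tangents, start_section$e1)
  # distribute the in-plane rotation between the transported start frame
  # and the end section's own frame so both end rings lie exactly on the
  # given sections
  phi_end <- inplane_angle(end_section$e1, fr$e1[n_rings, ], fr$e2[n_rings, ])
  theta <- 2 * pi * (seq_len(m_samples) - 1L) / m_samples
  ft <- f(u)
  verts <- matrix(NA_real_, n_rings * m_samples, 3L)
  for (i in seq_len(n_rings)) {
    if (i == 1L) {
      ring <- section_points(start_section)
    } else if (i == n_rings) {
      ring <- section_points(end_section)
    } else {
      phi <- phi_end * u[i]
      a1 <- cos(phi) * fr$e1[i, ] + sin(phi) * fr$e2[i, ]
      a2 <- -sin(phi) * fr$e1[i, ] + cos(phi) * fr$e2[i, ]
      r_i <- start_section$radii + (end_section$radii - start_section$radii) * ft[i]
      ring <- outer(rep(1, m_samples), centers[i, ]) +
        r_i * (cos(theta) %o% a1 + sin(theta) %o% a2)
    }
    verts[(i - 1L) * m_samples + seq_len(m_samples), ] <- ring
  }
  # quad strip faces between consecutive rings, split into triangles;
  # winding chosen so normals point outward when (e1, e2, tangent) is
  # right-handed
  fc <- vector("list", n_rings - 1L)
  for (i in seq_len(n_rings - 1L)) {
    j <- seq_len(m_samples)
    jn <- c(j[-1L], j[1L])
    a <- (i - 1L) * m_samples + j
    b <- (i - 1L) * m_samples + jn
    c_ <- i * m_samples + jn
    d <- i * m_samples + j
    fc[[i]] <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  }
  list(vertices = verts, faces = do.call(rbind, fc),
       n_rings = n_rings, m = m_samples, u = u, centers = centers)
}

#' Loft a tube between two cross-sections along a path
#'
#' Sweeps `n_rings` cross-sections along the path at arc-length-uniform
#' positions. Each intermediate ring's radius at angle `theta_j` is the
#' adjusted interpolation `r0_j + (r1_j - r0_j) f(t)` between the
#' corresponding start and end radii; the two end rings lie exactly on the
#' given sections. Section orientation along the path uses
#' rotation-minimizing frames (double-reflection method) with any residual
#' in-plane rotation to the end section distributed linearly, so the sweep
#' carries no twist artifacts.
#'
#' @param path A [bezier_path()].
#' @param start_section,end_section [cross_section()]s with `m_samples`
#'   radii each.
#' @param n_rings Number of rings along the path (>= 2).
#' @param m_samples Number of angular samples per ring (>= 8).
#' @param f Interpolation adjustment function or name (see [smoothstep()]).
#' @param caps If `TRUE`, close both ends with triangle fans to the ring
#'   centers, giving a watertight genus-0 mesh; if `FALSE`, leave the two
#'   rims as tagged open loops.
#' @param tags Length-2 character vector naming the start and end loops.
#' @return A [graft_mesh()].
#' @export
#' @examples
#' p <- bezier_path(bezier_segment(c(0, 0, 0), c(0, 0, 7),
#'                                 c(0, 0, 13), c(0, 0, 20)))
#' cs <- circular_section(c(0, 0, 0), c(0, 0, 1), 5, 32)
#' ce <- circular_section(c(0, 0, 20), c(0, 0, 1), 5, 32)
#' m <- loft_tube(p, cs, ce, n_rings = 16, m_samples = 32, caps = TRUE)
#' mesh_is_watertight(m)
loft_tube <- function(path, start_section, end_section,
                      n_rings = 32L, m_samples = 32L, f = smoothstep,
                      caps = TRUE, tags = c("inlet", "outlet")) {
  g <- loft_grid(path, start_section, end_section, n_rings, m_samples, f)
  ring_idx <- function(i) (i - 1L) * g$m + seq_len(g$m)
  tags_list <- list(rev(ring_idx(1L)), ring_idx(g$n_rings))
  names(tags_list) <- tags
  mesh <- graft_mesh(g$vertices, g$faces, tags_list)
  mesh <- drop_degenerate_faces(mesh)
  if (caps) mesh <- cap_mesh(mesh) else mesh <- orient_mesh(mesh)
  mesh
}
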