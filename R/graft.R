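# Tube and bifurcated graft construction.

# Keep the part of a path from global parameter 0 to u_cut (arc-length
# normalized), splitting the segment that contains u_cut.
path_truncate <- function(path, u_cut) {
  stopifnot(u_cut > 0, u_cut < 1)
  tab <- path_arclength_table(path)
  total <- tab$s[length(tab$s)]
  idx <- findInterval(u_cut * total, tab$s, rightmost.closed = TRUE)
  k <- tab$seg[idx]
  # local parameter within segment k at the cut
  tt <- tab$t[idx]
  tt2 <- if (idx < length(tab$s) && tab$seg[idx + 1L] == k) tab$t[idx + 1L] else tt
  frac <- (u_cut * total - tab$s[idx]) /
    max(tab$s[min(idx + 1L, length(tab$s))] - tab$s[idx], 1e-300)
  t_loc <- tt + frac * (tt2 - tt)
  t_loc <- min(max(t_loc, 1e-6), 1 - 1e-6)
  seg <- path$segments[[k]]
  t <- t_loc
  q0 <- (1 - t) * seg$p0 + t * seg$p1
  q1 <- (1 - t) * seg$p1 + t * seg$p2
  q2 <- (1 - t) * seg$p2 + t * seg$p3
  r0 <- (1 - t) * q0 + t * q1
  r1 <- (1 - t) * q1 + t * q2
  s0 <- (1 - t) * r0 + t * r1
  left <- bezier_segment(seg$p0, q0, r0, s0)
  segs <- c(if (k > 1L) path$segments[seq_len(k - 1L)], list(left))
  bezier_path(segs)
}

check_endpoint <- function(point, target, what, tol) {
  d <- sqrt(sum((point - target)^2))
  if (d > tol) {
    stop(sprintf("%s is %.3f mm from the path endpoint (tolerance %g mm)",
                 what, d, tol), call. = FALSE)
  }
}

#' Build a tube-shaped Fontan graft
#'
#' Lofts a single-channel graft from the native IVC cross-section to a
#' user-defined anastomosis ellipse along a cubic Bezier pathway. The
#' path's first anchor must coincide with the IVC section center and its
#' last anchor with the anastomosis center.
#'
#' @param ivc_section A [cross_section()] of the native IVC surface.
#' @param anastomosis An [anastomosis_ellipse()] for the suturing region.
#' @param path A [bezier_path()] from the IVC center to the ellipse center.
#' @param n_rings,m_samples Sampling resolution of the sweep.
#' @param f Interpolation adjustment function or name.
#' @param caps Close the ends (watertight solid) or leave the two rims
#'   open, tagged `"IVC_inlet"` and `"PA_anastomosis_1"`.
#' @param tol Endpoint-coincidence tolerance, mm.
#' @return A [graft_mesh()].
#' @export
build_tube_graft <- function(ivc_section, anastomosis, path,
                             n_rings = 32L, m_samples = 32L,
                             f = smoothstep, caps = FALSE, tol = 0.1) {
  stopifnot(inherits(ivc_section, "cross_section"),
            inherits(anastomosis, "anastomosis_ellipse"),
            inherits(path, "bezier_path"))
  if (length(ivc_section$radii) != m_samples) {
    stop("ivc_section must be sampled at m_samples angles", call. = FALSE)
  }
  check_endpoint(path$segments[[1L]]$p0, ivc_section$center,
                 "IVC section center", tol)
  check_endpoint(path$segments[[length(path$segments)]]$p3,
                 anastomosis$center, "anastomosis center", tol)
  end_section <- section_from_ellipse(anastomosis, m_samples)
  loft_tube(path, ivc_section, end_section, n_rings, m_samples, f,
            caps = caps, tags = c("IVC_inlet", "PA_anastomosis_1"))
}

# Ordered perimeter of a rectangular window cut from the trunk ring grid.
# Rows ib..it (rings), columns are the circular index set js of cells.
window_perimeter <- function(ib, it, cols, m) {
  wrap <- function(j) ((j - 1L) %% m) + 1L
  vcols <- wrap(seq(cols[1L], cols[1L] + length(cols)))  # cell cols + 1 extra
  idx <- function(i, j) (i - 1L) * m + j
  bottom <- idx(ib, vcols)
  right <- idx(seq(ib + 1L, it), vcols[length(vcols)])
  top <- idx(it, rev(vcols[-length(vcols)]))
  left <- idx(seq(it - 1L, ib + 1L), vcols[1L])
  c(bottom, right, top, if (it - ib >= 2L) left)
}

# Bridge two ordered vertex-index loops with a triangle "zipper" keyed to
# normalized cumulative arc length; direction/phase of the second loop is
# chosen to minimize total rung length.
zipper_loops <- function(vertices, loop_a, loop_b) {
  params <- function(loop) {
    p <- vertices[loop, , drop = FALSE]
    d <- sqrt(rowSums((p - p[c(2:nrow(p), 1L), , drop = FALSE])^2))
    s <- c(0, cumsum(d))
    s[-length(s)] / s[length(s)]
  }
  score <- function(lb) {
    pa <- vertices[loop_a, , drop = FALSE]
    pb <- vertices[lb, , drop = FALSE]
    sa <- params(loop_a); sb <- params(lb)
    # nearest-parameter correspondence cost
    j <- pmin(findInterval(sa, sb) + 1L, length(lb))
    sum(sqrt(rowSums((pa - pb[pmax(j, 1L), , drop = FALSE])^2)))
  }
  best <- NULL; best_cost <- Inf
  nb <- length(loop_b)
  for (dir in list(loop_b, rev(loop_b))) {
    # phase: start the second loop at its vertex nearest the first loop's start
    d0 <- sqrt(rowSums((vertices[dir, , drop = FALSE] -
                        matrix(vertices[loop_a[1L], ], nb, 3L, byrow = TRUE))^2))
    ph <- which.min(d0)
    cand <- c(dir[ph:nb], if (ph > 1L) dir[1:(ph - 1L)])
    cost <- score(cand)
    if (cost < best_cost) { best <- cand; best_cost <- cost }
  }
  loop_b <- best
  sa <- params(loop_a); sb <- params(loop_b)
  na <- length(loop_a)
  faces <- matrix(0L, na + nb, 3L)
  i <- 1L; j <- 1L; k <- 0L
  while (i <= na || j <= nb) {
    a_next <- if (i < na) sa[i + 1L] else 1
    b_next <- if (j < nb) sb[j + 1L] else 1
    ai <- loop_a[((i - 1L) %% na) + 1L]
    bi <- loop_b[((j - 1L) %% nb) + 1L]
    k <- k + 1L
    if ((i <= na && a_next <= b_next) || j > nb) {
      faces[k, ] <- c(ai, loop_a[(i %% na) + 1L], bi)
      i <- i + 1L
    } else {
      faces[k, ] <- c(ai, loop_b[(j %% nb) + 1L], bi)
      j <- j + 1L
    }
  }
  faces[seq_len(k), , drop = FALSE]
}

#' Build a bifurcated Fontan graft
#'
#' Constructs a single watertight surface with one IVC inlet and two
#' pulmonary-artery anastomoses. The trunk is lofted along `path1` from
#' the IVC section to the first anastomosis; the branch is lofted along
#' `path2` from the second anastomosis toward a user-specified split
#' region on the trunk (path position `split_point`). Where the branch
#' reaches the trunk surface, a window of the trunk's structured ring grid
#' is removed and the branch's end ring is stitched to the window
#' perimeter, which yields a watertight genus-0 mesh when capped.
#'
#' @param ivc_section A [cross_section()] of the native IVC surface.
#' @param anastomosis1,anastomosis2 [anastomosis_ellipse()]s for the two
#'   suturing regions (trunk end and branch inlet).
#' @param split_point Trunk path position in (0, 1) where the branch joins.
#' @param path1 Trunk [bezier_path()]: IVC center to `anastomosis1` center.
#' @param path2 Branch [bezier_path()]: `anastomosis2` center to the split
#'   region (its end anchor must reach the trunk; it is truncated at the
#'   trunk surface).
#' @param n_rings,m_samples Trunk sampling resolution.
#' @param branch_rings,branch_samples Branch sampling resolution.
#' @param f Interpolation adjustment function or name.
#' @param caps Close the three rims or leave them tagged open
#'   (`"IVC_inlet"`, `"PA_anastomosis_1"`, `"PA_anastomosis_2"`).
#' @param tol Endpoint-coincidence tolerance, mm.
#' @return A [graft_mesh()].
#' @export
build_bifurcated_graft <- function(ivc_section, anastomosis1, anastomosis2,
                                   split_point, path1, path2,
                                   n_rings = 48L, m_samples = 32L,
                                   branch_rings = 24L, branch_samples = 24L,
                                   f = smoothstep, caps = FALSE, tol = 0.1) {
  stopifnot(inherits(path1, "bezier_path"), inherits(path2, "bezier_path"))
  if (!is.numeric(split_point) || split_point <= 0 || split_point >= 1) {
    stop("split_point must lie strictly inside (0, 1) on the trunk",
         call. = FALSE)
  }
  check_endpoint(path1$segments[[1L]]$p0, ivc_section$center,
                 "IVC section center", tol)
  check_endpoint(path1$segments[[length(path1$segments)]]$p3,
                 anastomosis1$center, "anastomosis 1 center", tol)
  check_endpoint(path2$segments[[1L]]$p0, anastomosis2$center,
                 "anastomosis 2 center", tol)

  sec1 <- section_from_ellipse(anastomosis1, m_samples)
  g <- loft_grid(path1, ivc_section, sec1, n_rings, m_samples, f)
  fi <- interp_fun(f)
  ring_mean_r <- mean(ivc_section$radii) +
    (mean(sec1$radii) - mean(ivc_section$radii)) * fi(g$u)

  # truncate the branch path where it first enters the trunk surface
  us <- seq(0.01, 0.999, length.out = 400L)
  bp <- path_eval(path2, us)
  # distance from each branch sample to the trunk centerline (dense)
  tc <- path_eval(path1, seq(0, 1, length.out = 200L))
  tr <- mean(ivc_section$radii) +
    (mean(sec1$radii) - mean(ivc_section$radii)) *
    fi(seq(0, 1, length.out = 200L))
  nearest <- function(p) {
    d2 <- (tc[, 1] - p[1])^2 + (tc[, 2] - p[2])^2 + (tc[, 3] - p[3])^2
    which.min(d2)
  }
  hit <- NA_integer_
  for (i in seq_along(us)) {
    ni <- nearest(bp[i, ])
    if (sqrt(sum((bp[i, ] - tc[ni, ])^2)) <= tr[ni]) { hit <- i; break }
  }
  if (is.na(hit)) {
    stop("junction failure: the branch path never reaches the trunk surface",
         call. = FALSE)
  }
  u_cut <- us[max(hit - 1L, 1L)]     # last sample still outside the trunk
  p_surf <- path_eval(path2, u_cut)

  # locate the window on the trunk grid at the grid vertex nearest p_surf
  d2 <- (g$vertices[, 1] - p_surf[1])^2 + (g$vertices[, 2] - p_surf[2])^2 +
    (g$vertices[, 3] - p_surf[3])^2
  vi <- which.min(d2)
  i_s <- ((vi - 1L) %/% m_samples) + 1L
  j_s <- ((vi - 1L) %% m_samples) + 1L

  r_b <- mean(section_from_ellipse(anastomosis2, branch_samples)$radii)
  ds <- path_length(path1) / (n_rings - 1L)
  wi <- max(1L, as.integer(ceiling(r_b / ds)))
  wj <- max(1L, as.integer(ceiling(r_b / (ring_mean_r[i_s] * 2 * pi / m_samples))))
  wj <- min(wj, as.integer((m_samples - 4L) / 2L))
  ib <- i_s - wi; it <- i_s + wi
  if (ib < 2L || it > n_rings - 1L) {
    stop("split region too close to a trunk end for the branch girth; ",
         "move split_point or refine n_rings", call. = FALSE)
  }

  # drop the trunk faces inside the window
  wrap <- function(j) ((j - 1L) %% m_samples) + 1L
  cell_cols <- wrap(seq(j_s - wj, j_s + wj - 1L))
  drop_idx <- unlist(lapply(seq(ib, it - 1L), function(i) {
    base <- (i - 1L) * 2L * m_samples
    c(base + cell_cols, base + m_samples + cell_cols)
  }))
  trunk_faces <- g$faces[-drop_idx, , drop = FALSE]
  ring_idx <- function(i) (i - 1L) * m_samples + seq_len(m_samples)
  trunk <- graft_mesh(g$vertices, trunk_faces,
                      list(IVC_inlet = rev(ring_idx(1L)),
                           PA_anastomosis_1 = ring_idx(n_rings)))
  perimeter <- window_perimeter(ib, it, seq(j_s - wj, j_s + wj - 1L), m_samples)

  # branch lofted along the truncated path to a circular ring at the surface
  bpath <- path_truncate(path2, u_cut)
  sec2 <- section_from_ellipse(anastomosis2, branch_samples)
  end_n <- path_tangent_at(bpath, 1)
  end_sec <- circular_section(p_surf, end_n, r_b, branch_samples)
  branch <- loft_tube(bpath, sec2, end_sec, branch_rings, branch_samples, f,
                      caps = FALSE,
                      tags = c("PA_anastomosis_2", "junction_end"))

  merged <- merge_meshes(trunk, branch)
  end_loop <- merged$boundary_tags[["junction_end"]]
  merged$boundary_tags[["junction_end"]] <- NULL
  bridge <- zipper_loops(merged$vertices, perimeter, end_loop)
  merged$faces <- rbind(merged$faces, bridge)
  merged <- drop_degenerate_faces(merged)
  merged <- orient_mesh(merged)
  if (caps) merged <- cap_mesh(merged)
  merged
}
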