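# Boundary-loop operations: extensions for CFD boundary conditions and the
# inferior IVC extrusion, plus the largest-diameter support measure.

loop_newell_normal <- function(vertices, loop) {
  p <- vertices[loop, , drop = FALSE]
  q <- p[c(2:nrow(p), 1L), , drop = FALSE]
  n <- c(sum((p[, 2] - q[, 2]) * (p[, 3] + q[, 3])),
         sum((p[, 3] - q[, 3]) * (p[, 1] + q[, 1])),
         sum((p[, 1] - q[, 1]) * (p[, 2] + q[, 2])))
  unitize(n)
}

#' Extrude an open boundary loop
#'
#' Translates the tagged boundary loop along its mean (outward) normal by
#' `length` mm and triangulates the side wall, preserving the loop vertex
#' count. This is the boundary-extension mechanism used to prepare meshes
#' for flow simulation: the native IVC surface is extruded 10 mm
#' inferiorly, inlets by 10 times their largest diameter, and outlets by
#' 50 mm, so a stable velocity profile can develop.
#'
#' @param mesh A [graft_mesh()] with at least one tagged open loop.
#' @param tag Name of the boundary loop to extrude.
#' @param length Extrusion length, mm (>= 0); 0 returns the mesh unchanged.
#' @return The extended [graft_mesh()]; the tag now names the new rim.
#' @export
extrude_boundary <- function(mesh, tag, length) {
  loop <- mesh$boundary_tags[[tag]]
  if (is.null(loop)) stop("unknown boundary tag: ", tag, call. = FALSE)
  if (!is.numeric(length) || length < 0) {
    stop("extrusion length must be non-negative", call. = FALSE)
  }
  if (length == 0) return(mesh)
  n <- loop_newell_normal(mesh$vertices, loop)
  ctr_loop <- colMeans(mesh$vertices[loop, , drop = FALSE])
  ctr_mesh <- colMeans(mesh$vertices)
  if (sum(n * (ctr_loop - ctr_mesh)) < 0) n <- -n   # point away from the mesh
  nv <- nrow(mesh$vertices)
  k <- base::length(loop)
  new_pts <- mesh$vertices[loop, , drop = FALSE] +
    matrix(n * length, k, 3L, byrow = TRUE)
  new_idx <- nv + seq_len(k)
  jn <- c(2:k, 1L)
  side <- rbind(cbind(loop, loop[jn], new_idx[jn]),
                cbind(loop, new_idx[jn], new_idx))
  mesh$vertices <- rbind(mesh$vertices, new_pts)
  mesh$faces <- rbind(mesh$faces, side)
  mesh$boundary_tags[[tag]] <- new_idx
  orient_mesh(mesh)
}

#' Largest diameter of a boundary loop
#'
#' Maximum pairwise distance between the vertices of a tagged open loop —
#' the "largest diameter" that sizes inlet extensions (10 times this
#' value).
#'
#' @param mesh A [graft_mesh()].
#' @param tag Name of the boundary loop.
#' @return Diameter in mm.
#' @export
largest_boundary_diameter <- function(mesh, tag) {
  loop <- mesh$boundary_tags[[tag]]
  if (is.null(loop)) stop("unknown boundary tag: ", tag, call. = FALSE)
  p <- mesh$vertices[loop, , drop = FALSE]
  max(stats::dist(p))
}
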