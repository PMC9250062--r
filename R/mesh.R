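# Triangle surface meshes with tagged boundary loops.

#' Graft surface mesh
#'
#' A triangle surface mesh in mm. Boundary loops (open rims such as the
#' IVC inlet or a pulmonary-artery anastomosis) are stored as named,
#' ordered vertex-index cycles in `boundary_tags`; a closed (capped) mesh
#' has none. A closed graft mesh is expected to be watertight (every edge
#' shared by exactly two faces), genus 0 (`V - E + F = 2`), and wound
#' outward (positive signed volume).
#'
#' @param vertices Numeric `V x 3` matrix of vertex coordinates (mm).
#' @param faces Integer `F x 3` matrix of 1-based vertex indices.
#' @param boundary_tags Named list of integer vectors, each an ordered
#'   cycle of vertex indices along an open boundary loop.
#' @return An object of class `graft_mesh`.
#' @export
graft_mesh <- function(vertices, faces, boundary_tags = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be V x 3", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be F x 3", call. = FALSE)
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  structure(list(vertices = unname(vertices), faces = unname(faces),
                 boundary_tags = boundary_tags),
            class = "graft_mesh")
}

#' @export
print.graft_mesh <- function(x, ...) {
  cat(sprintf("<graft_mesh> V=%d F=%d", nrow(x$vertices), nrow(x$faces)))
  if (length(x$boundary_tags)) {
    cat(" open loops:", paste(names(x$boundary_tags), collapse = ", "))
  } else {
    cat(sprintf(" closed, watertight=%s, volume=%.3f mm^3",
                mesh_is_watertight(x), mesh_volume(x)))
  }
  cat("\n")
  invisible(x)
}

mesh_edge_table <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Mesh integrity measures
#'
#' `mesh_is_watertight()` checks every undirected edge is shared by exactly
#' two faces; `euler_characteristic()` returns `V - E + F`;
#' `mesh_volume()` returns the signed volume from the divergence theorem
#' (positive for outward winding).
#'
#' @param mesh A [graft_mesh()].
#' @return Logical / integer / numeric scalar respectively.
#' @export
mesh_is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  all(mesh_edge_table(mesh) == 2L)
}

#' @rdname mesh_is_watertight
#' @export
euler_characteristic <- function(mesh) {
  used <- sort(unique(as.integer(mesh$faces)))
  v <- length(used)
  e <- length(mesh_edge_table(mesh))
  v - e + nrow(mesh$faces)
}

#' @rdname mesh_is_watertight
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  ab <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  ac <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2]
  cy <- ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3]
  cz <- ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

drop_degenerate_faces <- function(mesh, tol = 1e-12) {
  keep <- face_areas(mesh) > tol &
    mesh$faces[, 1] != mesh$faces[, 2] &
    mesh$faces[, 2] != mesh$faces[, 3] &
    mesh$faces[, 1] != mesh$faces[, 3]
  mesh$faces <- mesh$faces[keep, , drop = FALSE]
  mesh
}

# Merge two meshes into one vertex/face set, concatenating boundary tags.
merge_meshes <- function(a, b) {
  off <- nrow(a$vertices)
  tags <- c(a$boundary_tags, lapply(b$boundary_tags, function(i) i + off))
  graft_mesh(rbind(a$vertices, b$vertices),
             rbind(a$faces, b$faces + off),
             tags)
}

# Cap an open boundary loop with a triangle fan to its centroid.
cap_loop <- function(mesh, tag) {
  loop <- mesh$boundary_tags[[tag]]
  if (is.null(loop)) stop("unknown boundary tag: ", tag, call. = FALSE)
  centroid <- colMeans(mesh$vertices[loop, , drop = FALSE])
  ci <- nrow(mesh$vertices) + 1L
  n <- length(loop)
  fan <- cbind(loop, c(loop[-1L], loop[1L]), rep(ci, n))
  mesh$vertices <- rbind(mesh$vertices, centroid)
  mesh$faces <- rbind(mesh$faces, fan)
  mesh$boundary_tags[[tag]] <- NULL
  mesh
}

#' Cap all open boundary loops
#'
#' Closes every tagged boundary loop with a triangle fan to the loop
#' centroid, then re-orients the mesh for consistent outward winding.
#'
#' @param mesh A [graft_mesh()] with tagged open loops.
#' @return A closed `graft_mesh`.
#' @export
cap_mesh <- function(mesh) {
  for (tag in names(mesh$boundary_tags)) mesh <- cap_loop(mesh, tag)
  orient_mesh(mesh)
}

# Make face winding consistent across shared edges (region growing), then
# flip globally so the signed volume is positive (only meaningful closed).
orient_mesh <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  if (nf == 0L) return(mesh)
  face_of <- rep(seq_len(nf), 3L)
  ha <- c(f[, 1], f[, 2], f[, 3])
  hb <- c(f[, 2], f[, 3], f[, 1])
  key <- paste(pmin(ha, hb), pmax(ha, hb))
  by_key <- split(seq_along(key), key)
  rows_of_face <- split(seq_along(face_of), face_of)
  visited <- rep(FALSE, nf)
  flip <- rep(FALSE, nf)
  for (start in seq_len(nf)) {
    if (visited[start]) next
    stack <- integer(nf)
    stack[1L] <- start
    top <- 1L
    visited[start] <- TRUE
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      for (r in rows_of_face[[cur]]) {
        for (mr in by_key[[key[r]]]) {
          if (mr == r) next
          nb <- face_of[mr]
          if (visited[nb]) next
          # consistent winding = the shared edge runs in opposite
          # directions in the two faces (after any flips applied so far)
          a_cur <- if (flip[cur]) hb[r] else ha[r]
          a_nb <- ha[mr]
          flip[nb] <- (a_cur == a_nb)
          visited[nb] <- TRUE
          top <- top + 1L
          stack[top] <- nb
        }
      }
    }
  }
  if (any(flip)) {
    f[flip, ] <- f[flip, c(1, 3, 2), drop = FALSE]
    mesh$faces <- f
  }
  if (length(mesh$boundary_tags) == 0L) {
    if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  } else if (outwardness(mesh) < 0) {
    # open surface: point face normals away from the vertex centroid
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  }
  mesh
}

outwardness <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  ctr <- colMeans(v)
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  nx <- ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2]
  ny <- ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3]
  nz <- ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
  fc <- (a + v[f[, 2], , drop = FALSE] + v[f[, 3], , drop = FALSE]) / 3
  sum(nx * (fc[, 1] - ctr[1]) + ny * (fc[, 2] - ctr[2]) + nz * (fc[, 3] - ctr[3]))
}

#' Surface area of a mesh (mm^2)
#' @param mesh A [graft_mesh()].
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))
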