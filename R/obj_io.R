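# Wavefront OBJ and STL exchange.
#
# OBJ: v/f records, 1-based indices, triangles only, counter-clockwise
# winding = outward. Boundary-loop tags are written as `#loop` comment
# lines so a saved graft reloads with its rims intact; other software
# ignores comments.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a mesh to a Wavefront OBJ file
#'
#' @param mesh A [graft_mesh()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# fontangraft OBJ export", con)
  for (tag in names(mesh$boundary_tags)) {
    writeLines(paste("#loop", tag,
                     paste(mesh$boundary_tags[[tag]], collapse = " ")), con)
  }
  v <- mesh$vertices
  writeLines(paste("v", fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])),
             con)
  f <- mesh$faces
  if (nrow(f)) writeLines(paste("f", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

#' Read a triangle mesh from a Wavefront OBJ file
#'
#' Reads `v` and `f` records (polygonal faces are fan-triangulated;
#' `v/vt/vn` references keep the vertex index). `#loop` comments written
#' by [write_obj()] are restored as boundary tags.
#'
#' @param path OBJ file path.
#' @return A [graft_mesh()].
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tags <- list()
  for (ln in grep("^#loop ", lines, value = TRUE)) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    tags[[parts[2]]] <- as.integer(parts[-(1:2)])
  }
  vlines <- grep("^v ", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  flines <- grep("^f ", lines, value = TRUE)
  faces <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(p) {
    idx <- as.integer(sub("/.*", "", p[-1L]))
    if (length(idx) < 3L) stop("OBJ face with fewer than 3 vertices",
                               call. = FALSE)
    if (length(idx) == 3L) return(matrix(idx, 1L))
    cbind(idx[1L], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
  }))
  graft_mesh(verts, faces, tags)
}

#' Write a mesh to a binary STL file
#'
#' Binary STL for 3D-printing workflows (no vertex sharing; facet normals
#' from the face winding).
#'
#' @param mesh A [graft_mesh()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("fontangraft binary STL", width = -80))
  writeBin(header[1:80], con)
  f <- mesh$faces
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  v <- mesh$vertices
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c_ <- v[f[i, 3], ]
    n <- cross3(b - a, c_ - a)
    nl <- sqrt(sum(n^2))
    if (nl > 0) n <- n / nl
    writeBin(as.numeric(c(n, a, b, c_)), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

#' Read a triangle mesh from an STL file (binary or ASCII)
#'
#' Duplicate vertices are merged so mesh-integrity checks work on the
#' result.
#'
#' @param path STL file path.
#' @return A [graft_mesh()].
#' @export
read_stl <- function(path) {
  head5 <- readBin(path, "raw", n = 5L)
  tris <- if (identical(rawToChar(head5), "solid") && is_ascii_stl(path)) {
    read_stl_ascii(path)
  } else {
    read_stl_binary(path)
  }
  # merge coincident vertices
  key <- apply(tris, 1L, function(r) paste(fmt_num(r), collapse = ","))
  uid <- match(key, unique(key))
  verts <- tris[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  graft_mesh(verts, faces)
}

is_ascii_stl <- function(path) {
  txt <- suppressWarnings(readLines(path, n = 50L, warn = FALSE))
  any(grepl("facet normal", txt, fixed = TRUE))
}

read_stl_binary <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nfac <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  out <- matrix(NA_real_, nfac * 3L, 3L)
  for (i in seq_len(nfac)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    out[(i - 1L) * 3L + 1:3, ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    readBin(con, "raw", n = 2L)
  }
  out
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                        function(p) as.numeric(p[2:4])))
}
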