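# Design-sketch CSV: saves everything needed to rebuild a graft with the
# same construction algorithm, and reloads by parsing top to bottom.
#
# Dialect (comma-delimited, '.' decimal separator, UTF-8, LF):
#   FONTAN_SKETCH,1
#   #TRANSFORMS            three rows: heart, glenn, graft
#     name,tx,ty,tz,qw,qx,qy,qz,sx,sy,sz
#   #BEZIER                trunk path first, then the branch path
#     path_id,segment,role,x,y,z        role in P0,P1,P2,P3
#   #RADII                 per-section frame vectors and sampled radii
#     section_id,kind,v1,v2,v3          kind in center,e1,e2,axis_a,axis_b
#     section_id,r,index,value
#   #PARAMS                build parameters as key,value rows
# Numbers are written with 17 significant digits so a save/load round
# trip reproduces the identical doubles, hence a bit-identical rebuild.

SKETCH_MAGIC <- "FONTAN_SKETCH,1"

identity_transform <- function() {
  list(translation = c(0, 0, 0), rotation = c(1, 0, 0, 0),
       scale = c(1, 1, 1))
}

#' Graft design sketch
#'
#' The saved state of a graft design: rigid transforms of the scene
#' objects (heart, Glenn anatomy, graft), the Bezier pathway(s), the
#' cross-section/ellipse records, and the build parameters. Rebuilding a
#' sketch with [build_sketch()] reproduces the original mesh exactly.
#'
#' @param shape_kind `"tube"` or `"bifurcated"`.
#' @param ivc_section The native-IVC [cross_section()].
#' @param anastomosis1 First [anastomosis_ellipse()] (trunk end).
#' @param paths List of [bezier_path()]s, trunk first.
#' @param anastomosis2 Second ellipse (bifurcated only).
#' @param split_point Trunk split position (bifurcated only).
#' @param params Named list of build parameters (`n_rings`, `m_samples`,
#'   `branch_rings`, `branch_samples`, `f`, `caps`).
#' @param transforms Named list (`heart`, `glenn`, `graft`) of rigid
#'   transforms: `translation` (mm), `rotation` (unit quaternion
#'   w,x,y,z), `scale`.
#' @return An object of class `design_sketch`.
#' @export
design_sketch <- function(shape_kind, ivc_section, anastomosis1, paths,
                          anastomosis2 = NULL, split_point = NA_real_,
                          params = list(), transforms = NULL) {
  shape_kind <- match.arg(shape_kind, c("tube", "bifurcated"))
  if (is.null(transforms)) {
    transforms <- list(heart = identity_transform(),
                       glenn = identity_transform(),
                       graft = identity_transform())
  }
  if (shape_kind == "bifurcated") {
    if (is.null(anastomosis2) || !is.finite(split_point)) {
      stop("a bifurcated sketch needs anastomosis2 and split_point",
           call. = FALSE)
    }
    if (length(paths) != 2L) stop("a bifurcated sketch needs 2 paths",
                                  call. = FALSE)
  } else if (length(paths) != 1L) {
    stop("a tube sketch needs exactly 1 path", call. = FALSE)
  }
  defaults <- list(n_rings = 32L, m_samples = 32L, branch_rings = 24L,
                   branch_samples = 24L, f = "smoothstep", caps = FALSE)
  params <- utils::modifyList(defaults, params)
  structure(list(shape_kind = shape_kind, transforms = transforms,
                 ivc_section = ivc_section, anastomosis1 = anastomosis1,
                 anastomosis2 = anastomosis2, split_point = split_point,
                 paths = paths, params = params),
            class = "design_sketch")
}

#' Save a design sketch to its CSV exchange file
#'
#' Writes one CSV file in the fixed section order: transforms (heart,
#' Glenn, graft), then the Bezier records (trunk path first), then the
#' per-section radii records, then the build parameters.
#'
#' @param sketch A [design_sketch()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_sketch <- function(sketch, path) {
  stopifnot(inherits(sketch, "design_sketch"))
  out <- c(SKETCH_MAGIC, "#TRANSFORMS")
  for (nm in c("heart", "glenn", "graft")) {
    tf <- sketch$transforms[[nm]]
    out <- c(out, paste(c(nm, fmt_num(c(tf$translation, tf$rotation,
                                        tf$scale))), collapse = ","))
  }
  out <- c(out, "#BEZIER")
  for (pid in seq_along(sketch$paths)) {
    segs <- sketch$paths[[pid]]$segments
    for (k in seq_along(segs)) {
      for (role in c("p0", "p1", "p2", "p3")) {
        out <- c(out, paste(c(pid, k, toupper(role),
                              fmt_num(segs[[k]][[role]])), collapse = ","))
      }
    }
  }
  out <- c(out, "#RADII")
  sec_row <- function(id, kind, v) paste(c(id, kind, fmt_num(v)),
                                         collapse = ",")
  cs <- sketch$ivc_section
  out <- c(out, sec_row("IVC", "center", cs$center),
           sec_row("IVC", "e1", cs$e1), sec_row("IVC", "e2", cs$e2),
           vapply(seq_along(cs$radii), function(i) {
             paste(c("IVC", "r", i, fmt_num(cs$radii[i])), collapse = ",")
           }, character(1)))
  write_ellipse <- function(id, el) {
    c(sec_row(id, "center", el$center),
      sec_row(id, "axis_a", el$axis_a),
      sec_row(id, "axis_b", el$axis_b))
  }
  out <- c(out, write_ellipse("ANAST1", sketch$anastomosis1))
  if (!is.null(sketch$anastomosis2)) {
    out <- c(out, write_ellipse("ANAST2", sketch$anastomosis2))
  }
  out <- c(out, "#PARAMS",
           paste("shape_kind", sketch$shape_kind, sep = ","),
           paste("split_point", fmt_num(sketch$split_point), sep = ","),
           vapply(names(sketch$params), function(k) {
             v <- sketch$params[[k]]
             paste(k, if (is.numeric(v)) fmt_num(v) else as.character(v),
                   sep = ",")
           }, character(1)))
  con <- file(path, open = "wb")   # binary: force LF line endings
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

sketch_parse_error <- function(line_no, msg) {
  stop(sprintf("sketch parse error at line %d: %s", line_no, msg),
       call. = FALSE)
}

#' Load a design sketch from its CSV exchange file
#'
#' Parses top to bottom, enforcing the section order; malformed files
#' raise an error naming the offending line or the missing section.
#'
#' @param path Sketch CSV path.
#' @return A [design_sketch()].
#' @export
load_sketch <- function(path) {
  if (!file.exists(path)) stop("no such sketch file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || lines[1L] != SKETCH_MAGIC) {
    sketch_parse_error(1L, paste("expected magic line", SKETCH_MAGIC))
  }
  headers <- c("#TRANSFORMS", "#BEZIER", "#RADII", "#PARAMS")
  pos <- match(headers, lines)
  for (h in seq_along(headers)) {
    if (is.na(pos[h])) {
      stop(sprintf("sketch parse error: missing section %s", headers[h]),
           call. = FALSE)
    }
  }
  if (is.unsorted(pos)) {
    stop("sketch parse error: sections out of order (expected ",
         paste(headers, collapse = " -> "), ")", call. = FALSE)
  }
  section <- function(h) {
    from <- pos[h] + 1L
    to <- if (h < length(headers)) pos[h + 1L] - 1L else length(lines)
    if (to < from) return(list(lines = character(0), at = integer(0)))
    list(lines = lines[from:to], at = from:to)
  }
  # transforms
  tr <- section(1L)
  if (length(tr$lines) != 3L) {
    sketch_parse_error(pos[1L], "expected exactly 3 transform rows")
  }
  transforms <- list()
  for (i in seq_len(3L)) {
    p <- strsplit(tr$lines[i], ",", fixed = TRUE)[[1L]]
    if (length(p) != 11L) sketch_parse_error(tr$at[i],
                                             "transform row needs 11 fields")
    if (p[1L] != c("heart", "glenn", "graft")[i]) {
      sketch_parse_error(tr$at[i],
                         paste("expected transform for",
                               c("heart", "glenn", "graft")[i]))
    }
    v <- as.numeric(p[-1L])
    transforms[[p[1L]]] <- list(translation = v[1:3], rotation = v[4:7],
                                scale = v[8:10])
  }
  # bezier records
  bz <- section(2L)
  recs <- lapply(seq_along(bz$lines), function(i) {
    p <- strsplit(bz$lines[i], ",", fixed = TRUE)[[1L]]
    if (length(p) != 6L) sketch_parse_error(bz$at[i],
                                            "bezier row needs 6 fields")
    list(pid = as.integer(p[1L]), seg = as.integer(p[2L]), role = p[3L],
         v = as.numeric(p[4:6]))
  })
  pids <- vapply(recs, `[[`, integer(1), "pid")
  paths <- lapply(sort(unique(pids)), function(pid) {
    rr <- recs[pids == pid]
    segs_id <- vapply(rr, `[[`, integer(1), "seg")
    segs <- lapply(sort(unique(segs_id)), function(k) {
      rk <- rr[segs_id == k]
      roles <- vapply(rk, `[[`, character(1), "role")
      get_pt <- function(role) {
        i <- which(roles == role)
        if (length(i) != 1L) {
          stop(sprintf("sketch parse error: path %d segment %d needs one %s",
                       pid, k, role), call. = FALSE)
        }
        rk[[i]]$v
      }
      bezier_segment(get_pt("P0"), get_pt("P1"), get_pt("P2"), get_pt("P3"))
    })
    bezier_path(segs)
  })
  # radii records
  rd <- section(3L)
  sec_data <- list()
  for (i in seq_along(rd$lines)) {
    p <- strsplit(rd$lines[i], ",", fixed = TRUE)[[1L]]
    id <- p[1L]; kind <- p[2L]
    if (kind == "r") {
      if (length(p) != 4L) sketch_parse_error(rd$at[i],
                                              "radius row needs 4 fields")
      idx <- as.integer(p[3L])
      sec_data[[id]]$radii[idx] <- as.numeric(p[4L])
    } else {
      if (length(p) != 5L) sketch_parse_error(rd$at[i],
                                              "frame row needs 5 fields")
      sec_data[[id]][[kind]] <- as.numeric(p[3:5])
    }
  }
  if (is.null(sec_data$IVC) || is.null(sec_data$ANAST1)) {
    stop("sketch parse error: missing IVC or ANAST1 section records",
         call. = FALSE)
  }
  ivc_section <- cross_section(sec_data$IVC$center, sec_data$IVC$e1,
                               sec_data$IVC$e2, sec_data$IVC$radii)
  mk_ellipse <- function(d) anastomosis_ellipse(d$center, d$axis_a, d$axis_b)
  anast1 <- mk_ellipse(sec_data$ANAST1)
  anast2 <- if (!is.null(sec_data$ANAST2)) mk_ellipse(sec_data$ANAST2)
  # params
  pm <- section(4L)
  params <- list()
  for (i in seq_along(pm$lines)) {
    p <- strsplit(pm$lines[i], ",", fixed = TRUE)[[1L]]
    if (length(p) != 2L) sketch_parse_error(pm$at[i],
                                            "param row needs 2 fields")
    params[[p[1L]]] <- p[2L]
  }
  shape_kind <- params$shape_kind %||% "tube"
  split_point <- suppressWarnings(as.numeric(params$split_point %||% NA))
  num <- function(k, d) if (is.null(params[[k]])) d else as.numeric(params[[k]])
  design_sketch(shape_kind, ivc_section, anast1, paths,
                anastomosis2 = anast2, split_point = split_point,
                params = list(
                  n_rings = as.integer(num("n_rings", 32)),
                  m_samples = as.integer(num("m_samples", 32)),
                  branch_rings = as.integer(num("branch_rings", 24)),
                  branch_samples = as.integer(num("branch_samples", 24)),
                  f = params$f %||% "smoothstep",
                  caps = identical(params$caps, "TRUE")),
                transforms = transforms)
}

#' Rebuild the graft mesh a sketch describes
#'
#' Runs the same construction algorithm the sketch was saved from, with
#' the saved parameters, so the rebuilt mesh is identical to the original
#' build.
#'
#' @param sketch A [design_sketch()].
#' @return A [graft_mesh()].
#' @export
build_sketch <- function(sketch) {
  stopifnot(inherits(sketch, "design_sketch"))
  p <- sketch$params
  if (sketch$shape_kind == "tube") {
    build_tube_graft(sketch$ivc_section, sketch$anastomosis1,
                     sketch$paths[[1L]],
                     n_rings = p$n_rings, m_samples = p$m_samples,
                     f = p$f, caps = p$caps)
  } else {
    build_bifurcated_graft(sketch$ivc_section, sketch$anastomosis1,
                           sketch$anastomosis2, sketch$split_point,
                           sketch$paths[[1L]], sketch$paths[[2L]],
                           n_rings = p$n_rings, m_samples = p$m_samples,
                           branch_rings = p$branch_rings,
                           branch_samples = p$branch_samples,
                           f = p$f, caps = p$caps)
  }
}

#' Apply a sketch rigid transform to a mesh
#'
#' Scale, then rotate by the unit quaternion (w,x,y,z), then translate.
#'
#' @param mesh A [graft_mesh()].
#' @param tf A transform list (`translation`, `rotation`, `scale`).
#' @return The transformed [graft_mesh()].
#' @export
apply_transform <- function(mesh, tf) {
  q <- tf$rotation / sqrt(sum(tf$rotation^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  Rm <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3L, 3L, byrow = TRUE)
  v <- sweep(mesh$vertices, 2L, tf$scale, `*`) %*% t(Rm)
  mesh$vertices <- sweep(v, 2L, tf$translation, `+`)
  mesh
}
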