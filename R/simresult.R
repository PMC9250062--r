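# Simulation-result exchange: HDF5 -> CSV conversion, the three-part CSV
# bundle, and WSS point-cloud thresholding.
#
# The CSV bundle concatenates three labelled parts:
#   #SIZE      n_designs and the total raw-WSS length
#   #SUMMARY   per-design iPL, %WSS, HFD
#   #WSS       raw per-point x, y, z, WSS value with its design index

#' Simulation result bundle
#'
#' @param summaries Tibble with columns `design, ipl, pct_wss, hfd_lpa,
#'   hfd_rpa` (one row per simulated design).
#' @param wss Tibble with columns `design, x, y, z, wss`: the raw WSS
#'   point cloud of every design.
#' @return An object of class `sim_result_bundle`.
#' @export
sim_result_bundle <- function(summaries, wss) {
  summaries <- tibble::as_tibble(summaries)
  wss <- tibble::as_tibble(wss)
  need_s <- c("design", "ipl", "pct_wss", "hfd_lpa", "hfd_rpa")
  need_w <- c("design", "x", "y", "z", "wss")
  if (!all(need_s %in% names(summaries))) {
    stop("summaries must have columns ", paste(need_s, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_w %in% names(wss))) {
    stop("wss must have columns ", paste(need_w, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(summaries$design)) {
    stop("duplicate design indices in summaries", call. = FALSE)
  }
  if (!all(wss$design %in% summaries$design)) {
    stop("wss rows reference designs absent from the summaries",
         call. = FALSE)
  }
  structure(list(summaries = summaries[need_s], wss = wss[need_w],
                 n_designs = nrow(summaries),
                 total_wss_length = nrow(wss)),
            class = "sim_result_bundle")
}

#' @export
print.sim_result_bundle <- function(x, ...) {
  cat(sprintf("<sim_result_bundle> %d design(s), %d WSS points\n",
              x$n_designs, x$total_wss_length))
  invisible(x)
}

#' Write / read the three-part simulation-result CSV
#'
#' @param bundle A [sim_result_bundle()].
#' @param path CSV file path.
#' @return `path` invisibly (write); a `sim_result_bundle` (read).
#' @export
write_sim_csv <- function(bundle, path) {
  stopifnot(inherits(bundle, "sim_result_bundle"))
  s <- bundle$summaries
  w <- bundle$wss
  out <- c("#SIZE",
           paste("n_designs", bundle$n_designs, sep = ","),
           paste("total_wss_length", bundle$total_wss_length, sep = ","),
           "#SUMMARY",
           "design,ipl,pct_wss,hfd_lpa,hfd_rpa",
           sprintf("%d,%s,%s,%s,%s", s$design, fmt_num(s$ipl),
                   fmt_num(s$pct_wss), fmt_num(s$hfd_lpa),
                   fmt_num(s$hfd_rpa)),
           "#WSS",
           "design,x,y,z,wss",
           sprintf("%d,%s,%s,%s,%s", w$design, fmt_num(w$x), fmt_num(w$y),
                   fmt_num(w$z), fmt_num(w$wss)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_sim_csv
#' @export
read_sim_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pos <- match(c("#SIZE", "#SUMMARY", "#WSS"), lines)
  if (any(is.na(pos)) || is.unsorted(pos)) {
    stop("malformed simulation CSV: expected sections #SIZE, #SUMMARY, #WSS",
         call. = FALSE)
  }
  kv <- strsplit(lines[(pos[1] + 1):(pos[2] - 1)], ",", fixed = TRUE)
  size <- stats::setNames(lapply(kv, function(p) as.numeric(p[2])),
                          vapply(kv, `[[`, character(1), 1L))
  parse_block <- function(from, to) {
    utils::read.csv(text = paste(lines[from:to], collapse = "\n"))
  }
  summaries <- tibble::as_tibble(parse_block(pos[2] + 1L, pos[3] - 1L))
  wss <- tibble::as_tibble(parse_block(pos[3] + 1L, length(lines)))
  bundle <- sim_result_bundle(summaries, wss)
  if (bundle$n_designs != size$n_designs ||
      bundle$total_wss_length != size$total_wss_length) {
    stop(sprintf(
      "simulation CSV size header (%g designs, %g points) disagrees with its body (%d, %d)",
      size$n_designs, size$total_wss_length,
      bundle$n_designs, bundle$total_wss_length), call. = FALSE)
  }
  bundle
}

default_h5_mapping <- function() {
  list(summaries = "/summaries",
       wss_points = "/wss/points",
       wss_values = "/wss/values",
       wss_design = "/wss/design")
}

find_python <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no python interpreter found for the HDF5 bridge", call. = FALSE)
}

h5_bridge <- function(args) {
  script <- system.file("python", "h5bridge.py", package = "fontangraft")
  if (!nzchar(script)) stop("h5bridge.py not found", call. = FALSE)
  res <- suppressWarnings(
    system2(find_python(), c(script, args), stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L) {
    stop("HDF5 bridge failed: ", paste(res, collapse = " | "),
         call. = FALSE)
  }
  res
}

#' Convert an HDF5 simulation result to the CSV bundle
#'
#' Reads the datasets named by the mapping (summaries matrix with columns
#' iPL, %WSS, HFD-LPA, HFD-RPA; WSS point coordinates; WSS values; and,
#' for multi-design files, the per-point design index), validates the
#' count invariants, and optionally writes the concatenated three-part
#' CSV.
#'
#' @param h5_path Input `.h5` file.
#' @param mapping Named list of dataset paths (see
#'   `default_h5_mapping()`), or the path of a YAML file holding one.
#' @param csv_out Optional output CSV path.
#' @return A [sim_result_bundle()].
#' @export
convert_h5_results <- function(h5_path, mapping = default_h5_mapping(),
                               csv_out = NULL) {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- yaml::read_yaml(mapping)
  }
  mapping <- utils::modifyList(default_h5_mapping(), mapping)
  if (!file.exists(h5_path)) stop("no such HDF5 file: ", h5_path,
                                  call. = FALSE)
  tmp <- tempfile("h5dump")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  spec <- vapply(names(mapping), function(nm) {
    paste0(nm, "=", mapping[[nm]])
  }, character(1))
  log <- h5_bridge(c("dump", h5_path, tmp, spec))
  got <- function(nm) file.exists(file.path(tmp, paste0(nm, ".csv")))
  for (nm in c("summaries", "wss_points", "wss_values")) {
    if (!got(nm)) {
      stop(sprintf("conversion error: dataset '%s' (%s) missing from %s",
                   mapping[[nm]], nm, h5_path), call. = FALSE)
    }
  }
  rd <- function(nm) as.matrix(utils::read.csv(
    file.path(tmp, paste0(nm, ".csv")), header = FALSE))
  sm <- rd("summaries")
  if (ncol(sm) != 4L) {
    stop("conversion error: summaries dataset must have 4 columns ",
         "(ipl, pct_wss, hfd_lpa, hfd_rpa)", call. = FALSE)
  }
  pts <- rd("wss_points")
  vals <- as.numeric(rd("wss_values"))
  if (ncol(pts) != 3L || nrow(pts) != length(vals)) {
    stop("conversion error: WSS points and values lengths disagree",
         call. = FALSE)
  }
  n_designs <- nrow(sm)
  design <- if (got("wss_design")) {
    as.integer(rd("wss_design"))
  } else if (n_designs == 1L) {
    rep(1L, length(vals))
  } else {
    stop(sprintf(
      "conversion error: %d designs but no per-point design dataset ('%s')",
      n_designs, mapping$wss_design), call. = FALSE)
  }
  if (length(design) != length(vals)) {
    stop("conversion error: design index length disagrees with WSS values",
         call. = FALSE)
  }
  summaries <- tibble::tibble(design = seq_len(n_designs),
                              ipl = unname(sm[, 1]),
                              pct_wss = unname(sm[, 2]),
                              hfd_lpa = unname(sm[, 3]),
                              hfd_rpa = unname(sm[, 4]))
  wss <- tibble::tibble(design = unname(design), x = unname(pts[, 1]),
                        y = unname(pts[, 2]), z = unname(pts[, 3]),
                        wss = vals)
  bundle <- sim_result_bundle(summaries, wss)
  if (!is.null(csv_out)) write_sim_csv(bundle, csv_out)
  bundle
}

#' Export a bundle to HDF5 (fixture round-trip support)
#'
#' Writes the bundle's datasets under the mapped names so the HDF5 -> CSV
#' code path can be exercised end-to-end with synthetic data.
#'
#' @param bundle A [sim_result_bundle()].
#' @param h5_path Output `.h5` file.
#' @param mapping Dataset-name mapping, as in [convert_h5_results()].
#' @return `h5_path`, invisibly.
#' @export
write_h5_bundle <- function(bundle, h5_path, mapping = default_h5_mapping()) {
  stopifnot(inherits(bundle, "sim_result_bundle"))
  mapping <- utils::modifyList(default_h5_mapping(), mapping)
  tmp <- tempfile("h5load")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  wr <- function(nm, m) {
    utils::write.table(m, file.path(tmp, paste0(nm, ".csv")), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  s <- bundle$summaries
  wr("summaries", cbind(s$ipl, s$pct_wss, s$hfd_lpa, s$hfd_rpa))
  wr("wss_points", cbind(bundle$wss$x, bundle$wss$y, bundle$wss$z))
  wr("wss_values", matrix(bundle$wss$wss, ncol = 1L))
  wr("wss_design", matrix(bundle$wss$design, ncol = 1L))
  spec <- vapply(names(mapping), function(nm) {
    paste0(nm, "=", mapping[[nm]])
  }, character(1))
  h5_bridge(c("write", h5_path, tmp, spec))
  invisible(h5_path)
}

#' WSS threshold window
#'
#' The rendering window for the WSS point cloud: default `[0, 1]`
#' dyne/cm^2, with the slider maximum clamped to the largest WSS value
#' present (the auto-detected maximum).
#'
#' @param wss_min,wss_max Window bounds, dyne/cm^2.
#' @param auto_max Largest WSS value present in the data.
#' @return An object of class `threshold_window`.
#' @export
threshold_window <- function(wss_min = 0, wss_max = 1, auto_max = Inf) {
  if (wss_min > wss_max) stop("wss_min must not exceed wss_max",
                              call. = FALSE)
  structure(list(wss_min = wss_min, wss_max = min(wss_max, auto_max),
                 auto_max = auto_max),
            class = "threshold_window")
}

#' Threshold a design's WSS point cloud
#'
#' Keeps the points with a nonzero WSS value lying within the window
#' (`wss_min <= wss <= wss_max`); the requested maximum is clamped to the
#' largest value present in the bundle.
#'
#' @param bundle A [sim_result_bundle()].
#' @param design_index Which design's point cloud to threshold.
#' @param wss_min,wss_max Window bounds, dyne/cm^2 (defaults 0 and 1).
#' @return A tibble of the retained `x, y, z, wss` rows.
#' @export
threshold_point_cloud <- function(bundle, design_index, wss_min = 0,
                                  wss_max = 1) {
  stopifnot(inherits(bundle, "sim_result_bundle"))
  if (!design_index %in% bundle$summaries$design) {
    stop("design index ", design_index, " not present in the bundle",
         call. = FALSE)
  }
  auto_max <- max(bundle$wss$wss)
  win <- threshold_window(wss_min, wss_max, auto_max)
  w <- bundle$wss[bundle$wss$design == design_index, ]
  keep <- w$wss > 0 & w$wss >= win$wss_min & w$wss <= win$wss_max
  w[keep, c("x", "y", "z", "wss")]
}
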