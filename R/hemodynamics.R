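# Benchmark hemodynamic performance metrics: iPL, %WSS, HFD, Reynolds.
#
# Units: flow boundaries and fluid properties are SI (m, Pa, m^3/s,
# kg/m^3, Pa*s); wall shear stress values are dyne/cm^2 (1 Pa = 10
# dyne/cm^2), the unit the physiologic 1-10 range is quoted in; mesh and
# particle coordinates are mm.

#' Blood fluid properties
#'
#' Newtonian blood defaults: density 1060 kg/m^3, dynamic viscosity
#' 3.5e-3 Pa*s.
#'
#' @param rho Density, kg/m^3.
#' @param mu Dynamic viscosity, Pa*s.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1060, mu = 3.5e-3) {
  stopifnot(is.numeric(rho), rho > 0, is.numeric(mu), mu > 0)
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Flow boundary records
#'
#' One row per TCPC boundary (IVC/SVC inlets, LPA/RPA outlets) carrying
#' the area-averaged quantities the power-loss balance needs.
#'
#' @param name Boundary label.
#' @param role `"inlet"` or `"outlet"`.
#' @param Q Volumetric flow rate magnitude, m^3/s (positive).
#' @param p Area-averaged static pressure, Pa.
#' @param v2 Area-averaged squared velocity magnitude, m^2/s^2.
#' @param area Boundary area, m^2.
#' @return A one-row tibble; bind rows to assemble a boundary table.
#' @export
flow_boundary <- function(name, role, Q, p, v2, area = NA_real_) {
  role <- match.arg(role, c("inlet", "outlet"))
  stopifnot(is.numeric(Q), Q > 0, is.numeric(p), is.numeric(v2), v2 >= 0)
  tibble::tibble(name = name, role = role, Q = Q, p = p, v2 = v2,
                 area = area)
}

check_mass_balance <- function(boundaries, tol = 0.01) {
  qin <- sum(boundaries$Q[boundaries$role == "inlet"])
  qout <- sum(boundaries$Q[boundaries$role == "outlet"])
  if (qin <= 0 || qout <= 0) {
    stop("boundaries must include at least one inlet and one outlet",
         call. = FALSE)
  }
  imbalance <- abs(qin - qout) / qin
  if (imbalance > tol) {
    stop(sprintf(
      "mass imbalance of %.2f%% between inlet and outlet flow exceeds %.0f%%",
      100 * imbalance, 100 * tol), call. = FALSE)
  }
  qin
}

#' Hydraulic power loss across the connection
#'
#' Total-pressure energy balance over the flow boundaries:
#' `PL = sum_inlets (p + rho v2 / 2) Q - sum_outlets (p + rho v2 / 2) Q`
#' in watts. Mass conservation between inlets and outlets must hold within
#' 1%; because of it, adding a constant offset to every static pressure
#' leaves the result unchanged. A negative value (unphysical for a passive
#' connection) raises a warning.
#'
#' @param boundaries A tibble of [flow_boundary()] rows.
#' @param fluid A [fluid_properties()].
#' @return Power loss, W.
#' @export
power_loss <- function(boundaries, fluid = fluid_properties()) {
  stopifnot(inherits(fluid, "fluid_properties"))
  check_mass_balance(boundaries)
  ptot <- boundaries$p + 0.5 * fluid$rho * boundaries$v2
  flux <- ptot * boundaries$Q
  pl <- sum(flux[boundaries$role == "inlet"]) -
    sum(flux[boundaries$role == "outlet"])
  if (pl < -1e-12 * max(abs(flux))) {
    warning(sprintf("negative power loss (%.3g W): check the flow field", pl))
  }
  pl
}

#' Indexed power loss
#'
#' Normalizes the power loss by patient size and flow:
#' `iPL = PL * BSA^2 / (rho * Qs^3)`, dimensionless. `Qs`, the systemic
#' venous flow, equals the sum of all inlet flow rates.
#'
#' @param PL Power loss, W.
#' @param Q_s Systemic venous flow, m^3/s.
#' @param BSA Body surface area, m^2.
#' @param fluid A [fluid_properties()].
#' @return Dimensionless iPL.
#' @export
indexed_power_loss <- function(PL, Q_s, BSA, fluid = fluid_properties()) {
  if (!is.numeric(Q_s) || Q_s <= 0) stop("Q_s must be positive", call. = FALSE)
  if (!is.numeric(BSA) || BSA <= 0) stop("BSA must be positive", call. = FALSE)
  PL * BSA^2 / (fluid$rho * Q_s^3)
}

#' Wall-shear-stress point field
#'
#' @param points Numeric `N x 3` matrix of sample coordinates, mm.
#' @param values WSS magnitudes, dyne/cm^2 (non-negative).
#' @return A tibble with columns `x, y, z, wss` and class `wss_field`.
#' @export
wss_field <- function(points, values) {
  points <- as.matrix(points)
  values <- as.numeric(values)
  stopifnot(ncol(points) == 3L, nrow(points) == length(values))
  if (any(values < 0)) stop("WSS magnitudes must be non-negative",
                            call. = FALSE)
  out <- tibble::tibble(x = points[, 1], y = points[, 2], z = points[, 3],
                        wss = values)
  class(out) <- c("wss_field", class(out))
  out
}

#' Nonphysiologic WSS percentage
#'
#' `100 * N_A / N_total`, where `N_A` counts WSS values strictly below the
#' threshold (default 1 dyne/cm^2, the lower bound of the physiologic
#' venous range; values below it mark thrombosis-prone regions). The
#' default is the count fraction; supply per-point `weights` (e.g. Voronoi
#' areas) for an area-weighted variant.
#'
#' @param field A [wss_field()] or numeric vector of WSS values.
#' @param threshold Threshold, dyne/cm^2.
#' @param weights Optional per-point positive weights.
#' @return Percentage in `[0, 100]`.
#' @export
pct_nonphysiologic_wss <- function(field, threshold = 1, weights = NULL) {
  values <- if (inherits(field, "wss_field")) field$wss else as.numeric(field)
  if (length(values) == 0L) stop("empty WSS field", call. = FALSE)
  if (is.null(weights)) {
    100 * sum(values < threshold) / length(values)
  } else {
    stopifnot(length(weights) == length(values), all(weights > 0))
    100 * sum(weights[values < threshold]) / sum(weights)
  }
}

#' Reynolds number of a pipe-like boundary
#'
#' `Re = rho * v * D / mu` with mean velocity `v = Q / (pi D^2 / 4)`;
#' flagged laminar below the standard pipe-flow transition value 2300.
#'
#' @param Q Flow rate, m^3/s (>= 0).
#' @param diameter Boundary diameter, m.
#' @param fluid A [fluid_properties()].
#' @return A list with `Re`, `velocity` (m/s), and `laminar`.
#' @export
reynolds_number <- function(Q, diameter, fluid = fluid_properties()) {
  if (!is.numeric(Q) || Q < 0) stop("Q must be non-negative", call. = FALSE)
  if (!is.numeric(diameter) || diameter <= 0) {
    stop("diameter must be positive", call. = FALSE)
  }
  v <- Q / (pi * diameter^2 / 4)
  re <- fluid$rho * v * diameter / fluid$mu
  list(Re = re, velocity = v, laminar = re < 2300)
}

#' Classify metrics against the clinical benchmark ranges
#'
#' Benchmarks: iPL strictly below 0.03; %WSS strictly below 10%; hepatic
#' flow distribution to the left PA within the inclusive range 40-60%.
#'
#' @param ipl Indexed power loss.
#' @param pct_wss Nonphysiologic WSS percentage.
#' @param hfd_lpa Hepatic flow share to the left PA, %.
#' @return Named logical vector `c(ipl, wss, hfd)`: `TRUE` = within range.
#' @export
classify_benchmarks <- function(ipl, pct_wss, hfd_lpa) {
  c(ipl = ipl < 0.03,
    wss = pct_wss < 10,
    hfd = hfd_lpa >= 40 & hfd_lpa <= 60)
}

#' Hemodynamic performance report
#'
#' Bundles the three benchmark metrics with their pass/fail flags.
#'
#' @param ipl Indexed power loss (dimensionless).
#' @param pct_wss Nonphysiologic WSS percentage.
#' @param hfd_lpa,hfd_rpa Hepatic flow shares, %.
#' @param bsa Body surface area, m^2.
#' @param stranded_pct Percentage of traced particles that never exited.
#' @param reynolds Optional [reynolds_number()] result.
#' @return An object of class `hemo_report`.
#' @export
hemo_report <- function(ipl, pct_wss, hfd_lpa, hfd_rpa = 100 - hfd_lpa,
                        bsa = NA_real_, stranded_pct = 0, reynolds = NULL) {
  if (hfd_lpa + hfd_rpa > 100 + 1e-9) {
    stop("hfd_lpa + hfd_rpa cannot exceed 100%", call. = FALSE)
  }
  structure(list(ipl = ipl, pct_wss = pct_wss, hfd_lpa = hfd_lpa,
                 hfd_rpa = hfd_rpa, bsa = bsa,
                 stranded_pct = stranded_pct, reynolds = reynolds,
                 flags = classify_benchmarks(ipl, pct_wss, hfd_lpa)),
            class = "hemo_report")
}

#' @export
print.hemo_report <- function(x, ...) {
  lab <- function(ok) if (ok) "within" else "outside"
  cat("Hemodynamic performance report\n")
  cat(sprintf("  iPL   : %-10.4g benchmark < 0.03    -> %s\n",
              x$ipl, lab(x$flags["ipl"])))
  cat(sprintf("  %%WSS  : %-10.4g benchmark < 10%%     -> %s\n",
              x$pct_wss, lab(x$flags["wss"])))
  cat(sprintf("  HFD   : %.4g%% LPA / %.4g%% RPA, benchmark 40-60%% -> %s\n",
              x$hfd_lpa, x$hfd_rpa, lab(x$flags["hfd"])))
  if (x$stranded_pct > 0) {
    cat(sprintf("  stranded particles: %.2f%%\n", x$stranded_pct))
  }
  if (!is.null(x$reynolds)) {
    cat(sprintf("  Reynolds: %.1f (%s)\n", x$reynolds$Re,
                if (x$reynolds$laminar) "laminar" else "not laminar"))
  }
  invisible(x)
}

#' Tidy a hemodynamic report into a one-row tibble
#' @param x A [hemo_report()].
#' @param ... Unused.
#' @export
as_tibble.hemo_report <- function(x, ...) {
  tibble::tibble(ipl = x$ipl, pct_wss = x$pct_wss, hfd_lpa = x$hfd_lpa,
                 hfd_rpa = x$hfd_rpa, bsa = x$bsa,
                 stranded_pct = x$stranded_pct,
                 ipl_within = unname(x$flags["ipl"]),
                 wss_within = unname(x$flags["wss"]),
                 hfd_within = unname(x$flags["hfd"]))
}

#' Serialize a hemodynamic report to JSON
#'
#' @param x A [hemo_report()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "hemo_report"))
  obj <- list(ipl = x$ipl, pct_wss = x$pct_wss, hfd_lpa = x$hfd_lpa,
              hfd_rpa = x$hfd_rpa, bsa = x$bsa,
              stranded_pct = x$stranded_pct,
              flags = as.list(x$flags))
  if (!is.null(x$reynolds)) obj$reynolds <- x$reynolds
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
  }
}
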