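# Analytic flow fixtures with known ground truth. These exist so every
# metric and geometric operation is testable without patient data or a
# flow solver: each fixture computes its ground truth in closed form at
# construction time.

#' Poiseuille pipe fixture
#'
#' Fully developed laminar flow in a straight rigid pipe along +z:
#' axial velocity `u(r) = (2Q / (pi R^2)) (1 - r^2/R^2)`, pressure drop
#' `dp = 8 mu L Q / (pi R^4)`, wall shear stress `tau_w = 4 mu Q / (pi R^3)`.
#' The returned boundary table carries consistent area-averaged pressure
#' and squared-velocity values, so the power-loss balance must recover
#' `PL = dp * Q` exactly, and the wall WSS field is single-valued at the
#' analytic stress.
#'
#' @param R Pipe radius, m.
#' @param L Pipe length, m.
#' @param Q Flow rate, m^3/s.
#' @param fluid A [fluid_properties()].
#' @param n_wall Number of wall sample points in the WSS field.
#' @return A list of class `poiseuille_fixture` with elements `sampler`
#'   (velocity-field sampler, positions in mm), `boundaries` (tibble),
#'   `wss` ([wss_field()], dyne/cm^2), and `analytic` (closed forms:
#'   `dp` Pa, `pl` W, `wall_wss_pa`, `wall_wss_dyne`, `u_max` m/s, and
#'   `ipl(BSA)`).
#' @export
make_poiseuille <- function(R = 0.0075, L = 0.05, Q = 2 / 60000,
                            fluid = fluid_properties(), n_wall = 400L) {
  stopifnot(R > 0, L > 0, Q > 0)
  u_max <- 2 * Q / (pi * R^2)
  dp <- 8 * fluid$mu * L * Q / (pi * R^4)
  tau_pa <- 4 * fluid$mu * Q / (pi * R^3)
  R_mm <- R * 1000; L_mm <- L * 1000
  sampler <- list(
    velocity = function(P) {
      r2 <- (P[, 1]^2 + P[, 2]^2) / R_mm^2
      ax <- u_max * pmax(1 - r2, 0)
      cbind(0, 0, ax, deparse.level = 0)
    },
    inside = function(P) {
      (P[, 1]^2 + P[, 2]^2) <= R_mm^2 * (1 + 1e-9) &
        P[, 3] >= -1e-9 & P[, 3] <= L_mm
    },
    outlet = function(P) ifelse(P[, 3] > L_mm, "OUT", NA_character_),
    outlets = "OUT")
  # area average of u^2 over the section: u_max^2 / 3
  v2 <- u_max^2 / 3
  boundaries <- rbind(
    flow_boundary("IVC", "inlet", Q, p = dp, v2 = v2, area = pi * R^2),
    flow_boundary("OUT", "outlet", Q, p = 0, v2 = v2, area = pi * R^2))
  phi <- 2 * pi * (seq_len(n_wall) - 1L) / n_wall
  zs <- L_mm * (seq_len(n_wall) - 0.5) / n_wall
  wall_pts <- cbind(R_mm * cos(phi), R_mm * sin(phi), zs)
  wss <- wss_field(wall_pts, rep(10 * tau_pa, n_wall))  # Pa -> dyne/cm^2
  structure(list(
    R = R, L = L, Q = Q, fluid = fluid,
    sampler = sampler, boundaries = boundaries, wss = wss,
    inlet_section = circular_section(c(0, 0, 0), c(0, 0, 1), R_mm, 64L),
    analytic = list(
      dp = dp, pl = dp * Q, u_max = u_max,
      wall_wss_pa = tau_pa, wall_wss_dyne = 10 * tau_pa,
      ipl = function(BSA) dp * Q * BSA^2 / (fluid$rho * Q^3))),
    class = "poiseuille_fixture")
}

# Area fraction of a disc of radius R lying left of the chord x = c.
disc_left_fraction <- function(c_, R) {
  (c_ * sqrt(R^2 - c_^2) + R^2 * asin(c_ / R) + R^2 * pi / 2) / (pi * R^2)
}

#' Y-junction fixture with an exact streamline split
#'
#' A piecewise unidirectional field: uniform axial flow up a trunk of
#' radius `R` (mm) for `z < H`, then purely horizontal flow toward the
#' left (`x` negative, labelled LPA) or right (RPA) exit plane. The
#' dividing plane `x = x_div` is placed analytically so the disc-area
#' fraction left of it equals the prescribed split `s`; every trunk
#' streamline exits exactly one branch and the field is divergence-free
#' within each piece. The exact split is therefore known by construction
#' and particle tracking must recover it up to seeding-grid quantization.
#'
#' @param s Fraction of IVC flow routed to the LPA, in (0, 1).
#' @param R Trunk radius, mm.
#' @param H Trunk height (z of the turning plane), mm.
#' @param X_exit Half-distance of the exit planes from the axis, mm.
#' @param speed Flow speed, m/s.
#' @return A list of class `yjunction_fixture` with `sampler`,
#'   `inlet_section` (the seeding disc at z = 0), `s` and `x_div`.
#' @export
make_y_junction <- function(s, R = 7.5, H = 30, X_exit = 40, speed = 0.2) {
  if (!is.numeric(s) || s <= 0 || s >= 1) {
    stop("the split fraction s must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  x_div <- stats::uniroot(function(c_) disc_left_fraction(c_, R) - s,
                          lower = -R + 1e-9, upper = R - 1e-9,
                          tol = 1e-12)$root
  sampler <- list(
    velocity = function(P) {
      below <- P[, 3] < H
      vx <- ifelse(below, 0, ifelse(P[, 1] < x_div, -speed, speed))
      vz <- ifelse(below, speed, 0)
      cbind(vx, 0, vz, deparse.level = 0)
    },
    inside = function(P) {
      abs(P[, 1]) <= X_exit + 1 & abs(P[, 2]) <= R + 1 &
        P[, 3] >= -1 & P[, 3] <= H + 2 * R
    },
    outlet = function(P) {
      ifelse(P[, 1] <= -X_exit, "LPA",
             ifelse(P[, 1] >= X_exit, "RPA", NA_character_))
    },
    outlets = c("LPA", "RPA"))
  structure(list(s = s, x_div = x_div, R = R, H = H, X_exit = X_exit,
                 speed = speed,
                 sampler = sampler,
                 inlet_section = circular_section(c(0, 0, 0), c(0, 0, 1),
                                                  R, 64L)),
            class = "yjunction_fixture")
}

#' Synthetic WSS field with an exact below-threshold fraction
#'
#' Generates `n_points` WSS samples of which exactly
#' `round(n_points * below_fraction)` lie strictly below 1 dyne/cm^2 and
#' the rest in `[1, 10]`, at random coordinates in a 10 mm box.
#'
#' @param n_points Number of samples.
#' @param below_fraction Target below-threshold fraction in `[0, 1]`.
#' @param seed Random seed (deterministic fixture).
#' @return A [wss_field()].
#' @export
make_wss_field <- function(n_points, below_fraction, seed = 0L) {
  stopifnot(n_points >= 1, below_fraction >= 0, below_fraction <= 1)
  set.seed(seed)
  k <- round(n_points * below_fraction)
  vals <- c(stats::runif(k, 0.02, 0.98),
            stats::runif(n_points - k, 1, 10))
  vals <- sample(vals)
  pts <- matrix(stats::runif(3 * n_points, 0, 10), ncol = 3L)
  wss_field(pts, vals)
}

#' Toy TCPC anatomy: open cylindrical boundary surfaces
#'
#' Emulates the segmented anatomy pair used for graft design: an inferior
#' IVC stub (with its 10 mm inferior extrusion already applied) and a
#' Glenn stage as a T of three cylinders (SVC from above, LPA and RPA to
#' the sides). These are open boundary surfaces, not a solved anatomy;
#' they give the graft builders realistic targets.
#'
#' @param r_ivc,r_svc,r_pa Radii, mm.
#' @param stub_length IVC stub length before the 10 mm extension, mm.
#' @param gap Vertical distance between the IVC stub top and the PA
#'   underside, mm.
#' @param m Angular samples per cylinder.
#' @return A list of class `toy_anatomy`: `surfaces` (named
#'   [graft_mesh()]s `ivc`, `svc`, `lpa`, `rpa`), `ivc_top`
#'   (a [cross_section()] at the top of the stub, the graft start), and
#'   `pa_center_z` (the PA axis height, mm).
#' @export
make_toy_anatomy <- function(r_ivc = 8, r_svc = 6, r_pa = 7,
                             stub_length = 5, gap = 40, m = 32L) {
  stopifnot(r_ivc > 0, r_svc > 0, r_pa > 0, stub_length > 0, gap > 0)
  straight <- function(a, b) {
    bezier_path(bezier_segment(a, a + (b - a) / 3, a + 2 * (b - a) / 3, b))
  }
  cyl <- function(a, b, r, tags) {
    n <- unitize(b - a)
    loft_tube(straight(a, b),
              circular_section(a, n, r, m), circular_section(b, n, r, m),
              n_rings = 8L, m_samples = m, caps = FALSE, tags = tags)
  }
  z_top <- 0                       # top of the IVC stub
  z_pa <- z_top + gap              # PA axis height
  ivc <- cyl(c(0, 0, z_top - stub_length), c(0, 0, z_top), r_ivc,
             c("IVC_bottom", "IVC_top"))
  ivc <- extrude_boundary(ivc, "IVC_bottom", 10)   # inferior extension
  svc <- cyl(c(0, 0, z_pa + r_pa), c(0, 0, z_pa + r_pa + 40), r_svc,
             c("SVC_bottom", "SVC_top"))
  lpa <- cyl(c(-10, 0, z_pa), c(-50, 0, z_pa), r_pa,
             c("LPA_root", "LPA_distal"))
  rpa <- cyl(c(10, 0, z_pa), c(50, 0, z_pa), r_pa,
             c("RPA_root", "RPA_distal"))
  structure(list(
    surfaces = list(ivc = ivc, svc = svc, lpa = lpa, rpa = rpa),
    ivc_top = circular_section(c(0, 0, z_top), c(0, 0, 1), r_ivc, m),
    pa_center_z = z_pa),
    class = "toy_anatomy")
}
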