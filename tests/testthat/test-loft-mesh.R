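make_cylinder <- function(r = 5, len = 20, n_rings = 16L, m = 64L,
                          caps = TRUE) {
  p <- straight_path(c(0, 0, 0), c(0, 0, len))
  loft_tube(p,
            circular_section(c(0, 0, 0), c(0, 0, 1), r, m),
            circular_section(c(0, 0, len), c(0, 0, 1), r, m),
            n_rings = n_rings, m_samples = m, caps = caps)
}

test_that("a capped straight loft is a closed cylinder of the right volume", {
  m <- make_cylinder()
  expect_closed_genus0(m)
  expect_equal(mesh_volume(m), pi * 25 * 20, tolerance = 0.02)
})

test_that("cylinder volume converges to pi r^2 L with angular refinement", {
  errs <- vapply(c(16L, 32L, 64L), function(ms) {
    abs(mesh_volume(make_cylinder(m = ms)) - pi * 25 * 20) / (pi * 25 * 20)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3L], 0.005)
})

test_that("an uncapped loft exposes exactly two tagged rims", {
  m <- make_cylinder(caps = FALSE)
  expect_false(mesh_is_watertight(m))
  expect_named(m$boundary_tags, c("inlet", "outlet"))
  expect_length(m$boundary_tags$inlet, 64L)
})

test_that("equal end radii yield constant-radius intermediate rings", {
  m <- make_cylinder(r = 5, caps = FALSE, n_rings = 12L, m = 32L)
  r <- sqrt(m$vertices[, 1]^2 + m$vertices[, 2]^2)
  expect_true(all(abs(r - 5) < 1e-9))
})

test_that("every ring radius equals the adjusted interpolation exactly", {
  r0 <- 4; r1 <- 9; n_rings <- 10L; msamp <- 16L
  p <- straight_path(c(0, 0, 0), c(0, 0, 30))
  m <- loft_tube(p,
                 circular_section(c(0, 0, 0), c(0, 0, 1), r0, msamp),
                 circular_section(c(0, 0, 30), c(0, 0, 1), r1, msamp),
                 n_rings = n_rings, m_samples = msamp, caps = FALSE)
  pr <- radius_profile(r0, r1, smoothstep)
  u <- seq(0, 1, length.out = n_rings)
  for (i in seq_len(n_rings)) {
    ring <- m$vertices[(i - 1L) * msamp + seq_len(msamp), ]
    radii <- sqrt(ring[, 1]^2 + ring[, 2]^2)
    expect_equal(radii, rep(interp_radius(pr, u[i]), msamp),
                 tolerance = 1e-9)
  }
})

test_that("randomized capped lofts are watertight genus-0 solids", {
  set.seed(99)
  for (i in 1:40) {
    r0 <- runif(1, 1, 8); r1 <- runif(1, 1, 8)
    len <- runif(1, 15, 60)
    bend <- runif(3, -15, 15)
    p <- bezier_path(bezier_segment(
      c(0, 0, 0), c(bend[1], bend[2], len / 3),
      c(bend[3], -bend[1], 2 * len / 3), c(0, 0, len)))
    ms <- sample(c(12L, 16L, 24L), 1L)
    m <- loft_tube(p,
                   circular_section(c(0, 0, 0), c(0, 0, 1), r0, ms),
                   circular_section(c(0, 0, len), c(0, 0, 1), r1, ms),
                   n_rings = sample(4:20, 1L), m_samples = ms, caps = TRUE)
    expect_closed_genus0(m)
  }
})

test_that("degenerate loft inputs are rejected", {
  cs <- circular_section(c(0, 0, 0), c(0, 0, 1), 5, 16L)
  ce <- circular_section(c(0, 0, 20), c(0, 0, 1), 5, 16L)
  p <- straight_path(c(0, 0, 0), c(0, 0, 20))
  expect_error(loft_tube(p, cs, ce, n_rings = 1L, m_samples = 16L),
               "n_rings")
  expect_error(loft_tube(p, cs, ce, n_rings = 8L, m_samples = 6L),
               "m_samples")
  expect_error(circular_section(c(0, 0, 0), c(0, 0, 1), 0.01, 16L),
               "at least")
  cs32 <- circular_section(c(0, 0, 0), c(0, 0, 1), 5, 32L)
  expect_error(loft_tube(p, cs32, ce, n_rings = 8L, m_samples = 16L),
               "matching sample counts|m_samples")
})

test_that("a tube graft end ring lies exactly on the polar ellipse", {
  msamp <- 32L
  ivc <- circular_section(c(0, 0, 0), c(0, 0, 1), 5, msamp)
  el <- anastomosis_ellipse(c(0, 0, 25), c(4, 0, 0), c(0, 2, 0))
  p <- straight_path(c(0, 0, 0), c(0, 0, 25))
  g <- build_tube_graft(ivc, el, p, n_rings = 10L, m_samples = msamp)
  expect_named(g$boundary_tags, c("IVC_inlet", "PA_anastomosis_1"))
  end_ring <- g$vertices[g$boundary_tags$PA_anastomosis_1, ]
  d <- sqrt((end_ring[, 1])^2 + (end_ring[, 2])^2)
  theta <- 2 * pi * (seq_len(msamp) - 1L) / msamp
  expect_equal(d, ellipse_radius(el, theta), tolerance = 1e-9)
})

test_that("path endpoints away from the section centers are rejected", {
  ivc <- circular_section(c(0, 0, 0), c(0, 0, 1), 5, 32L)
  el <- anastomosis_ellipse(c(0, 0, 25), c(4, 0, 0), c(0, 2, 0))
  p_off <- straight_path(c(5, 0, 0), c(0, 0, 25))
  expect_error(build_tube_graft(ivc, el, p_off, m_samples = 32L),
               "5.000 mm")
})

test_that("meshes recover from inconsistent winding", {
  m <- make_cylinder(n_rings = 6L, m = 16L)
  bad <- m
  flip <- sample(nrow(bad$faces), 40L)
  bad$faces[flip, ] <- bad$faces[flip, c(1, 3, 2)]
  fixed <- fontangraft:::orient_mesh(bad)
  expect_true(mesh_is_watertight(fixed))
  expect_equal(mesh_volume(fixed), mesh_volume(m), tolerance = 1e-12)
})
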