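test_that("particle seeding fills the inlet area at the requested pitch", {
  inlet <- circular_section(c(0, 0, 0), c(0, 0, 1), 10, 64L)
  seeds <- seed_particles(inlet, 1)         # R/10 pitch
  expect_equal(nrow(seeds), pi * 100, tolerance = 0.1)
  fine <- seed_particles(inlet, 0.5)
  expect_equal(nrow(fine) / nrow(seeds), 4, tolerance = 0.1)
  single <- seed_particles(inlet, 25)       # pitch > 2R
  expect_identical(nrow(single), 1L)
  expect_equal(single[1, ], c(0, 0, 0))
  expect_error(seed_particles(inlet, 0), "positive")
})

test_that("seeds honour an elliptical inlet boundary", {
  el <- anastomosis_ellipse(c(0, 0, 0), c(8, 0, 0), c(0, 4, 0))
  seeds <- seed_particles(el, 0.4)
  expect_equal(nrow(seeds), pi * 8 * 4 / 0.4^2, tolerance = 0.1)
  expect_true(all(seeds[, 1]^2 / 64 + seeds[, 2]^2 / 16 < 1 + 1e-6))
})

test_that("uniform axial flow carries every particle out of the one outlet", {
  fx <- make_poiseuille()
  seeds <- seed_particles(fx$inlet_section, 1.5)
  tr <- trace_particles(fx$sampler, seeds, step = 0.02, max_steps = 5000L)
  expect_identical(tr$n_stranded, 0L)
  expect_identical(tr$exits$OUT, as.integer(nrow(seeds)))
})

test_that("a zero velocity field strands every particle", {
  still <- list(velocity = function(P) matrix(0, nrow(P), 3L),
                inside = function(P) rep(TRUE, nrow(P)),
                outlet = function(P) rep(NA_character_, nrow(P)))
  tr <- trace_particles(still, matrix(runif(30), 10L, 3L), step = 0.01,
                        max_steps = 50L)
  expect_identical(tr$n_stranded, 10L)
  expect_length(tr$exits, 0L)
})

test_that("particle counts are conserved on every trace", {
  set.seed(21)
  for (s in c(0.3, 0.5, 0.7)) {
    fx <- make_y_junction(s)
    seeds <- seed_particles(fx$inlet_section, 1.5)
    for (budget in c(3L, 50L, 2000L)) {   # including early termination
      tr <- trace_particles(fx$sampler, seeds, step = 0.01,
                            max_steps = budget)
      n_exited <- sum(unlist(tr$exits))
      expect_identical(n_exited + tr$n_stranded, tr$n_seeded)
    }
  }
})

test_that("a non-finite velocity names the offending particle", {
  broken <- list(
    velocity = function(P) {
      v <- cbind(0, 0, rep(0.1, nrow(P)))
      v[P[, 1] > 5, 3] <- NaN
      v
    },
    inside = function(P) rep(TRUE, nrow(P)),
    outlet = function(P) rep(NA_character_, nrow(P)))
  seeds <- rbind(c(0, 0, 0), c(9, 0, 0))
  expect_error(trace_particles(broken, seeds, step = 0.01, max_steps = 5L),
               "particle 2")
})

test_that("the integrator shows fourth-order convergence on a rotation", {
  sampler <- rotation_sampler()
  start <- matrix(c(10, 0, 0), 1L, 3L)
  final_err <- function(step, n) {
    tr <- trace_particles(sampler, start, step = step, max_steps = n)
    angle <- step * n
    exact <- c(10 * cos(angle), 10 * sin(angle), 0)
    sqrt(sum((tr$final[1, ] - exact)^2))
  }
  e1 <- final_err(2 * pi / 16, 16L)
  e2 <- final_err(2 * pi / 32, 32L)
  order <- log2(e1 / e2)
  expect_gt(order, 3.5)
})

test_that("HFD shares divide outlet counts by the seeded total", {
  expect_equal(hfd(list(n_seeded = 100L, exits = list(LPA = 100L),
                        n_stranded = 0L)),
               list(hfd_lpa = 100, hfd_rpa = 0, stranded_pct = 0))
  h <- hfd(list(n_seeded = 100L, exits = list(LPA = 73L, RPA = 27L),
                n_stranded = 0L))
  expect_equal(h$hfd_lpa, 73)
  expect_equal(h$hfd_rpa, 27)
  expect_warning(
    h2 <- hfd(list(n_seeded = 200L, exits = list(LPA = 80L, RPA = 80L),
                   n_stranded = 40L)),
    "stranded")
  expect_equal(h2$hfd_lpa, 40)
  expect_equal(h2$hfd_rpa, 40)
  expect_equal(h2$stranded_pct, 20)
  expect_error(hfd(list(n_seeded = 0L)), "seeded")
})

test_that("the y-junction split is recovered within seeding resolution", {
  fx <- make_y_junction(0.7)
  seeds <- seed_particles(fx$inlet_section, 0.7)  # ~400 seeds
  expect_gte(nrow(seeds), 350)
  tr <- trace_particles(fx$sampler, seeds, step = 0.01, max_steps = 2000L)
  h <- hfd(tr)
  expect_equal(h$hfd_lpa, 70, tolerance = 0.07)   # +-5 points
  expect_equal(h$stranded_pct, 0)
})
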