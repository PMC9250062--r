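test_that("power loss vanishes for equal total pressure and is offset-invariant", {
  fluid <- fluid_properties()
  b <- rbind(flow_boundary("IVC", "inlet", 3e-5, p = 500, v2 = 0.01),
             flow_boundary("SVC", "inlet", 2e-5, p = 500, v2 = 0.01),
             flow_boundary("LPA", "outlet", 2.5e-5, p = 500, v2 = 0.01),
             flow_boundary("RPA", "outlet", 2.5e-5, p = 500, v2 = 0.01))
  expect_equal(power_loss(b, fluid), 0, tolerance = 1e-15)
  b2 <- b; b2$p <- b2$p + 123.4
  b3 <- b; b3$p <- b3$p + c(40, -10, 5, 30)   # distinct pressures
  pl3 <- power_loss(b3, fluid)
  b4 <- b3; b4$p <- b4$p + 9876.5
  expect_equal(power_loss(b4, fluid), pl3, tolerance = 1e-9)
})

test_that("mass imbalance beyond 1% is rejected", {
  b <- rbind(flow_boundary("IVC", "inlet", 3e-5, p = 100, v2 = 0),
             flow_boundary("LPA", "outlet", 2.8e-5, p = 0, v2 = 0))
  expect_error(power_loss(b), "mass imbalance")
})

test_that("power loss matches Hagen-Poiseuille on the pipe fixture grid", {
  fluid <- fluid_properties()
  for (R in c(0.005, 0.0075, 0.01)) {
    for (L in c(0.03, 0.05, 0.08)) {
      for (Q in c(1, 2, 4) / 60000) {
        fx <- make_poiseuille(R, L, Q, fluid)
        expect_equal(power_loss(fx$boundaries, fluid),
                     8 * fluid$mu * L * Q^2 / (pi * R^4),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("indexed power loss follows its scaling law and magnitudes", {
  fluid <- fluid_properties()
  expect_equal(indexed_power_loss(0, 1e-4, 1, fluid), 0)
  # constructed inputs with the native case magnitude
  Q_s <- 1e-4; BSA <- 1.2
  pl <- 0.0086 * fluid$rho * Q_s^3 / BSA^2
  expect_equal(indexed_power_loss(pl, Q_s, BSA, fluid), 0.0086,
               tolerance = 1e-12)
  expect_equal(indexed_power_loss(pl, Q_s, 2 * BSA, fluid),
               4 * 0.0086, tolerance = 1e-12)
  expect_error(indexed_power_loss(1, 0, 1), "Q_s")
  expect_error(indexed_power_loss(1, 1e-4, -1), "BSA")
})

test_that("nonphysiologic WSS percentage counts strict sub-threshold values", {
  expect_equal(pct_nonphysiologic_wss(c(0.5, 2.0, 0.3, 1.5)), 50)
  expect_equal(pct_nonphysiologic_wss(c(1, 2, 3)), 0)
  expect_equal(pct_nonphysiologic_wss(c(1, 2, 3), threshold = 2.5), 100 * 2 / 3)
  expect_error(pct_nonphysiologic_wss(numeric(0)), "empty")
  # area weights shift the percentage
  expect_equal(pct_nonphysiologic_wss(c(0.5, 2), weights = c(3, 1)), 75)
})

test_that("the count fraction of uniform samples sits at its binomial value", {
  set.seed(10)
  v <- runif(10000, 0, 2)
  expect_equal(pct_nonphysiologic_wss(v), 50, tolerance = 0.03)  # 3 sigma
})

test_that("Reynolds number and the laminar flag follow the pipe formula", {
  fluid <- fluid_properties(1060, 0.0035)
  D <- 0.015
  Q <- 0.1 * pi * D^2 / 4     # bulk velocity 0.1 m/s
  re <- reynolds_number(Q, D, fluid)
  expect_equal(re$Re, 1060 * 0.1 * 0.015 / 0.0035, tolerance = 1e-12)
  expect_equal(re$Re, 454, tolerance = 0.001)
  expect_true(re$laminar)
  expect_equal(reynolds_number(0, D, fluid)$Re, 0)
  expect_equal(reynolds_number(10 * Q, D, fluid)$Re, 10 * re$Re,
               tolerance = 1e-12)
  expect_false(reynolds_number(10 * Q, D, fluid)$laminar)
  expect_error(reynolds_number(Q, 0, fluid), "diameter")
})

test_that("benchmark flags use strict upper bounds and an inclusive HFD band", {
  f <- classify_benchmarks(0.0086, 55.36, 72.72)
  expect_identical(unname(f), c(TRUE, FALSE, FALSE))
  expect_true(all(classify_benchmarks(0.01, 5, 50)))
  expect_false(classify_benchmarks(0.03, 5, 50)["ipl"])    # boundary: outside
  expect_false(classify_benchmarks(0.01, 10, 50)["wss"])
  expect_true(classify_benchmarks(0.01, 5, 40)["hfd"])     # inclusive band
  expect_true(classify_benchmarks(0.01, 5, 60)["hfd"])
  expect_false(classify_benchmarks(0.01, 5, 60.01)["hfd"])
})

test_that("reports carry flags, serialize to JSON, and tidy to a tibble", {
  rep <- hemo_report(0.0086, 55.36, 72.72, 27.28, bsa = 1.2)
  expect_s3_class(rep, "hemo_report")
  j <- jsonlite::fromJSON(report_json(rep))
  expect_equal(j$ipl, 0.0086)
  expect_true(j$flags$ipl)
  expect_false(j$flags$wss)
  tb <- tibble::as_tibble(rep)
  expect_identical(nrow(tb), 1L)
  expect_true(tb$ipl_within)
  expect_error(hemo_report(0.01, 5, 70, 70), "exceed")
})
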