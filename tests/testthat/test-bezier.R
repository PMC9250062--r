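test_that("anchor endpoints are interpolated exactly", {
  set.seed(1)
  for (i in 1:20) {
    rs <- random_segment()
    expect_identical(bezier_eval(rs$seg, 0), rs$ctrl[1L, ])
    expect_identical(bezier_eval(rs$seg, 1), rs$ctrl[4L, ])
  }
})

test_that("collinear equally spaced control points give the line midpoint", {
  seg <- bezier_segment(c(0, 0, 0), c(1, 2, 3), c(2, 4, 6), c(3, 6, 9))
  expect_equal(bezier_eval(seg, 0.5), c(1.5, 3, 4.5), tolerance = 1e-14)
})

test_that("evaluation matches the de Casteljau oracle to 1e-12", {
  set.seed(42)
  for (i in 1:200) {
    rs <- random_segment()
    t <- runif(1)
    expect_equal(bezier_eval(rs$seg, t), de_casteljau(rs$ctrl, t),
                 tolerance = 1e-12)
  }
})

test_that("the curve stays inside the control-point convex hull (bounding box)", {
  set.seed(7)
  for (i in 1:20) {
    rs <- random_segment()
    pts <- bezier_eval(rs$seg, seq(0, 1, length.out = 50))
    for (d in 1:3) {
      expect_true(all(pts[, d] >= min(rs$ctrl[, d]) - 1e-12))
      expect_true(all(pts[, d] <= max(rs$ctrl[, d]) + 1e-12))
    }
  }
})

test_that("out-of-domain parameters and degenerate segments are rejected", {
  seg <- bezier_segment(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_error(bezier_eval(seg, -0.1), "\\[0, 1\\]")
  expect_error(bezier_eval(seg, 1.1), "\\[0, 1\\]")
  expect_error(bezier_segment(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0),
                              c(0.005, 0, 0)), "degenerate")
})

test_that("anchor insertion preserves the curve shape", {
  # de Casteljau subdivision at t_s maps the original parameter t onto the
  # left piece as t/t_s (t <= t_s) and the right piece as
  # (t - t_s)/(1 - t_s); the traced points must coincide
  set.seed(11)
  for (i in 1:10) {
    rs <- random_segment()
    path <- bezier_path(rs$seg)
    ts <- runif(1, 0.2, 0.8)
    split <- insert_anchor(path, 1L, ts)
    expect_length(split$segments, 2L)
    worst <- 0
    for (t in seq(0, 1, length.out = 200)) {
      p_orig <- bezier_eval(rs$seg, t)
      p_split <- if (t <= ts) {
        bezier_eval(split$segments[[1L]], t / ts)
      } else {
        bezier_eval(split$segments[[2L]], (t - ts) / (1 - ts))
      }
      worst <- max(worst, max(abs(p_orig - p_split)))
    }
    expect_lt(worst, 1e-10)
  }
})

test_that("splitting at the ends or out of range is rejected", {
  path <- bezier_path(bezier_segment(c(0, 0, 0), c(0, 0, 5),
                                     c(0, 0, 15), c(0, 0, 20)))
  expect_error(insert_anchor(path, 1L, 0), "degenerate split")
  expect_error(insert_anchor(path, 1L, 1), "degenerate split")
  expect_error(insert_anchor(path, 2L, 0.5), "out of range")
})

test_that("repeated insertion keeps C0 continuity and grows the anchor set", {
  path <- bezier_path(bezier_segment(c(0, 0, 0), c(10, 0, 5),
                                     c(20, 10, 15), c(30, 10, 20)))
  p2 <- insert_anchor(path, 1L, 0.4)
  p3 <- insert_anchor(p2, 2L, 0.5)
  expect_length(p3$segments, 3L)
  expect_identical(nrow(path_anchors(p3)), 4L)
  for (k in 1:2) {
    expect_equal(p3$segments[[k]]$p3, p3$segments[[k + 1L]]$p0,
                 tolerance = 1e-12)
  }
  # the two new handles flank each interior anchor
  a <- path_anchors(p3)[2L, ]
  h_before <- p3$segments[[1L]]$p2
  h_after <- p3$segments[[2L]]$p1
  expect_gt(sum((h_before - h_after)^2), 0)
})

test_that("non-contiguous segments are rejected at path construction", {
  s1 <- bezier_segment(c(0, 0, 0), c(0, 0, 5), c(0, 0, 15), c(0, 0, 20))
  s2 <- bezier_segment(c(5, 0, 20), c(5, 0, 25), c(5, 0, 30), c(5, 0, 40))
  expect_error(bezier_path(list(s1, s2)), "C0")
})

test_that("the global parameter is proportional to arc length", {
  # two segments of very different lengths along one straight line
  s1 <- bezier_segment(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2), c(0, 0, 3))
  s2 <- bezier_segment(c(0, 0, 3), c(0, 0, 12), c(0, 0, 21), c(0, 0, 30))
  path <- bezier_path(list(s1, s2))
  expect_equal(path_length(path), 30, tolerance = 1e-6)
  expect_equal(path_eval(path, 0.5)[3], 15, tolerance = 0.02)
})
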