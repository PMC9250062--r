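tube_sketch_fixture <- function() {
  ivc <- circular_section(c(0, 0, 0), c(0, 0, 1), 5.25, 24L)
  el <- anastomosis_ellipse(c(3, 1, 25), c(4.2, 0, 0), c(0, 2.8, 0))
  p <- bezier_path(bezier_segment(c(0, 0, 0), c(0, 0, 9),
                                  c(3, 1, 16), c(3, 1, 25)))
  design_sketch("tube", ivc, el, list(p),
                params = list(n_rings = 12L, m_samples = 24L))
}

bifurcated_sketch_fixture <- function() {
  ivc <- circular_section(c(0, 0, 0), c(0, 0, 1), 6, 32L)
  a1 <- anastomosis_ellipse(c(0, 0, 60), c(6, 0, 0), c(0, 6, 0))
  a2 <- anastomosis_ellipse(c(40, 0, 30), c(0, 4, 0), c(0, 0, 4))
  p1 <- straight_path(c(0, 0, 0), c(0, 0, 60))
  p2 <- straight_path(c(40, 0, 30), c(0, 0, 30))
  design_sketch("bifurcated", ivc, a1, list(p1, p2),
                anastomosis2 = a2, split_point = 0.5)
}

test_that("a sketch survives a save/load round trip", {
  sk <- tube_sketch_fixture()
  f <- tempfile(fileext = ".csv")
  save_sketch(sk, f)
  sk2 <- load_sketch(f)
  expect_identical(sk2$shape_kind, "tube")
  expect_identical(sk2$params, sk$params)
  expect_identical(sk2$ivc_section$radii, sk$ivc_section$radii)
  expect_identical(sk2$anastomosis1$axis_a, sk$anastomosis1$axis_a)
  expect_identical(sk2$paths[[1L]]$segments[[1L]]$p1,
                   sk$paths[[1L]]$segments[[1L]]$p1)
  expect_identical(sk2$transforms, sk$transforms)
})

test_that("rebuilding a reloaded sketch reproduces the mesh bit-exactly", {
  for (sk in list(tube_sketch_fixture(), bifurcated_sketch_fixture())) {
    original <- build_sketch(sk)
    f <- tempfile(fileext = ".csv")
    save_sketch(sk, f)
    rebuilt <- build_sketch(load_sketch(f))
    expect_identical(rebuilt$vertices, original$vertices)
    expect_identical(rebuilt$faces, original$faces)
    expect_identical(rebuilt$boundary_tags, original$boundary_tags)
  }
})

test_that("a bifurcated sketch stores both paths, trunk first", {
  sk <- bifurcated_sketch_fixture()
  f <- tempfile(fileext = ".csv")
  save_sketch(sk, f)
  lines <- readLines(f)
  bez <- grep("^[0-9]+,[0-9]+,P[0-3],", lines, value = TRUE)
  pids <- as.integer(sub(",.*", "", bez))
  expect_identical(sort(unique(pids)), c(1L, 2L))
  expect_true(all(diff(pids) >= 0))        # trunk block precedes branch
  sk2 <- load_sketch(f)
  expect_length(sk2$paths, 2L)
  expect_identical(sk2$split_point, 0.5)
})

test_that("anchor counts are recoverable from the bezier record count", {
  sk <- tube_sketch_fixture()
  sk$paths[[1L]] <- insert_anchor(insert_anchor(sk$paths[[1L]], 1L, 0.3),
                                  1L, 0.5)
  f <- tempfile(fileext = ".csv")
  save_sketch(sk, f)
  lines <- readLines(f)
  n_records <- length(grep("^1,[0-9]+,P[0-3],", lines))
  # 4 control-point records per segment; anchors = segments + 1
  expect_identical(n_records / 4 + 1, 4)    # 3 anchors inserted -> 4 total
  sk2 <- load_sketch(f)
  expect_identical(nrow(path_anchors(sk2$paths[[1L]])), 4L)
})

test_that("section reordering and truncation raise parse errors", {
  sk <- tube_sketch_fixture()
  f <- tempfile(fileext = ".csv")
  save_sketch(sk, f)
  lines <- readLines(f)
  # swap the #BEZIER and #RADII section headers
  swapped <- lines
  swapped[swapped == "#BEZIER"] <- "#TMP"
  swapped[swapped == "#RADII"] <- "#BEZIER"
  swapped[swapped == "#TMP"] <- "#RADII"
  f2 <- tempfile(fileext = ".csv")
  writeLines(swapped, f2)
  expect_error(load_sketch(f2), "out of order|parse error")
  # truncate before #PARAMS
  f3 <- tempfile(fileext = ".csv")
  writeLines(lines[seq_len(which(lines == "#PARAMS") - 1L)], f3)
  expect_error(load_sketch(f3), "missing section #PARAMS")
  # wrong magic
  f4 <- tempfile(fileext = ".csv")
  writeLines(c("NOT_A_SKETCH", lines[-1L]), f4)
  expect_error(load_sketch(f4), "magic")
  # mangled field count, error names the line
  f5 <- tempfile(fileext = ".csv")
  bad <- lines
  i <- grep("^1,1,P1,", bad)[1L]
  bad[i] <- "1,1,P1,0"
  writeLines(bad, f5)
  expect_error(load_sketch(f5), sprintf("line %d", i))
})

test_that("sketch transforms rotate and translate meshes rigidly", {
  m <- build_sketch(tube_sketch_fixture())
  tf <- list(translation = c(10, -5, 2),
             rotation = c(cos(pi / 8), 0, 0, sin(pi / 8)),  # 45 deg about z
             scale = c(1, 1, 1))
  m2 <- apply_transform(m, tf)
  expect_equal(mesh_area(m2), mesh_area(m), tolerance = 1e-9)
  d <- sqrt(sum((colMeans(m2$vertices) -
                 (c(10, -5, 2))) ^ 2))  # centroid moved near the translation
  expect_lt(abs(d - sqrt(sum(colMeans(m$vertices)^2))), 1e-6)
})
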