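# Independent oracles and small builders shared across the suite.

# Recursive de Casteljau evaluation: an implementation of the cubic
# Bezier point independent of the package's Bernstein-basis code path.
de_casteljau <- function(ctrl, t) {
  pts <- ctrl
  while (nrow(pts) > 1L) {
    pts <- (1 - t) * pts[-nrow(pts), , drop = FALSE] +
      t * pts[-1L, , drop = FALSE]
  }
  as.numeric(pts)
}

random_segment <- function() {
  repeat {
    ctrl <- matrix(runif(12, -50, 50), 4L, 3L)
    if (sqrt(sum((ctrl[4L, ] - ctrl[1L, ])^2)) > 1) break
  }
  list(ctrl = ctrl,
       seg = bezier_segment(ctrl[1L, ], ctrl[2L, ], ctrl[3L, ], ctrl[4L, ]))
}

straight_path <- function(a, b) {
  bezier_path(bezier_segment(a, a + (b - a) / 3, a + 2 * (b - a) / 3, b))
}

# Voxel membership count for a union of solids given as inside predicates
# over an N x 3 matrix; returns the volume estimate at the given pitch.
voxel_union_volume <- function(predicates, lower, upper, pitch) {
  gx <- seq(lower[1] + pitch / 2, upper[1], by = pitch)
  gy <- seq(lower[2] + pitch / 2, upper[2], by = pitch)
  gz <- seq(lower[3] + pitch / 2, upper[3], by = pitch)
  total <- 0
  for (z in gz) {                       # slab-wise to bound memory
    g <- as.matrix(expand.grid(x = gx, y = gy))
    P <- cbind(g, z)
    inside <- rep(FALSE, nrow(P))
    for (pred in predicates) inside <- inside | pred(P)
    total <- total + sum(inside)
  }
  total * pitch^3
}

# Sampler for a rigid rotation about the z axis (angular rate 1 rad/s):
# the analytic trajectory of any particle is a circle, giving an exact
# reference for integrator-order checks.
rotation_sampler <- function() {
  list(
    velocity = function(P) cbind(-P[, 2], P[, 1], 0) / 1000,
    inside = function(P) rep(TRUE, nrow(P)),
    outlet = function(P) rep(NA_character_, nrow(P)))
}

expect_closed_genus0 <- function(mesh) {
  expect_true(mesh_is_watertight(mesh))
  expect_identical(euler_characteristic(mesh), 2L)
  expect_gt(mesh_volume(mesh), 0)
}
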