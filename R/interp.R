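# Radius interpolation along the pathway: r_t = r0 + (r1 - r0) * f(t).

#' Interpolation adjustment functions
#'
#' Girth blending between two cross-sections uses an adjustment factor
#' `f : [0,1] -> [0,1]` with `f(0) = 0`, `f(1) = 1`, monotone
#' non-decreasing. The default `smoothstep`, `f(t) = 3 t^2 - 2 t^3`, has
#' zero end slope, giving tangent-continuous girth at the anastomoses; the
#' `linear` option is `f(t) = t`.
#'
#' @param t Values in `[0, 1]`.
#' @return `f(t)`.
#' @export
smoothstep <- function(t) 3 * t^2 - 2 * t^3

#' @rdname smoothstep
#' @export
linear_adjust <- function(t) t

interp_fun <- function(f) {
  if (is.function(f)) return(f)
  switch(match.arg(f, c("smoothstep", "linear")),
         smoothstep = smoothstep,
         linear = linear_adjust)
}

#' Radius profile between two cross-section radii
#'
#' @param r0 Start radius (mm), at path position `t = 0`.
#' @param r1 End radius (mm), at `t = 1`.
#' @param f Adjustment function or its name (`"smoothstep"`, `"linear"`).
#' @return An object of class `radius_profile`.
#' @export
radius_profile <- function(r0, r1, f = smoothstep) {
  stopifnot(is.numeric(r0), is.numeric(r1), r0 > 0, r1 > 0)
  structure(list(r0 = r0, r1 = r1, delta = r1 - r0, f = interp_fun(f)),
            class = "radius_profile")
}

#' Interpolated radius at a path position
#'
#' `r_t = r0 + (r1 - r0) * f(t)`: the start and end center points are
#' defined as `t = 0` and `t = 1`.
#'
#' @param profile A [radius_profile()].
#' @param t Path position(s) in `[0, 1]`.
#' @return Radius (mm), vectorized over `t`.
#' @export
interp_radius <- function(profile, t) {
  stopifnot(inherits(profile, "radius_profile"))
  if (any(t < 0) || any(t > 1)) stop("t must lie in [0, 1]", call. = FALSE)
  profile$r0 + profile$delta * profile$f(t)
}
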