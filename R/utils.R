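#' Run code with a fixed RNG seed, without touching global RNG state
#'
#' All stochastic operations in the package funnel through this helper so
#' that a seed recorded in a generator spec gives bit-identical output and
#' never perturbs the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

#' Angular span of an arc on a cylinder
#'
#' Converts a circumferential drag length on a cylindrical perch into the
#' angle subtended at the perch axis. Used for desk-checking drag-test
#' geometry: a 4 mm claw drag centred on a 19 mm (0.75 in) perch covers
#' +/- 12 degrees of local surface angle; a 5 mm toe-pad drag spans 30
#' degrees.
#'
#' @param arc_length_mm arc length along the surface, mm.
#' @param diameter_mm cylinder diameter, mm.
#' @return angle in degrees subtended by the arc.
#' @examples
#' arc_angle_span(4, 25.4 * 0.75) / 2   # half-span of a centred claw drag
#' arc_angle_span(5, 25.4 * 0.75)       # toe-pad drag span
#' @export
arc_angle_span <- function(arc_length_mm, diameter_mm) {
  stopifnot(diameter_mm > 0, arc_length_mm >= 0)
  (arc_length_mm / (diameter_mm / 2)) * 180 / pi
}

#' Convert a force in newtons to bodyweight units
#'
#' @param force_N force in newtons.
#' @param body_mass_kg body mass in kg.
#' @param g gravitational acceleration, m/s^2.
#' @return force in bodyweights (bw).
#' @examples
#' force_to_bw(0.2, 0.030)  # ~0.68 bw for a 30 g bird
#' @export
force_to_bw <- function(force_N, body_mass_kg, g = 9.81) {
  stopifnot(body_mass_kg > 0, g > 0)
  force_N / (body_mass_kg * g)
}

#' Depth ratio of an indentation
#'
#' Penetration depth divided by the indenting tip radius (both in the same
#' length unit). The dimensionless group controlling the Hertzian slope
#' correction in [penetration_slope()].
#'
#' @param depth penetration depth.
#' @param tip_radius tip radius, same unit as `depth`.
#' @return dimensionless depth ratio.
#' @examples
#' depth_ratio(2.5, 50)  # 0.05
#' @export
depth_ratio <- function(depth, tip_radius) {
  stopifnot(tip_radius > 0, depth >= 0)
  depth / tip_radius
}
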