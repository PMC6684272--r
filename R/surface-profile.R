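#' Construct a 1D surface height profile
#'
#' A `surface_profile` is the substrate every surface computation in the
#' package runs on: a uniformly sampled 1D trace of local surface height
#' along an arc-length coordinate, as obtained by unwrapping a 3D scan of a
#' perch circumferentially (the unwrapping itself is out of scope; profiles
#' enter as position/height tables).
#'
#' @param positions arc-length coordinates in mm, uniformly spaced,
#'   strictly increasing, at least 2 samples.
#' @param heights local surface heights in micrometres, same length.
#' @return an object of class `surface_profile` with fields `positions`
#'   (mm), `heights` (um) and `spacing` (um).
#' @examples
#' p <- surface_profile(seq(0, 1, by = 0.001), rnorm(1001))
#' compute_rms(p)
#' @export
surface_profile <- function(positions, heights) {
  positions <- as.numeric(positions)
  heights <- as.numeric(heights)
  if (length(positions) < 2L)
    stop_invalid("surface_profile needs at least 2 samples")
  if (length(positions) != length(heights))
    stop_invalid("positions and heights must have equal length")
  if (!all(is.finite(positions)) || !all(is.finite(heights)))
    stop_invalid("surface_profile values must be finite")
  d <- diff(positions)
  if (any(d <= 0))
    stop_invalid("positions must be strictly increasing")
  step <- sort(d)[ceiling(length(d) / 2)]  # lower median: an observed interval
  bad <- which(abs(d - step) > 1e-9 * max(abs(step), 1))
  if (length(bad) > 0L)
    stop_invalid(sprintf(
      "non-uniform spacing: interval after row %d is %.9g mm, expected %.9g mm",
      bad[1L], d[bad[1L]], step))
  structure(
    list(positions = positions, heights = heights, spacing = step * 1000),
    class = "surface_profile")
}

#' @export
print.surface_profile <- function(x, ...) {
  cat(sprintf(
    "<surface_profile> %d samples, %.4g mm long, spacing %.3g um, RMS %.3g um\n",
    length(x$heights), diff(range(x$positions)), x$spacing,
    sqrt(mean(x$heights^2))))
  invisible(x)
}

#' @export
length.surface_profile <- function(x) length(x$heights)

#' Read a surface profile from CSV
#'
#' Expects a header and two columns, `position_mm` and `height_um`.
#' Non-uniform spacing is rejected with an error naming the first
#' offending row.
#'
#' @param path file path.
#' @return a [surface_profile()].
#' @export
read_surface_profile <- function(path) {
  df <- utils::read.csv(path)
  need <- c("position_mm", "height_um")
  if (!all(need %in% names(df)))
    stop_invalid("surface profile CSV must have columns position_mm, height_um")
  surface_profile(df$position_mm, df$height_um)
}

#' Write a surface profile to CSV
#'
#' @param profile a [surface_profile()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_surface_profile <- function(profile, path) {
  stopifnot(inherits(profile, "surface_profile"))
  utils::write.csv(
    data.frame(position_mm = profile$positions, height_um = profile$heights),
    path, row.names = FALSE)
  invisible(path)
}

#' Root-mean-square roughness of a profile
#'
#' R_RMS = sqrt(mean(y_i^2)) over the profile heights. No mean removal or
#' detrending happens here; waviness removal is the separate, explicit
#' [highpass_detrend()] step, mirroring the scan-processing pipeline in
#' which the long-wavelength shape is subtracted before roughness is
#' quantified.
#'
#' @param profile a [surface_profile()].
#' @param cutoff_wavelength_mm optional record of the detrend cutoff that
#'   produced `profile` (carried through to the result, not applied).
#' @return a `roughness_result` list: `r_rms` (um), `cutoff_wavelength`
#'   (mm or NA), `n_samples`.
#' @export
compute_rms <- function(profile, cutoff_wavelength_mm = NA_real_) {
  stopifnot(inherits(profile, "surface_profile"))
  if (length(profile$heights) == 0L)
    stop_invalid("empty profile")
  structure(
    list(r_rms = sqrt(mean(profile$heights^2)),
         cutoff_wavelength = cutoff_wavelength_mm,
         n_samples = length(profile$heights)),
    class = "roughness_result")
}

#' @export
print.roughness_result <- function(x, ...) {
  cat(sprintf("<roughness_result> R_RMS = %.4g um over %d samples\n",
              x$r_rms, x$n_samples))
  invisible(x)
}

#' Remove long-wavelength shape from a profile
#'
#' Subtracts the low-pass component of the profile, leaving roughness at
#' wavelengths below the cutoff (1 mm by default in the scan pipeline: 5%
#' of a 19 mm perch diameter and 20 claw tip radii). The waviness
#' estimate is a zero-phase order-8 Butterworth-magnitude low-pass in
#' spatial frequency ([lowpass_trace()] with fs = samples per mm and
#' cutoff = 1/wavelength): zero phase avoids spatially shifting
#' asperities, and the sharp transition band makes the detrend close to
#' idempotent, which a plain moving-average smoother is not.
#'
#' @param profile a [surface_profile()].
#' @param cutoff_wavelength_mm cutoff wavelength in mm; must exceed twice
#'   the sample spacing.
#' @param order filter order (default 8).
#' @return a detrended [surface_profile()].
#' @export
highpass_detrend <- function(profile, cutoff_wavelength_mm = 1, order = 8) {
  stopifnot(inherits(profile, "surface_profile"))
  spacing_mm <- profile$spacing / 1000
  if (cutoff_wavelength_mm <= 2 * spacing_mm)
    stop_invalid("cutoff wavelength must exceed twice the sample spacing")
  y <- profile$heights
  low <- lowpass_trace(y, fs = 1 / spacing_mm,
                       cutoff_hz = 1 / cutoff_wavelength_mm, order = order)
  surface_profile(profile$positions, y - low)
}
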