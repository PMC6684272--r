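#' Specification for a synthetic rough-surface profile
#'
#' Describes a self-affine rough surface by its target RMS roughness and
#' the power-law slope of its height power spectrum. Real perch surfaces
#' behave approximately fractally (which is why usable surface does not
#' vanish for large claw tips), and spectral synthesis with a power-law
#' amplitude is the simplest generator consistent with that framing.
#'
#' @param target_rms target RMS roughness, um (>= 0; 0 gives a flat profile).
#' @param spectral_exponent power-law slope of the height PSD
#'   (amplitude ~ |k|^(-spectral_exponent/2)); larger values put more power
#'   at long wavelengths.
#' @param length_mm profile length, mm.
#' @param spacing_um sample spacing, um. `length_mm`/`spacing_um` must give
#'   at least 64 samples.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return object of class `surface_gen_spec`.
#' @export
surface_gen_spec <- function(target_rms = 30, spectral_exponent = 2,
                             length_mm = 20, spacing_um = 5, seed = 1) {
  if (target_rms < 0) stop_invalid("target_rms must be >= 0")
  if (spacing_um <= 0 || length_mm <= 0)
    stop_invalid("length and spacing must be positive")
  n <- floor(length_mm * 1000 / spacing_um)
  if (n < 64L)
    stop_invalid("spec yields fewer than 64 samples")
  structure(
    list(target_rms = target_rms, spectral_exponent = spectral_exponent,
         length_mm = length_mm, spacing_um = spacing_um,
         seed = as.integer(seed)),
    class = "surface_gen_spec")
}

#' Generate a self-affine rough surface profile
#'
#' Spectral synthesis: Gaussian random phases, amplitude proportional to
#' |k|^(-spectral_exponent/2), inverse FFT, mean removal, then an exact
#' rescale so the realized RMS equals `target_rms` to machine precision.
#' The rescale makes the RMS contract exact for every seed; the spectral
#' exponent controls whether the roughness lives at long wavelengths (high
#' exponent; large features a claw tip can follow) or short wavelengths
#' (low exponent; fine texture that vanishes from the traced surface).
#'
#' @param spec a [surface_gen_spec()].
#' @return a [surface_profile()] with zero mean and RMS exactly
#'   `spec$target_rms`.
#' @export
gen_surface_profile <- function(spec) {
  stopifnot(inherits(spec, "surface_gen_spec"))
  n <- floor(spec$length_mm * 1000 / spec$spacing_um)
  positions <- (seq_len(n) - 1L) * spec$spacing_um / 1000
  if (spec$target_rms == 0)
    return(surface_profile(positions, rep(0, n)))
  y <- with_seed(spec$seed, {
    nk <- n %/% 2L
    k <- seq_len(nk)
    amp <- k^(-spec$spectral_exponent / 2)
    phase <- stats::runif(nk, 0, 2 * pi)
    mag <- amp * abs(stats::rnorm(nk))
    coef <- complex(modulus = mag, argument = phase)
    spectrum <- complex(real = rep(0, n))
    spectrum[1L + k] <- coef
    spectrum[n + 1L - k] <- Conj(coef)  # Hermitian symmetry -> real signal
    Re(stats::fft(spectrum, inverse = TRUE)) / n
  })
  y <- y - mean(y)
  rms <- sqrt(mean(y^2))
  if (rms == 0) y <- rep(0, n) else y <- y * (spec$target_rms / rms)
  surface_profile(positions, y)
}
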