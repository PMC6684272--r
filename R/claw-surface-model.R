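#' Claw tip model parameters
#'
#' Bundles the three parameters of the claw-asperity engagement model: the
#' tip radius of the (spherical) claw tip, the depth ratio DR (Hertzian
#' penetration depth divided by tip radius), and theta_min, the minimum
#' surface slope angle at which static friction can be maintained.
#' theta_min is the angle between the vertical and the net contact force
#' when the tangential-to-normal force ratio is at its maximum, so higher
#' required friction ratios demand steeper asperities.
#'
#' @param tip_radius_um claw tip radius r_a, um (> 0).
#' @param depth_ratio depth ratio DR in [0, 1).
#' @param theta_min_deg minimum static-friction slope angle, degrees in
#'   [0, 90).
#' @return object of class `claw_tip_model`.
#' @export
claw_tip_model <- function(tip_radius_um = 50, depth_ratio = 0,
                           theta_min_deg = 10) {
  if (tip_radius_um <= 0) stop_invalid("tip_radius_um must be > 0")
  if (depth_ratio < 0 || depth_ratio >= 1)
    stop_invalid("depth_ratio must be in [0, 1)")
  if (theta_min_deg < 0 || theta_min_deg >= 90)
    stop_invalid("theta_min_deg must be in [0, 90)")
  structure(
    list(tip_radius_um = tip_radius_um, depth_ratio = depth_ratio,
         theta_min_deg = theta_min_deg),
    class = "claw_tip_model")
}

#' Traced surface swept by a circular claw tip
#'
#' The path of the centre of a circular tip of radius `r_a` rolling/sliding
#' over the profile, lowered by `r_a` so it is comparable to the original
#' surface: at each x the traced height is
#' `max over |x' - x| <= r_a of [y(x') + sqrt(r_a^2 - (x - x')^2)] - r_a`.
#' Asperities narrower than the tip vanish from the traced surface, which
#' is why large claws see less usable surface. `r_a = 0` returns the
#' profile unchanged.
#'
#' @param profile a [surface_profile()].
#' @param tip_radius_um tip radius r_a in um (>= 0).
#' @param strict if `TRUE`, violating the resolution guard
#'   (spacing <= r_a/5) is an error instead of a warning.
#' @return object of class `traced_surface`: fields `profile` (the traced
#'   [surface_profile()]), `original` (input), `tip_radius_um`.
#' @export
trace_surface <- function(profile, tip_radius_um, strict = FALSE) {
  stopifnot(inherits(profile, "surface_profile"), tip_radius_um >= 0)
  y <- profile$heights
  if (tip_radius_um > 0 && profile$spacing > tip_radius_um / 5) {
    msg <- sprintf(
      "profile spacing (%.3g um) coarser than r_a/5 (%.3g um); traced surface may be under-resolved",
      profile$spacing, tip_radius_um / 5)
    if (strict) stop_invalid(msg) else warning(msg, call. = FALSE)
  }
  if (tip_radius_um > 0) {
    n <- length(y)
    h <- profile$spacing
    # epsilon guard so the |dx| == r_a ring is kept when positions carry
    # float rounding from the mm-scale coordinate
    wmax <- floor(tip_radius_um / h + 1e-9)
    traced <- y  # offset 0 contributes y(x) + r_a - r_a
    for (j in seq_len(wmax)) {
      dx <- j * h
      lift <- sqrt(max(0, tip_radius_um^2 - dx^2)) - tip_radius_um
      # contribution of samples j to the left and right of each x
      left <- c(rep(-Inf, j), y[seq_len(n - j)]) + lift
      right <- c(y[(j + 1L):n], rep(-Inf, j)) + lift
      traced <- pmax(traced, left, right)
    }
    y <- traced
  }
  structure(
    list(profile = surface_profile(profile$positions, y),
         original = profile, tip_radius_um = tip_radius_um),
    class = "traced_surface")
}

#' @export
print.traced_surface <- function(x, ...) {
  cat(sprintf("<traced_surface> r_a = %.3g um over %d samples\n",
              x$tip_radius_um, length(x$profile$heights)))
  invisible(x)
}

#' Hertzian penetration slope
#'
#' When a rigid spherical tip of radius R indents an elastic half-space to
#' depth d = DR * R, the Hertz contact half-width is a = R * sqrt(DR). The
#' chord from the bottom of the tip (0, -R) to the edge of contact
#' (a, -sqrt(R^2 - a^2)) has slope
#' `m = (1 - sqrt(1 - DR)) / sqrt(DR)`,
#' with the continuous limit m = 0 at DR = 0 (series: m ~ sqrt(DR)/2).
#' Penetration effectively tilts the local surface by atan(m), lowering
#' the asperity slope needed for static friction.
#'
#' @param DR depth ratio(s) in [0, 1); vectorized.
#' @return dimensionless slope m.
#' @examples
#' penetration_slope(0.05)          # ~0.1132
#' atan(penetration_slope(0.05)) * 180 / pi  # ~6.46 degrees
#' @export
penetration_slope <- function(DR) {
  if (any(DR < 0 | DR >= 1)) stop_invalid("DR must be in [0, 1)")
  m <- ifelse(DR == 0, 0, (1 - sqrt(1 - DR)) / sqrt(DR))
  as.numeric(m)
}

#' Penetration-corrected minimum friction angle
#'
#' theta_eff = max(0, theta_min - atan(m(DR))), clamped at zero: the angle
#' gained from sinking into the surface is subtracted from the slope the
#' asperity itself must provide.
#'
#' @param theta_min_deg minimum static-friction angle, degrees.
#' @param DR depth ratio in [0, 1).
#' @return effective threshold angle, degrees.
#' @export
effective_theta <- function(theta_min_deg, DR) {
  m <- penetration_slope(DR)
  pmax(0, theta_min_deg - atan(m) * 180 / pi)
}

#' Usable-surface fraction of a traced surface
#'
#' The fraction of 1 um horizontal segments of the traced surface whose
#' slope angle, for faces rising in the drag direction, strictly exceeds
#' the penetration-corrected threshold [effective_theta()]. A claw dragged
#' in +x hooks asperity faces that rise with x; only those count (set
#' `direction = "both"` to count either sense, for sensitivity analysis).
#' Profiles coarser than the 1 um evaluation step are linearly
#' interpolated to it (with a warning).
#'
#' @param traced a [trace_surface()] result.
#' @param tip a [claw_tip_model()]; its `tip_radius_um` must match the one
#'   used to trace.
#' @param direction `+1`, `-1`, or `"both"`.
#' @param slope_eval_step_um slope evaluation step, um (default 1).
#' @return a scalar `n_a` in [0, 1], with attributes `n_segments` and
#'   `theta_eff_deg`.
#' @export
usable_surface <- function(traced, tip, direction = +1,
                           slope_eval_step_um = 1) {
  stopifnot(inherits(traced, "traced_surface"),
            inherits(tip, "claw_tip_model"))
  if (abs(traced$tip_radius_um - tip$tip_radius_um) > 1e-9)
    stop_invalid("traced surface was computed with a different tip radius")
  both <- identical(direction, "both")
  if (!both && !(identical(direction, +1) || identical(direction, -1) ||
                 identical(direction, 1) || identical(direction, -1L) ||
                 identical(direction, 1L)))
    stop_invalid("direction must be +1, -1 or \"both\"")
  prof <- traced$profile
  x_um <- prof$positions * 1000
  y_um <- prof$heights
  if (prof$spacing > slope_eval_step_um + 1e-12) {
    warning(sprintf(
      "profile spacing %.3g um coarser than %.3g um slope step; interpolating",
      prof$spacing, slope_eval_step_um), call. = FALSE)
  }
  xg <- seq(x_um[1L], x_um[length(x_um)], by = slope_eval_step_um)
  yg <- stats::approx(x_um, y_um, xout = xg)$y
  slopes <- diff(yg) / slope_eval_step_um
  theta_eff <- effective_theta(tip$theta_min_deg, tip$depth_ratio)
  thr <- tan(theta_eff * pi / 180)
  rising <- if (both) abs(slopes) else
    if (identical(direction, -1) || identical(direction, -1L)) -slopes else slopes
  n_a <- mean(rising > thr)
  structure(n_a, n_segments = length(slopes), theta_eff_deg = theta_eff)
}

#' Sweep usable surface over tip radii and friction angles
#'
#' Recomputes the traced surface for each tip radius and evaluates the
#' usable fraction n_a at each theta_min under one of three depth-ratio
#' policies: `"zero"` (DR = 0, rigid surface), `"fixed"` (a constant DR,
#' e.g. the 0.05 estimated for a small parrot landing), or `"isometric"`
#' (DR scales linearly with tip radius relative to a reference pair,
#' because isometry makes penetration depth grow with load ~ mass ~
#' length^3 while contact stiffness grows slower, so depth/tip-radius is
#' preserved only at the reference scale).
#'
#' @param profile a [surface_profile()].
#' @param tip_radii_um vector of tip radii, um.
#' @param theta_min_deg vector of theta_min values, degrees.
#' @param dr_policy `"zero"`, `"fixed"`, or `"isometric"`.
#' @param dr_value DR for `"fixed"`, or the reference DR for `"isometric"`.
#' @param dr_reference_radius_um reference tip radius for `"isometric"`.
#' @param direction passed to [usable_surface()].
#' @return tidy data.frame with columns `r_a`, `theta_min`, `DR`, `n_a`.
#' @export
sweep_usable_surface <- function(profile, tip_radii_um, theta_min_deg,
                                 dr_policy = c("zero", "fixed", "isometric"),
                                 dr_value = 0.05,
                                 dr_reference_radius_um = 50,
                                 direction = +1) {
  dr_policy <- match.arg(dr_policy)
  rows <- vector("list", length(tip_radii_um) * length(theta_min_deg))
  i <- 0L
  for (r_a in tip_radii_um) {
    traced <- trace_surface(profile, r_a)
    DR <- switch(dr_policy,
      zero = 0,
      fixed = dr_value,
      isometric = dr_value * r_a / dr_reference_radius_um)
    if (DR >= 1)
      stop_invalid("isometric policy drove DR above 1; narrow the radius range")
    for (th in theta_min_deg) {
      tip <- claw_tip_model(r_a, DR, th)
      i <- i + 1L
      rows[[i]] <- data.frame(
        r_a = r_a, theta_min = th, DR = DR,
        n_a = as.numeric(usable_surface(traced, tip, direction = direction)))
    }
  }
  do.call(rbind, rows)
}

#' Fit n_a(r_a) = A * exp(-r_a / lambda) + c
#'
#' The usable-surface fraction decays with tip radius but, on (approximately
#' fractal) natural surfaces, not to zero; an exponential with an offset
#' captures both the decay length and the residual usable surface at large
#' tips. Nonlinear least squares with starting values from a log-linear
#' regression on the offset-subtracted data.
#'
#' @param r_a_um tip radii, um.
#' @param n_a usable fractions.
#' @return object of class `exp_offset_fit`: `amplitude`, `decay_um`,
#'   `offset`, `residual_rms`, `fitted`.
#' @export
fit_exponential_offset <- function(r_a_um, n_a) {
  stopifnot(length(r_a_um) == length(n_a), length(n_a) >= 3)
  if (stats::sd(n_a) < 1e-12) {
    # constant data: amplitude 0, offset = the constant
    fit <- list(amplitude = 0, decay_um = diff(range(r_a_um)) + 1,
                offset = mean(n_a), residual_rms = 0, fitted = n_a)
    return(structure(fit, class = "exp_offset_fit"))
  }
  df <- data.frame(r = r_a_um, y = n_a)
  c0 <- min(n_a) - 0.05 * abs(diff(range(n_a)))
  pos <- pmax(n_a - c0, 1e-8)
  lf <- stats::lm(log(pos) ~ r_a_um)
  lam0 <- -1 / stats::coef(lf)[2L]
  if (!is.finite(lam0) || lam0 <= 0) lam0 <- diff(range(r_a_um)) / 2
  A0 <- exp(stats::coef(lf)[1L])
  fit <- stats::nls(y ~ A * exp(-r / lambda) + c, data = df,
                    start = list(A = A0, lambda = lam0, c = c0),
                    control = stats::nls.control(maxiter = 500, tol = 1e-9,
                                                 minFactor = 1e-10,
                                                 scaleOffset = 1,
                                                 warnOnly = TRUE))
  cf <- stats::coef(fit)
  res <- df$y - stats::predict(fit)
  structure(
    list(amplitude = unname(cf["A"]), decay_um = unname(cf["lambda"]),
         offset = unname(cf["c"]),
         residual_rms = sqrt(mean(res^2)),
         fitted = as.numeric(stats::predict(fit))),
    class = "exp_offset_fit")
}

#' @export
print.exp_offset_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_offset_fit> n_a = %.4g * exp(-r_a / %.4g um) + %.4g (residual RMS %.2g)\n",
    x$amplitude, x$decay_um, x$offset, x$residual_rms))
  invisible(x)
}

#' Fit a sphere (circle) radius to a claw-tip width profile
#'
#' For a circular tip of radius R, the sagittal half-width at height h
#' above the tip satisfies (w/2)^2 = 2*R*h - h^2. Rearranged,
#' (w/2)^2 + h^2 = 2*R*h, which is linear in R, so the least-squares
#' radius over samples with h <= `height_limit_um` is the through-origin
#' regression R = sum(x*y)/sum(x^2) with x = 2h, y = (w/2)^2 + h^2.
#' Algebraic and deterministic; adequate at metrology noise levels.
#'
#' @param claw a [claw_profile()] (heights/widths in um).
#' @param height_limit_um only samples with h at or below this height are
#'   used (the tip region where the spherical approximation holds).
#' @return fitted tip radius, um.
#' @export
fit_sphere_tip <- function(claw, height_limit_um = 50) {
  stopifnot(inherits(claw, "claw_profile"))
  keep <- claw$heights_um <= height_limit_um & claw$heights_um > 0
  if (sum(keep) < 2L)
    stop_invalid("need at least 2 samples with 0 < h <= height_limit_um")
  h <- claw$heights_um[keep]
  w <- claw$widths_um[keep]
  x <- 2 * h
  y <- (w / 2)^2 + h^2
  sum(x * y) / sum(x^2)
}

#' Fit a cubic penetration curve constrained through the origin
#'
#' Fits depth = c1*F + c2*F^2 + c3*F^3 (no constant term: zero force must
#' give zero depth) to indentation measurements, so that penetration at
#' low force levels (below the smallest tested load) can be interpolated
#' from tests run at higher loads where sensor noise is negligible.
#'
#' @param force_bw normal forces, bodyweights.
#' @param depth_um measured penetration depths, um.
#' @return object of class `penetration_curve_fit` with `coefficients`
#'   (c1, c2, c3) and the fitted force range.
#' @export
fit_penetration_curve <- function(force_bw, depth_um) {
  stopifnot(length(force_bw) == length(depth_um), length(force_bw) >= 3)
  fit <- stats::lm(depth_um ~ 0 + force_bw + I(force_bw^2) + I(force_bw^3))
  structure(
    list(coefficients = unname(stats::coef(fit)),
         force_range = range(force_bw)),
    class = "penetration_curve_fit")
}

#' Evaluate a fitted penetration curve
#'
#' @param fit a [fit_penetration_curve()] result.
#' @param force_bw forces at which to evaluate, bw. Values outside the
#'   fitted range trigger an extrapolation warning (evaluating below the
#'   smallest tested load is the intended use; far extrapolation is not).
#' @return predicted depths, um.
#' @export
predict_penetration <- function(fit, force_bw) {
  stopifnot(inherits(fit, "penetration_curve_fit"))
  if (any(force_bw < 0 | force_bw > fit$force_range[2L]))
    warning("evaluating penetration curve outside the fitted force range",
            call. = FALSE)
  cf <- fit$coefficients
  cf[1L] * force_bw + cf[2L] * force_bw^2 + cf[3L] * force_bw^3
}

#' Claw sagittal width profile
#'
#' Width of the claw cross-section as a function of height from the tip,
#' the form in which claw-tip geometry is measured under a microscope.
#'
#' @param heights_um heights from the claw tip, um, non-negative and
#'   increasing.
#' @param widths_um sagittal widths at those heights, um, non-negative and
#'   non-decreasing.
#' @return object of class `claw_profile`.
#' @export
claw_profile <- function(heights_um, widths_um) {
  stopifnot(length(heights_um) == length(widths_um))
  if (any(heights_um < 0) || is.unsorted(heights_um, strictly = TRUE))
    stop_invalid("heights must be non-negative and strictly increasing")
  if (any(widths_um < 0) || is.unsorted(widths_um))
    stop_invalid("widths must be non-negative and non-decreasing")
  structure(list(heights_um = heights_um, widths_um = widths_um),
            class = "claw_profile")
}

#' Specification for a synthetic claw profile
#'
#' A circular-arc tip blended tangentially into straight flanks: the
#' simplest shape matching measured claw cross-sections near the tip (a
#' ~50 um radius sphere up to moderate loads) while widening linearly
#' further up.
#'
#' @param tip_radius_um tip radius, um (> 0).
#' @param opening_halfangle_deg flank slope away from the tip axis,
#'   degrees in (0, 90).
#' @param profile_height_um height range to generate, um.
#' @param step_um height sampling step, um.
#' @param seed integer seed (profiles are deterministic; the seed is
#'   recorded for provenance).
#' @return object of class `claw_gen_spec`.
#' @export
claw_gen_spec <- function(tip_radius_um = 50, opening_halfangle_deg = 25,
                          profile_height_um = 400, step_um = 1, seed = 1) {
  if (tip_radius_um <= 0) stop_invalid("tip_radius_um must be > 0")
  if (opening_halfangle_deg <= 0 || opening_halfangle_deg >= 90)
    stop_invalid("opening_halfangle_deg must be in (0, 90)")
  if (profile_height_um <= 0 || step_um <= 0)
    stop_invalid("profile_height_um and step_um must be > 0")
  structure(
    list(tip_radius_um = tip_radius_um,
         opening_halfangle_deg = opening_halfangle_deg,
         profile_height_um = profile_height_um, step_um = step_um,
         seed = as.integer(seed)),
    class = "claw_gen_spec")
}

#' Generate a synthetic claw width profile
#'
#' Below the arc-flank tangency height h_t = r*(1 - sin(phi)) the width is
#' the circle chord w/2 = sqrt(2*r*h - h^2); above it the flanks continue
#' straight at the opening half-angle phi, tangent to the arc. Profiles
#' differing only in phi are identical below the smaller tangency height.
#'
#' @param spec a [claw_gen_spec()].
#' @return a [claw_profile()] with the ground-truth spec attached as
#'   attribute `ground_truth`.
#' @export
gen_claw_profile <- function(spec) {
  stopifnot(inherits(spec, "claw_gen_spec"))
  r <- spec$tip_radius_um
  phi <- spec$opening_halfangle_deg * pi / 180
  h <- seq(spec$step_um, spec$profile_height_um, by = spec$step_um)
  h_t <- r * (1 - sin(phi))
  x_t <- r * cos(phi)
  half <- ifelse(h <= h_t,
                 sqrt(pmax(0, 2 * r * h - h^2)),
                 x_t + (h - h_t) * tan(phi))
  structure(claw_profile(h, 2 * half), ground_truth = spec)
}
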