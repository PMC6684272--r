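#' Stick-slip drag trace container
#'
#' Synchronized normal and tangential force series recorded while a toe
#' pad or claw is dragged along a surface, with the drag-distance
#' coordinate used to localize slip events.
#'
#' @param time_s time, s, monotone increasing.
#' @param FN_bw normal force, bodyweights, non-negative.
#' @param FT_bw tangential (friction) force, bodyweights.
#' @param position_mm drag-distance coordinate, mm (optional; defaults to
#'   a uniform sweep inferred from time if omitted is not allowed - must
#'   be supplied).
#' @param surface surface label (metadata).
#' @param contact `"toe_pad"` or `"claw"`.
#' @return object of class `drag_trace`.
#' @export
drag_trace <- function(time_s, FN_bw, FT_bw, position_mm,
                       surface = "synthetic", contact = c("claw", "toe_pad")) {
  contact <- match.arg(contact)
  n <- length(time_s)
  stopifnot(length(FN_bw) == n, length(FT_bw) == n, length(position_mm) == n)
  if (!all(is.finite(FN_bw)) || !all(is.finite(FT_bw)))
    stop_invalid("forces must be finite")
  if (any(FN_bw < 0)) stop_invalid("normal force must be non-negative")
  if (is.unsorted(time_s, strictly = TRUE))
    stop_invalid("time must be strictly increasing")
  structure(
    list(time_s = time_s, FN_bw = FN_bw, FT_bw = FT_bw,
         position_mm = position_mm, surface = surface, contact = contact),
    class = "drag_trace")
}

#' Read / write drag traces as CSV
#'
#' Columns: `time_s`, `FN_bw`, `FT_bw`, `position_mm`.
#' @param path file path.
#' @param ... passed to [drag_trace()] (surface, contact).
#' @return a [drag_trace()] / `path` invisibly.
#' @export
read_drag_trace <- function(path, ...) {
  df <- utils::read.csv(path)
  need <- c("time_s", "FN_bw", "FT_bw", "position_mm")
  if (!all(need %in% names(df)))
    stop_invalid("drag trace CSV must have columns ",
                 paste(need, collapse = ", "))
  drag_trace(df$time_s, df$FN_bw, df$FT_bw, df$position_mm, ...)
}

#' @rdname read_drag_trace
#' @param trace a [drag_trace()].
#' @export
write_drag_trace <- function(trace, path) {
  stopifnot(inherits(trace, "drag_trace"))
  utils::write.csv(
    data.frame(time_s = trace$time_s, FN_bw = trace$FN_bw,
               FT_bw = trace$FT_bw, position_mm = trace$position_mm),
    path, row.names = FALSE)
  invisible(path)
}

#' Specification for a synthetic stick-slip drag trace
#'
#' Emulates quasi-static claw/toe-pad drag tests: the force ratio F_T/F_N
#' ramps up as elastic load builds, releases when an asperity lets go
#' (slip), and the peak ratio reached at each asperity is a draw from a
#' surface-specific distribution. Asperity positions are Poisson along the
#' drag path (real surfaces give only mean densities).
#'
#' @param mu baseline Coulomb friction ratio the trace ramps toward
#'   between asperities (>= 0).
#' @param asperity_density mean asperities per mm (>= 0).
#' @param peak_dist distribution of pre-slip F_T/F_N peaks: a list with
#'   `family` one of `"degenerate"`, `"exponential"`, `"lognormal"`,
#'   `"uniform"`, and parameters (`value`; `rate`; `meanlog`, `sdlog`;
#'   `min`, `max`).
#' @param normal_force_bw constant applied normal force, bw.
#' @param sample_rate_hz sampling rate.
#' @param drag_length_mm total drag distance (> 0).
#' @param drag_speed_mm_s drag speed (quasi-static tests are slow; default
#'   1 mm/s).
#' @param residual_fraction fraction of the peak the ratio drops to after
#'   a slip (default 0.2, i.e. an 80% drop).
#' @param seed integer seed.
#' @return object of class `drag_gen_spec`.
#' @export
drag_gen_spec <- function(mu = 0.3, asperity_density = 2,
                          peak_dist = list(family = "lognormal",
                                           meanlog = 0, sdlog = 0.4),
                          normal_force_bw = 0.05, sample_rate_hz = 1000,
                          drag_length_mm = 5, drag_speed_mm_s = 1,
                          residual_fraction = 0.2, seed = 1) {
  if (mu < 0) stop_invalid("mu must be >= 0")
  if (asperity_density < 0) stop_invalid("asperity_density must be >= 0")
  if (drag_length_mm <= 0) stop_invalid("drag_length_mm must be > 0")
  if (residual_fraction < 0 || residual_fraction >= 1)
    stop_invalid("residual_fraction must be in [0, 1)")
  stopifnot(is.list(peak_dist), !is.null(peak_dist$family))
  structure(
    list(mu = mu, asperity_density = asperity_density,
         peak_dist = peak_dist, normal_force_bw = normal_force_bw,
         sample_rate_hz = sample_rate_hz, drag_length_mm = drag_length_mm,
         drag_speed_mm_s = drag_speed_mm_s,
         residual_fraction = residual_fraction, seed = as.integer(seed)),
    class = "drag_gen_spec")
}

draw_peaks <- function(dist, n) {
  switch(dist$family,
    degenerate = rep(dist$value, n),
    exponential = stats::rexp(n, rate = dist$rate),
    lognormal = stats::rlnorm(n, meanlog = dist$meanlog, sdlog = dist$sdlog),
    uniform = stats::runif(n, min = dist$min, max = dist$max),
    stop_invalid("unknown peak distribution family: ", dist$family))
}

#' Generate a synthetic stick-slip drag trace
#'
#' Piecewise-rising sawtooth of F_T/F_N: between asperities the ratio
#' ramps linearly; at each (Poisson-spaced) asperity it attains a peak
#' drawn from `peak_dist`, then drops to `residual_fraction` of that peak.
#' After the last asperity the ratio ramps toward the baseline `mu`.
#' Asperity positions are snapped to the sample grid so the ground-truth
#' peak values appear exactly in the trace.
#'
#' @param spec a [drag_gen_spec()].
#' @return a [drag_trace()] with attribute `ground_truth`: a list with
#'   `peak_values`, `peak_positions_mm`, and the generating spec.
#' @export
gen_drag_trace <- function(spec) {
  stopifnot(inherits(spec, "drag_gen_spec"))
  dx <- spec$drag_speed_mm_s / spec$sample_rate_hz  # mm per sample
  n <- max(16L, ceiling(spec$drag_length_mm / dx))
  pos <- (seq_len(n) - 1L) * dx
  gt <- with_seed(spec$seed, {
    n_events <- stats::rpois(1L, spec$asperity_density * spec$drag_length_mm)
    p <- sort(stats::runif(n_events, 0, spec$drag_length_mm))
    list(positions = p, values = draw_peaks(spec$peak_dist, n_events))
  })
  # snap events to grid; merge events landing on the same sample (keep max)
  idx <- pmin(n, pmax(2L, round(gt$positions / dx) + 1L))
  keep <- !duplicated(idx, fromLast = TRUE)
  idx <- idx[keep]; vals <- gt$values[keep]
  ratio <- numeric(n)
  start <- 1L
  level <- 0
  if (length(idx) > 0L) {
    for (e in seq_along(idx)) {
      i <- idx[e]
      seg <- start:i
      if (i == start) {
        ratio[i] <- vals[e]
      } else {
        ratio[seg] <- level + (vals[e] - level) * (seg - start) / (i - start)
      }
      level <- spec$residual_fraction * vals[e]
      start <- i + 1L
      if (start > n) break
    }
  }
  if (start <= n) {
    seg <- start:n
    # trailing ramp toward the baseline Coulomb level over ~1 mm
    ramp_len <- max(2L, round(1 / dx))
    ratio[seg] <- pmin(spec$mu,
                       level + (spec$mu - level) * (seg - start + 1L) / ramp_len)
  }
  tr <- drag_trace(time_s = pos / spec$drag_speed_mm_s,
                   FN_bw = rep(spec$normal_force_bw, n),
                   FT_bw = ratio * spec$normal_force_bw,
                   position_mm = pos, surface = "synthetic",
                   contact = "claw")
  attr(tr, "ground_truth") <- list(
    peak_values = vals, peak_positions_mm = pos[idx], spec = spec)
  tr
}

#' Extract pre-slip force-ratio peaks from a drag trace
#'
#' A slip event is a local maximum of F_T/F_N followed by a decline of at
#' least `drop_fraction` of the peak value before the ratio rises again.
#' Implemented as a running-maximum detector: track the largest ratio since
#' the last event; when the ratio falls below (1 - drop_fraction) times
#' that maximum, emit the maximum as an event and restart. The returned
#' asperity linear density is events per mm of drag.
#'
#' @param trace a [drag_trace()].
#' @param drop_fraction relative drop defining a slip (default 0.2; the
#'   slip detector is not standardized, and 20% separates asperity
#'   releases from ramp jitter on generated traces).
#' @param lowpass_hz optional pre-smoothing cutoff for measured data
#'   (e.g. 5 Hz for toe pads, 1 Hz for quasi-static claw drags); `NULL`
#'   skips filtering (synthetic traces need none).
#' @return object of class `slip_event_series`: `peaks` (F_T/F_N values),
#'   `positions_mm`, `density_per_mm`, `drag_length_mm`.
#' @export
extract_slip_peaks <- function(trace, drop_fraction = 0.2,
                               lowpass_hz = NULL) {
  stopifnot(inherits(trace, "drag_trace"))
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop_invalid("drop_fraction must be in (0, 1)")
  if (all(trace$FN_bw == 0))
    stop_invalid("normal force is zero everywhere; force ratio undefined")
  FT <- trace$FT_bw
  if (!is.null(lowpass_hz)) {
    dt <- stats::median(diff(trace$time_s))
    FT <- butterworth_lowpass(FT, fs = 1 / dt, cutoff_hz = lowpass_hz)
  }
  ok <- trace$FN_bw > 0
  ratio <- ifelse(ok, FT / trace$FN_bw, NA_real_)
  peaks <- numeric(0)
  positions <- numeric(0)
  cand <- -Inf
  cand_i <- NA_integer_
  for (i in which(ok)) {
    r <- ratio[i]
    if (r > cand) {
      cand <- r
      cand_i <- i
    } else if (cand > 0 && r <= cand * (1 - drop_fraction)) {
      peaks <- c(peaks, cand)
      positions <- c(positions, trace$position_mm[cand_i])
      cand <- r
      cand_i <- i
    }
  }
  len <- diff(range(trace$position_mm))
  structure(
    list(peaks = peaks, positions_mm = positions,
         density_per_mm = if (len > 0) length(peaks) / len else NA_real_,
         drag_length_mm = len),
    class = "slip_event_series")
}

#' @export
print.slip_event_series <- function(x, ...) {
  cat(sprintf(
    "<slip_event_series> %d events over %.3g mm (%.3g per mm), mean peak %.3g\n",
    length(x$peaks), x$drag_length_mm, x$density_per_mm,
    if (length(x$peaks)) mean(x$peaks) else NA_real_))
  invisible(x)
}

#' Build a slip event series directly from peak values
#'
#' @param peaks pre-slip F_T/F_N values (> 0).
#' @param density_per_mm asperity linear density.
#' @param positions_mm optional event positions.
#' @return a `slip_event_series`.
#' @export
slip_event_series <- function(peaks, density_per_mm,
                              positions_mm = NULL) {
  if (any(peaks <= 0)) stop_invalid("all peaks must be > 0")
  structure(
    list(peaks = as.numeric(peaks), positions_mm = positions_mm,
         density_per_mm = density_per_mm,
         drag_length_mm = if (is.null(positions_mm)) NA_real_
                          else diff(range(positions_mm))),
    class = "slip_event_series")
}

#' Through-origin Coulomb friction fit
#'
#' mu = sum(F_N * F_T,max) / sum(F_N^2): the least-squares slope of maximum
#' sustained friction against normal force with no intercept (zero normal
#' force can sustain zero friction). The standard error comes from the
#' through-origin regression residuals.
#'
#' @param FN_bw normal forces, bw.
#' @param FTmax_bw maximum sustained tangential forces, bw.
#' @return object of class `coulomb_fit`: `mu`, `se`, `n`.
#' @export
fit_coulomb <- function(FN_bw, FTmax_bw) {
  stopifnot(length(FN_bw) == length(FTmax_bw), length(FN_bw) >= 1)
  if (any(FN_bw < 0)) stop_invalid("normal forces must be >= 0")
  mu <- sum(FN_bw * FTmax_bw) / sum(FN_bw^2)
  n <- length(FN_bw)
  se <- if (n > 1) {
    res <- FTmax_bw - mu * FN_bw
    sqrt(sum(res^2) / (n - 1) / sum(FN_bw^2))
  } else NA_real_
  structure(list(mu = mu, se = se, n = n), class = "coulomb_fit")
}

#' @export
print.coulomb_fit <- function(x, ...) {
  cat(sprintf("<coulomb_fit> mu = %.4g (SE %.2g, n = %d)\n", x$mu, x$se, x$n))
  invisible(x)
}

#' Monte Carlo spread of mean claw force under load sharing
#'
#' Birds engage several claws at once; each claw's maximum friction is an
#' independent draw from the slip-peak distribution, and the force the
#' body feels is their mean. Resampling the empirical distribution (no
#' standard distribution fits slip peaks well), this returns the standard
#' deviation of the k-claw mean over `n_trials` trials: for i.i.d. draws
#' it contracts like sigma/sqrt(k), which is the benefit of load sharing.
#'
#' @param peaks a `slip_event_series` (non-empty).
#' @param k number of engaged claws (>= 1).
#' @param n_trials Monte Carlo trials (default 10000).
#' @param seed integer seed.
#' @return object of class `load_sharing_result`: `k`, `sd`, `mc_se`
#'   (approximate standard error of the reported sd), `n_trials`, `seed`.
#' @export
load_sharing_sd <- function(peaks, k, n_trials = 10000, seed = 1) {
  stopifnot(inherits(peaks, "slip_event_series"))
  if (length(peaks$peaks) == 0L) stop_invalid("empty peak distribution")
  if (k < 1) stop_invalid("k must be >= 1")
  means <- with_seed(seed, {
    draws <- matrix(sample(peaks$peaks, k * n_trials, replace = TRUE),
                    nrow = k)
    colMeans(draws)
  })
  s <- stats::sd(means)
  # SE of the sample SD allowing for non-normality of the k-claw means:
  # var(s^2) ~ (m4 - m2^2 (n-3)/(n-1)) / n, delta method for s
  n <- n_trials
  m2 <- mean((means - mean(means))^2)
  m4 <- mean((means - mean(means))^4)
  var_s2 <- (m4 - m2^2 * (n - 3) / (n - 1)) / n
  mc_se <- if (s > 0) sqrt(max(var_s2, 0)) / (2 * s) else 0
  structure(
    list(k = k, sd = s, mc_se = mc_se,
         n_trials = n_trials, seed = as.integer(seed)),
    class = "load_sharing_result")
}

#' Expected maximum claw friction versus drag distance
#'
#' Dragging further exposes the claw to more asperities; the best of them
#' sets the available friction. For each drag distance d the expected
#' asperity count is N_a(d) = density * d; each Monte Carlo trial draws
#' `floor(N_a) + Bernoulli(frac(N_a))` samples (so the average count over
#' trials equals N_a exactly), takes their maximum, and a trial with zero
#' draws contributes 0 (no asperity encountered means no claw-interlock
#' friction, so the curve starts near zero at d -> 0). The curve of mean
#' maxima is non-decreasing in d up to Monte Carlo error.
#'
#' @param peaks a `slip_event_series` with a positive `density_per_mm`
#'   (or supply `density_per_mm` explicitly).
#' @param d_mm vector of drag distances, mm (> 0).
#' @param n_trials Monte Carlo trials per distance (default 10000).
#' @param seed integer seed.
#' @param density_per_mm overrides the density stored in `peaks`.
#' @return object of class `expected_max_curve`: data.frame `curve` with
#'   columns `d_mm`, `expected_max`, `mc_se`, plus `n_trials`, `seed`.
#' @export
expected_max_friction <- function(peaks, d_mm, n_trials = 10000, seed = 1,
                                  density_per_mm = NULL) {
  stopifnot(inherits(peaks, "slip_event_series"))
  if (length(peaks$peaks) == 0L) stop_invalid("empty peak distribution")
  if (any(d_mm <= 0)) stop_invalid("drag distances must be > 0")
  if (n_trials < 1) stop_invalid("n_trials must be >= 1")
  dens <- if (is.null(density_per_mm)) peaks$density_per_mm else density_per_mm
  if (!is.finite(dens) || dens < 0)
    stop_invalid("a finite non-negative asperity density is required")
  rows <- with_seed(seed, {
    lapply(d_mm, function(d) {
      na <- dens * d
      counts <- floor(na) + stats::rbinom(n_trials, 1L, na - floor(na))
      maxima <- numeric(n_trials)
      pos <- counts > 0L
      if (any(pos)) {
        total <- sum(counts[pos])
        draws <- sample(peaks$peaks, total, replace = TRUE)
        grp <- rep(seq_len(sum(pos)), counts[pos])
        maxima[pos] <- vapply(split(draws, grp), max, numeric(1))
      }
      data.frame(d_mm = d, expected_max = mean(maxima),
                 mc_se = stats::sd(maxima) / sqrt(n_trials))
    })
  })
  structure(
    list(curve = do.call(rbind, rows), n_trials = n_trials,
         seed = as.integer(seed)),
    class = "expected_max_curve")
}

#' Map claw curl angle to drag distance
#'
#' Linear mapping with a user-supplied coefficient (never measured
#' directly; kinematic curl angles stand in for how far the claw tip
#' travelled along the surface). Identity at zero.
#'
#' @param curl_angle_deg claw curl angle(s), degrees.
#' @param mm_per_degree linear coefficient, mm of drag per degree of curl.
#' @return drag distance(s), mm.
#' @export
curl_angle_to_drag_distance <- function(curl_angle_deg, mm_per_degree) {
  stopifnot(is.numeric(mm_per_degree), mm_per_degree >= 0)
  curl_angle_deg * mm_per_degree
}
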