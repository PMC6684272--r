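#' Zero-phase Butterworth-magnitude low-pass filter
#'
#' Applies the magnitude response of an order-`order` Butterworth low-pass
#' (|H(f)| = 1/sqrt(1 + (f/fc)^(2*order))) in the frequency domain, which
#' is exactly zero-phase, so stage boundaries and slip events are not
#' shifted in time. The series is reflect-padded before the FFT to
#' suppress wrap-around transients. Force and kinematic channels are
#' conventionally filtered at 100 Hz (about five wingbeats) with order 8.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param cutoff_hz cutoff frequency (-3 dB), Hz; must be below fs/2.
#' @param order filter order (default 8).
#' @return filtered series, same length.
#' @export
lowpass_trace <- function(x, fs, cutoff_hz = 100, order = 8) {
  stopifnot(fs > 0, cutoff_hz > 0, order >= 1)
  if (cutoff_hz >= fs / 2)
    stop_invalid("cutoff must be below the Nyquist frequency")
  n <- length(x)
  if (n < 3L) return(x)
  npad <- min(n - 1L, ceiling(4 * fs / cutoff_hz))
  xp <- c(2 * x[1L] - x[(npad + 1L):2L],      # odd reflection at both ends
          x,
          2 * x[n] - x[(n - 1L):(n - npad)])
  m <- length(xp)
  f <- (seq_len(m) - 1L) / m * fs
  f <- pmin(f, fs - f)                        # two-sided frequency axis
  H <- 1 / sqrt(1 + (f / cutoff_hz)^(2 * order))
  y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / m
  y[(npad + 1L):(npad + n)]
}

butterworth_lowpass <- lowpass_trace

#' Approach trace: distance to the perch over time
#'
#' @param time_s time, s, strictly increasing.
#' @param distance_m distance from the bird (eye) to the perch centre, m,
#'   non-negative.
#' @return object of class `approach_trace`.
#' @export
approach_trace <- function(time_s, distance_m) {
  stopifnot(length(time_s) == length(distance_m))
  if (is.unsorted(time_s, strictly = TRUE))
    stop_invalid("time must be strictly increasing")
  if (any(distance_m < 0)) stop_invalid("distance must be non-negative")
  structure(list(time_s = time_s, distance_m = distance_m),
            class = "approach_trace")
}

#' Time-to-contact (tau) series from an approach trace
#'
#' tau(t) = s(t) / v(t), the visually available first-order estimate of
#' time to contact, with closing speed v = -ds/dt computed by central
#' differences (one-sided at the endpoints). Samples where v <= 0 (not
#' approaching) are masked as NA, with a warning if the analysis window is
#' not monotone.
#'
#' @param trace an [approach_trace()].
#' @return data.frame with `time_s`, `distance_m`, `speed_m_s`, `tau_s`
#'   (NA where v <= 0).
#' @export
compute_tau <- function(trace) {
  stopifnot(inherits(trace, "approach_trace"))
  t <- trace$time_s
  s <- trace$distance_m
  n <- length(t)
  v <- numeric(n)
  if (n > 2L) {
    i <- 2L:(n - 1L)
    v[i] <- -(s[i + 1L] - s[i - 1L]) / (t[i + 1L] - t[i - 1L])
    # second-order one-sided endpoints (uniform grid assumed there),
    # exact for quadratic trajectories like a constant-deceleration stop
    v[1L] <- -(-3 * s[1L] + 4 * s[2L] - s[3L]) / (t[3L] - t[1L])
    v[n] <- -(3 * s[n] - 4 * s[n - 1L] + s[n - 2L]) / (t[n] - t[n - 2L])
  } else {
    v[] <- -(s[2L] - s[1L]) / (t[2L] - t[1L])
  }
  tau <- ifelse(v > 0, s / v, NA_real_)
  if (anyNA(tau))
    warning("non-approaching samples masked (v <= 0)", call. = FALSE)
  data.frame(time_s = t, distance_m = s, speed_m_s = v, tau_s = tau)
}

#' Fit the time rate of change of tau
#'
#' Ordinary least squares of tau against time over the unmasked samples.
#' tau decreases to zero at contact, so the raw slope is negative;
#' `tau_dot` is reported as the slope magnitude, matching the convention
#' that a constant-deceleration stop gives tau_dot = 0.5 and controlled
#' collisions lie in 0.5 < tau_dot < 1.
#'
#' @param tau data.frame from [compute_tau()], or any data.frame with
#'   `time_s` and `tau_s` columns.
#' @return object of class `tau_fit`: `tau_dot` (slope magnitude),
#'   `r_squared` (NA for a constant series), `n`.
#' @export
fit_tau_dot <- function(tau) {
  stopifnot(is.data.frame(tau), all(c("time_s", "tau_s") %in% names(tau)))
  ok <- is.finite(tau$tau_s)
  if (sum(ok) < 2L) stop_invalid("need at least 2 unmasked tau samples")
  t <- tau$time_s[ok]
  y <- tau$tau_s[ok]
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2L])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(tau_dot = abs(slope), r_squared = r2, n = sum(ok)),
            class = "tau_fit")
}

#' @export
print.tau_fit <- function(x, ...) {
  cat(sprintf("<tau_fit> tau_dot = %.4g (R^2 = %.4g, n = %d)\n",
              x$tau_dot, x$r_squared, x$n))
  invisible(x)
}

#' Specification for a synthetic landing trial
#'
#' Emulates a high-speed-tracked landing: a constant-tau-dot approach, a
#' stereotyped stage sequence in the foot-spread and claw-angle traces
#' (resting, spreading, open, pre-shaping before contact; foot wrapping
#' and claw curling after), and net/squeeze force envelopes with a fast
#' rise and slow decay. Default stage durations are the measured means
#' (spreading 40 ms, open 21 ms, pre-shaping 31 ms, foot wrapping 19 ms,
#' claw curling 185 ms).
#'
#' @param tau_dot constant tau rate in (0, 1].
#' @param stage_durations_ms named list of stage durations, ms; names
#'   `resting`, `spreading`, `open`, `pre_shaping`, `foot_wrapping`,
#'   `claw_curling`.
#' @param peak_spread_angle_deg peak foot spread angle, degrees.
#' @param squeeze_peak_bw peak squeeze force, bw.
#' @param body_mass_kg body mass, kg (30 g bird by default).
#' @param sample_rate_hz sampling rate, >= 1000 Hz (landings were tracked
#'   at 3000 fps).
#' @param noise_sd named list of per-channel noise SDs: `angle_deg`,
#'   `force_bw`, `distance_m` (all 0 by default).
#' @param approach_distance_m distance at the start of the trace, m.
#' @param superfast_times_s optional times (s, relative to trace start) at
#'   which to inject superfast claw displacements (0.4 mm in 1.5 ms).
#' @param seed integer seed.
#' @return object of class `landing_gen_spec`.
#' @export
landing_gen_spec <- function(tau_dot = 0.8,
                             stage_durations_ms = list(
                               resting = 50, spreading = 40, open = 21,
                               pre_shaping = 31, foot_wrapping = 19,
                               claw_curling = 185),
                             peak_spread_angle_deg = 60,
                             squeeze_peak_bw = 2,
                             body_mass_kg = 0.030,
                             sample_rate_hz = 3000,
                             noise_sd = list(angle_deg = 0, force_bw = 0,
                                             distance_m = 0),
                             approach_distance_m = 0.5,
                             superfast_times_s = numeric(0),
                             seed = 1) {
  if (tau_dot <= 0 || tau_dot > 1) stop_invalid("tau_dot must be in (0, 1]")
  need <- c("resting", "spreading", "open", "pre_shaping",
            "foot_wrapping", "claw_curling")
  if (!all(need %in% names(stage_durations_ms)))
    stop_invalid("stage_durations_ms must name all of: ",
                 paste(need, collapse = ", "))
  if (any(unlist(stage_durations_ms[need]) <= 0))
    stop_invalid("all stage durations must be > 0")
  if (sample_rate_hz < 1000) stop_invalid("sample_rate_hz must be >= 1000")
  structure(
    list(tau_dot = tau_dot, stage_durations_ms = stage_durations_ms[need],
         peak_spread_angle_deg = peak_spread_angle_deg,
         squeeze_peak_bw = squeeze_peak_bw, body_mass_kg = body_mass_kg,
         sample_rate_hz = sample_rate_hz, noise_sd = noise_sd,
         approach_distance_m = approach_distance_m,
         superfast_times_s = superfast_times_s, seed = as.integer(seed)),
    class = "landing_gen_spec")
}

# fast-rise/slow-decay envelope, peaking at 1 when t == rise
rise_decay <- function(t, rise, decay) {
  ifelse(t <= 0, 0,
         ifelse(t <= rise, t / rise, exp(-(t - rise) / decay)))
}

#' Generate a synthetic landing trial
#'
#' The approach distance follows the closed-form constant-tau-dot
#' trajectory s(t) = s0 * ((t_c - t)/t_c)^(1/tau_dot) (so tau(t) =
#' tau_dot * (t_c - t) exactly); the foot-spread trace rises through the
#' 10%/90%/100% thresholds at the specified stage boundaries; the claw
#' angle drops steeply during foot wrapping and slowly during claw
#' curling; squeeze and net body forces follow fast-rise/slow-decay
#' envelopes after contact. All ground truth (stage boundaries, contact
#' time, tau parameters) is embedded so downstream estimators can be
#' scored without external data.
#'
#' @param spec a [landing_gen_spec()].
#' @return object of class `landing_trial` with fields `time_s`,
#'   `approach_m`, `foot_spread_deg`, `claw_angle_deg`, `claw_pos_mm`,
#'   `force_x_bw`, `force_y_bw`, `torque_z_bwmm`, `squeeze_bw`,
#'   `contact_time_s`, `sample_rate_hz`, `body_mass_kg`, and
#'   `ground_truth` (spec plus exact stage boundaries).
#' @export
gen_landing_trial <- function(spec) {
  stopifnot(inherits(spec, "landing_gen_spec"))
  fs <- spec$sample_rate_hz
  dur <- vapply(spec$stage_durations_ms, as.numeric, numeric(1)) / 1000
  # snap stage boundaries to the sample grid
  bounds <- round(cumsum(dur) * fs) / fs
  names(bounds) <- names(dur)
  t_end <- bounds[["claw_curling"]]
  t_c <- bounds[["pre_shaping"]]   # contact = end of pre-shaping
  n <- round(t_end * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  A <- spec$peak_spread_angle_deg

  # approach distance: constant tau-dot closed form before contact
  s <- ifelse(t < t_c,
              spec$approach_distance_m * ((t_c - t) / t_c)^(1 / spec$tau_dot),
              0)

  # Foot spread angle: the foot stays closed through most of resting and
  # the 10% crossing sits on the steep spreading ramp (one straight
  # segment from rise onset through the 10% and 90% crossings), so
  # threshold crossings are robust to tracking noise. The rise onset is
  # placed so 10% of the peak is reached exactly at the resting boundary.
  spread_slope <- 0.8 * A / (bounds[["spreading"]] - bounds[["resting"]])
  t_on <- bounds[["resting"]] - 0.1 * A / spread_slope
  if (t_on <= 0)
    stop_invalid("resting stage too short relative to spreading ",
                 "(need resting > spreading/8)")
  spread <- stats::approx(
    x = c(0, t_on, bounds[["spreading"]], bounds[["open"]],
          t_c, bounds[["foot_wrapping"]], t_end),
    y = c(0, 0, 0.9 * A, A, 0.55 * A, 0.30 * A, 0.30 * A),
    xout = t)$y
  # Round the peak with a quadratic cap tangent to the open-stage ramp:
  # real spread traces peak smoothly, and a symmetric cap keeps the
  # argmax at the stage boundary under zero-phase filtering, unlike a
  # slope-discontinuous corner between unequal ramps.
  t_p <- bounds[["open"]]
  w_cap <- min(0.003, (t_p - bounds[["spreading"]]) / 2, (t_c - t_p) / 2)
  slope_open <- 0.1 * A / (t_p - bounds[["spreading"]])
  c_cap <- slope_open / w_cap
  in_cap <- abs(t - t_p) <= w_cap
  spread[in_cap] <- A - c_cap * (t[in_cap] - t_p)^2
  right_edge <- t_p + w_cap
  post_cap <- t > right_edge & t < t_c
  spread[post_cap] <- stats::approx(
    x = c(right_edge, t_c),
    y = c(A - c_cap * w_cap^2, 0.55 * A),
    xout = t[post_cap])$y

  # claw angle: plateau, steep wrapping descent, shallow curling descent
  claw <- stats::approx(
    x = c(0, t_c, bounds[["foot_wrapping"]], t_end),
    y = c(120, 120, 60, 40),
    xout = t)$y

  # claw tip position relative to foot centre, mm: slow drift after
  # contact plus optional superfast steps
  pos <- ifelse(t < t_c, 0, (t - t_c) * 2)  # 2 mm/s slow drift
  for (ts in spec$superfast_times_s) {
    step <- 0.4 * pmin(1, pmax(0, (t - ts) / 0.0015))
    pos <- pos + step
  }

  # force envelopes after contact
  imp <- rise_decay(t - t_c, rise = 0.010, decay = 0.050)
  sqz <- spec$squeeze_peak_bw *
    (0.25 + 0.75 * rise_decay(t - t_c, rise = 0.030, decay = 0.150)) *
    (t >= t_c)
  fy <- -1 * (t >= t_c) - 2 * imp      # weight + landing impulse, downward
  fx <- 0.4 * imp
  tz <- 0.5 * imp                      # bw mm

  gt_bounds <- c(start = 0, bounds)
  out <- with_seed(spec$seed, {
    nz <- spec$noise_sd
    ang_sd <- if (is.null(nz$angle_deg)) 0 else nz$angle_deg
    f_sd <- if (is.null(nz$force_bw)) 0 else nz$force_bw
    d_sd <- if (is.null(nz$distance_m)) 0 else nz$distance_m
    list(
      s = pmax(0, s + stats::rnorm(n, 0, d_sd)),
      spread = spread + stats::rnorm(n, 0, ang_sd),
      claw = claw + stats::rnorm(n, 0, ang_sd),
      fx = fx + stats::rnorm(n, 0, f_sd),
      fy = fy + stats::rnorm(n, 0, f_sd),
      tz = tz + stats::rnorm(n, 0, f_sd),
      sqz = pmax(0, sqz + stats::rnorm(n, 0, f_sd)))
  })
  structure(
    list(time_s = t, approach_m = out$s, foot_spread_deg = out$spread,
         claw_angle_deg = out$claw, claw_pos_mm = pos,
         force_x_bw = out$fx, force_y_bw = out$fy, torque_z_bwmm = out$tz,
         squeeze_bw = out$sqz, contact_time_s = t_c, sample_rate_hz = fs,
         body_mass_kg = spec$body_mass_kg,
         ground_truth = list(spec = spec, stage_bounds_s = gt_bounds,
                             contact_time_s = t_c)),
    class = "landing_trial")
}

#' @export
print.landing_trial <- function(x, ...) {
  cat(sprintf(
    "<landing_trial> %.3g s at %g Hz, contact at %.4g s\n",
    max(x$time_s), x$sample_rate_hz, x$contact_time_s))
  invisible(x)
}

#' Segment a landing trial into kinematic stages
#'
#' Stage boundaries from the foot-spread and claw-angle traces:
#' resting ends at the first sample reaching 10% of the peak foot spread
#' angle; spreading at 90%; open at the peak itself (first sample
#' attaining the maximum, the stated tie-break for plateaued peaks);
#' pre-shaping at the first point of contact; foot wrapping when the
#' tracked claw makes stable contact (supplied explicitly or detected as
#' the first post-contact span of at least `min_plateau_ms` with
#' claw-angle rate below `rate_cap_deg_ms`); claw curling at the end of
#' tracking.
#'
#' @param trial a `landing_trial`.
#' @param stable_contact_time_s optional explicit end of foot wrapping, s.
#' @param rate_cap_deg_ms claw-angle rate cap defining "stable", deg/ms.
#' @param min_plateau_ms minimum quiet span, ms.
#' @param lowpass_hz optional cutoff for pre-filtering the angle traces
#'   ([lowpass_trace()], order 8), as tracked kinematics conventionally
#'   are (100 Hz); `NULL` skips filtering, which keeps boundaries exact
#'   on noise-free synthetic trials.
#' @return data.frame with columns `stage`, `start_s`, `end_s`.
#' @export
segment_stages <- function(trial, stable_contact_time_s = NULL,
                           rate_cap_deg_ms = 0.5, min_plateau_ms = 5,
                           lowpass_hz = NULL) {
  stopifnot(inherits(trial, "landing_trial"))
  t <- trial$time_s
  spread <- trial$foot_spread_deg
  claw_angle <- trial$claw_angle_deg
  if (!is.null(lowpass_hz)) {
    spread <- lowpass_trace(spread, trial$sample_rate_hz, lowpass_hz)
    claw_angle <- lowpass_trace(claw_angle, trial$sample_rate_hz,
                                lowpass_hz)
  }
  t_c <- trial$contact_time_s
  pre <- t < t_c + 1e-12
  if (!any(pre)) stop_invalid("no samples before contact")
  peak_val <- max(spread[pre])
  eps <- 1e-9 * max(1, abs(peak_val))
  i_peak <- which(pre & spread >= peak_val - eps)[1L]
  if (t[i_peak] >= t_c)
    stop_invalid("foot spread angle has no peak before contact; cannot segment")
  i10 <- which(spread >= 0.1 * peak_val - eps)[1L]
  i90 <- which(spread >= 0.9 * peak_val - eps)[1L]
  if (is.na(i10) || is.na(i90) || !(i10 <= i90 && i90 <= i_peak))
    stop_invalid("spread thresholds not crossed in order; cannot segment")
  if (is.null(stable_contact_time_s)) {
    # mean claw-angle rate over the plateau span: averaging over the whole
    # min_plateau window makes the criterion robust to frame-to-frame
    # tracking noise without shifting the boundary the way pre-filtering
    # the angle trace would
    dt_ms <- 1000 / trial$sample_rate_hz
    h <- max(1L, round(min_plateau_ms / dt_ms))
    ca <- claw_angle
    nn <- length(ca)
    j <- pmin(nn, seq_len(nn) + h)
    rate <- abs(ca[j] - ca) / ((j - seq_len(nn)) * dt_ms)
    rate[nn] <- 0
    quiet <- rate < rate_cap_deg_ms & t >= t_c
    if (!any(quiet))
      stop_invalid("no stable claw contact found; supply stable_contact_time_s")
    stable_t <- t[which(quiet)[1L]]
  } else stable_t <- stable_contact_time_s
  if (stable_t < t_c) stop_invalid("stable contact precedes contact time")
  data.frame(
    stage = c("resting", "spreading", "open", "pre_shaping",
              "foot_wrapping", "claw_curling"),
    start_s = c(t[1L], t[i10], t[i90], t[i_peak], t_c, stable_t),
    end_s = c(t[i10], t[i90], t[i_peak], t_c, stable_t, t[length(t)]))
}

#' Detect superfast claw movements
#'
#' A superfast movement is a claw-tip displacement of at least
#' `threshold_mm` completed within `window_ms`, starting from no
#' perceptible motion (instantaneous speed below `quiescence_mm_ms`).
#' Overlapping detections are merged into a single event reporting the
#' earliest onset and the largest displacement achieved within the window.
#' Such movements (~0.3 mm within 1-2 ms, a few percent of a wingbeat
#' period) are faster than any vertebrate muscle contraction and point to
#' elastic-tendon energy release.
#'
#' @param time_s time, s.
#' @param pos_mm claw-tip position relative to the foot centre, mm.
#' @param threshold_mm displacement threshold (default 0.3, about one
#'   tracking pixel).
#' @param window_ms time window (default 2).
#' @param quiescence_mm_ms speed cap defining "no perceptible motion",
#'   mm/ms (default 0.05; not quantified by measurement, exposed as a
#'   parameter).
#' @return data.frame with columns `onset_s`, `displacement_mm`,
#'   `window_ms`; zero rows if no events.
#' @export
detect_superfast <- function(time_s, pos_mm, threshold_mm = 0.3,
                             window_ms = 2, quiescence_mm_ms = 0.05) {
  n <- length(time_s)
  stopifnot(length(pos_mm) == n, n >= 3L)
  dt <- diff(time_s)
  speed <- abs(c(diff(pos_mm), 0) / c(dt, dt[n - 1L])) / 1000  # mm per ms
  win_s <- window_ms / 1000
  detected <- logical(n)
  disp <- numeric(n)
  j_hi <- 1L
  for (i in seq_len(n)) {
    if (speed[i] >= quiescence_mm_ms) next
    while (j_hi < n && time_s[j_hi + 1L] <= time_s[i] + win_s + 1e-12)
      j_hi <- j_hi + 1L
    if (j_hi <= i) j_hi <- i
    d <- max(abs(pos_mm[i:j_hi] - pos_mm[i]))
    if (d >= threshold_mm) {
      detected[i] <- TRUE
      disp[i] <- d
    }
  }
  if (!any(detected))
    return(data.frame(onset_s = numeric(0), displacement_mm = numeric(0),
                      window_ms = numeric(0)))
  # merge detections whose windows overlap
  runs <- rle(detected)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  # also merge adjacent runs separated by less than a window
  onset <- numeric(0); dmax <- numeric(0)
  last_end_t <- -Inf
  for (k in keep) {
    s_i <- starts[k]; e_i <- ends[k]
    if (time_s[s_i] <= last_end_t + win_s) {
      dmax[length(dmax)] <- max(dmax[length(dmax)], disp[s_i:e_i])
    } else {
      onset <- c(onset, time_s[s_i])
      dmax <- c(dmax, max(disp[s_i:e_i]))
    }
    last_end_t <- time_s[e_i]
  }
  data.frame(onset_s = onset, displacement_mm = dmax, window_ms = window_ms)
}

#' Write / read a landing trial as a CSV bundle with JSON sidecar
#'
#' The CSV holds the synchronized channels; the JSON sidecar holds contact
#' time, sample rate and body mass (and ground truth when present).
#'
#' @param trial a `landing_trial`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path` invisibly / a `landing_trial`.
#' @export
write_landing_trial <- function(trial, path) {
  stopifnot(inherits(trial, "landing_trial"))
  utils::write.csv(
    data.frame(time_s = trial$time_s, approach_m = trial$approach_m,
               foot_spread_deg = trial$foot_spread_deg,
               claw_angle_deg = trial$claw_angle_deg,
               claw_pos_mm = trial$claw_pos_mm,
               force_x_bw = trial$force_x_bw,
               force_y_bw = trial$force_y_bw,
               torque_z_bwmm = trial$torque_z_bwmm,
               squeeze_bw = trial$squeeze_bw),
    path, row.names = FALSE)
  side <- list(contact_time_s = trial$contact_time_s,
               sample_rate_hz = trial$sample_rate_hz,
               body_mass_kg = trial$body_mass_kg)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_landing_trial
#' @export
read_landing_trial <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    c(as.list(df),
      list(contact_time_s = side$contact_time_s,
           sample_rate_hz = side$sample_rate_hz,
           body_mass_kg = side$body_mass_kg,
           ground_truth = NULL)),
    class = "landing_trial")
}
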