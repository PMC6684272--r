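test_that("trace_surface identity and bridging cases", {
  pos <- (0:999) / 100                       # 10 mm at 10 um
  y <- rep(0, 1000)
  flat <- surface_profile(pos, y)
  expect_equal(trace_surface(flat, 80)$profile$heights, y)
  # r_a = 0 is the identity on any profile
  sp <- gen_surface_profile(surface_gen_spec(seed = 9))
  expect_equal(trace_surface(sp, 0)$profile$heights, sp$heights)
  # V-notch narrower than the tip is bridged; brute-force agreement
  yn <- y
  notch <- 480:520                           # 400 um wide, r_a = 300
  yn[notch] <- -abs(seq(-20, 20)) * 10
  p <- surface_profile(pos, yn)
  tr <- trace_surface(p, 300)
  expect_lt(max(abs(tr$profile$heights - oracle_trace(pos, yn, 300))), 1e-9)
  expect_gt(min(tr$profile$heights[notch]), -60)  # notch floor not reached
  expect_equal(min(yn), -200)
})

test_that("tracing is extensive and monotone in tip radius", {
  sp <- gen_surface_profile(surface_gen_spec(target_rms = 25, length_mm = 4,
                                             spacing_um = 4, seed = 21))
  t1 <- trace_surface(sp, 30)$profile$heights
  t2 <- trace_surface(sp, 90)$profile$heights
  expect_true(all(t1 >= sp$heights - 1e-12))
  expect_true(all(t2 >= t1 - 1e-12))
})

test_that("trace_surface resolution guard", {
  sp <- gen_surface_profile(surface_gen_spec(spacing_um = 10, seed = 1))
  expect_warning(trace_surface(sp, 20), "under-resolved")
  expect_error(trace_surface(sp, 20, strict = TRUE), "under-resolved")
})

test_that("usable_surface counts directional faces above threshold", {
  # flat surface: nothing usable even at theta_eff = 0
  pos <- (0:2000) / 1000
  flat <- trace_surface(surface_profile(pos, rep(0, 2001)), 0)
  expect_equal(as.numeric(usable_surface(flat, claw_tip_model(1e-9, 0, 10))),
               0)
  # symmetric triangular sawtooth with 20 deg faces, theta_min = 10:
  # only faces opposing the drag count -> n_a ~ 0.5
  x_um <- pos * 1000
  tooth <- 200  # um half-period, >> 1 um slope step
  saw <- (tooth / 2 - abs((x_um %% (2 * tooth)) - tooth)) * tan(20 * pi / 180)
  psaw <- surface_profile(pos, saw)
  trs <- trace_surface(psaw, 0)
  tip <- claw_tip_model(1e-9, 0, 10)
  expect_equal(as.numeric(usable_surface(trs, tip, direction = +1)), 0.5,
               tolerance = 0.01)
  expect_equal(as.numeric(usable_surface(trs, tip, direction = -1)), 0.5,
               tolerance = 0.01)
  expect_equal(as.numeric(usable_surface(trs, tip, direction = "both")), 1,
               tolerance = 0.01)
  # faces at 20 deg stop counting once theta_min exceeds 20
  expect_equal(
    as.numeric(usable_surface(trs, claw_tip_model(1e-9, 0, 25))), 0)
  # mismatched tip radius is rejected
  expect_error(usable_surface(trs, claw_tip_model(50, 0, 10)), "different")
  # profiles coarser than the 1 um slope step are interpolated, with a
  # warning
  coarse <- gen_surface_profile(surface_gen_spec(
    target_rms = 20, length_mm = 2, spacing_um = 5, seed = 51))
  trc <- trace_surface(coarse, 50)
  expect_warning(usable_surface(trc, claw_tip_model(50, 0, 10)),
                 "interpolating")
})

test_that("rougher surfaces expose at least as much usable surface", {
  tip <- claw_tip_model(50, 0, 10)
  n_a <- vapply(c(10, 40), function(rms) {
    sp <- gen_surface_profile(surface_gen_spec(
      target_rms = rms, spectral_exponent = 2, length_mm = 5,
      spacing_um = 1, seed = 31))
    as.numeric(usable_surface(trace_surface(sp, 50), tip))
  }, numeric(1))
  expect_gte(n_a[2], n_a[1])
})

test_that("penetration_slope matches the geometric construction", {
  expect_equal(penetration_slope(0), 0)
  for (DR in c(1e-6, 1e-3, 0.05, 0.3, 0.7, 0.99)) {
    expect_equal(penetration_slope(DR), oracle_penetration_slope(DR),
                 tolerance = 1e-9)
  }
  # small-DR series: m ~ sqrt(DR)/2
  expect_equal(penetration_slope(1e-8), sqrt(1e-8) / 2, tolerance = 1e-4)
  # spot values from the construction (slope angle ~6.46 deg at DR=0.05)
  expect_equal(penetration_slope(0.05), 0.113237011, tolerance = 1e-8)
  expect_equal(atan(penetration_slope(0.05)) * 180 / pi,
               atan(oracle_penetration_slope(0.05)) * 180 / pi,
               tolerance = 1e-9)  # ~6.46 deg
  expect_equal(penetration_slope(0.99), (1 - 0.1) / sqrt(0.99),
               tolerance = 1e-9)
  expect_error(penetration_slope(1), "DR")
})

test_that("effective_theta subtracts the penetration angle and clamps", {
  expect_equal(effective_theta(10, 0), 10)
  expect_equal(effective_theta(10, 0.05),
               10 - atan(oracle_penetration_slope(0.05)) * 180 / pi,
               tolerance = 1e-9)  # ~3.54 deg
  expect_equal(effective_theta(5, 0.05), 0)  # clamp
})

test_that("penetration increases usable surface; n_a monotone in theta_min", {
  sp <- gen_surface_profile(surface_gen_spec(
    target_rms = 20, length_mm = 4, spacing_um = 1, seed = 41))
  sw <- sweep_usable_surface(sp, tip_radii_um = c(25, 50, 100),
                             theta_min_deg = c(5, 10, 20, 35),
                             dr_policy = "zero")
  expect_true(all(sw$DR == 0))
  expect_true(all(sw$n_a >= 0 & sw$n_a <= 1))
  # monotone non-increasing in theta_min along every tip-radius row
  for (r in unique(sw$r_a)) {
    v <- sw$n_a[sw$r_a == r][order(unique(sw$theta_min))]
    expect_true(all(diff(v) <= 1e-12))
  }
  swf <- sweep_usable_surface(sp, c(25, 50, 100), c(5, 10, 20, 35),
                              dr_policy = "fixed", dr_value = 0.05)
  expect_true(all(swf$n_a >= sw$n_a - 1e-12))
  # policies coincide at the reference radius
  swi <- sweep_usable_surface(sp, c(25, 50, 100), c(5, 10, 20, 35),
                              dr_policy = "isometric", dr_value = 0.05,
                              dr_reference_radius_um = 50)
  at_ref <- swi$r_a == 50
  expect_equal(swi$n_a[at_ref], swf$n_a[swf$r_a == 50])
  expect_equal(swi$DR[swi$r_a == 100], rep(0.10, 4))
})

test_that("fit_exponential_offset recovers parameters", {
  r <- seq(5, 200, by = 5)
  A <- 0.55; lam <- 60; c0 <- 0.08
  y <- A * exp(-r / lam) + c0
  fit <- fit_exponential_offset(r, y)
  expect_equal(fit$amplitude, A, tolerance = 1e-6)
  expect_equal(fit$decay_um, lam, tolerance = 1e-6)
  expect_equal(fit$offset, c0, tolerance = 1e-6)
  # constant data
  fc <- fit_exponential_offset(r, rep(0.3, length(r)))
  expect_equal(fc$amplitude, 0)
  expect_equal(fc$offset, 0.3)
  # noisy recovery: mean estimates within 3 SE over 100 seeds
  ests <- t(vapply(1:100, function(s) {
    yn <- withr::with_seed(s, y + rnorm(length(y), 0, 0.02))
    f <- fit_exponential_offset(r, yn)
    c(f$amplitude, f$decay_um, f$offset)
  }, numeric(3)))
  for (j in 1:3) {
    se <- sd(ests[, j]) / sqrt(nrow(ests))
    expect_lt(abs(mean(ests[, j]) - c(A, lam, c0)[j]), 3 * se + 1e-3)
  }
})

test_that("fit_sphere_tip: exact, osculating and synthetic-claw cases", {
  # exact circular arc
  h <- seq(1, 40, by = 1)
  R <- 50
  w <- 2 * sqrt(2 * R * h - h^2)
  expect_equal(fit_sphere_tip(claw_profile(h, w), 40), R, tolerance = 1e-12)
  # parabolic tip w/2 = sqrt(2 R h): osculating circle ~ R for h << R
  hp <- seq(0.1, 2, by = 0.1)
  wp <- 2 * sqrt(2 * R * hp)
  expect_equal(fit_sphere_tip(claw_profile(hp, wp), 2), R, tolerance = 0.02)
  # generated parrotlet-like claw: 50 +/- 1 um
  cp <- gen_claw_profile(claw_gen_spec(tip_radius_um = 50))
  expect_equal(fit_sphere_tip(cp, 20), 50, tolerance = 1 / 50)
})

test_that("fit_penetration_curve: origin constraint and exact recovery", {
  # linear data: higher-order terms vanish
  f <- c(0.4, 1, 1.8, 3)
  fit <- fit_penetration_curve(f, 4.2 * f)
  expect_equal(fit$coefficients, c(4.2, 0, 0), tolerance = 1e-9)
  expect_equal(predict_penetration(fit, 0), 0)
  # noiseless cubic at the four standard load levels: exact recovery
  cf <- c(2.5, -0.4, 0.08)
  d <- cf[1] * f + cf[2] * f^2 + cf[3] * f^3
  fit2 <- fit_penetration_curve(f, d)
  expect_equal(fit2$coefficients, cf, tolerance = 1e-9)
  # low-force evaluation (the intended use) and extrapolation warning
  expect_equal(predict_penetration(fit2, 0.25),
               cf[1] * 0.25 + cf[2] * 0.25^2 + cf[3] * 0.25^3)
  expect_warning(predict_penetration(fit2, 5), "outside")
})
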