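lay075 <- build_layout(0.75, 0, mu_pad = 0.3, mu_claw = 2)

test_that("build_layout constants and rejections", {
  expect_equal(sort(c(lay075$pad_angles_deg, lay075$claw_angles_deg)),
               c(-85, -45, 0, 45, 85))
  lay15 <- build_layout(1.5)
  expect_equal(sort(c(lay15$pad_angles_deg, lay15$claw_angles_deg)),
               c(-45, -20, 0, 20, 45))
  expect_equal(lay15$radius_mm, 1.5 * 25.4 / 2)
  expect_error(build_layout(0.25), "not modelled")
  expect_error(build_layout(0.5), "unsupported")
  expect_error(contact_layout(10, pad_angles_deg = c(-30, 5, 30)),
               "symmetric")
})

test_that("trivial feasibility cases", {
  # zero wrench, zero squeeze: all-zero forces satisfy everything
  r0 <- check_feasible(lay075, wrench_query(0, 0, 0, 0))
  expect_true(r0$feasible)
  expect_equal(r0$objective_bw, 0, tolerance = 1e-9)
  # frictionless pull-off away from the perch is impossible: every
  # contact normal on the upper arc points downward
  lay_mu0 <- build_layout(0.75, 0, mu_pad = 0, mu_claw = 0)
  for (sq in c(0, 1, 3)) {
    expect_false(
      check_feasible(lay_mu0, wrench_query(0, 0.5, 0, sq))$feasible)
  }
  # hanging weight with squeeze is fine
  expect_true(check_feasible(lay075, wrench_query(0, -1, 0, 0.5))$feasible)
  # feasible solutions respect cones, caps and balances
  s <- check_feasible(lay075, wrench_query(0.3, -1, 2, 1))
  expect_true(s$feasible)
  expect_true(all(s$forces$normal_bw >= -1e-9))
  mu <- ifelse(grepl("C", s$forces$contact), lay075$mu_claw, lay075$mu_pad)
  expect_true(all(abs(s$forces$shear_bw) <= mu * s$forces$normal_bw + 1e-8))
  claws <- grepl("C", s$forces$contact)
  expect_true(all(s$forces$normal_bw[claws] <= lay075$claw_cap_bw + 1e-8))
  expect_lt(s$max_residual, 1e-8)
})

test_that("feasibility agrees with the cone-enumeration oracle (spot check)", {
  # the full >= 200-query sweep runs in test-acceptance.R
  set.seed(202)
  layouts <- list(
    lay075,
    build_layout(0.75, -35, mu_pad = 0.5, mu_claw = 1, claw_cap_bw = 1),
    build_layout(1.5, 10, mu_pad = 0.3, mu_claw = 2,
                 split_center_pad = TRUE))
  for (lay in layouts) {
    for (i in 1:10) {
      q <- wrench_query(runif(1, -2, 2), runif(1, -2, 2),
                        runif(1, -10, 10), runif(1, 0, 2))
      expect_identical(check_feasible(lay, q)$feasible,
                       oracle_feasible(lay, q))
    }
  }
})

test_that("monotonicity in squeeze and friction on a grid", {
  fx <- seq(-1.5, 1.5, by = 0.5)
  fy <- seq(-1.5, 1.5, by = 0.5)
  ws_lo <- wrench_space(lay075, fx, fy, 0, F_sqz_bw = 0.2)
  ws_hi <- wrench_space(lay075, fx, fy, 0, F_sqz_bw = 1.0)
  expect_true(all(ws_hi$grid$feasible | !ws_lo$grid$feasible))
  lay_slick <- build_layout(0.75, 0, mu_pad = 0.1, mu_claw = 0.8)
  ws_slick <- wrench_space(lay_slick, fx, fy, 0, F_sqz_bw = 0.5)
  ws_grip <- wrench_space(lay075, fx, fy, 0, F_sqz_bw = 0.5)
  expect_true(all(ws_grip$grid$feasible | !ws_slick$grid$feasible))
  # mirror symmetry at zero landing angle and zero torque
  g <- ws_grip$grid
  for (i in seq_len(nrow(g))) {
    j <- which(g$F_x == -g$F_x[i] & g$F_y == g$F_y[i])
    expect_identical(g$feasible[i], g$feasible[j])
  }
})

test_that("landing angle rotates the force cross-section", {
  delta <- 25 * pi / 180
  layr <- build_layout(0.75, 25, mu_pad = 0.3, mu_claw = 2)
  set.seed(77)
  for (i in 1:40) {
    v <- c(runif(1, -2, 2), runif(1, -2, 2))
    sq <- runif(1, 0, 1.5)
    base <- check_feasible(lay075, wrench_query(v[1], v[2], 0, sq))$feasible
    # rotate the query the same way the contact set rotated: angles are
    # measured clockwise from vertical, i.e. from +y toward +x
    vr <- c(cos(delta) * v[1] + sin(delta) * v[2],
            -sin(delta) * v[1] + cos(delta) * v[2])
    rot <- check_feasible(layr, wrench_query(vr[1], vr[2], 0, sq))$feasible
    expect_identical(base, rot)
  }
})

test_that("feasibility is positively homogeneous", {
  set.seed(99)
  for (i in 1:25) {
    q <- wrench_query(runif(1, -2, 2), runif(1, -2, 2), runif(1, -8, 8),
                      runif(1, 0, 2))
    f1 <- check_feasible(lay075, q)$feasible
    for (c in c(0.25, 3)) {
      layc <- build_layout(0.75, 0, mu_pad = 0.3, mu_claw = 2,
                           claw_cap_bw = 3 * c)
      qc <- wrench_query(c * q$F_x, c * q$F_y, c * q$T_z, c * q$F_sqz)
      expect_identical(check_feasible(layc, qc)$feasible, f1)
    }
  }
})

test_that("safety margins: boundary, grid agreement, SM_x > SM_y", {
  q <- wrench_query(0, -1, 0, 0.5)
  smx <- safety_margin(lay075, q, "x")
  smy <- safety_margin(lay075, q, "y")
  expect_true(smx$query_feasible && smy$query_feasible)
  # representative perch with moderate squeeze: sideways pulls load one
  # half of the foot harder, pull-off unloads the toes
  expect_gt(smx$margin, smy$margin)
  # the wrench at (query + margin) along the direction is on the boundary
  g_bx <- c(1, 0)
  on_edge <- wrench_query(q$F_x + (smy$margin) * 0, q$F_y + smy$margin,
                          0, 0.5)
  expect_true(check_feasible(lay075, on_edge)$feasible ||
                check_feasible(lay075, wrench_query(
                  q$F_x, q$F_y + smy$margin - 2e-3, 0, 0.5))$feasible)
  expect_false(check_feasible(lay075, wrench_query(
    q$F_x, q$F_y + smy$margin + 2e-3, 0, 0.5))$feasible)
  # query on the boundary: margin ~ 0
  qb <- wrench_query(q$F_x, q$F_y + smy$margin, 0, 0.5)
  if (check_feasible(lay075, qb)$feasible) {
    expect_lt(safety_margin(lay075, qb, "y")$margin, 2e-3)
  }
  # margins agree with a dense-grid boundary distance within one cell
  step <- 0.05
  ygrid <- seq(q$F_y, q$F_y + 6, by = step)
  feas <- vapply(ygrid, function(yy) {
    check_feasible(lay075, wrench_query(q$F_x, yy, 0, 0.5))$feasible
  }, logical(1))
  first_bad <- ygrid[which(!feas)[1]]
  expect_lt(abs((first_bad - q$F_y) - smy$margin), step + 1e-6)
  # infeasible query reports zero margin with the flag
  bad <- safety_margin(lay_mu0 <- build_layout(0.75, 0, 0, 0),
                       wrench_query(0, 1, 0, 0), "y")
  expect_false(bad$query_feasible)
  expect_equal(bad$margin, 0)
  # torque margin search caps out as unbounded=FALSE here
  smt <- safety_margin(lay075, q, "T")
  expect_true(smt$margin > 0)
})

test_that("margin_trace emits margins only while claws are in contact", {
  tr <- data.frame(time_s = c(0, 0.01, 0.02),
                   force_x_bw = c(0, 0.1, 0.1),
                   force_y_bw = c(-1, -1.2, -0.9),
                   torque_z_bwmm = c(0, 0.5, 0.2),
                   squeeze_bw = c(0.5, 0.8, 0.6))
  out <- margin_trace(lay075, tr, claws_in_contact = c(FALSE, TRUE, TRUE),
                      tol = 1e-2)
  expect_true(is.na(out$SM_x[1]))
  expect_true(all(is.finite(out$SM_x[2:3])))
  expect_true(all(out$SM_x[2:3] >= 0))
})

test_that("solver determinism", {
  q <- wrench_query(0.7, -0.4, 3, 0.8)
  r1 <- check_feasible(lay075, q)
  r2 <- check_feasible(lay075, q)
  expect_identical(r1$feasible, r2$feasible)
  expect_identical(r1$forces, r2$forces)
})
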