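# Independent oracles used across the suite. Each deliberately avoids the
# package's own implementation path: direct formulas, geometric
# construction, closed forms, and exhaustive enumeration.

# Traced surface by the direct max-over-window formula, looping over
# positions (the package loops over offsets).
oracle_trace <- function(positions_mm, heights_um, r_a_um) {
  x <- positions_mm * 1000
  n <- length(x)
  out <- numeric(n)
  spacing <- x[2] - x[1]
  w <- floor(r_a_um / spacing) + 1L
  for (i in seq_len(n)) {
    j <- max(1L, i - w):min(n, i + w)
    dx <- x[j] - x[i]
    ok <- abs(dx) <= r_a_um + 1e-9   # keep the |dx| == r_a ring under float noise
    out[i] <- max(heights_um[j][ok] +
                    sqrt(pmax(0, r_a_um^2 - dx[ok]^2))) - r_a_um
  }
  out
}

# Hertzian chord slope by explicit geometric construction: indent a circle
# of radius R to depth d, find the contact point at a = sqrt(R*d), take
# the chord slope from the tip numerically.
oracle_penetration_slope <- function(DR, R = 50) {
  d <- DR * R
  a <- sqrt(R * d)
  tip <- c(0, -R)
  contact <- c(a, -sqrt(R^2 - a^2))
  (contact[2] - tip[2]) / (contact[1] - tip[1])
}

# Exact expected maximum of n i.i.d. draws from the empirical distribution
# of `values` (resampling with replacement), by order statistics:
# P(max <= v_(i)) = (i/N)^n.
oracle_empirical_max <- function(values, n_draws) {
  if (n_draws == 0) return(0)
  v <- sort(values)
  N <- length(v)
  i <- seq_len(N)
  sum(v * ((i / N)^n_draws - ((i - 1) / N)^n_draws))
}

# Same, with the fractional-count Bernoulli mixture used by the package.
oracle_expected_max <- function(values, n_a) {
  fl <- floor(n_a)
  fr <- n_a - fl
  (1 - fr) * oracle_empirical_max(values, fl) +
    fr * oracle_empirical_max(values, fl + 1)
}

# Grasp feasibility by friction-cone ray decomposition plus exhaustive
# basic-solution enumeration. In 2D each Coulomb cone is spanned by two
# extreme rays g+/- = normal +/- mu * tangent; a wrench is feasible iff
# non-negative ray weights (and cap slacks) solve the equality system.
# Any nonempty feasible region {x >= 0 : Ax = b} contains a basic feasible
# solution supported on at most rank(A) linearly independent columns, so
# enumerating all column subsets of size <= rank(A) is complete.
oracle_feasible <- function(layout, query, tol = 1e-7) {
  gam <- c(layout$claw_angles_deg, layout$pad_angles_deg)
  is_claw <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  mu <- ifelse(is_claw, layout$mu_claw, layout$mu_pad)
  lam <- layout$landing_angle_deg * pi / 180
  alpha <- lam + gam * pi / 180
  u <- cbind(sin(alpha), cos(alpha))
  nrm <- -u
  tng <- cbind(-u[, 2], u[, 1])
  b_x <- c(cos(lam), -sin(lam))
  rho <- layout$radius_mm
  side1 <- ifelse(abs(gam) < 1e-9, if (layout$split_center_pad) 0.5 else 1,
                  as.numeric(gam < 0))
  side2 <- ifelse(abs(gam) < 1e-9, if (layout$split_center_pad) 0.5 else 1,
                  as.numeric(gam > 0))
  Fxb <- query$F_x * b_x[1] + query$F_y * b_x[2]
  ray_cols <- list()
  for (i in 1:5) {
    for (sgn in c(1, -1)) {
      f <- nrm[i, ] + sgn * mu[i] * tng[i, ]    # force per unit weight
      trq <- rho * sgn * mu[i]                  # torque per unit weight
      fb <- sum(f * b_x)
      cap_row <- c(as.numeric(is_claw[i] && i == 1),
                   as.numeric(is_claw[i] && i == 2))
      ray_cols[[length(ray_cols) + 1]] <-
        c(f[1], f[2], trq, side1[i] * fb, side2[i] * fb, cap_row)
    }
  }
  A <- cbind(do.call(cbind, ray_cols),
             c(0, 0, 0, 0, 0, 1, 0), c(0, 0, 0, 0, 0, 0, 1))
  b <- c(query$F_x, query$F_y, query$T_z,
         query$F_sqz + max(Fxb, 0), -query$F_sqz + min(Fxb, 0),
         layout$claw_cap_bw, layout$claw_cap_bw)
  r <- qr(A)$rank
  nc <- ncol(A)
  for (k in 1:r) {
    subsets <- utils::combn(nc, k)
    for (j in seq_len(ncol(subsets))) {
      S <- subsets[, j]
      As <- A[, S, drop = FALSE]
      if (qr(As)$rank < length(S)) next
      x <- qr.coef(qr(As), b)
      if (anyNA(x)) next
      if (all(x >= -tol) && max(abs(As %*% x - b)) <= tol) return(TRUE)
    }
  }
  FALSE
}

# Exact tau series for a constant-tau-dot trajectory
oracle_tau <- function(t, t_contact, tau_dot) tau_dot * (t_contact - t)
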