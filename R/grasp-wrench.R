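#' Foot-perch contact layout
#'
#' The planar grasp model represents both feet as a single 2D foot with
#' five contacts on the perch circle: three toe pads (P1, P2 centre, P3)
#' and two claws (C1, C2), mirrored about the ray from the perch centre
#' through the foot centre. Contact angles are measured from that ray,
#' positive toward +b_x; the landing angle rotates the whole foot (and its
#' squeeze axis) about the perch axis relative to vertical.
#'
#' Wrench queries are expressed in the perch-fixed frame (x horizontal,
#' y vertical up); the foot frame b_x/b_y rotates with the landing angle,
#' so rotating the landing angle rotates the feasible force region.
#'
#' @param radius_mm perch radius, mm (> 0).
#' @param pad_angles_deg toe pad contact angles from the foot-centre ray,
#'   degrees; must be symmetric with the centre pad at 0.
#' @param claw_angles_deg claw contact angles, degrees, mirrored pair.
#' @param landing_angle_deg rotation of the foot frame from vertical,
#'   degrees.
#' @param mu_pad,mu_claw Coulomb friction coefficients (>= 0). Claw
#'   "hooking" on asperities is represented by mu_claw much larger than
#'   mu_pad.
#' @param claw_cap_bw maximum claw normal force, bw (default 3: claws wear
#'   heavily beyond about three bodyweights, which is also about the
#'   largest squeeze force observed).
#' @param split_center_pad if `FALSE` (as printed in the model equations)
#'   the centre pad appears in the squeeze balance of both halves of the
#'   foot, which forces its shear to carry no squeeze-axis component; if
#'   `TRUE`, half of its squeeze-axis force is assigned to each side.
#' @return object of class `contact_layout`.
#' @export
contact_layout <- function(radius_mm, pad_angles_deg = c(-45, 0, 45),
                           claw_angles_deg = c(-85, 85),
                           landing_angle_deg = 0,
                           mu_pad = 0.3, mu_claw = 2,
                           claw_cap_bw = 3, split_center_pad = FALSE) {
  if (radius_mm <= 0) stop_invalid("radius must be > 0")
  if (mu_pad < 0 || mu_claw < 0) stop_invalid("friction coefficients >= 0")
  if (claw_cap_bw <= 0) stop_invalid("claw cap must be > 0")
  pads <- sort(pad_angles_deg)
  claws <- sort(claw_angles_deg)
  if (length(pads) != 3L || length(claws) != 2L)
    stop_invalid("need 3 pad contacts and 2 claw contacts")
  if (abs(pads[2L]) > 1e-9 || abs(pads[1L] + pads[3L]) > 1e-9 ||
      abs(claws[1L] + claws[2L]) > 1e-9)
    stop_invalid("contacts must be symmetric about the foot-centre ray")
  structure(
    list(radius_mm = radius_mm, pad_angles_deg = pads,
         claw_angles_deg = claws, landing_angle_deg = landing_angle_deg,
         mu_pad = mu_pad, mu_claw = mu_claw, claw_cap_bw = claw_cap_bw,
         split_center_pad = split_center_pad),
    class = "contact_layout")
}

#' Build the standard contact layout for a tested perch diameter
#'
#' Observed contact geometry: on 0.75 in (19 mm) perches the claws reach
#' +/-85 deg from the foot centre and the outer pads sit at +/-45 deg; on
#' the 1.5 in (38 mm) perch the foot wraps less, with claws at +/-45 deg
#' and outer pads at +/-20 deg. The 0.25 in perch is not modelled: the
#' foot wraps fully around it and stability is set by muscular and
#' structural limits, not surface friction.
#'
#' @param diameter_in perch diameter in inches, 0.75 or 1.5.
#' @param landing_angle_deg foot orientation, degrees from vertical.
#' @param mu_pad,mu_claw friction coefficients.
#' @param ... passed to [contact_layout()] (claw_cap_bw,
#'   split_center_pad).
#' @return a [contact_layout()].
#' @export
build_layout <- function(diameter_in, landing_angle_deg = 0,
                         mu_pad = 0.3, mu_claw = 2, ...) {
  if (isTRUE(all.equal(diameter_in, 0.25)))
    stop_invalid("0.25 in perch is not modelled: with the foot fully ",
                 "wrapped, grasp is limited by muscular and structural ",
                 "constraints rather than surface friction")
  if (isTRUE(all.equal(diameter_in, 0.75))) {
    pads <- c(-45, 0, 45); claws <- c(-85, 85)
  } else if (isTRUE(all.equal(diameter_in, 1.5))) {
    pads <- c(-20, 0, 20); claws <- c(-45, 45)
  } else {
    stop_invalid("unsupported perch diameter: ", diameter_in,
                 " in (modelled diameters: 0.75, 1.5)")
  }
  contact_layout(radius_mm = diameter_in * 25.4 / 2,
                 pad_angles_deg = pads, claw_angles_deg = claws,
                 landing_angle_deg = landing_angle_deg,
                 mu_pad = mu_pad, mu_claw = mu_claw, ...)
}

#' A wrench (force-torque) query
#'
#' @param F_x,F_y external force components on the foot, bw, in the
#'   perch-fixed frame (x horizontal, y vertical up).
#' @param T_z external torque about the perch axis, bw mm.
#' @param F_sqz internal squeeze force the two halves of the foot exert
#'   toward each other, bw (>= 0). Squeeze raises contact normal forces
#'   without net external force, expanding the feasible wrench set.
#' @return object of class `wrench_query`.
#' @export
wrench_query <- function(F_x = 0, F_y = 0, T_z = 0, F_sqz = 0) {
  vals <- c(F_x, F_y, T_z, F_sqz)
  if (!all(is.finite(vals))) stop_invalid("wrench components must be finite")
  if (F_sqz < 0) stop_invalid("squeeze force must be >= 0")
  structure(list(F_x = F_x, F_y = F_y, T_z = T_z, F_sqz = F_sqz),
            class = "wrench_query")
}

# contact geometry in the perch-fixed frame; angles in degrees
layout_geometry <- function(layout) {
  gam <- c(layout$claw_angles_deg[2L], layout$pad_angles_deg[3L],
           layout$pad_angles_deg[2L], layout$pad_angles_deg[1L],
           layout$claw_angles_deg[1L])
  names(gam) <- c("C1", "P1", "P2", "P3", "C2")
  lam <- layout$landing_angle_deg * pi / 180
  alpha <- lam + gam * pi / 180
  u <- cbind(sin(alpha), cos(alpha))            # perch-centre -> contact
  list(
    names = names(gam),
    u = u,
    normal = -u,                                # contact pushes toward O
    tangent = cbind(-u[, 2L], u[, 1L]),
    b_x = c(cos(lam), -sin(lam)),
    b_y = c(sin(lam), cos(lam)),
    mu = c(layout$mu_claw, layout$mu_pad, layout$mu_pad,
           layout$mu_pad, layout$mu_claw),
    is_claw = c(TRUE, FALSE, FALSE, FALSE, TRUE),
    # Squeeze-side membership. The side whose balance reads
    # "+F_sqz + max(Fx,0)" must be the one whose inward normals push in
    # +b_x, i.e. the contacts at negative gamma; the +gamma side carries
    # "-F_sqz + min(Fx,0)". The centre pad P2 appears on both sides as
    # printed (which, combined with the x balance, forces its shear to
    # carry no b_x component), or half-half with split_center_pad.
    side1 = c(0, 0, if (layout$split_center_pad) 0.5 else 1, 1, 1),
    side2 = c(1, 1, if (layout$split_center_pad) 0.5 else 1, 0, 0))
}

# assemble the LP for check_feasible; variable order: q[1:5], sp[1:5], sm[1:5]
grasp_lp <- function(layout, query) {
  g <- layout_geometry(layout)
  rho <- layout$radius_mm
  Fxb <- query$F_x * g$b_x[1L] + query$F_y * g$b_x[2L]
  tx <- g$tangent[, 1L]; ty <- g$tangent[, 2L]
  nx <- g$normal[, 1L]; ny <- g$normal[, 2L]
  nbx <- g$normal %*% g$b_x
  tbx <- g$tangent %*% g$b_x
  A3 <- rbind(
    c(nx, tx, -tx),
    c(ny, ty, -ty),
    c(rep(0, 5), rep(rho, 5), rep(-rho, 5)),
    c(g$side1 * nbx, g$side1 * tbx, -g$side1 * tbx),
    c(g$side2 * nbx, g$side2 * tbx, -g$side2 * tbx))
  b3 <- c(query$F_x, query$F_y, query$T_z,
          query$F_sqz + max(Fxb, 0),
          -query$F_sqz + min(Fxb, 0))
  # friction cones: sp_i + sm_i - mu_i q_i <= 0; claw caps: q <= cap
  A1 <- cbind(-diag(g$mu), diag(5), diag(5))
  A1 <- rbind(A1, cbind(diag(5)[g$is_claw, , drop = FALSE],
                        matrix(0, 2, 10)))
  b1 <- c(rep(0, 5), rep(layout$claw_cap_bw, 2))
  list(A1 = A1, b1 = b1, A3 = A3, b3 = b3, geometry = g)
}

#' Test whether a wrench is feasible for a static grasp
#'
#' Decides whether contact forces exist that balance the queried wrench
#' subject to: force and torque balance (3 equalities), the squeeze
#' balance of each half of the foot (2 equalities), Coulomb cones
#' |shear| <= mu * normal with non-negative normals at all five contacts,
#' and the claw normal-force caps. In 2D every constraint is linear, so
#' the problem is solved exactly as a linear program minimizing the total
#' normal force (the bird's presumed effort), with no initialization
#' sensitivity; a nonlinear solver is unnecessary.
#'
#' @param layout a [contact_layout()].
#' @param query a [wrench_query()].
#' @param tol residual tolerance for the returned solution, bw.
#' @return object of class `contact_force_solution`: `feasible` (logical),
#'   `forces` (data.frame: contact, normal_bw, shear_bw), `objective_bw`
#'   (sum of normals), `status` (`"optimal"`, `"infeasible"`, or
#'   `"unconverged"`), `max_residual`.
#' @export
check_feasible <- function(layout, query, tol = 1e-8) {
  stopifnot(inherits(layout, "contact_layout"),
            inherits(query, "wrench_query"))
  lp <- grasp_lp(layout, query)
  # boot::simplex needs non-negative right-hand sides: flip equality rows
  flip <- lp$b3 < 0
  A3 <- lp$A3; b3 <- lp$b3
  A3[flip, ] <- -A3[flip, , drop = FALSE]
  b3[flip] <- -b3[flip]
  obj <- c(rep(1, 5), rep(0, 10))
  sol <- boot::simplex(a = obj, A1 = lp$A1, b1 = lp$b1, A3 = A3, b3 = b3,
                       maxi = FALSE, n.iter = 500, eps = 1e-10)
  status <- switch(as.character(sol$solved),
                   "1" = "optimal", "-1" = "infeasible", "unconverged")
  if (status != "optimal") {
    return(structure(
      list(feasible = FALSE, forces = NULL, objective_bw = NA_real_,
           status = status, max_residual = NA_real_),
      class = "contact_force_solution"))
  }
  x <- sol$soln
  q <- x[1:5]; s <- x[6:10] - x[11:15]
  res <- max(abs(lp$A3 %*% x - lp$b3))
  structure(
    list(feasible = res <= tol,
         forces = data.frame(contact = lp$geometry$names,
                             normal_bw = q, shear_bw = s),
         objective_bw = sum(q),
         status = "optimal", max_residual = res),
    class = "contact_force_solution")
}

#' @export
print.contact_force_solution <- function(x, ...) {
  cat(sprintf("<contact_force_solution> %s",
              if (x$feasible) "feasible" else
                sprintf("not feasible (%s)", x$status)))
  if (x$feasible)
    cat(sprintf(", total normal force %.4g bw", x$objective_bw))
  cat("\n")
  invisible(x)
}

#' Map the feasible wrench space on a grid
#'
#' Evaluates [check_feasible()] on a 3D grid of (F_x, F_y, T_z) at a fixed
#' squeeze force. Slicing the result at fixed T_z gives the 2D force-plane
#' cross-sections of the stable region; the region grows with squeeze
#' force and with friction, and rotates with the landing angle.
#'
#' @param layout a [contact_layout()].
#' @param F_x_bw,F_y_bw,T_z_bwmm grid coordinate vectors.
#' @param F_sqz_bw squeeze force, bw.
#' @return object of class `wrench_space`: `grid` (tidy data.frame with
#'   `F_x`, `F_y`, `T_z`, `feasible`), `volume` (logical array
#'   len(Fx) x len(Fy) x len(Tz)), and the axes.
#' @export
wrench_space <- function(layout, F_x_bw, F_y_bw, T_z_bwmm = 0,
                         F_sqz_bw = 0) {
  stopifnot(inherits(layout, "contact_layout"))
  grid <- expand.grid(F_x = F_x_bw, F_y = F_y_bw, T_z = T_z_bwmm,
                      KEEP.OUT.ATTRS = FALSE)
  feas <- vapply(seq_len(nrow(grid)), function(i) {
    check_feasible(layout,
                   wrench_query(grid$F_x[i], grid$F_y[i], grid$T_z[i],
                                F_sqz_bw))$feasible
  }, logical(1))
  grid$feasible <- feas
  structure(
    list(grid = grid,
         volume = array(feas, dim = c(length(F_x_bw), length(F_y_bw),
                                      length(T_z_bwmm))),
         F_x_bw = F_x_bw, F_y_bw = F_y_bw, T_z_bwmm = T_z_bwmm,
         F_sqz_bw = F_sqz_bw),
    class = "wrench_space")
}

#' Directional safety margin of a feasible wrench
#'
#' How much additional load along a body-frame direction the grasp could
#' sustain before leaving the feasible wrench set, found by bisection on
#' the added magnitude. `SM_x` and `SM_T` take the minimum over the + and
#' - senses; `SM_y` is searched along +b_y only (away from the perch:
#' pulling off is the failure mode of interest, since pushing into the
#' perch only loads the normals).
#'
#' @param layout a [contact_layout()].
#' @param query a [wrench_query()]; if itself infeasible the margin is
#'   reported as 0 with `query_feasible = FALSE`.
#' @param direction `"x"`, `"y"`, or `"T"`.
#' @param tol bisection tolerance, bw (or bw mm for `"T"`).
#' @param cap search cap; a margin still feasible at the cap is reported
#'   as the cap with `unbounded = TRUE`.
#' @return object of class `safety_margin`: `margin`, `direction`,
#'   `query_feasible`, `unbounded`.
#' @export
safety_margin <- function(layout, query, direction = c("x", "y", "T"),
                          tol = 1e-3, cap = 20) {
  direction <- match.arg(direction)
  base <- check_feasible(layout, query)
  if (!base$feasible) {
    return(structure(
      list(margin = 0, direction = direction, query_feasible = FALSE,
           unbounded = FALSE),
      class = "safety_margin"))
  }
  g <- layout_geometry(layout)
  probe <- function(dirvec, amount) {
    q2 <- wrench_query(query$F_x + amount * dirvec[1L],
                       query$F_y + amount * dirvec[2L],
                       query$T_z + amount * dirvec[3L],
                       query$F_sqz)
    check_feasible(layout, q2)$feasible
  }
  senses <- switch(direction,
    x = list(c(g$b_x, 0), c(-g$b_x, 0)),
    y = list(c(g$b_y, 0)),
    T = list(c(0, 0, 1), c(0, 0, -1)))
  margins <- vapply(senses, function(d) {
    if (probe(d, cap)) return(Inf)
    lo <- 0; hi <- cap
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (probe(d, mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  m <- min(margins)
  structure(
    list(margin = if (is.finite(m)) m else cap, direction = direction,
         query_feasible = TRUE, unbounded = !is.finite(m)),
    class = "safety_margin")
}

#' @export
print.safety_margin <- function(x, ...) {
  cat(sprintf("<safety_margin> SM_%s = %.4g%s%s\n", x$direction, x$margin,
              if (x$unbounded) " (search cap reached)" else "",
              if (x$query_feasible) "" else " (query itself infeasible)"))
  invisible(x)
}

#' Safety margins along a landing force trace
#'
#' Computes SM_x, SM_y and SM_T for each time step of a landing force
#' trace (F_x, F_y, T_z, F_sqz). Margins are meaningful only while all
#' claws are in contact; rows where `claws_in_contact` is `FALSE` get NA.
#'
#' @param layout a [contact_layout()].
#' @param trace data.frame with columns `time_s`, `force_x_bw`,
#'   `force_y_bw`, `torque_z_bwmm`, `squeeze_bw`.
#' @param claws_in_contact logical vector (default all `TRUE`).
#' @param ... passed to [safety_margin()].
#' @return data.frame with `time_s`, `SM_x`, `SM_y`, `SM_T`,
#'   `query_feasible`.
#' @export
margin_trace <- function(layout, trace, claws_in_contact = NULL, ...) {
  need <- c("time_s", "force_x_bw", "force_y_bw", "torque_z_bwmm",
            "squeeze_bw")
  stopifnot(all(need %in% names(trace)))
  n <- nrow(trace)
  if (is.null(claws_in_contact)) claws_in_contact <- rep(TRUE, n)
  out <- data.frame(time_s = trace$time_s, SM_x = NA_real_,
                    SM_y = NA_real_, SM_T = NA_real_,
                    query_feasible = NA)
  for (i in seq_len(n)) {
    if (!claws_in_contact[i]) next
    q <- wrench_query(trace$force_x_bw[i], trace$force_y_bw[i],
                      trace$torque_z_bwmm[i], max(0, trace$squeeze_bw[i]))
    mx <- safety_margin(layout, q, "x", ...)
    my <- safety_margin(layout, q, "y", ...)
    mt <- safety_margin(layout, q, "T", ...)
    out$SM_x[i] <- mx$margin
    out$SM_y[i] <- my$margin
    out$SM_T[i] <- mt$margin
    out$query_feasible[i] <- mx$query_feasible
  }
  out
}
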