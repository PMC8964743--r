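# Lower leg trajectory engine: resolve the lower-leg pose for each stance
# load case from the deformed foot and the ground-contact constraints, and
# evaluate the trajectory-error metric.
#
# Sign conventions (one table):
#   theta_shank  deg, + when the knee is anterior to the ankle
#   phi          foot orientation; user-facing value in deg equals
#                theta_shank for the rigidly attached shank; internally the
#                counterclockwise lab rotation phi_ccw = -theta (radians)
#   knee moment  N m, + counterclockwise with +x the walking direction
#
# Calibration pose: with the foot flat on the ground and unloaded, the knee
# point lies on the vertical through the ankle at `lower_leg_length` above
# the ground (the virtual-marker definition used in gait analysis).

rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)

# deformed bottom-fibre points of the sole chain, foot frame
deformed_sole_bottom <- function(mesh, state) {
  idx <- mesh$sole_nodes
  rot <- state$u[idx, 3L]
  off <- mesh$sole_offset
  cbind(state$node_pos[idx, 1L] + cos(rot) * off[, 1L] - sin(rot) * off[, 2L],
        state$node_pos[idx, 2L] + sin(rot) * off[, 1L] + cos(rot) * off[, 2L])
}

# tangent angle of a chain at position k (central difference)
chain_tangent_angle <- function(pts, k) {
  n <- nrow(pts)
  a <- max(1L, k - 1L); b <- min(n, k + 1L)
  d <- pts[b, ] - pts[a, ]
  atan2(d[2L], d[1L])
}

failed_pose <- function(case) {
  structure(list(knee_x = NA_real_, knee_y = NA_real_,
                 theta_shank = NA_real_, phi = NA_real_,
                 regime = case$regime, converged = FALSE,
                 state = NULL),
            class = "lower_leg_pose")
}

make_pose <- function(phi_ccw, knee, case, state) {
  structure(list(knee_x = knee[1L], knee_y = knee[2L],
                 theta_shank = -phi_ccw * 180 / pi,
                 phi = -phi_ccw * 180 / pi,
                 regime = case$regime, converged = TRUE,
                 state = state),
            class = "lower_leg_pose")
}

#' @export
print.lower_leg_pose <- function(x, ...) {
  if (!x$converged) cat("Lower leg pose: FAILED (", x$regime, ")\n")
  else cat(sprintf("Lower leg pose [%s]: knee (%.3f, %.3f) m, theta %.2f deg\n",
                   x$regime, x$knee_x, x$knee_y, x$theta_shank))
  invisible(x)
}

# knee position from the attachment frame: the foot frame (origin at the C1
# attachment, knee at (0, L_leg - h_ank) above it) is rotated by phi_ccw and
# translated so the sole reference point p_ref lands at (cop_x, 0) on the
# ground.
knee_from_attachment <- function(phi_ccw, p_ref, cop_x, lower_leg_length,
                                 h_ank) {
  drop(rot2(phi_ccw) %*% (c(0, lower_leg_length - h_ank) - p_ref)) +
    c(cop_x, 0)
}

#' Resolve the lower-leg pose for a flat-contact stance instance
#'
#' During mid-stance the foot orientation follows from requiring the
#' deformed sole to be tangent to the ground at the CoP under a no-slip
#' condition: the GRF (rotated into the foot frame) is applied at the sole
#' node nearest the CoP station, the structure is solved, and the foot
#' orientation is iterated until the lab-frame sole tangent at the loaded
#' node is horizontal (tolerance 1e-4 rad).  The lower leg then follows
#' rigidly from the attachment frame, positioned so the deformed contact
#' point sits at the CoP on the ground; for an undeformable foot the pose
#' reduces to pure rigid-rolling kinematics of the sole profile.
#'
#' @param mesh A [mesh_geometry()] result (carries its `foot_design`).
#' @param mat A [material()].
#' @param case A flat-contact `load_case` from [resample_stance()].
#' @param lower_leg_length User lower leg length, m.
#' @param opts [solver_options()].
#' @param warm_start Starting foot orientation, deg (dorsiflexion +);
#'   default from the case's reference shank angle.
#' @param tol_tangency Tangency tolerance, rad.
#' @return A `lower_leg_pose` (with `converged = FALSE` on failure).
#' @export
solve_flat_contact_pose <- function(mesh, mat, case, lower_leg_length,
                                    opts = solver_options(),
                                    warm_start = NULL,
                                    tol_tangency = 1e-4) {
  h <- mesh$design$h_ank
  phi <- if (is.null(warm_start)) case$theta_shank * pi / 180 * -1
         else -warm_start * pi / 180
  ln <- sole_node_at(mesh, case$cop_x)
  kpos <- which(mesh$sole_nodes == ln)
  state <- NULL
  for (it in seq_len(30L)) {
    Ff <- drop(rot2(-phi) %*% case$grf)
    state <- solve_quasi_static(mesh, mat, point_load(Ff, node = ln), opts)
    if (!state$converged) return(failed_pose(case))
    bottom <- deformed_sole_bottom(mesh, state)
    tau <- chain_tangent_angle(bottom, kpos)
    if (abs(phi + tau) < tol_tangency) break
    phi <- -tau
    if (it == 30L) return(failed_pose(case))
  }
  p_ref <- bottom[kpos, ]           # deformed contact point
  knee <- knee_from_attachment(phi, p_ref, case$cop_x, lower_leg_length, h)
  make_pose(phi, knee, case, state)
}

#' Moment residual of a line-contact pose
#'
#' For a trial foot orientation, solves the structure with the GRF at the
#' pivot node, places the deformed pivot at the CoP, and returns the
#' difference between the knee moment implied by the resulting pose and the
#' reference knee moment of the case.  The line-contact pose is the root of
#' this residual in the foot orientation.
#'
#' @param phi_deg Trial foot orientation, deg (dorsiflexion +).
#' @inheritParams solve_flat_contact_pose
#' @param pivot `"heel"` or `"toe"`.
#' @return List with `residual` (N m) and the pose.
#' @export
line_contact_residual <- function(mesh, mat, case, pivot, phi_deg,
                                  lower_leg_length,
                                  opts = solver_options()) {
  h <- mesh$design$h_ank
  phi <- -phi_deg * pi / 180
  pn <- sole_node_at(mesh, case$cop_x)
  kpos <- which(mesh$sole_nodes == pn)
  Ff <- drop(rot2(-phi) %*% case$grf)
  state <- solve_quasi_static(mesh, mat, point_load(Ff, node = pn), opts)
  if (!state$converged) return(list(residual = NA_real_, pose = failed_pose(case)))
  bottom <- deformed_sole_bottom(mesh, state)
  p_def <- bottom[kpos, ]
  knee <- knee_from_attachment(phi, p_def, case$cop_x, lower_leg_length, h)
  M <- knee_moment_from_kinetics(knee, case$grf, case$cop_x)
  list(residual = M - case$knee_moment, pose = make_pose(phi, knee, case, state))
}

#' Resolve the lower-leg pose for a heel- or toe-contact instance
#'
#' At heel strike and toe off the foot is in line contact with the ground
#' and the lower leg system rotates about the stationary CoP; the CoP and
#' GRF alone leave the foot orientation free, so the reference knee moment
#' is applied as the additional constraint.  The orientation is found by
#' root-finding on the moment residual ([line_contact_residual()]): the
#' bracket is grown outward from the warm start (up to +/-45 deg) until the
#' residual changes sign, then polished; the returned residual is below
#' 0.1 N m.
#'
#' @inheritParams solve_flat_contact_pose
#' @param pivot `"heel"` or `"toe"`.
#' @param warm_start Starting orientation, deg; defaults to the case's
#'   reference shank angle.
#' @return A `lower_leg_pose`.
#' @export
solve_line_contact_pose <- function(mesh, mat, case, pivot = c("heel", "toe"),
                                    lower_leg_length,
                                    opts = solver_options(),
                                    warm_start = NULL) {
  pivot <- match.arg(pivot)
  phi0 <- if (is.null(warm_start)) case$theta_shank else warm_start
  r <- function(p) line_contact_residual(mesh, mat, case, pivot, p,
                                         lower_leg_length, opts)$residual
  r0 <- r(phi0)
  if (!is.finite(r0)) return(failed_pose(case))
  if (abs(r0) < 0.1) {
    return(line_contact_residual(mesh, mat, case, pivot, phi0,
                                 lower_leg_length, opts)$pose)
  }
  # expanding bracket around the warm start
  lo <- hi <- phi0; rlo <- rhi <- r0; h <- 2
  found <- FALSE
  while (h <= 64) {
    for (side in c(-1, 1)) {
      p <- phi0 + side * h
      if (abs(p - phi0) > 45) next
      rp <- r(p)
      if (!is.finite(rp)) next
      if (sign(rp) != sign(r0)) {
        if (side < 0) { lo <- p; rlo <- rp; hi <- phi0; rhi <- r0 }
        else          { hi <- p; rhi <- rp; lo <- phi0; rlo <- r0 }
        found <- TRUE
      }
      if (found) break
    }
    if (found) break
    h <- h * 2
  }
  if (!found) return(failed_pose(case))
  root <- stats::uniroot(r, lower = min(lo, hi), upper = max(lo, hi),
                         f.lower = if (lo < hi) rlo else rhi,
                         f.upper = if (lo < hi) rhi else rlo,
                         tol = 1e-4)$root
  out <- line_contact_residual(mesh, mat, case, pivot, root,
                               lower_leg_length, opts)
  if (!is.finite(out$residual) || abs(out$residual) > 0.1)
    return(failed_pose(case))
  out$pose
}

#' Compute the model lower-leg trajectory over stance load cases
#'
#' Dispatches each stance instance to the pose solver matching its contact
#' regime (flat tangency during mid-stance, moment-constrained line contact
#' at heel strike and toe off), warm-starting each solve from the previous
#' instance, and records the peak combined stress per case.  Infeasible or
#' unconverged instances are flagged rather than raised, so an optimizer
#' can penalise them.
#'
#' @param design A `foot_design` (finite-element path) or `analytic_foot`
#'   (closed-form path).
#' @param mat A [material()].
#' @param cases Load cases from [resample_stance()].
#' @param user A [user_characteristics()].
#' @param ... Passed on to methods.
#' @return An object of class `llte_trajectory`: data frame of poses
#'   (stance percent, knee coordinates, shank angle, foot orientation,
#'   convergence flag, max combined stress) with the design attached.
#' @export
compute_trajectory <- function(design, mat, cases, user, ...) {
  UseMethod("compute_trajectory")
}

#' @rdname compute_trajectory
#' @param n_elements,width Meshing controls for the finite-element path.
#' @param opts [solver_options()].
#' @export
compute_trajectory.foot_design <- function(design, mat, cases, user,
                                           n_elements = 60L, width = 0.06,
                                           opts = solver_options(), ...) {
  geom <- evaluate_geometry(design)
  if (check_self_intersection(geom)$violated)
    stop("design is self-intersecting; cannot mesh")
  mesh <- mesh_geometry(geom, n_elements = n_elements, width = width)
  ord <- order(vapply(cases, `[[`, numeric(1L), "stance_percent"))
  cases <- cases[ord]
  L <- user$lower_leg_length
  warm <- NULL
  rows <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    pose <- switch(cs$regime,
      flat_contact = solve_flat_contact_pose(mesh, mat, cs, L, opts,
                                             warm_start = warm),
      heel_line_contact = solve_line_contact_pose(mesh, mat, cs, "heel", L,
                                                  opts, warm_start = warm),
      toe_line_contact = solve_line_contact_pose(mesh, mat, cs, "toe", L,
                                                 opts, warm_start = warm))
    ms <- if (pose$converged)
      max_stress(recover_stresses(mesh, mat, pose$state)) else NA_real_
    if (pose$converged) warm <- pose$theta_shank
    rows[[i]] <- data.frame(stance_percent = cs$stance_percent,
                            knee_x = pose$knee_x, knee_y = pose$knee_y,
                            theta_shank = pose$theta_shank, phi = pose$phi,
                            regime = cs$regime, converged = pose$converged,
                            max_stress = ms)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("llte_trajectory", "data.frame"),
            design = design, user = user)
}

#' @export
print.llte_trajectory <- function(x, ...) {
  cat(sprintf("Lower-leg trajectory: %d stance instances, %d converged, max stress %.1f MPa\n",
              nrow(x), sum(x$converged),
              max(x$max_stress, na.rm = TRUE) / 1e6))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
plot.llte_trajectory <- function(x, ref = NULL, ...) {
  graphics::plot(x$knee_x, x$knee_y, type = "b", pch = 16, col = "firebrick",
                 xlab = "knee x [m]", ylab = "knee y [m]", ...)
  if (!is.null(ref))
    graphics::lines(ref$knee_x, ref$knee_y, col = "grey30")
  invisible(x)
}

#' Lower leg trajectory error of a model trajectory against a reference
#'
#' The scalar design objective: the root of the mean, over the N included
#' stance instances, of the squared knee-coordinate and shank-angle
#' deviations between model and reference, each normalized by the mean
#' absolute value of the corresponding reference variable over the portion
#' of the step considered.  Failed (unconverged) instances contribute a
#' squared penalty term of 10^2 so infeasible designs rank behind any
#' feasible one.
#'
#' @param model An `llte_trajectory`.
#' @param ref A [reference_gait()].
#' @param percents Stance percents to include; default the model's.
#' @param failure_penalty Squared-term value added per failed frame.
#' @return An object of class `llte_value`: `value`, per-frame term matrix,
#'   `N` and the three normalizers.
#' @export
compute_llte <- function(model, ref, percents = NULL, failure_penalty = 100) {
  if (is.null(percents)) percents <- model$stance_percent
  ip <- function(ch) stats::approx(ref$stance_percent, ch, xout = percents)$y
  rx <- ip(ref$knee_x); ry <- ip(ref$knee_y); rt <- ip(ref$theta_shank)
  xbar <- mean(abs(rx)); ybar <- mean(abs(ry)); tbar <- mean(abs(rt))
  if (any(c(xbar, ybar, tbar) < 1e-12))
    stop("degenerate reference: zero normalizer")
  m <- model[match(percents, model$stance_percent), , drop = FALSE]
  terms <- cbind(x = ((m$knee_x - rx) / xbar)^2,
                 y = ((m$knee_y - ry) / ybar)^2,
                 theta = ((m$theta_shank - rt) / tbar)^2)
  failed <- !m$converged | !is.finite(rowSums(terms))
  frame_sum <- ifelse(failed, failure_penalty, rowSums(terms))
  structure(list(value = sqrt(mean(frame_sum)),
                 per_frame = terms, failed = failed,
                 N = length(percents),
                 normalizers = c(x_bar = xbar, y_bar = ybar,
                                 theta_bar = tbar)),
            class = "llte_value")
}

#' @export
print.llte_value <- function(x, ...) {
  cat(sprintf("LLTE value: %.4f over %d stance instances (%d failed)\n",
              x$value, x$N, sum(x$failed)))
  invisible(x)
}

#' Predict the lower-leg trajectory from measured kinetics
#'
#' Runs the constitutive model on measured (rather than published
#' reference) kinetics: the measured GRF, CoP and knee-moment series are
#' resampled at the requested stance percents and pushed through the same
#' trajectory machinery, giving the model-predicted lower leg trajectory
#' that in-vivo validation compares against motion capture.
#'
#' @param design A `foot_design` or `analytic_foot`.
#' @param mat A [material()].
#' @param measured A [reference_gait()] built from measured kinetics.
#' @param user A [user_characteristics()].
#' @param percents Stance percents, default the nine representative ones.
#' @param ... Passed to [compute_trajectory()].
#' @return An `llte_trajectory`.
#' @export
predict_trajectory_from_measured <- function(design, mat, measured, user,
                                             percents = default_stance_percents(),
                                             ...) {
  cases <- resample_stance(measured, percents)
  compute_trajectory(design, mat, cases, user, ...)
}

#' Per-channel mean absolute error between two trajectories
#'
#' @param predicted,measured `llte_trajectory`-like data frames sharing
#'   stance percents (columns `knee_x`, `knee_y`, `theta_shank`).
#' @return Named vector: mean absolute error of knee x (m), knee y (m) and
#'   shank angle (deg).
#' @export
trajectory_rmse <- function(predicted, measured) {
  m <- measured[match(predicted$stance_percent, measured$stance_percent), ]
  c(knee_x = mean(abs(predicted$knee_x - m$knee_x)),
    knee_y = mean(abs(predicted$knee_y - m$knee_y)),
    theta_shank = mean(abs(predicted$theta_shank - m$theta_shank)))
}

# ---- analytic foot model ---------------------------------------------------

#' Analytic two-beam foot model
#'
#' A low-dimensional closed-form foot: a rigid flat sole with the keel
#' (forefoot) and heel acting as cantilever arms of lumped bending
#' stiffness.  Under a flat-contact load at lever arm d from the ankle the
#' sole slope at the CoP is F_y d^2 / (2 EI) of the loaded arm, which sets
#' the foot orientation directly; line-contact instances pivot rigidly and
#' are resolved from the knee moment.  Used for instance-set studies and
#' optimizer verification where thousands of evaluations are needed.
#'
#' @param user A [user_characteristics()].
#' @param keel_scale,heel_scale Thickness scale factors on the nominal
#'   arms (stiffness scales with the cube).
#' @param keel_thickness,heel_thickness Nominal arm thicknesses, m.
#' @param width Out-of-plane width, m.
#' @param E_f Flexural modulus, Pa (defaults to Nylon 6/6).
#' @return An object of class `analytic_foot`.
#' @export
analytic_foot <- function(user, keel_scale = 1, heel_scale = 1,
                          keel_thickness = 0.012, heel_thickness = 0.008,
                          width = 0.06, E_f = 3.15e9) {
  if (keel_scale <= 0 || heel_scale <= 0)
    stop("thickness scales must be positive")
  tk <- keel_thickness * keel_scale
  th <- heel_thickness * heel_scale
  structure(list(EI_keel = E_f * width * tk^3 / 12,
                 EI_heel = E_f * width * th^3 / 12,
                 keel_thickness = tk, heel_thickness = th,
                 keel_scale = keel_scale, heel_scale = heel_scale,
                 width = width, E_f = E_f,
                 h_ank = user$build_height_h_ank,
                 L_foot = user$foot_length,
                 ankle_fraction = 0.25),
            class = "analytic_foot")
}

#' @export
print.analytic_foot <- function(x, ...) {
  cat(sprintf("Analytic foot: EI keel %.2f N m2 (t %.1f mm), EI heel %.2f N m2 (t %.1f mm)\n",
              x$EI_keel, 1000 * x$keel_thickness, x$EI_heel,
              1000 * x$heel_thickness))
  invisible(x)
}

analytic_flat_pose <- function(foot, case, L) {
  d <- case$cop_x
  EI <- if (d >= 0) foot$EI_keel else foot$EI_heel
  psi <- sign(d) * case$grf[2L] * d^2 / (2 * EI)   # rad, + knee anterior
  # contact point at the CoP: knee = R(-psi) (-d, L) + (cop, 0)
  c(knee_x = d * (1 - cos(psi)) + L * sin(psi),
    knee_y = L * cos(psi) + d * sin(psi),
    theta = psi * 180 / pi)
}

analytic_line_pose <- function(foot, case, L) {
  xp <- max(-foot$ankle_fraction * foot$L_foot,
            min((1 - foot$ankle_fraction) * foot$L_foot, case$cop_x))
  EI <- if (xp >= 0) foot$EI_keel else foot$EI_heel
  resid <- function(phi_ccw) {
    # pivot arm bends under the transverse (foot-frame) load component
    Fyf <- drop(rot2(-phi_ccw) %*% case$grf)[2L]
    delta <- Fyf * abs(xp)^3 / (3 * EI)
    knee <- drop(rot2(phi_ccw) %*% c(-xp, L - delta)) + c(case$cop_x, 0)
    knee_moment_from_kinetics(knee, case$grf, case$cop_x) - case$knee_moment
  }
  warm <- -case$theta_shank * pi / 180
  lo <- warm - pi / 4; hi <- warm + pi / 4
  rl <- resid(lo); rh <- resid(hi)
  if (!is.finite(rl) || !is.finite(rh) || sign(rl) == sign(rh))
    return(c(knee_x = NA_real_, knee_y = NA_real_, theta = NA_real_))
  phi <- stats::uniroot(resid, lower = lo, upper = hi, tol = 1e-9)$root
  Fyf <- drop(rot2(-phi) %*% case$grf)[2L]
  delta <- Fyf * abs(xp)^3 / (3 * EI)
  knee <- drop(rot2(phi) %*% c(-xp, L - delta)) + c(case$cop_x, 0)
  c(knee_x = knee[1L], knee_y = knee[2L], theta = -phi * 180 / pi)
}

#' @rdname compute_trajectory
#' @export
compute_trajectory.analytic_foot <- function(design, mat = NULL, cases, user,
                                             ...) {
  L <- user$lower_leg_length
  ord <- order(vapply(cases, `[[`, numeric(1L), "stance_percent"))
  cases <- cases[ord]
  rows <- lapply(cases, function(cs) {
    p <- if (cs$regime == "flat_contact") analytic_flat_pose(design, cs, L)
         else analytic_line_pose(design, cs, L)
    d <- cs$cop_x
    arm <- if (d >= 0) "keel" else "heel"
    t_a <- if (arm == "keel") design$keel_thickness else design$heel_thickness
    I_a <- design$width * t_a^3 / 12
    sigma <- abs(cs$grf[2L] * d) * (t_a / 2) / I_a
    data.frame(stance_percent = cs$stance_percent,
               knee_x = p[["knee_x"]], knee_y = p[["knee_y"]],
               theta_shank = p[["theta"]], phi = p[["theta"]],
               regime = cs$regime, converged = is.finite(p[["knee_x"]]),
               max_stress = sigma)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("llte_trajectory", "data.frame"),
            design = design, user = user)
}
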