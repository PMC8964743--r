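# Shared fixtures: reference gaits, users, designs and independent oracles.

default_user <- function()
  user_characteristics(70, 0.26, 0.50, residuum_length = 0.15,
                       build_height_h_ank = 0.07)

ref_gait <- function(seed = 1L) synthesize_reference_gait(gait_config(), seed)

# flat-soled design: forefoot/heel share the C4 diameter, so the unloaded
# bottom fibre is the straight line y = -h_ank
flat_sole_design <- function(d_sole = 0.016)
  complete_design(c(C1.d = 0.030, C2.x = 0.005, C2.y = -0.020, C2.d = 0.024,
                    C3.x = 0.020, C3.y = -0.045, C3.d = 0.020, C4.x = 0.030,
                    C4.d = d_sole, C5.d = d_sole, C6.d = d_sole),
                  default_user())

# Nylon 6/6 stiffened by 1e6: a practically undeformable foot
near_rigid_material <- function()
  material(2.51e15, 82.7e6, 3.15e15, 92.0e6, 0.41, 1130)

# geometry-only rigid-rolling pose oracle for a flat-soled foot (no FEA):
# flat contact -> the sole contact point at the CoP, foot unrotated;
# line contact -> rigid pivot at the CoP-station sole point, orientation
# from the knee-moment balance.
rigid_pose_oracle <- function(mesh, case, lower_leg_length) {
  h <- mesh$design$h_ank
  sole_x <- mesh$nodes[mesh$sole_nodes, 1L]
  xp <- sole_x[which.min(abs(sole_x - case$cop_x))]
  p <- c(xp, -h)   # flat sole: bottom fibre at -h_ank
  knee_at <- function(phi_ccw)
    drop(rot2_test(phi_ccw) %*% (c(0, lower_leg_length - h) - p)) +
      c(case$cop_x, 0)
  if (case$regime == "flat_contact") {
    knee <- knee_at(0)
    return(c(knee_x = knee[1L], knee_y = knee[2L], theta = 0))
  }
  resid <- function(phi_ccw) {
    knee <- knee_at(phi_ccw)
    knee_moment_from_kinetics(knee, case$grf, case$cop_x) - case$knee_moment
  }
  w <- -case$theta_shank * pi / 180
  phi <- stats::uniroot(resid, c(w - pi / 4, w + pi / 4), tol = 1e-12)$root
  knee <- knee_at(phi)
  c(knee_x = knee[1L], knee_y = knee[2L], theta = -phi * 180 / pi)
}

rot2_test <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)

count_interior_maxima <- function(y) sum(diff(sign(diff(y))) == -2)

cantilever <- function(n = 40L) straight_frame_mesh(0.25, n, 0.01, 0.06)

# elastica oracle: EI theta'' = -P cos(theta), theta(0) = 0, theta'(L) = 0,
# solved by RK4 shooting on the root moment
elastica_tip <- function(P, L, EI, n = 2000L) {
  shoot <- function(m0) {
    h <- L / n; th <- 0; v <- m0 / EI
    f <- function(th) -P / EI * cos(th)
    xs <- 0; ys <- 0
    for (i in seq_len(n)) {
      k1t <- v;             k1v <- f(th)
      k2t <- v + h / 2 * k1v; k2v <- f(th + h / 2 * k1t)
      k3t <- v + h / 2 * k2v; k3v <- f(th + h / 2 * k2t)
      k4t <- v + h * k3v;     k4v <- f(th + h * k3t)
      dth <- h / 6 * (k1t + 2 * k2t + 2 * k3t + k4t)
      xs <- xs + h * cos(th + dth / 2); ys <- ys + h * sin(th + dth / 2)
      th <- th + dth
      v <- v + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    }
    list(end_slope = v, tip_rot = th, tip_y = ys)
  }
  m0 <- stats::uniroot(function(m) shoot(m)$end_slope,
                       c(0.1 * P * L, 2 * P * L), tol = 1e-10)$root
  shoot(m0)
}

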