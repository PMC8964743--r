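# Synthetic marker + force-plate step recordings with known ground truth
# for every gait metric: a rigid-rocker rolling model for the stance-leg
# kinematics (so the roll-over shape is a circle of programmed radius and
# the rigid contact-point velocity vanishes), periodic GRF curves scaled to
# support body weight over a stride, and a free-moment channel programmed
# so the unified-deformable distal power integrates to the requested
# stored/returned elastic energy.

s6 <- function(u) 6 * u^5 - 15 * u^4 + 10 * u^3
s6p <- function(u) 30 * u^4 - 60 * u^3 + 30 * u^2

#' Configuration of the synthetic step-recording generator
#'
#' Defaults emulate the study population walking over-ground at
#' self-selected speed: 1.18 m/s, symmetric 0.65 s stance times over a
#' 1.05 s stride, 0.13 m step width, 6.6 deg trunk sway range, a 0.165 m
#' roll-over rocker under a 0.50 m lower leg (0.33 m/m), 0.21 J/kg of
#' elastic energy stored and returned by the foot, and 11.1 / 5.4 deg
#' dorsi/plantarflexion peaks.
#'
#' @param ... Overrides of the default fields.
#' @return Named list of generator parameters.
#' @export
step_config <- function(...) {
  cfg <- list(
    body_mass = 70, foot_length = 0.26, lower_leg_length = 0.50,
    leg_length = 0.90, h_ank = 0.08,
    speed = 1.18, stride_time = 1.05,
    stance_time_p = 0.65, stance_time_i = 0.65,
    step_width = 0.13, trunk_sway = 6.6,
    theta_start = -15, theta_end = 25,
    rocker_radius = 0.165,
    energy_stored = 0.21, energy_return = 0.21,
    peak_dorsiflexion = 11.1, peak_plantarflexion = 5.4,
    knee_marker_offset = 5,
    grf_peak1 = 1.15, grf_peak2 = 1.12, grf_peak_width = 0.14,
    grf_x_peak = 0.17,
    marker_rate = 120, force_rate = 960,
    marker_noise_sd = 1e-4, force_noise_sd = 2)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown step_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$energy_stored < 0 || cfg$energy_return < 0)
    stop("work budgets must be non-negative")
  if (any(unlist(cfg[c("body_mass", "foot_length", "lower_leg_length",
                       "leg_length", "speed", "stride_time",
                       "stance_time_p", "stance_time_i")]) <= 0))
    stop("body and timing parameters must be positive")
  cfg
}

# stance-leg pose at times t for a leg with contact schedule c0 + k T
leg_kinematics <- function(t, c0, cfg, X) {
  T <- cfg$stride_time
  th1 <- cfg$theta_start * pi / 180
  th2 <- cfg$theta_end * pi / 180
  rho <- cfg$rocker_radius
  h <- cfg$h_ank
  stance_pose <- function(tau, ck) {
    th <- th1 + (th2 - th1) * s6(tau)
    base <- cfg$speed * (ck + X / 2)
    cx <- base + rho * (th - th1)
    ankle_x <- cx - (rho - h) * sin(th)
    ankle_y <- rho - (rho - h) * cos(th)
    delta <- (-cfg$peak_plantarflexion * exp(-((tau - 0.15) / 0.12)^2) +
              cfg$peak_dorsiflexion * exp(-((tau - 0.70) / 0.18)^2)) *
      (1 - exp(-(tau / 0.05)^2)) * (1 - exp(-((1 - tau) / 0.05)^2))
    list(th = th, ankle_x = ankle_x, ankle_y = ankle_y, cop_x = cx,
         delta = delta)
  }
  k <- floor((t - c0) / T)
  ck <- c0 + k * T
  tau <- (t - ck) / X
  st <- tau <= 1
  out <- list(th = numeric(length(t)), ankle_x = numeric(length(t)),
              ankle_y = numeric(length(t)), cop_x = numeric(length(t)),
              delta = numeric(length(t)), stance = st, tau = tau)
  if (any(st)) {
    p <- stance_pose(tau[st], ck[st])
    for (nm in c("th", "ankle_x", "ankle_y", "cop_x", "delta"))
      out[[nm]][st] <- p[[nm]]
  }
  if (any(!st)) {
    uw <- (t[!st] - ck[!st] - X) / (T - X)
    pA <- stance_pose(1, ck[!st])
    pB <- stance_pose(0, ck[!st] + T)
    b <- s6(uw)
    out$th[!st] <- th2 + (th1 - th2) * b
    out$ankle_x[!st] <- pA$ankle_x + (pB$ankle_x - pA$ankle_x) * b
    out$ankle_y[!st] <- pA$ankle_y + (pB$ankle_y - pA$ankle_y) * b +
      0.05 * sin(pi * uw)^2
    out$cop_x[!st] <- pA$cop_x
    out$delta[!st] <- 0
  }
  out
}

leg_markers <- function(kin, z, cfg) {
  th <- kin$th
  off <- cfg$knee_marker_offset * pi / 180
  L <- cfg$lower_leg_length
  knee_x <- kin$ankle_x + L * sin(th + off)
  knee_y <- kin$ankle_y + L * cos(th + off)
  eta <- -th + kin$delta * pi / 180
  fm_x <- kin$ankle_x; fm_y <- kin$ankle_y - 0.05
  data.frame(
    knee_x = knee_x, knee_y = knee_y, knee_z = z,
    shank_x = (kin$ankle_x + knee_x) / 2,
    shank_y = (kin$ankle_y + knee_y) / 2, shank_z = z,
    ankle_x = kin$ankle_x, ankle_y = kin$ankle_y, ankle_z = z,
    heel_x = fm_x - 0.25 * cfg$foot_length * cos(eta),
    heel_y = fm_y - 0.25 * cfg$foot_length * sin(eta), heel_z = z,
    toe_x = fm_x + 0.75 * cfg$foot_length * cos(eta),
    toe_y = fm_y + 0.75 * cfg$foot_length * sin(eta), toe_z = z)
}

# per-leg GRF and free moment on the force timebase (noise-free)
leg_kinetics <- function(tf, c0, cfg, X) {
  T <- cfg$stride_time
  bw <- 9.81 * cfg$body_mass
  gy <- gx <- mf <- cop <- numeric(length(tf))
  th1 <- cfg$theta_start * pi / 180
  th2 <- cfg$theta_end * pi / 180
  dth <- th2 - th1
  gN <- function(u) exp(-((u - 0.35) / 0.10)^2)
  gP <- function(u) exp(-((u - 0.85) / 0.07)^2)
  ug <- seq(0, 1, length.out = 2001L)
  In <- X * trapz(ug, gN(ug) * s6p(ug))
  Ip <- X * trapz(ug, gP(ug) * s6p(ug))
  contacts <- c0 + (-2:3) * T
  for (ck in contacts) {
    sel <- tf >= ck & tf <= ck + X
    if (!any(sel)) next
    u <- (tf[sel] - ck) / X
    ends <- (1 - exp(-(u / 0.04)^2)) * (1 - exp(-((1 - u) / 0.04)^2))
    gy[sel] <- gy[sel] + bw * ends *
      (cfg$grf_peak1 * exp(-((u - 0.25) / cfg$grf_peak_width)^2) +
       cfg$grf_peak2 * exp(-((u - 0.76) / cfg$grf_peak_width)^2))
    gx[sel] <- gx[sel] - bw * cfg$grf_x_peak * sin(2 * pi * u) *
      sin(pi * u)^0.5
    # M_free = P* / omega with the s6' factors cancelled analytically
    mf[sel] <- mf[sel] - cfg$body_mass * X / dth *
      (-cfg$energy_stored * gN(u) / In + cfg$energy_return * gP(u) / Ip)
  }
  kin <- leg_kinematics(tf, c0, cfg, X)
  cop <- kin$cop_x
  list(grf_x = gx, grf_y = gy, free_moment = mf, cop_x = cop)
}

#' Synthesize a step recording with known ground truth
#'
#' Builds one stride (plus the start of the next prosthetic stance) of
#' marker trajectories at the kinematic rate and per-side force-plate
#' series at the kinetic rate.  The stance-leg kinematics roll a rigid
#' rocker of the programmed radius under the shank, the per-leg GRFs are
#' periodic double-peaked curves rescaled so their stride average supports
#' body weight, and the free moment encodes the programmed stored/returned
#' elastic energy through the unified-deformable power.  Gaussian
#' measurement noise is added to markers and forces; the programmed values
#' are attached as the `truth` attribute.
#'
#' @param config From [step_config()].
#' @param seed Integer seed; deterministic per seed.
#' @return A `step_recording` with attribute `truth`.
#' @export
synthesize_step_recording <- function(config = step_config(), seed = 1L) {
  cfg <- config
  T <- cfg$stride_time
  # pre-contact margin: makes the first contact a true detected event and
  # keeps zero-phase filter edge transients clear of the first stance
  lead_in <- 0.15
  D <- lead_in + T + 0.5 * cfg$stance_time_p
  tm <- seq(0, D, by = 1 / cfg$marker_rate)
  tf <- seq(0, D, by = 1 / cfg$force_rate)
  c0p <- lead_in; c0i <- lead_in + T / 2

  kin_p <- leg_kinematics(tm, c0p, cfg, cfg$stance_time_p)
  kin_i <- leg_kinematics(tm, c0i, cfg, cfg$stance_time_i)
  mk_p <- leg_markers(kin_p, cfg$step_width / 2, cfg)
  mk_i <- leg_markers(kin_i, -cfg$step_width / 2, cfg)
  rename_leg <- function(df, sfx) {
    nm <- names(df)
    names(df) <- sub("^([a-z]+)_([xyz])$", paste0("\\1_", sfx, "_\\2"), nm)
    df
  }
  mk_p <- rename_leg(mk_p, "p")
  mk_i <- rename_leg(mk_i, "i")

  k1 <- max(1L, round(D / T))
  sac_x <- 2 + cfg$speed * tm + 0.012 * sin(2 * pi * 2 * k1 * tm / D)
  sac_y <- 0.95 + 0.015 * sin(2 * pi * 2 * k1 * tm / D + 0.7)
  sac_z <- 0.008 * sin(2 * pi * k1 * tm / D)
  phi_r <- (cfg$trunk_sway / 2) * pi / 180 * sin(2 * pi * k1 * tm / D)
  shoulder <- function(s) {
    z0 <- s * 0.18; y0 <- 0.05
    data.frame(x = sac_x,
               y = sac_y + 0.45 + z0 * sin(phi_r) + y0 * cos(phi_r),
               z = sac_z + z0 * cos(phi_r) - y0 * sin(phi_r))
  }
  sl <- shoulder(+1); sr <- shoulder(-1)
  markers <- cbind(data.frame(time = tm,
                              sacrum_x = sac_x, sacrum_y = sac_y,
                              sacrum_z = sac_z,
                              shoulder_l_x = sl$x, shoulder_l_y = sl$y,
                              shoulder_l_z = sl$z,
                              shoulder_r_x = sr$x, shoulder_r_y = sr$y,
                              shoulder_r_z = sr$z),
                   mk_p, mk_i)

  fp_p <- leg_kinetics(tf, c0p, cfg, cfg$stance_time_p)
  fp_i <- leg_kinetics(tf, c0i, cfg, cfg$stance_time_i)
  # rescale vertical GRFs so the stride-average supports body weight
  # (rectangle sum over exactly one period = the exact periodic integral)
  stride_sel <- tf >= c0p & tf < c0p + T
  lam <- 9.81 * cfg$body_mass * sum(stride_sel) /
    sum(fp_p$grf_y[stride_sel] + fp_i$grf_y[stride_sel])
  fp_p$grf_y <- fp_p$grf_y * lam
  fp_i$grf_y <- fp_i$grf_y * lam

  # ground truth before noise: stance samples of the filtered clean series
  truth_windows <- function(gy) {
    gyf <- lowpass_filter(gy, cfg$force_rate, 12)
    detect_stance(gyf, cfg$force_rate)
  }
  truth <- list(
    walking_speed = cfg$speed,
    froude = froude_number(cfg$speed, cfg$leg_length),
    stance_times = c(prosthetic = cfg$stance_time_p,
                     intact = cfg$stance_time_i),
    symmetry_index = symmetry_index(cfg$stance_time_p, cfg$stance_time_i),
    step_width = cfg$step_width,
    trunk_sway_range = cfg$trunk_sway,
    rollover_radius_norm = cfg$rocker_radius / cfg$lower_leg_length,
    energy_return = cfg$energy_return,
    peak_dorsiflexion = cfg$peak_dorsiflexion,
    peak_plantarflexion = cfg$peak_plantarflexion,
    stance_samples = list(prosthetic = truth_windows(fp_p$grf_y),
                          intact = truth_windows(fp_i$grf_y)))
  # prosthetic-side pose at the opposite (intact) heel contact
  kin_half <- leg_kinematics(c0i, c0p, cfg, cfg$stance_time_p)
  heel0 <- leg_markers(leg_kinematics(c0p, c0p, cfg, cfg$stance_time_p), 0, cfg)$heel_x
  truth$eflr <- (kin_half$cop_x - heel0) / cfg$foot_length

  old <- .Random.seed_exists()
  set.seed(seed)
  noise <- function(n, sd) stats::rnorm(n, 0, sd)
  mcols <- setdiff(names(markers), "time")
  for (cc in mcols)
    markers[[cc]] <- markers[[cc]] + noise(length(tm), cfg$marker_noise_sd)
  plate <- function(fp) {
    data.frame(time = tf,
               grf_x = fp$grf_x + noise(length(tf), cfg$force_noise_sd),
               grf_y = pmax(0, fp$grf_y + noise(length(tf),
                                                cfg$force_noise_sd)),
               grf_z = noise(length(tf), cfg$force_noise_sd / 2),
               cop_x = fp$cop_x,
               free_moment = fp$free_moment)
  }
  out <- list(markers = markers,
              forceplate = list(prosthetic = plate(fp_p),
                                intact = plate(fp_i)),
              meta = list(body_mass = cfg$body_mass,
                          foot_length = cfg$foot_length,
                          lower_leg_length = cfg$lower_leg_length,
                          leg_length = cfg$leg_length,
                          marker_rate = cfg$marker_rate,
                          force_rate = cfg$force_rate))
  if (old$had) .Random.seed_restore(old)
  structure(out, class = "step_recording", truth = truth,
            config = cfg)
}

#' @export
print.step_recording <- function(x, ...) {
  cat(sprintf("Step recording: %.2f s, markers %d Hz, force plates %d Hz, %.1f kg subject\n",
              max(x$markers$time), x$meta$marker_rate, x$meta$force_rate,
              x$meta$body_mass))
  invisible(x)
}

#' Write / read a step recording as CSV + JSON
#'
#' The on-disk layout is a directory with `markers.csv` (kinematic rate),
#' `forceplate_prosthetic.csv`, `forceplate_intact.csv` (kinetic rate) and
#' `meta.json`.
#'
#' @param rec A `step_recording`.
#' @param dir Directory path.
#' @return `dir` (write) or a `step_recording` (read).
#' @export
write_step_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rec$markers, file.path(dir, "markers.csv"),
                   row.names = FALSE)
  utils::write.csv(rec$forceplate$prosthetic,
                   file.path(dir, "forceplate_prosthetic.csv"),
                   row.names = FALSE)
  utils::write.csv(rec$forceplate$intact,
                   file.path(dir, "forceplate_intact.csv"),
                   row.names = FALSE)
  jsonlite::write_json(rec$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_step_recording
#' @export
read_step_recording <- function(dir) {
  structure(list(
    markers = utils::read.csv(file.path(dir, "markers.csv")),
    forceplate = list(
      prosthetic = utils::read.csv(file.path(dir, "forceplate_prosthetic.csv")),
      intact = utils::read.csv(file.path(dir, "forceplate_intact.csv"))),
    meta = jsonlite::fromJSON(file.path(dir, "meta.json"))),
    class = "step_recording")
}
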