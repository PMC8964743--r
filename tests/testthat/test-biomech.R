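# Gait-analysis layer: filtering, event detection, spatiotemporal and
# angular parameters, roll-over geometry, foot power and CoM work,
# deviation scores, and the synthetic recording generator.

test_that("the zero-phase Butterworth filter matches its analytic response", {
  fs <- 120
  t <- seq(0, 5, by = 1 / fs)
  expect_lt(max(abs(lowpass_filter(rep(3.2, length(t)), fs, 6) - 3.2)), 1e-9)

  s1 <- sin(2 * pi * 1 * t)
  f1 <- lowpass_filter(s1, fs, 6)
  mid <- t > 1 & t < 4
  expect_equal(max(abs(f1[mid])), 1, tolerance = 0.01)
  # phase shift below 0.5 deg: peak of the cross-correlation at zero lag
  lag <- which.max(stats::ccf(f1[mid], s1[mid], lag.max = 5,
                              plot = FALSE)$acf) - 6L
  expect_equal(lag, 0L)

  s30 <- sin(2 * pi * 30 * t)
  f30 <- lowpass_filter(s30, fs, 6)
  expect_lt(max(abs(f30[mid])), 0.01)   # >= 99% attenuation at 5x cutoff

  expect_error(lowpass_filter(s1, fs, 60), "Nyquist")
})

test_that("stance detection thresholds, merges chatter and matches truth", {
  expect_equal(nrow(detect_stance(rep(0, 1000), 960)), 0L)
  expect_equal(nrow(detect_stance(rep(39, 1000), 960)), 0L)
  one <- detect_stance(rep(41, 1000), 960)
  expect_equal(unname(unlist(one)), c(1L, 1000L))
  # sub-10 ms chatter is merged away
  g <- rep(100, 960)
  g[400:404] <- 0          # 5 ms dropout
  expect_equal(nrow(detect_stance(g, 960)), 1L)
  g2 <- rep(0, 960); g2[500:503] <- 100   # 4 ms blip
  expect_equal(nrow(detect_stance(g2, 960)), 0L)

  rec <- synthesize_step_recording(step_config(), 4L)
  truth <- attr(rec, "truth")
  for (side in c("prosthetic", "intact")) {
    gy <- lowpass_filter(rec$forceplate[[side]]$grf_y, 960, 12)
    got <- detect_stance(gy, 960)
    expect_equal(nrow(got), nrow(truth$stance_samples[[side]]))
    expect_true(all(abs(got$start - truth$stance_samples[[side]]$start) <= 1))
    expect_true(all(abs(got$end - truth$stance_samples[[side]]$end) <= 1))
  }
})

test_that("stance normalization is affine-exact and idempotent", {
  ramp <- seq(2, 10, length.out = 481)
  out <- normalize_to_stance(ramp, c(1, 481), n_points = 100)
  expect_equal(out[1L], 2); expect_equal(out[100L], 10)
  expect_equal(as.numeric(out), seq(2, 10, length.out = 100))
  again <- normalize_to_stance(out, c(1, 100), n_points = 100)
  expect_equal(as.numeric(again), as.numeric(out), tolerance = 1e-12)
  expect_error(normalize_to_stance(ramp, c(5, 5)), "at least 2")
})

test_that("virtual knee correction is a rigid rotation about the ankle", {
  t <- seq(0, 1, by = 1 / 120)
  ankle <- cbind(0.1 * t, 0.08 + 0 * t)
  th <- (-10 + 30 * t) * pi / 180
  off <- 10 * pi / 180
  knee <- ankle + 0.45 * cbind(sin(th + off), cos(th + off))
  # calibration frame where th = 0
  cal <- which.min(abs(th))
  th[cal] <- 0
  knee[cal, ] <- ankle[cal, ] + 0.45 * c(sin(off), cos(off))
  corr <- virtual_knee_correction(knee, ankle, cal)
  expect_equal(corr[cal, ], ankle[cal, ] + c(0, 0.45), tolerance = 1e-12)
  # corrected = measured rotated by -offset about the ankle, rigidly
  expected <- ankle + 0.45 * cbind(sin(th), cos(th))
  expect_equal(corr, expected, tolerance = 1e-9)
  d <- sqrt(rowSums((corr - ankle)^2))
  expect_lt(diff(range(d)), 1e-9)
  # already vertical at calibration: identity
  knee_v <- ankle + 0.45 * cbind(sin(th), cos(th))
  expect_equal(virtual_knee_correction(knee_v, ankle, cal), knee_v,
               tolerance = 1e-12)
})

test_that("symmetry index and Froude number match their closed forms", {
  expect_equal(symmetry_index(0.62, 0.62), 100)
  expect_equal(symmetry_index(0.60, 0.66), 100 * (1 - 0.06 / 0.63))
  expect_equal(symmetry_index(0.60, 0.66), 90.47619, tolerance = 1e-6)
  expect_error(symmetry_index(0.5, -0.5), "undefined")
  expect_equal(froude_number(1.2, 0.9), 1.44 / (9.81 * 0.9))
  expect_equal(froude_number(1.2, 0.9), 0.16310, tolerance = 1e-4)
})

test_that("spatiotemporal parameters recover the programmed gait", {
  rec <- synthesize_step_recording(step_config(), 2L)
  truth <- attr(rec, "truth")
  sp <- spatiotemporal(rec)
  expect_equal(sp$walking_speed, truth$walking_speed, tolerance = 0.01)
  expect_equal(sp$froude, truth$froude, tolerance = 0.01)
  expect_equal(sp$symmetry_index, truth$symmetry_index, tolerance = 0.005)
  expect_equal(sp$step_width, truth$step_width, tolerance = 0.01)
  expect_equal(sp$trunk_sway_range, truth$trunk_sway_range,
               tolerance = 0.02)
})

test_that("foot-shank angles recover programmed peaks and are rotation-invariant", {
  rec <- synthesize_step_recording(step_config(), 5L)
  truth <- attr(rec, "truth")
  fa <- foot_angles(rec, "prosthetic")
  expect_equal(fa$peak_dorsiflexion, truth$peak_dorsiflexion,
               tolerance = 0.1 / truth$peak_dorsiflexion)  # within 0.1 deg
  expect_equal(fa$peak_plantarflexion, truth$peak_plantarflexion,
               tolerance = 0.1)
  # neutral reflects the constant 5 deg knee-marker offset
  expect_equal(fa$neutral_angle, 85, tolerance = 0.001)

  # rotating the whole leg rigidly leaves the relative angle unchanged
  a <- 17 * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
  rec2 <- rec
  for (nm in c("knee_p", "ankle_p", "heel_p", "toe_p")) {
    xy <- as.matrix(rec$markers[, paste0(nm, c("_x", "_y"))])
    rec2$markers[, paste0(nm, c("_x", "_y"))] <- t(R %*% t(xy))
  }
  fa2 <- foot_angles(rec2, "prosthetic")
  expect_equal(fa2$angle$foot_shank_angle, fa$angle$foot_shank_angle,
               tolerance = 1e-6)
})

test_that("roll-over geometry recovers the programmed rocker", {
  # rigid rocker of 0.15 m under a 0.45 m lower leg, clean measurement
  cfg <- step_config(rocker_radius = 0.15, lower_leg_length = 0.45,
                     marker_noise_sd = 0, force_noise_sd = 0)
  ro <- rollover(synthesize_step_recording(cfg, 1L), "prosthetic")
  expect_equal(ro$radius, 0.15 / 0.45, tolerance = 0.01)

  # default noisy recording: radius and EFLR near truth
  rec <- synthesize_step_recording(step_config(), 3L)
  truth <- attr(rec, "truth")
  ro2 <- rollover(rec, "prosthetic")
  expect_equal(ro2$radius, truth$rollover_radius_norm, tolerance = 0.02)
  expect_equal(ro2$eflr, truth$eflr, tolerance = 0.03)

  # frozen CoP: degenerate fit
  bad <- rec
  bad$forceplate$prosthetic$cop_x <- 0.2
  bad$markers[, grep("_x$", names(bad$markers))] <-
    bad$markers[, grep("_x$", names(bad$markers))] * 0 + 0.2
  expect_error(rollover(bad, "prosthetic"), "degenerate")
})

test_that("unified-deformable power recovers the elastic work budget", {
  rec <- synthesize_step_recording(step_config(), 6L)
  truth <- attr(rec, "truth")
  fe <- foot_power_and_energy(rec, "prosthetic")
  expect_equal(fe$energy_return, truth$energy_return, tolerance = 0.05)
  expect_true(fe$free_moment_used)

  # rigid rolling without programmed elastic work: distal power ~ 0
  calm <- step_config(energy_stored = 0, energy_return = 0,
                      marker_noise_sd = 0, force_noise_sd = 0)
  fr <- foot_power_and_energy(synthesize_step_recording(calm, 1L),
                              "prosthetic")
  expect_lt(max(abs(fr$power$power)), 0.15)  # W/kg, vs ~2.8 peak with work
  expect_lt(abs(fr$net_work), 0.01)

  # sign structure: storage (P < 0) precedes return (P > 0)
  clean <- foot_power_and_energy(
    synthesize_step_recording(step_config(marker_noise_sd = 0,
                                          force_noise_sd = 0), 1L),
    "prosthetic")
  P <- clean$power$power
  n <- length(P)
  early <- P[seq(floor(0.25 * n), floor(0.45 * n))]
  late <- P[seq(floor(0.8 * n), floor(0.95 * n))]
  expect_lt(mean(early), 0)
  expect_gt(mean(late), 0)
})

test_that("CoM transition work is symmetric and conserves energy over a stride", {
  rec <- synthesize_step_recording(step_config(marker_noise_sd = 0,
                                               force_noise_sd = 0), 1L)
  cw <- com_transition_work(rec)
  expect_lt(abs(cw$collision[["prosthetic"]] - cw$collision[["intact"]]) /
              abs(cw$collision[["prosthetic"]]), 0.01)
  expect_lt(abs(cw$propulsion[["prosthetic"]] - cw$propulsion[["intact"]]) /
              cw$propulsion[["prosthetic"]], 0.01)
  expect_true(all(cw$collision < 0))
  expect_true(all(cw$propulsion > 0))

  # energy bookkeeping: net external work of both limbs over the periodic
  # stride is small next to the total positive work
  fpp <- lltefoot:::filtered_plate(rec, "prosthetic")
  fpi <- lltefoot:::filtered_plate(rec, "intact")
  v <- cw$com_velocity
  sel <- fpp$time >= v$time[1L] & fpp$time <= v$time[nrow(v)]
  P_tot <- (fpp$grf_x[sel] * v$vx + fpp$grf_y[sel] * v$vy +
              fpi$grf_x[sel] * v$vx + fpi$grf_y[sel] * v$vy) /
    rec$meta$body_mass
  net <- lltefoot:::trapz(v$time, P_tot)
  pos <- lltefoot:::trapz(v$time, pmax(P_tot, 0))
  expect_lt(abs(net), 0.05 * pos)
})

test_that("deviation scores are NRMSE sums with the documented normalizers", {
  ref <- ref_gait(1)
  user <- user_characteristics(ref$body_mass, ref$foot_length,
                               ref$lower_leg_length)
  pct <- seq(0, 100, length.out = 101)
  ip <- function(ch) approx(ref$stance_percent, ch, xout = pct)$y
  leg <- data.frame(grf_x = ip(ref$grf_x), grf_y = ip(ref$grf_y),
                    cop_x = ip(ref$cop_x), knee_x = ip(ref$knee_x),
                    knee_y = ip(ref$knee_y),
                    theta_shank = ip(ref$theta_shank))
  measured <- list(percent = pct, prosthetic = leg, intact = leg)
  s0 <- deviation_scores(measured, ref, user)
  expect_equal(s0$total, 0)
  expect_equal(unname(s0$per_leg), matrix(0, 2, 6))

  # constant vertical-GRF offset of 0.05 BW -> that score is exactly 0.05
  off <- measured
  off$prosthetic$grf_y <- off$prosthetic$grf_y +
    0.05 * 9.81 * user$body_mass
  s1 <- deviation_scores(off, ref, user)
  expect_equal(s1$per_leg["prosthetic", "grf_y"], 0.05)
  expect_equal(s1$total, 0.05)
  expect_equal(s1$total, sum(s1$per_leg))   # additivity by construction

  short <- measured; short$intact <- measured$intact[1:50, ]
  expect_error(deviation_scores(short, ref, user), "mismatch")
})

test_that("step recordings are deterministic per seed and round-trip to disk", {
  a <- synthesize_step_recording(step_config(), 9L)
  b <- synthesize_step_recording(step_config(), 9L)
  expect_identical(a$markers, b$markers)
  expect_identical(a$forceplate, b$forceplate)
  expect_false(identical(a$markers,
                         synthesize_step_recording(step_config(), 10L)$markers))
  expect_error(step_config(energy_return = -1), "non-negative")

  dir <- file.path(withr::local_tempdir(), "rec")
  write_step_recording(a, dir)
  back <- read_step_recording(dir)
  expect_equal(back$markers$sacrum_x, a$markers$sacrum_x, tolerance = 1e-9)
  expect_equal(back$meta$body_mass, a$meta$body_mass)
  sp <- spatiotemporal(back)
  expect_equal(sp$walking_speed, attr(a, "truth")$walking_speed,
               tolerance = 0.01)
})

test_that("metrics are invariant to time shift and lab translation", {
  rec <- synthesize_step_recording(step_config(), 8L)
  sp <- spatiotemporal(rec)
  ro <- rollover(rec, "prosthetic")
  shifted <- rec
  shifted$markers$time <- rec$markers$time + 5
  for (side in c("prosthetic", "intact"))
    shifted$forceplate[[side]]$time <- rec$forceplate[[side]]$time + 5
  xcols <- grep("_x$", names(rec$markers), value = TRUE)
  shifted$markers[, xcols] <- shifted$markers[, xcols] + 12.3
  for (side in c("prosthetic", "intact"))
    shifted$forceplate[[side]]$cop_x <- shifted$forceplate[[side]]$cop_x + 12.3
  sp2 <- spatiotemporal(shifted)
  ro2 <- rollover(shifted, "prosthetic")
  expect_equal(sp2$walking_speed, sp$walking_speed, tolerance = 1e-9)
  expect_equal(sp2$symmetry_index, sp$symmetry_index, tolerance = 1e-9)
  expect_equal(ro2$radius, ro$radius, tolerance = 1e-9)
  expect_equal(ro2$eflr, ro$eflr, tolerance = 1e-9)
})
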