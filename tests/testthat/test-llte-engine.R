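# Pose resolution and the trajectory-error metric.

test_that("a rigid flat-soled foot gives geometry-determined flat poses", {
  design <- flat_sole_design()
  mesh <- mesh_geometry(evaluate_geometry(design), 40L, 0.06)
  rigid <- near_rigid_material()
  ref <- ref_gait(1)
  cs <- resample_stance(ref, 50)[[1L]]

  p1 <- solve_flat_contact_pose(mesh, rigid, cs, 0.50)
  cs2 <- cs; cs2$grf <- 2 * cs$grf
  p2 <- solve_flat_contact_pose(mesh, rigid, cs2, 0.50)
  expect_lt(abs(p1$knee_x - p2$knee_x), 1e-8)
  expect_lt(abs(p1$theta_shank - p2$theta_shank), 1e-6)

  # the planted rigid flat foot keeps its lower leg still as the CoP
  # advances: the knee stays put (to within the node snapping of the point
  # load, which is applied at the nearest sole node by design) and the
  # shank angle is unchanged
  cs3 <- cs; cs3$cop_x <- cs$cop_x + 0.02
  p3 <- solve_flat_contact_pose(mesh, rigid, cs3, 0.50)
  spacing <- max(mesh$elements$length)
  expect_lt(abs(p3$knee_x - p1$knee_x), spacing)
  expect_lt(abs(p3$theta_shank - p1$theta_shank), 1e-6)
  expect_equal(p1$knee_y, 0.50, tolerance = 1e-6)
})

test_that("near-rigid poses match the geometric rigid-rolling oracle", {
  design <- flat_sole_design()
  mesh <- mesh_geometry(evaluate_geometry(design), 40L, 0.06)
  rigid <- near_rigid_material()
  ref <- ref_gait(1)
  cases <- resample_stance(ref)
  traj <- compute_trajectory(design, rigid, cases,
                             user = default_user(), n_elements = 40L)
  expect_true(all(traj$converged))
  for (i in seq_along(cases)) {
    oracle <- rigid_pose_oracle(mesh, cases[[i]], 0.50)
    expect_lt(abs(traj$knee_x[i] - oracle[["knee_x"]]), 1e-6)
    expect_lt(abs(traj$knee_y[i] - oracle[["knee_y"]]), 1e-6)
    expect_lt(abs(traj$theta_shank[i] - oracle[["theta"]]), 1e-4)
  }
})

test_that("the line-contact solver finds the bracketed moment-balance root", {
  design <- flat_sole_design()
  mesh <- mesh_geometry(evaluate_geometry(design), 30L, 0.06)
  mat <- nylon66()
  ref <- ref_gait(1)
  cs <- resample_stance(ref, 8)[[1L]]
  pose <- solve_line_contact_pose(mesh, mat, cs, "heel", 0.50)
  expect_true(pose$converged)
  out <- line_contact_residual(mesh, mat, cs, "heel", pose$phi, 0.50)
  expect_lt(abs(out$residual), 0.1)

  # brute-force 50-point bracketing around the root confirms a single sign
  # change at the returned orientation
  grid <- seq(pose$phi - 10, pose$phi + 10, length.out = 50L)
  r <- vapply(grid, function(p)
    line_contact_residual(mesh, mat, cs, "heel", p, 0.50)$residual,
    numeric(1L))
  sign_changes <- which(diff(sign(r)) != 0)
  expect_length(sign_changes, 1L)
  expect_true(grid[sign_changes] <= pose$phi &&
                pose$phi <= grid[sign_changes + 1L])
  # a +1 N m knee-moment perturbation moves the orientation along the
  # residual's monotone branch
  expect_true(all(diff(r) > 0) || all(diff(r) < 0))
  cs_p <- cs; cs_p$knee_moment <- cs$knee_moment + 1
  pose_p <- solve_line_contact_pose(mesh, mat, cs_p, "heel", 0.50,
                                    warm_start = pose$phi)
  expect_gt((pose_p$phi - pose$phi) * sign(mean(diff(r))), 0)
})

test_that("the rigid self-consistent line case returns the reference pose", {
  design <- flat_sole_design()
  mesh <- mesh_geometry(evaluate_geometry(design), 40L, 0.06)
  rigid <- near_rigid_material()
  ref <- ref_gait(1)
  cs <- resample_stance(ref, 8)[[1L]]
  # set the knee moment to the value implied by the rigid pose itself
  oracle <- rigid_pose_oracle(mesh, cs, 0.50)
  cs$knee_moment <- knee_moment_from_kinetics(
    c(oracle[["knee_x"]], oracle[["knee_y"]]), cs$grf, cs$cop_x)
  pose <- solve_line_contact_pose(mesh, rigid, cs, "heel", 0.50)
  expect_equal(pose$knee_x, oracle[["knee_x"]], tolerance = 1e-6)
  expect_equal(pose$theta_shank, oracle[["theta"]], tolerance = 1e-4)
})

test_that("the LLTE metric satisfies its closed-form identities", {
  ref <- ref_gait(1)
  percents <- default_stance_percents()
  ip <- function(ch) approx(ref$stance_percent, ch, xout = percents)$y
  model <- data.frame(stance_percent = percents, knee_x = ip(ref$knee_x),
                      knee_y = ip(ref$knee_y),
                      theta_shank = ip(ref$theta_shank),
                      phi = ip(ref$theta_shank), regime = "flat_contact",
                      converged = TRUE, max_stress = 0)
  expect_equal(compute_llte(model, ref)$value, 0)

  # single frame with all three normalized deviations equal to 0.1
  one <- model[5L, ]
  l <- compute_llte(one, ref, percents = one$stance_percent)
  xbar <- abs(one$knee_x); ybar <- abs(one$knee_y); tbar <- abs(one$theta_shank)
  one$knee_x <- one$knee_x + 0.1 * xbar
  one$knee_y <- one$knee_y + 0.1 * ybar
  one$theta_shank <- one$theta_shank + 0.1 * tbar
  l1 <- compute_llte(one, ref, percents = one$stance_percent)
  expect_equal(l1$value, 0.173205, tolerance = 1e-5)

  # scale invariance: scaling a variable together with its normalizer
  # leaves its error term unchanged (normalizers are reference means)
  sc <- scale_to_user(ref, user_characteristics(70, 0.26, 1.0))
  model_sc <- model
  model_sc$knee_x <- model$knee_x * 2; model_sc$knee_y <- model$knee_y * 2
  expect_equal(compute_llte(model_sc, sc)$value, 0, tolerance = 1e-12)

  # failed frames dominate any feasible value
  fail <- model; fail$converged[3L] <- FALSE
  expect_gt(compute_llte(fail, ref)$value, 3)
})

test_that("trajectories are stance-ordered, converged, and stiffness-monotone", {
  ref <- ref_gait(1)
  user <- default_user()
  cases <- resample_stance(ref)
  traj <- compute_trajectory(example_foot_design(), nylon66(), cases, user,
                             n_elements = 40L,
                             opts = solver_options(increments = 4L))
  expect_equal(nrow(traj), 9L)
  expect_true(all(diff(traj$stance_percent) > 0))
  expect_true(all(traj$converged))
  expect_true(all(is.finite(traj$max_stress)))

  # analytic model: a stiffer foot deviates less from the rigid pose
  soft <- compute_trajectory(analytic_foot(user), NULL, cases, user)
  stiff <- compute_trajectory(analytic_foot(user, keel_scale = 1.5,
                                            heel_scale = 1.5),
                              NULL, cases, user)
  flat <- traj$regime == "flat_contact"
  dev_soft <- abs(soft$theta_shank[flat])
  dev_stiff <- abs(stiff$theta_shank[flat])
  expect_true(all(dev_stiff <= dev_soft + 1e-12))
})

test_that("prediction from model-generated kinetics closes the loop", {
  ref <- ref_gait(1)
  user <- default_user()
  foot <- analytic_foot(user)
  # run the model over the full stance description, then rebuild a
  # "measured" dataset whose lower-leg channels are the model's own poses
  # and whose kinetics are the reference's
  full <- compute_trajectory(foot, NULL,
                             resample_stance(ref, ref$stance_percent), user)
  # the unloaded stance endpoints (zero GRF) have no moment-balance root;
  # hold the nearest resolved pose there so the container is valid
  for (ch in c("knee_x", "knee_y", "theta_shank")) {
    ok <- which(is.finite(full[[ch]]))
    full[[ch]] <- approx(full$stance_percent[ok], full[[ch]][ok],
                         xout = full$stance_percent, rule = 2)$y
  }
  measured <- reference_gait(full$stance_percent, ref$grf_x, ref$grf_y,
                             ref$cop_x, full$knee_x, full$knee_y,
                             full$theta_shank, ref$knee_moment,
                             ref$body_mass, ref$foot_length,
                             ref$lower_leg_length)
  percents <- default_stance_percents()
  pred <- predict_trajectory_from_measured(foot, NULL, measured, user,
                                           percents = percents)
  keep <- full$stance_percent %in% percents
  err <- trajectory_rmse(pred, data.frame(
    stance_percent = full$stance_percent[keep], knee_x = full$knee_x[keep],
    knee_y = full$knee_y[keep], theta_shank = full$theta_shank[keep]))
  expect_lt(err[["knee_x"]], 1e-9)
  expect_lt(err[["knee_y"]], 1e-9)
  expect_lt(err[["theta_shank"]], 1e-7)
})

test_that("trajectory errors grow smoothly under kinetic noise", {
  ref <- ref_gait(1)
  user <- default_user()
  foot <- analytic_foot(user)
  percents <- default_stance_percents()
  base <- compute_trajectory(foot, NULL, resample_stance(ref, percents), user)
  base_poses <- data.frame(stance_percent = base$stance_percent,
                           knee_x = base$knee_x, knee_y = base$knee_y,
                           theta_shank = base$theta_shank)
  set.seed(99)
  for (rep in 1:3) {
    noisy <- ref
    noisy$grf_y <- ref$grf_y * (1 + rnorm(101, 0, 0.01))
    noisy$grf_y <- pmax(noisy$grf_y, 0)
    nt <- compute_trajectory(foot, NULL, resample_stance(noisy, percents),
                             user)
    err <- trajectory_rmse(nt, base_poses)
    expect_lt(err[["theta_shank"]], 1.0)   # ~1% force noise, bounded effect
    expect_lt(err[["knee_x"]], 0.01)
  }
})
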