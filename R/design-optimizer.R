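# Shape and size optimization: minimize the LLTE value over the 11
# independent wide-Bezier variables under stress, bound and
# self-intersection constraints with a real-coded genetic algorithm.

#' Optimization configuration
#'
#' GA settings and constraint handling.  Genes are the 11 independent
#' variables scaled to \[0, 1\] by the bounds; selection is tournament of 3,
#' crossover is blend (BLX-alpha, alpha 0.5) at rate 0.9, mutation is
#' per-gene Gaussian (sd 0.1) at rate 0.15, with one elite individual kept.
#' Constraints are static penalties: out-of-bounds and self-intersecting
#' candidates short-circuit (no structural analysis) to a large penalty
#' ranked by violation magnitude, a stress violation adds
#' `stress_weight * (max_stress / allowable - 1)`, and failed stance frames
#' are penalised inside the objective itself.
#'
#' @param pop Population size (>= 4).
#' @param generations Number of generations.
#' @param p_cross,p_mut Crossover and per-gene mutation rates in \[0, 1\].
#' @param mut_sd Gaussian mutation sd on the unit-scaled genes.
#' @param seed Integer seed: fixed seed gives bit-reproducible histories.
#' @param safety_factor Stress safety factor (>= 1), default 1.75.
#' @param stress_weight Penalty weight on relative stress violation.
#' @param infeasible_penalty Base penalty for short-circuited candidates.
#' @param bounds A `design_bounds` (default from the context's user).
#' @param n_elements,width,opts Structural analysis pass-through.
#' @return A named list of settings.
#' @export
optimization_config <- function(pop = 50L, generations = 60L, p_cross = 0.9,
                                p_mut = 0.15, mut_sd = 0.1, seed = 1L,
                                safety_factor = 1.75, stress_weight = 10,
                                infeasible_penalty = 1e3, bounds = NULL,
                                n_elements = 60L, width = 0.06,
                                opts = solver_options(increments = 5L)) {
  if (pop < 4L) stop("population must be at least 4")
  if (p_cross < 0 || p_cross > 1 || p_mut < 0 || p_mut > 1)
    stop("rates must lie in [0, 1]")
  if (safety_factor < 1) stop("safety factor must be >= 1")
  list(pop = as.integer(pop), generations = as.integer(generations),
       p_cross = p_cross, p_mut = p_mut, mut_sd = mut_sd,
       seed = as.integer(seed), safety_factor = safety_factor,
       stress_weight = stress_weight,
       infeasible_penalty = infeasible_penalty, bounds = bounds,
       n_elements = as.integer(n_elements), width = width, opts = opts)
}

#' Prepare the evaluation context for design optimization
#'
#' Scales the reference gait to the user, resamples the stance load cases,
#' and bundles everything a candidate evaluation needs.
#'
#' @param user A [user_characteristics()].
#' @param ref A [reference_gait()] (the target walking dataset).
#' @param mat A [material()], default Nylon 6/6.
#' @param percents Stance instances for the objective, default the nine
#'   representative ones.
#' @return A list with the scaled reference, load cases, user, material
#'   and percents.
#' @export
design_context <- function(user, ref, mat = nylon66(),
                           percents = default_stance_percents()) {
  scaled <- scale_to_user(ref, user)
  list(user = user, ref = scaled, mat = mat, percents = sort(percents),
       cases = resample_stance(scaled, percents))
}

#' Evaluate one candidate design
#'
#' @param vars The 11 independent variable values (natural units).
#' @param context From [design_context()].
#' @param config From [optimization_config()].
#' @return List with `objective` and a `constraint_report` (max stress,
#'   stress/bounds/self-intersection flags, failed frame count).
#' @export
evaluate_candidate <- function(vars, context, config = optimization_config()) {
  bounds <- config$bounds %||% default_design_bounds(context$user)
  report <- list(max_stress = NA_real_, stress_ok = NA, self_intersects = NA,
                 bounds_ok = TRUE, failed_frames = NA_integer_)
  span <- bounds$upper - bounds$lower
  viol <- pmax(0, bounds$lower - vars) / span +
          pmax(0, vars - bounds$upper) / span
  if (any(viol > 0)) {
    report$bounds_ok <- FALSE
    return(list(objective = config$infeasible_penalty + sum(viol),
                constraint_report = report))
  }
  design <- tryCatch(complete_design(vars, context$user),
                     error = function(e) NULL)
  if (is.null(design))
    return(list(objective = config$infeasible_penalty + 1,
                constraint_report = report))
  geom <- tryCatch(evaluate_geometry(design), error = function(e) NULL)
  if (is.null(geom))
    return(list(objective = config$infeasible_penalty + 1,
                constraint_report = report))
  chk <- check_self_intersection(geom)
  report$self_intersects <- chk$violated
  if (chk$violated)
    return(list(objective = config$infeasible_penalty +
                  nrow(chk$pairs) / 10,
                constraint_report = report))
  traj <- compute_trajectory(design, context$mat, context$cases,
                             context$user, n_elements = config$n_elements,
                             width = config$width, opts = config$opts)
  llte <- compute_llte(traj, context$ref, context$percents)
  ms <- suppressWarnings(max(traj$max_stress, na.rm = TRUE))
  if (!is.finite(ms)) ms <- NA_real_
  allow <- context$mat$sigma_yf / config$safety_factor
  report$max_stress <- ms
  report$stress_ok <- is.finite(ms) && ms <= allow
  report$failed_frames <- sum(!traj$converged)
  pen <- if (is.finite(ms)) config$stress_weight * max(0, ms / allow - 1)
         else 0
  list(objective = llte$value + pen, constraint_report = report,
       llte = llte$value, design = design)
}

feasible_report <- function(rep) {
  isTRUE(rep$bounds_ok) && isTRUE(rep$stress_ok) &&
    isFALSE(rep$self_intersects) &&
    !is.na(rep$failed_frames) && rep$failed_frames == 0
}

# Generic real-coded GA engine on [0, 1]^k: tournament selection (3),
# blend crossover, per-gene Gaussian mutation, elitism of 1, fixed seed.
# eval_fn(genes) must return list(objective, feasible, ...); the best
# feasible individual ever seen is returned.
ga_minimize <- function(eval_fn, k, config) {
  old <- .Random.seed_exists()
  set.seed(config$seed)
  pop <- matrix(stats::runif(config$pop * k), config$pop, k)
  best <- NULL
  history <- NULL
  evals <- NULL
  for (gen in seq_len(config$generations)) {
    evals <- lapply(seq_len(nrow(pop)), function(i) eval_fn(pop[i, ]))
    obj <- vapply(evals, `[[`, numeric(1L), "objective")
    feas <- vapply(evals, function(e) isTRUE(e$feasible), logical(1L))
    for (i in which(feas)) {
      if (is.null(best) || obj[i] < best$objective)
        best <- list(objective = obj[i], genes = pop[i, ],
                     eval = evals[[i]])
    }
    history <- rbind(history, data.frame(
      generation = gen,
      best = if (is.null(best)) min(obj) else best$objective,
      median = stats::median(obj),
      feasible_fraction = mean(feas)))
    if (gen == config$generations) break
    sel <- function() {
      cand <- sample.int(config$pop, 3L)
      cand[which.min(obj[cand])]
    }
    newpop <- matrix(NA_real_, config$pop, k)
    i <- 1L
    while (i <= config$pop) {
      p1 <- pop[sel(), ]; p2 <- pop[sel(), ]
      if (stats::runif(1L) < config$p_cross) {
        al <- 0.5
        lo <- pmin(p1, p2) - al * abs(p1 - p2)
        hi <- pmax(p1, p2) + al * abs(p1 - p2)
        c1 <- stats::runif(k, lo, hi); c2 <- stats::runif(k, lo, hi)
      } else { c1 <- p1; c2 <- p2 }
      for (ch in list(c1, c2)) {
        if (i > config$pop) break
        mut <- stats::runif(k) < config$p_mut
        ch[mut] <- ch[mut] + stats::rnorm(sum(mut), 0, config$mut_sd)
        newpop[i, ] <- pmin(1, pmax(0, ch))
        i <- i + 1L
      }
    }
    if (!is.null(best)) newpop[1L, ] <- best$genes  # elitism
    pop <- newpop
  }
  if (old$had) .Random.seed_restore(old)
  list(best = best, history = history, last_evals = evals)
}

#' Minimize the LLTE value with a genetic algorithm
#'
#' Real-coded GA over the 11 independent design variables (unit-scaled by
#' the bounds), with elitism, static constraint penalties and a fixed seed
#' for bit-reproducible runs.  Returns the best feasible individual ever
#' seen.
#'
#' @param context From [design_context()].
#' @param config From [optimization_config()].
#' @param start Optional matrix of initial individuals (rows, natural
#'   units) seeded into the first population.
#' @return An object of class `llte_optim`: best design and variables,
#'   best objective, its constraint report, per-generation history and the
#'   config echo.
#' @export
optimize_design <- function(context, config = optimization_config(),
                            start = NULL) {
  bounds <- config$bounds %||% default_design_bounds(context$user)
  config$bounds <- bounds
  k <- length(bounds$lower)
  span <- bounds$upper - bounds$lower
  to_nat <- function(g) bounds$lower + g * span
  eval_fn <- function(genes) {
    ev <- evaluate_candidate(to_nat(genes), context, config)
    ev$feasible <- feasible_report(ev$constraint_report)
    ev
  }
  res <- ga_minimize(eval_fn, k, config)
  if (is.null(res$best)) {
    least <- which.min(vapply(res$last_evals, `[[`, numeric(1L),
                              "objective"))
    stop("no feasible individual found; least-infeasible objective ",
         signif(res$last_evals[[least]]$objective, 4))
  }
  best <- res$best
  structure(list(best_vars = stats::setNames(to_nat(best$genes),
                                             independent_var_names),
                 best_design = best$eval$design,
                 best_objective = best$objective,
                 constraint_report = best$eval$constraint_report,
                 history = res$history, seed = config$seed,
                 config = config),
            class = "llte_optim")
}

#' GA optimization of the two-scale analytic foot
#'
#' Runs the same genetic algorithm on the analytic foot's keel and heel
#' thickness scales, minimizing the LLTE over a stance instance set.  Used
#' to verify the GA against the exhaustive grid search of
#' [instance_set_study()].
#'
#' @param ref A [reference_gait()].
#' @param user A [user_characteristics()]; defaults to the reference
#'   subject.
#' @param config From [optimization_config()].
#' @param percents Stance instances, default the nine representative ones.
#' @param scale_range Bounds of both scales, default \[0.5, 1.5\].
#' @return An `llte_optim`-like list with `best_vars` (keel/heel scales),
#'   `best_objective` and `history`.
#' @export
optimize_analytic_scales <- function(ref, user = NULL,
                                     config = optimization_config(),
                                     percents = default_stance_percents(),
                                     scale_range = c(0.5, 1.5)) {
  if (is.null(user))
    user <- user_characteristics(ref$body_mass, ref$foot_length,
                                 ref$lower_leg_length)
  study <- prepare_study(ref, user, percents)
  to_nat <- function(g) scale_range[1L] + g * diff(scale_range)
  eval_fn <- function(genes) {
    list(objective = analytic_llte_fast(to_nat(genes), study),
         feasible = TRUE)
  }
  res <- ga_minimize(eval_fn, 2L, config)
  structure(list(best_vars = stats::setNames(to_nat(res$best$genes),
                                             c("keel", "heel")),
                 best_objective = res$best$objective,
                 constraint_report = list(bounds_ok = TRUE,
                                          stress_ok = TRUE,
                                          self_intersects = FALSE,
                                          failed_frames = 0L,
                                          max_stress = NA_real_),
                 history = res$history, seed = config$seed,
                 config = config),
            class = "llte_optim")
}

#' @export
print.llte_optim <- function(x, ...) {
  cat(sprintf("LLTE optimization: best objective %.4f after %d generations (seed %d)\n",
              x$best_objective, nrow(x$history), x$seed))
  cat(sprintf("  max stress %.1f MPa, feasible fraction (last gen) %.2f\n",
              x$constraint_report$max_stress / 1e6,
              x$history$feasible_fraction[nrow(x$history)]))
  invisible(x)
}

#' @export
plot.llte_optim <- function(x, ...) {
  graphics::plot(x$history$generation, x$history$best, type = "l",
                 lwd = 2, xlab = "generation", ylab = "objective",
                 ylim = range(c(x$history$best, x$history$median)), ...)
  graphics::lines(x$history$generation, x$history$median, lty = 2)
  graphics::legend("topright", c("best", "median"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Compare optimization under two stance instance sets
#'
#' Runs the optimizer (matched seeds) under a full and a reduced set of
#' stance percents, and reports the per-variable percent differences of the
#' optima plus the relative difference in the LLTE of the full-set optimum
#' when evaluated under either set.
#'
#' @param context From [design_context()] (its percents are overridden).
#' @param config From [optimization_config()].
#' @param full_percents,reduced_percents The two instance sets.
#' @return List with both optima, `variable_pct_diff` and `llte_pct_diff`.
#' @export
compare_instance_sets <- function(context, config, full_percents,
                                  reduced_percents) {
  ctx_full <- design_context(context$user, context$ref, context$mat,
                             full_percents)
  ctx_red <- design_context(context$user, context$ref, context$mat,
                            reduced_percents)
  opt_full <- optimize_design(ctx_full, config)
  opt_red <- optimize_design(ctx_red, config)
  vd <- abs(opt_red$best_vars - opt_full$best_vars) /
    pmax(abs(opt_full$best_vars), 1e-12) * 100
  traj_f <- compute_trajectory(opt_full$best_design, context$mat,
                               ctx_full$cases, context$user,
                               n_elements = config$n_elements,
                               width = config$width, opts = config$opts)
  traj_r <- compute_trajectory(opt_full$best_design, context$mat,
                               ctx_red$cases, context$user,
                               n_elements = config$n_elements,
                               width = config$width, opts = config$opts)
  l_f <- compute_llte(traj_f, ctx_full$ref, full_percents)$value
  l_r <- compute_llte(traj_r, ctx_red$ref, reduced_percents)$value
  list(full = opt_full, reduced = opt_red,
       variable_pct_diff = vd,
       llte_pct_diff = abs(l_r - l_f) / l_f * 100)
}

# ---- analytic instance-set study -------------------------------------------

# LLTE of an analytic foot over a prepared percent set (lean path used by
# the exhaustive grid search: reference interpolants and normalizers are
# precomputed once per set).
analytic_llte_fast <- function(scales, study) {
  foot <- analytic_foot(study$user, keel_scale = scales[1L],
                        heel_scale = scales[2L])
  L <- study$user$lower_leg_length
  p <- vapply(study$cases, function(cs) {
    if (cs$regime == "flat_contact") analytic_flat_pose(foot, cs, L)
    else analytic_line_pose(foot, cs, L)
  }, numeric(3L))
  sqrt(mean(((p[1L, ] - study$rx) / study$xbar)^2 +
            ((p[2L, ] - study$ry) / study$ybar)^2 +
            ((p[3L, ] - study$rt) / study$tbar)^2))
}

prepare_study <- function(ref, user, percents) {
  percents <- sort(percents)
  scaled <- scale_to_user(ref, user)
  cases <- resample_stance(scaled, percents)
  ip <- function(ch) stats::approx(scaled$stance_percent, ch,
                                   xout = percents)$y
  rx <- ip(scaled$knee_x); ry <- ip(scaled$knee_y)
  rt <- ip(scaled$theta_shank)
  list(user = user, ref = scaled, percents = percents, cases = cases,
       rx = rx, ry = ry, rt = rt,
       xbar = mean(abs(rx)), ybar = mean(abs(ry)), tbar = mean(abs(rt)))
}

#' Instance-set sufficiency study on the analytic foot model
#'
#' Exhaustive grid search of the two thickness scales of the analytic foot
#' under a full set of stance instances and under the nine representative
#' ones, reporting how far the reduced-set optimum falls from the full-set
#' optimum (max per-variable percent difference) and how much the LLTE of
#' the fixed full-set optimum changes when evaluated with the reduced set.
#'
#' @param ref A [reference_gait()].
#' @param user A [user_characteristics()].
#' @param full_percents Full stance description, default 1..99%.
#' @param reduced_percents Default the nine representative instances.
#' @param n_grid Grid resolution per variable, default 50.
#' @param scale_range Range of both thickness scales, default \[0.5, 1.5\].
#' @return List: optimal scales under each set, `max_variable_pct_diff`,
#'   and `llte_pct_diff` of the full-set optimum across sets.
#' @export
instance_set_study <- function(ref, user = NULL,
                               full_percents = 1:99,
                               reduced_percents = default_stance_percents(),
                               n_grid = 50L, scale_range = c(0.5, 1.5)) {
  if (is.null(user))
    user <- user_characteristics(ref$body_mass, ref$foot_length,
                                 ref$lower_leg_length)
  sk <- seq(scale_range[1L], scale_range[2L], length.out = n_grid)
  grid <- as.matrix(expand.grid(keel = sk, heel = sk))
  st_full <- prepare_study(ref, user, full_percents)
  st_red <- prepare_study(ref, user, reduced_percents)
  v_full <- apply(grid, 1L, analytic_llte_fast, study = st_full)
  v_red <- apply(grid, 1L, analytic_llte_fast, study = st_red)
  opt_full <- grid[which.min(v_full), ]
  opt_red <- grid[which.min(v_red), ]
  vd <- abs(opt_red - opt_full) / abs(opt_full) * 100
  l_full <- min(v_full)
  l_red_of_full <- analytic_llte_fast(opt_full, st_red)
  list(opt_full = opt_full, opt_red = opt_red,
       variable_pct_diff = vd,
       max_variable_pct_diff = max(vd),
       llte_full = l_full, llte_reduced_of_full_opt = l_red_of_full,
       llte_pct_diff = abs(l_red_of_full - l_full) / l_full * 100)
}
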