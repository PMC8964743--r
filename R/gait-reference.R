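# Reference gait handling: validated containers, synthesis, scaling and
# resampling into the stance load cases consumed by the trajectory engine.
#
# Frame conventions (used throughout the package):
#   * lab frame: x forward (+ anterior, walking direction), y up; origin on
#     the ground directly below the ankle at the calibration pose (foot flat
#     on the ground, unloaded).
#   * `cop_x` in a reference gait table is heel-relative (0 at the heel
#     strike point); the ankle sits `ankle_fraction * foot_length` anterior
#     of the heel (default 0.25), so ankle-frame CoP = cop_x - 0.25 L_foot.
#   * knee coordinates are in the lab (ankle-origin) frame.
#   * theta_shank in degrees, positive when the knee is anterior to the
#     ankle (dorsiflexion direction).  Angles are degrees at every interface
#     and radians internally.

#' User body characteristics
#'
#' Bundle of the body parameters a prosthetic foot is designed for.
#'
#' @param body_mass Body mass in kg.
#' @param foot_length Physical foot length in m.
#' @param lower_leg_length Knee point to ground distance in m, measured with
#'   the foot flat on the ground and unloaded.
#' @param residuum_length Residual limb length below the knee in m.
#' @param build_height_h_ank Build height of the prosthesis (ankle height,
#'   ground to attachment) in m.  Together with the residuum it must fit
#'   under the lower leg length.
#' @return An object of class `user_characteristics`.
#' @export
user_characteristics <- function(body_mass, foot_length, lower_leg_length,
                                 residuum_length = 0.15,
                                 build_height_h_ank = 0.07) {
  vals <- c(body_mass = body_mass, foot_length = foot_length,
            lower_leg_length = lower_leg_length,
            residuum_length = residuum_length,
            build_height_h_ank = build_height_h_ank)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all user characteristics must be finite and strictly positive")
  if (build_height_h_ank + residuum_length > lower_leg_length)
    stop("build_height_h_ank + residuum_length must not exceed lower_leg_length")
  structure(as.list(vals), class = "user_characteristics")
}

#' @export
print.user_characteristics <- function(x, ...) {
  cat("User characteristics:\n")
  cat(sprintf("  mass %.1f kg, foot %.3f m, lower leg %.3f m\n",
              x$body_mass, x$foot_length, x$lower_leg_length))
  cat(sprintf("  residuum %.3f m, build height %.3f m\n",
              x$residuum_length, x$build_height_h_ank))
  invisible(x)
}

#' Construct and validate a stance-phase reference gait
#'
#' A reference gait holds the stance-phase kinetic and kinematic curves the
#' design framework targets, together with the body parameters they were
#' recorded at.  Invariants are checked on construction.
#'
#' @param stance_percent Strictly increasing vector spanning 0 to 100
#'   (0 = heel strike, 100 = toe off).
#' @param grf_x,grf_y Fore-aft (+ anterior) and vertical (+ up) ground
#'   reaction force, N.
#' @param cop_x Centre of pressure along the ground, m, heel-relative and
#'   non-decreasing.
#' @param knee_x,knee_y Sagittal knee-point coordinates, m, lab frame.
#' @param theta_shank Shank angle from vertical, degrees, + forward lean.
#' @param knee_moment Sagittal knee moment, N m, + counterclockwise with +x
#'   the walking direction.
#' @param body_mass,foot_length,lower_leg_length Body parameters of the
#'   subject the curves belong to.
#' @return An object of class `reference_gait` (a list of the validated
#'   channels and body parameters).
#' @export
reference_gait <- function(stance_percent, grf_x, grf_y, cop_x, knee_x,
                           knee_y, theta_shank, knee_moment,
                           body_mass, foot_length, lower_leg_length) {
  chans <- list(stance_percent = stance_percent, grf_x = grf_x,
                grf_y = grf_y, cop_x = cop_x, knee_x = knee_x,
                knee_y = knee_y, theta_shank = theta_shank,
                knee_moment = knee_moment)
  n <- length(stance_percent)
  if (n < 2L) stop("reference gait needs at least 2 samples")
  for (nm in names(chans)) {
    if (length(chans[[nm]]) != n)
      stop(sprintf("channel '%s' length differs from stance_percent", nm))
    if (any(!is.finite(chans[[nm]])))
      stop(sprintf("channel '%s' contains non-finite values", nm))
  }
  if (any(diff(stance_percent) <= 0))
    stop("stance_percent must be strictly increasing")
  if (abs(stance_percent[1L]) > 1e-9 || abs(stance_percent[n] - 100) > 1e-9)
    stop("stance_percent must span [0, 100]")
  if (any(diff(cop_x) < -1e-9))
    stop("cop_x must be non-decreasing (heel to toe progression)")
  if (any(grf_y < -1e-9))
    stop("grf_y must be non-negative throughout stance")
  body <- c(body_mass = body_mass, foot_length = foot_length,
            lower_leg_length = lower_leg_length)
  if (any(!is.finite(body)) || any(body <= 0))
    stop("body parameters must be finite and strictly positive")
  structure(c(chans, as.list(body)), class = "reference_gait")
}

#' @export
print.reference_gait <- function(x, ...) {
  cat(sprintf(
    "Reference gait: %d stance samples, subject %.1f kg / foot %.3f m / leg %.3f m\n",
    length(x$stance_percent), x$body_mass, x$foot_length, x$lower_leg_length))
  cat(sprintf("  peak vertical GRF %.2f BW, CoP excursion %.3f m, theta %.1f..%.1f deg\n",
              max(x$grf_y) / (9.81 * x$body_mass), max(x$cop_x) - min(x$cop_x),
              min(x$theta_shank), max(x$theta_shank)))
  invisible(x)
}

gait_table_columns <- c("stance_percent", "grf_x_N", "grf_y_N", "cop_x_m",
                        "knee_x_m", "knee_y_m", "theta_shank_deg",
                        "knee_moment_Nm")

#' Read a stance-phase gait table
#'
#' Reads the package's documented CSV layout (columns `stance_percent,
#' grf_x_N, grf_y_N, cop_x_m, knee_x_m, knee_y_m, theta_shank_deg,
#' knee_moment_Nm`) plus a JSON sidecar holding `body_mass_kg`,
#' `foot_length_m` and `lower_leg_length_m`.  An alternative column naming
#' can be supplied through `layout`.
#'
#' @param path CSV file path; the sidecar is `<path without .csv>.json`
#'   unless `sidecar` is given.
#' @param layout Named character vector mapping the canonical column names
#'   to the file's column names; defaults to the canonical layout.
#' @param sidecar Optional explicit path of the JSON metadata sidecar.
#' @return A validated [reference_gait()].
#' @export
read_gait_table <- function(path, layout = NULL, sidecar = NULL) {
  if (!file.exists(path)) stop("gait table not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  cols <- stats::setNames(gait_table_columns, gait_table_columns)
  if (!is.null(layout)) cols[names(layout)] <- layout
  missing <- setdiff(unname(cols), names(tab))
  if (length(missing))
    stop("gait table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(sidecar)) sidecar <- sub("\\.csv$", ".json", path)
  if (!file.exists(sidecar)) stop("gait table sidecar not found: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  need <- c("body_mass_kg", "foot_length_m", "lower_leg_length_m")
  if (!all(need %in% names(meta)))
    stop("sidecar is missing field(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  reference_gait(
    stance_percent = tab[[cols["stance_percent"]]],
    grf_x = tab[[cols["grf_x_N"]]], grf_y = tab[[cols["grf_y_N"]]],
    cop_x = tab[[cols["cop_x_m"]]], knee_x = tab[[cols["knee_x_m"]]],
    knee_y = tab[[cols["knee_y_m"]]],
    theta_shank = tab[[cols["theta_shank_deg"]]],
    knee_moment = tab[[cols["knee_moment_Nm"]]],
    body_mass = meta$body_mass_kg, foot_length = meta$foot_length_m,
    lower_leg_length = meta$lower_leg_length_m)
}

#' Write a reference gait to the documented CSV + JSON layout
#'
#' @param ref A [reference_gait()].
#' @param path Output CSV path; the JSON sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_gait_table <- function(ref, path) {
  stopifnot(inherits(ref, "reference_gait"))
  tab <- data.frame(stance_percent = ref$stance_percent,
                    grf_x_N = ref$grf_x, grf_y_N = ref$grf_y,
                    cop_x_m = ref$cop_x, knee_x_m = ref$knee_x,
                    knee_y_m = ref$knee_y, theta_shank_deg = ref$theta_shank,
                    knee_moment_Nm = ref$knee_moment)
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(body_mass_kg = ref$body_mass,
                            foot_length_m = ref$foot_length,
                            lower_leg_length_m = ref$lower_leg_length),
                       sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default configuration of the synthetic reference gait generator
#'
#' The defaults emulate able-bodied level-ground walking at a self-selected
#' speed for a 70 kg subject with a 0.26 m foot and 0.50 m lower leg:
#' double-peaked vertical GRF (~1.15 body weight peaks), braking then
#' propulsive fore-aft GRF (~0.17 BW), monotone heel-to-toe CoP progression
#' to 83% of foot length, and a smooth shank rotation from -15 to +25
#' degrees.  The knee moment is computed from the knee pose, GRF and CoP so
#' the curves are dynamically consistent by construction.
#'
#' @param ... Overrides of the default fields.
#' @return A named list of generator parameters.
#' @export
gait_config <- function(...) {
  cfg <- list(
    body_mass = 70, foot_length = 0.26, lower_leg_length = 0.50,
    n = 101L,
    grf_peak1 = 1.15, grf_peak2 = 1.12,   # body-weight multiples
    grf_peak_width = 0.14,                # fraction of stance
    grf_x_peak = 0.17,                    # body-weight multiple
    cop_excursion = 0.83,                 # fraction of foot length
    theta_start = -15, theta_end = 25,    # deg
    ankle_fraction = 0.25,                # ankle station from heel / L_foot
    noise_sd = 0.01,                      # smooth multiplicative wiggle
    regime_bounds = c(10, 70))            # heel-line / flat / toe-line, %
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown gait_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Synthesize a dynamically consistent stance-phase reference gait
#'
#' Generates an able-bodied-like stance-phase dataset from smooth parametric
#' curve shapes.  The knee point follows the shank rotation about the ankle
#' (knee = lower_leg_length along the shank from the ankle ground point) and
#' the knee moment is set to the cross product of the CoP-to-knee lever with
#' the GRF at every frame, so the moment-consistency identity holds exactly.
#' A small smooth seeded perturbation is applied to the force and angle
#' curves so different seeds give different (but always valid) gaits.
#'
#' @param config Generator parameters from [gait_config()].
#' @param seed Integer seed; the same seed and config reproduce the output
#'   bit for bit.
#' @return A [reference_gait()].
#' @export
synthesize_reference_gait <- function(config = gait_config(), seed = 1L) {
  cfg <- config
  if (any(c(cfg$body_mass, cfg$foot_length, cfg$lower_leg_length) <= 0))
    stop("body parameters in the generator config must be positive")
  s <- seq(0, 1, length.out = cfg$n)
  bw <- 9.81 * cfg$body_mass

  old <- .Random.seed_exists()
  set.seed(seed)
  # smooth low-order Fourier wiggle, zero at both stance ends
  wig <- function(amp) {
    k <- sample(2:4, 1L); ph <- stats::runif(1L, 0, 2 * pi)
    amp * stats::rnorm(1L) * sin(pi * s) * sin(2 * pi * k * s + ph)
  }
  peak_jit <- stats::rnorm(2L, 1, cfg$noise_sd)

  ends <- (1 - exp(-(s / 0.04)^2)) * (1 - exp(-((1 - s) / 0.04)^2))
  gy <- bw * ends * (cfg$grf_peak1 * peak_jit[1L] *
                       exp(-((s - 0.25) / cfg$grf_peak_width)^2) +
                     cfg$grf_peak2 * peak_jit[2L] *
                       exp(-((s - 0.76) / cfg$grf_peak_width)^2))
  gy <- pmax(gy * (1 + wig(cfg$noise_sd)), 0)
  gx <- -bw * cfg$grf_x_peak * sin(2 * pi * s) * sin(pi * s)^0.5
  gx <- gx + bw * wig(cfg$noise_sd / 2)

  cop <- cfg$cop_excursion * cfg$foot_length * (3 * s^2 - 2 * s^3)
  # Shank progression: through mid-stance the knee stays roughly over the
  # CoP (inverted-pendulum vaulting over the planted foot), which keeps the
  # implied knee moment small and physiological; heel-strike and push-off
  # transients blend the end-range angles in.
  cop_ankle0 <- cop - cfg$ankle_fraction * cfg$foot_length
  pend <- asin(pmax(-0.9, pmin(0.9, cop_ankle0 / cfg$lower_leg_length))) *
    180 / pi
  A_hs <- cfg$theta_start - pend[1L]
  A_to <- cfg$theta_end - pend[cfg$n]
  theta <- pend + A_hs * exp(-(s / 0.15)^2) +
    A_to * exp(-((1 - s) / 0.18)^2)
  theta <- theta + 20 * wig(cfg$noise_sd / 4)
  if (old$had) .Random.seed_restore(old)

  th <- theta * pi / 180
  kx <- cfg$lower_leg_length * sin(th)
  ky <- cfg$lower_leg_length * cos(th)
  cop_ankle <- cop - cfg$ankle_fraction * cfg$foot_length
  km <- knee_moment_from_kinetics(cbind(kx, ky), cbind(gx, gy), cop_ankle)

  ref <- reference_gait(stance_percent = 100 * s, grf_x = gx, grf_y = gy,
                        cop_x = cop, knee_x = kx, knee_y = ky,
                        theta_shank = theta, knee_moment = km,
                        body_mass = cfg$body_mass,
                        foot_length = cfg$foot_length,
                        lower_leg_length = cfg$lower_leg_length)
  attr(ref, "ankle_fraction") <- cfg$ankle_fraction
  attr(ref, "regime_bounds") <- cfg$regime_bounds
  ref
}

# preserve the caller's RNG state around seeded generation
.Random.seed_exists <- function() {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  list(had = had, seed = if (had) get(".Random.seed", envir = globalenv()))
}
.Random.seed_restore <- function(old) {
  assign(".Random.seed", old$seed, envir = globalenv())
}

#' Sagittal knee moment implied by the applied kinetics
#'
#' Statics of the lower-leg system: the knee moment equals the 2-D cross
#' product of the lever from the knee to the CoP with the ground reaction
#' force, `(cop - knee) x grf`, with the CoP at `(cop_x, 0)`.  All inputs
#' must share one frame (the lab, ankle-origin frame in this package).
#'
#' @param knee_xy Knee position, length-2 vector or 2-column matrix, m.
#' @param grf Ground reaction force, length-2 vector or 2-column matrix, N.
#' @param cop_x CoP abscissa (same frame as `knee_xy`), m.
#' @return Knee moment in N m (+ counterclockwise), vectorised over rows.
#' @export
knee_moment_from_kinetics <- function(knee_xy, grf, cop_x) {
  knee_xy <- rbind(knee_xy); grf <- rbind(grf)
  unname((cop_x - knee_xy[, 1L]) * grf[, 2L] + knee_xy[, 2L] * grf[, 1L])
}

#' Scale a reference gait to a user's body characteristics
#'
#' GRFs scale with body mass, CoP locations with foot length and the lower
#' leg trajectory (knee coordinates) with lower leg length; the shank angle
#' is dimensionless and unchanged.  Knee moments scale with
#' mass ratio x lower-leg-length ratio (force x lever).
#'
#' @param ref A [reference_gait()].
#' @param user A [user_characteristics()].
#' @return A [reference_gait()] carrying the user's body parameters.
#' @export
scale_to_user <- function(ref, user) {
  stopifnot(inherits(ref, "reference_gait"),
            inherits(user, "user_characteristics"))
  mr <- user$body_mass / ref$body_mass
  fr <- user$foot_length / ref$foot_length
  lr <- user$lower_leg_length / ref$lower_leg_length
  out <- reference_gait(stance_percent = ref$stance_percent,
                        grf_x = ref$grf_x * mr, grf_y = ref$grf_y * mr,
                        cop_x = ref$cop_x * fr,
                        knee_x = ref$knee_x * lr, knee_y = ref$knee_y * lr,
                        theta_shank = ref$theta_shank,
                        knee_moment = ref$knee_moment * mr * lr,
                        body_mass = user$body_mass,
                        foot_length = user$foot_length,
                        lower_leg_length = user$lower_leg_length)
  for (a in c("ankle_fraction", "regime_bounds"))
    if (!is.null(attr(ref, a))) attr(out, a) <- attr(ref, a)
  out
}

#' The nine representative stance instances
#'
#' Stance percents at which the trajectory error is evaluated by default:
#' 8, 20, 27, 36, 50, 62, 75, 80 and 82% of stance (0% heel strike,
#' 100% toe off).  Using these nine instead of the full stance description
#' keeps design-variable optima within 5% at a tenth of the cost.
#'
#' @return Numeric vector of nine stance percents.
#' @export
default_stance_percents <- function() c(8, 20, 27, 36, 50, 62, 75, 80, 82)

#' Resample a reference gait into stance load cases
#'
#' Linearly interpolates every channel at the requested stance percents and
#' assigns each instance a contact regime: heel line contact before the
#' first regime boundary, toe line contact after the second, flat contact
#' in between.  The load-case CoP is expressed in the lab (ankle-origin)
#' frame, shifted from the heel-relative table value by
#' `ankle_fraction * foot_length`.
#'
#' @param ref A [reference_gait()].
#' @param percents Stance percents in \[0, 100\]; defaults to the nine
#'   representative instances of [default_stance_percents()].
#' @param regime_bounds Length-2 vector (percent) separating heel line
#'   contact / flat contact / toe line contact; default `c(10, 70)`.
#' @param ankle_fraction Ankle station from the heel as a fraction of foot
#'   length; default 0.25.
#' @return A list of `load_case` objects, ordered by stance percent, each
#'   with fields `stance_percent`, `grf` (2-vector N), `cop_x` (m, lab
#'   frame), `knee_moment` (N m), `regime`, and the interpolated reference
#'   pose (`knee_x`, `knee_y`, `theta_shank`).
#' @export
resample_stance <- function(ref, percents = default_stance_percents(),
                            regime_bounds = NULL, ankle_fraction = NULL) {
  stopifnot(inherits(ref, "reference_gait"))
  if (length(percents) == 0L) stop("percents must be non-empty")
  if (any(percents < 0 | percents > 100))
    stop("percents must lie within [0, 100]")
  if (is.null(regime_bounds))
    regime_bounds <- attr(ref, "regime_bounds") %||% c(10, 70)
  if (is.null(ankle_fraction))
    ankle_fraction <- attr(ref, "ankle_fraction") %||% 0.25
  percents <- sort(percents)
  ip <- function(ch) stats::approx(ref$stance_percent, ch, xout = percents,
                                   rule = 1)$y
  gx <- ip(ref$grf_x); gy <- ip(ref$grf_y); cop <- ip(ref$cop_x)
  kx <- ip(ref$knee_x); ky <- ip(ref$knee_y)
  th <- ip(ref$theta_shank); km <- ip(ref$knee_moment)
  regime <- ifelse(percents < regime_bounds[1L], "heel_line_contact",
            ifelse(percents > regime_bounds[2L], "toe_line_contact",
                   "flat_contact"))
  lapply(seq_along(percents), function(i) {
    structure(list(stance_percent = percents[i],
                   grf = c(gx[i], gy[i]),
                   cop_x = cop[i] - ankle_fraction * ref$foot_length,
                   cop_x_heel = cop[i],
                   knee_moment = km[i],
                   regime = regime[i],
                   knee_x = kx[i], knee_y = ky[i], theta_shank = th[i]),
              class = "load_case")
  })
}

#' @export
print.load_case <- function(x, ...) {
  cat(sprintf("Load case %5.1f%% [%s]: GRF (%.0f, %.0f) N at CoP %.3f m, M_knee %.1f N m\n",
              x$stance_percent, x$regime, x$grf[1L], x$grf[2L], x$cop_x,
              x$knee_moment))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
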