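# Gait-analysis computations on marker + force-plate step recordings:
# filtering, stance detection, stance normalization, spatiotemporal and
# angular parameters, roll-over geometry, unified-deformable foot power,
# centre-of-mass step-to-step transition work and trajectory deviation
# scores.
#
# A step recording holds 3-D marker trajectories at the kinematic rate
# (default 120 Hz) and per-side force-plate series at the kinetic rate
# (default 960 Hz); x is the direction of travel, y up, z lateral.

#' Zero-phase low-pass Butterworth filter
#'
#' Fourth-order bidirectional (forward-backward, zero phase) low-pass
#' Butterworth, the standard conditioning for motion-capture data: 6 Hz for
#' kinematic and 12 Hz for kinetic channels.
#'
#' @param series Numeric vector, matrix or data frame (filtered by column).
#' @param sample_rate Sampling rate, Hz.
#' @param cutoff_hz Cutoff frequency, Hz; must be below Nyquist.
#' @param order Filter order, default 4.
#' @return The filtered series, same shape as the input.
#' @export
lowpass_filter <- function(series, sample_rate, cutoff_hz, order = 4L) {
  if (cutoff_hz >= sample_rate / 2)
    stop("cutoff must be below the Nyquist frequency")
  if (sample_rate <= 2 * cutoff_hz)
    stop("sample rate must exceed twice the cutoff")
  bf <- signal::butter(order, cutoff_hz / (sample_rate / 2), type = "low")
  f1 <- function(v) {
    # edge handling: remove the endpoint-to-endpoint linear trend and pad
    # by odd reflection (value- and slope-continuous) so the zero-phase
    # pass starts settled; plain filtfilt otherwise leaks edge transients
    # well into the series
    n <- length(v)
    trend <- v[1L] + (v[n] - v[1L]) * (seq_len(n) - 1L) / (n - 1L)
    w <- v - trend
    np <- min(n - 1L, max(16L, ceiling(6 * sample_rate / cutoff_hz)))
    pad <- c(2 * w[1L] - w[(np + 1L):2L],
             w,
             2 * w[n] - w[(n - 1L):(n - np)])
    out <- as.numeric(signal::filtfilt(bf, pad))[(np + 1L):(np + n)]
    out + trend
  }
  if (is.null(dim(series))) return(f1(series))
  out <- series
  for (j in seq_len(ncol(series))) out[, j] <- f1(series[, j])
  out
}

#' Detect stance intervals from vertical GRF
#'
#' Maximal intervals with vertical GRF at or above the contact threshold
#' (default 40 N); gaps and islands shorter than 10 ms (chatter) are
#' merged away.
#'
#' @param grf_vertical Vertical GRF series, N (filtered).
#' @param sample_rate Sampling rate, Hz.
#' @param threshold_N Contact threshold, default 40 N.
#' @return Data frame with `start` and `end` sample indices (inclusive),
#'   one row per stance interval; zero rows when no contact.
#' @export
detect_stance <- function(grf_vertical, sample_rate, threshold_N = 40) {
  on <- grf_vertical >= threshold_N
  if (!any(on)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(on)
  min_len <- max(1L, round(0.010 * sample_rate))
  # merge sub-10 ms gaps, then drop sub-10 ms islands
  gap <- !r$values & r$lengths < min_len
  gap[c(1L, length(gap))] <- FALSE
  r$values[gap] <- TRUE
  r <- rle(inverse.rle(r))
  isl <- r$values & r$lengths < min_len
  r$values[isl] <- FALSE
  r <- rle(inverse.rle(r))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Normalize a series to percent of stance
#'
#' Linear time-interpolation of a series onto an even 0-100% stance grid.
#'
#' @param series Numeric vector or matrix (columns are channels).
#' @param interval Length-2 vector of start/end sample indices.
#' @param n_points Output samples, default 100.
#' @return The resampled series with attribute `percent` (the grid).
#' @export
normalize_to_stance <- function(series, interval, n_points = 100L) {
  i0 <- interval[1L]; i1 <- interval[2L]
  if (i1 - i0 < 1L) stop("stance interval must span at least 2 samples")
  xs <- seq(i0, i1, length.out = n_points)
  f <- function(v) stats::approx(seq_along(v), v, xout = xs)$y
  out <- if (is.null(dim(series))) f(series)
         else apply(series, 2L, f)
  attr(out, "percent") <- seq(0, 100, length.out = n_points)
  out
}

#' Virtual knee marker correction
#'
#' Rotates the measured knee marker about the ankle by the constant sagittal
#' offset angle observed at a calibration frame (foot flat and unloaded), so
#' the corrected knee lies vertically above the ankle at calibration and
#' stays rigid with the shank thereafter.
#'
#' @param knee_marker,ankle_marker n x 2 sagittal (x, y) marker series, m.
#' @param calibration_frame Row index of the calibration frame.
#' @return n x 2 corrected knee series.
#' @export
virtual_knee_correction <- function(knee_marker, ankle_marker,
                                    calibration_frame = 1L) {
  v0 <- knee_marker[calibration_frame, ] - ankle_marker[calibration_frame, ]
  r0 <- sqrt(sum(v0^2))
  if (r0 < 1e-12) stop("zero knee-ankle distance at calibration")
  a_off <- atan2(v0[1L], v0[2L])       # anterior offset from vertical
  R <- rot2(a_off)
  d <- knee_marker - ankle_marker
  ankle_marker + t(R %*% t(d))
}

#' Stance-time symmetry index
#'
#' `SI = 100 (1 - |X_P - X_S| / (0.5 |X_P + X_S|))`; 100% is perfect
#' symmetry between the prosthetic and intact side stance times.
#'
#' @param X_P,X_S Prosthetic and intact stance times, s.
#' @return SI in percent.
#' @export
symmetry_index <- function(X_P, X_S) {
  if (abs(X_P + X_S) < 1e-12) stop("symmetry index undefined for X_P + X_S = 0")
  100 * (1 - abs(X_P - X_S) / (0.5 * abs(X_P + X_S)))
}

#' Froude number of walking
#'
#' `Fr = v^2 / (g L)` with leg length L (hip to floor) and g = 9.81 m/s^2.
#'
#' @param speed Walking speed, m/s.
#' @param leg_length Leg length, m.
#' @return Dimensionless Froude number.
#' @export
froude_number <- function(speed, leg_length) speed^2 / (9.81 * leg_length)

marker_cols <- function(rec, name)
  as.matrix(rec$markers[, paste0(name, c("_x", "_y", "_z"))])

filtered_markers <- function(rec, cutoff = 6) {
  m <- rec$markers
  m[, -1L] <- lowpass_filter(as.matrix(m[, -1L]), rec$meta$marker_rate, cutoff)
  m
}

filtered_plate <- function(rec, side, cutoff = 12) {
  fp <- rec$forceplate[[side]]
  # CoP is a derived location, undefined when unloaded: filtering it across
  # the between-step discontinuity would smear the jump into early stance
  ch <- setdiff(names(fp), c("time", "cop_x"))
  fp[, ch] <- lowpass_filter(as.matrix(fp[, ch]), rec$meta$force_rate, cutoff)
  fp
}

stance_windows <- function(rec, side, threshold_N = 40) {
  fp <- filtered_plate(rec, side)
  iv <- detect_stance(fp$grf_y, rec$meta$force_rate, threshold_N)
  data.frame(t_start = fp$time[iv$start], t_end = fp$time[iv$end])
}

#' Spatiotemporal gait parameters of a step recording
#'
#' Walking speed (mean sacrum velocity along travel), Froude number,
#' stance-time symmetry index, step width (mean lateral ankle distance at
#' foot contacts) and lateral trunk sway range from the shoulder-sacrum
#' trunk frame.
#'
#' @param rec A `step_recording`.
#' @param leg_length Hip-to-floor leg length, m; default from the
#'   recording metadata.
#' @return List: `walking_speed`, `froude`, `symmetry_index`,
#'   `step_width`, `trunk_sway_range`, `stance_times`.
#' @export
spatiotemporal <- function(rec, leg_length = NULL) {
  stopifnot(inherits(rec, "step_recording"))
  if (is.null(leg_length)) leg_length <- rec$meta$leg_length
  m <- filtered_markers(rec)
  tm <- m$time
  sac <- as.matrix(m[, c("sacrum_x", "sacrum_y", "sacrum_z")])
  v <- unname((sac[nrow(sac), 1L] - sac[1L, 1L]) /
                (tm[length(tm)] - tm[1L]))
  wp <- stance_windows(rec, "prosthetic")
  wi <- stance_windows(rec, "intact")
  full_p <- wp[wp$t_start > min(rec$forceplate$prosthetic$time) &
                 wp$t_end < max(rec$forceplate$prosthetic$time), ]
  full_i <- wi[wi$t_start > min(rec$forceplate$intact$time) &
                 wi$t_end < max(rec$forceplate$intact$time), ]
  if (nrow(full_p) == 0L || nrow(full_i) == 0L)
    stop("need at least one complete stance per side")
  X_P <- full_p$t_end[1L] - full_p$t_start[1L]
  X_S <- full_i$t_end[1L] - full_i$t_start[1L]
  contacts <- sort(c(wp$t_start, wi$t_start))
  zp <- stats::approx(tm, m$ankle_p_z, xout = contacts, rule = 2)$y
  zi <- stats::approx(tm, m$ankle_i_z, xout = contacts, rule = 2)$y
  step_width <- mean(abs(zp - zi))
  dz <- m$shoulder_l_z - m$shoulder_r_z
  dy <- m$shoulder_l_y - m$shoulder_r_y
  sway <- atan2(dy, dz) * 180 / pi
  list(walking_speed = v,
       froude = froude_number(v, leg_length),
       symmetry_index = symmetry_index(X_P, X_S),
       step_width = step_width,
       trunk_sway_range = diff(range(sway)),
       stance_times = c(prosthetic = X_P, intact = X_S))
}

leg_suffix <- function(leg) switch(leg, prosthetic = "p", intact = "i",
                                   stop("leg must be prosthetic or intact"))

#' Sagittal foot-shank angle metrics
#'
#' The angle between the foot segment (heel to toe markers) and the shank
#' segment (ankle to knee markers) projected into the sagittal plane.  The
#' neutral angle is its mean during swing (no load); peaks during stance
#' are reported relative to neutral, dorsiflexion positive (foot toward
#' the shin, i.e. decreasing segment angle).
#'
#' @param rec A `step_recording`.
#' @param leg `"prosthetic"` or `"intact"`.
#' @return List: `peak_dorsiflexion`, `peak_plantarflexion`,
#'   `neutral_angle` (deg), and the angle series.
#' @export
foot_angles <- function(rec, leg = "prosthetic") {
  sfx <- leg_suffix(leg)
  m <- filtered_markers(rec)
  tm <- m$time
  g2 <- function(nm) as.matrix(m[, paste0(nm, "_", sfx, c("_x", "_y"))])
  foot <- g2("toe") - g2("heel")
  shank <- g2("knee") - g2("ankle")
  cosg <- rowSums(foot * shank) /
    (sqrt(rowSums(foot^2)) * sqrt(rowSums(shank^2)))
  gamma <- acos(pmin(1, pmax(-1, cosg))) * 180 / pi
  w <- stance_windows(rec, leg)
  in_stance <- rep(FALSE, length(tm))
  for (i in seq_len(nrow(w)))
    in_stance <- in_stance | (tm >= w$t_start[i] & tm <= w$t_end[i])
  if (!any(!in_stance)) stop("no swing samples to define the neutral angle")
  neutral <- mean(gamma[!in_stance])
  dev <- neutral - gamma          # + dorsiflexion
  list(peak_dorsiflexion = max(dev[in_stance]),
       peak_plantarflexion = max(-dev[in_stance]),
       neutral_angle = neutral,
       angle = data.frame(time = tm, foot_shank_angle = gamma,
                          stance = in_stance))
}

# least-squares (Kasa) circle fit; returns centre and radius
fit_circle <- function(pts) {
  if (nrow(pts) < 3L) stop("need at least 3 points for a circle fit")
  if (max(stats::sd(pts[, 1L]), stats::sd(pts[, 2L])) < 1e-9)
    stop("degenerate point cloud: circle fit undefined")
  A <- cbind(2 * pts[, 1L], 2 * pts[, 2L], 1)
  b <- rowSums(pts^2)
  sol <- tryCatch(qr.solve(A, b), error = function(e)
    stop("degenerate point cloud: circle fit undefined"))
  r2 <- sol[3L] + sol[1L]^2 + sol[2L]^2
  if (r2 <= 0) stop("degenerate circle fit")
  list(centre = sol[1:2], radius = sqrt(r2))
}

#' Roll-over shape radius and effective foot length
#'
#' Transforms the CoP path from heel strike to the opposite heel strike
#' into a shank-fixed sagittal frame and fits a circle: its radius
#' (normalized by lower leg length) is the roll-over radius.  The
#' effective foot length is the heel-to-CoP distance at the time of
#' opposite heel contact; EFLR divides it by the physical foot length.
#'
#' @param rec A `step_recording`.
#' @param leg Which leg's roll-over, default prosthetic.
#' @param min_load_frac Minimum vertical load (fraction of body weight)
#'   for a CoP sample to enter the circle fit, default 0.10: force-plate
#'   CoP locations are metrologically unreliable at low loads.
#' @return List: `radius` (m/m), `radius_m`, `effective_foot_length` (m),
#'   `eflr`, and the shank-frame CoP points.
#' @export
rollover <- function(rec, leg = "prosthetic", min_load_frac = 0.10) {
  sfx <- leg_suffix(leg)
  other <- if (leg == "prosthetic") "intact" else "prosthetic"
  m <- filtered_markers(rec)
  fp <- filtered_plate(rec, leg)
  w <- stance_windows(rec, leg)
  wo <- stance_windows(rec, other)
  if (nrow(w) == 0L) stop("no stance detected for ", leg)
  t0 <- w$t_start[1L]
  t1s <- wo$t_start[wo$t_start > t0]
  if (length(t1s) == 0L) stop("no opposite heel strike after heel strike")
  t1 <- t1s[1L]
  thr <- max(40, min_load_frac * 9.81 * rec$meta$body_mass)
  sel <- fp$time >= t0 & fp$time <= t1 & fp$grf_y >= thr
  tt <- fp$time[sel]
  ank <- cbind(stats::approx(m$time, m[[paste0("ankle_", sfx, "_x")]], tt)$y,
               stats::approx(m$time, m[[paste0("ankle_", sfx, "_y")]], tt)$y)
  kne <- cbind(stats::approx(m$time, m[[paste0("knee_", sfx, "_x")]], tt)$y,
               stats::approx(m$time, m[[paste0("knee_", sfx, "_y")]], tt)$y)
  sh <- kne - ank
  th <- atan2(sh[, 1L], sh[, 2L])      # shank angle from vertical
  vx <- fp$cop_x[sel] - ank[, 1L]
  vy <- -ank[, 2L]
  xs <- vx * cos(th) - vy * sin(th)
  ys <- vx * sin(th) + vy * cos(th)
  fit <- fit_circle(cbind(xs, ys))
  cop_t1 <- stats::approx(fp$time, fp$cop_x, xout = t1)$y
  heel_x0 <- stats::approx(m$time, m[[paste0("heel_", sfx, "_x")]],
                           xout = t0)$y
  efl <- cop_t1 - heel_x0
  list(radius = fit$radius / rec$meta$lower_leg_length,
       radius_m = fit$radius,
       effective_foot_length = efl,
       eflr = efl / rec$meta$foot_length,
       shank_frame_cop = cbind(x = xs, y = ys))
}

grad_ct <- function(v, t) {
  n <- length(v)
  g <- numeric(n)
  g[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  g[1L] <- (v[2L] - v[1L]) / (t[2L] - t[1L])
  g[n] <- (v[n] - v[n - 1L]) / (t[n] - t[n - 1L])
  g
}

trapz <- function(t, v) sum(diff(t) * (utils::head(v, -1L) + utils::tail(v, -1L)) / 2)

#' Unified-deformable foot power and energy return
#'
#' Distal shank power of a deformable (non-jointed) foot:
#' `P = F . v + M_free w`, where v is the velocity of the shank material
#' point instantaneously at the CoP, w the sagittal shank angular velocity
#' and M_free the force-plate free moment.  The energy stored and returned
#' is integrated over stance and normalized by body mass; the returned
#' energy is the positive-power integral from the final negative-to-positive
#' crossing to toe off, and the peak push-off power its maximum.
#'
#' @param rec A `step_recording`.
#' @param leg Which leg, default prosthetic.
#' @return List: `power` (data frame, W/kg over stance), `energy_return`
#'   (J/kg), `peak_push_off_power` (W/kg), `net_work` (J/kg),
#'   `free_moment_used` flag.
#' @export
foot_power_and_energy <- function(rec, leg = "prosthetic") {
  sfx <- leg_suffix(leg)
  m <- filtered_markers(rec)
  fp <- filtered_plate(rec, leg)
  w <- stance_windows(rec, leg)
  if (nrow(w) == 0L) stop("no stance detected for ", leg)
  full <- w[w$t_start > fp$time[1L], ]
  t0 <- if (nrow(full)) full$t_start[1L] else w$t_start[1L]
  t1 <- w$t_end[w$t_start == t0][1L]
  tt <- m$time[m$time >= t0 & m$time <= t1]
  ip <- function(v, tb = fp$time) stats::approx(tb, v, xout = tt)$y
  ank <- cbind(ip(m[[paste0("ankle_", sfx, "_x")]], m$time),
               ip(m[[paste0("ankle_", sfx, "_y")]], m$time))
  kne <- cbind(ip(m[[paste0("knee_", sfx, "_x")]], m$time),
               ip(m[[paste0("knee_", sfx, "_y")]], m$time))
  psi <- atan2(kne[, 2L] - ank[, 2L], kne[, 1L] - ank[, 1L])
  omega <- grad_ct(psi, tt)
  v_ank <- cbind(grad_ct(ank[, 1L], tt), grad_ct(ank[, 2L], tt))
  Fx <- ip(fp$grf_x); Fy <- ip(fp$grf_y); cop <- ip(fp$cop_x)
  has_free <- !is.null(fp$free_moment)
  Mf <- if (has_free) ip(fp$free_moment) else 0
  rx <- cop - ank[, 1L]; ry <- -ank[, 2L]
  vmx <- v_ank[, 1L] - omega * ry
  vmy <- v_ank[, 2L] + omega * rx
  P <- (Fx * vmx + Fy * vmy + Mf * omega) / rec$meta$body_mass
  neg2pos <- which(P[-length(P)] < 0 & P[-1L] >= 0)
  i0 <- if (length(neg2pos)) neg2pos[length(neg2pos)] + 1L else 1L
  list(power = data.frame(time = tt, power = P),
       energy_return = trapz(tt[i0:length(tt)], P[i0:length(tt)]),
       peak_push_off_power = max(P[i0:length(P)]),
       net_work = trapz(tt, P),
       free_moment_used = has_free)
}

#' Centre-of-mass step-to-step transition work
#'
#' External mechanical power of each limb is the dot product of its GRF
#' with the CoM velocity, obtained by integrating the net GRF with
#' periodicity constraints over one stride (mean forward velocity equals
#' the walking speed, zero mean vertical velocity).  Collision work is the
#' negative-power integral of the leading limb over double support;
#' propulsion work the positive-power integral of the trailing limb; both
#' per body mass, per leg.
#'
#' @param rec A `step_recording` covering a full stride (both double
#'   supports).
#' @return List: `collision` and `propulsion`, each a named vector
#'   (prosthetic / intact), J/kg, plus the CoM velocity series.
#' @export
com_transition_work <- function(rec) {
  mfilt <- filtered_markers(rec)
  fpp <- filtered_plate(rec, "prosthetic")
  fpi <- filtered_plate(rec, "intact")
  tt <- fpp$time
  mass <- rec$meta$body_mass
  v_walk <- (mfilt$sacrum_x[nrow(mfilt)] - mfilt$sacrum_x[1L]) /
    (mfilt$time[nrow(mfilt)] - mfilt$time[1L])
  wp <- stance_windows(rec, "prosthetic")
  wi <- stance_windows(rec, "intact")
  if (nrow(wp) < 2L)
    stop("stride does not cover both double supports (need two prosthetic contacts)")
  t_str <- c(wp$t_start[1L], wp$t_start[2L])
  # closing sample included so the periodicity constraint spans a full
  # stride
  sel <- tt >= t_str[1L] & tt <= t_str[2L]
  ax <- (fpp$grf_x[sel] + fpi$grf_x[sel]) / mass
  ay <- (fpp$grf_y[sel] + fpi$grf_y[sel]) / mass - 9.81
  ts <- tt[sel]
  n <- length(ts)
  ctrapz <- function(a) c(0, cumsum((a[-1L] + a[-n]) / 2 * diff(ts)))
  detrend <- function(v) v - (v[n] - v[1L]) * (ts - ts[1L]) / (ts[n] - ts[1L])
  # periodicity constraints: v is periodic over the stride, mean forward
  # velocity equals the walking speed, zero mean vertical velocity
  vx <- detrend(ctrapz(ax)); vy <- detrend(ctrapz(ay))
  vx <- vx - mean(vx) + v_walk
  vy <- vy - mean(vy)
  P_p <- (fpp$grf_x[sel] * vx + fpp$grf_y[sel] * vy) / mass
  P_i <- (fpi$grf_x[sel] * vx + fpi$grf_y[sel] * vy) / mass
  loaded_p <- fpp$grf_y[sel] >= 40
  loaded_i <- fpi$grf_y[sel] >= 40
  ds <- loaded_p & loaded_i
  ds[ts >= t_str[2L]] <- FALSE    # the closing instant opens the next cycle
  # the leading limb in a double support is the one that landed last; an
  # interval truncated at the recording start is not a true contact event
  true_starts <- function(w, fp) w$t_start[w$t_start > fp$time[1L] + 1e-9]
  last_contact <- function(starts) vapply(ts, function(t) {
    s <- starts[starts <= t + 1e-9]
    if (length(s)) max(s) else -Inf
  }, numeric(1L))
  lead_p <- ds & last_contact(true_starts(wp, fpp)) >
    last_contact(true_starts(wi, fpi))
  lead_i <- ds & !lead_p
  collision <- c(prosthetic = trapz_mask(ts, pmin(P_p, 0), lead_p),
                 intact = trapz_mask(ts, pmin(P_i, 0), lead_i))
  propulsion <- c(prosthetic = trapz_mask(ts, pmax(P_p, 0), lead_i),
                  intact = trapz_mask(ts, pmax(P_i, 0), lead_p))
  list(collision = collision, propulsion = propulsion,
       com_velocity = data.frame(time = ts, vx = vx, vy = vy))
}

trapz_mask <- function(t, v, mask) {
  if (!any(mask)) return(0)
  idx <- which(mask)
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  sum(vapply(runs, function(i) if (length(i) < 2L) 0 else trapz(t[i], v[i]),
             numeric(1L)))
}

#' Trajectory deviation scores against a reference gait
#'
#' Normalized root-mean-square error between measured percent-normalized
#' step data and the target reference for six variables per leg: GRFs
#' (normalized by body weight), CoP (by foot length), knee coordinates (by
#' lower leg length) and shank angle (by the reference shank-angle range).
#' The total score sums the twelve NRMSE values over both legs.
#'
#' @param measured List with `percent` (the stance grid) and per-leg data
#'   frames `prosthetic` / `intact`, each with columns `grf_x`, `grf_y`,
#'   `cop_x`, `knee_x`, `knee_y`, `theta_shank`.
#' @param ref A [reference_gait()] (already scaled to the user).
#' @param user A [user_characteristics()].
#' @return An object of class `deviation_score`: per-leg NRMSE matrix and
#'   `total`.
#' @export
deviation_scores <- function(measured, ref, user) {
  pct <- measured$percent
  if (any(pct < min(ref$stance_percent) - 1e-9) ||
      any(pct > max(ref$stance_percent) + 1e-9))
    stop("measured percent grid does not match the reference stance range")
  ip <- function(ch) stats::approx(ref$stance_percent, ch, xout = pct)$y
  refs <- list(grf_x = ip(ref$grf_x), grf_y = ip(ref$grf_y),
               cop_x = ip(ref$cop_x), knee_x = ip(ref$knee_x),
               knee_y = ip(ref$knee_y), theta_shank = ip(ref$theta_shank))
  bw <- 9.81 * user$body_mass
  norms <- c(grf_x = bw, grf_y = bw, cop_x = user$foot_length,
             knee_x = user$lower_leg_length, knee_y = user$lower_leg_length,
             theta_shank = diff(range(refs$theta_shank)))
  legs <- c("prosthetic", "intact")
  sc <- matrix(NA_real_, 2L, 6L,
               dimnames = list(legs, names(norms)))
  for (lg in legs) {
    dat <- measured[[lg]]
    for (v in names(norms)) {
      if (length(dat[[v]]) != length(pct))
        stop("grid mismatch for ", lg, " ", v)
      sc[lg, v] <- sqrt(mean((dat[[v]] - refs[[v]])^2)) / norms[[v]]
    }
  }
  structure(list(per_leg = sc, total = sum(sc)), class = "deviation_score")
}

#' @export
print.deviation_score <- function(x, ...) {
  cat("Deviation scores (NRMSE):\n")
  print(round(x$per_leg, 4))
  cat(sprintf("  total %.4f\n", x$total))
  invisible(x)
}
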