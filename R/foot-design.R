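# Wide-Bezier parametric foot model: 6 control circles, 18 stored scalars,
# 11 free design variables, 7 dependent values set by the user's body
# characteristics or coupled to other variables.
#
# Foot frame: origin at the C1 (ankle/attachment) centre, x forward, y up.
# The unloaded sole rests on the ground line y = -h_ank.  The heel extremity
# (C6 centre) sits at x = -ankle_fraction * L_foot and the toe extremity
# (C5 centre) at x = +(1 - ankle_fraction) * L_foot.

independent_var_names <- c("C1.d", "C2.x", "C2.y", "C2.d", "C3.x", "C3.y",
                           "C3.d", "C4.x", "C4.d", "C5.d", "C6.d")

#' Complete a foot design from its 11 independent variables
#'
#' Fills the 7 dependent values: the C1 centre is the frame origin, the toe
#' and heel abscissae are fixed by the user's foot length (ankle at
#' `ankle_fraction` of foot length from the heel), and C4, C5, C6 rest on
#' the ground line (centre y = -h_ank + diameter / 2).
#'
#' @param independent_vars Numeric vector of the 11 free values, in the
#'   order `C1.d, C2.x, C2.y, C2.d, C3.x, C3.y, C3.d, C4.x, C4.d, C5.d,
#'   C6.d` (named vectors are reordered by name).
#' @param user A [user_characteristics()]; supplies `L_foot` (foot length)
#'   and `h_ank` (build height).
#' @param ankle_fraction Ankle station from the heel as a fraction of foot
#'   length, default 0.25.
#' @return An object of class `foot_design`: control-circle matrix
#'   (6 x 3: x, y, diameter), `h_ank`, `L_foot`, `ankle_fraction` and the
#'   11 independent values.
#' @export
complete_design <- function(independent_vars, user, ankle_fraction = 0.25) {
  v <- independent_vars
  if (!is.null(names(v))) {
    if (!setequal(names(v), independent_var_names))
      stop("independent_vars names must be exactly the 11 design variables")
    v <- v[independent_var_names]
  }
  if (length(v) != 11L || any(!is.finite(v)))
    stop("independent_vars must be 11 finite values")
  v <- stats::setNames(as.numeric(v), independent_var_names)
  h <- user$build_height_h_ank
  L <- user$foot_length
  circ <- matrix(NA_real_, 6L, 3L,
                 dimnames = list(paste0("C", 1:6), c("x", "y", "d")))
  circ["C1", ] <- c(0, 0, v["C1.d"])
  circ["C2", ] <- c(v["C2.x"], v["C2.y"], v["C2.d"])
  circ["C3", ] <- c(v["C3.x"], v["C3.y"], v["C3.d"])
  circ["C4", ] <- c(v["C4.x"], -h + v["C4.d"] / 2, v["C4.d"])
  circ["C5", ] <- c((1 - ankle_fraction) * L, -h + v["C5.d"] / 2, v["C5.d"])
  circ["C6", ] <- c(-ankle_fraction * L, -h + v["C6.d"] / 2, v["C6.d"])
  if (any(circ[, "d"] <= 0))
    stop("all control circle diameters must be positive")
  structure(list(circles = circ, h_ank = h, L_foot = L,
                 ankle_fraction = ankle_fraction,
                 independent_vars = v),
            class = "foot_design")
}

#' Extract the 11 independent variables of a design
#' @param design A `foot_design`.
#' @return Named numeric vector of the 11 free values.
#' @export
independent_vars <- function(design) design$independent_vars

#' @export
print.foot_design <- function(x, ...) {
  cat(sprintf("Wide-Bezier foot design: L_foot %.3f m, h_ank %.3f m\n",
              x$L_foot, x$h_ank))
  print(round(x$circles, 4))
  invisible(x)
}

# Bernstein basis of degree n at parameter t (vector), returns matrix
bernstein <- function(t, n) {
  k <- 0:n
  outer(t, k, function(tt, kk) choose(n, kk) * tt^kk * (1 - tt)^(n - kk))
}

# sample one wide-Bezier segment: control points P (m x 2), radii r (m)
sample_wide_bezier <- function(P, r, n_samples) {
  n <- nrow(P) - 1L
  t <- seq(0, 1, length.out = n_samples)
  B <- bernstein(t, n)
  xy <- B %*% P
  # derivative: n * sum (P[k+1]-P[k]) B_{k,n-1}
  dP <- n * diff(P)
  Bd <- bernstein(t, n - 1L)
  d <- Bd %*% dP
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-12)) stop("degenerate Bezier segment (coincident adjacent control centres)")
  list(t = t, xy = xy, tangent = d / len, half_thickness = drop(B %*% r))
}

#' Evaluate the wide-Bezier geometry of a foot design
#'
#' Samples the three centreline segments: the keel as a cubic wide Bezier
#' on the C1..C4 circle centres, and the forefoot (C4 to C5) and heel (C4
#' to C6) as linear wide Beziers.  The half-thickness along each segment is
#' the Bernstein interpolation of the circle radii, so all three segments
#' share the C4 junction point and radius.
#'
#' @param design A `foot_design` from [complete_design()].
#' @param samples_per_segment Number of sample points per segment.
#' @return An object of class `foot_geometry`: list of three segments
#'   (`keel`, `forefoot`, `heel`), each with sampled positions, unit
#'   tangents and half-thicknesses, plus the design.
#' @export
evaluate_geometry <- function(design, samples_per_segment = 40L) {
  stopifnot(inherits(design, "foot_design"))
  C <- design$circles
  r <- C[, "d"] / 2
  keel <- sample_wide_bezier(C[1:4, 1:2, drop = FALSE], r[1:4],
                             samples_per_segment)
  forefoot <- sample_wide_bezier(C[c(4L, 5L), 1:2, drop = FALSE],
                                 r[c(4L, 5L)], samples_per_segment)
  heel <- sample_wide_bezier(C[c(4L, 6L), 1:2, drop = FALSE],
                             r[c(4L, 6L)], samples_per_segment)
  if (any(c(keel$half_thickness, forefoot$half_thickness,
            heel$half_thickness) <= 0))
    stop("half-thickness must be positive everywhere")
  structure(list(keel = keel, forefoot = forefoot, heel = heel,
                 design = design),
            class = "foot_geometry")
}

# offset boundary polylines of one sampled segment (left = +normal)
segment_offsets <- function(seg) {
  n <- cbind(-seg$tangent[, 2L], seg$tangent[, 1L])
  list(left = seg$xy + seg$half_thickness * n,
       right = seg$xy - seg$half_thickness * n)
}

# brute-force test: do segments (p1,p2) and (p3,p4) properly intersect?
segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
  if (abs(den) < 1e-15) return(FALSE)
  s <- ((p3[1L] - p1[1L]) * d2[2L] - (p3[2L] - p1[2L]) * d2[1L]) / den
  u <- ((p3[1L] - p1[1L]) * d1[2L] - (p3[2L] - p1[2L]) * d1[1L]) / den
  s > 1e-9 && s < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
}

#' Check a foot geometry for self-intersection
#'
#' Tests whether any two offset boundary polylines (centreline offset by the
#' local half-thickness along the normal) cross, excluding the neighbourhood
#' of the shared C4 junction where the three segments legitimately meet.
#' Used as a geometric feasibility constraint in the shape optimization.
#'
#' @param geom A `foot_geometry`.
#' @return A list with `violated` (logical) and `pairs`, a matrix of
#'   offending polyline pairs (names of the two polylines).
#' @export
check_self_intersection <- function(geom) {
  stopifnot(inherits(geom, "foot_geometry"))
  C4 <- geom$design$circles["C4", 1:2]
  r4 <- geom$design$circles["C4", "d"] / 2
  polys <- halves <- list()
  for (sn in c("keel", "forefoot", "heel")) {
    off <- segment_offsets(geom[[sn]])
    polys[[paste0(sn, ".left")]] <- off$left
    polys[[paste0(sn, ".right")]] <- off$right
    halves[[paste0(sn, ".left")]] <- geom[[sn]]$half_thickness
    halves[[paste0(sn, ".right")]] <- geom[[sn]]$half_thickness
  }
  hits <- NULL
  pn <- names(polys)
  for (a in seq_along(polys)) for (b in a:length(polys)) {
    A <- polys[[a]]; B <- polys[[b]]
    same <- a == b
    base_a <- sub("\\..*", "", pn[a]); base_b <- sub("\\..*", "", pn[b])
    hit_here <- FALSE
    for (i in seq_len(nrow(A) - 1L)) {
      jj <- if (same) seq(i + 2L, nrow(B) - 1L) else seq_len(nrow(B) - 1L)
      jj <- jj[jj >= 1L & jj <= nrow(B) - 1L]
      for (j in jj) {
        p1 <- A[i, ]; p2 <- A[i + 1L, ]; p3 <- B[j, ]; p4 <- B[j + 1L, ]
        if (base_a != base_b) {
          # crossings inside the junction blend are expected: the three
          # thick segments merge there; the physical blend region extends
          # roughly one combined thickness around the C4 circle
          mid <- (p1 + p2 + p3 + p4) / 4
          blend <- r4 + halves[[a]][i] + halves[[b]][j]
          if (sqrt(sum((mid - C4)^2)) < 1.2 * blend) next
        }
        if (segments_intersect(p1, p2, p3, p4)) {
          hits <- rbind(hits, c(pn[a], pn[b]))
          hit_here <- TRUE
          break
        }
      }
      if (hit_here) break
    }
  }
  list(violated = !is.null(hits), pairs = hits)
}

# resample a sampled segment at equally spaced arc lengths (n_el elements)
resample_by_arc <- function(seg, n_el) {
  d <- sqrt(rowSums(diff(seg$xy)^2))
  s <- c(0, cumsum(d))
  st <- seq(0, s[length(s)], length.out = n_el + 1L)
  ix <- function(v) stats::approx(s, v, xout = st)$y
  list(xy = cbind(ix(seg$xy[, 1L]), ix(seg$xy[, 2L])),
       half_thickness = ix(seg$half_thickness),
       arc = st)
}

#' Mesh a foot geometry into plane-frame elements
#'
#' Allocates elements to the three segments proportionally to arc length,
#' resamples each centreline at equal arc increments, and builds a connected
#' frame mesh sharing a single node at the C4 junction.  Element thickness
#' is twice the mean half-thickness over its span; cross-section area is
#' `width * thickness` and the second moment `width * thickness^3 / 12`.
#' The attachment node (rigid joint to the shank adapter) is at C1.
#'
#' @param geom A `foot_geometry`.
#' @param n_elements Total element count, default 300 (from a mesh
#'   convergence analysis; the tip response changes by less than 1% when
#'   doubled).
#' @param width Out-of-plane extrusion depth in m, default 0.06.
#' @return An object of class `frame_mesh`: `nodes` (n x 2), `elements`
#'   data frame (node pair, length, thickness, width, area, I),
#'   `attachment_node`, and the ordered sole description (`sole_nodes`
#'   heel tip to toe tip, with undeformed bottom-fibre offsets).
#' @export
mesh_geometry <- function(geom, n_elements = 300L, width = 0.06) {
  stopifnot(inherits(geom, "foot_geometry"))
  if (n_elements < 3L) stop("n_elements must be at least 3 (one per segment)")
  segs <- list(keel = geom$keel, forefoot = geom$forefoot, heel = geom$heel)
  arc <- vapply(segs, function(s) sum(sqrt(rowSums(diff(s$xy)^2))),
                numeric(1L))
  n_el <- pmax(1L, round(n_elements * arc / sum(arc)))
  # adjust to the exact requested total
  while (sum(n_el) != n_elements) {
    i <- if (sum(n_el) > n_elements) which.max(n_el) else which.min(n_el)
    n_el[i] <- n_el[i] + sign(n_elements - sum(n_el))
  }
  rs <- Map(resample_by_arc, segs, n_el)

  nodes <- rs$keel$xy                      # node 1 = C1 ... node nk+1 = C4
  junction <- nrow(nodes)
  half <- rs$keel$half_thickness
  seg_nodes <- list(keel = seq_len(junction))
  for (sn in c("forefoot", "heel")) {
    new <- rs[[sn]]$xy[-1L, , drop = FALSE]
    idx <- c(junction, nrow(nodes) + seq_len(nrow(new)))
    nodes <- rbind(nodes, new)
    half <- c(half, rs[[sn]]$half_thickness[-1L])
    seg_nodes[[sn]] <- idx
  }
  el <- NULL
  for (sn in names(seg_nodes)) {
    idx <- seg_nodes[[sn]]
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      th <- half[i] + half[j]              # mean half-thickness * 2
      el <- rbind(el, c(i, j, th))
    }
  }
  L0 <- sqrt(rowSums((nodes[el[, 2L], , drop = FALSE] -
                      nodes[el[, 1L], , drop = FALSE])^2))
  elements <- data.frame(node_i = as.integer(el[, 1L]),
                         node_j = as.integer(el[, 2L]),
                         length = L0, thickness = el[, 3L], width = width,
                         area = width * el[, 3L],
                         I = width * el[, 3L]^3 / 12)
  # sole chain from heel tip to toe tip (heel reversed, then forefoot)
  sole_nodes <- c(rev(seg_nodes$heel[-1L]), seg_nodes$forefoot)
  sole_tangent <- sole_chain_tangents(nodes, sole_nodes)
  sole_offset <- -half[sole_nodes] * cbind(-sole_tangent[, 2L],
                                           sole_tangent[, 1L])
  structure(list(nodes = nodes, elements = elements,
                 attachment_node = 1L, junction_node = junction,
                 sole_nodes = sole_nodes, sole_offset = sole_offset,
                 sole_half = half[sole_nodes],
                 segment_nodes = seg_nodes,
                 design = geom$design),
            class = "frame_mesh")
}

sole_chain_tangents <- function(nodes, chain) {
  p <- nodes[chain, , drop = FALSE]
  n <- nrow(p)
  d <- rbind(p[2L, ] - p[1L, ],
             p[3:n, , drop = FALSE] - p[1:(n - 2L), , drop = FALSE],
             p[n, ] - p[n - 1L, ])
  d / sqrt(rowSums(d^2))
}

#' @export
print.frame_mesh <- function(x, ...) {
  cat(sprintf("Frame mesh: %d nodes, %d elements, attachment at node %d\n",
              nrow(x$nodes), nrow(x$elements), x$attachment_node))
  cat(sprintf("  sole span x = %.3f .. %.3f m, thickness %.1f .. %.1f mm\n",
              min(x$nodes[x$sole_nodes, 1L]), max(x$nodes[x$sole_nodes, 1L]),
              1000 * min(x$elements$thickness),
              1000 * max(x$elements$thickness)))
  invisible(x)
}

#' @export
plot.foot_geometry <- function(x, ...) {
  allxy <- rbind(x$keel$xy, x$forefoot$xy, x$heel$xy)
  graphics::plot(allxy, type = "n", asp = 1, xlab = "x [m]", ylab = "y [m]",
                 ...)
  for (sn in c("keel", "forefoot", "heel")) {
    off <- segment_offsets(x[[sn]])
    graphics::lines(x[[sn]]$xy, col = "grey50")
    graphics::lines(off$left, col = "steelblue")
    graphics::lines(off$right, col = "steelblue")
  }
  graphics::abline(h = -x$design$h_ank, lty = 3)
  invisible(x)
}

# ---- outline construction and export ---------------------------------------

# arc points on a circle from angle a1 to a2, clockwise or counterclockwise
arc_points <- function(centre, r, a1, a2, ccw = FALSE, step = 0.1) {
  if (ccw) { while (a2 < a1) a2 <- a2 + 2 * pi }
  else     { while (a2 > a1) a2 <- a2 - 2 * pi }
  if (abs(a2 - a1) < 1e-9) return(NULL)
  ang <- seq(a1, a2, by = if (ccw) step else -step)
  if (ang[length(ang)] != a2) ang <- c(ang, a2)
  cbind(centre[1L] + r * cos(ang), centre[2L] + r * sin(ang))
}

# Single closed outer boundary of the Y-shaped thick structure.  Segments
# are oriented away from the shared C4 junction and walked in CCW order of
# their outgoing directions: right offset edge out, CCW tip cap, left edge
# back, then a clockwise arc on the C4 circle across the wedge to the next
# segment.  All three segments end with the C4 radius at the junction
# (Bernstein endpoint property), so the connecting arcs are exact.
foot_outline <- function(geom) {
  C4 <- geom$design$circles["C4", 1:2]
  r4 <- geom$design$circles["C4", "d"] / 2
  segs <- list(
    keel = reverse_segment(geom$keel),     # C4 -> C1
    forefoot = geom$forefoot,              # C4 -> C5
    heel = geom$heel)                      # C4 -> C6
  ang <- vapply(segs, function(s) atan2(s$tangent[1L, 2L], s$tangent[1L, 1L]),
                numeric(1L))
  ord <- order(ang)                        # counterclockwise walk
  segs <- segs[ord]; ang <- ang[ord]
  pts <- NULL
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    off <- segment_offsets(s)
    n <- nrow(s$xy)
    tip <- s$xy[n, ]; rt <- s$half_thickness[n]
    tip_ang <- atan2(s$tangent[n, 2L], s$tangent[n, 1L])
    pts <- rbind(pts,
                 off$right,
                 arc_points(tip, rt, tip_ang - pi / 2, tip_ang + pi / 2,
                            ccw = TRUE),
                 off$left[n:1, , drop = FALSE])
    kn <- if (k == length(segs)) 1L else k + 1L
    pts <- rbind(pts,
                 arc_points(C4, r4, ang[k] + pi / 2, ang[kn] - pi / 2))
  }
  pts
}

reverse_segment <- function(seg) {
  n <- nrow(seg$xy)
  list(t = rev(seg$t), xy = seg$xy[n:1, , drop = FALSE],
       tangent = -seg$tangent[n:1, , drop = FALSE],
       half_thickness = seg$half_thickness[n:1])
}

#' Export the foot outline for manufacture
#'
#' Writes the closed outer boundary polyline of a non-self-intersecting
#' foot geometry in millimetres, as a single-path SVG or a minimal ASCII
#' DXF (one closed LWPOLYLINE), suitable for waterjet or milling toolpaths.
#'
#' @param geom A `foot_geometry`.
#' @param format `"svg"` or `"dxf"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_outline <- function(geom, format = c("svg", "dxf"), path) {
  format <- match.arg(format)
  chk <- check_self_intersection(geom)
  if (chk$violated)
    stop("geometry is self-intersecting; refusing to export an outline")
  pts <- foot_outline(geom) * 1000  # mm
  if (format == "svg") {
    d <- paste0("M ", paste(sprintf("%.6f %.6f", pts[, 1L], -pts[, 2L]),
                            collapse = " L "), " Z")
    xmlv <- c('<?xml version="1.0" encoding="UTF-8"?>',
              sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%.3fmm" height="%.3fmm">',
                      diff(range(pts[, 1L])), diff(range(pts[, 2L]))),
              sprintf('<path d="%s" fill="none" stroke="black"/>', d),
              '</svg>')
    writeLines(xmlv, path)
  } else {
    lines <- c("0", "SECTION", "2", "ENTITIES", "0", "LWPOLYLINE",
               "8", "0", "90", as.character(nrow(pts)), "70", "1")
    for (i in seq_len(nrow(pts)))
      lines <- c(lines, "10", sprintf("%.6f", pts[i, 1L]),
                 "20", sprintf("%.6f", pts[i, 2L]))
    lines <- c(lines, "0", "ENDSEC", "0", "EOF")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back an outline written by [export_outline()]
#'
#' Parses the single SVG path (or DXF LWPOLYLINE) into its vertex matrix in
#' millimetres, for round-trip checks of exported geometry.
#'
#' @param path File written by [export_outline()].
#' @return Numeric matrix of outline vertices (mm), y up.
#' @export
read_outline <- function(path) {
  txt <- readLines(path)
  if (any(grepl("<svg", txt))) {
    d <- sub('.*<path d="([^"]*)".*', "\\1", paste(txt, collapse = " "))
    d <- gsub("[MLZ]", "", d)
    v <- as.numeric(strsplit(trimws(gsub("\\s+", " ", d)), " ")[[1L]])
    m <- matrix(v, ncol = 2L, byrow = TRUE)
    m[, 2L] <- -m[, 2L]
    m
  } else {
    xi <- which(txt == "10"); yi <- which(txt == "20")
    cbind(as.numeric(txt[xi + 1L]), as.numeric(txt[yi + 1L]))
  }
}

#' Default bounds on the 11 independent design variables
#'
#' Keeps every candidate structure within a box of roughly the biological
#' foot envelope: `L_foot` long and `h_ank + 0.02 m` tall.
#'
#' @param user A [user_characteristics()].
#' @return A `design_bounds` object: list with `lower` and `upper` named
#'   vectors over the 11 independent variables.
#' @export
default_design_bounds <- function(user) {
  h <- user$build_height_h_ank
  L <- user$foot_length
  lower <- c(C1.d = 0.010, C2.x = -0.2 * L, C2.y = -h + 0.004,
             C2.d = 0.006, C3.x = -0.1 * L, C3.y = -h + 0.004,
             C3.d = 0.006, C4.x = 0.0, C4.d = 0.006,
             C5.d = 0.006, C6.d = 0.006)
  upper <- c(C1.d = 0.050, C2.x = 0.45 * L, C2.y = 0.0,
             C2.d = 0.050, C3.x = 0.55 * L, C3.y = 0.0,
             C3.d = 0.050, C4.x = 0.45 * L, C4.d = 0.040,
             C5.d = 0.030, C6.d = 0.030)
  if (any(lower >= upper)) stop("degenerate bounds")
  structure(list(lower = lower, upper = upper), class = "design_bounds")
}

#' A representative shipped foot design
#'
#' A feasible mid-of-design-space wide-Bezier foot for the default user
#' (70 kg, 0.26 m foot, 0.50 m lower leg, 0.07 m build height), used in
#' examples and as the standard test foot.
#'
#' @param user Optional [user_characteristics()]; default the reference
#'   subject of [gait_config()].
#' @return A `foot_design`.
#' @export
example_foot_design <- function(user = NULL) {
  if (is.null(user))
    user <- user_characteristics(70, 0.26, 0.50, residuum_length = 0.15,
                                 build_height_h_ank = 0.07)
  complete_design(c(C1.d = 0.030, C2.x = 0.010, C2.y = -0.025,
                    C2.d = 0.024, C3.x = 0.030, C3.y = -0.048,
                    C3.d = 0.020, C4.x = 0.035, C4.d = 0.018,
                    C5.d = 0.012, C6.d = 0.012), user)
}

#' Serialize / restore a foot design as JSON
#'
#' @param design A `foot_design`.
#' @param path JSON output path.
#' @return `path` (write) or a `foot_design` (read).
#' @export
write_foot_design <- function(design, path) {
  jsonlite::write_json(list(units = "m",
                            independent_vars = as.list(design$independent_vars),
                            h_ank_m = design$h_ank,
                            L_foot_m = design$L_foot,
                            ankle_fraction = design$ankle_fraction),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_foot_design
#' @export
read_foot_design <- function(path) {
  j <- jsonlite::fromJSON(path)
  v <- unlist(j$independent_vars)
  # rebuild through the completion rules; h_ank/L_foot stored directly
  user <- user_characteristics(body_mass = 70, foot_length = j$L_foot_m,
                               lower_leg_length = j$h_ank_m + 0.4,
                               residuum_length = 0.1,
                               build_height_h_ank = j$h_ank_m)
  complete_design(v, user, ankle_fraction = j$ankle_fraction)
}
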