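test_that("design completion fills the dependent values from the user", {
  user <- user_characteristics(55.9, 0.252, 0.440, residuum_length = 0.15,
                               build_height_h_ank = 0.06)
  vars <- c(C1.d = 0.030, C2.x = 0.010, C2.y = -0.020, C2.d = 0.024,
            C3.x = 0.030, C3.y = -0.040, C3.d = 0.020, C4.x = 0.035,
            C4.d = 0.018, C5.d = 0.020, C6.d = 0.012)
  d <- complete_design(vars, user)
  expect_equal(unname(d$circles["C1", c("x", "y")]), c(0, 0))
  expect_equal(unname(d$circles["C5", "y"]), -0.06 + 0.020 / 2)
  # heel-to-toe centre extent equals the foot length
  expect_equal(unname(d$circles["C5", "x"] - d$circles["C6", "x"]), 0.252)
  # completion then extraction is the identity on the 11 free values
  expect_equal(independent_vars(d), vars)
  # shuffled named input is reordered
  expect_equal(independent_vars(complete_design(rev(vars), user)), vars)

  bad <- vars; bad["C3.d"] <- -0.01
  expect_error(complete_design(bad, user), "positive")
})

test_that("wide-Bezier sampling honours endpoint and partition-of-unity properties", {
  user <- default_user()
  # collinear, equally spaced keel centres -> straight centreline
  vars <- c(C1.d = 0.020, C2.x = 0.010, C2.y = -0.021, C2.d = 0.020,
            C3.x = 0.020, C3.y = -0.042, C3.d = 0.020, C4.x = 0.030,
            C4.d = 0.016, C5.d = 0.016, C6.d = 0.016)
  d <- complete_design(vars, user)
  # make C4 exactly on the C1..C3 line: C4 centre y = -h + d/2 = -0.062
  # and the line through (0,0),(0.01,-0.021),(0.02,-0.042) has slope -2.1;
  # adjust C2/C3 instead to the exact line through C1 and C4
  C4 <- d$circles["C4", ]
  t <- c(1, 2) / 3
  vars["C2.x"] <- t[1L] * C4["x"]; vars["C2.y"] <- t[1L] * C4["y"]
  vars["C3.x"] <- t[2L] * C4["x"]; vars["C3.y"] <- t[2L] * C4["y"]
  d <- complete_design(vars, user)
  g <- evaluate_geometry(d, samples_per_segment = 21L)
  # endpoints interpolate the first/last control centres
  expect_equal(unname(g$keel$xy[1L, ]), unname(d$circles["C1", 1:2]))
  expect_equal(unname(g$keel$xy[21L, ]), unname(d$circles["C4", 1:2]))
  # straight segment: all points on the C1-C4 line
  dir <- unname(d$circles["C4", 1:2]) / sqrt(sum(d$circles["C4", 1:2]^2))
  cross <- g$keel$xy[, 1L] * dir[2L] - g$keel$xy[, 2L] * dir[1L]
  expect_lt(max(abs(cross)), 1e-12)
  # equal diameters on the forefoot -> constant half-thickness d/2
  expect_equal(g$forefoot$half_thickness, rep(0.008, 21L))
  # keel half-thickness endpoints are the C1 and C4 radii
  expect_equal(g$keel$half_thickness[1L], vars[["C1.d"]] / 2)
  expect_equal(g$keel$half_thickness[21L], vars[["C4.d"]] / 2)

  degen <- vars
  degen["C2.x"] <- 0; degen["C2.y"] <- 0   # C2 coincides with C1
  dd <- complete_design(degen, user)
  expect_error(evaluate_geometry(dd, 5L), "degenerate")
})

test_that("the keel centreline stays inside the convex hull of its control centres", {
  user <- default_user()
  set.seed(42)
  for (i in 1:10) {
    vars <- c(C1.d = runif(1, 0.015, 0.04), C2.x = runif(1, -0.02, 0.06),
              C2.y = runif(1, -0.06, -0.005), C2.d = runif(1, 0.01, 0.03),
              C3.x = runif(1, 0.0, 0.08), C3.y = runif(1, -0.06, -0.01),
              C3.d = runif(1, 0.01, 0.03), C4.x = runif(1, 0.01, 0.06),
              C4.d = runif(1, 0.01, 0.03), C5.d = 0.012, C6.d = 0.012)
    d <- complete_design(vars, user)
    g <- evaluate_geometry(d, 25L)
    P <- d$circles[1:4, 1:2]
    hull <- grDevices::chull(P)
    hp <- P[hull, , drop = FALSE]
    # every sampled point inside (or on) the hull polygon
    inside <- apply(g$keel$xy, 1L, function(q) {
      n <- nrow(hp)
      s <- vapply(seq_len(n), function(k) {
        a <- hp[k, ]; b <- hp[if (k == n) 1L else k + 1L, ]
        (b[1L] - a[1L]) * (q[2L] - a[2L]) - (b[2L] - a[2L]) * (q[1L] - a[1L])
      }, numeric(1L))
      all(s >= -1e-10) || all(s <= 1e-10)
    })
    expect_true(all(inside))
  }
})

test_that("self-intersection is detected for steered-through and over-thick designs", {
  user <- default_user()
  ok <- evaluate_geometry(example_foot_design())
  expect_false(check_self_intersection(ok)$violated)

  # heel steered through the keel body: keel pulled far posterior and low,
  # so the heel segment crosses it away from the junction
  bad <- complete_design(c(C1.d = 0.020, C2.x = -0.045, C2.y = -0.055,
                           C2.d = 0.010, C3.x = -0.040, C3.y = -0.060,
                           C3.d = 0.010, C4.x = 0.030, C4.d = 0.012,
                           C5.d = 0.012, C6.d = 0.012), user)
  gb <- evaluate_geometry(bad)
  chk <- check_self_intersection(gb)
  expect_true(chk$violated)
  # confirmed by a brute-force pairwise crossing count on the offsets
  n_cross <- 0L
  polys <- list()
  for (sn in c("keel", "forefoot", "heel")) {
    off <- lltefoot:::segment_offsets(gb[[sn]])
    polys <- c(polys, list(off$left, off$right))
  }
  C4 <- bad$circles["C4", 1:2]
  for (a in 1:5) for (b in (a + 1):6) {
    A <- polys[[a]]; B <- polys[[b]]
    for (i in seq_len(nrow(A) - 1L)) for (j in seq_len(nrow(B) - 1L)) {
      mid <- (A[i, ] + A[i + 1L, ] + B[j, ] + B[j + 1L, ]) / 4
      if (sqrt(sum((mid - C4)^2)) < 0.05) next
      if (lltefoot:::segments_intersect(A[i, ], A[i + 1L, ], B[j, ], B[j + 1L, ]))
        n_cross <- n_cross + 1L
    }
  }
  expect_gt(n_cross, 0L)

  # thickness so large at a tight keel bend that the inner offsets cross
  thick <- complete_design(c(C1.d = 0.045, C2.x = 0.055, C2.y = -0.008,
                             C2.d = 0.050, C3.x = -0.020, C3.y = -0.055,
                             C3.d = 0.050, C4.x = 0.045, C4.d = 0.040,
                             C5.d = 0.014, C6.d = 0.014), user)
  expect_true(check_self_intersection(evaluate_geometry(thick))$violated)
})

test_that("meshing preserves element count, arc length and section properties", {
  g <- evaluate_geometry(example_foot_design())
  mesh <- mesh_geometry(g, 300L, width = 0.06)
  expect_equal(nrow(mesh$elements), 300L)
  arc_geom <- sum(vapply(list(g$keel, g$forefoot, g$heel),
                         function(s) sum(sqrt(rowSums(diff(s$xy)^2))),
                         numeric(1L)))
  expect_equal(sum(mesh$elements$length), arc_geom, tolerance = 1e-3)
  expect_equal(mesh$attachment_node, 1L)
  expect_equal(unname(mesh$nodes[1L, ]), c(0, 0))
  # connectivity: every node reachable from the attachment
  adj <- lapply(seq_len(nrow(mesh$nodes)), function(i) integer(0))
  for (e in seq_len(nrow(mesh$elements))) {
    i <- mesh$elements$node_i[e]; j <- mesh$elements$node_j[e]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(nrow(mesh$nodes)); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  expect_true(all(seen))

  expect_equal(mesh$elements$I, 0.06 * mesh$elements$thickness^3 / 12)
  expect_equal(mesh$elements$area, 0.06 * mesh$elements$thickness)
  # straight uniform forefoot of a flat-sole design -> equal element lengths
  mf <- mesh_geometry(evaluate_geometry(flat_sole_design()), 60L, 0.06)
  ff <- mf$segment_nodes$forefoot
  lens <- mf$elements$length[mf$elements$node_j %in% ff[-1L] &
                               mf$elements$node_i %in% ff]
  expect_lt(diff(range(lens)), 1e-9)
  expect_error(mesh_geometry(g, 2L), "at least 3")
})

test_that("a 0.01 x 0.06 m section yields I = 5e-9 m^4", {
  m <- straight_frame_mesh(0.25, 10L, 0.01, 0.06)
  expect_equal(unique(m$elements$I), 5e-9)
  expect_equal(unique(m$elements$area), 6e-4)
})

test_that("tip response is mesh-converged between 300 and 600 elements", {
  user <- default_user()
  mat <- nylon66()
  g <- evaluate_geometry(example_foot_design())
  tip <- function(n) {
    mesh <- mesh_geometry(g, n, 0.06)
    toe <- mesh$sole_nodes[length(mesh$sole_nodes)]
    st <- solve_quasi_static(mesh, mat, point_load(c(0, 300), node = toe),
                             solver_options(increments = 4L))
    st$u[toe, 2L]
  }
  d300 <- tip(300L); d600 <- tip(600L)
  expect_lt(abs(d600 - d300) / abs(d600), 0.01)
})

test_that("outline export round-trips and refuses bad geometry", {
  dir <- withr::local_tempdir()
  g <- evaluate_geometry(example_foot_design())
  svg <- file.path(dir, "foot.svg")
  export_outline(g, "svg", svg)
  expect_true(file.exists(svg))
  expect_equal(sum(grepl("<path", readLines(svg))), 1L)  # one closed path
  pts <- read_outline(svg)
  expect_lt(max(abs(pts - lltefoot:::foot_outline(g) * 1000)), 1e-6)

  dxf <- file.path(dir, "foot.dxf")
  export_outline(g, "dxf", dxf)
  expect_lt(max(abs(read_outline(dxf) - lltefoot:::foot_outline(g) * 1000)),
            1e-6)

  bad <- evaluate_geometry(complete_design(
    c(C1.d = 0.020, C2.x = -0.045, C2.y = -0.055, C2.d = 0.010,
      C3.x = -0.040, C3.y = -0.060, C3.d = 0.010, C4.x = 0.030,
      C4.d = 0.012, C5.d = 0.012, C6.d = 0.012), default_user()))
  out <- file.path(dir, "bad.svg")
  expect_error(export_outline(bad, "svg", out), "self-intersect")
  expect_false(file.exists(out))
})

test_that("foot designs serialize to JSON and back", {
  d <- example_foot_design()
  path <- file.path(withr::local_tempdir(), "foot.json")
  write_foot_design(d, path)
  back <- read_foot_design(path)
  expect_equal(independent_vars(back), independent_vars(d))
  expect_equal(back$circles, d$circles)
})
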