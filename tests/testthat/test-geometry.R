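# Flight-direction angles, inter-bat bearings, the angle-decomposed
# relative velocity and the received-frequency estimator.

# straight-line trajectory helper: constant velocity from p0
line_traj <- function(p0, vel, n_frames = 31, fr = 30, id = "b") {
  t <- (seq_len(n_frames) - 1) / fr
  data.frame(bat_id = id, frame = seq_len(n_frames) - 1L, t_s = t,
             x_m = p0[1] + vel[1] * t, y_m = p0[2] + vel[2] * t,
             z_m = p0[3] + vel[3] * t)
}

sm_line <- function(p0, vel, id = "b")
  fit_polynomials(line_traj(p0, vel, id = id), segment_len_s = 2, order = 3)

test_that("flight directions obey the quadrant contract", {
  fr <- 30
  d <- flight_directions(sm_line(c(0, 0, 0), c(1, 0, 0)), n = 5L)
  expect_equal(d$theta, 0, tolerance = 1e-9)
  expect_equal(d$phi, 0, tolerance = 1e-9)

  d <- flight_directions(sm_line(c(0, 0, 0), c(0, 1, 0)), n = 5L)
  expect_equal(d$theta, pi / 2, tolerance = 1e-9)

  # displacement (1, 1, -1) m per frame
  d <- flight_directions(sm_line(c(0, 0, 0), c(1, 1, -1) * fr), n = 5L)
  expect_equal(d$theta, pi / 4, tolerance = 1e-9)
  expect_equal(d$phi, -pi / 4, tolerance = 1e-9)
  expect_equal(d$v, sqrt(3) * fr, tolerance = 1e-9)
})

test_that("inter-bat bearings and separation match hand evaluation", {
  a <- sm_line(c(1, 1, 1), c(0.1, 0, 0), id = "a")
  b <- sm_line(c(2, 3, 0), c(0.1, 0, 0), id = "b")
  g <- inter_bat_geometry(a, b, n = 0L)
  expect_equal(g$theta_ab, atan2(2, 1), tolerance = 1e-9)
  expect_equal(g$phi_ab, atan2(-1, 1), tolerance = 1e-9)
  expect_equal(g$separation, sqrt(6), tolerance = 1e-9)

  # B directly +x / +y of A
  bx <- sm_line(c(3, 1, 1), c(0.1, 0, 0), id = "bx")
  g <- inter_bat_geometry(a, bx, n = 0L)
  expect_equal(g$theta_ab, 0, tolerance = 1e-9)
  expect_equal(g$phi_ab, 0, tolerance = 1e-9)
  by <- sm_line(c(1, 3, 1), c(0.1, 0, 0), id = "by")
  expect_equal(inter_bat_geometry(a, by, n = 0L)$theta_ab, pi / 2,
               tolerance = 1e-9)

  # swapping the pair flips the azimuth bearing by pi (mod 2 pi)
  g_ab <- inter_bat_geometry(a, b, n = 3L)
  g_ba <- inter_bat_geometry(b, a, n = 3L)
  expect_equal((g_ab$theta_ab - g_ba$theta_ab) %% (2 * pi), pi,
               tolerance = 1e-9)
  expect_equal(g_ab$separation, g_ba$separation, tolerance = 1e-12)

  expect_error(inter_bat_geometry(a, a, n = 0L), "coincident")
})

test_that("relative velocity matches hand-worked cases", {
  mk_dir <- function(theta, phi, v) data.frame(theta = theta, phi = phi, v = v)
  mk_geom <- function(theta_ab, phi_ab) data.frame(theta_ab = theta_ab,
                                                   phi_ab = phi_ab,
                                                   separation = 1)
  # both stationary
  expect_equal(relative_velocity(mk_dir(0, 0, 0), mk_dir(0, 0, 0),
                                 mk_geom(0, 0)), 0)
  # head-on closure: A at origin moving +x at 1 m/s, B at (2,0,0) moving -x
  v_ba <- relative_velocity(mk_dir(0, 0, 1), mk_dir(pi, 0, 1), mk_geom(0, 0))
  expect_equal(v_ba, -2, tolerance = 1e-12)
})

test_that("planar configurations reproduce the exact vector projection", {
  set.seed(42)
  n <- 2000
  worst <- 0
  for (k in seq_len(n)) {
    pa <- runif(2, -5, 5); pb <- runif(2, -5, 5)
    if (sqrt(sum((pb - pa)^2)) < 1e-3) next
    va <- runif(2, -4, 4); vb <- runif(2, -4, 4)
    dir_a <- data.frame(theta = atan2(va[2], va[1]), phi = 0,
                        v = sqrt(sum(va^2)))
    dir_b <- data.frame(theta = atan2(vb[2], vb[1]), phi = 0,
                        v = sqrt(sum(vb^2)))
    d <- pb - pa
    geom <- data.frame(theta_ab = atan2(d[2], d[1]),
                       phi_ab = 0, separation = sqrt(sum(d^2)))
    v_eq <- relative_velocity(dir_a, dir_b, geom)
    v_or <- sum((vb - va) * d / sqrt(sum(d^2)))   # brute-force projection
    worst <- max(worst, abs(v_eq - v_or))
  }
  expect_lt(worst, 1e-9)
})

test_that("|v_BA| never exceeds the sum of the speeds", {
  set.seed(7)
  for (k in 1:500) {
    da <- data.frame(theta = runif(1, -pi, pi), phi = runif(1, -pi/2, pi/2),
                     v = runif(1, 0, 6))
    db <- data.frame(theta = runif(1, -pi, pi), phi = runif(1, -pi/2, pi/2),
                     v = runif(1, 0, 6))
    g <- data.frame(theta_ab = runif(1, -pi, pi),
                    phi_ab = runif(1, -pi/2, pi/2), separation = 1)
    expect_lte(abs(relative_velocity(da, db, g)), da$v + db$v + 1e-12)
  }
})

test_that("received CF2 obeys the Doppler identity and mode contracts", {
  # zero relative velocity: identity in both modes
  expect_equal(as.numeric(received_cf2(68000, 0, mode = "as_printed")), 68000)
  expect_equal(as.numeric(received_cf2(68000, 0, mode = "signed")), 68000)

  # direct evaluation of the published magnitude form
  expect_equal(as.numeric(received_cf2(68000, -2, 343.5, "as_printed")),
               68000 * 343.5 / 341.5, tolerance = 1e-12)

  # the published form never down-shifts, and grows with |v|
  v <- seq(-10, 10, by = 0.5)
  est <- as.numeric(received_cf2(68000, v, mode = "as_printed"))
  expect_true(all(est >= 68000))
  o <- order(abs(v))
  expect_true(all(diff(est[o]) >= -1e-9))

  # the signed mode distinguishes approach from recession
  expect_gt(as.numeric(received_cf2(68000, -2, mode = "signed")), 68000)
  expect_lt(as.numeric(received_cf2(68000, 2, mode = "signed")), 68000)

  expect_error(received_cf2(68000, 400), "sound speed")
  expect_error(received_cf2(-1, 0), "cf2_b")
  expect_identical(attr(received_cf2(68000, 1), "mode"), "as_printed")
})
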