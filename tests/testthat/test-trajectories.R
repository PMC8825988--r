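# Kinematic properties of the group-flight trajectory generator.

test_that("a degenerate speed band yields constant-speed flight", {
  sc <- simulation_scene("wide", n_bats = 1, duration_s = 10, seed = 2,
                         speed_band = c(2.2, 2.2))
  tr <- simulate_trajectories(sc, a_max = Inf)[[1]]
  sp <- sqrt(diff(tr$x_m)^2 + diff(tr$y_m)^2 + diff(tr$z_m)^2) *
    sc$frame_rate
  expect_true(all(abs(sp - 2.2) < 0.01))
})

test_that("trajectories stay inside the chamber and have exact frame counts", {
  for (preset in c("narrow", "wide")) {
    sc <- simulation_scene(preset, n_bats = 3, duration_s = 6, seed = 9)
    trs <- simulate_trajectories(sc)
    dims <- sc$chamber_dims
    for (tr in trs) {
      expect_equal(nrow(tr), 6 * 30)
      expect_identical(tr$frame, 0:(nrow(tr) - 1L))
      expect_true(all(tr$x_m > 0 & tr$x_m < dims[1]))
      expect_true(all(tr$y_m > 0 & tr$y_m < dims[2]))
      expect_true(all(tr$z_m > 0 & tr$z_m < dims[3]))
    }
  }
})

test_that("bats fly closer together in the narrow space than the wide space", {
  mean_pair_dist <- function(trs) {
    pairs <- utils::combn(length(trs), 2)
    mean(apply(pairs, 2, function(p) {
      a <- trs[[p[1]]]; b <- trs[[p[2]]]
      mean(sqrt((a$x_m - b$x_m)^2 + (a$y_m - b$y_m)^2 + (a$z_m - b$z_m)^2))
    }))
  }
  d_n <- mean_pair_dist(simulate_trajectories(
    simulation_scene("narrow", n_bats = 3, duration_s = 20, seed = 7)))
  d_w <- mean_pair_dist(simulate_trajectories(
    simulation_scene("wide", n_bats = 3, duration_s = 20, seed = 7)))
  expect_lt(d_n, d_w)
})

test_that("identical seeds reproduce identical coordinates", {
  sc <- simulation_scene("narrow", n_bats = 2, duration_s = 4, seed = 13)
  t1 <- simulate_trajectories(sc)
  t2 <- simulate_trajectories(sc)
  for (k in seq_along(t1))
    expect_identical(t1[[k]][c("x_m", "y_m", "z_m")],
                     t2[[k]][c("x_m", "y_m", "z_m")])
})

test_that("mean speeds track the configured band", {
  sc <- simulation_scene("narrow", n_bats = 3, duration_s = 10, seed = 7)
  trs <- simulate_trajectories(sc)
  targets <- seq(sc$speed_band[1], sc$speed_band[2], length.out = 3)
  for (k in 1:3) {
    tr <- trs[[k]]
    sp <- sqrt(diff(tr$x_m)^2 + diff(tr$y_m)^2 + diff(tr$z_m)^2) * 30
    expect_lt(abs(mean(sp) - targets[k]), 0.15)
  }
})

test_that("a chamber too small for the turn radius is rejected", {
  sc <- simulation_scene(chamber_dims = c(1.0, 1.0, 2.4), n_bats = 1,
                         duration_s = 2, seed = 1)
  expect_error(simulate_trajectories(sc), "too small")
})
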