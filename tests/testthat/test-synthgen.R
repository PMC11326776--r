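test_that("degenerate motion (D = 0, V = 0, no noise) stays in place", {
  d <- straight_dendrite(20)
  cfg <- sim_config(sigma_loc_um = 0,
                    states = data.frame(kind = "D", d_um2_s = 0,
                                        speed_um_s = 0, orientation = NA),
                    trans = matrix(1, 1, 1), init = 1)
  sim <- simulate_trajectory(cfg, d, 50, start = c(10, 0), seed = 1)
  expect_equal(length(unique(sim$trajectory$x_um)), 1L)
  expect_equal(length(unique(sim$trajectory$y_um)), 1L)
})

test_that("frame interval is exactly the configured 20 Hz spacing", {
  d <- straight_dendrite(20)
  sim <- simulate_trajectory(sim_config_control(), d, 40, start = c(10, 0),
                             seed = 2)
  expect_true(all(abs(diff(sim$trajectory$t_s) - 0.05) < 1e-12))
})

test_that("a start position outside the shaft is rejected", {
  d <- straight_dendrite(20, halfwidth_um = 1)
  expect_error(
    simulate_trajectory(sim_config_control(), d, 10, start = c(10, 5)),
    "outside")
})

test_that("same seed gives identical outputs (full reproducibility)", {
  d <- simulate_dendrite(40, n_spines = 3, seed = 1)
  a <- simulate_experiment(sim_config_control(), sim_config_stimulated(),
                           d, n_particles = 5, n_frames = 40,
                           exo_fraction = 0.3, seed = 99)
  b <- simulate_experiment(sim_config_control(), sim_config_stimulated(),
                           d, n_particles = 5, n_frames = 40,
                           exo_fraction = 0.3, seed = 99)
  expect_identical(a, b)
})

test_that("per-axis steps of a pure-diffusion state are Gaussian 2D dt", {
  d <- straight_dendrite(2000, halfwidth_um = 50)  # wide: no reflections
  D <- 0.08
  cfg <- sim_config(sigma_loc_um = 0,
                    states = data.frame(kind = "D", d_um2_s = D,
                                        speed_um_s = 0, orientation = NA),
                    trans = matrix(1, 1, 1), init = 1,
                    reflect_boundaries = FALSE)
  sim <- simulate_trajectory(cfg, d, 10001, start = c(1000, 0), seed = 1)
  dx <- diff(sim$trajectory$x_um)
  dy <- diff(sim$trajectory$y_um)
  v_target <- 2 * D * 0.05
  n <- length(dx)
  se <- v_target * sqrt(2 / n)  # SE of a Gaussian variance estimate
  expect_lt(abs(var(dx) - v_target), 3 * se)
  expect_lt(abs(var(dy) - v_target), 3 * se)
  expect_gt(shapiro.test(sample(dx, 3000))$p.value, 1e-3)
})

test_that("ensemble MSD matches the closed form 4 D t + (V t)^2", {
  # single mixed state, no localisation noise, free 2D motion
  st <- data.frame(kind = "DV", d_um2_s = 0.1, vx_um_s = 0.5, vy_um_s = 0)
  dt <- 0.05
  n_traj <- 400
  disp2 <- matrix(NA_real_, n_traj, 1)
  set.seed(5)
  r2_lag1 <- replicate(n_traj, {
    g <- simulate_hmm_steps(st, matrix(1, 1, 1), 20, dt_s = dt,
                            sigma_loc_um = 0)
    (g$trajectory$x_um[2] - g$trajectory$x_um[1])^2 +
      (g$trajectory$y_um[2] - g$trajectory$y_um[1])^2
  })
  expected <- 4 * 0.1 * dt + (0.5 * dt)^2
  se <- sd(r2_lag1) / sqrt(n_traj)
  expect_lt(abs(mean(r2_lag1) - expected), 3 * se)
})

test_that("ground-truth chains re-estimate the configured transition matrix", {
  d <- straight_dendrite(400, halfwidth_um = 20)
  A <- matrix(c(0.95, 0.05, 0.08, 0.92), 2, byrow = TRUE)
  cfg <- sim_config(trans = A)
  set.seed(6)
  from <- integer(0); to <- integer(0)
  for (r in 1:20) {
    sim <- simulate_trajectory(cfg, d, 501, start = c(200, 0))
    z <- sim$truth$states
    from <- c(from, z[-length(z)])
    to <- c(to, z[-1])
  }
  for (a in 1:2) {
    n_a <- sum(from == a)
    for (b in 1:2) {
      p_hat <- sum(from == a & to == b) / n_a
      se <- sqrt(A[a, b] * (1 - A[a, b]) / n_a)
      expect_lt(abs(p_hat - A[a, b]), 3 * se)
    }
  }
})

test_that("region modulation applies exactly where ground truth says IN", {
  d <- straight_dendrite(90)
  cfg <- sim_config_stimulated()
  sim <- simulate_trajectory(cfg, d, 301, start = c(50, 0), seed = 8)
  pr <- project_to_path(sim$truth$true_positions, d)
  in_ref <- abs(pr$s - d$uncaging_s) <= cfg$region_halfwidth_um
  # per-step flag refers to the position before the step
  expect_identical(sim$truth$in_region,
                   in_ref[seq_along(sim$truth$in_region)])
})

test_that("bleaching traces follow per-fluorophore geometric survival", {
  # no bleaching: constant trace, never complete
  b0 <- simulate_bleaching(4, 0, 50, seed = 1)
  expect_equal(unique(b0$intensity), 4)
  expect_true(is.na(b0$bleach_complete_frame))

  # single fluorophore: mean bleach frame ~ geometric mean 1/p
  p <- 0.5
  set.seed(2)
  frames <- replicate(4000, simulate_bleaching(1, p, 1000)$bleach_complete_frame)
  se <- sd(frames) / sqrt(length(frames))
  expect_lt(abs(mean(frames) - 1 / p), 3 * se)

  # tetramer: completion within 100 frames matches a direct Monte-Carlo
  # estimate of P(max of 4 geometrics <= 100)
  p4 <- 0.04
  set.seed(3)
  done <- replicate(2000, {
    !is.na(simulate_bleaching(4, p4, 100)$bleach_complete_frame)
  })
  p_ref <- mean(replicate(20000, max(rgeom(4, p4) + 1) <= 100))
  se <- sqrt(p_ref * (1 - p_ref) * (1 / 2000 + 1 / 20000))
  expect_lt(abs(mean(done) - p_ref), 3 * se)
})

test_that("stimulated experiments raise AT->D switching only inside", {
  d <- straight_dendrite(90)
  ctrl <- sim_config_control()
  stim <- sim_config_stimulated()
  ex <- simulate_experiment(ctrl, stim, d, n_particles = 60,
                            n_frames = 200, seed = 11)
  count_rates <- function(cond) {
    from_in <- c(); to_in <- c(); from_out <- c(); to_out <- c()
    for (id in names(ex$truth)) {
      if (!startsWith(id, cond)) next
      tr <- ex$truth[[id]]
      z <- tr$states
      inr <- tr$in_region
      ok <- !is.na(z[-length(z)]) & !is.na(z[-1])
      f <- z[-length(z)][ok]; t <- z[-1][ok]; r <- inr[-length(inr)][ok]
      from_in <- c(from_in, f[r]); to_in <- c(to_in, t[r])
      from_out <- c(from_out, f[!r]); to_out <- c(to_out, t[!r])
    }
    c(k_in = sum(from_in == 2 & to_in == 1) / max(1, sum(from_in == 2)),
      n_in = sum(from_in == 2),
      k_out = sum(from_out == 2 & to_out == 1) / max(1, sum(from_out == 2)),
      n_out = sum(from_out == 2))
  }
  rc <- count_rates("control")
  # control: inside and outside AT->D frequencies equal within sampling err
  se <- sqrt(0.02 * 0.98 * (1 / rc["n_in"] + 1 / rc["n_out"]))
  expect_lt(abs(rc["k_in"] - rc["k_out"]), 3 * se)

  rs <- count_rates("stimulated")
  # stimulated: inside k_AT->D raised threefold (0.06 vs 0.02)
  se_in <- sqrt(0.06 * 0.94 / rs["n_in"])
  se_out <- sqrt(0.02 * 0.98 / rs["n_out"])
  expect_lt(abs(rs["k_in"] - 0.06), 3 * se_in)
  expect_lt(abs(rs["k_out"] - 0.02), 3 * se_out)
})

test_that("exocytosis-linked trajectories end docked at the event site", {
  d <- straight_dendrite(60)
  ex <- simulate_experiment(sim_config_control(), NULL, d,
                            n_particles = 30, n_frames = 120,
                            exo_fraction = 0.5, docked_tail_frames = 25,
                            seed = 13)
  expect_gt(nrow(ex$events), 0)
  for (e in seq_len(nrow(ex$events))) {
    id <- ex$events$trajectory_id[e]
    tr <- ex$trajectories[ex$trajectories$trajectory_id == id, ]
    term <- c(tail(tr$x_um, 1), tail(tr$y_um, 1))
    dist <- sqrt((term[1] - ex$events$x_um[e])^2 +
                 (term[2] - ex$events$y_um[e])^2)
    expect_lt(dist, 0.15)  # only localisation noise away
    expect_equal(ex$events$onset_frame[e], nrow(tr) + 1L)
    # docked tail is immobile up to localisation noise
    tail_x <- tail(tr$x_um, 25)
    expect_lt(sd(tail_x), 0.05)
  }
})

test_that("trajectory CSV round trip preserves the table", {
  d <- straight_dendrite(20)
  sim <- simulate_trajectory(sim_config_control(), d, 30, start = c(10, 0),
                             seed = 4)
  path <- tempfile(fileext = ".csv")
  write_trajectories(sim$trajectory, path)
  back <- read_trajectories(path)
  expect_equal(back$x_um, sim$trajectory$x_um, tolerance = 1e-12)
  expect_equal(back$frame, sim$trajectory$frame)
  unlink(path)
})
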