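test_that("radius of confinement is the max centroid distance", {
  expect_equal(radius_of_confinement(make_traj(1, 2)), 0)
  expect_equal(radius_of_confinement(make_traj(c(0, 2), c(0, 0))), 1)
  set.seed(3)
  tr <- make_traj(rnorm(100), rnorm(100))
  cm <- c(mean(tr$x_um), mean(tr$y_um))
  ref <- 0
  for (i in 1:100)
    ref <- max(ref, sqrt((tr$x_um[i] - cm[1])^2 + (tr$y_um[i] - cm[2])^2))
  expect_equal(radius_of_confinement(tr), ref, tolerance = 1e-12)
})

test_that("radius of confinement is translation invariant and scales", {
  set.seed(4)
  tr <- make_traj(rnorm(50), rnorm(50))
  r0 <- radius_of_confinement(tr)
  shifted <- make_traj(tr$x_um + 100, tr$y_um - 7)
  expect_equal(radius_of_confinement(shifted), r0, tolerance = 1e-12)
  scaled <- make_traj(3 * tr$x_um, 3 * tr$y_um)
  expect_equal(radius_of_confinement(scaled), 3 * r0, tolerance = 1e-12)
})

test_that("theta endpoints: longitudinal = 90, lateral = 0", {
  d <- straight_dendrite(90)
  long <- make_traj(seq(0, 4, length.out = 9), rep(1, 9))
  expect_equal(directional_bias_theta(long, d)$theta_deg, 90,
               tolerance = 1e-9)
  lat <- make_traj(rep(0, 11), seq(0.5, 1.5, length.out = 11))
  expect_equal(directional_bias_theta(lat, d)$theta_deg, 0,
               tolerance = 1e-9)
})

test_that("theta for an oblique trajectory matches direct vector algebra", {
  d <- straight_dendrite(90)
  # two points symmetric about CM = (10, 1), farthest displacement at 45
  # degrees to the path, CM offset laterally from the centerline
  tr <- make_traj(c(10 - 1, 10 + 1), c(1 - 1, 1 + 1))
  res <- directional_bias_theta(tr, d)
  u <- c(0, -1)                       # CM -> nearest centerline point
  v <- c(-1, -1) / sqrt(2)            # CM -> farthest point (earliest tie)
  ref <- acos(abs(sum(u * v))) * 180 / pi
  expect_equal(res$theta_deg, ref, tolerance = 1e-6)
  expect_equal(res$theta_deg, 45, tolerance = 1e-6)
})

test_that("theta is invariant under joint rigid motion", {
  d <- straight_dendrite(40)
  set.seed(5)
  tr <- make_traj(5 + cumsum(rnorm(30, 0.05, 0.1)),
                  0.8 + cumsum(rnorm(30, 0, 0.05)))
  t0 <- directional_bias_theta(tr, d)$theta_deg
  # rotate dendrite and trajectory together by 37 degrees + translate
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(11, -4)
  d2 <- d
  pts <- cbind(tr$x_um, tr$y_um) %*% t(R)
  tr2 <- make_traj(pts[, 1] + shift[1], pts[, 2] + shift[2])
  d2$centerline <- d$centerline %*% t(R)
  d2$centerline[, 1] <- d2$centerline[, 1] + shift[1]
  d2$centerline[, 2] <- d2$centerline[, 2] + shift[2]
  t1 <- directional_bias_theta(tr2, d2)$theta_deg
  expect_equal(t1, t0, tolerance = 1e-9)
})

test_that("degenerate trajectories are flagged, on-path CM uses the normal", {
  d <- straight_dendrite(40)
  allsame <- make_traj(rep(3, 5), rep(1, 5))
  res <- directional_bias_theta(allsame, d)
  expect_true(res$degenerate)
  expect_true(is.na(res$theta_deg))
  # CM exactly on the centerline: reference line = local normal, so a
  # longitudinal trajectory still reads 90 degrees
  onpath <- make_traj(c(2, 4), c(0, 0))
  expect_equal(directional_bias_theta(onpath, d)$theta_deg, 90,
               tolerance = 1e-9)
})

test_that("photobleach adjustment is the control fold loss", {
  expect_equal(adjust_counts(8, 10, 10), 8)       # identity fold loss
  expect_equal(adjust_counts(8, 20, 10), 16)      # printed example
  # adjusted / raw equals fold loss for any inputs
  set.seed(6)
  for (i in 1:20) {
    pre <- sample(5:50, 1); post <- sample(1:50, 1); n <- sample(1:30, 1)
    expect_equal(adjust_counts(n, pre, post) / n, pre / post,
                 tolerance = 1e-12)
  }
  expect_error(adjust_counts(5, 10, 0), "n_post_control")
})

test_that("a constant-background movie has no exocytic events", {
  empty <- data.frame(trajectory_id = integer(), frame = integer(),
                      t_s = numeric(), x_um = numeric(), y_um = numeric(),
                      intensity = numeric(), channel = character())
  st <- render_movie(empty, nx = 32, ny = 16, background = 20, seed = 7)
  st$data <- array(rep(st$data[1, , ], 40), dim = c(40, 16, 32))
  res <- detect_exocytosis(st)
  expect_equal(nrow(res$events), 0L)
})

test_that("injected appearance transients are each found once, on time", {
  d <- straight_dendrite(10)
  inj <- data.frame(
    trajectory_id = rep(1:3, each = 21),
    frame = c(30:50, 60:80, 20:40), t_s = 0,
    x_um = rep(c(2, 5, 8), each = 21),
    y_um = rep(c(1.0, 1.3, 0.8), each = 21),
    intensity = 3000, channel = "sim")
  st <- render_movie(inj, nx = 70, ny = 16, background = 10, seed = 9)
  res <- detect_exocytosis(st, d)
  expect_equal(nrow(res$events), 3L)
  got <- res$events[order(res$events$onset_frame), ]
  expect_equal(got$onset_frame, c(20, 30, 60), tolerance = 1)
  expect_equal(got$x_um, c(8, 2, 5), tolerance = 0.16)
  expect_equal(got$y_um, c(0.8, 1.0, 1.3), tolerance = 0.16)
  # rate normalisation: events per um of dendrite per minute
  dur_min <- (dim(st$data)[1] - 1) * st$dt_s / 60
  expect_equal(res$rate_per_um_min, 3 / (10 * dur_min))
})

test_that("the event rate helper is plain arithmetic", {
  expect_equal(exocytosis_rate(6, 20, 3), 0.1)
  expect_error(exocytosis_rate(1, 0, 3), "> 0")
})

test_that("pre-exocytosis linkage finds docked tails and strips them", {
  d <- straight_dendrite(60)
  ex <- simulate_experiment(sim_config_control(), NULL, d,
                            n_particles = 12, n_frames = 180,
                            exo_fraction = 0.5, docked_tail_frames = 40,
                            seed = 23)
  # events fire 2 frames after each docked trajectory ends
  ev <- ex$events
  ev$onset_frame <- ev$onset_frame + 1L
  res <- link_pre_exocytosis(ex$trajectories, ev)
  truth_linked <- vapply(ex$truth, function(t) !is.na(t$exo_event_id),
                         logical(1))
  expect_equal(res$label == "pre_exocytosis",
               unname(truth_linked[res$trajectory_id]))
  linked <- res[res$label == "pre_exocytosis", ]
  for (i in seq_len(nrow(linked))) {
    dock_true <- ex$truth[[linked$trajectory_id[i]]]$dock_onset_frame
    expect_lt(abs(linked$dock_onset_step[i] - dock_true), 10)
  }

  # no events at all: everything is non_exocytosis
  res0 <- link_pre_exocytosis(ex$trajectories, ev[0, ])
  expect_true(all(res0$label == "non_exocytosis"))

  # an event far from every trajectory links nothing
  far <- data.frame(event_id = 99L, x_um = 500, y_um = 500,
                    onset_frame = 100L)
  res1 <- link_pre_exocytosis(ex$trajectories, far)
  expect_true(all(res1$label == "non_exocytosis"))
})
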