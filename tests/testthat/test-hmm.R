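two_state <- data.frame(kind = c("D", "DV"), d_um2_s = c(0.02, 0.02),
                        vx_um_s = c(0, 1.2), vy_um_s = c(0, 0),
                        stringsAsFactors = FALSE)
A2 <- matrix(c(0.98, 0.02, 0.02, 0.98), 2, byrow = TRUE)

test_that("a zero-displacement trajectory collapses to one diffusive state", {
  tr <- make_traj(rep(1, 60), rep(2, 60))
  m <- fit_hmm(tr, sigma_loc_um = 0)
  expect_equal(m$K, 1L)
  expect_equal(m$states$kind, "D")
  expect_lt(m$states$d_um2_s, 1e-9)
})

test_that("K = 1 diffusive fit equals the closed-form step estimator", {
  g <- simulate_hmm_steps(data.frame(kind = "D", d_um2_s = 0.1,
                                     vx_um_s = 0, vy_um_s = 0),
                          matrix(1, 1, 1), 300, sigma_loc_um = 0.02,
                          seed = 1)
  sigma <- 0.02
  m <- fit_hmm(g$trajectory, max_states = 1, sigma_loc_um = sigma)
  dt <- 0.05
  dr2 <- diff(g$trajectory$x_um)^2 + diff(g$trajectory$y_um)^2
  d_closed <- max(sum(dr2) / (4 * length(dr2) * dt) - sigma^2 / dt, 0)
  expect_equal(m$states$d_um2_s[1], d_closed, tolerance = 1e-9)
})

test_that("model selection is consistent on pure diffusion across lengths", {
  pure <- data.frame(kind = "D", d_um2_s = 0.1, vx_um_s = 0, vy_um_s = 0)
  for (len in c(100, 500, 2000)) {
    k1 <- sapply(1:10, function(s) {
      g <- simulate_hmm_steps(pure, matrix(1, 1, 1), len,
                              seed = 1000 * len + s)
      fit_hmm(g$trajectory)$K
    })
    expect_gte(mean(k1 == 1), 0.9)
  }
})

test_that("a two-state diffusion/transport chain is recovered", {
  g <- simulate_hmm_steps(two_state, A2, 1000, seed = 4)
  m <- fit_hmm(g$trajectory)
  expect_equal(m$K, 2L)
  expect_equal(sum(m$states$kind == "DV"), 1L)
  dv <- which(m$states$kind == "DV")
  expect_lt(abs(m$states$speed_um_s[dv] - 1.2) / 1.2, 0.15)
  acc <- mean((m$states$kind[m$path] == "DV") == (g$states == 2))
  expect_gte(acc, 0.8)
  # transition rows are normalised
  expect_true(all(abs(rowSums(m$trans) - 1) < 1e-9))
})

test_that("short trajectories fall back to a single state with a warning", {
  g <- simulate_hmm_steps(two_state, A2, 15, seed = 5)
  expect_warning(m <- fit_hmm(g$trajectory), "single-state")
  expect_equal(m$K, 1L)
})

test_that("transition rates count decoded switches and flag undefined rows", {
  # hand-constructed model around the decoded path D,D,AT,AT,AT,D
  hand_model <- function(states, path) {
    structure(list(K = nrow(states), states = states,
                   trans = diag(nrow(states)),
                   init = rep(1 / nrow(states), nrow(states)),
                   path = path,
                   posterior = matrix(1, length(path), nrow(states)),
                   loglik = 0, bic = 0, converged = TRUE,
                   candidates = NULL, dt_s = 0.05,
                   n_steps = length(path), sigma_loc_um = 0.02),
              class = "motion_state_model")
  }
  two <- data.frame(kind = c("D", "DV"), d_um2_s = c(0.05, 0.05),
                    vx_um_s = c(0, 1), vy_um_s = c(0, 0),
                    speed_um_s = c(0, 1), occupancy = c(0.5, 0.5),
                    stringsAsFactors = FALSE)
  m <- hand_model(two, c(1L, 1L, 2L, 2L, 2L, 1L))
  tr <- transition_rates(m)
  expect_equal(unname(tr$rates["k_D_AT"]), 1 / 2)
  expect_equal(unname(tr$rates["k_D_D"]), 1 / 2)
  expect_equal(unname(tr$rates["k_AT_D"]), 1 / 3)
  expect_equal(unname(tr$rates["k_AT_AT"]), 2 / 3)

  # single-state model: k_D_D = 1, AT rates undefined (NA, not zero)
  one <- data.frame(kind = "D", d_um2_s = 0.05, vx_um_s = 0, vy_um_s = 0,
                    speed_um_s = 0, occupancy = 1, stringsAsFactors = FALSE)
  m1 <- hand_model(one, rep(1L, 30))
  tr1 <- transition_rates(m1)
  expect_equal(unname(tr1$rates["k_D_D"]), 1)
  expect_true(is.na(tr1$rates["k_AT_D"]))
  expect_true(is.na(tr1$rates["k_AT_AT"]))
})

test_that("motion-type classification follows the DV-state definition", {
  g <- simulate_hmm_steps(data.frame(kind = "D", d_um2_s = 0.1,
                                     vx_um_s = 0, vy_um_s = 0),
                          matrix(1, 1, 1), 200, seed = 6)
  m <- fit_hmm(g$trajectory)
  cl <- classify_motion_type(m)
  expect_equal(cl$motion_type, "diffusion_only")
  expect_false(cl$multi_state)

  g2 <- simulate_hmm_steps(two_state, A2, 1000, seed = 7)
  m2 <- fit_hmm(g2$trajectory)
  cl2 <- classify_motion_type(m2)
  expect_equal(cl2$motion_type, "active_transport")
  expect_true(cl2$multi_state)
})

test_that("classified transport fraction tracks the generated fraction", {
  res <- sapply(1:60, function(i) {
    if (i <= 24) {  # 40% generated with a transport state
      g <- simulate_hmm_steps(two_state, A2, 300, seed = 300 + i)
    } else {
      g <- simulate_hmm_steps(data.frame(kind = "D", d_um2_s = 0.1,
                                         vx_um_s = 0, vy_um_s = 0),
                              matrix(1, 1, 1), 300, seed = 300 + i)
    }
    classify_motion_type(fit_hmm(g$trajectory))$motion_type
  })
  frac <- mean(res == "active_transport")
  expect_lt(abs(frac - 0.4), 0.1)
})

test_that("re-segmentation leaves unambiguous fits unchanged and splits
           concatenated single-state tracks near the junction", {
  g <- simulate_hmm_steps(two_state, A2, 600, seed = 8)
  m <- fit_hmm(g$trajectory)
  expect_identical(segment_and_refit(g$trajectory, m), m)

  # two long single-state halves joined at step 400
  ga <- simulate_hmm_steps(data.frame(kind = "D", d_um2_s = 0.02,
                                      vx_um_s = 0, vy_um_s = 0),
                           matrix(1, 1, 1), 400, seed = 9)
  gb <- simulate_hmm_steps(data.frame(kind = "DV", d_um2_s = 0.02,
                                      vx_um_s = 1.2, vy_um_s = 0),
                           matrix(1, 1, 1), 400, seed = 10)
  xb <- gb$trajectory$x_um - gb$trajectory$x_um[1] +
    tail(ga$trajectory$x_um, 1)
  yb <- gb$trajectory$y_um - gb$trajectory$y_um[1] +
    tail(ga$trajectory$y_um, 1)
  tr <- make_traj(c(ga$trajectory$x_um, xb[-1]),
                  c(ga$trajectory$y_um, yb[-1]))
  m0 <- fit_hmm(tr)
  ref <- segment_and_refit(tr, m0, posterior_threshold = 1.01)
  change <- which(diff(ref$path) != 0)
  expect_true(any(abs(change - 400) <= 10))
  # refit never lowers the decoded-path posterior
  mp0 <- mean(m0$posterior[cbind(seq_along(m0$path), m0$path)])
  mp1 <- mean(ref$posterior[cbind(seq_along(ref$path), ref$path)])
  expect_gte(mp1, mp0 - 1e-12)
})
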