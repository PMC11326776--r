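#' Simulate displacement steps directly from the motion-state HMM
#'
#' Step-level companion to [simulate_trajectory()]: generates a trajectory
#' whose displacements follow the hidden-Markov emission model exactly
#' (fixed per-state velocity vectors, Gaussian steps with per-axis variance
#' `2 D dt`, plus localisation noise), with no dendrite geometry, boundary
#' reflection or heading re-draws. This is the reference generator for
#' motion-state inference tests, where the generative process must match
#' the model family being fitted.
#'
#' @param states data.frame with columns `kind` ("D"/"DV"), `d_um2_s`,
#'   `vx_um_s`, `vy_um_s`.
#' @param trans K x K transition matrix (rows sum to 1).
#' @param n_steps Number of steps (the trajectory has `n_steps + 1` points).
#' @param dt_s Frame interval (s).
#' @param sigma_loc_um Localisation noise SD per axis (um).
#' @param init Initial state distribution (default uniform).
#' @param seed Optional integer seed.
#' @return A list with `trajectory` (common schema) and `states` (true
#'   state index per step).
#' @export
simulate_hmm_steps <- function(states, trans, n_steps, dt_s = 0.05,
                               sigma_loc_um = 0.02, init = NULL,
                               seed = NULL) {
  K <- nrow(states)
  if (!is.matrix(trans) || nrow(trans) != K || ncol(trans) != K ||
      any(abs(rowSums(trans) - 1) > 1e-9))
    .stopf("'trans' must be a %d x %d stochastic matrix", K, K)
  if (n_steps < 1) .stopf("'n_steps' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- rep(1 / K, K)
  z <- integer(n_steps)
  z[1] <- sample.int(K, 1, prob = init)
  for (i in seq_len(n_steps - 1L))
    z[i + 1L] <- sample.int(K, 1, prob = trans[z[i], ])
  mux <- states$vx_um_s * dt_s
  muy <- states$vy_um_s * dt_s
  sdv <- sqrt(2 * states$d_um2_s * dt_s)
  dx <- rnorm(n_steps, mux[z], sdv[z])
  dy <- rnorm(n_steps, muy[z], sdv[z])
  x <- c(0, cumsum(dx)) + rnorm(n_steps + 1L, 0, sigma_loc_um)
  y <- c(0, cumsum(dy)) + rnorm(n_steps + 1L, 0, sigma_loc_um)
  trajectory <- data.frame(
    trajectory_id = 1L, frame = seq_len(n_steps + 1L),
    t_s = (seq_len(n_steps + 1L) - 1) * dt_s,
    x_um = x, y_um = y, intensity = 1000, channel = "sim",
    stringsAsFactors = FALSE)
  list(trajectory = trajectory, states = z)
}
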