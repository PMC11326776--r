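#' Simulation configuration for vesicle motion
#'
#' Bundles the parameters of the Markov-switching motion model used by the
#' trajectory generator: frame interval, localisation noise, the per-state
#' motion parameters (diffusion coefficient `D` for purely diffusive states,
#' and `D` plus a drift speed for directed-transport states), the baseline
#' state-transition matrix, and an optional spatial modulation that applies
#' a different transition matrix and a scaling of `D` inside the stimulated
#' region `|s - uncaging_s| <= region_halfwidth_um`.
#'
#' State displacements over one frame are Gaussian per axis with mean
#' `V * dt` and variance `2 * D * dt`, i.e. directed transport is drift plus
#' Brownian diffusion, consistent with the mean-squared-displacement model
#' `<r^2> = 4 D dt + (V dt)^2`. Directed-state headings are drawn once per
#' state entry: aligned with the local centerline tangent (random sign) for
#' `orientation = "longitudinal"` states, or with the local normal for
#' `"lateral"` states.
#'
#' @param dt_s Frame interval in seconds (default 0.05, i.e. 20 Hz).
#' @param pixel_size_nm Camera pixel size (default 160 nm).
#' @param sigma_loc_um Localisation noise standard deviation per axis (um).
#' @param states data.frame with columns `kind` ("D" or "DV"), `d_um2_s`,
#'   `speed_um_s` and `orientation` ("longitudinal"/"lateral"/NA).
#' @param trans Baseline K x K transition matrix (rows sum to 1).
#' @param init Initial state distribution (default stationary-ish uniform).
#' @param region_trans Optional K x K transition matrix used inside the
#'   stimulated region.
#' @param region_d_scale Multiplier applied to all `D` inside the region.
#' @param region_halfwidth_um Half-width of the stimulated region (um).
#' @param n_fluorophores Fluorophores per surface-like particle (homotetramer
#'   default 4).
#' @param p_bleach Per-frame per-fluorophore bleach probability.
#' @param reflect_boundaries Reflect motion at the shaft walls and dendrite
#'   ends (default TRUE).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt_s = 0.05, pixel_size_nm = 160, sigma_loc_um = 0.02,
                       states = NULL, trans = NULL, init = NULL,
                       region_trans = NULL, region_d_scale = 1,
                       region_halfwidth_um = 15,
                       n_fluorophores = 4L, p_bleach = 0.04,
                       reflect_boundaries = TRUE) {
  if (dt_s <= 0) .stopf("'dt_s' must be > 0")
  if (p_bleach < 0 || p_bleach > 1) .stopf("'p_bleach' must be in [0, 1]")
  if (sigma_loc_um < 0) .stopf("'sigma_loc_um' must be >= 0")
  if (is.null(states)) {
    states <- data.frame(
      kind = c("D", "DV"),
      d_um2_s = c(0.1, 0.05),
      speed_um_s = c(0, 1.0),
      orientation = c(NA, "longitudinal"),
      stringsAsFactors = FALSE)
  }
  K <- nrow(states)
  if (any(states$d_um2_s < 0)) .stopf("all D must be >= 0")
  if (is.null(trans)) {
    trans <- matrix(0.02 / max(1, K - 1), K, K)
    diag(trans) <- 0
    diag(trans) <- 1 - rowSums(trans)
  }
  .check_trans <- function(m, what) {
    if (!is.matrix(m) || nrow(m) != K || ncol(m) != K)
      .stopf("'%s' must be a %d x %d matrix", what, K, K)
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9))
      .stopf("'%s' rows must be non-negative and sum to 1 (tol 1e-9)", what)
  }
  .check_trans(trans, "trans")
  if (!is.null(region_trans)) .check_trans(region_trans, "region_trans")
  if (is.null(init)) init <- rep(1 / K, K)
  if (abs(sum(init) - 1) > 1e-9 || any(init < 0))
    .stopf("'init' must be a probability vector")
  structure(list(dt_s = dt_s, pixel_size_nm = pixel_size_nm,
                 sigma_loc_um = sigma_loc_um, states = states,
                 trans = trans, init = init,
                 region_trans = region_trans,
                 region_d_scale = region_d_scale,
                 region_halfwidth_um = region_halfwidth_um,
                 n_fluorophores = as.integer(n_fluorophores),
                 p_bleach = p_bleach,
                 reflect_boundaries = reflect_boundaries),
            class = "sim_config")
}

#' Preset configurations for the control and stimulated conditions
#'
#' `sim_config_control()` is spatially uniform: a two-state vesicle model
#' (diffusive state D = 0.1 um^2/s; transport state D = 0.05 um^2/s,
#' |V| = 1 um/s) with balanced switching (k_D-AT = k_AT-D = 0.02 per frame).
#' `sim_config_stimulated()` applies, inside the 30 um region flanking the
#' uncaging site, a transition matrix with the transport-to-diffusion
#' switching probability raised threefold (0.06), the diffusion-to-transport
#' probability suppressed (0.005), and all diffusion coefficients scaled by
#' 0.4 — the statistical signature of local confinement by activity-induced
#' actin polymerisation.
#'
#' @param ... Passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_control <- function(...) {
  sim_config(trans = matrix(c(0.98, 0.02, 0.02, 0.98), 2, byrow = TRUE), ...)
}

#' @rdname sim_config_control
#' @export
sim_config_stimulated <- function(...) {
  sim_config(trans = matrix(c(0.98, 0.02, 0.02, 0.98), 2, byrow = TRUE),
             region_trans = matrix(c(0.995, 0.005, 0.06, 0.94), 2,
                                   byrow = TRUE),
             region_d_scale = 0.4, ...)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: dt = %g s, %d states, sigma_loc = %g um\n",
              x$dt_s, nrow(x$states), x$sigma_loc_um))
  print(x$states)
  if (!is.null(x$region_trans))
    cat(sprintf("region-modulated inside |s - u| <= %g um (D scale %g)\n",
                x$region_halfwidth_um, x$region_d_scale))
  invisible(x)
}

#' Write / read a simulation configuration as JSON
#' @param config A `sim_config`.
#' @param path File path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  obj <- unclass(config)
  obj$trans <- unname(obj$trans)
  if (!is.null(obj$region_trans)) obj$region_trans <- unname(obj$region_trans)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_config(dt_s = obj$dt_s, pixel_size_nm = obj$pixel_size_nm,
             sigma_loc_um = obj$sigma_loc_um,
             states = as.data.frame(obj$states),
             trans = as.matrix(obj$trans),
             init = obj$init,
             region_trans = if (!is.null(obj$region_trans))
               as.matrix(obj$region_trans),
             region_d_scale = obj$region_d_scale,
             region_halfwidth_um = obj$region_halfwidth_um,
             n_fluorophores = obj$n_fluorophores, p_bleach = obj$p_bleach,
             reflect_boundaries = obj$reflect_boundaries)
}
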