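#' Simulate stochastic photobleaching of a multi-fluorophore particle
#'
#' Each fluorophore bleaches independently with a fixed per-frame
#' probability, so its survival time is geometric; a particle carrying
#' `n_fluorophores` dyes is completely bleached at the maximum of the
#' individual bleach frames. With four dyes (a labelled receptor
#' homotetramer on the cell surface) and the default per-frame probability,
#' complete bleaching typically occurs within ~100 frames, which is the
#' basis of the 100-frame bleach filter used in vesicle identification.
#'
#' @param n_fluorophores Number of fluorophores (>= 1).
#' @param p_bleach Per-frame per-fluorophore bleach probability in `[0, 1]`.
#' @param n_frames Trace length.
#' @param seed Optional integer seed.
#' @return A list with `intensity` (surviving-fluorophore count per frame)
#'   and `bleach_complete_frame` (first frame with zero survivors, or `NA`
#'   if the particle never fully bleaches within `n_frames`).
#' @export
simulate_bleaching <- function(n_fluorophores, p_bleach, n_frames,
                               seed = NULL) {
  if (n_fluorophores < 1) .stopf("'n_fluorophores' must be >= 1")
  if (p_bleach < 0 || p_bleach > 1) .stopf("'p_bleach' must be in [0, 1]")
  if (n_frames < 1) .stopf("'n_frames' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  bleach_frame <- if (p_bleach == 0) rep(Inf, n_fluorophores) else
    rgeom(n_fluorophores, p_bleach) + 1
  frames <- seq_len(n_frames)
  intensity <- vapply(frames, function(t) sum(bleach_frame > t), numeric(1))
  complete <- max(bleach_frame)
  list(intensity = intensity,
       bleach_complete_frame = if (is.finite(complete) &&
                                   complete <= n_frames)
         as.integer(complete) else NA_integer_,
       bleach_frames = bleach_frame)
}

# reflect a scalar into [lo, hi] by folding (triangle wave)
.reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  if (w <= 0) return(rep(lo, length(x)))
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  lo + y
}

#' Simulate one Markov-switching vesicle trajectory
#'
#' Generates a single-particle trajectory on a dendrite under the motion
#' model of a [sim_config()]: a hidden Markov chain over diffusive (`D`) and
#' directed-transport (`DV`) states, per-frame displacements Gaussian per
#' axis with mean `V * dt` and variance `2 * D * dt`, optional region
#' modulation of the transition matrix and of `D` inside the stimulated
#' region (evaluated at the particle's true position before each step), and
#' i.i.d. Gaussian localisation noise added to the observed positions.
#' Motion is optionally reflected at the shaft walls and dendrite ends.
#'
#' @param config A [sim_config()].
#' @param dendrite A [simulate_dendrite()] model.
#' @param n_frames Number of frames (>= 2).
#' @param start Length-2 numeric start position (um), or `NULL` for a random
#'   position inside the shaft.
#' @param category Particle category label stored in the ground truth; one
#'   of "vesicle", "surface", "psd_trapped", "spine_localized". "surface"
#'   particles get a tetramer photobleaching intensity trace; the others are
#'   treated as carrying an effectively inexhaustible dye pool.
#' @param trajectory_id Identifier used in the output table.
#' @param base_intensity Intensity of a fully labelled particle (a.u.).
#' @param seed Optional integer seed; output is fully reproducible given it.
#' @return A list with `trajectory` (data.frame: `trajectory_id`, `frame`,
#'   `t_s`, `x_um`, `y_um`, `intensity`, `channel`) and `truth` (list:
#'   per-step true `states`, `in_region` flags, true positions, the state
#'   definition table, `category`, `bleach_complete_frame`, and
#'   `exo_event_id`, `NA` here).
#' @export
simulate_trajectory <- function(config, dendrite, n_frames, start = NULL,
                                category = "vesicle", trajectory_id = 1L,
                                base_intensity = 1000, seed = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(dendrite, "dendrite_model"))
  if (n_frames < 2) .stopf("'n_frames' must be >= 2")
  if (!is.null(seed)) set.seed(seed)

  hw <- dendrite$halfwidth_um
  if (is.null(start)) {
    s0 <- runif(1, 0, dendrite$L)
    d0 <- runif(1, -hw, hw)
    fr <- .frame_at_s(dendrite$centerline, dendrite$s, s0)
    start <- fr$point + d0 * fr$normal
  } else {
    pr <- project_to_path(start, dendrite)
    if (pr$d > hw + 1e-9)
      .stopf("'start' lies outside the dendrite shaft (d = %.3f um)", pr$d)
  }

  K <- nrow(config$states)
  dt <- config$dt_s
  n_steps <- n_frames - 1L
  pos <- matrix(NA_real_, n_frames, 2)
  pos[1, ] <- start
  states <- integer(n_steps)
  in_region <- logical(n_steps)
  heading <- c(1, 0)
  cur_state <- sample.int(K, 1, prob = config$init)
  modulated <- !is.null(config$region_trans) || config$region_d_scale != 1

  cl <- dendrite$centerline
  sv <- dendrite$s
  kinds <- config$states$kind
  speeds <- config$states$speed_um_s
  Ds <- config$states$d_um2_s
  seg_hint <- 1L
  for (i in seq_len(n_steps)) {
    pr <- .project_point(cl, sv, pos[i, ], hint = seg_hint)
    seg_hint <- pr$seg
    inr <- abs(pr$s - dendrite$uncaging_s) <= config$region_halfwidth_um
    in_region[i] <- inr
    use_region <- inr && modulated
    A <- if (use_region && !is.null(config$region_trans))
      config$region_trans else config$trans
    if (i > 1) {
      new_state <- sample.int(K, 1, prob = A[cur_state, ])
      if (new_state != cur_state) {
        cur_state <- new_state
        if (kinds[cur_state] == "DV")
          heading <- .draw_heading(config$states[cur_state, ], dendrite,
                                   pr$s)
      }
    } else if (kinds[cur_state] == "DV") {
      heading <- .draw_heading(config$states[cur_state, ], dendrite, pr$s)
    }
    states[i] <- cur_state
    D_eff <- Ds[cur_state] * if (use_region) config$region_d_scale else 1
    v <- if (kinds[cur_state] == "DV") speeds[cur_state] * heading else
      c(0, 0)
    step <- v * dt + rnorm(2, 0, sqrt(2 * D_eff * dt))
    newpos <- pos[i, ] + step
    if (config$reflect_boundaries) {
      pr2 <- .project_point(cl, sv, newpos, hint = seg_hint)
      s_f <- .reflect_into(pr2$s, 0, dendrite$L)
      d_f <- .reflect_into(pr2$d_signed, -hw, hw)
      if (abs(d_f - pr2$d_signed) > 1e-12 || abs(s_f - pr2$s) > 1e-12) {
        fr2 <- .frame_at_s(cl, sv, s_f)
        newpos <- fr2$point + d_f * fr2$normal
      }
    }
    pos[i + 1L, ] <- newpos
  }

  obs <- pos + matrix(rnorm(2 * n_frames, 0, config$sigma_loc_um), n_frames)

  bleach_complete <- NA_integer_
  if (identical(category, "surface")) {
    bl <- simulate_bleaching(config$n_fluorophores, config$p_bleach, n_frames)
    intensity <- base_intensity * bl$intensity / config$n_fluorophores
    bleach_complete <- bl$bleach_complete_frame
  } else {
    intensity <- rep(base_intensity, n_frames)
  }

  trajectory <- data.frame(
    trajectory_id = trajectory_id,
    frame = seq_len(n_frames),
    t_s = (seq_len(n_frames) - 1) * dt,
    x_um = obs[, 1], y_um = obs[, 2],
    intensity = intensity, channel = "sim",
    stringsAsFactors = FALSE)

  truth <- list(states = states, in_region = in_region,
                true_positions = pos, state_defs = config$states,
                category = category,
                bleach_complete_frame = bleach_complete,
                exo_event_id = NA_integer_)
  list(trajectory = trajectory, truth = truth)
}

.draw_heading <- function(state_row, dendrite, s) {
  fr <- .frame_at_s(dendrite$centerline, dendrite$s, s)
  ori <- state_row$orientation
  base <- if (!is.na(ori) && ori == "lateral") fr$normal else fr$tangent
  sample(c(-1, 1), 1) * base
}

#' Simulate a full control + stimulated tracking experiment
#'
#' End-to-end fixture generator: draws a cohort of particles per condition
#' (categories with gate-separated motion parameters: mobile vesicles under
#' the condition's switching model, fast surface receptors with tetramer
#' photobleaching at D = 0.6 um^2/s, receptors trapped in postsynaptic
#' densities at D = 0.005 um^2/s, and spine-localized particles), simulates
#' their trajectories, and emits exocytosis events for a configurable
#' fraction of vesicles, which end in a docked (immobile) tail at the event
#' position. Under the stimulated configuration, the transition matrix and
#' diffusion scaling are modulated inside the region flanking the uncaging
#' site; the control configuration is spatially uniform.
#'
#' @param config_control,config_stimulated [sim_config()]s for the two
#'   conditions; pass `config_stimulated = NULL` to simulate only controls.
#' @param dendrite A [simulate_dendrite()] model.
#' @param n_particles Particles per condition (>= 1).
#' @param n_frames Frames per trajectory.
#' @param category_probs Named probabilities for categories `vesicle`,
#'   `surface`, `psd_trapped`, `spine_localized`.
#' @param exo_fraction Fraction of vesicle trajectories that end in a docked
#'   segment followed by an exocytosis event.
#' @param docked_tail_frames Length of the immobile docked tail (frames).
#' @param seed Integer seed; same seed gives byte-identical output.
#' @return A list with `trajectories` (one data.frame, with a `condition`
#'   column), `events` (data.frame of exocytic events), and `truth` (named
#'   list of per-trajectory ground-truth records).
#' @export
simulate_experiment <- function(config_control, config_stimulated, dendrite,
                                n_particles, n_frames = 200,
                                category_probs = c(vesicle = 1, surface = 0,
                                                   psd_trapped = 0,
                                                   spine_localized = 0),
                                exo_fraction = 0, docked_tail_frames = 20,
                                seed = NULL) {
  stopifnot(inherits(config_control, "sim_config"),
            inherits(dendrite, "dendrite_model"))
  if (n_particles < 1) .stopf("'n_particles' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cats <- c("vesicle", "surface", "psd_trapped", "spine_localized")
  p <- setNames(rep(0, 4), cats)
  p[names(category_probs)] <- category_probs
  if (abs(sum(p) - 1) > 1e-9) .stopf("'category_probs' must sum to 1")
  if (p["spine_localized"] > 0 && length(dendrite$spines) == 0)
    .stopf("spine_localized particles requested but dendrite has no spines")

  conds <- list(control = config_control)
  if (!is.null(config_stimulated)) {
    stopifnot(inherits(config_stimulated, "sim_config"))
    conds$stimulated <- config_stimulated
  }

  traj_list <- list()
  truth <- list()
  events <- list()
  ev_id <- 0L
  for (cond in names(conds)) {
    cfg <- conds[[cond]]
    for (i in seq_len(n_particles)) {
      id <- sprintf("%s_%04d", cond, i)
      category <- sample(cats, 1, prob = p)
      cfg_i <- .category_config(cfg, category)
      dock <- category == "vesicle" && runif(1) < exo_fraction
      n_main <- if (dock) max(2L, n_frames - docked_tail_frames) else n_frames
      sim <- if (category == "spine_localized")
        .simulate_spine_particle(cfg_i, dendrite, n_main, id)
      else
        simulate_trajectory(cfg_i, dendrite, n_main, category = category,
                            trajectory_id = id)
      if (dock) {
        ev_id <- ev_id + 1L
        sim <- .append_docked_tail(sim, cfg_i, docked_tail_frames)
        term <- sim$truth$true_positions[nrow(sim$truth$true_positions), ]
        sim$truth$exo_event_id <- ev_id
        sim$truth$dock_onset_frame <- n_main
        events[[length(events) + 1L]] <- data.frame(
          event_id = ev_id, x_um = term[1], y_um = term[2],
          onset_frame = nrow(sim$trajectory) + 1L,
          condition = cond, trajectory_id = id, stringsAsFactors = FALSE)
      }
      sim$trajectory$condition <- cond
      traj_list[[id]] <- sim$trajectory
      truth[[id]] <- sim$truth
    }
  }
  trajectories <- do.call(rbind, traj_list)
  rownames(trajectories) <- NULL
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = integer(), x_um = numeric(), y_um = numeric(),
               onset_frame = integer(), condition = character(),
               trajectory_id = character(), stringsAsFactors = FALSE)
  list(trajectories = trajectories, events = events, truth = truth)
}

# motion parameters per ground-truth category; vesicles use the condition
# config unchanged, the other categories get gate-separated single states
.category_config <- function(cfg, category) {
  if (category == "vesicle") return(cfg)
  st <- switch(category,
    surface = data.frame(kind = "D", d_um2_s = 0.6, speed_um_s = 0,
                         orientation = NA, stringsAsFactors = FALSE),
    psd_trapped = data.frame(kind = "D", d_um2_s = 0.005, speed_um_s = 0,
                             orientation = NA, stringsAsFactors = FALSE),
    spine_localized = data.frame(kind = "D", d_um2_s = 0.02, speed_um_s = 0,
                                 orientation = NA, stringsAsFactors = FALSE))
  sim_config(dt_s = cfg$dt_s, pixel_size_nm = cfg$pixel_size_nm,
             sigma_loc_um = cfg$sigma_loc_um, states = st,
             trans = matrix(1, 1, 1), init = 1,
             n_fluorophores = cfg$n_fluorophores, p_bleach = cfg$p_bleach,
             reflect_boundaries = cfg$reflect_boundaries)
}

# spine-localized particle: slow diffusion confined to one spine polygon
.simulate_spine_particle <- function(cfg, dendrite, n_frames, id) {
  sp <- dendrite$spines[[sample.int(length(dendrite$spines), 1)]]
  centroid <- colMeans(sp$polygon)
  D <- cfg$states$d_um2_s[1]
  dt <- cfg$dt_s
  pos <- matrix(NA_real_, n_frames, 2)
  pos[1, ] <- centroid
  for (i in seq_len(n_frames - 1L)) {
    for (try in 1:25) {
      cand <- pos[i, ] + rnorm(2, 0, sqrt(2 * D * dt))
      if (point_in_polygon(cand, sp$polygon)) break
      cand <- pos[i, ]
    }
    pos[i + 1L, ] <- cand
  }
  obs <- pos + matrix(rnorm(2 * n_frames, 0, cfg$sigma_loc_um), n_frames)
  trajectory <- data.frame(
    trajectory_id = id, frame = seq_len(n_frames),
    t_s = (seq_len(n_frames) - 1) * dt,
    x_um = obs[, 1], y_um = obs[, 2],
    intensity = rep(1000, n_frames), channel = "sim",
    stringsAsFactors = FALSE)
  truth <- list(states = rep(1L, n_frames - 1L),
                in_region = rep(FALSE, n_frames - 1L),
                true_positions = pos, state_defs = cfg$states,
                category = "spine_localized",
                bleach_complete_frame = NA_integer_,
                exo_event_id = NA_integer_)
  list(trajectory = trajectory, truth = truth)
}

# freeze the particle at its terminal position for the docked segment
.append_docked_tail <- function(sim, cfg, tail_frames) {
  traj <- sim$trajectory
  n <- nrow(traj)
  term <- sim$truth$true_positions[n, ]
  dt <- cfg$dt_s
  tail_pos <- matrix(rep(term, each = tail_frames), tail_frames)
  tail_obs <- tail_pos +
    matrix(rnorm(2 * tail_frames, 0, cfg$sigma_loc_um), tail_frames)
  tail_df <- data.frame(
    trajectory_id = traj$trajectory_id[1],
    frame = n + seq_len(tail_frames),
    t_s = (n + seq_len(tail_frames) - 1) * dt,
    x_um = tail_obs[, 1], y_um = tail_obs[, 2],
    intensity = traj$intensity[n], channel = traj$channel[1],
    stringsAsFactors = FALSE)
  sim$trajectory <- rbind(traj, tail_df)
  sim$truth$true_positions <- rbind(sim$truth$true_positions, tail_pos)
  sim$truth$states <- c(sim$truth$states, rep(NA_integer_, tail_frames))
  sim$truth$in_region <- c(sim$truth$in_region, rep(NA, tail_frames))
  sim
}

#' Write / read trajectory tables as CSV
#'
#' The on-disk schema is `trajectory_id, frame, t_s, x_um, y_um, intensity,
#' channel` and is shared between the generator and the tracker, so
#' downstream analyses are agnostic to the trajectory source.
#'
#' @param trajectories Trajectory data.frame.
#' @param path File path.
#' @export
write_trajectories <- function(trajectories, path) {
  write.csv(trajectories, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trajectory_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df)))
    .stopf("trajectory CSV must contain columns: %s",
           paste(need, collapse = ", "))
  df
}

#' Split a trajectory table into a list of per-particle tables
#' @param trajectories Trajectory data.frame.
#' @return Named list of data.frames, ordered by frame.
#' @export
split_trajectories <- function(trajectories) {
  out <- split(trajectories, trajectories$trajectory_id)
  lapply(out, function(df) df[order(df$frame), , drop = FALSE])
}
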