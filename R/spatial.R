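#' Radius of confinement of a trajectory
#'
#' Maximum distance from the trajectory centroid (unweighted mean of all
#' points) to any trajectory point: the radius of the smallest
#' centroid-centred disc containing the whole trajectory.
#'
#' @param trajectory Trajectory data.frame (`x_um`, `y_um`) with >= 1 point.
#' @return Radius in um.
#' @export
radius_of_confinement <- function(trajectory) {
  pts <- cbind(trajectory$x_um, trajectory$y_um)
  if (nrow(pts) < 1) .stopf("trajectory needs >= 1 point")
  cm <- colMeans(pts)
  sqrt(max((pts[, 1] - cm[1])^2 + (pts[, 2] - cm[2])^2))
}

#' Directional bias of a trajectory relative to the dendrite path
#'
#' Computes the angle theta between two lines anchored at the trajectory
#' centroid (CM): the line from the CM to the nearest point on the dendrite
#' centerline, and the line from the CM to the trajectory point farthest
#' from the CM. Theta is the unsigned angle between the two lines
#' (`arccos(|u . v|)`, range 0-90 degrees): theta = 90 means the dominant
#' displacement is parallel to the dendrite (longitudinal motion), theta =
#' 0 means it points along the CM-to-path line (lateral motion). Ties for
#' the farthest point are broken by earliest time. If the CM lies on the
#' centerline (within 1 nm) the local centerline normal is used as the
#' reference direction (the continuity limit); if all points coincide with
#' the CM the angle is undefined and flagged.
#'
#' @param trajectory Trajectory data.frame (`x_um`, `y_um`, >= 2 points).
#' @param dendrite A [simulate_dendrite()] model.
#' @return An object of class `directional_bias`: list with `theta_deg`,
#'   `radius_um`, `cm`, `farthest_point`, `nearest_path_point`,
#'   `degenerate`.
#' @export
directional_bias_theta <- function(trajectory, dendrite) {
  stopifnot(inherits(dendrite, "dendrite_model"))
  pts <- cbind(trajectory$x_um, trajectory$y_um)
  if (nrow(pts) < 2) .stopf("trajectory needs >= 2 points")
  cm <- colMeans(pts)
  d2 <- (pts[, 1] - cm[1])^2 + (pts[, 2] - cm[2])^2
  far_i <- which.max(d2)  # which.max returns the earliest maximum
  radius <- sqrt(d2[far_i])
  if (radius < 1e-12) {
    return(structure(list(theta_deg = NA_real_, radius_um = 0, cm = cm,
                          farthest_point = pts[far_i, ],
                          nearest_path_point = NULL, degenerate = TRUE),
                     class = "directional_bias"))
  }
  pr <- project_to_path(cm, dendrite)
  fr <- .frame_at_s(dendrite$centerline, dendrite$s, pr$s)
  if (pr$d < 1e-3) {  # CM on the centerline: use the local normal
    u <- fr$normal
    nearest <- fr$point
  } else {
    nearest <- fr$point
    u <- (nearest - cm) / pr$d
  }
  v <- (pts[far_i, ] - cm) / radius
  theta <- acos(.clamp(abs(sum(u * v)), 0, 1)) * 180 / pi
  structure(list(theta_deg = theta, radius_um = radius, cm = cm,
                 farthest_point = pts[far_i, ], nearest_path_point = nearest,
                 degenerate = FALSE),
            class = "directional_bias")
}

#' Photobleach-adjusted vesicle count
#'
#' Vesicle counts measured after photostimulation are corrected for the
#' photobleaching incurred during imaging, using unstimulated control
#' experiments: `fold_loss = n_pre_control / n_post_control` quantifies how
#' many vesicles are lost to bleaching alone, and the condition's
#' post-stimulation count is multiplied by it.
#'
#' @param n_post_condition Post-stimulation count in the condition.
#' @param n_pre_control,n_post_control Pre and post counts in the
#'   no-stimulation control.
#' @return Adjusted count (`n_post_condition * fold_loss`).
#' @export
adjust_counts <- function(n_post_condition, n_pre_control, n_post_control) {
  if (n_post_control <= 0) .stopf("'n_post_control' must be > 0")
  n_post_condition * (n_pre_control / n_post_control)
}

#' Detect exocytosis events in a fluorescence movie
#'
#' An exocytic event appears as a sudden local fluorescence increase (a
#' bright punctum) that persists for at least `min_persist` frames. For
#' each pixel, frame-to-frame differences are compared against `k` times a
#' locally pooled median-absolute-deviation estimate of the temporal noise;
#' super-threshold onsets that persist are clustered in space and time into
#' events and localised by a 2D Gaussian fit of the difference image at
#' onset. The event rate is normalised per micrometre of dendrite per
#' minute when a dendrite model is supplied.
#'
#' @param stack An `image_stack` with >= 10 frames.
#' @param dendrite Optional [simulate_dendrite()] model for arc-length
#'   assignment and rate normalisation.
#' @param k Detection threshold in noise MADs (default 6).
#' @param min_persist Minimum persistence above the pre-onset level
#'   (frames).
#' @return A list with `events` (data.frame: `event_id`, `x_um`, `y_um`,
#'   `onset_frame`, `amplitude`, plus `s_um` and `region` when a dendrite
#'   is given) and `rate_per_um_min` (or `NA` without a dendrite).
#' @export
detect_exocytosis <- function(stack, dendrite = NULL, k = 6,
                              min_persist = 2) {
  stopifnot(inherits(stack, "image_stack"))
  arr <- stack$data
  nT <- dim(arr)[1]; ny <- dim(arr)[2]; nx <- dim(arr)[3]
  if (nT < 10) .stopf("stack needs >= 10 frames")
  diffs <- arr[-1, , , drop = FALSE] - arr[-nT, , , drop = FALSE]
  # per-pixel temporal noise scale, pooled over a 3x3 neighbourhood and
  # floored at the global scale so quiet pixels do not over-trigger
  mad_px <- apply(diffs, c(2, 3), mad)
  box <- matrix(1 / 9, 3, 3)
  mad_loc <- EBImage::filter2(mad_px, box)
  mad_glob <- mad(diffs)
  mad_loc <- pmax(mad_loc, mad_glob, 1e-12)
  baseline <- apply(arr, c(2, 3), median)

  hits <- NULL
  for (f in seq_len(nT - 1L)) {
    over <- diffs[f, , ] > k * mad_loc
    if (!any(over)) next
    # an appearance starts from the local baseline (not a fluctuation of
    # an already-bright particle) ...
    over <- over & (arr[f, , ] <= baseline + k * mad_loc)
    # ... and must stay elevated relative to the pre-onset frame
    if (min_persist > 1) {
      for (g in seq_len(min_persist - 1L)) {
        fg <- min(nT, f + 1L + g)
        over <- over & (arr[fg, , ] - arr[f, , ] > k * mad_loc)
      }
    }
    if (any(over)) {
      w <- which(over, arr.ind = TRUE)
      hits <- rbind(hits, cbind(frame = f + 1L, y = w[, 1], x = w[, 2]))
    }
  }
  events <- data.frame(event_id = integer(), x_um = numeric(),
                       y_um = numeric(), onset_frame = integer(),
                       amplitude = numeric())
  if (!is.null(hits)) {
    hits <- as.data.frame(hits)
    hits <- hits[order(hits$frame), , drop = FALSE]
    # single-link clustering of super-threshold pixels in space and time
    cluster <- rep(0L, nrow(hits))
    n_cl <- 0L
    for (r in seq_len(nrow(hits))) {
      near <- which(cluster > 0 & abs(hits$frame - hits$frame[r]) <= 3 &
                    (hits$x - hits$x[r])^2 + (hits$y - hits$y[r])^2 <= 36)
      if (length(near)) {
        ids <- unique(cluster[near])
        cluster[r] <- ids[1]
        if (length(ids) > 1) cluster[cluster %in% ids[-1]] <- ids[1]
      } else {
        n_cl <- n_cl + 1L
        cluster[r] <- n_cl
      }
    }
    px_um <- stack$pixel_size_nm / 1000
    ev <- 0L
    for (cl in unique(cluster)) {
      same <- cluster == cl
      ev <- ev + 1L
      f0 <- min(hits$frame[same])
      dimg <- arr[f0, , ] - arr[f0 - 1L, , ]
      cx <- mean(hits$x[same & hits$frame == f0])
      cy <- mean(hits$y[same & hits$frame == f0])
      ft <- .fit_gaussian_2d(dimg, cx - 0.5, cy - 0.5, 1.5, 4L)
      events <- rbind(events, data.frame(
        event_id = ev, x_um = ft$x * px_um, y_um = ft$y * px_um,
        onset_frame = f0, amplitude = ft$A))
    }
  }
  rate <- NA_real_
  if (!is.null(dendrite)) {
    if (nrow(events)) {
      pr <- project_to_path(cbind(events$x_um, events$y_um), dendrite)
      events$s_um <- pr$s
      events$region <- assign_region(pr$s, dendrite)
    }
    duration_min <- (nT - 1) * stack$dt_s / 60
    rate <- nrow(events) / (dendrite$L * duration_min)
  }
  list(events = events, rate_per_um_min = rate)
}

#' Exocytosis rate from an event count
#'
#' @param n_events Number of detected events.
#' @param length_um Dendrite length imaged (um).
#' @param duration_min Imaging duration (minutes).
#' @return Events per um per minute.
#' @export
exocytosis_rate <- function(n_events, length_um, duration_min) {
  if (length_um <= 0 || duration_min <= 0)
    .stopf("length and duration must be > 0")
  n_events / (length_um * duration_min)
}

#' Link trajectories to subsequent exocytosis events
#'
#' A trajectory is labelled `pre_exocytosis` if its terminal position lies
#' within `link_radius_um` of an event and its terminal frame falls within
#' `link_window_frames` before the event onset; when several trajectories
#' match one event, the nearest terminal position wins. Vesicles dock
#' (become immobile) immediately before exocytosis, so for each linked
#' trajectory the terminal decoded immobile segment (state `D` below
#' `d_immobile_um2_s` and speed below `v_floor_um_s`) is stripped and the
#' motion summary recomputed on the remainder, characterising the motion
#' that delivered the vesicle rather than the docked dwell.
#'
#' @param trajectories Trajectory data.frame.
#' @param events Event data.frame (`event_id`, `x_um`, `y_um`,
#'   `onset_frame`).
#' @param models Optional named list of [fit_hmm()] models keyed by
#'   trajectory id; fitted on demand when missing.
#' @param link_radius_um Maximum terminal-position-to-event distance
#'   (default 0.32 um = 2 pixels).
#' @param link_window_frames Maximum frames between trajectory end and
#'   event onset (default 10).
#' @param d_immobile_um2_s Diffusion ceiling for the docked state.
#' @param v_floor_um_s Speed ceiling for the docked state.
#' @param ... Passed to [fit_hmm()] when models are fitted on demand.
#' @return A data.frame with one row per trajectory: `trajectory_id`,
#'   `label` (`pre_exocytosis`/`non_exocytosis`), `event_id`,
#'   `dock_onset_step` (first stripped step or `NA`), and the post-strip
#'   motion summary columns.
#' @export
link_pre_exocytosis <- function(trajectories, events, models = NULL,
                                link_radius_um = 0.32,
                                link_window_frames = 10,
                                d_immobile_um2_s = 0.01,
                                v_floor_um_s = 0.1, ...) {
  tr_list <- split_trajectories(trajectories)
  ids <- names(tr_list)
  term <- t(vapply(tr_list, function(tr) {
    c(tr$x_um[nrow(tr)], tr$y_um[nrow(tr)], tr$frame[nrow(tr)])
  }, numeric(3)))

  label <- setNames(rep("non_exocytosis", length(ids)), ids)
  event_of <- setNames(rep(NA_integer_, length(ids)), ids)
  if (!is.null(events) && nrow(events)) {
    for (e in seq_len(nrow(events))) {
      dx <- term[, 1] - events$x_um[e]
      dy <- term[, 2] - events$y_um[e]
      dist <- sqrt(dx^2 + dy^2)
      dtf <- events$onset_frame[e] - term[, 3]
      ok <- which(dist <= link_radius_um & dtf >= 0 &
                  dtf <= link_window_frames &
                  label == "non_exocytosis")
      if (!length(ok)) next
      win <- ok[which.min(dist[ok])]
      label[win] <- "pre_exocytosis"
      event_of[win] <- events$event_id[e]
    }
  }

  rows <- lapply(ids, function(id) {
    tr <- tr_list[[id]]
    m <- models[[id]]
    if (is.null(m)) m <- suppressWarnings(fit_hmm(tr, ...))
    dock_onset <- NA_integer_
    if (label[id] == "pre_exocytosis") {
      immobile <- m$states$d_um2_s[m$path] < d_immobile_um2_s &
        m$states$speed_um_s[m$path] < v_floor_um_s
      n <- length(immobile)
      if (immobile[n]) {
        first <- n
        while (first > 1 && immobile[first - 1]) first <- first - 1
        dock_onset <- first
        if (first > 20) {  # enough steps left to refit
          tr <- tr[seq_len(first), , drop = FALSE]
          m <- suppressWarnings(fit_hmm(tr, ...))
        }
      }
    }
    cbind(data.frame(trajectory_id = id, label = unname(label[id]),
                     event_id = unname(event_of[id]),
                     dock_onset_step = dock_onset,
                     radius_um = radius_of_confinement(tr),
                     stringsAsFactors = FALSE),
          summarize_motion(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dendrite-referenced spatial summary of a trajectory cohort
#'
#' Per-trajectory pipeline combining the motion model with the dendrite
#' geometry: each trajectory is assigned to a proximity zone and to the
#' IN/OUT stimulation region by the projection of its centroid (or by
#' per-step majority when `method = "stepwise"`), and annotated with its
#' motion summary, radius of confinement and directional-bias angle.
#'
#' @param trajectories Trajectory data.frame.
#' @param dendrite A [simulate_dendrite()] model.
#' @param method Assignment rule: `"centroid"` (default) or `"stepwise"`
#'   (majority vote over per-point assignments).
#' @param region_halfwidth_um Passed to [assign_region()].
#' @param ... Passed to [fit_hmm()].
#' @return A data.frame with one row per trajectory.
#' @export
analyze_cohort <- function(trajectories, dendrite,
                           method = c("centroid", "stepwise"),
                           region_halfwidth_um = 15, ...) {
  method <- match.arg(method)
  tr_list <- split_trajectories(trajectories)
  rows <- lapply(names(tr_list), function(id) {
    tr <- tr_list[[id]]
    model <- suppressWarnings(fit_hmm(tr, ...))
    motion <- summarize_motion(model)
    if (method == "centroid") {
      cm <- c(mean(tr$x_um), mean(tr$y_um))
      pr <- project_to_path(cm, dendrite)
      s <- pr$s
      zone <- assign_zone(s, dendrite)
      region <- assign_region(s, dendrite, region_halfwidth_um)
    } else {
      pr <- project_to_path(cbind(tr$x_um, tr$y_um), dendrite)
      s <- stats::median(pr$s)
      zones <- assign_zone(.clamp(pr$s, 0, dendrite$L), dendrite)
      zone <- as.integer(names(which.max(table(zones))))
      regs <- assign_region(pr$s, dendrite, region_halfwidth_um)
      region <- names(which.max(table(regs)))
    }
    db <- directional_bias_theta(tr, dendrite)
    cbind(data.frame(trajectory_id = id, s_um = s, zone = zone,
                     region = region, theta_deg = db$theta_deg,
                     radius_um = db$radius_um, stringsAsFactors = FALSE),
          motion)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
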