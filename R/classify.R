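#' Fraction of trajectory points inside spine regions
#'
#' Point-in-polygon test of every trajectory point against all spine
#' polygons of the dendrite model (boundary counts as inside).
#'
#' @param trajectory Trajectory data.frame (`x_um`, `y_um`).
#' @param dendrite A [simulate_dendrite()] model (possibly without spines).
#' @return Fraction in `[0, 1]`.
#' @export
spine_fraction <- function(trajectory, dendrite) {
  stopifnot(inherits(dendrite, "dendrite_model"))
  if (length(dendrite$spines) == 0) return(0)
  pts <- cbind(trajectory$x_um, trajectory$y_um)
  inside <- rep(FALSE, nrow(pts))
  for (sp in dendrite$spines)
    inside <- inside | point_in_polygon(pts, sp$polygon)
  mean(inside)
}

#' First frame of complete photobleaching in an intensity trace
#'
#' A particle is considered completely bleached at the first frame from
#' which its intensity stays within `n_sd` standard deviations of the
#' background for all remaining frames. A transient dip that recovers
#' (blinking) therefore does not count as bleaching. Returns `NA` if the
#' trace never settles at background.
#'
#' @param intensity Numeric intensity trace.
#' @param background_mean Background intensity level.
#' @param background_sd Background noise SD (the band half-width is
#'   `n_sd * background_sd`).
#' @param n_sd Band width in SDs (default 2).
#' @return Integer frame index or `NA`.
#' @export
bleach_frame_from_intensity <- function(intensity, background_mean,
                                        background_sd, n_sd = 2) {
  if (length(intensity) < 1) .stopf("empty intensity trace")
  at_bg <- abs(intensity - background_mean) <= n_sd * background_sd
  # first index from which all remaining frames sit at background
  ok_from <- rev(cumprod(rev(at_bg))) > 0
  if (!any(ok_from)) return(NA_integer_)
  as.integer(which(ok_from)[1])
}

#' Classify a tracked particle as vesicle, surface, PSD-trapped or other
#'
#' Sequential vesicle-identification rules separating intracellular
#' receptor-carrying vesicles from other particle classes:
#' \enumerate{
#'   \item particles localised inside spines for the majority of steps
#'     (`spine_fraction > 0.5`) are `spine_localized`;
#'   \item particles exhibiting active transport are vesicles (membrane
#'     receptors and PSD-trapped receptors do not undergo directed
#'     transport);
#'   \item among diffusion-only particles, those that bleach completely
#'     within `bleach_window` frames (the time for a labelled receptor
#'     homotetramer to bleach) are excluded as probable surface receptors
#'     (`bleach_excluded`);
#'   \item diffusion-only particles with `D > d_high` (default 0.45
#'     um^2/s) are classified `surface`;
#'   \item diffusion-only particles with `D < d_low` (default 0.02
#'     um^2/s) are classified `psd_trapped`;
#'   \item everything else is a `vesicle`.
#' }
#' The gated `D` is the diffusive-state diffusion coefficient from the
#' motion model (the `d_diffusive_um2_s` column of [summarize_motion()]).
#'
#' @param motion One-row data.frame from [summarize_motion()] (needs
#'   `motion_type` and `d_diffusive_um2_s`).
#' @param spine_fraction Fraction of steps inside spines.
#' @param bleach_frame First complete-bleach frame or `NA`.
#' @param gates List with `d_low`, `d_high` (um^2/s), `bleach_window`
#'   (frames) and `spine_majority`.
#' @return An object of class `particle_classification`: list with
#'   `category` and the inputs used.
#' @export
classify_particle <- function(motion, spine_fraction, bleach_frame,
                              gates = list(d_low = 0.02, d_high = 0.45,
                                           bleach_window = 100,
                                           spine_majority = 0.5)) {
  if (is.null(motion) || is.null(motion$motion_type))
    .stopf("missing motion summary")
  category <- if (spine_fraction > gates$spine_majority) {
    "spine_localized"
  } else if (motion$motion_type == "active_transport") {
    "vesicle"
  } else if (!is.na(bleach_frame) && bleach_frame <= gates$bleach_window) {
    "bleach_excluded"
  } else if (!is.na(motion$d_diffusive_um2_s) &&
             motion$d_diffusive_um2_s > gates$d_high) {
    "surface"
  } else if (!is.na(motion$d_diffusive_um2_s) &&
             motion$d_diffusive_um2_s < gates$d_low) {
    "psd_trapped"
  } else {
    "vesicle"
  }
  structure(list(category = category, spine_fraction = spine_fraction,
                 bleach_complete_frame = bleach_frame,
                 motion_type = motion$motion_type,
                 d_gated_um2_s = motion$d_diffusive_um2_s, gates = gates),
            class = "particle_classification")
}

#' Run the full vesicle-identification pipeline on a trajectory cohort
#'
#' For every trajectory: fits the motion-state model, measures the spine
#' fraction, derives the complete-bleach frame from the intensity trace,
#' and applies [classify_particle()].
#'
#' @param trajectories Trajectory data.frame (common schema).
#' @param dendrite A [simulate_dendrite()] model.
#' @param background_mean,background_sd Intensity background model for
#'   bleach detection (defaults: 0 and 2% of the cohort's maximum
#'   intensity).
#' @param gates Passed to [classify_particle()].
#' @param ... Passed to [fit_hmm()].
#' @return A data.frame with one row per trajectory: `trajectory_id`,
#'   `category`, `motion_type`, `d_diffusive_um2_s`, `spine_fraction`,
#'   `bleach_complete_frame`.
#' @export
classify_cohort <- function(trajectories, dendrite,
                            background_mean = 0, background_sd = NULL,
                            gates = list(d_low = 0.02, d_high = 0.45,
                                         bleach_window = 100,
                                         spine_majority = 0.5), ...) {
  tr_list <- split_trajectories(trajectories)
  if (is.null(background_sd))
    background_sd <- 0.02 * max(trajectories$intensity, 1)
  rows <- lapply(names(tr_list), function(id) {
    tr <- tr_list[[id]]
    model <- suppressWarnings(fit_hmm(tr, ...))
    motion <- summarize_motion(model)
    sf <- spine_fraction(tr, dendrite)
    bf <- bleach_frame_from_intensity(tr$intensity, background_mean,
                                      background_sd)
    cl <- classify_particle(motion, sf, bf, gates)
    data.frame(trajectory_id = id, category = cl$category,
               motion_type = motion$motion_type,
               d_diffusive_um2_s = motion$d_diffusive_um2_s,
               at_step_fraction = motion$at_step_fraction,
               spine_fraction = sf, bleach_complete_frame = bf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
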