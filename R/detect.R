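#' Detection and linking parameters
#'
#' Parameters of the particle detector and of the multi-target linker,
#' following the conventions of multiple-target tracing (MTT) software: the
#' per-pixel false-alarm probability of the detection test, the number of
#' deflation loops used to recover overlapping particles, the maximum number
#' of competing assignment hypotheses per localisation, and the maximum
#' diffusion coefficient, which bounds the linking search radius
#' `r_max = sqrt(4 * D_max * dt * (gap + 1))`. Defaults are the values used
#' for receptor-scale particles (`d_max_um2_s = 1`); passive rheological
#' probes are linked with `d_max_um2_s = 3`.
#'
#' @param false_alarm Per-pixel false-alarm probability (0 < p < 1).
#' @param deflation_loops Deflation passes (>= 0).
#' @param max_competitors Competing assignment hypotheses (>= 1).
#' @param d_max_um2_s Maximum diffusion coefficient (um^2/s, > 0).
#' @param psf_sigma_nm PSF sigma guess used by the detector (nm).
#' @param max_gap_frames Maximum number of missed frames bridged by a link.
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(false_alarm = 1e-6, deflation_loops = 3,
                            max_competitors = 3, d_max_um2_s = 1,
                            psf_sigma_nm = 160, max_gap_frames = 2) {
  if (false_alarm <= 0 || false_alarm >= 1)
    .stopf("'false_alarm' must be in (0, 1)")
  if (deflation_loops < 0) .stopf("'deflation_loops' must be >= 0")
  if (max_competitors < 1) .stopf("'max_competitors' must be >= 1")
  if (d_max_um2_s <= 0) .stopf("'d_max_um2_s' must be > 0")
  structure(list(false_alarm = false_alarm,
                 deflation_loops = as.integer(deflation_loops),
                 max_competitors = as.integer(max_competitors),
                 d_max_um2_s = d_max_um2_s, psf_sigma_nm = psf_sigma_nm,
                 max_gap_frames = as.integer(max_gap_frames)),
            class = "tracking_config")
}

# matched-filter GLRT score map: for each pixel, test a Gaussian peak
# against a flat background in the surrounding window; under H0 the
# statistic is Student-t with n - 2 degrees of freedom
.glrt_score <- function(frame, sigma_px, noise_floor = 0) {
  w <- max(2L, ceiling(3 * sigma_px))
  side <- 2L * w + 1L
  ax <- seq(-w, w)
  g <- outer(dnorm(ax, 0, sigma_px), dnorm(ax, 0, sigma_px))
  g <- g / sum(g)
  cmat <- g - mean(g)
  n <- side^2
  box <- matrix(1, side, side)
  num <- EBImage::filter2(frame, cmat)
  sx <- EBImage::filter2(frame, box)
  sxx <- EBImage::filter2(frame^2, box)
  cc <- sum(cmat^2)
  ss_res <- pmax(sxx - sx^2 / n - num^2 / cc, 0)
  sigma2 <- ss_res / (n - 2)
  # the floor (from the original frame's scale) keeps deflation passes
  # from amplifying numerical residue left by subtracted fits
  tval <- num / sqrt(pmax(sigma2 * cc, noise_floor^2 * cc, 1e-300))
  tval[!is.finite(tval)] <- 0
  list(t = tval, df = n - 2, w = w)
}

# least-squares pixel-integrated 2D Gaussian fit around (cx, cy) [pixel
# units]; the model integrates the PSF over each pixel (pixel i spans
# [i-1, i]) so the amplitude A is the spot's total integrated intensity
.fit_gaussian_2d <- function(frame, cx, cy, sigma_px, w) {
  ny <- nrow(frame); nx <- ncol(frame)
  i0 <- max(1L, round(cx) - w); i1 <- min(nx, round(cx) + w)
  j0 <- max(1L, round(cy) - w); j1 <- min(ny, round(cy) + w)
  z <- as.vector(frame[j0:j1, i0:i1])
  xx <- rep(i0:i1 - 0.5, each = j1 - j0 + 1L)
  yy <- rep(j0:j1 - 0.5, times = i1 - i0 + 1L)
  b0 <- min(z); a0 <- (max(z) - b0) * 2 * pi * sigma_px^2
  wgt <- pmax(z - b0, 0)
  x0 <- if (sum(wgt) > 0) sum(wgt * xx) / sum(wgt) else cx
  y0 <- if (sum(wgt) > 0) sum(wgt * yy) / sum(wgt) else cy
  if (!is.finite(x0)) x0 <- cx
  if (!is.finite(y0)) y0 <- cy
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A * (pnorm(xx + 0.5, x0, s) - pnorm(xx - 0.5, x0, s)) *
        (pnorm(yy + 0.5, y0, s) - pnorm(yy - 0.5, y0, s)),
      start = list(b = b0, A = max(a0, 1e-6), x0 = x0, y0 = y0,
                   s = sigma_px),
      lower = c(-Inf, 0, i0 - 1, j0 - 1, sigma_px * 0.85),
      upper = c(Inf, Inf, i1, j1, sigma_px * 1.15),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(x = x0, y = y0, A = a0, b = b0, s = sigma_px, r2 = NA_real_,
                ok = FALSE))
  }
  cf <- coef(fit)
  if (any(!is.finite(cf))) {
    return(list(x = x0, y = y0, A = a0, b = b0, s = sigma_px, r2 = NA_real_,
                ok = FALSE))
  }
  ssr <- sum(resid(fit)^2)
  sst <- sum((z - mean(z))^2)
  list(x = unname(cf["x0"]), y = unname(cf["y0"]), A = unname(cf["A"]),
       b = unname(cf["b"]), s = unname(cf["s"]),
       r2 = if (sst > 0) 1 - ssr / sst else 1, ok = TRUE)
}

# attempt to split one fitted spot into two emitters: refit the window
# (other spots removed) with a two-emitter pixel-integrated model at fixed
# PSF width and accept when the F-test on the RSS reduction is significant
.try_split_spot <- function(frame, spot, sigma_px, w, alpha = 1e-6) {
  ny <- nrow(frame); nx <- ncol(frame)
  cx <- spot$x; cy <- spot$y
  if (!is.finite(cx) || !is.finite(cy) || !is.finite(spot$A) ||
      !is.finite(spot$b)) return(NULL)
  i0 <- max(1L, round(cx) - w); i1 <- min(nx, round(cx) + w)
  j0 <- max(1L, round(cy) - w); j1 <- min(ny, round(cy) + w)
  z <- as.vector(frame[j0:j1, i0:i1])
  xx <- rep(i0:i1 - 0.5, each = j1 - j0 + 1L)
  yy <- rep(j0:j1 - 0.5, times = i1 - i0 + 1L)
  n <- length(z)
  if (n < 12) return(NULL)
  s <- sigma_px
  # Poisson-like noise: weight by the inverse expected variance so the
  # F-test is not dominated by shot noise at the spot peak
  wz <- 1 / pmax(z, 1)
  g1 <- function(x0, y0) (pnorm(xx + 0.5, x0, s) - pnorm(xx - 0.5, x0, s)) *
    (pnorm(yy + 0.5, y0, s) - pnorm(yy - 0.5, y0, s))
  resid1 <- z - spot$b - spot$A * g1(cx, cy)
  rss1 <- sum(wz * resid1^2)
  # seed the pair along the direction of the largest residual lobe
  top <- which.max(resid1)
  dx <- xx[top] - cx; dy <- yy[top] - cy
  nrm <- sqrt(dx^2 + dy^2)
  if (nrm < 1e-6) { dx <- 1; dy <- 0; nrm <- 1 }
  ux <- dx / nrm; uy <- dy / nrm
  off <- 0.75 * s
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A1 * (pnorm(xx + 0.5, x1, s) - pnorm(xx - 0.5, x1, s)) *
            (pnorm(yy + 0.5, y1, s) - pnorm(yy - 0.5, y1, s)) +
          A2 * (pnorm(xx + 0.5, x2, s) - pnorm(xx - 0.5, x2, s)) *
            (pnorm(yy + 0.5, y2, s) - pnorm(yy - 0.5, y2, s)),
      start = list(b = spot$b, A1 = spot$A / 2, x1 = cx - off * ux,
                   y1 = cy - off * uy, A2 = spot$A / 2,
                   x2 = cx + off * ux, y2 = cy + off * uy),
      lower = c(-Inf, 0, i0 - 1, j0 - 1, 0, i0 - 1, j0 - 1),
      upper = c(Inf, Inf, i1, j1, Inf, i1, j1),
      weights = wz,
      control = minpack.lm::nls.lm.control(maxiter = 120)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  rss2 <- sum(wz * (z - fitted(fit))^2)
  df2 <- n - 7
  if (rss2 <= 0 || df2 < 1) return(NULL)
  Fstat <- ((rss1 - rss2) / 3) / (rss2 / df2)
  if (is.na(Fstat) || stats::pf(Fstat, 3, df2, lower.tail = FALSE) > alpha)
    return(NULL)
  cf <- coef(fit)
  sep2 <- (cf["x1"] - cf["x2"])^2 + (cf["y1"] - cf["y2"])^2
  if (sep2 < (0.5 * s)^2) return(NULL)  # unresolvable: keep single spot
  if (cf["A1"] <= 0 || cf["A2"] <= 0) return(NULL)
  sst <- sum((z - mean(z))^2)
  r2 <- if (sst > 0) 1 - rss2 / sst else 1
  list(
    list(x = unname(cf["x1"]), y = unname(cf["y1"]), A = unname(cf["A1"]),
         b = unname(cf["b"]), s = s, r2 = r2, ok = TRUE),
    list(x = unname(cf["x2"]), y = unname(cf["y2"]), A = unname(cf["A2"]),
         b = unname(cf["b"]), s = s, r2 = r2, ok = TRUE))
}

# pixel-integrated Gaussian patch used for deflation subtraction
.gauss_patch <- function(ny, nx, x0, y0, A, s) {
  if (!is.finite(x0) || !is.finite(y0) || !is.finite(A) || !is.finite(s))
    return(matrix(0, ny, nx))
  w <- ceiling(5 * s)
  i0 <- max(1L, floor(x0 - w)); i1 <- min(nx, ceiling(x0 + w))
  j0 <- max(1L, floor(y0 - w)); j1 <- min(ny, ceiling(y0 + w))
  out <- matrix(0, ny, nx)
  if (i0 > i1 || j0 > j1) return(out)
  gx <- pnorm(i0:i1, x0, s) - pnorm(i0:i1 - 1, x0, s)
  gy <- pnorm(j0:j1, y0, s) - pnorm(j0:j1 - 1, y0, s)
  out[j0:j1, i0:i1] <- A * outer(gy, gx)
  out
}

#' Detect fluorescent particles in one frame
#'
#' Candidate pixels are selected by a generalized-likelihood-ratio test of a
#' Gaussian peak against a locally flat background, thresholded at the
#' configured per-pixel false-alarm probability. Each accepted candidate is
#' refined by least-squares 2D Gaussian fitting to sub-pixel precision.
#' After each of `deflation_loops` passes the fitted spots are subtracted
#' from the frame and detection is re-run on the residual, recovering
#' overlapping particles.
#'
#' @param frame Numeric matrix (one image; row = y, column = x).
#' @param config A [tracking_config()].
#' @param pixel_size_nm Pixel size (nm).
#' @return A data.frame of localisations: `x_um`, `y_um`, `x_px`, `y_px`,
#'   `sigma_nm`, `amplitude`, `background`, `score`, `r2`.
#' @export
detect_particles <- function(frame, config = tracking_config(),
                             pixel_size_nm = 160) {
  if (!all(is.finite(frame))) .stopf("'frame' contains non-finite pixels")
  stopifnot(inherits(config, "tracking_config"))
  sigma_px <- config$psf_sigma_nm / pixel_size_nm
  ny <- nrow(frame); nx <- ncol(frame)
  found <- list()
  work <- frame
  wfit <- max(2L, ceiling(3 * sigma_px))
  for (pass in 0:config$deflation_loops) {
    if (pass >= 1 && length(found)) {
      # deflation also tries to split each fitted spot into two emitters
      for (idx in seq_along(found)) {
        if (isTRUE(found[[idx]]$split_tested)) next
        found[[idx]]$split_tested <- TRUE
        others <- frame
        for (k in seq_along(found)) {
          if (k == idx) next
          others <- others - .gauss_patch(ny, nx, found[[k]]$x,
                                          found[[k]]$y, found[[k]]$A,
                                          found[[k]]$s)
        }
        sp <- .try_split_spot(others, found[[idx]], sigma_px, wfit,
                              alpha = config$false_alarm)
        if (!is.null(sp)) {
          sp[[1]]$score <- found[[idx]]$score
          sp[[2]]$score <- found[[idx]]$score
          sp[[1]]$split_tested <- TRUE
          sp[[2]]$split_tested <- TRUE
          found[[idx]] <- sp[[1]]
          found[[length(found) + 1L]] <- sp[[2]]
        }
      }
      # refresh the residual used for re-detection
      work <- frame
      for (k in seq_along(found))
        work <- work - .gauss_patch(ny, nx, found[[k]]$x, found[[k]]$y,
                                    found[[k]]$A, found[[k]]$s)
    }
    if (pass == 0) noise_floor <- 1e-6 * max(diff(range(frame)), 1e-12)
    sc <- .glrt_score(work, sigma_px, noise_floor)
    thr <- qt(1 - config$false_alarm, df = sc$df)
    tmap <- sc$t
    cand <- which(tmap > thr, arr.ind = TRUE)
    if (nrow(cand) == 0) break
    # local maxima only, then greedy exclusion within one PSF sigma
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      j <- cand[r, 1]; i <- cand[r, 2]
      nb <- tmap[max(1, j - 1):min(ny, j + 1), max(1, i - 1):min(nx, i + 1)]
      keep[r] <- tmap[j, i] >= max(nb)
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) break
    ord <- order(tmap[cand], decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    sel <- rep(TRUE, nrow(cand))
    min_sep2 <- max(1, sigma_px)^2
    for (r in seq_len(nrow(cand))) {
      if (!sel[r]) next
      if (r < nrow(cand)) {
        later <- (r + 1):nrow(cand)
        d2 <- (cand[later, 1] - cand[r, 1])^2 +
              (cand[later, 2] - cand[r, 2])^2
        sel[later][d2 < min_sep2] <- FALSE
      }
    }
    cand <- cand[sel, , drop = FALSE]
    new_spots <- list()
    for (r in seq_len(nrow(cand))) {
      j <- cand[r, 1]; i <- cand[r, 2]
      ft <- .fit_gaussian_2d(work, i - 0.5, j - 0.5, sigma_px, sc$w)
      ft$score <- tmap[j, i]
      if (!is.finite(ft$A) || ft$A <= 0 ||
          !is.finite(ft$x) || !is.finite(ft$y)) next
      # discard fits that land (nearly) on an already-fitted spot; the
      # radius is kept below one PSF sigma so deflation can still split
      # partially overlapping emitters
      prev <- do.call(rbind, lapply(c(found, new_spots),
                                    function(f) c(f$x, f$y)))
      if (!is.null(prev) &&
          any((prev[, 1] - ft$x)^2 + (prev[, 2] - ft$y)^2 < 0.36)) next
      new_spots[[length(new_spots) + 1L]] <- ft
    }
    if (length(new_spots) == 0) break
    found <- c(found, new_spots)
    if (pass < config$deflation_loops) {
      for (ft in new_spots)
        work <- work - .gauss_patch(ny, nx, ft$x, ft$y, ft$A, ft$s)
    }
  }
  if (length(found) == 0) {
    return(data.frame(x_um = numeric(), y_um = numeric(), x_px = numeric(),
                      y_px = numeric(), sigma_nm = numeric(),
                      amplitude = numeric(), background = numeric(),
                      score = numeric(), r2 = numeric()))
  }
  px_um <- pixel_size_nm / 1000
  data.frame(
    x_um = vapply(found, function(f) f$x, 1) * px_um,
    y_um = vapply(found, function(f) f$y, 1) * px_um,
    x_px = vapply(found, function(f) f$x, 1),
    y_px = vapply(found, function(f) f$y, 1),
    sigma_nm = vapply(found, function(f) f$s, 1) * pixel_size_nm,
    amplitude = vapply(found, function(f) f$A, 1),
    background = vapply(found, function(f) f$b, 1),
    score = vapply(found, function(f) f$score, 1),
    r2 = vapply(found, function(f) f$r2, 1))
}

#' Detect particles in every frame of an image stack
#'
#' @param stack An `image_stack` (see [render_movie()]).
#' @param config A [tracking_config()].
#' @return A data.frame of localisations with a `frame` column.
#' @export
detect_movie <- function(stack, config = tracking_config()) {
  stopifnot(inherits(stack, "image_stack"))
  out <- lapply(seq_len(dim(stack$data)[1]), function(f) {
    df <- detect_particles(stack$data[f, , ], config, stack$pixel_size_nm)
    if (nrow(df)) df$frame <- f
    df
  })
  out <- out[vapply(out, nrow, 1L) > 0]
  if (!length(out)) {
    return(data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                      amplitude = numeric()))
  }
  do.call(rbind, out)
}

#' Link per-frame localisations into trajectories
#'
#' Frame-by-frame assignment in the style of multiple-target tracing:
#' candidate links are restricted to displacements within
#' `r_max = sqrt(4 * D_max * dt * (gap + 1))`; when several candidates
#' compete, up to `max_competitors` hypotheses per localisation are scored
#' by displacement likelihood plus intensity continuity and the best global
#' greedy assignment wins. Ties are broken by smaller displacement, then
#' lower trajectory id, so linking is deterministic. Unmatched
#' localisations start new trajectories; tracks may bridge up to
#' `max_gap_frames` missed frames.
#'
#' @param localizations data.frame with `frame`, `x_um`, `y_um` and
#'   optionally `amplitude`.
#' @param config A [tracking_config()].
#' @param dt_s Frame interval (s).
#' @param intensity_weight Weight of the relative intensity change in the
#'   assignment score.
#' @return Trajectory data.frame in the common schema (`trajectory_id`,
#'   `frame`, `t_s`, `x_um`, `y_um`, `intensity`, `channel`). Empty input
#'   yields an empty table.
#' @export
link_trajectories <- function(localizations, config = tracking_config(),
                              dt_s = 0.05, intensity_weight = 0.5) {
  stopifnot(inherits(config, "tracking_config"))
  empty <- data.frame(trajectory_id = integer(), frame = integer(),
                      t_s = numeric(), x_um = numeric(), y_um = numeric(),
                      intensity = numeric(), channel = character(),
                      stringsAsFactors = FALSE)
  if (is.null(localizations) || nrow(localizations) == 0) return(empty)
  locs <- localizations[order(localizations$frame), , drop = FALSE]
  if (is.null(locs$amplitude)) locs$amplitude <- 1
  frames <- sort(unique(locs$frame))

  track_last <- data.frame(id = integer(), x = numeric(), y = numeric(),
                           I = numeric(), frame = integer())
  rows <- list()
  next_id <- 1L
  for (f in frames) {
    cur <- locs[locs$frame == f, , drop = FALSE]
    nl <- nrow(cur)
    assigned_loc <- rep(FALSE, nl)
    if (nrow(track_last)) {
      act <- track_last[track_last$frame >= f - 1L - config$max_gap_frames &
                        track_last$frame < f, , drop = FALSE]
      if (nrow(act)) {
        cands <- list()
        for (li in seq_len(nl)) {
          gap <- f - act$frame - 1L
          rmax <- sqrt(4 * config$d_max_um2_s * dt_s * (gap + 1))
          dx <- cur$x_um[li] - act$x
          dy <- cur$y_um[li] - act$y
          disp <- sqrt(dx^2 + dy^2)
          ok <- which(disp <= rmax)
          if (!length(ok)) next
          cost <- disp[ok]^2 / (4 * config$d_max_um2_s * dt_s * (gap[ok] + 1)) +
            intensity_weight * abs(cur$amplitude[li] - act$I[ok]) /
              pmax(act$I[ok], 1e-12)
          ord <- order(cost, disp[ok], act$id[ok])
          ord <- ord[seq_len(min(length(ord), config$max_competitors))]
          cands[[length(cands) + 1L]] <- data.frame(
            loc = li, track = act$id[ok][ord], cost = cost[ord],
            disp = disp[ok][ord])
        }
        if (length(cands)) {
          cands <- do.call(rbind, cands)
          cands <- cands[order(cands$cost, cands$disp, cands$track), ,
                         drop = FALSE]
          used_track <- integer(0)
          for (r in seq_len(nrow(cands))) {
            li <- cands$loc[r]; ti <- cands$track[r]
            if (assigned_loc[li] || ti %in% used_track) next
            assigned_loc[li] <- TRUE
            used_track <- c(used_track, ti)
            k <- which(track_last$id == ti)
            track_last$x[k] <- cur$x_um[li]
            track_last$y[k] <- cur$y_um[li]
            track_last$I[k] <- cur$amplitude[li]
            track_last$frame[k] <- f
            rows[[length(rows) + 1L]] <- data.frame(
              trajectory_id = ti, frame = f, x_um = cur$x_um[li],
              y_um = cur$y_um[li], intensity = cur$amplitude[li])
          }
        }
      }
    }
    for (li in which(!assigned_loc)) {
      track_last <- rbind(track_last, data.frame(
        id = next_id, x = cur$x_um[li], y = cur$y_um[li],
        I = cur$amplitude[li], frame = f))
      rows[[length(rows) + 1L]] <- data.frame(
        trajectory_id = next_id, frame = f, x_um = cur$x_um[li],
        y_um = cur$y_um[li], intensity = cur$amplitude[li])
      next_id <- next_id + 1L
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$trajectory_id, out$frame), , drop = FALSE]
  out$t_s <- (out$frame - 1) * dt_s
  out$channel <- "track"
  rownames(out) <- NULL
  out[, c("trajectory_id", "frame", "t_s", "x_um", "y_um", "intensity",
          "channel")]
}

#' Quality-control filter for reconstructed tracks
#'
#' Automated replacement for manual track curation: drops trajectories
#' shorter than `min_steps` steps.
#'
#' @param trajectories Trajectory data.frame.
#' @param min_steps Minimum number of steps (points - 1) per track.
#' @export
filter_tracks <- function(trajectories, min_steps = 10) {
  n <- table(trajectories$trajectory_id)
  keep <- names(n)[n >= min_steps + 1]
  trajectories[trajectories$trajectory_id %in% keep, , drop = FALSE]
}
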