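#' Render trajectories into a synthetic fluorescence movie
#'
#' Emulates camera acquisition of the simulated particles under inclined
#' light-sheet illumination: every particle with non-zero intensity
#' contributes a pixel-integrated 2D Gaussian point-spread function, a flat
#' fluorescence background is added, and per-pixel Poisson shot noise
#' followed by camera gain, offset and Gaussian read noise are applied.
#'
#' @param trajectories Trajectory data.frame (`frame`, `x_um`, `y_um`,
#'   `intensity`); the `intensity` column scales the emitted photons.
#' @param nx,ny Field of view in pixels (width, height).
#' @param pixel_size_nm Pixel size (default 160 nm).
#' @param psf_sigma_nm PSF standard deviation (> 0).
#' @param dt_s Frame interval stored with the stack.
#' @param photons_per_unit Expected photons per unit of `intensity`.
#' @param background Background photon level per pixel.
#' @param gain,offset Camera gain (counts/photon) and offset (counts).
#' @param read_noise_sd Gaussian read noise (counts).
#' @param noise If `FALSE`, return the noiseless expected image (offset and
#'   gain still applied).
#' @param seed Optional integer seed.
#' @return An object of class `image_stack`: list with `data` (T x ny x nx
#'   array of counts), acquisition metadata, and the noise parameters.
#'   Particles outside the field of view are skipped with a warning.
#' @export
render_movie <- function(trajectories, nx = 64, ny = 64,
                         pixel_size_nm = 160, psf_sigma_nm = 160,
                         dt_s = 0.05, photons_per_unit = 1,
                         background = 10, gain = 1, offset = 100,
                         read_noise_sd = 2, noise = TRUE, seed = NULL) {
  if (psf_sigma_nm <= 0) .stopf("'psf_sigma_nm' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  px_um <- pixel_size_nm / 1000
  sigma_px <- psf_sigma_nm / pixel_size_nm
  frames <- if (nrow(trajectories)) sort(unique(trajectories$frame)) else
    integer(0)
  n_frames <- if (length(frames)) max(frames) else 1L
  stack <- array(background, dim = c(n_frames, ny, nx))

  n_clipped <- 0L
  if (nrow(trajectories)) {
    xs_px <- trajectories$x_um / px_um
    ys_px <- trajectories$y_um / px_um
    outside <- xs_px < 0 | xs_px > nx | ys_px < 0 | ys_px > ny
    n_clipped <- sum(outside)
    w <- ceiling(5 * sigma_px)
    for (r in which(!outside & trajectories$intensity > 0)) {
      fr <- trajectories$frame[r]
      amp <- trajectories$intensity[r] * photons_per_unit
      cx <- xs_px[r]; cy <- ys_px[r]
      i0 <- max(1L, floor(cx - w)); i1 <- min(nx, ceiling(cx + w))
      j0 <- max(1L, floor(cy - w)); j1 <- min(ny, ceiling(cy + w))
      if (i0 > i1 || j0 > j1) next
      ix <- i0:i1; jy <- j0:j1
      # pixel i covers [i-1, i); integrate the Gaussian over each pixel
      gx <- pnorm(ix, cx, sigma_px) - pnorm(ix - 1, cx, sigma_px)
      gy <- pnorm(jy, cy, sigma_px) - pnorm(jy - 1, cy, sigma_px)
      stack[fr, jy, ix] <- stack[fr, jy, ix] + amp * outer(gy, gx)
    }
  }
  if (n_clipped > 0)
    .warnf("%d localisations outside the field of view were clipped",
           n_clipped)

  if (noise) {
    counts <- rpois(length(stack), stack) * gain + offset +
      rnorm(length(stack), 0, read_noise_sd)
    stack <- array(pmax(counts, 0), dim = dim(stack))
  } else {
    stack <- stack * gain + offset
  }
  structure(list(data = stack, pixel_size_nm = pixel_size_nm, dt_s = dt_s,
                 background = background, gain = gain, offset = offset,
                 read_noise_sd = read_noise_sd),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d frames of %d x %d px (%g nm/px, dt = %g s)\n",
              d[1], d[3], d[2], x$pixel_size_nm, x$dt_s))
  invisible(x)
}

#' Write / read an image stack as 16-bit multi-page TIFF with JSON sidecar
#'
#' Counts are linearly scaled into the 16-bit range; the scale factor,
#' pixel size and frame interval are stored in a `.json` sidecar next to the
#' TIFF so the stack can be restored losslessly up to 16-bit quantisation.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(stack$data, 1e-12)
  pages <- lapply(seq_len(dim(stack$data)[1]),
                  function(i) stack$data[i, , ] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(pixel_size_nm = stack$pixel_size_nm, dt_s = stack$dt_s,
               scale_max = mx, background = stack$background,
               gain = stack$gain, offset = stack$offset,
               read_noise_sd = stack$read_noise_sd)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(NA_real_, dim = c(length(pages), nrow(pages[[1]]),
                                 ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * meta$scale_max
  structure(list(data = arr, pixel_size_nm = meta$pixel_size_nm,
                 dt_s = meta$dt_s, background = meta$background,
                 gain = meta$gain, offset = meta$offset,
                 read_noise_sd = meta$read_noise_sd),
            class = "image_stack")
}

#' Simulate an image containing filamentous structures
#'
#' Draws smooth curvilinear filaments of a given stroke width on a noisy
#' background, as a test image for the filament skeletonisation pipeline.
#' Each filament is specified as a polyline (n x 2 matrix of pixel
#' coordinates); pixels within half the stroke width of a polyline are set
#' to `amplitude` above background.
#'
#' @param paths List of polylines (n x 2 matrices, pixel units).
#' @param nx,ny Image size in pixels.
#' @param width_px Stroke width of the filaments.
#' @param amplitude Filament intensity above background.
#' @param background Background level.
#' @param noise_sd Gaussian noise SD.
#' @param seed Optional seed.
#' @return A ny x nx numeric matrix.
#' @export
simulate_filament_image <- function(paths, nx = 128, ny = 128, width_px = 3,
                                    amplitude = 100, background = 10,
                                    noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  img <- matrix(background, ny, nx)
  half <- width_px / 2
  xs <- matrix(rep(seq_len(nx), each = ny), ny)
  ys <- matrix(rep(seq_len(ny), nx), ny)
  for (p in paths) {
    p <- as.matrix(p)
    # dense resampling of the polyline at sub-pixel resolution
    seg_len <- sqrt(rowSums(diff(p)^2))
    pts <- do.call(rbind, lapply(seq_len(nrow(p) - 1L), function(j) {
      n <- max(2L, ceiling(seg_len[j] / 0.25))
      t <- seq(0, 1, length.out = n)
      cbind(p[j, 1] + t * (p[j + 1, 1] - p[j, 1]),
            p[j, 2] + t * (p[j + 1, 2] - p[j, 2]))
    }))
    hit <- matrix(FALSE, ny, nx)
    for (k in seq_len(nrow(pts))) {
      i0 <- max(1L, floor(pts[k, 1] - half - 1))
      i1 <- min(nx, ceiling(pts[k, 1] + half + 1))
      j0 <- max(1L, floor(pts[k, 2] - half - 1))
      j1 <- min(ny, ceiling(pts[k, 2] + half + 1))
      if (i0 > i1 || j0 > j1) next
      sub_d2 <- (xs[j0:j1, i0:i1] - pts[k, 1])^2 +
                (ys[j0:j1, i0:i1] - pts[k, 2])^2
      hit[j0:j1, i0:i1] <- hit[j0:j1, i0:i1] | sub_d2 <= half^2
    }
    img[hit] <- background + amplitude
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(nx * ny, 0, noise_sd), ny)
  img
}
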