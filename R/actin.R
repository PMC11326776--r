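# grayscale neighbourhood filters via shifted copies (square structuring
# element of radius r); edges are padded by replication
.shift_pad <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- .clamp(seq_len(nr) + dr, 1L, nr)
  ci <- .clamp(seq_len(nc) + dc, 1L, nc)
  m[ri, ci, drop = FALSE]
}

.min_filter <- function(m, r) {
  out <- m
  for (dr in -r:r) for (dc in -r:r)
    out <- pmin(out, .shift_pad(m, dr, dc))
  out
}

.max_filter <- function(m, r) {
  out <- m
  for (dr in -r:r) for (dc in -r:r)
    out <- pmax(out, .shift_pad(m, dr, dc))
  out
}

#' Preprocess a filament (F-actin reporter) image
#'
#' Signal-to-noise preparation before filament thresholding: a rolling
#' background (grayscale morphological opening with a square structuring
#' element of radius `background_radius_px`) is subtracted, a grayscale
#' minimum filter suppresses isolated hot pixels, and pixels inside the
#' spine mask are set to zero, restricting all downstream measurements to
#' the dendritic shaft.
#'
#' @param image 2D numeric matrix, finite.
#' @param spine_mask Optional logical matrix of the same shape (TRUE =
#'   spine pixel, zeroed).
#' @param background_radius_px Background (opening) radius; the default of
#'   12 px corresponds to about 2 um shaft width at Airyscan sampling.
#' @param min_filter_radius_px Minimum-filter radius (default 1).
#' @return Preprocessed matrix (non-negative).
#' @export
preprocess_tractin <- function(image, spine_mask = NULL,
                               background_radius_px = 12,
                               min_filter_radius_px = 1) {
  if (!all(is.finite(image))) .stopf("'image' contains non-finite pixels")
  if (!is.null(spine_mask) && !all(dim(spine_mask) == dim(image)))
    .stopf("'spine_mask' shape does not match the image")
  bg <- .max_filter(.min_filter(image, background_radius_px),
                    background_radius_px)
  out <- pmax(image - bg, 0)
  if (min_filter_radius_px > 0)
    out <- .min_filter(out, min_filter_radius_px)
  if (!is.null(spine_mask)) out[spine_mask] <- 0
  out
}

#' Threshold an image into a binary filament mask
#'
#' `method = "otsu"` maximises the between-class variance over a 256-bin
#' histogram (used for live filament-reporter images); `method =
#' "intermodes"` iteratively smooths the 256-bin histogram with a running
#' mean of three until exactly two modes remain and takes the midpoint
#' between them (used for fixed-sample masking). A constant image is
#' degenerate and yields an empty mask with a warning.
#'
#' @param image 2D numeric matrix.
#' @param method `"otsu"` or `"intermodes"`.
#' @return A list with `mask` (logical matrix, TRUE above threshold) and
#'   `threshold` (in image intensity units).
#' @export
threshold_mask <- function(image, method = c("otsu", "intermodes")) {
  method <- match.arg(method)
  rng <- range(image)
  if (diff(rng) == 0) {
    .warnf("constant image: empty mask returned")
    return(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                threshold = NA_real_))
  }
  if (method == "otsu") {
    norm <- (image - rng[1]) / diff(rng)
    th01 <- EBImage::otsu(norm, range = c(0, 1), levels = 256)
    threshold <- rng[1] + th01 * diff(rng)
  } else {
    brk <- seq(rng[1], rng[2], length.out = 257)
    h <- hist(as.vector(image), breaks = brk, plot = FALSE)$counts
    h <- as.numeric(h)
    n_modes <- function(v) {
      left <- c(-Inf, v[-length(v)])
      right <- c(v[-1], -Inf)
      sum(v > left & v >= right)
    }
    it <- 0L
    while (n_modes(h) > 2 && it < 10000L) {
      h <- (c(h[1], h[-length(h)]) + h + c(h[-1], h[length(h)])) / 3
      it <- it + 1L
    }
    left <- c(-Inf, h[-length(h)])
    right <- c(h[-1], -Inf)
    modes <- which(h > left & h >= right)
    if (length(modes) < 2) {
      .warnf("histogram not bimodal: empty mask returned")
      return(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                  threshold = NA_real_))
    }
    mid <- (modes[1] + modes[length(modes)]) / 2
    threshold <- brk[1] + (mid - 0.5) * diff(rng) / 256
  }
  list(mask = image > threshold, threshold = threshold)
}

# Zhang-Suen morphological thinning to a 1-pixel-wide skeleton
.thin_mask <- function(mask) {
  m <- mask * 1L
  sh <- function(dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0L, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- sh(-1, 0); p3 <- sh(-1, 1); p4 <- sh(0, 1); p5 <- sh(1, 1)
      p6 <- sh(1, 0); p7 <- sh(1, -1); p8 <- sh(0, -1); p9 <- sh(-1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (seqs[[i]] == 0L & seqs[[i + 1]] == 1L)
      if (sub == 1) {
        cond <- m == 1L & B >= 2 & B <= 6 & A == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- m == 1L & B >= 2 & B <= 6 & A == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# staircase removal: a corner pixel whose only two neighbours are
# orthogonal to it and diagonal to each other is redundant (the path can
# take the diagonal step), and such corners make thinned curves zigzag
.remove_staircase <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  repeat {
    pad <- matrix(FALSE, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- skel
    at <- function(dr, dc) pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    n_up <- at(-1, 0); n_dn <- at(1, 0); n_lf <- at(0, -1); n_rt <- at(0, 1)
    n_ul <- at(-1, -1); n_ur <- at(-1, 1); n_dl <- at(1, -1); n_dr <- at(1, 1)
    deg <- n_up + n_dn + n_lf + n_rt + n_ul + n_ur + n_dl + n_dr
    corner <- skel & deg == 2 &
      ((n_up & n_rt) | (n_rt & n_dn) | (n_dn & n_lf) | (n_lf & n_up))
    if (!any(corner)) break
    # remove one corner per connected run at a time to avoid breaking paths
    idx <- which(corner)
    skel[idx[seq(1, length(idx), by = 2)]] <- FALSE
  }
  skel
}

# remove skeleton branches shorter than min_px that end in a free endpoint
.prune_spurs <- function(skel, min_px) {
  if (min_px <= 0) return(skel)
  nb_count <- function(s) {
    m <- s * 1L
    tot <- matrix(0L, nrow(m), ncol(m))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nr <- nrow(m); nc <- ncol(m)
      out <- matrix(0L, nr, nc)
      rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
      ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
      out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
      tot <- tot + out
    }
    tot
  }
  repeat {
    cnt <- nb_count(skel)
    endpoints <- which(skel & cnt == 1, arr.ind = TRUE)
    removed_any <- FALSE
    for (e in seq_len(nrow(endpoints))) {
      path <- list(endpoints[e, ])
      cur <- endpoints[e, ]
      prev <- c(-1L, -1L)
      hit_junction <- FALSE
      while (length(path) <= min_px) {
        nbs <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r <- cur[1] + dr; c <- cur[2] + dc
          if (r < 1 || c < 1 || r > nrow(skel) || c > ncol(skel)) next
          if (skel[r, c] && !(r == prev[1] && c == prev[2]))
            nbs <- rbind(nbs, c(r, c))
        }
        if (is.null(nbs) || nrow(nbs) == 0) break     # isolated branch
        if (nrow(nbs) > 1 || cnt[nbs[1, 1], nbs[1, 2]] >= 3) {
          hit_junction <- TRUE
          break
        }
        prev <- cur
        cur <- nbs[1, ]
        path[[length(path) + 1L]] <- cur
      }
      if (hit_junction && length(path) < min_px) {
        for (p in path) skel[p[1], p[2]] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  skel
}

#' Skeletonise a filament mask and measure total skeleton length
#'
#' The binary mask is thinned to a 1-pixel-wide skeleton (Zhang-Suen
#' thinning), short spur branches are pruned, and the total length is the
#' sum over adjacent skeleton-pixel pairs of `pixel_size_um` for
#' 4-neighbours and `sqrt(2) * pixel_size_um` for diagonal neighbours,
#' summed over all branches.
#'
#' @param mask Logical matrix (filament mask).
#' @param pixel_size_um Pixel size (um).
#' @param prune_px Branches shorter than this many pixels ending in a free
#'   endpoint are removed (default 3; 0 disables pruning).
#' @return An object of class `skeleton_result`: list with `skeleton`
#'   (logical matrix), `length_um`, `n_skeleton_px`, `pixel_size_um`.
#' @export
skeletonize_and_measure <- function(mask, pixel_size_um, prune_px = 3) {
  if (!is.logical(mask)) mask <- mask > 0
  if (!any(mask)) {
    return(structure(list(skeleton = mask, length_um = 0,
                          n_skeleton_px = 0L,
                          pixel_size_um = pixel_size_um),
                     class = "skeleton_result"))
  }
  skel <- .thin_mask(mask)
  skel <- .remove_staircase(skel)
  skel <- .prune_spurs(skel, prune_px)
  nr <- nrow(skel); nc <- ncol(skel)
  n_orth <- sum(skel[, -1] & skel[, -nc]) + sum(skel[-1, ] & skel[-nr, ])
  # a diagonal pair whose two pixels share an orthogonal skeleton
  # neighbour is a corner shortcut, not a path step: skip it so L-turns
  # are not double-counted
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- skel
  at <- function(dr, dc) pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  n_diag <- 0L
  for (d in list(c(1, 1), c(1, -1))) {
    pair <- skel & at(d[1], d[2])
    shared <- at(d[1], 0) | at(0, d[2])  # the pair's common 4-neighbours
    n_diag <- n_diag + sum(pair & !shared)
  }
  structure(list(skeleton = skel,
                 length_um = (n_orth + sqrt(2) * n_diag) * pixel_size_um,
                 n_skeleton_px = sum(skel), pixel_size_um = pixel_size_um),
            class = "skeleton_result")
}

#' @export
print.skeleton_result <- function(x, ...) {
  cat(sprintf("skeleton_result: %d skeleton px, total length %.3f um\n",
              x$n_skeleton_px, x$length_um))
  invisible(x)
}

#' Mean fluorescence intensity in the dendritic shaft
#'
#' Mean of the pixels inside the shaft mask and outside the spine mask;
#' the shaft readout used for fixed-sample F-actin quantification.
#'
#' @param image 2D numeric matrix.
#' @param spine_mask,shaft_mask Logical matrices matching the image.
#' @return Mean intensity (scalar).
#' @export
shaft_mfi <- function(image, spine_mask, shaft_mask) {
  if (!all(dim(spine_mask) == dim(image)) ||
      !all(dim(shaft_mask) == dim(image)))
    .stopf("mask shapes do not match the image")
  sel <- shaft_mask & !spine_mask
  if (!any(sel)) .stopf("empty effective shaft region")
  mean(image[sel])
}
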