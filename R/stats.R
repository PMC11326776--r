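#' Knock-in efficiency from neuron counts
#'
#' Efficiency of endogenous-tag integration estimated from fluorescence
#' counts of cultured neurons: the fraction of successfully edited neurons
#' among those co-transfected with both the donor and the nuclease
#' construct. Only the donor carries a transfection marker, so the
#' co-transfection rate is extrapolated as the marker transfection rate
#' squared:
#' `KI = n_halo_pos / ((n_marker_pos / n_total)^2 * n_total)`.
#'
#' @param n_halo_pos Neurons expressing the knocked-in tag.
#' @param n_marker_pos Neurons expressing the transfection marker.
#' @param n_total Total neurons counted.
#' @return Efficiency (fraction; can exceed 1 if the squared-rate
#'   extrapolation underestimates co-transfection).
#' @export
knockin_efficiency <- function(n_halo_pos, n_marker_pos, n_total) {
  if (n_total <= 0) .stopf("'n_total' must be > 0")
  if (n_marker_pos <= 0) .stopf("'n_marker_pos' must be > 0")
  if (n_halo_pos < 0) .stopf("'n_halo_pos' must be >= 0")
  n_halo_pos / ((n_marker_pos / n_total)^2 * n_total)
}

#' Convert a physical distance to a linearized nucleotide count
#'
#' Number of nucleotides spanned by a physical distance along a fully
#' linearized nucleic acid, at a rise of 0.34 nm per nucleotide, truncated
#' to a whole nucleotide: 0.5 um corresponds to 1470 nucleotides. Used to
#' translate a colocalisation distance cutoff into sequence length.
#'
#' @param distance_um Distance (um, >= 0).
#' @param rise_per_nt_nm Axial rise per nucleotide (nm).
#' @return Integer nucleotide count.
#' @export
linearized_nt_for_distance <- function(distance_um, rise_per_nt_nm = 0.34) {
  if (any(distance_um < 0)) .stopf("'distance_um' must be >= 0")
  as.integer(floor(distance_um * 1000 / rise_per_nt_nm))
}

#' Distance between two fluorescence line-profile peaks
#'
#' Fits one Gaussian per channel to an intensity line profile (adjacent
#' puncta crossed by a single line) and returns the absolute distance
#' between the fitted peak centres; the readout for signals that co-occur
#' but do not colocalise.
#'
#' @param position_um Positions along the profile (um).
#' @param intensity_a,intensity_b Intensities of the two channels.
#' @param min_r2 Minimum fit R^2 per channel; below it the result is
#'   flagged and `NA`.
#' @return A list with `separation_um`, `center_a_um`, `center_b_um`,
#'   `r2_a`, `r2_b`, `ok`.
#' @export
peak_separation <- function(position_um, intensity_a, intensity_b,
                            min_r2 = 0.5) {
  fit1 <- .fit_gaussian_1d(position_um, intensity_a)
  fit2 <- .fit_gaussian_1d(position_um, intensity_b)
  ok <- !is.na(fit1$r2) && !is.na(fit2$r2) &&
    fit1$r2 >= min_r2 && fit2$r2 >= min_r2
  list(separation_um = if (ok) abs(fit1$mu - fit2$mu) else NA_real_,
       center_a_um = fit1$mu, center_b_um = fit2$mu,
       r2_a = fit1$r2, r2_b = fit2$r2, ok = ok)
}

.fit_gaussian_1d <- function(x, y) {
  b0 <- min(y); a0 <- max(y) - b0
  mu0 <- x[which.max(y)]
  s0 <- max(diff(range(x)) / 10, 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ b + A * exp(-(x - mu)^2 / (2 * s^2)),
                      start = list(b = b0, A = max(a0, 1e-9), mu = mu0,
                                   s = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(mu = NA_real_, r2 = NA_real_))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(resid(fit)^2) / sst else 1
  list(mu = unname(coef(fit)["mu"]), r2 = r2)
}

#' Gaussian kernel density estimate on a grid
#'
#' Density summaries of per-trajectory statistics (diffusion coefficients,
#' directional-bias angles). The bandwidth is chosen by the Sheather-Jones
#' plug-in rule, falling back to Silverman's rule when the plug-in
#' estimate fails; the rule used is recorded in the output. With fewer
#' than 5 samples a histogram fallback is returned with a warning.
#'
#' @param samples Numeric vector.
#' @param n_grid Grid size.
#' @return A list with `x`, `y`, `bw`, `bw_rule`, `type`
#'   (`"kde"`/`"histogram"`).
#' @export
kde_density <- function(samples, n_grid = 512) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 5) {
    .warnf("fewer than 5 samples: histogram fallback")
    h <- hist(samples, plot = FALSE)
    return(list(x = h$mids, y = h$density, bw = NA_real_,
                bw_rule = "histogram", type = "histogram"))
  }
  bw <- tryCatch(bw.SJ(samples), error = function(e) NULL)
  rule <- "sheather-jones"
  if (is.null(bw)) {
    bw <- bw.nrd0(samples)
    rule <- "silverman"
  }
  d <- density(samples, bw = bw, n = n_grid)
  list(x = d$x, y = d$y, bw = bw, bw_rule = rule, type = "kde")
}

#' Two-sample distribution comparison
#'
#' The hypothesis tests used to compare per-condition distributions:
#' two-sample Kolmogorov-Smirnov, Mann-Whitney (unpaired rank sum), or
#' Wilcoxon matched-pairs signed rank. Two-sided p-values.
#'
#' @param a,b Numeric samples (`wilcoxon_paired` requires equal lengths).
#' @param test One of `"ks"`, `"mann_whitney"`, `"wilcoxon_paired"`.
#' @return A list with `statistic`, `p_value`, `test`, `flag` (degenerate
#'   cases, e.g. all-zero paired differences).
#' @export
compare_distributions <- function(a, b,
                                  test = c("ks", "mann_whitney",
                                           "wilcoxon_paired")) {
  test <- match.arg(test)
  if (length(a) < 2 || length(b) < 2) .stopf("need >= 2 samples per group")
  flag <- NA_character_
  res <- switch(test,
    ks = suppressWarnings(ks.test(a, b)),
    mann_whitney = suppressWarnings(wilcox.test(a, b, paired = FALSE)),
    wilcoxon_paired = {
      if (length(a) != length(b))
        .stopf("'wilcoxon_paired' requires equal lengths")
      if (all(a - b == 0)) {
        flag <- "all paired differences are zero"
        return(list(statistic = 0, p_value = 1, test = test, flag = flag))
      }
      suppressWarnings(wilcox.test(a, b, paired = TRUE))
    })
  list(statistic = unname(res$statistic), p_value = res$p.value,
       test = test, flag = flag)
}
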