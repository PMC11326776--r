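#' Time-averaged mean squared displacement of a trajectory
#'
#' For lag `k`, MSD(k * dt) is the average squared displacement over all
#' ordered pairs of points separated by `k` frames. Sampling must be
#' uniform in time.
#'
#' @param trajectory Trajectory data.frame (`t_s`, `x_um`, `y_um`) with at
#'   least 3 points.
#' @param max_lag_fraction Largest lag as a fraction of the number of steps.
#' @return An object of class `msd_fit`: data.frame with `lag_s`,
#'   `msd_um2`, `n_pairs`, plus attributes `dt_s` and `n_steps`.
#' @export
compute_msd <- function(trajectory, max_lag_fraction = 0.25) {
  if (nrow(trajectory) < 3) .stopf("trajectory needs >= 3 points")
  t <- trajectory$t_s
  dts <- diff(t)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * max(dt, 1)))
    .stopf("trajectory is not uniformly sampled")
  x <- trajectory$x_um; y <- trajectory$y_um
  n_steps <- length(x) - 1L
  max_lag <- max(1L, floor(max_lag_fraction * n_steps))
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(k) {
    i <- seq_len(length(x) - k)
    mean((x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)
  }, numeric(1))
  out <- data.frame(lag_s = lags * dt, msd_um2 = msd,
                    n_pairs = length(x) - lags)
  attr(out, "dt_s") <- dt
  attr(out, "n_steps") <- n_steps
  class(out) <- c("msd_fit", "data.frame")
  out
}

#' Fit the diffusion-plus-drift model to an MSD curve
#'
#' Least-squares fit of `MSD(t) = 4 D t + (V t)^2` with `D >= 0` and
#' `|V| >= 0`, the two-dimensional model separating Brownian diffusion from
#' directed transport. Fits with `R^2 >= 0.8` are conventionally accepted
#' for pure-diffusion validation.
#'
#' @param msd An `msd_fit` curve from [compute_msd()], or any data.frame
#'   with `lag_s` and `msd_um2`.
#' @return A list with `d_um2_s`, `speed_um_s`, `r2` (two-parameter
#'   model), plus the pure-diffusion validation fit: `d_pure_um2_s`,
#'   `r2_pure` and `pure_accepted` (`r2_pure >= 0.8`).
#' @export
fit_msd_model <- function(msd) {
  t <- msd$lag_s; y <- msd$msd_um2
  if (length(t) < 3) .stopf("need >= 3 lag points")
  if (all(y == 0)) {
    return(list(d_um2_s = 0, speed_um_s = 0, r2 = 1, d_pure_um2_s = 0,
                r2_pure = 1, pure_accepted = TRUE))
  }
  X <- cbind(4 * t, t^2)  # coefficients (D, V^2)
  cf <- tryCatch(qr.solve(X, y), error = function(e) c(0, 0))
  if (any(cf < 0)) {
    # clamp the offending coefficient and refit the other
    cf_d <- max(0, sum(X[, 1] * y) / sum(X[, 1]^2))
    cf_v <- max(0, sum(X[, 2] * y) / sum(X[, 2]^2))
    fit_d <- sum((y - X[, 1] * cf_d)^2)
    fit_v <- sum((y - X[, 2] * cf_v)^2)
    cf <- if (fit_d <= fit_v) c(cf_d, 0) else c(0, cf_v)
  }
  yhat <- X %*% cf
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum((y - yhat)^2) / sst else 1
  # pure-diffusion (through-origin linear) validation fit
  d_pure <- max(0, sum(X[, 1] * y) / sum(X[, 1]^2))
  r2_pure <- if (sst > 0) 1 - sum((y - X[, 1] * d_pure)^2) / sst else 1
  list(d_um2_s = unname(cf[1]), speed_um_s = unname(sqrt(cf[2])),
       r2 = r2, d_pure_um2_s = d_pure, r2_pure = r2_pure,
       pure_accepted = r2_pure >= 0.8)
}

#' Anomalous diffusion exponent from an MSD curve
#'
#' Slope of `log(MSD)` against `log(lag)`: 1 for Brownian motion, 2 for
#' ballistic transport, < 1 for subdiffusion (constrained motion due to
#' crowding or binding).
#'
#' @param msd An `msd_fit` curve.
#' @return The exponent `alpha` (scalar).
#' @export
fit_anomalous_exponent <- function(msd) {
  ok <- msd$msd_um2 > 0 & msd$lag_s > 0
  if (any(!ok)) .warnf("%d non-positive MSD points excluded", sum(!ok))
  if (sum(ok) < 2) .stopf("need >= 2 positive MSD points")
  fit <- lm(log(msd$msd_um2[ok]) ~ log(msd$lag_s[ok]))
  unname(coef(fit)[2])
}
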