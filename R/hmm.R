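#' Fit a hidden Markov motion-state model to a trajectory
#'
#' Infers per-step motion states from the displacement series of a single
#' trajectory. Candidate models are enumerated over the number of states
#' `K` in `1..max_states` and over the per-state kind: purely diffusive
#' (`D`) or directed transport (`DV`, drift plus diffusion). Emissions are
#' Gaussian per axis with mean `V * dt` and variance
#' `2 * D * dt + 2 * sigma_loc^2`; each candidate is fitted by
#' expectation-maximisation (Baum-Welch) on the displacements, and the
#' model with the lowest BIC is returned together with the Viterbi-decoded
#' state path and per-step posterior state probabilities. Candidates within
#' `bic_margin` of the best score are resolved in favour of fewer states
#' (then fewer parameters), so a simpler motion model is preferred when the
#' evidence is equivocal. Single-state models are fitted in closed form;
#' for `K = 1` purely diffusive motion the estimate equals the
#' noise-corrected mean-squared-step estimator
#' `sum(|dr|^2) / (4 n dt) - sigma_loc^2 / dt` (floored at zero).
#'
#' @param trajectory Trajectory data.frame (`t_s`, `x_um`, `y_um`).
#'   Trajectories shorter than 20 steps fall back to a single-state fit
#'   with a warning.
#' @param max_states Maximum number of states (1-3).
#' @param sigma_loc_um Localisation noise SD per axis (um), subtracted from
#'   the emission variance when converting to diffusion coefficients.
#' @param n_restarts EM restarts per candidate (k-means initialisation on
#'   step speeds, then jittered).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param bic_margin Within this BIC margin the model with fewer states
#'   wins.
#' @param seed Seed for the (deterministic) initialisation draws.
#' @return An object of class `motion_state_model`: `K`, `states`
#'   (data.frame: `kind`, `d_um2_s`, `vx_um_s`, `vy_um_s`, `speed_um_s`,
#'   `occupancy`), `trans`, `init`, `path` (decoded state per step),
#'   `posterior` (n_steps x K), `loglik`, `bic`, `converged`, `candidates`
#'   (model-selection table), `dt_s`, `n_steps`.
#' @export
fit_hmm <- function(trajectory, max_states = 3, sigma_loc_um = 0.02,
                    n_restarts = 5, max_iter = 50, tol = 1e-5,
                    bic_margin = 2, seed = 1L) {
  n_pts <- nrow(trajectory)
  if (n_pts < 3) .stopf("trajectory needs >= 3 points")
  dt <- stats::median(diff(trajectory$t_s))
  delta <- cbind(diff(trajectory$x_um), diff(trajectory$y_um))
  n <- nrow(delta)
  if (n < 20) {
    .warnf("trajectory has %d steps (< 20); single-state fallback", n)
    max_states <- 1
  }
  max_states <- max(1L, min(3L, as.integer(max_states)))

  cands <- list()
  for (K in seq_len(max_states)) {
    for (m in 0:K) {  # m = number of DV states
      kinds <- c(rep("D", K - m), rep("DV", m))
      fit <- if (K == 1) .fit_k1(delta, kinds, dt) else
        .fit_em(delta, kinds, dt, n_restarts, max_iter, tol, seed)
      if (is.null(fit)) next
      p <- sum(ifelse(kinds == "D", 1, 3)) + K * (K - 1) + (K - 1)
      fit$bic <- -2 * fit$loglik + p * log(n)
      fit$p <- p
      fit$K <- K
      fit$kinds <- kinds
      cands[[length(cands) + 1L]] <- fit
    }
  }
  tab <- data.frame(
    K = vapply(cands, function(f) f$K, 1L),
    kinds = vapply(cands, function(f) paste(f$kinds, collapse = "+"), ""),
    loglik = vapply(cands, function(f) f$loglik, 1),
    p = vapply(cands, function(f) f$p, 1),
    bic = vapply(cands, function(f) f$bic, 1),
    stringsAsFactors = FALSE)
  best_bic <- min(tab$bic)
  near <- which(tab$bic <= best_bic + bic_margin)
  near <- near[order(tab$K[near], tab$p[near], tab$bic[near])]
  sel <- cands[[near[1]]]

  # decode with the selected model
  path <- as.integer(hmm_viterbi(delta, sel$mu, sel$s2, sel$pi0, sel$A))
  fb <- hmm_forward_backward(delta, sel$mu, sel$s2, sel$pi0, sel$A)
  K <- sel$K
  occ <- tabulate(path, nbins = K) / length(path)
  D <- pmax((sel$s2 - 2 * sigma_loc_um^2) / (2 * dt), 0)
  Vx <- sel$mu[, 1] / dt
  Vy <- sel$mu[, 2] / dt
  states <- data.frame(kind = sel$kinds, d_um2_s = D, vx_um_s = Vx,
                       vy_um_s = Vy, speed_um_s = sqrt(Vx^2 + Vy^2),
                       occupancy = occ, stringsAsFactors = FALSE)
  structure(list(K = K, states = states, trans = sel$A, init = sel$pi0,
                 path = path, posterior = fb$gamma, loglik = sel$loglik,
                 bic = sel$bic, converged = isTRUE(sel$converged),
                 candidates = tab, dt_s = dt, n_steps = length(path),
                 sigma_loc_um = sigma_loc_um),
            class = "motion_state_model")
}

#' @export
print.motion_state_model <- function(x, ...) {
  cat(sprintf("motion_state_model: K = %d, %d steps, BIC = %.1f\n",
              x$K, x$n_steps, x$bic))
  print(x$states, digits = 3)
  invisible(x)
}

# closed-form single-state fits
.fit_k1 <- function(delta, kinds, dt) {
  n <- nrow(delta)
  mu <- if (kinds[1] == "DV") matrix(colMeans(delta), 1) else
    matrix(0, 1, 2)
  res2 <- (delta[, 1] - mu[1, 1])^2 + (delta[, 2] - mu[1, 2])^2
  s2 <- max(mean(res2) / 2, 1e-12)
  loglik <- -n * log(2 * pi * s2) - sum(res2) / (2 * s2)
  list(mu = mu, s2 = s2, pi0 = 1, A = matrix(1, 1, 1), loglik = loglik,
       converged = TRUE)
}

# Baum-Welch EM over a fixed state-kind layout
.fit_em <- function(delta, kinds, dt, n_restarts, max_iter, tol, seed) {
  n <- nrow(delta)
  K <- length(kinds)
  speeds <- sqrt(delta[, 1]^2 + delta[, 2]^2)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed * 1000L + r)
    assign <- tryCatch({
      km <- kmeans(speeds, centers = K, nstart = 1)
      # order clusters by center so slow clusters seed D states
      rank <- order(order(km$centers))
      rank[km$cluster]
    }, error = function(e) sample.int(K, n, replace = TRUE))
    mu <- matrix(0, K, 2)
    s2 <- numeric(K)
    for (k in seq_len(K)) {
      idx <- which(assign == k)
      if (length(idx) < 2) idx <- sample.int(n, max(2, n %/% K))
      if (kinds[k] == "DV") mu[k, ] <- colMeans(delta[idx, , drop = FALSE])
      res2 <- (delta[idx, 1] - mu[k, 1])^2 + (delta[idx, 2] - mu[k, 2])^2
      s2[k] <- max(mean(res2) / 2, 1e-12)
    }
    if (r > 1) {  # jitter restarts
      s2 <- s2 * runif(K, 0.5, 2)
      mu <- mu * matrix(runif(2 * K, 0.5, 1.5), K)
    }
    A <- matrix(0.1 / max(1, K - 1), K, K)
    diag(A) <- 0
    diag(A) <- 1 - rowSums(A)
    pi0 <- rep(1 / K, K)

    loglik_prev <- -Inf
    converged <- FALSE
    fb <- NULL
    for (it in seq_len(max_iter)) {
      fb <- hmm_forward_backward(delta, mu, s2, pi0, A)
      g <- fb$gamma
      w <- colSums(g)
      for (k in seq_len(K)) {
        if (w[k] < 1e-8) next
        if (kinds[k] == "DV")
          mu[k, ] <- colSums(g[, k] * delta) / w[k]
        res2 <- (delta[, 1] - mu[k, 1])^2 + (delta[, 2] - mu[k, 2])^2
        s2[k] <- max(sum(g[, k] * res2) / (2 * w[k]), 1e-12)
      }
      xs <- rowSums(fb$xi)
      for (j in seq_len(K)) if (xs[j] > 0) A[j, ] <- fb$xi[j, ] / xs[j]
      pi0 <- pmax(g[1, ], 1e-12)
      pi0 <- pi0 / sum(pi0)
      if (abs(fb$loglik - loglik_prev) <
          tol * (abs(fb$loglik) + 1)) { converged <- TRUE; break }
      loglik_prev <- fb$loglik
    }
    fit <- list(mu = mu, s2 = s2, pi0 = pi0, A = A, loglik = fb$loglik,
                converged = converged)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

#' Motion-state switching rates from a decoded path
#'
#' Each state is mapped to the diffusion (`D`) or active-transport (`AT`,
#' any directed state) class and switching probabilities are estimated by
#' transition counting on the decoded state path, with each outgoing row
#' normalised to 1. A rate whose source class is never visited is reported
#' as `NA` (undefined), not zero.
#'
#' @param model A [fit_hmm()] model.
#' @return A list with `rates` (named vector `k_D_D`, `k_D_AT`, `k_AT_D`,
#'   `k_AT_AT`) and the raw transition `counts` matrix.
#' @export
transition_rates <- function(model) {
  stopifnot(inherits(model, "motion_state_model"))
  cls <- ifelse(model$states$kind == "DV", "AT", "D")[model$path]
  counts <- matrix(0, 2, 2, dimnames = list(c("D", "AT"), c("D", "AT")))
  if (length(cls) >= 2) {
    from <- cls[-length(cls)]
    to <- cls[-1]
    for (a in c("D", "AT")) for (b in c("D", "AT"))
      counts[a, b] <- sum(from == a & to == b)
  }
  rates <- c(k_D_D = NA_real_, k_D_AT = NA_real_,
             k_AT_D = NA_real_, k_AT_AT = NA_real_)
  if (sum(counts["D", ]) > 0) {
    rates["k_D_D"] <- counts["D", "D"] / sum(counts["D", ])
    rates["k_D_AT"] <- counts["D", "AT"] / sum(counts["D", ])
  }
  if (sum(counts["AT", ]) > 0) {
    rates["k_AT_D"] <- counts["AT", "D"] / sum(counts["AT", ])
    rates["k_AT_AT"] <- counts["AT", "AT"] / sum(counts["AT", ])
  }
  list(rates = rates, counts = counts)
}

#' Classify a trajectory's motion type
#'
#' A trajectory exhibits active transport if any selected state is a
#' directed (`DV`) state with speed above `v_floor_um_s`; otherwise it is
#' diffusion-only. `multi_state` flags models with two or more states.
#'
#' @param model A [fit_hmm()] model.
#' @param v_floor_um_s Minimum speed for a DV state to count as transport.
#' @return A list with `motion_type` (`"active_transport"` or
#'   `"diffusion_only"`) and `multi_state`.
#' @export
classify_motion_type <- function(model, v_floor_um_s = 0.1) {
  stopifnot(inherits(model, "motion_state_model"))
  at <- any(model$states$kind == "DV" &
            model$states$speed_um_s > v_floor_um_s)
  list(motion_type = if (at) "active_transport" else "diffusion_only",
       multi_state = model$K >= 2)
}

#' One-row motion summary of a fitted model
#'
#' Convenience extractor used by the vesicle filter and the spatial
#' summaries: motion type, the diffusion coefficient of the dominant
#' diffusive state (the `D`-kind state with the largest step occupancy; the
#' quantity gated by the vesicle-identification thresholds), the fraction
#' of decoded steps spent in transport states, and the mean decoded-state
#' posterior probability.
#'
#' @param model A [fit_hmm()] model.
#' @param v_floor_um_s Passed to [classify_motion_type()].
#' @return A one-row data.frame.
#' @export
summarize_motion <- function(model, v_floor_um_s = 0.1) {
  cl <- classify_motion_type(model, v_floor_um_s)
  is_d <- model$states$kind == "D"
  d_diff <- if (any(is_d)) {
    k <- which(is_d)[which.max(model$states$occupancy[is_d])]
    model$states$d_um2_s[k]
  } else NA_real_
  at_steps <- mean(model$states$kind[model$path] == "DV")
  data.frame(motion_type = cl$motion_type, multi_state = cl$multi_state,
             n_states = model$K, d_diffusive_um2_s = d_diff,
             at_step_fraction = at_steps,
             mean_posterior = mean(apply(model$posterior, 1, max)),
             stringsAsFactors = FALSE)
}

#' Re-segment an ambiguous trajectory and refit each segment
#'
#' When the decoded state path of a model is ambiguous (mean posterior
#' probability of the decoded states below `posterior_threshold`), the
#' trajectory is split at the decoded change-points, segments shorter than
#' `min_segment` steps are merged into their neighbours, each segment is
#' refitted independently, and the per-segment models are concatenated into
#' a combined model. If the combined decoding does not improve the mean
#' decoded-path posterior, the original model is returned unchanged.
#'
#' @param trajectory The trajectory the model was fitted to.
#' @param model A [fit_hmm()] model.
#' @param posterior_threshold Ambiguity threshold on the mean decoded-state
#'   posterior.
#' @param min_segment Minimum segment length in steps.
#' @param ... Passed to [fit_hmm()] for the per-segment refits.
#' @return A `motion_state_model` (possibly the input, unchanged).
#' @export
segment_and_refit <- function(trajectory, model, posterior_threshold = 0.7,
                              min_segment = 10, ...) {
  stopifnot(inherits(model, "motion_state_model"))
  mp <- mean(apply(model$posterior, 1, max))
  if (mp >= posterior_threshold) return(model)

  runs <- rle(model$path)
  while (length(runs$lengths) > 1 && any(runs$lengths < min_segment)) {
    i <- which.min(runs$lengths)
    j <- if (i == 1) 2L else i - 1L  # merge into the (preceding) neighbour
    runs$lengths[j] <- runs$lengths[j] + runs$lengths[i]
    runs$lengths <- runs$lengths[-i]
    runs$values <- runs$values[-i]
    # collapse newly adjacent equal values
    runs <- rle(inverse.rle(runs))
  }
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1) + 1L)

  seg_models <- list()
  path <- integer(0)
  post_rows <- list()
  states <- NULL
  offset <- 0L
  loglik <- 0
  for (g in seq_along(starts)) {
    idx_pts <- starts[g]:(ends[g] + 1L)  # step range -> point range
    seg <- trajectory[idx_pts, , drop = FALSE]
    m <- suppressWarnings(fit_hmm(seg, sigma_loc_um = model$sigma_loc_um,
                                  ...))
    seg_models[[g]] <- m
    path <- c(path, m$path + offset)
    post_rows[[g]] <- m$posterior
    states <- rbind(states, m$states)
    offset <- offset + m$K
    loglik <- loglik + m$loglik
  }
  Ktot <- offset
  n_steps <- length(path)
  posterior <- matrix(0, n_steps, Ktot)
  row0 <- 0L; col0 <- 0L
  for (g in seq_along(post_rows)) {
    pr <- post_rows[[g]]
    posterior[row0 + seq_len(nrow(pr)), col0 + seq_len(ncol(pr))] <- pr
    row0 <- row0 + nrow(pr); col0 <- col0 + ncol(pr)
  }
  mp_new <- mean(posterior[cbind(seq_len(n_steps), path)])
  if (mp_new <= mp) return(model)

  trans <- matrix(0, Ktot, Ktot)
  if (n_steps >= 2) {
    for (i in seq_len(n_steps - 1))
      trans[path[i], path[i + 1]] <- trans[path[i], path[i + 1]] + 1
    rs <- rowSums(trans)
    for (j in which(rs > 0)) trans[j, ] <- trans[j, ] / rs[j]
    for (j in which(rs == 0)) trans[j, j] <- 1
  }
  states$occupancy <- tabulate(path, nbins = Ktot) / n_steps
  structure(list(K = Ktot, states = states, trans = trans,
                 init = as.numeric(seq_len(Ktot) == path[1]),
                 path = path, posterior = posterior, loglik = loglik,
                 bic = NA_real_, converged = all(vapply(
                   seg_models, function(m) m$converged, TRUE)),
                 candidates = NULL, dt_s = model$dt_s, n_steps = n_steps,
                 sigma_loc_um = model$sigma_loc_um, segmented = TRUE),
            class = "motion_state_model")
}
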