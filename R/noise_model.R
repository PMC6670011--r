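#' Per-amplicon robust noise model on logit allele frequencies
#'
#' The core of the caller. Every non-reference allele observed in any
#' sample is one observation; its logit allele frequency is modelled per
#' amplicon as
#'
#' \deqn{\log\frac{a}{1-a} = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \epsilon}
#'
#' where \eqn{X_1} is the position on the amplicon (PCR error drifts
#' along the amplicon but is on average position-stationary) and
#' \eqn{X_2} the sequenced sample, encoded as a reference-coded factor
#' (sequencing error at a given position is equally likely in each
#' sample, up to a sample-level offset). Because the vast majority of
#' observations are PCR or sequencing errors, a robust M-estimated fit
#' of this plane is a noise model: true mutations survive as large
#' positive residuals. An observation is called a mutation when its
#' residual exceeds the median residual by at least `sd_threshold`
#' standard deviations and its allele frequency is at least `min_af`.
#'
#' @name noise_model
NULL

#' Logit-transform an allele frequency
#'
#' `a = count/depth` is clamped to at most `(depth - 0.5)/depth` so that
#' the transform stays finite for homozygous columns (`count == depth`).
#' Zero counts are rejected: reference-only positions are not variant
#' observations.
#'
#' @param count variant-supporting read count (>= 1).
#' @param depth total qualifying reads (> 0).
#' @return `log(a / (1 - a))`.
#' @export
logit_af <- function(count, depth) {
  if (any(depth <= 0)) stop("depth must be positive", call. = FALSE)
  if (any(count < 1)) stop("variant observations require count >= 1",
                           call. = FALSE)
  if (any(count > depth)) stop("count exceeds depth", call. = FALSE)
  a <- pmin(count / depth, (depth - 0.5) / depth)
  log(a / (1 - a))
}

# Robust losses: IRLS weight w(u) = psi(u)/u, influence psi and its
# derivative (needed for the M-estimator covariance).
huber_loss <- function(k = 1.345) {
  list(w = function(u) pmin(1, k / pmax(abs(u), 1e-300)),
       psi = function(u) pmax(pmin(u, k), -k),
       dpsi = function(u) as.numeric(abs(u) <= k))
}

bisquare_loss <- function(c = 4.685) {
  list(w = function(u) ifelse(abs(u) < c, (1 - (u / c)^2)^2, 0),
       psi = function(u) ifelse(abs(u) < c, u * (1 - (u / c)^2)^2, 0),
       dpsi = function(u) ifelse(abs(u) < c,
                                 (1 - (u / c)^2) * (1 - 5 * (u / c)^2), 0))
}

# Iteratively reweighted least squares M-estimation. The scale is
# re-estimated each iteration as the MAD of the residuals / 0.6745;
# convergence when the largest absolute coefficient change drops below
# `tol`.
irls_mfit <- function(X, y, loss, max_iter = 50L, tol = 1e-8) {
  qrX <- qr(X)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xr <- X[, keep, drop = FALSE]
  beta <- qr.coef(qr(Xr), y)
  converged <- FALSE
  iter <- 0L
  w <- rep(1, length(y))
  s <- 1
  repeat {
    iter <- iter + 1L
    r <- y - drop(Xr %*% beta)
    s <- max(stats::mad(r, constant = 1 / 0.6745), 1e-8)
    w <- loss$w(r / s)
    sw <- sqrt(w)
    fit <- qr.coef(qr(Xr * sw), y * sw)
    delta <- max(abs(fit - beta))
    beta <- fit
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  r <- unname(y - drop(Xr %*% beta))
  # M-estimator covariance (Huber's proposal, as used by classical
  # robust-regression implementations): the naive weighted-LS formula
  # underestimates the sampling variance
  n <- length(y)
  p <- ncol(Xr)
  u <- r / s
  psi <- loss$psi(u)
  dpsi <- loss$dpsi(u)
  m1 <- mean(dpsi)
  K <- 1 + p / n * stats::var(dpsi) / max(m1^2, 1e-12)
  stddev2 <- K^2 * s^2 * sum(psi^2) / max(n - p, 1L) / max(m1^2, 1e-12)
  se_r <- sqrt(pmax(diag(solve(crossprod(Xr))) * stddev2, 0))
  full_beta <- setNames(rep(0, ncol(X)), colnames(X))
  full_se <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  full_beta[keep] <- beta
  full_se[keep] <- se_r
  list(coefficients = full_beta, se = full_se, residuals = r,
       weights = w, converged = converged, n_iter = iter,
       rank = qrX$rank)
}

noise_design <- function(obs) {
  samples <- sort(unique(obs$sample_id))
  X <- cbind(`(Intercept)` = 1, offset = as.numeric(obs$offset))
  if (length(samples) > 1L) {
    f <- factor(obs$sample_id, levels = samples)
    D <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
    colnames(D) <- paste0("sample:", samples[-1L])
    X <- cbind(X, D)
  }
  list(X = X, samples = samples)
}

unfittable_fit <- function(amplicon, obs, reason) {
  structure(list(amplicon = amplicon, beta0 = NA_real_, beta1 = NA_real_,
                 beta_sample = numeric(0), se = NULL,
                 residuals = rep(NA_real_, nrow(obs)),
                 residual_median = NA_real_, residual_sd = NA_real_,
                 n_obs = nrow(obs), n_samples = length(unique(obs$sample_id)),
                 converged = FALSE, n_iter = 0L, unfittable = TRUE,
                 reason = reason, obs = obs),
            class = "noise_fit")
}

#' Fit the noise model for one amplicon
#'
#' @param obs variant observations of a single amplicon across all
#'   samples, as produced by [compute_af()].
#' @param loss robust loss: Huber (tuning constant 1.345, the default)
#'   or Tukey bisquare (4.685).
#' @param robust_sd if `TRUE`, the residual spread used by
#'   [call_mutations()] is the MAD-based scale instead of the sample
#'   standard deviation.
#' @param max_iter,tol IRLS iteration cap and coefficient-change
#'   convergence tolerance.
#' @return a `noise_fit` object: coefficients (`beta0`, `beta1`, one
#'   offset per non-reference sample in `beta_sample`), standard
#'   errors, per-observation residuals with their median and spread,
#'   and convergence diagnostics. Underdetermined designs (fewer
#'   observations than free parameters) come back flagged
#'   `unfittable`; their observations are later rejected with reason
#'   `"insufficient-data"`.
#' @export
fit_noise_model <- function(obs, loss = c("huber", "bisquare"),
                            robust_sd = FALSE, max_iter = 50L, tol = 1e-8) {
  loss <- match.arg(loss)
  obs <- as.data.frame(obs)
  amplicon <- if (nrow(obs)) obs$amplicon[1L] else NA_character_
  if (nrow(obs) && length(unique(obs$amplicon)) != 1L)
    stop("fit_noise_model() expects observations of a single amplicon",
         call. = FALSE)
  des <- noise_design(obs)
  if (nrow(obs) < ncol(des$X))
    return(unfittable_fit(amplicon, obs, "insufficient data"))
  y <- logit_af(obs$count, obs$depth)
  lo <- if (loss == "huber") huber_loss() else bisquare_loss()
  fit <- irls_mfit(des$X, y, lo, max_iter = max_iter, tol = tol)
  r <- fit$residuals
  res_sd <- if (robust_sd) stats::mad(r, constant = 1 / 0.6745) else
    stats::sd(r)
  if (!is.finite(res_sd) || res_sd < 1e-8) res_sd <- 1e-8
  beta <- fit$coefficients
  sample_idx <- grep("^sample:", names(beta))
  structure(list(amplicon = amplicon,
                 beta0 = unname(beta["(Intercept)"]),
                 beta1 = unname(beta["offset"]),
                 beta_sample = setNames(unname(beta[sample_idx]),
                                        sub("^sample:", "",
                                            names(beta)[sample_idx])),
                 se = fit$se,
                 residuals = r,
                 residual_median = median(r),
                 residual_sd = res_sd,
                 n_obs = nrow(obs),
                 n_samples = length(des$samples),
                 converged = fit$converged,
                 n_iter = fit$n_iter,
                 unfittable = FALSE,
                 reason = NA_character_,
                 obs = obs),
            class = "noise_fit")
}

#' @export
print.noise_fit <- function(x, ...) {
  if (x$unfittable) {
    cat(sprintf("noise_fit [%s]: unfittable (%s), %d observation(s)\n",
                x$amplicon, x$reason, x$n_obs))
    return(invisible(x))
  }
  cat(sprintf(
    "noise_fit [%s]: %d obs, %d sample(s); beta0 = %.3f, beta1 = %.4g\n",
    x$amplicon, x$n_obs, x$n_samples, x$beta0, x$beta1))
  cat(sprintf(
    "  residuals: median %.3f, sd %.3f; %sconverged in %d iteration(s)\n",
    x$residual_median, x$residual_sd,
    if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

#' Fit the noise model for every amplicon in an observation table
#'
#' @param obs variant observations across amplicons ([compute_af()]).
#' @param ... passed to [fit_noise_model()].
#' @return named list of `noise_fit` objects, one per amplicon present.
#' @export
fit_noise_models <- function(obs, ...) {
  obs <- as.data.frame(obs)
  amps <- unique(obs$amplicon)
  fits <- lapply(amps, function(a)
    fit_noise_model(obs[obs$amplicon == a, , drop = FALSE], ...))
  setNames(fits, amps)
}

#' Summarise fitted noise models as a diagnostics table
#' @param fits list of `noise_fit` objects ([fit_noise_models()]).
#' @return data frame with one row per amplicon (coefficients, residual
#'   summary, convergence).
#' @export
noise_fit_diagnostics <- function(fits) {
  if (inherits(fits, "noise_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f)
    data.frame(amplicon = f$amplicon, n_obs = f$n_obs,
               n_samples = f$n_samples, beta0 = f$beta0, beta1 = f$beta1,
               residual_median = f$residual_median,
               residual_sd = f$residual_sd, converged = f$converged,
               n_iter = f$n_iter, unfittable = f$unfittable,
               stringsAsFactors = FALSE)))
}

#' Call mutations from fitted noise models
#'
#' For every observation the residual excess
#' `z = (residual - median(residuals)) / sd(residuals)` is computed; by
#' default the median and SD come from the residuals of *all* amplicons
#' pooled (the noise assumptions -- position-stationary PCR error,
#' sample-homogeneous sequencing error -- are panel-wide, and pooling
#' stabilises the scale for amplicons with few observations), while
#' `pool_residuals = FALSE` uses each amplicon's own residual vector.
#' An observation is `called` when `z >= sd_threshold` and its allele
#' frequency is at least `min_af`; everything else is rejected with a
#' machine-readable reason (`within-noise`, `below-min-af`, or
#' `insufficient-data` for unfittable amplicons).
#'
#' @param fits a `noise_fit` or list of them.
#' @param sd_threshold residual-excess threshold in residual SDs.
#' @param min_af minimum allele frequency for a clinically reportable
#'   mutation.
#' @param pool_residuals compute the residual median/SD over all
#'   amplicons pooled (default) rather than per amplicon.
#' @return data frame of all observations with `residual`, `z_excess`,
#'   `status` (`called`/`rejected`) and `reason`.
#' @export
call_mutations <- function(fits, sd_threshold = 3, min_af = 0.005,
                           pool_residuals = TRUE) {
  if (inherits(fits, "noise_fit")) fits <- list(fits)
  if (pool_residuals) {
    pooled <- unlist(lapply(fits, function(f)
      if (f$unfittable) numeric(0) else f$residuals))
    if (length(pooled) == 0L) {
      pool_med <- NA_real_
      pool_sd <- NA_real_
    } else {
      pool_med <- median(pooled)
      pool_sd <- max(stats::sd(pooled), 1e-8)
      if (!is.finite(pool_sd)) pool_sd <- 1e-8
    }
  }
  rows <- lapply(fits, function(f) {
    out <- f$obs
    if (nrow(out) == 0L) return(NULL)
    out$residual <- f$residuals
    if (f$unfittable) {
      out$z_excess <- NA_real_
      out$status <- "rejected"
      out$reason <- "insufficient-data"
      return(out)
    }
    med <- if (pool_residuals) pool_med else f$residual_median
    s <- if (pool_residuals) pool_sd else f$residual_sd
    out$z_excess <- (out$residual - med) / s
    pass_z <- out$z_excess >= sd_threshold
    pass_af <- out$af >= min_af
    out$status <- ifelse(pass_z & pass_af, "called", "rejected")
    out$reason <- ifelse(pass_z & pass_af, NA_character_,
                         ifelse(!pass_z, "within-noise", "below-min-af"))
    out
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  calls
}
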