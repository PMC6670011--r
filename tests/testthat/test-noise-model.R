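test_that("logit transform is exact, clamps a = 1, and rejects zero counts", {
  expect_equal(logit_af(500, 1000), 0)
  expect_equal(logit_af(225, 10000), -3.771483, tolerance = 1e-6)
  expect_equal(logit_af(1000, 1000), log(999.5 / 0.5))
  expect_error(logit_af(0, 1000), "count >= 1")
  expect_error(logit_af(5, 0), "depth")
  expect_error(logit_af(11, 10), "exceeds")
})

test_that("a noise-free logit plane is recovered exactly with zero residuals", {
  obs <- plane_obs()   # odds 1/100, 1/10, 1 at offsets 10, 20, 30
  fit <- fit_noise_model(obs)
  expect_true(fit$converged)
  expect_equal(fit$beta1, log(10) / 10, tolerance = 1e-8)
  expect_equal(fit$beta0, -3 * log(10), tolerance = 1e-7)
  expect_equal(fit$residuals, rep(0, 3), tolerance = 1e-9)

  # second sample with all odds doubled: exact sample effect log(2)
  s2 <- obs_from_counts(c(2L, 1L, 100L), c(102L, 6L, 150L),
                        c(10L, 20L, 30L), sample_id = "s2")
  fit2 <- fit_noise_model(rbind(obs, s2))
  expect_equal(fit2$beta1, log(10) / 10, tolerance = 1e-8)
  expect_equal(unname(fit2$beta_sample["s2"]), log(2), tolerance = 1e-8)
  expect_equal(fit2$residuals, rep(0, 6), tolerance = 1e-9)
})

test_that("Huber IRLS equals OLS on outlier-free data and tracks MASS::rlm with outliers", {
  skip_if_not_installed("MASS")
  # "outlier-free" operationally: every OLS residual inside the Huber
  # linear zone (|r| < 1.345 * scale), where the M-estimate and OLS
  # coincide; bounded sign noise makes such instances common
  set.seed(21)
  found <- 0L
  while (found < 5L) {
    n <- sample(12:30, 1)
    offs <- sample(5:150, n, replace = TRUE)
    sid <- sample(c("s1", "s2", "s3"), n, replace = TRUE)
    eta <- -6.5 + 0.004 * offs + c(s1 = 0, s2 = 0.1, s3 = -0.1)[sid] +
      sample(c(-0.1, 0.1), n, replace = TRUE)
    obs <- obs_from_eta(eta, offs, sample_id = sid)
    y <- logit_af(obs$count, obs$depth)
    ols <- lm(y ~ offs + factor(sid))
    r <- residuals(ols)
    if (max(abs(r)) >= 1.345 * mad(r, constant = 1 / 0.6745)) next
    found <- found + 1L
    fit <- fit_noise_model(obs)
    expect_equal(fit$beta0, unname(coef(ols)[1]), tolerance = 1e-6)
    expect_equal(fit$beta1, unname(coef(ols)[2]), tolerance = 1e-6)
  }
  # with a gross outlier the hand-rolled IRLS matches the reference
  # Huber M-estimator, and both resist the outlier
  set.seed(22)
  offs <- rep(seq(10, 140, by = 10), each = 2)
  eta <- -6.5 + 0.004 * offs + rnorm(length(offs), 0, 0.1)
  eta[5] <- eta[5] + 4   # a true mutation among the noise
  obs <- obs_from_eta(eta, offs)
  fit <- fit_noise_model(obs)
  y <- logit_af(obs$count, obs$depth)
  # scale estimators differ slightly (centred vs uncentred MAD), so the
  # two Huber fits agree closely but not to machine precision
  rr <- MASS::rlm(y ~ offs, k = 1.345, maxit = 100, acc = 1e-10)
  expect_equal(fit$beta0, unname(coef(rr)[1]), tolerance = 0.02)
  expect_equal(fit$beta1, unname(coef(rr)[2]), tolerance = 0.02)
  ols <- lm(y ~ offs)
  expect_lt(abs(fit$beta1 - 0.004), abs(coef(ols)[2] - 0.004) + 1e-6)
})

test_that("generating parameters are recovered from simulated logit noise", {
  # 150 positions x 10 samples on a known plane
  set.seed(23)
  offs <- rep(1:150, times = 10)
  sid <- rep(sprintf("s%02d", 1:10), each = 150)
  s_eff <- setNames(c(0, rnorm(9, 0, 0.2)), sprintf("s%02d", 1:10))
  eta <- -6.9 + 0.005 * offs + s_eff[sid] + rnorm(1500, 0, 0.3)
  fit <- fit_noise_model(obs_from_eta(eta, offs, sample_id = sid))
  se1 <- fit$se[["offset"]]
  expect_lt(abs(fit$beta1 - 0.005), 4 * se1)
  expect_lt(abs(fit$beta0 - (-6.9)), 0.2)
  est <- fit$beta_sample[sprintf("s%02d", 2:10)]
  expect_lt(max(abs(est - s_eff[2:10])), 0.1)
})

test_that("relabeling samples changes neither residuals nor calls", {
  set.seed(24)
  offs <- rep(seq(5, 145, by = 5), times = 4)
  sid <- rep(c("alpha", "beta", "gamma", "delta"), each = 29)
  eta <- -6.6 + 0.004 * offs + rnorm(length(offs), 0, 0.3)
  eta[10] <- eta[10] + 3
  obs <- obs_from_eta(eta, offs, sample_id = sid)
  fit <- fit_noise_model(obs)
  relab <- obs
  relab$sample_id <- c(alpha = "z4", beta = "z3", gamma = "z2",
                       delta = "z1")[obs$sample_id]
  fit2 <- fit_noise_model(relab)
  expect_equal(fit2$residuals, fit$residuals, tolerance = 1e-7)
  c1 <- call_mutations(fit)
  c2 <- call_mutations(fit2)
  expect_identical(c1$status, c2$status)
  expect_identical(which(c1$status == "called"),
                   which(c2$status == "called"))
})

test_that("degenerate designs are handled: single sample fits, underdetermined flags", {
  obs <- plane_obs()
  fit <- fit_noise_model(obs)        # single sample: intercept + slope
  expect_true(fit$converged)
  expect_length(fit$beta_sample, 0)

  two <- obs_from_counts(c(5L, 7L), c(1000L, 1000L), c(10L, 20L),
                         sample_id = c("s1", "s2"))
  fit <- fit_noise_model(two)        # 2 obs, 3 parameters
  expect_true(fit$unfittable)
  calls <- call_mutations(fit)
  expect_true(all(calls$status == "rejected"))
  expect_true(all(calls$reason == "insufficient-data"))

  # zero residual variance hits the SD floor without blowing up
  flat <- obs_from_counts(rep(10L, 8), rep(10000L, 8), rep(50L, 8))
  fit <- fit_noise_model(flat)
  expect_equal(fit$residual_sd, 1e-8)
})

test_that("calling applies the residual and allele-frequency rules with reasons", {
  # decision rule exercised against a fit with known residual summary:
  # median 0, SD 0.3; the fitting machinery is covered elsewhere
  afs <- c(0.02, 0.004, 0.05, 0.008)
  resid <- c(4 * 0.3, 4 * 0.3, 2 * 0.3, 3 * 0.3)   # +4, +4, +2, +3 SD
  obs <- obs_from_counts(round(afs * 1e5), rep(1e5, 4), c(30L, 60L, 90L,
                                                          120L))
  obs$af <- afs
  fit <- structure(list(
    amplicon = "A", beta0 = -6.9, beta1 = 0, beta_sample = numeric(0),
    se = NULL, residuals = resid, residual_median = 0, residual_sd = 0.3,
    n_obs = 4L, n_samples = 1L, converged = TRUE, n_iter = 1L,
    unfittable = FALSE, reason = NA_character_, obs = obs),
    class = "noise_fit")
  calls <- call_mutations(fit, pool_residuals = FALSE)
  expect_identical(calls$status, c("called", "rejected", "rejected",
                                   "called"))
  expect_identical(calls$reason, c(NA, "below-min-af", "within-noise", NA))
  expect_equal(calls$z_excess, c(4, 4, 2, 3))
})

test_that("the call threshold is monotone in sd_threshold", {
  set.seed(26)
  offs <- rep(seq(5, 145, by = 10), times = 3)
  sid <- rep(c("s1", "s2", "s3"), each = 15)
  eta <- -6.7 + 0.004 * offs + rnorm(length(offs), 0, 0.3)
  obs <- obs_from_eta(eta, offs, sample_id = sid, depth = 2e5)
  fit <- fit_noise_model(obs)
  none <- call_mutations(fit, sd_threshold = Inf)
  expect_false(any(none$status == "called"))
  all_above <- call_mutations(fit, sd_threshold = 0, min_af = 0)
  expect_identical(all_above$status == "called",
                   all_above$residual >= fit$residual_median)
  n_called <- vapply(c(0, 1, 2, 3, Inf), function(th)
    sum(call_mutations(fit, sd_threshold = th, min_af = 0)$status ==
          "called"), numeric(1))
  expect_true(all(diff(n_called) <= 0))
})

test_that("an injected 2% variant is recovered against a structured noise plane", {
  sp <- synthetic_panel(n_amplicons = 3L, seed = 31)
  site <- catalogue_sites(sp)[1, ]
  hits <- 0L
  n_seeds <- 25L
  for (s in seq_len(n_seeds)) {
    counts <- simulate_pileup_counts(
      sp$panel, sprintf("s%02d", 1:10),
      variants = data.frame(amplicon = site$amplicon,
                            offset = site$offset, alt = site$alt_amp,
                            maf = 0.02, sample_id = "s01"),
      depth = 7500, seed = 400 + s)
    obs <- compute_af(counts, panel = sp$panel)
    calls <- call_mutations(fit_noise_models(obs))
    hit <- calls$status == "called" & calls$sample_id == "s01" &
      calls$chrom == site$chrom & calls$pos == site$pos &
      calls$alt == site$alt
    hits <- hits + any(hit)
  }
  expect_gte(hits / n_seeds, 0.99)
})
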