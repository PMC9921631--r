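test_that("pseudo log-likelihood: analytic anchor points", {
  # one frame, unit variance, y on the mean: both terms vanish
  p1 <- htmm_params(1, frozen_bright_chain(), emission_model(1, 0, 1))
  expect_equal(as.numeric(pseudo_log_likelihood(1, p1, 1)), 0,
               tolerance = 1e-6)
  # two independent unit-variance frames, residual (1, 0): quadratic only
  expect_equal(as.numeric(pseudo_log_likelihood(c(2, 1), p1, 1:2)), -0.5,
               tolerance = 1e-6)
})

test_that("pseudo log-likelihood matches explicit inverse/determinant", {
  set.seed(101)
  for (nn in c(5, 17, 41)) {
    pa <- alexa_params(sample(2:8, 1))
    fr <- sort(sample(1:800, nn))
    mu <- mean_trace(pa, fr)
    S <- covariance_matrix(pa, fr)
    S <- S + 1e-8 * mean(diag(S)) * diag(nn)  # stabilization contract
    y <- mu + stats::rnorm(nn, sd = sqrt(diag(S)))
    brute <- -0.5 * (t(y - mu) %*% solve(S) %*% (y - mu) +
                       determinant(S, logarithm = TRUE)$modulus)
    expect_equal(as.numeric(pseudo_log_likelihood(y, pa, fr)),
                 as.numeric(brute), tolerance = 1e-10)
  }
})

test_that("likelihood is maximized at the generating parameters in expectation", {
  pa <- alexa_params(5)
  sch <- build_subsample_schedule(1500, 120)
  idx <- sch$indices
  pa_lo <- htmm_params(4, alexa647_chain(), alexa_emission())
  pa_hi <- htmm_params(6, alexa647_chain(), alexa_emission())
  ns <- 30 * sqrt(5)
  ll <- matrix(0, 50, 3)
  for (i in 1:50) {
    y <- simulate_traces(pa, 1500, 1, read_noise_sd = ns, seed = 3000 + i,
                         format = "matrix")[1, idx]
    ll[i, ] <- c(pseudo_log_likelihood(y, pa_lo, idx, noise_sd = ns),
                 pseudo_log_likelihood(y, pa, idx, noise_sd = ns),
                 pseudo_log_likelihood(y, pa_hi, idx, noise_sd = ns))
  }
  means <- colMeans(ll)
  expect_gt(means[2], means[1])
  expect_gt(means[2], means[3])
})

test_that("count from amplitudes is the normalized first-frame sum", {
  sf <- structure(list(eigenvalues = c(0.9, 0.999, 0.99999),
                       coefficients_bright = c(0.6, 0.3, 0.1),
                       coefficients_dark = rep(NA_real_, 3),
                       amplitudes = c(600, 300, 100),
                       initial_bright_fraction = 1),
                  class = "spectral_form")
  expect_equal(count_from_amplitudes(sf, 100), 10)
  sf$amplitudes <- c(100, 0, 0)
  expect_equal(count_from_amplitudes(sf, 100), 1)
  expect_error(count_from_amplitudes(sf, -5), "positive")
  # exact equality with m whenever the bright coefficients sum to 1
  pa <- alexa_params(7)
  expect_equal(count_from_amplitudes(spectral_decomposition(pa), 1000), 7,
               tolerance = 1e-9)
})

test_that("fitting a model-true sample path is self-consistent", {
  # a full stochastic trace (occupancy fluctuations included), init at truth
  pa <- alexa_params(6)
  ns <- 30 * sqrt(6)
  y <- simulate_traces(pa, 2000, 1, read_noise_sd = ns, seed = 1001,
                       format = "matrix")[1, ]
  sch <- build_subsample_schedule(2000, 400)
  fit <- fit_htmm(y, sch, init = pa,
                  options = htmm_fit_options(n_starts = 1, maxit = 250),
                  noise_sd = ns)
  # the optimum cannot be worse than the start, and stays in the
  # neighborhood of the generating parameters at this information level
  ll_truth <- as.numeric(pseudo_log_likelihood(y[sch$indices], pa,
                                               sch$indices, noise_sd = ns))
  expect_gte(fit$logLik, ll_truth)
  expect_lt(abs(fit$m_hat - 6), 3)
  expect_lt(abs(fit$params$emission$mean_bright_signal - 1000), 350)
  # the amplitude-sum count reproduces the fitted m exactly
  expect_equal(fit$m_from_amplitudes, fit$m_hat, tolerance = 1e-6)
  g <- glance(fit)
  expect_identical(nrow(g), 1L)
  td <- tidy(fit)
  expect_true(all(c("m", "E_Y", "sigma_e2") %in% td$term))
})

test_that("blink frames follow the threshold / first-frame / early-frame rules", {
  cal <- list(mu = 0, s = 1)
  y <- rep(0, 2600)
  expect_length(detect_blink_frames(y, cal)$frames, 0L)
  y[2001:2003] <- 10
  bf <- detect_blink_frames(y, cal)
  expect_identical(bf$frames, c(2002L, 2003L))
  y2 <- rep(0, 2600)
  y2[1500:1502] <- 10
  y2[2500:2501] <- 10
  bf2 <- detect_blink_frames(y2, cal)
  expect_identical(bf2$frames, 2501L)
  expect_identical(nrow(bf2$events), 2L)
})

test_that("blink brightness and the simplified count", {
  cal <- list(mu = 0, s = 1)
  y <- rep(0, 2300)
  y[2100:2102] <- c(10, 400, 600)
  bf <- detect_blink_frames(y, cal)
  expect_equal(mean_blink_brightness(y, bf), 500)
  y1 <- rep(0, 2300); y1[2100:2101] <- c(5, 512)
  expect_equal(mean_blink_brightness(y1, detect_blink_frames(y1, cal)), 512)
  expect_error(mean_blink_brightness(rep(0, 10),
                                     detect_blink_frames(rep(0, 10), cal)),
               "no usable blink")
  expect_equal(simplified_count(5000, 500), 10)
  expect_equal(simplified_count(0, 500), 0)
  expect_error(simplified_count(100, 0), "positive")
})

test_that("simplified estimator is centered on the truth for simulated traces", {
  m <- 4
  pa <- alexa_params(m)
  ns <- 30 * sqrt(m)
  est <- vapply(1:200, function(i) {
    y <- simulate_traces(pa, 3000, 1, read_noise_sd = ns, seed = 5000 + i,
                         format = "matrix")[1, ]
    out <- tryCatch(simplified_estimate(y, list(mu = 0, s = ns),
                                        min_frame = 2000)$m_hat,
                    error = function(e) NA_real_)
    out
  }, numeric(1))
  est <- est[!is.na(est)]
  expect_gt(length(est), 150)
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - m), 4 * se)
  # blink brightness itself is unbiased for E(Y)
  yb <- vapply(1:150, function(i) {
    y <- simulate_traces(alexa_params(1), 3000, 1, read_noise_sd = 30,
                         seed = 8000 + i, format = "matrix")[1, ]
    tryCatch(mean_blink_brightness(y, detect_blink_frames(
      y, list(mu = 0, s = 30), min_frame = 1000)), error = function(e) NA)
  }, numeric(1))
  yb <- yb[!is.na(yb)]
  expect_lt(abs(mean(yb) - 1000), 4 * stats::sd(yb) / sqrt(length(yb)))
})

test_that("averaging independent estimates reduces the recovery error", {
  res <- cached("crit5_m6", recovery_study(6, 45, seed = 1))
  single_rmse <- sqrt(mean((res$m_hat - 6)^2))
  groups <- split(res$m_hat, rep(1:9, each = 5))
  pooled <- vapply(groups, mean, numeric(1))
  pooled_rmse <- sqrt(mean((pooled - 6)^2))
  expect_lt(pooled_rmse, single_rmse)
})
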