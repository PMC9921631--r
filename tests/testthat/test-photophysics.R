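test_that("per-trace excess variance follows its defining formula", {
  # deterministic blink values c give exactly -1/c
  y <- rep(0, 400)
  y[101:110] <- 250  # one event; first frame dropped, rest identical
  ev <- estimate_excess_variance(matrix(y, 1), list(mu = 0, s = 1),
                                 min_frame = 0) |>
    suppressWarnings()
  expect_equal(ev$per_trace$sigma_e2[1], -1 / 250, tolerance = 1e-12)
  # exact transformation law under detector-unit rescaling
  set.seed(3)
  y2 <- rep(0, 600)
  y2[sample(50:600, 80)] <- stats::rnorm(80, 300, 40)
  per_sig <- function(yy) {
    suppressWarnings(estimate_excess_variance(
      matrix(yy, 1), list(mu = 0, s = 1), min_frame = 0)$per_trace$sigma_e2[1])
  }
  s_1 <- per_sig(y2)
  s_c <- per_sig(3 * y2)
  bf <- detect_blink_frames(y2, list(mu = 0, s = 1), min_frame = 0)
  E1 <- mean(y2[bf$frames])
  expect_equal(s_c, s_1 + 1 / E1 - 1 / (3 * E1), tolerance = 1e-10)
})

test_that("ensemble excess variance recovers the generator's value", {
  n_tr <- 120
  ts <- cached("sig_e_traces",
               simulate_traces(alexa_params(1), 3000, n_tr,
                               read_noise_sd = 30, seed = 71,
                               format = "matrix"))
  ev <- estimate_excess_variance(ts, list(mu = 0, s = 30))
  expect_lt(abs(ev$center - 0.097), 4 * ev$width / sqrt(ev$n_used))
  # Poissonian emitters have zero excess variance
  pp <- htmm_params(1, single_dark_chain(0.05, 0.001, 0.02),
                    emission_model(500, 0, 1))
  tsp <- simulate_traces(pp, 3000, 120, read_noise_sd = 3, seed = 72,
                         format = "matrix")
  evp <- estimate_excess_variance(tsp, list(mu = 0, s = 3))
  # read noise inflates per-trace values by its own relative variance
  allowance <- 3^2 / 500^2
  expect_lt(abs(evp$center), 4 * evp$width / sqrt(evp$n_used) + allowance)
})

test_that("multi-exponential fits are exact on noiseless model curves", {
  t <- 1:300
  f1 <- fit_multiexponential(100 * 0.95^(t - 1), n_components = 1)
  expect_equal(f1$amplitudes, 100, tolerance = 1e-8)
  expect_equal(f1$eigenvalues, 0.95, tolerance = 1e-8)
  # three components at the canonical starting magnitudes
  al <- c(20000, 100, 10); la <- c(0.9, 0.999, 0.99999)
  tt <- unique(round(seq(1, 20000, length.out = 800)))
  y3 <- vapply(tt, function(ti) sum(al * la^(ti - 1)), numeric(1))
  f3 <- fit_multiexponential(tibble::tibble(frame = tt, value = y3),
                             n_components = 3)
  expect_equal(sort(f3$amplitudes), sort(al), tolerance = 1e-6)
  expect_equal(sort(f3$eigenvalues), sort(la), tolerance = 1e-6)
  expect_error(fit_multiexponential(y3[1:6], n_components = 3),
               "too short")
})

test_that("averaged-trace fit plus amplitude sum counts the ensemble", {
  m <- 5
  M <- simulate_traces(alexa_params(m), 1500, 400, seed = 91,
                       format = "matrix")
  avg <- colMeans(M)
  sdv <- apply(M, 2, stats::sd) / sqrt(nrow(M))
  # 1500 frames cannot resolve the 1e5-frame bleached-tail eigenvalue, so
  # fit the two resolvable timescales; the amplitude sum still gives m
  fit <- fit_multiexponential(avg, weights = 1 / pmax(sdv, 1),
                              n_components = 2)
  m_est <- count_from_amplitudes(as_spectral_form(fit), 1000)
  expect_equal(m_est, m, tolerance = 0.15)
})

test_that("dwell-time mixtures identify the number of dark timescales", {
  # one geometric scale
  set.seed(41)
  g1 <- rgeom(600, 0.03) + 1
  f1 <- fluorcount:::fit_exp_mixture(g1, 1)
  gof1 <- fluorcount:::dwell_gof(g1, f1)
  expect_gt(gof1$p_value, 0.01)
  # trace-level: single dark state -> 1 component
  em <- alexa_emission()
  ch1 <- single_dark_chain(0.05, 0.0005, 0.02)
  ts1 <- cached("dwell_1dark",
                simulate_traces(htmm_params(1, ch1, em), 4000, 60,
                                read_noise_sd = 30, seed = 11,
                                format = "matrix"))
  d1 <- dwell_time_analysis(ts1, list(mu = 0, s = 30))
  expect_identical(d1$n_components, 1L)
  # 50/50 mixture of two well-separated geometric scales -> 2 components
  set.seed(42)
  g2 <- c(rgeom(1500, 0.1) + 1, rgeom(1500, 0.002) + 1)
  f2a <- fluorcount:::fit_exp_mixture(g2, 1)
  f2b <- fluorcount:::fit_exp_mixture(g2, 2)
  expect_lt(fluorcount:::dwell_gof(g2, f2a)$p_value, 0.01)
  expect_gt(fluorcount:::dwell_gof(g2, f2b)$p_value, 0.01)
  # two reversible dark states -> 2 components, never above the cap
  ch4 <- alexa647_chain(p_dl1_bright = 0.05, p_dl2_bright = 0.002,
                        p_bright_bl = 0.001)
  ts4 <- cached("dwell_2dark",
                simulate_traces(htmm_params(1, ch4, em), 8000, 80,
                                read_noise_sd = 30, seed = 12,
                                format = "matrix"))
  d4 <- dwell_time_analysis(ts4, list(mu = 0, s = 30))
  expect_identical(d4$n_components, 2L)
  expect_lte(max(d4$gof$n_components), 3L)
  expect_error(dwell_time_analysis(matrix(0, 2, 100), list(mu = 0, s = 1)),
               "dwell intervals")
})

test_that("conditional binomial fit: exact, boundary and argument handling", {
  fit <- fit_conditional_binomial(c(4, 6, 4, 1), n = 4)
  expect_equal(fit$p_hat, 0.5, tolerance = 1e-6)
  expect_equal(sum(fit$pmf$prob), 1, tolerance = 1e-12)
  # all mass at k = n drives the yield to the boundary
  expect_equal(fit_conditional_binomial(c(0, 0, 0, 60), n = 4)$p_hat, 1)
  expect_error(fit_conditional_binomial(c(0, 0, 0, 0), n = 4), "mass")
  expect_error(fit_conditional_binomial(c(1, 2), n = 4), "length")
  td <- tidy(fit)
  expect_identical(td$term, "p")
})

test_that("yield estimates are consistent as the histogram grows", {
  p <- 0.45; n <- 5
  bias_at <- function(n_draws, reps) {
    mean(vapply(seq_len(reps), function(i) {
      set.seed(i * 7 + n_draws)
      k <- rcond_binomial(n_draws, n, p)
      hist_k <- vapply(1:n, function(j) sum(k == j), integer(1))
      fit_conditional_binomial(hist_k, n)$p_hat
    }, numeric(1))) - p
  }
  b2 <- abs(bias_at(100, 60))
  b4 <- abs(bias_at(10000, 60))
  expect_lt(b4, b2)
  expect_lt(b4, 0.005)
})
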