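test_that("mean trace is m * E(Y) * occupancy", {
  p1 <- htmm_params(1, alexa647_chain(), emission_model(1000, 0.097, 2))
  expect_equal(mean_trace(p1, 1), 1000)
  p50 <- htmm_params(50, alexa647_chain(), emission_model(1000, 0.097, 2))
  expect_equal(mean_trace(p50, 1), 50000)
  p2 <- htmm_params(2, two_state_chain(0.1), emission_model(100))
  expect_equal(mean_trace(p2, 3), 2 * 100 * 0.81)
  expect_identical(mean_trace(p1, integer(0)), numeric(0))
})

test_that("variance trace follows the two-timescale formula", {
  # pure shot-noise limit
  pp <- htmm_params(1, frozen_bright_chain(),
                    emission_model(500, 0, 1))
  expect_equal(variance_trace(pp, 1), 500)
  # EMCCD + overdispersion at frame 1
  pa <- alexa_params(1)
  expect_equal(variance_trace(pa, 1), 99000)
  # m = 0 degenerates to zero
  p0 <- htmm_params(0, alexa647_chain(), alexa_emission())
  expect_equal(variance_trace(p0, 1:5), rep(0, 5))
})

test_that("the binomial occupancy term is a vanishing correction to the variance", {
  em <- alexa_emission()
  ch <- alexa647_chain()
  # Var(Y_t) = ((s2+1)E(Y) + f2)E(Y_t) - E(Y_t)^2/m: always below the
  # m -> infinity envelope, approaching it as the occupancy empties
  pa <- htmm_params(8, ch, em)
  fr <- c(1L, 3L, 10L, 50L, 300L)
  v <- variance_trace(pa, fr)
  mu <- mean_trace(pa, fr)
  envelope <- ((em$excess_relative_variance + 1) * 1000 + 2) * mu
  expect_true(all(v < envelope))
  expect_equal(v, envelope - mu^2 / 8, tolerance = 1e-12)
  ratio <- v / envelope
  expect_true(all(diff(ratio) > 0))
  expect_gt(ratio[5], 0.99)
})

test_that("covariance matrix: diagonal, degenerate cases, enumeration oracle", {
  pa <- alexa_params(3)
  fr <- c(1L, 2L, 5L, 20L, 100L)
  S <- covariance_matrix(pa, fr)
  expect_equal(diag(S), variance_trace(pa, fr))
  expect_true(isSymmetric(S))
  # no occupancy fluctuation when bright is absorbing
  pf <- htmm_params(1, frozen_bright_chain(), emission_model(500, 0, 1))
  Sf <- covariance_matrix(pf, 1:4)
  expect_equal(Sf, diag(rep(500, 4)))
  # m = 0 gives the zero matrix
  expect_equal(covariance_matrix(htmm_params(0, alexa647_chain(),
                                             alexa_emission()), 1:3),
               matrix(0, 3, 3))
  # two-state enumeration: deterministic start kills the (1, t) covariance
  p2 <- htmm_params(4, two_state_chain(0.1), emission_model(100))
  S2 <- covariance_matrix(p2, 1:3)
  expect_equal(S2[1, 2], 0)
  expect_equal(S2[2, 3], 4 * 100^2 * (0.81 - 0.9 * 0.81))
  expect_error(covariance_matrix(p2, c(3, 2)), "strictly increasing")
})

test_that("covariance is positive semi-definite and marginalization-consistent", {
  pa <- alexa_params(6)
  fr <- sort(sample(1:2000, 60))
  S <- covariance_matrix(pa, fr)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  sub <- c(3, 10, 41, 55)
  Ssub <- covariance_matrix(pa, fr[sub])
  expect_equal(Ssub, S[sub, sub], tolerance = 1e-12)
})

test_that("spectral and matrix forms of the mean trace agree to 1e-8", {
  pa <- alexa_params(2)
  sf <- spectral_decomposition(pa)
  tt <- unique(round(seq(1, 5000, length.out = 80)))
  via_spectral <- vapply(tt, function(t) {
    sum(sf$amplitudes * sf$eigenvalues^(t - 1))
  }, numeric(1))
  expect_equal(via_spectral, mean_trace(pa, tt), tolerance = 1e-8)
})

test_that("simulated ensembles reproduce model mean, variance and lag covariance", {
  pa <- alexa_params(1)
  nrep <- 8000
  M <- cached("mom8000", simulate_traces(pa, 60, nrep, seed = 421,
                                         format = "matrix"))
  fr <- c(1L, 5L, 30L, 55L)
  mu_th <- mean_trace(pa, fr)
  va_th <- variance_trace(pa, fr)
  for (k in seq_along(fr)) {
    y <- M[, fr[k]]
    se_m <- stats::sd(y) / sqrt(nrep)
    expect_lt(abs(mean(y) - mu_th[k]), 4 * se_m)
    dev2 <- (y - mean(y))^2
    se_v <- stats::sd(dev2) / sqrt(nrep)
    expect_lt(abs(stats::var(y) - va_th[k]), 4 * se_v)
  }
  # temporal covariance at lags 1, 5, 20 from frame 5
  S_th <- covariance_matrix(pa, c(5L, 6L, 10L, 25L))
  for (j in 2:4) {
    x <- M[, 5]; z <- M[, c(6, 10, 25)[j - 1]]
    prod_dev <- (x - mean(x)) * (z - mean(z))
    emp <- mean(prod_dev)
    se <- stats::sd(prod_dev) / sqrt(nrep)
    expect_lt(abs(emp - S_th[1, j]), 4 * se)
  }
})
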