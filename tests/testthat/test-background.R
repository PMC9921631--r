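test_that("signal-pixel identification isolates bright structures", {
  img <- matrix(10, 40, 40)
  expect_equal(sum(identify_signal_pixels(img)), 0L)
  # hot pixels are masked together with a 2-pixel dilation halo
  set.seed(1)
  img2 <- matrix(stats::rnorm(1600, 10, 0.5), 40, 40)
  hot <- cbind(c(5, 20, 33), c(7, 21, 30))
  img2[hot] <- 1000
  mask <- identify_signal_pixels(img2)
  expect_true(all(mask[hot]))
  expect_true(all(mask[cbind(c(7, 22, 31), c(9, 23, 32))]))  # halo
  expect_lt(mean(mask), 0.1)
  set.seed(2)
  noisy <- matrix(stats::rnorm(100, 10, 0.5), 10, 10)
  expect_warning(
    identify_signal_pixels(noisy,
                           evaluation_regions = data.frame(x = 5, y = 5),
                           region_size = 21),
    "90%")
})

test_that("pixels near planted emitters are masked", {
  cfg <- sim_config(alexa_params(1), n_frames = 1, psf_sigma = 1.2,
                    image_size = c(48, 48),
                    background_coefficients = c(rep(0, 5), 50, rep(0, 4)),
                    background_noise = "poisson", seed = 17)
  em <- data.frame(x = c(12, 35), y = c(14, 30))
  mv <- simulate_movie(cfg, emitters = em)
  mask <- identify_signal_pixels(mv$frames[, , 1])
  for (e in seq_len(nrow(em))) {
    for (dx in -3:3) for (dy in -3:3) {
      if (sqrt(dx^2 + dy^2) <= 3 * 1.2) {
        expect_true(mask[em$y[e] + dy + 1, em$x[e] + dx + 1])
      }
    }
  }
})

test_that("polynomial background fit is exact on model-true fields", {
  # constant field
  f <- fit_polynomial_background(matrix(7.5, 30, 30))
  expect_equal(f$coefficients, c(0, 0, 0, 0, 0, 7.5, 0, 0, 0, 0),
               tolerance = 1e-9)
  # planted 2 x^3 - y^2 + 5
  xs <- rep(0:29, each = 25); ys <- rep(0:24, times = 30)
  img <- matrix(2 * xs^3 - ys^2 + 5, 25, 30)
  f2 <- fit_polynomial_background(img)
  expect_equal(f2$coefficients, c(0, -1, 0, 0, 0, 5, 2, 0, 0, 0),
               tolerance = 1e-9)
  expect_lt(f2$residual_rms, 1e-6 * max(abs(img)))
})

test_that("rank-deficient background designs are refused", {
  img <- matrix(1.0, 30, 30)
  mask <- matrix(TRUE, 30, 30)
  mask[3, ] <- FALSE  # a single row cannot separate the y terms
  expect_error(fit_polynomial_background(img, mask), "rank")
})

test_that("coefficient errors shrink with pixel count under noise", {
  coefs <- c(0.02, -0.01, 0.005, 0.3, -0.2, 20, 1e-4, -2e-4, 5e-5, 1e-4)
  err_for <- function(n_side, seeds) {
    xs <- rep(0:(n_side - 1), each = n_side)
    ys <- rep(0:(n_side - 1), times = n_side)
    planted <- eval_poly_background(coefs, xs, ys)
    vapply(seeds, function(s) {
      set.seed(s)
      img <- matrix(planted + stats::rnorm(n_side^2, 0, 5), n_side, n_side)
      f <- fit_polynomial_background(img)
      abs(f$coefficients[6] - coefs[6])
    }, numeric(1))
  }
  e_small <- mean(err_for(16, 1:40))
  e_large <- mean(err_for(64, 1:40))
  expect_lt(e_large, e_small)
})

test_that("region offset estimation recovers the calibration mean", {
  set.seed(5)
  cal0 <- estimate_region_offset(stats::rnorm(3000, 0, 8))
  expect_lt(abs(cal0$mu), 4 * cal0$s / sqrt(3000))
  cal <- estimate_region_offset(stats::rnorm(3000, 12.5, 8))
  expect_lt(abs(cal$mu - 12.5), 4 * cal$s / sqrt(3000))
  expect_error(estimate_region_offset(rep(3, 100)), "degenerate")
})

test_that("blink contamination is trimmed out of the offset fit", {
  set.seed(6)
  n <- 4000
  v <- stats::rnorm(n, 12.5, 8)
  blink <- sample(n, round(0.02 * n))
  v[blink] <- v[blink] + 900
  cal <- estimate_region_offset(v)
  expect_lt(abs(cal$mu - 12.5), 4 * cal$s / sqrt(n))
})

test_that("trace correction subtracts region background and offset", {
  coefs_t <- function(t) c(0, 0, 0, 0.2, -0.1, 30 + 0.5 * t, 0, 0, 0, 0)
  nf <- 12
  bg <- structure(list(coefficients = t(vapply(1:nf, coefs_t,
                                               numeric(10))),
                       mask = NULL, residual_rms = rep(0, nf)),
                  class = "polynomial_background")
  center <- c(9, 8)
  px <- region_pixels(center, 7)
  bsum <- vapply(1:nf, function(t) {
    sum(eval_poly_background(coefs_t(t), px$x, px$y))
  }, numeric(1))
  cal <- structure(list(mu = 4, s = 1), class = "region_calibration")
  raw <- bsum + 4
  out <- correct_trace(raw, bg, cal, center)
  expect_equal(out$value, rep(0, nf), tolerance = 1e-9)
  # additivity of the signal component
  sig <- stats::runif(nf, 0, 100)
  out2 <- correct_trace(raw + sig, bg, cal, center)
  expect_equal(out2$value, out$value + sig, tolerance = 1e-9)
  # constant background: Y = raw - 49 c (mu = 0)
  bgc <- structure(list(coefficients = matrix(rep(c(0, 0, 0, 0, 0, 3,
                                                    0, 0, 0, 0), 2),
                                              2, 10, byrow = TRUE),
                        mask = NULL, residual_rms = c(0, 0)),
                   class = "polynomial_background")
  expect_equal(correct_trace(c(1000, 1000), bgc, NULL, c(5, 5))$value,
               rep(1000 - 49 * 3, 2))
  expect_error(correct_trace(rep(1, 5), bgc, NULL, c(5, 5)),
               "2 frames")
})

test_that("end-to-end: emitter-free regions correct to zero mean", {
  coefs <- function(t) c(0, 0, 0, 0.3, 0.2, 80 + 0.2 * t, 0, 0, 0, 0)
  cfg <- sim_config(alexa_params(1), n_frames = 40,
                    background_coefficients = coefs,
                    image_size = c(64, 64),
                    background_noise = "poisson", seed = 23)
  em <- data.frame(x = 14, y = 15)
  mv <- simulate_movie(cfg, emitters = em)
  empty_center <- c(45, 44)
  mask <- identify_signal_pixels(
    mv$frames[, , 1],
    evaluation_regions = rbind(em, data.frame(x = 45, y = 44)))
  bg <- fit_background_stack(mv, mask)
  raw <- extract_region_trace(mv, empty_center, 7)
  sub <- correct_trace(raw, bg, NULL, empty_center)
  cal <- estimate_region_offset(sub$value)
  corr <- correct_trace(raw, bg, cal, empty_center)
  se <- stats::sd(corr$value) / sqrt(nrow(corr))
  expect_lt(abs(mean(corr$value)), 4 * se)
})

test_that("evaluation-region detection finds isolated planted emitters", {
  cfg <- sim_config(alexa_params(2), n_frames = 1, psf_sigma = 1.2,
                    image_size = c(64, 64),
                    background_coefficients = c(rep(0, 5), 60, rep(0, 4)),
                    background_noise = "poisson", seed = 37)
  em <- data.frame(x = c(15, 44), y = c(20, 47))
  mv <- simulate_movie(cfg, emitters = em)
  found <- detect_evaluation_regions(mv$frames[, , 1])
  expect_gte(nrow(found), 2)
  for (e in seq_len(2)) {
    d <- sqrt((found$x - em$x[e])^2 + (found$y - em$y[e])^2)
    expect_lt(min(d), 2)
  }
})
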