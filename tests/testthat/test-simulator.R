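test_that("state paths respect the chain and the bleached trap", {
  ch <- alexa647_chain()
  expect_equal(nrow(simulate_state_paths(ch, 0, 10, seed = 1)), 0L)
  # absorbing bright state: every row stays bright
  sp <- simulate_state_paths(frozen_bright_chain(), 20, 50, seed = 2)
  expect_true(all(sp$state == 1L))
  # bleached is never left
  S <- attr(simulate_state_paths(ch, 200, 300, seed = 3), "state_matrix")
  for (i in seq_len(nrow(S))) {
    hit <- which(S[i, ] == 4L)
    if (length(hit)) expect_true(all(S[i, hit[1]:ncol(S)] == 4L))
  }
})

test_that("two-state survival matches the geometric law within binomial error", {
  ch <- two_state_chain(0.1)
  S <- attr(simulate_state_paths(ch, 10000, 11, seed = 11), "state_matrix")
  frac <- mean(S[, 11] == 1L)
  p <- 0.9^10
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / 10000))
})

test_that("traces have the advertised single-frame moments", {
  pa <- alexa_params(1)
  y1 <- cached("sim_frame1",
               simulate_traces(pa, 1, 20000, seed = 77,
                               format = "matrix"))[, 1]
  expect_lt(abs(mean(y1) - 1000), 4 * stats::sd(y1) / sqrt(20000))
  dev2 <- (y1 - mean(y1))^2
  expect_lt(abs(stats::var(y1) - 99000), 4 * stats::sd(dev2) / sqrt(20000))
  # m = 0 gives an identically zero signal
  z <- simulate_traces(htmm_params(0, alexa647_chain(), alexa_emission()),
                       20, 3, seed = 5, format = "matrix")
  expect_true(all(z == 0))
})

test_that("Poisson limit has unit index of dispersion", {
  pp <- htmm_params(1, frozen_bright_chain(), emission_model(200, 0, 1))
  y <- simulate_traces(pp, 1, 20000, seed = 13, format = "matrix")[, 1]
  disp <- stats::var(y) / mean(y)
  # dispersion SE for Poisson ~ sqrt(2/n)
  expect_lt(abs(disp - 1), 4 * sqrt(2 / 20000))
})

test_that("simulation is reproducible and linear in m at frame 1", {
  pa <- alexa_params(3)
  a <- simulate_traces(pa, 30, 4, seed = 99)
  b <- simulate_traces(pa, 30, 4, seed = 99)
  expect_identical(a$value, b$value)
  m1 <- mean(simulate_traces(alexa_params(2), 1, 5000, seed = 21,
                             format = "matrix")[, 1])
  m2 <- mean(simulate_traces(alexa_params(4), 1, 5000, seed = 22,
                             format = "matrix")[, 1])
  se <- sqrt(2) * sqrt(99000 * 4 / 5000)
  expect_lt(abs(m2 - 2 * m1), 4 * se)
})

test_that("unsupported camera excess noise is refused by the generator", {
  bad <- htmm_params(1, alexa647_chain(), emission_model(1000, 0.097, 1.5))
  expect_error(simulate_traces(bad, 5, 1, seed = 1), "f\\^2")
})

test_that("movies render the planted background exactly when noise-free", {
  coefs <- c(0.01, -0.02, 0, 0.5, 0.1, 40, 0, 0, 0, 0)
  cfg <- sim_config(alexa_params(0), n_frames = 3,
                    background_coefficients = coefs,
                    image_size = c(24, 32), seed = 4)
  mv <- simulate_movie(cfg)
  xs <- rep(0:31, each = 24); ys <- rep(0:23, times = 32)
  planted <- matrix(eval_poly_background(coefs, xs, ys), 24, 32)
  for (t in 1:3) expect_equal(mv$frames[, , t], planted, tolerance = 1e-12)
})

test_that("a rendered spot integrates to its drawn signal", {
  cfg <- sim_config(alexa_params(1), n_frames = 4, psf_sigma = 1.4,
                    image_size = c(40, 40), seed = 8)
  mv <- simulate_movie(cfg, emitters = data.frame(x = 19.3, y = 21.7))
  for (t in 1:4) {
    expect_equal(sum(mv$frames[, , t]), mv$ground_truth[1, t],
                 tolerance = 1e-6)
  }
})

test_that("region extraction equals brute-force pixel summation", {
  set.seed(31)
  arr <- array(stats::runif(20 * 22 * 5), dim = c(20, 22, 5))
  tr <- extract_region_trace(arr, center = c(10, 9), region_size = 7)
  brute <- numeric(5)
  for (t in 1:5) {
    s <- 0
    for (dx in -3:3) for (dy in -3:3) {
      s <- s + arr[9 + dy + 1, 10 + dx + 1, t]
    }
    brute[t] <- s
  }
  expect_equal(tr$value, brute, tolerance = 1e-12)
  # constant image: 49 * c
  carr <- array(2.5, dim = c(9, 9, 2))
  expect_equal(extract_region_trace(carr, c(4, 4), 7)$value, rep(49 * 2.5, 2))
  expect_error(extract_region_trace(carr, c(1, 4), 7), "clipped")
})

test_that("region traces from movies reproduce trace-mode statistics", {
  cfg <- sim_config(alexa_params(1), n_frames = 1, psf_sigma = 1.0,
                    image_size = c(15, 15), seed = 55)
  nrep <- 3000
  vals <- numeric(nrep)
  set.seed(55)
  for (i in seq_len(nrep)) {
    cfg$seed <- NULL
    mv <- simulate_movie(cfg, emitters = data.frame(x = 7, y = 7))
    vals[i] <- extract_region_trace(mv, c(7, 7), 7)$value[1]
  }
  # the 7x7 box holds ~99.9% of a sigma = 1 spot at the center
  expect_lt(abs(mean(vals) - 1000), 4 * stats::sd(vals) / sqrt(nrep) + 2)
})
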