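#' Estimate the excess relative variance from single-molecule traces
#'
#' For each background-corrected single-fluorophore trace, blink frames are
#' selected (`Y > mu + 3 s`, first frame of each event rejected so the
#' fluorophore started the frame bright) and the per-trace excess relative
#' variance is computed as
#' `sigma_e^2 = Var(Y_blink) / mean(Y_blink)^2 - 1 / mean(Y_blink)`.
#' The per-trace values are histogrammed and the center of a Gaussian fit to
#' the histogram is reported as the ensemble estimate.
#'
#' @param traces A `trace_set` tibble (columns `trace`, `frame`, `value`) or
#'   an `n_traces x n_frames` matrix.
#' @param calibrations A single `region_calibration` applied to all traces,
#'   or a list with one calibration per trace.
#' @param min_frame Passed to [detect_blink_frames()]; default 0 (all events
#'   of a single-molecule trace are usable).
#' @param min_blink_frames Traces with fewer retained blink frames are
#'   skipped (at least 2 are required to form a variance).
#' @return An object of class `excess_variance_estimate`: list with
#'   `center`, `width`, a `per_trace` tibble and `n_used`. A warning is
#'   attached when fewer than 10 traces were usable.
#' @export
estimate_excess_variance <- function(traces, calibrations, min_frame = 0,
                                     min_blink_frames = 2) {
  M <- traces_as_matrix(traces)
  n_tr <- nrow(M)
  cal_for <- function(i) {
    if (inherits(calibrations, "region_calibration") ||
        (is.list(calibrations) && !is.null(calibrations$mu))) {
      calibrations
    } else calibrations[[i]]
  }
  vals <- rep(NA_real_, n_tr)
  nbl <- integer(n_tr)
  for (i in seq_len(n_tr)) {
    y <- M[i, ]
    bf <- detect_blink_frames(y, cal_for(i), min_frame = min_frame)
    nbl[i] <- length(bf$frames)
    if (nbl[i] >= max(2, min_blink_frames)) {
      v <- y[bf$frames]
      vals[i] <- stats::var(v) / mean(v)^2 - 1 / mean(v)
    }
  }
  use <- which(!is.na(vals))
  if (length(use) == 0) {
    stop("no trace yielded enough blink frames", call. = FALSE)
  }
  warn <- NULL
  if (length(use) < 10) {
    warn <- paste0("only ", length(use),
                   " usable traces; ensemble estimate is unreliable")
    warning(warn, call. = FALSE)
  }
  fit <- if (length(use) >= 10) {
    gaussian_histogram_fit(vals[use], stats::median(vals[use]),
                           stats::mad(vals[use]))
  } else list(mu = mean(vals[use]), s = stats::sd(vals[use]),
              converged = FALSE)
  structure(list(center = fit$mu, width = fit$s,
                 per_trace = tibble::tibble(trace = seq_len(n_tr),
                                            sigma_e2 = vals,
                                            n_blink_frames = nbl),
                 n_used = length(use), fit = fit, warning = warn),
            class = "excess_variance_estimate")
}

#' @export
print.excess_variance_estimate <- function(x, ...) {
  cat("<excess_variance_estimate> sigma_e^2 =", format(x$center, digits = 4),
      "(width", format(x$width, digits = 3), ",", x$n_used, "traces )\n")
  invisible(x)
}

traces_as_matrix <- function(traces) {
  if (is.matrix(traces)) return(traces)
  stopifnot(is.data.frame(traces),
            all(c("trace", "frame", "value") %in% names(traces)))
  ids <- unique(traces$trace)
  nf <- max(traces$frame)
  M <- matrix(NA_real_, length(ids), nf)
  for (i in seq_along(ids)) {
    sub <- traces[traces$trace == ids[i], ]
    M[i, sub$frame] <- sub$value
  }
  M
}

#' Weighted multi-exponential fit of an averaged trace
#'
#' Fits `f(t) = sum_k alpha_k * lambda_k^(t-1)` to an averaged fluorescence
#' trace by Levenberg-Marquardt least squares, weighted with the inverse
#' per-frame standard deviations of the averaged data. The default
#' three-component start is `alpha = (20000, 100, 10)`,
#' `lambda = (0.9, 0.999, 0.99999)` — magnitudes appropriate for Alexa-647
#' traces in detector units at 15 ms exposure.
#'
#' @param mean_trace Averaged trace: numeric vector or data frame with
#'   `frame`, `value`.
#' @param weights Inverse per-frame standard deviations (same length as the
#'   trace); `NULL` for an unweighted fit.
#' @param n_components Number of exponential components.
#' @param init Optional list with `alpha` and `lambda` start vectors.
#' @return An object of class `multiexp_fit`: `amplitudes`, `eigenvalues`
#'   (sorted by increasing eigenvalue), `weighted_rss`, `converged`, `fit`.
#' @export
#' @examples
#' t <- 1:300
#' y <- 100 * 0.95^(t - 1)
#' fit_multiexponential(y, n_components = 1)$eigenvalues  # 0.95
fit_multiexponential <- function(mean_trace, weights = NULL,
                                 n_components = 3, init = NULL) {
  if (is.data.frame(mean_trace)) {
    t <- mean_trace$frame; y <- mean_trace$value
  } else {
    y <- as.numeric(mean_trace); t <- seq_along(y)
  }
  K <- as.integer(n_components)
  stopifnot(K >= 1)
  if (length(y) <= 2 * K + 2) {
    stop("trace too short for ", K, " components (need > ", 2 * K + 2,
         " frames)", call. = FALSE)
  }
  if (is.null(init)) {
    init <- switch(as.character(K),
      "1" = list(alpha = max(y), lambda = 0.9),
      "2" = list(alpha = c(max(y), max(y) / 100), lambda = c(0.9, 0.999)),
      "3" = list(alpha = c(20000, 100, 10),
                 lambda = c(0.9, 0.999, 0.99999)),
      list(alpha = max(y) / 10^(0:(K - 1)),
           lambda = 1 - 10^(-(1:K))))
  }
  stopifnot(length(init$alpha) == K, length(init$lambda) == K)
  w2 <- if (is.null(weights)) rep(1, length(y)) else {
    stopifnot(length(weights) == length(y), all(weights > 0))
    weights^2
  }
  d <- data.frame(t = t, y = y, w2 = w2)
  par0 <- stats::setNames(c(init$alpha, init$lambda),
                          c(paste0("a", 1:K), paste0("l", 1:K)))
  form <- stats::as.formula(paste0(
    "y ~ ", paste0("a", 1:K, " * l", 1:K, "^(t - 1)", collapse = " + ")))
  run_fit <- function(start) {
    minpack.lm::nlsLM(
      form, data = d, start = start, weights = d$w2,
      lower = c(rep(0, K), rep(1e-8, K)),
      upper = c(rep(Inf, K), rep(1, K)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14))
  }
  fit <- tryCatch(run_fit(as.list(par0)), error = function(e) e)
  if (inherits(fit, "error")) {
    # rescale the amplitude start to the data before giving up
    par1 <- par0
    par1[1:K] <- par0[1:K] * max(y[1], 1) / sum(par0[1:K])
    fit <- run_fit(as.list(par1))
  }
  cf <- stats::coef(fit)
  a <- unname(cf[1:K]); l <- unname(cf[(K + 1):(2 * K)])
  o <- order(l)
  res <- stats::resid(fit)
  structure(list(amplitudes = a[o], eigenvalues = l[o],
                 weighted_rss = sum(w2 * res^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 n_components = K, fit = fit),
            class = "multiexp_fit")
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat("<multiexp_fit>", x$n_components, "components\n")
  print(tibble::tibble(amplitude = x$amplitudes,
                       eigenvalue = x$eigenvalues))
  invisible(x)
}

#' Spectral form from a multi-exponential fit
#'
#' Repackages a fitted decay curve as a `spectral_form` whose amplitudes are
#' the fitted `alpha_k`, so the fluorophore number can be derived via
#' [count_from_amplitudes()].
#'
#' @param x A `multiexp_fit`.
#' @return A `spectral_form`.
#' @export
as_spectral_form <- function(x) {
  stopifnot(inherits(x, "multiexp_fit"))
  structure(list(eigenvalues = x$eigenvalues,
                 coefficients_bright = x$amplitudes / sum(x$amplitudes),
                 coefficients_dark = rep(NA_real_, length(x$amplitudes)),
                 amplitudes = x$amplitudes,
                 initial_bright_fraction = 1),
            class = "spectral_form")
}

#' Dwell-time analysis of dark-state residences
#'
#' Pools the times between consecutive blinking events (the frames spent in
#' dark states) across traces and determines the smallest number of
#' exponential components that adequately describes their distribution — an
#' empirical count of the distinguishable reversible dark states. Mixtures
#' of 1..`max_components` frame-discrete exponential (geometric) components
#' are fit by maximum likelihood (EM);
#' a fit is adequate when a Pearson chi-squared test on binned residuals
#' does not reject it at the 1% level, with BIC as tie-break when no
#' component count is adequate. Intervals truncated by the end of the
#' recording never form (two events are required), and the initial dark
#' period before the first event is not counted.
#'
#' @param traces A `trace_set` tibble or trace matrix.
#' @param calibrations As in [estimate_excess_variance()].
#' @param max_components Largest mixture size to consider.
#' @param min_intervals Minimum pooled dwell count (error below).
#' @param threshold_sigma Event-detection threshold in units of the
#'   calibration spread. The default is stricter than the 3-sigma blink rule:
#'   at 3 sigma, Gaussian background crosses the threshold at a rate of
#'   1.35e-3 per frame, which plants a spurious slow "dark state" with the
#'   inter-false-event timescale into the dwell histogram; 5 sigma makes
#'   false events negligible while real blinks (many sigma bright) are
#'   unaffected.
#' @return An object of class `dwell_time_fit`: `n_components` (selected),
#'   `components` tibble (`weight`, per-frame escape `rate`, `mean_frames`),
#'   `gof` tibble per candidate size, and the pooled `dwell_times`.
#' @export
dwell_time_analysis <- function(traces, calibrations, max_components = 3,
                                min_intervals = 50, threshold_sigma = 5) {
  M <- traces_as_matrix(traces)
  cal_for <- function(i) {
    if (is.list(calibrations) && !is.null(calibrations$mu)) calibrations
    else calibrations[[i]]
  }
  dw <- integer(0)
  for (i in seq_len(nrow(M))) {
    bf <- detect_blink_frames(M[i, ], cal_for(i), min_frame = 0,
                              n_sigma = threshold_sigma)
    ev <- bf$events
    if (nrow(ev) >= 2) {
      dw <- c(dw, ev$start[-1] - ev$end[-nrow(ev)] - 1L)
    }
  }
  dw <- dw[dw >= 1]
  if (length(dw) < min_intervals) {
    stop("only ", length(dw), " dwell intervals pooled; need at least ",
         min_intervals, call. = FALSE)
  }
  gof <- NULL
  fits <- list()
  for (K in seq_len(max_components)) {
    f <- fit_exp_mixture(dw, K)
    ch <- dwell_gof(dw, f)
    fits[[K]] <- f
    gof <- rbind(gof, data.frame(n_components = K, logLik = f$logLik,
                                 bic = -2 * f$logLik +
                                   (2 * K - 1) * log(length(dw)),
                                 chisq = ch$chisq, df = ch$df,
                                 p_value = ch$p_value))
  }
  adequate <- which(gof$p_value > 0.01)
  sel <- if (length(adequate)) min(adequate) else which.min(gof$bic)
  f <- fits[[sel]]
  structure(list(n_components = sel,
                 components = tibble::tibble(weight = f$weight,
                                             rate = f$rate,
                                             mean_frames = 1 / f$rate),
                 gof = tibble::as_tibble(gof),
                 dwell_times = dw,
                 adequate = length(adequate) > 0),
            class = "dwell_time_fit")
}

#' @export
print.dwell_time_fit <- function(x, ...) {
  cat("<dwell_time_fit>", x$n_components, "exponential component(s) from",
      length(x$dwell_times), "dwell intervals\n")
  print(x$components)
  invisible(x)
}

# ML fit of a K-component geometric mixture by EM. Dwell times live on the
# frame grid, so the discrete-time exponential decay (1 - p)^(t - 1) * p is
# the exact per-component law; a continuous exponential would be rejected
# on large samples purely for its discretization mismatch.
fit_exp_mixture <- function(x, K, max_iter = 500, tol = 1e-10) {
  q <- stats::quantile(x, probs = seq(0.15, 0.85, length.out = K))
  rate <- 1 / pmax(as.numeric(q), 1)
  rate <- pmin(rate, 0.95)
  w <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K),
                   function(k) w[k] * rate[k] * (1 - rate[k])^(x - 1),
                   numeric(length(x)))
    dens <- matrix(dens, ncol = K)
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    r <- dens / tot
    nk <- colSums(r)
    w <- nk / length(x)
    rate <- pmin(pmax(nk / colSums(r * x), 1e-9), 1 - 1e-9)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  o <- order(rate, decreasing = TRUE)
  list(weight = w[o], rate = rate[o], logLik = ll, iterations = it)
}

# Pearson chi-squared adequacy of a geometric-mixture fit on binned dwell
# times; bins merged to expected counts >= 5
dwell_gof <- function(x, fit) {
  K <- length(fit$rate)
  brks <- unique(c(floor(stats::quantile(x, probs = seq(0, 1, length.out =
                                                          min(30, max(6, length(x) %/% 10))))) + 0.5,
                   Inf))
  brks <- c(0.5, brks[brks > 0.5])
  obs <- as.vector(table(cut(x, brks, right = TRUE)))
  pmix <- function(q) {
    if (!is.finite(q)) return(1)
    s <- 0
    for (k in seq_len(K)) {
      s <- s + fit$weight[k] * (1 - (1 - fit$rate[k])^floor(q))
    }
    s
  }
  pr <- diff(vapply(brks, pmix, numeric(1)))
  pr <- pr / sum(pr)
  expd <- pr * length(x)
  # merge small-expectation bins from the right
  while (length(expd) > 2 && any(expd < 5)) {
    i <- which(expd < 5)[1]
    j <- if (i == length(expd)) i - 1 else i + 1
    expd[j] <- expd[j] + expd[i]; obs[j] <- obs[j] + obs[i]
    expd <- expd[-i]; obs <- obs[-i]
  }
  chisq <- sum((obs - expd)^2 / expd)
  df <- max(length(expd) - 1 - (2 * K - 1), 1)
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Conditional-binomial labeling-yield fit
#'
#' Detected structures carry at least one dye, so observed per-structure
#' counts follow a binomial `B(k | p, n)` conditioned on `k > 0`:
#' `P(k) = choose(n, k) p^k (1-p)^(n-k) / (1 - (1-p)^n)` for `k = 1..n`.
#' The labeling yield `p` is estimated by maximum likelihood on the count
#' histogram.
#'
#' @param count_histogram Integer vector of observed counts for
#'   `k = 1, ..., n` (length `n`), or a data frame with columns `k`, `count`.
#' @param n Number of designed labeling positions.
#' @return An object of class `binomial_yield_fit`: `p_hat`, `se` (from the
#'   observed Fisher information), `n`, `logLik`, and a `pmf` tibble with
#'   observed and predicted counts.
#' @export
#' @examples
#' fit_conditional_binomial(c(4, 6, 4, 1), n = 4)$p_hat  # 0.5
fit_conditional_binomial <- function(count_histogram, n) {
  stopifnot(n >= 1)
  cnt <- if (is.data.frame(count_histogram)) {
    out <- numeric(n)
    out[count_histogram$k] <- count_histogram$count
    out
  } else as.numeric(count_histogram)
  if (length(cnt) != n) {
    stop("`count_histogram` must give counts for k = 1..n (length ", n, ")",
         call. = FALSE)
  }
  if (any(cnt < 0) || sum(cnt) == 0) {
    stop("histogram must be non-negative with some mass", call. = FALSE)
  }
  k <- seq_len(n)
  ll <- function(p) {
    sum(cnt * (stats::dbinom(k, n, p, log = TRUE) -
                 log1p(-(1 - p)^n)))
  }
  opt <- stats::optimize(ll, interval = c(1e-9, 1 - 1e-9), maximum = TRUE,
                         tol = 1e-10)
  p_hat <- opt$maximum
  if (p_hat > 1 - 1e-6 && which.max(cnt) == n && all(cnt[-n] == 0)) {
    p_hat <- 1
  }
  # observed Fisher information by central difference of the score
  se <- NA_real_
  if (p_hat > 1e-6 && p_hat < 1 - 1e-6) {
    h <- 1e-5
    d2 <- (ll(p_hat + h) - 2 * ll(p_hat) + ll(p_hat - h)) / h^2
    if (is.finite(d2) && d2 < 0) se <- sqrt(-1 / d2)
  }
  pmf <- stats::dbinom(k, n, p_hat) / (1 - (1 - p_hat)^n)
  structure(list(p_hat = p_hat, se = se, n = n,
                 logLik = ll(min(max(p_hat, 1e-9), 1 - 1e-9)),
                 pmf = tibble::tibble(k = k, prob = pmf,
                                      expected = pmf * sum(cnt),
                                      observed = cnt)),
            class = "binomial_yield_fit")
}

#' @export
print.binomial_yield_fit <- function(x, ...) {
  cat("<binomial_yield_fit> p_hat =", format(x$p_hat, digits = 4),
      "(se", format(x$se, digits = 3), ", n =", x$n, ")\n")
  invisible(x)
}

#' Draw counts from a conditional binomial distribution
#'
#' Samples `k ~ B(. | p, n)` conditioned on `k > 0` — the distribution of
#' per-structure fluorophore numbers among detectable structures.
#'
#' @param n_draws Number of draws.
#' @param size Number of labeling positions `n`.
#' @param prob Labeling yield `p`.
#' @return Integer vector of counts in `1..size`.
#' @export
rcond_binomial <- function(n_draws, size, prob) {
  k <- seq_len(size)
  pmf <- stats::dbinom(k, size, prob) / (1 - (1 - prob)^size)
  sample(k, n_draws, replace = TRUE, prob = pmf)
}
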