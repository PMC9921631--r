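#' Gaussian pseudo log-likelihood of a trace
#'
#' Second-order (Gaussian-process) surrogate for the intractable exact
#' likelihood of the two-timescale model: the trace on the schedule frames
#' is scored against the model's mean vector and temporal covariance matrix,
#' `l = -1/2 [ (y - mu)' Sigma^-1 (y - mu) + log det Sigma ]`,
#' with no further additive constant. Near-singular covariances (long
#' schedules with eigenvalues close to 1) are stabilized by adding a jitter
#' of `1e-8 * mean(diag(Sigma))` to the diagonal, escalated tenfold up to
#' `1e-4` before failing.
#'
#' @param y Corrected trace values on the schedule frames: numeric vector,
#'   or data frame with `frame` and `value` columns.
#' @param params An [htmm_params()].
#' @param frames Frame indices the values of `y` belong to; defaults to the
#'   `frame` column of `y` or `seq_along(y)`.
#' @param noise_sd Residual background noise level of the corrected trace
#'   (the calibration spread `s`), added as `noise_sd^2` to the covariance
#'   diagonal; 0 recovers the bare model covariance.
#' @return The pseudo log-likelihood (scalar), with attribute `"jitter"`
#'   giving the diagonal jitter that was applied.
#' @export
pseudo_log_likelihood <- function(y, params, frames = NULL, noise_sd = 0) {
  stopifnot(inherits(params, "htmm_params"), noise_sd >= 0)
  if (is.data.frame(y)) {
    frames <- frames %||% y$frame
    y <- y$value
  }
  frames <- frames %||% seq_along(y)
  stopifnot(length(y) == length(frames), all(frames >= 1))
  ch <- params$chain
  em <- params$emission
  res <- cpp_pseudo_loglik(as.numeric(y), as.numeric(frames),
                           ch$transition_matrix, params$m,
                           em$mean_bright_signal,
                           em$excess_relative_variance,
                           em$camera_excess_noise,
                           ch$initial_bright_fraction,
                           ch$dark_start_state, noise_sd^2,
                           1e-8, 1e-4)
  if (!isTRUE(res$ok)) {
    stop("covariance matrix not positive definite after maximal jitter ",
         "(mean diagonal ", format(res$diag_mean),
         ", last jitter ", format(res$jitter), ")", call. = FALSE)
  }
  structure(res$value, jitter = res$jitter)
}

#' Fluorophore number from spectral amplitudes
#'
#' With all fluorophores starting bright, the expected first-frame signal is
#' the sum of the exponential amplitudes, so the count is
#' `m = sum_k alpha_k / E(Y)`.
#'
#' @param spectral A `spectral_form` with amplitudes in detector units
#'   (e.g. from [spectral_decomposition()] of an [htmm_params()], or a
#'   [fit_multiexponential()] result via [as_spectral_form()]).
#' @param E_Y Mean single-fluorophore bright-frame signal, > 0.
#' @return The fluorophore number (real).
#' @export
count_from_amplitudes <- function(spectral, E_Y) {
  stopifnot(inherits(spectral, "spectral_form"))
  if (!is.numeric(E_Y) || length(E_Y) != 1 || E_Y <= 0) {
    stop("`E_Y` must be a single positive value", call. = FALSE)
  }
  if (anyNA(spectral$amplitudes)) {
    stop("spectral form carries no amplitudes (decompose an htmm_params, ",
         "not a bare chain)", call. = FALSE)
  }
  sum(spectral$amplitudes) / E_Y
}

#' Options for the pseudo-likelihood fit
#'
#' @param n_starts Number of optimizer starts (first is the supplied or
#'   data-derived initialization, the rest are jittered copies).
#' @param maxit Maximum BFGS iterations for the final polish.
#' @param stage1_maxit Iteration cap for the exploratory stage run from
#'   every start; only the best stage-one result is polished to `maxit`.
#' @param factr L-BFGS-B convergence tolerance (relative to machine
#'   precision); see [stats::optim()].
#' @param brightness_band The single-fluorophore brightness `E(Y)` is
#'   constrained to within this factor of the late-trace blink level when
#'   blink frames anchor it (widened to 10 otherwise).
#' @param sigma_e_max Upper bound for the free excess relative variance;
#'   the default of 2 is far above the ~0.1 measured for switching dyes.
#' @param start_jitter_sd Standard deviation of the Gaussian jitter applied
#'   to the transformed parameters for the extra starts.
#' @param fix_sigma_e `NULL` to estimate the excess relative variance freely
#'   (the default during counting) or a number to pin it (used when
#'   computing theoretical variance curves).
#' @param seed Integer seed for the start jitter (fits are deterministic
#'   given the seed).
#' @return A list of options for [fit_htmm()].
#' @export
htmm_fit_options <- function(n_starts = 5, maxit = 150, stage1_maxit = 15,
                             factr = 1e7, start_jitter_sd = 0.3,
                             fix_sigma_e = NULL, brightness_band = 1.35,
                             sigma_e_max = 2,
                             seed = 1L) {
  list(n_starts = n_starts, maxit = maxit, stage1_maxit = stage1_maxit,
       factr = factr, start_jitter_sd = start_jitter_sd,
       fix_sigma_e = fix_sigma_e, brightness_band = brightness_band,
       sigma_e_max = sigma_e_max, seed = seed)
}

#' Fit the counting model to a corrected trace
#'
#' Jointly estimates the fluorophore number `m`, the bright-frame emission
#' moments and the chain transition probabilities by numerically maximizing
#' the Gaussian pseudo log-likelihood over the schedule frames. Parameters
#' are optimized on unconstrained scales (log for `m`, `E(Y)` and
#' `sigma_e^2`; multinomial-logit for the bright-row exits; logit for the
#' dark-state returns) with a box-constrained quasi-Newton optimizer
#' (L-BFGS-B) and multiple starts. The initial bright fraction `nu` and
#' camera excess noise `f^2` are protocol constants and stay fixed.
#'
#' The Gaussian surrogate has a degenerate ridge at `E(Y) -> 0`,
#' `m -> Inf`, `sigma_e^2 -> Inf`, where the model collapses to independent
#' per-frame noise with a free variance profile and the count loses all
#' meaning. The fit therefore constrains `E(Y)` to within a factor
#' `brightness_band` of the data-derived single-fluorophore brightness (the
#' late-trace blink level) and caps `sigma_e^2` — both bounds far
#' outside the physically plausible range.
#'
#' @param trace Corrected trace: numeric vector over frames `1..N`, or a
#'   data frame with `frame`, `value` columns (a `trace_set` with one trace).
#' @param schedule A [build_subsample_schedule()]; `NULL` uses every frame
#'   for traces up to 500 frames, otherwise a power-law schedule of nominal
#'   length 400.
#' @param init Optional [htmm_params()] starting point; when `NULL` a
#'   data-driven start is derived (brightness from late-trace blink levels,
#'   count from the first frame, chain probabilities from the
#'   [alexa647_chain()] timescales).
#' @param options An [htmm_fit_options()] list.
#' @param chain_template An [ltm_chain()] fixing the state topology (number
#'   of dark states, `nu`, dark-start convention); default [alexa647_chain()].
#' @param f2 Camera excess noise factor, fixed during the fit.
#' @param noise_sd Residual background noise level of the corrected trace
#'   (the region calibration's spread `s`), held fixed; see
#'   [pseudo_log_likelihood()]. Traces whose dark frames are exactly zero
#'   (noise-free synthetic input) can use 0, but a Gaussian likelihood with
#'   vanishing dark-frame variance is degenerate on real data, so supply the
#'   calibrated `s` whenever there is one.
#' @return An object of class `htmm_fit`: list with `m_hat`, `m_int`,
#'   `params` (fitted [htmm_params()]), `spectral`, `m_from_amplitudes`,
#'   `logLik`, `convergence`, and a per-start diagnostics tibble `starts`.
#' @export
#' @examples
#' \donttest{
#' pars <- htmm_params(6, alexa647_chain(), emission_model(1000, 0.097, 2))
#' y <- simulate_traces(pars, 2000, 1, seed = 7, format = "matrix")[1, ]
#' fit <- fit_htmm(y, build_subsample_schedule(2000, 150),
#'                 options = htmm_fit_options(n_starts = 2, maxit = 150))
#' fit$m_hat
#' }
fit_htmm <- function(trace, schedule = NULL, init = NULL,
                     options = htmm_fit_options(),
                     chain_template = alexa647_chain(), f2 = 2,
                     noise_sd = 0) {
  y <- trace_values(trace)
  N <- length(y)
  if (is.null(schedule)) {
    schedule <- if (N <= 500) {
      structure(list(N = N, n = N, beta = NA_real_, indices = seq_len(N)),
                class = "subsample_schedule")
    } else build_subsample_schedule(N, min(400L, N))
  }
  stopifnot(inherits(schedule, "subsample_schedule"))
  if (schedule$N > N) {
    stop("trace has ", N, " frames but the schedule expects ", schedule$N,
         call. = FALSE)
  }
  idx <- schedule$indices
  ysub <- y[idx]
  ch <- chain_template
  ns <- ch$num_states
  nu <- ch$initial_bright_fraction
  user_init <- !is.null(init)
  auto_init <- default_init_params(y, ch, f2, noise_sd)
  if (!user_init) init <- auto_init
  fixed_s2 <- options$fix_sigma_e

  theta0 <- params_to_theta(init, fixed_s2)
  # a user-supplied start also fixes the brightness anchor; otherwise it is
  # the late-trace blink level, with a widened band if no blinks anchor it
  EY0 <- if (user_init) init$emission$mean_bright_signal else
    auto_init$emission$mean_bright_signal
  lower <- rep(-Inf, length(theta0))
  upper <- rep(Inf, length(theta0))
  band <- if (user_init || isTRUE(attr(auto_init, "anchored"))) {
    options$brightness_band
  } else max(options$brightness_band, 10)
  lower[2] <- log(EY0 / band); upper[2] <- log(EY0 * band)
  if (is.null(fixed_s2)) {
    lower[3] <- log(1e-6); upper[3] <- log(options$sigma_e_max)
  }
  negpll <- function(theta) {
    p <- theta_to_params(theta, ch, f2, fixed_s2)
    res <- cpp_pseudo_loglik(ysub, as.numeric(idx),
                             p$T, p$m, p$EY, p$s2, f2, nu,
                             ch$dark_start_state, noise_sd^2, 1e-8, 1e-4)
    if (!isTRUE(res$ok) || !is.finite(res$value)) return(1e12)
    -res$value
  }

  # forward-difference gradient with memoized base value: half the
  # function evaluations of optim's internal central differences
  last_theta <- NULL; last_val <- NULL
  negpll_memo <- function(theta) {
    v <- negpll(theta)
    last_theta <<- theta; last_val <<- v
    v
  }
  grad_fd <- function(theta) {
    f0 <- if (!is.null(last_theta) && identical(theta, last_theta)) {
      last_val
    } else negpll(theta)
    g <- numeric(length(theta))
    for (i in seq_along(theta)) {
      h <- 1e-7 * max(1, abs(theta[i]))
      th <- theta; th[i] <- th[i] + h
      g[i] <- (negpll(th) - f0) / h
    }
    g
  }

  set.seed(options$seed)
  starts <- list(theta0)
  if (options$n_starts > 1) {
    for (k in seq_len(options$n_starts - 1)) {
      starts[[k + 1]] <- theta0 +
        stats::rnorm(length(theta0), sd = options$start_jitter_sd)
    }
  }
  # exploratory stage from every start, then polish the best
  runs <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    runs[[k]] <- tryCatch(
      stats::optim(pmin(pmax(starts[[k]], lower), upper), negpll_memo,
                   gr = grad_fd, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = options$stage1_maxit,
                                  factr = options$factr)),
      error = function(e) list(value = Inf, convergence = 99L,
                               message = conditionMessage(e)))
  }
  vals <- vapply(runs, function(r) r$value, numeric(1))
  if (any(is.finite(vals) & vals < 1e12)) {
    kb <- which.min(vals)
    polished <- tryCatch(
      stats::optim(runs[[kb]]$par, negpll_memo, gr = grad_fd,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = options$maxit,
                                  factr = options$factr)),
      error = function(e) NULL)
    if (!is.null(polished) && polished$value <= runs[[kb]]$value) {
      runs[[kb]] <- polished
    }
    vals[kb] <- runs[[kb]]$value
  }
  diag_tb <- tibble::tibble(
    start = seq_along(runs),
    neg_pll = vals,
    convergence = vapply(runs, function(r) as.integer(r$convergence %||% 99L),
                         integer(1)),
    iterations = vapply(runs, function(r) {
      cnt <- r$counts
      if (is.null(cnt)) NA_integer_ else as.integer(cnt[["function"]])
    }, integer(1)))
  if (all(!is.finite(vals)) || all(vals >= 1e12)) {
    return(structure(list(m_hat = NA_real_, m_int = NA_integer_,
                          params = NULL, spectral = NULL,
                          m_from_amplitudes = NA_real_,
                          logLik = NA_real_, convergence = 99L,
                          starts = diag_tb, schedule = schedule),
                     class = "htmm_fit"))
  }
  best <- runs[[which.min(vals)]]
  pb <- theta_to_params(best$par, ch, f2, fixed_s2)
  fitted_chain <- ltm_chain(pb$T, state_labels = ch$state_labels,
                            initial_bright_fraction = nu,
                            dark_start_state = ch$dark_start_state)
  fitted <- htmm_params(pb$m, fitted_chain,
                        emission_model(pb$EY, pb$s2, f2))
  spectral <- tryCatch(spectral_decomposition(fitted), error = function(e) NULL)
  m_amp <- if (is.null(spectral)) NA_real_ else
    count_from_amplitudes(spectral, pb$EY)
  structure(list(m_hat = pb$m, m_int = as.integer(round(pb$m)),
                 params = fitted, spectral = spectral,
                 m_from_amplitudes = m_amp,
                 logLik = -best$value,
                 convergence = best$convergence,
                 starts = diag_tb, schedule = schedule,
                 data = tibble::tibble(frame = idx, value = ysub)),
            class = "htmm_fit")
}

#' @export
print.htmm_fit <- function(x, ...) {
  cat("<htmm_fit> m_hat =", format(x$m_hat, digits = 4),
      " (integer", x$m_int, ") pseudo-logLik =",
      format(x$logLik, digits = 8), "\n")
  if (!is.null(x$params)) {
    cat("  E(Y) =", format(x$params$emission$mean_bright_signal, digits = 5),
        " sigma_e^2 =",
        format(x$params$emission$excess_relative_variance, digits = 3), "\n")
  }
  invisible(x)
}

trace_values <- function(trace) {
  if (is.data.frame(trace)) {
    if ("trace" %in% names(trace) && length(unique(trace$trace)) > 1) {
      stop("`trace` contains several traces; fit them one at a time",
           call. = FALSE)
    }
    o <- order(trace$frame)
    v <- trace$value[o]
    if (!identical(as.integer(trace$frame[o]), seq_along(v))) {
      stop("trace frames must be 1..N without gaps", call. = FALSE)
    }
    v
  } else as.numeric(trace)
}

# Data-driven initialization: the late-trace blink level estimates the
# single-fluorophore brightness E(Y) directly (late blinking is sparse, so
# above-threshold frames carry mostly one bright fluorophore), the first
# frame then gives m. Blink detection reuses the mu + 3s rule with the
# known residual noise level; "anchored" reports whether enough blink
# frames existed for the estimate to be trustworthy.
default_init_params <- function(y, chain_template, f2, noise_sd = 0) {
  N <- length(y)
  s <- if (noise_sd > 0) noise_sd else {
    tail_part <- y[max(1, floor(N / 2)):N]
    max(stats::mad(tail_part), 1e-9)
  }
  # search progressively earlier windows until enough blink frames exist;
  # the latest retained frames are the least likely to hold two
  # simultaneously bright fluorophores
  anchored <- FALSE
  EY0 <- NA_real_
  for (min_frame in unique(pmin(c(floor(N / 3), 100L, 20L), N - 1L))) {
    bf <- detect_blink_frames(y, list(mu = 0, s = s),
                              min_frame = min_frame)
    if (length(bf$frames) >= 5) {
      vals <- y[utils::tail(bf$frames, 80)]
      # density mode: robust against frames holding two bright fluorophores
      EY0 <- if (length(vals) >= 10) {
        d <- stats::density(vals, bw = "nrd0")
        d$x[which.max(d$y)]
      } else stats::median(vals)
      anchored <- TRUE
      break
    }
  }
  if (!anchored) {
    EY0 <- max(y[-seq_len(min(5, N - 1))], s) / 1.5
  }
  EY0 <- max(EY0, 1e-6)
  m0 <- min(max(y[1] / EY0, 0.5), 1e3)
  p <- htmm_params(m0, chain_template, emission_model(EY0, 0.1, f2))
  attr(p, "anchored") <- anchored
  p
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# theta layout: log m, log EY, log s2 (if free), mlogit bright-row exits
# (ns - 1), logit dark returns (ns - 2)
params_to_theta <- function(params, fixed_s2) {
  T <- params$chain$transition_matrix
  ns <- nrow(T)
  exits <- pmin(pmax(T[1, -1], 1e-10), 1 - 1e-10)
  stay <- max(1 - sum(exits), 1e-10)
  th <- c(log(params$m), log(params$emission$mean_bright_signal))
  if (is.null(fixed_s2)) {
    th <- c(th, log(max(params$emission$excess_relative_variance, 1e-6)))
  }
  th <- c(th, log(exits / stay))
  if (ns > 2) {
    ret <- vapply(2:(ns - 1), function(i) T[i, 1], numeric(1))
    th <- c(th, logit(pmin(pmax(ret, 1e-10), 1 - 1e-10)))
  }
  unname(th)
}

theta_to_params <- function(theta, chain_template, f2, fixed_s2) {
  ns <- chain_template$num_states
  i <- 1L
  m <- exp(theta[i]); i <- i + 1L
  EY <- exp(theta[i]); i <- i + 1L
  s2 <- if (is.null(fixed_s2)) {
    v <- exp(theta[i]); i <- i + 1L; v
  } else fixed_s2
  z <- theta[i:(i + ns - 2L)]; i <- i + ns - 1L
  ez <- exp(z - max(z, 0))
  denom <- exp(-max(z, 0)) + sum(ez)
  exits <- ez / denom
  T <- matrix(0, ns, ns)
  T[1, 1] <- 1 - sum(exits)
  T[1, -1] <- exits
  if (ns > 2) {
    ret <- inv_logit(theta[i:(i + ns - 3L)])
    for (k in 2:(ns - 1)) {
      T[k, 1] <- ret[k - 1L]
      T[k, k] <- 1 - ret[k - 1L]
    }
  }
  T[ns, ns] <- 1
  list(m = m, EY = EY, s2 = s2, T = T)
}
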