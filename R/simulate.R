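#' Simulation configuration
#'
#' Collects everything needed to generate synthetic traces or camera movies:
#' the model parameters, recording length, camera gain and read noise, the
#' planted polynomial background, and the optical/geometric constants of the
#' emulated protocol (15 ms exposure, 7 x 7 pixel evaluation regions).
#'
#' @param params An [htmm_params()].
#' @param n_frames Number of recorded frames (>= 1).
#' @param em_gain EM register gain in detector units per photoelectron.
#' @param background_coefficients Either `NULL` (no background), a length-10
#'   numeric vector of polynomial coefficients `a1..a10` (see
#'   [fit_polynomial_background()] for the basis order) used for every frame,
#'   or a function `f(t)` returning the length-10 vector for frame `t`.
#' @param background_offset Region-specific additive offset `mu` planted on
#'   extracted region traces (detector units).
#' @param psf_sigma Gaussian spot width in pixels (movie mode).
#' @param region_size Odd integer edge length of the evaluation region.
#' @param image_size Integer vector `c(height, width)` for movie mode.
#' @param frame_exposure Exposure time in seconds (metadata only; sub-frame
#'   dynamics are already summarized by the emission model).
#' @param read_noise_sd Additive Gaussian camera noise, detector units per
#'   trace value (trace mode) or per pixel (movie mode).
#' @param background_noise `"none"` for exact planted backgrounds or
#'   `"poisson"` for shot noise (EM-amplified when `f^2 = 2`) on background
#'   pixels in movie mode.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(params, n_frames,
                       em_gain = 100,
                       background_coefficients = NULL,
                       background_offset = 0,
                       psf_sigma = 1.2,
                       region_size = 7,
                       image_size = c(64, 64),
                       frame_exposure = 0.015,
                       read_noise_sd = 0,
                       background_noise = c("none", "poisson"),
                       seed = NULL) {
  stopifnot(inherits(params, "htmm_params"),
            n_frames >= 1, psf_sigma > 0, em_gain > 0,
            region_size %% 2 == 1, read_noise_sd >= 0)
  background_noise <- match.arg(background_noise)
  structure(list(params = params, n_frames = as.integer(n_frames),
                 em_gain = em_gain,
                 background_coefficients = background_coefficients,
                 background_offset = background_offset,
                 psf_sigma = psf_sigma,
                 region_size = as.integer(region_size),
                 image_size = as.integer(image_size),
                 frame_exposure = frame_exposure,
                 read_noise_sd = read_noise_sd,
                 background_noise = background_noise,
                 seed = seed),
            class = "sim_config")
}

#' Simulate slow-state paths of independent fluorophores
#'
#' Draws start-of-frame states for `m` independent fluorophores over
#' `n_frames` frames. Each fluorophore starts bright with probability `nu`
#' (otherwise in the configured dark start state) and then follows the
#' chain's per-frame transition probabilities; the bleached state is never
#' left.
#'
#' @param chain An [ltm_chain()].
#' @param m Number of fluorophores (>= 0).
#' @param n_frames Number of frames.
#' @param seed Optional integer seed.
#' @return A tibble with columns `fluorophore`, `frame`, `state` (integer
#'   state index, 1 = bright) — empty when `m = 0`. The underlying
#'   `m x n_frames` integer matrix is available via `attr(, "state_matrix")`.
#' @export
simulate_state_paths <- function(chain, m, n_frames, seed = NULL) {
  stopifnot(inherits(chain, "ltm_chain"), m >= 0, n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  S <- draw_state_matrix(chain, as.integer(m), as.integer(n_frames))
  tb <- if (m == 0) {
    tibble::tibble(fluorophore = integer(0), frame = integer(0),
                   state = integer(0))
  } else {
    tibble::tibble(
      fluorophore = rep(seq_len(m), times = n_frames),
      frame = rep(seq_len(n_frames), each = m),
      state = as.integer(S))
  }
  attr(tb, "state_matrix") <- S
  attr(tb, "state_labels") <- chain$state_labels
  tb
}

# m x n_frames integer matrix of start-of-frame states; vectorized over
# molecules, sequential over frames
draw_state_matrix <- function(chain, m, n_frames) {
  ns <- chain$num_states
  Tcum <- t(apply(chain$transition_matrix, 1, cumsum))
  S <- matrix(0L, m, n_frames)
  if (m == 0L) return(S)
  nu <- chain$initial_bright_fraction
  s <- ifelse(stats::runif(m) < nu, 1L, chain$dark_start_state)
  S[, 1] <- s
  if (n_frames >= 2L) {
    for (t in 2:n_frames) {
      u <- stats::runif(m)
      # row-specific inverse-CDF draw
      s <- apply_transition(s, u, Tcum, ns)
      S[, t] <- s
    }
  }
  S
}

apply_transition <- function(s, u, Tcum, ns) {
  new <- integer(length(s))
  for (k in seq_len(ns)) {
    idx <- which(s == k)
    if (length(idx)) {
      new[idx] <- findInterval(u[idx], Tcum[k, ], left.open = TRUE) + 1L
    }
  }
  new
}

# Per-bright-frame signal draws in gain-normalized detector units.
# Photon count: Poisson mixed with a gamma rate (shape 1/sigma_e^2,
# scale sigma_e^2 * E(Y)), so Var(N) = E(Y) + sigma_e^2 E(Y)^2.
# EM register (f^2 = 2): output | N ~ Gamma(shape N, scale gain) / gain,
# which doubles the Poisson part of the variance. f^2 = 1 skips the
# register.
draw_bright_signals <- function(n, emission, em_gain) {
  if (n == 0L) return(numeric(0))
  EY <- emission$mean_bright_signal
  s2 <- emission$excess_relative_variance
  f2 <- emission$camera_excess_noise
  if (!isTRUE(all.equal(f2, 1)) && !isTRUE(all.equal(f2, 2))) {
    stop("the simulator realizes camera excess noise f^2 = 1 (no EM ",
         "register) or f^2 = 2 (EM register); got f^2 = ", f2,
         call. = FALSE)
  }
  lam <- if (s2 > 0) {
    stats::rgamma(n, shape = 1 / s2, scale = s2 * EY)
  } else rep(EY, n)
  N <- stats::rpois(n, lam)
  if (isTRUE(all.equal(f2, 2))) {
    out <- numeric(n)
    pos <- N > 0L
    out[pos] <- stats::rgamma(sum(pos), shape = N[pos],
                              scale = em_gain) / em_gain
    out
  } else {
    as.numeric(N)
  }
}

#' Simulate background-corrected intensity traces
#'
#' Generates `n_traces` independent per-region traces from the two-timescale
#' model: each fluorophore that starts a frame bright contributes one draw of
#' the bright-frame emission model (overdispersed photon count passed through
#' the EM register), and contributes nothing otherwise. Optional additive
#' Gaussian read noise emulates the residual background fluctuation of a
#' corrected trace. Means, variances and lag covariances of the resulting
#' ensembles match [mean_trace()], [variance_trace()] and
#' [covariance_matrix()].
#'
#' @param params An [htmm_params()] (its `m` is the per-trace fluorophore
#'   number).
#' @param n_frames Frames per trace.
#' @param n_traces Number of independent traces.
#' @param em_gain EM gain (detector units per photoelectron).
#' @param read_noise_sd Additive Gaussian noise sd per frame value, default 0.
#' @param seed Optional integer seed; with a fixed seed the output is
#'   reproducible bit for bit.
#' @param format `"tibble"` for a tidy `trace_set` (columns `trace`, `frame`,
#'   `value`), `"matrix"` for an `n_traces x n_frames` matrix (large
#'   ensembles).
#' @return A `trace_set` tibble or a matrix, with ground truth in attributes.
#' @export
#' @examples
#' pars <- htmm_params(1, alexa647_chain(), emission_model(1000, 0.097, 2))
#' ts <- simulate_traces(pars, n_frames = 50, n_traces = 3, seed = 1)
#' head(ts)
simulate_traces <- function(params, n_frames, n_traces = 1,
                            em_gain = 100, read_noise_sd = 0, seed = NULL,
                            format = c("tibble", "matrix")) {
  stopifnot(inherits(params, "htmm_params"), n_frames >= 1, n_traces >= 1)
  format <- match.arg(format)
  if (!is.null(seed)) set.seed(seed)
  n_frames <- as.integer(n_frames)
  n_traces <- as.integer(n_traces)
  m <- as.integer(round(params$m))
  Y <- matrix(0, n_traces, n_frames)
  if (m > 0L) {
    S <- draw_state_matrix(params$chain, m * n_traces, n_frames)
    bright <- which(S == 1L)
    v <- draw_bright_signals(length(bright), params$emission, em_gain)
    V <- matrix(0, m * n_traces, n_frames)
    V[bright] <- v
    Y <- rowsum(V, group = rep(seq_len(n_traces), each = m))
  }
  if (read_noise_sd > 0) {
    Y <- Y + matrix(stats::rnorm(length(Y), sd = read_noise_sd),
                    nrow(Y), ncol(Y))
  }
  dimnames(Y) <- NULL
  if (format == "matrix") {
    attr(Y, "params") <- params
    return(Y)
  }
  ts <- tibble::tibble(
    trace = rep(seq_len(n_traces), each = n_frames),
    frame = rep(seq_len(n_frames), times = n_traces),
    value = as.vector(t(Y)))
  new_trace_set(ts,
                ground_truth = tibble::tibble(trace = seq_len(n_traces),
                                              m = params$m),
                params = params)
}

#' Simulate one trace from a configuration
#'
#' Thin wrapper around [simulate_traces()] driven by a [sim_config()]; adds
#' the configured region offset `mu` to every frame so that the trace is
#' "raw" with respect to the offset calibration step.
#'
#' @param config A [sim_config()].
#' @return A single-trace `trace_set` tibble.
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ts <- simulate_traces(config$params, config$n_frames, n_traces = 1,
                        em_gain = config$em_gain,
                        read_noise_sd = config$read_noise_sd,
                        seed = config$seed)
  if (config$background_offset != 0) {
    ts$value <- ts$value + config$background_offset
  }
  ts
}

# trace_set constructor: tidy table of traces plus ground-truth attributes
new_trace_set <- function(tb, ground_truth = NULL, params = NULL) {
  stopifnot(all(c("trace", "frame", "value") %in% names(tb)))
  structure(tb, ground_truth = ground_truth, params = params,
            class = c("trace_set", class(tb)))
}

#' Simulate a synthetic camera movie
#'
#' Renders a frame stack consisting of a planted time-dependent cubic
#' polynomial background, fluorophore spots drawn as normalized 2-D Gaussians
#' carrying the per-frame signals of [simulate_traces()], optional background
#' shot noise and Gaussian read noise. Ground truth (emitter positions,
#' per-emitter state paths, background coefficients) is stored for
#' end-to-end validation of the background correction.
#'
#' Coordinates are 0-based pixel centers: `x` runs over columns, `y` over
#' rows, both starting at 0.
#'
#' @param config A [sim_config()]; `image_size`, `psf_sigma`,
#'   `background_coefficients` and the noise settings are honored.
#' @param emitters A data frame with columns `x`, `y` (subpixel positions)
#'   and optionally `m` (fluorophores per emitter, default the `m` of
#'   `config$params`).
#' @return An object of class `synthetic_movie`: list with `frames`
#'   (`height x width x n_frames` array, detector units), `emitter_positions`,
#'   `true_background` (`n_frames x 10` coefficient matrix, or NULL),
#'   `ground_truth` (per-emitter trace matrix), and the `config`.
#' @export
simulate_movie <- function(config, emitters = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  H <- config$image_size[1]; W <- config$image_size[2]
  nf <- config$n_frames
  if (is.null(emitters)) {
    emitters <- tibble::tibble(x = numeric(0), y = numeric(0),
                               m = numeric(0))
  }
  emitters <- tibble::as_tibble(emitters)
  if (!"m" %in% names(emitters)) emitters$m <- config$params$m
  if (nrow(emitters) > 0 &&
      (any(emitters$x < 0) || any(emitters$x > W - 1) ||
       any(emitters$y < 0) || any(emitters$y > H - 1))) {
    stop("emitter positions must lie inside the image", call. = FALSE)
  }
  # planted background coefficients per frame
  bg_coef <- NULL
  if (!is.null(config$background_coefficients)) {
    bg_coef <- matrix(0, nf, 10)
    for (t in seq_len(nf)) {
      bg_coef[t, ] <- if (is.function(config$background_coefficients)) {
        config$background_coefficients(t)
      } else config$background_coefficients
    }
  }
  xs <- rep(0:(W - 1), each = H)   # column-major grids, 0-based centers
  ys <- rep(0:(H - 1), times = W)
  basis <- poly_background_basis(xs, ys)
  frames <- array(0, dim = c(H, W, nf))
  # per-emitter per-frame signals
  gt <- NULL
  if (nrow(emitters) > 0) {
    sig <- matrix(0, nrow(emitters), nf)
    for (e in seq_len(nrow(emitters))) {
      pe <- htmm_params(emitters$m[e], config$params$chain,
                        config$params$emission)
      sig[e, ] <- simulate_traces(pe, nf, n_traces = 1,
                                  em_gain = config$em_gain,
                                  format = "matrix")[1, ]
    }
    gt <- sig
    kernels <- lapply(seq_len(nrow(emitters)), function(e) {
      k <- matrix(stats::dnorm(xs, emitters$x[e], config$psf_sigma) *
                    stats::dnorm(ys, emitters$y[e], config$psf_sigma),
                  H, W)
      k / sum(k)  # exact normalization over the finite image
    })
  }
  for (t in seq_len(nf)) {
    img <- matrix(0, H, W)
    if (!is.null(bg_coef)) {
      img <- img + matrix(basis %*% bg_coef[t, ], H, W)
      if (config$background_noise == "poisson") {
        n_pe <- stats::rpois(length(img), pmax(img, 0))
        amp <- numeric(length(n_pe))
        pos <- n_pe > 0L
        if (isTRUE(all.equal(config$params$emission$camera_excess_noise, 2))) {
          amp[pos] <- stats::rgamma(sum(pos), shape = n_pe[pos],
                                    scale = config$em_gain) / config$em_gain
        } else amp[pos] <- n_pe[pos]
        img <- matrix(amp, H, W)
      }
    }
    if (nrow(emitters) > 0) {
      for (e in seq_len(nrow(emitters))) {
        if (gt[e, t] > 0) img <- img + gt[e, t] * kernels[[e]]
      }
    }
    if (config$read_noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img),
                                       sd = config$read_noise_sd), H, W)
    }
    frames[, , t] <- img
  }
  structure(list(frames = frames,
                 emitter_positions = emitters,
                 true_background = bg_coef,
                 ground_truth = gt,
                 config = config),
            class = "synthetic_movie")
}

#' Extract a region intensity trace from a movie
#'
#' Sums pixel values over a square evaluation region centered on a pixel for
#' every frame — the raw per-region signal the background correction and
#' estimators operate on.
#'
#' @param movie A `synthetic_movie` or a `height x width x n_frames` array.
#' @param center Numeric `c(x, y)` pixel coordinates (0-based) of the region
#'   center.
#' @param region_size Odd integer edge length (default 7).
#' @return A tibble with columns `frame`, `value`.
#' @export
extract_region_trace <- function(movie, center, region_size = 7) {
  frames <- if (inherits(movie, "synthetic_movie")) movie$frames else movie
  stopifnot(length(dim(frames)) == 3, region_size %% 2 == 1,
            length(center) == 2)
  H <- dim(frames)[1]; W <- dim(frames)[2]
  half <- (region_size - 1) / 2
  cx <- round(center[1]); cy <- round(center[2])
  x0 <- cx - half; x1 <- cx + half
  y0 <- cy - half; y1 <- cy + half
  if (x0 < 0 || y0 < 0 || x1 > W - 1 || y1 > H - 1) {
    stop("evaluation region clipped by the image edge", call. = FALSE)
  }
  sub <- frames[(y0:y1) + 1L, (x0:x1) + 1L, , drop = FALSE]
  tibble::tibble(frame = seq_len(dim(frames)[3]),
                 value = apply(sub, 3, sum))
}

#' Pixel indices of a square region
#'
#' @param center `c(x, y)` 0-based center.
#' @param region_size Odd edge length.
#' @return A tibble of 0-based `x`, `y` pixel coordinates in the region.
#' @export
region_pixels <- function(center, region_size = 7) {
  half <- (region_size - 1) / 2
  cx <- round(center[1]); cy <- round(center[2])
  g <- expand.grid(x = (cx - half):(cx + half),
                   y = (cy - half):(cy + half))
  tibble::as_tibble(g)
}
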