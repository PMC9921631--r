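#' Bright-frame emission model
#'
#' Summarizes the sub-frame (short-timescale) photophysics and the camera by
#' the first two moments of the background-corrected signal `Y` a single
#' fluorophore produces in one frame, given it starts that frame bright:
#' mean `E(Y)` and excess relative variance
#' `sigma_e^2 = Var(Y) / E(Y)^2 - 1 / E(Y)`, plus the excess noise factor
#' `f^2` of the electron-multiplying camera register (2 for an EMCCD, 1 for
#' an ideal photon counter).
#'
#' @param mean_bright_signal `E(Y)` in detector units, > 0.
#' @param excess_relative_variance `sigma_e^2`, dimensionless; 0 for a purely
#'   Poissonian emitter; must satisfy `sigma_e^2 >= -1 / E(Y)`.
#' @param camera_excess_noise `f^2 >= 1`.
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(mean_bright_signal,
                           excess_relative_variance = 0,
                           camera_excess_noise = 2) {
  EY <- mean_bright_signal
  s2 <- excess_relative_variance
  f2 <- camera_excess_noise
  stopifnot(is.numeric(EY), length(EY) == 1L, EY > 0,
            is.numeric(s2), length(s2) == 1L,
            is.numeric(f2), length(f2) == 1L, f2 >= 1)
  if (s2 < -1 / EY) {
    stop("`excess_relative_variance` below the Poisson bound -1/E(Y); ",
         "implied Var(Y) would be negative", call. = FALSE)
  }
  structure(list(mean_bright_signal = EY,
                 excess_relative_variance = s2,
                 camera_excess_noise = f2),
            class = "emission_model")
}

#' @export
print.emission_model <- function(x, ...) {
  cat("<emission_model> E(Y) =", x$mean_bright_signal,
      " sigma_e^2 =", x$excess_relative_variance,
      " f^2 =", x$camera_excess_noise, "\n")
  invisible(x)
}

#' Full parameter set of the two-timescale counting model
#'
#' Bundles the fluorophore number `m`, the long-timescale chain and the
#' bright-frame emission model into the parameter vector over which the
#' pseudo log-likelihood is maximized. `m` is treated as a positive real
#' during optimization; integer counts are a reporting convention.
#'
#' @param m Fluorophore number, > 0 (0 is allowed for degenerate/simulation
#'   use).
#' @param chain An [ltm_chain()].
#' @param emission An [emission_model()].
#' @return An object of class `htmm_params`.
#' @export
#' @examples
#' pars <- htmm_params(m = 6, chain = alexa647_chain(),
#'                     emission = emission_model(1000, 0.097, 2))
#' mean_trace(pars, 1:5)
htmm_params <- function(m, chain, emission) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 0,
            inherits(chain, "ltm_chain"),
            inherits(emission, "emission_model"))
  structure(list(m = m, chain = chain, emission = emission),
            class = "htmm_params")
}

#' @export
print.htmm_params <- function(x, ...) {
  cat("<htmm_params> m =", x$m, "\n")
  print(x$emission)
  print(x$chain)
  invisible(x)
}

#' @export
spectral_decomposition.htmm_params <- function(x, ...) {
  sf <- spectral_decomposition(x$chain)
  sf$amplitudes <- x$m * x$emission$mean_bright_signal *
    sf$coefficients_bright
  sf
}

#' Expected background-corrected signal per frame
#'
#' `E(Y_t) = m * E(Y) * p_t` where `p_t` is the bright occupancy at frame
#' `t`. With all fluorophores starting bright (`nu = 1`) the first frame has
#' mean exactly `m * E(Y)` — the identity the counting estimators exploit.
#'
#' @param params An [htmm_params()].
#' @param frames Vector of frame indices (>= 1).
#' @return Numeric vector of expected signals (detector units).
#' @export
mean_trace <- function(params, frames) {
  stopifnot(inherits(params, "htmm_params"))
  if (length(frames) == 0L) return(numeric(0))
  params$m * params$emission$mean_bright_signal *
    bright_occupancy(params$chain, frames)
}

#' Variance of the background-corrected signal per frame
#'
#' Implements the single-frame variance of the two-timescale model:
#' `Var(Y_t) = ((sigma_e^2 + 1) E(Y) + f^2 - E(Y_t) / m) * E(Y_t)`.
#' The three contributions are fluorophore-intrinsic overdispersion, camera
#' excess noise, and the binomial occupancy fluctuation of `m` independent
#' fluorophores (which vanishes as `m -> Inf` at fixed `E(Y_t)/m`).
#'
#' @inheritParams mean_trace
#' @return Numeric vector of variances (detector units squared).
#' @export
variance_trace <- function(params, frames) {
  stopifnot(inherits(params, "htmm_params"))
  if (length(frames) == 0L) return(numeric(0))
  if (params$m == 0) return(rep(0, length(frames)))
  em <- params$emission
  mu_t <- mean_trace(params, frames)
  ((em$excess_relative_variance + 1) * em$mean_bright_signal +
      em$camera_excess_noise - mu_t / params$m) * mu_t
}

#' Temporal covariance matrix of a trace
#'
#' Builds the covariance of the signal over a set of frames. Diagonal
#' entries follow [variance_trace()]. Off-diagonal entries treat per-frame
#' emissions as conditionally independent given the slow state path, which
#' gives, for frames `t < t'`,
#' `Cov = m * E(Y)^2 * (g_tt' - p_t * p_t')` with the joint bright
#' probability `g_tt' = p_t * (T^(t'-t))[bright, bright]`.
#'
#' @param params An [htmm_params()].
#' @param frames Strictly increasing vector of frame indices.
#' @return Symmetric positive semi-definite matrix of size
#'   `length(frames)` squared.
#' @export
covariance_matrix <- function(params, frames) {
  stopifnot(inherits(params, "htmm_params"))
  n <- length(frames)
  if (n == 0L) return(matrix(0, 0, 0))
  if (any(frames < 1) || any(frames != floor(frames))) {
    stop("`frames` must be integers >= 1", call. = FALSE)
  }
  if (n > 1L && any(diff(frames) <= 0)) {
    stop("`frames` must be strictly increasing", call. = FALSE)
  }
  if (params$m == 0) return(matrix(0, n, n))
  ch <- params$chain
  em <- params$emission
  EY <- em$mean_bright_signal
  p <- occupancy_path(ch, max(frames))[frames]
  # h(d) = (T^d)[bright, bright] for all lags d appearing between frames
  dmax <- max(frames) - min(frames)
  h <- bright_return_path(ch, dmax)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i < n) {
      j <- (i + 1L):n
      d <- frames[j] - frames[i]
      S[i, j] <- params$m * EY^2 * (p[i] * h[d + 1L] - p[i] * p[j])
      S[j, i] <- S[i, j]
    }
  }
  diag(S) <- variance_trace(params, frames)
  S
}

# (T^d)[bright, bright] for d = 0..d_max, returned as vector of length
# d_max + 1 (index d + 1)
bright_return_path <- function(chain, d_max) {
  T <- chain$transition_matrix
  v <- numeric(chain$num_states)
  v[1] <- 1
  out <- numeric(d_max + 1L)
  out[1] <- 1
  if (d_max >= 1L) {
    for (d in seq_len(d_max)) {
      v <- as.vector(v %*% T)
      out[d + 1L] <- v[1]
    }
  }
  out
}
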