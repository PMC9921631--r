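#' Long-timescale photoswitching chain
#'
#' Defines the frame-to-frame Markov chain of one fluorophore's slow
#' photophysical states: one bright state, `r - 1` reversible dark states and
#' one absorbing bleached state. The chain operates on the camera's frame
#' grid: entry `T[i, j]` is the probability that a fluorophore starting a
#' frame in state `i` starts the next frame in state `j`.
#'
#' @param transition_matrix Square numeric matrix of per-frame transition
#'   probabilities. Row/column 1 is the bright state; the last row/column is
#'   the bleached state, which must be absorbing. Rows must sum to 1.
#' @param state_labels Optional character vector of state names. Defaults to
#'   `"bright"`, `"DL1"`, ..., `"BL"`.
#' @param initial_bright_fraction Probability `nu` in `[0, 1]` that a
#'   fluorophore starts frame 1 in the bright state. The recording protocol
#'   modeled here drives all fluorophores bright before acquisition, so the
#'   default is 1.
#' @param dark_start_state Index of the dark state receiving the `1 - nu`
#'   initial mass when `nu < 1`. Defaults to the last non-bleached dark state
#'   (the long-lived one).
#'
#' @return An object of class `ltm_chain`.
#' @export
#' @examples
#' ch <- two_state_chain(q_bleach = 0.1)
#' bright_occupancy(ch, 1:5)
ltm_chain <- function(transition_matrix, state_labels = NULL,
                      initial_bright_fraction = 1, dark_start_state = NULL) {
  T <- as.matrix(transition_matrix)
  ns <- nrow(T)
  if (ns < 2L || ncol(T) != ns) {
    stop("`transition_matrix` must be square with at least 2 states ",
         "(bright + bleached)", call. = FALSE)
  }
  if (any(T < -1e-12) || any(T > 1 + 1e-12)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(T)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("every row of `transition_matrix` must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  if (abs(T[ns, ns] - 1) > 1e-12) {
    stop("the bleached state (last row) must be absorbing", call. = FALSE)
  }
  nu <- initial_bright_fraction
  if (!is.numeric(nu) || length(nu) != 1L || nu < 0 || nu > 1) {
    stop("`initial_bright_fraction` must be a single value in [0, 1]",
         call. = FALSE)
  }
  if (is.null(state_labels)) {
    state_labels <- if (ns == 2L) c("bright", "BL") else
      c("bright", paste0("DL", seq_len(ns - 2L)), "BL")
  }
  if (is.null(dark_start_state)) {
    dark_start_state <- max(2L, ns - 1L)
  }
  dark_start_state <- as.integer(dark_start_state)
  if (dark_start_state < 2L || dark_start_state > ns) {
    stop("`dark_start_state` must index a dark state (2..", ns, ")",
         call. = FALSE)
  }
  dimnames(T) <- list(state_labels, state_labels)
  structure(
    list(transition_matrix = T,
         num_states = ns,
         state_labels = state_labels,
         initial_bright_fraction = nu,
         dark_start_state = dark_start_state),
    class = "ltm_chain")
}

#' @export
print.ltm_chain <- function(x, ...) {
  cat("<ltm_chain> ", x$num_states, " states (",
      paste(x$state_labels, collapse = ", "), "), nu = ",
      x$initial_bright_fraction, "\n", sep = "")
  print(round(x$transition_matrix, 6))
  invisible(x)
}

#' Number of dark states (incl. bleached) of a chain
#' @param chain An [ltm_chain()].
#' @return Integer `r`, the number of non-bright states.
#' @export
n_dark_states <- function(chain) {
  stopifnot(inherits(chain, "ltm_chain"))
  chain$num_states - 1L
}

#' Two-state bright/bleached chain
#'
#' Minimal chain in which the bright state decays irreversibly into the
#' bleached state; bright occupancy is a single geometric decay.
#'
#' @param q_bleach Per-frame probability of bleaching from the bright state.
#' @param initial_bright_fraction See [ltm_chain()].
#' @return An [ltm_chain()] with 2 states.
#' @export
two_state_chain <- function(q_bleach, initial_bright_fraction = 1) {
  stopifnot(q_bleach >= 0, q_bleach <= 1)
  ltm_chain(matrix(c(1 - q_bleach, q_bleach, 0, 1), 2, 2, byrow = TRUE),
            initial_bright_fraction = initial_bright_fraction)
}

#' Bright / single reversible dark / bleached chain
#'
#' Three-state chain with one reversible dark state, useful as the
#' single-dark-state null model in dwell-time analyses.
#'
#' @param p_bright_dark,p_bright_bleach Exit probabilities per frame from the
#'   bright state into the dark and bleached states.
#' @param p_dark_bright Per-frame return probability dark -> bright.
#' @param initial_bright_fraction See [ltm_chain()].
#' @return An [ltm_chain()] with 3 states.
#' @export
single_dark_chain <- function(p_bright_dark = 0.05, p_bright_bleach = 0.005,
                              p_dark_bright = 0.02,
                              initial_bright_fraction = 1) {
  T <- matrix(0, 3, 3)
  T[1, ] <- c(1 - p_bright_dark - p_bright_bleach, p_bright_dark,
              p_bright_bleach)
  T[2, ] <- c(p_dark_bright, 1 - p_dark_bright, 0)
  T[3, 3] <- 1
  ltm_chain(T, initial_bright_fraction = initial_bright_fraction)
}

#' Four-state Alexa-647-style chain
#'
#' Default long-timescale model for Alexa 647 in a thiol-containing imaging
#' buffer: bright, a triplet-like dark state DL1, a long-lived (thiol-adduct)
#' dark state DL2, and the absorbing bleached state BL. Direct DL1 <-> DL2
#' transitions are fixed to zero. The default probabilities put the three
#' transient eigenvalues near (0.9, 0.999, 0.99999) — the timescales
#' characteristic of this dye at 15 ms exposure — and keep photobleaching
#' rare relative to switching (this dye survives on the order of a hundred
#' switching cycles in a reducing buffer), so single molecules keep blinking
#' far into a recording.
#'
#' @param p_bright_dl1,p_bright_dl2,p_bright_bl Per-frame exit probabilities
#'   from the bright state.
#' @param p_dl1_bright,p_dl2_bright Per-frame return probabilities from the
#'   dark states.
#' @param initial_bright_fraction See [ltm_chain()]; the UV pre-activation
#'   protocol justifies the default of 1.
#' @return An [ltm_chain()] with 4 states.
#' @export
#' @examples
#' spectral_decomposition(alexa647_chain())$eigenvalues
alexa647_chain <- function(p_bright_dl1 = 0.092, p_bright_dl2 = 0.003,
                           p_bright_bl = 0.005, p_dl1_bright = 8e-4,
                           p_dl2_bright = 1e-5,
                           initial_bright_fraction = 1) {
  stopifnot(p_bright_dl1 + p_bright_dl2 + p_bright_bl <= 1)
  T <- matrix(0, 4, 4)
  T[1, ] <- c(1 - p_bright_dl1 - p_bright_dl2 - p_bright_bl,
              p_bright_dl1, p_bright_dl2, p_bright_bl)
  T[2, ] <- c(p_dl1_bright, 1 - p_dl1_bright, 0, 0)
  T[3, ] <- c(p_dl2_bright, 0, 1 - p_dl2_bright, 0)
  T[4, 4] <- 1
  ltm_chain(T, state_labels = c("bright", "DL1", "DL2", "BL"),
            initial_bright_fraction = initial_bright_fraction)
}

# initial state distribution implied by nu and the dark-start convention
initial_distribution <- function(chain) {
  p0 <- numeric(chain$num_states)
  p0[1] <- chain$initial_bright_fraction
  p0[chain$dark_start_state] <- p0[chain$dark_start_state] +
    1 - chain$initial_bright_fraction
  p0
}

#' Probability of starting a frame in the bright state
#'
#' Propagates the initial state distribution through the chain and returns
#' the bright-state occupancy at the start of each requested frame. Frames
#' are 1-based: `bright_occupancy(chain, 1)` equals the initial bright
#' fraction `nu`.
#'
#' @param chain An [ltm_chain()].
#' @param t Vector of frame indices (integers >= 1).
#' @return Numeric vector of occupancy probabilities, same length as `t`.
#' @export
bright_occupancy <- function(chain, t) {
  stopifnot(inherits(chain, "ltm_chain"))
  if (length(t) == 0L) return(numeric(0))
  if (any(t < 1) || any(t != floor(t))) {
    stop("frame indices `t` must be integers >= 1", call. = FALSE)
  }
  occ <- occupancy_path(chain, max(t))
  occ[t]
}

# bright occupancy at frames 1..t_max via iterated propagation
occupancy_path <- function(chain, t_max) {
  T <- chain$transition_matrix
  v <- initial_distribution(chain)
  out <- numeric(t_max)
  out[1] <- v[1]
  if (t_max >= 2) {
    for (i in 2:t_max) {
      v <- as.vector(v %*% T)
      out[i] <- v[1]
    }
  }
  out
}

#' Spectral (multi-exponential) form of the bright occupancy
#'
#' Diagonalizes the transition matrix and expresses the bright occupancy as a
#' superposition of exponentials,
#' `p_t = sum_k (nu * a0_k + (1 - nu) * a1_k) * lambda_k^(t-1)`,
#' over the `r` transient eigenvalues of the chain (the absorbing eigenvalue
#' 1 carries no bright weight and is dropped). For a full parameter set the
#' amplitudes `alpha_k = m * E(Y) * a0_k` of the expected trace are attached.
#'
#' Chains with complex or defective eigenstructure are rejected with a
#' diagnostic; all computations elsewhere fall back to matrix form, so such
#' chains remain usable for everything except this decomposition.
#'
#' @param x An [ltm_chain()] or [htmm_params()].
#' @param ... Unused.
#' @return An object of class `spectral_form`: a list with `eigenvalues`,
#'   `coefficients_bright` (`a0_k`), `coefficients_dark` (`a1_k`), and
#'   `amplitudes` (`alpha_k`; `NA` unless called on [htmm_params()]).
#' @export
#' @examples
#' sf <- spectral_decomposition(two_state_chain(0.1))
#' sf$eigenvalues  # 0.9
spectral_decomposition <- function(x, ...) UseMethod("spectral_decomposition")

#' @export
spectral_decomposition.ltm_chain <- function(x, ...) {
  T <- x$transition_matrix
  ns <- x$num_states
  eg <- eigen(T)
  vals <- eg$values
  if (any(abs(Im(vals)) > 1e-10)) {
    bad <- vals[abs(Im(vals)) > 1e-10]
    stop("transition matrix has complex eigenvalues (",
         paste(format(bad, digits = 6), collapse = ", "),
         "); no real spectral form exists", call. = FALSE)
  }
  V <- Re(eg$vectors)
  if (rcond(V) < 1e-12) {
    stop("transition matrix is defective (eigenvector matrix numerically ",
         "singular); eigenvalues: ",
         paste(format(Re(vals), digits = 8), collapse = ", "), call. = FALSE)
  }
  Vinv <- solve(V)
  vals <- Re(vals)
  # coefficient of lambda_k^(t-1) in (T^(t-1))[i, bright] for start state i
  coef_from <- function(i) V[i, ] * Vinv[, 1]
  c_bright <- coef_from(1L)
  c_dark <- coef_from(x$dark_start_state)
  # drop the absorbing component(s): eigenvalue 1 with no bright weight
  absorbing <- abs(vals - 1) < 1e-12 &
    abs(c_bright) < 1e-9 & abs(c_dark) < 1e-9
  if (sum(!absorbing) != ns - 1L) {
    # keep exactly r components: drop the smallest-weight eigenvalue-1 entry
    cand <- which(abs(vals - 1) < 1e-12)
    drop <- cand[which.min(abs(c_bright[cand]) + abs(c_dark[cand]))]
    absorbing <- seq_len(ns) == drop
  }
  keep <- which(!absorbing)
  ord <- keep[order(vals[keep])]
  structure(
    list(eigenvalues = vals[ord],
         coefficients_bright = c_bright[ord],
         coefficients_dark = c_dark[ord],
         amplitudes = rep(NA_real_, length(ord)),
         initial_bright_fraction = x$initial_bright_fraction),
    class = "spectral_form")
}

#' @export
print.spectral_form <- function(x, ...) {
  cat("<spectral_form> ", length(x$eigenvalues), " components\n", sep = "")
  print(tibble::tibble(eigenvalue = x$eigenvalues,
                       coef_bright = x$coefficients_bright,
                       coef_dark = x$coefficients_dark,
                       amplitude = x$amplitudes))
  invisible(x)
}

#' Evaluate the bright occupancy from a spectral form
#'
#' @param spectral A `spectral_form`.
#' @param t Frame indices (>= 1).
#' @param initial_bright_fraction Override for `nu`; defaults to the value
#'   stored in the spectral form.
#' @return Occupancy probabilities at `t`.
#' @export
occupancy_from_spectral <- function(spectral, t,
                                    initial_bright_fraction = NULL) {
  stopifnot(inherits(spectral, "spectral_form"))
  nu <- initial_bright_fraction %||% spectral$initial_bright_fraction
  w <- nu * spectral$coefficients_bright +
    (1 - nu) * spectral$coefficients_dark
  vapply(t, function(ti) sum(w * spectral$eigenvalues^(ti - 1)), numeric(1))
}

#' Structure of the mean-trace model implied by a chain
#'
#' For a chain with `r` non-bright states the expected trace is a
#' superposition of `r` exponentials with amplitudes `alpha_k` and decay
#' factors `lambda_k`; together with the single-frame brightness `E(Y)` and
#' the fluorophore number `m` this gives `2r + 2` free parameters before the
#' normalization constraint `sum_k a0_k = 1` removes one.
#'
#' @param chain An [ltm_chain()].
#' @return A list with `n_components` and `n_parameters`.
#' @export
mean_model_structure <- function(chain) {
  stopifnot(inherits(chain, "ltm_chain"))
  r <- n_dark_states(chain)
  list(n_components = r, n_parameters = 2L * r + 2L)
}
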