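# shared builders for the test suite

alexa_emission <- function() emission_model(1000, 0.097, 2)

alexa_params <- function(m = 1) {
  htmm_params(m, alexa647_chain(), alexa_emission())
}

# chain whose bright state never empties (both bright and bleached absorbing)
frozen_bright_chain <- function() {
  ltm_chain(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
}

# Build a 4-state chain (DL1<->DL2 = 0) whose transient eigenvalues are
# exactly the requested lambdas, by matching the characteristic polynomial
# of the transient block: trace, principal 2x2 minors and determinant give
# one linear equation for the bright self-transition and a 2x2 linear
# system for the bright->dark probabilities.
chain_with_eigenvalues <- function(lambda, r1 = 1.5e-3, r2 = 1.5e-5) {
  stopifnot(length(lambda) == 3)
  c1 <- sum(lambda)
  c2 <- lambda[1] * lambda[2] + lambda[1] * lambda[3] +
    lambda[2] * lambda[3]
  c3 <- prod(lambda)
  x <- c1 - (1 - r1) - (1 - r2)
  A <- rbind(c(1, 1), c(1 - r2, 1 - r1))
  b <- c(x * (2 - r1 - r2) + (1 - r1) * (1 - r2) - c2,
         x * (1 - r1) * (1 - r2) - c3)
  uv <- solve(A, b)
  e1 <- uv[1] / r1
  e2 <- uv[2] / r2
  bl <- 1 - x - e1 - e2
  stopifnot(e1 >= 0, e2 >= 0, bl >= 0)
  alexa647_chain(p_bright_dl1 = e1, p_bright_dl2 = e2, p_bright_bl = bl,
                 p_dl1_bright = r1, p_dl2_bright = r2)
}

# memoized heavy computations shared between test files
.fc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fc_cache)) {
    assign(key, force(expr), envir = .fc_cache)
  }
  get(key, envir = .fc_cache)
}
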