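#' Frame-subsampling schedule for trace evaluation
#'
#' The estimator does not use every recorded frame: the first 20 frames are
#' kept densely (they carry most of the counting information, since all
#' fluorophores start bright) and later frames are thinned on a power-law
#' grid, `t_j = round(19 + (j - 19)^beta)` for `j > 20` with
#' `beta = log(N - 19) / log(n - 19)`, so that the last index lands exactly
#' on the final recorded frame. Non-integer values are rounded to the
#' nearest frame and duplicates are merged, which can make the schedule
#' slightly shorter than `n`.
#'
#' @param N Total number of recorded frames (protocol default 14060).
#' @param n Nominal schedule length (protocol default 4000), `>= 21`.
#' @return An object of class `subsample_schedule`: list with `N`, `n`,
#'   `beta` and the strictly increasing integer `indices`.
#' @export
#' @examples
#' sch <- build_subsample_schedule(14060, 4000)
#' head(sch$indices, 25)
#' utils::tail(sch$indices, 1)  # 14060
build_subsample_schedule <- function(N = 14060, n = 4000) {
  stopifnot(is.numeric(N), is.numeric(n), length(N) == 1, length(n) == 1)
  if (n < 21) stop("`n` must be at least 21", call. = FALSE)
  if (N < n) stop("`N` must be at least `n`", call. = FALSE)
  N <- as.integer(N); n <- as.integer(n)
  beta <- log(N - 19) / log(n - 19)
  j <- 21:n
  idx <- c(1:20, round(19 + (j - 19)^beta))
  idx <- unique(as.integer(idx))
  idx[length(idx)] <- N  # guard against last-index rounding drift
  structure(list(N = N, n = n, beta = beta, indices = idx),
            class = "subsample_schedule")
}

#' @export
print.subsample_schedule <- function(x, ...) {
  cat("<subsample_schedule> N =", x$N, " n =", x$n,
      " beta =", format(x$beta, digits = 6),
      " (", length(x$indices), "distinct frames )\n")
  invisible(x)
}
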