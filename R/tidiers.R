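#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted counting model
#'
#' @param x An `htmm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter (`term`,
#'   `estimate`).
#' @export
tidy.htmm_fit <- function(x, ...) {
  if (is.null(x$params)) {
    return(tibble::tibble(term = character(0), estimate = numeric(0)))
  }
  T <- x$params$chain$transition_matrix
  lab <- x$params$chain$state_labels
  ns <- nrow(T)
  terms <- c("m", "E_Y", "sigma_e2",
             paste0("p_", lab[1], "_", lab[-1]),
             if (ns > 2) paste0("p_", lab[2:(ns - 1)], "_", lab[1]))
  est <- c(x$m_hat, x$params$emission$mean_bright_signal,
           x$params$emission$excess_relative_variance,
           T[1, -1],
           if (ns > 2) T[cbind(2:(ns - 1), 1)])
  tibble::tibble(term = terms, estimate = unname(est))
}

#' Fit summary of a counting model
#'
#' @param x An `htmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `m_hat`, `m_int`, `m_from_amplitudes`,
#'   `logLik`, `convergence`, `n_frames_used`.
#' @export
glance.htmm_fit <- function(x, ...) {
  tibble::tibble(m_hat = x$m_hat, m_int = x$m_int,
                 m_from_amplitudes = x$m_from_amplitudes,
                 logLik = as.numeric(x$logLik),
                 convergence = x$convergence,
                 n_frames_used = length(x$schedule$indices))
}

#' @export
tidy.spectral_form <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 coef_bright = x$coefficients_bright,
                 coef_dark = x$coefficients_dark,
                 amplitude = x$amplitudes)
}

#' @export
tidy.multiexp_fit <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 amplitude = x$amplitudes,
                 eigenvalue = x$eigenvalues)
}

#' @export
glance.multiexp_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 weighted_rss = x$weighted_rss,
                 converged = isTRUE(x$converged))
}

#' @export
tidy.binomial_yield_fit <- function(x, ...) {
  tibble::tibble(term = "p", estimate = x$p_hat, std.error = x$se)
}

#' @export
glance.binomial_yield_fit <- function(x, ...) {
  tibble::tibble(p_hat = x$p_hat, se = x$se, n = x$n, logLik = x$logLik)
}

#' @export
tidy.dwell_time_fit <- function(x, ...) {
  dplyr::mutate(x$components, component = dplyr::row_number(),
                .before = 1)
}

#' @export
glance.dwell_time_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 n_intervals = length(x$dwell_times),
                 adequate = x$adequate)
}

#' @export
tidy.excess_variance_estimate <- function(x, ...) x$per_trace

#' @export
glance.excess_variance_estimate <- function(x, ...) {
  tibble::tibble(sigma_e2 = x$center, width = x$width, n_used = x$n_used)
}

#' Plot intensity traces
#'
#' @param object A `trace_set`.
#' @param max_traces Plot at most this many traces (facets).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trace_set <- function(object, max_traces = 6, ...) {
  ids <- utils::head(unique(object$trace), max_traces)
  d <- object[object$trace %in% ids, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$trace), scales = "free_y") +
    ggplot2::labs(x = "frame", y = "corrected signal (detector units)")
}

#' Plot a fitted counting model over its trace
#'
#' @param object An `htmm_fit`.
#' @param ... Unused.
#' @return A ggplot object: the schedule-frame data with the fitted
#'   expected trace overlaid.
#' @export
autoplot.htmm_fit <- function(object, ...) {
  stopifnot(!is.null(object$data), !is.null(object$params))
  d <- object$data
  d$fitted <- mean_trace(object$params, d$frame)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.4,
                        alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frame (log scale)", y = "signal (detector units)",
                  title = sprintf("m_hat = %.2f", object$m_hat))
}

#' Plot a labeling-yield fit
#'
#' @param object A `binomial_yield_fit`.
#' @param ... Unused.
#' @return A ggplot object: observed count histogram with the fitted
#'   conditional-binomial expectations.
#' @export
autoplot.binomial_yield_fit <- function(object, ...) {
  ggplot2::ggplot(object$pmf, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "steelblue",
                      alpha = 0.7) +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected), size = 2,
                        colour = "black") +
    ggplot2::labs(x = "fluorophores per structure", y = "structures",
                  title = sprintf("conditional binomial, p_hat = %.3f",
                                  object$p_hat))
}

#' Plot a dwell-time fit
#'
#' @param object A `dwell_time_fit`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dwell_time_fit <- function(object, bins = 30, ...) {
  d <- tibble::tibble(dwell = object$dwell_times)
  xs <- unique(round(seq(1, max(d$dwell), length.out = 200)))
  dens <- rowSums(vapply(seq_len(nrow(object$components)), function(k) {
    w <- object$components$weight[k]; r <- object$components$rate[k]
    w * r * (1 - r)^(xs - 1)
  }, numeric(length(xs))))
  fitd <- tibble::tibble(dwell = xs, density = dens)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dwell)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70") +
    ggplot2::geom_line(data = fitd,
                       ggplot2::aes(y = .data$density), colour = "red") +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "dark dwell time (frames)", y = "density",
                  title = sprintf("%d exponential component(s)",
                                  object$n_components))
}
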