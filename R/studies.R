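#' Count-recovery simulation study
#'
#' Desk-scale analogue of the added-trace verification experiments: simulate
#' ensembles of `m` independent fluorophores with Alexa-647-like
#' photophysics, then re-estimate `m` per ensemble with the pseudo
#' log-likelihood fit on a power-law frame schedule. Each simulated trace
#' carries the residual background noise a corrected real trace would have
#' (`noise_sd_per_trace * sqrt(m)` for `m` added traces), and the fit is
#' told that noise level, as it would be from the region calibrations.
#'
#' @param m True fluorophore number per ensemble.
#' @param n_ensembles Number of independent ensembles (one fit each).
#' @param N Recorded frames per trace.
#' @param n_schedule Nominal schedule length for [build_subsample_schedule()].
#' @param E_Y,sigma_e2,f2 Emission model of a single fluorophore.
#' @param chain Long-timescale chain (default [alexa647_chain()]).
#' @param noise_sd_per_trace Residual background noise of one corrected
#'   single-molecule trace, detector units.
#' @param seed Master seed; ensemble `i` uses `seed * 1000 + i` for its
#'   trace and `seed + i` for the optimizer starts.
#' @param options An [htmm_fit_options()] list.
#' @return A tibble with one row per ensemble: `ensemble`, `m_true`,
#'   `m_hat`, `m_int`, `E_Y_hat`, `sigma_e2_hat`, `logLik`, `convergence`.
#' @export
#' @examples
#' \donttest{
#' res <- recovery_study(6, n_ensembles = 3, seed = 1)
#' mean(res$m_hat)
#' }
recovery_study <- function(m, n_ensembles, N = 2000, n_schedule = 400,
                           E_Y = 1000, sigma_e2 = 0.097, f2 = 2,
                           chain = alexa647_chain(),
                           noise_sd_per_trace = 30, seed = 1,
                           options = htmm_fit_options()) {
  stopifnot(m >= 1, n_ensembles >= 1)
  pars <- htmm_params(m, chain, emission_model(E_Y, sigma_e2, f2))
  sch <- build_subsample_schedule(N, min(n_schedule, N))
  ns <- noise_sd_per_trace * sqrt(m)
  rows <- vector("list", n_ensembles)
  for (i in seq_len(n_ensembles)) {
    y <- simulate_traces(pars, N, n_traces = 1, read_noise_sd = ns,
                         seed = (seed * 1000L + i) %% .Machine$integer.max,
                         format = "matrix")[1, ]
    opts <- options
    opts$seed <- (seed + i) %% .Machine$integer.max
    fit <- fit_htmm(y, sch, options = opts, chain_template = chain,
                    f2 = f2, noise_sd = ns)
    rows[[i]] <- tibble::tibble(
      ensemble = i, m_true = m, m_hat = fit$m_hat, m_int = fit$m_int,
      E_Y_hat = if (is.null(fit$params)) NA_real_ else
        fit$params$emission$mean_bright_signal,
      sigma_e2_hat = if (is.null(fit$params)) NA_real_ else
        fit$params$emission$excess_relative_variance,
      logLik = fit$logLik, convergence = fit$convergence)
  }
  dplyr::bind_rows(rows)
}
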