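# Tidiers and plots for sampler runs and study summaries.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a sampler run
#'
#' Per-parameter posterior summaries (mean, sd, median and a central
#' credible interval) from the trace, optionally after burn-in removal.
#'
#' @param x a `sampler_run`.
#' @param burnin iterations to drop (`"auto"` runs [estimate_burnin()]).
#' @param level credible-interval level.
#' @param ... unused.
#' @return a tibble with one row per parameter.
#' @export
tidy.sampler_run <- function(x, burnin = 0, level = 0.95, ...) {
  trace <- x$trace
  if (identical(burnin, "auto")) burnin <- estimate_burnin(trace)$n_bi
  if (burnin >= nrow(trace)) stop("burn-in removes the entire trace")
  trace <- trace[(burnin + 1):nrow(trace), , drop = FALSE]
  a <- (1 - level) / 2
  tibble::tibble(
    term = colnames(trace) %||% paste0("theta", seq_len(ncol(trace))),
    estimate = colMeans(trace),
    std.error = apply(trace, 2, stats::sd),
    median = apply(trace, 2, stats::median),
    conf.low = apply(trace, 2, stats::quantile, probs = a, names = FALSE),
    conf.high = apply(trace, 2, stats::quantile, probs = 1 - a, names = FALSE))
}

#' Glance at a sampler run
#'
#' @param x a `sampler_run`.
#' @param ... unused.
#' @return a one-row tibble with run-level statistics.
#' @export
glance.sampler_run <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, problem = x$problem,
                 n_iter = x$n_iter, acceptance_rate = x$acceptance_rate,
                 cpu_seconds = x$cpu_seconds,
                 max_log_posterior = max(x$log_posterior))
}

#' Trace plot of a sampler run
#'
#' @param object a `sampler_run`.
#' @param parameters optional subset of parameter names.
#' @param thin plot every `thin`-th iteration.
#' @param ... unused.
#' @return a ggplot object (one facet per parameter).
#' @export
autoplot.sampler_run <- function(object, parameters = NULL, thin = 1, ...) {
  df <- tibble::as_tibble(as.data.frame(object$trace))
  df$iteration <- seq_len(nrow(df))
  df <- df[seq(1, nrow(df), by = thin), , drop = FALSE]
  long <- tidyr::pivot_longer(df, -"iteration",
                              names_to = "parameter", values_to = "value")
  if (!is.null(parameters))
    long <- dplyr::filter(long, .data$parameter %in% parameters)
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = paste(object$algorithm, "on", object$problem)) +
    ggplot2::theme_minimal()
}

#' Plot a study summary
#'
#' Bar panels of exploration quality and conditioned efficiency per
#' scenario.
#'
#' @param object a [summarize_study()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.study_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "scenario", "eq", "conditioned_ess_per_s"),
    -"scenario", names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$scenario, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Glance at a study summary
#'
#' @param x a [summarize_study()] result.
#' @param ... unused.
#' @return a one-row tibble with study-level aggregates.
#' @export
glance.study_summary <- function(x, ...) {
  tibble::tibble(n_scenarios = nrow(x),
                 mean_eq = mean(x$eq),
                 mean_conditioned_ess_per_s = mean(x$conditioned_ess_per_s))
}
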