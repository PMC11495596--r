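#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(
    "Group-based trajectory model: K = %d groups, %d areas x %d periods\n",
    x$K, nrow(x$Y), ncol(x$Y)
  ))
  cat(sprintf("  basis: %s (d = %d); sigma = %.4g\n",
              x$basis$kind, x$basis$df, sqrt(x$sigma2)))
  cat(sprintf("  logLik = %.3f  BIC = %.3f  WMAE = %.4f  WRSS = %.3f\n",
              x$logLik, x$bic, x$wmae, x$wrss))
  cat(sprintf("  pi: %s\n", paste(sprintf("%.3f", x$pi), collapse = ", ")))
  cat(sprintf("  EM: %d iterations, converged = %s\n", x$iterations, x$converged))
  invisible(x)
}

#' @export
print.trajectory_selection <- function(x, ...) {
  cat(sprintf("Model selection over K = {%s}; chosen K = %d (min BIC)\n",
              paste(x$k, collapse = ", "), chosen_k(x)))
  NextMethod()
}

#' Tidy a fitted trajectory model
#'
#' One row per (group, basis coefficient), broom style.
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @return A tibble `group, term, estimate, pi`.
#' @export
tidy.trajectory_fit <- function(x, ...) {
  d <- ncol(x$beta)
  tibble::tibble(
    group = rep(seq_len(x$K), each = d),
    term = rep(paste0("b", seq_len(d) - 1L), times = x$K),
    estimate = as.vector(t(x$beta)),
    pi = rep(x$pi, each = d)
  )
}

#' Glance at a fitted trajectory model
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @return One-row tibble with `k, logLik, n_params, bic, wmae, wrss,
#'   sigma2, iterations, converged`.
#' @export
glance.trajectory_fit <- function(x, ...) {
  tibble::tibble(
    k = x$K, logLik = x$logLik, n_params = x$n_params, bic = x$bic,
    wmae = x$wmae, wrss = x$wrss, sigma2 = x$sigma2,
    iterations = x$iterations, converged = x$converged
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Spaghetti plot of area trajectories
#'
#' @param data Long data frame with one row per (area, period), e.g. the
#'   output of [shrink_panel()].
#' @param value Column (tidy-select) to plot, default `shrunk_prop`.
#' @param area_col,period_col Column names of area id and period.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(data, value = .data$shrunk_prop,
                              area_col = "area_id", period_col = "period",
                              alpha = 0.25) {
  value <- rlang::enquo(value)
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data[[period_col]], y = !!value, group = .data[[area_col]]
  )) +
    ggplot2::geom_line(alpha = alpha, colour = "grey30") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "period", y = "proportion") +
    ggplot2::theme_minimal()
}

#' Plot fitted class-mean curves over member trajectories
#'
#' @param object A `trajectory_fit`.
#' @param thresholds Naming thresholds passed to [assign_groups()].
#' @param ... Unused.
#' @return A ggplot object: member trajectories coloured by modal group,
#'   class mean curves overlaid.
#' @export
autoplot.trajectory_fit <- function(object, thresholds = c(0.45, 0.60), ...) {
  asg <- assign_groups(object, thresholds)
  long <- tibble::as_tibble(object$Y, .name_repair = "minimal") |>
    stats::setNames(as.character(object$periods)) |>
    dplyr::mutate(area_id = object$area_ids) |>
    tidyr::pivot_longer(-"area_id", names_to = "period", values_to = "value") |>
    dplyr::mutate(period = as.numeric(.data$period)) |>
    dplyr::left_join(dplyr::select(asg, "area_id", "group_name"), by = "area_id")
  mu <- fitted_curves(object)[, attr(asg, "order"), drop = FALSE]
  mu_long <- tibble::tibble(
    period = rep(object$periods, times = object$K),
    value = as.vector(mu),
    group_name = rep(attr(asg, "group_names"), each = length(object$periods))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period, y = .data$value,
                                     colour = .data$group_name)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$area_id), alpha = 0.2) +
    ggplot2::geom_line(data = mu_long, linewidth = 1.2) +
    ggplot2::labs(x = "period", y = "proportion", colour = "group") +
    ggplot2::theme_minimal()
}

#' Plot the model-selection table
#'
#' BIC and WMAE against the number of groups; the chosen K is marked.
#'
#' @param object A `trajectory_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_selection <- function(object, ...) {
  long <- object |>
    tibble::as_tibble() |>
    dplyr::select("k", "bic", "wmae") |>
    tidyr::pivot_longer(-"k", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = chosen_k(object), linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of groups K") +
    ggplot2::theme_minimal()
}
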