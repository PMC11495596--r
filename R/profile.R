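#' Profile trajectory groups by area covariates
#'
#' Post-hoc characterisation of the fitted groups: per (group, covariate),
#' the member count, median and first/third quartiles over the areas
#' modally assigned to the group. Quartiles use linear interpolation
#' between order statistics (R's default quantile type 7) so results are
#' reproducible across software. Areas with a missing value for a
#' covariate are excluded from that covariate only; the `n_missing` column
#' records how many.
#'
#' @param assignment A [assign_groups()] result (or any data frame with
#'   `area_id`, `group`, `group_name`).
#' @param covariates Data frame with `area_id` and numeric covariate
#'   columns; every assigned area must have a row.
#' @param vars Optional character vector restricting which covariate
#'   columns to profile (default: all numeric columns).
#' @param weighted If `TRUE`, use posterior-weighted quantiles instead of
#'   modal assignment (requires the `.pr_<g>` columns of
#'   [assign_groups()]).
#' @return A tibble with columns
#'   `group, group_name, covariate, n, n_missing, q1, median, q3`.
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(n_areas = 30, n_regions = 5, seed = 3))
#' shrunk <- shrink_panel(sim$panel)
#' Y <- panel_to_matrix(shrunk, shrunk_prop)
#' fit <- fit_trajectories(Y, 2, spec = basis_spec("linear"), seed = 1)
#' profile_groups(assign_groups(fit), sim$covariates)
profile_groups <- function(assignment, covariates, vars = NULL, weighted = FALSE) {
  check_assignment_cols(assignment)
  if (!"area_id" %in% names(covariates)) {
    stop_domain("`covariates` must contain an `area_id` column.")
  }
  unmatched <- setdiff(assignment$area_id, covariates$area_id)
  if (length(unmatched)) {
    stop_domain(
      sprintf("Assigned area(s) without covariate rows: %s.",
              paste(unmatched, collapse = ", ")),
      areas = unmatched
    )
  }
  if (is.null(vars)) {
    vars <- names(covariates)[vapply(covariates, is.numeric, TRUE)]
  }
  joined <- dplyr::inner_join(
    dplyr::select(assignment, dplyr::any_of(c("area_id", "group", "group_name",
                                              grep("^\\.pr_", names(assignment), value = TRUE)))),
    covariates,
    by = "area_id"
  )
  long <- joined |>
    tidyr::pivot_longer(dplyr::all_of(vars),
                        names_to = "covariate", values_to = "value") |>
    dplyr::mutate(covariate = factor(.data$covariate, levels = vars))

  if (!weighted) {
    out <- long |>
      dplyr::group_by(.data$group, .data$group_name, .data$covariate) |>
      dplyr::summarise(
        n = dplyr::n(),
        n_missing = sum(is.na(.data$value)),
        q1 = quantile_or_na(.data$value, 0.25),
        median = quantile_or_na(.data$value, 0.50),
        q3 = quantile_or_na(.data$value, 0.75),
        .groups = "drop"
      )
  } else {
    groups <- sort(unique(assignment$group))
    out <- purrr::map_dfr(groups, function(g) {
      w_col <- paste0(".pr_", g)
      if (!w_col %in% names(long)) {
        stop_config("Posterior columns (.pr_*) required for weighted profiling.")
      }
      long |>
        dplyr::group_by(.data$covariate) |>
        dplyr::summarise(
          group = g,
          group_name = assignment$group_name[match(g, assignment$group)],
          n = sum(.data$group == g),
          n_missing = sum(is.na(.data$value)),
          q1 = weighted_quantile(.data$value, .data[[w_col]], 0.25),
          median = weighted_quantile(.data$value, .data[[w_col]], 0.50),
          q3 = weighted_quantile(.data$value, .data[[w_col]], 0.75),
          .groups = "drop"
        )
    }) |>
      dplyr::relocate("group", "group_name")
  }
  out |>
    dplyr::mutate(covariate = as.character(.data$covariate)) |>
    dplyr::arrange(.data$group)
}

check_assignment_cols <- function(assignment) {
  miss <- setdiff(c("area_id", "group", "group_name"), names(assignment))
  if (length(miss)) {
    stop_domain(sprintf("`assignment` is missing column(s): %s.",
                        paste(miss, collapse = ", ")))
  }
  invisible(NULL)
}

quantile_or_na <- function(x, p) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  unname(quantile(x, p, type = 7))
}

# interpolated weighted quantile over the posterior mass; positions are
# centred on each observation's mass so equal weights reproduce the
# ordinary sample median
weighted_quantile <- function(x, w, p) {
  keep <- !is.na(x) & w > 0
  x <- x[keep]; w <- w[keep]
  if (!length(x)) return(NA_real_)
  if (length(x) == 1L) return(x)
  o <- order(x)
  x <- x[o]; w <- w[o]
  pk <- (cumsum(w) - 0.5 * w) / sum(w)
  stats::approx(pk, x, xout = p, rule = 2, ties = "ordered")$y
}

#' Per-group trends of staffing and hospital covariates across survey years
#'
#' For covariates observed in two survey years (columns `<stem>_<year1>`
#' and `<stem>_<year2>`), tabulates per-group medians in each year and the
#' year2 - year1 difference. Empty groups are kept with `NA` medians and
#' zero counts.
#'
#' @inheritParams profile_groups
#' @param stems Character vector of covariate stems; each must have both
#'   year columns present.
#' @param years Length-2 integer vector of survey years, default
#'   `c(2014, 2018)`.
#' @return A tibble `group, group_name, covariate, n, median_y1, median_y2,
#'   diff`.
#' @export
trend_table <- function(assignment, covariates,
                        stems = c("physicians_per_100k", "cardiologists_per_100k",
                                  "general_hospitals_per_100k",
                                  "emergency_hospitals_per_100k"),
                        years = c(2014L, 2018L)) {
  check_assignment_cols(assignment)
  if (length(years) != 2L) stop_config("`years` must have exactly two entries.")
  cols <- c(outer(stems, years, function(s, y) paste0(s, "_", y)))
  miss <- setdiff(cols, names(covariates))
  if (length(miss)) {
    stop_config(sprintf("Missing survey-year column(s): %s.",
                        paste(miss, collapse = ", ")))
  }
  joined <- dplyr::left_join(
    dplyr::select(assignment, "area_id", "group", "group_name"),
    covariates, by = "area_id"
  )
  # groups with no modal members still get a row (NA medians, n = 0)
  lev <- attr(assignment, "group_levels")
  all_groups <- if (!is.null(lev)) {
    dplyr::select(lev, "group", "group_name")
  } else {
    dplyr::distinct(assignment, .data$group, .data$group_name)
  }

  purrr::map_dfr(stems, function(stem) {
    y1 <- paste0(stem, "_", years[1])
    y2 <- paste0(stem, "_", years[2])
    joined |>
      dplyr::group_by(.data$group, .data$group_name) |>
      dplyr::summarise(
        covariate = stem,
        n = dplyr::n(),
        median_y1 = quantile_or_na(.data[[y1]], 0.5),
        median_y2 = quantile_or_na(.data[[y2]], 0.5),
        .groups = "drop"
      )
  }) |>
    dplyr::right_join(
      tidyr::expand_grid(
        all_groups,
        covariate = stems
      ),
      by = c("group", "group_name", "covariate")
    ) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      diff = .data$median_y2 - .data$median_y1
    ) |>
    dplyr::arrange(.data$group, match(.data$covariate, stems))
}
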