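#' Continuity-corrected logit of an event proportion
#'
#' `log((r + 0.5) / (n - r + 0.5))`, the raw area-level logit used by the
#' empirical-Bayes shrinkage estimator. The 0.5 corrections keep the logit
#' finite at r = 0 and r = n. Natural logarithm.
#'
#' @param r Event count(s), `0 <= r <= n`.
#' @param n Case count(s) (denominator), `n >= 0`.
#' @return Numeric vector of logits.
#' @export
#' @examples
#' raw_logit(5, 10)  # 0
#' raw_logit(0, 1)   # log(0.5 / 1.5)
raw_logit <- function(r, n) {
  check_counts(r, n)
  log((r + 0.5) / (n - r + 0.5))
}

#' Squared standard error of the continuity-corrected logit
#'
#' `s^2 = (n + 1)(n + 2) / (n (r + 1)(n - r + 1))`, the sampling variance
#' attached to [raw_logit()]. Undefined at n = 0 (the denominator contains
#' n); callers handle zero-case cells through the completion policy of
#' [shrink_panel()].
#'
#' @inheritParams raw_logit
#' @return Strictly positive numeric vector (logit^2 units).
#' @export
#' @examples
#' logit_se_squared(5, 10)  # 132 / 360
logit_se_squared <- function(r, n) {
  check_counts(r, n)
  if (any(n == 0)) {
    stop_domain("`n` must be >= 1: s^2 is undefined at n = 0 (apply a zero-case policy).")
  }
  (n + 1) * (n + 2) / (n * (r + 1) * (n - r + 1))
}

#' Pooled-region logit
#'
#' The same continuity-corrected logit as [raw_logit()], applied to counts
#' pooled over all member areas of a region for one period.
#'
#' @param pooled_r Pooled event count over the region's areas.
#' @param pooled_n Pooled case count.
#' @return Numeric logit.
#' @export
region_logit <- function(pooled_r, pooled_n) {
  raw_logit(pooled_r, pooled_n)
}

#' Inter-area variance of member logits
#'
#' Sample variance (denominator k - 1) of the k member-area raw logits
#' within one region-period; the between-area variance component of the
#' shrinkage weight. With a single member (k = 1) the variance is undefined
#' and `NA_real_` is returned as the no-shrink marker.
#'
#' @param member_logits Numeric vector of member-area logits.
#' @return Non-negative variance, or `NA_real_` when k = 1.
#' @export
#' @examples
#' inter_area_variance(c(0, 2))  # 2
inter_area_variance <- function(member_logits) {
  if (length(member_logits) == 0L) {
    stop_domain("`member_logits` must be non-empty.")
  }
  if (anyNA(member_logits)) {
    stop_domain("`member_logits` must not contain NA.")
  }
  if (length(member_logits) == 1L) return(NA_real_)
  m <- mean(member_logits)
  sum((member_logits - m)^2) / (length(member_logits) - 1)
}

#' Precision-based shrinkage weight
#'
#' `w = (1/s^2) / (1/s^2 + 1/t^2)`, computed in the algebraically equal
#' form `t^2 / (t^2 + s^2)` so that t^2 = 0 cleanly gives w = 0 (full
#' shrinkage toward the region).
#'
#' @param s2 Area-level sampling variance of the logit, > 0.
#' @param t2 Inter-area variance, >= 0.
#' @return Weight in \[0, 1\].
#' @export
#' @examples
#' shrinkage_weight(1, 1)  # 0.5
#' shrinkage_weight(1, 0)  # 0
shrinkage_weight <- function(s2, t2) {
  if (any(s2 <= 0, na.rm = TRUE) || anyNA(s2)) {
    stop_domain("`s2` must be strictly positive.")
  }
  if (any(t2 < 0, na.rm = TRUE) || anyNA(t2)) {
    stop_domain("`t2` must be non-negative.")
  }
  t2 / (t2 + s2)
}

#' Shrink one area logit toward its region
#'
#' Convex combination `w * raw + (1 - w) * region`: w = 1 keeps the raw
#' area logit, w = 0 returns the pooled region logit.
#'
#' @param raw Raw area logit.
#' @param region Pooled region logit.
#' @param w Weight in \[0, 1\].
#' @return Shrunk logit.
#' @export
shrink_area <- function(raw, region, w) {
  if (any(w < 0 | w > 1, na.rm = TRUE) || anyNA(w)) {
    stop_domain("`w` must lie in [0, 1].")
  }
  w * raw + (1 - w) * region
}

check_counts <- function(r, n) {
  if (anyNA(r) || anyNA(n) || any(r < 0) || any(n < 0) || any(r > n)) {
    stop_domain("Counts must satisfy 0 <= r <= n with no missing values.")
  }
  invisible(NULL)
}

#' Empirical-Bayes shrinkage of a whole area-period panel
#'
#' Applies the logit shrinkage estimator to every (area, period) cell of a
#' long panel: per region-period, member raw logits are pooled into a
#' region logit and an inter-area variance t^2; each area's logit is then
#' pulled toward the region logit with precision weight
#' `w = t^2 / (t^2 + s^2)`. Pooled region counts include the area itself.
#'
#' Edge policies:
#' * `t^2 = 0` (identical members) gives w = 0 (full shrinkage).
#' * A singleton region (k = 1) has undefined t^2; the area keeps its raw
#'   logit (w = 1), flagged in the `policy` column.
#' * Zero-case cells (n = 0) have undefined s^2 and are handled by
#'   `zero_case`: `"region-fill"` (default) assigns the pooled region value
#'   with w = 0; `"drop-area"` removes every period of any area with a
#'   zero-case cell; `"error"` aborts listing the offending cells.
#'
#' @param panel Data frame with columns `area_id`, `region_id`, `period`,
#'   `r`, `n` (extra columns are preserved on input but not returned).
#' @param zero_case Zero-case completion policy (see above).
#' @return A tibble with one row per (area, period):
#'   `area_id, region_id, period, raw_logit, se2, region_logit, t2, weight,
#'   shrunk_logit, shrunk_prop, policy`.
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(n_areas = 12, n_regions = 3, seed = 2))
#' shrunk <- shrink_panel(sim$panel)
#' head(shrunk)
shrink_panel <- function(panel, zero_case = c("region-fill", "drop-area", "error")) {
  zero_case <- match.arg(zero_case)
  required <- c("area_id", "region_id", "period", "r", "n")
  miss <- setdiff(required, names(panel))
  if (length(miss)) {
    stop_domain(sprintf("`panel` is missing column(s): %s.", paste(miss, collapse = ", ")))
  }
  check_counts(panel$r, panel$n)
  dup <- panel |>
    dplyr::count(.data$area_id, .data$period) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop_domain("Every (area_id, period) pair may appear at most once in `panel`.")
  }
  multi_region <- panel |>
    dplyr::distinct(.data$area_id, .data$region_id) |>
    dplyr::count(.data$area_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi_region)) {
    stop_domain(sprintf(
      "Area(s) mapped to more than one region: %s.",
      paste(multi_region$area_id, collapse = ", ")
    ))
  }

  zero_cells <- dplyr::filter(panel, .data$n == 0L)
  if (zero_case == "error" && nrow(zero_cells)) {
    stop_domain(
      sprintf(
        "Zero-case cells present: %s.",
        paste(sprintf("(%s, %s)", zero_cells$area_id, zero_cells$period), collapse = ", ")
      ),
      cells = zero_cells[, c("area_id", "period")]
    )
  }
  if (zero_case == "drop-area" && nrow(zero_cells)) {
    panel <- dplyr::filter(panel, !(.data$area_id %in% unique(zero_cells$area_id)))
    if (!nrow(panel)) stop_domain("All areas dropped by the zero-case policy.")
  }

  panel |>
    dplyr::mutate(raw_logit = raw_logit(.data$r, .data$n)) |>
    dplyr::group_by(.data$region_id, .data$period) |>
    dplyr::mutate(
      region_logit = region_logit(sum(.data$r), sum(.data$n)),
      # t^2 and the member count only use informative cells (n > 0);
      # zero-case cells carry no logit information
      t2 = if (any(.data$n > 0L)) {
        inter_area_variance(.data$raw_logit[.data$n > 0L])
      } else {
        NA_real_
      },
      .k = sum(.data$n > 0L)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      se2 = dplyr::if_else(.data$n > 0L,
        (.data$n + 1) * (.data$n + 2) / (.data$n * (.data$r + 1) * (.data$n - .data$r + 1)),
        NA_real_
      ),
      weight = dplyr::case_when(
        .data$n == 0L ~ 0,                    # region-fill: no information
        .data$.k == 1L ~ 1,                   # singleton region: no shrink
        TRUE ~ .data$t2 / (.data$t2 + .data$se2)
      ),
      policy = dplyr::case_when(
        .data$n == 0L ~ "zero-case-region-fill",
        .data$.k == 1L ~ "singleton-no-shrink",
        .data$t2 == 0 ~ "t2-zero-full-shrink",
        TRUE ~ "shrunk"
      ),
      shrunk_logit = dplyr::case_when(
        .data$n == 0L ~ .data$region_logit,
        .data$.k == 1L ~ .data$raw_logit,
        TRUE ~ .data$weight * .data$raw_logit + (1 - .data$weight) * .data$region_logit
      ),
      shrunk_prop = plogis(.data$shrunk_logit)
    ) |>
    dplyr::select(
      "area_id", "region_id", "period", "raw_logit", "se2", "region_logit",
      "t2", "weight", "shrunk_logit", "shrunk_prop", "policy"
    ) |>
    dplyr::arrange(.data$area_id, .data$period)
}
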