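#' Configuration for the synthetic claims-like panel generator
#'
#' Builds and validates the parameter set for [simulate_panel()]. The
#' defaults emulate the setting the package targets: 335 small areas
#' (secondary medical areas) nested in 47 parent regions (prefectures),
#' seven fiscal years starting 2014, four latent trajectory groups with
#' shares 62/20/5/13 percent, binomial event counts (primary PCI within one
#' day of an AMI admission) on Poisson case denominators, and area
#' covariates whose locations shift with the latent group.
#'
#' @param n_regions Number of parent regions.
#' @param n_areas Number of areas; must be at least `n_regions` so every
#'   region receives at least one area.
#' @param n_periods Number of fiscal-year periods (period index is 0-based).
#' @param first_fiscal_year Calendar label of period 0.
#' @param group_probs Probability vector over latent trajectory groups; must
#'   sum to 1 and be strictly positive.
#' @param group_logit_curves List of numeric vectors, one per group, giving
#'   the group mean logit at each period; each must have length `n_periods`.
#'   Defaults are three flat groups (logits 1.1, 0.3, -0.5) and one rising
#'   group (-1.3 to 0.2), imitating high/middle/low flat levels plus a
#'   catching-up group.
#' @param area_random_sd Standard deviation of the area-level logit
#'   intercept around its group curve.
#' @param case_rate_per_100k Expected annual case count (AMI
#'   hospitalisations) per 100,000 population.
#' @param population_log_mean,population_log_sd Log-scale mean and sd of
#'   area populations (log-normal).
#' @param covariate_effects Named list mapping covariate names to numeric
#'   vectors (one value per group) of additive log-scale location shifts.
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_areas = 20, n_regions = 4, seed = 1)
#' names(cfg)
sim_config <- function(n_regions = 47L,
                       n_areas = 335L,
                       n_periods = 7L,
                       first_fiscal_year = 2014L,
                       group_probs = c(0.62, 0.20, 0.05, 0.13),
                       group_logit_curves = NULL,
                       area_random_sd = 0.03,
                       case_rate_per_100k = 60,
                       population_log_mean = log(2.5e5),
                       population_log_sd = 0.35,
                       covariate_effects = NULL,
                       seed = 1L) {
  n_regions <- assert_scalar_count(n_regions, "n_regions")
  n_areas <- assert_scalar_count(n_areas, "n_areas")
  n_periods <- assert_scalar_count(n_periods, "n_periods", min = 2L)
  if (n_areas < n_regions) {
    stop_config("`n_areas` must be >= `n_regions` (every region gets at least one area).")
  }
  if (!is.numeric(group_probs) || length(group_probs) < 1L || any(group_probs <= 0)) {
    stop_config("`group_probs` must be a numeric vector with all entries > 0.")
  }
  if (abs(sum(group_probs) - 1) > 1e-12) {
    stop_config("`group_probs` must sum to 1 (within 1e-12).")
  }
  K <- length(group_probs)
  if (is.null(group_logit_curves)) {
    group_logit_curves <- default_group_curves(K, n_periods)
  }
  if (!is.list(group_logit_curves) || length(group_logit_curves) != K) {
    stop_config("`group_logit_curves` must be a list with one curve per group.")
  }
  bad_len <- which(vapply(group_logit_curves, length, 1L) != n_periods)
  if (length(bad_len)) {
    stop_config(sprintf(
      "`group_logit_curves`: curve(s) %s do not have length n_periods = %d.",
      paste(bad_len, collapse = ", "), n_periods
    ))
  }
  if (!is.numeric(area_random_sd) || length(area_random_sd) != 1L || area_random_sd < 0) {
    stop_config("`area_random_sd` must be a single non-negative number.")
  }
  if (!is.numeric(case_rate_per_100k) || case_rate_per_100k < 0) {
    stop_config("`case_rate_per_100k` must be non-negative.")
  }
  if (is.null(covariate_effects)) {
    covariate_effects <- default_covariate_effects(K)
  }
  bad_eff <- names(covariate_effects)[vapply(covariate_effects, length, 1L) != K]
  if (length(bad_eff)) {
    stop_config(sprintf(
      "`covariate_effects`: entries %s must have one shift per group (length %d).",
      paste(bad_eff, collapse = ", "), K
    ))
  }
  seed <- assert_scalar_count(seed, "seed", min = 0L)

  structure(
    list(
      n_regions = n_regions, n_areas = n_areas, n_periods = n_periods,
      first_fiscal_year = as.integer(first_fiscal_year),
      group_probs = group_probs, group_logit_curves = group_logit_curves,
      area_random_sd = area_random_sd,
      case_rate_per_100k = case_rate_per_100k,
      population_log_mean = population_log_mean,
      population_log_sd = population_log_sd,
      covariate_effects = covariate_effects,
      seed = seed
    ),
    class = "sim_config"
  )
}

# Flat high / flat middle / rising / flat low, 0.8 logit gaps between
# adjacent flat levels; extended or truncated for other K.
default_group_curves <- function(K, n_periods) {
  base <- list(
    rep(1.1, n_periods),
    rep(0.3, n_periods),
    seq(-1.3, 0.2, length.out = n_periods),
    rep(-0.5, n_periods)
  )
  if (K <= 4L) return(base[seq_len(K)])
  extra <- lapply(seq_len(K - 4L), function(i) rep(-1.3 - 0.8 * i, n_periods))
  c(base, extra)
}

# Log-scale location shifts per group: high-trajectory groups get denser,
# better-staffed areas; the rising and low groups sit below baseline.
default_covariate_effects <- function(K) {
  shift4 <- function(hi, mid, rise, lo) c(hi, mid, rise, lo)[seq_len(min(K, 4L))]
  pad <- function(x) c(x, rep(x[length(x)], max(0L, K - 4L)))
  lapply(list(
    pop_density                    = shift4(0.9, 0.2, -0.5, -0.6),
    physicians_per_100k            = shift4(0.15, 0.05, -0.10, -0.15),
    cardiologists_per_100k         = shift4(0.30, 0.10, -0.20, -0.30),
    general_hospitals_per_100k     = shift4(0.10, 0.00, -0.10, -0.10),
    emergency_hospitals_per_100k   = shift4(0.15, 0.05, -0.10, -0.15),
    general_hospital_beds_per_100k = shift4(0.10, 0.00, -0.05, -0.10)
  ), pad)
}

#' Simulate an area-period panel with known latent trajectory groups
#'
#' Draws a complete long-format panel of event/case counts plus an area
#' covariate table, with the latent structure the downstream analysis
#' assumes: each area belongs to one latent group, its true proportion at
#' period t is `plogis(curve[g][t] + a_i)` with an area intercept
#' `a_i ~ N(0, area_random_sd)`; case counts are Poisson in the area
#' population and event counts are binomial. Covariates are log-normal or
#' zero-truncated normal with additive log-scale group shifts.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `area_sim` with elements
#'   \describe{
#'     \item{panel}{tibble of `area_id`, `region_id`, `period`,
#'       `fiscal_year`, `r` (events), `n` (cases), `population`.}
#'     \item{truth}{tibble of `area_id`, `group` (1-based latent index),
#'       `area_intercept`, plus the true group curves as an attribute
#'       `"curves"`.}
#'     \item{covariates}{tibble of per-area covariates (see Details).}
#'     \item{config}{the config used.}
#'   }
#' @details Covariates: `population`, `prop_age65`, `pop_density`,
#'   `unemployment_rate`, `taxable_income_per_capita`, per-100k counts of
#'   physicians, cardiologists, dentists, pharmacists, general hospitals,
#'   emergency hospitals and general hospital beds, and two survey-year
#'   columns (`*_2014`, `*_2018`) for the four trend covariates.
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(n_areas = 12, n_regions = 3, seed = 7))
#' head(sim$panel)
simulate_panel <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    stop_config("`config` must be created by sim_config().")
  }
  withr::local_seed(config$seed)

  n_areas <- config$n_areas
  n_regions <- config$n_regions
  n_periods <- config$n_periods
  K <- length(config$group_probs)

  area_id <- sprintf("A%04d", seq_len(n_areas))
  # every region gets one area, the remainder are assigned at random
  region_idx <- c(
    seq_len(n_regions),
    if (n_areas > n_regions) {
      sample.int(n_regions, n_areas - n_regions, replace = TRUE)
    }
  )
  region_id <- sprintf("R%02d", region_idx)

  group <- sample.int(K, n_areas, replace = TRUE, prob = config$group_probs)
  a_i <- rnorm(n_areas, 0, config$area_random_sd)
  population <- rlnorm(n_areas, config$population_log_mean, config$population_log_sd)

  curves <- do.call(rbind, config$group_logit_curves) # K x T
  true_logit <- curves[group, , drop = FALSE] + a_i   # N x T
  true_p <- plogis(true_logit)

  lambda <- population * config$case_rate_per_100k / 1e5
  n_mat <- matrix(rpois(n_areas * n_periods, rep(lambda, n_periods)),
                  nrow = n_areas)
  r_mat <- matrix(rbinom(n_areas * n_periods, as.vector(n_mat), as.vector(true_p)),
                  nrow = n_areas)

  panel <- tibble::tibble(
    area_id = rep(area_id, n_periods),
    region_id = rep(region_id, n_periods),
    period = rep(seq_len(n_periods) - 1L, each = n_areas),
    fiscal_year = config$first_fiscal_year + rep(seq_len(n_periods) - 1L, each = n_areas),
    r = as.integer(r_mat),
    n = as.integer(n_mat),
    population = rep(population, n_periods)
  ) |>
    dplyr::arrange(.data$area_id, .data$period)

  truth <- tibble::tibble(
    area_id = area_id, region_id = region_id,
    group = as.integer(group), area_intercept = a_i
  )
  attr(truth, "curves") <- curves

  covariates <- simulate_covariates(area_id, group, population, config)

  structure(
    list(panel = panel, truth = truth, covariates = covariates, config = config),
    class = "area_sim"
  )
}

# positive covariate with multiplicative (log-scale) group shift
r_pos_shifted <- function(n, mean, sd, shift_by_group, group) {
  base <- pmax(rnorm(n, mean, sd), mean * 0.05)
  base * exp(shift_by_group[group])
}

simulate_covariates <- function(area_id, group, population, config) {
  n <- length(area_id)
  eff <- config$covariate_effects
  K <- length(config$group_probs)
  shift <- function(name) eff[[name]] %||% rep(0, K)

  pop_density <- rlnorm(n, log(300), 1.1) * exp(shift("pop_density")[group])
  phys <- r_pos_shifted(n, 230, 55, shift("physicians_per_100k"), group)
  cardio <- r_pos_shifted(n, 10, 3.5, shift("cardiologists_per_100k"), group)
  gen_hosp <- r_pos_shifted(n, 6, 2.2, shift("general_hospitals_per_100k"), group)
  emer_hosp <- r_pos_shifted(n, 3, 1.2, shift("emergency_hospitals_per_100k"), group)
  beds <- r_pos_shifted(n, 900, 260, shift("general_hospital_beds_per_100k"), group)

  # survey-year versions of the trend covariates: mild national growth with
  # small area-level jitter around the mid-period value
  trend_year <- function(base, drift) base * exp(drift + rnorm(n, 0, 0.03))

  tibble::tibble(
    area_id = area_id,
    population = population,
    prop_age65 = pmin(pmax(rnorm(n, 0.28, 0.045), 0), 1),
    pop_density = pop_density,
    unemployment_rate = pmin(pmax(rnorm(n, 0.045, 0.01), 0), 1),
    taxable_income_per_capita = rlnorm(n, log(1.3e6), 0.22),
    physicians_per_100k = phys,
    cardiologists_per_100k = cardio,
    dentists_per_100k = r_pos_shifted(n, 75, 18, rep(0, K), group),
    pharmacists_per_100k = r_pos_shifted(n, 160, 35, rep(0, K), group),
    general_hospitals_per_100k = gen_hosp,
    emergency_hospitals_per_100k = emer_hosp,
    general_hospital_beds_per_100k = beds,
    physicians_per_100k_2014 = trend_year(phys, -0.04),
    physicians_per_100k_2018 = trend_year(phys, 0.04),
    cardiologists_per_100k_2014 = trend_year(cardio, -0.08),
    cardiologists_per_100k_2018 = trend_year(cardio, 0.08),
    general_hospitals_per_100k_2014 = trend_year(gen_hosp, 0.01),
    general_hospitals_per_100k_2018 = trend_year(gen_hosp, -0.01),
    emergency_hospitals_per_100k_2014 = trend_year(emer_hosp, 0.02),
    emergency_hospitals_per_100k_2018 = trend_year(emer_hosp, -0.02)
  )
}

#' Reshape a long panel into an areas-by-periods trajectory matrix
#'
#' @param data Long-format data frame with one row per (area, period).
#' @param value Column (tidy-select) holding the per-record proportion.
#' @param area_col,period_col Names of the area and period columns.
#' @return A numeric matrix (areas x periods), rows sorted by area id and
#'   named by it, columns named by period; values must lie in \[0, 1\].
#' @export
#' @examples
#' df <- tidyr::expand_grid(area_id = c("a", "b"), period = 0:2)
#' df$p <- 0.5
#' panel_to_matrix(df, p)
panel_to_matrix <- function(data, value, area_col = "area_id", period_col = "period") {
  value <- rlang::enquo(value)
  df <- dplyr::transmute(
    data,
    .area = .data[[area_col]],
    .period = .data[[period_col]],
    .value = !!value
  )
  dup <- df |>
    dplyr::count(.data$.area, .data$.period) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop_domain(sprintf(
      "Duplicate (area, period) cells: %s.",
      paste(sprintf("(%s, %s)", dup$.area, dup$.period), collapse = ", ")
    ))
  }
  areas <- sort(unique(df$.area))
  periods <- sort(unique(df$.period))
  full <- tidyr::expand_grid(.area = areas, .period = periods)
  missing <- dplyr::anti_join(full, df, by = c(".area", ".period"))
  if (nrow(missing)) {
    stop_domain(
      sprintf(
        "Panel is not rectangular; missing cells: %s.",
        paste(sprintf("(%s, %s)", missing$.area, missing$.period), collapse = ", ")
      ),
      cells = missing
    )
  }
  if (any(df$.value < 0 | df$.value > 1, na.rm = TRUE) || anyNA(df$.value)) {
    stop_domain("Trajectory values must be proportions in [0, 1] with no missing entries.")
  }
  wide <- df |>
    dplyr::arrange(.data$.area, .data$.period) |>
    tidyr::pivot_wider(names_from = ".period", values_from = ".value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$.area
  storage.mode(m) <- "double"
  m
}
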