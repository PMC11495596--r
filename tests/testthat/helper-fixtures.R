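# Small panels and matrices built in code, shared across test files.

# random long panel with guaranteed n >= 1 and >= 2 areas per region,
# exercising the printed shrinkage formulas without edge policies
random_panel <- function(n_regions = 3L, areas_per_region = 4L, n_periods = 3L,
                         n_range = c(5L, 400L)) {
  n_areas <- n_regions * areas_per_region
  tidyr::expand_grid(
    .area = seq_len(n_areas),
    period = seq_len(n_periods) - 1L
  ) |>
    dplyr::mutate(
      area_id = sprintf("A%03d", .area),
      region_id = sprintf("R%02d", (.area - 1L) %/% areas_per_region + 1L),
      n = sample(seq(n_range[1], n_range[2]), dplyr::n(), replace = TRUE),
      r = rbinom(dplyr::n(), n, runif(dplyr::n(), 0.05, 0.95))
    ) |>
    dplyr::select(area_id, region_id, period, r, n)
}

# scalar-composed shrinkage: mirrors the printed formulas step by step,
# independent of shrink_panel's grouped-mutate implementation
shrink_by_scalar_ops <- function(panel) {
  out <- panel[order(panel$area_id, panel$period), ]
  out$raw_logit <- NA_real_
  out$se2 <- NA_real_
  out$region_logit <- NA_real_
  out$t2 <- NA_real_
  out$weight <- NA_real_
  out$shrunk_logit <- NA_real_
  for (i in seq_len(nrow(out))) {
    ri <- out$r[i]; ni <- out$n[i]
    members <- out[out$region_id == out$region_id[i] & out$period == out$period[i], ]
    m_j <- vapply(seq_len(nrow(members)),
                  function(j) raw_logit(members$r[j], members$n[j]), 1)
    out$raw_logit[i] <- raw_logit(ri, ni)
    out$se2[i] <- logit_se_squared(ri, ni)
    out$region_logit[i] <- region_logit(sum(members$r), sum(members$n))
    out$t2[i] <- inter_area_variance(m_j)
    out$weight[i] <- shrinkage_weight(out$se2[i], out$t2[i])
    out$shrunk_logit[i] <- shrink_area(out$raw_logit[i], out$region_logit[i],
                                       out$weight[i])
  }
  out$shrunk_prop <- plogis(out$shrunk_logit)
  out
}

# exactly separable matrix: two flat classes, no noise
two_flat_classes <- function(n_per = 10L, n_periods = 5L,
                             levels = c(0.2, 0.8)) {
  Y <- rbind(
    matrix(levels[1], n_per, n_periods),
    matrix(levels[2], n_per, n_periods)
  )
  rownames(Y) <- sprintf("A%03d", seq_len(2L * n_per))
  Y
}

small_sim <- function(seed = 11L, ...) {
  simulate_panel(sim_config(
    n_areas = 30L, n_regions = 5L, n_periods = 5L, seed = seed, ...
  ))
}
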