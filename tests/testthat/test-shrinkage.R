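test_that("scalar shrinkage formulas match hand evaluation", {
  # continuity-corrected logit
  expect_equal(raw_logit(5, 10), 0)
  expect_equal(raw_logit(0, 1), log(0.5 / 1.5))
  expect_equal(raw_logit(3, 3), log(3.5 / 0.5))
  # sampling variance of the logit
  expect_equal(logit_se_squared(5, 10), 132 / 360)
  expect_equal(logit_se_squared(0, 1), 3)
  expect_equal(logit_se_squared(1, 1), 3) # symmetric in r <-> n - r
  # pooled region logit
  expect_equal(region_logit(10, 20), 0)
  expect_equal(region_logit(0, 0), 0) # log(0.5/0.5)
  expect_equal(region_logit(25, 40), log(25.5 / 15.5))
  # inter-area variance
  expect_equal(inter_area_variance(c(0.7, 0.7)), 0)
  expect_equal(inter_area_variance(c(0, 2)), 2)
  expect_true(is.na(inter_area_variance(1.3))) # k = 1: no-shrink marker
  # precision weight
  expect_equal(shrinkage_weight(0.37, 0.37), 0.5)
  expect_equal(shrinkage_weight(1, 0), 0)
  expect_equal(shrinkage_weight(132 / 360, 1.1), 1.1 / (1.1 + 132 / 360))
  # convex combination
  expect_equal(shrink_area(-1, 1, 1), -1)
  expect_equal(shrink_area(-1, 1, 0), 1)
  expect_equal(shrink_area(-1, 1, 0.25), 0.5)
})

test_that("scalar operations reject out-of-domain inputs", {
  expect_error(raw_logit(5, 3), class = "qitraj_domain_error")
  expect_error(raw_logit(-1, 3), class = "qitraj_domain_error")
  expect_error(logit_se_squared(0, 0), class = "qitraj_domain_error")
  expect_error(inter_area_variance(numeric(0)), class = "qitraj_domain_error")
  expect_error(shrinkage_weight(0, 1), class = "qitraj_domain_error")
  expect_error(shrinkage_weight(1, -0.1), class = "qitraj_domain_error")
  expect_error(shrink_area(0, 0, 1.2), class = "qitraj_domain_error")
})

test_that("shrink_panel equals composed scalar operations on random panels", {
  withr::local_seed(101)
  for (i in 1:25) {
    panel <- random_panel()
    got <- shrink_panel(panel)
    want <- shrink_by_scalar_ops(panel)
    for (col in c("raw_logit", "se2", "region_logit", "t2", "weight",
                  "shrunk_logit", "shrunk_prop")) {
      expect_equal(got[[col]], want[[col]], tolerance = 1e-12, label = col)
    }
  }
})

test_that("shrunk logits are convex combinations and contract variance", {
  withr::local_seed(202)
  for (i in 1:50) {
    panel <- random_panel(n_regions = 2L, areas_per_region = 5L, n_periods = 2L)
    sh <- shrink_panel(panel)
    expect_true(all(
      sh$shrunk_logit >= pmin(sh$raw_logit, sh$region_logit) - 1e-12 &
        sh$shrunk_logit <= pmax(sh$raw_logit, sh$region_logit) + 1e-12
    ))
    vars <- sh |>
      dplyr::group_by(region_id, period) |>
      dplyr::summarise(v_raw = var(raw_logit), v_shr = var(shrunk_logit),
                       .groups = "drop")
    expect_true(all(vars$v_shr <= vars$v_raw + 1e-12))
  }
})

test_that("weight increases with the case count at a fixed rate", {
  ns <- c(2, 4, 10, 50, 100, 1000, 10000)
  w <- vapply(ns, function(n) {
    shrinkage_weight(logit_se_squared(n / 2, n), t2 = 0.5)
  }, 1)
  expect_true(all(diff(w) > 0))
  expect_true(all(w >= 0 & w <= 1))
})

test_that("identical areas in one region shrink to their common value", {
  panel <- tidyr::expand_grid(area_id = sprintf("A%d", 1:5), period = 0L) |>
    dplyr::mutate(region_id = "R1", r = 50L, n = 100L)
  sh <- shrink_panel(panel)
  common <- raw_logit(50, 100)
  expect_equal(sh$t2, rep(0, 5))
  expect_equal(sh$weight, rep(0, 5))
  # pooled logit of identical-rate areas stays within 1e-9 of the common raw
  expect_equal(sh$shrunk_logit, rep(common, 5), tolerance = 1e-9)
  expect_equal(unique(sh$policy), "t2-zero-full-shrink")
})

test_that("a very well-measured area keeps its raw logit", {
  panel <- tibble::tibble(
    area_id = c("A1", "A2"), region_id = "R1", period = 0L,
    r = c(5e5, 10L), n = c(1e6, 40L)
  )
  sh <- shrink_panel(panel)
  big <- sh[sh$area_id == "A1", ]
  expect_gt(big$weight, 0.999)
  expect_equal(big$shrunk_logit, big$raw_logit, tolerance = 1e-3)
})

test_that("zero-case policies behave as documented", {
  panel <- tibble::tibble(
    area_id = c("A1", "A1", "A2", "A2"), region_id = "R1",
    period = c(0L, 1L, 0L, 1L), r = c(3L, 0L, 5L, 4L), n = c(10L, 0L, 12L, 9L)
  )
  expect_error(shrink_panel(panel, zero_case = "error"),
               class = "qitraj_domain_error")
  err <- tryCatch(shrink_panel(panel, zero_case = "error"),
                  error = function(e) e)
  expect_match(conditionMessage(err), "A1")

  filled <- shrink_panel(panel, zero_case = "region-fill")
  cell <- filled[filled$area_id == "A1" & filled$period == 1L, ]
  expect_equal(cell$weight, 0)
  expect_equal(cell$shrunk_logit, cell$region_logit)
  expect_true(is.na(cell$se2))
  expect_equal(cell$policy, "zero-case-region-fill")
  # the informative member of that period is a singleton: keeps raw
  other <- filled[filled$area_id == "A2" & filled$period == 1L, ]
  expect_equal(other$shrunk_logit, other$raw_logit)
  expect_equal(other$policy, "singleton-no-shrink")

  dropped <- shrink_panel(panel, zero_case = "drop-area")
  expect_false("A1" %in% dropped$area_id)
  expect_equal(nrow(dropped), 2L)
})

test_that("singleton regions are left unshrunk", {
  panel <- tibble::tibble(
    area_id = c("A1", "B1", "B2"), region_id = c("R1", "R2", "R2"),
    period = 0L, r = c(3L, 8L, 2L), n = c(9L, 20L, 15L)
  )
  sh <- shrink_panel(panel)
  solo <- sh[sh$area_id == "A1", ]
  expect_equal(solo$weight, 1)
  expect_equal(solo$shrunk_logit, solo$raw_logit)
  expect_equal(solo$policy, "singleton-no-shrink")
  expect_true(all(sh$policy[sh$region_id == "R2"] == "shrunk"))
})

test_that("shrink_panel validates panel structure", {
  panel <- random_panel()
  expect_error(shrink_panel(panel[, -2]), class = "qitraj_domain_error")
  dup <- dplyr::bind_rows(panel, panel[1, ])
  expect_error(shrink_panel(dup), class = "qitraj_domain_error")
  moved <- panel
  moved$region_id[1] <- "R99"
  expect_error(shrink_panel(moved), class = "qitraj_domain_error")
})

test_that("shrunk proportion is the inverse-logit of the shrunk logit", {
  withr::local_seed(7)
  sh <- shrink_panel(random_panel())
  expect_equal(sh$shrunk_prop, plogis(sh$shrunk_logit), tolerance = 1e-12)
})
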