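test_that("basis construction matches its definitions", {
  lin <- build_basis(basis_spec("linear"), 0:2)
  expect_equal(lin, cbind(c(1, 1, 1), c(0, 1, 2)))
  quad <- build_basis(basis_spec("quadratic"), 0:3)
  expect_equal(quad[, 3], (0:3)^2)
  expect_error(build_basis(basis_spec("quadratic"), 0:1),
               class = "qitraj_config_error")
  sp <- build_basis(basis_spec("spline", 4), 0:6)
  expect_equal(dim(sp), c(7L, 4L))
  expect_equal(qr(sp)$rank, 4L)
  expect_true(all(sp[, 1] == 1))
  expect_error(basis_spec("spline", 1), class = "qitraj_config_error")
  expect_error(build_basis(basis_spec("spline", 8), 0:6),
               class = "qitraj_config_error")
})

test_that("K = 1 reduces to pooled least squares", {
  withr::local_seed(31)
  Y <- matrix(runif(20 * 5), 20, 5)
  spec <- basis_spec("linear")
  fit <- fit_trajectories(Y, 1, spec = spec, seed = 1)
  B <- build_basis(spec, 0:4)
  ols <- qr.solve(B[rep(1:5, times = 20), ], as.vector(t(Y)))
  expect_equal(as.vector(fit$beta), unname(ols), tolerance = 1e-8)
  expect_equal(fit$pi, 1)
})

test_that("noiseless two-class data is recovered exactly", {
  Y <- two_flat_classes()
  fit <- fit_trajectories(Y, 2, spec = basis_spec("linear"), seed = 3)
  P <- fit$posterior
  expect_true(all(abs(P - round(P)) < 1e-6))
  mu <- sort(unique(round(as.vector(fit$basis_matrix %*% t(fit$beta)), 6)))
  expect_equal(mu, c(0.2, 0.8), tolerance = 1e-6)
  expect_equal(fit$pi[order(fit$pi)], c(0.5, 0.5), tolerance = 1e-6)
  expect_lt(fit$wmae, 1e-6)
  expect_lt(fit$wrss, 1e-6)
})

test_that("row permutation leaves the likelihood and posteriors invariant", {
  sim <- small_sim(seed = 17)
  Y <- panel_to_matrix(shrink_panel(sim$panel), shrunk_prop)
  fit <- fit_trajectories(Y, 2, seed = 5, spec = basis_spec("linear"))
  perm <- sample(nrow(Y))
  fit_p <- fit_trajectories(Y[perm, ], 2, seed = 5, spec = basis_spec("linear"))
  expect_equal(fit_p$logLik, fit$logLik, tolerance = 1e-6)
  # identical posteriors up to the same row permutation (classes may swap)
  P1 <- fit$posterior[perm, ]
  P2 <- fit_p$posterior
  direct <- max(abs(P1 - P2))
  swapped <- max(abs(P1 - P2[, 2:1]))
  expect_lt(min(direct, swapped), 1e-6)
})

test_that("EM is deterministic under a fixed seed", {
  sim <- small_sim(seed = 23)
  Y <- panel_to_matrix(shrink_panel(sim$panel), shrunk_prop)
  f1 <- fit_trajectories(Y, 3, seed = 9)
  f2 <- fit_trajectories(Y, 3, seed = 9)
  expect_identical(f1$logLik, f2$logLik)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$posterior, f2$posterior)
})

test_that("log-likelihood is non-decreasing along every EM trace", {
  withr::local_seed(47)
  for (i in 1:20) {
    N <- sample(15:40, 1)
    T_ <- sample(4:7, 1)
    Y <- matrix(plogis(rnorm(N * T_, 0, 1.2)), N, T_)
    K <- sample(1:4, 1)
    fit <- fit_trajectories(Y, K, spec = basis_spec("linear"),
                            n_starts = 2, seed = i)
    expect_true(all(diff(fit$logLik_trace) >= -1e-8))
  }
})

test_that("posterior rows sum to one and modal labels are argmax", {
  sim <- small_sim(seed = 29)
  Y <- panel_to_matrix(shrink_panel(sim$panel), shrunk_prop)
  fit <- fit_trajectories(Y, 3, seed = 2)
  expect_equal(rowSums(fit$posterior), rep(1, nrow(Y)), tolerance = 1e-10)
  expect_equal(fit$modal, max.col(fit$posterior, ties.method = "first"))
  expect_equal(sum(fit$pi), 1, tolerance = 1e-10)
  expect_equal(fit$n_params, 3 * 4 + 2 + 1)
})

test_that("metric formulas match hand evaluation", {
  expect_equal(compute_bic(0, 2, 100), 2 * log(100))
  expect_equal(compute_bic(10, 1, 1), -20)
  expect_equal(compute_bic(-5, 3, exp(3)), 19)
  expect_error(compute_bic(0, 0, 10), class = "qitraj_domain_error")

  # one area, one period: |0.6 - 0.5| and (0.6 - 0.5)^2
  one <- list(basis_matrix = matrix(1, 1, 1), beta = matrix(0.5, 1, 1),
              posterior = matrix(1, 1, 1))
  expect_equal(compute_wmae(matrix(0.6, 1, 1), one), 0.1)
  expect_equal(compute_wrss(matrix(0.6, 1, 1), one), 0.01)

  # two classes at -1 / +1, y = 0, equal posteriors
  two <- list(basis_matrix = matrix(1, 1, 1), beta = matrix(c(-1, 1), 2, 1),
              posterior = matrix(0.5, 1, 2))
  expect_equal(compute_wmae(matrix(0, 1, 1), two), 1)
  expect_equal(compute_wrss(matrix(0, 1, 1), two), 1)
})

test_that("class relabelling leaves the fit metrics unchanged", {
  sim <- small_sim(seed = 37)
  Y <- panel_to_matrix(shrink_panel(sim$panel), shrunk_prop)
  fit <- fit_trajectories(Y, 3, seed = 4)
  perm <- c(3, 1, 2)
  relab <- fit
  relab$beta <- fit$beta[perm, ]
  relab$posterior <- fit$posterior[, perm]
  relab$pi <- fit$pi[perm]
  expect_equal(compute_wmae(Y, relab), fit$wmae, tolerance = 1e-12)
  expect_equal(compute_wrss(Y, relab), fit$wrss, tolerance = 1e-12)
})

test_that("selection table covers the K range and picks min-BIC", {
  Y <- two_flat_classes(n_per = 8, n_periods = 4)
  # add small noise so likelihoods are finite and distinct
  withr::local_seed(53)
  Y <- pmin(pmax(Y + rnorm(length(Y), 0, 0.02), 0), 1)
  sel <- select_trajectories(Y, 1:3, spec = basis_spec("linear"), seed = 6)
  expect_equal(sel$k, 1:3)
  expect_equal(chosen_k(sel), sel$k[which.min(sel$bic)])
  expect_equal(chosen_k(sel), 2L)
  expect_s3_class(chosen_fit(sel), "trajectory_fit")

  single <- select_trajectories(Y, 1, spec = basis_spec("linear"), seed = 6)
  expect_equal(chosen_k(single), 1L)
})

test_that("identical trajectories select K = 1", {
  Y <- matrix(0.5, 12, 5) + matrix(rnorm(60, 0, 0.01), 12, 5)
  Y <- pmin(pmax(Y, 0), 1)
  sel <- select_trajectories(Y, 1:3, spec = basis_spec("linear"), seed = 8)
  expect_equal(chosen_k(sel), 1L)
})

test_that("group ordering and naming follow the band thresholds", {
  # flat 0.70 and rising 0.40 -> 0.55 classes, exactly on the basis
  T_ <- 5
  Y <- rbind(
    matrix(0.70, 8, T_),
    matrix(rep(seq(0.40, 0.55, length.out = T_), each = 8), 8, T_)
  )
  fit <- fit_trajectories(Y, 2, spec = basis_spec("linear"), seed = 2)
  asg <- assign_groups(fit, thresholds = c(0.45, 0.60))
  lev <- attr(asg, "group_levels")
  expect_equal(lev$group_name, c("high to high", "low to middle"))
  expect_equal(lev$group, 1:2) # ranked by final-period mean, highest first
  expect_setequal(asg$group_name[1:8], "high to high")
  expect_setequal(asg$group_name[9:16], "low to middle")
  expect_error(assign_groups(fit, thresholds = c(0.7, 0.3)),
               class = "qitraj_config_error")
})

test_that("duplicate names get deterministic rank suffixes", {
  Y <- rbind(matrix(0.62, 6, 4), matrix(0.75, 6, 4))
  fit <- fit_trajectories(Y, 2, spec = basis_spec("linear"), seed = 2)
  asg <- assign_groups(fit, thresholds = c(0.45, 0.60))
  expect_setequal(attr(asg, "group_names"),
                  c("high to high (1)", "high to high (2)"))
})

test_that("tidy and glance return the documented shapes", {
  Y <- two_flat_classes(n_per = 6, n_periods = 4)
  fit <- fit_trajectories(Y, 2, spec = basis_spec("linear"), seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 2)
  expect_named(td, c("group", "term", "estimate", "pi"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("k", "bic", "wmae", "wrss", "converged") %in% names(gl)))
  expect_equal(gl$k, 2L)
})

test_that("input validation rejects bad matrices and K", {
  Y <- two_flat_classes()
  expect_error(fit_trajectories(Y, 0), "K")
  expect_error(fit_trajectories(Y, nrow(Y) + 1), class = "qitraj_domain_error")
  Yna <- Y; Yna[1, 1] <- NA
  expect_error(fit_trajectories(Yna, 2), class = "qitraj_domain_error")
  Ybad <- Y; Ybad[1, 1] <- 1.4
  expect_error(fit_trajectories(Ybad, 2), class = "qitraj_domain_error")
})
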