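#' Time-basis specification for trajectory curves
#'
#' Declares the functional form of the class mean curves: `"linear"`
#' (intercept + slope), `"quadratic"`, or `"spline"` — a cubic B-spline
#' with an intercept column and `df - 1` spline columns, interior knots at
#' equally spaced quantiles of the period range.
#'
#' @param kind One of `"linear"`, `"quadratic"`, `"spline"`.
#' @param df Total number of basis columns (spline only); must be >= 2 and
#'   no larger than the number of periods.
#' @return A list of class `basis_spec`.
#' @export
#' @examples
#' basis_spec("spline", df = 4)
basis_spec <- function(kind = c("spline", "linear", "quadratic"), df = 4L) {
  kind <- match.arg(kind)
  if (kind == "spline") {
    df <- assert_scalar_count(df, "df", min = 2L)
  } else {
    df <- switch(kind, linear = 2L, quadratic = 3L)
  }
  structure(list(kind = kind, df = df), class = "basis_spec")
}

#' Build the design matrix for a basis over observed periods
#'
#' @param spec A [basis_spec()].
#' @param periods Strictly increasing numeric vector of time indices.
#' @return A full-column-rank T x d matrix.
#' @export
#' @examples
#' build_basis(basis_spec("linear"), 0:2)
build_basis <- function(spec, periods) {
  if (!inherits(spec, "basis_spec")) stop_config("`spec` must be a basis_spec().")
  if (length(periods) < 2L || any(diff(periods) <= 0)) {
    stop_config("`periods` must be strictly increasing with length >= 2.")
  }
  T_ <- length(periods)
  if (spec$df > T_) {
    stop_config(sprintf(
      "Basis has %d columns but only %d periods: rank-deficient design.",
      spec$df, T_
    ))
  }
  B <- switch(spec$kind,
    linear = cbind(1, periods),
    quadratic = cbind(1, periods, periods^2),
    spline = cbind(1, splines::bs(periods, df = spec$df - 1L, degree = 3L))
  )
  colnames(B) <- paste0("b", seq_len(ncol(B)) - 1L)
  if (qr(B)$rank < ncol(B)) {
    stop_config("Basis design matrix is rank-deficient for these periods.")
  }
  unname(B)
}

#' Fit a group-based trajectory model by EM
#'
#' Latent-class growth analysis: a K-component Gaussian mixture of
#' regressions over a shared time basis,
#' `l = sum_i log sum_k pi_k prod_t N(y_it; B(t) beta_k, sigma^2)`,
#' with a single residual variance shared across classes and periods.
#' The E-step computes posterior class memberships; the M-step updates
#' `beta_k` by posterior-weighted least squares, `pi_k` by the posterior
#' means, and `sigma^2` by the posterior-weighted mean squared residual.
#' The best of `n_starts` initialisations (k-means on the raw trajectories
#' first, random posterior draws after) is returned. An initialisation
#' that empties a class (max posterior below `1/(10N)`) is discarded and
#' redrawn.
#'
#' @param Y Areas x periods matrix of proportions in \[0, 1\] (e.g. from
#'   [panel_to_matrix()] on `shrunk_prop`), complete (no NA).
#' @param K Number of latent groups, `1 <= K <= nrow(Y)`.
#' @param spec Time [basis_spec()].
#' @param periods Time indices for the columns of `Y`; defaults to
#'   `0:(ncol(Y)-1)` or numeric column names when present.
#' @param n_starts Number of EM initialisations.
#' @param seed Integer seed; same seed, same fit.
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Maximum EM iterations per start.
#' @return An object of class `trajectory_fit`: a list with
#'   `K`, `pi` (mixing proportions), `beta` (K x d coefficients), `sigma2`,
#'   `logLik`, `n_params`, `basis`/`basis_matrix`/`periods`, `posterior`
#'   (N x K), `modal` (1-based modal labels), metrics `bic`, `wmae`,
#'   `wrss`, and a convergence record (`iterations`, `delta_loglik`,
#'   `logLik_trace`, `converged`, `n_restarts`).
#' @export
#' @examples
#' Y <- rbind(matrix(0.2, 5, 4), matrix(0.8, 5, 4))
#' fit <- fit_trajectories(Y, K = 2, spec = basis_spec("linear"), seed = 1)
#' fit$pi
fit_trajectories <- function(Y, K, spec = basis_spec("spline", 4L),
                             periods = NULL, n_starts = 10L, seed = 1L,
                             tol = 1e-8, max_iter = 500L) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (anyNA(Y)) stop_domain("`Y` must be complete (no missing cells).")
  if (any(Y < 0 | Y > 1)) stop_domain("`Y` entries must be proportions in [0, 1].")
  K <- assert_scalar_count(K, "K")
  if (K > nrow(Y)) stop_domain("`K` cannot exceed the number of trajectories.")
  if (is.null(periods)) {
    periods <- suppressWarnings(as.numeric(colnames(Y)))
    if (anyNA(periods) || is.null(colnames(Y))) periods <- seq_len(ncol(Y)) - 1
  }
  B <- build_basis(spec, periods)
  N <- nrow(Y); T_ <- ncol(Y); d <- ncol(B)
  withr::local_seed(seed)

  floor_pi <- 1 / (10 * N)
  best <- NULL
  n_restarts <- 0L
  attempts <- 0L
  max_attempts <- n_starts + 10L  # allow redraws after degenerate starts

  start_no <- 0L
  while (start_no < n_starts && attempts < max_attempts) {
    attempts <- attempts + 1L
    P0 <- init_posterior(Y, K, attempt = attempts)
    run <- em_run(Y, B, K, P0, tol, max_iter, floor_pi)
    if (is.null(run)) { # degenerate (empty class): redraw
      n_restarts <- n_restarts + 1L
      next
    }
    start_no <- start_no + 1L
    if (is.null(best) || run$logLik > best$logLik) best <- run
  }
  if (is.null(best)) {
    abort(
      sprintf(
        "EM failed: all %d initialisations produced an empty class (K = %d, N = %d).",
        attempts, K, N
      ),
      class = "qitraj_convergence_error"
    )
  }

  n_params <- K * d + (K - 1L) + 1L
  fit <- structure(
    list(
      K = K, pi = best$pi, beta = best$beta, sigma2 = best$sigma2,
      logLik = best$logLik, n_params = n_params,
      basis = spec, basis_matrix = B, periods = periods,
      posterior = best$posterior,
      modal = max.col(best$posterior, ties.method = "first"),
      area_ids = rownames(Y) %||% as.character(seq_len(N)),
      Y = Y,
      iterations = best$iterations, delta_loglik = best$delta,
      logLik_trace = best$trace, converged = best$converged,
      n_restarts = n_restarts
    ),
    class = "trajectory_fit"
  )
  fit$bic <- compute_bic(fit$logLik, n_params, N)
  fit$wmae <- compute_wmae(Y, fit, fit$posterior)
  fit$wrss <- compute_wrss(Y, fit, fit$posterior)
  fit
}

# Initial posteriors: Ward agglomerative clustering first (robust to
# unbalanced groups), then k-means, then random trajectories as class
# centres with hard nearest-centre assignment for the remaining starts.
init_posterior <- function(Y, K, attempt) {
  N <- nrow(Y)
  if (K == 1L) return(matrix(1, N, 1L))
  hard <- function(cl) {
    P <- matrix(0, N, K)
    P[cbind(seq_len(N), cl)] <- 1
    P
  }
  if (attempt == 1L) {
    cl <- tryCatch(
      stats::cutree(stats::hclust(stats::dist(Y), method = "ward.D2"), k = K),
      error = function(e) NULL
    )
    if (!is.null(cl)) return(hard(cl))
  }
  if (attempt == 2L) {
    km <- tryCatch(
      kmeans(Y, centers = K, nstart = 10L, iter.max = 50L),
      error = function(e) NULL
    )
    if (!is.null(km)) return(hard(km$cluster))
  }
  centres <- Y[sample.int(N, K), , drop = FALSE]
  d2 <- sapply(seq_len(K), function(k) colSums((t(Y) - centres[k, ])^2))
  hard(max.col(-matrix(d2, N, K), ties.method = "first"))
}

# One EM run from a posterior initialisation. Returns NULL if a class
# empties (caller redraws); sigma2 is floored at 1e-10 so exactly
# separable data cannot drive the likelihood to infinity.
em_run <- function(Y, B, K, P, tol, max_iter, floor_pi, sigma2_floor = 1e-10) {
  N <- nrow(Y); T_ <- ncol(Y)
  BtB <- crossprod(B)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  delta <- NA_real_
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    # --- M-step from current posteriors
    wk <- colSums(P)
    if (any(apply(P, 2L, max) < floor_pi)) return(NULL) # empty class
    pi_k <- wk / N
    # beta_k solves (B'B) beta = B' ybar_k with ybar_k the posterior-
    # weighted mean trajectory (shared design across areas)
    ybar <- t(Y) %*% P %*% diag(1 / wk, K)          # T x K
    beta <- t(solve(BtB, crossprod(B, ybar)))        # K x d
    mu <- B %*% t(beta)                              # T x K
    rss_ik <- sapply(seq_len(K), function(k) {
      colSums((t(Y) - mu[, k])^2)                    # length N
    })
    rss_ik <- matrix(rss_ik, N, K)
    sigma2 <- max(sum(P * rss_ik) / (N * T_), sigma2_floor)

    # --- E-step / log-likelihood
    log_num <- sweep(-rss_ik / (2 * sigma2), 2L, log(pi_k), `+`) -
      T_ / 2 * log(2 * pi * sigma2)
    ll_i <- logsumexp_rows(log_num)
    ll <- sum(ll_i)
    P <- exp(log_num - ll_i)
    trace <- c(trace, ll)
    delta <- ll - ll_old
    if (is.finite(ll_old) && abs(delta) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  wk <- colSums(P)
  if (any(apply(P, 2L, max) < floor_pi)) return(NULL)
  list(
    pi = wk / N, beta = beta, sigma2 = sigma2, logLik = ll,
    posterior = P, iterations = iter, delta = delta, trace = trace,
    converged = converged
  )
}

#' Bayesian information criterion
#'
#' `BIC = -2 l + p log(N)` with N the number of trajectories; lower is
#' better. Can be negative when the log-likelihood is positive (Gaussian
#' densities above 1 on a narrow response scale).
#'
#' @param loglik Maximised log-likelihood (nats).
#' @param n_params Number of free parameters.
#' @param n Number of trajectories.
#' @return BIC value.
#' @export
#' @examples
#' compute_bic(0, 2, 100)  # 2 * log(100)
compute_bic <- function(loglik, n_params, n) {
  if (n < 1 || n_params < 1) stop_domain("`n` and `n_params` must be >= 1.")
  -2 * loglik + n_params * log(n)
}

fitted_curves <- function(fit) fit$basis_matrix %*% t(fit$beta)  # T x K

#' Posterior-weighted mean absolute error
#'
#' `WMAE = (1/(N T)) sum_i sum_k p_ik sum_t |y_it - mu_k(t)|`: the mean
#' absolute deviation of observed trajectories from the class mean curves,
#' weighted by posterior class membership.
#'
#' @param Y Areas x periods matrix.
#' @param fit A `trajectory_fit` (or any object with `basis_matrix` and
#'   `beta`).
#' @param P Posterior membership matrix (defaults to `fit$posterior`).
#' @return Non-negative scalar on the response scale.
#' @export
compute_wmae <- function(Y, fit, P = fit$posterior) {
  Y <- as.matrix(Y)
  mu <- fitted_curves(fit)
  abs_ik <- sapply(seq_len(ncol(P)), function(k) colSums(abs(t(Y) - mu[, k])))
  sum(P * matrix(abs_ik, nrow(Y), ncol(P))) / (nrow(Y) * ncol(Y))
}

#' Posterior-weighted residual sum of squares
#'
#' `WRSS = sum_i sum_k p_ik sum_t (y_it - mu_k(t))^2`; no normalisation.
#'
#' @inheritParams compute_wmae
#' @return Non-negative scalar (squared-response units).
#' @export
compute_wrss <- function(Y, fit, P = fit$posterior) {
  Y <- as.matrix(Y)
  mu <- fitted_curves(fit)
  sq_ik <- sapply(seq_len(ncol(P)), function(k) colSums((t(Y) - mu[, k])^2))
  sum(P * matrix(sq_ik, nrow(Y), ncol(P)))
}

#' Fit a range of group counts and select by BIC
#'
#' Fits the trajectory model for every K in `k_range`, tabulates
#' log-likelihood, parameter count, BIC, WMAE and WRSS, and selects the K
#' minimising BIC (ties broken toward smaller K). WMAE is reported as a
#' diagnostic alongside. A K whose EM fails to converge is flagged and
#' excluded from the argmin.
#'
#' @inheritParams fit_trajectories
#' @param k_range Integer vector of candidate group counts (e.g. `1:5`).
#' @return An object of class `trajectory_selection`: a tibble with columns
#'   `k, loglik, n_params, bic, wmae, wrss, converged`, plus attributes
#'   `chosen_k` and `fits` (the per-K `trajectory_fit` objects).
#' @export
#' @examples
#' Y <- rbind(matrix(0.2, 6, 4), matrix(0.8, 6, 4))
#' sel <- select_trajectories(Y, 1:2, spec = basis_spec("linear"), seed = 1)
#' chosen_k(sel)
select_trajectories <- function(Y, k_range = 1:5, spec = basis_spec("spline", 4L),
                                periods = NULL, n_starts = 10L, seed = 1L,
                                tol = 1e-8, max_iter = 500L) {
  if (!length(k_range)) stop_config("`k_range` must be non-empty.")
  k_range <- sort(unique(as.integer(k_range)))
  fits <- purrr::map(k_range, function(k) {
    tryCatch(
      fit_trajectories(Y, k, spec = spec, periods = periods,
                       n_starts = n_starts, seed = seed + k,
                       tol = tol, max_iter = max_iter),
      qitraj_convergence_error = function(e) e
    )
  })
  ok <- !vapply(fits, inherits, TRUE, what = "condition")
  tab <- tibble::tibble(
    k = k_range,
    loglik = ifelse(ok, vapply(fits, function(f) if (inherits(f, "trajectory_fit")) f$logLik else NA_real_, 1), NA_real_),
    n_params = ifelse(ok, vapply(fits, function(f) if (inherits(f, "trajectory_fit")) f$n_params else NA_real_, 1), NA_real_),
    bic = ifelse(ok, vapply(fits, function(f) if (inherits(f, "trajectory_fit")) f$bic else NA_real_, 1), NA_real_),
    wmae = ifelse(ok, vapply(fits, function(f) if (inherits(f, "trajectory_fit")) f$wmae else NA_real_, 1), NA_real_),
    wrss = ifelse(ok, vapply(fits, function(f) if (inherits(f, "trajectory_fit")) f$wrss else NA_real_, 1), NA_real_),
    converged = ok & vapply(fits, function(f) isTRUE(f$converged), TRUE)
  )
  eligible <- which(ok)
  if (!length(eligible)) {
    abort("No candidate K converged.", class = "qitraj_convergence_error")
  }
  chosen <- k_range[eligible[which.min(tab$bic[eligible])]]
  structure(
    tab,
    class = c("trajectory_selection", class(tab)),
    chosen_k = chosen,
    fits = stats::setNames(fits[ok], paste0("K", k_range[ok]))
  )
}

#' @rdname select_trajectories
#' @param selection A `trajectory_selection`.
#' @export
chosen_k <- function(selection) attr(selection, "chosen_k")

#' @rdname select_trajectories
#' @export
chosen_fit <- function(selection) {
  attr(selection, "fits")[[paste0("K", chosen_k(selection))]]
}

band_of <- function(x, thresholds) {
  dplyr::case_when(
    x < thresholds[1] ~ "low",
    x < thresholds[2] ~ "middle",
    TRUE ~ "high"
  )
}

#' Order fitted groups and assign display names
#'
#' Groups are ranked by their fitted mean proportion at the final period
#' (highest first) and named `"<band(first)> to <band(final)>"`, where the
#' band maps a fitted mean to low / middle / high by two cutoffs on the
#' proportion scale. Two groups sharing a name are disambiguated with a
#' rank suffix, e.g. `"middle to middle (1)"`.
#'
#' @param fit A `trajectory_fit`.
#' @param thresholds Length-2 numeric `c(low, high)` with `low < high`,
#'   both in (0, 1). Defaults `c(0.45, 0.60)`.
#' @return A tibble of class `group_assignment` with one row per area:
#'   `area_id`, `group` (1 = highest final level), `group_name`,
#'   `posterior` (modal posterior probability), and one `.pr_<g>` column
#'   per ordered group. Attributes: `group_names`, `group_levels` (first
#'   and final fitted means per ordered group), `order` (permutation from
#'   fit classes to display order).
#' @export
#' @examples
#' Y <- rbind(matrix(0.2, 6, 4), matrix(0.8, 6, 4))
#' fit <- fit_trajectories(Y, 2, spec = basis_spec("linear"), seed = 1)
#' assign_groups(fit)
assign_groups <- function(fit, thresholds = c(0.45, 0.60)) {
  if (!inherits(fit, "trajectory_fit")) stop_config("`fit` must be a trajectory_fit.")
  if (length(thresholds) != 2L || thresholds[1] >= thresholds[2] ||
      any(thresholds <= 0) || any(thresholds >= 1)) {
    stop_config("`thresholds` must be c(low, high) with 0 < low < high < 1.")
  }
  mu <- fitted_curves(fit)                 # T x K
  first_mean <- mu[1L, ]
  final_mean <- mu[nrow(mu), ]
  ord <- order(final_mean, decreasing = TRUE)

  names0 <- paste(band_of(first_mean[ord], thresholds), "to",
                  band_of(final_mean[ord], thresholds))
  dup <- names0 %in% names0[duplicated(names0)]
  if (any(dup)) {
    for (nm in unique(names0[dup])) {
      idx <- which(names0 == nm)
      names0[idx] <- sprintf("%s (%d)", nm, seq_along(idx))
    }
  }

  P_ord <- fit$posterior[, ord, drop = FALSE]
  colnames(P_ord) <- paste0(".pr_", seq_len(fit$K))
  modal_ord <- max.col(P_ord, ties.method = "first")

  out <- tibble::tibble(
    area_id = fit$area_ids,
    group = modal_ord,
    group_name = names0[modal_ord],
    posterior = P_ord[cbind(seq_len(nrow(P_ord)), modal_ord)]
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(P_ord))
  structure(
    out,
    class = c("group_assignment", class(out)),
    group_names = names0,
    group_levels = tibble::tibble(
      group = seq_len(fit$K), group_name = names0,
      first_mean = first_mean[ord], final_mean = final_mean[ord],
      pi = fit$pi[ord]
    ),
    order = ord
  )
}
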