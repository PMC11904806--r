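# Pleiotropy-robust estimators: robust IVW, contamination mixture,
# MR-PRESSO, constrained maximum likelihood.

#' Robust IVW via Tukey-biweight M-estimation
#'
#' Fits the through-origin regression of `beta_outcome/se_outcome` on
#' `beta_exposure/se_outcome` by iteratively reweighted least squares with
#' the Tukey biweight (tuning constant 4.685 gives 95% efficiency under
#' normality), downweighting instruments with outlying ratio residuals.
#' The SE uses the M-estimation sandwich form. When residuals vanish the
#' fit reduces exactly to fixed-effect IVW with first-order weights.
#'
#' @param data Harmonized instrument tibble (>= 3 usable rows).
#' @param tuning Tukey biweight tuning constant.
#' @param max_iter IRLS iteration cap.
#' @return An `mr_result` (method `"ivw_robust"`).
#' @export
mr_ivw_robust <- function(data, tuning = 4.685, max_iter = 100) {
  data <- check_instruments(data, 3, "ivw_robust")
  x <- data$beta_exposure / data$se_outcome
  y <- data$beta_outcome / data$se_outcome
  theta <- sum(x * y) / sum(x^2) # WLS start = first-order IVW
  se_fe <- sqrt(1 / sum(x^2))
  psi <- function(u) ifelse(abs(u) <= tuning, u * (1 - (u / tuning)^2)^2, 0)
  dpsi <- function(u) {
    ifelse(abs(u) <= tuning, (1 - (u / tuning)^2) * (1 - 5 * (u / tuning)^2), 0)
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- y - theta * x
    s <- mad(r, center = 0)
    if (s < 1e-10) { # exact fit: robust = plain fixed-effect IVW
      return(new_mr_result("ivw_robust", theta, se_fe, length(x),
        extras = list(tuning = tuning, iterations = it, scale = 0, data = data)
      ))
    }
    u <- r / s
    w <- ifelse(abs(u) <= tuning, (1 - (u / tuning)^2)^2, 0)
    if (sum(w * x^2) <= 0) {
      abort_convergence("ivw_robust: all instruments downweighted to zero")
    }
    theta_new <- sum(w * x * y) / sum(w * x^2)
    if (abs(theta_new - theta) < 1e-10 * max(1, abs(theta))) {
      theta <- theta_new
      converged <- TRUE
      break
    }
    theta <- theta_new
  }
  if (!converged) {
    abort_convergence(paste0(
      "ivw_robust failed to converge after ", max_iter,
      " iterations (last theta = ", signif(theta, 6), ")"
    ))
  }
  r <- y - theta * x
  s <- mad(r, center = 0)
  u <- r / s
  denom <- sum(dpsi(u) * x^2)
  se <- if (denom > 0) s * sqrt(sum(psi(u)^2 * x^2)) / denom else se_fe
  new_mr_result("ivw_robust", theta, se, length(x),
    extras = list(tuning = tuning, iterations = it, scale = s, data = data)
  )
}

#' Contamination-mixture causal estimate
#'
#' Profiles a two-component likelihood over a grid of candidate causal
#' effects: each instrument's ratio estimate is explained either by the
#' valid component `N(theta, se_j^2)` or by an invalid component
#' `N(0, se_j^2 + psi^2)`, whichever is more likely. The estimate
#' maximizes the summed per-instrument log-likelihood; the 95% CI is the
#' span of grid points within `qchisq(0.95, 1)/2` of the maximum, and the
#' valid set is read off at the maximizing effect.
#'
#' @param data Harmonized instrument tibble (>= 3 usable rows).
#' @param psi SD of the invalid component; default `1.5 * sd(ratio
#'   estimates)`.
#' @param theta_grid `c(lo, hi, step)` on the standardized scale: the grid
#'   evaluated is `weighted_mean(ratios) + z * sd(ratios)` for `z` in
#'   `seq(lo, hi, step)` (default `c(-2, 2, 0.001)`).
#' @param weights Delta-weight order for ratio variances.
#' @return An `mr_result` (method `"conmix"`) with `extras$valid_set` (ids)
#'   and `extras$psi`.
#' @export
mr_conmix <- function(data, psi = NULL, theta_grid = c(-2, 2, 0.001),
                      weights = c("second", "first")) {
  weights <- arg_match(weights)
  data <- check_instruments(data, 3, "conmix")
  rs <- ratio_stats(data, weights)
  sej <- sqrt(rs$var)
  s <- sd(rs$theta)
  if (!is.finite(s) || s <= 0) s <- max(sej)
  psi <- psi %||% (1.5 * s)
  if (psi <= 0) abort_config("conmix: psi must be positive")
  mu <- sum(rs$w * rs$theta) / sum(rs$w)
  grid <- mu + seq(theta_grid[1], theta_grid[2], by = theta_grid[3]) * s
  ll_invalid <- stats::dnorm(rs$theta, 0, sqrt(sej^2 + psi^2), log = TRUE)
  # G x J valid log-likelihoods, each row capped below by the invalid component
  ll <- vapply(seq_along(grid), function(g) {
    sum(pmax(stats::dnorm(rs$theta, grid[g], sej, log = TRUE), ll_invalid))
  }, numeric(1))
  i_max <- which.max(ll)
  if (i_max == 1 || i_max == length(grid)) {
    warn("conmix: estimate lies on the grid boundary; widen theta_grid")
  }
  theta <- grid[i_max]
  in_ci <- ll >= ll[i_max] - qchisq(0.95, 1) / 2
  ci_low <- min(grid[in_ci])
  ci_high <- max(grid[in_ci])
  se <- max((ci_high - ci_low) / (2 * qnorm(0.975)), theta_grid[3] * s / 2)
  valid <- stats::dnorm(rs$theta, theta, sej, log = TRUE) >= ll_invalid
  new_mr_result("conmix", theta, se, nrow(data),
    ci_low = ci_low, ci_high = ci_high,
    extras = list(
      psi = psi, valid_set = data$variant_id[valid],
      n_valid = sum(valid), loglik = ll[i_max], data = data
    )
  )
}

#' MR-PRESSO global pleiotropy test with outlier correction
#'
#' The observed residual sum of squares of leave-one-out IVW predictions
#' is compared with its parametric null distribution: in each of `n_sim`
#' simulations, outcome effects are redrawn as
#' `beta_Yj* ~ N(theta_(-j) * beta_Xj, se_Yj^2)` and the LOO RSS
#' recomputed. Per-instrument outlier p-values come from each instrument's
#' simulated squared-residual distribution, Bonferroni-adjusted across
#' instruments; the corrected estimate is IVW on the non-outliers, and the
#' distortion test compares the observed raw-vs-corrected shift against
#' the shift obtained by removing equally many random instruments in the
#' simulations. Residuals are standardized by `se_outcome`, and IVW inside
#' the test uses first-order weights (independent of the simulated outcome
#' betas).
#'
#' @param data Harmonized instrument tibble (>= 4 usable rows).
#' @param n_sim Number of parametric simulations (>= 100).
#' @param seed Integer seed.
#' @param outlier_alpha Significance level for flagging outliers after
#'   Bonferroni adjustment.
#' @return An `mr_result` (method `"presso"`): theta/se are the
#'   outlier-corrected IVW (identical to raw when nothing is flagged);
#'   `extras` carry `global_p`, `outliers`, `outlier_p`, `distortion_p`,
#'   `theta_raw`.
#' @export
mr_presso <- function(data, n_sim = 1000, seed = 1, outlier_alpha = 0.05) {
  if (n_sim < 100) abort_config("mr_presso: n_sim must be >= 100")
  data <- check_instruments(data, 4, "presso")
  J <- nrow(data)
  bx <- data$beta_exposure
  sy <- data$se_outcome
  w <- bx^2 / sy^2 # first-order ratio weights

  loo_theta <- function(by) {
    th <- by / bx
    s1 <- sum(w * th)
    s0 <- sum(w)
    (s1 - w * th) / (s0 - w)
  }
  th_loo <- loo_theta(data$beta_outcome)
  res_obs <- (data$beta_outcome - th_loo * bx) / sy
  rss_obs <- sum(res_obs^2)

  sim <- withr::with_seed(seed, {
    by_star <- matrix(rnorm(J * n_sim, mean = th_loo * bx, sd = sy), nrow = J)
    th_star <- by_star / bx
    s1 <- colSums(w * th_star)
    s0 <- sum(w)
    th_loo_star <- (rep(s1, each = J) - w * th_star) / (s0 - w)
    res_star <- (by_star - th_loo_star * bx) / sy
    list(res2 = res_star^2, rss = colSums(res_star^2))
  })
  global_p <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  outlier_p <- vapply(seq_len(J), function(j) {
    (1 + sum(sim$res2[j, ] >= res_obs[j]^2)) / (n_sim + 1)
  }, numeric(1))
  outlier_p_adj <- pmin(1, outlier_p * J)
  outliers <- which(outlier_p_adj < outlier_alpha)

  raw <- mr_ivw(data, random_effects = "fixed", weights = "first")
  if (length(outliers) > 0 && J - length(outliers) >= 2) {
    corrected <- mr_ivw(data[-outliers, , drop = FALSE],
      random_effects = "fixed", weights = "first"
    )
    # Distortion null: the raw-vs-corrected shift when equally many
    # instruments are removed at random from each simulated dataset.
    obs_shift <- raw$theta - corrected$theta
    dist_null <- withr::with_seed(derive_seed(seed, "distortion"), {
      by_star <- matrix(rnorm(J * n_sim, mean = th_loo * bx, sd = sy), nrow = J)
      vapply(seq_len(n_sim), function(b) {
        drop <- sample.int(J, length(outliers))
        th_all <- sum(w * by_star[, b] / bx) / sum(w)
        th_sub <- sum((w * by_star[, b] / bx)[-drop]) / sum(w[-drop])
        th_all - th_sub
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(dist_null) >= abs(obs_shift))) / (n_sim + 1)
    est <- corrected
  } else {
    est <- raw
    distortion_p <- NA_real_
  }
  new_mr_result("presso", est$theta, est$se, est$n_snps,
    extras = list(
      global_p = global_p, rss_obs = rss_obs,
      outlier_p = setNames(outlier_p_adj, data$variant_id),
      outliers = data$variant_id[outliers],
      theta_raw = raw$theta, se_raw = raw$se,
      distortion_p = distortion_p, n_sim = n_sim, data = data
    )
  )
}

#' Constrained-maximum-likelihood estimate with BIC model selection
#'
#' For each candidate count `K` of invalid instruments, maximizes the
#' Gaussian likelihood in which exactly `K` instruments receive free
#' pleiotropy parameters, by coordinate ascent: given the causal effect,
#' the `K` instruments with the largest standardized squared residuals are
#' declared invalid; given the invalid set, the effect is the first-order
#' IVW of the valid instruments. `K` is selected by
#' `BIC(K) = 2 negloglik + K log(n)`, with `n` the smaller of the two GWAS
#' sample sizes (the standard cML penalty; the instrument count would
#' under-penalize and inflate `K` on clean data). Multiple deterministic
#' and seeded random starts guard against local optima. This is the
#' BIC-selection variant; no model averaging or data perturbation is
#' applied.
#'
#' @param data Harmonized instrument tibble (>= 3 usable rows).
#' @param K_max Largest invalid count considered; default `J - 2`.
#' @param seed Seed for the random starts.
#' @param max_iter Coordinate-ascent iteration cap per start.
#' @param bic_n Sample size used in the BIC penalty; defaults to
#'   `min(median(n_exposure), median(n_outcome))`, falling back to `J`
#'   when the table carries no sample sizes.
#' @return An `mr_result` (method `"cml"`) with `extras$K_selected`,
#'   `extras$invalid_set`, `extras$bic` (per-K table).
#' @export
mr_cml <- function(data, K_max = NULL, seed = 1, max_iter = 200, bic_n = NULL) {
  data <- check_instruments(data, 3, "cml")
  J <- nrow(data)
  K_max <- min(K_max %||% (J - 2), J - 2)
  if (is.null(bic_n)) {
    ns <- c(
      if ("n_exposure" %in% names(data)) median(data$n_exposure, na.rm = TRUE),
      if ("n_outcome" %in% names(data)) median(data$n_outcome, na.rm = TRUE)
    )
    bic_n <- if (length(ns) > 0 && any(is.finite(ns))) min(ns, na.rm = TRUE) else J
  }
  bx <- data$beta_exposure
  by <- data$beta_outcome
  w <- 1 / data$se_outcome^2
  ratios <- by / bx

  fit_K <- function(K, starts) {
    best <- NULL
    for (theta0 in starts) {
      theta <- theta0
      invalid <- integer(0)
      ok <- FALSE
      for (it in seq_len(max_iter)) {
        r2 <- w * (by - theta * bx)^2
        invalid_new <- if (K > 0) order(r2, decreasing = TRUE)[seq_len(K)] else integer(0)
        valid <- setdiff(seq_len(J), invalid_new)
        theta_new <- sum((w * bx * by)[valid]) / sum((w * bx^2)[valid])
        if (setequal(invalid_new, invalid) &&
          abs(theta_new - theta) < 1e-10 * max(1, abs(theta))) {
          theta <- theta_new
          invalid <- invalid_new
          ok <- TRUE
          break
        }
        theta <- theta_new
        invalid <- invalid_new
      }
      if (!ok) next
      valid <- setdiff(seq_len(J), invalid)
      nll2 <- sum((w * (by - theta * bx)^2)[valid]) # 2 * negloglik + const
      cand <- list(theta = theta, invalid = invalid, nll2 = nll2, valid = valid)
      if (is.null(best) || cand$nll2 < best$nll2) best <- cand
    }
    if (is.null(best)) {
      abort_convergence(paste0("mr_cml: no start converged for K = ", K))
    }
    best
  }

  starts <- withr::with_seed(seed, {
    c(
      sum(w * bx * by) / sum(w * bx^2), median(ratios),
      sample(ratios, min(4, J))
    )
  })
  fits <- map(0:K_max, function(K) {
    f <- fit_K(K, starts)
    f$K <- K
    f$bic <- f$nll2 + K * log(bic_n)
    f
  })
  bic_tbl <- tibble(
    K = map_dbl(fits, "K"), bic = map_dbl(fits, "bic"),
    nll2 = map_dbl(fits, "nll2")
  )
  sel <- fits[[which.min(bic_tbl$bic)]]
  se <- sqrt(1 / sum((w * bx^2)[sel$valid]))
  new_mr_result("cml", sel$theta, se, length(sel$valid),
    extras = list(
      K_selected = sel$K, BIC = min(bic_tbl$bic), bic = bic_tbl,
      invalid_set = data$variant_id[sel$invalid], data = data
    )
  )
}
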