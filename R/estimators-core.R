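# Core causal estimators: Wald ratio, IVW delta, MR-Egger, weighted
# median, weighted mode, Cochran's Q, Steiger directionality.
#
# All estimators consume a harmonized instrument table (columns
# beta_exposure, se_exposure, beta_outcome, se_outcome, ...) restricted to
# usable rows, and return an mr_result.

check_instruments <- function(data, min_n, method) {
  data <- usable_instruments(data)
  if (any(data$se_exposure <= 0) || any(data$se_outcome <= 0)) {
    abort_input(paste0(method, ": standard errors must be positive"))
  }
  if (nrow(data) < min_n) {
    abort_insufficient(paste0(
      method, " needs at least ", min_n, " usable instruments (got ", nrow(data), ")"
    ))
  }
  data
}

# Per-instrument Wald ratios and their delta-method variances.
# Second-order delta (default): var = se_Y^2/bX^2 + bY^2 * se_X^2 / bX^4.
# First-order: var = se_Y^2 / bX^2.
ratio_stats <- function(data, weights = c("second", "first")) {
  weights <- arg_match(weights)
  bx <- data$beta_exposure
  by <- data$beta_outcome
  if (any(bx == 0)) abort_input("ratio estimate undefined: beta_exposure = 0")
  v1 <- data$se_outcome^2 / bx^2
  v <- if (weights == "first") v1 else v1 + by^2 * data$se_exposure^2 / bx^4
  tibble(theta = by / bx, var = v, w = 1 / v)
}

#' Wald ratio estimate from a single instrument
#'
#' The single-instrument causal estimate `theta = beta_Y / beta_X` with a
#' delta-method SE: first-order `|se_Y / beta_X|` or second-order
#' `sqrt(se_Y^2/beta_X^2 + beta_Y^2 se_X^2 / beta_X^4)`.
#'
#' @param data One-row harmonized instrument tibble.
#' @param order `"second"` (default) or `"first"` delta expansion.
#' @return An `mr_result` (method `"wald"`).
#' @export
mr_wald_ratio <- function(data, order = c("second", "first")) {
  order <- arg_match(order)
  data <- check_instruments(data, 1, "wald_ratio")
  data <- slice(data, 1)
  rs <- ratio_stats(data, weights = order)
  new_mr_result("wald", rs$theta, sqrt(rs$var), 1,
    extras = list(order = order, data = data)
  )
}

#' Inverse-variance-weighted (IVW delta) estimate
#'
#' The primary estimator: the inverse-variance-weighted average of the
#' per-instrument Wald ratios, with delta-method ratio variances
#' (second-order by default). Under multiplicative random effects the SE is
#' inflated by `max(1, sqrt(Q/(J-1)))`; `random_effects = "auto"` (the
#' default) uses multiplicative inflation for J >= 4 and fixed effects for
#' smaller instrument sets. Cochran's Q, its p-value and the realized
#' inflation are returned in `extras`.
#'
#' @param data Harmonized instrument tibble (>= 2 usable rows).
#' @param random_effects `"auto"`, `"fixed"` or `"multiplicative"`.
#' @param weights `"second"` (default) or `"first"` order delta weights.
#' @return An `mr_result` (method `"ivw"`).
#' @export
mr_ivw <- function(data, random_effects = c("auto", "fixed", "multiplicative"),
                   weights = c("second", "first")) {
  random_effects <- arg_match(random_effects)
  weights <- arg_match(weights)
  data <- check_instruments(data, 2, "ivw")
  rs <- ratio_stats(data, weights)
  J <- nrow(rs)
  theta <- sum(rs$w * rs$theta) / sum(rs$w)
  se_fe <- sqrt(1 / sum(rs$w))
  Q <- sum(rs$w * (rs$theta - theta)^2)
  p_q <- pchisq(Q, df = J - 1, lower.tail = FALSE)
  re <- switch(random_effects,
    auto = if (J >= 4) "multiplicative" else "fixed",
    random_effects
  )
  inflation <- if (re == "multiplicative") max(1, sqrt(Q / (J - 1))) else 1
  new_mr_result("ivw", theta, se_fe * inflation, J,
    extras = list(
      Q = Q, df_Q = J - 1, p_Q = p_q, re_inflation = inflation,
      random_effects = re, weights = weights, data = data
    )
  )
}

#' MR-Egger regression with the intercept pleiotropy test
#'
#' Instruments are first oriented so that `beta_exposure >= 0`; the
#' weighted linear regression of `beta_outcome` on `beta_exposure` (weights
#' `1/se_outcome^2`) then gives the causal slope and an intercept whose
#' deviation from zero measures directional pleiotropy (consistent under
#' InSIDE). Both SEs carry the multiplicative inflation
#' `max(1, sqrt(RSS_w/(J-2)))`. The regression is solved in closed form
#' from the weighted normal equations.
#'
#' @param data Harmonized instrument tibble (>= 3 usable rows).
#' @return An `mr_result` (method `"egger"`) whose `extras` carry
#'   `intercept`, `se_intercept`, `p_intercept` and the inflation factor.
#' @export
mr_egger <- function(data) {
  data <- check_instruments(data, 3, "egger")
  flip <- sign(data$beta_exposure)
  flip[flip == 0] <- 1
  x <- data$beta_exposure * flip
  y <- data$beta_outcome * flip
  v <- 1 / data$se_outcome^2
  J <- length(x)
  W <- sum(v); Sx <- sum(v * x); Sy <- sum(v * y)
  Sxx <- sum(v * x^2); Sxy <- sum(v * x * y)
  det <- W * Sxx - Sx^2
  if (det <= 0) abort_input("egger: degenerate design (no spread in beta_exposure)")
  slope <- (W * Sxy - Sx * Sy) / det
  intercept <- (Sxx * Sy - Sx * Sxy) / det
  rss <- sum(v * (y - intercept - slope * x)^2)
  sigma <- max(1, sqrt(rss / (J - 2)))
  se_slope <- sqrt(W / det) * sigma
  se_int <- sqrt(Sxx / det) * sigma
  new_mr_result("egger", slope, se_slope, J,
    extras = list(
      intercept = intercept, se_intercept = se_int,
      p_intercept = z_pvalue(intercept, se_int),
      Q_egger = rss, re_inflation = sigma, data = data
    )
  )
}

# Weighted median of ratio estimates: order theta ascending, form
# standardized cumulative weights s_j = (cumsum(w) - w/2)/sum(w), and
# interpolate theta at s = 0.5.
weighted_median_point <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  ws <- w[o]
  s <- (cumsum(ws) - ws / 2) / sum(ws)
  approx(s, th, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' Consistent when instruments contributing at least half the total weight
#' are valid. The SE comes from a parametric bootstrap: `n_boot` resamples
#' of `(beta_X, beta_Y)` from their normal sampling distributions, the
#' weighted median recomputed on each.
#'
#' @param data Harmonized instrument tibble (>= 3 usable rows).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param weights Delta-weight order for the ratio variances.
#' @return An `mr_result` (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = 1,
                               weights = c("second", "first")) {
  weights <- arg_match(weights)
  data <- check_instruments(data, 3, "weighted_median")
  rs <- ratio_stats(data, weights)
  theta <- weighted_median_point(rs$theta, rs$w)
  se <- boot_ratio_se(data, weights, n_boot, seed, weighted_median_point)
  new_mr_result("weighted_median", theta, se, nrow(data),
    extras = list(n_boot = n_boot, data = data)
  )
}

# Parametric bootstrap SE for ratio-based point estimators.
boot_ratio_se <- function(data, weights, n_boot, seed, point_fun, ...) {
  J <- nrow(data)
  withr::with_seed(seed, {
    bx <- matrix(rnorm(J * n_boot, data$beta_exposure, data$se_exposure), nrow = J)
    by <- matrix(rnorm(J * n_boot, data$beta_outcome, data$se_outcome), nrow = J)
    est <- vapply(seq_len(n_boot), function(b) {
      bxb <- bx[, b]
      bxb[bxb == 0] <- .Machine$double.eps
      th <- by[, b] / bxb
      v1 <- data$se_outcome^2 / bxb^2
      v <- if (weights == "first") v1 else v1 + by[, b]^2 * data$se_exposure^2 / bxb^4
      point_fun(th, 1 / v, ...)
    }, numeric(1))
    sd(est)
  })
}

# Weighted kernel-density mode of the ratio estimates.
weighted_mode_point <- function(theta, w, bandwidth_factor = 1) {
  w <- w / sum(w)
  spread <- min(sd(theta), mad(theta))
  if (!is.finite(spread) || spread <= 0) spread <- sd(theta)
  if (!is.finite(spread) || spread <= 0) return(theta[1])
  h <- bandwidth_factor * 0.9 * spread * length(theta)^(-1 / 5)
  dens <- function(x) {
    vapply(x, function(xx) sum(w * stats::dnorm((xx - theta) / h)), numeric(1))
  }
  grid <- seq(min(theta) - h, max(theta) + h, length.out = 512)
  fg <- dens(grid)
  i <- which.max(fg)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  optimize(dens, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
}

#' Weighted-mode causal estimate
#'
#' The mode of a weighted normal-kernel density over the per-instrument
#' ratio estimates (bandwidth: `bandwidth_factor` times the modified
#' Silverman rule `0.9 min(sd, mad) J^{-1/5}`), consistent when the largest
#' homogeneous cluster of instruments is valid (ZEMPA). SE by parametric
#' bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the Silverman bandwidth
#'   (default 1).
#' @return An `mr_result` (method `"weighted_mode"`).
#' @export
mr_weighted_mode <- function(data, bandwidth_factor = 1, n_boot = 1000,
                             seed = 1, weights = c("second", "first")) {
  weights <- arg_match(weights)
  data <- check_instruments(data, 3, "weighted_mode")
  rs <- ratio_stats(data, weights)
  theta <- weighted_mode_point(rs$theta, rs$w, bandwidth_factor)
  se <- boot_ratio_se(data, weights, n_boot, seed, weighted_mode_point, bandwidth_factor)
  new_mr_result("weighted_mode", theta, se, nrow(data),
    extras = list(bandwidth_factor = bandwidth_factor, n_boot = n_boot, data = data)
  )
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (theta_j - theta_ref)^2` over per-instrument ratio
#' estimates, referred to a chi-square with `J - 1` degrees of freedom.
#'
#' @param data Harmonized instrument tibble (>= 2 usable rows).
#' @param theta_ref Reference causal effect; defaults to the fixed-effect
#'   IVW estimate computed from the same weights.
#' @param weights Delta-weight order.
#' @return A list with `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(data, theta_ref = NULL, weights = c("second", "first")) {
  weights <- arg_match(weights)
  data <- check_instruments(data, 2, "cochran_q")
  rs <- ratio_stats(data, weights)
  if (is.null(theta_ref)) theta_ref <- sum(rs$w * rs$theta) / sum(rs$w)
  Q <- sum(rs$w * (rs$theta - theta_ref)^2)
  df <- nrow(rs) - 1
  list(Q = Q, df = df, pvalue = pchisq(Q, df, lower.tail = FALSE))
}

#' Steiger directionality test
#'
#' Sums per-variant variance explained on the exposure and outcome sides,
#' `r2_j = 2 eaf (1-eaf) beta^2 / (2 eaf (1-eaf) (beta^2 + se^2 n))`, and
#' compares the implied correlations `r = sqrt(R2)` with a two-sample
#' Fisher-z test: `z = (atanh r_X - atanh r_Y) / sqrt(1/(n_X-3) + 1/(n_Y-3))`.
#' The inferred direction is exposure-to-outcome iff `R2_exposure >
#' R2_outcome`. For binary outcomes the observed-scale approximation is
#' used and flagged as approximate.
#'
#' @param data Harmonized instrument tibble; `eaf` must be present for
#'   every usable row.
#' @param n_exposure,n_outcome Effective sample sizes; default to the
#'   median of the per-variant `n_*` columns.
#' @param outcome_type `"quantitative"` or `"binary"`.
#' @return A list of class `steiger_result`: `r2_exposure`, `r2_outcome`,
#'   `direction`, `z`, `pvalue`, `approx_binary`.
#' @export
mr_steiger <- function(data, n_exposure = NULL, n_outcome = NULL,
                       outcome_type = c("quantitative", "binary")) {
  outcome_type <- arg_match(outcome_type)
  data <- check_instruments(data, 1, "steiger")
  if (anyNA(data$eaf)) {
    abort_input(paste0(
      "steiger: missing eaf for variant(s) ",
      paste(data$variant_id[is.na(data$eaf)], collapse = ", ")
    ))
  }
  n_exposure <- n_exposure %||% median(data$n_exposure, na.rm = TRUE)
  n_outcome <- n_outcome %||% median(data$n_outcome, na.rm = TRUE)
  r2_one <- function(eaf, beta, se, n) {
    het <- 2 * eaf * (1 - eaf)
    het * beta^2 / (het * beta^2 + het * se^2 * n)
  }
  r2x <- sum(r2_one(data$eaf, data$beta_exposure, data$se_exposure, n_exposure))
  r2y <- sum(r2_one(data$eaf, data$beta_outcome, data$se_outcome, n_outcome))
  r2x <- min(r2x, 1 - 1e-12)
  r2y <- min(r2y, 1 - 1e-12)
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  structure(
    list(
      r2_exposure = r2x, r2_outcome = r2y,
      direction = if (r2x > r2y) "exposure_to_outcome" else "outcome_to_exposure",
      z = z, pvalue = 2 * pnorm(-abs(z)),
      approx_binary = outcome_type == "binary",
      n_snps = nrow(data)
    ),
    class = "steiger_result"
  )
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf(
    "<steiger_result> direction = %s\n  R2 exposure = %.4g, R2 outcome = %.4g, z = %.3g, p = %.3g%s\n",
    x$direction, x$r2_exposure, x$r2_outcome, x$z, x$pvalue,
    if (x$approx_binary) " (binary outcome: observed-scale approximation)" else ""
  ))
  invisible(x)
}

#' @method tidy steiger_result
#' @export
tidy.steiger_result <- function(x, ...) {
  tibble(
    r2_exposure = x$r2_exposure, r2_outcome = x$r2_outcome,
    direction = x$direction, z = x$z, pvalue = x$pvalue
  )
}
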