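test_that("Wald ratio matches its closed forms", {
  # first-order: se_X plays no role
  h <- make_inst(bx = 2, sx = 1e-9, by = 1, sy = 0.2)
  fit <- mr_wald_ratio(h, order = "first")
  expect_equal(fit$theta, 0.5)
  expect_equal(fit$se, 0.1)

  # zero numerator: null estimate, p = 1
  h0 <- make_inst(bx = 2, sx = 0.1, by = 0, sy = 0.2)
  fit0 <- mr_wald_ratio(h0)
  expect_equal(fit0$theta, 0)
  expect_equal(fit0$pvalue, 1)

  # second-order delta expression evaluated independently:
  # sqrt(se_Y^2/bX^2 + bY^2 se_X^2 / bX^4) at (0.5, 0.05, 0.1, 0.05)
  h2 <- make_inst(bx = 0.5, sx = 0.05, by = 0.1, sy = 0.05)
  fit2 <- mr_wald_ratio(h2, order = "second")
  expect_equal(fit2$theta, 0.2)
  expect_equal(fit2$se, sqrt(0.05^2 / 0.5^2 + 0.1^2 * 0.05^2 / 0.5^4), tolerance = 1e-14)
})

test_that("IVW reduces correctly under homogeneity and matches the WLS oracle", {
  # two identical instruments, equal weights: theta unchanged, se / sqrt(2)
  h <- make_inst(bx = c(1, 1), sx = 1e-9, by = c(0.3, 0.3), sy = 0.1)
  single <- mr_wald_ratio(h[1, ])
  fit <- mr_ivw(h)
  expect_equal(fit$theta, 0.3)
  expect_equal(fit$se, single$se / sqrt(2), tolerance = 1e-12)
  expect_equal(fit$extras$Q, 0)

  # first-order IVW equals the through-origin WLS slope with 1/se_Y^2 weights
  for (s in 1:10) {
    h <- gen_ratio_data(12, 0.25, seed = 100 + s)
    fit <- mr_ivw(h, random_effects = "fixed", weights = "first")
    wls <- stats::lm(beta_outcome ~ beta_exposure - 1,
      data = h, weights = 1 / h$se_outcome^2
    )
    expect_equal(fit$theta, unname(coef(wls)), tolerance = 1e-10)
  }
})

test_that("IVW outputs are invariant to instrument order and allele flips", {
  h <- gen_ratio_data(15, 0.2, seed = 7)
  fit <- mr_ivw(h)
  perm <- h[sample(nrow(h)), ]
  expect_mr_equal(mr_ivw(perm), fit, tol = 1e-14)

  flip <- h
  idx <- c(2, 5, 11)
  flip$beta_exposure[idx] <- -flip$beta_exposure[idx]
  flip$beta_outcome[idx] <- -flip$beta_outcome[idx]
  expect_mr_equal(mr_ivw(flip), fit, tol = 1e-14)
  # stochastic SEs are flip-invariant only in distribution (the RNG stream
  # maps onto different instruments); the point estimate is exact
  expect_equal(
    mr_weighted_median(flip, n_boot = 100, seed = 3)$theta,
    mr_weighted_median(h, n_boot = 100, seed = 3)$theta,
    tolerance = 1e-12
  )
  # Egger re-orients internally, so flipping is a no-op by construction
  expect_mr_equal(mr_egger(flip), mr_egger(h), tol = 1e-14)
})

test_that("Egger recovers an exact affine relation and matches weighted lm", {
  h <- make_inst(bx = c(1, 2, 3), sx = 1e-9, by = c(0.6, 1.1, 1.6), sy = 0.1)
  fit <- mr_egger(h)
  expect_equal(fit$theta, 0.5, tolerance = 1e-12)
  expect_equal(fit$extras$intercept, 0.1, tolerance = 1e-12)
  expect_equal(fit$extras$Q_egger, 0, tolerance = 1e-20)

  # exactly proportional: zero intercept with p -> 1
  hp <- make_inst(bx = c(1, 2, 3), sx = 1e-9, by = 0.4 * c(1, 2, 3), sy = 0.1)
  fitp <- mr_egger(hp)
  expect_equal(fitp$extras$intercept, 0, tolerance = 1e-12)
  expect_equal(fitp$extras$p_intercept, 1, tolerance = 1e-9)

  # weighted-regression oracle (with the same not-below-1 dispersion rule)
  for (s in 1:6) {
    h <- gen_ratio_data(20, 0.3, seed = 300 + s, alpha = 0.03)
    fit <- mr_egger(h)
    o <- sign(h$beta_exposure)
    lmfit <- stats::lm(I(o * beta_outcome) ~ I(o * beta_exposure),
      data = h, weights = 1 / h$se_outcome^2
    )
    expect_equal(fit$theta, unname(coef(lmfit)[2]), tolerance = 1e-10)
    expect_equal(fit$extras$intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
    sigma_hat <- summary(lmfit)$sigma
    adj <- max(1, sigma_hat) / sigma_hat
    expect_equal(fit$se, unname(sqrt(diag(vcov(lmfit)))[2]) * adj, tolerance = 1e-8)
    expect_equal(fit$extras$se_intercept,
      unname(sqrt(diag(vcov(lmfit)))[1]) * adj,
      tolerance = 1e-8
    )
  }
})

test_that("weighted median interpolates the 0.5 quantile of ratio weight", {
  h <- make_inst(bx = c(1, 1, 1), sx = 1e-9, by = c(0.2, 0.3, 10), sy = 0.1)
  fit <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(fit$theta, 0.3)

  hc <- make_inst(bx = c(1, 2, 4), sx = 1e-9, by = 0.7 * c(1, 2, 4), sy = 1e-6)
  fitc <- mr_weighted_median(hc, n_boot = 200, seed = 1)
  expect_equal(fitc$theta, 0.7, tolerance = 1e-6)
  expect_lt(fitc$se, 1e-4)
})

test_that("weighted median resists 30% directional pleiotropy better than IVW", {
  reps <- 150
  th_ivw <- th_wm <- numeric(reps)
  for (i in seq_len(reps)) {
    scn <- mr_scenario(
      theta = 0.3, J = 50, outcome_type = "quantitative", n_outcome = 30000,
      n_exposure = 30000, pleiotropy = "directional", prop_invalid = 0.3,
      pleiotropy_mean = 0.05, pleiotropy_sd = 0.01,
      seed = derive_seed(11, paste0("rep", i))
    )
    h <- sim_harmonized(scn)
    th_ivw[i] <- mr_ivw(h)$theta
    th_wm[i] <- mr_weighted_median(h, n_boot = 50, seed = i)$theta
  }
  expect_lt(abs(mean(th_wm) - 0.3), abs(mean(th_ivw) - 0.3))
  expect_gt(abs(mean(th_ivw) - 0.3), 0.01) # IVW is visibly biased here
})

test_that("weighted mode finds the dominant ratio cluster and its grid oracle", {
  h <- make_inst(bx = rep(1, 4), sx = 1e-9, by = c(0.3, 0.3, 0.3, 5), sy = 0.1)
  fit <- mr_weighted_mode(h, n_boot = 100, seed = 1)
  expect_lt(abs(fit$theta - 0.3), 0.1)

  # argmax equals a brute-force fine-grid scan of the same kernel density
  h2 <- gen_ratio_data(15, 0.4, seed = 21)
  fit2 <- mr_weighted_mode(h2, n_boot = 50, seed = 2)
  rs <- pqtlmr:::ratio_stats(h2, "second")
  w <- rs$w / sum(rs$w)
  spread <- min(stats::sd(rs$theta), stats::mad(rs$theta))
  bw <- 0.9 * spread * length(w)^(-1 / 5)
  grid <- seq(min(rs$theta) - bw, max(rs$theta) + bw, by = 1e-4)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm((x - rs$theta) / bw)), numeric(1))
  expect_lt(abs(fit2$theta - grid[which.max(dens)]), 2e-4)
})

test_that("Cochran's Q matches closed forms and its chi-square moments", {
  h <- make_inst(bx = c(1, 2, 3), sx = 1e-9, by = 0.5 * c(1, 2, 3), sy = 0.1)
  q0 <- cochran_q(h)
  expect_equal(q0$Q, 0, tolerance = 1e-18)
  expect_equal(q0$pvalue, 1)

  # J = 2 closed form about the weighted mean
  h2 <- make_inst(bx = c(1, 1), sx = 1e-9, by = c(0.2, 0.5), sy = c(0.1, 0.2))
  rs <- pqtlmr:::ratio_stats(h2, "second")
  expected <- rs$w[1] * rs$w[2] * (rs$theta[1] - rs$theta[2])^2 / sum(rs$w)
  expect_equal(cochran_q(h2)$Q, expected, tolerance = 1e-12)

  # homogeneous simulation: E[Q] = df
  withr::with_seed(9, {
    J <- 30
    reps <- 1000
    qs <- vapply(seq_len(reps), function(i) {
      bx <- runif(J, 0.1, 0.3)
      sy <- runif(J, 0.02, 0.05)
      by <- rnorm(J, 0.3 * bx, sy)
      cochran_q(make_inst(bx, 1e-9, by, sy), weights = "first")$Q
    }, numeric(1))
    expect_lt(abs(mean(qs) - (J - 1)) / (J - 1), 0.05)
  })
})

test_that("Steiger compares variance explained with the two-sample z formula", {
  # single instrument engineered to r2_exp = 0.05, r2_out = 0.001
  n <- 30000
  r2x <- 0.05
  r2y <- 0.001
  sex <- 1 / sqrt(2 * 0.3 * 0.7 * n)
  bx <- sqrt(r2x / (1 - r2x) * sex^2 * n)
  sey <- sex
  by <- sqrt(r2y / (1 - r2y) * sey^2 * n)
  h <- make_inst(bx = bx, sx = sex, by = by, sy = sey, n_exposure = n, n_outcome = n)
  st <- mr_steiger(h)
  expect_equal(st$r2_exposure, r2x, tolerance = 1e-10)
  expect_equal(st$r2_outcome, r2y, tolerance = 1e-10)
  expect_equal(st$direction, "exposure_to_outcome")
  z_expected <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) / sqrt(2 / (n - 3))
  expect_equal(st$z, z_expected, tolerance = 1e-10)
  expect_lt(st$pvalue, 1e-6)

  # symmetry: equal variance explained, equal n
  hs <- make_inst(bx = 0.1, sx = 0.02, by = 0.1, sy = 0.02)
  sts <- mr_steiger(hs)
  expect_equal(sts$z, 0)
  expect_equal(sts$pvalue, 1)

  # antisymmetry under exchanging the roles
  h2 <- gen_ratio_data(5, 0.4, seed = 4)
  fwd <- mr_steiger(h2)
  swapped <- dplyr::rename(h2,
    beta_exposure = "beta_outcome", beta_outcome = "beta_exposure",
    se_exposure = "se_outcome", se_outcome = "se_exposure",
    n_exposure = "n_outcome", n_outcome = "n_exposure"
  )
  rev <- mr_steiger(swapped)
  expect_equal(rev$z, -fwd$z, tolerance = 1e-12)
  expect_equal(rev$direction, "outcome_to_exposure")

  # missing frequency names the offending variant
  hmiss <- h2
  hmiss$eaf[2] <- NA
  expect_error(mr_steiger(hmiss), "v002", class = "pqtlmr_error_input")
})

test_that("estimators refuse instrument sets below their minimum", {
  h <- gen_ratio_data(2, 0.3, seed = 1)
  expect_error(mr_egger(h), class = "pqtlmr_error_insufficient")
  expect_error(mr_weighted_median(h), class = "pqtlmr_error_insufficient")
  expect_error(mr_ivw(h[1, ]), class = "pqtlmr_error_insufficient")
  expect_error(mr_presso(gen_ratio_data(3, 0.3, seed = 1)),
    class = "pqtlmr_error_insufficient"
  )
})
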