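# Shared fixture builders: everything is generated in code at test time.

# A harmonized instrument table built directly from effect sizes.
make_inst <- function(bx, sx, by, sy, eaf = 0.3, n_exposure = 30000,
                      n_outcome = 30000) {
  J <- length(bx)
  stopifnot(length(sx) %in% c(1, J), length(by) == J, length(sy) %in% c(1, J))
  sx <- rep(sx, length.out = J)
  sy <- rep(sy, length.out = J)
  eaf <- rep(eaf, length.out = J)
  tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(J)),
    chrom = "1", pos = 1000L + seq_len(J) * 100L,
    effect_allele = "A", other_allele = "G",
    eaf = eaf,
    beta_exposure = bx, se_exposure = sx,
    pvalue_exposure = 2 * stats::pnorm(-abs(bx / sx)),
    n_exposure = n_exposure,
    beta_outcome = by, se_outcome = sy,
    pvalue_outcome = 2 * stats::pnorm(-abs(by / sy)),
    n_outcome = n_outcome,
    eaf_outcome = eaf, is_cis = TRUE, drop_reason = NA_character_
  )
}

# A raw summary-statistics tibble in the canonical column layout.
make_sumstats <- function(variant_id, beta, se, chrom = "1",
                          pos = NULL, effect_allele = "A", other_allele = "G",
                          eaf = 0.3, n = 30000, pvalue = NULL) {
  k <- length(variant_id)
  tibble::tibble(
    variant_id = variant_id,
    chrom = rep(chrom, length.out = k),
    pos = if (is.null(pos)) 1000L + seq_len(k) * 100L else pos,
    effect_allele = rep(effect_allele, length.out = k),
    other_allele = rep(other_allele, length.out = k),
    eaf = rep(eaf, length.out = k),
    beta = beta, se = rep(se, length.out = k),
    pvalue = if (is.null(pvalue)) 2 * stats::pnorm(-abs(beta / se)) else pvalue,
    n = rep(n, length.out = k)
  )
}

# Simulate one scenario and return the harmonized cohort-1 table.
sim_harmonized <- function(scn) {
  sim <- simulate_protein_scenario(scn)
  harmonize_instruments(sim$cohorts[[1]]$exposure, sim$cohorts[[1]]$outcome)
}

# Seeded instrument set with ratio noise only (fast estimator fixtures):
# true causal effect theta, exposure betas fixed, outcome noise sy.
gen_ratio_data <- function(J, theta, seed, sy = 0.05, sx = 0.02,
                           bx_range = c(0.1, 0.4), alpha = 0) {
  withr::with_seed(seed, {
    bx_true <- runif(J, bx_range[1], bx_range[2]) * sample(c(-1, 1), J, TRUE)
    alpha <- rep(alpha, length.out = J)
    bx <- rnorm(J, bx_true, sx)
    by <- rnorm(J, theta * bx_true + sign(bx_true) * alpha, sy)
    make_inst(bx, sx, by, sy)
  })
}

# Minimal tidy-report rows for multiple-testing checks.
fake_reports_acc <- function(p, phenotype = "SCZ", class = "cis") {
  tibble::tibble(
    protein_id = sprintf("P%03d", seq_along(p)),
    gene_symbol = sprintf("G%03d", seq_along(p)),
    phenotype = phenotype, cohort_id = "c1", instrument_class = class,
    n_snps = 5L, theta = 0.1, se = 0.05, pvalue = p
  )
}

expect_mr_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$theta, b$theta, tolerance = tol)
  expect_equal(a$se, b$se, tolerance = tol)
  expect_equal(a$pvalue, b$pvalue, tolerance = tol)
}
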