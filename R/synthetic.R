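# Synthetic two-cohort pQTL / outcome-GWAS generator with known ground
# truth. Emits the exact table dialects the pipeline consumes, so every
# stage is testable without restricted GWAS data.

#' Expected GWAS standard error from allele frequency and sample size
#'
#' For a unit-variance quantitative trait,
#' `se = 1 / sqrt(2 maf (1-maf) n)`; for a binary (log-odds) outcome,
#' `se = 1 / sqrt(2 maf (1-maf) n_case n_control / n)`.
#'
#' @param maf Minor/effect allele frequency in (0,1).
#' @param n Total sample size.
#' @param outcome_type `"quantitative"` or `"binary"`.
#' @param n_case,n_control Case/control counts (binary only).
#' @return Positive numeric vector of standard errors.
#' @export
#' @examples
#' expected_se(0.5, 20000) # 0.01
expected_se <- function(maf, n, outcome_type = c("quantitative", "binary"),
                        n_case = NULL, n_control = NULL) {
  outcome_type <- arg_match(outcome_type)
  stopifnot(all(maf > 0 & maf < 1), all(n > 1))
  het <- 2 * maf * (1 - maf)
  if (outcome_type == "quantitative") {
    1 / sqrt(het * n)
  } else {
    if (is.null(n_case) || is.null(n_control)) {
      abort_config("expected_se: binary outcomes need n_case and n_control")
    }
    1 / sqrt(het * n_case * n_control / n)
  }
}

#' Define a synthetic protein scenario
#'
#' A complete parameterization of the generative model for one protein:
#' the true causal effect, instrument count and strength, cohort sample
#' sizes, the pleiotropy regime, and the between-cohort effect
#' correlation. Defaults mirror the real study's design: exposure panels
#' of ~35,000 individuals (UKB-PPP: 34,557; deCODE: 35,559), case-control
#' psychiatric outcomes, and a handful of independent genome-wide
#' significant instruments explaining a few percent of protein variance.
#'
#' @param theta True causal effect (outcome per unit protein); may be a
#'   vector with one value per cohort.
#' @param J Number of instruments.
#' @param maf_range Range the allele frequencies are drawn from.
#' @param exposure_r2_total Total protein variance explained by the J
#'   instruments (split randomly across them).
#' @param n_exposure Exposure GWAS sample size (per cohort; recycled).
#' @param n_outcome Outcome GWAS total sample size.
#' @param outcome_type `"quantitative"` or `"binary"`.
#' @param n_case,n_control Case/control counts for binary outcomes.
#' @param pleiotropy `"none"`, `"balanced"`, `"directional"`, or
#'   `"correlated"` (direct effects proportional to instrument strength,
#'   violating InSIDE).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the direct effects
#'   given to invalid instruments.
#' @param prop_invalid Proportion of instruments receiving a direct
#'   effect.
#' @param n_cohorts Number of exposure cohorts (platforms).
#' @param between_cohort_effect_corr Correlation of true per-variant
#'   effects (and, in [simulate_study()], of per-protein causal effects)
#'   across cohorts.
#' @param reverse_causal If `TRUE` the generative arrow is flipped: the
#'   variants act on the outcome and the protein responds to outcome
#'   liability with coefficient `theta`.
#' @param seed Integer seed.
#' @return A validated list of class `mr_scenario`.
#' @export
mr_scenario <- function(theta = 0.3, J = 30, maf_range = c(0.05, 0.5),
                        exposure_r2_total = 0.05, n_exposure = 34557,
                        n_outcome = 160779,
                        outcome_type = c("binary", "quantitative"),
                        n_case = 67323, n_control = 93456,
                        pleiotropy = c("none", "balanced", "directional", "correlated"),
                        pleiotropy_mean = 0.05, pleiotropy_sd = 0.01,
                        prop_invalid = 0, n_cohorts = 1,
                        between_cohort_effect_corr = 0.5,
                        reverse_causal = FALSE, seed = 1) {
  outcome_type <- arg_match(outcome_type)
  pleiotropy <- arg_match(pleiotropy)
  if (!(prop_invalid >= 0 && prop_invalid <= 1)) {
    abort_config("prop_invalid must lie in [0,1]")
  }
  if (!(exposure_r2_total > 0 && exposure_r2_total < 1)) {
    abort_config("exposure_r2_total must lie in (0,1)")
  }
  rho <- between_cohort_effect_corr
  if (!(rho >= -1 && rho <= 1)) {
    abort_config("between_cohort_effect_corr must lie in [-1,1]")
  }
  if (outcome_type == "binary" && (is.null(n_case) || is.null(n_control))) {
    abort_config("binary outcomes need n_case and n_control")
  }
  structure(
    list(
      theta = theta, J = as.integer(J), maf_range = maf_range,
      exposure_r2_total = exposure_r2_total, n_exposure = n_exposure,
      n_outcome = if (outcome_type == "binary") n_case + n_control else n_outcome,
      outcome_type = outcome_type, n_case = n_case, n_control = n_control,
      pleiotropy = pleiotropy, pleiotropy_mean = pleiotropy_mean,
      pleiotropy_sd = pleiotropy_sd, prop_invalid = prop_invalid,
      n_cohorts = as.integer(n_cohorts),
      between_cohort_effect_corr = rho,
      reverse_causal = isTRUE(reverse_causal), seed = as.integer(seed)
    ),
    class = "mr_scenario"
  )
}

# Draw per-variant true effects that sum to the requested r2 on a
# unit-variance trait: random shares, random signs.
draw_true_effects <- function(J, maf, r2_total) {
  shares <- runif(J, 0.5, 1.5)
  r2 <- r2_total * shares / sum(shares)
  sign <- sample(c(-1, 1), J, replace = TRUE)
  sign * sqrt(r2 / (2 * maf * (1 - maf)))
}

draw_pleiotropy <- function(scn, b) {
  J <- length(b)
  alpha <- numeric(J)
  if (scn$pleiotropy == "none" || scn$prop_invalid == 0) {
    return(list(alpha = alpha, invalid = logical(J)))
  }
  n_invalid <- ceiling(scn$prop_invalid * J)
  invalid <- seq_len(J) %in% sample.int(J, n_invalid)
  # "directional" is directional relative to the exposure-increasing
  # allele: the direct effect is aligned with sign(b), so it biases the
  # causal estimate in one direction regardless of allele coding.
  alpha[invalid] <- switch(scn$pleiotropy,
    balanced = rnorm(n_invalid, 0, scn$pleiotropy_sd),
    directional = sign(b[invalid]) *
      rnorm(n_invalid, scn$pleiotropy_mean, scn$pleiotropy_sd),
    correlated = scn$pleiotropy_mean * b[invalid] / sqrt(mean(b^2)) +
      rnorm(n_invalid, 0, scn$pleiotropy_sd)
  )
  list(alpha = alpha, invalid = invalid)
}

#' Simulate summary statistics for one protein scenario
#'
#' Draws true per-variant effects to hit the scenario's total variance
#' explained, observes them with exposure sampling noise, and generates
#' outcome associations under the causal effect plus the configured
#' pleiotropy regime (binary outcomes on the log-odds scale with
#' case/control-based SEs). With several cohorts, true variant effects are
#' correlated across cohorts at `between_cohort_effect_corr`. With
#' `reverse_causal = TRUE` the variants act on the outcome and the protein
#' responds with coefficient `theta`. Identical scenarios with identical
#' seeds reproduce bit-identical tables.
#'
#' @param scn An [mr_scenario()].
#' @param protein_id Id stem used in variant/protein labels.
#' @param gene Optional one-row tibble (`chrom`, `gene_start`, `gene_end`)
#'   placing the synthetic gene; defaults to chr1:1,000,000-1,010,000.
#' @return A list: `cohorts` (per cohort, `exposure` and `outcome`
#'   summary-statistics tibbles), `truth` (per-variant latent quantities),
#'   `target` (annotation row), `scenario`.
#' @export
simulate_protein_scenario <- function(scn, protein_id = "P1", gene = NULL) {
  stopifnot(inherits(scn, "mr_scenario"))
  gene <- gene %||% tibble(chrom = "1", gene_start = 1000000L, gene_end = 1010000L)
  theta <- rep(scn$theta, length.out = scn$n_cohorts)
  n_exposure <- rep(scn$n_exposure, length.out = scn$n_cohorts)
  rho <- scn$between_cohort_effect_corr

  withr::with_seed(scn$seed, {
    J <- scn$J
    maf <- runif(J, scn$maf_range[1], scn$maf_range[2])
    pos <- sort(sample.int(1000000L, J)) + gene$gene_start - 500000L
    pos <- pmax(pos, 1L)
    b1 <- draw_true_effects(J, maf, scn$exposure_r2_total)

    cohorts <- vector("list", scn$n_cohorts)
    truth <- vector("list", scn$n_cohorts)
    for (ci in seq_len(scn$n_cohorts)) {
      b <- if (ci == 1) {
        b1
      } else {
        rho * b1 + sqrt(1 - rho^2) * rnorm(J, 0, max(sd(b1), 1e-12))
      }
      pl <- draw_pleiotropy(scn, b)
      se_q <- expected_se(maf, n_exposure[ci], "quantitative")
      se_o <- expected_se(
        maf, scn$n_outcome, scn$outcome_type,
        n_case = scn$n_case, n_control = scn$n_control
      )
      if (!scn$reverse_causal) {
        b_exp_true <- b
        gamma_true <- theta[ci] * b + pl$alpha
      } else {
        # variants act on the outcome; the protein responds to liability
        b_exp_true <- theta[ci] * b
        gamma_true <- b + pl$alpha
      }
      beta_exp <- rnorm(J, b_exp_true, se_q)
      beta_out <- rnorm(J, gamma_true, se_o)
      ids <- sprintf("%s_c%d_v%03d", protein_id, ci, seq_len(J))
      mk <- function(beta, se, n) {
        tibble(
          variant_id = ids, chrom = gene$chrom, pos = as.integer(pos),
          effect_allele = "A", other_allele = "G", eaf = maf,
          beta = beta, se = se, pvalue = z_pvalue(beta, se), n = n
        )
      }
      cohorts[[ci]] <- list(
        exposure = mutate(mk(beta_exp, se_q, n_exposure[ci]), protein_id = protein_id),
        outcome = mk(beta_out, se_o, scn$n_outcome)
      )
      truth[[ci]] <- tibble(
        variant_id = ids, cohort = ci, protein_id = protein_id,
        maf = maf, beta_exposure_true = b_exp_true,
        beta_outcome_true = gamma_true, alpha = pl$alpha,
        invalid = pl$invalid, theta = theta[ci],
        reverse_causal = scn$reverse_causal
      )
    }
    list(
      cohorts = cohorts, truth = list_rbind(truth),
      target = mutate(gene, protein_id = protein_id, gene_symbol = protein_id),
      scenario = scn
    )
  })
}

#' Default outcome phenotype panel
#'
#' The four outcome GWAS designs emulated by [simulate_study()]: three
#' case-control psychiatric phenotypes and one quantitative cognitive
#' phenotype, with the published sample sizes (SCZ 67,323/93,456; BIP
#' 40,463/313,436; MDD 166,773/507,679; CTP N = 215,333).
#'
#' @return A named list of phenotype descriptors.
#' @export
study_phenotypes <- function() {
  list(
    SCZ = list(type = "binary", n_case = 67323, n_control = 93456),
    BIP = list(type = "binary", n_case = 40463, n_control = 313436),
    MDD = list(type = "binary", n_case = 166773, n_control = 507679),
    CTP = list(type = "quantitative", n = 215333)
  )
}

#' Simulate a complete multi-protein, multi-phenotype, two-cohort study
#'
#' Generates a full input bundle for [run_study()]: per-cohort stacked
#' exposure pQTL tables over disjoint variant panels (different platforms
#' index different variants), one outcome GWAS table per phenotype
#' covering all variants, a protein annotation table, a ground-truth
#' table, and a versioned YAML config. Per-protein causal effects are
#' drawn per phenotype, null with probability `prop_null` and otherwise
#' `N(0, theta_sd^2)`, correlated across cohorts at the template's
#' `between_cohort_effect_corr`. Per-protein seeds derive from the master
#' seed and the protein index, so adding proteins never changes existing
#' proteins' draws.
#'
#' @param n_proteins Number of proteins.
#' @param template An [mr_scenario()] supplying instrument count/strength,
#'   sample sizes and the pleiotropy regime.
#' @param phenotypes Phenotype panel, as [study_phenotypes()].
#' @param cohort_n Exposure sample size per cohort.
#' @param theta_sd SD of non-null per-protein causal effects.
#' @param prop_null Probability a protein is causally null (for all
#'   cohorts) for a given phenotype.
#' @param seed Master seed.
#' @param out_dir If non-NULL, write the bundle there (TSVs + config.yaml).
#' @param force Overwrite a non-empty `out_dir`.
#' @param block_ld Also emit an LD matrix containing, per instrument, one
#'   tightly linked shadow variant (r^2 = 0.9), to exercise clumping.
#' @param n_boot,n_sim Stochastic-estimator effort recorded in the config.
#' @return Invisibly, a list with `files` (paths, when written), `config`,
#'   `truth`, and the in-memory `tables`.
#' @export
simulate_study <- function(n_proteins = 20, template = mr_scenario(),
                           phenotypes = study_phenotypes(),
                           cohort_n = c(34557, 35559),
                           theta_sd = 0.15, prop_null = 0.5, seed = 1,
                           out_dir = NULL, force = FALSE, block_ld = FALSE,
                           n_boot = 500, n_sim = 200) {
  n_cohorts <- length(cohort_n)
  rho <- template$between_cohort_effect_corr
  cohort_ids <- paste0("cohort", seq_len(n_cohorts))
  J <- template$J

  exposures <- setNames(rep(list(list()), n_cohorts), cohort_ids)
  outcomes <- setNames(rep(list(list()), length(phenotypes)), names(phenotypes))
  annotations <- list()
  truth <- list()
  ld_pairs <- list()

  sumstat_row <- function(ids, gene, pos, maf, beta, se, n) {
    tibble(
      variant_id = ids, chrom = gene$chrom, pos = as.integer(pos),
      effect_allele = "A", other_allele = "G", eaf = maf,
      beta = beta, se = se, pvalue = z_pvalue(beta, se), n = n
    )
  }

  for (i in seq_len(n_proteins)) {
    pid <- sprintf("PROT%03d", i)
    seed_i <- derive_seed(seed, paste0("protein", i))
    gene <- withr::with_seed(seed_i, tibble(
      chrom = as.character(sample.int(22, 1)),
      gene_start = sample.int(200000000L, 1) + 1000000L
    ))
    gene$gene_end <- gene$gene_start + 20000L

    # One exposure panel per cohort, shared across phenotypes: disjoint
    # variant ids per cohort, same allele frequencies, true effects
    # correlated across cohorts at rho.
    panel <- withr::with_seed(derive_seed(seed_i, "panel"), {
      maf <- runif(J, template$maf_range[1], template$maf_range[2])
      b1 <- draw_true_effects(J, maf, template$exposure_r2_total)
      lapply(seq_len(n_cohorts), function(ci) {
        b <- if (ci == 1) {
          b1
        } else {
          rho * b1 + sqrt(1 - rho^2) * rnorm(J, 0, max(sd(b1), 1e-12))
        }
        pos <- sort(sample.int(900000L, J)) + gene$gene_start - 450000L
        list(
          ids = sprintf("%s_c%d_v%03d", pid, ci, seq_len(J)),
          maf = maf, pos = pmax(pos, 1L), b = b
        )
      })
    })
    for (ci in seq_len(n_cohorts)) {
      p <- panel[[ci]]
      se_x <- expected_se(p$maf, cohort_n[ci], "quantitative")
      beta_x <- withr::with_seed(
        derive_seed(seed_i, paste0("exposure_c", ci)),
        rnorm(J, p$b, se_x)
      )
      ex <- sumstat_row(p$ids, gene, p$pos, p$maf, beta_x, se_x, cohort_n[ci])
      if (block_ld) {
        # a tightly linked shadow for every instrument (r^2 = 0.9); the
        # shadow repeats the lead with a slightly larger SE so the lead
        # always wins the greedy clump.
        sh <- mutate(ex,
          variant_id = paste0(.data$variant_id, "s"),
          pos = .data$pos + 1L, se = .data$se * 1.05,
          pvalue = z_pvalue(.data$beta, .data$se * 1.05)
        )
        ld_pairs[[length(ld_pairs) + 1]] <- tibble(a = ex$variant_id, b = sh$variant_id)
        ex <- bind_rows(ex, sh)
      }
      ex$protein_id <- pid
      exposures[[ci]][[length(exposures[[ci]]) + 1]] <- ex

      annotations[[length(annotations) + 1]] <- tibble(
        protein_id = pid, gene_symbol = pid, chrom = gene$chrom,
        gene_start = gene$gene_start, gene_end = gene$gene_end,
        cohort_id = cohort_ids[ci]
      )
    }

    for (ph in names(phenotypes)) {
      pheno <- phenotypes[[ph]]
      th <- withr::with_seed(derive_seed(seed_i, paste0("theta_", ph)), {
        if (runif(1) < prop_null) {
          rep(0, n_cohorts)
        } else {
          z1 <- rnorm(1)
          z <- c(z1, rho * z1 + sqrt(1 - rho^2) * rnorm(max(0, n_cohorts - 1)))
          theta_sd * z[seq_len(n_cohorts)]
        }
      })
      for (ci in seq_len(n_cohorts)) {
        p <- panel[[ci]]
        scn_ph <- template
        scn_ph$pleiotropy <- template$pleiotropy
        res <- withr::with_seed(derive_seed(seed_i, paste0(ph, "_c", ci)), {
          pl <- draw_pleiotropy(scn_ph, p$b)
          gamma <- th[ci] * p$b + pl$alpha
          se_o <- if (pheno$type == "binary") {
            expected_se(p$maf, pheno$n_case + pheno$n_control, "binary",
              n_case = pheno$n_case, n_control = pheno$n_control
            )
          } else {
            expected_se(p$maf, pheno$n, "quantitative")
          }
          beta_o <- rnorm(J, gamma, se_o)
          list(pl = pl, gamma = gamma, se_o = se_o, beta_o = beta_o)
        })
        n_out <- if (pheno$type == "binary") pheno$n_case + pheno$n_control else pheno$n
        out <- sumstat_row(p$ids, gene, p$pos, p$maf, res$beta_o, res$se_o, n_out)
        if (block_ld) {
          sh <- mutate(out,
            variant_id = paste0(.data$variant_id, "s"),
            pos = .data$pos + 1L, se = .data$se * 1.05,
            pvalue = z_pvalue(.data$beta, .data$se * 1.05)
          )
          out <- bind_rows(out, sh)
        }
        outcomes[[ph]][[length(outcomes[[ph]]) + 1]] <- out
        truth[[length(truth) + 1]] <- tibble(
          protein_id = pid, phenotype = ph, cohort_id = cohort_ids[ci],
          variant_id = p$ids, maf = p$maf,
          beta_exposure_true = p$b, beta_outcome_true = res$gamma,
          alpha = res$pl$alpha, invalid = res$pl$invalid, theta = th[ci]
        )
      }
    }
  }

  tables <- list(
    exposures = map(exposures, list_rbind),
    outcomes = map(outcomes, list_rbind),
    annotations = list_rbind(annotations),
    truth = list_rbind(truth)
  )
  ld <- NULL
  if (block_ld) {
    pairs <- list_rbind(ld_pairs)
    ids <- sort(unique(c(
      unlist(map(tables$exposures, ~ unique(.x$variant_id)))
    )))
    ld <- diag(1, length(ids))
    dimnames(ld) <- list(ids, ids)
    ia <- match(pairs$a, ids)
    ib <- match(pairs$b, ids)
    ld[cbind(ia, ib)] <- 0.9
    ld[cbind(ib, ia)] <- 0.9
  }

  config <- list(
    version = 1,
    seed = seed,
    classes = list("cis"),
    cohorts = map(seq_len(n_cohorts), function(ci) {
      list(
        id = cohort_ids[ci],
        exposure = paste0("exposure_", cohort_ids[ci], ".tsv"),
        annotations = "annotations.tsv",
        n = cohort_n[ci]
      )
    }),
    phenotypes = imap(phenotypes, function(p, nm) {
      c(list(id = nm, file = paste0("outcome_", nm, ".tsv")), p)
    }),
    ld = if (block_ld) "ld.tsv" else NULL,
    instrument = list(
      p_threshold = 5e-8, cis_window_bp = 1e6, clump_r2 = 0.01,
      clump_window_bp = 1e7, min_f = 10
    ),
    estimators = list(
      n_boot = n_boot, n_sim = n_sim, weights = "second",
      random_effects = "auto", outlier_alpha = 0.05
    )
  )

  files <- NULL
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
      abort_input(paste0(
        "output directory exists and is not empty (use force = TRUE): ", out_dir
      ))
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
    for (ci in cohort_ids) {
      f <- file.path(out_dir, paste0("exposure_", ci, ".tsv"))
      readr::write_tsv(tables$exposures[[ci]], f, progress = FALSE)
      files[[paste0("exposure_", ci)]] <- f
    }
    for (ph in names(phenotypes)) {
      f <- file.path(out_dir, paste0("outcome_", ph, ".tsv"))
      readr::write_tsv(tables$outcomes[[ph]], f, progress = FALSE)
      files[[paste0("outcome_", ph)]] <- f
    }
    readr::write_tsv(tables$annotations, file.path(out_dir, "annotations.tsv"),
      progress = FALSE
    )
    readr::write_tsv(tables$truth, file.path(out_dir, "truth.tsv"), progress = FALSE)
    if (!is.null(ld)) {
      ld_tbl <- as_tibble(ld)
      ld_tbl <- dplyr::bind_cols(tibble(variant_id = rownames(ld)), ld_tbl)
      readr::write_tsv(ld_tbl, file.path(out_dir, "ld.tsv"), progress = FALSE)
    }
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
    files$annotations <- file.path(out_dir, "annotations.tsv")
    files$truth <- file.path(out_dir, "truth.tsv")
    files$config <- file.path(out_dir, "config.yaml")
  }
  invisible(list(
    tables = tables, config = config, truth = tables$truth,
    ld = ld, files = files, out_dir = out_dir
  ))
}
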