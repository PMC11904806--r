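# Per-protein orchestration: instrument selection -> harmonization ->
# primary estimate + sensitivity battery -> Steiger -> flags.

#' Full pipeline configuration
#'
#' Bundles instrument-selection thresholds with estimator settings and the
#' run-level master seed. Every stochastic step (bootstraps, MR-PRESSO
#' simulations, cML starts) derives its own seed from the master seed and
#' the protein/phenotype/cohort/method labels, so runs are reproducible
#' and insensitive to protein ordering.
#'
#' @param instrument An [instrument_config()].
#' @param palindrome_maf_limit See [harmonize_instruments()].
#' @param weights Ratio-variance order for IVW-family weights
#'   (`"second"`-order delta by default).
#' @param random_effects IVW random-effects mode (`"auto"`: multiplicative
#'   for J >= 4).
#' @param n_boot Bootstrap resamples for weighted median/mode.
#' @param n_sim MR-PRESSO simulation count.
#' @param outlier_alpha MR-PRESSO outlier significance level.
#' @param psi ConMix invalid-component SD (`NULL`: 1.5 x SD of ratios).
#' @param theta_grid ConMix grid, `c(lo, hi, step)` on the standardized
#'   scale.
#' @param bandwidth_factor Weighted-mode bandwidth multiplier.
#' @param K_max cML maximum invalid count (`NULL`: J - 2).
#' @param battery Sensitivity methods to run when enough instruments are
#'   available.
#' @param reverse `"flagged"` runs reverse MR only for reports whose
#'   Steiger test is non-significant; `"always"` or `"never"`.
#' @param alpha Study-wide significance level for the two-tier correction.
#' @param seed Master seed.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(instrument = instrument_config(),
                      palindrome_maf_limit = 0.42,
                      weights = c("second", "first"),
                      random_effects = c("auto", "fixed", "multiplicative"),
                      n_boot = 1000, n_sim = 1000, outlier_alpha = 0.05,
                      psi = NULL, theta_grid = c(-2, 2, 0.001),
                      bandwidth_factor = 1, K_max = NULL,
                      battery = c(
                        "ivw_robust", "egger", "weighted_median",
                        "weighted_mode", "conmix", "presso", "cml"
                      ),
                      reverse = c("flagged", "always", "never"),
                      alpha = 0.05, seed = 1) {
  structure(
    list(
      instrument = instrument,
      palindrome_maf_limit = palindrome_maf_limit,
      weights = arg_match(weights),
      random_effects = arg_match(random_effects),
      n_boot = n_boot, n_sim = n_sim, outlier_alpha = outlier_alpha,
      psi = psi, theta_grid = theta_grid,
      bandwidth_factor = bandwidth_factor, K_max = K_max,
      battery = battery, reverse = arg_match(reverse),
      alpha = alpha, seed = as.integer(seed)
    ),
    class = "mr_config"
  )
}

BATTERY_MIN_J <- c(
  ivw_robust = 3, egger = 3, weighted_median = 3, weighted_mode = 3,
  conmix = 3, presso = 4, cml = 3
)

run_battery_method <- function(method, h, cfg, seed_key) {
  seed <- derive_seed(cfg$seed, paste0(seed_key, "_", method))
  switch(method,
    ivw_robust = mr_ivw_robust(h),
    egger = mr_egger(h),
    weighted_median = mr_weighted_median(h, n_boot = cfg$n_boot, seed = seed, weights = cfg$weights),
    weighted_mode = mr_weighted_mode(h,
      bandwidth_factor = cfg$bandwidth_factor,
      n_boot = cfg$n_boot, seed = seed, weights = cfg$weights
    ),
    conmix = mr_conmix(h, psi = cfg$psi, theta_grid = cfg$theta_grid, weights = cfg$weights),
    presso = mr_presso(h, n_sim = cfg$n_sim, seed = seed, outlier_alpha = cfg$outlier_alpha),
    cml = mr_cml(h, K_max = cfg$K_max, seed = seed),
    abort_config(paste0("unknown battery method: ", method))
  )
}

mr_skip <- function(protein_id, phenotype, cohort_id, instrument_class, reason,
                    stage_counts = NULL) {
  structure(
    list(
      protein_id = protein_id, phenotype = phenotype, cohort_id = cohort_id,
      instrument_class = instrument_class, reason = reason,
      stage_counts = stage_counts
    ),
    class = "mr_skip"
  )
}

#' @export
print.mr_skip <- function(x, ...) {
  cat(sprintf(
    "<mr_skip> %s / %s / %s (%s): %s\n",
    x$protein_id, x$phenotype, x$cohort_id %||% "-", x$instrument_class, x$reason
  ))
  invisible(x)
}

#' Run the MR battery for one protein-phenotype-cohort triple
#'
#' Selects instruments (significance filter, cis/trans classification, LD
#' clumping, F screen), harmonizes them against the outcome GWAS, fits the
#' primary estimator (Wald ratio for a single instrument, IVW delta
#' otherwise) plus every sensitivity method whose minimum instrument count
#' is met, always computes the Steiger directionality test, evaluates the
#' report flags, and — when exclusion lists are supplied — records the
#' primary estimate recomputed after each exclusion next to the
#' pre-exclusion result.
#'
#' @param exposure Exposure (pQTL) summary statistics for one protein.
#' @param outcome Outcome GWAS summary statistics.
#' @param target One-row protein target annotation.
#' @param ld LD matrix or `NULL`.
#' @param cfg An [mr_config()].
#' @param mode Instrument class to analyse: `"cis"` or `"trans"`.
#' @param phenotype,cohort_id Labels recorded in the report.
#' @param outcome_type `"quantitative"` or `"binary"` (Steiger scale).
#' @param exclusions Named list of variant-id vectors; names must be
#'   `excluded_confounder` and/or `excluded_phewas`.
#' @return A `sensitivity_report`, or an `mr_skip` record when no usable
#'   instrument survives (never an error).
#' @export
run_protein_mr <- function(exposure, outcome, target, ld = NULL,
                           cfg = mr_config(), mode = c("cis", "trans"),
                           phenotype = "outcome", cohort_id = NULL,
                           outcome_type = c("quantitative", "binary"),
                           exclusions = list()) {
  mode <- arg_match(mode)
  outcome_type <- arg_match(outcome_type)
  pid <- target$protein_id
  seed_key <- paste(pid, phenotype, cohort_id %||% "", mode, sep = "_")

  sel <- select_instruments(exposure, target, ld, cfg$instrument, mode)
  counts <- attr(sel, "stage_counts")
  if (nrow(sel) == 0) {
    return(mr_skip(pid, phenotype, cohort_id, mode, "no_instruments", counts))
  }
  h <- harmonize_instruments(sel, outcome, cfg$palindrome_maf_limit)
  h$is_cis <- mode == "cis"
  u <- usable_instruments(h)
  counts <- c(counts, harmonized = nrow(u))
  if (nrow(u) == 0) {
    return(mr_skip(pid, phenotype, cohort_id, mode, "no_instruments", counts))
  }

  J <- nrow(u)
  flags <- character(0)
  battery <- list()
  notes <- character(0)
  if (J == 1) {
    primary <- mr_wald_ratio(u, order = cfg$weights)
    flags <- c(flags, "single_instrument")
  } else {
    primary <- mr_ivw(u, random_effects = cfg$random_effects, weights = cfg$weights)
    if (primary$extras$p_Q < 0.05) flags <- c(flags, "heterogeneity_p_lt_0.05")
    for (m in cfg$battery) {
      if (J < BATTERY_MIN_J[[m]]) next
      battery[[m]] <- tryCatch(
        run_battery_method(m, u, cfg, seed_key),
        pqtlmr_error_convergence = function(e) {
          notes <<- c(notes, paste0(m, ": ", conditionMessage(e)))
          NULL
        }
      )
    }
    battery <- compact(battery)
    if (!is.null(battery$egger) && battery$egger$extras$p_intercept < 0.05) {
      flags <- c(flags, "egger_intercept_p_lt_0.05")
    }
  }
  steiger <- mr_steiger(u, outcome_type = outcome_type)
  if (steiger$pvalue > 0.05) flags <- c(flags, "steiger_p_gt_0.05")

  reruns <- list()
  for (reason in intersect(names(exclusions), c("excluded_confounder", "excluded_phewas"))) {
    hx <- apply_snp_exclusions(h, exclusions[[reason]], reason)
    log <- attr(hx, "removal_log")
    if (nrow(log) == 0) next
    ux <- usable_instruments(hx)
    reruns[[reason]] <- if (nrow(ux) == 0) {
      mr_skip(pid, phenotype, cohort_id, mode, "no_instruments_after_exclusion")
    } else if (nrow(ux) == 1) {
      mr_wald_ratio(ux, order = cfg$weights)
    } else {
      mr_ivw(ux, random_effects = cfg$random_effects, weights = cfg$weights)
    }
    attr(reruns[[reason]], "removed") <- log$variant_id
  }

  structure(
    list(
      protein_id = pid,
      gene_symbol = target$gene_symbol %||% pid,
      phenotype = phenotype, cohort_id = cohort_id,
      instrument_class = mode,
      primary = primary, battery = battery, steiger = steiger,
      reverse = NULL, exclusion_reruns = reruns,
      flags = flags, stage_counts = counts, notes = notes,
      instruments = h
    ),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_report> %s ~ %s [%s%s]\n",
    x$protein_id, x$phenotype, x$instrument_class,
    if (!is.null(x$cohort_id)) paste0(", ", x$cohort_id) else ""
  ))
  print(x$primary)
  if (length(x$battery) > 0) {
    cat("  battery:", paste(names(x$battery), collapse = ", "), "\n")
  }
  cat(sprintf(
    "  steiger: %s (p = %.3g)%s\n", x$steiger$direction, x$steiger$pvalue,
    if (length(x$flags) > 0) paste0("; flags: ", paste(x$flags, collapse = ", ")) else ""
  ))
  invisible(x)
}

#' Tidy a sensitivity report into one wide row
#'
#' Produces a fixed column set (missing statistics become `NA`) so rows
#' from heterogeneous reports bind into one results table: primary
#' estimate, heterogeneity and Egger-intercept diagnostics, Steiger
#' verdict, one `<method>_theta`/`<method>_pvalue` pair per battery
#' method, MR-PRESSO global p, reverse-MR and exclusion-rerun estimates,
#' and the flag set collapsed to a comma-separated string.
#'
#' @param x A `sensitivity_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy sensitivity_report
#' @export
tidy.sensitivity_report <- function(x, ...) {
  row <- tibble(
    protein_id = x$protein_id,
    gene_symbol = x$gene_symbol,
    phenotype = x$phenotype,
    cohort_id = x$cohort_id %||% NA_character_,
    instrument_class = x$instrument_class,
    primary_method = x$primary$method,
    n_snps = x$primary$n_snps,
    theta = x$primary$theta, se = x$primary$se,
    ci_low = x$primary$ci_low, ci_high = x$primary$ci_high,
    pvalue = x$primary$pvalue,
    Q = x$primary$extras$Q %||% NA_real_,
    p_Q = x$primary$extras$p_Q %||% NA_real_,
    egger_intercept = NA_real_, egger_intercept_p = NA_real_,
    steiger_direction = x$steiger$direction,
    steiger_p = x$steiger$pvalue,
    r2_exposure = x$steiger$r2_exposure,
    r2_outcome = x$steiger$r2_outcome,
    flags = paste(x$flags, collapse = ",")
  )
  for (m in names(BATTERY_MIN_J)) {
    fit <- x$battery[[m]]
    row[[paste0(m, "_theta")]] <- if (is.null(fit)) NA_real_ else fit$theta
    row[[paste0(m, "_pvalue")]] <- if (is.null(fit)) NA_real_ else fit$pvalue
  }
  if (!is.null(x$battery$egger)) {
    row$egger_intercept <- x$battery$egger$extras$intercept
    row$egger_intercept_p <- x$battery$egger$extras$p_intercept
  }
  row$presso_global_p <- if (!is.null(x$battery$presso)) {
    x$battery$presso$extras$global_p
  } else {
    NA_real_
  }
  if (!is.null(x$reverse) && inherits(x$reverse, "mr_result")) {
    row$reverse_theta <- x$reverse$theta
    row$reverse_pvalue <- x$reverse$pvalue
  } else {
    row$reverse_theta <- NA_real_
    row$reverse_pvalue <- NA_real_
  }
  for (reason in c("excluded_confounder", "excluded_phewas")) {
    fit <- x$exclusion_reruns[[reason]]
    ok <- !is.null(fit) && inherits(fit, "mr_result")
    row[[paste0(reason, "_theta")]] <- if (ok) fit$theta else NA_real_
    row[[paste0(reason, "_pvalue")]] <- if (ok) fit$pvalue else NA_real_
    row[[paste0(reason, "_n_removed")]] <- if (is.null(fit)) {
      0L
    } else {
      length(attr(fit, "removed") %||% integer(0))
    }
  }
  row
}

#' Reverse-direction Mendelian randomization
#'
#' Uses the outcome phenotype as the exposure: selects
#' genome-wide-significant phenotype instruments (no cis/trans filter),
#' harmonizes them against the protein pQTL statistics, and fits IVW (or
#' the Wald ratio for a single instrument). Triggered by [run_study()] for
#' reports whose Steiger test is non-significant (configurable to
#' always-on).
#'
#' @param phenotype_data Outcome GWAS summary statistics (now the
#'   exposure).
#' @param protein_data Protein pQTL summary statistics (now the outcome).
#' @param ld LD matrix or `NULL`.
#' @param cfg An [mr_config()].
#' @return An `mr_result`, or an `mr_skip` when no phenotype instrument is
#'   available.
#' @export
reverse_mr <- function(phenotype_data, protein_data, ld = NULL, cfg = mr_config()) {
  dummy_target <- tibble(
    protein_id = "phenotype", gene_symbol = "phenotype",
    chrom = "0", gene_start = 1, gene_end = 1
  )
  sel <- select_instruments(phenotype_data, dummy_target, ld, cfg$instrument, mode = "all")
  if (nrow(sel) == 0) {
    return(mr_skip("phenotype", "reverse", NULL, "all", "no_phenotype_instruments"))
  }
  h <- harmonize_instruments(sel, protein_data, cfg$palindrome_maf_limit)
  u <- usable_instruments(h)
  if (nrow(u) == 0) {
    return(mr_skip("phenotype", "reverse", NULL, "all", "no_phenotype_instruments"))
  }
  if (nrow(u) == 1) {
    mr_wald_ratio(u, order = cfg$weights)
  } else {
    mr_ivw(u, random_effects = cfg$random_effects, weights = cfg$weights)
  }
}
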