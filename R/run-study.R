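# Study-level orchestration: cross-cohort meta-analysis, two-tier
# multiple-testing control, cross-platform concordance, full runs.

#' Fixed-effect inverse-variance meta-analysis across cohorts
#'
#' `theta_meta = sum(theta_c / se_c^2) / sum(1 / se_c^2)`,
#' `se_meta = sqrt(1 / sum(1 / se_c^2))`. A single cohort passes through
#' unchanged.
#'
#' @param results A tibble with columns `theta` and `se` (one row per
#'   cohort; an optional `phenotype` column must be constant), or a list
#'   of `mr_result` objects.
#' @return An `mr_result` (method `"ivw"`, `extras$pool = "meta_fixed"`).
#' @export
#' @examples
#' meta_analyze(tibble::tibble(theta = c(0.3, 0.3), se = c(0.1, 0.1)))
meta_analyze <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- list_rbind(map(results, tidy))
  }
  if (nrow(results) < 1) abort_usage("meta_analyze: no cohort results supplied")
  if ("phenotype" %in% names(results) &&
    length(unique(results$phenotype)) > 1) {
    abort_usage(paste0(
      "meta_analyze: mismatched phenotype labels: ",
      paste(unique(results$phenotype), collapse = ", ")
    ))
  }
  w <- 1 / results$se^2
  theta <- sum(w * results$theta) / sum(w)
  se <- sqrt(1 / sum(w))
  new_mr_result("ivw", theta, se,
    n_snps = if ("n_snps" %in% names(results)) sum(results$n_snps) else nrow(results),
    extras = list(pool = "meta_fixed", n_cohorts = nrow(results))
  )
}

#' Two-tier multiple-testing control
#'
#' Labels every report with its significance tier. The Bonferroni level is
#' `alpha / m` where `m` counts the tests actually executed, separately
#' for cis and trans runs (each class carries its own genome of tests, as
#' the study's separate cis/trans thresholds do). Benjamini-Hochberg FDR
#' is applied within each phenotype-by-class stratum, and the realized
#' per-stratum p-value threshold (the largest p still called significant
#' at `FDR < alpha`) is reported. Bonferroni significance always implies
#' FDR significance within a stratum.
#'
#' @param reports A tidy results table (rows from
#'   [tidy.sensitivity_report()]) or a list of `sensitivity_report`
#'   objects; `mr_skip` records are ignored.
#' @param alpha Family-wise / FDR level (default 0.05).
#' @return The table with `qvalue` and `tier` (`"none"`, `"fdr"`,
#'   `"bonferroni"`) columns, plus attributes `bonferroni_alpha` (named by
#'   class) and `fdr_thresholds` (tibble: phenotype, instrument_class,
#'   n_tests, p_threshold).
#' @export
adjust_pvalues <- function(reports, alpha = 0.05) {
  if (is.list(reports) && !is.data.frame(reports)) {
    reports <- keep(reports, ~ inherits(.x, "sensitivity_report"))
    reports <- list_rbind(map(reports, tidy))
  }
  if (nrow(reports) == 0) {
    attr(reports, "bonferroni_alpha") <- numeric(0)
    attr(reports, "fdr_thresholds") <- tibble(
      phenotype = character(0), instrument_class = character(0),
      n_tests = integer(0), p_threshold = numeric(0)
    )
    return(reports)
  }
  m_class <- table(reports$instrument_class)
  bonf <- alpha / as.numeric(m_class)
  names(bonf) <- names(m_class)

  out <- reports |>
    group_by(.data$phenotype, .data$instrument_class) |>
    mutate(qvalue = p.adjust(.data$pvalue, method = "BH")) |>
    ungroup() |>
    mutate(
      tier = case_when(
        .data$pvalue < bonf[.data$instrument_class] ~ "bonferroni",
        .data$qvalue < alpha ~ "fdr",
        TRUE ~ "none"
      )
    )
  thresholds <- out |>
    group_by(.data$phenotype, .data$instrument_class) |>
    summarise(
      n_tests = n(),
      p_threshold = ifelse(any(.data$qvalue < alpha),
        suppressWarnings(max(.data$pvalue[.data$qvalue < alpha])), NA_real_
      ),
      .groups = "drop"
    )
  attr(out, "bonferroni_alpha") <- bonf
  attr(out, "fdr_thresholds") <- thresholds
  out
}

#' Cross-platform concordance of per-protein causal effects
#'
#' Pearson correlation of primary MR estimates across two cohorts
#' (platforms), matched by `(gene_symbol, phenotype)`. Multi-assay
#' collisions within a cohort are resolved by keeping the assay with the
#' most instruments (logged via message).
#'
#' @param reports_a,reports_b Tidy results tables for the two cohorts.
#' @return A one-row tibble: `r`, `n_shared`.
#' @export
cross_platform_correlation <- function(reports_a, reports_b) {
  dedupe <- function(tbl, label) {
    key <- paste(tbl$gene_symbol, tbl$phenotype, sep = "\r")
    if (anyDuplicated(key) > 0) {
      inform(paste0(
        label, ": resolved ", sum(duplicated(key)),
        " multi-assay collision(s) by largest instrument count"
      ))
      tbl <- tbl |>
        group_by(.data$gene_symbol, .data$phenotype) |>
        arrange(desc(.data$n_snps)) |>
        slice(1) |>
        ungroup()
    }
    tbl
  }
  a <- dedupe(as_tibble(reports_a), "reports_a")
  b <- dedupe(as_tibble(reports_b), "reports_b")
  shared <- inner_join(
    select(a, "gene_symbol", "phenotype", theta_a = "theta"),
    select(b, "gene_symbol", "phenotype", theta_b = "theta"),
    by = c("gene_symbol", "phenotype")
  )
  if (nrow(shared) < 3) {
    abort_insufficient(paste0(
      "cross_platform_correlation needs >= 3 shared (gene, phenotype) pairs; got ",
      nrow(shared)
    ))
  }
  tibble(r = cor(shared$theta_a, shared$theta_b), n_shared = nrow(shared))
}

cfg_need <- function(x, field, context) {
  if (is.null(x[[field]])) {
    abort_config(paste0("config: missing field '", field, "' in ", context))
  }
  x[[field]]
}

read_study_config <- function(config) {
  if (is.character(config)) {
    dir <- dirname(config)
    config <- yaml::read_yaml(config)
    config$.dir <- dir
  }
  if (is.null(config$.dir)) config$.dir <- "."
  cfg_need(config, "version", "top level")
  cfg_need(config, "cohorts", "top level")
  cfg_need(config, "phenotypes", "top level")
  config$classes <- config$classes %||% list("cis")
  for (cl in config$classes) {
    if (!cl %in% c("cis", "trans")) {
      abort_config(paste0("config: classes entry must be 'cis' or 'trans', got '", cl, "'"))
    }
  }
  for (i in seq_along(config$phenotypes)) {
    ph <- config$phenotypes[[i]]
    cfg_need(ph, "id", paste0("phenotypes[", i, "]"))
    cfg_need(ph, "file", paste0("phenotypes[", i, "]"))
    type <- cfg_need(ph, "type", paste0("phenotypes[", i, "]"))
    if (!type %in% c("binary", "quantitative")) {
      abort_config(paste0(
        "config: phenotypes[", i, "].type ('", ph$id,
        "') must be 'binary' or 'quantitative', got '", type, "'"
      ))
    }
  }
  for (i in seq_along(config$cohorts)) {
    co <- config$cohorts[[i]]
    cfg_need(co, "id", paste0("cohorts[", i, "]"))
    cfg_need(co, "exposure", paste0("cohorts[", i, "]"))
    cfg_need(co, "annotations", paste0("cohorts[", i, "]"))
  }
  config
}

study_mr_config <- function(config, seed) {
  ic <- config$instrument %||% list()
  es <- config$estimators %||% list()
  mr_config(
    instrument = instrument_config(
      p_threshold = ic$p_threshold %||% 5e-8,
      cis_window_bp = ic$cis_window_bp %||% 1e6,
      clump_r2 = ic$clump_r2 %||% 0.01,
      clump_window_bp = ic$clump_window_bp %||% 1e7,
      min_f = ic$min_f %||% 10
    ),
    weights = es$weights %||% "second",
    random_effects = es$random_effects %||% "auto",
    n_boot = es$n_boot %||% 1000,
    n_sim = es$n_sim %||% 1000,
    outlier_alpha = es$outlier_alpha %||% 0.05,
    reverse = es$reverse %||% "flagged",
    alpha = config$alpha %||% 0.05,
    seed = seed
  )
}

#' Run the full proteome-wide MR study from a config
#'
#' Orchestrates every stage across proteins, phenotypes, cohorts and
#' instrument classes: per-protein MR with the sensitivity battery,
#' Steiger-triggered reverse MR (phenotype instruments drawn from the same
#' outcome files), optional confounder/PheWAS exclusion reruns,
#' cross-cohort fixed-effect meta-analysis matched by gene symbol, and
#' two-tier multiple-testing control. Deterministic for a fixed master
#' seed.
#'
#' @param config Path to a YAML config (as written by [simulate_study()])
#'   or an equivalent list. File paths are resolved relative to the
#'   config's directory.
#' @param out_dir If non-NULL, write `results.tsv` (+ JSON manifest) and
#'   `meta.tsv` there.
#' @param seed Master seed; defaults to the config's `seed` (or 1).
#' @return An object of class `mr_study`: `table` (tidy per-report rows
#'   with `qvalue`/`tier`), `meta` (per gene x phenotype meta-analysis),
#'   `reports` (full report objects), `skips`, `manifest` (run config,
#'   Bonferroni denominators, FDR thresholds, per-tier tallies).
#' @export
run_study <- function(config, out_dir = NULL, seed = NULL) {
  config <- read_study_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1)
  cfg <- study_mr_config(config, seed)
  rel <- function(f) if (is.null(f)) NULL else file.path(config$.dir, f)

  ld <- if (!is.null(config$ld)) read_ld_matrix(rel(config$ld)) else NULL
  exclusions <- list()
  if (!is.null(config$exclusions)) {
    for (reason in intersect(
      names(config$exclusions),
      c("excluded_confounder", "excluded_phewas")
    )) {
      exclusions[[reason]] <- read_exclusion_list(rel(config$exclusions[[reason]]))
    }
  }

  outcome_data <- list()
  outcome_type <- list()
  for (ph in config$phenotypes) {
    outcome_data[[ph$id]] <- read_summary_stats(rel(ph$file))
    outcome_type[[ph$id]] <- ph$type
  }

  reports <- list()
  skips <- list()
  for (co in config$cohorts) {
    exposure_all <- read_summary_stats(
      rel(co$exposure),
      column_map = sumstats_columns(protein_id = "protein_id")
    )
    ann <- readr::read_tsv(rel(co$annotations), show_col_types = FALSE, progress = FALSE)
    targets <- map_protein_targets(ann)
    targets_co <- filter(targets, .data$cohort_id %in% c(co$id, ""))
    for (pid in unique(targets_co$protein_id)) {
      target <- target_for(targets_co, pid)
      exposure <- filter(exposure_all, .data$protein_id == pid)
      if (nrow(exposure) == 0) {
        skips[[length(skips) + 1]] <- mr_skip(
          pid, NA_character_, co$id, NA_character_, "no_exposure_rows"
        )
        next
      }
      for (ph in config$phenotypes) {
        for (cl in config$classes) {
          rep <- run_protein_mr(
            exposure, outcome_data[[ph$id]], target,
            ld = ld, cfg = cfg, mode = cl,
            phenotype = ph$id, cohort_id = co$id,
            outcome_type = outcome_type[[ph$id]],
            exclusions = exclusions
          )
          if (inherits(rep, "mr_skip")) {
            skips[[length(skips) + 1]] <- rep
            next
          }
          run_rev <- cfg$reverse == "always" ||
            (cfg$reverse == "flagged" && "steiger_p_gt_0.05" %in% rep$flags)
          if (run_rev) {
            rev <- reverse_mr(outcome_data[[ph$id]], exposure, ld = ld, cfg = cfg)
            if (inherits(rev, "mr_result")) {
              rep$reverse <- rev
              if (rev$pvalue < 0.05) rep$flags <- c(rep$flags, "reverse_significant")
            }
          }
          reports[[length(reports) + 1]] <- rep
        }
      }
    }
  }

  table <- adjust_pvalues(reports, alpha = cfg$alpha)

  meta <- tibble()
  if (nrow(table) > 0) {
    meta <- table |>
      group_by(.data$gene_symbol, .data$phenotype, .data$instrument_class) |>
      # multi-assay collisions within a cohort: keep the assay with most SNPs
      group_by(.data$cohort_id, .add = TRUE) |>
      arrange(desc(.data$n_snps)) |>
      slice(1) |>
      group_by(.data$gene_symbol, .data$phenotype, .data$instrument_class) |>
      summarise(
        n_cohorts = n(),
        theta_meta = sum(.data$theta / .data$se^2) / sum(1 / .data$se^2),
        se_meta = sqrt(1 / sum(1 / .data$se^2)),
        .groups = "drop"
      ) |>
      mutate(pvalue_meta = z_pvalue(.data$theta_meta, .data$se_meta))
  }

  tallies <- if (nrow(table) > 0) {
    table |>
      group_by(.data$phenotype, .data$instrument_class, .data$tier) |>
      summarise(n = n(), .groups = "drop")
  } else {
    tibble()
  }
  manifest <- list(
    seed = seed,
    n_reports = nrow(table),
    n_skips = length(skips),
    bonferroni_alpha = as.list(attr(table, "bonferroni_alpha")),
    bonferroni_denominator = as.list(table(table$instrument_class)),
    fdr_thresholds = attr(table, "fdr_thresholds"),
    tallies = tallies
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mr_results(table, file.path(out_dir, "results.tsv"),
      config = config[setdiff(names(config), ".dir")], seed = seed
    )
    readr::write_tsv(meta, file.path(out_dir, "meta.tsv"), progress = FALSE)
  }

  structure(
    list(
      table = table, meta = meta, reports = reports, skips = skips,
      manifest = manifest, config = config
    ),
    class = "mr_study"
  )
}

#' @export
print.mr_study <- function(x, ...) {
  cat(sprintf(
    "<mr_study> %d reports (%d skipped), %d meta-analysed gene-phenotype pairs\n",
    nrow(x$table), length(x$skips), nrow(x$meta)
  ))
  if (nrow(x$table) > 0) {
    print(table(x$table$phenotype, x$table$tier))
  }
  invisible(x)
}

#' Glance at a study run
#'
#' @param x An `mr_study`.
#' @param ... Unused.
#' @return One row: report/skip counts and per-tier totals.
#' @method glance mr_study
#' @export
glance.mr_study <- function(x, ...) {
  tibble(
    n_reports = nrow(x$table),
    n_skips = length(x$skips),
    n_bonferroni = sum(x$table$tier == "bonferroni"),
    n_fdr = sum(x$table$tier %in% c("fdr", "bonferroni")),
    n_meta = nrow(x$meta)
  )
}

#' Significance overview plot for a study run
#'
#' Per-phenotype volcano plot of primary estimates, coloured by
#' significance tier.
#'
#' @param object An `mr_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_study
#' @export
autoplot.mr_study <- function(object, ...) {
  d <- object$table
  if (nrow(d) == 0) abort_usage("empty study: nothing to plot")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$theta, y = -log10(.data$pvalue), colour = .data$tier
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$phenotype), scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(
      none = "grey60", fdr = "#2166ac", bonferroni = "#b2182b"
    )) +
    ggplot2::labs(
      x = "Causal effect (per SD protein)", y = "-log10 p (primary MR)",
      colour = "Tier"
    ) +
    ggplot2::theme_minimal()
}
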