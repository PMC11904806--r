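# Reading, validating and harmonizing GWAS / pQTL summary statistics.

#' Column mapping for summary-statistics tables
#'
#' Maps the canonical field names used throughout the package to the column
#' names found in a particular file. Only the names that differ from the
#' canonical ones need to be given.
#'
#' @param variant_id,chrom,pos,effect_allele,other_allele,eaf,beta,se,pvalue,n
#'   Source column names. `eaf` may be `NA` to declare it absent.
#' @param protein_id Optional source column carrying an assay/protein id for
#'   stacked multi-protein tables.
#' @return A named list usable as `column_map` in [read_summary_stats()].
#' @export
#' @examples
#' sumstats_columns(variant_id = "SNP", pvalue = "P")
sumstats_columns <- function(variant_id = "variant_id", chrom = "chrom",
                             pos = "pos", effect_allele = "effect_allele",
                             other_allele = "other_allele", eaf = "eaf",
                             beta = "beta", se = "se", pvalue = "pvalue",
                             n = "n", protein_id = NULL) {
  list(
    variant_id = variant_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele, eaf = eaf,
    beta = beta, se = se, pvalue = pvalue, n = n, protein_id = protein_id
  )
}

MANDATORY_SUMSTAT_FIELDS <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "beta", "se", "pvalue", "n"
)

#' Read a summary-statistics table
#'
#' Reads a tab-separated GWAS or pQTL association table, renames columns to
#' the canonical schema, and validates every row against the field
#' invariants (positive SE, frequencies strictly inside (0,1), p-values in
#' (0,1], single-nucleotide alleles, distinct alleles, positive sample
#' size). Malformed rows are removed, counted, and reported through the
#' `rejects` attribute and a warning — never silently dropped. Reported
#' p-values that disagree with the two-sided normal p implied by `beta/se`
#' by more than 0.5 on the log10 scale trigger a warning but are kept.
#'
#' @param path Path to the file.
#' @param column_map Output of [sumstats_columns()].
#' @param dialect `"tsv"` for a plain tab-separated table or
#'   `"gwas_vcf_lite"` for a minimal GWAS-VCF-style text layout
#'   (`#CHROM POS ID REF ALT QUAL FILTER INFO FORMAT sample` with a
#'   colon-separated `ES:SE:LP:AF:SS` sample field; ALT is the effect
#'   allele).
#' @return A tibble of validated associations with attributes `n_input`
#'   (rows read) and `rejects` (tibble of row, variant_id, reason).
#' @export
read_summary_stats <- function(path, column_map = sumstats_columns(),
                               dialect = c("tsv", "gwas_vcf_lite")) {
  dialect <- arg_match(dialect)
  if (!file.exists(path)) abort_input(paste0("summary-statistics file not found: ", path))
  raw <- switch(dialect,
    tsv = read_sumstats_tsv(path, column_map),
    gwas_vcf_lite = read_sumstats_vcf_lite(path)
  )
  validate_sumstats(raw, source = path)
}

read_sumstats_tsv <- function(path, column_map) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cmap <- compact(column_map)
  missing_src <- setdiff(unlist(cmap[MANDATORY_SUMSTAT_FIELDS]), names(tbl))
  if (length(missing_src) > 0) {
    abort_config(paste0(
      "mandatory column(s) not found in ", path, ": ",
      paste(missing_src, collapse = ", ")
    ))
  }
  present <- cmap[map_lgl(cmap, ~ .x %in% names(tbl))]
  out <- tbl[unlist(present)]
  names(out) <- names(present)
  if (!"eaf" %in% names(out)) out$eaf <- NA_real_
  out
}

read_sumstats_vcf_lite <- function(path) {
  tbl <- readr::read_tsv(path, comment = "##", show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- sub("^#", "", names(tbl)[1])
  needed <- c("CHROM", "POS", "ID", "REF", "ALT", "FORMAT")
  if (!all(needed %in% names(tbl)) || ncol(tbl) < 10) {
    abort_config(paste0("not a gwas_vcf_lite layout: ", path))
  }
  sample_col <- names(tbl)[10]
  fields <- strsplit(tbl$FORMAT, ":", fixed = TRUE)
  values <- strsplit(tbl[[sample_col]], ":", fixed = TRUE)
  tibble(
    variant_id = as.character(tbl$ID),
    chrom = as.character(tbl$CHROM),
    pos = as.integer(tbl$POS),
    effect_allele = toupper(tbl$ALT),
    other_allele = toupper(tbl$REF),
    eaf = map2_dbl_(fields, values, "AF"),
    beta = map2_dbl_(fields, values, "ES"),
    se = map2_dbl_(fields, values, "SE"),
    pvalue = 10^(-map2_dbl_(fields, values, "LP")),
    n = map2_dbl_(fields, values, "SS")
  )
}

map2_dbl_ <- function(fields, values, key) {
  map_dbl(seq_along(fields), function(i) {
    j <- match(key, fields[[i]])
    if (is.na(j)) NA_real_ else suppressWarnings(as.numeric(values[[i]][j]))
  })
}

validate_sumstats <- function(tbl, source = "input") {
  tbl <- mutate(tbl,
    .row = row_number(),
    variant_id = as.character(.data$variant_id),
    chrom = as.character(.data$chrom),
    effect_allele = toupper(as.character(.data$effect_allele)),
    other_allele = toupper(as.character(.data$other_allele))
  )
  reason <- rep(NA_character_, nrow(tbl))
  flag <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- flag(is.na(tbl$beta) | is.na(tbl$se) | is.na(tbl$pvalue) |
    is.na(tbl$pos) | is.na(tbl$variant_id), "missing_value")
  reason <- flag(!is.na(tbl$se) & tbl$se <= 0, "nonpositive_se")
  reason <- flag(!(tbl$effect_allele %in% names(DNA_COMPLEMENT)) |
    !(tbl$other_allele %in% names(DNA_COMPLEMENT)) |
    tbl$effect_allele == tbl$other_allele, "bad_alleles")
  reason <- flag(!is.na(tbl$eaf) & (tbl$eaf <= 0 | tbl$eaf >= 1), "bad_eaf")
  reason <- flag(!is.na(tbl$pvalue) & (tbl$pvalue <= 0 | tbl$pvalue > 1), "bad_pvalue")
  reason <- flag(!is.na(tbl$n) & tbl$n <= 0, "nonpositive_n")
  reason <- flag(!is.na(tbl$pos) & tbl$pos < 1, "bad_pos")

  rejects <- tibble(
    row = tbl$.row[!is.na(reason)],
    variant_id = tbl$variant_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  keep <- tbl[is.na(reason), , drop = FALSE]

  # Consistency of reported p with |beta/se| under the two-sided normal map;
  # disagreement warns but never rejects (many GWAS report exact-test p).
  if (nrow(keep) > 0) {
    p_z <- z_pvalue(keep$beta, keep$se)
    lg <- abs(log10(pmax(keep$pvalue, 1e-300)) - log10(pmax(p_z, 1e-300)))
    n_bad <- sum(lg > 0.5, na.rm = TRUE)
    if (n_bad > 0) {
      warn(paste0(
        source, ": ", n_bad, " row(s) have reported p inconsistent with beta/se ",
        "(|log10 difference| > 0.5); kept as reported"
      ))
    }
  }
  if (nrow(rejects) > 0) {
    warn(paste0(source, ": rejected ", nrow(rejects), " malformed row(s)"))
  }
  if (nrow(keep) == 0) abort_input(paste0(source, ": zero valid rows"))
  out <- select(keep, -".row")
  attr(out, "n_input") <- nrow(tbl)
  attr(out, "rejects") <- rejects
  out
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome records to the exposure's effect-allele orientation. If
#' the outcome's alleles are swapped relative to the exposure, the outcome
#' beta sign is flipped and its frequency complemented; strand-complement
#' records (e.g. A/G vs T/C) are resolved by complementing; palindromic
#' variants (A/T, C/G) are kept only when both allele frequencies are
#' available, lie on the same side of 0.5, and fall outside
#' `[palindrome_maf_limit, 1 - palindrome_maf_limit]` — otherwise they are
#' retained with `drop_reason = "palindromic_ambiguous"`. Irreconcilable
#' alleles give `"allele_mismatch"`; exposure variants absent from the
#' outcome give `"missing_outcome"`. Rows with a non-missing `drop_reason`
#' are excluded from estimation downstream but kept for provenance.
#'
#' @param exposure,outcome Validated summary-statistics tibbles (see
#'   [read_summary_stats()]).
#' @param palindrome_maf_limit Palindromic variants whose frequency falls
#'   within `[limit, 1 - limit]` on either side are treated as strand
#'   ambiguous (default 0.42, a conservative standard choice).
#' @return A tibble of harmonized instruments: `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf` (exposure effect-allele
#'   frequency), `beta_exposure`, `se_exposure`, `pvalue_exposure`,
#'   `n_exposure`, `beta_outcome`, `se_outcome`, `pvalue_outcome`,
#'   `n_outcome`, `eaf_outcome`, `is_cis` (NA until classified),
#'   `drop_reason`.
#' @export
harmonize_instruments <- function(exposure, outcome, palindrome_maf_limit = 0.42) {
  stopifnot(palindrome_maf_limit > 0, palindrome_maf_limit < 0.5)
  x <- rename(as_tibble(exposure),
    beta_exposure = "beta", se_exposure = "se",
    pvalue_exposure = "pvalue", n_exposure = "n"
  )
  y <- select(as_tibble(outcome),
    variant_id = "variant_id", ea_out = "effect_allele", oa_out = "other_allele",
    eaf_out_raw = "eaf", beta_out_raw = "beta", se_outcome = "se",
    pvalue_outcome = "pvalue", n_outcome = "n"
  )
  if (anyDuplicated(y$variant_id) > 0) {
    y <- distinct(y, .data$variant_id, .keep_all = TRUE)
  }
  h <- left_join(x, y, by = "variant_id")

  ea_x <- h$effect_allele
  oa_x <- h$other_allele
  ea_y <- h$ea_out
  oa_y <- h$oa_out
  missing_out <- is.na(ea_y)
  pal <- is_palindromic(ea_x, oa_x)

  same <- !missing_out & ea_y == ea_x & oa_y == oa_x
  swap <- !missing_out & ea_y == oa_x & oa_y == ea_x
  cea <- complement_allele(ifelse(missing_out, "A", ea_y))
  coa <- complement_allele(ifelse(missing_out, "A", oa_y))
  comp_same <- !missing_out & cea == ea_x & coa == oa_x
  comp_swap <- !missing_out & cea == oa_x & coa == ea_x

  reconcilable <- same | swap | comp_same | comp_swap
  # Palindromic pairs: keep only with unambiguous, concordant frequencies.
  maf_ok <- function(f) {
    !is.na(f) & (f < palindrome_maf_limit | f > 1 - palindrome_maf_limit)
  }
  pal_keep <- pal & reconcilable & maf_ok(h$eaf) & maf_ok(h$eaf_out_raw) &
    ((h$eaf > 0.5) == (h$eaf_out_raw > 0.5))

  flip <- (!pal & (swap | comp_swap)) # palindromic keepers are concordant: no flip
  drop_reason <- case_when(
    missing_out ~ "missing_outcome",
    !reconcilable ~ "allele_mismatch",
    pal & !pal_keep ~ "palindromic_ambiguous",
    TRUE ~ NA_character_
  )

  out <- mutate(h,
    beta_outcome = ifelse(flip, -.data$beta_out_raw, .data$beta_out_raw),
    eaf_outcome = ifelse(flip, 1 - .data$eaf_out_raw, .data$eaf_out_raw),
    is_cis = NA,
    drop_reason = drop_reason
  )
  select(
    out, "variant_id", "chrom", "pos", "effect_allele", "other_allele",
    "eaf", "beta_exposure", "se_exposure", "pvalue_exposure", "n_exposure",
    "beta_outcome", "se_outcome", "pvalue_outcome", "n_outcome",
    "eaf_outcome", "is_cis", "drop_reason"
  )
}

#' Harmonize a single exposure/outcome record pair
#'
#' Scalar convenience wrapper around [harmonize_instruments()].
#'
#' @param exposure,outcome One-row summary-statistics tibbles for the same
#'   variant.
#' @inheritParams harmonize_instruments
#' @return A one-row harmonized tibble.
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_maf_limit = 0.42) {
  stopifnot(nrow(exposure) == 1, nrow(outcome) == 1)
  if (!identical(as.character(exposure$variant_id), as.character(outcome$variant_id))) {
    abort_usage("harmonize_pair: exposure and outcome records have different variant_id")
  }
  harmonize_instruments(exposure, outcome, palindrome_maf_limit)
}

# Usable (non-dropped) instruments of a harmonized table.
usable_instruments <- function(h) filter(h, is.na(.data$drop_reason))

#' Build a protein-target annotation map
#'
#' Validates a protein annotation table (gene coordinates used for cis/trans
#' classification). Rows with `gene_start > gene_end` are rejected with a
#' reason; duplicated `(protein_id, cohort_id)` keys are an input error.
#'
#' @param annotations A data frame with columns `protein_id`, `gene_symbol`,
#'   `chrom`, `gene_start`, `gene_end`, and optionally `cohort_id`.
#' @return A validated tibble (class `protein_targets`) with a `rejects`
#'   attribute.
#' @export
map_protein_targets <- function(annotations) {
  need <- c("protein_id", "gene_symbol", "chrom", "gene_start", "gene_end")
  missing_cols <- setdiff(need, names(annotations))
  if (length(missing_cols) > 0) {
    abort_input(paste0(
      "annotation table lacks column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  tbl <- as_tibble(annotations)
  if (!"cohort_id" %in% names(tbl)) tbl$cohort_id <- ""
  tbl <- mutate(tbl,
    protein_id = as.character(.data$protein_id),
    chrom = as.character(.data$chrom),
    cohort_id = as.character(.data$cohort_id)
  )
  bad <- tbl$gene_start > tbl$gene_end
  rejects <- tibble(
    protein_id = tbl$protein_id[bad],
    reason = rep("gene_start_gt_gene_end", sum(bad))
  )
  if (nrow(rejects) > 0) {
    warn(paste0("rejected ", nrow(rejects), " annotation row(s): gene_start > gene_end"))
  }
  tbl <- tbl[!bad, , drop = FALSE]
  key <- paste(tbl$protein_id, tbl$cohort_id, sep = "\r")
  if (anyDuplicated(key) > 0) {
    abort_input(paste0(
      "duplicate (protein_id, cohort_id) in annotations: ",
      paste(unique(tbl$protein_id[duplicated(key)]), collapse = ", ")
    ))
  }
  attr(tbl, "rejects") <- rejects
  class(tbl) <- c("protein_targets", class(tbl))
  tbl
}

#' Look up one protein target
#'
#' @param targets Output of [map_protein_targets()].
#' @param protein_id Assay/protein id.
#' @param cohort_id Optional cohort filter.
#' @return A one-row tibble.
#' @export
target_for <- function(targets, protein_id, cohort_id = NULL) {
  hit <- filter(targets, .data$protein_id == !!protein_id)
  if (!is.null(cohort_id)) hit <- filter(hit, .data$cohort_id == !!cohort_id)
  if (nrow(hit) == 0) {
    abort_input(paste0("unknown protein target: ", protein_id))
  }
  slice(hit, 1)
}

#' Write a results table with a JSON run manifest
#'
#' Writes one row per protein–phenotype–cohort–class report to
#' tab-separated text (full double precision, round-trip safe) and a JSON
#' sidecar (`<path>.manifest.json`) carrying the run configuration and
#' master seed.
#'
#' @param results A tidy results tibble (e.g. from [tidy.sensitivity_report()]
#'   rows bound together or [run_study()]'s `$table`), or a list of
#'   `sensitivity_report` objects.
#' @param path Output TSV path.
#' @param config Run configuration list stored in the manifest.
#' @param seed Master seed stored in the manifest.
#' @return `path`, invisibly.
#' @export
write_mr_results <- function(results, path, config = list(), seed = NULL) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- list_rbind(map(results, tidy))
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(results, path, progress = FALSE)
  manifest <- list(
    package = "pqtlmr",
    version = as.character(utils::packageVersion("pqtlmr")),
    seed = seed,
    n_rows = nrow(results),
    config = config
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}

#' Read back a results table written by [write_mr_results()]
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_mr_results <- function(path) {
  # an empty flag set is data ("" = no flags), not missingness
  readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE, na = "NA",
    col_types = readr::cols(
      flags = readr::col_character(), .default = readr::col_guess()
    )
  )
}
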