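# Instrument selection: cis/trans classification, LD clumping,
# weak-instrument screening, exclusion-list filtering.

#' Instrument-selection configuration
#'
#' Thresholds governing pQTL instrument selection. Defaults follow standard
#' practice for proteome-wide MR: genome-wide significance 5e-8, a cis
#' window of +/- 1 Mb around the gene body, LD clumping at r^2 < 0.01
#' within 10 Mb, and a minimum approximate F-statistic of 10.
#'
#' @param p_threshold Significance cutoff for candidate instruments.
#' @param cis_window_bp Window (bp) around the gene body defining cis.
#' @param clump_r2 LD r^2 ceiling between retained instruments.
#' @param clump_window_bp Window (bp) within which clumping applies.
#' @param min_f Minimum per-instrument F-statistic `(beta/se)^2`.
#' @return A list of class `instrument_config`.
#' @export
instrument_config <- function(p_threshold = 5e-8, cis_window_bp = 1e6,
                              clump_r2 = 0.01, clump_window_bp = 1e7,
                              min_f = 10) {
  if (!(p_threshold > 0 && p_threshold < 1)) abort_config("p_threshold must be in (0,1)")
  if (cis_window_bp < 0) abort_config("cis_window_bp must be >= 0")
  if (!(clump_r2 >= 0 && clump_r2 < 1)) abort_config("clump_r2 must be in [0,1)")
  if (min_f < 0) abort_config("min_f must be >= 0")
  structure(
    list(
      p_threshold = p_threshold, cis_window_bp = cis_window_bp,
      clump_r2 = clump_r2, clump_window_bp = clump_window_bp, min_f = min_f
    ),
    class = "instrument_config"
  )
}

#' Classify variants as cis or trans for a protein target
#'
#' A variant is cis when it lies on the target gene's chromosome within
#' `[gene_start - cis_window_bp, gene_end + cis_window_bp]`; trans
#' otherwise.
#'
#' @param variants Tibble with `chrom` and `pos`.
#' @param target One-row protein target (see [target_for()]).
#' @param cis_window_bp Window in base pairs (default 1 Mb).
#' @return Character vector `"cis"`/`"trans"`, one per variant row.
#' @export
classify_cis_trans <- function(variants, target, cis_window_bp = 1e6) {
  lo <- target$gene_start - cis_window_bp
  hi <- target$gene_end + cis_window_bp
  ifelse(
    as.character(variants$chrom) == as.character(target$chrom) &
      variants$pos >= lo & variants$pos <= hi,
    "cis", "trans"
  )
}

#' Read a square LD matrix from TSV
#'
#' Expects a header row of variant ids and a leading id column; entries are
#' r^2 values.
#'
#' @param path TSV path.
#' @return A numeric matrix with dimnames, validated by [validate_ld()].
#' @export
read_ld_matrix <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(tbl[[1]])
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- ids
  validate_ld(m)
}

#' Validate an LD matrix
#'
#' Checks symmetry, unit diagonal and r^2 values in `[0, 1]`.
#'
#' @param ld Square numeric matrix with variant-id dimnames.
#' @return The matrix, invisibly validated.
#' @export
validate_ld <- function(ld) {
  if (is.null(rownames(ld)) || is.null(colnames(ld))) {
    abort_input("LD matrix needs variant ids as dimnames")
  }
  if (nrow(ld) != ncol(ld) || !identical(rownames(ld), colnames(ld))) {
    abort_input("LD matrix must be square with matching row/column ids")
  }
  if (max(abs(ld - t(ld))) > 1e-8) abort_input("LD matrix is not symmetric")
  if (any(abs(diag(ld) - 1) > 1e-8)) abort_input("LD matrix diagonal must be 1")
  if (any(ld < -1e-12 | ld > 1 + 1e-12)) abort_input("LD r^2 values must lie in [0,1]")
  ld
}

#' Greedy LD clumping
#'
#' Standard clumping semantics: visit variants in ascending p-value order
#' (ties broken lexicographically by variant id, so the result is fully
#' deterministic), retain the best, and discard every not-yet-retained
#' variant within `clump_window_bp` on the same chromosome whose r^2 with a
#' retained variant exceeds `clump_r2`. Variants absent from the LD matrix
#' are treated as unlinked and flagged with a warning (partial LD panels
#' are the norm).
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos`, `pvalue`.
#' @param ld LD matrix (r^2) or `NULL` for all-unlinked.
#' @param clump_r2 r^2 ceiling (default 0.01).
#' @param clump_window_bp Window in bp (default 10 Mb).
#' @return The retained subset of `variants` (original row content), in
#'   p-value order of retention.
#' @export
ld_clump <- function(variants, ld = NULL, clump_r2 = 0.01, clump_window_bp = 1e7) {
  if (nrow(variants) == 0) return(variants)
  if (!is.null(ld)) {
    validate_ld(ld)
    unknown <- setdiff(variants$variant_id, rownames(ld))
    if (length(unknown) > 0) {
      warn(paste0(
        length(unknown), " variant(s) absent from LD matrix; treated as unlinked"
      ))
    }
  }
  ord <- order(variants$pvalue, variants$variant_id)
  v <- variants[ord, , drop = FALSE]
  n <- nrow(v)
  alive <- rep(TRUE, n)
  retained <- logical(n)
  in_ld <- if (is.null(ld)) rep(FALSE, n) else v$variant_id %in% rownames(ld)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    retained[i] <- TRUE
    if (!in_ld[i]) next
    later <- which(alive & !retained)
    if (length(later) == 0) next
    same_window <- v$chrom[later] == v$chrom[i] &
      abs(v$pos[later] - v$pos[i]) <= clump_window_bp
    cand <- later[same_window & in_ld[later]]
    if (length(cand) > 0) {
      r2 <- ld[v$variant_id[i], v$variant_id[cand]]
      alive[cand[r2 > clump_r2]] <- FALSE
    }
  }
  v[retained, , drop = FALSE]
}

#' Approximate per-instrument F-statistic
#'
#' Uses the summary-statistic approximation `F = (beta / se)^2`.
#'
#' @param beta,se Exposure effect and standard error (vectorized).
#' @return Nonnegative numeric vector.
#' @export
#' @examples
#' f_statistic(0.1, 0.01) # 100
f_statistic <- function(beta, se) {
  stopifnot(all(se > 0))
  (beta / se)^2
}

#' Select instruments for one protein
#'
#' Composes the selection pipeline: p-value threshold, cis/trans filter for
#' the requested mode, greedy LD clumping, then the weak-instrument
#' F-statistic screen. The result is ordered by genomic coordinate and
#' carries per-stage retention counts in the `stage_counts` attribute.
#'
#' @param exposure Exposure summary-statistics tibble for one protein.
#' @param target One-row protein target.
#' @param ld LD matrix or `NULL`.
#' @param cfg An [instrument_config()].
#' @param mode `"cis"`, `"trans"`, or `"all"` (no class filter; used for
#'   phenotype exposures in reverse MR).
#' @return Tibble of selected variants with an `is_cis` column and
#'   attribute `stage_counts` (named: input, significant, class, clumped,
#'   strong).
#' @export
select_instruments <- function(exposure, target, ld = NULL,
                               cfg = instrument_config(),
                               mode = c("cis", "trans", "all")) {
  mode <- arg_match(mode)
  sig <- filter(exposure, .data$pvalue < cfg$p_threshold)
  if (mode == "all") {
    cls <- mutate(sig, is_cis = NA)
  } else {
    cls <- mutate(sig,
      is_cis = classify_cis_trans(sig, target, cfg$cis_window_bp) == "cis"
    )
    cls <- filter(cls, .data$is_cis == (mode == "cis"))
  }
  clumped <- ld_clump(cls, ld, cfg$clump_r2, cfg$clump_window_bp)
  strong <- filter(clumped, f_statistic(.data$beta, .data$se) >= cfg$min_f)
  out <- arrange(strong, .data$chrom, .data$pos, .data$variant_id)
  attr(out, "stage_counts") <- c(
    input = nrow(exposure), significant = nrow(sig), class = nrow(cls),
    clumped = nrow(clumped), strong = nrow(strong)
  )
  out
}

#' Read a one-id-per-line SNP exclusion list
#'
#' @param path Text file with one variant id per line (blank lines and
#'   `#` comments ignored).
#' @return Character vector of ids.
#' @export
read_exclusion_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Flag instruments present in an exclusion list
#'
#' Marks matching instruments with the given `drop_reason` (confounder GWAS
#' hits or PheWAS hits); downstream estimation uses only undropped rows.
#'
#' @param instruments Harmonized instrument tibble.
#' @param exclusion_ids Character vector of variant ids to exclude.
#' @param reason `"excluded_confounder"` or `"excluded_phewas"`.
#' @return The tibble with updated `drop_reason` and an attribute
#'   `removal_log` (tibble of variant_id, reason).
#' @export
apply_snp_exclusions <- function(instruments, exclusion_ids,
                                 reason = c("excluded_confounder", "excluded_phewas")) {
  reason <- arg_match(reason)
  hit <- instruments$variant_id %in% exclusion_ids & is.na(instruments$drop_reason)
  out <- mutate(instruments,
    drop_reason = ifelse(hit, reason, .data$drop_reason)
  )
  attr(out, "removal_log") <- tibble(
    variant_id = instruments$variant_id[hit],
    reason = rep(reason, sum(hit))
  )
  out
}
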