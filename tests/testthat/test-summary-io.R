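test_that("well-formed tables parse losslessly and keep row order", {
  tbl <- make_sumstats(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05), se = 0.02)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path)
  got <- read_summary_stats(path)
  expect_equal(nrow(got), 3)
  expect_equal(nrow(attr(got, "rejects")), 0)
  expect_equal(got$variant_id, tbl$variant_id)
  expect_equal(got$beta, tbl$beta, tolerance = 1e-12)
})

test_that("malformed rows are rejected with reasons, never silently dropped", {
  tbl <- make_sumstats(c("rs1", "rs2", "rs3", "rs4"), beta = 0.1, se = 0.02)
  tbl$se[2] <- 0
  tbl$eaf[3] <- 1.2
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path)
  expect_warning(got <- read_summary_stats(path), "rejected 2 malformed")
  rejects <- attr(got, "rejects")
  expect_equal(nrow(got) + nrow(rejects), attr(got, "n_input"))
  expect_equal(rejects$reason[rejects$variant_id == "rs2"], "nonpositive_se")
  expect_equal(rejects$reason[rejects$variant_id == "rs3"], "bad_eaf")
})

test_that("missing mandatory columns and empty tables raise typed errors", {
  tbl <- make_sumstats("rs1", beta = 0.1, se = 0.02)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::select(tbl, -"se"), path)
  expect_error(read_summary_stats(path), class = "pqtlmr_error_config")

  tbl$se <- -1
  readr::write_tsv(tbl, path)
  expect_error(
    suppressWarnings(read_summary_stats(path)),
    class = "pqtlmr_error_input"
  )
})

test_that("inconsistent reported p-values warn but are kept", {
  tbl <- make_sumstats(c("rs1", "rs2"), beta = c(0.1, 0.1), se = 0.02)
  tbl$pvalue[1] <- 0.9 # |z| = 5: reported p wildly off
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path)
  expect_warning(got <- read_summary_stats(path), "inconsistent with beta/se")
  expect_equal(got$pvalue[1], 0.9)
})

test_that("gwas_vcf_lite dialect parses the colon-packed sample field", {
  lines <- c(
    "##fileformat=VCFv4.2-lite",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "gwas",
      sep = "\t"
    ),
    paste("1", "5000", "rs9", "G", "A", ".", "PASS", ".",
      "ES:SE:LP:AF:SS", "0.1:0.02:6.2417:0.3:30000",
      sep = "\t"
    )
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, path)
  got <- read_summary_stats(path, dialect = "gwas_vcf_lite")
  expect_equal(got$variant_id, "rs9")
  expect_equal(got$effect_allele, "A") # ALT is the effect allele
  expect_equal(got$other_allele, "G")
  expect_equal(got$beta, 0.1)
  expect_equal(got$pvalue, 10^-6.2417, tolerance = 1e-10)
})

test_that("harmonization aligns swapped, complemented and exact records", {
  exp1 <- make_sumstats("rs1", beta = 0.10, se = 0.02,
    effect_allele = "A", other_allele = "G", eaf = 0.3
  )
  # swapped alleles: outcome beta sign flips, frequency complements
  out_swap <- make_sumstats("rs1", beta = -0.05, se = 0.02,
    effect_allele = "G", other_allele = "A", eaf = 0.7
  )
  h <- harmonize_pair(exp1, out_swap)
  expect_equal(h$beta_outcome, 0.05)
  expect_equal(h$eaf_outcome, 0.3)
  expect_true(is.na(h$drop_reason))

  # strand complement, same orientation: no flip
  out_comp <- make_sumstats("rs1", beta = 0.07, se = 0.02,
    effect_allele = "T", other_allele = "C", eaf = 0.3
  )
  h2 <- harmonize_pair(exp1, out_comp)
  expect_equal(h2$beta_outcome, 0.07)
  expect_true(is.na(h2$drop_reason))

  # irreconcilable alleles
  out_bad <- make_sumstats("rs1", beta = 0.07, se = 0.02,
    effect_allele = "C", other_allele = "A"
  )
  expect_equal(harmonize_pair(exp1, out_bad)$drop_reason, "allele_mismatch")

  # differing ids are a usage error
  out2 <- make_sumstats("rs2", beta = 0.05, se = 0.02)
  expect_error(harmonize_pair(exp1, out2), class = "pqtlmr_error_usage")
})

test_that("palindromic variants follow the frequency-ambiguity policy", {
  pal <- function(eaf_x, eaf_y, limit = 0.42) {
    e <- make_sumstats("rs1", beta = 0.1, se = 0.02,
      effect_allele = "A", other_allele = "T", eaf = eaf_x
    )
    o <- make_sumstats("rs1", beta = 0.05, se = 0.02,
      effect_allele = "A", other_allele = "T", eaf = eaf_y
    )
    harmonize_pair(e, o, palindrome_maf_limit = limit)
  }
  expect_equal(pal(0.50, 0.50)$drop_reason, "palindromic_ambiguous")
  expect_equal(pal(0.45, 0.45)$drop_reason, "palindromic_ambiguous")
  # clear and concordant frequencies: kept, no flip
  keep <- pal(0.10, 0.12)
  expect_true(is.na(keep$drop_reason))
  expect_equal(keep$beta_outcome, 0.05)
  # opposite sides of 0.5: ambiguous
  expect_equal(pal(0.10, 0.90)$drop_reason, "palindromic_ambiguous")
  # missing outcome frequency: ambiguous
  expect_equal(pal(0.10, NA)$drop_reason, "palindromic_ambiguous")
})

test_that("harmonization is involutive under exposure allele swaps", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      alleles <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))[[sample(4, 1)]]
      e <- make_sumstats("rs1", beta = rnorm(1, 0, 0.2), se = 0.02,
        effect_allele = alleles[1], other_allele = alleles[2], eaf = runif(1, 0.05, 0.95)
      )
      ea_out <- sample(alleles, 1)
      o <- make_sumstats("rs1", beta = rnorm(1, 0, 0.1), se = 0.03,
        effect_allele = ea_out, other_allele = setdiff(alleles, ea_out)
      )
      e_sw <- dplyr::mutate(e,
        effect_allele = e$other_allele, other_allele = e$effect_allele,
        beta = -.data$beta, eaf = 1 - .data$eaf
      )
      h1 <- harmonize_pair(e, o)
      h2 <- harmonize_pair(e_sw, o)
      expect_true(is.na(h1$drop_reason) && is.na(h2$drop_reason))
      expect_equal(
        h1$beta_outcome / h1$beta_exposure,
        h2$beta_outcome / h2$beta_exposure,
        tolerance = 1e-12
      )
    }
  })
})

test_that("exposure variants absent from the outcome are kept with a drop reason", {
  e <- make_sumstats(c("rs1", "rs2"), beta = c(0.1, 0.2), se = 0.02)
  o <- make_sumstats("rs1", beta = 0.05, se = 0.02)
  h <- harmonize_instruments(e, o)
  expect_equal(h$drop_reason, c(NA, "missing_outcome"))
  expect_equal(nrow(pqtlmr:::usable_instruments(h)), 1)
})

test_that("protein target maps validate keys and coordinates", {
  ann <- tibble::tibble(
    protein_id = c("P1", "P2"), gene_symbol = c("G1", "G2"),
    chrom = c("1", "2"), gene_start = c(100L, 5000L), gene_end = c(200L, 9000L),
    cohort_id = "ukb"
  )
  targets <- map_protein_targets(ann)
  expect_equal(nrow(targets), 2)
  expect_equal(target_for(targets, "P2")$gene_symbol, "G2")
  expect_error(target_for(targets, "P9"), class = "pqtlmr_error_input")

  expect_error(
    map_protein_targets(dplyr::bind_rows(ann, ann[1, ])),
    class = "pqtlmr_error_input"
  )

  bad <- ann
  bad$gene_start[2] <- 99999L
  expect_warning(t2 <- map_protein_targets(bad), "gene_start > gene_end")
  expect_equal(nrow(t2), 1)
  expect_equal(attr(t2, "rejects")$protein_id, "P2")
})

test_that("results tables round-trip through TSV with a JSON manifest", {
  h <- gen_ratio_data(5, 0.3, seed = 8)
  ann <- tibble::tibble(
    protein_id = "P1", gene_symbol = "G1", chrom = "1",
    gene_start = 1L, gene_end = 10L, cohort_id = ""
  )
  rep1 <- run_protein_mr(
    make_sumstats(h$variant_id, beta = h$beta_exposure, se = h$se_exposure),
    make_sumstats(h$variant_id, beta = h$beta_outcome, se = h$se_outcome),
    target_for(map_protein_targets(ann), "P1"),
    cfg = mr_config(n_boot = 50, n_sim = 120, seed = 4),
    mode = "cis", phenotype = "PH", cohort_id = "c1"
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mr_results(list(rep1), path, config = list(note = "unit"), seed = 4)
  back <- read_mr_results(path)
  expect_equal(nrow(back), 1)
  orig <- tidy(rep1)
  for (col in names(orig)) {
    if (is.numeric(orig[[col]])) {
      expect_equal(signif(back[[col]], 12), signif(orig[[col]], 12))
    } else {
      expect_equal(back[[col]], orig[[col]])
    }
  }
  manifest <- jsonlite::read_json(paste0(path, ".manifest.json"))
  expect_equal(manifest$seed, 4)
  expect_equal(manifest$n_rows, 1)

  # empty collection: header-only table
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_mr_results(orig[0, ], path2)
  expect_equal(nrow(read_mr_results(path2)), 0)
})
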