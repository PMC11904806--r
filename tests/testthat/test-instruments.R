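target_fixture <- function(chrom = "1", start = 2000000L, end = 2020000L) {
  ann <- tibble::tibble(
    protein_id = "P1", gene_symbol = "G1", chrom = chrom,
    gene_start = start, gene_end = end, cohort_id = ""
  )
  target_for(map_protein_targets(ann), "P1")
}

test_that("cis/trans classification respects the window boundaries", {
  tg <- target_fixture()
  w <- 1e6
  v <- tibble::tibble(
    chrom = c("1", "2", "1", "1", "1"),
    pos = c(
      tg$gene_start - 1, tg$gene_start, tg$gene_end + w,
      tg$gene_end + w + 1, tg$gene_start - w
    )
  )
  expect_equal(
    classify_cis_trans(v, tg, w),
    c("cis", "trans", "cis", "trans", "cis")
  )
})

test_that("F statistic matches its closed form and threshold algebra", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(0, 0.3), 0)
  withr::with_seed(5, {
    beta <- rnorm(50)
    se <- runif(50, 0.01, 0.2)
    expect_equal(
      f_statistic(beta, se) >= 10,
      abs(beta / se) >= sqrt(10)
    )
  })
})

test_that("greedy clumping keeps the best of each linked pair", {
  v <- tibble::tibble(
    variant_id = c("v1", "v2", "v3"), chrom = "1",
    pos = c(100L, 200L, 9000000L), pvalue = c(1e-10, 1e-9, 1e-8)
  )
  ld <- diag(1, 3)
  dimnames(ld) <- list(v$variant_id, v$variant_id)
  ld["v1", "v2"] <- ld["v2", "v1"] <- 0.5
  out <- ld_clump(v, ld, clump_r2 = 0.01, clump_window_bp = 1e7)
  expect_setequal(out$variant_id, c("v1", "v3"))

  # all unlinked: identity
  eye <- diag(1, 3)
  dimnames(eye) <- list(v$variant_id, v$variant_id)
  out2 <- ld_clump(v, eye)
  expect_equal(nrow(out2), 3)

  # asymmetric matrix is rejected
  bad <- ld
  bad["v1", "v2"] <- 0.9
  expect_error(ld_clump(v, bad), class = "pqtlmr_error_input")
})

test_that("clumping satisfies the greedy certificate on random panels", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- 20
      ids <- sprintf("v%02d", 1:n)
      v <- tibble::tibble(
        variant_id = ids, chrom = "1",
        pos = sort(sample.int(5e6, n)), pvalue = runif(n, 1e-12, 1e-4)
      )
      m <- matrix(0, n, n, dimnames = list(ids, ids))
      pairs <- which(upper.tri(m), arr.ind = TRUE)
      r2 <- ifelse(runif(nrow(pairs)) < 0.2, runif(nrow(pairs), 0.1, 1), 0)
      m[pairs] <- r2
      m <- m + t(m)
      diag(m) <- 1
      thr <- 0.05
      win <- 1e7
      kept <- ld_clump(v, m, thr, win)$variant_id
      dropped <- setdiff(ids, kept)
      rank <- function(id) {
        i <- match(id, v$variant_id)
        c(v$pvalue[i], v$variant_id[i])
      }
      # retained set is pairwise below threshold (within the window)
      for (a in kept) {
        for (b in setdiff(kept, a)) {
          pa <- v$pos[match(a, ids)]
          pb <- v$pos[match(b, ids)]
          if (abs(pa - pb) <= win) expect_lte(m[a, b], thr)
        }
      }
      # every dropped variant is linked to a retained, better-ranked one
      for (d in dropped) {
        pd <- v$pos[match(d, ids)]
        linked_better <- any(vapply(kept, function(k) {
          pk <- v$pos[match(k, ids)]
          m[d, k] > thr && abs(pd - pk) <= win &&
            (v$pvalue[match(k, ids)] < v$pvalue[match(d, ids)] ||
              (v$pvalue[match(k, ids)] == v$pvalue[match(d, ids)] && k < d))
        }, logical(1)))
        expect_true(linked_better)
      }
    }
  })
})

test_that("instrument selection composes its four filters", {
  tg <- target_fixture()
  v <- make_sumstats(sprintf("v%d", 1:5),
    beta = rep(0.2, 5), se = 0.02,
    chrom = "1", pos = tg$gene_start + seq(0, 4000L, 1000L)
  )
  sel <- select_instruments(v, tg, ld = NULL, mode = "cis")
  expect_equal(nrow(sel), 5)
  expect_equal(
    unname(attr(sel, "stage_counts")),
    c(5, 5, 5, 5, 5)
  )
  expect_equal(nrow(select_instruments(v, tg, mode = "trans")), 0)
})

test_that("selection equals a hand-composed oracle on a 200-variant panel", {
  tg <- target_fixture()
  cfg <- instrument_config()
  withr::with_seed(77, {
    n <- 200
    ids <- sprintf("v%03d", 1:n)
    chrom <- sample(c("1", "2"), n, replace = TRUE, prob = c(0.7, 0.3))
    pos <- ifelse(
      chrom == "1",
      tg$gene_start + sample.int(4e6, n) - 2e6,
      sample.int(1e8, n)
    )
    beta <- rnorm(n, 0, 0.15)
    se <- runif(n, 0.01, 0.05)
    v <- make_sumstats(ids, beta = beta, se = se, chrom = chrom, pos = as.integer(pmax(pos, 1)))
    # seeded LD blocks among chromosome-1 variants
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    block_members <- split(ids, sample(rep(1:40, length.out = n)))
    for (bl in block_members) {
      if (length(bl) > 1) {
        for (a in bl) for (b in setdiff(bl, a)) m[a, b] <- 0.5
      }
    }
    m <- pmax(m, t(m))
    diag(m) <- 1

    got <- select_instruments(v, tg, ld = m, cfg = cfg, mode = "cis")

    # independent composition of the four filters
    s1 <- v[v$pvalue < cfg$p_threshold, ]
    s2 <- s1[classify_cis_trans(s1, tg, cfg$cis_window_bp) == "cis", ]
    s3 <- ld_clump(s2, m, cfg$clump_r2, cfg$clump_window_bp)
    s4 <- s3[(s3$beta / s3$se)^2 >= cfg$min_f, ]
    expect_setequal(got$variant_id, s4$variant_id)
    # output ordered by genomic coordinate
    expect_equal(got$pos, sort(got$pos))
  })
})

test_that("tightening the significance threshold never adds instruments", {
  tg <- target_fixture()
  withr::with_seed(13, {
    v <- make_sumstats(sprintf("v%03d", 1:80),
      beta = rnorm(80, 0, 0.1), se = runif(80, 0.01, 0.04),
      chrom = "1", pos = tg$gene_start + sample.int(2e6, 80) - 1e6
    )
    thresholds <- c(1e-4, 1e-6, 5e-8, 1e-10)
    prev <- NULL
    for (pt in thresholds) {
      cfg <- instrument_config(p_threshold = pt)
      cur <- select_instruments(v, tg, cfg = cfg, mode = "cis")$variant_id
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  })
})

test_that("exclusion lists mark instruments and drive recomputed estimates", {
  h <- gen_ratio_data(3, 0.4, seed = 9)

  same <- apply_snp_exclusions(h, character(0), "excluded_confounder")
  expect_equal(same$drop_reason, h$drop_reason)
  expect_equal(nrow(attr(same, "removal_log")), 0)

  all_out <- apply_snp_exclusions(h, h$variant_id, "excluded_phewas")
  expect_equal(nrow(pqtlmr:::usable_instruments(all_out)), 0)
  expect_setequal(attr(all_out, "removal_log")$variant_id, h$variant_id)

  # one-of-three excluded: the pipeline records both pre- and
  # post-exclusion estimates, and they differ
  ann <- tibble::tibble(
    protein_id = "P1", gene_symbol = "G1", chrom = "1",
    gene_start = 1L, gene_end = 10L, cohort_id = ""
  )
  rep1 <- run_protein_mr(
    make_sumstats(h$variant_id, beta = h$beta_exposure, se = h$se_exposure),
    make_sumstats(h$variant_id, beta = h$beta_outcome, se = h$se_outcome),
    target_for(map_protein_targets(ann), "P1"),
    cfg = mr_config(n_boot = 50, n_sim = 120, seed = 2),
    mode = "cis", phenotype = "PH", cohort_id = "c1",
    exclusions = list(excluded_confounder = h$variant_id[1])
  )
  rerun <- rep1$exclusion_reruns$excluded_confounder
  expect_s3_class(rerun, "mr_result")
  expect_equal(rerun$n_snps, 2)
  expect_false(isTRUE(all.equal(rerun$theta, rep1$primary$theta)))
  expect_equal(attr(rerun, "removed"), h$variant_id[1])
})
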