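# Gene-set over-representation testing (GMT in, hypergeometric/Fisher p,
# BH across sets).

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member gene symbols (one
#' line per set). Symbols are uppercased on load; lines without members
#' are rejected with a reason; duplicate set names are suffixed and
#' warned.
#'
#' @param path GMT file path.
#' @return A list of class `gene_set_collection`: `sets` (named list of
#'   symbol vectors), `description` (named character), and a `rejects`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort_input(paste0("empty GMT file: ", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rejects <- tibble(line = integer(0), reason = character(0))
  sets <- list()
  descriptions <- character(0)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    members <- unique(toupper(p[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(p) < 3 || length(members) == 0) {
      rejects <- bind_rows(rejects, tibble(line = i, reason = "no_members"))
      next
    }
    nm <- p[1]
    if (nm %in% names(sets)) {
      k <- sum(startsWith(names(sets), paste0(nm, ".")))
      nm2 <- paste0(nm, ".", k + 2)
      warn(paste0("duplicate gene-set name '", nm, "' renamed to '", nm2, "'"))
      nm <- nm2
    }
    sets[[nm]] <- members
    descriptions[nm] <- p[2]
  }
  if (length(sets) == 0) abort_input(paste0("no usable gene sets in ", path))
  if (nrow(rejects) > 0) {
    warn(paste0(path, ": rejected ", nrow(rejects), " GMT line(s) without members"))
  }
  structure(
    list(sets = sets, description = descriptions),
    rejects = rejects, class = "gene_set_collection"
  )
}

#' Write a gene-set collection to GMT
#'
#' @param collection A `gene_set_collection` (see [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- imap(collection$sets, function(members, nm) {
    paste(c(nm, collection$description[[nm]] %||% "", members), collapse = "\t")
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "<gene_set_collection> %d sets (sizes %d-%d)\n",
    length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))
  ))
  invisible(x)
}

#' Hypergeometric over-representation test against a gene-set collection
#'
#' For each set, tests whether the query list is enriched for set members
#' relative to the background universe: with `N` background genes, `K` set
#' members in the background, query size `n` and overlap `k`, the p-value
#' is the hypergeometric upper tail `P[X >= k]` (equivalently, one-sided
#' Fisher's exact test on the 2x2 table). BH correction is applied across
#' sets; sets with zero background overlap are skipped with a note. The
#' background should be the selection universe — for MR results, all
#' proteins tested, not the genome.
#'
#' @param query Character vector of gene symbols (case-insensitive); must
#'   be a subset of `background`.
#' @param background Character vector of background gene symbols.
#' @param sets A `gene_set_collection`.
#' @return A tibble (one row per tested set): `set_name`, `k`, `K`, `n`,
#'   `N`, `odds_ratio`, `pvalue`, `qvalue`; skipped sets are listed in the
#'   `skipped` attribute.
#' @export
hypergeometric_enrichment <- function(query, background, sets) {
  query <- unique(toupper(query))
  background <- unique(toupper(background))
  missing_genes <- setdiff(query, background)
  if (length(missing_genes) > 0) {
    abort_usage(paste0(
      "query gene(s) absent from background: ",
      paste(head(missing_genes, 5), collapse = ", "),
      if (length(missing_genes) > 5) ", ..." else ""
    ))
  }
  N <- length(background)
  n <- length(query)
  rows <- list()
  skipped <- character(0)
  for (nm in names(sets$sets)) {
    members <- intersect(sets$sets[[nm]], background)
    K <- length(members)
    if (K == 0) {
      skipped <- c(skipped, nm)
      next
    }
    k <- length(intersect(query, members))
    pvalue <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or_num <- k * (N - K - n + k)
    or_den <- (K - k) * (n - k)
    rows[[nm]] <- tibble(
      set_name = nm, k = k, K = K, n = n, N = N,
      odds_ratio = if (or_den == 0) Inf else or_num / or_den,
      pvalue = min(pvalue, 1)
    )
  }
  if (length(rows) == 0) {
    abort_input("no gene set overlaps the background universe")
  }
  out <- list_rbind(rows)
  out$qvalue <- p.adjust(out$pvalue, method = "BH")
  out <- arrange(out, .data$pvalue, .data$set_name)
  if (length(skipped) > 0) {
    inform(paste0(
      length(skipped), " set(s) without background overlap skipped: ",
      paste(head(skipped, 5), collapse = ", ")
    ))
  }
  attr(out, "skipped") <- skipped
  out
}
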