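# Internal helpers shared across modules.

abort_config <- function(msg, ...) abort(msg, class = "pqtlmr_error_config", ...)
abort_input <- function(msg, ...) abort(msg, class = "pqtlmr_error_input", ...)
abort_usage <- function(msg, ...) abort(msg, class = "pqtlmr_error_usage", ...)
abort_insufficient <- function(msg, ...) abort(msg, class = "pqtlmr_error_insufficient", ...)
abort_convergence <- function(msg, ...) abort(msg, class = "pqtlmr_error_convergence", ...)

#' Derive a reproducible child seed from a master seed and a label
#'
#' Run-level reproducibility uses one master seed; every stochastic step
#' (per-protein bootstrap, MR-PRESSO simulations, ...) draws its own seed
#' deterministically from the master seed and a string key, so adding or
#' reordering proteins never perturbs another protein's random draws.
#'
#' @param master Integer master seed.
#' @param key Character label (e.g. a protein id).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "PROT_007")
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(key))
  m <- 2147483647 # 2^31 - 1, keeps products below 2^53 so doubles stay exact
  h <- abs(master) %% m
  codes <- utf8ToInt(paste(key, collapse = "|"))
  for (cc in codes) h <- (h * 69069 + cc) %% m
  as.integer(max(1, h %% (m - 1)))
}

# Two-sided normal p-value from an estimate and its SE, floored at 1e-300
# (a normal-range double that survives text round-trips) so extreme
# z-scores never underflow to 0.
z_pvalue <- function(theta, se) {
  p <- ifelse(se > 0, 2 * pnorm(-abs(theta / se)), as.numeric(theta == 0))
  pmax(p, 1e-300)
}

`%||%` <- rlang::`%||%`

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) unname(DNA_COMPLEMENT[x])

is_palindromic <- function(a1, a2) complement_allele(a1) == a2
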