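# The mr_result container shared by every causal estimator.

new_mr_result <- function(method, theta, se, n_snps, pvalue = NULL,
                          ci_low = NULL, ci_high = NULL, extras = list()) {
  z <- qnorm(0.975)
  if (is.null(pvalue)) pvalue <- z_pvalue(theta, se)
  if (is.null(ci_low)) ci_low <- theta - z * se
  if (is.null(ci_high)) ci_high <- theta + z * se
  structure(
    list(
      method = method, theta = theta, se = se,
      ci_low = ci_low, ci_high = ci_high,
      pvalue = min(max(pvalue, 1e-300), 1),
      n_snps = as.integer(n_snps), extras = extras
    ),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf(
    "<mr_result: %s>\n  theta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g]\n  p = %.3g, n_snps = %d\n",
    x$method, x$theta, x$se, x$ci_low, x$ci_high, x$pvalue, x$n_snps
  ))
  invisible(x)
}

#' Tidy an MR estimate
#'
#' One row per fitted estimator: method, causal-effect estimate (`theta`,
#' outcome units per unit exposure), its SE, 95% CI, p-value and the number
#' of instruments used.
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  tibble(
    method = x$method, theta = x$theta, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high,
    pvalue = x$pvalue, n_snps = x$n_snps
  )
}

#' One-row model summary including method-specific diagnostics
#'
#' Adds the estimator's auxiliary statistics (heterogeneity Q and its p for
#' IVW, Egger intercept and its p, MR-PRESSO global/distortion p, cML
#' selected invalid count, ...) to the [tidy.mr_result()] columns.
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  base <- tidy(x)
  ex <- x$extras
  scalars <- ex[map_lgl(ex, ~ is.atomic(.x) && length(.x) == 1 && !is.character(.x))]
  if (length(scalars) > 0) {
    base <- dplyr::bind_cols(base, as_tibble(scalars))
  }
  base
}

#' Forest plot of per-instrument ratio estimates with the overall estimate
#'
#' @param object An `mr_result` that retains its instrument data (all
#'   estimators store the harmonized instruments in `extras$data`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_result
#' @export
autoplot.mr_result <- function(object, ...) {
  d <- object$extras$data
  if (is.null(d)) {
    abort_usage("this mr_result carries no instrument data to plot")
  }
  rs <- ratio_stats(d, weights = "second")
  z <- qnorm(0.975)
  per <- tibble(
    label = d$variant_id, theta = rs$theta,
    lo = rs$theta - z * sqrt(rs$var), hi = rs$theta + z * sqrt(rs$var)
  )
  overall <- tibble(
    label = paste0("Overall (", object$method, ")"),
    theta = object$theta, lo = object$ci_low, hi = object$ci_high
  )
  dat <- bind_rows(per, overall)
  dat$label <- factor(dat$label, levels = rev(dat$label))
  dat$what <- c(rep("instrument", nrow(per)), "overall")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$theta, y = .data$label, colour = .data$what)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
      show.legend = FALSE
    ) +
    ggplot2::scale_colour_manual(values = c(instrument = "grey30", overall = "#b2182b")) +
    ggplot2::labs(
      x = "Causal effect (outcome units per unit exposure)", y = NULL,
      title = sprintf("Per-instrument Wald ratios and %s estimate", object$method)
    ) +
    ggplot2::theme_minimal()
}
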