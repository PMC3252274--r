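#' Plot the ARD variance spectrum of a fitted model
#'
#' Bar plot of per-factor variances relative to the total, with the ARD
#' threshold marked: factors above the line are the effective confounders.
#'
#' @param object A `panama_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.panama_model <- function(object, ...) {
  td <- tidy(object) |> dplyr::filter(.data$type == "factor")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$share,
                                   fill = .data$effective)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$config$ard_threshold,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70"),
                               name = "effective") +
    ggplot2::labs(x = NULL, y = "share of total variance",
                  title = "Hidden-factor variance spectrum (ARD)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a ROC curve
#'
#' @param object A `panama_roc` from [roc_against_truth()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.panama_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Q-Q plot of association p-values
#'
#' Observed versus expected -log10 p under the uniform null, the standard
#' diagnostic for inflation or deflation of the test statistics; the
#' genomic-control inflation factor is shown in the title.
#'
#' @param table A `panama_assoc` table.
#' @param max_points Subsample cap for plotting very large tables.
#' @return A ggplot.
#' @export
plot_qq <- function(table, max_points = 20000L) {
  p <- sort(table$p)
  n <- length(p)
  expected <- (seq_len(n) - 0.5) / n
  if (n > max_points) {
    keep <- unique(round(seq(1, n, length.out = max_points)))
    p <- p[keep]; expected <- expected[keep]
  }
  df <- tibble::tibble(expected = -log10(expected), observed = -log10(p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = expression(expected ~ -log[10](p)),
      y = expression(observed ~ -log[10](p)),
      title = sprintf("Q-Q plot (lambda = %.3f)", inflation_factor(table$lrt))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a genome-wide hotspot profile
#'
#' Number of significant trans associations per SNP along the genome,
#' faceted by chromosome.
#'
#' @param profile Output of [hotspot_profile()].
#' @return A ggplot.
#' @export
plot_hotspot_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$pos / 1e3, y = .data$n_trans)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos / 1e3, yend = 0)) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (kb)", y = "significant trans genes",
                  title = "Trans-regulation hotspot profile") +
    ggplot2::theme_minimal()
}

#' Plot cis/trans counts against the FDR cutoff
#'
#' @param counts Output of [counts_vs_fdr()], optionally with a `method`
#'   column to compare several scans.
#' @return A ggplot.
#' @export
plot_counts_vs_fdr <- function(counts) {
  long <- tidyr::pivot_longer(counts, c("cis", "trans"),
                              names_to = "class", values_to = "n")
  aes <- if ("method" %in% names(counts)) {
    ggplot2::aes(x = .data$cutoff, y = .data$n, colour = .data$method)
  } else {
    ggplot2::aes(x = .data$cutoff, y = .data$n)
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$class), scales = "free_y") +
    ggplot2::labs(x = "FDR cutoff", y = "associations (linkage-aware count)") +
    ggplot2::theme_minimal()
}
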