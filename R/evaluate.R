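#' Baseline correction covariances
#'
#' Internal reconstructions of the main correction-method families used as
#' comparison points: `linear` (no correction; zero matrix), `pca_factors`
#' (covariance of the top-k expression principal components, scaled by their
#' variances), `sample_cov` (the whole-expression sample covariance
#' `Y Y' / G`, the covariance-based family), and `ideal` (the exact covariance
#' of the simulated confounder component; requires ground truth). These are
#' deliberately not reimplementations of any published method.
#'
#' @param dataset An `eqtl_dataset` (centered automatically).
#' @param kind One of `"linear"`, `"pca_factors"`, `"sample_cov"`, `"ideal"`.
#' @param k Number of components for `pca_factors` (default 10).
#' @param truth A `sim_truth`, required for `"ideal"`.
#' @return A `covariance_structure`.
#' @export
baseline_covariance <- function(dataset,
                                kind = c("linear", "pca_factors", "sample_cov", "ideal"),
                                k = 10L, truth = NULL) {
  kind <- match.arg(kind)
  if (!dataset$centered) dataset <- center_expression(dataset)
  Y <- active_expression(dataset)
  N <- nrow(Y); G <- ncol(Y)
  S <- tcrossprod(Y) / G
  K <- switch(kind,
    linear = matrix(0, N, N),
    pca_factors = {
      k <- min(k, N - 1L)
      e <- eigen(S, symmetric = TRUE)
      e$vectors[, seq_len(k), drop = FALSE] %*%
        (e$values[seq_len(k)] * t(e$vectors[, seq_len(k), drop = FALSE]))
    },
    sample_cov = S,
    ideal = {
      if (is.null(truth)) stop("'ideal' baseline requires simulation truth")
      truth$confounder_covariance
    }
  )
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(Y), rownames(Y))
  structure(
    list(matrix = K, included_terms = kind, noise_variance = 1),
    class = "covariance_structure"
  )
}

# Logical vector: is each (gene, SNP) row of `table` consistent with a causal
# pair, i.e. is the SNP within `match_window_bp` of a causal SNP for that gene
# on the same chromosome? The window absorbs linkage: a call on a SNP tightly
# linked to the causal one still counts as a recovery.
truth_match <- function(table, truth, match_window_bp = 50000L) {
  snp_pos <- dplyr::distinct(table, .data$snp_id, .data$chrom, .data$pos)
  causal <- truth$effects |>
    dplyr::left_join(snp_pos, by = "snp_id") |>
    dplyr::select("gene_id", causal_chrom = "chrom", causal_pos = "pos")
  hits <- table |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::inner_join(causal, by = "gene_id", relationship = "many-to-many") |>
    dplyr::filter(.data$chrom == .data$causal_chrom,
                  abs(.data$pos - .data$causal_pos) <= match_window_bp) |>
    dplyr::distinct(.data$.row)
  out <- rep(FALSE, nrow(table))
  out[hits$.row] <- TRUE
  out
}

#' ROC curve and AUC against simulated ground truth
#'
#' Ranks all tested (gene, SNP) pairs by p-value and sweeps the threshold:
#' a pair counts as a true recovery when the SNP lies within
#' `match_window_bp` of a causal SNP for that gene on the same chromosome
#' (the linkage-tolerant matching rule). Tied p-values move together. The
#' AUC is the trapezoidal area, equivalent to the Mann-Whitney statistic
#' with ties given half credit.
#'
#' @param table A `panama_assoc` table.
#' @param truth A `sim_truth`.
#' @param match_window_bp Linkage tolerance for truth matching.
#' @return A list of class `panama_roc` with `roc` (tibble of FPR/TPR) and
#'   `auc`.
#' @export
roc_against_truth <- function(table, truth, match_window_bp = 50000L) {
  is_true <- truth_match(table, truth, match_window_bp)
  n_t <- sum(is_true); n_f <- sum(!is_true)
  if (n_t == 0 || n_f == 0) {
    stop("ROC undefined: need both true and false pairs under the matching rule")
  }
  ord <- order(table$p)
  p_sorted <- table$p[ord]
  t_sorted <- is_true[ord]
  grp_last <- which(!duplicated(p_sorted, fromLast = TRUE))  # last index of each tie group
  tpr <- cumsum(t_sorted)[grp_last] / n_t
  fpr <- cumsum(!t_sorted)[grp_last] / n_f
  roc <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  structure(list(roc = roc, auc = auc, n_true = n_t, n_false = n_f),
            class = "panama_roc")
}

#' @export
print.panama_roc <- function(x, ...) {
  cat(sprintf("<panama_roc> AUC %.4f (%d true, %d false pairs)\n",
              x$auc, x$n_true, x$n_false))
  invisible(x)
}

#' Estimated versus empirical FDR
#'
#' At each q-value cutoff, compares the estimated FDR (the cutoff itself,
#' i.e. the level at which BH was controlled) with the empirical FDR, the
#' fraction of calls at that cutoff that do not match the ground truth under
#' the linkage-tolerant matching rule. Cutoffs with zero calls are omitted
#' and recorded in the `omitted` attribute.
#'
#' @param table A `panama_assoc` table with q-values.
#' @param truth A `sim_truth`.
#' @param cutoffs FDR cutoffs to evaluate.
#' @param match_window_bp Linkage tolerance for truth matching.
#' @return A tibble with `cutoff`, `estimated_fdr`, `empirical_fdr`,
#'   `n_calls`.
#' @export
fdr_calibration <- function(table, truth, cutoffs = c(0.01, 0.05, 0.1, 0.2),
                            match_window_bp = 50000L) {
  is_true <- truth_match(table, truth, match_window_bp)
  rows <- lapply(cutoffs, function(cut) {
    called <- table$q <= cut
    n <- sum(called)
    if (n == 0) return(NULL)
    tibble::tibble(cutoff = cut, estimated_fdr = cut,
                   empirical_fdr = mean(!is_true[called]), n_calls = n)
  })
  omitted <- cutoffs[vapply(rows, is.null, logical(1))]
  out <- dplyr::bind_rows(rows)
  attr(out, "omitted") <- omitted
  out
}

#' Per-SNP trans-regulation profile
#'
#' For each tested SNP, the number of genes with a significant trans
#' association at the given FDR cutoff - the genome-wide hotspot profile.
#'
#' @param table A `panama_assoc` table.
#' @param fdr_cutoff Significance cutoff on q.
#' @return A tibble with `snp_id`, `chrom`, `pos`, `n_trans`, covering every
#'   tested SNP (zeros included).
#' @export
hotspot_profile <- function(table, fdr_cutoff = 0.05) {
  table |>
    dplyr::group_by(.data$snp_id, .data$chrom, .data$pos) |>
    dplyr::summarise(
      n_trans = sum(.data$q <= fdr_cutoff & .data$label == "trans"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Consistency of two hotspot rankings
#'
#' Orders the SNPs of each profile by the extent of trans regulation and
#' reports, for each k in `top_k_grid`, the fraction of the top-k SNPs shared
#' by both rankings. Ties are broken by genome order, deterministically.
#'
#' @param profile_a,profile_b Hotspot profiles over the same SNP set
#'   (output of [hotspot_profile()]).
#' @param top_k_grid Values of k to evaluate.
#' @return A tibble with `k` and `overlap`.
#' @export
ranking_consistency <- function(profile_a, profile_b,
                                top_k_grid = c(5, 10, 20, 50)) {
  if (!setequal(profile_a$snp_id, profile_b$snp_id)) {
    stop("profiles must cover the same SNP set")
  }
  rank_ids <- function(pr) {
    pr <- dplyr::arrange(pr, dplyr::desc(.data$n_trans), .data$chrom, .data$pos)
    pr$snp_id
  }
  a <- rank_ids(profile_a)
  b <- rank_ids(profile_b)
  top_k_grid <- pmin(as.integer(top_k_grid), length(a))
  tibble::tibble(
    k = top_k_grid,
    overlap = vapply(top_k_grid, function(k) {
      length(intersect(a[seq_len(k)], b[seq_len(k)])) / k
    }, numeric(1))
  )
}

#' Counts of associations as a function of the FDR cutoff
#'
#' Applies the linkage-aware counting rules of [count_associations()] over a
#' grid of cutoffs, giving the cis/trans counts-versus-FDR curves.
#'
#' @param table A `panama_assoc` table.
#' @param cutoffs FDR cutoffs.
#' @return A tibble with `cutoff`, `cis`, `trans`.
#' @export
counts_vs_fdr <- function(table, cutoffs = c(0.01, 0.05, 0.1, 0.2)) {
  dplyr::bind_rows(lapply(cutoffs, function(cut) {
    ct <- count_associations(table, cut)
    tibble::tibble(cutoff = cut, cis = ct$cis_count, trans = ct$trans_count)
  }))
}

#' Bundle the full evaluation of one or two scans
#'
#' Computes every evaluation axis available for the supplied inputs: the
#' inflation factor and counts-versus-FDR curves always; ROC/AUC and FDR
#' calibration when ground truth is supplied; the ranking-consistency curve
#' when a second table is supplied.
#'
#' @param table A `panama_assoc` table.
#' @param truth Optional `sim_truth`.
#' @param table2 Optional second `panama_assoc` table (e.g. an independent
#'   study) for ranking consistency.
#' @param fdr_cutoff Cutoff used for the hotspot profiles.
#' @param cutoffs Cutoff grid for counts and FDR calibration.
#' @param match_window_bp Linkage tolerance for truth matching.
#' @return A list of class `eval_metrics`.
#' @export
evaluate_scan <- function(table, truth = NULL, table2 = NULL,
                          fdr_cutoff = 0.05,
                          cutoffs = c(0.01, 0.05, 0.1, 0.2),
                          match_window_bp = 50000L) {
  out <- list(
    lambda = inflation_factor(table$lrt),
    counts = counts_vs_fdr(table, cutoffs),
    hotspot_profile = hotspot_profile(table, fdr_cutoff)
  )
  if (!is.null(truth)) {
    roc <- roc_against_truth(table, truth, match_window_bp)
    out$roc <- roc$roc
    out$auc <- roc$auc
    out$fdr_calibration <- fdr_calibration(table, truth, cutoffs, match_window_bp)
  }
  if (!is.null(table2)) {
    out$ranking_consistency <- ranking_consistency(
      out$hotspot_profile, hotspot_profile(table2, fdr_cutoff)
    )
  }
  structure(out, class = "eval_metrics")
}
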