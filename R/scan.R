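#' Scan configuration
#'
#' @param delta_grid Candidate values of the covariance/noise weight ratio
#'   delta = s2_noise / s2_K searched for every test (log-spaced), locally
#'   refined by golden-section search around the best grid point.
#' @param cis_window_bp A SNP within this distance of a gene's ORF (same
#'   chromosome) is classified cis; everything else is trans.
#' @param min_snp_variance SNPs with genotype variance below this are skipped.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(delta_grid = 10^seq(-5, 5, length.out = 100),
                        cis_window_bp = 10000L,
                        min_snp_variance = 1e-8) {
  stopifnot(all(diff(delta_grid) > 0), all(delta_grid > 0), cis_window_bp >= 0)
  structure(
    list(delta_grid = delta_grid,
         cis_window_bp = as.integer(cis_window_bp),
         min_snp_variance = min_snp_variance),
    class = "scan_config"
  )
}

#' Eigendecompose a correction covariance for scanning
#'
#' Factorising `K = U diag(lambda) U'` once lets every likelihood evaluation
#' in the scan run in O(N) after rotating the phenotype and design into the
#' eigenbasis, which is what makes per-test refitting of the variance ratio
#' affordable genome-wide.
#'
#' @param covariance A `covariance_structure` or a bare symmetric PSD matrix.
#' @return A list with orthonormal basis `U` and eigenvalues `values`
#'   (clipped at zero; an eigenvalue below -1e-8 is an error).
#' @export
rotate <- function(covariance) {
  K <- if (inherits(covariance, "covariance_structure")) covariance$matrix else covariance
  if (max(abs(K - t(K))) > 1e-8) stop("covariance is not symmetric within 1e-8")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    stop(sprintf("covariance is not PSD (min eigenvalue %.3g)", min(e$values)))
  }
  list(U = e$vectors, values = pmax(e$values, 0))
}

#' Profiled log-likelihood at a fixed variance ratio
#'
#' For the model `y ~ N(F beta, s2 (K + delta I))` with inputs already rotated
#' into the eigenbasis of K, returns the GLS estimate of `beta`, the profiled
#' maximum-likelihood `s2`, and the profiled log-likelihood, all in closed
#' form given `delta`.
#'
#' @param y_rot Rotated phenotype (length N).
#' @param fixed_rot Rotated fixed-effect design matrix (N x p), including an
#'   intercept column.
#' @param eigvals Eigenvalues of K (length N, non-negative).
#' @param delta Positive variance ratio (noise / covariance).
#' @return A list with `loglik`, `beta`, `sigma2`.
#' @export
profiled_loglik <- function(y_rot, fixed_rot, eigvals, delta) {
  N <- length(y_rot)
  fixed_rot <- as.matrix(fixed_rot)
  w <- 1 / (eigvals + delta)
  A <- crossprod(fixed_rot, w * fixed_rot)
  if (rcond(A) < 1e-12) stop("collinear fixed effects")
  b <- crossprod(fixed_rot, w * y_rot)
  beta <- solve(A, b)
  rss <- max(sum(w * y_rot^2) - sum(beta * b), 1e-300)
  sigma2 <- rss / N
  ll <- -N / 2 * (log(2 * pi) + 1 + log(sigma2)) - 0.5 * sum(log(eigvals + delta))
  list(loglik = as.numeric(ll), beta = as.numeric(beta), sigma2 = sigma2)
}

# Grid search + golden-section refinement of delta, maximizing fn(delta).
# Mirrors the compiled scan path so the two stay numerically interchangeable.
optimize_delta <- function(fn, grid, golden_iters = 60L) {
  vals <- vapply(grid, fn, numeric(1))
  i <- which.max(vals)
  lo <- log(grid[max(i - 1L, 1L)])
  hi <- log(grid[min(i + 1L, length(grid))])
  if (hi - lo < 1e-12) return(list(delta = grid[i], value = vals[i]))
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- fn(exp(c1)); fd <- fn(exp(d1))
  for (iter in seq_len(golden_iters)) {
    if (fc > fd) {
      b <- d1; d1 <- c1; fd <- fc
      c1 <- b - gr * (b - a); fc <- fn(exp(c1))
    } else {
      a <- c1; c1 <- d1; fc <- fd
      d1 <- a + gr * (b - a); fd <- fn(exp(d1))
    }
  }
  best <- if (fc > fd) c1 else d1
  fbest <- max(fc, fd)
  if (vals[i] >= fbest) list(delta = grid[i], value = vals[i])
  else list(delta = exp(best), value = fbest)
}

#' Single-pair likelihood ratio test (reference path)
#'
#' Readable R implementation of one association test: the variance ratio
#' delta is optimised (grid + golden-section) separately for the null
#' (intercept-only) and alternative (intercept + SNP) models, and the
#' alternative is additionally evaluated at the null's optimum so the LRT is
#' non-negative by construction. The genome-wide [panama_scan()] uses the
#' compiled equivalent.
#'
#' @param y Phenotype vector (one gene's centered expression).
#' @param snp Genotype vector.
#' @param rotation Output of [rotate()].
#' @param config A [scan_config()].
#' @return A one-row tibble with `beta`, `lrt`, `p`, `delta_null`, `delta_alt`.
#' @export
lrt_single <- function(y, snp, rotation, config = scan_config()) {
  if (stats::var(snp) < config$min_snp_variance) {
    stop("constant SNP: variance below min_snp_variance; excluded from testing")
  }
  N <- length(y)
  U <- rotation$U
  y_rot <- crossprod(U, y)[, 1]
  one_rot <- crossprod(U, rep(1, N))[, 1]
  snp_rot <- crossprod(U, as.numeric(snp))[, 1]
  F0 <- matrix(one_rot, ncol = 1)
  F1 <- cbind(one_rot, snp_rot)

  null_fit <- optimize_delta(
    function(d) profiled_loglik(y_rot, F0, rotation$values, d)$loglik,
    config$delta_grid
  )
  alt_fit <- optimize_delta(
    function(d) profiled_loglik(y_rot, F1, rotation$values, d)$loglik,
    config$delta_grid
  )
  # warm start: the alternative can always do at least as well as the null
  at_null_delta <- profiled_loglik(y_rot, F1, rotation$values, null_fit$delta)$loglik
  if (at_null_delta > alt_fit$value) {
    alt_fit <- list(delta = null_fit$delta, value = at_null_delta)
  }
  beta <- profiled_loglik(y_rot, F1, rotation$values, alt_fit$delta)$beta[2]
  lrt <- max(2 * (alt_fit$value - null_fit$value), 0)
  tibble::tibble(
    beta = beta, lrt = lrt,
    p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    delta_null = null_fit$delta, delta_alt = alt_fit$delta
  )
}

#' Genome-wide association scan under a fixed correction covariance
#'
#' Tests every gene against every non-constant SNP by likelihood ratio in the
#' mixed model `y ~ N(mu + g beta, s2 (K + delta I))`, with the correction
#' covariance `K` fixed for all tests and the weight `delta` refit per test in
#' both the null and alternative model. P-values come from the chi-squared
#' distribution with 1 df; q-values are Benjamini-Hochberg over the full
#' table; each pair is labelled cis (SNP within `cis_window_bp` of the ORF on
#' the same chromosome) or trans.
#'
#' @param dataset An `eqtl_dataset` (centered automatically if needed).
#' @param covariance A `covariance_structure` from [build_covariance()] or
#'   [baseline_covariance()].
#' @param config A [scan_config()].
#' @return A tibble of class `panama_assoc` with columns `gene_id`, `snp_id`,
#'   `chrom`, `pos`, `beta`, `lrt`, `p`, `q`, `label`. Attributes: `lambda`
#'   (genomic-control inflation factor), `terms` (covariance provenance),
#'   `skipped_snps`.
#' @export
panama_scan <- function(dataset, covariance, config = scan_config()) {
  if (!dataset$centered) dataset <- center_expression(dataset)
  Y <- active_expression(dataset)
  N <- nrow(Y)
  gvar <- apply(dataset$geno, 2, stats::var)
  testable <- gvar >= config$min_snp_variance
  skipped <- colnames(dataset$geno)[!testable]
  Gmat <- dataset$geno[, testable, drop = FALSE]
  storage.mode(Gmat) <- "double"
  if (ncol(Gmat) == 0) stop("no testable SNPs (all constant)")

  rot <- rotate(covariance)
  Yrot <- crossprod(rot$U, Y)
  Grot <- crossprod(rot$U, Gmat)
  one_rot <- crossprod(rot$U, rep(1, N))[, 1]

  res <- scan_cpp(Yrot, Grot, one_rot, rot$values, config$delta_grid, 60L)

  gene_ids <- colnames(Y)
  snp_ids <- colnames(Gmat)
  nG <- length(gene_ids); nP <- length(snp_ids)
  tab <- tibble::tibble(
    gene_id = rep(gene_ids, each = nP),
    snp_id = rep(snp_ids, times = nG),
    beta = as.vector(t(res$beta)),
    lrt = as.vector(t(res$lrt))
  )
  tab$p <- stats::pchisq(tab$lrt, df = 1, lower.tail = FALSE)
  tab <- tab |>
    dplyr::left_join(dataset$snps, by = "snp_id") |>
    dplyr::left_join(dataset$genes, by = "gene_id", suffix = c("", "_gene"))
  tab$label <- classify_cis_trans(
    tab$chrom, tab$pos, tab$chrom_gene, tab$start, tab$end,
    cis_window_bp = config$cis_window_bp
  )
  tab$q <- bh_fdr(tab$p)
  tab <- tab |>
    dplyr::select("gene_id", "snp_id", "chrom", "pos", "beta", "lrt", "p", "q", "label")
  structure(
    tab,
    class = c("panama_assoc", class(tab)),
    lambda = inflation_factor(tab$lrt),
    terms = if (inherits(covariance, "covariance_structure")) covariance$included_terms else NULL,
    skipped_snps = skipped,
    n_samples = N
  )
}

#' Distance from a SNP to a gene's ORF, and cis/trans classification
#'
#' Coordinates are 0-based with half-open gene intervals; the distance is the
#' minimal bp distance from the SNP position to the interval (0 inside).
#' A pair is cis when SNP and ORF are on the same chromosome within
#' `cis_window_bp`, trans otherwise.
#'
#' @param snp_chrom,snp_pos SNP coordinates (vectorised).
#' @param gene_chrom,gene_start,gene_end Gene ORF coordinates (vectorised).
#' @param cis_window_bp The cis window (default 10 kb).
#' @return For `snp_gene_distance`, integer distances (NA across chromosomes);
#'   for `classify_cis_trans`, a character vector of `"cis"` / `"trans"`.
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, gene_chrom, gene_start,
                               gene_end, cis_window_bp = 10000L) {
  if (any(is.na(snp_chrom) | is.na(gene_chrom))) stop("missing annotation")
  d <- snp_gene_distance(snp_chrom, snp_pos, gene_chrom, gene_start, gene_end)
  ifelse(!is.na(d) & d <= cis_window_bp, "cis", "trans")
}

#' @rdname classify_cis_trans
#' @export
snp_gene_distance <- function(snp_chrom, snp_pos, gene_chrom, gene_start, gene_end) {
  d <- pmax(gene_start - snp_pos, snp_pos - (gene_end - 1L), 0L)
  d[snp_chrom != gene_chrom] <- NA_integer_
  d
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values controlling the false discovery rate; a thin wrapper over
#' [stats::p.adjust()] kept as the package's single multiple-testing surface.
#'
#' @param pvalues Vector of p-values in (0, 1].
#' @return q-values of the same length and order.
#' @export
bh_fdr <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Count associations with linkage-aware rules
#'
#' To avoid counting the same underlying locus many times through linked
#' SNPs, each gene contributes at most one cis association (its best-q
#' significant cis SNP) and at most one trans association per chromosome
#' (the best-q significant trans SNP on that chromosome).
#'
#' @param table A `panama_assoc` table (q-values present).
#' @param fdr_cutoff Significance cutoff on q.
#' @return A list with `cis_count`, `trans_count`, and a `per_gene` tibble.
#' @export
count_associations <- function(table, fdr_cutoff = 0.05) {
  sig <- dplyr::filter(table, .data$q <= fdr_cutoff)
  cis <- sig |>
    dplyr::filter(.data$label == "cis") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_min(.data$q, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  trans <- sig |>
    dplyr::filter(.data$label == "trans") |>
    dplyr::group_by(.data$gene_id, .data$chrom) |>
    dplyr::slice_min(.data$q, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  per_gene <- dplyr::full_join(
    dplyr::count(cis, .data$gene_id, name = "cis"),
    dplyr::count(trans, .data$gene_id, name = "trans"),
    by = "gene_id"
  ) |>
    dplyr::mutate(
      cis = dplyr::coalesce(.data$cis, 0L),
      trans = dplyr::coalesce(.data$trans, 0L)
    )
  list(cis_count = nrow(cis), trans_count = nrow(trans), per_gene = per_gene)
}

#' Genomic-control inflation factor
#'
#' Ratio of the median observed likelihood-ratio statistic to the median of
#' its null chi-squared(1 df) distribution. Values above 1 indicate inflated
#' test statistics, below 1 deflation.
#'
#' @param lrt_values Vector of LRT statistics, or a `panama_assoc` table.
#' @return The scalar inflation factor lambda.
#' @export
inflation_factor <- function(lrt_values) {
  if (inherits(lrt_values, "panama_assoc")) lrt_values <- lrt_values$lrt
  stopifnot(length(lrt_values) > 0)
  stats::median(lrt_values) / stats::qchisq(0.5, df = 1)
}

#' Write / summarise an association table
#'
#' `write_association_table` writes the TSV form; `assoc_summary` computes the
#' counts at standard FDR cutoffs plus the inflation factor.
#'
#' @param table A `panama_assoc` table.
#' @param path Output TSV path.
#' @param cutoffs FDR cutoffs to summarise at.
#' @return The path / a summary list.
#' @export
write_association_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @export
assoc_summary <- function(table, cutoffs = c(0.01, 0.05, 0.1, 0.2)) {
  counts <- lapply(cutoffs, function(cut) {
    ct <- count_associations(table, cut)
    list(fdr = cut, cis = ct$cis_count, trans = ct$trans_count)
  })
  list(lambda = inflation_factor(table$lrt), counts = counts,
       n_tests = nrow(table))
}
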