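#' Assemble and validate an eQTL dataset
#'
#' Bundles a gene expression matrix, a genotype matrix, genomic annotation for
#' genes and SNPs, and an optional known sample-sample covariance (e.g. a
#' kinship matrix) into a single validated container. All components are
#' aligned to the sample order of the expression matrix.
#'
#' @param expr Numeric matrix, samples x genes, with sample IDs as rownames
#'   and gene IDs as colnames. Log-scale expression values are expected.
#' @param geno Integer matrix, samples x SNPs, entries in `{0,1}` (haploid /
#'   cross designs) or `{0,1,2}` (diploid dosage), with sample IDs as rownames
#'   and SNP IDs as colnames.
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos` (0-based bp).
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open ORF interval).
#' @param known_covariance Optional square numeric matrix over samples,
#'   symmetric positive semi-definite (e.g. kinship or replicate structure).
#'
#' @return An object of class `eqtl_dataset`: a list with elements `expr`
#'   (samples x genes), `geno` (samples x SNPs), `snps`, `genes` (tibbles),
#'   `known_covariance`, `centered` flag and bookkeeping of flagged
#'   zero-variance genes/SNPs.
#' @export
eqtl_dataset <- function(expr, geno, snps, genes, known_covariance = NULL) {
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  geno <- as.matrix(geno)
  snps <- tibble::as_tibble(snps)
  genes <- tibble::as_tibble(genes)

  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix must carry sample IDs (rownames) and gene IDs (colnames)")
  }
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    stop("genotype matrix must carry sample IDs (rownames) and SNP IDs (colnames)")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate sample IDs in expression matrix")
  if (anyDuplicated(colnames(expr))) stop("duplicate gene IDs in expression matrix")
  if (anyDuplicated(colnames(geno))) stop("duplicate SNP IDs in genotype matrix")

  if (!all(is.finite(expr))) {
    bad <- which(!is.finite(expr), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-finite expression value at sample '%s', gene '%s'",
      rownames(expr)[bad[1]], colnames(expr)[bad[2]]
    ))
  }

  s_expr <- rownames(expr)
  s_geno <- rownames(geno)
  if (!setequal(s_expr, s_geno)) {
    only_e <- setdiff(s_expr, s_geno)
    only_g <- setdiff(s_geno, s_expr)
    stop(sprintf(
      "sample IDs differ between expression and genotypes; only in expression: [%s]; only in genotypes: [%s]",
      paste(only_e, collapse = ", "), paste(only_g, collapse = ", ")
    ))
  }
  geno <- geno[s_expr, , drop = FALSE]

  vals <- sort(unique(as.vector(geno)))
  if (!all(vals %in% c(0L, 1L, 2L))) {
    stop(sprintf(
      "genotype entries outside allowed alphabet {0,1}/{0,1,2}: found %s",
      paste(utils::head(setdiff(vals, 0:2), 5), collapse = ", ")
    ))
  }
  alphabet <- if (all(vals %in% c(0L, 1L))) c(0L, 1L) else c(0L, 1L, 2L)
  storage.mode(geno) <- "integer"

  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(sprintf("%s annotation missing columns: %s", what, paste(miss, collapse = ", ")))
  }
  req(snps, c("snp_id", "chrom", "pos"), "SNP")
  req(genes, c("gene_id", "chrom", "start", "end"), "gene")
  if (!all(colnames(geno) %in% snps$snp_id)) {
    stop(sprintf(
      "SNPs without annotation: %s",
      paste(utils::head(setdiff(colnames(geno), snps$snp_id), 5), collapse = ", ")
    ))
  }
  if (!all(colnames(expr) %in% genes$gene_id)) {
    stop(sprintf(
      "genes without annotation: %s",
      paste(utils::head(setdiff(colnames(expr), genes$gene_id), 5), collapse = ", ")
    ))
  }
  if (any(genes$start >= genes$end)) stop("gene annotation must satisfy start < end")
  snps <- snps[match(colnames(geno), snps$snp_id), ]
  genes <- genes[match(colnames(expr), genes$gene_id), ]

  if (!is.null(known_covariance)) {
    known_covariance <- as.matrix(known_covariance)
    if (!all(dim(known_covariance) == length(s_expr))) {
      stop("known covariance must be square over the samples")
    }
    if (!is.null(rownames(known_covariance))) {
      if (!setequal(rownames(known_covariance), s_expr)) {
        stop("known covariance sample IDs do not match the expression samples")
      }
      known_covariance <- known_covariance[s_expr, s_expr]
    } else {
      dimnames(known_covariance) <- list(s_expr, s_expr)
    }
    if (max(abs(known_covariance - t(known_covariance))) > 1e-8) {
      stop("known covariance is not symmetric within 1e-8")
    }
    ev <- eigen((known_covariance + t(known_covariance)) / 2,
                symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop(sprintf("known covariance is not PSD (min eigenvalue %.3g)", min(ev)))
    }
  }

  structure(
    list(
      expr = expr,
      geno = geno,
      snps = snps,
      genes = genes,
      known_covariance = known_covariance,
      centered = FALSE,
      zero_var_genes = character(0),
      geno_alphabet = alphabet
    ),
    class = "eqtl_dataset"
  )
}

#' @export
print.eqtl_dataset <- function(x, ...) {
  cat(sprintf(
    "<eqtl_dataset> %d samples, %d genes, %d SNPs on %d chromosome(s)%s%s\n",
    nrow(x$expr), ncol(x$expr), ncol(x$geno),
    length(unique(x$snps$chrom)),
    if (x$centered) ", centered" else "",
    if (!is.null(x$known_covariance)) ", with known covariance" else ""
  ))
  invisible(x)
}

#' Number of samples / genes / SNPs in a dataset
#' @param x An `eqtl_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$expr)

#' @rdname n_samples
#' @export
n_genes <- function(x) ncol(x$expr)

#' @rdname n_samples
#' @export
n_snps <- function(x) ncol(x$geno)

#' Center expression gene-wise
#'
#' Subtracts each gene's mean across samples, so the mean term of the additive
#' model can be dropped from all likelihood computations. Genes with zero
#' variance are flagged and excluded from fitting and association testing
#' (they stay in the matrix).
#'
#' @param x An `eqtl_dataset` (or a bare samples x genes matrix).
#' @param eps Variance below which a gene counts as constant.
#' @return The same type of object, centered.
#' @export
center_expression <- function(x, eps = 1e-12) {
  if (is.matrix(x)) {
    return(sweep(x, 2, colMeans(x)))
  }
  stopifnot(inherits(x, "eqtl_dataset"))
  if (x$centered) stop("expression is already centered")
  v <- apply(x$expr, 2, stats::var)
  x$zero_var_genes <- colnames(x$expr)[v < eps]
  x$expr <- sweep(x$expr, 2, colMeans(x$expr))
  x$centered <- TRUE
  x
}

# Centered expression with flagged genes dropped; used by fitting and the scan.
active_expression <- function(dataset) {
  stopifnot(dataset$centered)
  keep <- setdiff(colnames(dataset$expr), dataset$zero_var_genes)
  dataset$expr[, keep, drop = FALSE]
}

#' Read an eQTL dataset from delimited text files
#'
#' Expression and genotypes are TSV files with an `id` header column: genes
#' (resp. SNPs) as rows and samples as columns, the common on-disk convention.
#' Positions are BED-like, 0-based half-open: genes as
#' `chrom start end gene_id`, SNPs as `chrom pos pos+1 snp_id`.
#'
#' @param expr_path Path to the expression TSV (genes x samples).
#' @param geno_path Path to the genotype TSV (SNPs x samples).
#' @param snp_bed Path to the SNP BED file.
#' @param gene_bed Path to the gene BED file.
#' @param cov_path Optional path to a square known-covariance TSV with sample
#'   IDs as header and first column.
#' @return A validated [eqtl_dataset()]. Sample order is taken from the
#'   expression file.
#' @export
read_dataset <- function(expr_path, geno_path, snp_bed, gene_bed, cov_path = NULL) {
  for (p in c(expr_path, geno_path, snp_bed, gene_bed, cov_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  }
  read_id_matrix <- function(path) {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    m
  }
  expr <- t(read_id_matrix(expr_path))  # to samples x genes
  geno <- t(read_id_matrix(geno_path))  # to samples x SNPs

  bed_cols <- c("chrom", "start", "end", "id")
  genes_bed <- readr::read_tsv(gene_bed, col_names = bed_cols,
                               show_col_types = FALSE, progress = FALSE)
  snps_bed <- readr::read_tsv(snp_bed, col_names = bed_cols,
                              show_col_types = FALSE, progress = FALSE)
  genes <- tibble::tibble(
    gene_id = as.character(genes_bed$id), chrom = as.character(genes_bed$chrom),
    start = as.integer(genes_bed$start), end = as.integer(genes_bed$end)
  )
  snps <- tibble::tibble(
    snp_id = as.character(snps_bed$id), chrom = as.character(snps_bed$chrom),
    pos = as.integer(snps_bed$start)
  )

  known <- NULL
  if (!is.null(cov_path)) {
    known <- read_id_matrix(cov_path)
    colnames(known) <- colnames(known)
  }
  eqtl_dataset(expr, geno, snps, genes, known_covariance = known)
}

#' Write an eQTL dataset as delimited text files
#'
#' Inverse of [read_dataset()]: writes `expression.tsv`, `genotypes.tsv`,
#' `genes.bed`, `snps.bed` and, when present, `covariance.tsv` into `dir`.
#'
#' @param dataset An `eqtl_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_id_matrix <- function(m, path, id_name) {
    df <- tibble::as_tibble(m, .name_repair = "minimal")
    df <- dplyr::bind_cols(tibble::tibble(!!id_name := rownames(m)), df)
    readr::write_tsv(df, path, progress = FALSE)
  }
  write_id_matrix(t(dataset$expr), file.path(dir, "expression.tsv"), "id")
  write_id_matrix(t(dataset$geno), file.path(dir, "genotypes.tsv"), "id")
  readr::write_tsv(
    tibble::tibble(chrom = dataset$genes$chrom, start = dataset$genes$start,
                   end = dataset$genes$end, id = dataset$genes$gene_id),
    file.path(dir, "genes.bed"), col_names = FALSE, progress = FALSE
  )
  readr::write_tsv(
    tibble::tibble(chrom = dataset$snps$chrom, start = dataset$snps$pos,
                   end = dataset$snps$pos + 1L, id = dataset$snps$snp_id),
    file.path(dir, "snps.bed"), col_names = FALSE, progress = FALSE
  )
  if (!is.null(dataset$known_covariance)) {
    write_id_matrix(dataset$known_covariance, file.path(dir, "covariance.tsv"), "id")
  }
  invisible(dir)
}

#' Read a dataset previously written with [write_dataset()]
#' @param dir Directory holding the dataset files.
#' @return An `eqtl_dataset`.
#' @export
read_dataset_dir <- function(dir) {
  cov <- file.path(dir, "covariance.tsv")
  read_dataset(
    expr_path = file.path(dir, "expression.tsv"),
    geno_path = file.path(dir, "genotypes.tsv"),
    snp_bed = file.path(dir, "snps.bed"),
    gene_bed = file.path(dir, "genes.bed"),
    cov_path = if (file.exists(cov)) cov else NULL
  )
}
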