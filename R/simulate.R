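#' Simulation parameters for a synthetic eQTL study
#'
#' Defines the generative conditions of a synthetic study: a segregant-cross
#' style genotype map with linkage, cis effects, trans regulatory hotspots,
#' low-rank confounders and Gaussian noise. The defaults are the package's
#' standard scenario, shaped like a yeast cross study at desk scale.
#'
#' @param n_samples,n_genes,n_snps,n_chromosomes Study dimensions.
#' @param recomb_prob Probability that adjacent SNPs differ within a sample
#'   (Markov recombination along each chromosome).
#' @param n_cis Number of genes given one cis-acting SNP (within the cis
#'   window).
#' @param n_hotspots Number of trans hotspot SNPs.
#' @param targets_per_hotspot Target genes per hotspot (always on other
#'   chromosomes, so every hotspot association is unambiguously trans).
#' @param cis_effect,trans_effect Effect-size distributions, lists with
#'   `family` `"gaussian"` (`sd`) or `"empirical"` (`values`, resampled with
#'   random sign). Cis effects default larger than trans.
#' @param n_confounders Number of hidden confounding factors.
#' @param variance_shares Named fractions for `genetic`, `confounder`, `noise`
#'   components (must sum to 1); each component is globally rescaled so the
#'   realized average per-gene variance shares match.
#' @param replicate_design If `TRUE`, every sample is duplicated across two
#'   conditions sharing genetics (and therefore the genetic expression
#'   component), inducing a block replicate population structure; the
#'   corresponding block kinship is attached as the known covariance.
#' @param trans_keep_fraction Fraction of hotspot target effects retained
#'   (subsampling knob for sensitivity sweeps).
#' @param confounder_strength Multiplier applied to the confounder component
#'   after share calibration (strength sweep knob).
#' @param snp_spacing_bp Spacing between adjacent SNPs on a chromosome.
#' @param gene_length_bp ORF length used for simulated genes.
#' @param cis_window_bp Window defining cis (matches the scan default).
#' @param hotspot_min_separation_bp Minimum distance between hotspot SNPs on
#'   the same chromosome, so simulated hotspots are distinct loci.
#' @param seed Integer seed; the whole study is a deterministic function of
#'   the parameters and this seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_samples = 100L, n_genes = 500L, n_snps = 300L,
                       n_chromosomes = 5L, recomb_prob = 0.1,
                       n_cis = 100L, n_hotspots = 10L,
                       targets_per_hotspot = 20L,
                       cis_effect = list(family = "gaussian", sd = 1),
                       trans_effect = list(family = "gaussian", sd = 0.5),
                       n_confounders = 3L,
                       variance_shares = c(genetic = 0.3, confounder = 0.4,
                                           noise = 0.3),
                       replicate_design = FALSE,
                       trans_keep_fraction = 1,
                       confounder_strength = 1,
                       snp_spacing_bp = 5000L,
                       gene_length_bp = 1500L,
                       cis_window_bp = 10000L,
                       hotspot_min_separation_bp = 100000L,
                       seed = 1L) {
  p <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_snps = as.integer(n_snps), n_chromosomes = as.integer(n_chromosomes),
    recomb_prob = recomb_prob, n_cis = as.integer(n_cis),
    n_hotspots = as.integer(n_hotspots),
    targets_per_hotspot = as.integer(targets_per_hotspot),
    cis_effect = cis_effect, trans_effect = trans_effect,
    n_confounders = as.integer(n_confounders),
    variance_shares = variance_shares,
    replicate_design = isTRUE(replicate_design),
    trans_keep_fraction = trans_keep_fraction,
    confounder_strength = confounder_strength,
    snp_spacing_bp = as.integer(snp_spacing_bp),
    gene_length_bp = as.integer(gene_length_bp),
    cis_window_bp = as.integer(cis_window_bp),
    hotspot_min_separation_bp = as.integer(hotspot_min_separation_bp),
    seed = as.integer(seed)
  )
  stopifnot(
    p$n_samples >= 2, p$n_genes >= 1, p$n_snps >= p$n_chromosomes,
    p$n_chromosomes >= 1, p$recomb_prob >= 0, p$recomb_prob <= 1,
    p$n_cis >= 0, p$n_cis <= p$n_genes, p$n_hotspots >= 0,
    p$n_hotspots <= p$n_snps, p$n_confounders >= 0,
    p$trans_keep_fraction >= 0, p$trans_keep_fraction <= 1,
    p$confounder_strength >= 0,
    length(p$variance_shares) == 3,
    all(p$variance_shares >= 0)
  )
  if (is.null(names(p$variance_shares)) || !setequal(
    names(p$variance_shares), c("genetic", "confounder", "noise"))) {
    names(p$variance_shares) <- c("genetic", "confounder", "noise")
  }
  if (abs(sum(p$variance_shares) - 1) > 1e-6) {
    stop("variance_shares must sum to 1 within 1e-6")
  }
  if (p$n_hotspots * p$targets_per_hotspot > p$n_genes - p$n_cis &&
      p$n_hotspots > 0) {
    # targets may overlap cis genes, but not each other; need enough genes
    if (p$n_hotspots * p$targets_per_hotspot > p$n_genes) {
      stop("infeasible: n_hotspots * targets_per_hotspot exceeds n_genes")
    }
  }
  structure(p, class = "sim_params")
}

#' Read / write simulation parameters (YAML or JSON)
#' @param path File path; keys mirror [sim_params()] arguments.
#' @return A `sim_params` (reader) or the path, invisibly (writer).
#' @export
read_sim_params <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_params)))
  if (length(unknown)) {
    stop(sprintf("unknown simulation parameter(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  if (!is.null(vals$variance_shares)) {
    vals$variance_shares <- unlist(vals$variance_shares)
  }
  do.call(sim_params, vals)
}

#' @rdname read_sim_params
#' @param params A `sim_params`.
#' @export
write_sim_params <- function(params, path) {
  p <- unclass(params)
  p$variance_shares <- as.list(p$variance_shares)
  yaml::write_yaml(p, path)
  invisible(path)
}

#' Simulate linked genotypes and genomic annotation
#'
#' Cross-like Markov genotypes: per chromosome and sample, the first allele is
#' Bernoulli(0.5) and each subsequent SNP flips with probability
#' `recomb_prob`. SNPs are evenly spaced; genes are assigned to random
#' chromosomes and evenly spaced along each.
#'
#' @param params A [sim_params()].
#' @return A list with `geno` (samples x SNPs, 0/1), `snps` and `genes`
#'   annotation tibbles. Uses the current RNG state (seed management happens
#'   in [simulate_eqtl_study()]).
#' @export
simulate_genotypes <- function(params) {
  N <- params$n_samples
  per_chr <- diff(round(seq(0, params$n_snps, length.out = params$n_chromosomes + 1)))
  chrom_names <- paste0("chr", seq_len(params$n_chromosomes))
  geno_cols <- list()
  snps <- list()
  snp_i <- 0L
  for (ci in seq_len(params$n_chromosomes)) {
    nc <- per_chr[ci]
    if (nc == 0) next
    m <- matrix(0L, N, nc)
    m[, 1] <- stats::rbinom(N, 1, 0.5)
    if (nc > 1) {
      for (j in 2:nc) {
        flip <- stats::rbinom(N, 1, params$recomb_prob)
        m[, j] <- ifelse(flip == 1L, 1L - m[, j - 1], m[, j - 1])
      }
    }
    geno_cols[[ci]] <- m
    snps[[ci]] <- tibble::tibble(
      snp_id = sprintf("snp_%04d", snp_i + seq_len(nc)),
      chrom = chrom_names[ci],
      pos = params$snp_spacing_bp * seq_len(nc)
    )
    snp_i <- snp_i + nc
  }
  geno <- do.call(cbind, geno_cols)
  snps <- dplyr::bind_rows(snps)
  colnames(geno) <- snps$snp_id
  rownames(geno) <- sprintf("s%04d", seq_len(N))

  chrom_len <- (per_chr + 1L) * params$snp_spacing_bp
  gene_chrom <- sample.int(params$n_chromosomes, params$n_genes, replace = TRUE)
  genes <- dplyr::bind_rows(lapply(seq_len(params$n_chromosomes), function(ci) {
    ids <- which(gene_chrom == ci)
    if (!length(ids)) return(NULL)
    span <- max(chrom_len[ci] - params$gene_length_bp, 1L)
    starts <- round(seq(0, span, length.out = length(ids) + 2L))[-c(1, length(ids) + 2L)]
    tibble::tibble(
      gene_id = sprintf("g%04d", ids),
      chrom = chrom_names[ci],
      start = as.integer(starts),
      end = as.integer(starts + params$gene_length_bp)
    )
  })) |>
    dplyr::arrange(.data$gene_id)
  list(geno = geno, snps = snps, genes = genes)
}

draw_effects <- function(dist, n) {
  if (dist$family == "gaussian") {
    stats::rnorm(n, 0, dist$sd)
  } else if (dist$family == "empirical") {
    sample(abs(dist$values), n, replace = TRUE) * sample(c(-1, 1), n, replace = TRUE)
  } else {
    stop(sprintf("unknown effect-size family '%s'", dist$family))
  }
}

#' Assign causal cis and trans-hotspot effects
#'
#' Picks `n_cis` genes with a SNP inside the cis window and draws cis effect
#' sizes; picks `n_hotspots` SNPs (pairwise at least
#' `hotspot_min_separation_bp` apart) and for each `targets_per_hotspot`
#' distinct target genes on other chromosomes with trans effect sizes. No
#' gene is a target of two hotspots.
#'
#' @param params A [sim_params()].
#' @param geno,snps,genes Output of [simulate_genotypes()].
#' @return A tibble of causal pairs: `gene_id`, `snp_id`, `beta`, `label`.
#' @export
assign_effects <- function(params, geno, snps, genes) {
  effects <- list()

  if (params$n_cis > 0) {
    cand <- dplyr::inner_join(genes, snps, by = "chrom",
                              suffix = c("", "_snp"),
                              relationship = "many-to-many")
    cand$dist <- snp_gene_distance(cand$chrom, cand$pos, cand$chrom,
                                   cand$start, cand$end)
    cand <- dplyr::filter(cand, .data$dist <= params$cis_window_bp)
    cis_genes <- unique(cand$gene_id)
    if (length(cis_genes) < params$n_cis) {
      stop(sprintf(
        "infeasible: only %d gene(s) have a SNP within the cis window, need %d",
        length(cis_genes), params$n_cis))
    }
    chosen <- sample(cis_genes, params$n_cis)
    pick <- cand |>
      dplyr::filter(.data$gene_id %in% chosen) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::slice_sample(n = 1) |>
      dplyr::ungroup()
    effects$cis <- tibble::tibble(
      gene_id = pick$gene_id, snp_id = pick$snp_id,
      beta = draw_effects(params$cis_effect, nrow(pick)), label = "cis"
    )
  }

  if (params$n_hotspots > 0) {
    ord <- sample.int(nrow(snps))
    kept <- integer(0)
    for (i in ord) {
      if (length(kept) >= params$n_hotspots) break
      ok <- TRUE
      for (k in kept) {
        if (snps$chrom[k] == snps$chrom[i] &&
            abs(snps$pos[k] - snps$pos[i]) < params$hotspot_min_separation_bp) {
          ok <- FALSE; break
        }
      }
      if (ok) kept <- c(kept, i)
    }
    if (length(kept) < params$n_hotspots) {
      stop("infeasible: cannot place hotspots with the required separation")
    }
    taken <- character(0)
    hs <- list()
    for (j in seq_along(kept)) {
      hchrom <- snps$chrom[kept[j]]
      pool <- setdiff(genes$gene_id[genes$chrom != hchrom], taken)
      if (length(pool) < params$targets_per_hotspot) {
        stop("infeasible: not enough distinct target genes on other chromosomes")
      }
      targets <- sample(pool, params$targets_per_hotspot)
      taken <- c(taken, targets)
      hs[[j]] <- tibble::tibble(
        gene_id = targets, snp_id = snps$snp_id[kept[j]],
        beta = draw_effects(params$trans_effect, length(targets)),
        label = "trans"
      )
    }
    hs <- dplyr::bind_rows(hs)
    if (params$trans_keep_fraction < 1) {
      keep_n <- round(nrow(hs) * params$trans_keep_fraction)
      hs <- hs[sort(sample.int(nrow(hs), keep_n)), ]
    }
    effects$trans <- hs
  }

  out <- dplyr::bind_rows(effects)
  if (nrow(out) == 0) {
    out <- tibble::tibble(gene_id = character(0), snp_id = character(0),
                          beta = numeric(0), label = character(0))
  }
  out
}

#' Simulate expression from assigned effects
#'
#' Builds `Y = genetic + confounder + noise`: the genetic term sums
#' `beta * genotype` over causal pairs, the confounder term is a rank-
#' `n_confounders` Gaussian factor product, and the noise is iid Gaussian.
#' Each component is globally rescaled so the average per-gene variance
#' shares match `variance_shares` (then the confounder component is
#' multiplied by `confounder_strength`).
#'
#' @param geno Samples x SNPs genotype matrix.
#' @param truth Causal-pair tibble from [assign_effects()].
#' @param params A [sim_params()].
#' @param gene_ids Gene IDs (columns of the result).
#' @return A list with `expr` (samples x genes), `confounders` (samples x
#'   n_confounders), `confounder_covariance` (the exact N x N covariance of
#'   the confounder component, for the idealized baseline) and
#'   `realized_shares`.
#' @export
simulate_expression <- function(geno, truth, params, gene_ids) {
  N <- nrow(geno)
  G <- length(gene_ids)
  shares <- params$variance_shares

  genetic <- matrix(0, N, G, dimnames = list(rownames(geno), gene_ids))
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      j <- match(truth$gene_id[i], gene_ids)
      genetic[, j] <- genetic[, j] + truth$beta[i] * geno[, truth$snp_id[i]]
    }
  }
  Z <- if (params$n_confounders > 0) {
    matrix(stats::rnorm(N * params$n_confounders), N)
  } else {
    matrix(0, N, 0)
  }
  V <- matrix(stats::rnorm(params$n_confounders * G), ncol = G)
  conf <- if (params$n_confounders > 0) Z %*% V else matrix(0, N, G)
  noise <- matrix(stats::rnorm(N * G), N, G)

  mean_var <- function(m) sum(sweep(m, 2, colMeans(m))^2) / ((N - 1) * G)
  comp_scale <- function(m, share, what) {
    v <- mean_var(m)
    if (share == 0) return(m * 0)
    if (v < 1e-12) {
      stop(sprintf("%s share is %.2g but the %s component is empty", what, share, what))
    }
    m * sqrt(share / v)
  }
  genetic <- comp_scale(genetic, shares[["genetic"]], "genetic")
  conf <- comp_scale(conf, shares[["confounder"]], "confounder") *
    sqrt(params$confounder_strength)
  noise <- comp_scale(noise, shares[["noise"]], "noise")

  expr <- genetic + conf + noise
  total <- mean_var(expr)
  realized <- c(genetic = mean_var(genetic), confounder = mean_var(conf),
                noise = mean_var(noise)) / total
  list(
    expr = expr,
    confounders = Z,
    confounder_covariance = tcrossprod(conf) / G,
    realized_shares = realized
  )
}

#' Simulate a complete synthetic eQTL study
#'
#' Deterministic given `params` (including its seed): genotypes with linkage,
#' causal effect assignment, expression synthesis, and (optionally) the
#' replicate-design duplication with its block kinship.
#'
#' @param params A [sim_params()].
#' @param seed Optional override of `params$seed`.
#' @return A list of class `eqtl_sim` with elements `dataset` (an
#'   [eqtl_dataset()]), `truth` (class `sim_truth`: causal pairs, true
#'   confounder matrix, realized variance shares, exact confounder
#'   covariance) and `params`.
#' @export
simulate_eqtl_study <- function(params = sim_params(), seed = NULL) {
  if (!is.null(seed)) params$seed <- as.integer(seed)
  set.seed(params$seed)
  gen <- simulate_genotypes(params)
  truth_pairs <- assign_effects(params, gen$geno, gen$snps, gen$genes)

  geno <- gen$geno
  known <- NULL
  if (params$replicate_design) {
    ids <- rownames(geno)
    geno <- rbind(geno, geno)
    rownames(geno) <- c(paste0(ids, "_c1"), paste0(ids, "_c2"))
    strain <- rep(seq_along(ids), times = 2)
    known <- outer(strain, strain, "==") * 1
    dimnames(known) <- list(rownames(geno), rownames(geno))
  }

  sim <- simulate_expression(geno, truth_pairs, params, gen$genes$gene_id)
  dataset <- eqtl_dataset(
    expr = sim$expr, geno = geno, snps = gen$snps, genes = gen$genes,
    known_covariance = known
  )
  truth <- structure(
    list(
      effects = truth_pairs,
      confounders = sim$confounders,
      realized_shares = sim$realized_shares,
      confounder_covariance = sim$confounder_covariance
    ),
    class = "sim_truth"
  )
  structure(list(dataset = dataset, truth = truth, params = params),
            class = "eqtl_sim")
}

#' @export
print.eqtl_sim <- function(x, ...) {
  cat(sprintf(
    "<eqtl_sim> seed %d: %d causal pair(s) (%d cis, %d trans), %d confounder(s)\n",
    x$params$seed, nrow(x$truth$effects),
    sum(x$truth$effects$label == "cis"), sum(x$truth$effects$label == "trans"),
    x$params$n_confounders
  ))
  print(x$dataset)
  invisible(x)
}

#' Write / read simulation ground truth as JSON
#' @param truth A `sim_truth`.
#' @param path JSON file path.
#' @return The path / a `sim_truth`.
#' @export
write_truth <- function(truth, path) {
  payload <- list(
    effects = truth$effects,
    confounders = truth$confounders,
    realized_shares = as.list(truth$realized_shares),
    confounder_covariance = truth$confounder_covariance
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      effects = tibble::as_tibble(p$effects),
      confounders = as.matrix(p$confounders),
      realized_shares = unlist(p$realized_shares),
      confounder_covariance = as.matrix(p$confounder_covariance)
    ),
    class = "sim_truth"
  )
}

#' Estimate simulation parameters from a fitted model and scan
#'
#' The fit-then-simulate route: extracts from a fitted model and its
#' association table the ingredients of a matched synthetic study - counts of
#' significant cis genes, number and size of trans hotspots (clustered within
#' the regulator exclusion window so linked SNPs count once), empirical
#' effect-size distributions (resampled from fitted effect estimates of
#' significant associations), the effective number of confounding factors,
#' and variance shares.
#'
#' @param model A fitted `panama_model`.
#' @param table A `panama_assoc` table for the same dataset.
#' @param fdr_cutoff Significance cutoff used for all counting.
#' @param min_hotspot_genes Minimum significant trans genes for a SNP to
#'   count as a hotspot.
#' @param snps Optional SNP annotation (defaults to positions parsed from the
#'   table) used for hotspot clustering.
#' @param dataset Optional `eqtl_dataset` the model was fitted to. When
#'   supplied, switched-on factors are classified as genetic or confounding
#'   by the fraction of their variance explained by the genotype subspace
#'   (per-chromosome genotype principal components): linked genetic effects
#'   form low-rank expression structure that maximum likelihood legitimately
#'   captures as factors, and counting those as confounders would overstate
#'   both the confounder number and share. Without a dataset, all effective
#'   factors count as confounders.
#' @return A [sim_params()] whose effect-size families are `"empirical"`.
#'   Falls back to the default parameters with a warning when nothing is
#'   significant.
#' @export
estimate_sim_params <- function(model, table, fdr_cutoff = 0.05,
                                min_hotspot_genes = 5L, snps = NULL,
                                dataset = NULL) {
  N <- nrow(model$factors)
  gene_ids <- unique(table$gene_id)
  snp_tab <- if (is.null(snps)) {
    dplyr::distinct(table, .data$snp_id, .data$chrom, .data$pos)
  } else snps
  n_chrom <- length(unique(snp_tab$chrom))

  ca <- count_associations(table, fdr_cutoff)
  if (ca$cis_count + ca$trans_count == 0) {
    warning("no significant associations at the requested FDR; returning default simulation parameters")
    G <- length(gene_ids); P <- nrow(snp_tab)
    return(sim_params(
      n_samples = N, n_genes = G, n_snps = P, n_chromosomes = n_chrom,
      n_cis = min(100L, max(1L, G %/% 5L)),
      n_hotspots = min(10L, max(1L, P %/% 30L)),
      targets_per_hotspot = min(20L, max(1L, G %/% 25L))
    ))
  }

  # hotspots: per-SNP significant trans-gene counts, clustered in linkage windows
  prof <- hotspot_profile(table, fdr_cutoff) |>
    dplyr::filter(.data$n_trans >= min_hotspot_genes) |>
    dplyr::arrange(dplyr::desc(.data$n_trans))
  kept <- integer(0)
  if (nrow(prof) > 0) {
    for (i in seq_len(nrow(prof))) {
      clash <- FALSE
      for (k in kept) {
        if (prof$chrom[k] == prof$chrom[i] &&
            abs(prof$pos[k] - prof$pos[i]) <= model$config$regulator_exclusion_bp) {
          clash <- TRUE; break
        }
      }
      if (!clash) kept <- c(kept, i)
    }
  }
  n_hot <- length(kept)
  targets <- if (n_hot > 0) as.integer(round(mean(prof$n_trans[kept]))) else 20L

  sig <- dplyr::filter(table, .data$q <= fdr_cutoff)
  cis_best <- sig |>
    dplyr::filter(.data$label == "cis") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_min(.data$q, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  trans_best <- sig |>
    dplyr::filter(.data$label == "trans") |>
    dplyr::group_by(.data$gene_id, .data$chrom) |>
    dplyr::slice_min(.data$q, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  cis_eff <- if (nrow(cis_best) > 0) {
    list(family = "empirical", values = abs(cis_best$beta))
  } else list(family = "gaussian", sd = 1)
  trans_eff <- if (nrow(trans_best) > 0) {
    list(family = "empirical", values = abs(trans_best$beta))
  } else list(family = "gaussian", sd = 0.5)

  # variance shares: non-genetic effective factors -> confounder; counted
  # association effects -> genetic; noise from the fit. Effect variances use
  # the actual genotype variances when the dataset is available, else the
  # Bernoulli(1/2) value 1/4.
  total <- sum(model$factor_variances) + sum(model$regulator_variances) +
    model$covariate_variance + model$noise_variance
  on <- which(model$factor_variances > model$config$ard_threshold * total)
  if (!is.null(dataset)) {
    r2 <- vapply(on, function(k) {
      genotype_subspace_r2(model$factors[, k], dataset)
    }, numeric(1))
    conf_idx <- on[r2 < 0.5]
  } else {
    conf_idx <- on
  }
  n_conf <- length(conf_idx)
  conf_var <- sum(model$factor_variances[conf_idx]) + model$covariate_variance

  gvar_of <- function(ids) {
    if (is.null(dataset)) return(rep(0.25, length(ids)))
    apply(dataset$geno[, ids, drop = FALSE], 2, stats::var)
  }
  gen_var <- (sum(cis_best$beta^2 * gvar_of(cis_best$snp_id)) +
                sum(trans_best$beta^2 * gvar_of(trans_best$snp_id))) /
    length(gene_ids)
  noise_var <- model$noise_variance
  shares <- c(genetic = gen_var, confounder = conf_var, noise = noise_var)
  shares <- shares / sum(shares)

  sim_params(
    n_samples = N, n_genes = length(gene_ids), n_snps = nrow(snp_tab),
    n_chromosomes = n_chrom,
    n_cis = max(ca$cis_count, 0L),
    n_hotspots = n_hot, targets_per_hotspot = max(targets, 1L),
    cis_effect = cis_eff, trans_effect = trans_eff,
    n_confounders = n_conf,
    variance_shares = shares
  )
}

# Fraction of a vector's variance explained by the genotype subspace,
# summarised as the top principal components of each chromosome's genotype
# block (bounded predictor count keeps the projection honest at N ~ 100).
genotype_subspace_r2 <- function(x, dataset, pcs_per_chrom = 5L) {
  x <- x - mean(x)
  if (sum(x^2) < 1e-12) return(0)
  preds <- lapply(split(seq_len(ncol(dataset$geno)), dataset$snps$chrom),
                  function(idx) {
    Gc <- scale(dataset$geno[, idx, drop = FALSE], scale = FALSE)
    q <- min(pcs_per_chrom, ncol(Gc), nrow(Gc) - 1L)
    svd(Gc, nu = q, nv = 0)$u
  })
  P <- do.call(cbind, preds)
  fitted <- qr.fitted(qr(P), x)
  sum(fitted^2) / sum(x^2)
}
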