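#' Construct a variance-model object
#'
#' Mostly used internally and in tests; [fit_panama()] is the user entry
#' point. Factor columns are expected to satisfy the scale-identifiability
#' convention `sum(x_k^2) = N` after fitting.
#'
#' @param factors Numeric matrix, samples x k_max: the hidden factor states.
#' @param factor_variances Non-negative per-factor variances (ARD parameters).
#' @param regulator_set Integer column indices into the genotype matrix of the
#'   SNPs whose variance contribution is modelled jointly with the factors.
#' @param regulator_variances Non-negative per-regulator variances.
#' @param noise_variance Positive residual variance.
#' @param covariate_variance Non-negative scale of the known covariance term.
#' @param fit_log Per-iteration objective values (non-decreasing).
#' @param config The `fit_config` used (echoed for provenance).
#' @param regulator_ids Optional SNP IDs matching `regulator_set`.
#' @param converged Logical optimizer status.
#' @param iterations Optional list of per-outer-iteration provenance.
#' @return An object of class `panama_model`.
#' @export
panama_model <- function(factors, factor_variances,
                         regulator_set = integer(0),
                         regulator_variances = numeric(0),
                         noise_variance = 1,
                         covariate_variance = 0,
                         fit_log = numeric(0),
                         config = fit_config(),
                         regulator_ids = character(0),
                         converged = NA,
                         iterations = list()) {
  stopifnot(noise_variance > 0, all(factor_variances >= 0),
            all(regulator_variances >= 0), covariate_variance >= 0,
            length(regulator_set) == length(regulator_variances))
  structure(
    list(
      factors = as.matrix(factors),
      factor_variances = unname(as.numeric(factor_variances)),
      regulator_set = unname(as.integer(regulator_set)),
      regulator_ids = unname(as.character(regulator_ids)),
      regulator_variances = unname(as.numeric(regulator_variances)),
      noise_variance = unname(as.numeric(noise_variance)),
      covariate_variance = unname(as.numeric(covariate_variance)),
      fit_log = fit_log,
      config = config,
      converged = converged,
      iterations = iterations
    ),
    class = "panama_model"
  )
}

#' @export
print.panama_model <- function(x, ...) {
  cat(sprintf(
    "<panama_model> %d samples, %d candidate factors (%d effective), %d regulator(s), noise variance %.4g\n",
    nrow(x$factors), ncol(x$factors), effective_num_factors(x),
    length(x$regulator_set), x$noise_variance
  ))
  invisible(x)
}

#' Fit the variance model for a fixed regulator set
#'
#' Jointly maximises the marginal likelihood over the hidden factor matrix and
#' all variance parameters (per-factor, per-regulator, known-covariate scale,
#' noise) by quasi-Newton ascent (L-BFGS-B) with variances on the log scale.
#' Because a factor direction and a regulator genotype direction are
#' additively interchangeable in the covariance, the likelihood is flat in
#' how their shared variance is split; initialisation therefore decides the
#' split, and it is chosen to preserve genetic signal. With an empty
#' regulator set, factors are initialised from the top principal components
#' of the centered expression (variances matching the PC variances). With
#' regulators present, each regulator variance is initialised from the
#' average squared per-gene regression effect of its genotype, and the
#' factors from the principal components of the expression *residualized on
#' the regulator genotypes*, so confounder structure - not genetic structure
#' - seeds the factor space. After convergence factor columns are rescaled
#' to squared norm N (the sample count), the variances absorbing the scale.
#'
#' @param dataset A centered `eqtl_dataset`.
#' @param regulator_set Integer SNP column indices to include as joint
#'   variance terms (possibly empty).
#' @param config A [fit_config()].
#' @return A fitted `panama_model` with a non-decreasing `fit_log`.
#' @export
fit_variance_model <- function(dataset, regulator_set = integer(0),
                               config = fit_config()) {
  if (!dataset$centered) dataset <- center_expression(dataset)
  Y <- active_expression(dataset)
  N <- nrow(Y); G <- ncol(Y)
  Kf <- min(config$k_max, N - 1L)
  R <- length(regulator_set)
  Gmat <- if (R > 0) {
    g <- dataset$geno[, regulator_set, drop = FALSE]
    storage.mode(g) <- "double"
    g
  } else NULL
  Cmat <- dataset$known_covariance
  has_cov <- !is.null(Cmat)

  total_var <- sum(Y^2) / (N * G)
  if (R > 0) {
    Gc <- sweep(Gmat, 2, colMeans(Gmat))
    # per-regulator average squared regression effect across genes
    gss <- colSums(Gc^2)
    th0 <- pmax(rowMeans((crossprod(Gc, Y) / gss)^2), 1e-6 * total_var)
    Yres <- Y - Gc %*% qr.solve(crossprod(Gc), crossprod(Gc, Y))
  } else {
    th0 <- numeric(0)
    Yres <- Y
  }
  sv <- svd(Yres, nu = Kf, nv = 0)
  X0 <- sv$u * sqrt(N)
  s2k0 <- pmax(sv$d[seq_len(Kf)]^2 / (N * G), 1e-8 * total_var)
  s2e0 <- 0.5 * total_var
  # moment estimate of the known-covariate scale: project the off-diagonal
  # sample covariance onto C (log-scale optimization cannot escape a near-zero
  # start, so the initial value must carry the right order of magnitude)
  s2c0 <- if (has_cov) {
    Smean <- tcrossprod(Y) / G
    co <- Cmat; diag(co) <- 0
    so <- Smean; diag(so) <- 0
    max(sum(co * so) / max(sum(co * co), 1e-12), 1e-3 * total_var)
  } else 0

  obj <- make_objective(Y, Gmat, Cmat, N, Kf, R)
  par0 <- pack_params(X0, s2k0, th0, s2e0, s2c0, has_cov)

  trace_env <- new.env()
  trace_env$log <- numeric(0)
  fn_traced <- function(par) {
    v <- obj$fn(par)
    trace_env$log <- c(trace_env$log, -v)
    v
  }

  res <- stats::optim(
    par = par0, fn = fn_traced, gr = obj$gr, method = "L-BFGS-B",
    control = list(
      maxit = config$max_evals,
      factr = config$optimizer_tol / .Machine$double.eps
    )
  )
  if (res$value > obj$fn(par0) + 1e-9) {
    # never accept a worse iterate than the start
    res$par <- par0
    res$value <- obj$fn(par0)
  }
  p <- unpack_params(res$par, N, Kf, R, has_cov)

  # rescale factor columns to squared norm N; variances absorb the scale
  nrm2 <- colSums(p$X^2)
  for (k in seq_len(Kf)) {
    if (nrm2[k] > 1e-12) {
      p$s2k[k] <- p$s2k[k] * nrm2[k] / N
      p$X[, k] <- p$X[, k] * sqrt(N / nrm2[k])
    } else {
      p$X[, k] <- rep(1, N)  # collapsed direction; norm^2 = N, variance pinned to 0
      p$s2k[k] <- 0
    }
  }

  fit_log <- cummax(trace_env$log)
  panama_model(
    factors = p$X,
    factor_variances = p$s2k,
    regulator_set = regulator_set,
    regulator_ids = dataset$snps$snp_id[regulator_set],
    regulator_variances = p$th,
    noise_variance = p$s2e,
    covariate_variance = p$s2c,
    fit_log = fit_log,
    config = config,
    converged = res$convergence == 0
  )
}

#' Number of effective (switched-on) factors
#'
#' A factor counts as effective when its variance exceeds `ard_threshold`
#' times the total of all variance parameters (factor + regulator + covariate
#' + noise). Maximum likelihood drives unused factor variances towards zero,
#' so this count is the model's automatic choice of factor dimensionality.
#'
#' @param model A fitted `panama_model`.
#' @param ard_threshold Fraction of the summed variance parameters; defaults
#'   to the fitted model's config value.
#' @return Integer count.
#' @export
effective_num_factors <- function(model, ard_threshold = NULL) {
  if (is.null(ard_threshold)) ard_threshold <- model$config$ard_threshold
  total <- sum(model$factor_variances) + sum(model$regulator_variances) +
    model$covariate_variance + model$noise_variance
  sum(model$factor_variances > ard_threshold * total)
}

#' Select prominent trans regulators
#'
#' Runs a genome-wide association scan under the factor-only (regulators
#' excluded) covariance of the current model, counts for each SNP the genes
#' significant at the genome-wide BH FDR `regulator_fdr`, and greedily keeps
#' the highest-counting SNPs with at least `regulator_min_genes` significant
#' genes, skipping SNPs within `regulator_exclusion_bp` of an already kept
#' SNP on the same chromosome (linkage guard), up to `max_regulators`.
#' Ties are broken by the smaller best p-value, then by genome order.
#'
#' @param dataset A centered `eqtl_dataset`.
#' @param model A fitted `panama_model`.
#' @param config A [fit_config()].
#' @return Integer vector of SNP column indices (possibly empty), in rank order.
#' @export
select_regulators <- function(dataset, model, config = model$config) {
  if (config$max_regulators == 0L) return(integer(0))
  cov <- build_covariance(model, "panama", dataset)
  tab <- panama_scan(dataset, cov)
  counts <- tab |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(
      n_sig = sum(.data$q <= config$regulator_fdr),
      best_p = min(.data$p),
      .groups = "drop"
    ) |>
    dplyr::left_join(dataset$snps, by = "snp_id") |>
    dplyr::arrange(dplyr::desc(.data$n_sig), .data$best_p, .data$chrom, .data$pos) |>
    dplyr::filter(.data$n_sig >= config$regulator_min_genes)
  if (nrow(counts) == 0) return(integer(0))

  kept <- character(0)
  kept_chrom <- character(0)
  kept_pos <- integer(0)
  for (i in seq_len(nrow(counts))) {
    if (length(kept) >= config$max_regulators) break
    ch <- counts$chrom[i]; po <- counts$pos[i]
    same <- kept_chrom == ch
    if (any(same) && min(abs(kept_pos[same] - po)) <= config$regulator_exclusion_bp) next
    kept <- c(kept, counts$snp_id[i])
    kept_chrom <- c(kept_chrom, ch)
    kept_pos <- c(kept_pos, po)
  }
  match(kept, dataset$snps$snp_id)
}

#' Fit the joint confounder / regulator model
#'
#' The main model-fitting entry point. Alternates (i) maximum-likelihood
#' fitting of hidden factors and all variance parameters given the current
#' regulator set (initially empty) with (ii) regulator selection under the
#' learned factor covariance, until the regulator set is unchanged or
#' `max_outer_iterations` is reached. Learning the factors jointly with the
#' variance contribution of prominent regulators prevents genuine trans
#' hotspots from being absorbed into the confounder factors.
#'
#' @param dataset An `eqtl_dataset` (centered automatically if not yet).
#' @param config A [fit_config()].
#' @param verbose Print per-iteration progress to stderr.
#' @return A fitted `panama_model`; `$iterations` records per-iteration
#'   regulator sets and objective values.
#' @export
fit_panama <- function(dataset, config = fit_config(), verbose = FALSE) {
  if (!dataset$centered) dataset <- center_expression(dataset)
  reg <- integer(0)
  model <- NULL
  iterations <- list()
  for (it in seq_len(config$max_outer_iterations)) {
    model <- fit_variance_model(dataset, regulator_set = reg, config = config)
    new_reg <- select_regulators(dataset, model, config)
    iterations[[it]] <- list(
      iteration = it,
      regulator_set = dataset$snps$snp_id[reg],
      proposed_set = dataset$snps$snp_id[new_reg],
      objective = max(model$fit_log),
      effective_factors = effective_num_factors(model)
    )
    if (verbose) {
      message(sprintf(
        "outer iteration %d: objective %.2f, %d effective factor(s), regulators [%s] -> [%s]",
        it, max(model$fit_log), effective_num_factors(model),
        paste(dataset$snps$snp_id[reg], collapse = ","),
        paste(dataset$snps$snp_id[new_reg], collapse = ",")
      ))
    }
    if (setequal(new_reg, reg)) break
    reg <- new_reg
  }
  model$iterations <- iterations
  model
}

#' Build a correction covariance from a fitted model
#'
#' @param model A fitted `panama_model`.
#' @param mode `"panama"`: factors (+ known covariates) only, regulators
#'   excluded so their signal survives testing; `"panama_trans"`: additionally
#'   includes the regulator terms (conservative, ICE-like behaviour);
#'   `"linear"`: zero matrix, reducing the scan to ordinary regression.
#' @param dataset The `eqtl_dataset` the model was fitted to (supplies the
#'   regulator genotype columns and the known covariance).
#' @return A `covariance_structure`: the N x N correction matrix (noise kept
#'   separate) plus a record of the included terms.
#' @export
build_covariance <- function(model, mode = c("panama", "panama_trans", "linear"),
                             dataset) {
  mode <- match.arg(mode)
  N <- nrow(dataset$expr)
  terms <- character(0)
  if (mode == "linear") {
    K <- matrix(0, N, N)
  } else {
    K <- model$factors %*% (model$factor_variances * t(model$factors))
    terms <- "factors"
    if (!is.null(dataset$known_covariance) && model$covariate_variance > 0) {
      K <- K + model$covariate_variance * dataset$known_covariance
      terms <- c(terms, "known_covariates")
    }
    if (mode == "panama_trans" && length(model$regulator_set)) {
      Gm <- dataset$geno[, model$regulator_set, drop = FALSE]
      storage.mode(Gm) <- "double"
      K <- K + Gm %*% (model$regulator_variances * t(Gm))
      terms <- c(terms, "regulators")
    }
    K <- (K + t(K)) / 2
  }
  dimnames(K) <- list(rownames(dataset$expr), rownames(dataset$expr))
  structure(
    list(matrix = K, included_terms = terms, noise_variance = model$noise_variance),
    class = "covariance_structure"
  )
}

#' @export
print.covariance_structure <- function(x, ...) {
  cat(sprintf(
    "<covariance_structure> %d x %d, terms: %s, separate noise variance %.4g\n",
    nrow(x$matrix), ncol(x$matrix),
    if (length(x$included_terms)) paste(x$included_terms, collapse = "+") else "(none)",
    x$noise_variance
  ))
  invisible(x)
}
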