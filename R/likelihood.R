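#' Fitting configuration
#'
#' Collects the tunable parameters of the variance-model fit and the iterative
#' regulator-selection loop.
#'
#' @param k_max Number of candidate hidden factors; set generously, automatic
#'   relevance determination switches unused ones off.
#' @param max_outer_iterations Cap on fit / select-regulators rounds.
#' @param max_regulators Cap on the size of the regulator set (0 disables
#'   joint regulator modelling, giving a factor-only fit).
#' @param regulator_min_genes Minimum number of significantly associated genes
#'   a SNP needs to qualify as a candidate regulator.
#' @param regulator_fdr Genome-wide BH FDR used when counting a SNP's
#'   significant genes during regulator selection.
#' @param regulator_exclusion_bp SNPs within this distance of an already
#'   selected regulator on the same chromosome are skipped (linkage guard).
#' @param optimizer_tol Relative objective-change convergence tolerance.
#' @param max_evals Cap on optimizer iterations.
#' @param ard_threshold A factor counts as "on" when its variance exceeds this
#'   fraction of the summed variance parameters.
#' @param seed Integer seed controlling any stochastic pieces of the fit.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(k_max = 20L,
                       max_outer_iterations = 5L,
                       max_regulators = 10L,
                       regulator_min_genes = 5L,
                       regulator_fdr = 0.01,
                       regulator_exclusion_bp = 100000L,
                       optimizer_tol = 1e-6,
                       max_evals = 2000L,
                       ard_threshold = 0.01,
                       seed = 1L) {
  stopifnot(
    k_max >= 1, max_outer_iterations >= 1, max_regulators >= 0,
    regulator_min_genes >= 1, regulator_fdr > 0, regulator_fdr < 1,
    regulator_exclusion_bp >= 0, optimizer_tol > 0, max_evals >= 1,
    ard_threshold > 0
  )
  structure(
    list(
      k_max = as.integer(k_max),
      max_outer_iterations = as.integer(max_outer_iterations),
      max_regulators = as.integer(max_regulators),
      regulator_min_genes = as.integer(regulator_min_genes),
      regulator_fdr = regulator_fdr,
      regulator_exclusion_bp = as.integer(regulator_exclusion_bp),
      optimizer_tol = optimizer_tol,
      max_evals = as.integer(max_evals),
      ard_threshold = ard_threshold,
      seed = as.integer(seed)
    ),
    class = "fit_config"
  )
}

#' Read a fit configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [fit_config()]; unknown keys are an error,
#' absent keys keep their defaults.
#'
#' @param path Path to a YAML/JSON file.
#' @return A `fit_config`.
#' @export
read_fit_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(fit_config)))
  if (length(unknown)) {
    stop(sprintf("unknown fit config field(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(fit_config, vals)
}

# Model covariance K = X diag(s2k) X' + sum_s th_s g_s g_s' + s2c C + s2e I.
# `model` is a panama_model (or a bare list with the same fields); `dataset`
# supplies genotype columns for the regulator terms and the known covariate
# covariance C.
model_covariance <- function(model, dataset) {
  N <- nrow(model$factors)
  K <- model$factors %*% (model$factor_variances * t(model$factors))
  if (length(model$regulator_set)) {
    Gm <- dataset$geno[, model$regulator_set, drop = FALSE]
    K <- K + Gm %*% (model$regulator_variances * t(Gm))
  }
  if (!is.null(dataset$known_covariance) && model$covariate_variance > 0) {
    K <- K + model$covariate_variance * dataset$known_covariance
  }
  K <- (K + t(K)) / 2
  diag(K) <- diag(K) + model$noise_variance
  K
}

#' Marginal log-likelihood of the variance model
#'
#' Evaluates the factorised Gaussian marginal likelihood of centered
#' expression under the shared sample covariance
#' `K = sum_k s2_k x_k x_k' + sum_s th_s g_s g_s' + s2_c C + s2_e I`,
#' with factor and SNP regression weights integrated out:
#' `-GN/2 log(2 pi) - G/2 log|K| - 1/2 tr(K^-1 Y Y')`.
#'
#' @param model A `panama_model` (fitted or hand-built).
#' @param dataset A centered `eqtl_dataset` matching the model dimensions.
#' @return The scalar log-likelihood.
#' @export
marginal_log_likelihood <- function(model, dataset) {
  Y <- active_expression(dataset)
  K <- model_covariance(model, dataset)
  ll_given_K(K, Y)
}

ll_given_K <- function(K, Y) {
  N <- nrow(Y); G <- ncol(Y)
  ch <- tryCatch(chol(K), error = function(e) {
    stop(sprintf(
      "model covariance numerically singular (diag range [%.3g, %.3g]): %s",
      min(diag(K)), max(diag(K)), conditionMessage(e)), call. = FALSE)
  })
  logdet <- 2 * sum(log(diag(ch)))
  Kinv <- chol2inv(ch)
  S <- tcrossprod(Y)
  -G * N / 2 * log(2 * pi) - G / 2 * logdet - 0.5 * sum(Kinv * S)
}

# Pack/unpack the free parameters: vec(X), log s2k, log th, log s2e, [log s2c].
pack_params <- function(X, s2k, th, s2e, s2c, has_cov) {
  c(as.vector(X), log(s2k), if (length(th)) log(th), log(s2e),
    if (has_cov) log(s2c))
}

unpack_params <- function(par, N, K, R, has_cov) {
  i <- N * K
  X <- matrix(par[seq_len(i)], N, K)
  s2k <- exp(par[i + seq_len(K)]); i <- i + K
  th <- if (R > 0) exp(par[i + seq_len(R)]) else numeric(0); i <- i + R
  s2e <- exp(par[i + 1]); i <- i + 1
  s2c <- if (has_cov) exp(par[i + 1]) else 0
  list(X = X, s2k = s2k, th = th, s2e = s2e, s2c = s2c)
}

# Objective (negative log-likelihood) and analytic gradient on the packed
# parameter vector. Variances are optimized on the log scale, which keeps them
# positive and lets ARD drive unused factor variances towards -Inf in log
# space (i.e. ~0).
make_objective <- function(Y, Gmat, Cmat, N, K, R) {
  S <- tcrossprod(Y)
  G <- ncol(Y)
  has_cov <- !is.null(Cmat)

  build_K <- function(p) {
    Km <- p$X %*% (p$s2k * t(p$X))
    if (R > 0) Km <- Km + Gmat %*% (p$th * t(Gmat))
    if (has_cov) Km <- Km + p$s2c * Cmat
    Km <- (Km + t(Km)) / 2
    diag(Km) <- diag(Km) + p$s2e
    Km
  }

  fn <- function(par) {
    p <- unpack_params(par, N, K, R, has_cov)
    Km <- build_K(p)
    ch <- tryCatch(chol(Km), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    Kinv <- chol2inv(ch)
    -(-G * N / 2 * log(2 * pi) - G / 2 * logdet - 0.5 * sum(Kinv * S))
  }

  gr <- function(par) {
    p <- unpack_params(par, N, K, R, has_cov)
    Km <- build_K(p)
    ch <- tryCatch(chol(Km), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(par)))
    Kinv <- chol2inv(ch)
    # dL/dK for L the log-likelihood
    M <- -G / 2 * Kinv + 0.5 * Kinv %*% S %*% Kinv
    MX <- M %*% p$X
    gX <- 2 * MX %*% diag(p$s2k, K)
    g_s2k <- p$s2k * colSums(p$X * MX)
    g_th <- if (R > 0) {
      MG <- M %*% Gmat
      p$th * colSums(Gmat * MG)
    } else numeric(0)
    g_s2e <- p$s2e * sum(diag(M))
    g_s2c <- if (has_cov) p$s2c * sum(M * Cmat) else NULL
    -c(as.vector(gX), g_s2k, g_th, g_s2e, g_s2c)
  }

  list(fn = fn, gr = gr, has_cov = has_cov)
}

#' Gradient of the marginal log-likelihood
#'
#' Analytic gradients of the objective of [marginal_log_likelihood()] with
#' respect to the factor matrix and all log-scale variance parameters.
#' Primarily exposed for verification against finite differences.
#'
#' @inheritParams marginal_log_likelihood
#' @return A list with elements `factors` (matrix gradient), `log_factor_variances`,
#'   `log_regulator_variances`, `log_noise_variance`, `log_covariate_variance`.
#' @export
objective_gradients <- function(model, dataset) {
  Y <- active_expression(dataset)
  N <- nrow(Y)
  K <- ncol(model$factors)
  R <- length(model$regulator_set)
  Gmat <- if (R > 0) dataset$geno[, model$regulator_set, drop = FALSE] else NULL
  if (!is.null(Gmat)) storage.mode(Gmat) <- "double"
  obj <- make_objective(Y, Gmat, dataset$known_covariance, N, K, R)
  par <- pack_params(model$factors, model$factor_variances,
                     model$regulator_variances, model$noise_variance,
                     max(model$covariate_variance, 1e-300), obj$has_cov)
  g <- -obj$gr(par)  # gradient of the log-likelihood (not the negated objective)
  i <- N * K
  out <- list(
    factors = matrix(g[seq_len(i)], N, K),
    log_factor_variances = g[i + seq_len(K)]
  )
  i <- i + K
  out$log_regulator_variances <- if (R > 0) g[i + seq_len(R)] else numeric(0)
  i <- i + R
  out$log_noise_variance <- g[i + 1]
  out$log_covariate_variance <- if (obj$has_cov) g[i + 2] else numeric(0)
  out
}
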