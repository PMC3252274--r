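test_that("marginal log-likelihood matches the dense MVN density", {
  # pinned minimal case: N=2, G=1, y=0, identity covariance
  ds0 <- make_toy_dataset(N = 2, G = 1, P = 2, seed = 1)
  ds0$expr[, 1] <- c(1, -1)  # centers to a known vector
  ds0 <- center_expression(ds0)
  ds0$expr[, 1] <- c(0, 0)
  m0 <- panama_model(factors = matrix(0, 2, 1), factor_variances = 0,
                     noise_variance = 1)
  expect_equal(marginal_log_likelihood(m0, ds0), -log(2 * pi), tolerance = 1e-12)

  # a null term (factor with zero variance) changes nothing
  ds <- center_expression(make_toy_dataset(N = 8, G = 5, P = 4, seed = 3))
  m <- make_toy_model(ds, k = 2)
  m_plus <- m
  m_plus$factors <- cbind(m$factors, rnorm(8))
  m_plus$factor_variances <- c(m$factor_variances, 0)
  expect_equal(marginal_log_likelihood(m_plus, ds),
               marginal_log_likelihood(m, ds), tolerance = 1e-12)

  # random instances against the dense per-gene MVN oracle
  for (seed in 1:3) {
    ds <- center_expression(make_toy_dataset(N = 8, G = 5, P = 4, seed = seed))
    m <- make_toy_model(ds, k = 2, seed = seed,
                        regulator_set = c(1L, 3L),
                        regulator_variances = c(0.2, 0.1))
    K <- panamaqtl:::model_covariance(m, ds)
    expect_equal(marginal_log_likelihood(m, ds),
                 dense_mvn_loglik(active_expression(ds), K),
                 tolerance = 1e-8)
  }
})

test_that("analytic gradients match central finite differences", {
  N <- 6
  C <- tcrossprod(matrix(rnorm(N * 2), N)) + diag(N)
  dimnames(C) <- NULL
  ds <- make_toy_dataset(N = N, G = 4, P = 4, seed = 11, known_covariance = C)
  ds <- center_expression(ds)
  m <- make_toy_model(ds, k = 2, seed = 2, regulator_set = 2L,
                      regulator_variances = 0.3, covariate_variance = 0.15)
  g <- objective_gradients(m, ds)

  Y <- active_expression(ds)
  ll_at <- function(par) {
    p <- panamaqtl:::unpack_params(par, N, 2, 1, TRUE)
    mm <- m
    mm$factors <- p$X
    mm$factor_variances <- p$s2k
    mm$regulator_variances <- p$th
    mm$noise_variance <- p$s2e
    mm$covariate_variance <- p$s2c
    marginal_log_likelihood(mm, ds)
  }
  par <- panamaqtl:::pack_params(m$factors, m$factor_variances,
                                 m$regulator_variances, m$noise_variance,
                                 m$covariate_variance, TRUE)
  num <- finite_diff_grad(ll_at, par, h = 1e-5)
  ana <- unname(c(as.vector(g$factors), g$log_factor_variances,
                  g$log_regulator_variances, g$log_noise_variance,
                  g$log_covariate_variance))
  expect_equal(ana, num, tolerance = 1e-4)

  # a switched-off factor has zero gradient in its direction
  m_off <- m
  m_off$factor_variances <- c(m$factor_variances[1], 0)
  g_off <- objective_gradients(m_off, ds)
  expect_equal(g_off$factors[, 2], rep(0, N), tolerance = 1e-12)
})

test_that("the objective is invariant to factor/variance rescaling", {
  ds <- center_expression(make_toy_dataset(N = 10, G = 6, P = 4, seed = 8))
  m <- make_toy_model(ds, k = 3)
  ll <- marginal_log_likelihood(m, ds)
  for (c_scale in c(0.5, 2, 10)) {
    m2 <- m
    m2$factors[, 2] <- m$factors[, 2] * c_scale
    m2$factor_variances[2] <- m$factor_variances[2] / c_scale^2
    expect_equal(marginal_log_likelihood(m2, ds), ll, tolerance = 1e-10)
  }
})

test_that("the fit ascends, converges, and matches the closed-form factor-model ML", {
  sim <- simulate_eqtl_study(sim_params(
    n_samples = 60, n_genes = 300, n_snps = 20, n_cis = 0, n_hotspots = 0,
    n_confounders = 2,
    variance_shares = c(genetic = 0, confounder = 0.4, noise = 0.6), seed = 9
  ))
  ds <- center_expression(sim$dataset)
  cfg <- fit_config(k_max = 5)
  m <- fit_variance_model(ds, config = cfg)

  expect_true(all(diff(m$fit_log) >= 0))
  expect_true(m$fit_log[length(m$fit_log)] >= m$fit_log[1])
  expect_true(all(abs(colSums(m$factors^2) - n_samples(ds)) < 1e-6))

  # gradient at the optimum is small relative to the objective
  g <- objective_gradients(m, ds)
  gmax <- max(abs(c(as.vector(g$factors), g$log_factor_variances,
                    g$log_noise_variance)))
  expect_lt(gmax, 1e-3 * abs(max(m$fit_log)))

  # factor-only, no covariates: the ML solution is the probabilistic-PCA
  # eigendecomposition of the sample covariance (independent closed form)
  Y <- active_expression(ds)
  N <- nrow(Y); G <- ncol(Y); K <- 5
  ev <- eigen(tcrossprod(Y) / G, symmetric = TRUE, only.values = TRUE)$values
  s2e_cf <- mean(ev[(K + 1):N])
  s2k_cf <- pmax((ev[1:K] - s2e_cf) / N, 0)
  expect_equal(m$noise_variance, s2e_cf, tolerance = 1e-3)
  expect_equal(sort(m$factor_variances, decreasing = TRUE), s2k_cf,
               tolerance = 1e-2)
})

test_that("ARD recovers the planted factor dimensionality", {
  # one confounder: exactly one factor stays on, in at least 9/10 seeds
  hits <- 0L
  for (seed in 1:10) {
    sim <- simulate_eqtl_study(sim_params(
      n_samples = 100, n_genes = 500, n_snps = 20, n_cis = 0, n_hotspots = 0,
      n_confounders = 1,
      variance_shares = c(genetic = 0, confounder = 0.4, noise = 0.6),
      seed = 400 + seed
    ))
    m <- fit_variance_model(center_expression(sim$dataset),
                            config = fit_config(k_max = 5))
    if (effective_num_factors(m) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)

  # pure noise: everything off
  sim0 <- simulate_eqtl_study(sim_params(
    n_samples = 50, n_genes = 2000, n_snps = 20, n_cis = 0, n_hotspots = 0,
    n_confounders = 0,
    variance_shares = c(genetic = 0, confounder = 0, noise = 1), seed = 12
  ))
  m0 <- fit_variance_model(center_expression(sim0$dataset),
                           config = fit_config(k_max = 5))
  expect_identical(effective_num_factors(m0), 0L)
})

test_that("effective_num_factors applies the documented threshold", {
  ds <- center_expression(make_toy_dataset())
  m <- make_toy_model(ds, k = 3)
  m$factor_variances <- c(0, 0, 0)
  m$noise_variance <- 1
  expect_identical(effective_num_factors(m), 0L)
  m$factor_variances <- c(10, 0, 0)
  expect_identical(effective_num_factors(m, ard_threshold = 0.01), 1L)
})

test_that("regulator selection finds a planted hotspot and honours its knobs", {
  sim <- simulate_eqtl_study(sim_params(
    n_samples = 80, n_genes = 200, n_snps = 60, n_chromosomes = 3,
    n_cis = 30, n_hotspots = 2, targets_per_hotspot = 15, n_confounders = 2,
    snp_spacing_bp = 10000,
    variance_shares = c(genetic = 0.3, confounder = 0.3, noise = 0.4),
    seed = 31
  ))
  ds <- center_expression(sim$dataset)
  cfg <- fit_config(k_max = 8)
  m <- fit_variance_model(ds, config = cfg)
  sel <- select_regulators(ds, m, cfg)
  expect_gte(length(sel), 1L)
  hots <- unique(sim$truth$effects$snp_id[sim$truth$effects$label == "trans"])
  hot_rows <- ds$snps[match(hots, ds$snps$snp_id), ]
  top <- ds$snps[sel[1], ]
  same <- hot_rows$chrom == top$chrom
  expect_true(any(same) &&
                min(abs(hot_rows$pos[same] - top$pos)) <= cfg$regulator_exclusion_bp)

  # disabled feature: no regulators, downstream fit equals the factor-only fit
  cfg0 <- fit_config(k_max = 8, max_regulators = 0)
  expect_identical(select_regulators(ds, m, cfg0), integer(0))
  full0 <- fit_panama(ds, cfg0)
  expect_identical(full0$regulator_set, integer(0))
  expect_equal(max(full0$fit_log), max(fit_variance_model(ds, config = cfg0)$fit_log),
               tolerance = 1e-8)
})

test_that("the outer loop stops at a regulator fixed point", {
  sim <- simulate_eqtl_study(sim_params(
    n_samples = 50, n_genes = 80, n_snps = 40, n_chromosomes = 2,
    n_cis = 0, n_hotspots = 0, n_confounders = 1, snp_spacing_bp = 10000,
    variance_shares = c(genetic = 0, confounder = 0.3, noise = 0.7), seed = 17
  ))
  ds <- center_expression(sim$dataset)
  m <- fit_panama(ds, fit_config(k_max = 4))
  expect_identical(m$regulator_set, integer(0))
  expect_identical(length(m$iterations), 1L)  # no genetic effects: one pass
})

test_that("build_covariance composes the documented terms and stays PSD", {
  ds <- center_expression(make_toy_dataset(N = 3, G = 4, P = 4, seed = 19))
  m <- make_toy_model(ds, k = 2, seed = 5)
  # hand-computed rank-1 sums on a 3-sample instance
  K_hand <- m$factor_variances[1] * tcrossprod(m$factors[, 1]) +
    m$factor_variances[2] * tcrossprod(m$factors[, 2])
  cp <- build_covariance(m, "panama", ds)
  expect_equal(unname(cp$matrix), K_hand, tolerance = 1e-12)

  m_reg <- make_toy_model(ds, k = 2, seed = 5, regulator_set = 2L,
                          regulator_variances = 0.4)
  g <- as.numeric(ds$geno[, 2])
  ct <- build_covariance(m_reg, "panama_trans", ds)
  expect_equal(unname(ct$matrix), K_hand + 0.4 * tcrossprod(g), tolerance = 1e-12)

  # empty regulator set: panama and panama_trans coincide
  expect_equal(build_covariance(m, "panama_trans", ds)$matrix, cp$matrix,
               tolerance = 1e-12)
  # linear mode is the zero matrix; all modes PSD
  cl <- build_covariance(m_reg, "linear", ds)
  expect_true(all(cl$matrix == 0))
  for (mode in c("panama", "panama_trans", "linear")) {
    K <- build_covariance(m_reg, mode, ds)$matrix
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
  expect_error(build_covariance(m, "bogus", ds))
})
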