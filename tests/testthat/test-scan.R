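test_that("rotation reproduces the covariance and rejects bad inputs", {
  N <- 7
  expect_equal(rotate(diag(N))$values, rep(1, N))
  x <- rnorm(N)
  x <- x * sqrt(N) / sqrt(sum(x^2))
  r1 <- rotate(tcrossprod(x))
  expect_equal(sort(r1$values, decreasing = TRUE), c(N, rep(0, N - 1)),
               tolerance = 1e-10)
  for (seed in 1:3) {
    set.seed(seed)
    K <- tcrossprod(matrix(rnorm(N * 3), N))
    r <- rotate(K)
    expect_equal(r$U %*% (r$values * t(r$U)), K, tolerance = 1e-10)
  }
  K_bad <- diag(N)
  K_bad[1, 2] <- 1e-4
  expect_error(rotate(K_bad), "symmetric")
})

test_that("profiled likelihood matches brute-force joint optimization", {
  N <- 6
  set.seed(21)
  K <- tcrossprod(matrix(rnorm(N * 2), N))
  y <- rnorm(N)
  F <- cbind(1, rbinom(N, 1, 0.5) + 0.0)
  F[1, 2] <- 1  # guard against a constant column
  rot <- rotate(K)
  y_rot <- crossprod(rot$U, y)[, 1]
  F_rot <- crossprod(rot$U, F)
  for (delta in c(0.1, 1, 10)) {
    ours <- profiled_loglik(y_rot, F_rot, rot$values, delta)
    bf <- brute_force_profiled(y, F, K, delta)
    expect_equal(ours$loglik, bf$loglik, tolerance = 1e-8)
    expect_equal(ours$beta, bf$beta, tolerance = 1e-4)
    # GLS normal equations: residuals orthogonal to the design in the
    # (K + delta I)^-1 inner product
    r <- y - F %*% ours$beta
    W <- solve(K + delta * diag(N))
    expect_equal(as.vector(t(F) %*% W %*% r), c(0, 0), tolerance = 1e-8)
  }
  expect_error(profiled_loglik(y_rot, cbind(F_rot[, 1], F_rot[, 1]),
                               rot$values, 1), "collinear")
})

test_that("with zero covariance the profiled likelihood is the OLS ML likelihood", {
  N <- 9
  set.seed(4)
  y <- rnorm(N)
  F <- cbind(1, rnorm(N))
  vals <- rep(0, N)  # K = 0: delta cancels out of the profile
  lls <- vapply(c(1e-4, 1, 1e4), function(d) {
    profiled_loglik(y, F, vals, d)$loglik
  }, numeric(1))
  fit <- lm(y ~ F - 1)
  s2 <- sum(residuals(fit)^2) / N
  ll_ols <- -N / 2 * (log(2 * pi) + 1 + log(s2))
  expect_equal(lls, rep(ll_ols, 3), tolerance = 1e-10)
})

test_that("single-pair LRT matches a dense brute-force optimizer", {
  N <- 10
  for (seed in 1:4) {
    set.seed(seed)
    K <- tcrossprod(matrix(rnorm(N * 2), N)) / 2
    y <- rnorm(N) + 0.5 * rbinom(N, 1, 0.5)
    snp <- rbinom(N, 1, 0.5)
    if (var(snp) == 0) snp[1] <- 1 - snp[1]
    rot <- rotate(K)
    ours <- lrt_single(y, snp, rot)
    expect_equal(ours$lrt, brute_force_lrt(y, snp, K), tolerance = 1e-6)
    expect_gte(ours$lrt, 0)
    expect_equal(ours$p, pchisq(ours$lrt, 1, lower.tail = FALSE), tolerance = 1e-12)
  }
  expect_error(lrt_single(rnorm(N), rep(1, N), rotate(diag(N))), "constant")
})

test_that("the compiled genome-wide scan agrees with the reference single tests", {
  sim <- simulate_eqtl_study(sim_params(
    n_samples = 20, n_genes = 6, n_snps = 10, n_chromosomes = 2,
    n_cis = 2, n_hotspots = 1, targets_per_hotspot = 2, n_confounders = 1,
    snp_spacing_bp = 20000, seed = 13
  ))
  ds <- center_expression(sim$dataset)
  m <- fit_variance_model(ds, config = fit_config(k_max = 3))
  cov <- build_covariance(m, "panama", ds)
  tab <- panama_scan(ds, cov)
  expect_identical(nrow(tab), n_genes(ds) * n_snps(ds))
  rot <- rotate(cov)
  for (i in sample(nrow(tab), 12)) {
    single <- lrt_single(ds$expr[, tab$gene_id[i]], ds$geno[, tab$snp_id[i]], rot)
    expect_equal(tab$lrt[i], single$lrt, tolerance = 1e-6)
    expect_equal(tab$beta[i], single$beta, tolerance = 1e-4)
  }
})

test_that("a consistent sample permutation leaves the scan invariant", {
  sim <- simulate_eqtl_study(sim_params(
    n_samples = 25, n_genes = 8, n_snps = 8, n_chromosomes = 2,
    n_cis = 2, n_hotspots = 0, n_confounders = 1, snp_spacing_bp = 20000,
    seed = 23
  ))
  ds <- center_expression(sim$dataset)
  m <- fit_variance_model(ds, config = fit_config(k_max = 2))
  cov <- build_covariance(m, "panama", ds)
  tab <- panama_scan(ds, cov)

  perm <- sample(n_samples(ds))
  ds_p <- ds
  ds_p$expr <- ds$expr[perm, ]
  ds_p$geno <- ds$geno[perm, ]
  cov_p <- cov
  cov_p$matrix <- cov$matrix[perm, perm]
  tab_p <- panama_scan(ds_p, cov_p)
  expect_equal(tab_p$lrt, tab$lrt, tolerance = 1e-8)
})

test_that("with zero covariance the scan reproduces OLS likelihood-ratio tests", {
  sim <- simulate_eqtl_study(sim_params(
    n_samples = 30, n_genes = 5, n_snps = 6, n_chromosomes = 2,
    n_cis = 1, n_hotspots = 0, n_confounders = 0, snp_spacing_bp = 20000,
    variance_shares = c(genetic = 0.3, confounder = 0, noise = 0.7), seed = 29
  ))
  ds <- center_expression(sim$dataset)
  tab <- panama_scan(ds, baseline_covariance(ds, "linear"))
  N <- n_samples(ds)
  for (i in seq_len(nrow(tab))) {
    y <- ds$expr[, tab$gene_id[i]]
    g <- ds$geno[, tab$snp_id[i]]
    rss1 <- sum(residuals(lm(y ~ g))^2)
    rss0 <- sum(residuals(lm(y ~ 1))^2)
    expect_equal(tab$lrt[i], N * log(rss0 / rss1), tolerance = 1e-8)
  }
})

test_that("constant SNPs are skipped and recorded", {
  ds <- make_toy_dataset(N = 10, G = 3, P = 4, seed = 3)
  ds$geno[, 2] <- 1L
  ds <- eqtl_dataset(ds$expr, ds$geno, ds$snps, ds$genes)
  ds <- center_expression(ds)
  tab <- panama_scan(ds, baseline_covariance(ds, "linear"))
  expect_identical(attr(tab, "skipped_snps"), "m02")
  expect_identical(nrow(tab), 3L * 3L)
  expect_false("m02" %in% tab$snp_id)
})

test_that("cis/trans classification follows the distance-to-ORF rule", {
  # 7 kb upstream of the ORF on the same chromosome: cis
  expect_identical(
    classify_cis_trans("chr1", 5000L, "chr1", 12000L, 13000L), "cis")
  expect_identical(
    snp_gene_distance("chr1", 5000L, "chr1", 12000L, 13000L), 7000L)
  # inside the ORF: distance 0, cis
  expect_identical(snp_gene_distance("chr1", 12500L, "chr1", 12000L, 13000L), 0L)
  expect_identical(classify_cis_trans("chr1", 12500L, "chr1", 12000L, 13000L), "cis")
  # just outside the window: trans; different chromosome: always trans
  expect_identical(
    classify_cis_trans("chr1", 1000L, "chr1", 12000L, 13000L), "trans")
  expect_identical(
    classify_cis_trans("chr2", 12500L, "chr1", 12000L, 13000L), "trans")
  expect_error(classify_cis_trans(NA, 1L, "chr1", 1L, 2L), "missing annotation")
})

test_that("BH q-values follow the step-up rule and ignore input order", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.9)), c(0.04, 0.04, 0.04, 0.9))
  set.seed(6)
  p <- runif(50)^2
  perm <- sample(50)
  expect_equal(sort(bh_fdr(p)), sort(bh_fdr(p[perm])))
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("association counting applies the per-gene / per-chromosome caps", {
  toy <- tibble::tibble(
    gene_id = c("g1", "g1", "g1", "g1", "g2", "g2", "g3"),
    snp_id  = c("m1", "m2", "m3", "m4", "m5", "m6", "m7"),
    chrom   = c("c1", "c1", "c2", "c3", "c1", "c1", "c2"),
    pos     = c(1L, 2L, 3L, 4L, 5L, 6L, 7L),
    beta = 1, lrt = 10,
    p = c(.001, .002, .001, .003, .001, .2, .4),
    q = c(.01, .02, .01, .03, .01, .6, .9),
    label = c("cis", "cis", "trans", "trans", "trans", "trans", "cis")
  )
  ct <- count_associations(toy, fdr_cutoff = 0.05)
  # g1: two significant cis SNPs count once; trans on chr2+chr3 count twice
  # g2: one significant trans; g3: nothing significant
  expect_identical(ct$cis_count, 1L)
  expect_identical(ct$trans_count, 3L)

  # brute-force enumeration over genes and chromosomes agrees
  sig <- toy[toy$q <= 0.05, ]
  cis_bf <- length(unique(sig$gene_id[sig$label == "cis"]))
  trans_bf <- nrow(unique(sig[sig$label == "trans", c("gene_id", "chrom")]))
  expect_identical(ct$cis_count, cis_bf)
  expect_identical(ct$trans_count, trans_bf)
})

test_that("the inflation factor is the LRT median over the chi-square(1) median", {
  med <- qchisq(0.5, df = 1)
  expect_equal(inflation_factor(rep(med, 11)), 1.0)
  set.seed(10)
  x <- rchisq(501, df = 1)
  expect_equal(inflation_factor(2 * x), 2 * inflation_factor(x), tolerance = 1e-12)
  y <- rchisq(1e5, df = 1)
  expect_gt(inflation_factor(y), 0.97)
  expect_lt(inflation_factor(y), 1.03)
})

test_that("null scans give uniform p-values and calibrated lambda", {
  ks_pass <- 0L
  lrt_all <- numeric(0)
  for (seed in 1:10) {
    sim <- simulate_eqtl_study(sim_params(
      n_samples = 60, n_genes = 40, n_snps = 50, n_chromosomes = 2,
      recomb_prob = 0.5, n_cis = 0, n_hotspots = 0, n_confounders = 0,
      variance_shares = c(genetic = 0, confounder = 0, noise = 1),
      seed = 600 + seed
    ))
    ds <- center_expression(sim$dataset)
    tab <- panama_scan(ds, baseline_covariance(ds, "linear"))
    ks <- suppressWarnings(ks.test(tab$p, "punif"))
    if (ks$p.value > 0.01) ks_pass <- ks_pass + 1L
    lrt_all <- c(lrt_all, tab$lrt)
  }
  expect_gte(ks_pass, 9L)
  lam <- inflation_factor(lrt_all)
  expect_gt(lam, 0.9)
  expect_lt(lam, 1.1)
})
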