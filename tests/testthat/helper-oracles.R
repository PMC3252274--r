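# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths (Cholesky trace identities, rotation):
# densities go through mvtnorm / eigen, optimizations through stats::optim.

# Dense multivariate-normal log-density, summed over the columns of Y.
dense_mvn_loglik <- function(Y, K) {
  Y <- as.matrix(Y)
  sum(mvtnorm::dmvnorm(t(Y), sigma = K, log = TRUE))
}

# Central finite differences of f at x.
finite_diff_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Log-likelihood of y ~ N(F b, s2 (K + delta I)) by direct dense evaluation.
dense_profile_point <- function(y, F, K, delta, beta, sigma2) {
  V <- sigma2 * (K + delta * diag(length(y)))
  mvtnorm::dmvnorm(y, mean = as.vector(F %*% beta), sigma = V, log = TRUE)
}

# Brute-force joint ML over (beta, log sigma2) at fixed delta.
brute_force_profiled <- function(y, F, K, delta) {
  p <- ncol(F)
  obj <- function(par) {
    -dense_profile_point(y, F, K, delta, par[seq_len(p)], exp(par[p + 1]))
  }
  fit <- stats::optim(c(rep(0, p), 0), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  list(loglik = -fit$value, beta = fit$par[seq_len(p)],
       sigma2 = exp(fit$par[p + 1]))
}

# Brute-force LRT: numerically optimize delta (on log scale) for null and
# alternative models through the dense path.
brute_force_lrt <- function(y, snp, K) {
  N <- length(y)
  ll_at <- function(F, log_delta) {
    delta <- exp(log_delta)
    W <- solve(K + delta * diag(N))
    A <- t(F) %*% W %*% F
    b <- t(F) %*% W %*% y
    beta <- solve(A, b)
    r <- y - F %*% beta
    s2 <- as.numeric(t(r) %*% W %*% r) / N
    as.numeric(
      -N / 2 * log(2 * pi) - N / 2 - N / 2 * log(s2) -
        0.5 * determinant(K + delta * diag(N))$modulus
    )
  }
  # same search domain as the scan's delta grid
  F0 <- matrix(1, N, 1)
  F1 <- cbind(1, snp)
  o0 <- stats::optimize(function(ld) ll_at(F0, ld), c(log(1e-5), log(1e5)),
                        maximum = TRUE, tol = 1e-10)
  o1 <- stats::optimize(function(ld) ll_at(F1, ld), c(log(1e-5), log(1e5)),
                        maximum = TRUE, tol = 1e-10)
  ll1 <- max(o1$objective, ll_at(F1, o0$maximum))
  max(2 * (ll1 - o0$objective), 0)
}

# Small deterministic dataset with hand-buildable structure.
make_toy_dataset <- function(N = 12, G = 6, P = 8, seed = 42,
                             known_covariance = NULL) {
  set.seed(seed)
  expr <- matrix(rnorm(N * G), N, G,
                 dimnames = list(sprintf("s%02d", 1:N), sprintf("g%02d", 1:G)))
  geno <- matrix(rbinom(N * P, 1, 0.5), N, P,
                 dimnames = list(sprintf("s%02d", 1:N), sprintf("m%02d", 1:P)))
  # ensure no constant SNPs
  for (j in seq_len(P)) {
    if (length(unique(geno[, j])) == 1) geno[1, j] <- 1L - geno[1, j]
  }
  snps <- tibble::tibble(
    snp_id = colnames(geno),
    chrom = rep(c("chr1", "chr2"), length.out = P),
    pos = rep(seq(5000, by = 20000, length.out = ceiling(P / 2)), each = 2)[1:P]
  )
  genes <- tibble::tibble(
    gene_id = colnames(expr),
    chrom = rep(c("chr1", "chr2"), length.out = G),
    start = seq(2000, by = 30000, length.out = G),
    end = seq(2000, by = 30000, length.out = G) + 1500
  )
  eqtl_dataset(expr, geno, snps, genes, known_covariance = known_covariance)
}

# Hand-built model over a dataset (factors scaled to norm^2 = N).
make_toy_model <- function(dataset, k = 2, seed = 7, regulator_set = integer(0),
                           regulator_variances = numeric(0),
                           noise_variance = 0.8, covariate_variance = 0) {
  set.seed(seed)
  N <- nrow(dataset$expr)
  X <- matrix(rnorm(N * k), N, k)
  X <- sweep(X, 2, sqrt(colSums(X^2) / N), "/")
  panama_model(
    factors = X,
    factor_variances = seq_len(k) / 10,
    regulator_set = regulator_set,
    regulator_ids = dataset$snps$snp_id[regulator_set],
    regulator_variances = regulator_variances,
    noise_variance = noise_variance,
    covariate_variance = covariate_variance
  )
}
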