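#' Tidy a fitted variance model
#'
#' One row per variance component: each candidate factor (with its ARD
#' on/off status), each selected regulator, the known-covariate term when
#' present, and the noise.
#'
#' @param x A `panama_model`.
#' @param ... Unused.
#' @return A tibble with `term`, `type`, `variance`, `share`, `effective`.
#' @export
tidy.panama_model <- function(x, ...) {
  terms <- tibble::tibble(
    term = c(
      sprintf("factor_%02d", seq_along(x$factor_variances)),
      if (length(x$regulator_ids)) x$regulator_ids,
      if (x$covariate_variance > 0) "known_covariates",
      "noise"
    ),
    type = c(
      rep("factor", length(x$factor_variances)),
      rep("regulator", length(x$regulator_ids)),
      if (x$covariate_variance > 0) "covariate",
      "noise"
    ),
    variance = c(
      x$factor_variances,
      x$regulator_variances,
      if (x$covariate_variance > 0) x$covariate_variance,
      x$noise_variance
    )
  )
  total <- sum(terms$variance)
  terms |>
    dplyr::mutate(
      share = .data$variance / total,
      effective = .data$type != "factor" |
        .data$variance > x$config$ard_threshold * total
    )
}

#' Glance at a fitted variance model
#'
#' @param x A `panama_model`.
#' @param ... Unused.
#' @return A one-row tibble: objective, effective factor count, regulator
#'   count, noise variance, convergence status, outer iterations.
#' @export
glance.panama_model <- function(x, ...) {
  tibble::tibble(
    logLik = if (length(x$fit_log)) max(x$fit_log) else NA_real_,
    n_factors = ncol(x$factors),
    n_factors_effective = effective_num_factors(x),
    n_regulators = length(x$regulator_set),
    noise_variance = x$noise_variance,
    covariate_variance = x$covariate_variance,
    converged = x$converged,
    n_outer_iterations = length(x$iterations)
  )
}

#' Tidy an association table
#'
#' The scan result is already tabular; `tidy()` strips the class and
#' attributes, returning a plain tibble.
#'
#' @param x A `panama_assoc` table.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.panama_assoc <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Glance at an association scan
#'
#' @param x A `panama_assoc` table.
#' @param fdr_cutoff Cutoff for the summarised counts.
#' @param ... Unused.
#' @return A one-row tibble: test count, inflation factor, linkage-aware
#'   cis/trans counts at `fdr_cutoff`.
#' @export
glance.panama_assoc <- function(x, fdr_cutoff = 0.05, ...) {
  ct <- count_associations(x, fdr_cutoff)
  tibble::tibble(
    n_tests = nrow(x),
    lambda = inflation_factor(x$lrt),
    fdr_cutoff = fdr_cutoff,
    cis_count = ct$cis_count,
    trans_count = ct$trans_count
  )
}
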