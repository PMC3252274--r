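MODEL_FORMAT_VERSION <- "1"

#' Save / load a fitted model
#'
#' A model is stored as a directory holding a JSON manifest (format version,
#' all scalar parameters, regulator IDs, config echo, fit log) plus a TSV
#' payload for the factor matrix. The round trip is lossless at text
#' precision.
#'
#' @param model A `panama_model`.
#' @param path Directory to write to (created if needed).
#' @return `path` invisibly (save); a `panama_model` (load).
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format_version = MODEL_FORMAT_VERSION,
    n_samples = nrow(model$factors),
    k_max = ncol(model$factors),
    factor_variances = model$factor_variances,
    regulator_set = model$regulator_set,
    regulator_ids = model$regulator_ids,
    regulator_variances = model$regulator_variances,
    noise_variance = model$noise_variance,
    covariate_variance = model$covariate_variance,
    fit_log = model$fit_log,
    converged = model$converged,
    config = unclass(model$config),
    iterations = model$iterations
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  fac <- tibble::as_tibble(model$factors, .name_repair = ~ sprintf("factor_%02d", seq_along(.x)))
  if (!is.null(rownames(model$factors))) {
    fac <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(model$factors)), fac)
  }
  readr::write_tsv(fac, file.path(path, "factors.tsv"), progress = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) stop(sprintf("no model manifest at %s", path))
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(as.character(m$format_version), MODEL_FORMAT_VERSION)) {
    stop(sprintf("model format version mismatch: file has '%s', package reads '%s'",
                 m$format_version, MODEL_FORMAT_VERSION))
  }
  fac_df <- readr::read_tsv(file.path(path, "factors.tsv"),
                            show_col_types = FALSE, progress = FALSE)
  sample_ids <- NULL
  if ("sample_id" %in% names(fac_df)) {
    sample_ids <- fac_df$sample_id
    fac_df$sample_id <- NULL
  }
  factors <- as.matrix(fac_df)
  rownames(factors) <- sample_ids
  if (nrow(factors) != m$n_samples || ncol(factors) != m$k_max) {
    stop("model payload does not match its manifest (truncated file?)")
  }
  as_num <- function(x) if (length(x)) as.numeric(x) else numeric(0)
  panama_model(
    factors = factors,
    factor_variances = as_num(m$factor_variances),
    regulator_set = if (length(m$regulator_set)) as.integer(m$regulator_set) else integer(0),
    regulator_ids = if (length(m$regulator_ids)) as.character(m$regulator_ids) else character(0),
    regulator_variances = as_num(m$regulator_variances),
    noise_variance = m$noise_variance,
    covariate_variance = m$covariate_variance,
    fit_log = as_num(m$fit_log),
    config = do.call(fit_config, m$config),
    converged = m$converged,
    iterations = if (is.null(m$iterations)) list() else m$iterations
  )
}
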