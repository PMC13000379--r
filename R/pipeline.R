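#' End-to-end pipeline configuration
#'
#' Bundles the stage parameters of the full pipeline: the synthetic-cohort
#' generator, the episode gap and rolling-window lengths, label
#' definitions, feature-hash width, the boosted-tree configuration and the
#' multilabel strategy.
#'
#' @param generator A [generator_config()].
#' @param gap_days Episode gap threshold in days (default 30).
#' @param window_days Rolling-window length in days (default 90).
#' @param label_specs Named list of label [code_spec()]s.
#' @param hash_bits Feature-hash width exponent (default 18).
#' @param model A [model_config()].
#' @param strategy `"cc"` (classifier-chain ensemble, default) or `"ovr"`.
#' @param n_chains Chain-ensemble size (default 5).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(generator = generator_config(n_patients = 10000L),
                            gap_days = 30L, window_days = 90L,
                            label_specs = default_label_specs(),
                            hash_bits = 18L,
                            model = model_config(),
                            strategy = c("cc", "ovr"),
                            n_chains = 5L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(generator, "generator_config"),
            inherits(model, "model_config"), gap_days > 0, window_days > 0)
  structure(list(generator = generator, gap_days = as.integer(gap_days),
                 window_days = as.integer(window_days),
                 label_specs = label_specs, hash_bits = as.integer(hash_bits),
                 model = model, strategy = strategy,
                 n_chains = as.integer(n_chains)),
            class = "pipeline_config")
}

#' Prepare modeling inputs from a raw encounter table
#'
#' Runs the preprocessing chain — date standardization, sex cleansing,
#' deduplication — then builds the patient-level label matrix and the
#' hashed feature matrix with defining codes excluded.
#'
#' @param raw_table Raw (possibly messy) encounter table.
#' @param config A [pipeline_config()].
#' @return List: `X` (sparse hashed features), `Y` (binary labels), `table`
#'   (the deduplicated event table), `reports` (per-stage drop reports).
#' @export
prepare_model_inputs <- function(raw_table, config = pipeline_config()) {
  std <- standardize_dates(raw_table)
  cln <- cleanse(std$table)
  ded <- deduplicate(cln$table)
  sets <- patient_code_multisets(ded, exclude = config$label_specs)
  X <- hash_features(sets, n_bits = config$hash_bits)
  Y <- build_label_matrix(ded, config$label_specs)
  Y <- Y[rownames(X), , drop = FALSE]
  list(X = X, Y = Y, table = ded,
       reports = list(dates = std$report, cleanse = cln$report))
}

fit_pipeline_model <- function(X, Y, config) {
  if (config$strategy == "ovr") {
    fit_ovr(X, Y, config = config$model)
  } else {
    fit_cc_ensemble(X, Y, orderings = NULL, config = config$model)
  }
}
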