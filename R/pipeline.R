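# Run configuration and the end-to-end pipeline: curate -> split ->
# strategy -> train -> evaluate -> compare, with a provenance manifest.

# derive a stage-specific seed from the global one (stable string hash)
derive_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483629)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}

#' Load / validate a run configuration
#'
#' A run configuration is a single YAML document (or an equivalent named
#' list) with top-level fields `seed`, `out_dir`, and one of `input`
#' (a raw bioactivity CSV/TSV) or `synthetic` (arguments of
#' [synthetic_spec()]); optional fields `curation`, `fingerprint`, `dnn`,
#' `charrnn`, `strategies`, `k_folds`, `train_fraction` override module
#' defaults.
#'
#' @param x path to a YAML file, or a named list.
#' @return validated configuration list.
#' @export
load_run_config <- function(x) {
  config <- if (is.character(x)) yaml::read_yaml(x) else x
  for (field in c("seed", "out_dir")) {
    if (is.null(config[[field]])) stop("config is missing required field: ", field)
  }
  if (is.null(config$input) && is.null(config$synthetic)) {
    stop("config is missing required field: input (or synthetic)")
  }
  if (is.null(config$strategies)) config$strategies <- c("none")
  if (is.null(config$k_folds)) config$k_folds <- 10L
  if (is.null(config$train_fraction)) config$train_fraction <- 0.8
  config
}

#' Execute the full pipeline
#'
#' Stages: obtain the curated dataset (from a file or the synthetic
#' generator), scaffold-split with post-split fingerprint dedup, run
#' stratified cross-validation for each configured strategy with the
#' scaffold test set as an external surface, and compare strategies with
#' the Friedman / Conover-Friedman protocol on MCC, ROC AUC and G-mean.
#' Every output lands in `out_dir` together with a manifest recording the
#' configuration hash and derived seeds.
#'
#' @param config a path or list accepted by [load_run_config()].
#' @return (invisibly) the output directory.
#' @export
run_pipeline <- function(config) {
  config <- load_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "init"
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   r_version = as.character(getRversion()),
                   stages = list())
  fail <- function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         " (partial outputs kept in ", out_dir, ")", call. = FALSE)
  }
  tryCatch({
    stage <- "curate"
    fpcfg <- do.call(fp_config, as.list(config$fingerprint))
    ds <- if (!is.null(config$input)) {
      cur <- do.call(curation_config, as.list(config$curation))
      build_dataset(config$input, cur)
    } else {
      args <- as.list(config$synthetic)
      args$seed <- derive_seed(config$seed, "synthetic")
      generate_dataset(do.call(synthetic_spec, args))$dataset
    }
    write_dataset(ds, file.path(out_dir, "curated.csv"),
                  file.path(out_dir, "curation_log.json"))
    manifest$stages$curate <- list(n = nrow(ds))

    stage <- "split"
    split <- scaffold_split(ds, config$train_fraction)
    split <- remove_cross_split_duplicates(split, fpcfg)
    write_dataset(split$train, file.path(out_dir, "train.csv"))
    write_dataset(split$test, file.path(out_dir, "test.csv"))
    manifest$stages$split <- list(n_train = nrow(split$train),
                                  n_test = nrow(split$test),
                                  n_dedup_removed = attr(split, "n_removed"))

    stage <- "cross_validate"
    folds <- stratified_kfold(split$train, config$k_folds,
                              derive_seed(config$seed, "folds"))
    dnn_cfg <- do.call(dnn_config, c(list(input_width = fpcfg$n_bits),
                                     as.list(config$dnn)))
    reports <- lapply(config$strategies, function(strategy) {
      spec <- list(model = "dnn", strategy = strategy, dnn_cfg = dnn_cfg)
      if (strategy == "generator_augment") {
        spec$charrnn_cfg <- do.call(charrnn_config, as.list(config$charrnn))
      }
      if (strategy == "transfer") {
        if (is.null(config$source_model_dir)) {
          stop("transfer strategy requires source_model_dir")
        }
        spec$source_model <- load_model(config$source_model_dir)
      }
      cross_validate(split$train, folds, spec,
                     external_tests = list(scaffold_test = split$test),
                     config = fpcfg)
    })
    report <- do.call(rbind, reports)
    utils::write.csv(report, file.path(out_dir, "evaluation.csv"),
                     row.names = FALSE)

    stage <- "compare"
    comparison <- NULL
    if (length(config$strategies) >= 3) {
      tables <- lapply(c(mcc = "mcc", roc_auc = "roc_auc", gmean = "gmean"),
                       function(m) metric_table(report, m))
      fr <- lapply(tables, friedman_test)
      posthoc <- lapply(tables, conover_posthoc)
      verdicts <- declare_better(tables)
      comparison <- list(friedman = fr, conover = posthoc, better = verdicts)
      jsonlite::write_json(
        list(friedman = fr,
             conover = lapply(posthoc, function(m) as.data.frame(m)),
             better = as.data.frame(verdicts)),
        file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA)
    }
    manifest$stages$evaluate <- list(n_rows = nrow(report))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(out_dir)
  }, error = fail)
}
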