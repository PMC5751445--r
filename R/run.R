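# Orchestration commands behind the `ssgc` command-line script: simulate,
# similarity, fuse, predict, evaluate. Each command takes a run config
# (defaults pre-filled with the method's standard parameters), writes its
# outputs into the config's output directory and drops a JSON manifest
# (config echo, package version, seed, timing) so a run can be repeated
# exactly.

#' Default run configuration
#'
#' Top-level keys: `data_dir` (dataset directory in the formats of
#' [write_dataset()]), `out_dir`, `seed`, `mode` (`"ssgc"` or `"hgbi"`),
#' `layers` (`"base"`, `"base+gene"`, `"base+gene+treatment"` or `"all"`),
#' `prior`, `k_folds`, `hold_out_fraction`, `pipeline` (options forwarded to
#' [pipeline_options()]) and `synthetic` (overrides for
#' [synthetic_config()]). Unknown keys are an error naming the key.
#'
#' @param ... overrides (possibly nested lists for `pipeline`/`synthetic`).
#' @param file optional YAML or JSON config file merged before `...`.
#' @return validated config list.
#' @export
ssgc_config <- function(..., file = NULL) {
  defaults <- list(
    data_dir = NULL, out_dir = NULL, seed = 1L,
    mode = "ssgc", layers = "all", prior = TRUE,
    k_folds = 10L, hold_out_fraction = 0.1,
    pipeline = list(), synthetic = list()
  )
  cfg <- defaults
  merge_in <- function(cfg, over, where = "config") {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
    utils::modifyList(cfg, over)
  }
  if (!is.null(file)) {
    over <- if (grepl("\\.json$", file)) jsonlite::read_json(file, simplifyVector = TRUE)
            else yaml::read_yaml(file)
    cfg <- merge_in(cfg, over)
  }
  cfg <- merge_in(cfg, list(...))
  if (!cfg$mode %in% c("ssgc", "hgbi")) stop("mode must be 'ssgc' or 'hgbi'")
  if (!cfg$layers %in% c("base", "base+gene", "base+gene+treatment", "all"))
    stop("layers must be one of base, base+gene, base+gene+treatment, all")
  do.call(pipeline_options, cfg$pipeline)           # validates pipeline keys
  do.call(synthetic_config, cfg$synthetic)          # validates synthetic keys
  cfg
}

#' @keywords internal
layer_set <- function(layers) {
  switch(layers,
         "base" = "base",
         "base+gene" = c("base", "gene"),
         "base+gene+treatment" = ,
         "all" = c("base", "gene", "treatment"))
}

#' @keywords internal
run_manifest <- function(cfg, out_dir, command, t0, extra = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(list(command = command, config = cfg,
                     package_version = as.character(utils::packageVersion("ssgc")),
                     seed = cfg$seed,
                     elapsed_sec = as.numeric(Sys.time()) - t0), extra)
  jsonlite::write_json(manifest, file.path(out_dir, paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' @keywords internal
load_run_dataset <- function(cfg) {
  if (is.null(cfg$data_dir)) stop("config needs data_dir")
  read_dataset(cfg$data_dir)
}

#' Generate and write a synthetic dataset (CLI `simulate`)
#' @param cfg a [ssgc_config()]; uses `synthetic`, `seed`, `out_dir`.
#' @return the generated dataset, invisibly.
#' @export
run_simulate <- function(cfg = ssgc_config()) {
  t0 <- as.numeric(Sys.time())
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  synth <- do.call(synthetic_config, utils::modifyList(list(seed = cfg$seed),
                                                       cfg$synthetic))
  dataset <- generate_network(synth)
  write_dataset(dataset, cfg$out_dir)
  run_manifest(cfg, cfg$out_dir, "simulate", t0,
               list(m = synth$m, n = synth$n, l = synth$l,
                    positives = sum(dataset$Y)))
  invisible(dataset)
}

#' Compute and write the per-layer similarity matrices (CLI `similarity`)
#' @param cfg a [ssgc_config()].
#' @return list of layer matrices, invisibly.
#' @export
run_similarity <- function(cfg = ssgc_config()) {
  t0 <- as.numeric(Sys.time())
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  dataset <- load_run_dataset(cfg)
  opts <- do.call(pipeline_options, cfg$pipeline)
  static <- precompute_static_layers(dataset, opts)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("S_bc", "S_bd", "S_gc", "S_gd"))
    write_similarity_matrix(static[[nm]], file.path(cfg$out_dir, paste0(nm, ".tsv")))
  if ("treatment" %in% layer_set(cfg$layers)) {
    sims <- assemble_similarities(static, dataset$Y, layer_set(cfg$layers), opts)
    write_similarity_matrix(sims$drug_layers$treatment,
                            file.path(cfg$out_dir, "S_tc.tsv"))
    write_similarity_matrix(sims$disease_layers$treatment,
                            file.path(cfg$out_dir, "S_td.tsv"))
  }
  run_manifest(cfg, cfg$out_dir, "similarity", t0)
  invisible(static)
}

#' Fuse layers and write the comprehensive similarities (CLI `fuse`)
#' @param cfg a [ssgc_config()].
#' @return the [assemble_similarities()] result, invisibly.
#' @export
run_fuse <- function(cfg = ssgc_config()) {
  t0 <- as.numeric(Sys.time())
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  dataset <- load_run_dataset(cfg)
  opts <- do.call(pipeline_options, cfg$pipeline)
  static <- precompute_static_layers(dataset, opts)
  sims <- assemble_similarities(static, dataset$Y, layer_set(cfg$layers), opts)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_similarity_matrix(sims$Sc, file.path(cfg$out_dir, "S_c.tsv"))
  write_similarity_matrix(sims$Sd, file.path(cfg$out_dir, "S_d.tsv"))
  run_manifest(cfg, cfg$out_dir, "fuse", t0,
               list(drug_weights = as.list(sims$drug_weights),
                    disease_weights = as.list(sims$disease_weights)))
  invisible(sims)
}

#' Score all drug-disease pairs and write the ranking (CLI `predict`)
#' @param cfg a [ssgc_config()].
#' @return the [ssgc_pipeline()] result, invisibly.
#' @export
run_predict <- function(cfg = ssgc_config()) {
  t0 <- as.numeric(Sys.time())
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  dataset <- load_run_dataset(cfg)
  opts <- do.call(pipeline_options, cfg$pipeline)
  fit <- ssgc_pipeline(dataset, dataset$Y, layers = layer_set(cfg$layers),
                       prior = cfg$prior, opts = opts, mode = cfg$mode)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pair_scores(fit$result$scores, file.path(cfg$out_dir, "pair_scores.tsv"))
  run_manifest(cfg, cfg$out_dir, "predict", t0,
               list(iterations = fit$result$iterations,
                    converged = fit$result$converged,
                    final_loss = fit$result$final_loss))
  invisible(fit)
}

#' Cross-validate and write the metrics (CLI `evaluate`)
#' @param cfg a [ssgc_config()].
#' @return the [cross_validate()] result, invisibly.
#' @export
run_evaluate <- function(cfg = ssgc_config()) {
  t0 <- as.numeric(Sys.time())
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  dataset <- load_run_dataset(cfg)
  opts <- do.call(pipeline_options, cfg$pipeline)
  cv <- cross_validate(dataset, k = cfg$k_folds, seed = cfg$seed,
                       layers = layer_set(cfg$layers), prior = cfg$prior,
                       opts = opts)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cv$per_fold, file.path(cfg$out_dir, "fold_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  roc <- data.frame(threshold = cv$pooled$thresholds, fpr = cv$pooled$fpr,
                    tpr = cv$pooled$tpr)
  utils::write.table(roc, file.path(cfg$out_dir, "pooled_roc.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  run_manifest(cfg, cfg$out_dir, "evaluate", t0,
               list(pooled_auc = cv$pooled$auc,
                    mean_fold_auc = cv$mean_fold_auc))
  invisible(cv)
}
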