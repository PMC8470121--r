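#' Pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end run: synthetic data
#' generation (or a user manifest), train/test split, segmentation and
#' feature parameters, fusion mode, and the GA-SVM optimiser. One master
#' seed fans out deterministically to every stage.
#'
#' @param sim a [sim_config()] used when no manifest is supplied.
#' @param profiles action profiles for the generator.
#' @param manifest optional [semg_manifest] of real recordings; overrides the
#'   generator.
#' @param split_fraction per-class training fraction.
#' @param L,I onset-detection frame length and increment.
#' @param n_win,inc_win feature window length and increment.
#' @param features a [feature_config()].
#' @param mode fusion mode, `"concat"` or `"sum"`.
#' @param use_wfm apply channel weights (`TRUE`), skip them (`FALSE`), or
#'   `"both"` to run the ablation pair in one report.
#' @param denoise_cfg `NULL` to skip denoising, or a list of [denoise()]
#'   arguments.
#' @param ga a [ga_config()].
#' @param optimizer `"iga"` (tiered selection) or `"plain"` (tournament GA).
#' @param threshold_from onset threshold source, see
#'   [detect_onset_recording()].
#' @param seed master seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(n_per_class = 20L),
                            profiles = default_action_profiles(),
                            manifest = NULL, split_fraction = 0.5,
                            L = 64L, I = 32L, n_win = 64L, inc_win = 32L,
                            features = feature_config(),
                            mode = "concat", use_wfm = TRUE,
                            denoise_cfg = NULL, ga = ga_config(pop_size = 20L,
                                                              max_generations = 5L,
                                                              cv_folds = 3L),
                            optimizer = c("iga", "plain"),
                            threshold_from = "all", seed = 1L) {
  optimizer <- match.arg(optimizer)
  structure(list(sim = sim, profiles = profiles, manifest = manifest,
                 split_fraction = split_fraction, L = L, I = I,
                 n_win = n_win, inc_win = inc_win, features = features,
                 mode = mode, use_wfm = use_wfm, denoise_cfg = denoise_cfg,
                 ga = ga, optimizer = optimizer,
                 threshold_from = threshold_from, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_variant <- function(Xtr, ytr, Xte, yte, cfg) {
  norm <- normalize_features(Xtr, Xte)
  ga <- cfg$ga
  ga$seed <- derive_seed(cfg$seed, 31L)
  evo <- if (cfg$optimizer == "plain") {
    evolve_plain_ga(norm$train, ytr, ga)
  } else {
    evolve(norm$train, ytr, ga)
  }
  model <- train_svm(norm$train, ytr, evo$best_c, evo$best_g)
  ev <- evaluate_model(model, norm$test, yte)
  list(best_c = evo$best_c, best_g = evo$best_g,
       best_fitness = evo$best_fitness, fitness_history = evo$history,
       accuracy = ev$accuracy, per_class = ev$per_class,
       confusion = ev$confusion)
}

#' Run the full recognition pipeline
#'
#' Orchestrates data generation (or loading), per-class train/test split,
#' denoising, onset detection, main-segment extraction, feature extraction,
#' weighted fusion, GA optimisation of the SVM hyperparameters, final
#' training, and test evaluation. Per-channel features are extracted once
#' and reused by both arms of the WFM ablation when `use_wfm = "both"`.
#' Fully deterministic for a fixed config and seed.
#'
#' @param config a [pipeline_config()].
#' @return a report list: `seed`, record counts, `excluded` diagnostics, and
#'   one result block per variant (`wfm` and/or `raw`) carrying `best_c`,
#'   `best_g`, `best_fitness`, `fitness_history`, test `accuracy`,
#'   `per_class` accuracy, and the `confusion` matrix.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- config$manifest
  if (is.null(manifest)) {
    manifest <- generate_dataset(config$sim, config$profiles,
                                 seed = derive_seed(config$seed, 11L),
                                 materialize = FALSE)
  }
  manifest <- split_dataset(manifest, config$split_fraction,
                            seed = derive_seed(config$seed, 21L))
  variants <- if (identical(config$use_wfm, "both")) c(TRUE, FALSE) else isTRUE(config$use_wfm)
  built <- lapply(variants, function(w) {
    build_dataset(manifest, L = config$L, I = config$I, n_win = config$n_win,
                  inc_win = config$inc_win, config = config$features,
                  mode = config$mode, weighted = w,
                  denoise_cfg = config$denoise_cfg,
                  threshold_from = config$threshold_from)
  })
  report <- list(seed = config$seed, optimizer = config$optimizer,
                 n_records = length(manifest$entries),
                 n_train = sum(manifest$split == "train"),
                 n_test = sum(manifest$split == "test"),
                 excluded = built[[1L]]$excluded)
  for (k in seq_along(variants)) {
    ds <- built[[k]]
    split <- manifest$split[ds$kept]
    res <- run_variant(ds$X[split == "train", , drop = FALSE],
                       droplevels(ds$y[split == "train"]),
                       ds$X[split == "test", , drop = FALSE],
                       ds$y[split == "test"], config)
    report[[if (variants[k]) "wfm" else "raw"]] <- res
  }
  report
}

#' Serialise a pipeline report to JSON
#'
#' Stable, fixed-precision serialisation: identical reports produce
#' byte-identical JSON, so determinism can be checked by comparing files.
#'
#' @param report a report from [run_pipeline()].
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
report_json <- function(report, path = NULL) {
  txt <- jsonlite::toJSON(report, digits = 15, auto_unbox = TRUE,
                          dataframe = "columns", matrix = "rowmajor")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
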