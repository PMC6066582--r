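#' Load and save run configurations
#'
#' Run configurations are flat key-value YAML files. Recognized keys:
#' `command` (one of `simulate`, `fc`, `correct`, `pretrain`, `train`,
#' `evaluate`, `rank`), `preset` (optional, one of the shipped site
#' presets), hyperparameter fields (`layer_sizes`, `lambda_l2`, `beta`,
#' `rho`, `cost_goal`, `max_epochs`, `decoder_activation`,
#' `feature_scaling`, `softmax_intercept`), `k` (CV folds), `seed`,
#' `positive` class, scenario fields for `simulate` (any [sim_scenario()]
#' argument prefixed `sim_`), and paths (`features`, `phenotype`,
#' `offline_features`, `offline_phenotype`, `model`, `out_dir`).
#' Explicit keys override preset values.
#'
#' @param path YAML file path.
#' @return A list of class `"run_config"`.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

as_run_config <- function(cfg) {
  if (!is.null(cfg$preset)) {
    base <- load_preset(cfg$preset, seed = cfg$seed %||% 1L)
    hp <- base$hyperparams
  } else {
    hp <- hyperparams(cfg$layer_sizes %||% c(20L, 20L, 20L),
                      seed = cfg$seed %||% 1L)
  }
  for (f in c("lambda_l2", "beta", "rho", "cost_goal", "max_epochs",
              "decoder_activation", "feature_scaling", "softmax_intercept"))
    if (!is.null(cfg[[f]])) hp[[f]] <- cfg[[f]]
  if (!is.null(cfg$layer_sizes)) hp$layer_sizes <- as.integer(cfg$layer_sizes)
  hp <- do.call(hyperparams, unclass(hp))   # re-validate
  cfg$hyperparams <- hp
  cfg$k <- as.integer(cfg$k %||% 5L)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "run_config")
}

#' @rdname load_run_config
#' @param config a `"run_config"`.
#' @export
save_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$hyperparams <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

pipeline_log <- function(out_dir, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  message(msg)
  cat(msg, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
}

#' Run a pipeline subcommand
#'
#' Thin orchestration over the package's functions, suitable for driving
#' from a shell script. Every subcommand writes its artifacts plus a run
#' log under `config$out_dir` and is bit-reproducible from the same
#' config and seed.
#'
#' \describe{
#'   \item{simulate}{write synthetic feature/phenotype TSVs and a
#'     ground-truth JSON from a [sim_scenario()].}
#'   \item{fc}{convert a directory of per-subject ROI time-series files
#'     (`config$timeseries_dir`) into a vectorized FC feature table.}
#'   \item{correct}{apply [site_bias_correct()] to a feature+phenotype
#'     table pair.}
#'   \item{pretrain}{train an offline SSAE prototype on a healthy corpus;
#'     refuses a corpus sharing subjects with the target phenotype.}
#'   \item{train}{train a DTL-NN from a prototype (or the DNN baseline if
#'     `config$model_type == "DNN"`) on the full target cohort.}
#'   \item{evaluate}{stratified k-fold cross-validation of DTL-NN and DNN
#'     on the target cohort; writes per-subject predictions and a metrics
#'     summary per model.}
#'   \item{rank}{accumulate weight-product saliency across CV folds of
#'     the DTL-NN and write the edge ranking.}
#' }
#'
#' @param config a `"run_config"` (see [load_run_config()]).
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cmd <- config$command %||% stop("config$command is required")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  handler <- switch(cmd,
    simulate = pipeline_simulate, fc = pipeline_fc,
    correct = pipeline_correct, pretrain = pipeline_pretrain,
    train = pipeline_train, evaluate = pipeline_evaluate,
    rank = pipeline_rank,
    stop("unknown command '", cmd, "'"))
  pipeline_log(out_dir, "[", cmd, "] start (seed ", config$seed, ")")
  files <- tryCatch(handler(config, out_dir),
                    error = function(e)
                      stop("[", cmd, "] ", conditionMessage(e),
                           call. = FALSE))
  pipeline_log(out_dir, "[", cmd, "] wrote: ",
               paste(basename(files), collapse = ", "))
  invisible(files)
}

sim_from_config <- function(config) {
  args <- config[startsWith(names(config), "sim_")]
  names(args) <- sub("^sim_", "", names(args))
  args$seed <- args$seed %||% config$seed
  do.call(sim_scenario, args)
}

pipeline_simulate <- function(config, out_dir) {
  sim <- simulate_cohort(sim_from_config(config))
  ds <- sim$dataset
  f1 <- file.path(out_dir, "features.tsv")
  f2 <- file.path(out_dir, "phenotype.tsv")
  f3 <- file.path(out_dir, "truth.json")
  write_feature_table(ds$subject_ids, ds$features, f1)
  write_phenotype(cbind(subject_id = ds$subject_ids,
                        ds$covariates[c("site", "age", "sex", "handedness",
                                        "cohort")],
                        group = ds$labels), f2)
  writeLines(jsonlite::toJSON(sim$truth, auto_unbox = TRUE, digits = I(17)),
             f3)
  c(f1, f2, f3)
}

pipeline_fc <- function(config, out_dir) {
  dir <- config$timeseries_dir %||% stop("timeseries_dir is required")
  files <- sort(list.files(dir, full.names = TRUE))
  if (!length(files)) stop("no time-series files in ", dir)
  feats <- lapply(files, function(f) {
    ts <- roi_timeseries(sub("\\.[^.]*$", "", basename(f)),
                         as.matrix(utils::read.table(f)))
    vectorize_fc(compute_fc_matrix(ts))
  })
  out <- file.path(out_dir, "features.tsv")
  write_feature_table(sub("\\.[^.]*$", "", basename(files)),
                      do.call(rbind, feats), out)
  out
}

pipeline_correct <- function(config, out_dir) {
  ds <- load_dataset(config$features, config$phenotype)
  ds <- site_bias_correct(ds, fit_on = config$fit_on %||% "all")
  out <- file.path(out_dir, "features_corrected.tsv")
  write_feature_table(ds$subject_ids, ds$features, out)
  out
}

pipeline_pretrain <- function(config, out_dir) {
  off <- load_dataset(config$offline_features, config$offline_phenotype)
  if (!is.null(config$phenotype)) {    # target cohort, for disjointness check
    target <- read_phenotype(config$phenotype)
    overlap <- intersect(off$subject_ids, target$subject_id)
    if (length(overlap))
      stop("offline corpus shares ", length(overlap),
           " subject(s) with the target cohort (e.g. ", overlap[1],
           "); offline learning must be independent")
  }
  proto <- train_ssae(off$features, config$hyperparams,
                      provenance = "offline")
  out <- file.path(out_dir, "prototype.json")
  write_model(proto, out)
  out
}

pipeline_train <- function(config, out_dir) {
  ds <- load_dataset(config$features, config$phenotype)
  hp <- config$hyperparams
  model <- if (identical(config$model_type, "DNN")) {
    train_dnn_baseline(ds$features, ds$labels, hp,
                       positive = config$positive)
  } else {
    proto <- read_model(config$model %||% stop("model (prototype) required"))
    train_dtl_nn(proto, ds$features, ds$labels, hp,
                 positive = config$positive)
  }
  out <- file.path(out_dir, "model.json")
  write_model(model, out)
  out
}

evaluate_both <- function(config) {
  ds <- load_dataset(config$features, config$phenotype)
  hp <- config$hyperparams
  proto <- read_model(config$model %||% stop("model (prototype) required"))
  dtl_trainer <- function(tr) train_dtl_nn(proto, tr$features, tr$labels, hp,
                                           positive = config$positive)
  dnn_trainer <- function(tr) train_dnn_baseline(tr$features, tr$labels, hp,
                                                 positive = config$positive)
  list(dtl = cross_validate(dtl_trainer, ds, k = config$k,
                            seed = config$seed, positive = config$positive),
       dnn = cross_validate(dnn_trainer, ds, k = config$k,
                            seed = config$seed, positive = config$positive))
}

pipeline_evaluate <- function(config, out_dir) {
  cvs <- evaluate_both(config)
  files <- character(0)
  for (m in names(cvs)) {
    f1 <- file.path(out_dir, paste0("cv_", m, ".tsv"))
    f2 <- file.path(out_dir, paste0("metrics_", m, ".tsv"))
    write_cv_result(cvs[[m]], f1, f2)
    files <- c(files, f1, f2)
  }
  files
}

pipeline_rank <- function(config, out_dir) {
  cvs <- evaluate_both(config)
  ranking <- accumulate_rankings(lapply(cvs$dtl$per_fold_models,
                                        saliency_scores))
  out <- file.path(out_dir, "saliency.tsv")
  write_saliency(ranking, out)
  out
}
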