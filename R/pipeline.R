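# End-to-end orchestration: synthesize (or load) a cohort, split it at
# lesion level, preprocess with a chosen ROI strategy, augment the training
# and validation patches, train SFFNet, and evaluate on the held-out
# lesions, writing a JSON run record plus metrics/history/ROC/confusion
# files that fully describe the run.

#' Pipeline configuration
#'
#' Bundles the sub-configurations of every stage with one seed per random
#' procedure. `augment_test` must remain `FALSE`: augmenting the held-out
#' split is refused.
#'
#' @param n_per_class Lesions per class of the synthetic cohort.
#' @param phantom A [phantom_spec()].
#' @param strategy ROI strategy, see [apply_strategy()].
#' @param clip_limit,tile_grid CLAHE parameters.
#' @param augment An [augment_spec()].
#' @param augment_validation Also augment the validation patches.
#' @param augment_test Must be `FALSE`; present so a misconfiguration is
#'   refused loudly rather than silently ignored.
#' @param model An [sffnet_config()].
#' @param train A [train_config()].
#' @param ratios Train/validation/test lesion ratios.
#' @param split_seed,model_seed,cohort_seed Stage seeds.
#' @param slices_per_lesion Optional fixed slices per lesion.
#' @param out_dir Output directory (created); `NULL` keeps results in
#'   memory only.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_class = 30L,
                            phantom = phantom_spec(),
                            strategy = "semi_sp",
                            clip_limit = 2, tile_grid = c(8, 8),
                            augment = augment_spec(copies_per_image = 0L),
                            augment_validation = FALSE,
                            augment_test = FALSE,
                            model = sffnet_config("reduced"),
                            train = train_config(epochs = 25L),
                            ratios = c(0.6, 0.2, 0.2),
                            split_seed = 1L, model_seed = 1L,
                            cohort_seed = 1L,
                            slices_per_lesion = 4L,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes synth -> split -> preprocess -> augment -> train -> eval and
#' returns (and optionally writes) the run record with the resolved
#' configuration, seeds, stage timings and the final metrics report.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return List with `metrics` (a [metrics_report()]), `train_result`,
#'   `split`, `manifest`, and `record` (the run record, also written as
#'   JSON when `out_dir` is set).
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (isTRUE(config$augment_test))
    stopf("augment_test = TRUE is refused: the held-out split is never augmented")
  t0 <- Sys.time()
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(name, start) timings[[name]] <<- as.numeric(Sys.time() - start, units = "secs")
  say <- function(...) if (verbose) message(sprintf(...))

  st <- tic()
  cohort <- make_cohort(config$n_per_class, config$phantom,
                        seed = config$cohort_seed,
                        slices_per_lesion = config$slices_per_lesion)
  toc("synth", st)
  say("stage synth: %d slices, %d lesions", nrow(cohort$manifest),
      length(unique(cohort$manifest$lesion_id)))

  st <- tic()
  split <- split_lesions(cohort$manifest, config$ratios, config$split_seed)
  split_of <- setNames(split$split, split$lesion_id)
  toc("split", st)

  st <- tic()
  patches <- preprocess_cohort(cohort, config$strategy, config$clip_limit,
                               config$tile_grid)
  for (i in seq_along(patches))
    patches[[i]]$provenance$split <-
      unname(split_of[cohort$manifest$lesion_id[i]])
  toc("preprocess", st)

  st <- tic()
  sel <- function(part) patches[vapply(patches, function(p)
    p$provenance$split == part, logical(1))]
  tr <- sel("train"); va <- sel("validation"); te <- sel("test")
  if (config$augment$copies_per_image > 0) {
    tr <- expand_dataset(tr, config$augment)
    if (isTRUE(config$augment_validation)) va <- expand_dataset(va, config$augment)
  }
  toc("augment", st)
  say("stage data: train %d, validation %d, test %d patches",
      length(tr), length(va), length(te))

  lab <- function(ps) vapply(ps, function(p) p$provenance$class_label, character(1))
  st <- tic()
  model <- sffnet_model(config$model, seed = config$model_seed)
  fit <- train_sffnet(model, tr, lab(tr), va, lab(va), config$train,
                      verbose = verbose)
  toc("train", st)

  st <- tic()
  metrics <- evaluate_model(model, te, lab(te))
  lesion_metrics <- lesion_vote_report(
    .classes[max.col(predict_proba(model, te), ties.method = "first")],
    vapply(te, function(p) p$provenance$lesion_id, character(1)),
    lab(te))
  toc("eval", st)
  say("stage eval: accuracy %.4f, AUC %.4f", metrics$accuracy, metrics$auc)

  record <- list(
    package_version = as.character(utils::packageVersion("sffnet")),
    r_version = R.version.string,
    config = serialize_config(config),
    seeds = list(cohort = config$cohort_seed, split = config$split_seed,
                 model = config$model_seed, train = config$train$seed,
                 augment = config$augment$seed),
    stage_timings_sec = timings,
    n_patches = list(train = length(tr), validation = length(va),
                     test = length(te)),
    best_epoch = fit$best_epoch,
    best_val_accuracy = fit$best_val_accuracy,
    metrics = metrics_to_list(metrics),
    total_sec = as.numeric(Sys.time() - t0, units = "secs")
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(record, file.path(config$out_dir, "run_record.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(metrics_to_list(metrics),
                         file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(fit$history, file.path(config$out_dir, "history.csv"),
              row.names = FALSE)
    write.csv(metrics$per_class, file.path(config$out_dir, "per_class.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(metrics$confusion),
              file.path(config$out_dir, "confusion.csv"), row.names = FALSE)
    probs <- predict_proba(model, te)
    roc <- roc_auc(probs[, "MF-ICC"], lab(te))
    write.csv(roc$points, file.path(config$out_dir, "roc.csv"),
              row.names = FALSE)
    save_checkpoint(model, file.path(config$out_dir, "checkpoint.rds"))
  }

  list(metrics = metrics, lesion_metrics = lesion_metrics,
       train_result = fit, split = split, manifest = cohort$manifest,
       model = model, record = record)
}

metrics_to_list <- function(m) {
  list(accuracy = m$accuracy,
       auc = if (is.null(m$auc)) NA else m$auc,
       auc_per_class = as.list(m$auc_per_class),
       per_class = m$per_class,
       confusion = unclass(m$confusion),
       n = m$n)
}

serialize_config <- function(config) {
  drop_class <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, drop_class)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  drop_class(config[setdiff(names(config), "out_dir")])
}
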