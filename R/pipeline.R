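#' End-to-end pipeline configuration
#'
#' Bundles every knob of the simulate -> split -> train -> recognize ->
#' evaluate -> guide pipeline; all randomness is derived from `seed`.
#'
#' @param seed master seed.
#' @param n_subjects,instances_per_posture database size (defaults 11 and
#'   10, the study-scale synthetic conditions).
#' @param spec a [perturbation_spec()].
#' @param train_fraction instance-level training fraction.  Default 0.3.
#' @param ann an [ann_config()] (its seed is overridden from `seed`).
#' @param recognizer a [recognizer_config()].
#' @param eval_subjects subjects whose training-split frames fit the
#'   evaluation networks (`NULL` = all training subjects).
#' @param eval_posture posture id for the evaluation/guidance demo.
#' @param eval_deviations named list segment -> rotation vector injected
#'   into the demo nonstandard instance.
#' @param eval_threshold nonstandard score threshold.  Default 0.3.
#' @param min_extent guidance suppression threshold (rad).  Default 0.1.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, n_subjects = 11L,
                       instances_per_posture = 10L,
                       spec = perturbation_spec(),
                       train_fraction = 0.3,
                       ann = ann_config(),
                       recognizer = recognizer_config(),
                       eval_subjects = NULL,
                       eval_posture = 1L,
                       eval_deviations = list(RShank = c(0, 0, 0.5),
                                              LUArm = c(0, 0.5, 0)),
                       eval_threshold = 0.3, min_extent = 0.1) {
  ann$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 instances_per_posture = instances_per_posture,
                 spec = spec, train_fraction = train_fraction,
                 ann = ann, recognizer = recognizer,
                 eval_subjects = eval_subjects,
                 eval_posture = eval_posture,
                 eval_deviations = eval_deviations,
                 eval_threshold = eval_threshold,
                 min_extent = min_extent),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline on a synthetic database
#'
#' Generates (or accepts) a database, splits it at instance granularity,
#' trains the two-stage classifier, recognizes every test instance,
#' reports frame- and instance-level accuracy, fits the per-posture
#' Bayesian network of the demo posture, evaluates a matched
#' standard/nonstandard instance pair with injected deviations, and
#' renders the corrective guidance.  Deterministic given the config seed.
#' When `out_dir` is given, the trained model, the network, the accuracy
#' tables and the summary (stamped with the config hash and seed) are
#' written there.
#'
#' @param config a [run_config()].
#' @param db optional pre-built `posture_db` (otherwise simulated).
#' @param out_dir optional artifact directory.
#' @return a `pipeline_summary` list: accuracy tables, evaluation scores,
#'   guidance sentences, provenance.
#' @export
run_pipeline <- function(config = run_config(), db = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  templates <- make_templates(seed)
  subjects <- make_subjects(config$n_subjects, config$spec, seed + 1L)
  if (is.null(db))
    db <- generate_database(config$n_subjects, config$instances_per_posture,
                            config$spec, seed, templates = templates,
                            subjects = subjects)
  sp <- split_posture_db(db, config$train_fraction, seed + 10L)
  model <- train_two_stage(sp$train, config = config$ann, seed = seed + 20L)
  rec <- recognize_database(model, sp$test, config = config$recognizer)
  acc <- accuracy_report(rec)

  # evaluation stage: network for the demo posture, fitted on the training
  # split (optionally restricted to designated well-performing subjects)
  trf <- sp$train$frames
  eval_rows <- trf$posture == config$eval_posture &
    (if (is.null(config$eval_subjects)) TRUE
     else trf$subject %in% config$eval_subjects)
  net <- fit_posture_network(trf[eval_rows, , drop = FALSE],
                             posture = config$eval_posture)
  tpl <- templates[[config$eval_posture]]
  # the probe performer executes the nominal posture (the standard model
  # itself) with sensor jitter only; the nonstandard twin shares the RNG
  # stream so the pair differs exactly by the injected deviations
  probe_subject <- make_subjects(1L, config$spec, seed + 30L,
                                 standard = TRUE)[[1L]]
  probe_spec <- config$spec
  probe_spec$sigma_instance <- 0
  pair_seed <- seed + 31L
  std <- generate_instance(tpl, probe_subject, probe_spec, seed = pair_seed)
  nonstd <- generate_nonstandard(tpl, config$eval_deviations, probe_subject,
                                 probe_spec, seed = pair_seed)
  ev_std <- evaluate_posture(net, std, threshold = config$eval_threshold)
  ev_non <- evaluate_posture(net, nonstd$instance,
                             threshold = config$eval_threshold)
  guide <- guidance_report(net, nonstd$instance, category = tpl$category,
                           threshold = config$eval_threshold,
                           min_extent = config$min_extent)

  summary <- structure(list(
    provenance = list(config_hash = config_hash(config), seed = seed,
                      n_train_instances = nrow(db_instances(sp$train)),
                      n_test_instances = nrow(db_instances(sp$test))),
    accuracy = acc,
    frame_accuracy_pct = acc$frames$accuracy_pct[nrow(acc$frames)],
    instance_accuracy_pct = acc$instances$accuracy_pct[nrow(acc$instances)],
    evaluation = list(
      posture = config$eval_posture,
      injected = nonstd$truth,
      standard_mean_scores = colMeans(ev_std$scores),
      nonstandard_mean_scores = colMeans(ev_non$scores)),
    guidance = list(items = guide$items, sentences = guide$sentences)),
    class = "pipeline_summary")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_model(model, file.path(out_dir, "two_stage_model.json"))
    save_model(net, file.path(out_dir, "bayes_net.json"))
    utils::write.csv(acc$frames, file.path(out_dir, "accuracy_frames.csv"),
                     row.names = FALSE)
    utils::write.csv(acc$instances,
                     file.path(out_dir, "accuracy_instances.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  summary
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("Pipeline summary (seed", x$provenance$seed, ", config",
      substr(x$provenance$config_hash, 1, 8), ")\n")
  cat(sprintf("  frame accuracy    %.2f%%\n", x$frame_accuracy_pct))
  cat(sprintf("  instance accuracy %.2f%%\n", x$instance_accuracy_pct))
  cat("  nonstandard segments injected:",
      paste(x$evaluation$injected$segment, collapse = ", "), "\n")
  for (s in x$guidance$sentences) cat("  -", s, "\n")
  invisible(x)
}
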