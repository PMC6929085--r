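#' Recognizer configuration
#'
#' Thresholds of the two-stage classifier and the cumulative-likelihood
#' smoother: `t1` on the category score, `t2` on the cluster membership,
#' `t3` on the accumulated likelihood, and the per-frame update step
#' `tau` (default 0.1 - six net supporting frames reach the default
#' `t3 = 0.5`).  Whether frames rejected as noisy decay the likelihoods
#' or leave them unchanged is exposed as `noisy`.
#'
#' @param t1,t2,t3 thresholds in (0, 1).
#' @param tau likelihood update step (> 0, `t3 >= tau`).
#' @param noisy `"hold"` (default: noisy frames update nothing) or
#'   `"decay"` (all likelihoods lose `tau`).
#' @return a `recognizer_config` list.
#' @export
recognizer_config <- function(t1 = 0.5, t2 = 0.3, t3 = 0.5, tau = 0.1,
                              noisy = c("hold", "decay")) {
  stopifnot(t1 > 0, t1 < 1, t2 > 0, t2 < 1, t3 > 0, t3 < 1,
            tau > 0, t3 >= tau)
  structure(list(t1 = t1, t2 = t2, t3 = t3, tau = tau,
                 noisy = match.arg(noisy)), class = "recognizer_config")
}

#' Train the two-stage posture classifier
#'
#' Fits the category network on waist features of all training frames and
#' one fuzzy C-means model per category on the body-relative features of
#' that category's frames, with cluster centers initialized at the
#' per-posture labelled means and clusters mapped to posture labels by
#' membership mass.  Training optionally runs on a seeded stratified
#' frame subsample (predictions always use every frame).
#'
#' @param db training `posture_db` (animation-frame data, or raw + `cal`).
#' @param cal optional [calibration_set()].
#' @param config an [ann_config()].
#' @param b fuzzy weight index.  Default 2.
#' @param ann_frames,fcm_frames caps on the training subsample per stage
#'   (`Inf` to use all frames).
#' @param seed subsampling seed.
#' @return a `two_stage_model` (ann + per-category fcm + category map).
#' @export
train_two_stage <- function(db, cal = NULL, config = ann_config(), b = 2,
                            ann_frames = 20000L, fcm_frames = 10000L,
                            seed = 1L) {
  stopifnot(inherits(db, "posture_db"))
  f <- db$frames
  if (!nrow(f)) stop("empty training database")
  cat_map <- db$category_map
  cat_of <- unname(cat_map[as.character(f$posture)])
  K1 <- max(cat_map)
  missing_cat <- setdiff(seq_len(K1), unique(cat_of))
  if (length(missing_cat))
    stop("training data is missing categories: ",
         paste(missing_cat, collapse = ", "))
  Q <- frames_quat_matrix(f)
  if (!is.null(cal)) Q <- calibrate_frames(Q, cal)

  sub_ann <- stratified_rows(cat_of, ann_frames, seed)
  ann <- ann_train(extract_waist_features(Q[sub_ann, , drop = FALSE]),
                   cat_of[sub_ann], config, sizes = c(9L, 15L, K1))

  fcms <- vector("list", K1)
  for (cc in seq_len(K1)) {
    rows <- which(cat_of == cc)
    rows <- rows[stratified_rows(f$posture[rows], fcm_frames, seed + cc)]
    postures <- sort(unique(as.integer(names(cat_map)[cat_map == cc])))
    have <- sort(unique(f$posture[rows]))
    if (!identical(have, postures))
      stop("category ", cc, " is missing postures: ",
           paste(setdiff(postures, have), collapse = ", "))
    X2 <- extract_body_features(Q[rows, , drop = FALSE])
    lab <- f$posture[rows]
    means <- t(vapply(postures, function(p)
      colMeans(X2[lab == p, , drop = FALSE]), numeric(ncol(X2))))
    m <- fcm_fit(X2, K2 = length(postures), b = b, init_centers = means)
    m <- fcm_assign_labels(m, X2, lab)
    m$U <- NULL  # memberships of the training subsample are not part of the model
    m$category <- cc
    fcms[[cc]] <- m
  }
  structure(list(ann = ann, fcm = fcms, category_map = cat_map),
            class = "two_stage_model")
}

stratified_rows <- function(strata, cap, seed) {
  n <- length(strata)
  if (n <= cap) return(seq_len(n))
  with_seed(seed, {
    idx <- unlist(lapply(split(seq_len(n), strata), function(rows) {
      k <- max(1L, floor(cap * length(rows) / n))
      sort(sample(rows, min(k, length(rows))))
    }), use.names = FALSE)
    sort(idx)
  })
}

#' @export
print.two_stage_model <- function(x, ...) {
  cat("Two-stage posture classifier\n  stage 1: ")
  print(x$ann)
  cat(sprintf("  stage 2: %d FCM models covering %d postures\n",
              length(x$fcm), length(x$category_map)))
  invisible(x)
}

#' Per-frame two-stage classification
#'
#' Waist features go through the category network; frames whose best
#' category score exceeds `t1` are routed to that category's FCM model,
#' which emits the posture of the best cluster if its membership exceeds
#' `t2`.  Frames rejected at either stage are classed noisy (`NA`).
#'
#' @param model a `two_stage_model`.
#' @param frames frame rows (see [extract_waist_features()]).
#' @param cal optional [calibration_set()].
#' @param config a [recognizer_config()].
#' @return integer posture ids per frame, `NA` = noisy.
#' @export
classify_frames <- function(model, frames, cal = NULL,
                            config = recognizer_config()) {
  stopifnot(inherits(model, "two_stage_model"))
  Q <- frames_quat_matrix(frames)
  if (!is.null(cal)) Q <- calibrate_frames(Q, cal)
  cats <- predict_category(model$ann, extract_waist_features(Q), config$t1)
  out <- rep(NA_integer_, nrow(Q))
  for (cc in unique(cats[!is.na(cats)])) {
    rows <- which(!is.na(cats) & cats == cc)
    X2 <- extract_body_features(Q[rows, , drop = FALSE])
    out[rows] <- predict_posture(model$fcm[[cc]], X2, config$t2)
  }
  out
}

#' Cumulative-likelihood update for one frame result
#'
#' The recognized posture's likelihood gains `tau`, every other posture
#' loses `tau`, and the vector is clipped to `[0, 1]`.  A noisy frame
#' (`NA`) leaves the vector unchanged under the default `"hold"` policy or
#' decays every entry by `tau` under `"decay"`.
#'
#' @param likelihoods numeric vector over postures (names = posture ids).
#' @param frame_result integer posture id or `NA`.
#' @param config a [recognizer_config()].
#' @return updated likelihood vector.
#' @export
update_likelihoods <- function(likelihoods, frame_result,
                               config = recognizer_config()) {
  if (is.na(frame_result)) {
    if (config$noisy == "decay")
      likelihoods[] <- pmax(likelihoods - config$tau, 0)
    return(likelihoods)
  }
  k <- match(as.character(frame_result), names(likelihoods))
  if (is.na(k)) stop("frame result ", frame_result,
                     " is not a posture of the likelihood vector")
  likelihoods <- likelihoods - config$tau
  likelihoods[k] <- likelihoods[k] + 2 * config$tau
  likelihoods[] <- pmin(pmax(likelihoods, 0), 1)
  likelihoods
}

#' Recognize one posture instance from its frame stream
#'
#' Likelihoods over the 18 postures start at zero; frames stream through
#' the two-stage classifier and the cumulative update, and the first
#' posture whose likelihood strictly exceeds `t3` is emitted and frozen
#' as the instance result (ties at the crossing resolve to the lowest
#' posture id).  Isolated misclassified or noisy frames inside a long
#' correct run cannot reach `t3` and are thereby smoothed away.
#'
#' @param model a `two_stage_model`.
#' @param frames the instance's frame rows, in time order.
#' @param cal optional [calibration_set()].
#' @param config a [recognizer_config()].
#' @return list: `posture` (id or `NA` if never emitted), `emit_frame`,
#'   `frame_results`, final `likelihoods`.
#' @export
recognize_instance <- function(model, frames, cal = NULL,
                               config = recognizer_config()) {
  res <- classify_frames(model, frames, cal, config)
  postures <- sort(as.integer(names(model$category_map)))
  lik <- stats::setNames(numeric(length(postures)), postures)
  emitted <- NA_integer_
  emit_frame <- NA_integer_
  for (i in seq_along(res)) {
    lik <- update_likelihoods(lik, res[i], config)
    if (is.na(emitted)) {
      over <- which(lik > config$t3)
      if (length(over)) {
        emitted <- postures[over[1L]]
        emit_frame <- i
      }
    }
  }
  list(posture = emitted, emit_frame = emit_frame,
       frame_results = res, likelihoods = lik)
}

#' Recognize every instance of a database
#'
#' @param model a `two_stage_model`.
#' @param db a `posture_db`.
#' @param cal optional [calibration_set()].
#' @param config a [recognizer_config()].
#' @return list with `instances` (subject, posture, instance, truth,
#'   recognized, emit_frame, frame counts) and `frames` (per-frame truth
#'   and result).
#' @export
recognize_database <- function(model, db, cal = NULL,
                               config = recognizer_config()) {
  stopifnot(inherits(db, "posture_db"))
  idx <- db_instances(db)
  if (!nrow(idx)) stop("empty database")
  f <- db$frames
  key <- paste(f$subject, f$posture, f$instance)
  rows_of <- split(seq_len(nrow(f)), key)
  inst_res <- integer(nrow(idx)); inst_emit <- integer(nrow(idx))
  frame_truth <- integer(0); frame_res <- integer(0)
  for (r in seq_len(nrow(idx))) {
    rows <- rows_of[[paste(idx$subject[r], idx$posture[r], idx$instance[r])]]
    rows <- rows[order(f$time[rows])]
    rec <- recognize_instance(model, f[rows, , drop = FALSE], cal, config)
    inst_res[r] <- rec$posture
    inst_emit[r] <- rec$emit_frame
    frame_truth <- c(frame_truth, rep.int(idx$posture[r], length(rows)))
    frame_res <- c(frame_res, rec$frame_results)
  }
  list(instances = data.frame(idx[, c("subject", "posture", "instance")],
                              n_frames = idx$n_frames,
                              recognized = inst_res, emit_frame = inst_emit),
       frames = data.frame(truth = frame_truth, recognized = frame_res))
}

#' Frame- and instance-level accuracy report
#'
#' Builds the per-posture correct/total/percent tables (with a summed
#' totals row) for both granularities from a [recognize_database()]
#' result.
#'
#' @param results a [recognize_database()] return value.
#' @return list of two [accuracy_table()] data.frames, `frames` and
#'   `instances`.
#' @export
accuracy_report <- function(results) {
  if (!is.list(results) || is.null(results$instances) ||
      !nrow(results$instances))
    stop("empty recognition results")
  per <- function(truth, got) {
    ids <- sort(unique(truth))
    correct <- vapply(ids, function(p)
      sum(truth == p & !is.na(got) & got == p), integer(1))
    total <- vapply(ids, function(p) sum(truth == p), integer(1))
    accuracy_table(correct, total, ids)
  }
  list(frames = per(results$frames$truth, results$frames$recognized),
       instances = per(results$instances$posture,
                       results$instances$recognized))
}
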