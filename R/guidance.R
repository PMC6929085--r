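#' Nominal waist orientation of each posture category
#'
#' The five waist-orientation categories correspond to nominal waist
#' rotations in the animation frame: stand = identity, lean left/right =
#' +/-90 degrees about y, lie on stomach / on back = +/-90 degrees about
#' x.  Used by the generator's category geometry and by the guidance
#' perspective remapping.
#'
#' @param category category id 1..5.
#' @return unit quaternion.
#' @export
category_waist_quat <- function(category) {
  stopifnot(category %in% 1:5)
  switch(category,
         quat_identity(),
         axis_angle_quat(c(0, 1, 0), pi / 2),
         axis_angle_quat(c(0, 1, 0), -pi / 2),
         axis_angle_quat(c(1, 0, 0), pi / 2),
         axis_angle_quat(c(1, 0, 0), -pi / 2))
}

#' Deviation rotation of an observed segment from its conditional model
#'
#' The deviation quaternion `q_dev = mu_s|t^-1 * q_rel` (conditional mean
#' normalized to unit norm first, observation hemisphere-aligned to it),
#' returned as a rotation matrix for the planar angle extraction.
#'
#' @param mu conditional mean 4-vector (need not be unit).
#' @param q_rel observed segment quaternion relative to the waist.
#' @return 3 x 3 rotation matrix of the deviation.
#' @export
deviation_quaternion <- function(mu, q_rel) {
  if (sqrt(sum(mu^2)) < 1e-8) stop("conditional mean has near-zero norm")
  mu <- quat_normalize(mu)
  q_rel <- quat_normalize(q_rel)
  if (sum(mu * q_rel) < 0) q_rel <- -q_rel
  quat_to_matrix(qmul(qinv(mu), q_rel))
}

#' Planar angular differences of a deviation rotation
#'
#' Projections of the deviated segment axis (column 1 of `R`) onto the
#' two guidance planes:
#' `d_fore_back = sign(-R21) * arccos(R11 / sqrt(R11^2 + R21^2))` and
#' `d_up_down  = sign(-R31) * arccos(R11 / sqrt(R11^2 + R31^2))`,
#' both in `[-pi, pi]`.  A degenerate projection (both components ~ 0)
#' returns 0 with a warning.
#'
#' @param R 3 x 3 deviation rotation matrix.
#' @return named vector `c(fore_back, up_down)` in radians.
#' @export
planar_diffs <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == 3L))
  one <- function(r11, r21) {
    h <- sqrt(r11^2 + r21^2)
    if (h < 1e-12) {
      warning("degenerate planar projection; returning 0")
      return(0)
    }
    s <- sign(-r21)
    if (s == 0) s <- 1
    s * acos(max(-1, min(1, r11 / h)))
  }
  c(fore_back = one(R[1, 1], R[2, 1]), up_down = one(R[1, 1], R[3, 1]))
}

#' Bend-stretch angular difference of a hinge segment
#'
#' Compares the joint angle of the model and the observation: the child
#' longitudinal axis (local x, the pure quaternion (0,1,0,0)) is expressed
#' in the parent frame for both the conditional-mean child orientation and
#' the observed one, and the difference of the arccos of the x-components
#' is returned.  Positive means the observation is straighter than the
#' model (guidance: bend); negative means over-bent (guidance: stretch).
#'
#' @param q_parent_rel observed parent quaternion relative to the waist.
#' @param q_child_rel observed child quaternion relative to the waist.
#' @param mu_child conditional mean 4-vector of the child.
#' @return signed difference in radians, in `[-pi, pi]`.
#' @export
bend_stretch_diff <- function(q_parent_rel, q_child_rel, mu_child) {
  mu <- quat_normalize(mu_child)
  qp <- quat_normalize(q_parent_rel)
  qc <- quat_normalize(q_child_rel)
  if (sum(mu * qc) < 0) qc <- -qc
  v_model <- rotate_vector(quat_normalize(qmul(qinv(qp), mu)), c(1, 0, 0))
  v_actual <- rotate_vector(qmul(qinv(qp), qc), c(1, 0, 0))
  acos(max(-1, min(1, v_model[1]))) - acos(max(-1, min(1, v_actual[1])))
}

guidable_segments <- function() {
  list(planar_arm = c("LUArm", "RUArm"),
       planar_axial = c("head", "LThigh", "RThigh"),
       hinge = c("LFArm", "RFArm", "LShank", "RShank"))
}

#' Orientation word for a segment's signed differences
#'
#' Applies the sign conventions of the guidance vocabulary: upper arms use
#' fore/back (d >= 0: backward) and up/down (d >= 0: downward); head and
#' thighs use fore/back and left/right (d >= 0: leftward, a documented
#' convention); forearms and shanks use bend/stretch (d >= 0: bend).  The
#' word of the larger-magnitude difference is chosen and the extent is its
#' absolute value.
#'
#' @param segment guidable segment name.
#' @param diffs named numeric: `fore_back` and `up_down` for planar
#'   segments, `bend_stretch` for hinge segments.
#' @return list `word`, `extent` (rad), `diffs`.
#' @export
orientation_word <- function(segment, diffs) {
  g <- guidable_segments()
  if (segment %in% g$hinge) {
    d <- diffs[["bend_stretch"]]
    return(list(word = if (d >= 0) "bend" else "stretch",
                extent = abs(d), diffs = diffs))
  }
  if (!segment %in% c(g$planar_arm, g$planar_axial))
    stop("segment ", segment, " has no guidance vocabulary")
  d1 <- diffs[["fore_back"]]; d2 <- diffs[["up_down"]]
  w1 <- if (d1 >= 0) "backward" else "forward"
  w2 <- if (segment %in% g$planar_arm) {
    if (d2 >= 0) "downward" else "upward"
  } else {
    if (d2 >= 0) "leftward" else "rightward"
  }
  if (abs(d1) >= abs(d2)) list(word = w1, extent = abs(d1), diffs = diffs)
  else list(word = w2, extent = abs(d2), diffs = diffs)
}

#' Corrective-guidance report for frames of a recognized posture
#'
#' Evaluates the frames against the posture's Bayesian network, averages
#' the per-frame angular differences of every flagged guidable segment
#' (upper arms and head/thighs through the planar projections of the
#' deviation rotation, forearms/shanks through the hinge difference), and
#' converts them into orientation words and extents.  For non-stand
#' categories the deviation rotation is conjugated by the category's
#' nominal waist rotation first, so words are expressed from the
#' trainer's perspective.  Differences below `min_extent` are considered
#' within the acceptable range and produce no item.
#'
#' @param net a `posture_bayes_net`.
#' @param frames frame rows of the recognized posture.
#' @param category posture category id (drives the perspective remap).
#' @param cal optional [calibration_set()].
#' @param threshold nonstandard flag threshold on the mean score.
#' @param min_extent acceptable-range suppression threshold (rad).
#' @return a `guidance_report`: `posture`, `scores` (mean per segment),
#'   `flagged`, `items` (data.frame segment/word/extent/d1/d2),
#'   `sentences`.
#' @export
guidance_report <- function(net, frames, category = 1L, cal = NULL,
                            threshold = 0.3, min_extent = 0.1) {
  stopifnot(inherits(net, "posture_bayes_net"))
  ev <- evaluate_posture(net, frames, cal = cal, threshold = threshold)
  mean_scores <- colMeans(ev$scores)
  flagged <- names(mean_scores)[mean_scores < threshold]
  Q <- frames_quat_matrix(frames)
  if (!is.null(cal)) Q <- calibrate_frames(Q, cal)
  rel <- relative_to_waist(Q, keep_waist = TRUE)
  topo <- net$topology
  Rw <- quat_to_matrix(category_waist_quat(category))
  g <- guidable_segments()
  items <- list()
  for (s in flagged) {
    if (!s %in% unlist(g)) next  # breast/waist: flagged, not guidable
    i <- segment_index(topo, s)
    ip <- segment_index(topo, topo$parent[[s]])
    n <- nrow(Q)
    if (s %in% g$hinge) {
      d <- vapply(seq_len(n), function(r) {
        tp <- rel[r, seg_cols(ip)]
        cond <- conditional_params(net$edges[[s]], tp)
        bend_stretch_diff(tp, rel[r, seg_cols(i)], cond$mu)
      }, numeric(1))
      diffs <- c(bend_stretch = mean(d))
    } else {
      dm <- vapply(seq_len(n), function(r) {
        tp <- rel[r, seg_cols(ip)]
        cond <- conditional_params(net$edges[[s]], tp)
        R <- deviation_quaternion(cond$mu, rel[r, seg_cols(i)])
        suppressWarnings(planar_diffs(Rw %*% R %*% t(Rw)))
      }, numeric(2))
      diffs <- c(fore_back = mean(dm[1, ]), up_down = mean(dm[2, ]))
    }
    it <- orientation_word(s, diffs)
    if (it$extent >= min_extent)
      items[[s]] <- data.frame(segment = s, word = it$word,
                               extent = it$extent,
                               d1 = diffs[[1]],
                               d2 = if (length(diffs) > 1) diffs[[2]] else NA_real_)
  }
  items <- if (length(items)) do.call(rbind, c(items, make.row.names = FALSE))
  else data.frame(segment = character(), word = character(),
                  extent = numeric(), d1 = numeric(), d2 = numeric())
  rep <- structure(list(posture = net$posture, category = category,
                        scores = mean_scores, flagged = flagged,
                        items = items, threshold = threshold,
                        min_extent = min_extent),
                   class = "guidance_report")
  rep$sentences <- render_report(rep)
  rep
}

side_of <- function(segment) {
  if (startsWith(segment, "L")) "left" else if (startsWith(segment, "R")) "right" else ""
}

#' Render guidance items as imperative sentences
#'
#' One sentence per item with the extent in radians to 2 decimals, e.g.
#' "lift up your left arm (0.30 rad)" or "straighten your right forearm
#' (0.45 rad)"; an empty item list renders as a posture-standard message.
#'
#' @param report a `guidance_report` (or any list with an `items`
#'   data.frame).
#' @return character vector of sentences.
#' @export
render_report <- function(report) {
  items <- report$items
  if (!nrow(items)) return("Posture standard: no correction needed.")
  phrase <- function(segment, word) {
    side <- side_of(segment)
    if (segment %in% c("LUArm", "RUArm")) {
      switch(word,
             upward = paste0("lift up your ", side, " arm"),
             downward = paste0("put down your ", side, " arm"),
             forward = paste0("move your ", side, " arm forward"),
             backward = paste0("move your ", side, " arm backward"))
    } else if (segment %in% c("LFArm", "RFArm")) {
      switch(word,
             stretch = paste0("straighten your ", side, " forearm"),
             bend = paste0("bend your ", side, " forearm"))
    } else if (segment %in% c("LShank", "RShank")) {
      switch(word,
             stretch = paste0("straighten your ", side, " knee"),
             bend = paste0("bend your ", side, " knee"))
    } else if (segment %in% c("LThigh", "RThigh")) {
      switch(word,
             leftward = paste0("put your ", side, " leg to left"),
             rightward = paste0("put your ", side, " leg to right"),
             forward = paste0("move your ", side, " leg forward"),
             backward = paste0("move your ", side, " leg backward"))
    } else if (segment == "head") {
      switch(word,
             leftward = "tilt your head to left",
             rightward = "tilt your head to right",
             forward = "tilt your head forward",
             backward = "tilt your head backward")
    } else paste("adjust your", segment)
  }
  vapply(seq_len(nrow(items)), function(r)
    sprintf("%s (%.2f rad)", phrase(items$segment[r], items$word[r]),
            items$extent[r]), character(1))
}

#' @export
print.guidance_report <- function(x, ...) {
  cat(sprintf("Guidance report (posture %s, category %d)\n",
              x$posture, x$category))
  cat("  segment scores:",
      paste(sprintf("%s=%.2f", names(x$scores), x$scores), collapse = " "),
      "\n")
  for (s in x$sentences) cat("  -", s, "\n")
  invisible(x)
}
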