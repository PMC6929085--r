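#' Default mounting-frame constants
#'
#' Constant unit quaternions mapping the two sensor mounting frames (O1:
#' trunk, head and legs; O2: arms) into the animation frame, recorded once
#' for the suit geometry.
#'
#' @return a list with unit quaternions `init1` = (0, sqrt(2)/2,
#'   sqrt(2)/2, 0) and `init2` = (1/2, -1/2, -1/2, -1/2).
#' @export
default_init_quats <- function() {
  list(init1 = c(0, sqrt(2) / 2, sqrt(2) / 2, 0),
       init2 = c(0.5, -0.5, -0.5, -0.5))
}

#' Build a calibration set
#'
#' A calibration set holds the 11 sensor quaternions recorded while the
#' subject holds the known calibration posture, plus the two constant
#' mounting-frame quaternions.  It anchors the map from raw sensor output
#' to the common animation frame: for segment i,
#' `q_i_interface = q_init * q_cali_i^-1 * q_i_global`,
#' with `q_init` = `init1` for O1 segments and `init2` for O2 segments.
#'
#' @param cali 11 x 4 matrix (IMU index order 0..10) of unit quaternions
#'   recorded in the calibration posture.
#' @param init1,init2 unit quaternions for the two mounting groups.
#' @return a `calibration_set` object.
#' @export
calibration_set <- function(cali,
                            init1 = default_init_quats()$init1,
                            init2 = default_init_quats()$init2) {
  cali <- as.matrix(cali)
  if (!is.numeric(cali) || nrow(cali) != 11L || ncol(cali) != 4L)
    stop("cali must be an 11 x 4 numeric matrix of quaternions")
  for (i in 1:11)
    if (abs(sqrt(sum(cali[i, ]^2)) - 1) > 1e-6)
      stop("calibration quaternion for segment index ", i - 1L,
           " is not unit norm")
  check_quat(init1); check_quat(init2)
  rownames(cali) <- body_topology()$segments
  structure(list(cali = cali, init1 = init1, init2 = init2),
            class = "calibration_set")
}

#' Identity calibration for data already in the animation frame
#'
#' Raw quaternions equal to `q_init * q_cali^-1 * q` reduce to `q` when
#' `cali_i` is chosen as the applicable init constant, so this calibration
#' passes already-calibrated (e.g. synthetic) frames through unchanged.
#'
#' @return a `calibration_set`.
#' @export
identity_calibration <- function() {
  ini <- default_init_quats()
  topo <- body_topology()
  cali <- t(vapply(topo$segments, function(s) {
    if (topo$init_group[[s]] == "O1") ini$init1 else ini$init2
  }, numeric(4)))
  calibration_set(cali)
}

#' Calibrate raw sensor quaternions into the animation frame
#'
#' Applies `q_i_interface = q_init_g(i) * q_cali_i^-1 * q_i_global` to each
#' of the 11 segments, where g(i) selects `init1` for segments mounted in
#' frame O1 (head, breast, waist, thighs, shanks) and `init2` for frame O2
#' (upper arms, forearms).
#'
#' @param raw 11 x 4 matrix of raw unit quaternions in IMU index order, or
#'   an n x 44 matrix of frame rows.
#' @param cal a [calibration_set()].
#' @param topo a [body_topology()].
#' @return matrix of the same shape with animation-frame quaternions.
#' @export
calibrate_frames <- function(raw, cal, topo = body_topology()) {
  stopifnot(inherits(cal, "calibration_set"))
  wide <- is.matrix(raw) && ncol(raw) == 44L
  if (!wide) {
    raw <- as.matrix(raw)
    if (nrow(raw) != 11L || ncol(raw) != 4L)
      stop("raw must be 11 x 4 (one frame) or n x 44 (frame rows)")
    raw <- matrix(t(raw), nrow = 1)  # one wide row
  }
  bad <- which(abs(sqrt(raw[, seq(1, 44, 4), drop = FALSE]^2 +
                        raw[, seq(2, 44, 4), drop = FALSE]^2 +
                        raw[, seq(3, 44, 4), drop = FALSE]^2 +
                        raw[, seq(4, 44, 4), drop = FALSE]^2) - 1) > 1e-6,
               arr.ind = TRUE)
  if (length(bad))
    stop("non-unit raw quaternion for segment index ",
         bad[1, 2] - 1L, " (frame ", bad[1, 1], ")")
  out <- raw
  for (s in topo$segments) {
    i <- topo$imu_index[[s]]
    ini <- if (topo$init_group[[s]] == "O1") cal$init1 else cal$init2
    pre <- qmul(ini, qinv(cal$cali[s, ]))
    out[, seg_cols(i)] <- qmul_rows(pre, raw[, seg_cols(i), drop = FALSE])
  }
  if (wide) out else matrix(out, nrow = 11, byrow = TRUE)
}

#' Body-segment quaternions relative to the waist
#'
#' For every segment i except the waist root, `q_i_rel = q_waist^-1 * q_i`
#' in the animation frame; results are hemisphere-canonical.
#'
#' @param frame 11 x 4 matrix of calibrated quaternions, or n x 44 frame
#'   rows.
#' @param keep_waist if `TRUE` the waist column block is retained (as the
#'   identity); otherwise rows/blocks follow IMU order skipping index 6.
#' @return 10 x 4 matrix named by segment (single frame) or n x 40 matrix
#'   (frame rows).
#' @export
relative_to_waist <- function(frame, keep_waist = FALSE) {
  wide <- is.matrix(frame) && ncol(frame) == 44L
  if (!wide) frame <- matrix(t(as.matrix(frame)), nrow = 1)
  winv <- qinv_rows(frame[, seg_cols(6L), drop = FALSE])
  segs <- if (keep_waist) 0:10 else setdiff(0:10, 6L)
  out <- matrix(0, nrow(frame), 4L * length(segs))
  for (k in seq_along(segs)) {
    q <- canonical_rows(qmul_rows(winv, frame[, seg_cols(segs[k]), drop = FALSE]))
    out[, 4L * (k - 1L) + 1:4] <- q
  }
  if (wide) return(out)
  m <- matrix(out, ncol = 4, byrow = TRUE)
  rownames(m) <- body_topology()$segments[segs + 1L]
  m
}

#' Angle between two segments along a shared local axis
#'
#' Rotates `axis` (default the segment longitudinal axis, local x) by each
#' quaternion and returns the arccos of the dot product of the two world
#' directions, in `[0, pi]`.
#'
#' @param qa,qb unit quaternions in a common frame.
#' @param axis nonzero 3-vector.
#' @return angle in radians.
#' @export
inter_segment_angle <- function(qa, qb, axis = c(1, 0, 0)) {
  if (sqrt(sum(axis^2)) < 1e-12) stop("axis must be nonzero")
  a <- axis / sqrt(sum(axis^2))
  va <- rotate_vector(qa, a)
  vb <- rotate_vector(qb, a)
  acos(max(-1, min(1, sum(va * vb))))
}

#' Read / write a calibration set as JSON
#'
#' The JSON document stores the 11 named calibration quaternions and the
#' two init constants, components in scalar-first (w, x, y, z) order.
#'
#' @param cal a [calibration_set()].
#' @param path file path.
#' @return `read_calibration` returns a `calibration_set`.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_set"))
  doc <- list(format = "imupose-calibration/1",
              component_order = c("w", "x", "y", "z"),
              init1 = cal$init1, init2 = cal$init2,
              cali = stats::setNames(
                lapply(seq_len(11), function(i) unname(cal$cali[i, ])),
                rownames(cal$cali)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- body_topology()$segments
  if (!all(segs %in% names(doc$cali)))
    stop("calibration file is missing segments: ",
         paste(setdiff(segs, names(doc$cali)), collapse = ", "))
  cali <- do.call(rbind, doc$cali[segs])
  calibration_set(cali, init1 = doc$init1, init2 = doc$init2)
}
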