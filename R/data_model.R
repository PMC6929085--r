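#' Posture-to-category map
#'
#' The 18 modelled static postures fall into 5 waist-orientation
#' categories: postures 1-5 "stand", 6-7 "lean left", 8-9 "lean right",
#' 10-13 "lie on stomach", 14-18 "lie on back".
#'
#' @return integer vector of length 18, names "1".."18", values 1..5.
#' @export
default_category_map <- function() {
  stats::setNames(rep.int(1:5, c(5L, 2L, 2L, 4L, 5L)), as.character(1:18))
}

#' @rdname default_category_map
#' @export
category_names <- function() {
  c("stand", "lean left", "lean right", "lie on stomach", "lie on back")
}

frame_col_names <- function() {
  c("subject", "posture", "instance", "time",
    paste0("q", rep(0:10, each = 4), "_", c("w", "x", "y", "z")))
}

#' Construct a posture database
#'
#' A posture database is a frame table (one row per 40 Hz sample) plus the
#' posture-to-category map.  Frame columns: `subject`, `posture` (1-18),
#' `instance` (id unique within subject x posture), `time` (s, strictly
#' increasing within an instance) and 44 quaternion components `q0_w` ..
#' `q10_z` in IMU index order (scalar first).
#'
#' @param frames data.frame with the 48 columns above.
#' @param category_map named integer vector posture id -> category id.
#' @param validate check quaternion unit norm and timestamp ordering.
#' @return a `posture_db` object.
#' @export
posture_database <- function(frames, category_map = default_category_map(),
                             validate = TRUE) {
  cols <- frame_col_names()
  if (!all(cols %in% names(frames)))
    stop("frame table is missing columns: ",
         paste(setdiff(cols, names(frames)), collapse = ", "))
  frames <- as.data.frame(frames)[cols]
  if (validate && nrow(frames)) {
    Q <- as.matrix(frames[, -(1:4)])
    n2 <- Q[, seq(1, 44, 4)]^2 + Q[, seq(2, 44, 4)]^2 +
      Q[, seq(3, 44, 4)]^2 + Q[, seq(4, 44, 4)]^2
    bad <- which(abs(sqrt(n2) - 1) > 1e-6, arr.ind = TRUE)
    if (length(bad))
      stop("non-unit quaternion in frame ", bad[1, 1],
           " (segment index ", bad[1, 2] - 1L, ")")
    ok <- unlist(lapply(split(frames$time,
                              interaction(frames$subject, frames$posture,
                                          frames$instance, drop = TRUE)),
                        function(tt) all(diff(tt) > 0)), use.names = FALSE)
    if (!all(ok)) stop("timestamps must be strictly increasing within an instance")
    if (!all(frames$posture %in% as.integer(names(category_map))))
      stop("frames contain posture labels outside the category map")
  }
  structure(list(frames = frames, category_map = category_map),
            class = "posture_db")
}

#' @export
print.posture_db <- function(x, ...) {
  idx <- db_instances(x)
  cat(sprintf(paste0("Posture database: %d frames, %d instances, ",
                     "%d subjects, %d postures in %d categories\n"),
              nrow(x$frames), nrow(idx), length(unique(x$frames$subject)),
              length(unique(x$frames$posture)),
              length(unique(x$category_map))))
  invisible(x)
}

#' Instance index of a database
#'
#' @param db a `posture_db`.
#' @return data.frame with one row per (subject, posture, instance) and the
#'   frame count of each.
#' @export
db_instances <- function(db) {
  f <- db$frames
  if (!nrow(f))
    return(data.frame(subject = integer(), posture = integer(),
                      instance = integer(), n_frames = integer()))
  agg <- stats::aggregate(list(n_frames = f$time),
                          by = list(subject = f$subject, posture = f$posture,
                                    instance = f$instance), FUN = length)
  agg[order(agg$subject, agg$posture, agg$instance), , drop = FALSE]
}

#' Write / read a posture database as CSV
#'
#' One row per frame, 48 columns (see [posture_database()]), full double
#' precision; lossless round-trip.
#'
#' @param db a `posture_db`.
#' @param path CSV file path.
#' @return `read_posture_db` returns a `posture_db`.
#' @export
write_posture_db <- function(db, path) {
  stopifnot(inherits(db, "posture_db"))
  out <- db$frames
  # format doubles with 17 significant digits so the CSV round-trips the
  # quaternions exactly (fwrite's default is 15)
  for (j in which(vapply(out, is.double, logical(1))))
    out[[j]] <- sprintf("%.17g", out[[j]])
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_posture_db
#' @param category_map posture-to-category map for the read database.
#' @export
read_posture_db <- function(path, category_map = default_category_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty database file: ", path)
    empty <- as.data.frame(matrix(numeric(), 0, 48,
                                  dimnames = list(NULL, frame_col_names())))
    return(posture_database(empty, category_map, validate = FALSE))
  }
  frames <- as.data.frame(data.table::fread(path))
  if (!nrow(frames)) {
    warning("database file has a header but no frames: ", path)
    frames <- as.data.frame(matrix(numeric(), 0, 48,
                                   dimnames = list(NULL, frame_col_names())))
    return(posture_database(frames, category_map, validate = FALSE))
  }
  if (ncol(frames) != 48L)
    stop("malformed database file (", ncol(frames),
         " columns, expected 48): ", path)
  tryCatch(posture_database(frames, category_map),
           error = function(e) stop("while reading ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Split a database into train and test sets at instance granularity
#'
#' Stratified per (subject, posture) cell: from each cell, round(fraction
#' x n) whole instances go to the training set (e.g. 3 of 10 at 30%), the
#' rest to the test set.  Splitting whole instances avoids temporal
#' leakage of frames from one performance across the split.
#'
#' @param db a `posture_db`.
#' @param train_fraction in (0, 1).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with `posture_db` elements `train` and `test`.
#' @export
split_posture_db <- function(db, train_fraction = 0.3, seed = 1L) {
  stopifnot(inherits(db, "posture_db"),
            train_fraction > 0, train_fraction < 1)
  idx <- db_instances(db)
  if (!nrow(idx)) stop("cannot split an empty database")
  cells <- split(idx, list(idx$subject, idx$posture), drop = TRUE)
  keys <- paste(db$frames$subject, db$frames$posture, db$frames$instance)
  train_keys <- character(0)
  with_seed(seed, {
    for (nm in sort(names(cells))) {
      cell <- cells[[nm]]
      n_train <- floor(train_fraction * nrow(cell) + 0.5)
      pick <- sort(sample(cell$instance, n_train))
      train_keys <- c(train_keys,
                      paste(cell$subject[1], cell$posture[1], pick))
    }
  })
  in_train <- keys %in% train_keys
  list(train = posture_database(db$frames[in_train, , drop = FALSE],
                                db$category_map, validate = FALSE),
       test = posture_database(db$frames[!in_train, , drop = FALSE],
                               db$category_map, validate = FALSE))
}

#' Per-subject inter-segment angle statistics for one posture
#'
#' For every subject, the mean, standard deviation and range (max - min)
#' of the angle between two segments over all frames of the given posture,
#' plus the across-subject range of the per-subject means.  This is the
#' inter-subject variability summary used to quantify how differently
#' subjects shape the same posture.
#'
#' @param db a `posture_db` (frames assumed in the animation frame).
#' @param posture posture id.
#' @param seg_a,seg_b segment name or IMU index.
#' @param axis local axis compared across segments (default longitudinal).
#' @return list with `per_subject` (data.frame subject/mean/sd/range) and
#'   `range_of_means`.
#' @export
angle_statistics <- function(db, posture, seg_a, seg_b, axis = c(1, 0, 0)) {
  stopifnot(inherits(db, "posture_db"))
  topo <- body_topology()
  ia <- segment_index(topo, seg_a); ib <- segment_index(topo, seg_b)
  f <- db$frames[db$frames$posture == posture, , drop = FALSE]
  if (!nrow(f)) stop("posture ", posture, " not present in the database")
  if (sqrt(sum(axis^2)) < 1e-12) stop("axis must be nonzero")
  Q <- as.matrix(f[, -(1:4)])
  a <- axis / sqrt(sum(axis^2))
  Ra <- quat_to_matrix_rows(Q[, seg_cols(ia), drop = FALSE])
  Rb <- quat_to_matrix_rows(Q[, seg_cols(ib), drop = FALSE])
  # world direction of `a` under each rotation: R %*% a, rows of R row-major
  va <- cbind(Ra[, 1] * a[1] + Ra[, 2] * a[2] + Ra[, 3] * a[3],
              Ra[, 4] * a[1] + Ra[, 5] * a[2] + Ra[, 6] * a[3],
              Ra[, 7] * a[1] + Ra[, 8] * a[2] + Ra[, 9] * a[3])
  vb <- cbind(Rb[, 1] * a[1] + Rb[, 2] * a[2] + Rb[, 3] * a[3],
              Rb[, 4] * a[1] + Rb[, 5] * a[2] + Rb[, 6] * a[3],
              Rb[, 7] * a[1] + Rb[, 8] * a[2] + Rb[, 9] * a[3])
  ang <- acos(pmin(1, pmax(-1, rowSums(va * vb))))
  per <- lapply(split(ang, f$subject), function(x)
    c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
      range = diff(range(x))))
  tab <- data.frame(subject = as.integer(names(per)),
                    do.call(rbind, per), row.names = NULL)
  tab <- tab[order(tab$subject), , drop = FALSE]
  list(per_subject = tab, range_of_means = diff(range(tab$mean)))
}

#' Per-posture accuracy table with totals row
#'
#' Aggregates correct/total counts per posture in the reporting style used
#' for recognition benchmarks: a row per posture plus a `Total` row whose
#' counts are summed before dividing; percentages rounded to 2 decimals.
#'
#' @param correct,total integer vectors of per-posture counts.
#' @param posture posture ids (default sequence along counts).
#' @return data.frame with columns posture, correct, total, accuracy_pct.
#' @export
accuracy_table <- function(correct, total, posture = seq_along(correct)) {
  if (length(correct) != length(total) || !length(correct))
    stop("correct and total must be nonempty vectors of equal length")
  if (any(total < correct)) stop("correct counts exceed totals")
  pct <- function(c, t) if (t == 0) NA_real_ else round(100 * c / t, 2)
  data.frame(posture = c(as.character(posture), "Total"),
             correct = c(correct, sum(correct)),
             total = c(total, sum(total)),
             accuracy_pct = c(mapply(pct, correct, total),
                              pct(sum(correct), sum(total))))
}

# run code under a temporary RNG state, restoring afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  eval.parent(substitute(code))
}
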