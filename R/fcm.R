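#' Body-relative rotation-matrix features
#'
#' The second-stage feature is 90-dimensional: for each of the ten
#' non-waist segments (IMU order 0, 1, 2, 3, 4, 5, 7, 8, 9, 10), the nine
#' row-major rotation-matrix components of the segment quaternion relative
#' to the waist (`q_rel = q_waist^-1 * q_i`).
#'
#' @inheritParams extract_waist_features
#' @return n x 90 numeric matrix.
#' @export
extract_body_features <- function(frames, cal = NULL) {
  Q <- frames_quat_matrix(frames)
  if (!is.null(cal)) Q <- calibrate_frames(Q, cal)
  rel <- relative_to_waist(Q)           # n x 40
  out <- matrix(0, nrow(rel), 90)
  for (k in 1:10)
    out[, 9L * (k - 1L) + 1:9] <-
      quat_to_matrix_rows(rel[, 4L * (k - 1L) + 1:4, drop = FALSE])
  out
}

# squared euclidean distances of rows of X (n x d) to rows of M (K x d)
dist2_to_centers <- function(X, M) {
  D <- -2 * X %*% t(M)
  D <- sweep(D, 2, rowSums(M^2), "+") + rowSums(X^2)
  pmax(D, 0)
}

#' Fuzzy membership degrees
#'
#' `mu_j(x) proportional to ||x - m_j||^(-2/(b-1))`, normalized to sum 1
#' over clusters.  A sample coinciding with a center gets crisp membership
#' 1 on that cluster (the singular limit of the update).
#'
#' @param X n x d sample matrix (or a single sample vector).
#' @param centers K x d center matrix.
#' @param b fuzzy weight index (> 1).  Default 2.
#' @return n x K membership matrix, rows summing to 1.
#' @export
fcm_membership <- function(X, centers, b = 2) {
  stopifnot(b > 1)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  D2 <- dist2_to_centers(X, centers)
  U <- D2^(-1 / (b - 1))
  sing <- which(apply(D2 < 1e-24, 1, any))
  U <- U / rowSums(U)
  for (i in sing) {
    U[i, ] <- 0
    U[i, which.min(D2[i, ])] <- 1
  }
  U
}

#' Membership-weighted center update
#'
#' `m_j = sum_i mu_ij^b x_i / sum_i mu_ij^b`.  A cluster with (near) zero
#' total weight is reinitialized at the sample farthest from the current
#' centers.
#'
#' @param X n x d samples.
#' @param U n x K memberships.
#' @param b fuzzy weight index.
#' @param centers current centers, used only to reseed empty clusters.
#' @return K x d center matrix.
#' @export
fcm_update_centers <- function(X, U, b = 2, centers = NULL) {
  Ub <- U^b
  w <- colSums(Ub)
  M <- crossprod(Ub, X) / w
  empty <- which(w < 1e-12)
  if (length(empty)) {
    ref <- if (is.null(centers)) M[-empty, , drop = FALSE] else centers
    far <- order(-apply(dist2_to_centers(X, ref), 1, min))
    for (j in seq_along(empty)) M[empty[j], ] <- X[far[j], ]
  }
  M
}

fcm_objective <- function(X, M, U, b) sum(U^b * dist2_to_centers(X, M))

#' Fit a fuzzy C-means model
#'
#' Alternates the membership and center updates until the objective
#' `J_f = sum_ij mu_ij^b ||x_i - m_j||^2` decreases by less than `tol`;
#' alternating minimization makes `J_f` non-increasing.  Centers start
#' from `init_centers` when given (the per-posture labelled means in the
#' two-stage trainer), otherwise from `K2` distinct samples drawn with
#' `seed`.
#'
#' @param X n x d samples.
#' @param K2 cluster count (the category's posture count).
#' @param b fuzzy weight index.  Default 2.
#' @param seed seed for random initialization.
#' @param tol convergence tolerance on `J_f`.  Default 1e-8.
#' @param max_iter iteration cap.  Default 500.
#' @param init_centers optional K2 x d matrix.
#' @return an unlabelled `fcm_model` (centers, `U`, objective trace).
#' @export
fcm_fit <- function(X, K2, b = 2, seed = 1L, tol = 1e-8, max_iter = 500L,
                    init_centers = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(K2 >= 2)
  if (nrow(unique(as.data.frame(X))) < K2)
    stop("K2 exceeds the number of distinct samples")
  M <- if (!is.null(init_centers)) {
    stopifnot(nrow(init_centers) == K2, ncol(init_centers) == ncol(X))
    as.matrix(init_centers)
  } else {
    with_seed(seed, {
      picks <- integer(0)
      cand <- sample(nrow(X))
      for (i in cand) {
        if (!length(picks) ||
            min(dist2_to_centers(X[i, , drop = FALSE],
                                 X[picks, , drop = FALSE])) > 1e-24)
          picks <- c(picks, i)
        if (length(picks) == K2) break
      }
      X[picks, , drop = FALSE]
    })
  }
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    U <- fcm_membership(X, M, b)
    M <- fcm_update_centers(X, U, b, centers = M)
    J <- fcm_objective(X, M, U, b)
    trace <- c(trace, J)
    if (it > 1L && trace[it - 1L] - J < tol) break
  }
  structure(list(K2 = as.integer(K2), b = b, centers = M, U = U,
                 objective = trace, labels = NULL, category = NA_integer_),
            class = "fcm_model")
}

#' Map clusters to posture labels
#'
#' Each cluster takes the posture label with the greatest total membership
#' mass; bijectivity is enforced greedily (best unassigned cluster-label
#' pair first).  A forced non-argmax assignment raises a warning and the
#' remaining clusters are matched by exclusion.
#'
#' @param model an `fcm_model`.
#' @param X the labelled samples (n x d).
#' @param labels posture labels of the samples; the label set must have
#'   exactly `K2` distinct values.
#' @return the model with `labels` set (cluster j -> posture `labels[j]`).
#' @export
fcm_assign_labels <- function(model, X, labels) {
  stopifnot(inherits(model, "fcm_model"))
  labs <- sort(unique(labels))
  if (length(labs) != model$K2)
    stop("need exactly K2 = ", model$K2, " distinct labels, got ",
         length(labs))
  U <- fcm_membership(X, model$centers, model$b)
  mass <- vapply(labs, function(l)
    colSums(U[labels == l, , drop = FALSE]), numeric(model$K2))
  # mass: K2 clusters x K2 labels; greedy best-pair assignment
  assign <- integer(model$K2)
  m <- mass
  forced <- FALSE
  for (step in seq_len(model$K2)) {
    ij <- which(m == max(m), arr.ind = TRUE)[1, ]
    if (mass[ij[1], ij[2]] < max(mass[ij[1], ])) forced <- TRUE
    assign[ij[1]] <- ij[2]
    m[ij[1], ] <- -Inf
    m[, ij[2]] <- -Inf
  }
  if (forced)
    warning("cluster-label assignment was not mutually argmax; ",
            "remaining clusters matched by exclusion")
  model$labels <- labs[assign]
  model
}

#' Thresholded posture prediction from an FCM model
#'
#' Label of the maximum-membership cluster if that membership exceeds
#' `t2`, else rejected (`NA`).  Ties resolve to the lowest cluster index.
#'
#' @param model a labelled `fcm_model`.
#' @param X samples (vector or n x d matrix).
#' @param t2 acceptance threshold.  Default 0.3.
#' @return integer posture ids, `NA` where rejected.
#' @export
predict_posture <- function(model, X, t2 = 0.3) {
  stopifnot(inherits(model, "fcm_model"))
  if (is.null(model$labels)) stop("model has no cluster-label map; ",
                                  "run fcm_assign_labels() first")
  U <- fcm_membership(X, model$centers, model$b)
  j <- max.col(U, ties.method = "first")
  out <- model$labels[j]
  out[U[cbind(seq_len(nrow(U)), j)] <= t2] <- NA_integer_
  out
}

#' @export
print.fcm_model <- function(x, ...) {
  cat(sprintf("Fuzzy C-means model: K2 = %d clusters, b = %g, %d-dim centers\n",
              x$K2, x$b, ncol(x$centers)))
  if (!is.null(x$labels))
    cat("  cluster -> posture:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}
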