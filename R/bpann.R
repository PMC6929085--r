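#' Waist rotation-matrix features
#'
#' The first-stage feature is the 9-vector of row-major rotation-matrix
#' components of the waist orientation in the animation frame,
#' `(R11, R12, ..., R33)`.
#'
#' @param frames n x 44 matrix of frame rows (or a `posture_db`, or a
#'   data.frame of frame rows), already calibrated, or raw with `cal`.
#' @param cal optional [calibration_set()] applied to raw frames.
#' @return n x 9 numeric matrix.
#' @export
extract_waist_features <- function(frames, cal = NULL) {
  Q <- frames_quat_matrix(frames)
  if (!is.null(cal)) Q <- calibrate_frames(Q, cal)
  quat_to_matrix_rows(Q[, seg_cols(6L), drop = FALSE])
}

frames_quat_matrix <- function(frames) {
  if (inherits(frames, "posture_db")) frames <- frames$frames
  if (is.data.frame(frames)) {
    qc <- frame_col_names()[-(1:4)]
    frames <- as.matrix(frames[, qc])
  }
  if (is.matrix(frames) && ncol(frames) == 4L && nrow(frames) == 11L)
    frames <- matrix(t(frames), nrow = 1)
  if (!is.matrix(frames) || ncol(frames) != 44L)
    stop("frames must be n x 44 quaternion rows, an 11 x 4 frame, ",
         "a frame data.frame, or a posture_db")
  frames
}

#' Initialize a three-layer sigmoid classification network
#'
#' Architecture 9-15-5 with bias units in the input and hidden layers:
#' weights `W2` (15 x 10) map the biased input to the hidden layer and
#' `W3` (5 x 16) map the biased hidden layer to the 5 category outputs.
#' Weights start uniform in +/- sqrt(6 / (fan_in + fan_out)).
#'
#' @param sizes layer sizes `c(input, hidden, output)`.
#' @param seed integer seed for the weight draw.
#' @return an `ann_model`.
#' @export
ann_init <- function(sizes = c(9L, 15L, 5L), seed = 1L) {
  stopifnot(length(sizes) == 3L, all(sizes >= 1L))
  with_seed(seed, {
    lim2 <- sqrt(6 / (sizes[1] + sizes[2]))
    lim3 <- sqrt(6 / (sizes[2] + sizes[3]))
    structure(list(sizes = as.integer(sizes),
                   W2 = matrix(stats::runif(sizes[2] * (sizes[1] + 1L),
                                            -lim2, lim2), sizes[2]),
                   W3 = matrix(stats::runif(sizes[3] * (sizes[2] + 1L),
                                            -lim3, lim3), sizes[3]),
                   meta = list(seed = as.integer(seed))),
              class = "ann_model")
  })
}

check_ann <- function(model) {
  stopifnot(inherits(model, "ann_model"))
  if (!all(is.finite(model$W2)) || !all(is.finite(model$W3)))
    stop("model weights contain non-finite values")
  s <- model$sizes
  stopifnot(all(dim(model$W2) == c(s[2], s[1] + 1L)),
            all(dim(model$W3) == c(s[3], s[2] + 1L)))
  invisible(model)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass of the category network
#'
#' Layer-wise `o = sigmoid(W %*% c(1, o_prev))`; the five outputs are
#' independent sigmoid scores in (0, 1) (no softmax coupling).
#'
#' @param model an `ann_model`.
#' @param X n x 9 feature matrix (or a single feature vector).
#' @return n x 5 matrix of category scores.
#' @export
ann_forward <- function(model, X) {
  check_ann(model)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == model$sizes[1])
  H <- sigmoid(cbind(1, X) %*% t(model$W2))
  sigmoid(cbind(1, H) %*% t(model$W3))
}

one_hot <- function(y, K) {
  Y <- matrix(0, length(y), K)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

clip01 <- function(p, eps = 1e-12) pmin(1 - eps, pmax(eps, p))

#' Regularized cross-entropy cost
#'
#' Mean over samples of the summed per-output binary cross-entropies plus
#' an L2 penalty `lambda/(2m)` on all non-bias weights.  Predicted
#' probabilities are clipped to `[1e-12, 1 - 1e-12]` to keep the logs
#' finite.
#'
#' @param model an `ann_model`.
#' @param X n x 9 features; `y` integer categories in 1..5 (or an n x 5
#'   one-hot matrix).
#' @param y labels.
#' @param lambda L2 coefficient (>= 0).
#' @return scalar cost J.
#' @export
ann_cost <- function(model, X, y, lambda = 0) {
  check_ann(model)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Y <- if (is.matrix(y)) y else one_hot(y, model$sizes[3])
  O <- clip01(ann_forward(model, X))
  m <- nrow(X)
  ce <- -sum(Y * log(O) + (1 - Y) * log(1 - O)) / m
  reg <- (lambda / (2 * m)) *
    (sum(model$W2[, -1]^2) + sum(model$W3[, -1]^2))
  ce + reg
}

#' Analytic gradients of the cost
#'
#' Exact backpropagation gradient of [ann_cost()]: output delta `o - y`,
#' hidden delta through the sigmoid derivative, penalty `lambda/m` on
#' non-bias entries.
#'
#' @inheritParams ann_cost
#' @return list with matrices `W2`, `W3` shaped like the weights.
#' @export
ann_gradients <- function(model, X, y, lambda = 0) {
  check_ann(model)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Y <- if (is.matrix(y)) y else one_hot(y, model$sizes[3])
  m <- nrow(X)
  A1 <- cbind(1, X)
  H <- sigmoid(A1 %*% t(model$W2))
  A2 <- cbind(1, H)
  O <- sigmoid(A2 %*% t(model$W3))
  D3 <- O - Y
  gW3 <- crossprod(D3, A2) / m
  D2 <- (D3 %*% model$W3[, -1, drop = FALSE]) * H * (1 - H)
  gW2 <- crossprod(D2, A1) / m
  if (lambda > 0) {
    gW3[, -1] <- gW3[, -1] + (lambda / m) * model$W3[, -1]
    gW2[, -1] <- gW2[, -1] + (lambda / m) * model$W2[, -1]
  }
  list(W2 = gW2, W3 = gW3)
}

#' Training configuration for the category network
#'
#' @param lambda L2 coefficient.  Default 0.01.
#' @param learning_rate initial full-batch step.  Default 0.5.
#' @param max_epochs iteration cap.  Default 5000.
#' @param tol convergence tolerance on the cost decrease.  Default 1e-6.
#' @param seed weight-initialization seed.
#' @return an `ann_config` list.
#' @export
ann_config <- function(lambda = 0.01, learning_rate = 0.5,
                       max_epochs = 5000L, tol = 1e-6, seed = 1L) {
  stopifnot(lambda >= 0, learning_rate > 0, max_epochs >= 1, tol >= 0)
  structure(list(lambda = lambda, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), tol = tol,
                 seed = as.integer(seed)), class = "ann_config")
}

#' Train the category network by full-batch backpropagation
#'
#' Gradient descent with a backtracking line search (the step is halved
#' until the cost does not increase), so the cost sequence is monotone
#' non-increasing; stops when the decrease falls below `tol` or at
#' `max_epochs`.  Deterministic given the config seed.
#'
#' @param X n x 9 waist features.
#' @param y integer category labels in 1..K (K = output size, 5).
#' @param config an [ann_config()].
#' @param sizes layer sizes.
#' @return a trained `ann_model` with `meta` holding the cost trace tail,
#'   epochs used, lambda and seed.
#' @export
ann_train <- function(X, y, config = ann_config(), sizes = c(9L, 15L, 5L)) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  K <- sizes[3]
  missing_cat <- setdiff(seq_len(K), unique(y))
  if (length(missing_cat))
    stop("training data is missing categories: ",
         paste(missing_cat, collapse = ", "))
  model <- ann_init(sizes, config$seed)
  Y <- one_hot(y, K)
  eta <- config$learning_rate
  J <- ann_cost(model, X, Y, config$lambda)
  trace <- J
  for (epoch in seq_len(config$max_epochs)) {
    g <- ann_gradients(model, X, Y, config$lambda)
    accepted <- FALSE
    while (eta > 1e-12) {
      cand <- model
      cand$W2 <- model$W2 - eta * g$W2
      cand$W3 <- model$W3 - eta * g$W3
      Jc <- ann_cost(cand, X, Y, config$lambda)
      if (Jc <= J) { accepted <- TRUE; break }
      eta <- eta / 2
    }
    if (!accepted) break
    dJ <- J - Jc
    model <- cand
    J <- Jc
    trace <- c(trace, J)
    eta <- min(eta * 1.1, config$learning_rate * 20)
    if (dJ < config$tol) break
  }
  model$meta <- list(seed = config$seed, lambda = config$lambda,
                     epochs = length(trace) - 1L, final_cost = J,
                     cost_trace = utils::tail(trace, 50L))
  model
}

#' Thresholded category prediction
#'
#' Argmax category if its score exceeds `t1`, else rejected (`NA`).  Ties
#' at the max resolve to the lowest category index.
#'
#' @param model an `ann_model`.
#' @param X features (vector or n x 9 matrix).
#' @param t1 acceptance threshold in (0, 1).  Default 0.5.
#' @return integer vector of category ids, `NA` where rejected.
#' @export
predict_category <- function(model, X, t1 = 0.5) {
  P <- ann_forward(model, X)
  k <- max.col(P, ties.method = "first")
  k[P[cbind(seq_len(nrow(P)), k)] <= t1] <- NA_integer_
  k
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("Sigmoid classification network %d-%d-%d (bias units in layers 1-2)\n",
              x$sizes[1], x$sizes[2], x$sizes[3]))
  if (!is.null(x$meta$epochs))
    cat(sprintf("  trained %d epochs, final cost %.6g (lambda = %g)\n",
                x$meta$epochs, x$meta$final_cost, x$meta$lambda))
  invisible(x)
}
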