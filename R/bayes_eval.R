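#' Fit the joint child-parent Gaussian of one topology edge
#'
#' Stacks child and parent quaternion samples into 8-vectors `z = (s, t)`,
#' takes population moments (divide by m), adds a ridge `epsilon I` to the
#' covariance (unit-norm quaternion data is rank-deficient), and partitions
#' the precision into the 4 x 4 blocks `B11, B12, B21, B22` used by the
#' conditional.  Samples are hemisphere-canonicalized and then aligned to
#' the per-edge mean direction so the Gaussian lives on one sheet of the
#' double cover.
#'
#' @param S m x 4 child quaternion samples (relative to the waist).
#' @param T_ m x 4 parent quaternion samples.
#' @param ridge ridge epsilon.  Default 1e-6.
#' @return an `edge_gaussian` (means, joint covariance, precision blocks).
#' @export
fit_joint_gaussian <- function(S, T_, ridge = 1e-6) {
  S <- as.matrix(S); T_ <- as.matrix(T_)
  m <- nrow(S)
  if (m < 2L) stop("need at least 2 samples to fit an edge Gaussian")
  if (nrow(T_) != m || ncol(S) != 4L || ncol(T_) != 4L)
    stop("S and T_ must be m x 4 matrices with equal m")
  if (!all(is.finite(S)) || !all(is.finite(T_)))
    stop("non-finite samples rejected")
  S <- align_hemisphere(canonical_rows(S))
  T_ <- align_hemisphere(canonical_rows(T_))
  Z <- cbind(S, T_)
  mu <- colMeans(Z)
  Zc <- sweep(Z, 2, mu)
  Sigma <- crossprod(Zc) / m                 # population covariance
  P <- solve(Sigma + diag(ridge, 8L))
  structure(list(mu_s = mu[1:4], mu_t = mu[5:8], mu = mu,
                 Sigma = Sigma, ridge = ridge,
                 B11 = P[1:4, 1:4], B12 = P[1:4, 5:8],
                 B21 = P[5:8, 1:4], B22 = P[5:8, 5:8],
                 m = m), class = "edge_gaussian")
}

# flip rows to the hemisphere of the (iterated) mean direction
align_hemisphere <- function(Q, iters = 3L) {
  for (i in seq_len(iters)) {
    mu <- colMeans(Q)
    n <- sqrt(sum(mu^2))
    if (n < 1e-12) break
    flip <- drop(Q %*% mu) < 0
    if (!any(flip)) break
    Q[flip, ] <- -Q[flip, , drop = FALSE]
  }
  Q
}

#' Conditional Gaussian of the child given a parent observation
#'
#' `mu_s|t = mu_s - B11^-1 B12 (t - mu_t)`, `Sigma_s|t = B11^-1`, the
#' child-given-parent conditional derived from the joint precision
#' blocks.  The parent observation is hemisphere-aligned to the fitted
#' parent mean first.
#'
#' @param edge an `edge_gaussian`.
#' @param t_obs parent quaternion (4-vector).
#' @return a `cond_gaussian` with `mu` (4-vector) and `Sigma` (4 x 4).
#' @export
conditional_params <- function(edge, t_obs) {
  stopifnot(inherits(edge, "edge_gaussian"), length(t_obs) == 4L)
  if (sum(t_obs * edge$mu_t) < 0) t_obs <- -t_obs
  Sig <- solve(edge$B11)
  Sig <- (Sig + t(Sig)) / 2
  mu <- drop(edge$mu_s - Sig %*% edge$B12 %*% (t_obs - edge$mu_t))
  structure(list(mu = mu, Sigma = Sig), class = "cond_gaussian")
}

#' Standard-degree score of an observed child quaternion
#'
#' The criterion is the probability that a random draw S from the
#' conditional lies at least as far from the conditional mean as the
#' observation, `P(||S - mu|| > ||s - mu||)`, so a segment matching the
#' model scores near 1 and a deviated segment near 0.  Under the default
#' Euclidean norm `||S - mu||^2` is a central Gaussian quadratic form
#' (eigenvalue-weighted sum of chi-squares) whose upper tail is computed
#' exactly by Imhof's integral; under `"mahalanobis"` it is the upper
#' chi-square tail with 4 degrees of freedom at
#' `d^2 = (s - mu)' Sigma^-1 (s - mu)`.  The Euclidean norm is the
#' default because unit-norm quaternion data makes the radial direction
#' of the conditional nearly degenerate: Mahalanobis weighting inflates
#' that direction and marks even perfectly standard segments down.
#'
#' @param cond a `cond_gaussian` (or any list with `mu`, `Sigma`).
#' @param s_obs observed child quaternion (4-vector).
#' @param method `"euclidean"` (default) or `"mahalanobis"`.
#' @return probability in `[0, 1]`.
#' @export
standard_degree <- function(cond, s_obs,
                            method = c("euclidean", "mahalanobis")) {
  method <- match.arg(method)
  stopifnot(length(s_obs) == 4L)
  if (sum(s_obs * cond$mu) < 0) s_obs <- -s_obs
  d <- s_obs - cond$mu
  if (method == "mahalanobis") {
    d2 <- drop(crossprod(d, solve(cond$Sigma, d)))
    return(stats::pchisq(d2, df = 4, lower.tail = FALSE))
  }
  lambda <- eigen((cond$Sigma + t(cond$Sigma)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values
  quadform_upper(sum(d^2), lambda)
}

# Upper tail P(sum_i lambda_i z_i^2 > x) for iid standard normal z
# (central case of Imhof's 1961 inversion integral), vectorized over x.
# The integrand sin(theta(u)) / (u rho(u)) with
#   theta(u) = 0.5 sum_i atan(lambda_i u) - x u / 2,
#   rho(u)   = prod_i (1 + lambda_i^2 u^2)^(1/4)
# is evaluated by the midpoint rule on a grid fine enough for both the
# sine oscillation (period 4 pi / x) and the atan/envelope scale
# (1 / max lambda), truncated where the envelope 1/(u rho) is negligible.
quadform_upper <- function(x, lambda) {
  lambda <- lambda[lambda > 1e-12 * max(lambda, 0)]
  if (!length(lambda)) return(as.numeric(x <= 0))
  out <- rep(1, length(x))
  pos <- which(x > 0)
  if (!length(pos)) return(out)
  if (length(lambda) == 1L) {
    out[pos] <- stats::pchisq(x[pos] / lambda, df = 1, lower.tail = FALSE)
    return(out)
  }
  xs <- x[pos]
  step <- min(pi / (4 * max(xs)), 0.25 / max(lambda))
  env <- function(u) 1 / (u * exp(0.25 * sum(log1p(lambda^2 * u^2))))
  U <- 16 * step
  while (env(U) > 3e-8 && U / step < 4e5) U <- U * 2
  n_u <- ceiling(U / step)
  val <- numeric(length(xs))
  done <- 0L
  chunk <- 20000L
  while (done < n_u) {
    k <- (done + 1L):min(done + chunk, n_u)
    u <- (k - 0.5) * step
    a <- 0.5 * colSums(atan(outer(lambda, u)))
    w <- step / (u * exp(0.25 * colSums(log1p(outer(lambda^2, u^2)))))
    # sin(a - x u / 2) summed over the grid, all x at once
    val <- val + drop(sin(outer(xs, -u / 2) +
                            rep(a, each = length(xs))) %*% w)
    done <- done + length(k)
  }
  out[pos] <- pmin(1, pmax(0, 0.5 + val / pi))
  out
}

#' Fit the per-posture Bayesian network
#'
#' One joint child-parent Gaussian per edge of the body tree over the
#' relative-to-waist quaternions, plus a marginal 4-D Gaussian of the
#' waist's animation-frame quaternion for the root.  Edges whose parent
#' is the waist condition on a constant (identity) parent and so reduce
#' to the child marginal, which the ridge handles cleanly.
#'
#' @param frames frame rows of one posture (n x 44 or data.frame).
#' @param posture posture id recorded in the model.
#' @param topo a [body_topology()].
#' @param cal optional [calibration_set()].
#' @param ridge covariance ridge.  Default 1e-6.
#' @return a `posture_bayes_net` with one `edge_gaussian` per non-root
#'   segment and the root marginal.
#' @export
fit_posture_network <- function(frames, posture = NA_integer_,
                                topo = body_topology(), cal = NULL,
                                ridge = 1e-6) {
  Q <- frames_quat_matrix(frames)
  if (!is.null(cal)) Q <- calibrate_frames(Q, cal)
  if (nrow(Q) < 2L) stop("need at least 2 training frames")
  rel <- relative_to_waist(Q, keep_waist = TRUE)  # waist block = identity
  seg_rel <- function(s) {
    i <- segment_index(topo, s)
    rel[, seg_cols(i), drop = FALSE]
  }
  edges <- list()
  for (s in setdiff(topo$segments, "waist"))
    edges[[s]] <- fit_joint_gaussian(seg_rel(s), seg_rel(topo$parent[[s]]),
                                     ridge = ridge)
  W <- align_hemisphere(canonical_rows(Q[, seg_cols(6L), drop = FALSE]))
  mu_w <- colMeans(W)
  Sig_w <- crossprod(sweep(W, 2, mu_w)) / nrow(W) + diag(ridge, 4L)
  structure(list(posture = posture, topology = topo, ridge = ridge,
                 edges = edges,
                 root = structure(list(mu = mu_w, Sigma = Sig_w),
                                  class = "cond_gaussian"),
                 m = nrow(Q)),
            class = "posture_bayes_net")
}

#' @export
print.posture_bayes_net <- function(x, ...) {
  cat(sprintf(paste0("Posture Bayesian network (posture %s): %d edges + ",
                     "waist root marginal, fitted on %d frames\n"),
              x$posture, length(x$edges), x$m))
  invisible(x)
}

#' Standard-degree evaluation of frames against a posture network
#'
#' Scores every segment of every frame: non-root segments by the
#' child-given-parent conditional at the observed parent, the waist root
#' by its marginal Gaussian; segments scoring below `threshold` are
#' flagged nonstandard.
#'
#' @param net a `posture_bayes_net`.
#' @param frames frame rows (n x 44, data.frame, or one 11 x 4 frame).
#' @param cal optional [calibration_set()].
#' @param threshold nonstandard flag threshold.  Default 0.3.
#' @param method norm of the exceedance probability, see
#'   [standard_degree()].
#' @param posture if given, must match the network's posture id.
#' @return an `evaluation_report`: `scores` (n x 11 matrix, columns in
#'   segment order), `flags` (same shape, logical), `threshold`.
#' @export
evaluate_posture <- function(net, frames, cal = NULL, threshold = 0.3,
                             method = c("euclidean", "mahalanobis"),
                             posture = NULL) {
  stopifnot(inherits(net, "posture_bayes_net"))
  method <- match.arg(method)
  if (!is.null(posture) && !is.na(net$posture) && posture != net$posture)
    stop("network was fitted for posture ", net$posture,
         ", not posture ", posture)
  Q <- frames_quat_matrix(frames)
  if (!is.null(cal)) Q <- calibrate_frames(Q, cal)
  topo <- net$topology
  rel <- relative_to_waist(Q, keep_waist = TRUE)
  n <- nrow(Q)
  scores <- matrix(NA_real_, n, 11L,
                   dimnames = list(NULL, topo$segments))
  score_block <- function(D, Sigma) {
    # rows of D: observation minus (conditional) mean
    if (method == "mahalanobis") {
      d2 <- rowSums((D %*% solve(Sigma)) * D)
      stats::pchisq(d2, df = 4, lower.tail = FALSE)
    } else {
      lambda <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values
      quadform_upper(rowSums(D^2), lambda)
    }
  }
  for (s in topo$segments) {
    i <- segment_index(topo, s)
    if (s == "waist") {
      obs <- Q[, seg_cols(6L), drop = FALSE]
      flip <- drop(obs %*% net$root$mu) < 0
      obs[flip, ] <- -obs[flip, , drop = FALSE]
      scores[, s] <- score_block(sweep(obs, 2, net$root$mu), net$root$Sigma)
    } else {
      edge <- net$edges[[s]]
      ip <- segment_index(topo, topo$parent[[s]])
      Sobs <- rel[, seg_cols(i), drop = FALSE]
      Tobs <- rel[, seg_cols(ip), drop = FALSE]
      Sig <- solve(edge$B11)
      Sig <- (Sig + t(Sig)) / 2
      A <- Sig %*% edge$B12
      flip_t <- drop(Tobs %*% edge$mu_t) < 0
      Tobs[flip_t, ] <- -Tobs[flip_t, , drop = FALSE]
      MU <- matrix(edge$mu_s, n, 4, byrow = TRUE) -
        sweep(Tobs, 2, edge$mu_t) %*% t(A)
      flip_s <- rowSums(Sobs * MU) < 0
      Sobs[flip_s, ] <- -Sobs[flip_s, , drop = FALSE]
      scores[, s] <- score_block(Sobs - MU, Sig)
    }
  }
  structure(list(posture = net$posture, scores = scores,
                 flags = scores < threshold, threshold = threshold),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Posture evaluation: %d frame(s), threshold %.2f\n",
              nrow(x$scores), x$threshold))
  med <- apply(x$scores, 2, stats::median)
  flagged <- colMeans(x$flags) > 0.5
  for (s in colnames(x$scores))
    cat(sprintf("  %-7s median score %.3f%s\n", s, med[[s]],
                if (flagged[[s]]) "  ** nonstandard" else ""))
  invisible(x)
}
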