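test_that("membership degrees follow the inverse-distance formula", {
  # equidistant point -> uniform memberships
  ctr <- rbind(c(1, 0), c(-1, 0))
  expect_equal(drop(fcm_membership(c(0, 5), ctr)), c(0.5, 0.5))
  # at a center -> crisp
  expect_equal(drop(fcm_membership(c(1, 0), ctr)), c(1, 0))
  # b = 2, distances 1 and 2 -> (0.8, 0.2)
  expect_equal(drop(fcm_membership(c(0, 0), rbind(c(1, 0), c(2, 0)))),
               c(0.8, 0.2), tolerance = 1e-12)
})

test_that("memberships normalize to one for arbitrary inputs", {
  set.seed(61)
  for (rep in 1:20) {
    X <- matrix(stats::rnorm(40 * 5), 40, 5)
    M <- X[sample(40, 4), ] + stats::rnorm(20, 0, 0.1)
    U <- fcm_membership(X, M, b = 2)
    expect_equal(rowSums(U), rep(1, 40), tolerance = 1e-12)
    expect_true(all(U >= 0))
  }
  # singular rows included
  X <- rbind(c(0, 0), c(1, 1))
  U <- fcm_membership(X, X, b = 2)
  expect_equal(U, diag(2))
})

test_that("center updates are weighted means with an empty-cluster guard", {
  set.seed(62)
  X <- matrix(stats::rnorm(30), 10, 3)
  # crisp memberships -> per-cluster means
  U <- matrix(0, 10, 2); U[1:4, 1] <- 1; U[5:10, 2] <- 1
  M <- fcm_update_centers(X, U, b = 2)
  expect_equal(M[1, ], colMeans(X[1:4, ]))
  expect_equal(M[2, ], colMeans(X[5:10, ]))
  # all-equal memberships -> every center at the global mean
  U2 <- matrix(0.5, 10, 2)
  M2 <- fcm_update_centers(X, U2, b = 2)
  expect_equal(M2[1, ], colMeans(X))
  expect_equal(M2[2, ], colMeans(X))
  # random case vs direct weighted-mean oracle
  U3 <- matrix(stats::runif(20), 10, 2); U3 <- U3 / rowSums(U3)
  M3 <- fcm_update_centers(X, U3, b = 2)
  for (j in 1:2)
    expect_equal(M3[j, ], colSums(U3[, j]^2 * X) / sum(U3[, j]^2),
                 tolerance = 1e-12)
})

test_that("fitting recovers separated blobs with a monotone objective", {
  set.seed(63)
  mu <- rbind(c(0, 0, 0), c(6, 0, 0))
  X <- rbind(matrix(stats::rnorm(150, 0, 0.5), 50, 3) +
               rep(mu[1, ], each = 50),
             matrix(stats::rnorm(150, 0, 0.5), 50, 3) +
               rep(mu[2, ], each = 50))
  fit <- fcm_fit(X, K2 = 2, seed = 64)
  expect_true(all(diff(fit$objective) <= 1e-9))
  d <- function(M) apply(M, 1, function(m)
    min(sum((m - mu[1, ])^2), sum((m - mu[2, ])^2)))
  expect_lt(max(sqrt(d(fit$centers))), 3 * 0.5)  # centers near blob means
  fit2 <- fcm_fit(X, K2 = 2, seed = 64)
  expect_identical(fit$centers, fit2$centers)
  expect_error(fcm_fit(rbind(c(1, 1, 1), c(1, 1, 1)), K2 = 2), "distinct")
})

test_that("fitting agrees with an independent FCM implementation", {
  set.seed(65)
  X <- rbind(matrix(stats::rnorm(100, 0, 0.4), 50, 2),
             matrix(stats::rnorm(100, 5, 0.4), 50, 2))
  init <- rbind(X[1, ], X[51, ])
  ours <- fcm_fit(X, K2 = 2, init_centers = init, tol = 1e-12)
  ref <- e1071::cmeans(X, centers = init, m = 2, iter.max = 500,
                       method = "cmeans")
  # same optimum up to cluster order
  err <- min(max(abs(ours$centers - ref$centers)),
             max(abs(ours$centers - ref$centers[2:1, ])))
  expect_lt(err, 1e-3)
})

test_that("cluster labelling recovers permutations and enforces coverage", {
  set.seed(66)
  means <- matrix(stats::rnorm(12, sd = 4), 3, 4)
  X <- means[rep(1:3, each = 40), ] + matrix(stats::rnorm(480, 0, 0.3), 120, 4)
  labels <- rep(c(7L, 6L, 9L), each = 40)
  fit <- fcm_fit(X, K2 = 3, init_centers = means)
  fit <- fcm_assign_labels(fit, X, labels)
  expect_setequal(fit$labels, c(6L, 7L, 9L))
  expect_equal(fit$labels, c(7L, 6L, 9L))  # cluster j was seeded at class j
  # permuted initialization recovers the permutation
  fitp <- fcm_fit(X, K2 = 3, init_centers = means[c(2, 3, 1), ])
  fitp <- fcm_assign_labels(fitp, X, labels)
  expect_equal(fitp$labels, c(6L, 9L, 7L))
  expect_error(fcm_assign_labels(fit, X[1:80, ], labels[1:80]),
               "K2 = 3 distinct labels")
})

test_that("posture prediction applies threshold and tie rules", {
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4))
  model <- structure(list(K2 = 3L, b = 2, centers = centers,
                          labels = c(11L, 12L, 13L)), class = "fcm_model")
  expect_equal(predict_posture(model, c(0.1, 0), t2 = 0.5), 11L)
  # equidistant point: max membership 1/3 <= t2 -> rejected
  eq <- c(2, 2)
  expect_true(is.na(predict_posture(model, eq, t2 = 0.5)))
  unlabelled <- structure(list(K2 = 3L, b = 2, centers = centers,
                               labels = NULL), class = "fcm_model")
  expect_error(predict_posture(unlabelled, c(0, 0)), "label map")
})
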