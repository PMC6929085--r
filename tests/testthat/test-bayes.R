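rand_quat_cloud <- function(m, center, sd) {
  t(replicate(m, quat_canonical(qmul(center, rotvec_quat(
    stats::rnorm(3, 0, sd))))))
}

test_that("joint edge Gaussians use population moments and a ridge", {
  set.seed(81)
  q <- rand_unit_quat()
  S <- matrix(rep(q, 5), 5, 4, byrow = TRUE)
  T_ <- matrix(rep(quat_identity(), 5), 5, 4, byrow = TRUE)
  e <- fit_joint_gaussian(S, T_, ridge = 1e-6)
  expect_equal(e$mu_s, quat_canonical(q))
  expect_equal(e$Sigma, matrix(0, 8, 8))  # identical samples: zero variance
  expect_equal(e$B11, diag(1e6, 4), tolerance = 1e-6)  # (ridge I)^-1 block
  expect_error(fit_joint_gaussian(S[1, , drop = FALSE], T_[1, , drop = FALSE]),
               "at least 2")
  Sbad <- S; Sbad[2, 1] <- Inf
  expect_error(fit_joint_gaussian(Sbad, T_), "non-finite")
})

test_that("moments match a naive two-pass oracle", {
  set.seed(82)
  S <- rand_quat_cloud(60, rand_unit_quat(), 0.1)
  T_ <- rand_quat_cloud(60, rand_unit_quat(), 0.1)
  e <- fit_joint_gaussian(S, T_, ridge = 0)
  # oracle on the hemisphere-aligned data the fit uses
  Z <- cbind(imupose:::align_hemisphere(S), imupose:::align_hemisphere(T_))
  mu <- colSums(Z) / nrow(Z)
  Sg <- matrix(0, 8, 8)
  for (i in seq_len(nrow(Z)))
    Sg <- Sg + tcrossprod(Z[i, ] - mu)
  Sg <- Sg / nrow(Z)
  expect_equal(e$mu, mu, tolerance = 1e-12)
  expect_equal(e$Sigma, Sg, tolerance = 1e-12)
})

test_that("independent child and parent give a near-zero coupling block", {
  set.seed(83)
  S <- rand_quat_cloud(4000, rand_unit_quat(), 0.05)
  T_ <- rand_quat_cloud(4000, rand_unit_quat(), 0.05)
  e <- fit_joint_gaussian(S, T_, ridge = 1e-8)
  cross <- e$Sigma[1:4, 5:8]
  scale <- sqrt(outer(diag(e$Sigma)[1:4], diag(e$Sigma)[5:8]))
  # correlations are O(1/sqrt(m)); allow 3 standard errors
  expect_lt(max(abs(cross / scale)), 3 / sqrt(4000) * 3)
})

test_that("conditional parameters equal the Schur-complement identity", {
  set.seed(84)
  for (rep in 1:100) {
    A <- matrix(stats::rnorm(64), 8)
    Sigma <- crossprod(A) / 8 + diag(0.05, 8)
    mu <- stats::runif(8, 0.5, 1.5)
    P <- solve(Sigma)
    edge <- structure(list(mu_s = mu[1:4], mu_t = mu[5:8], mu = mu,
                           Sigma = Sigma, ridge = 0,
                           B11 = P[1:4, 1:4], B12 = P[1:4, 5:8],
                           B21 = P[5:8, 1:4], B22 = P[5:8, 5:8], m = 8L),
                      class = "edge_gaussian")
    t_obs <- mu[5:8] + stats::rnorm(4, 0, 0.3)
    got <- conditional_params(edge, t_obs)
    Sst <- Sigma[1:4, 5:8]; Stt <- Sigma[5:8, 5:8]
    mu_ref <- mu[1:4] + drop(Sst %*% solve(Stt, t_obs - mu[5:8]))
    Sig_ref <- Sigma[1:4, 1:4] - Sst %*% solve(Stt, t(Sst))
    expect_equal(got$mu, mu_ref, tolerance = 1e-9)
    expect_equal(got$Sigma, Sig_ref, tolerance = 1e-9)
  }
})

test_that("a zero coupling block leaves the conditional at the marginal", {
  Sigma <- diag(c(1, 2, 3, 4, 5, 6, 7, 8) / 10)
  mu <- stats::setNames(rep(0.6, 8), NULL)
  P <- solve(Sigma)
  edge <- structure(list(mu_s = mu[1:4], mu_t = mu[5:8], mu = mu,
                         Sigma = Sigma, ridge = 0,
                         B11 = P[1:4, 1:4], B12 = P[1:4, 5:8] * 0,
                         B21 = P[5:8, 1:4] * 0, B22 = P[5:8, 5:8], m = 2L),
                    class = "edge_gaussian")
  got <- conditional_params(edge, c(2, 2, 2, 2))
  expect_equal(got$mu, mu[1:4])
  # and at the parent mean the shift vanishes even with coupling
  edge$B12 <- matrix(stats::rnorm(16), 4)
  expect_equal(conditional_params(edge, mu[5:8])$mu, mu[1:4])
})

test_that("standard degree is an exceedance probability in [0,1]", {
  set.seed(85)
  A <- matrix(stats::rnorm(16, sd = 0.1), 4)
  cond <- list(mu = c(0.9, 0.2, -0.1, 0.3), Sigma = crossprod(A) + diag(1e-4, 4))
  expect_equal(standard_degree(cond, cond$mu), 1)
  expect_equal(standard_degree(cond, cond$mu, method = "mahalanobis"), 1)
  # chi-square median scores one half under the Mahalanobis norm
  L <- chol(cond$Sigma)
  dirn <- drop(c(1, 0, 0, 0) %*% L)
  med <- sqrt(stats::qchisq(0.5, df = 4))
  s <- cond$mu + med * dirn
  expect_equal(standard_degree(cond, s, method = "mahalanobis"), 0.5,
               tolerance = 1e-9)
  # Euclidean method matches a 1e5-draw Monte-Carlo oracle within 0.01
  set.seed(86)
  Z <- matrix(stats::rnorm(4 * 1e5), 1e5, 4) %*% L
  for (r in c(0.05, 0.12, 0.25, 0.5)) {
    s_obs <- cond$mu + r * c(0.5, 0.5, 0.5, 0.5)
    mc <- mean(rowSums(Z^2) > sum((s_obs - cond$mu)^2))
    expect_equal(standard_degree(cond, s_obs), mc, tolerance = 0.01)
  }
  # monotone decreasing in the distance
  sc <- vapply(seq(0, 0.8, 0.05), function(r)
    standard_degree(cond, cond$mu + r * dirn), numeric(1))
  expect_true(all(diff(sc) <= 1e-12))
})

test_that("posture networks cover the tree and round-trip through JSON", {
  fx <- eval_fixture()
  net <- fx$net
  expect_length(net$edges, 10L)
  expect_setequal(names(net$edges),
                  setdiff(body_topology()$segments, "waist"))
  path <- tempfile(fileext = ".json")
  save_model(net, path)
  back <- load_model(path)
  sub <- standard_probe_subject(fx$spec)
  probe <- generate_instance(fx$templates[[1]], sub, probe_spec(fx$spec),
                             seed = 87)[1:20, ]
  expect_equal(evaluate_posture(back, probe)$scores,
               evaluate_posture(net, probe)$scores, tolerance = 1e-9)
  unlink(path)
  expect_error(fit_posture_network(probe[1, , drop = FALSE]), "at least 2")
  expect_error(evaluate_posture(net, probe, posture = 5), "posture 1")
})

test_that("noiseless training makes conditional means the template relations", {
  tpl <- tiny_templates()[[2]]
  sub <- make_subjects(1, silent_spec(), seed = 88, standard = TRUE)[[1]]
  inst <- rbind(generate_instance(tpl, sub, silent_spec(), 1, seed = 89),
                generate_instance(tpl, sub, silent_spec(), 2, seed = 90))
  net <- fit_posture_network(inst, posture = 2L)
  topo <- body_topology()
  for (s in c("breast", "LFArm", "RShank")) {
    rel <- quat_canonical(qmul(qinv(tpl$quats["waist", ]), tpl$quats[s, ]))
    expect_equal(net$edges[[s]]$mu_s, unname(rel), tolerance = 1e-9)
  }
})

test_that("injected deviations are flagged and clean segments are not", {
  fx <- eval_fixture()
  sub <- standard_probe_subject(fx$spec)
  ns <- generate_nonstandard(fx$templates[[1]],
                             list(RShank = c(0, 0, 0.5), head = c(0.5, 0, 0)),
                             sub, probe_spec(fx$spec), seed = 91)
  ev <- evaluate_posture(fx$net, ns$instance)
  m <- colMeans(ev$scores)
  expect_lt(m[["RShank"]], 0.3)
  expect_lt(m[["head"]], 0.3)
  clean <- setdiff(colnames(ev$scores), c("RShank", "head"))
  expect_true(all(m[clean] > 0.3))
  expect_true(all(ev$scores >= 0 & ev$scores <= 1))
})
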