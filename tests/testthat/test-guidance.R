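test_that("the deviation rotation isolates the model-observation mismatch", {
  set.seed(101)
  mu <- rand_unit_quat()
  expect_equal(deviation_quaternion(mu, mu), diag(3), tolerance = 1e-9)
  r <- axis_angle_quat(c(0, 0, 1), 0.4)
  R <- deviation_quaternion(mu, qmul(mu, r))
  expect_equal(R, quat_to_matrix(r), tolerance = 1e-9)
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
  # scale of the conditional mean does not matter; zero norm does
  expect_equal(deviation_quaternion(0.3 * mu, mu), diag(3), tolerance = 1e-9)
  expect_error(deviation_quaternion(c(0, 0, 0, 0), mu), "norm")
})

test_that("planar differences follow the printed sign conventions", {
  expect_equal(planar_diffs(diag(3)), c(fore_back = 0, up_down = 0))
  # R11 = 0, R21 = -1: fore-back difference is +pi/2 (the orthogonal
  # plane's projection is degenerate there and warns)
  R <- quat_to_matrix(axis_angle_quat(c(0, 0, 1), -pi / 2))
  expect_equal(R[2, 1], -1, tolerance = 1e-12)
  expect_equal(unname(suppressWarnings(planar_diffs(R))["fore_back"]),
               pi / 2)
  # R11 = 0, R31 = -1, R21 = 0: up-down difference is +pi/2
  R2 <- quat_to_matrix(axis_angle_quat(c(0, 1, 0), pi / 2))
  expect_equal(R2[3, 1], -1, tolerance = 1e-12)
  expect_equal(unname(suppressWarnings(planar_diffs(R2))["up_down"]),
               pi / 2)
  # rotations about z: d_fore_back recovers minus the angle; odd under
  # transposition (inverse rotation)
  for (th in c(0.2, 0.5, 1.0)) {
    R3 <- quat_to_matrix(axis_angle_quat(c(0, 0, 1), th))
    d <- planar_diffs(R3)
    expect_equal(unname(d["fore_back"]), -th, tolerance = 1e-9)
    dT <- planar_diffs(t(R3))
    expect_equal(unname(dT["fore_back"]), th, tolerance = 1e-9)
  }
  expect_warning(
    planar_diffs(matrix(c(0, 0, 1, 0, 1, 0, 1, 0, 0), 3)), "degenerate")
})

test_that("bend-stretch differences measure the joint-angle mismatch", {
  set.seed(102)
  qp <- rand_unit_quat()
  alpha <- 0.6
  mu <- qmul(qp, axis_angle_quat(c(0, 0, 1), alpha))
  expect_equal(bend_stretch_diff(qp, mu, mu), 0, tolerance = 1e-12)
  # actual 0.3 rad straighter (more extended) than the model: difference
  # is positive, guidance word "bend"
  actual <- qmul(qp, axis_angle_quat(c(0, 0, 1), alpha - 0.3))
  d <- bend_stretch_diff(qp, actual, mu)
  expect_equal(d, 0.3, tolerance = 1e-9)
  expect_equal(orientation_word("LFArm", c(bend_stretch = d))$word, "bend")
  # over-bent: negative difference, word "stretch"
  bent <- qmul(qp, axis_angle_quat(c(0, 0, 1), alpha + 0.25))
  d2 <- bend_stretch_diff(qp, bent, mu)
  expect_equal(d2, -0.25, tolerance = 1e-9)
  expect_equal(orientation_word("RShank", c(bend_stretch = d2))$word,
               "stretch")
  expect_gte(d, -pi); expect_lte(d, pi)
})

test_that("orientation words follow the segment vocabulary and sign rules", {
  # upper arm: positive fore-back -> backward; negative up-down -> upward
  it <- orientation_word("LUArm", c(fore_back = 0.2, up_down = 0.05))
  expect_equal(it$word, "backward"); expect_equal(it$extent, 0.2)
  it2 <- orientation_word("LUArm", c(fore_back = 0.05, up_down = -0.3))
  expect_equal(it2$word, "upward"); expect_equal(it2$extent, 0.3)
  it3 <- orientation_word("RUArm", c(fore_back = 0.05, up_down = 0.3))
  expect_equal(it3$word, "downward")
  # head and thighs use the left-right vocabulary
  it4 <- orientation_word("LThigh", c(fore_back = 0.01, up_down = -0.4))
  expect_equal(it4$word, "rightward")
  it5 <- orientation_word("head", c(fore_back = -0.5, up_down = 0.1))
  expect_equal(it5$word, "forward")
  expect_error(orientation_word("breast", c(fore_back = 1, up_down = 0)),
               "vocabulary")
})

test_that("reports render the guidance phrasebook", {
  items <- data.frame(segment = c("RFArm", "LThigh", "LUArm", "RShank"),
                      word = c("stretch", "rightward", "upward", "bend"),
                      extent = c(0.45, 0.31, 0.22, 0.18),
                      d1 = 0, d2 = 0)
  lines <- render_report(list(items = items))
  expect_equal(lines[1], "straighten your right forearm (0.45 rad)")
  expect_equal(lines[2], "put your left leg to right (0.31 rad)")
  expect_equal(lines[3], "lift up your left arm (0.22 rad)")
  expect_equal(lines[4], "bend your right knee (0.18 rad)")
  expect_match(render_report(list(items = items[0, ])), "standard")
})

test_that("guidance recovers injected deviations via matched pairs", {
  fx <- eval_fixture()
  spec <- probe_spec(fx$spec)
  sub <- standard_probe_subject(spec)
  tpl <- fx$templates[[1]]
  signed_diff <- function(report, seg) {
    i <- match(seg, report$items$segment)
    report$items$d1[i]
  }
  for (theta in c(0.2, 0.3, 0.5)) {
    ns <- generate_nonstandard(tpl, list(RShank = c(0, 0, theta)), sub,
                               spec, seed = 103)
    std <- generate_instance(tpl, sub, spec, seed = 103)
    # report every guidable segment in both reports (threshold ~1) so the
    # matched pair compares the measured differences, not flag decisions;
    # the injected bend shifts the signed bend-stretch difference by
    # exactly -theta relative to the standard twin
    gn <- guidance_report(fx$net, ns$instance, category = tpl$category,
                          threshold = 1 - 1e-9, min_extent = 0)
    gs <- guidance_report(fx$net, std, category = tpl$category,
                          threshold = 1 - 1e-9, min_extent = 0)
    recovered <- signed_diff(gs, "RShank") - signed_diff(gn, "RShank")
    expect_lt(abs(recovered - theta), 0.05)
  }
  # a standard instance produces no guidance items at the default gate
  g0 <- guidance_report(fx$net, std <- generate_instance(tpl, sub, spec,
                                                         seed = 104),
                        category = tpl$category)
  expect_equal(nrow(g0$items), 0L)
  expect_match(g0$sentences[1], "standard")
})
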