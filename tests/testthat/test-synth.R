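test_that("templates respect the category partition and separation rules", {
  tpls <- tiny_templates()
  expect_length(tpls, 18L)
  cats <- vapply(tpls, `[[`, integer(1), "category")
  expect_equal(cats, unname(default_category_map()))
  # waist orientations of different categories separated by >= 60 degrees
  for (a in 1:17) for (b in (a + 1):18) {
    if (cats[a] != cats[b]) {
      ang <- quat_angle(tpls[[a]]$quats["waist", ], tpls[[b]]$quats["waist", ])
      expect_gte(ang, 60 * pi / 180)
    } else {
      segs <- setdiff(body_topology()$segments, "waist")
      sep <- max(vapply(segs, function(s)
        quat_angle(tpls[[a]]$quats[s, ], tpls[[b]]$quats[s, ]), numeric(1)))
      expect_gte(sep, 20 * pi / 180)
    }
  }
  expect_identical(make_templates(301L), tpls)  # seed determinism
})

test_that("a noiseless instance reproduces the template exactly", {
  tpl <- tiny_templates()[[3]]
  sub <- make_subjects(1, silent_spec(), seed = 41, standard = TRUE)[[1]]
  inst <- generate_instance(tpl, sub, silent_spec(), seed = 42)
  Q <- as.matrix(inst[, -(1:4)])
  for (i in 0:10)
    expect_equal(unname(Q[1, 4 * i + 1:4]), unname(tpl$quats[i + 1, ]),
                 tolerance = 1e-12)
  expect_true(all(apply(Q, 2, function(x) all(x == x[1]))))
})

test_that("instance duration and determinism follow the spec", {
  tpl <- tiny_templates()[[1]]
  spec <- perturbation_spec()  # 6-10 s at 40 Hz
  sub <- make_subjects(1, spec, seed = 43)[[1]]
  inst <- generate_instance(tpl, sub, spec, seed = 44)
  expect_gte(nrow(inst), 240L)
  expect_lte(nrow(inst), 400L)
  expect_equal(diff(inst$time[1:3]), rep(1 / 40, 2))
  expect_identical(generate_instance(tpl, sub, spec, seed = 44), inst)
})

test_that("database generation yields the full labelled design", {
  db <- generate_database(3, 2, tiny_spec(), seed = 45)
  idx <- db_instances(db)
  expect_equal(nrow(idx), 3 * 18 * 2)
  expect_equal(sort(unique(idx$posture)), 1:18)
  expect_equal(as.vector(table(idx$subject, idx$posture)),
               rep(2L, 3 * 18))
  # frames satisfy the database invariants (unit quats, ordered times)
  expect_s3_class(posture_database(db$frames), "posture_db")
})

test_that("subject offsets are bounded and flagged standard when asked", {
  spec <- perturbation_spec(sigma_subject = 0.5, max_offset = 0.3)
  subs <- make_subjects(20, spec, seed = 46)
  norms <- unlist(lapply(subs, function(s) sqrt(rowSums(s$offsets^2))))
  expect_lte(max(norms), 0.3 + 1e-12)
  std <- make_subjects(2, spec, seed = 46, standard = TRUE)
  expect_true(all(std[[1]]$offsets == 0))
})

test_that("nonstandard generation records ground truth and matches its twin", {
  tpl <- tiny_templates()[[5]]
  spec <- probe_spec(tiny_spec())
  sub <- standard_probe_subject(spec)
  dev <- list(RShank = c(0, 0, 0.5), LUArm = c(0, 0.3, 0))
  ns <- generate_nonstandard(tpl, dev, sub, spec, seed = 47)
  expect_equal(nrow(ns$truth), 2L)
  expect_equal(ns$truth$angle, c(0.5, 0.3))
  expect_equal(ns$truth$segment, c("RShank", "LUArm"))
  expect_false(any(ns$truth$root))
  # empty deviations = ordinary generation
  plain <- generate_nonstandard(tpl, list(), sub, spec, seed = 47)
  std <- generate_instance(tpl, sub, spec, seed = 47)
  expect_identical(plain$instance, std)
  expect_equal(nrow(plain$truth), 0L)
  # matched twin: only the deviated segments' columns differ
  topo <- body_topology()
  devcols <- unlist(lapply(c(10, 2), function(i) 4 + 4 * i + 1:4))  # RShank, LUArm
  same <- setdiff(5:48, devcols)
  expect_identical(ns$instance[, same], std[, same])
  expect_false(isTRUE(all.equal(ns$instance[, devcols], std[, devcols])))
  # waist deviation is allowed but flagged
  expect_warning(wd <- generate_nonstandard(tpl, list(waist = c(0.4, 0, 0)),
                                            sub, spec, seed = 48), "root")
  expect_true(wd$truth$root)
  expect_error(generate_nonstandard(tpl, list(nosuch = c(1, 0, 0)), sub,
                                    spec), "unknown segment")
})
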