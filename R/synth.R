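#' Perturbation specification for the synthetic generator
#'
#' Controls the three stochastic layers of the generator: systematic
#' per-subject segment offsets (inter-subject shape variability),
#' per-frame isotropic sensor/pose jitter, and instance duration.
#'
#' @param sigma_subject std dev (rad) of the per-subject, per-segment
#'   rotation-vector offset.  Default 0.15.
#' @param sigma_instance std dev (rad) of the per-instance, per-segment
#'   offset: subjects do not reproduce a posture exactly across repeated
#'   performances.  Default 0.1.
#' @param sigma_sway stationary std dev (rad) of the within-instance
#'   postural sway, an AR(1) rotation-vector wander with correlation time
#'   `tau_sway`: a person holding a static posture drifts slowly around
#'   it.  Default 0.05.
#' @param tau_sway sway correlation time in seconds.  Default 0.5.
#' @param sigma_frame std dev (rad) of the per-frame white rotation-vector
#'   sensor jitter.  Default 0.02.
#' @param max_offset hard bound (rad) on a subject offset norm.  Default 0.3.
#' @param duration_range instance duration range in seconds.  Default 6-10.
#' @param rate sampling rate in Hz.  Default 40.
#' @return a `perturbation_spec` list.
#' @export
perturbation_spec <- function(sigma_subject = 0.15, sigma_instance = 0.1,
                              sigma_sway = 0.05, tau_sway = 0.5,
                              sigma_frame = 0.02,
                              max_offset = 0.3, duration_range = c(6, 10),
                              rate = 40) {
  stopifnot(sigma_subject >= 0, sigma_instance >= 0, sigma_sway >= 0,
            tau_sway > 0, sigma_frame >= 0, max_offset >= 0,
            length(duration_range) == 2L, all(duration_range > 0),
            diff(duration_range) >= 0, rate > 0)
  structure(list(sigma_subject = sigma_subject,
                 sigma_instance = sigma_instance,
                 sigma_sway = sigma_sway, tau_sway = tau_sway,
                 sigma_frame = sigma_frame,
                 max_offset = max_offset, duration_range = duration_range,
                 rate = rate), class = "perturbation_spec")
}

#' Generate the 18 posture templates
#'
#' Builds nominal animation-frame quaternions for 18 static postures in
#' the 5 waist-orientation categories.  The 5 nominal waist orientations
#' (identity; +/-90 deg about y; +/-90 deg about x) are mutually separated
#' by at least 90 deg, so the first-stage classifier sees separable
#' categories; non-waist segments are drawn hierarchically along the body
#' tree with elbows/knees given a nominal bend about the local z axis.
#' Within a category, any two postures are required to differ by at least
#' 20 deg on some non-waist segment (resampled until satisfied), so the
#' second-stage clusters are separable too.
#'
#' @param seed integer seed; same seed, identical templates.
#' @return list of 18 templates, each `list(posture, category, quats)`
#'   with `quats` an 11 x 4 matrix in IMU index order.
#' @export
make_templates <- function(seed = 1L) {
  topo <- body_topology()
  cat_map <- default_category_map()
  base_waist <- lapply(1:5, category_waist_quat)
  rand_rotvec <- function(lo, hi) {
    ax <- stats::rnorm(3)
    ax / sqrt(sum(ax^2)) * stats::runif(1, lo, hi)
  }
  min_sep <- 20 * pi / 180
  with_seed(seed, {
    templates <- vector("list", 18L)
    for (p in 1:18) {
      cat_id <- unname(cat_map[[as.character(p)]])
      repeat {
        q <- matrix(0, 11, 4, dimnames = list(topo$segments, c("w", "x", "y", "z")))
        q["waist", ] <- quat_canonical(qmul(base_waist[[cat_id]],
                                            rotvec_quat(rand_rotvec(0, 0.15))))
        rel <- list(
          breast = rotvec_quat(rand_rotvec(0.1, 0.5)),
          head   = rotvec_quat(rand_rotvec(0.1, 0.5)),
          LUArm  = rotvec_quat(rand_rotvec(0.3, 1.0)),
          RUArm  = rotvec_quat(rand_rotvec(0.3, 1.0)),
          LThigh = rotvec_quat(rand_rotvec(0.3, 1.0)),
          RThigh = rotvec_quat(rand_rotvec(0.3, 1.0)),
          # nominal elbow/knee bend about the joint (local z) plus wobble
          LFArm  = qmul(axis_angle_quat(c(0, 0, 1), stats::runif(1, 0.3, 1.1)),
                        rotvec_quat(rand_rotvec(0, 0.1))),
          RFArm  = qmul(axis_angle_quat(c(0, 0, 1), stats::runif(1, 0.3, 1.1)),
                        rotvec_quat(rand_rotvec(0, 0.1))),
          LShank = qmul(axis_angle_quat(c(0, 0, 1), stats::runif(1, 0.3, 1.1)),
                        rotvec_quat(rand_rotvec(0, 0.1))),
          RShank = qmul(axis_angle_quat(c(0, 0, 1), stats::runif(1, 0.3, 1.1)),
                        rotvec_quat(rand_rotvec(0, 0.1))))
        for (s in c("breast", "head", "LUArm", "LFArm", "RUArm", "RFArm",
                    "LThigh", "LShank", "RThigh", "RShank")) {
          par <- topo$parent[[s]]
          q[s, ] <- quat_canonical(qmul(q[par, ], rel[[s]]))
        }
        same_cat <- Filter(function(t) t$category == cat_id,
                           templates[seq_len(p - 1L)])
        sep_ok <- all(vapply(same_cat, function(t) {
          segs <- setdiff(topo$segments, "waist")
          max(vapply(segs, function(s) quat_angle(q[s, ], t$quats[s, ]),
                     numeric(1))) >= min_sep
        }, logical(1)))
        if (sep_ok) break
      }
      templates[[p]] <- list(posture = p, category = cat_id, quats = q)
    }
    templates
  })
}

#' Generate subject profiles
#'
#' Each subject gets a systematic per-segment rotation-vector offset
#' (Gaussian with std `sigma_subject`, norm clipped to `max_offset`) and a
#' flexibility scale multiplying the frame jitter.  Subject 0 can be used
#' as an idealised "standard performer" via `standard = TRUE` offsets of
#' zero.
#'
#' @param n number of subjects.
#' @param spec a [perturbation_spec()].
#' @param seed integer seed.
#' @param standard logical vector (recycled): `TRUE` gives zero offsets.
#' @return list of `subject_profile` lists.
#' @export
make_subjects <- function(n, spec = perturbation_spec(), seed = 1L,
                          standard = FALSE) {
  standard <- rep_len(standard, n)
  with_seed(seed, {
    lapply(seq_len(n), function(id) {
      off <- matrix(stats::rnorm(33, 0, spec$sigma_subject), 11, 3)
      nrm <- sqrt(rowSums(off^2))
      over <- nrm > spec$max_offset
      off[over, ] <- off[over, , drop = FALSE] * (spec$max_offset / nrm[over])
      flex <- stats::runif(1, 0.8, 1.2)
      if (standard[id]) off[] <- 0
      structure(list(subject = id, offsets = off, flexibility = flex),
                class = "subject_profile")
    })
  })
}

# stationary AR(1) rotation-vector sway, n x 3 (zero matrix if sigma = 0)
sway_series <- function(n, sigma, tau, rate) {
  if (sigma <= 0) return(matrix(0, n, 3))
  if (n == 1L) return(matrix(stats::rnorm(3, 0, sigma), 1, 3))
  phi <- exp(-1 / (rate * tau))
  innov <- matrix(stats::rnorm(3L * n, 0, sigma * sqrt(1 - phi^2)), n, 3)
  innov[1, ] <- stats::rnorm(3, 0, sigma)
  apply(innov, 2, function(x)
    as.numeric(stats::filter(x, phi, method = "recursive")))
}

# core frame synthesis: base 11 x 4 quats -> n x 44 wide rows; per-frame
# rotation = sway (autocorrelated) + white jitter, composed on the right
synth_frames <- function(base_quats, n, spec, flexibility = 1) {
  out <- matrix(0, n, 44)
  sigma <- spec$sigma_frame * flexibility
  for (i in 0:10) {
    b <- base_quats[i + 1L, ]
    W <- sway_series(n, spec$sigma_sway * flexibility, spec$tau_sway,
                     spec$rate)
    if (sigma > 0) W <- W + matrix(stats::rnorm(3L * n, 0, sigma), n, 3)
    if (all(W == 0)) {
      out[, seg_cols(i)] <- matrix(b, n, 4, byrow = TRUE)
    } else {
      th <- sqrt(rowSums(W^2))
      th[th < 1e-300] <- 1e-300
      noise <- cbind(cos(th / 2), sin(th / 2) * W / th)
      out[, seg_cols(i)] <- qmul_rows(matrix(b, n, 4, byrow = TRUE), noise)
    }
  }
  out
}

#' Generate one posture instance
#'
#' Each frame composes, on the right: the posture template, the subject's
#' systematic segment offsets, a per-instance segment offset (repeated
#' performances differ), an optional deliberate deviation, and per-frame
#' isotropic rotation jitter.  Duration is drawn uniformly from the
#' spec's range; frame count = duration x rate.
#'
#' @param template one element of [make_templates()].
#' @param subject a profile from [make_subjects()].
#' @param spec a [perturbation_spec()].
#' @param instance_id instance id recorded in the rows.
#' @param seed optional integer; if given the instance is byte-identical
#'   across calls (used for matched standard/nonstandard pairs).
#' @param deviations optional named list `segment -> c(axis*angle)` rotation
#'   vector (rad) of deliberate nonstandard deviations.
#' @return data.frame of frame rows (see [posture_database()]).
#' @export
generate_instance <- function(template, subject, spec = perturbation_spec(),
                              instance_id = 1L, seed = NULL,
                              deviations = NULL) {
  gen <- function() {
    inst_off <- matrix(stats::rnorm(33, 0, spec$sigma_instance), 11, 3)
    base <- template$quats
    for (s in body_topology()$segments) {
      i <- segment_index(body_topology(), s)
      b <- qmul(qmul(base[s, ], rotvec_quat(subject$offsets[i + 1L, ])),
                rotvec_quat(inst_off[i + 1L, ]))
      if (!is.null(deviations) && s %in% names(deviations))
        b <- qmul(b, rotvec_quat(deviations[[s]]))
      base[s, ] <- b
    }
    dur <- stats::runif(1, spec$duration_range[1], spec$duration_range[2])
    n <- max(1L, as.integer(round(dur * spec$rate)))
    rows <- synth_frames(base, n, spec, subject$flexibility)
    data.frame(subject = subject$subject, posture = template$posture,
               instance = instance_id, time = (seq_len(n) - 1L) / spec$rate,
               rows)
  }
  out <- if (is.null(seed)) gen() else with_seed(seed, gen())
  names(out) <- frame_col_names()
  out
}

#' Generate a labelled multi-subject posture database
#'
#' `n_subjects` x 18 postures x `instances_per_posture` instances with the
#' generator's three noise layers; all randomness flows through `seed`.
#'
#' @param n_subjects number of subjects.  Default 11.
#' @param instances_per_posture instances per (subject, posture) cell.
#'   Default 10.
#' @param spec a [perturbation_spec()].
#' @param seed integer seed.
#' @param templates optional template list (default [make_templates()]
#'   seeded from `seed`).
#' @param subjects optional subject list (default [make_subjects()]).
#' @return a `posture_db`.
#' @export
generate_database <- function(n_subjects = 11L, instances_per_posture = 10L,
                              spec = perturbation_spec(), seed = 1L,
                              templates = NULL, subjects = NULL) {
  if (is.null(templates)) templates <- make_templates(seed)
  if (is.null(subjects)) subjects <- make_subjects(n_subjects, spec, seed + 1L)
  parts <- vector("list", length(subjects) * 18L * instances_per_posture)
  k <- 0L
  with_seed(seed + 2L, {
    for (sub in subjects)
      for (tpl in templates)
        for (inst in seq_len(instances_per_posture)) {
          k <- k + 1L
          parts[[k]] <- generate_instance(tpl, sub, spec, instance_id = inst)
        }
  })
  posture_database(do.call(rbind, parts), validate = FALSE)
}

#' Generate a deliberately nonstandard instance with known ground truth
#'
#' Applies the named per-segment deviations (rotation vectors, typical
#' magnitude 0.3-0.6 rad) on top of ordinary instance generation and
#' returns the ground-truth record for evaluation tests.  With the same
#' `seed`, the instance is the exact matched twin of the standard
#' [generate_instance()] output apart from the injected deviations.
#'
#' @inheritParams generate_instance
#' @param deviations named list `segment -> rotation vector` (rad).
#' @return list with `instance` (frame rows) and `truth` (data.frame
#'   segment / angle / axis columns / root flag).
#' @export
generate_nonstandard <- function(template, deviations, subject,
                                 spec = perturbation_spec(),
                                 instance_id = 1L, seed = NULL) {
  if (!is.list(deviations) ||
      (length(deviations) && is.null(names(deviations))))
    stop("deviations must be a named list segment -> rotation vector")
  segs <- body_topology()$segments
  bad <- setdiff(names(deviations), segs)
  if (length(bad)) stop("unknown segment(s) in deviations: ",
                        paste(bad, collapse = ", "))
  if ("waist" %in% names(deviations))
    warning("deviation on the waist root: the root is scored marginally, ",
            "not against a parent")
  inst <- generate_instance(template, subject, spec, instance_id, seed,
                            deviations = deviations)
  truth <- if (length(deviations)) {
    data.frame(segment = names(deviations),
               angle = vapply(deviations, function(w) sqrt(sum(w^2)),
                              numeric(1)),
               t(vapply(deviations, function(w) {
                 n <- sqrt(sum(w^2)); if (n > 0) w / n else c(0, 0, 0)
               }, numeric(3))),
               root = names(deviations) == "waist", row.names = NULL)
  } else {
    data.frame(segment = character(), angle = numeric(),
               X1 = numeric(), X2 = numeric(), X3 = numeric(),
               root = logical())
  }
  names(truth)[3:5] <- c("axis_x", "axis_y", "axis_z")
  list(instance = inst, truth = truth)
}
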