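# imupose

Full-body posture recognition and corrective guidance from wearable-IMU
quaternion streams.

A trainee practising static full-body exercises (yoga being the
motivating case) cannot see most of their own body. `imupose`
implements the complete chain from an 11-sensor orientation suit (head,
breast, upper arms, forearms, waist, thighs, shanks; unit quaternions
at 40 Hz) to spoken-style corrective feedback:

* **Calibration** — raw sensor quaternions are mapped into a common
  animation frame via a recorded calibration posture:
  `q_i = q_init_g(i) ⊗ q_cali,i⁻¹ ⊗ q_i,global`.
* **Two-stage recognition** — a 9–15–5 sigmoid backpropagation network
  classifies the waist-orientation *category* (stand, lean left/right,
  lie on stomach/back) from the waist rotation-matrix components; a
  per-category fuzzy C-means model (`μ_j ∝ ‖x−m_j‖^(−2/(b−1))`, b = 2)
  over the 90-dimensional body-relative features picks the posture
  (18 modelled postures).
* **Cumulative-likelihood smoothing** — per-frame results accumulate
  ±τ (τ = 0.1) into per-posture likelihoods clipped to [0, 1]; the
  first posture to strictly exceed t3 = 0.5 is the instance result,
  which suppresses isolated misclassified frames.
* **Evaluation** — per posture, a Bayesian network over the body tree
  models each segment jointly with its parent as an 8-D Gaussian on
  waist-relative quaternions; the child-given-parent conditional is
  `μ_s|t = μ_s − B11⁻¹B12(t−μ_t)`, `Σ_s|t = B11⁻¹`, and a segment's
  *standard degree* is the exceedance probability
  `P(‖S−μ_s|t‖ > ‖s−μ_s|t‖)` (Euclidean norm, computed exactly via
  Imhof's integral for Gaussian quadratic forms). Scores below 0.3
  flag a nonstandard segment.
* **Guidance** — flagged segments become an orientation word plus an
  angular extent: planar projections
  `d = sign(−R21)·arccos(R11/√(R11²+R21²))` for arms/head/thighs,
  joint-angle differences for forearms/shanks (bend/stretch), rendered
  as sentences such as `"straighten your right forearm (0.45 rad)"`.

No public dataset accompanies this class of systems, so the package
includes a seeded synthetic-data generator (18 separable posture
templates, per-subject/per-instance offsets, AR(1) postural sway,
sensor jitter) that emulates an 11-subject study; the methods vignette
(`vignettes/posture-evaluation.Rmd`) documents the model, every default
and the generator's limits.

## Worked example

```r
library(imupose)

spec <- perturbation_spec(duration_range = c(2, 3))   # short demo instances
db   <- generate_database(n_subjects = 6, instances_per_posture = 6,
                          spec, seed = 7)
sp   <- split_posture_db(db, train_fraction = 0.3, seed = 5)
model <- train_two_stage(sp$train)

rec <- recognize_database(model, sp$test)
tail(accuracy_report(rec)$instances, 1)
#>    posture correct total accuracy_pct
#> 19   Total     432   432          100

# evaluate a deliberately nonstandard performance of posture 1
trf <- sp$train$frames
net <- fit_posture_network(trf[trf$posture == 1, ], posture = 1)
tpl <- make_templates(7)[[1]]
probe <- make_subjects(1, spec, 99, standard = TRUE)[[1]]
pspec <- spec; pspec$sigma_instance <- 0
bad <- generate_nonstandard(tpl, list(RShank = c(0, 0, 0.5)),
                            probe, pspec, seed = 11)
g <- guidance_report(net, bad$instance, category = tpl$category)
g$sentences
#> [1] "straighten your right knee (0.32 rad)"
```

The recognized-instance table mirrors the standard per-posture
correct/total/percent report. The guidance sentence flags exactly the
injected knee deviation; its extent is measured against the model
trained on the six-subject population, so it folds in that model's
finite-sample mean offset (comparing against the matched standard twin
of the same instance recovers the injected 0.5 rad to within a few
thousandths of a radian — the acceptance script reports that number).

A thin command-line interface over the same functions is installed at
`inst/cli/imupose` (`simulate`, `train`, `recognize`, `evaluate`,
`guide`, `pipeline` subcommands), and `run_pipeline()` executes the
whole chain from one seeded config.

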