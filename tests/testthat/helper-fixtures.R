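# Shared fixtures, generated in code and cached across test files.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

rand_unit_quat <- function() quat_normalize(stats::rnorm(4))

# short instances, full noise structure: fast enough for unit tests
tiny_spec <- function() perturbation_spec(duration_range = c(1, 1.5))

# noiseless spec: frames reproduce the template exactly
silent_spec <- function() {
  perturbation_spec(sigma_subject = 0, sigma_instance = 0, sigma_sway = 0,
                    sigma_frame = 0, duration_range = c(0.5, 0.5))
}

tiny_db <- function() cached("tiny_db", function()
  generate_database(3L, 6L, tiny_spec(), seed = 301L))

tiny_split <- function() cached("tiny_split", function()
  split_posture_db(tiny_db(), 0.3, seed = 302L))

tiny_model <- function() cached("tiny_model", function()
  train_two_stage(tiny_split()$train,
                  config = ann_config(max_epochs = 2000L, seed = 303L),
                  seed = 304L))

tiny_templates <- function() cached("tiny_templates", function()
  make_templates(301L))

# evaluation fixture: 6 subjects x 6 instances, 2-3 s instances; the
# posture-1 Bayesian network is fitted on its 30% training split
eval_fixture <- function() cached("eval_fixture", function() {
  spec <- perturbation_spec(duration_range = c(2, 3))
  db <- generate_database(6L, 6L, spec, seed = 401L)
  sp <- split_posture_db(db, 0.3, seed = 402L)
  trf <- sp$train$frames
  net <- fit_posture_network(trf[trf$posture == 1L, , drop = FALSE],
                             posture = 1L)
  list(spec = spec, templates = make_templates(401L), net = net)
})

# a careful probe performer: nominal posture + sway and sensor jitter only
probe_spec <- function(spec) {
  spec$sigma_instance <- 0
  spec
}

standard_probe_subject <- function(spec, seed = 499L)
  make_subjects(1L, spec, seed, standard = TRUE)[[1L]]
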