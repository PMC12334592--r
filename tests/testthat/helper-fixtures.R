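# Shared fixtures, computed lazily and memoized so each expensive object is
# built at most once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

gt_params <- function() fixture("gt_params", function() default_parameters("d2fc2"))

pulse_library <- function() fixture("pulse_library", make_pulse_condition_library)

gt_model <- function() fixture("gt_model", function() {
  build_model("d2fc2", params = gt_params())
})

gt_steady <- function() fixture("gt_steady", function() {
  run_to_steady_state(gt_model())
})

# mean-condition simulations for the main conditions, reused across tests
gt_condition_sims <- function() fixture("gt_condition_sims", function() {
  lib <- pulse_library()
  sims <- list()
  for (cond in c("control", "1x6", "1x15", "4x1.5", "1x30")) {
    sims[[cond]] <- simulate_response(gt_model(),
                                      ci_input = fit_gaussian_sum(lib[[cond]]),
                                      steady = gt_steady())
  }
  sims
})

# small noisy cohort used by feature/prediction tests
small_cohort <- function() fixture("small_cohort", function() {
  generate_cohort(gt_params(), pulse_library()[c("1x6", "1x15", "4x1.5")],
                  n_cells_per_condition = 10, ci_jitter = 0.1,
                  noise_sd = 0.05, seed = 101)
})

# relative change between two state vectors, floored at a small fraction of
# the NF-kB scale so empty species do not blow up the ratio
state_rel_diff <- function(a, b, scale = 1e-4) {
  max(abs(a - b) / pmax(pmax(abs(a), abs(b)), scale))
}
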