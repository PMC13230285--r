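# reference parameter set used throughout the tests (the simulation-study
# configuration: Gamma(2.36, 3) growth-rate prior, log-hazards -4.5/-6.5/-8.75,
# logistic sensitivities b0 = -5, b1 = 0.1, b2 = 0.56)
ref_params <- function() nh_params()

# small screened population shared by several tests (cached per session)
.test_env <- new.env()
screened_population <- function(rate = 20L, seed = 11L) {
  key <- paste0("pop_", rate, "_", seed)
  if (is.null(.test_env[[key]])) {
    pop <- population_config(onsets_per_step = rate, step = 0.01,
                             t_start = 0, t_end = 342, seed = seed)
    .test_env[[key]] <- simulate_population(ref_params(), pop,
                                            biennial_schedule(),
                                            keep_window = c(340, 342))
  }
  .test_env[[key]]
}
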