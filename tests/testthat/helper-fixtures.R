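# Small simulated bundles shared across test files. Sizes are kept well
# below the default experiment so unit tests stay fast; the full-size
# defaults are exercised in the acceptance tests.

small_config <- function(seed = 101, ...) {
  simulation_config(n_asvs = 24, n_timepoints = 18, n_responders = 6,
                    overlap_time_independent = 2, n_drift = 4,
                    read_depth = 800, seed = seed, ...)
}

# memoise the default small bundle; many tests only need its shape
.small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_experiment(small_config())
    cache
  }
})

fast_rf <- function(seed = 1) rf_spec(n_trees = 300, seed = seed)

toy_counts <- function() {
  abundance_table(matrix(c(3, 1, 0, 4), 2, byrow = TRUE,
                         dimnames = list(c("s1", "s2"), c("a1", "a2"))))
}
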