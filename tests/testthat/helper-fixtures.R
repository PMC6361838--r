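# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# the default synthetic benchmark: 12 subjects x 5 runs per task, 60 nodes,
# 196 time points, intrinsic-dominant variances
benchmark_dataset <- function() {
  memo("benchmark", function() generate_dataset(generator_config(seed = 101)))
}

# same design without any shared stimulus-locked signal
null_benchmark_dataset <- function() {
  memo("null_benchmark", function()
    generate_dataset(generator_config(sigma_shared = 0, seed = 101)))
}

# small dataset for structural tests
tiny_dataset <- function(seed = 1, ...) {
  generate_dataset(generator_config(K = 4, runs_per_task = 2, P = 12, N = 60,
                                    n_networks = 3, L = 3, L_int = 3,
                                    seed = seed, ...))
}

# reduced design for permutation-heavy checks
reduced_dataset <- function(seed = 3, ...) {
  generate_dataset(generator_config(K = 6, runs_per_task = 2, P = 24, N = 80,
                                    n_networks = 4, seed = seed, ...))
}

tiny_atlas_table <- function(P = 6, labels = rep(c("A", "B"), each = 3)) {
  data.frame(node_id = seq_len(P), x = seq_len(P), y = -seq_len(P),
             z = rep(0, P), network_label = labels)
}

random_run <- function(P = 5, N = 40, TR = 2, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  run_ts(matrix(rnorm(P * N), P, N), TR = TR, ...)
}
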