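# Small seeded fixtures shared across test files.

tiny_config <- function(...) {
  args <- list(n_blocks = 1, n_heads = 2, n_features = 8, cheb_order = 2,
               window_length = 5, window_overlap = 1, batch_size = 8,
               learning_rate = 1e-3, lr_patience = 2, max_epochs = 3, seed = 1)
  do.call(model_config, utils::modifyList(args, list(...)))
}

tiny_cohort <- function(n_per_class = 3, n_nodes = 4, L = 30, seed = 7,
                        coupling = c(0.8, 0), planted = 0:1, ...) {
  generate_cohort(cohort_spec(n_per_class = n_per_class, n_nodes = n_nodes,
                              series_length = L, planted_nodes = planted,
                              coupling_by_class = coupling, seed = seed, ...))
}

# Random feature tensor and matching random fc networks.
rand_tensor <- function(B, T_, N, F, seed = 1) {
  set.seed(seed)
  array(rnorm(B * T_ * N * F), c(B, T_, N, F))
}

rand_network <- function(N, T_ = 30, seed = 1) {
  set.seed(seed)
  pearson_fc(matrix(rnorm(T_ * N), T_, N))
}

# The study conditions used by the recovery/ablation experiments: 40 + 40
# subjects, 20 nodes, a 6-node planted subnetwork coupled at 0.8 in class 0
# and 0 in class 1, 200 time points, windows of 25 with overlap 5.
study_cohort <- function(seed = 11) {
  generate_cohort(cohort_spec(
    n_per_class = 40, n_nodes = 20, series_length = 200, planted_nodes = 0:5,
    coupling_by_class = c(0.8, 0), seed = seed))
}

study_config <- function(seed = 1, ...) {
  args <- list(n_blocks = 1, n_heads = 2, n_features = 8, cheb_order = 3,
               window_length = 25, window_overlap = 5, batch_size = 50,
               learning_rate = 2e-3, lr_patience = 2, max_epochs = 6,
               seed = seed)
  do.call(model_config, utils::modifyList(args, list(...)))
}
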