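# Shared fixtures: light training configuration and clearly separable
# population specs used by the classifier oracles. Effect sizes here are
# deliberately strong so that classifier sanity properties (high AUC on
# separable data, chance on permuted labels) are tested away from the
# decision boundary.

light_config <- function(seed = 1L, ...) {
  mechanoage_config(folds = 3L, repeats = 1L, rf_tune_length = 2L,
                    num_trees = 80L, bagged_resamples = 25L,
                    meta_folds = 3L, meta_tune_length = 3L, seed = seed, ...)
}

separable_younger_spec <- function(n_cells, seed) {
  population_spec("younger", wcdi_location = 4.2, wcdi_scale = 0.35,
                  recovery_distribution = c(0.70, 0.15, 0.08, 0.05, 0.02),
                  n_cells = n_cells, seed = seed)
}

separable_older_spec <- function(n_cells, seed) {
  population_spec("older", wcdi_location = 3.0, wcdi_scale = 0.35,
                  recovery_distribution = c(0.05, 0.10, 0.15, 0.35, 0.35),
                  n_cells = n_cells, seed = seed)
}

separable_feature_table <- function(n_per_group, seed) {
  build_feature_table(rbind(
    simulate_population(separable_younger_spec(n_per_group, seed)),
    simulate_population(separable_older_spec(n_per_group, seed + 1L))
  ))
}
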