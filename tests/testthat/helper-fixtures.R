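# Shared fixture builders (everything generated in code; no stored data).

# Small dataset on a complete grid with deterministic placeholder sequences.
make_grid_dataset <- function(n_drugs, n_targets, seed = 1) {
  withr::local_seed(seed)
  d_ids <- sprintf("d%02d", seq_len(n_drugs))
  t_ids <- sprintf("t%02d", seq_len(n_targets))
  drugs <- stats::setNames(
    vapply(seq_len(n_drugs),
           function(i) paste(sample(c("C", "N", "O", "="), 10, TRUE), collapse = ""),
           character(1)), d_ids)
  targets <- stats::setNames(
    vapply(seq_len(n_targets),
           function(i) paste(sample(LETTERS[1:20], 20, TRUE), collapse = ""),
           character(1)), t_ids)
  grid <- expand.grid(drug_id = d_ids, target_id = t_ids,
                      stringsAsFactors = FALSE)
  grid$affinity <- stats::rnorm(nrow(grid), 6, 1)
  dt_dataset(drugs, targets, grid)
}

# Random token sequence with a padded tail.
make_tokens <- function(ids, max_len) {
  n <- length(ids)
  structure(list(ids = c(ids, rep(0L, max_len - n)),
                 mask = seq_len(max_len) <= n,
                 original_length = n,
                 tokens = rep("x", n)),
            class = "mildta_tokens")
}

# A tiny architecture used across layer-level tests.
tiny_model_config <- function(...) {
  model_config(d_model = 8, n_heads = 2, n_layers = 1, ffn_dim = 16,
               n_gate_blocks = 2, kernel_size = 3, dilation_rates = c(1L, 2L),
               max_len_drug = 6, max_len_protein = 10,
               scorer_widths = c(12L, 6L), ...)
}

random_ctx <- function(T, d, n_real = T, seed = 1) {
  withr::local_seed(seed)
  list(values = matrix(stats::rnorm(T * d), T, d),
       mask = seq_len(T) <= n_real)
}
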