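# Shared fixtures, built in code at test time.

# tiny labeled dataset with hand-set values
toy_dataset <- function(values = NULL, n_features = 3L, n_per_class = 2L,
                        seed = 1L, positive = "A") {
  if (is.null(values)) {
    values <- multisol:::with_seed(seed, {
      matrix(rnorm(n_features * 2L * n_per_class), nrow = n_features)
    })
  }
  rownames(values) <- paste0("g", seq_len(nrow(values)))
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  labels <- rep(c("A", "B"), each = ncol(values) / 2L)
  expression_dataset(values, labels, positive_class = positive)
}

# random dataset with a planted shift on the first `k_inf` features
random_dataset <- function(n_features = 20L, n_per_class = 10L, effect = 0,
                           k_inf = 0L, seed = 1L) {
  generate_dataset(synthetic_spec(
    n_features = n_features,
    n_samples_per_class = c(n_per_class, n_per_class),
    n_informative = k_inf, effect_size = effect, seed = seed
  ))
}

# write a dataset to tempfiles, returning c(matrix, labels)
write_temp_dataset <- function(ds, sep = "\t") {
  paths <- c(tempfile(fileext = ".tsv"), tempfile(fileext = ".tsv"))
  write_dataset(ds, paths[1L], paths[2L], sep = sep)
  paths
}
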