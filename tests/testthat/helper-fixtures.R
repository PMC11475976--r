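# Shared fixtures, all generated in code.

# small balanced table with planted signal, cheap enough for optimizer loops
small_table <- function(n_per_class = 60, d = 8, n_informative = 3,
                        effect = 2, seed = 11) {
  generate_feature_table(synthetic_table_spec(
    class_sizes = c(a = n_per_class, b = n_per_class),
    n_features = d, n_informative = n_informative,
    effect_size = effect, seed = seed))
}

# enumerate every non-empty mask of length d and return the wrapper optimum
enumerate_oracle <- function(table, split, d = ncol(table$features),
                             fit_cfg = fitness_config()) {
  best <- list(fitness = -Inf, mask = NULL)
  for (m in seq_len(2^d - 1)) {
    mask <- as.integer(intToBits(m)[seq_len(d)])
    f <- evaluate_mask(mask, table, split, fit_cfg)$fitness
    if (f > best$fitness) best <- list(fitness = f, mask = mask)
  }
  best
}

short_sine_clip <- function(freq = 440, sr = 22050, dur = 1) {
  audio_clip(sin(2 * pi * freq * seq_len(round(sr * dur)) / sr), sr,
             paste0("sine_", freq))
}
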