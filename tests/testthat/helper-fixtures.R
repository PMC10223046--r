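# Small datasets built in code for fast tests.

tiny_grid <- function(n = 10) wavelength_grid(350, 350 + n - 1, 1)

# Hand-built dataset on a tiny grid: deterministic values, both states.
tiny_dataset <- function(n_per_cell = 2, n_wl = 10) {
  grid <- tiny_grid(n_wl)
  rows <- expand.grid(rep = seq_len(n_per_cell), class = 0:1,
                      state = c("frozen", "thawed"),
                      stringsAsFactors = FALSE)
  refl <- outer(seq_len(nrow(rows)), seq_len(n_wl),
                function(i, j) 0.3 + 0.01 * i + 0.001 * j)
  spectra_dataset(refl,
                  data.frame(sample_id = sprintf("S%02d", rows$class * 10 + rows$rep),
                             product_class = rows$class,
                             physical_state = rows$state),
                  grid)
}

# Small synthetic dataset from the generator on a reduced grid, sized so
# that the 7:3 split and pca_k features still feed every deep model.
small_synth <- function(seed = 1, n_samples = 2, n_rep = 25,
                        end_nm = 500, ...) {
  generate_dataset(generator_config(
    n_samples_per_class = n_samples,
    n_spectra_per_sample_per_state = n_rep,
    grid = wavelength_grid(350, end_nm, 1),
    seed = seed, ...))
}
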