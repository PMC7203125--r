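# Shared fixtures: small screens built in code so every test is
# self-contained and fast.

small_panel <- function(n = 8) default_gene_panel()[seq_len(n)]

small_config <- function(..., n_media = 2) {
  sim_config(panel = small_panel(), n_sl_pairs = 3, n_epistatic_pairs = 5,
             media = default_media()[seq_len(n_media), ], ...)
}

small_noiseless <- function(..., n_media = 2) {
  noiseless_config(panel = small_panel(), n_sl_pairs = 3,
                   n_epistatic_pairs = 5,
                   media = default_media()[seq_len(n_media), ], ...)
}

small_screen <- function(config = small_config(), truth_seed = 7,
                         sim_seed = 8, ...) {
  simulate_screen(make_truth(config, seed = truth_seed), seed = sim_seed, ...)
}

# Minimal hand-built plate: one WT row pair is not needed; uses the real
# scheme on a tiny grid. Rows 1-2 WT, rows 3-6 mutants (2x2 blocks), 4 cols.
tiny_scheme <- function() plate_scheme(n_rows = 6, n_cols = 4,
                                       wt_rows = c("A", "B"))

# Long colony table from a layout and a rate lookup: exact linear series.
linear_sizes <- function(layout, rates, times = c(12, 24, 36, 48, 60),
                         s0 = 0, media = "YPD") {
  key <- paste(layout$plate, layout$row, layout$col)
  tidyr::expand_grid(i = seq_len(nrow(layout)), time_h = times) |>
    dplyr::mutate(plate = layout$plate[i], media = media,
                  row = layout$row[i], col = layout$col[i],
                  size = unname(rates[key[i]]) * time_h + s0) |>
    dplyr::select(plate, media, row, col, time_h, size)
}
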