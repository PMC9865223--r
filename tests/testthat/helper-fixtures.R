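# Shared fixtures: small random stacks and plot tables built in code.

# random but valid reflectance stack, all six phases, ten bands
make_test_stack <- function(seed = 1, rows = 8, cols = 8) {
  set.seed(seed)
  refl <- array(runif(6 * 10 * rows * cols, 0.01, 0.6),
                dim = c(6, 10, rows, cols))
  multi_temporal_stack(refl)
}

# n_plots 3x3 plots on a regular grid, all one class unless classes given
make_test_plots <- function(n_plots, classes = "crops", plot_size = 3,
                            ncol_cells = 10, cell = 5) {
  classes <- rep_len(classes, n_plots)
  do.call(rbind, lapply(seq_len(n_plots), function(i) {
    cr <- (i - 1) %/% ncol_cells
    cc <- (i - 1) %% ncol_cells
    px <- expand.grid(row = cr * cell + seq_len(plot_size),
                      col = cc * cell + seq_len(plot_size))
    data.frame(plot_id = sprintf("P%03d", i), class = classes[i],
               row = px$row, col = px$col, stringsAsFactors = FALSE)
  }))
}

# long sample table with exact per-cell values (for screening tests)
make_sample_rows <- function(class, band, phase, values) {
  data.frame(class = class, pixel = seq_along(values), band = band,
             phase = phase, reflectance = values,
             stringsAsFactors = FALSE)
}
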