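# Builders for in-code fixtures: noiseless performance tables generated
# straight from the theory curves, so fits can be checked for exact
# self-consistency.

make_perf_table <- function(mse_tbl, sem = 1e-4, n_trials = 660L,
                            n_subjects = 10L) {
  tab <- dplyr::arrange(mse_tbl, set_size, delay_s)
  tab$sem_norm <- rep_len(sem, nrow(tab))
  tab$var_norm <- rep_len(2 * tab$mse_norm^2 + 1e-8, nrow(tab))
  tab$n_trials <- n_trials
  tab$n_subjects <- n_subjects
  structure(tab,
            class = c("performance_table", class(tab)),
            baseline_delay = min(tab$delay_s))
}

# anchored noiseless table: theory increments on top of fixed baselines
noiseless_table <- function(model, baselines = c(`1` = 0.0015, `2` = 0.003,
                                                 `4` = 0.007, `6` = 0.012),
                            set_sizes = c(1, 2, 4, 6),
                            delays = c(0.1, 1, 2, 3), ...) {
  curve <- theory_curve(model, set_sizes, delays, ...)
  t0 <- min(delays)
  base_curve <- theory_curve(model, set_sizes, t0, ...)
  increment <- curve$mse_norm -
    base_curve$mse_norm[match(curve$set_size, base_curve$set_size)]
  curve$mse_norm <- unname(baselines[as.character(curve$set_size)] +
                             increment)
  make_perf_table(curve)
}

small_design <- function(n_subjects = 3L, blocks = 2L, ...) {
  experiment_design(n_subjects = n_subjects,
                    blocks_range = c(blocks, blocks), ...)
}
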