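# Independent oracles used across tests.

# cycle-by-cycle frequency recurrence, written independently of
# simulate_assay
recurrence_oracle <- function(f0, s, n_cycles) {
  f <- f0 / sum(f0)
  out <- matrix(NA_real_, length(f), n_cycles + 1)
  out[, 1] <- f
  for (k in seq_len(n_cycles)) {
    w <- f * exp(s)
    f <- w / sum(w)
    out[, k + 1] <- f
  }
  out
}

# expected number of distinct values when n draws are made uniformly
# from a space of size U (birthday-problem bound)
expected_distinct <- function(n, U) U * (1 - (1 - 1 / U)^n)

# theoretical early/late correlation for the linear trade-off model
tradeoff_r_closed_form <- function(slope, sd_early, residual_sd) {
  slope * sd_early / sqrt(slope^2 * sd_early^2 + residual_sd^2)
}

# panel of phenotypes + fitted fitness used by several tests
make_small_panel <- function(n = 220, frac_adaptive = 200 / 220, seed = 1,
                             conditions = c("GE_2day", "GE_4day", "GE_6day",
                                            "GE_8day", "GE_10day")) {
  ph <- sample_phenotypes(n, tradeoff_config(fraction_adaptive = frac_adaptive),
                          seed = seed)
  pan <- simulate_fitness_panel(ph, assay_regimes()[conditions], seed = seed)
  list(ph = ph, pan = pan, perf = performance_table(pan$fitness))
}
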