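# Forward simulation of barcoded lineages through growth cycles.
#
# Per cycle the lineage frequencies update as
#   f_i <- f_i exp(s_i) / sum_j f_j exp(s_j)
# where s_i is the lineage's per-cycle fitness in the regime, so the
# log fold change of a lineage over a cycle is its fitness minus the
# population mean fitness m = log sum_j f_j exp(s_j). The transfer
# bottleneck is a multinomial draw of bottleneck_cells; sequencing
# counts are Dirichlet-multinomial with variance inflation kappa.

#' Sequencing / counting noise configuration
#'
#' @param reads_per_timepoint total reads drawn per timepoint (> 0).
#' @param overdispersion_kappa multiplier (>= 1) on the multinomial
#'   count variance; 1 gives plain multinomial sampling, larger values
#'   are realized as Dirichlet-multinomial.
#' @param read_error_rate per-base substitution probability used by
#'   [emit_reads()].
#' @param deterministic if `TRUE`, all sampling is replaced by expected
#'   values (no bottleneck, counts are `reads_per_timepoint * f_i` as
#'   reals); used for exact oracles.
#' @param seed integer seed for all stochastic draws.
#' @return an object of class `noise_config`.
#' @export
noise_config <- function(reads_per_timepoint = 1e6, overdispersion_kappa = 1,
                         read_error_rate = 0, deterministic = FALSE, seed = 1) {
  check_field(is_num1(reads_per_timepoint) && reads_per_timepoint > 0,
              "reads_per_timepoint", "must be > 0")
  check_field(is_num1(overdispersion_kappa) && overdispersion_kappa >= 1,
              "overdispersion_kappa", "must be >= 1")
  check_field(is_prob(read_error_rate), "read_error_rate", "must be in [0, 1]")
  structure(list(reads_per_timepoint = reads_per_timepoint,
                 overdispersion_kappa = overdispersion_kappa,
                 read_error_rate = read_error_rate,
                 deterministic = isTRUE(deterministic), seed = as.integer(seed)),
            class = "noise_config")
}

# Dirichlet-multinomial draw with target variance inflation kappa:
# var = kappa * R * f (1 - f). kappa = 1 reduces to multinomial.
rdirmnom <- function(R, f, kappa) {
  if (kappa <= 1 + 1e-12) {
    drop(stats::rmultinom(1, R, f))
  } else {
    alpha0 <- (R - kappa) / (kappa - 1)
    if (alpha0 <= 0) stopf("overdispersion_kappa too large for reads_per_timepoint")
    g <- stats::rgamma(length(f), shape = alpha0 * f, rate = 1)
    if (sum(g) == 0) g[which.max(f)] <- 1
    drop(stats::rmultinom(1, R, g / sum(g)))
  }
}

#' Simulate a fitness-measurement assay
#'
#' Propagates lineage frequencies through `n_cycles` growth cycles in a
#' regime and returns sequencing counts at each timepoint (cycles
#' 0..n_cycles) together with the true frequency and mean-fitness
#' trajectories.
#'
#' @param phenotypes a `phenotype_set` from [sample_phenotypes()], or a
#'   named numeric vector of per-cycle fitnesses (advanced use).
#' @param regime a [regime_spec()].
#' @param n_cycles number of growth cycles (>= 2).
#' @param noise a [noise_config()].
#' @param init_freq optional initial frequencies (default uniform).
#' @param replicate replicate index recorded on the count matrix.
#' @param unobserved_neutral_fraction optional fraction of the culture
#'   made up of an unbarcoded neutral strain; it competes (entering the
#'   mean fitness) but is never sequenced. Off (0) by default.
#' @return list with `counts` (a [count_matrix()]), `truth` (list with
#'   `freq` barcode x timepoint matrix, `s` true per-cycle fitness,
#'   `mean_fitness` the per-cycle population mean fitness
#'   `log sum f exp(s)`).
#' @examples
#' ph <- sample_phenotypes(50, tradeoff_config(), seed = 1)
#' sim <- simulate_assay(ph, regime_spec(6, "GlyEth"), n_cycles = 4,
#'                       noise = noise_config(1e5, seed = 2))
#' sim$counts
#' @export
simulate_assay <- function(phenotypes, regime, n_cycles, noise = noise_config(),
                           init_freq = NULL, replicate = 1L,
                           unobserved_neutral_fraction = 0) {
  stopifnot(inherits(regime, "regime_spec"), inherits(noise, "noise_config"))
  if (!is_count(n_cycles) || n_cycles < 2) stopf("n_cycles must be an integer >= 2")
  s <- if (inherits(phenotypes, "phenotype_set")) cycle_fitness(phenotypes, regime) else phenotypes
  if (is.null(names(s))) stopf("per-cycle fitnesses must be named by lineage")
  if (anyDuplicated(names(s))) stopf("lineage ids must be distinct")
  check_field(is_prob(unobserved_neutral_fraction) && unobserved_neutral_fraction < 1,
              "unobserved_neutral_fraction", "must be in [0, 1)")
  n <- length(s)
  if (!is.null(init_freq) && (any(init_freq < 0) || sum(init_freq) <= 0))
    stopf("initial frequencies are all zero or negative")
  f <- if (is.null(init_freq)) rep(1 / n, n) else init_freq / sum(init_freq)
  if (unobserved_neutral_fraction > 0) {
    s <- c(s, UNBARCODED_NEUTRAL = 0)
    f <- c(f * (1 - unobserved_neutral_fraction), unobserved_neutral_fraction)
    n <- n + 1
  }
  set.seed(noise$seed)
  R <- noise$reads_per_timepoint
  freq <- matrix(NA_real_, n, n_cycles + 1, dimnames = list(names(s), NULL))
  counts <- matrix(NA_real_, n, n_cycles + 1, dimnames = list(names(s), NULL))
  mbar <- numeric(n_cycles)
  observe <- function(f) {
    if (noise$deterministic) R * f else rdirmnom(R, f, noise$overdispersion_kappa)
  }
  freq[, 1] <- f
  counts[, 1] <- observe(f)
  for (k in seq_len(n_cycles)) {
    w <- f * exp(s)
    mbar[k] <- log(sum(w))
    f <- w / sum(w)
    if (!noise$deterministic) {
      cells <- drop(stats::rmultinom(1, regime$bottleneck_cells, f))
      f <- cells / sum(cells)
    }
    freq[, k + 1] <- f
    counts[, k + 1] <- observe(f)
  }
  obs <- !grepl("^UNBARCODED_NEUTRAL$", rownames(counts))
  cm <- count_matrix(counts[obs, , drop = FALSE], timepoint_cycles = 0:n_cycles,
                     condition = condition_label(regime), replicate = replicate)
  list(counts = cm,
       truth = list(freq = freq, s = s, mean_fitness = mbar))
}

#' Simulate an evolving population with beneficial-mutation supply
#'
#' Propagates an initially neutral barcoded pool through growth cycles;
#' each cycle every still-neutral lineage acquires a beneficial
#' mutation with probability `cfg$mutation_rate_per_cycle`, with
#' per-cycle effect size drawn from `cfg$dfe`. Tracks the barcode
#' frequency trajectory, e.g. for diversity-loss dynamics under
#' different stationary-phase lengths.
#'
#' @param n_lineages initial number of barcoded lineages.
#' @param regime a [regime_spec()].
#' @param n_cycles number of growth cycles.
#' @param cfg a [tradeoff_config()] (supplies mutation rate and DFE).
#' @param noise a [noise_config()].
#' @return list with `counts` (a [count_matrix()]), `s` (final per-cycle
#'   fitness per lineage), `mutated_cycle` (cycle at which each lineage
#'   mutated, NA if never).
#' @export
simulate_evolution <- function(n_lineages, regime, n_cycles,
                               cfg = tradeoff_config(mutation_rate_per_cycle = 1e-3),
                               noise = noise_config(1e5)) {
  stopifnot(inherits(regime, "regime_spec"), inherits(cfg, "tradeoff_config"),
            inherits(noise, "noise_config"))
  set.seed(noise$seed)
  n <- as.integer(n_lineages)
  ids <- sprintf("BC%05d", seq_len(n))
  s <- stats::setNames(numeric(n), ids)
  mutated <- rep(NA_integer_, n)
  f <- rep(1 / n, n)
  R <- noise$reads_per_timepoint
  counts <- matrix(NA_real_, n, n_cycles + 1, dimnames = list(ids, NULL))
  counts[, 1] <- if (noise$deterministic) R * f else rdirmnom(R, f, noise$overdispersion_kappa)
  for (k in seq_len(n_cycles)) {
    neutral <- is.na(mutated)
    if (cfg$mutation_rate_per_cycle > 0 && any(neutral)) {
      hit <- neutral & stats::runif(n) < cfg$mutation_rate_per_cycle
      if (any(hit)) {
        s[hit] <- draw_dfe(cfg$dfe, sum(hit))
        mutated[hit] <- k
      }
    }
    w <- f * exp(s)
    f <- w / sum(w)
    if (!noise$deterministic) {
      cells <- drop(stats::rmultinom(1, regime$bottleneck_cells, f))
      f <- cells / sum(cells)
    }
    counts[, k + 1] <- if (noise$deterministic) R * f else rdirmnom(R, f, noise$overdispersion_kappa)
  }
  cm <- count_matrix(counts, timepoint_cycles = 0:n_cycles,
                     condition = condition_label(regime), replicate = 1L)
  list(counts = cm, s = s, mutated_cycle = mutated)
}
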