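# End-to-end driver: simulate and fit a multi-condition fitness panel.
#
# The measurement design pools evolved clones with unevolved ancestor
# barcodes and assays the pool in several transfer regimes, in
# triplicate. This driver reproduces that design on synthetic
# phenotypes and returns the stacked fitness table the performance
# decomposition consumes.

#' Append neutral ancestor barcodes to a phenotype set
#'
#' Adds `n` all-zero-phenotype lineages labelled `"ancestor"` whose
#' barcode trajectories are later pooled by [aggregate_ancestors()].
#'
#' @param phenotypes a `phenotype_set`.
#' @param n number of ancestor barcodes (default 3).
#' @return the extended `phenotype_set`; ancestor ids are `ANC01 ...`.
#' @export
add_ancestors <- function(phenotypes, n = 3) {
  stopifnot(inherits(phenotypes, "phenotype_set"))
  anc <- phenotypes[rep(1, n), ]
  anc$lineage_id <- sprintf("ANC%02d", seq_len(n))
  anc$is_adaptive <- FALSE
  anc$mutation_label <- "ancestor"
  anc$ploidy <- 1L
  seg <- c(names(segment_grid("GlyEth")), names(segment_grid("glucose")))
  anc[, seg] <- 0
  out <- rbind(phenotypes, anc)
  rownames(out) <- NULL
  class(out) <- c("phenotype_set", "data.frame")
  out
}

#' Default assay regime panel
#'
#' The nine measurement conditions: Gly/Eth transfers every 2, 4, 6, 8
#' and 10 days plus glucose transfers every 1, 2, 3 and 5 days, at an
#' assay-scale bottleneck.
#'
#' @param bottleneck_cells bottleneck for the assay simulations;
#'   default 1e7 so that pools of a few hundred lineages keep roughly
#'   the per-lineage bottleneck population of the real assay and drift
#'   stays subdominant to sequencing noise.
#' @return named list of [regime_spec()] objects.
#' @export
assay_regimes <- function(bottleneck_cells = 1e7) {
  regs <- c(lapply(c(2, 4, 6, 8, 10), regime_spec, medium = "GlyEth",
                   bottleneck_cells = bottleneck_cells),
            lapply(c(1, 2, 3, 5), regime_spec, medium = "glucose",
                   bottleneck_cells = bottleneck_cells))
  stats::setNames(regs, vapply(regs, condition_label, character(1)))
}

#' Simulate and fit a multi-condition fitness panel
#'
#' For each regime and replicate, simulates a pooled fitness assay of
#' the given phenotypes (ancestor barcodes appended), aggregates the
#' ancestors, fits [lineage_fitness()] with the gauge pinned to the
#' marked-neutral reference set, and stacks the per-lineage estimates.
#'
#' @param phenotypes a `phenotype_set` (without ancestors; they are
#'   added here).
#' @param regimes list of [regime_spec()] (default [assay_regimes()]).
#' @param n_cycles growth cycles per assay (default 5).
#' @param replicates replicates per condition (default 3).
#' @param reads_per_timepoint,kappa sequencing depth and
#'   overdispersion.
#' @param n_ancestors ancestor barcodes pooled into `"ANCESTOR"`.
#' @param seed base seed; each (regime, replicate) uses a distinct
#'   derived seed.
#' @param deterministic run all assays in deterministic (expected
#'   value) mode.
#' @return list with `fitness` (stacked data frame: `lineage`,
#'   `condition`, `replicate`, `s`, `error`, `n_intervals`,
#'   `reads_min`), `truth` (per-condition true per-cycle fitness
#'   matrix, lineages x conditions), and `phenotypes` (with
#'   ancestors).
#' @export
simulate_fitness_panel <- function(phenotypes, regimes = assay_regimes(),
                                   n_cycles = 5, replicates = 3,
                                   reads_per_timepoint = 1e6, kappa = 2,
                                   n_ancestors = 3, seed = 1,
                                   deterministic = FALSE) {
  stopifnot(inherits(phenotypes, "phenotype_set"))
  ph <- add_ancestors(phenotypes, n_ancestors)
  anc_ids <- grep("^ANC[0-9]+$", ph$lineage_id, value = TRUE)
  neutral <- c("ANCESTOR", ph$lineage_id[!ph$is_adaptive & !(ph$lineage_id %in% anc_ids)])
  rows <- list()
  truth <- sapply(regimes, function(rg) cycle_fitness(ph, rg))
  for (ci in seq_along(regimes)) {
    rg <- regimes[[ci]]
    for (r in seq_len(replicates)) {
      ns <- noise_config(reads_per_timepoint, overdispersion_kappa = kappa,
                         deterministic = deterministic,
                         seed = seed + 1000L * ci + r)
      sim <- simulate_assay(ph, rg, n_cycles, noise = ns, replicate = r)
      cm <- aggregate_ancestors(sim$counts, anc_ids)
      fit <- lineage_fitness(cm, neutral_ids = intersect(neutral, rownames(cm)),
                             reference = intersect(neutral, rownames(cm)))
      est <- fit$estimates
      est$condition <- fit$condition
      est$replicate <- fit$replicate
      rows[[length(rows) + 1]] <- est
    }
  }
  fitness <- do.call(rbind, rows)
  fitness <- fitness[, c("lineage", "condition", "replicate", "s", "error",
                         "n_intervals", "reads_min")]
  rownames(fitness) <- NULL
  list(fitness = fitness, truth = truth, phenotypes = ph)
}
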