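# Ground-truth lineage phenotypes.
#
# Each lineage carries an hourly growth advantage in every segment of
# the growth cycle (the segment grids of segment_grid()). The per-cycle
# fitness implied in a regime of L hours is the sum over segments
# intersecting [0, L) of hourly advantage x hours covered, which is the
# additivity the phase-performance decomposition later recovers.

#' Trade-off configuration for phenotype sampling
#'
#' Parameters of the generative model behind [sample_phenotypes()].
#' Adaptive lineages draw one early stationary-phase hourly effect
#' (applied to the day 2-4 and day 4-6 segments) and one late effect
#' (applied to the day 6-8 and day 8-10 segments) generated as
#' `slope_late_on_early * early + Normal(0, residual_sd_late)`, so a
#' negative slope produces an early/late trade-off. The glucose
#' stationary-phase segments are coupled to the same early effect with
#' coefficient `glucose_coupling` plus independent noise, emulating the
#' cross-medium overlap in stationary-phase traits.
#'
#' @param mean_early_effect,sd_early_effect mean and SD of the early
#'   stationary-phase hourly advantage (per-hour log units).
#' @param slope_late_on_early dimensionless slope linking late to early
#'   effects (negative for a trade-off).
#' @param residual_sd_late SD of the late-effect residual (per hour).
#' @param fraction_adaptive fraction of lineages carrying a beneficial
#'   mutation, in `[0, 1]`.
#' @param mutation_rate_per_cycle probability that a neutral lineage
#'   acquires a beneficial mutation per growth cycle (used by
#'   [simulate_evolution()]).
#' @param dfe named distribution of per-cycle effect sizes for new
#'   mutations, `list(dist = "exponential", mean = ...)` or
#'   `list(dist = "fixed", value = ...)`.
#' @param mean_growth_effect,sd_growth_effect hourly advantage during
#'   the growth segment (defaults 0: purely stationary-phase biology).
#' @param glucose_coupling,residual_sd_glucose coupling of the glucose
#'   stationary-phase segments to the early Gly/Eth effect.
#' @param fraction_diploid fraction of adaptive lineages that are
#'   diploid.
#' @param labels character vector of mutation labels assigned to
#'   adaptive lineages (uniformly at random).
#' @return an object of class `tradeoff_config`.
#' @export
tradeoff_config <- function(mean_early_effect = 0.010, sd_early_effect = 0.005,
                            slope_late_on_early = -0.5, residual_sd_late = 0.0026,
                            fraction_adaptive = 0.1,
                            mutation_rate_per_cycle = 0,
                            dfe = list(dist = "exponential", mean = 0.5),
                            mean_growth_effect = 0, sd_growth_effect = 0,
                            glucose_coupling = 1, residual_sd_glucose = 0.003,
                            fraction_diploid = 0,
                            labels = c("SMF2", "chr11dup", "Ras/PKA", "other")) {
  check_field(is_num1(mean_early_effect), "mean_early_effect", "must be a finite number")
  check_field(is_num1(sd_early_effect) && sd_early_effect >= 0, "sd_early_effect", "must be >= 0")
  check_field(is_num1(slope_late_on_early), "slope_late_on_early", "must be a finite number")
  check_field(is_num1(residual_sd_late) && residual_sd_late >= 0, "residual_sd_late", "must be >= 0")
  check_field(is_prob(fraction_adaptive), "fraction_adaptive", "must be in [0, 1]")
  check_field(is_prob(mutation_rate_per_cycle), "mutation_rate_per_cycle", "must be in [0, 1]")
  check_field(is.list(dfe) && !is.null(dfe$dist), "dfe", "must be a named distribution list")
  check_field(is_num1(sd_growth_effect) && sd_growth_effect >= 0, "sd_growth_effect", "must be >= 0")
  check_field(is_num1(residual_sd_glucose) && residual_sd_glucose >= 0, "residual_sd_glucose", "must be >= 0")
  check_field(is_prob(fraction_diploid), "fraction_diploid", "must be in [0, 1]")
  structure(list(
    mean_early_effect = mean_early_effect, sd_early_effect = sd_early_effect,
    slope_late_on_early = slope_late_on_early, residual_sd_late = residual_sd_late,
    fraction_adaptive = fraction_adaptive,
    mutation_rate_per_cycle = mutation_rate_per_cycle, dfe = dfe,
    mean_growth_effect = mean_growth_effect, sd_growth_effect = sd_growth_effect,
    glucose_coupling = glucose_coupling, residual_sd_glucose = residual_sd_glucose,
    fraction_diploid = fraction_diploid, labels = labels
  ), class = "tradeoff_config")
}

draw_dfe <- function(dfe, n) {
  switch(dfe$dist,
         exponential = stats::rexp(n, rate = 1 / dfe$mean),
         fixed = rep(dfe$value, n),
         stopf("invalid configuration: field 'dfe' has unknown distribution '%s'", dfe$dist))
}

#' Sample ground-truth lineage phenotypes
#'
#' Draws a barcoded pool of `n_lineages` lineages. Exactly
#' `round(fraction_adaptive * n_lineages)` are adaptive; neutral
#' lineages have all-zero segment advantages. Deterministic given
#' `seed`.
#'
#' @param n_lineages number of lineages (>= 1).
#' @param cfg a [tradeoff_config()].
#' @param seed integer seed.
#' @return a data frame of class `phenotype_set` with one row per
#'   lineage: `lineage_id`, `is_adaptive`, `mutation_label`, `ploidy`,
#'   the five Gly/Eth segment columns (`growth_0_48` ... `sp_192_240`)
#'   and the three glucose segment columns, all in per-hour log units.
#' @examples
#' ph <- sample_phenotypes(100, tradeoff_config(), seed = 1)
#' table(ph$is_adaptive)
#' @export
sample_phenotypes <- function(n_lineages, cfg = tradeoff_config(), seed = 1) {
  if (!is_count(n_lineages) || n_lineages < 1) stopf("n_lineages must be an integer >= 1")
  stopifnot(inherits(cfg, "tradeoff_config"))
  set.seed(seed)
  n <- as.integer(n_lineages)
  n_adapt <- round(cfg$fraction_adaptive * n)
  adaptive <- rep(FALSE, n)
  if (n_adapt > 0) adaptive[sample.int(n, n_adapt)] <- TRUE

  ge <- matrix(0, n, 5, dimnames = list(NULL, names(segment_grid("GlyEth"))))
  gl <- matrix(0, n, 3, dimnames = list(NULL, names(segment_grid("glucose"))))
  if (n_adapt > 0) {
    early <- stats::rnorm(n_adapt, cfg$mean_early_effect, cfg$sd_early_effect)
    late <- cfg$slope_late_on_early * early + stats::rnorm(n_adapt, 0, cfg$residual_sd_late)
    growth <- stats::rnorm(n_adapt, cfg$mean_growth_effect, cfg$sd_growth_effect)
    gsp <- cfg$glucose_coupling * early + stats::rnorm(n_adapt, 0, cfg$residual_sd_glucose)
    ge[adaptive, "growth_0_48"] <- growth
    ge[adaptive, "sp_48_96"] <- early
    ge[adaptive, "sp_96_144"] <- early
    ge[adaptive, "sp_144_192"] <- late
    ge[adaptive, "sp_192_240"] <- late
    gl[adaptive, "gluc_growth_0_24"] <- growth
    gl[adaptive, "gluc_sp_24_72"] <- gsp
    gl[adaptive, "gluc_sp_72_120"] <- gsp
  }
  label <- rep("none", n)
  if (n_adapt > 0)
    label[adaptive] <- sample(cfg$labels, n_adapt, replace = TRUE)
  ploidy <- rep(1L, n)
  if (n_adapt > 0 && cfg$fraction_diploid > 0)
    ploidy[adaptive][stats::runif(n_adapt) < cfg$fraction_diploid] <- 2L
  out <- data.frame(
    lineage_id = sprintf("BC%05d", seq_len(n)),
    is_adaptive = adaptive, mutation_label = label, ploidy = ploidy,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(ge), as.data.frame(gl))
  class(out) <- c("phenotype_set", "data.frame")
  out
}

#' Per-cycle fitness implied by phenotypes in a regime
#'
#' Integrates each lineage's hourly segment advantages over the cycle:
#' the per-cycle fitness in a regime lasting L hours is the sum over
#' segments intersecting `[0, L)` of hourly advantage times hours
#' covered. Additive by construction, so
#' `fitness(L2) - fitness(L1)` equals the contribution of the segments
#' between L1 and L2 hours.
#'
#' @param phenotypes a `phenotype_set` from [sample_phenotypes()].
#' @param regime a [regime_spec()].
#' @return named numeric vector of per-cycle fitnesses (log units per
#'   cycle), one per lineage.
#' @export
cycle_fitness <- function(phenotypes, regime) {
  stopifnot(inherits(phenotypes, "phenotype_set"), inherits(regime, "regime_spec"))
  grid <- segment_grid(regime$medium)
  breaks <- attr(grid, "breaks")
  L <- regime$cycle_days * 24
  hours <- pmax(0, pmin(breaks[-1], L) - pmin(breaks[-length(breaks)], L))
  seg <- as.matrix(phenotypes[, names(grid), drop = FALSE])
  stats::setNames(as.numeric(seg %*% hours), phenotypes$lineage_id)
}
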