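test_that("variant verification applies read floor and ploidy thresholds", {
  expect_true(verify_variant(9, 10, 1))
  expect_false(verify_variant(5, 10, 1))
  expect_true(verify_variant(5, 10, 2))
  expect_false(verify_variant(2, 2, 1))   # 100% but below the 3-read floor
  expect_false(verify_variant(4, 10, 2))  # 40% is not "over 40%"
  expect_false(verify_variant(8, 10, 1))  # 80% is not "over 80%"
  expect_error(verify_variant(0, 0, 1), "total_reads")
  expect_error(verify_variant(5, 4, 1), "alt_reads")
})

toy_variants <- function() {
  data.frame(
    clone_id = c("c1", "c1", "c2", "c3", "c4", "c5", "c5"),
    gene = c("SMF2", "SMF2", "SMF2", "IRA1", "FZF1", "SMF2", "ACE2"),
    alt_reads = c(10, 9, 9, 10, 5, 10, 10),
    total_reads = c(10, 10, 10, 10, 10, 10, 10),
    stringsAsFactors = FALSE)
}

toy_metadata <- function() {
  data.frame(clone_id = paste0("c", 1:5),
             evolution_condition = c("GE_6day", "GE_6day", "GE_2day", "GE_8day", "GE_6day"),
             ploidy = c(1, 1, 1, 2, 1), stringsAsFactors = FALSE)
}

test_that("parallelism counts clones once per gene per condition", {
  tab <- parallelism_table(toy_variants(), toy_metadata())
  smf2 <- tab[tab$gene == "SMF2", ]
  # c1 has two SMF2 mutations but counts once; c2 and c5 also carry SMF2
  expect_equal(smf2$GE_6day, 3)
  expect_equal(smf2$GE_2day, 0)
  fzf1 <- tab[tab$gene == "FZF1", ]
  expect_equal(fzf1$GE_8day, 1) # diploid at 50% passes the 40% rule
  expect_equal(unname(attr(tab, "denominators")["GE_6day"]), 3)
  # row order of the variant table does not matter
  shuffled <- toy_variants()[sample(7), ]
  expect_equal(parallelism_table(shuffled, toy_metadata()), tab, ignore_attr = TRUE)
  expect_error(parallelism_table(toy_variants(),
                                 toy_metadata()[-1, ]), "missing from metadata")
})

test_that("pathway rollup maps genes through the shipped table", {
  pm <- pathway_map()
  expect_true(all(c("gene", "pathway") %in% names(pm)))
  expect_equal(pm$pathway[pm$gene == "IRA1"], "Ras/PKA")
  tab <- parallelism_table(toy_variants(), toy_metadata(), pm, by = "pathway")
  ras <- tab[tab$pathway == "Ras/PKA", ]
  expect_equal(ras$GE_2day, 1) # IRA1 clone rolled into Ras/PKA
  expect_equal(tab[tab$pathway == "Metal ion transport", "GE_6day"], 3)
})

test_that("target fractions reproduce the printed percentage arithmetic", {
  expect_equal(target_fraction(c(84, 69), 179, overlap = 1, decimals = 1), 84.9)
  expect_equal(target_fraction(84, 179, decimals = 1), 46.9)
  expect_equal(target_fraction(69, 179, decimals = 1), 38.5)
  expect_equal(target_fraction(c(7, 10, 10), 71, decimals = 0), 38)
  expect_equal(target_fraction(7, 49, decimals = 1), 14.3)
  expect_error(target_fraction(5, 0), "denominator")
  expect_error(target_fraction(c(5, 3), 10, overlap = 4), "overlap")
})

test_that("mutation multiplicities sum to total mutation counts", {
  expect_equal(mutation_multiplicity_total(c(rep(1, 71), rep(2, 5), 5)), 86)
  expect_equal(mutation_multiplicity_total(rep(1, 12)), 12)
  expect_error(mutation_multiplicity_total(c(1, 0)), "multiplicities")
  set.seed(13)
  for (i in 1:5) {
    m <- sample(1:5, 30, TRUE)
    expect_equal(mutation_multiplicity_total(m), sum(m)) # brute-force oracle
  }
})

make_perf <- function(x, y) {
  rbind(data.frame(clone = names(x), metric = "GE_earliest_d2_4", value = x,
                   error = 0.001, n_replicates = 3, delta = x, delta_error = 0.001),
        data.frame(clone = names(y), metric = "GE_late_d6_10", value = y,
                   error = 0.001, n_replicates = 3, delta = y, delta_error = 0.001))
}

test_that("tradeoff recovers exact and null correlations", {
  x <- setNames(seq(-0.01, 0.01, length.out = 20), paste0("c", 1:20))
  tr <- tradeoff(make_perf(x, -x), "GE_earliest_d2_4", "GE_late_d6_10")
  expect_equal(tr$pearson_r, -1, tolerance = 1e-12)
  expect_equal(tr$slope, -1, tolerance = 1e-12)
  expect_equal(tr$r_squared, 1, tolerance = 1e-12)
  for (seed in 1:5) {
    set.seed(seed)
    xs <- setNames(rnorm(1e4), paste0("c", 1:1e4))
    ys <- setNames(rnorm(1e4), paste0("c", 1:1e4))
    trn <- tradeoff(make_perf(xs, ys), "GE_earliest_d2_4", "GE_late_d6_10")
    expect_lt(abs(trn$pearson_r), 0.05)
  }
})

test_that("slope equals r on standardized inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(100); y <- 0.3 * x + rnorm(100)
    x <- (x - mean(x)) / sd(x); y <- (y - mean(y)) / sd(y)
    tr <- tradeoff(make_perf(setNames(x, paste0("c", 1:100)),
                             setNames(y, paste0("c", 1:100))),
                   "GE_earliest_d2_4", "GE_late_d6_10")
    expect_equal(tr$slope, tr$pearson_r, tolerance = 1e-12)
  }
})

test_that("metric pairs sharing an underlying fitness are rejected", {
  x <- setNames(rnorm(10), paste0("c", 1:10))
  perf <- rbind(data.frame(clone = names(x), metric = "GE_early_d2_6", value = x,
                           error = 0.001, n_replicates = 3, delta = x, delta_error = 0.001),
                data.frame(clone = names(x), metric = "GE_late_d6_10", value = -x,
                           error = 0.001, n_replicates = 3, delta = -x, delta_error = 0.001))
  # early (2-6) and late (6-10) share the 6-day fitness
  expect_error(tradeoff(perf, "GE_early_d2_6", "GE_late_d6_10"), "GE_6day")
  tr <- tradeoff(perf, "GE_early_d2_6", "GE_late_d6_10", allow_shared = TRUE)
  expect_equal(tr$pearson_r, -1, tolerance = 1e-12)
  # the steered pair is admissible
  expect_error(tradeoff(make_perf(x, -x)[0, ], "GE_earliest_d2_4", "GE_late_d6_10"),
               "at least 3")
})

test_that("subset filters act on clone metadata", {
  set.seed(14)
  x <- setNames(rnorm(40, 0, 0.01), paste0("c", 1:40))
  y <- -0.5 * x + rnorm(40, 0, 1e-4)
  names(y) <- names(x)
  md <- data.frame(clone_id = names(x),
                   evolution_condition = rep(c("GE_6day", "GE_10day"), 20),
                   ploidy = rep(c(1, 2), each = 20),
                   karyotype_normal = TRUE,
                   mutation_labels = rep(c("SMF2", "chr11dup"), each = 20),
                   ancestor_background = "anc1", stringsAsFactors = FALSE)
  perf <- make_perf(x, y)
  tr_hap <- tradeoff(perf, "GE_earliest_d2_4", "GE_late_d6_10", metadata = md,
                     haploid_only = TRUE)
  expect_equal(tr_hap$n_clones, 20)
  tr_no_smf2 <- tradeoff(perf, "GE_earliest_d2_4", "GE_late_d6_10", metadata = md,
                         exclude_label = "SMF2")
  expect_equal(tr_no_smf2$n_clones, 20)
  tr_cond <- tradeoff(perf, "GE_earliest_d2_4", "GE_late_d6_10", metadata = md,
                      condition = "GE_6day", include_label = "SMF2")
  expect_equal(tr_cond$n_clones, 10) # SMF2 clones alternate between conditions
  expect_match(tr_cond$subset, "GE_6day")
  # weighted mode agrees with unweighted under equal errors
  trw <- tradeoff(perf, "GE_earliest_d2_4", "GE_late_d6_10", weighted = TRUE)
  tru <- tradeoff(perf, "GE_earliest_d2_4", "GE_late_d6_10")
  expect_equal(trw$slope, tru$slope, tolerance = 1e-6)
  expect_equal(trw$pearson_r, tru$pearson_r, tolerance = 1e-6)
})

test_that("simulated trade-off structure is recovered from the pipeline", {
  x <- make_small_panel(n = 110, frac_adaptive = 100 / 110, seed = 5,
                        conditions = c("GE_2day", "GE_4day", "GE_6day",
                                       "GE_8day", "GE_10day"))
  adaptive <- x$ph$lineage_id[x$ph$is_adaptive]
  tr <- tradeoff(x$perf[x$perf$clone %in% adaptive, ],
                 "GE_earliest_d2_4", "GE_late_d6_10")
  expect_lt(tr$pearson_r, 0)
  expect_lt(tr$p_value, 0.01)
  expect_equal(tr$slope, -0.5, tolerance = 0.15)
})
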