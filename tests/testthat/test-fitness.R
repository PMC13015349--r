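det_sim <- function(s, days = 6, n_cycles = 5, reads = 1e6, ...) {
  simulate_assay(s, regime_spec(days, "GlyEth"), n_cycles,
                 noise_config(reads, deterministic = TRUE), ...)
}

test_that("constant frequencies give the neutral fixed point", {
  s <- setNames(rep(0, 4), paste0("L", 1:4))
  fit <- lineage_fitness(det_sim(s)$counts)
  expect_equal(unname(coef(fit)), rep(0, 4), tolerance = 1e-10)
  expect_equal(fit$mean_fitness$sbar, rep(0, 5), tolerance = 1e-10)
})

test_that("deterministic counts recover relative fitness to 1e-6", {
  s <- c(A = 0, B = 0.5)
  fit <- lineage_fitness(det_sim(s)$counts)
  expect_equal(unname(diff(coef(fit))), 0.5, tolerance = 1e-6)
  # with the gauge pinned to the neutral lineage, values are absolute
  fitr <- lineage_fitness(det_sim(s)$counts, reference = "A")
  expect_equal(unname(coef(fitr)), c(0, 0.5), tolerance = 1e-6)
  # 5 lineages x 5 cycles: all pairwise differences
  set.seed(2)
  s5 <- setNames(c(0, rnorm(4, 0, 0.3)), paste0("L", 1:5))
  fit5 <- lineage_fitness(det_sim(s5)$counts)
  est <- coef(fit5)[names(s5)]
  expect_equal(outer(est, est, "-"), outer(s5, s5, "-"), tolerance = 1e-6)
})

test_that("the model identifies only relative fitness (gauge property)", {
  set.seed(3)
  s <- setNames(rnorm(5, 0, 0.2), paste0("L", 1:5))
  d1 <- coef(lineage_fitness(det_sim(s)$counts))
  d2 <- coef(lineage_fitness(det_sim(s + 0.7)$counts))
  expect_equal(outer(d1, d1, "-"), outer(d2, d2, "-"), tolerance = 1e-8)
})

test_that("weighted mean fitness is self-consistent under weak selection", {
  s <- c(P = 0, Q = 0.001, R = -0.0005)
  fit <- lineage_fitness(det_sim(s, n_cycles = 4)$counts)
  expect_lt(abs(sum(fit$freq[, 1] * coef(fit)) - fit$mean_fitness$sbar[1]), 1e-6)
})

test_that("standard errors shrink as one over sqrt reads", {
  ph <- sample_phenotypes(100, tradeoff_config(), seed = 4)
  reg <- regime_spec(6, "GlyEth", bottleneck_cells = 1e7)
  med_err <- sapply(c(1e4, 1e5, 1e6), function(R) {
    sim <- simulate_assay(ph, reg, 5, noise_config(R, seed = 5))
    median(lineage_fitness(sim$counts)$estimates$error)
  })
  slope <- coef(lm(log(med_err) ~ log(c(1e4, 1e5, 1e6))))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
})

test_that("the error inflator calibrates neutral-lineage z-scores", {
  ph <- sample_phenotypes(300, tradeoff_config(fraction_adaptive = 0.1), seed = 6)
  reg <- regime_spec(6, "GlyEth", bottleneck_cells = 1e7)
  sim <- simulate_assay(ph, reg, 5, noise_config(1e6, overdispersion_kappa = 2, seed = 7))
  neut <- ph$lineage_id[!ph$is_adaptive]
  fit <- lineage_fitness(sim$counts, neutral_ids = neut, reference = neut)
  expect_gt(fit$inflator, 1)
  e <- fit$estimates[match(neut, fit$estimates$lineage), ]
  z <- e$s / e$error
  expect_lt(abs(sd(z) - 1), 0.25)
  # a fixed kappa is honored verbatim
  fitk <- lineage_fitness(sim$counts, kappa = 4)
  expect_equal(fitk$inflator, 4)
})

test_that("sparse lineages are excluded and zeros get pseudocounts", {
  m <- rbind(BC1 = c(1000, 900, 800, 700),
             BC2 = c(100, 0, 120, 90),     # one zero endpoint: pseudocount
             BC3 = c(5, 0, 0, 0))          # observed once: excluded
  cm <- count_matrix(m, 0:3, "GE_4day", 1)
  expect_warning(fit <- lineage_fitness(cm), "fewer than 2")
  expect_setequal(fit$estimates$lineage, c("BC1", "BC2"))
  expect_true(all(is.finite(fit$estimates$s)))
  expect_true(all(fit$estimates$error >= 0))
})

test_that("timepoint masks drop under-sequenced columns", {
  s <- c(A = 0, B = 0.4)
  sim <- det_sim(s, n_cycles = 4)
  full <- lineage_fitness(sim$counts)
  masked <- lineage_fitness(sim$counts, timepoint_mask = c(1, 2, 3, 5))
  expect_equal(nrow(masked$mean_fitness), 3)
  expect_equal(unname(diff(coef(masked))), 0.4, tolerance = 1e-6)
  expect_equal(unname(diff(coef(full))), unname(diff(coef(masked))), tolerance = 1e-8)
})

test_that("model methods are consistent with the fitted trajectories", {
  set.seed(10)
  s <- setNames(rnorm(6, 0, 0.25), paste0("L", 1:6))
  sim <- det_sim(s, n_cycles = 4)
  fit <- lineage_fitness(sim$counts)
  # deterministic data: predictions reproduce the observed frequencies
  expect_equal(predict(fit), fit$freq, tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(abs(residuals(fit)), na.rm = TRUE), 1e-6)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "count_matrix")
  expect_equal(dim(sims[[1]]), dim(sim$counts))
  expect_output(print(fit), "lineage_fit")
  expect_output(print(summary(fit)), "fittest")
})

test_that("ancestor aggregation pools rows and conserves totals", {
  m <- rbind(A1 = c(10, 12), A2 = c(20, 18), A3 = c(30, 33),
             BC1 = c(100, 90), BC2 = c(50, 60))
  cm <- count_matrix(m, 0:1, "GE_2day", 1)
  agg <- aggregate_ancestors(cm, c("A1", "A2", "A3"))
  expect_equal(unname(unclass(agg)["ANCESTOR", ]), c(60, 63))
  expect_equal(unclass(agg)[c("BC1", "BC2"), ], unclass(cm)[c("BC1", "BC2"), ])
  expect_equal(colSums(agg), colSums(cm))
  expect_error(aggregate_ancestors(cm, character(0)), "empty")
  expect_error(aggregate_ancestors(cm, c("A1", "NOPE")), "NOPE")
})

test_that("the error filter is strict and matches a brute-force filter", {
  est <- data.frame(lineage = paste0("L", 1:4), error = c(0.1, 4.9, 5.0, 7))
  expect_message(kept <- filter_by_error(est, 5), "2 estimate")
  expect_equal(kept$lineage, c("L1", "L2"))
  expect_equal(filter_by_error(est, Inf), est)
  set.seed(11)
  for (i in 1:5) {
    e <- data.frame(lineage = 1:50, error = runif(50, 0, 10))
    expect_equal(filter_by_error(e, 5)$lineage, e$lineage[e$error < 5])
  }
})

test_that("the adaptive filter keeps ties and needs the ancestor", {
  est <- data.frame(
    lineage = rep(c("ANCESTOR", "C1", "C2", "C3"), each = 2),
    condition = "GE_6day", replicate = rep(1:2, 4),
    s = c(0.1, 0.1, 0.3, 0.3, 0.04, 0.06, 0.1, 0.1))
  evo <- c(C1 = "GE_6day", C2 = "GE_6day", C3 = "GE_6day")
  expect_message(kept <- filter_adaptive(est, evo), "1 clone")
  expect_setequal(unique(kept$lineage), c("ANCESTOR", "C1", "C3")) # tie C3 kept
  expect_error(filter_adaptive(est, c(C1 = "GE_8day")), "GE_8day")
})
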