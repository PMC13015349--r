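# grid with exactly the marginals of the printed-formula example:
# empty cell (F1, R1) holds 100 reads, FOS F1 carries 1e5, ROS R1
# carries 1e6, lane total 1e7
formula_grid <- function() {
  counts <- data.frame(
    fos = c("F1", "F1", "F2", "F2"),
    ros = c("R1", "R2", "R1", "R2"),
    barcode = "BC1",
    count = c(100, 1e5 - 100, 1e6 - 100, 1e7 - 1e5 - 1e6 + 100))
  used <- data.frame(fos = c("F1", "F2", "F2"), ros = c("R2", "R1", "R2"))
  index_grid(counts, used)
}

test_that("hop-rate estimator evaluates the printed formula exactly", {
  g <- formula_grid()
  est <- estimate_hop_rate(g)
  expect_equal(est$rate, 100 / (1e6 * (1e5 / 1e7)), tolerance = 1e-12)
  expect_equal(est$rate, 0.01, tolerance = 1e-12)
  expect_equal(nrow(est$per_combo), 1)
})

test_that("a clean lane estimates rate zero and rate needs empty combos", {
  g <- simulate_index_grid(n_fos = 4, n_ros = 3, n_empty = 2,
                           reads_per_sample = 1e4, seed = 1)
  expect_equal(estimate_hop_rate(g)$rate, 0)
  full <- index_grid(g$counts, expand.grid(fos = g$fos_levels, ros = g$ros_levels,
                                           stringsAsFactors = FALSE))
  expect_error(estimate_hop_rate(full), "not estimable")
})

test_that("hopping conserves lane totals and rate zero is the identity", {
  g <- simulate_index_grid(n_fos = 5, n_ros = 4, n_empty = 3,
                           reads_per_sample = 5e4, seed = 2)
  expect_identical(apply_index_hopping(g, 0, seed = 1), g)
  for (rate in c(0.002, 0.01, 0.05)) {
    obs <- apply_index_hopping(g, rate, seed = 3)
    expect_equal(sum(obs$counts$count), sum(g$counts$count))
  }
  expect_error(apply_index_hopping(g, 1), "hop_rate")
})

test_that("empty-cell counts match the inverted-estimator expectation", {
  # 2x2 grid, one empty cell, 1e6 reads
  counts <- data.frame(fos = c("F1", "F1", "F2"), ros = c("R1", "R2", "R1"),
                       barcode = "BC1", count = c(4e5, 3e5, 3e5))
  g <- index_grid(counts, data.frame(fos = c("F1", "F1", "F2"),
                                     ros = c("R1", "R2", "R1")))
  obs <- apply_index_hopping(g, 0.01, seed = 7)
  marg <- spfit:::grid_marginals(obs)
  expected <- 0.01 * as.numeric(marg$ros["R2"]) * as.numeric(marg$fos["F2"]) / marg$total
  cell <- obs$counts$count[obs$counts$fos == "F2" & obs$counts$ros == "R2"]
  expect_lt(abs(sum(cell) - expected), 3 * sqrt(expected))
})

test_that("lane rate is recovered from simulated hopping", {
  for (seed in 1:3) {
    g <- simulate_index_grid(n_fos = 6, n_ros = 4, n_empty = 4,
                             reads_per_sample = 1e5, seed = seed)
    obs <- apply_index_hopping(g, 0.005, seed = seed + 50)
    est <- estimate_hop_rate(obs)
    expect_lt(abs(est$rate - 0.005) / 0.005, 0.2)
    # read-weighted variant stays close to the unweighted mean
    estw <- estimate_hop_rate(obs, weighted = TRUE)
    expect_lt(abs(estw$rate - 0.005) / 0.005, 0.2)
  }
})

test_that("corrected counts follow the printed formula and clip at zero", {
  # direct evaluation: 1000 - (50000*0.01*1e5/1e7 + 40000*0.01*2e5/1e7)/2
  #                  = 1000 - (5 + 8)/2
  expect_equal(corrected_count(1000, 50000, 40000, 1e5, 2e5, 1e7, 0.01), 993.5)
  expect_equal(corrected_count(1000, 50000, 40000, 1e5, 2e5, 1e7, 0), 1000)
  expect_equal(corrected_count(10, 5e6, 5e6, 1e6, 1e6, 1e7, 0.01), 0)
  expect_error(corrected_count(10, 1, 1, 1, 1, 10, -0.1), "rate")
})

test_that("grid correction is the identity at rate 0 and monotone otherwise", {
  g <- simulate_index_grid(n_fos = 4, n_ros = 4, n_empty = 3,
                           reads_per_sample = 2e4, seed = 4)
  obs <- apply_index_hopping(g, 0.01, seed = 5)
  same <- correct_counts(obs, 0)
  expect_equal(same$counts, obs$counts)
  corr <- correct_counts(obs, 0.01)
  key <- function(d) paste(d$fos, d$ros, d$barcode, sep = "\r")
  m <- match(key(corr$counts), key(obs$counts))
  expect_true(all(corr$counts$count <= obs$counts$count[m] + 1e-9))
  expect_true(all(corr$counts$count >= 0))
  expect_lt(attr(corr, "total_after"), attr(corr, "total_before"))
})

test_that("correction reduces error against truth in empty and low cells", {
  g <- simulate_index_grid(n_fos = 6, n_ros = 4, n_empty = 4,
                           reads_per_sample = 2e5, seed = 6)
  obs <- apply_index_hopping(g, 0.01, seed = 7)
  corr <- correct_counts(obs, estimate_hop_rate(obs)$rate)
  key <- function(d) paste(d$fos, d$ros, d$barcode, sep = "\r")
  truth <- setNames(g$counts$count, key(g$counts))
  lookup <- function(d, k) { v <- setNames(d$count, key(d))[k]; ifelse(is.na(v), 0, v) }
  # cells in empty combos plus used cells in the lowest true-count decile
  ec <- empty_combos(g)
  ek <- unlist(lapply(seq_len(nrow(ec)), function(i)
    paste(ec$fos[i], ec$ros[i], unique(g$counts$barcode), sep = "\r")))
  low <- names(truth)[truth <= quantile(g$counts$count, 0.1)]
  cells <- c(ek, low)
  tr <- c(setNames(rep(0, length(ek)), ek), truth[low])
  mae_raw <- mean(abs(lookup(obs$counts, cells) - tr))
  mae_corr <- mean(abs(lookup(corr$counts, cells) - tr))
  expect_lt(mae_corr, mae_raw)
})

test_that("technical-replicate correlation improves after correction", {
  # two used combos carry the same sample (same expected composition);
  # the rest of the lane holds unrelated samples that bleed in by hopping
  set.seed(9)
  bcs <- sprintf("BC%03d", 1:40)
  rp <- function() { p <- rgamma(40, 0.5); p / sum(p) }
  p_shared <- rp()
  mk <- function(fos, ros, p, n) data.frame(fos = fos, ros = ros, barcode = bcs,
                                            count = drop(rmultinom(1, n, p)))
  # each replicate's index-sharing neighbors carry distinct compositions,
  # so hopped-in bleed decorrelates the raw replicate counts
  counts <- rbind(mk("F1", "R1", p_shared, 2e5), mk("F2", "R2", p_shared, 2e5),
                  mk("F1", "R3", rp(), 2e6), mk("F3", "R1", rp(), 2e6),
                  mk("F2", "R3", rp(), 2e6), mk("F3", "R2", rp(), 2e6))
  used <- unique(counts[, c("fos", "ros")])
  g <- index_grid(counts, used)
  obs <- apply_index_hopping(g, 0.02, seed = 10)
  corr <- correct_counts(obs, estimate_hop_rate(obs)$rate)
  vec <- function(grid, fos, ros) {
    d <- grid$counts[grid$counts$fos == fos & grid$counts$ros == ros, ]
    v <- setNames(d$count, d$barcode)[bcs]; ifelse(is.na(v), 0, v)
  }
  r_before <- cor(vec(obs, "F1", "R1"), vec(obs, "F2", "R2"))
  r_after <- cor(vec(corr, "F1", "R1"), vec(corr, "F2", "R2"))
  expect_gt(r_after, r_before)
})

test_that("index grids round-trip through TSV including empty structure", {
  g <- simulate_index_grid(n_fos = 3, n_ros = 3, n_empty = 2,
                           reads_per_sample = 1e3, n_barcodes = 8, seed = 11)
  obs <- apply_index_hopping(g, 0.05, seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_index_grid(obs, path)
  back <- read_index_grid(path)
  o1 <- obs$counts[order(obs$counts$fos, obs$counts$ros, obs$counts$barcode), ]
  o2 <- back$counts[order(back$counts$fos, back$counts$ros, back$counts$barcode), ]
  expect_equal(o1$count, o2$count)
  expect_equal(nrow(empty_combos(back)), nrow(empty_combos(obs)))
  expect_equal(sort(paste(back$used$fos, back$used$ros)),
               sort(paste(obs$used$fos, obs$used$ros)))
})
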