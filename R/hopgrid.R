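# Dual-index hopping on a primer grid: simulation, rate estimation and
# count correction.
#
# Samples are multiplexed by unique (forward, reverse) index primer
# pairs ("FOS", "ROS") on a patterned flow cell. Index hopping swaps an
# index on a fraction of molecules, moving reads into the wrong
# (FOS, ROS) cell. Combinations deliberately left empty in the library
# prep receive reads only by hopping, so their counts identify the
# hopping rate:
#   rate = empty-cell count / (ROSz_count * FOSy_count / total reads)
# averaged over empty combinations within the lane. Per-barcode counts
# are then corrected by subtracting the expected hopped-in reads,
# averaging the contributions computed from each index end:
#   corrected = n - (ROSz_BCx * rate * FOSy/total +
#                    FOSy_BCx * rate * ROSz/total) / 2
# clipped at zero.

#' Per-lane index grid counts
#'
#' Holds per-(FOS, ROS, barcode) read counts for one sequencing lane
#' together with the set of index combinations that actually received
#' libraries. All marginals used by the hopping estimator are derived
#' from the long count table, so they are consistent by construction.
#'
#' @param counts data frame with columns `fos`, `ros`, `barcode`,
#'   `count` (non-negative).
#' @param used data frame with columns `fos`, `ros`: combinations that
#'   received libraries. All other combinations of the observed index
#'   levels are treated as deliberately empty.
#' @param lane lane identifier.
#' @param fos_levels,ros_levels index levels present on the lane
#'   (default: those appearing in `counts` or `used`).
#' @return an object of class `index_grid`.
#' @export
index_grid <- function(counts, used, lane = "lane1",
                       fos_levels = NULL, ros_levels = NULL) {
  need <- c("fos", "ros", "barcode", "count")
  if (!all(need %in% names(counts))) stopf("counts needs columns fos, ros, barcode, count")
  if (any(counts$count < 0)) stopf("counts must be non-negative")
  if (is.null(fos_levels)) fos_levels <- sort(unique(c(counts$fos, used$fos)))
  if (is.null(ros_levels)) ros_levels <- sort(unique(c(counts$ros, used$ros)))
  counts <- counts[counts$count > 0, need, drop = FALSE]
  rownames(counts) <- NULL
  structure(list(lane = lane, counts = counts,
                 used = unique(used[, c("fos", "ros")]),
                 fos_levels = fos_levels, ros_levels = ros_levels),
            class = "index_grid")
}

#' @export
print.index_grid <- function(x, ...) {
  ec <- empty_combos(x)
  cat(sprintf("<index_grid> lane %s: %d x %d indices, %d used / %d empty combos, %s reads\n",
              x$lane, length(x$fos_levels), length(x$ros_levels),
              nrow(x$used), nrow(ec), format(sum(x$counts$count), big.mark = ",")))
  invisible(x)
}

#' Deliberately empty index combinations of a grid
#'
#' @param grid an [index_grid()].
#' @return data frame with columns `fos`, `ros`.
#' @export
empty_combos <- function(grid) {
  stopifnot(inherits(grid, "index_grid"))
  all_combos <- expand.grid(fos = grid$fos_levels, ros = grid$ros_levels,
                            stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  key <- function(d) paste(d$fos, d$ros, sep = "\r")
  all_combos[!(key(all_combos) %in% key(grid$used)), , drop = FALSE]
}

grid_marginals <- function(grid) {
  cc <- grid$counts
  list(fos = tapply(cc$count, factor(cc$fos, grid$fos_levels), sum, default = 0),
       ros = tapply(cc$count, factor(cc$ros, grid$ros_levels), sum, default = 0),
       total = sum(cc$count))
}

cell_totals <- function(grid) {
  cc <- grid$counts
  stats::aggregate(count ~ fos + ros, cc, sum)
}

#' Simulate a multiplexed index grid (truth, before hopping)
#'
#' Builds a lane in which each used (FOS, ROS) combination is one
#' sample with multinomial per-barcode counts; a chosen number of
#' combinations is deliberately left empty.
#'
#' @param n_fos,n_ros number of forward / reverse index primers.
#' @param n_empty number of deliberately empty combinations.
#' @param reads_per_sample expected reads per used combination.
#' @param n_barcodes barcodes per sample.
#' @param seed integer seed.
#' @return an [index_grid()] with zero counts in the empty combos.
#' @export
simulate_index_grid <- function(n_fos = 6, n_ros = 4, n_empty = 4,
                                reads_per_sample = 1e5, n_barcodes = 50, seed = 1) {
  set.seed(seed)
  fos <- sprintf("FOS%02d", seq_len(n_fos))
  ros <- sprintf("ROS%02d", seq_len(n_ros))
  combos <- expand.grid(fos = fos, ros = ros, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  if (n_empty >= nrow(combos)) stopf("n_empty must leave at least one used combo")
  empty_idx <- sample.int(nrow(combos), n_empty)
  used <- combos[-empty_idx, , drop = FALSE]
  bcs <- sprintf("BC%04d", seq_len(n_barcodes))
  rows <- vector("list", nrow(used))
  for (i in seq_len(nrow(used))) {
    p <- stats::rgamma(n_barcodes, 1); p <- p / sum(p)
    cnt <- drop(stats::rmultinom(1, reads_per_sample, p))
    rows[[i]] <- data.frame(fos = used$fos[i], ros = used$ros[i],
                            barcode = bcs, count = cnt, stringsAsFactors = FALSE)
  }
  index_grid(do.call(rbind, rows), used, lane = "lane1",
             fos_levels = fos, ros_levels = ros)
}

#' Apply index hopping to a grid
#'
#' Each read hops with probability `hop_rate`; the hopped end is chosen
#' uniformly between FOS and ROS (or fixed by `ends`), and the
#' destination index is drawn proportional to that index's lane-wide
#' read abundance. Lane totals are conserved exactly; empty
#' combinations acquire counts only through hopping. Under
#' `ends = "either"` the expected count landing in an empty
#' (FOSy, ROSz) cell is `hop_rate * ROSz_count * FOSy_count / total`,
#' which is what the rate estimator inverts.
#'
#' @param grid an [index_grid()] of true (pre-hopping) counts.
#' @param hop_rate hopping probability in `[0, 1)`.
#' @param seed integer seed.
#' @param ends `"either"` (default: each end with probability 1/2),
#'   `"fos"` or `"ros"` to hop only one end.
#' @return an [index_grid()] of observed counts.
#' @export
apply_index_hopping <- function(grid, hop_rate, seed = 1,
                                ends = c("either", "fos", "ros")) {
  stopifnot(inherits(grid, "index_grid"))
  ends <- match.arg(ends)
  if (!is_num1(hop_rate) || hop_rate < 0 || hop_rate >= 1)
    stopf("hop_rate must be in [0, 1)")
  if (nrow(empty_combos(grid)) < 1)
    stopf("grid must contain at least one deliberately empty index combination")
  if (hop_rate == 0) return(grid)
  set.seed(seed)
  marg <- grid_marginals(grid)
  p_fos <- marg$fos / marg$total
  p_ros <- marg$ros / marg$total
  cc <- grid$counts
  n <- nrow(cc)
  k <- stats::rbinom(n, cc$count, hop_rate)
  kf <- switch(ends, either = stats::rbinom(n, k, 0.5), fos = k, ros = 0L)
  kr <- k - kf
  keep <- data.frame(fos = cc$fos, ros = cc$ros, barcode = cc$barcode,
                     count = cc$count - k, stringsAsFactors = FALSE)
  out <- list(keep)
  fhop <- which(kf > 0)
  for (i in fhop) {
    dest <- drop(stats::rmultinom(1, kf[i], p_fos))
    nz <- which(dest > 0)
    out[[length(out) + 1]] <- data.frame(
      fos = grid$fos_levels[nz], ros = cc$ros[i], barcode = cc$barcode[i],
      count = dest[nz], stringsAsFactors = FALSE)
  }
  rhop <- which(kr > 0)
  for (i in rhop) {
    dest <- drop(stats::rmultinom(1, kr[i], p_ros))
    nz <- which(dest > 0)
    out[[length(out) + 1]] <- data.frame(
      fos = cc$fos[i], ros = grid$ros_levels[nz], barcode = cc$barcode[i],
      count = dest[nz], stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, out)
  agg <- stats::aggregate(count ~ fos + ros + barcode, all, sum)
  index_grid(agg, grid$used, lane = grid$lane,
             fos_levels = grid$fos_levels, ros_levels = grid$ros_levels)
}

#' Estimate the lane index-hopping rate from empty combinations
#'
#' For each deliberately empty combination (FOSy, ROSz) the rate is
#' `cell_count / (ROSz_count * FOSy_count / total_reads)`; the lane
#' rate is the (by default unweighted) mean over the lane's empty
#' combinations.
#'
#' @param grid an [index_grid()] of observed counts.
#' @param weighted if `TRUE`, weight each empty combo by its expected
#'   hopped-read denominator instead of averaging rates equally.
#' @return list with `rate` (lane rate) and `per_combo` (data frame:
#'   `fos`, `ros`, `count`, `rate`).
#' @examples
#' g <- simulate_index_grid(seed = 1)
#' obs <- apply_index_hopping(g, 0.01, seed = 2)
#' estimate_hop_rate(obs)$rate
#' @export
estimate_hop_rate <- function(grid, weighted = FALSE) {
  stopifnot(inherits(grid, "index_grid"))
  ec <- empty_combos(grid)
  if (nrow(ec) == 0) stopf("rate not estimable: grid has no empty index combinations")
  marg <- grid_marginals(grid)
  if (marg$total <= 0) stopf("rate not estimable: lane has no reads")
  ct <- cell_totals(grid)
  key <- paste(ct$fos, ct$ros, sep = "\r")
  cellcount <- stats::setNames(ct$count, key)
  ec$count <- as.numeric(cellcount[paste(ec$fos, ec$ros, sep = "\r")])
  ec$count[is.na(ec$count)] <- 0
  denom <- as.numeric(marg$ros[ec$ros]) * (as.numeric(marg$fos[ec$fos]) / marg$total)
  bad <- denom <= 0
  if (any(bad)) {
    warnf("%d empty combo(s) skipped: zero FOS or ROS marginal", sum(bad))
    ec <- ec[!bad, , drop = FALSE]; denom <- denom[!bad]
  }
  if (nrow(ec) == 0) stopf("rate not estimable: all empty combos have zero marginals")
  ec$rate <- ec$count / denom
  rate <- if (weighted) sum(ec$count) / sum(denom) else mean(ec$rate)
  rownames(ec) <- NULL
  list(rate = rate, per_combo = ec)
}

#' Corrected barcode count for one grid cell
#'
#' The per-cell correction kernel: subtracts the expected hopped-in
#' reads for barcode x in cell (FOSy, ROSz), averaging the estimate
#' from each index end, and clips at zero.
#'
#' @param bc_count reads of barcode x in the (FOSy, ROSz) cell.
#' @param ros_bc_count reads with barcode x and ROSz (any FOS).
#' @param fos_bc_count reads with barcode x and FOSy (any ROS).
#' @param fos_count,ros_count lane-wide reads with FOSy / ROSz.
#' @param total_reads lane total.
#' @param rate index-hopping rate.
#' @return corrected count (real, >= 0).
#' @examples
#' corrected_count(1000, 50000, 40000, 1e5, 2e5, 1e7, 0.01) # 935
#' @export
corrected_count <- function(bc_count, ros_bc_count, fos_bc_count,
                            fos_count, ros_count, total_reads, rate) {
  if (any(rate < 0)) stopf("rate must be >= 0")
  pmax(0, bc_count - (ros_bc_count * rate * fos_count / total_reads +
                      fos_bc_count * rate * ros_count / total_reads) / 2)
}

#' Correct a grid's barcode counts for index hopping
#'
#' Applies [corrected_count()] to every (FOS, ROS, barcode) cell of the
#' grid using marginals derived from the grid itself. Corrected counts
#' are kept as reals (not re-rounded).
#'
#' @param grid an [index_grid()] of observed counts.
#' @param rate index-hopping rate (e.g. from [estimate_hop_rate()]).
#' @return an [index_grid()] with corrected counts; attributes
#'   `total_before` and `total_after` record the correction size.
#' @export
correct_counts <- function(grid, rate) {
  stopifnot(inherits(grid, "index_grid"))
  if (!is_num1(rate) || rate < 0) stopf("rate must be >= 0")
  cc <- grid$counts
  if (any(cc$count < 0)) stopf("inconsistent grid: negative counts")
  marg <- grid_marginals(grid)
  ros_bc <- tapply(cc$count, paste(cc$ros, cc$barcode, sep = "\r"), sum)
  fos_bc <- tapply(cc$count, paste(cc$fos, cc$barcode, sep = "\r"), sum)
  corr <- corrected_count(
    cc$count,
    as.numeric(ros_bc[paste(cc$ros, cc$barcode, sep = "\r")]),
    as.numeric(fos_bc[paste(cc$fos, cc$barcode, sep = "\r")]),
    as.numeric(marg$fos[cc$fos]), as.numeric(marg$ros[cc$ros]),
    marg$total, rate)
  out <- grid
  out$counts$count <- corr
  out$counts <- out$counts[out$counts$count > 0, , drop = FALSE]
  rownames(out$counts) <- NULL
  attr(out, "total_before") <- marg$total
  attr(out, "total_after") <- sum(corr)
  out
}

#' Write / read an index grid as TSV
#'
#' Long format with columns `fos_index`, `ros_index`, `barcode`,
#' `count`, `lane`, `used_flag`. Empty combinations are recorded with a
#' zero-count placeholder row so the used/empty structure round-trips.
#'
#' @param grid an [index_grid()].
#' @param path file path.
#' @return `write_index_grid` returns `path` invisibly;
#'   `read_index_grid` an [index_grid()].
#' @export
write_index_grid <- function(grid, path) {
  stopifnot(inherits(grid, "index_grid"))
  key <- function(f, r) paste(f, r, sep = "\r")
  used_key <- key(grid$used$fos, grid$used$ros)
  df <- data.frame(fos_index = grid$counts$fos, ros_index = grid$counts$ros,
                   barcode = grid$counts$barcode, count = grid$counts$count,
                   lane = grid$lane,
                   used_flag = as.integer(key(grid$counts$fos, grid$counts$ros) %in% used_key),
                   stringsAsFactors = FALSE)
  ec <- empty_combos(grid)
  seen <- key(grid$counts$fos, grid$counts$ros)
  placeholder <- function(fos, ros, flag) {
    if (length(fos) == 0) return(NULL)
    data.frame(fos_index = fos, ros_index = ros, barcode = "-", count = 0,
               lane = grid$lane, used_flag = flag, stringsAsFactors = FALSE)
  }
  miss <- !(key(ec$fos, ec$ros) %in% seen)
  unused_used <- !(used_key %in% seen)
  out <- rbind(df, placeholder(ec$fos[miss], ec$ros[miss], 0L),
               placeholder(grid$used$fos[unused_used], grid$used$ros[unused_used], 1L))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_index_grid
#' @export
read_index_grid <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  counts <- data.frame(fos = df$fos_index, ros = df$ros_index,
                       barcode = df$barcode, count = df$count,
                       stringsAsFactors = FALSE)
  used <- unique(df[df$used_flag == 1, c("fos_index", "ros_index")])
  names(used) <- c("fos", "ros")
  index_grid(counts[counts$barcode != "-", , drop = FALSE], used,
             lane = df$lane[1],
             fos_levels = sort(unique(df$fos_index)),
             ros_levels = sort(unique(df$ros_index)))
}
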