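# Phase-specific performance: decomposing per-cycle fitness across
# transfer regimes into per-hour performance within growth-cycle
# intervals.
#
# Two regimes that differ only in cycle length isolate the added
# interval: performance = (fitnessA - fitnessB) / d, with d the hours
# separating the cycle lengths, in units of hour^-1. Errors propagate
# as sqrt(errA^2 + errB^2) / d; replicate means carry error
# (1/n) sqrt(sum of squared replicate errors); a clone's change in
# performance is its performance minus its ancestor's in the same
# metric.

#' Registry of phase-performance metrics
#'
#' The named metrics, each defined as a difference of two per-cycle
#' fitnesses divided by the hours separating the regimes:
#' stationary phase after glucose limitation (day 3-5), and the
#' earliest (day 2-4), mid (day 4-6), early (day 2-6), late (day 6-10)
#' and latest (day 8-10) stationary-phase intervals after Gly/Eth
#' limitation.
#'
#' @return data frame with columns `metric`, `condA`, `condB`,
#'   `d_hours`.
#' @export
performance_metrics <- function() {
  data.frame(
    metric = c("gluc_SP_d3_5", "GE_earliest_d2_4", "GE_mid_d4_6",
               "GE_early_d2_6", "GE_late_d6_10", "GE_latest_d8_10"),
    condA = c("gluc_5day", "GE_4day", "GE_6day", "GE_6day", "GE_10day", "GE_10day"),
    condB = c("gluc_3day", "GE_2day", "GE_4day", "GE_2day", "GE_6day", "GE_8day"),
    d_hours = c(48, 48, 48, 96, 96, 48),
    stringsAsFactors = FALSE)
}

metric_row <- function(metric) {
  reg <- performance_metrics()
  i <- match(metric, reg$metric)
  if (is.na(i)) stopf("unknown performance metric '%s'", metric)
  reg[i, ]
}

#' Per-hour performance from two per-cycle fitnesses
#'
#' @param fitA,fitB per-cycle fitnesses of the longer (A) and shorter
#'   (B) regime.
#' @param d hours separating the two cycle lengths (> 0).
#' @return performance in hour^-1: `(fitA - fitB) / d`.
#' @examples
#' performance(1.00, 0.04, 48) # 0.02 per hour
#' @export
performance <- function(fitA, fitB, d) {
  if (any(d <= 0)) stopf("d must be > 0 hours")
  (fitA - fitB) / d
}

#' Propagated per-hour performance error
#'
#' @param errA,errB per-cycle standard errors of the two fitnesses
#'   (>= 0).
#' @param d hours separating the two cycle lengths.
#' @return `sqrt(errA^2 + errB^2) / d`.
#' @examples
#' propagate_performance_error(3, 4, 48) # 5/48
#' @export
propagate_performance_error <- function(errA, errB, d) {
  if (any(errA < 0) || any(errB < 0)) stopf("errors must be >= 0")
  if (any(d <= 0)) stopf("d must be > 0 hours")
  sqrt(errA^2 + errB^2) / d
}

#' Replicate mean with propagated error
#'
#' Arithmetic mean across replicates; the error on the mean is
#' `(1/n) * sqrt(sum of squared replicate errors)` (so equal errors e
#' give `e / sqrt(n)`).
#'
#' @param values,errors numeric vectors of equal length (n >= 1).
#' @return list with `mean` and `error`.
#' @examples
#' replicate_mean(c(1, 2, 3), c(3, 4, 12)) # mean 2, error 13/3
#' @export
replicate_mean <- function(values, errors) {
  n <- length(values)
  if (n < 1 || length(errors) != n) stopf("need n >= 1 values with matching errors")
  list(mean = mean(values), error = sqrt(sum(errors^2)) / n)
}

#' Change in performance relative to the ancestor
#'
#' @param clone,ancestor lists/rows with `metric`, `value`, `error`.
#' @return list with `delta` and `error`
#'   (`sqrt(clone error^2 + ancestor error^2)`).
#' @export
delta_performance <- function(clone, ancestor) {
  if (!identical(clone$metric, ancestor$metric))
    stopf("metric mismatch: clone '%s' vs ancestor '%s'", clone$metric, ancestor$metric)
  list(delta = clone$value - ancestor$value,
       error = sqrt(clone$error^2 + ancestor$error^2))
}

#' Phase-performance table from multi-condition fitness estimates
#'
#' For each clone, metric and replicate with both underlying fitnesses
#' available (and both passing the per-cycle error filter), computes
#' the per-hour performance and its propagated error; averages across
#' replicates; and, when the ancestor pseudo-lineage is present,
#' subtracts the ancestral performance to give the change in
#' performance. Clones with a missing underlying fitness yield no
#' record (nothing is imputed).
#'
#' @param fitness data frame with columns `lineage`, `condition`,
#'   `replicate`, `s`, `error` (stacked over conditions/replicates,
#'   e.g. from several [lineage_fitness()] fits).
#' @param metrics metric registry (default [performance_metrics()]).
#' @param max_error per-cycle error filter applied to the underlying
#'   fitnesses (strict `<`; default 5).
#' @param ancestor_id lineage id of the aggregated ancestor, or `NULL`
#'   to skip deltas.
#' @return data frame with one row per (clone, metric):
#'   `clone`, `metric`, `value`, `error`, `n_replicates`, `delta`,
#'   `delta_error` (deltas NA without an ancestor record).
#' @export
performance_table <- function(fitness, metrics = performance_metrics(),
                              max_error = 5, ancestor_id = "ANCESTOR") {
  need <- c("lineage", "condition", "replicate", "s", "error")
  stopifnot(all(need %in% names(fitness)))
  fitness <- fitness[fitness$error < max_error, , drop = FALSE]
  key <- paste(fitness$lineage, fitness$condition, fitness$replicate, sep = "\r")
  s_of <- stats::setNames(fitness$s, key)
  e_of <- stats::setNames(fitness$error, key)
  lineages <- unique(fitness$lineage)
  replicates <- sort(unique(fitness$replicate))
  rows <- list()
  for (m in seq_len(nrow(metrics))) {
    mt <- metrics[m, ]
    for (lin in lineages) {
      vals <- errs <- numeric(0)
      for (r in replicates) {
        ka <- paste(lin, mt$condA, r, sep = "\r")
        kb <- paste(lin, mt$condB, r, sep = "\r")
        if (!is.na(s_of[ka]) && !is.na(s_of[kb])) {
          vals <- c(vals, performance(s_of[[ka]], s_of[[kb]], mt$d_hours))
          errs <- c(errs, propagate_performance_error(e_of[[ka]], e_of[[kb]], mt$d_hours))
        }
      }
      if (length(vals) == 0) next
      rm <- replicate_mean(vals, errs)
      rows[[length(rows) + 1]] <- data.frame(
        clone = lin, metric = mt$metric, value = rm$mean, error = rm$error,
        n_replicates = length(vals), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$delta <- NA_real_; out$delta_error <- NA_real_
  if (!is.null(ancestor_id) && ancestor_id %in% out$clone) {
    for (m in unique(out$metric)) {
      anc <- out[out$clone == ancestor_id & out$metric == m, ]
      if (nrow(anc) != 1) next
      sel <- out$metric == m
      out$delta[sel] <- out$value[sel] - anc$value
      out$delta_error[sel] <- sqrt(out$error[sel]^2 + anc$error^2)
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a performance table as TSV
#'
#' @param perf data frame from [performance_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_performance_table <- function(perf, path) {
  utils::write.table(perf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
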