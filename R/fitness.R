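# Per-cycle lineage fitness from barcode count time series.
#
# Fitness s_i is defined per growth cycle, relative to the population
# mean: the expected log fold change of lineage i over an interval of
# Dc cycles is Dc * (s_i - sbar(t)), where sbar(t) is the mean fitness
# of the pool. The estimator solves this self-consistently:
#
#   s_i    = sum_t w_it [ log(f_i(t+1)/f_i(t)) / Dc_t + sbar(t) ] / sum_t w_it
#   sbar(t) = log sum_i f_i(t) exp(s_i)
#
# with weights w_it the harmonic mean of the endpoint read counts (the
# standard counting-noise approximation). The mean fitness is the
# log-mean-exponential of the lineage fitnesses -- the form under which
# the frequency updates stay normalized; it agrees with the linear
# frequency-weighted mean to first order in s. Only relative fitness is
# identified (adding a constant to every s and to sbar changes
# nothing), so the gauge can be pinned to a reference set of lineages
# (e.g. marked neutrals or the aggregated ancestor).

#' Infer per-cycle lineage fitness from a count matrix
#'
#' Fits the self-consistent per-cycle fitness model to a barcode count
#' time series: each lineage's fitness is the weighted mean of its
#' per-interval log-frequency slopes offset by the population mean
#' fitness, and the mean-fitness trajectory is recomputed from the
#' fitted values until convergence.
#'
#' Zero counts: when one endpoint of an interval is zero, a pseudocount
#' of `pseudocount` is added to both endpoints; intervals with both
#' endpoints zero are dropped. Lineages observed (nonzero) at fewer
#' than two timepoints are excluded with a warning.
#'
#' Errors: the nominal standard error is `sqrt(1 / sum_t w_it)`,
#' inflated by a dispersion factor. The factor is `kappa` when given;
#' otherwise, when `neutral_ids` marks lineages known to share a common
#' fitness, it is estimated from their excess scatter (floored at 1);
#' otherwise 1.
#'
#' @param cm a [count_matrix()] (counts may be corrected reals).
#' @param kappa optional fixed variance-inflation factor (>= 1).
#' @param neutral_ids optional barcodes of marked neutral lineages,
#'   used to estimate the error inflation from their scatter.
#' @param reference optional barcodes whose (weighted) mean fitness
#'   pins the gauge at zero; defaults to `neutral_ids`. `NULL` leaves
#'   the gauge at the iteration's own origin.
#' @param pseudocount added to both endpoints of an interval when
#'   either is zero.
#' @param timepoint_mask optional logical or integer vector selecting
#'   timepoints to keep (e.g. to drop an under-sequenced timepoint).
#' @param tol convergence tolerance on `max |change in sbar|`.
#' @param max_iter maximum iterations.
#' @return an object of class `lineage_fit` with components
#'   `estimates` (data frame: `lineage`, `s`, `error`, `n_intervals`,
#'   `reads_min`), `mean_fitness` (data frame per interval:
#'   `cycles_start`, `cycles_end`, `sbar`), `condition`, `replicate`,
#'   `iterations`, `inflator`, plus the usual modelling methods
#'   ([coef()], [summary()], [predict()], [simulate()], [residuals()],
#'   [plot()]).
#' @examples
#' ph <- sample_phenotypes(20, tradeoff_config(fraction_adaptive = 0.2), seed = 1)
#' sim <- simulate_assay(ph, regime_spec(6, "GlyEth"), n_cycles = 4,
#'                       noise = noise_config(1e5, seed = 2))
#' fit <- lineage_fitness(sim$counts)
#' head(coef(fit))
#' @export
lineage_fitness <- function(cm, kappa = NULL, neutral_ids = NULL,
                            reference = neutral_ids, pseudocount = 0.5,
                            timepoint_mask = NULL, tol = 1e-8, max_iter = 200) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- unclass(cm)
  cycles <- attr(cm, "timepoint_cycles")
  if (!is.null(timepoint_mask)) {
    counts <- counts[, timepoint_mask, drop = FALSE]
    cycles <- cycles[timepoint_mask]
  }
  Tn <- ncol(counts)
  if (Tn < 2) stopf("need at least 2 timepoints")
  observed <- rowSums(counts > 0)
  if (any(observed < 2)) {
    warnf("%d lineage(s) observed at fewer than 2 timepoints excluded", sum(observed < 2))
    counts <- counts[observed >= 2, , drop = FALSE]
  }
  n <- nrow(counts)
  totals <- colSums(counts)
  f <- sweep(counts, 2, totals, "/")
  dcyc <- diff(cycles)

  c1 <- counts[, -Tn, drop = FALSE]; c2 <- counts[, -1, drop = FALSE]
  usable <- !(c1 == 0 & c2 == 0)
  pc <- (c1 == 0 | c2 == 0) & usable
  a1 <- c1 + pc * pseudocount; a2 <- c2 + pc * pseudocount
  lfc <- log(sweep(a2, 2, totals[-1], "/") / sweep(a1, 2, totals[-Tn], "/"))
  slope <- sweep(lfc, 2, dcyc, "/")             # per-cycle log-frequency slope
  w <- 2 * a1 * a2 / (a1 + a2)                  # harmonic mean of endpoint reads
  w[!usable] <- 0
  slope[!usable] <- 0
  wsum <- rowSums(w)
  if (any(wsum <= 0)) stopf("lineage with no usable interval")
  d <- rowSums(w * slope) / wsum                # data part of s_i
  omega <- w / wsum                             # interval weights, rows sum to 1

  sbar <- numeric(Tn - 1)
  s <- d
  damp <- 1
  last_delta <- NULL
  it <- 0
  repeat {
    it <- it + 1
    s <- d + drop(omega %*% sbar)
    es <- exp(s - max(s))
    sbar_new <- vapply(seq_len(Tn - 1), function(t) {
      dc <- dcyc[t]
      if (dc <= 1 || dc != round(dc)) return(log(sum(f[, t] * es)) + max(s))
      # multi-cycle interval: the effective mean fitness per cycle is the
      # average of the per-cycle mean fitness over the covered cycles,
      # with frequencies propagated under the current estimates
      ft <- f[, t]
      m <- numeric(dc)
      for (k in seq_len(dc)) {
        wk <- ft * es
        m[k] <- log(sum(wk)) + max(s)
        ft <- wk / sum(wk)
      }
      mean(m)
    }, numeric(1))
    # only relative fitness is identified: remove the gauge (common-shift)
    # component so the iteration cannot drift along it on noisy data
    sbar_new <- sbar_new - mean(sbar_new)
    delta <- sbar_new - sbar
    if (!is.null(last_delta) && sum(delta * last_delta) < 0) damp <- 0.5
    sbar <- sbar + damp * delta
    last_delta <- delta
    if (max(abs(delta)) < tol) break
    if (it >= max_iter)
      stopf("fitness estimator did not converge: last max |delta sbar| = %.3g",
            max(abs(delta)))
  }
  s <- d + drop(omega %*% sbar)

  gauge <- 0
  if (!is.null(reference)) {
    ref <- intersect(reference, rownames(counts))
    if (length(ref) == 0) stopf("no reference lineage present in the count matrix")
    gauge <- sum(wsum[ref] * s[ref]) / sum(wsum[ref])
    s <- s - gauge
    sbar <- sbar - gauge
  }

  base_err <- sqrt(1 / wsum)
  inflator <- 1
  if (!is.null(kappa)) {
    if (!is_num1(kappa) || kappa < 1) stopf("kappa must be >= 1")
    inflator <- kappa
  } else if (!is.null(neutral_ids)) {
    nn <- intersect(neutral_ids, rownames(counts))
    if (length(nn) >= 2) {
      mN <- sum(wsum[nn] * s[nn]) / sum(wsum[nn])
      inflator <- max(1, mean((s[nn] - mN)^2 * wsum[nn]))
    }
  }
  err <- base_err * sqrt(inflator)

  estimates <- data.frame(
    lineage = rownames(counts), s = unname(s), error = unname(err),
    n_intervals = unname(rowSums(usable)),
    reads_min = unname(apply(counts, 1, min)),
    stringsAsFactors = FALSE)
  structure(list(
    estimates = estimates,
    mean_fitness = data.frame(cycles_start = cycles[-Tn], cycles_end = cycles[-1],
                              sbar = sbar),
    condition = attr(cm, "condition"), replicate = attr(cm, "replicate"),
    iterations = it, inflator = inflator, gauge = gauge,
    freq = f, slope = slope, omega = omega, usable = usable,
    timepoint_cycles = cycles, totals = totals,
    call = match.call()), class = "lineage_fit")
}

#' @export
print.lineage_fit <- function(x, ...) {
  cat(sprintf("<lineage_fit> %s rep %d: %d lineages, %d timepoints\n",
              x$condition, x$replicate, nrow(x$estimates), length(x$timepoint_cycles)))
  cat(sprintf("  converged in %d iterations; error inflator %.3g\n",
              x$iterations, x$inflator))
  cat("  mean fitness per interval:", paste(signif(x$mean_fitness$sbar, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.lineage_fit <- function(object, ...) {
  stats::setNames(object$estimates$s, object$estimates$lineage)
}

#' @export
summary.lineage_fit <- function(object, ...) {
  est <- object$estimates
  structure(list(fit = object,
                 s_quantiles = stats::quantile(est$s, c(0, .25, .5, .75, 1)),
                 median_error = stats::median(est$error),
                 top = est[order(-est$s), ][seq_len(min(5, nrow(est))), ]),
            class = "summary.lineage_fit")
}

#' @export
print.summary.lineage_fit <- function(x, ...) {
  print(x$fit)
  cat("  fitness quantiles (per cycle):\n")
  print(signif(x$s_quantiles, 4))
  cat(sprintf("  median standard error: %.4g\n", x$median_error))
  cat("  fittest lineages:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Predicted barcode frequency trajectories
#'
#' Starting from the observed initial frequencies, propagates each
#' lineage forward with its fitted fitness against the fitted
#' mean-fitness trajectory.
#'
#' @param object a `lineage_fit`.
#' @param ... unused.
#' @return barcode x timepoint matrix of predicted frequencies.
#' @export
predict.lineage_fit <- function(object, ...) {
  s <- coef(object)
  cycles <- object$timepoint_cycles
  Tn <- length(cycles)
  pred <- matrix(NA_real_, length(s), Tn,
                 dimnames = list(names(s), paste0("t", seq_len(Tn) - 1)))
  pred[, 1] <- object$freq[, 1]
  for (t in seq_len(Tn - 1)) {
    dc <- cycles[t + 1] - cycles[t]
    # s - sbar is gauge-invariant, so predictions do not depend on the pin
    pred[, t + 1] <- exp(log(pred[, t]) + dc * (s - object$mean_fitness$sbar[t]))
    pred[, t + 1] <- pred[, t + 1] / sum(pred[, t + 1])
  }
  pred
}

#' Per-interval residuals of a lineage fit
#'
#' Observed per-cycle log-frequency slope minus the fitted
#' `s_i - sbar(t)`, for every usable lineage x interval.
#'
#' @param object a `lineage_fit`.
#' @param ... unused.
#' @return lineage x interval matrix (NA where the interval was
#'   unusable).
#' @export
residuals.lineage_fit <- function(object, ...) {
  s <- coef(object)
  fitted_slope <- outer(s, object$mean_fitness$sbar, "-")
  r <- object$slope - fitted_slope
  r[!object$usable] <- NA
  r
}

#' Simulate count matrices from a fitted model
#'
#' Draws multinomial counts at each timepoint around the model's
#' predicted frequency trajectories, with the observed column totals.
#'
#' @param object a `lineage_fit`.
#' @param nsim number of simulated count matrices.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of [count_matrix()] objects.
#' @export
simulate.lineage_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pred <- predict(object)
  totals <- round(object$totals)
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    m <- vapply(seq_along(totals), function(t)
      drop(stats::rmultinom(1, totals[t], pred[, t])), numeric(nrow(pred)))
    rownames(m) <- rownames(pred)
    out[[k]] <- count_matrix(m, object$timepoint_cycles,
                             condition = object$condition, replicate = object$replicate)
  }
  out
}

#' Plot a lineage fit
#'
#' Left: observed log10 frequency trajectories (fittest lineages
#' highlighted); right: the fitted mean-fitness trajectory.
#'
#' @param x a `lineage_fit`.
#' @param max_lineages number of trajectories to draw.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.lineage_fit <- function(x, max_lineages = 50, ...) {
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  ord <- order(-x$estimates$s)
  keep <- ord[seq_len(min(max_lineages, length(ord)))]
  graphics::matplot(x$timepoint_cycles, t(log10(pmax(x$freq[keep, , drop = FALSE], 1e-9))),
                    type = "l", lty = 1, col = grDevices::hcl.colors(length(keep), "viridis"),
                    xlab = "cycles", ylab = "log10 frequency",
                    main = paste0(x$condition, " rep ", x$replicate), ...)
  mid <- (x$mean_fitness$cycles_start + x$mean_fitness$cycles_end) / 2
  graphics::plot(mid, x$mean_fitness$sbar, type = "b", pch = 19,
                 xlab = "cycles", ylab = "mean fitness (per cycle)",
                 main = "mean-fitness trajectory")
  invisible(x)
}

#' Aggregate ancestor barcodes into one pseudo-lineage
#'
#' Replaces the rows of the given ancestor barcodes by their column
#' sum under the label `label`; all other rows and the column totals
#' are unchanged.
#'
#' @param cm a [count_matrix()].
#' @param ancestor_ids barcodes to aggregate (must be present).
#' @param label name of the pooled pseudo-lineage.
#' @return a [count_matrix()].
#' @export
aggregate_ancestors <- function(cm, ancestor_ids, label = "ANCESTOR") {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(ancestor_ids) == 0) stopf("ancestor set is empty")
  if (!all(ancestor_ids %in% rownames(cm)))
    stopf("ancestor barcode(s) not present: %s",
          paste(setdiff(ancestor_ids, rownames(cm)), collapse = ", "))
  anc <- colSums(unclass(cm)[ancestor_ids, , drop = FALSE])
  rest <- unclass(cm)[setdiff(rownames(cm), ancestor_ids), , drop = FALSE]
  m <- rbind(rest, matrix(anc, 1, dimnames = list(label)))
  count_matrix(m, attr(cm, "timepoint_cycles"),
               condition = attr(cm, "condition"), replicate = attr(cm, "replicate"))
}

#' Filter fitness estimates by standard error
#'
#' Retains estimates with `error < max_error` (strict), the quality
#' filter applied before any performance computation.
#'
#' @param estimates data frame with an `error` column (e.g.
#'   `fit$estimates`, or a multi-condition fitness table).
#' @param max_error per-cycle error bound (default 5).
#' @return the filtered data frame; a message reports removals.
#' @export
filter_by_error <- function(estimates, max_error = 5) {
  if (inherits(estimates, "lineage_fit")) estimates <- estimates$estimates
  keep <- estimates$error < max_error
  if (any(!keep)) message(sum(!keep), " estimate(s) removed by error filter")
  estimates[keep, , drop = FALSE]
}

#' Keep only adaptive clones
#'
#' Retains clones whose mean-across-replicates fitness in their own
#' evolution condition is at least the ancestor's (ties kept).
#'
#' @param estimates data frame with columns `lineage`, `condition`,
#'   `replicate`, `s`.
#' @param evolution_condition named character vector mapping each clone
#'   to its evolution condition; clones missing from the map are kept
#'   untested.
#' @param ancestor_id lineage id of the (aggregated) ancestor; must
#'   have estimates in every evolution condition used.
#' @return the filtered data frame.
#' @export
filter_adaptive <- function(estimates, evolution_condition, ancestor_id = "ANCESTOR") {
  need <- c("lineage", "condition", "replicate", "s")
  stopifnot(all(need %in% names(estimates)))
  mean_s <- function(lin, cond) {
    v <- estimates$s[estimates$lineage == lin & estimates$condition == cond]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  clones <- setdiff(unique(estimates$lineage), ancestor_id)
  drop <- character(0)
  for (cl in clones) {
    cond <- evolution_condition[cl]
    if (is.na(cond) || is.null(cond)) next
    anc <- mean_s(ancestor_id, cond)
    if (is.na(anc)) stopf("no ancestor estimate in evolution condition '%s'", cond)
    sc <- mean_s(cl, cond)
    if (!is.na(sc) && sc < anc) drop <- c(drop, cl)
  }
  if (length(drop)) message(length(drop), " clone(s) below ancestral fitness removed")
  estimates[!(estimates$lineage %in% drop), , drop = FALSE]
}
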