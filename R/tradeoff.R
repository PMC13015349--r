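# Trade-offs between performance metrics and mutation parallelism.

#' Verify a variant call against read-support thresholds
#'
#' A variant passes when it is supported by at least 3 reads and by
#' more than 80% of aligned reads for haploids, or more than 40% for
#' diploids.
#'
#' @param alt_reads,total_reads supporting and total read counts
#'   (vectorized; `total_reads` must be > 0).
#' @param ploidy 1 or 2 (vectorized).
#' @return logical vector.
#' @examples
#' verify_variant(9, 10, 1)  # TRUE
#' verify_variant(5, 10, 1)  # FALSE
#' verify_variant(5, 10, 2)  # TRUE
#' verify_variant(2, 2, 1)   # FALSE: below the 3-read floor
#' @export
verify_variant <- function(alt_reads, total_reads, ploidy) {
  if (any(total_reads == 0)) stopf("total_reads must be > 0")
  if (any(alt_reads < 0 | alt_reads > total_reads))
    stopf("need 0 <= alt_reads <= total_reads")
  if (!all(ploidy %in% c(1, 2))) stopf("ploidy must be 1 or 2")
  frac <- alt_reads / total_reads
  alt_reads >= 3 & ifelse(ploidy == 1, frac > 0.80, frac > 0.40)
}

#' Parallelism table: clones per gene (or pathway) per condition
#'
#' Counts clones -- not mutations -- carrying at least one verified
#' mutation in each gene, per evolution condition; a clone with several
#' mutations in one gene counts once for that gene. With a pathway map
#' the counting is rolled up to pathways.
#'
#' @param variants data frame with columns `clone_id`, `gene`,
#'   `alt_reads`, `total_reads`; ploidy is taken from `metadata`.
#' @param metadata data frame with columns `clone_id`,
#'   `evolution_condition`, `ploidy`; its clones define the per-condition
#'   denominators (clones with sufficient coverage).
#' @param pathway_map optional data frame with columns `gene`,
#'   `pathway`; genes absent from the map keep their own name.
#' @param by count by `"gene"` (default) or `"pathway"`.
#' @param verify apply [verify_variant()] first (default `TRUE`).
#' @return data frame: one row per gene/pathway, one column per
#'   condition, plus a final `denominator` row is exposed via attribute
#'   `denominators` (named vector of clones per condition).
#' @export
parallelism_table <- function(variants, metadata, pathway_map = NULL,
                              by = c("gene", "pathway"), verify = TRUE) {
  by <- match.arg(by)
  stopifnot(all(c("clone_id", "gene") %in% names(variants)),
            all(c("clone_id", "evolution_condition") %in% names(metadata)))
  if (!all(variants$clone_id %in% metadata$clone_id))
    stopf("clone(s) in variants missing from metadata: %s",
          paste(utils::head(setdiff(variants$clone_id, metadata$clone_id), 3), collapse = ", "))
  cond_of <- stats::setNames(metadata$evolution_condition, metadata$clone_id)
  if (verify) {
    ploidy_of <- stats::setNames(metadata$ploidy, metadata$clone_id)
    ok <- verify_variant(variants$alt_reads, variants$total_reads,
                         ploidy_of[variants$clone_id])
    variants <- variants[ok, , drop = FALSE]
  }
  unit <- variants$gene
  if (by == "pathway" && !is.null(pathway_map)) {
    mapped <- pathway_map$pathway[match(variants$gene, pathway_map$gene)]
    unit <- ifelse(is.na(mapped), variants$gene, mapped)
  }
  df <- unique(data.frame(clone = variants$clone_id, unit = unit,
                          cond = cond_of[variants$clone_id], stringsAsFactors = FALSE))
  if (any(is.na(df$cond))) stopf("unknown evolution condition for some clones")
  conds <- sort(unique(metadata$evolution_condition))
  tab <- table(factor(df$unit), factor(df$cond, levels = conds))
  out <- data.frame(unit = rownames(tab), as.data.frame.matrix(tab),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[1] <- by
  rownames(out) <- NULL
  attr(out, "denominators") <- table(factor(metadata$evolution_condition, levels = conds))
  out
}

#' Percentage of clones hitting a target set
#'
#' `100 * (sum(counts) - overlap) / denominator`, rounded half away
#' from zero to `decimals` places -- the arithmetic behind statements
#' like "84.9% of clones adapted via a chromosome 11 duplication or an
#' SMF2 mutation" (counts 84 and 69, one double mutant, among 179
#' clones).
#'
#' @param counts clone counts per target (numeric vector).
#' @param denominator clones with sufficient coverage (> 0).
#' @param overlap clones counted more than once (default 0).
#' @param decimals decimal places of the reported percentage.
#' @return percentage.
#' @examples
#' target_fraction(c(84, 69), 179, overlap = 1, decimals = 1) # 84.9
#' @export
target_fraction <- function(counts, denominator, overlap = 0, decimals = 1) {
  if (!is_num1(denominator) || denominator <= 0) stopf("denominator must be > 0")
  if (overlap > min(counts)) stopf("overlap cannot exceed the smallest count")
  round_half_away(100 * (sum(counts) - overlap) / denominator, decimals)
}

#' Total mutations from per-clone multiplicities
#'
#' @param clone_multiplicities named vector: mutations per clone in a
#'   gene (all >= 1).
#' @return total mutation count.
#' @examples
#' mutation_multiplicity_total(c(rep(1, 71), rep(2, 5), 5)) # 86
#' @export
mutation_multiplicity_total <- function(clone_multiplicities) {
  if (any(clone_multiplicities < 1)) stopf("multiplicities must be >= 1")
  sum(clone_multiplicities)
}

#' Shipped gene-to-pathway map
#'
#' Editable table mapping recurrently mutated genes to pathways (e.g.
#' IRA1 to Ras/PKA), read from the package's `extdata`.
#'
#' @return data frame with columns `gene`, `pathway`.
#' @export
pathway_map <- function() {
  utils::read.table(system.file("extdata", "pathway_map.tsv", package = "spfit"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Trade-off between two performance metrics
#'
#' Unweighted Pearson correlation and least-squares slope between the
#' replicate-mean changes in two performance metrics across a clone
#' subset, with a two-sided p-value from the t-distribution on r. By
#' default the metric pair is rejected if the two metrics share an
#' underlying fitness condition, so that correlations are never driven
#' by shared measurement noise; an inverse-variance weighted mode is
#' available.
#'
#' @param perf performance table from [performance_table()].
#' @param metric_x,metric_y metric names from [performance_metrics()].
#' @param metadata optional data frame with columns `clone_id` and any
#'   of `evolution_condition`, `ploidy`, `karyotype_normal`,
#'   `mutation_labels` (comma-separated), `ancestor_background`, used
#'   by the subset filters.
#' @param condition,ancestor keep clones from this evolution condition
#'   / ancestor background.
#' @param haploid_only,karyotype_normal_only logical subset filters.
#' @param include_label,exclude_label keep / drop clones carrying a
#'   mutation label (e.g. `"SMF2"`).
#' @param use_delta correlate changes in performance (default) rather
#'   than raw performance values.
#' @param allow_shared permit metric pairs sharing an underlying
#'   fitness condition (default `FALSE`: error).
#' @param weighted inverse-variance weighted correlation/slope.
#' @return object of class `tradeoff_result`: list with `metric_x`,
#'   `metric_y`, `subset`, `n_clones`, `pearson_r`, `r_squared`,
#'   `slope`, `intercept`, `p_value`, `data`.
#' @export
tradeoff <- function(perf, metric_x, metric_y, metadata = NULL,
                     condition = NULL, ancestor = NULL,
                     haploid_only = FALSE, karyotype_normal_only = FALSE,
                     include_label = NULL, exclude_label = NULL,
                     use_delta = TRUE, allow_shared = FALSE, weighted = FALSE) {
  mx <- metric_row(metric_x); my <- metric_row(metric_y)
  shared <- intersect(c(mx$condA, mx$condB), c(my$condA, my$condB))
  if (length(shared) > 0 && !allow_shared)
    stopf("metrics %s and %s share underlying fitness condition %s",
          metric_x, metric_y, paste(shared, collapse = ", "))
  col <- if (use_delta) "delta" else "value"
  ecol <- if (use_delta) "delta_error" else "error"
  x <- perf[perf$metric == metric_x, c("clone", col, ecol)]
  y <- perf[perf$metric == metric_y, c("clone", col, ecol)]
  names(x) <- c("clone", "x", "ex"); names(y) <- c("clone", "y", "ey")
  d <- merge(x, y, by = "clone")
  d <- d[stats::complete.cases(d[, c("x", "y")]), , drop = FALSE]
  subset_desc <- "all clones"
  if (!is.null(metadata)) {
    md <- metadata[match(d$clone, metadata$clone_id), , drop = FALSE]
    keep <- rep(TRUE, nrow(d)); parts <- character(0)
    if (!is.null(condition)) {
      keep <- keep & md$evolution_condition %in% condition
      parts <- c(parts, paste0("condition ", paste(condition, collapse = "/")))
    }
    if (!is.null(ancestor)) {
      keep <- keep & md$ancestor_background %in% ancestor
      parts <- c(parts, paste0("ancestor ", ancestor))
    }
    if (haploid_only) { keep <- keep & md$ploidy == 1; parts <- c(parts, "haploid") }
    if (karyotype_normal_only) {
      keep <- keep & isTRUE_vec(md$karyotype_normal); parts <- c(parts, "normal karyotype")
    }
    has_label <- function(lab) {
      vapply(strsplit(ifelse(is.na(md$mutation_labels), "", md$mutation_labels), ","),
             function(v) lab %in% trimws(v), logical(1))
    }
    if (!is.null(include_label)) {
      keep <- keep & has_label(include_label); parts <- c(parts, paste0("with ", include_label))
    }
    if (!is.null(exclude_label)) {
      keep <- keep & !has_label(exclude_label); parts <- c(parts, paste0("without ", exclude_label))
    }
    keep[is.na(keep)] <- FALSE
    d <- d[keep, , drop = FALSE]
    if (length(parts)) subset_desc <- paste(parts, collapse = ", ")
  }
  n <- nrow(d)
  if (n < 3) stopf("need at least 3 clones after filtering (have %d)", n)
  if (weighted) {
    w <- 1 / (d$ex^2 + d$ey^2)
    w <- w / sum(w)
    mx_ <- sum(w * d$x); my_ <- sum(w * d$y)
    cxy <- sum(w * (d$x - mx_) * (d$y - my_))
    vx <- sum(w * (d$x - mx_)^2); vy <- sum(w * (d$y - my_)^2)
    r <- cxy / sqrt(vx * vy)
    slope <- cxy / vx
    intercept <- my_ - slope * mx_
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  } else {
    ct <- stats::cor.test(d$x, d$y)
    r <- unname(ct$estimate)
    p <- ct$p.value
    lmfit <- stats::lm(y ~ x, data = d)
    slope <- unname(stats::coef(lmfit)[2])
    intercept <- unname(stats::coef(lmfit)[1])
  }
  structure(list(metric_x = metric_x, metric_y = metric_y, subset = subset_desc,
                 n_clones = n, pearson_r = r, r_squared = r^2, slope = slope,
                 intercept = intercept, p_value = p, data = d),
            class = "tradeoff_result")
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == 1)

#' @export
print.tradeoff_result <- function(x, ...) {
  cat(sprintf("<tradeoff> %s vs %s (%s): n = %d\n",
              x$metric_y, x$metric_x, x$subset, x$n_clones))
  cat(sprintf("  Pearson r = %.3f (R2 = %.3f), slope = %.3f, p = %.3g\n",
              x$pearson_r, x$r_squared, x$slope, x$p_value))
  invisible(x)
}

#' @export
plot.tradeoff_result <- function(x, ...) {
  graphics::plot(x$data$x, x$data$y, pch = 19,
                 xlab = paste("change in", x$metric_x, "(per hour)"),
                 ylab = paste("change in", x$metric_y, "(per hour)"),
                 main = sprintf("r = %.2f, p = %.2g (%s)", x$pearson_r, x$p_value, x$subset), ...)
  graphics::abline(x$intercept, x$slope, col = "red3")
  invisible(x)
}
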