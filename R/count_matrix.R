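# Barcode x timepoint count matrices and diversity.

#' Barcode count matrix for one assay
#'
#' Wraps a barcode x timepoint matrix of non-negative counts (integers,
#' or reals after index-hopping correction) together with the cycles
#' elapsed at each timepoint and the (condition, replicate) labels.
#'
#' @param counts numeric matrix, rows = barcodes (rownames required),
#'   columns = timepoints.
#' @param timepoint_cycles numeric vector of cycles elapsed at each
#'   timepoint; strictly increasing, length `ncol(counts)`.
#' @param condition condition label (e.g. `"GE_6day"`).
#' @param replicate replicate index.
#' @return an object of class `count_matrix` (a matrix with attributes
#'   `timepoint_cycles`, `condition`, `replicate`).
#' @export
count_matrix <- function(counts, timepoint_cycles = seq_len(ncol(counts)) - 1,
                         condition = "cond", replicate = 1L) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stopf("counts must have barcode rownames")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (length(timepoint_cycles) != ncol(counts))
    stopf("timepoint_cycles must have one entry per timepoint column")
  if (any(diff(timepoint_cycles) <= 0))
    stopf("timepoint_cycles must be strictly increasing")
  colnames(counts) <- paste0("t", seq_len(ncol(counts)) - 1)
  structure(counts, timepoint_cycles = as.numeric(timepoint_cycles),
            condition = condition, replicate = as.integer(replicate),
            class = c("count_matrix", "matrix", "array"))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d barcodes x %d timepoints, condition %s rep %d\n",
              nrow(x), ncol(x), attr(x, "condition"), attr(x, "replicate")))
  cat("  cycles:", paste(attr(x, "timepoint_cycles"), collapse = ", "), "\n")
  cat("  column totals:", paste(signif(colSums(x), 6), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' The layout is one row per barcode with columns `barcode`,
#' `t0 ... tn`, `condition`, `replicate`; the cycles at each timepoint
#' are stored in a `# cycles:` header comment.
#'
#' @param cm a [count_matrix()].
#' @param path file path.
#' @return `write_count_matrix` returns `path` invisibly;
#'   `read_count_matrix` returns a `count_matrix`.
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cycles: %s", paste(attr(cm, "timepoint_cycles"), collapse = ",")), con)
  df <- data.frame(barcode = rownames(cm), as.data.frame(unclass(cm), check.names = FALSE),
                   condition = attr(cm, "condition"), replicate = attr(cm, "replicate"),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  first <- readLines(path, n = 1)
  cycles <- NULL
  if (startsWith(first, "# cycles:"))
    cycles <- as.numeric(strsplit(sub("# cycles:\\s*", "", first), ",")[[1]])
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  tcols <- grep("^t[0-9]+$", names(df), value = TRUE)
  m <- as.matrix(df[, tcols, drop = FALSE])
  rownames(m) <- df$barcode
  if (is.null(cycles)) cycles <- seq_along(tcols) - 1
  count_matrix(m, cycles, condition = df$condition[1], replicate = df$replicate[1])
}

#' Shannon diversity of a barcode count vector
#'
#' `H = -sum f_i log f_i` in nats over barcodes with positive counts.
#' Maximal (`log(k)`) for a uniform pool of k barcodes and 0 when a
#' single barcode remains.
#'
#' @param counts non-negative numeric vector (one timepoint column).
#' @return Shannon entropy in nats.
#' @examples
#' shannon_diversity(rep(1, 100)) # log(100)
#' @export
shannon_diversity <- function(counts) {
  if (!is.numeric(counts) || any(counts < 0)) stopf("counts must be non-negative numbers")
  tot <- sum(counts)
  if (tot <= 0) stopf("all counts are zero: diversity undefined")
  f <- counts[counts > 0] / tot
  -sum(f * log(f))
}

#' Diversity trajectory of a count matrix
#'
#' @param cm a [count_matrix()].
#' @return data frame with `condition`, `replicate`, `cycles`, `H_nats`.
#' @export
diversity_trajectory <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  data.frame(condition = attr(cm, "condition"), replicate = attr(cm, "replicate"),
             cycles = attr(cm, "timepoint_cycles"),
             H_nats = apply(unclass(cm), 2, shannon_diversity),
             row.names = NULL)
}
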