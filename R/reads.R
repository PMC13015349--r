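# Read-level simulation and barcode/UMI extraction.
#
# Reads have a fixed layout: a UMI field and a barcode field at known
# 0-based half-open character coordinates. Barcodes are counted by
# perfect match against a whitelist (no clustering or fuzzy rescue);
# reads failing the whitelist are tallied as unassigned. UMI
# dereplication collapses exact-duplicate (barcode, UMI) pairs to
# molecule counts.

BASES <- c("A", "C", "G", "T")

#' Fixed read layout
#'
#' 0-based, half-open character coordinates of the UMI and barcode
#' fields within a read.
#'
#' @param umi_offset,umi_length UMI field coordinates.
#' @param barcode_offset,barcode_length barcode field coordinates.
#' @param read_length total read length; defaults to the furthest field
#'   end.
#' @return an object of class `read_layout`.
#' @export
read_layout <- function(umi_offset = 0, umi_length = 8,
                        barcode_offset = 8, barcode_length = 20,
                        read_length = NULL) {
  for (f in c("umi_offset", "umi_length", "barcode_offset", "barcode_length")) {
    v <- get(f)
    check_field(is_count(v), f, "must be a non-negative integer")
  }
  check_field(umi_length > 0, "umi_length", "must be > 0")
  check_field(barcode_length > 0, "barcode_length", "must be > 0")
  u <- c(umi_offset, umi_offset + umi_length)
  b <- c(barcode_offset, barcode_offset + barcode_length)
  if (max(u[1], b[1]) < min(u[2], b[2]))
    stopf("invalid configuration: UMI and barcode intervals overlap")
  ext <- max(u[2], b[2])
  if (is.null(read_length)) read_length <- ext
  if (read_length < ext) stopf("layout exceeds read length")
  structure(list(umi_offset = umi_offset, umi_length = umi_length,
                 barcode_offset = barcode_offset, barcode_length = barcode_length,
                 read_length = read_length), class = "read_layout")
}

random_seq <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Emit simulated reads for one timepoint
#'
#' Produces one read per sequenced molecule: the barcode field carries
#' the lineage barcode, the UMI field a uniform random sequence over
#' `4^umi_length`, remaining positions random filler. Substitution
#' errors are applied i.i.d. per base at `noise$read_error_rate`.
#'
#' @param counts named non-negative integer vector: reads per barcode.
#'   All names must have length `layout$barcode_length`.
#' @param layout a [read_layout()].
#' @param noise a [noise_config()] (uses `read_error_rate` and `seed`).
#' @return character vector of reads, named `read1 ... readN`.
#' @examples
#' lay <- read_layout(0, 4, 4, 6)
#' emit_reads(c(ACGTAC = 2, TTTTTT = 1), lay, noise_config(seed = 1))
#' @export
emit_reads <- function(counts, layout, noise = noise_config()) {
  stopifnot(inherits(layout, "read_layout"), inherits(noise, "noise_config"))
  if (is.null(names(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stopf("counts must be named non-negative integers")
  if (any(nchar(names(counts)) != layout$barcode_length))
    stopf("all barcodes must have length barcode_length")
  set.seed(noise$seed)
  n <- sum(counts)
  bc <- rep(names(counts), counts)
  umi <- random_seq(n, layout$umi_length)
  filler_len <- layout$read_length - layout$umi_length - layout$barcode_length
  # assemble in field order
  fields <- list(list(off = layout$umi_offset, seq = umi),
                 list(off = layout$barcode_offset, seq = bc))
  fields <- fields[order(vapply(fields, `[[`, numeric(1), "off"))]
  pre <- fields[[1]]$off
  mid <- fields[[2]]$off - (fields[[1]]$off + nchar(fields[[1]]$seq[1]))
  post <- layout$read_length - (fields[[2]]$off + nchar(fields[[2]]$seq[1]))
  reads <- paste0(if (pre > 0) random_seq(n, pre) else "",
                  fields[[1]]$seq,
                  if (mid > 0) random_seq(n, mid) else "",
                  fields[[2]]$seq,
                  if (post > 0) random_seq(n, post) else "")
  if (noise$read_error_rate > 0 && n > 0) {
    L <- layout$read_length
    nerr <- stats::rbinom(n, L, noise$read_error_rate)
    idx <- which(nerr > 0)
    for (i in idx) {
      pos <- sample.int(L, nerr[i])
      ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      # substitution to one of the three other bases
      ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(BASES, b), 1), character(1))
      reads[i] <- paste(ch, collapse = "")
    }
  }
  stats::setNames(reads, paste0("read", seq_len(n)))
}

#' Write / read FASTQ
#'
#' Thin wrappers over Biostrings' FASTQ support. Written reads carry
#' uniform maximal Phred qualities (simulated reads have no quality
#' model).
#'
#' @param reads named character vector of reads.
#' @param path FASTQ file path.
#' @return `write_fastq` returns `path` invisibly; `read_fastq` a named
#'   character vector of reads.
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::PhredQuality(vapply(nchar(reads), function(l)
    paste(rep("I", l), collapse = ""), character(1)))
  qs <- Biostrings::QualityScaledDNAStringSet(s, q)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Extract barcode and UMI fields from reads
#'
#' Pulls the barcode and UMI substrings at the layout coordinates. A
#' barcode is reported only on an exact whitelist match; mismatching
#' reads yield `NA` and are tallied as unassigned (never fuzzily
#' rescued). The UMI is returned verbatim.
#'
#' @param reads character vector of reads (length >= layout extent).
#' @param layout a [read_layout()].
#' @param whitelist character vector of valid barcodes.
#' @return data frame with columns `barcode` (NA when unassigned) and
#'   `umi`, plus attribute `n_unassigned`.
#' @export
extract_barcodes <- function(reads, layout, whitelist) {
  stopifnot(inherits(layout, "read_layout"))
  if (any(nchar(reads) < layout$read_length)) stopf("read shorter than layout extent")
  bc <- substr(reads, layout$barcode_offset + 1,
               layout$barcode_offset + layout$barcode_length)
  umi <- substr(reads, layout$umi_offset + 1, layout$umi_offset + layout$umi_length)
  bc[!(bc %in% whitelist)] <- NA_character_
  out <- data.frame(barcode = bc, umi = umi, stringsAsFactors = FALSE)
  attr(out, "n_unassigned") <- sum(is.na(bc))
  out
}

#' Dereplicate UMIs per barcode
#'
#' Collapses exact-duplicate (barcode, UMI) pairs: the dereplicated
#' count per barcode is the number of distinct UMIs observed with that
#' barcode. UMIs are scoped per barcode.
#'
#' @param records data frame with columns `barcode` and `umi` (e.g.
#'   from [extract_barcodes()]); NA barcodes are dropped.
#' @return named integer vector of molecule counts per barcode.
#' @examples
#' dedup_umis(data.frame(barcode = c("A", "A", "A", "B"),
#'                       umi = c("u1", "u1", "u2", "u1")))
#' @export
dedup_umis <- function(records) {
  ok <- !is.na(records$barcode)
  pairs <- unique(records[ok, c("barcode", "umi")])
  tab <- table(pairs$barcode)
  stats::setNames(as.integer(tab), names(tab))
}

#' Count whitelisted barcodes in reads
#'
#' Full counting stage: extract by layout, keep exact whitelist
#' matches, optionally dereplicate UMIs.
#'
#' @param reads character vector of reads.
#' @param layout a [read_layout()].
#' @param whitelist character vector of valid barcodes.
#' @param dedup collapse to distinct-UMI molecule counts (default) or
#'   raw read counts.
#' @return named integer vector of counts per whitelisted barcode
#'   (zeros included), with attribute `n_unassigned`.
#' @export
count_barcodes <- function(reads, layout, whitelist, dedup = TRUE) {
  rec <- extract_barcodes(reads, layout, whitelist)
  counts <- if (dedup) dedup_umis(rec) else {
    tab <- table(rec$barcode[!is.na(rec$barcode)])
    stats::setNames(as.integer(tab), names(tab))
  }
  out <- stats::setNames(integer(length(whitelist)), whitelist)
  out[names(counts)] <- counts
  attr(out, "n_unassigned") <- attr(rec, "n_unassigned")
  out
}
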