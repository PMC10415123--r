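# SLAM-DUNK-style quantification layer: read trimming, per-read substitution
# counting against the reference, T>C read classification and per-gene
# tcount tallies with conversion-rate QC.

SUB_TYPES <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             function(a, b) paste0(a, ">", b)))
SUB_TYPES <- SUB_TYPES[substr(SUB_TYPES, 1, 1) != substr(SUB_TYPES, 3, 3)]

#' Trim aligned reads (5' adapter clip and terminal poly(A) removal)
#'
#' Removes the first `trim5` bases of every read, then removes a terminal
#' 3' adenine run entirely when its length exceeds `max_polya_keep` (runs of
#' `max_polya_keep` or fewer adenines are kept). Alignment starts are shifted
#' so trimmed reads stay consistent with the reference. Reads shorter than
#' `trim5` end up empty and are flagged `discarded`.
#'
#' @param reads `aligned_reads`
#' @param trim5 number of 5' bases to clip (adapter remnant)
#' @param max_polya_keep longest terminal adenine run kept; a run of
#'   `max_polya_keep + 1` or more is treated as residual poly(A) tail
#' @return trimmed `aligned_reads` with a logical `discarded` column
#' @export
trim_read <- function(reads, trim5 = 12L, max_polya_keep = 4L) {
  stopifnot(inherits(reads, "aligned_reads"))
  stopifnot_scalar_number(trim5, "trim5", lower = 0)
  stopifnot_scalar_number(max_polya_keep, "max_polya_keep", lower = 0)
  # trimming is a one-shot preprocessing step: a second application must not
  # clip further (idempotence)
  if (isTRUE(attr(reads, "trimmed"))) return(reads)
  ref <- attr(reads, "reference")
  if (nrow(reads) == 0) {
    reads$discarded <- logical(0)
    return(aligned_reads(reads, ref))
  }
  len <- nchar(reads$seq)
  keep5 <- as.integer(pmin(trim5, len))
  seq5 <- substr(reads$seq, keep5 + 1L, len)
  qual5 <- substr(reads$qual, keep5 + 1L, len)
  start5 <- reads$start + keep5

  # terminal adenine run length
  run <- vapply(seq5, function(s) {
    n <- nchar(s)
    if (n == 0) return(0L)
    r <- 0L
    while (r < n && substr(s, n - r, n - r) == "A") r <- r + 1L
    r
  }, integer(1), USE.NAMES = FALSE)
  clip <- ifelse(run > max_polya_keep, run, 0L)
  new_len <- nchar(seq5) - clip
  reads$seq <- substr(seq5, 1L, new_len)
  reads$qual <- substr(qual5, 1L, new_len)
  reads$start <- start5
  reads$discarded <- new_len == 0L
  out <- aligned_reads(reads, ref)
  attr(out, "trimmed") <- TRUE
  out
}

# Per-read substitution events and per-base coverage, quality-filtered.
# Returns a matrix: one row per read, columns = 12 substitution types plus
# cov_A, cov_C, cov_G, cov_T (reference-base coverage at quality >= min_bq,
# read base != N).
conversion_events <- function(reads, references, min_base_quality = 27L) {
  bases <- c("A", "C", "G", "T")
  cols <- c(SUB_TYPES, paste0("cov_", bases))
  out <- matrix(0L, nrow = nrow(reads), ncol = length(cols),
                dimnames = list(NULL, cols))
  if (nrow(reads) == 0) return(out)
  lens <- nchar(reads$seq)
  grp <- split(seq_len(nrow(reads)),
               paste(reads$gene_id, reads$start, lens, sep = "\r"))
  for (idx in grp) {
    g <- reads$gene_id[idx[1]]
    st <- reads$start[idx[1]]
    L <- lens[idx[1]]
    if (L == 0) next
    refseq <- references[[g]]
    refv <- strsplit(substr(refseq, st + 1L, st + L), "")[[1]]
    if (!all(refv %in% bases)) {
      stop("reference contains non-ACGT characters for gene ", g, call. = FALSE)
    }
    n <- length(idx)
    readm <- matrix(unlist(strsplit(reads$seq[idx], ""), use.names = FALSE),
                    nrow = n, byrow = TRUE)
    if (!all(readm %in% c(bases, "N"))) {
      stop("read sequence contains invalid characters", call. = FALSE)
    }
    qualm <- matrix(utf8ToInt(paste(reads$qual[idx], collapse = "")) - 33L,
                    nrow = n, byrow = TRUE)
    ok <- qualm >= min_base_quality & readm != "N"
    for (b in bases) {
      at_b <- refv == b
      if (!any(at_b)) next
      out[idx, paste0("cov_", b)] <-
        as.integer(rowSums(ok[, at_b, drop = FALSE]))
      for (b2 in setdiff(bases, b)) {
        ev <- ok[, at_b, drop = FALSE] & readm[, at_b, drop = FALSE] == b2
        out[idx, paste0(b, ">", b2)] <- as.integer(rowSums(ev))
      }
    }
  }
  out
}

#' Count substitutions in one aligned read against its reference
#'
#' Positions whose base quality falls below `min_base_quality` and read `N`
#' bases are excluded from both event counts and coverage.
#'
#' @param read single-row `aligned_reads` (or a one-row data.frame with the
#'   same columns)
#' @param reference named character vector of reference sequences (defaults
#'   to the read set's own `reference` attribute)
#' @param min_base_quality Phred threshold (SLAM-DUNK default 27)
#' @return a `conversion_vector`: named list with `counts` (12 substitution
#'   types), `coverage` (per reference base), `t_coverage` and `tc_count`
#' @export
count_conversions <- function(read, reference = attr(read, "reference"),
                              min_base_quality = 27L) {
  if (!inherits(read, "aligned_reads")) {
    read <- aligned_reads(read, reference)
  }
  if (nrow(read) != 1L) stop("`read` must be a single read", call. = FALSE)
  ev <- conversion_events(read, reference, min_base_quality)[1L, ]
  structure(
    list(counts = ev[SUB_TYPES],
         coverage = ev[paste0("cov_", c("A", "C", "G", "T"))],
         t_coverage = unname(ev[["cov_T"]]),
         tc_count = unname(ev[["T>C"]])),
    class = "conversion_vector"
  )
}

#' Classify a read as a T>C (nascent-evidence) read
#'
#' @param conv `conversion_vector` from [count_conversions()], or a numeric
#'   vector of T>C counts
#' @param min_tc minimum number of quality-filtered T>C events (default 1,
#'   the SLAM-DUNK convention)
#' @return logical
#' @export
classify_tc_read <- function(conv, min_tc = 1L) {
  if (min_tc < 1) stop("`min_tc` must be >= 1", call. = FALSE)
  tc <- if (inherits(conv, "conversion_vector")) conv$tc_count else conv
  tc >= min_tc
}

#' Tally per-gene read and T>C read counts into a tcount table
#'
#' The central quantification step: after quality filtering, every
#' non-discarded read contributes to its gene's `ReadCount`; reads with at
#' least `min_tc` T>C events contribute to `TcReadCount`. Reference-T
#' coverage and T>C events accumulate into `coverageOnTs` /
#' `conversionsOnTs`, and `readsCPM` normalizes `ReadCount` to reads per
#' million over the sample.
#'
#' @param reads `aligned_reads`
#' @param references named character vector of reference sequences (defaults
#'   to the read set's attribute)
#' @param min_base_quality Phred threshold for counting conversions
#' @param min_tc minimum T>C events for a read to count as converted
#' @return tcount data.frame (gene_id, length, ReadCount, TcReadCount,
#'   coverageOnTs, conversionsOnTs, conversionRate, readsCPM) covering every
#'   reference gene (zero rows for unobserved genes)
#' @export
tally_gene_counts <- function(reads, references = attr(reads, "reference"),
                              min_base_quality = 27L, min_tc = 1L) {
  stopifnot(inherits(reads, "aligned_reads"))
  if (!is.null(reads$discarded)) reads <- reads[!reads$discarded, ]
  if (nrow(reads) == 0) stop("no reads to tally", call. = FALSE)
  if (min_tc < 1) stop("`min_tc` must be >= 1", call. = FALSE)
  ev <- conversion_events(reads, references, min_base_quality)
  is_tc <- ev[, "T>C"] >= min_tc
  gene <- factor(reads$gene_id, levels = names(references))
  sum_by_gene <- function(x) {
    out <- stats::setNames(numeric(nlevels(gene)), levels(gene))
    agg <- rowsum(x, gene)
    out[rownames(agg)] <- agg[, 1]
    as.integer(out)
  }
  tab <- data.frame(
    gene_id = names(references),
    length = nchar(references),
    ReadCount = as.integer(tabulate(gene, nbins = nlevels(gene))),
    TcReadCount = sum_by_gene(as.integer(is_tc)),
    coverageOnTs = sum_by_gene(ev[, "cov_T"]),
    conversionsOnTs = sum_by_gene(ev[, "T>C"]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  tab$conversionRate <- ifelse(tab$coverageOnTs > 0,
                               tab$conversionsOnTs / tab$coverageOnTs,
                               NA_real_)
  tab$readsCPM <- tab$ReadCount * 1e6 / sum(tab$ReadCount)
  tab
}

#' Per-sample median conversion rates by substitution type
#'
#' For an aligned read set, computes per gene and substitution type the rate
#' events / eligible-base coverage and reports the median over genes (genes
#' with zero eligible coverage for a type are excluded from that type's
#' median). For a tcount table, only the T>C rate (`conversionRate`) is
#' available and its median is returned.
#'
#' @param x `aligned_reads` or a tcount data.frame
#' @param references reference sequences (read-set input only)
#' @param min_base_quality Phred threshold
#' @return named numeric vector of median rates per substitution type
#' @export
conversion_rate_summary <- function(x, references = attr(x, "reference"),
                                    min_base_quality = 27L) {
  if (!inherits(x, "aligned_reads")) {
    if (!all(c("conversionRate", "coverageOnTs") %in% names(x))) {
      stop("input must be aligned_reads or a tcount table", call. = FALSE)
    }
    keep <- x$coverageOnTs > 0
    return(c("T>C" = stats::median(x$conversionRate[keep])))
  }
  if (!is.null(x$discarded)) x <- x[!x$discarded, ]
  if (nrow(x) == 0) stop("no reads", call. = FALSE)
  ev <- conversion_events(x, references, min_base_quality)
  gene <- factor(x$gene_id)
  agg <- rowsum(ev, gene)
  out <- stats::setNames(numeric(length(SUB_TYPES)), SUB_TYPES)
  for (s in SUB_TYPES) {
    covcol <- paste0("cov_", substr(s, 1, 1))
    keep <- agg[, covcol] > 0
    out[s] <- if (any(keep)) {
      stats::median(agg[keep, s] / agg[keep, covcol])
    } else NA_real_
  }
  out
}

#' Analytic T>C read detection sensitivity
#'
#' Probability that a read from a labeled molecule covering `n_uridines`
#' uridine positions carries at least one T>C conversion when each uridine
#' converts independently with probability `p_conv`:
#' `1 - (1 - p_conv)^n_uridines`.
#'
#' @param p_conv per-uridine conversion probability in [0, 1]
#' @param n_uridines number of covered uridines, >= 0
#' @return detection probability; vectorized
#' @export
detection_sensitivity <- function(p_conv, n_uridines) {
  if (any(p_conv < 0 | p_conv > 1)) stop("`p_conv` must be in [0, 1]", call. = FALSE)
  if (any(n_uridines < 0)) stop("`n_uridines` must be >= 0", call. = FALSE)
  1 - (1 - p_conv)^n_uridines
}
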