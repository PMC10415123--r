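# Nascent / pre-existing decomposition: per-gene nascent proportions, the
# top-induced-gene sensitivity estimator, sensitivity correction, and
# non-T>C (pre-existing proxy) count tables.

#' Per-gene nascent proportion from a tcount table
#'
#' The raw proportion is `TcReadCount / ReadCount`. Genes with fewer than
#' `min_support` reads are reported as missing (NA), not zero: a small
#' denominator carries binomial noise larger than the signal.
#'
#' @param table tcount data.frame
#' @param min_support minimum ReadCount for a defined proportion (default 20)
#' @return data.frame (gene_id, raw_proportion, read_support)
#' @export
nascent_proportion <- function(table, min_support = 20L) {
  stopifnot(all(c("gene_id", "ReadCount", "TcReadCount") %in% names(table)))
  raw <- ifelse(table$ReadCount >= min_support,
                table$TcReadCount / table$ReadCount, NA_real_)
  data.frame(gene_id = table$gene_id, raw_proportion = raw,
             read_support = table$ReadCount, stringsAsFactors = FALSE)
}

#' Estimate T>C read detection sensitivity from top-induced genes
#'
#' Reads gained after induction by the most strongly induced genes are
#' (almost) all nascent, so the fraction of those excess reads that carry a
#' T>C conversion estimates the detection sensitivity directly. Both tables
#' are first scaled to the control library depth; genes are ranked by the
#' induction ratio `(ReadCount_t + 1) / (ReadCount_c + 1)` and the top
#' `top_k` genes pooled. The default `"excess"` formulation is
#' `s = sum(Tc_t - Tc_c) / sum(N_t - N_c)`, which removes the pre-existing
#' T>C background; `"treated"` uses `sum(Tc_t) / sum(N_t - N_c)`.
#'
#' Replicate tables should be summed within condition before calling (the
#' statistic is a pooled proportion); see [sum_tcount()].
#'
#' @param control,treated tcount data.frames over the same gene universe
#' @param top_k number of top induced genes to pool (default 3)
#' @param formulation `"excess"` (default) or `"treated"`
#' @param pseudocount added to both counts in the induction ratio
#' @return object of class `sensitivity_estimate`: list with `s`, `per_gene`
#'   component estimates, `genes_used` and `formulation`
#' @export
estimate_sensitivity <- function(control, treated, top_k = 3L,
                                 formulation = c("excess", "treated"),
                                 pseudocount = 1) {
  formulation <- match.arg(formulation)
  if (!setequal(control$gene_id, treated$gene_id)) {
    stop("control and treated tables must share a gene universe", call. = FALSE)
  }
  treated <- treated[match(control$gene_id, treated$gene_id), ]
  # scale treated to the control library depth
  sc <- sum(control$ReadCount) / sum(treated$ReadCount)
  n_c <- control$ReadCount
  tc_c <- control$TcReadCount
  n_t <- treated$ReadCount * sc
  tc_t <- treated$TcReadCount * sc

  ratio <- (n_t + pseudocount) / (n_c + pseudocount)
  ord <- order(ratio, decreasing = TRUE)
  sel <- ord[seq_len(min(top_k, length(ord)))]
  excess <- n_t[sel] - n_c[sel]
  excess_tc <- if (formulation == "excess") tc_t[sel] - tc_c[sel] else tc_t[sel]
  pos <- excess > 0
  if (!any(pos)) {
    stop("no selected gene shows positive read excess; cannot estimate ",
         "sensitivity (induction too weak or depth mismatch)", call. = FALSE)
  }
  s <- sum(excess_tc[pos]) / sum(excess[pos])
  s <- min(max(s, .Machine$double.eps), 1)
  per_gene <- data.frame(
    gene_id = control$gene_id[sel],
    induction_ratio = ratio[sel],
    excess_reads = excess,
    excess_tc_reads = excess_tc,
    s_gene = ifelse(excess > 0, pmin(pmax(excess_tc / excess, 0), 1), NA_real_),
    stringsAsFactors = FALSE
  )
  structure(
    list(s = s, per_gene = per_gene,
         genes_used = control$gene_id[sel][pos], formulation = formulation),
    class = "sensitivity_estimate"
  )
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat(sprintf("T>C detection sensitivity estimate: s = %.4f (%s formulation)\n",
              x$s, x$formulation))
  cat("genes used:", paste(x$genes_used, collapse = ", "), "\n")
  invisible(x)
}

#' Sensitivity-correct nascent proportions
#'
#' Divides raw proportions by the detection sensitivity `s` and clips to
#' [0, 1], compensating for nascent reads that carry no T>C conversion.
#'
#' @param props data.frame from [nascent_proportion()]
#' @param s `sensitivity_estimate` or a scalar in (0, 1]
#' @return `props` with a `corrected_proportion` column
#' @export
correct_proportion <- function(props, s) {
  if (inherits(s, "sensitivity_estimate")) s <- s$s
  stopifnot_scalar_number(s, "s")
  if (s <= 0 || s > 1) stop("`s` must be in (0, 1]", call. = FALSE)
  props$corrected_proportion <- pmin(props$raw_proportion / s, 1)
  props
}

#' Non-T>C (pre-existing RNA proxy) counts
#'
#' Subtracts T>C reads from total reads per gene; the remainder approximates
#' pre-existing RNA abundance (biased upward by undetected nascent reads,
#' which is what the sensitivity correction addresses).
#'
#' @param table tcount data.frame
#' @return data.frame (gene_id, length if present, NonTcReadCount)
#' @export
pre_existing_counts <- function(table) {
  non_tc <- table$ReadCount - table$TcReadCount
  if (any(non_tc < 0)) stop("TcReadCount exceeds ReadCount", call. = FALSE)
  out <- data.frame(gene_id = table$gene_id, stringsAsFactors = FALSE)
  if (!is.null(table$length)) out$length <- table$length
  out$NonTcReadCount <- non_tc
  out
}

#' Bulk and per-gene nascent proportion for a sample group
#'
#' The bulk scalar is the pooled proportion `sum(TcReadCount) /
#' sum(ReadCount)` over genes; the per-gene distribution (via
#' [nascent_proportion()]) supports box plots and rank tests.
#'
#' @param tables named list of tcount data.frames (one per sample)
#' @param min_support per-gene read support threshold
#' @return list with `bulk` (named numeric per sample) and `per_gene`
#'   (long data.frame: sample_id, gene_id, raw_proportion, read_support)
#' @export
bulk_nascent_proportion <- function(tables, min_support = 20L) {
  if (length(tables) < 1L) stop("need at least one sample", call. = FALSE)
  if (is.data.frame(tables)) tables <- list(sample = tables)
  bulk <- vapply(tables, function(tb) {
    tot <- sum(tb$ReadCount)
    if (tot == 0) 0 else sum(tb$TcReadCount) / tot
  }, numeric(1))
  per_gene <- do.call(rbind, lapply(names(tables), function(nm) {
    p <- nascent_proportion(tables[[nm]], min_support)
    cbind(sample_id = nm, p, stringsAsFactors = FALSE)
  }))
  list(bulk = bulk, per_gene = per_gene)
}

#' Sum tcount tables across replicates
#'
#' @param tables list of tcount data.frames sharing a gene universe
#' @return single tcount data.frame with summed count columns
#' @export
sum_tcount <- function(tables) {
  stopifnot(length(tables) >= 1L)
  base <- tables[[1]]
  for (tb in tables[-1]) {
    tb <- tb[match(base$gene_id, tb$gene_id), ]
    for (col in intersect(c("ReadCount", "TcReadCount", "coverageOnTs",
                            "conversionsOnTs"), names(base))) {
      base[[col]] <- base[[col]] + tb[[col]]
    }
  }
  if (all(c("conversionsOnTs", "coverageOnTs") %in% names(base))) {
    base$conversionRate <- ifelse(base$coverageOnTs > 0,
                                  base$conversionsOnTs / base$coverageOnTs,
                                  NA_real_)
  }
  if ("readsCPM" %in% names(base)) {
    base$readsCPM <- base$ReadCount * 1e6 / max(sum(base$ReadCount), 1)
  }
  base
}
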