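# Shared fixture builders and independent oracles for the test suite.

# Build an aligned_reads object by hand from parallel vectors.
make_reads <- function(gene_id, start, seq, qual = NULL, reference,
                       origin = NULL) {
  if (is.null(qual)) qual <- strrep("F", nchar(seq))
  df <- data.frame(
    read_id = sprintf("r%03d", seq_along(seq)),
    gene_id = gene_id, start = start, seq = seq, qual = qual,
    stringsAsFactors = FALSE
  )
  if (!is.null(origin)) df$origin <- origin
  aligned_reads(df, reference)
}

# Random read fixture over a few random references: random starts, lengths,
# substitutions and base qualities (some below typical thresholds).
random_read_fixture <- function(seed, n_reads, n_genes = 4) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  refs <- vapply(seq_len(n_genes), function(i) {
    paste(sample(bases, sample(60:120, 1), replace = TRUE), collapse = "")
  }, character(1))
  names(refs) <- sprintf("gene%02d", seq_len(n_genes))
  gene <- sample(names(refs), n_reads, replace = TRUE)
  len <- sample(20:50, n_reads, replace = TRUE)
  start <- vapply(seq_len(n_reads), function(i) {
    sample.int(nchar(refs[gene[i]]) - len[i] + 1L, 1L) - 1L
  }, integer(1))
  seqs <- quals <- character(n_reads)
  for (i in seq_len(n_reads)) {
    s <- strsplit(substr(refs[gene[i]], start[i] + 1L, start[i] + len[i]),
                  "")[[1]]
    nmut <- rpois(1, 1.5)
    if (nmut > 0) {
      pos <- sample.int(len[i], min(nmut, len[i]))
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
    }
    seqs[i] <- paste(s, collapse = "")
    q <- sample(c(40L, 37L, 30L, 20L, 10L), len[i], replace = TRUE,
                prob = c(0.4, 0.3, 0.1, 0.1, 0.1))
    quals[i] <- intToUtf8(q + 33L)
  }
  make_reads(gene, start, seqs, quals, refs)
}

# Brute-force tcount oracle: one explicit loop over reads and positions.
brute_tally <- function(reads, refs, min_bq, min_tc) {
  read_count <- tc_read <- cov_t <- conv_t <- stats::setNames(
    integer(length(refs)), names(refs))
  for (i in seq_len(nrow(reads))) {
    g <- reads$gene_id[i]
    rv <- strsplit(substr(refs[[g]], reads$start[i] + 1L,
                          reads$start[i] + nchar(reads$seq[i])), "")[[1]]
    sv <- strsplit(reads$seq[i], "")[[1]]
    qv <- utf8ToInt(reads$qual[i]) - 33L
    tc <- 0L; tcov <- 0L
    for (p in seq_along(rv)) {
      if (qv[p] < min_bq || sv[p] == "N") next
      if (rv[p] == "T") {
        tcov <- tcov + 1L
        if (sv[p] == "C") tc <- tc + 1L
      }
    }
    read_count[g] <- read_count[g] + 1L
    cov_t[g] <- cov_t[g] + tcov
    conv_t[g] <- conv_t[g] + tc
    if (tc >= min_tc) tc_read[g] <- tc_read[g] + 1L
  }
  data.frame(gene_id = names(refs), ReadCount = unname(read_count),
             TcReadCount = unname(tc_read), coverageOnTs = unname(cov_t),
             conversionsOnTs = unname(conv_t), stringsAsFactors = FALSE)
}

# Exact Mann-Whitney two-sided p by full enumeration over rank subsets
# (independent of the package's DP implementation).
mw_enum_p <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(N, m)
  U_all <- colSums(matrix(seq_len(N)[combos], nrow = m)) - m * (m + 1) / 2
  p_le <- mean(U_all <= U_obs)
  p_ge <- mean(U_all >= U_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small NB count matrix with planted condition effects (genes x 2*reps).
make_counts <- function(n_genes, mu, disp, reps = 3, lfc = 0, seed = 1) {
  set.seed(seed)
  lfc <- rep_len(lfc, n_genes)
  mu_mat <- cbind(matrix(mu, n_genes, reps),
                  matrix(mu * 2^lfc, n_genes, reps))
  cnt <- matrix(rnbinom(length(mu_mat), mu = as.vector(mu_mat),
                        size = 1 / max(disp, 1e-12)),
                nrow = n_genes)
  if (disp == 0) {
    cnt <- matrix(rpois(length(mu_mat), as.vector(mu_mat)), nrow = n_genes)
  }
  rownames(cnt) <- sprintf("g%04d", seq_len(n_genes))
  colnames(cnt) <- c(sprintf("a_rep%d", seq_len(reps)),
                     sprintf("b_rep%d", seq_len(reps)))
  cnt
}
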