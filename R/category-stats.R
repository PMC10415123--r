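# Gene-category statistics: Mann-Whitney U with exact small-sample
# enumeration, ECDF shift tests for gene sets, nascent-proportion group
# comparisons, ORF-length stratification, and hypergeometric
# over-representation analysis.

# Exact null distribution of the Mann-Whitney U statistic (no ties):
# P(U = u) for u = 0..m*n, via the subset-sum counting recurrence.
mw_exact_dist <- function(m, n) {
  N <- m + n
  maxw <- sum((N - m + 1):N)
  minw <- sum(1:m)
  # ways[w+1] = number of m-subsets of 1..N with rank sum w
  ways <- numeric(maxw + 1)
  ways[1] <- 1 # empty sum = 0 before adding elements
  # DP over elements 1..N, tracking subsets of each size
  tab <- matrix(0, nrow = m + 1, ncol = maxw + 1)
  tab[1, 1] <- 1
  for (el in seq_len(N)) {
    for (k in rev(seq_len(m))) {
      shifted <- c(rep(0, el), tab[k, seq_len(maxw + 1 - el)])
      tab[k + 1, ] <- tab[k + 1, ] + shifted
    }
  }
  counts <- tab[m + 1, (minw:maxw) + 1]
  u <- (minw:maxw) - minw
  stats::setNames(counts / choose(N, m), u)
}

#' Mann-Whitney U test
#'
#' U counts, over all pairs, how often an `x` value exceeds a `y` value
#' (ties count one half, via midranks). The p-value is exact (full
#' enumeration of the null distribution) when `length(x) + length(y) <= 16`
#' and there are no ties, otherwise a normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param x,y numeric samples (non-empty)
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#' @param method `"auto"` (exact when feasible), `"exact"` (requires no
#'   ties) or `"normal"` (force the approximation)
#' @return list with `U` (for `x` against `y`), `p_value` and `method`
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater"),
                           method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (method == "exact" && has_ties) {
    stop("exact p-value is not defined with ties", call. = FALSE)
  }
  use_exact <- method == "exact" ||
    (method == "auto" && !has_ties && N <= 16L)

  if (use_exact) {
    dist <- mw_exact_dist(m, n)
    u_vals <- as.numeric(names(dist))
    p_le <- sum(dist[u_vals <= U])
    p_ge <- sum(dist[u_vals >= U])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le,
                greater = p_ge)
    method <- "exact"
  } else {
    mu <- m * n / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(m * n / 12 * ((N + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      cc <- 0.5
      p <- switch(alternative,
        two.sided = {
          z <- (U - mu - sign(U - mu) * cc) / sigma
          if (U == mu) 1 else min(1, 2 * stats::pnorm(-abs(z)))
        },
        less = stats::pnorm((U - mu + cc) / sigma),
        greater = stats::pnorm(-(U - mu - cc) / sigma))
    }
    method <- "normal_approx"
  }
  list(U = U, p_value = p, method = method)
}

#' ECDF shift test of a gene set against the background
#'
#' Compares the log2 fold changes of a gene set against all other genes in
#' the universe (the background excludes set members to avoid
#' self-comparison) with a Mann-Whitney U test, and returns both empirical
#' CDFs for plotting.
#'
#' @param members character vector of set member gene ids
#' @param lfc_by_gene named numeric vector of per-gene log2 fold changes
#'   (the analysis universe)
#' @param min_set minimum number of set members present in the universe
#'   (default 5); smaller sets are skipped with a warning
#' @param set_name label carried into the result
#' @return list of class `shift_test` with n_set, n_background, U, p_value,
#'   median_shift, and `ecdf_set` / `ecdf_background` data.frames; NULL if
#'   skipped
#' @export
ecdf_shift <- function(members, lfc_by_gene, min_set = 5L, set_name = "set") {
  if (is.null(names(lfc_by_gene))) {
    stop("`lfc_by_gene` must be named by gene id", call. = FALSE)
  }
  lfc_by_gene <- lfc_by_gene[!is.na(lfc_by_gene)]
  in_set <- names(lfc_by_gene) %in% members
  if (sum(in_set) < min_set) {
    warning(sprintf("gene set '%s': %d members in universe (< %d), skipped",
                    set_name, sum(in_set), min_set))
    return(NULL)
  }
  x <- lfc_by_gene[in_set]
  y <- lfc_by_gene[!in_set]
  mw <- mann_whitney_u(x, y)
  make_ecdf <- function(v) {
    v <- sort(v)
    data.frame(value = v, cumulative = seq_along(v) / length(v))
  }
  structure(
    list(set_name = set_name, n_set = length(x), n_background = length(y),
         U = mw$U, p_value = mw$p_value,
         median_shift = stats::median(x) - stats::median(y),
         ecdf_set = make_ecdf(x), ecdf_background = make_ecdf(y)),
    class = "shift_test"
  )
}

#' Pairwise comparison of nascent proportions across groups
#'
#' Runs a Mann-Whitney U test on per-gene proportions for every pair of
#' groups and reports box-plot summaries (median and quartiles) per group.
#' Groups with fewer than `min_group` genes are excluded.
#'
#' @param values numeric vector of per-gene proportions
#' @param groups group label per value (e.g. assay x condition)
#' @param min_group minimum group size (default 5)
#' @return list with `summary` (per-group n/median/q1/q3) and `pairs`
#'   (per-pair U, p_value)
#' @export
compare_nascent_proportions <- function(values, groups, min_group = 5L) {
  keep <- !is.na(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  sizes <- table(groups)
  use <- names(sizes)[sizes >= min_group]
  if (length(use) < 2L) stop("need >= 2 groups of sufficient size", call. = FALSE)
  summary <- do.call(rbind, lapply(use, function(g) {
    v <- values[groups == g]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(v), q1 = q[1], median = q[2], q3 = q[3],
               stringsAsFactors = FALSE)
  }))
  combos <- utils::combn(use, 2L)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    g1 <- combos[1, i]; g2 <- combos[2, i]
    mw <- mann_whitney_u(values[groups == g1], values[groups == g2])
    data.frame(group1 = g1, group2 = g2, U = mw$U, p_value = mw$p_value,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, pairs = pairs)
}

#' ORF-length-stratified comparison of nascent proportions
#'
#' Bins genes by ORF length (default: quartiles of the universe), compares
#' translatome vs transcriptome proportions within each bin, and summarizes
#' the length dependence as the Spearman correlation between bin midpoints
#' and the per-bin median proportion difference (translatome minus
#' transcriptome).
#'
#' @param props data.frame with columns gene_id, group (exactly two levels;
#'   the second is tested against the first) and proportion
#' @param orf_lengths named numeric vector of ORF lengths by gene id
#' @param bin_edges numeric bin edges covering the observed lengths;
#'   default quartile edges
#' @param reference_group group treated as baseline (default first level)
#' @return list with `per_bin` data.frame (bin, midpoint, n, median_diff, U,
#'   p_value) and `trend_spearman` (NA with < 2 usable bins)
#' @export
stratify_by_orf_length <- function(props, orf_lengths, bin_edges = NULL,
                                   reference_group = NULL) {
  stopifnot(all(c("gene_id", "group", "proportion") %in% names(props)))
  groups <- unique(props$group)
  if (length(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  ref <- reference_group %||% groups[1]
  other <- setdiff(groups, ref)
  len <- orf_lengths[props$gene_id]
  if (anyNA(len)) stop("missing ORF length for some genes", call. = FALSE)
  if (is.null(bin_edges)) {
    bin_edges <- unique(stats::quantile(len, c(0, 0.25, 0.5, 0.75, 1),
                                        names = FALSE))
  }
  if (min(len) < bin_edges[1] || max(len) > bin_edges[length(bin_edges)]) {
    stop("bin edges must cover observed ORF lengths", call. = FALSE)
  }
  bins <- cut(len, bin_edges, include.lowest = TRUE)
  mids <- (bin_edges[-length(bin_edges)] + bin_edges[-1]) / 2

  rows <- lapply(seq_along(levels(bins)), function(bi) {
    sel <- bins == levels(bins)[bi] & !is.na(props$proportion)
    v_ref <- props$proportion[sel & props$group == ref]
    v_oth <- props$proportion[sel & props$group == other]
    if (length(v_ref) < 2L || length(v_oth) < 2L) {
      return(data.frame(bin = levels(bins)[bi], midpoint = mids[bi],
                        n_ref = length(v_ref), n_other = length(v_oth),
                        median_diff = NA_real_, U = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    mw <- mann_whitney_u(v_oth, v_ref)
    data.frame(bin = levels(bins)[bi], midpoint = mids[bi],
               n_ref = length(v_ref), n_other = length(v_oth),
               median_diff = stats::median(v_oth) - stats::median(v_ref),
               U = mw$U, p_value = mw$p_value, stringsAsFactors = FALSE)
  })
  per_bin <- do.call(rbind, rows)
  usable <- !is.na(per_bin$median_diff)
  trend <- if (sum(usable) >= 2L) {
    stats::cor(per_bin$midpoint[usable], per_bin$median_diff[usable],
               method = "spearman")
  } else NA_real_
  list(per_bin = per_bin, trend_spearman = trend)
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation set, tests whether the query gene list overlaps the
#' set more than expected by chance within the universe: the p-value is the
#' hypergeometric upper tail P(X >= k) and the enrichment ratio is
#' (k / |query|) / (|set in universe| / |universe|). BH adjustment across
#' sets.
#'
#' @param query character vector of genes of interest (must lie in universe)
#' @param universe character vector: the analysis universe
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()])
#' @return data.frame: set, n_set, overlap, expected, enrichment_ratio,
#'   p_value, p_adj
#' @export
hypergeometric_ora <- function(query, universe, gene_sets) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop("query genes must be a subset of the universe", call. = FALSE)
  }
  rows <- lapply(names(gene_sets), function(nm) {
    set_u <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(query, set_u))
    m <- length(set_u)
    expected <- length(query) * m / length(universe)
    ratio <- if (m > 0 && length(query) > 0) {
      (k / length(query)) / (m / length(universe))
    } else NA_real_
    p <- if (m > 0) {
      stats::phyper(k - 1, m, length(universe) - m, length(query),
                    lower.tail = FALSE)
    } else NA_real_
    data.frame(set = nm, n_set = m, overlap = k, expected = expected,
               enrichment_ratio = ratio, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_value)
  out
}
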