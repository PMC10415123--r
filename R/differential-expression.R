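# Negative-binomial differential expression: median-of-ratios size factors,
# cross-assay normalization (T>C counts modelled with total-read factors),
# moderated dispersion estimation, per-gene NB-GLM Wald tests, BH adjustment
# and DEG calling.

#' Median-of-ratios size factors
#'
#' Per gene, a geometric-mean pseudo-reference over samples; each sample's
#' factor is the median over genes of count / reference, rescaled so the
#' factors have geometric mean 1. Genes with a zero in any sample are
#' excluded from the reference; if no gene is positive everywhere, the
#' reference falls back to geometric means over positive entries only (with
#' a warning).
#'
#' @param counts genes x samples numeric matrix (non-negative)
#' @return positive numeric vector, one factor per sample
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (ncol(counts) == 1L) return(stats::setNames(1, colnames(counts)))
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    lg <- log(counts[all_pos, , drop = FALSE])
    ref <- rowMeans(lg)
    ratios <- lg - ref
  } else {
    warning("no gene has positive counts in every sample; ",
            "using positive-subset geometric means")
    some_pos <- rowSums(counts > 0) > 0
    cl <- counts[some_pos, , drop = FALSE]
    lg <- log(cl)
    lg[!is.finite(lg)] <- NA
    ref <- rowMeans(lg, na.rm = TRUE)
    ratios <- lg - ref
  }
  sf <- apply(ratios, 2L, stats::median, na.rm = TRUE)
  sf <- exp(sf - mean(sf))
  stats::setNames(sf, colnames(counts))
}

#' Attach total-read size factors to a T>C (or non-T>C) count matrix
#'
#' T>C counts must be normalized with factors computed from the matching
#' total-read counts, never recomputed from the T>C counts themselves: a
#' global change in labeled fraction at constant totals would otherwise be
#' absorbed into the normalization and vanish from the fold changes.
#'
#' @param counts genes x samples matrix of T>C or non-T>C counts
#' @param factors per-sample size factors from the total-read matrix
#' @return the normalized matrix (counts / factor per column) with the
#'   factors retained in attribute `size_factors`
#' @export
apply_cross_normalization <- function(counts, factors) {
  counts <- as.matrix(counts)
  if (length(factors) != ncol(counts)) {
    stop("need one size factor per sample", call. = FALSE)
  }
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("size factors must be positive and finite", call. = FALSE)
  }
  if (!is.null(colnames(counts)) && !is.null(names(factors))) {
    if (!all(colnames(counts) %in% names(factors))) {
      stop("missing size factor for some samples", call. = FALSE)
    }
    factors <- factors[colnames(counts)]
  }
  out <- sweep(counts, 2L, factors, "/")
  attr(out, "size_factors") <- factors
  out
}

#' Moderated per-gene NB dispersion
#'
#' Method-of-moments dispersion on size-factor-normalized counts, using
#' within-group residual variance so condition effects do not inflate the
#' estimate, then shrunk toward a fitted mean-dispersion trend
#' `a / mu + b` (a simplified stand-in for DESeq2's empirical-Bayes
#' machinery). With one replicate per group a global estimate is used for
#' every gene, with a warning.
#'
#' @param counts genes x samples matrix
#' @param factors per-sample size factors
#' @param groups factor of experimental groups (condition, or
#'   condition x assay cells for joint models)
#' @param prior_df weight (pseudo-degrees-of-freedom) of the trend in the
#'   moderated average; larger values shrink harder
#' @param floor minimum dispersion
#' @return numeric vector of per-gene dispersions
#' @export
estimate_dispersion <- function(counts, factors, groups, prior_df = 10,
                                floor = 1e-8) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  norm <- sweep(counts, 2L, factors, "/")
  n <- ncol(norm)
  g <- nlevels(groups)
  df <- n - g
  mu <- rowMeans(norm)
  xim <- mean(1 / factors) # normalization cost of the Poisson term
  if (df < 1L) {
    warning("single replicate per group: using a global dispersion")
    v <- apply(norm, 1L, stats::var)
    d <- (v - xim * mu) / mu^2
    d_global <- max(stats::median(d[is.finite(d) & mu > 0], na.rm = TRUE), floor)
    return(rep(d_global, nrow(counts)))
  }
  ss <- 0
  for (lev in levels(groups)) {
    cols <- which(groups == lev)
    sub <- norm[, cols, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  v <- ss / df
  d_mom <- ifelse(mu > 0, (v - xim * mu) / mu^2, NA_real_)

  # mean-dispersion trend a/mu + b; plain OLS keeps the intercept unbiased
  # for the right-skewed MoM estimates (trimming would bias it down)
  use <- is.finite(d_mom) & mu > 1
  trend <- rep(floor, nrow(counts))
  a <- 0; b <- floor
  if (sum(use) >= 10L) {
    fit <- stats::lm(d_mom[use] ~ I(1 / mu[use]))
    a <- max(unname(stats::coef(fit)[2]), 0)
    b <- max(unname(stats::coef(fit)[1]), floor)
  } else if (sum(use) > 0L) {
    b <- max(stats::median(d_mom[use]), floor)
  }
  trend <- a / pmax(mu, 1e-8) + b

  w <- df / (df + prior_df)
  out <- w * pmax(d_mom, floor) + (1 - w) * trend
  out[!is.finite(out)] <- trend[!is.finite(out)]
  pmax(out, floor)
}

# One-gene NB GLM fit by iteratively reweighted least squares with a fixed
# dispersion and log size-factor offsets. Returns coefficients, their
# covariance (inverse observed Fisher information) and a convergence flag.
nb_glm_fit <- function(y, X, offset, dispersion, max_iter = 80L, tol = 1e-10) {
  phi <- dispersion
  # initialize from regularized log counts
  z0 <- log((y + 0.5) / exp(offset))
  beta <- tryCatch(stats::lm.fit(X, z0)$coefficients,
                   error = function(e) rep(0, ncol(X)))
  beta[!is.finite(beta)] <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- offset + drop(X %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    xtwx <- crossprod(X, X * w)
    step <- tryCatch(solve(xtwx, crossprod(X, w * z)),
                     error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- drop(step)
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      converged <- TRUE
      break
    }
    beta <- new_beta
  }
  eta <- offset + drop(X %*% beta)
  eta <- pmin(pmax(eta, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + phi * mu)
  xtwx <- crossprod(X, X * w)
  vcov <- tryCatch(solve(xtwx), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  list(beta = beta, vcov = vcov, mu = mu, converged = converged)
}

#' Per-gene negative-binomial Wald test for a two-condition design
#'
#' Fits, per gene, an NB GLM with log link, intercept plus condition
#' coefficient, and log size-factor offsets; the condition coefficient
#' divided by log(2) is the reported log2 fold change (second vs first
#' condition level), with its standard error from the observed Fisher
#' information and a two-sided Wald p-value. Genes whose mean normalized
#' count falls below `min_filter_mean` are excluded from BH adjustment
#' (independent filtering); genes with an all-zero condition are fit with a
#' 0.5-count ridge and flagged.
#'
#' @param counts genes x samples matrix
#' @param condition factor/character with exactly two levels; the first
#'   level is the reference
#' @param factors per-sample size factors (e.g. total-read factors for T>C
#'   counts, see [apply_cross_normalization()])
#' @param dispersions per-gene dispersions; estimated with
#'   [estimate_dispersion()] when NULL
#' @param min_filter_mean independent-filtering threshold on mean normalized
#'   count (default 5)
#' @return data.frame: gene_id, base_mean, log2_fc, lfc_se, wald_stat,
#'   p_value, p_adj, status ("ok", "ridged", "not_converged", "low_count")
#' @export
nb_wald_test <- function(counts, condition, factors, dispersions = NULL,
                         min_filter_mean = 5) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L) {
    stop("`condition` must have exactly two levels", call. = FALSE)
  }
  if (length(condition) != ncol(counts)) {
    stop("one condition label per sample required", call. = FALSE)
  }
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(counts, factors, condition)
  }
  X <- cbind(1, as.numeric(condition == levels(condition)[2]))
  offset <- log(factors)
  norm <- sweep(counts, 2L, factors, "/")
  base_mean <- rowMeans(norm)

  n_genes <- nrow(counts)
  log2_fc <- lfc_se <- rep(NA_real_, n_genes)
  status <- rep("ok", n_genes)
  for (gidx in seq_len(n_genes)) {
    y <- counts[gidx, ]
    ridged <- FALSE
    for (lev in levels(condition)) {
      if (all(y[condition == lev] == 0)) ridged <- TRUE
    }
    yfit <- if (ridged) y + 0.5 else y
    fit <- nb_glm_fit(yfit, X, offset, dispersions[gidx])
    log2_fc[gidx] <- fit$beta[2] / log(2)
    lfc_se[gidx] <- sqrt(fit$vcov[2, 2]) / log(2)
    if (ridged) status[gidx] <- "ridged"
    if (!fit$converged) status[gidx] <- "not_converged"
  }
  wald <- log2_fc / lfc_se
  p <- 2 * stats::pnorm(-abs(wald))

  low <- base_mean < min_filter_mean
  status[low] <- "low_count"
  p_adj <- rep(NA_real_, n_genes)
  p_adj[!low] <- bh_adjust(p[!low])

  data.frame(
    gene_id = rownames(counts) %||% sprintf("g%d", seq_len(n_genes)),
    base_mean = base_mean, log2_fc = log2_fc, lfc_se = lfc_se,
    wald_stat = wald, p_value = p, p_adj = p_adj, status = status,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed)
#' @return BH step-up adjusted p-values
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is up-regulated when `p_adj < alpha` and `log2_fc > lfc_threshold`,
#' down-regulated when `p_adj < alpha` and `log2_fc < -lfc_threshold`.
#'
#' @param results data.frame from [nb_wald_test()]
#' @param alpha adjusted-p cutoff (default 0.05)
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1.5)
#' @return list with character vectors `up` and `down`
#' @export
call_degs <- function(results, alpha = 0.05, lfc_threshold = 1.5) {
  sig <- !is.na(results$p_adj) & results$p_adj < alpha
  list(
    up = results$gene_id[sig & results$log2_fc > lfc_threshold],
    down = results$gene_id[sig & results$log2_fc < -lfc_threshold]
  )
}

#' Counts per million
#'
#' @param counts genes x samples matrix
#' @param library_sizes per-sample library sizes (default column sums);
#'   size-factor-normalized CPMs can be obtained by passing
#'   `colSums(counts) * factors / mean(factors)` or similar
#' @return numeric matrix; columns sum to 1e6 when library sizes are the
#'   column sums
#' @export
cpm <- function(counts, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(library_sizes <= 0)) stop("library sizes must be positive", call. = FALSE)
  sweep(counts, 2L, library_sizes, "/") * 1e6
}
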