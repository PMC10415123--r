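# deltaTE analysis: joint NB-GLM of paired transcriptome (RNA) and
# translatome (TRAP) counts with a condition x assay interaction, and
# classification of genes into the four regulation modes.

#' Fit the deltaTE interaction model
#'
#' Per gene, an NB GLM over the combined RNA and TRAP samples with terms
#' `condition + assay + condition:assay` and total-read size-factor offsets.
#' The interaction coefficient is the translation-efficiency change
#' (deltaTE); the within-RNA condition contrast is deltaRNA and the
#' within-TRAP contrast deltaTRAP = deltaRNA + deltaTE. Dispersion is
#' estimated jointly across assays per gene (shared dispersion keeps the
#' interaction Wald test calibrated). Each effect gets a two-sided Wald
#' p-value, BH-adjusted across genes per effect.
#'
#' @param rna,trap genes x samples count matrices over the same gene
#'   universe and with the same condition/replicate layout
#' @param condition_rna,condition_trap two-level condition labels for the
#'   columns of `rna` and `trap` (first level = reference)
#' @param factors_rna,factors_trap per-sample size factors, computed from
#'   total-read counts (also when the input matrices hold T>C counts)
#' @param dispersions optional per-gene dispersions
#' @param min_filter_mean independent-filtering threshold on mean normalized
#'   count
#' @return data.frame of class `delta_te_result`: gene_id, base_mean,
#'   lfc_rna, lfc_trap, lfc_te, their SEs, p_adj_rna, p_adj_trap, p_adj_te,
#'   status
#' @export
fit_interaction_model <- function(rna, trap, condition_rna, condition_trap,
                                  factors_rna, factors_trap,
                                  dispersions = NULL, min_filter_mean = 5) {
  rna <- as.matrix(rna); trap <- as.matrix(trap)
  if (!identical(rownames(rna), rownames(trap))) {
    stop("`rna` and `trap` must share the same gene universe/order", call. = FALSE)
  }
  condition_rna <- as.factor(condition_rna)
  condition_trap <- factor(condition_trap, levels = levels(condition_rna))
  if (nlevels(condition_rna) != 2L || any(is.na(condition_trap))) {
    stop("conditions must have the same two levels in both assays", call. = FALSE)
  }
  if (length(condition_rna) != ncol(rna) ||
      length(condition_trap) != ncol(trap)) {
    stop("one condition label per sample required", call. = FALSE)
  }
  tab_r <- table(condition_rna); tab_t <- table(condition_trap)
  if (any(tab_r < 2L) || any(tab_t < 2L)) {
    stop("need >= 2 replicates per condition per assay", call. = FALSE)
  }

  counts <- cbind(rna, trap)
  cond <- c(as.character(condition_rna), as.character(condition_trap))
  cond <- factor(cond, levels = levels(condition_rna))
  assay <- factor(rep(c("rna", "trap"), c(ncol(rna), ncol(trap))),
                  levels = c("rna", "trap"))
  factors <- c(factors_rna, factors_trap)
  x_c <- as.numeric(cond == levels(cond)[2])
  x_a <- as.numeric(assay == "trap")
  X <- cbind(intercept = 1, cond = x_c, assay = x_a, inter = x_c * x_a)
  offset <- log(factors)

  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(counts, factors,
                                       interaction(cond, assay, drop = TRUE))
  }
  norm <- sweep(counts, 2L, factors, "/")
  base_mean <- rowMeans(norm)

  n_genes <- nrow(counts)
  eff <- matrix(NA_real_, n_genes, 3,
                dimnames = list(NULL, c("rna", "trap", "te")))
  se <- eff
  status <- rep("ok", n_genes)
  cells <- interaction(cond, assay, drop = TRUE)
  for (gidx in seq_len(n_genes)) {
    y <- counts[gidx, ]
    ridged <- any(vapply(levels(cells),
                         function(lv) all(y[cells == lv] == 0), logical(1)))
    yfit <- if (ridged) y + 0.5 else y
    fit <- nb_glm_fit(yfit, X, offset, dispersions[gidx])
    b <- fit$beta; V <- fit$vcov
    eff[gidx, "rna"] <- b[2]
    eff[gidx, "te"] <- b[4]
    eff[gidx, "trap"] <- b[2] + b[4]
    se[gidx, "rna"] <- sqrt(V[2, 2])
    se[gidx, "te"] <- sqrt(V[4, 4])
    se[gidx, "trap"] <- sqrt(V[2, 2] + V[4, 4] + 2 * V[2, 4])
    if (ridged) status[gidx] <- "ridged"
    if (!fit$converged) status[gidx] <- "not_converged"
  }
  eff <- eff / log(2)
  se <- se / log(2)
  p <- 2 * stats::pnorm(-abs(eff / se))
  low <- base_mean < min_filter_mean
  status[low] <- "low_count"
  padj <- apply(p, 2L, function(col) {
    out <- rep(NA_real_, length(col))
    out[!low] <- bh_adjust(col[!low])
    out
  })

  out <- data.frame(
    gene_id = rownames(counts) %||% sprintf("g%d", seq_len(n_genes)),
    base_mean = base_mean,
    lfc_rna = eff[, "rna"], lfc_trap = eff[, "trap"], lfc_te = eff[, "te"],
    se_rna = se[, "rna"], se_trap = se[, "trap"], se_te = se[, "te"],
    p_adj_rna = padj[, "rna"], p_adj_trap = padj[, "trap"],
    p_adj_te = padj[, "te"],
    status = status, stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("delta_te_result", "data.frame")
  out
}

#' Classify genes into deltaTE regulation modes
#'
#' With the significance predicate `S(effect) = p_adj < alpha AND |lfc| >
#' lfc_threshold`:
#' \describe{
#'   \item{intensified}{S(deltaTE) and S(deltaRNA), same sign}
#'   \item{buffered}{S(deltaTE) and S(deltaRNA), opposite signs}
#'   \item{exclusive}{S(deltaTE) and not S(deltaRNA)}
#'   \item{forwarded}{S(deltaRNA) and S(deltaTRAP) and not S(deltaTE),
#'     same sign of deltaRNA and deltaTRAP}
#'   \item{undetermined}{anything else}
#' }
#' Categories are mutually exclusive and exhaustive. The default
#' `lfc_threshold = 0` gates on significance only.
#'
#' @param result `delta_te_result` (or compatible data.frame)
#' @param alpha FDR cutoff (default 0.05)
#' @param lfc_threshold absolute log2 effect cutoff (default 0)
#' @param require_same_sign_forwarded require deltaRNA and deltaTRAP to share
#'   a sign for the forwarded call (default TRUE)
#' @return `result` with a `category` column
#' @export
classify_regulation <- function(result, alpha = 0.05, lfc_threshold = 0,
                                require_same_sign_forwarded = TRUE) {
  need <- c("lfc_rna", "lfc_trap", "lfc_te",
            "p_adj_rna", "p_adj_trap", "p_adj_te")
  miss <- setdiff(need, names(result))
  if (length(miss) > 0) {
    stop("missing effect columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  S <- function(p, lfc) !is.na(p) & p < alpha & abs(lfc) > lfc_threshold
  s_rna <- S(result$p_adj_rna, result$lfc_rna)
  s_trap <- S(result$p_adj_trap, result$lfc_trap)
  s_te <- S(result$p_adj_te, result$lfc_te)
  same <- sign(result$lfc_te) == sign(result$lfc_rna)
  fwd_sign <- if (require_same_sign_forwarded) {
    sign(result$lfc_rna) == sign(result$lfc_trap)
  } else TRUE

  category <- rep("undetermined", nrow(result))
  category[s_te & s_rna & same] <- "intensified"
  category[s_te & s_rna & !same] <- "buffered"
  category[s_te & !s_rna] <- "exclusive"
  category[!s_te & s_rna & s_trap & fwd_sign] <- "forwarded"
  result$category <- category
  result
}

#' Confusion matrix of planted vs called regulation modes
#'
#' Validation harness for simulated data: compares the categories called by
#' [classify_regulation()] against the modes planted in the transcript
#' models ("null" is expected to be called "undetermined").
#'
#' @param results classified `delta_te_result`
#' @param models `transcript_models` with a `regulation_mode` column
#' @return list with `confusion` (planted x called table), `recall` and
#'   `precision` per mode
#' @export
category_recovery_report <- function(results, models) {
  m <- match(results$gene_id, models$gene_id)
  if (anyNA(m)) stop("results contain genes absent from models", call. = FALSE)
  planted <- models$regulation_mode[m]
  planted[planted == "null"] <- "undetermined"
  lev <- c("forwarded", "exclusive", "intensified", "buffered", "undetermined")
  confusion <- table(planted = factor(planted, lev),
                     called = factor(results$category, lev))
  recall <- diag(confusion) / pmax(rowSums(confusion), 1)
  precision <- diag(confusion) / pmax(colSums(confusion), 1)
  list(confusion = confusion, recall = recall, precision = precision)
}
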