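# Synthetic-data generator: ground-truth transcript models, tcount-style
# count tables and read-level data with the statistical structure a combined
# metabolic-labeling (4sU/SLAM-seq) + TRAP-seq experiment produces.

#' Steady-state labeled (nascent) fraction under first-order turnover
#'
#' For a transcript degraded with first-order rate constant `k_deg` and a
#' labeling pulse of duration `t`, the fraction of the steady-state pool that
#' was synthesized during the pulse is `1 - exp(-k_deg * t)`.
#'
#' @param k_deg degradation rate constant (1/h), >= 0
#' @param t labeling time (h), >= 0
#' @return nascent fraction in [0, 1]; vectorized over both arguments
#' @export
#' @examples
#' nascent_fraction(log(2) / 3, 3) # half-life equal to the pulse: 0.5
nascent_fraction <- function(k_deg, t) {
  if (any(!is.finite(k_deg)) || any(k_deg < 0)) {
    stop("`k_deg` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  1 - exp(-k_deg * t)
}

#' Simulation design for a labeling + TRAP count experiment
#'
#' Bundles the experimental layout and noise model parameters used by
#' [simulate_counts()] and [simulate_reads()].
#'
#' Defaults mirror the experiment the package emulates: two conditions
#' (vehicle control vs ER-stress induction), three replicates, a cytosolic
#' RNA assay plus a ribosome-IP (TRAP) assay, a 3 h 4sU pulse, a per-uridine
#' T>C conversion probability of 0.024 in labeled molecules (the observed
#' median T>C conversion scale of 2.3-2.7 percent), a background conversion
#' probability of 0.001 per eligible base for every substitution type
#' (matching the observed "< 0.2 percent" scale of non-T>C conversions), and
#' negative-binomial dispersion 0.05 typical of bulk RNA-seq replicates.
#'
#' @param conditions character vector of condition labels; the first is the
#'   reference (unstressed) condition
#' @param n_replicates replicates per condition per assay
#' @param assays subset of `c("rna", "ptrap", "l10a")`; assays other than
#'   "rna" are treated as translatome (ribosome-IP) assays
#' @param labeling_time 4sU pulse duration in hours
#' @param library_size expected total reads per sample
#' @param dispersion negative-binomial dispersion (0 gives Poisson counts)
#' @param p_conv per-uridine T>C conversion probability in labeled molecules
#' @param p_err per-base background substitution probability (each of the 12
#'   substitution types independently)
#' @param kinetics `"steady_state"` treats each condition as at its own
#'   kinetic steady state during the pulse; `"step"` applies condition
#'   parameters as a step change at the start of the pulse and integrates
#'   the birth-death dynamics over the pulse
#' @param seed integer seed
#' @return object of class `sim_design` (a list)
#' @export
sim_design <- function(conditions = c("control", "stress"),
                       n_replicates = 3,
                       assays = c("rna", "ptrap"),
                       labeling_time = 3,
                       library_size = 1e6,
                       dispersion = 0.05,
                       p_conv = 0.024,
                       p_err = 0.001,
                       kinetics = c("steady_state", "step"),
                       seed = 1L) {
  kinetics <- match.arg(kinetics)
  if (length(conditions) < 1L || anyDuplicated(conditions)) {
    stop("`conditions` must be a non-empty vector of unique labels", call. = FALSE)
  }
  assays <- match.arg(assays, c("rna", "ptrap", "l10a"), several.ok = TRUE)
  stopifnot_scalar_number(n_replicates, "n_replicates", lower = 1)
  stopifnot_scalar_number(labeling_time, "labeling_time")
  if (labeling_time <= 0) stop("`labeling_time` must be > 0", call. = FALSE)
  stopifnot_scalar_number(library_size, "library_size")
  if (library_size <= 0) stop("`library_size` must be > 0", call. = FALSE)
  stopifnot_scalar_number(dispersion, "dispersion", lower = 0)
  stopifnot_scalar_number(p_conv, "p_conv", lower = 0, upper = 1)
  stopifnot_scalar_number(p_err, "p_err", lower = 0, upper = 1)
  if (p_err >= p_conv && p_conv > 0) {
    stop("`p_err` must be < `p_conv` (background below signal)", call. = FALSE)
  }
  structure(
    list(conditions = conditions, n_replicates = as.integer(n_replicates),
         assays = assays, labeling_time = labeling_time,
         library_size = library_size, dispersion = dispersion,
         p_conv = p_conv, p_err = p_err, kinetics = kinetics,
         seed = as.integer(seed)),
    class = "sim_design"
  )
}

#' Generate ground-truth transcript models
#'
#' Draws a population of transcripts with 3'UTR length and uridine content,
#' ORF length, first-order synthesis/degradation kinetics and a per-condition
#' translation efficiency. Half-lives are log-normal around 4 h (typical of
#' mammalian mRNA), synthesis rates log-normal so that steady-state
#' abundances span ~3 orders of magnitude, translation efficiencies
#' log-normal with ~30 percent spread. Both conditions start identical; use
#' [assign_regulation()] to plant condition effects.
#'
#' `n_uridines_per_read` is the number of reference-T positions covered by
#' one trimmed 3'-anchored read, drawn Binomial(read_length, u_content).
#'
#' @param n_genes number of genes
#' @param utr_length_range integer range (nt) for 3'UTR lengths
#' @param u_content_range range of per-gene uridine (reference T) content
#' @param orf_length_range integer range (nt) for ORF lengths
#' @param read_length trimmed read length (nt) used to size uridine coverage
#' @param conditions condition labels (first = reference)
#' @param seed integer seed; output is deterministic given the seed
#' @return data.frame of class `transcript_models`, one row per gene
#' @export
generate_transcriptome <- function(n_genes,
                                   utr_length_range = c(200L, 2000L),
                                   u_content_range = c(0.15, 0.35),
                                   orf_length_range = c(300L, 6000L),
                                   read_length = 100L,
                                   conditions = c("control", "stress"),
                                   seed = 1L) {
  stopifnot_scalar_number(n_genes, "n_genes", lower = 1)
  check_range <- function(r, name, lower = 0) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] < lower) {
      stop(sprintf("`%s` must be a valid non-empty range", name), call. = FALSE)
    }
  }
  check_range(utr_length_range, "utr_length_range", lower = 1)
  check_range(u_content_range, "u_content_range")
  if (u_content_range[2] > 1) stop("`u_content_range` must lie in [0, 1]", call. = FALSE)
  check_range(orf_length_range, "orf_length_range", lower = 1)
  n_genes <- as.integer(n_genes)

  with_seed(seed, {
    utr_length <- if (utr_length_range[1] == utr_length_range[2]) {
      rep(as.integer(utr_length_range[1]), n_genes)
    } else {
      sample(seq.int(utr_length_range[1], utr_length_range[2]), n_genes,
             replace = TRUE)
    }
    u_content <- stats::runif(n_genes, u_content_range[1], u_content_range[2])
    n_uridines <- stats::rbinom(n_genes, size = as.integer(read_length),
                                prob = u_content)
    orf_length <- if (orf_length_range[1] == orf_length_range[2]) {
      rep(as.integer(orf_length_range[1]), n_genes)
    } else {
      sample(seq.int(orf_length_range[1], orf_length_range[2]), n_genes,
             replace = TRUE)
    }
    half_life <- stats::rlnorm(n_genes, meanlog = log(4), sdlog = 0.5)
    k_deg <- log(2) / half_life
    # abundance spread ~ lognormal(sd 1.5 natural log) around 10 molecules
    abundance <- stats::rlnorm(n_genes, meanlog = log(10), sdlog = 1.5)
    k_syn <- abundance * k_deg
    te <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 0.3)

    models <- data.frame(
      gene_id = sprintf("G%05d", seq_len(n_genes)),
      utr_length = utr_length,
      u_content = u_content,
      n_uridines_per_read = n_uridines,
      orf_length = orf_length,
      k_deg = k_deg,
      loading_lag = 1,
      regulation_mode = "null",
      effect_rna_log2 = 0,
      effect_te_log2 = 0,
      stringsAsFactors = FALSE
    )
    for (cond in conditions) {
      models[[paste0("k_syn_", cond)]] <- k_syn
      models[[paste0("te_", cond)]] <- te
    }
    attr(models, "conditions") <- conditions
    attr(models, "read_length") <- as.integer(read_length)
    class(models) <- c("transcript_models", "data.frame")
    models
  })
}

#' Plant regulation modes onto transcript models
#'
#' Assigns each gene one of the deltaTE regulation modes and applies the
#' corresponding condition effect to the second (treated) condition:
#' \describe{
#'   \item{forwarded}{synthesis rate changes, translation efficiency fixed}
#'   \item{exclusive}{translation efficiency changes, synthesis fixed}
#'   \item{intensified}{both change with the same sign}
#'   \item{buffered}{both change with opposite signs}
#'   \item{null}{no change}
#' }
#' Effect signs are drawn uniformly; planted log2 effects are recorded in
#' `effect_rna_log2` (synthesis) and `effect_te_log2` (translation).
#'
#' @param models `transcript_models` from [generate_transcriptome()]
#' @param mode_fractions named numeric vector over the five modes, summing
#'   to 1 (missing modes get fraction 0)
#' @param effect_size_log2 magnitude of planted log2 effects
#' @param seed integer seed
#' @return modified `transcript_models`
#' @export
assign_regulation <- function(models,
                              mode_fractions = c(null = 0.6, forwarded = 0.1,
                                                 exclusive = 0.1,
                                                 intensified = 0.1,
                                                 buffered = 0.1),
                              effect_size_log2 = 2,
                              seed = 1L) {
  stopifnot(inherits(models, "transcript_models"))
  modes <- c("null", "forwarded", "exclusive", "intensified", "buffered")
  if (is.null(names(mode_fractions)) ||
      !all(names(mode_fractions) %in% modes)) {
    stop("`mode_fractions` must be named with regulation modes", call. = FALSE)
  }
  if (any(mode_fractions < 0)) {
    stop("`mode_fractions` must be non-negative", call. = FALSE)
  }
  full <- stats::setNames(numeric(length(modes)), modes)
  full[names(mode_fractions)] <- mode_fractions
  if (abs(sum(full) - 1) > 1e-8) {
    stop("`mode_fractions` must sum to 1", call. = FALSE)
  }
  conditions <- attr(models, "conditions")
  if (length(conditions) < 2L) {
    stop("need >= 2 conditions to plant regulation", call. = FALSE)
  }
  treated <- conditions[2]

  with_seed(seed, {
    n <- nrow(models)
    mode <- sample(modes, n, replace = TRUE, prob = full)
    sign <- sample(c(-1, 1), n, replace = TRUE)
    e <- effect_size_log2 * sign

    rna_eff <- ifelse(mode %in% c("forwarded", "intensified", "buffered"), e, 0)
    te_eff <- ifelse(mode == "exclusive", e,
              ifelse(mode == "intensified", e,
              ifelse(mode == "buffered", -e, 0)))

    models$regulation_mode <- mode
    models$effect_rna_log2 <- rna_eff
    models$effect_te_log2 <- te_eff
    ks <- paste0("k_syn_", treated)
    tec <- paste0("te_", treated)
    models[[ks]] <- models[[paste0("k_syn_", conditions[1])]] * 2^rna_eff
    models[[tec]] <- models[[paste0("te_", conditions[1])]] * 2^te_eff
    models
  })
}

# Per-gene abundance and nascent fraction for one condition under the
# design's kinetic model. Returns list(abundance, nascent_frac).
condition_kinetics <- function(models, design, condition) {
  ref <- attr(models, "conditions")[1]
  k_syn <- models[[paste0("k_syn_", condition)]]
  k_deg <- models$k_deg
  t <- design$labeling_time
  if (design$kinetics == "steady_state" || condition == ref) {
    abundance <- k_syn / k_deg
    f <- nascent_fraction(k_deg, t)
  } else {
    # step change from reference parameters at pulse start (t = 0)
    a0 <- models[[paste0("k_syn_", ref)]] / k_deg
    a_inf <- k_syn / k_deg
    abundance <- a_inf + (a0 - a_inf) * exp(-k_deg * t)
    nascent <- a_inf * (1 - exp(-k_deg * t))
    f <- ifelse(abundance > 0, pmin(nascent / abundance, 1), 0)
  }
  list(abundance = abundance, nascent_frac = f)
}

# Probability that a read from a labeled molecule carries >= 1 T>C event
# (signal plus background channel), and background-only per-read probability.
read_tc_probs <- function(p_conv, p_err, n_uridines) {
  list(
    nascent = 1 - ((1 - p_conv) * (1 - p_err))^n_uridines,
    background = 1 - (1 - p_err)^n_uridines
  )
}

#' Simulate tcount-style count tables with ground truth
#'
#' For every condition x assay x replicate, draws per-gene total read counts
#' from a negative binomial whose mean is proportional to steady-state
#' abundance (times translation efficiency for translatome assays) scaled to
#' the design library size. Each read is nascent with the gene's labeled
#' fraction (times `loading_lag` in translatome assays); nascent reads are
#' detected as T>C reads with probability
#' `1 - ((1 - p_conv) (1 - p_err))^nU` and pre-existing reads with the
#' background probability `1 - (1 - p_err)^nU`.
#'
#' @param models `transcript_models`
#' @param design `sim_design`
#' @return list with `tcount` (named list of tcount data.frames, one per
#'   sample), `samples` (metadata data.frame: sample_id, condition, assay,
#'   replicate) and `truth` (per gene x sample ground truth)
#' @export
simulate_counts <- function(models, design) {
  stopifnot(inherits(models, "transcript_models"), inherits(design, "sim_design"))
  nU <- models$n_uridines_per_read
  probs <- read_tc_probs(design$p_conv, design$p_err, nU)
  layout <- expand.grid(replicate = seq_len(design$n_replicates),
                        assay = design$assays,
                        condition = design$conditions,
                        stringsAsFactors = FALSE)
  layout$sample_id <- sprintf("%s_%s_rep%d", layout$assay, layout$condition,
                              layout$replicate)

  tcount <- vector("list", nrow(layout))
  names(tcount) <- layout$sample_id
  truth_rows <- vector("list", nrow(layout))

  for (i in seq_len(nrow(layout))) {
    cond <- layout$condition[i]
    assay <- layout$assay[i]
    kin <- condition_kinetics(models, design, cond)
    q <- kin$abundance
    is_trap <- assay != "rna"
    if (is_trap) q <- q * models[[paste0("te_", cond)]]
    mu <- design$library_size * q / sum(q)
    f <- kin$nascent_frac
    if (is_trap) f <- f * models$loading_lag

    s <- derive_seed(design$seed, i)
    res <- with_seed(s, {
      total <- if (design$dispersion > 0) {
        stats::rnbinom(length(mu), mu = mu, size = 1 / design$dispersion)
      } else {
        stats::rpois(length(mu), mu)
      }
      nasc <- stats::rbinom(length(total), total, f)
      tc <- stats::rbinom(length(total), nasc, probs$nascent) +
        stats::rbinom(length(total), total - nasc, probs$background)
      cov_t <- total * nU
      rate_mix <- f * (1 - (1 - design$p_conv) * (1 - design$p_err)) +
        (1 - f) * design$p_err
      conv_t <- stats::rbinom(length(total), cov_t, rate_mix)
      list(total = as.integer(total), nasc = as.integer(nasc),
           tc = as.integer(tc), cov_t = as.integer(cov_t),
           conv_t = as.integer(conv_t))
    })

    tab <- data.frame(
      gene_id = models$gene_id,
      length = models$utr_length,
      ReadCount = res$total,
      TcReadCount = res$tc,
      coverageOnTs = res$cov_t,
      conversionsOnTs = res$conv_t,
      conversionRate = ifelse(res$cov_t > 0, res$conv_t / res$cov_t, NA_real_),
      readsCPM = res$total * 1e6 / max(sum(res$total), 1),
      stringsAsFactors = FALSE
    )
    tcount[[i]] <- tab
    truth_rows[[i]] <- data.frame(
      gene_id = models$gene_id,
      sample_id = layout$sample_id[i],
      condition = cond, assay = assay, replicate = layout$replicate[i],
      true_nascent_fraction = f,
      expected_total_count = mu,
      expected_tc_detectable_fraction = probs$nascent,
      realized_total_count = res$total,
      realized_nascent_count = res$nasc,
      stringsAsFactors = FALSE
    )
  }

  list(
    tcount = tcount,
    samples = layout[, c("sample_id", "condition", "assay", "replicate")],
    truth = do.call(rbind, truth_rows)
  )
}

# Build one 3'UTR reference sequence whose terminal read-length window
# contains exactly n_uridines T positions; no terminal poly(A) run.
build_utr_sequence <- function(utr_length, u_content, n_uridines, read_length) {
  read_length <- min(read_length, utr_length)
  head_len <- utr_length - read_length
  non_t <- c("A", "C", "G")
  head_seq <- if (head_len > 0) {
    p_t <- min(max(u_content, 0), 1)
    bases <- ifelse(stats::runif(head_len) < p_t, "T",
                    sample(non_t, head_len, replace = TRUE))
    bases
  } else character(0)
  window <- sample(non_t, read_length, replace = TRUE)
  if (n_uridines > read_length) {
    stop("n_uridines_per_read exceeds read length", call. = FALSE)
  }
  if (n_uridines > 0) {
    window[sample.int(read_length, n_uridines)] <- "T"
  }
  # avoid a terminal adenine run that poly(A) trimming would clip
  if (window[read_length] == "A") window[read_length] <- "C"
  paste0(paste(head_seq, collapse = ""), paste(window, collapse = ""))
}

#' Simulate read-level data for a subset of samples
#'
#' Generates per-gene 3'UTR reference sequences (the terminal read window
#' holds exactly the gene's `n_uridines_per_read` T positions) and
#' fixed-length, sense-strand reads anchored at the 3' end, with counts and
#' nascent/pre-existing split taken from `truth`. Nascent reads convert each
#' covered uridine T>C with probability `p_conv`; every read additionally
#' acquires background substitutions at `p_err` per eligible base per
#' substitution type. Reads are emitted post-trimming (no adapter or poly(A)
#' remnants) with constant Phred 37 base qualities.
#'
#' @param models `transcript_models`
#' @param truth truth data.frame from [simulate_counts()]
#' @param design `sim_design`
#' @param read_length read length (nt); genes with shorter UTRs are
#'   truncated with a warning
#' @param samples sample_ids to simulate reads for (default: all in `truth`;
#'   read-level simulation is meant for desk-scale subsets)
#' @param seed integer seed (default derived from the design seed)
#' @return named list (per sample) of `aligned_reads` objects; the
#'   `reference` attribute on each holds the named reference sequences
#' @export
simulate_reads <- function(models, truth, design, read_length = 100L,
                           samples = unique(truth$sample_id), seed = NULL) {
  stopifnot(inherits(models, "transcript_models"))
  if (!all(models$gene_id %in% unique(truth$gene_id))) {
    stop("`truth` inconsistent with `models`", call. = FALSE)
  }
  seed <- seed %||% derive_seed(design$seed, 90001L)
  if (any(models$utr_length < read_length)) {
    warning("read_length exceeds some UTR lengths; reads truncated per gene")
  }

  refs <- with_seed(derive_seed(seed, 17L), {
    vapply(seq_len(nrow(models)), function(g) {
      build_utr_sequence(models$utr_length[g], models$u_content[g],
                         models$n_uridines_per_read[g], read_length)
    }, character(1))
  })
  names(refs) <- models$gene_id

  out <- vector("list", length(samples))
  names(out) <- samples
  for (si in seq_along(samples)) {
    tr <- truth[truth$sample_id == samples[si], ]
    tr <- tr[match(models$gene_id, tr$gene_id), ]
    out[[si]] <- with_seed(derive_seed(seed, 1000L + si), {
      gene_reads <- vector("list", nrow(models))
      for (g in seq_len(nrow(models))) {
        n_tot <- tr$realized_total_count[g]
        if (n_tot == 0) next
        n_nasc <- tr$realized_nascent_count[g]
        rl <- min(read_length, models$utr_length[g])
        ref <- refs[[g]]
        start0 <- nchar(ref) - rl # 0-based
        window <- strsplit(substr(ref, start0 + 1L, nchar(ref)), "")[[1]]
        mat <- matrix(rep(window, n_tot), nrow = n_tot, byrow = TRUE)
        origin <- rep(c("nascent", "pre"), c(n_nasc, n_tot - n_nasc))
        # signal channel: T>C in nascent reads
        t_pos <- which(window == "T")
        if (length(t_pos) > 0 && n_nasc > 0 && design$p_conv > 0) {
          hit <- matrix(stats::runif(n_nasc * length(t_pos)) < design$p_conv,
                        nrow = n_nasc)
          sub <- mat[seq_len(n_nasc), t_pos, drop = FALSE]
          sub[hit] <- "C"
          mat[seq_len(n_nasc), t_pos] <- sub
        }
        # background channel: each base, each of 3 alternatives at p_err
        if (design$p_err > 0) {
          n_cells <- length(mat)
          bg <- which(stats::runif(n_cells) < 3 * design$p_err)
          if (length(bg) > 0) {
            alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                         G = c("A", "C", "T"), T = c("A", "C", "G"))
            cur <- mat[bg]
            pick <- sample.int(3L, length(bg), replace = TRUE)
            mat[bg] <- vapply(seq_along(bg),
                              function(k) alts[[cur[k]]][pick[k]], character(1))
          }
        }
        seqs <- apply(mat, 1L, paste, collapse = "")
        gene_reads[[g]] <- data.frame(
          read_id = sprintf("%s_%s_r%06d", models$gene_id[g], samples[si],
                            seq_len(n_tot)),
          gene_id = models$gene_id[g],
          start = start0,
          seq = seqs,
          qual = strrep("F", rl),
          origin = origin,
          stringsAsFactors = FALSE
        )
      }
      reads <- do.call(rbind, gene_reads[!vapply(gene_reads, is.null, logical(1))])
      if (is.null(reads)) {
        reads <- data.frame(read_id = character(0), gene_id = character(0),
                            start = integer(0), seq = character(0),
                            qual = character(0), origin = character(0))
      }
      aligned_reads(reads, refs)
    })
  }
  out
}

#' Construct an aligned-read set
#'
#' @param reads data.frame with columns read_id, gene_id, start (0-based),
#'   seq, qual and optionally origin (simulation truth label)
#' @param reference named character vector of reference sequences
#' @return `aligned_reads` object (a data.frame with a `reference` attribute)
#' @export
aligned_reads <- function(reads, reference) {
  need <- c("read_id", "gene_id", "start", "seq", "qual")
  miss <- setdiff(need, names(reads))
  if (length(miss) > 0) {
    stop("missing read columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(reads) > 0) {
    if (any(reads$start < 0)) stop("negative read start", call. = FALSE)
    if (!all(reads$gene_id %in% names(reference))) {
      stop("reads reference unknown genes", call. = FALSE)
    }
    ends <- reads$start + nchar(reads$seq)
    if (any(ends > nchar(reference[reads$gene_id]))) {
      stop("read extends past reference end", call. = FALSE)
    }
    if (any(nchar(reads$qual) != nchar(reads$seq))) {
      stop("quality string length mismatch", call. = FALSE)
    }
  }
  attr(reads, "reference") <- reference
  class(reads) <- c("aligned_reads", "data.frame")
  reads
}
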