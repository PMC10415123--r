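test_that("nascent_fraction follows first-order labeling kinetics", {
  expect_identical(nascent_fraction(0, 3), 0)
  expect_equal(nascent_fraction(log(2) / 3, 3), 0.5)
  # closed form cross-checked by forward-simulating the birth-death ODE:
  # dA/dt = k - A, dL/dt = k - L, A(0) = k, L(0) = 0, fraction L(3)/A(3)
  k <- 1; dt <- 1e-4
  A <- k; L <- 0
  for (i in seq_len(3 / dt)) {
    A <- A + dt * (k - A)
    L <- L + dt * (k - L)
  }
  expect_equal(nascent_fraction(1, 3), L / A, tolerance = 1e-3)
  expect_equal(nascent_fraction(1, 3), 0.9502, tolerance = 1e-4)
  # monotone in both arguments
  kd <- seq(0.05, 2, length.out = 20)
  expect_true(all(diff(nascent_fraction(kd, 3)) > 0))
  expect_true(all(diff(nascent_fraction(0.3, seq(0.5, 10, 0.5))) > 0))
  expect_error(nascent_fraction(-1, 3), "k_deg")
  expect_error(nascent_fraction(0.5, -1), "t")
})

test_that("generate_transcriptome is seed-deterministic and matches its configuration", {
  m1 <- generate_transcriptome(100, seed = 1)
  m2 <- generate_transcriptome(100, seed = 1)
  expect_identical(m1, m2)
  expect_false(identical(m1, generate_transcriptome(100, seed = 2)))
  expect_false(anyDuplicated(m1$gene_id) > 0)
  expect_true(all(m1$k_deg > 0 & m1$k_syn_control > 0 & m1$te_control > 0))

  m0 <- generate_transcriptome(50, u_content_range = c(0, 0), seed = 3)
  expect_true(all(m0$n_uridines_per_read == 0))

  # law of large numbers: mean uridines per read ~ read_length * mean(u range)
  m <- generate_transcriptome(2000, seed = 7)
  expect_equal(mean(m$n_uridines_per_read), 100 * 0.25, tolerance = 0.02)

  expect_error(generate_transcriptome(10, utr_length_range = c(500, 100)),
               "range")
  expect_error(generate_transcriptome(0), "n_genes")
})

test_that("assign_regulation plants the advertised parameter changes", {
  m <- generate_transcriptome(200, seed = 1)
  m_null <- assign_regulation(m, mode_fractions = c(null = 1), seed = 2)
  expect_true(all(m_null$regulation_mode == "null"))
  expect_identical(m_null$k_syn_control, m_null$k_syn_stress)
  expect_identical(m_null$te_control, m_null$te_stress)

  m_fwd <- assign_regulation(m, mode_fractions = c(forwarded = 1),
                             effect_size_log2 = 2, seed = 3)
  expect_equal(m_fwd$k_syn_stress / m_fwd$k_syn_control,
               2^m_fwd$effect_rna_log2)
  expect_true(all(abs(m_fwd$effect_rna_log2) == 2))
  expect_equal(m_fwd$te_stress / m_fwd$te_control, rep(1, 200))

  # mode semantics across all planted modes
  m_all <- assign_regulation(m, mode_fractions = c(null = 0.2, forwarded = 0.2,
                                                   exclusive = 0.2,
                                                   intensified = 0.2,
                                                   buffered = 0.2), seed = 4)
  rna_changed <- m_all$k_syn_stress != m_all$k_syn_control
  te_changed <- m_all$te_stress != m_all$te_control
  expect_identical(rna_changed,
                   m_all$regulation_mode %in% c("forwarded", "intensified",
                                                "buffered"))
  expect_identical(te_changed,
                   m_all$regulation_mode %in% c("exclusive", "intensified",
                                                "buffered"))
  buf <- m_all$regulation_mode == "buffered"
  expect_true(all(sign(m_all$effect_rna_log2[buf]) ==
                  -sign(m_all$effect_te_log2[buf])))
  int <- m_all$regulation_mode == "intensified"
  expect_true(all(sign(m_all$effect_rna_log2[int]) ==
                  sign(m_all$effect_te_log2[int])))

  expect_error(assign_regulation(m, mode_fractions = c(null = 0.5)), "sum")
  expect_error(assign_regulation(m, mode_fractions = c(null = 1.4,
                                                       forwarded = -0.4)),
               "non-negative")
})

test_that("assign_regulation mode counts fall in the multinomial 99% region", {
  m <- generate_transcriptome(2000, seed = 1)
  fr <- c(null = 0.6, forwarded = 0.1, exclusive = 0.1, intensified = 0.1,
          buffered = 0.1)
  m <- assign_regulation(m, mode_fractions = fr, seed = 3)
  counts <- table(factor(m$regulation_mode, names(fr)))
  for (md in names(fr)) {
    lo <- qbinom(0.005, 2000, fr[[md]])
    hi <- qbinom(0.995, 2000, fr[[md]])
    expect_gte(counts[[md]], lo)
    expect_lte(counts[[md]], hi)
  }
})

test_that("simulate_counts respects conservation, determinism and degenerate designs", {
  m <- generate_transcriptome(80, seed = 1)
  d0 <- sim_design(library_size = 2e4, p_conv = 0, p_err = 0, seed = 5)
  sim0 <- simulate_counts(m, d0)
  expect_true(all(vapply(sim0$tcount, function(tb) all(tb$TcReadCount == 0),
                         logical(1))))

  d <- sim_design(library_size = 2e4, seed = 5)
  sim <- simulate_counts(m, d)
  expect_identical(sim, simulate_counts(m, d))
  expect_true(all(sim$truth$realized_nascent_count <=
                  sim$truth$realized_total_count))
  expect_true(all(vapply(sim$tcount,
                         function(tb) all(tb$TcReadCount <= tb$ReadCount),
                         logical(1))))
  expect_true(all(sim$truth$true_nascent_fraction >= 0 &
                  sim$truth$true_nascent_fraction <= 1))

  # doubling library size doubles mean ReadCount
  d2 <- sim_design(library_size = 4e4, seed = 5)
  sim2 <- simulate_counts(m, d2)
  tot1 <- mean(vapply(sim$tcount, function(tb) sum(tb$ReadCount), numeric(1)))
  tot2 <- mean(vapply(sim2$tcount, function(tb) sum(tb$ReadCount), numeric(1)))
  expect_equal(tot2 / tot1, 2, tolerance = 0.05)
})

test_that("simulated T>C proportions match the labeling kinetics", {
  # fast turnover, perfect conversion: Tc/Read ratio equals nascent fraction
  m <- generate_transcriptome(60, u_content_range = c(0.2, 0.4), seed = 2)
  m$k_deg <- rep(1, 60)
  d <- sim_design(library_size = 5e4, p_conv = 1, p_err = 0,
                  dispersion = 0.05, seed = 9)
  sim <- simulate_counts(m, d)
  for (sid in c("rna_control_rep1", "ptrap_stress_rep2")) {
    tb <- sim$tcount[[sid]]
    expect_equal(sum(tb$TcReadCount) / sum(tb$ReadCount),
                 nascent_fraction(1, 3), tolerance = 0.01)
  }
})

test_that("simulate_reads produces the stated conversion structure", {
  m <- generate_transcriptome(30, utr_length_range = c(150, 400), seed = 3)
  d1 <- sim_design(assays = "rna", n_replicates = 1, library_size = 2000,
                   p_conv = 1, p_err = 0, seed = 11)
  sim1 <- simulate_counts(m, d1)
  reads1 <- simulate_reads(m, sim1$truth, d1, samples = "rna_control_rep1")
  r1 <- reads1[[1]]
  ev <- nptrap:::conversion_events(r1, attr(r1, "reference"), 0L)
  nasc <- r1$origin == "nascent"
  expect_true(all(ev[nasc & ev[, "cov_T"] >= 1, "T>C"] >= 1))

  d0 <- sim_design(assays = "rna", n_replicates = 1, library_size = 2000,
                   p_conv = 0, p_err = 0, seed = 11)
  sim0 <- simulate_counts(m, d0)
  r0 <- simulate_reads(m, sim0$truth, d0, samples = "rna_control_rep1")[[1]]
  ev0 <- nptrap:::conversion_events(r0, attr(r0, "reference"), 0L)
  expect_true(all(ev0[, nptrap:::SUB_TYPES] == 0))

  # seed determinism
  r1b <- simulate_reads(m, sim1$truth, d1, samples = "rna_control_rep1")[[1]]
  expect_identical(r1, r1b)
})

test_that("nascent read detection probability matches 1 - (1 - p)^nU", {
  m <- generate_transcriptome(20, utr_length_range = c(150, 150), seed = 4)
  m$n_uridines_per_read <- rep(30L, 20)
  d <- sim_design(assays = "rna", n_replicates = 1, library_size = 2e4,
                  p_conv = 0.024, p_err = 0, seed = 13)
  sim <- simulate_counts(m, d)
  reads <- simulate_reads(m, sim$truth, d, read_length = 100,
                          samples = "rna_control_rep1")[[1]]
  ev <- nptrap:::conversion_events(reads, attr(reads, "reference"), 0L)
  nasc <- reads$origin == "nascent"
  frac <- mean(ev[nasc, "T>C"] >= 1)
  p_expect <- detection_sensitivity(0.024, 30)
  expect_equal(p_expect, 0.5175, tolerance = 1e-4)
  # binomial sampling envelope (4 sd)
  tol <- 4 * sqrt(p_expect * (1 - p_expect) / sum(nasc))
  expect_lt(abs(frac - p_expect), tol)
})

test_that("counting round trip matches the analytic T>C read probability", {
  m <- generate_transcriptome(40, utr_length_range = c(120, 300), seed = 6)
  d <- sim_design(assays = "rna", n_replicates = 1, library_size = 3e4,
                  p_conv = 0.1, p_err = 0.001, seed = 21)
  sim <- simulate_counts(m, d)
  reads <- simulate_reads(m, sim$truth, d, samples = "rna_control_rep1")[[1]]
  tab <- tally_gene_counts(reads, min_base_quality = 0)
  tr <- sim$truth[match(tab$gene_id, sim$truth$gene_id), ]
  nU <- m$n_uridines_per_read[match(tab$gene_id, m$gene_id)]
  bg <- 1 - (1 - d$p_err)^nU
  sens <- 1 - (1 - d$p_conv)^nU * (1 - bg)
  # expectation conditional on the realized nascent/pre-existing split
  n_n <- tr$realized_nascent_count
  n_p <- tr$realized_total_count - n_n
  exp_tc <- n_n * sens + n_p * bg
  var_tc <- n_n * sens * (1 - sens) + n_p * bg * (1 - bg)
  keep <- var_tc > 1
  z <- (tab$TcReadCount[keep] - exp_tc[keep]) / sqrt(var_tc[keep])
  expect_true(all(abs(z) < 4.5))
})
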