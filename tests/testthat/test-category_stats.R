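test_that("mann_whitney_u matches exact enumeration and known identities", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  # identical multisets: U = n^2/2, p ~ 1 (midranks force the approximation)
  x <- c(1, 2, 3, 4, 5)
  r2 <- mann_whitney_u(x, x)
  expect_equal(r2$U, length(x)^2 / 2)
  expect_gte(r2$p_value, 0.99)

  # U_x + U_y = n_x * n_y
  set.seed(1)
  for (i in 1:5) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1))
    expect_equal(mann_whitney_u(a, b)$U + mann_whitney_u(b, a)$U,
                 length(a) * length(b))
  }

  # exact p equals the combn enumeration oracle
  set.seed(2)
  for (i in 1:10) {
    m <- sample(3:8, 1); n <- sample(3:8, 1)
    a <- rnorm(m); b <- rnorm(n)
    expect_equal(mann_whitney_u(a, b)$p_value, mw_enum_p(a, b),
                 tolerance = 1e-12)
  }

  # large-sample approximation agrees with the reference implementation
  set.seed(3)
  a <- rnorm(40); b <- rnorm(35, 0.4)
  got <- mann_whitney_u(a, b)
  want <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, want$p.value, tolerance = 1e-10)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  expect_error(mann_whitney_u(c(1, 1, 2), c(1, 3), method = "exact"), "ties")
})

test_that("normal approximation tracks the exact distribution for small n", {
  # full enumeration over every U for all (m, n) with 8 <= m + n <= 16:
  # the worst-case |exact - approx| of the continuity-corrected normal
  # approximation is 0.0305 (at m = n = 4); it tightens as N grows
  worst <- 0
  for (m in 4:8) for (n in 4:8) {
    if (m + n > 16) next
    d <- nptrap:::mw_exact_dist(m, n)
    uv <- as.numeric(names(d))
    mu <- m * n / 2
    sigma <- sqrt(m * n * (m + n + 1) / 12)
    for (U in uv) {
      pe <- min(1, 2 * min(sum(d[uv <= U]), sum(d[uv >= U])))
      pa <- if (U == mu) 1 else {
        min(1, 2 * pnorm(-abs((U - mu - sign(U - mu) * 0.5) / sigma)))
      }
      worst <- max(worst, abs(pe - pa))
    }
  }
  expect_lte(worst, 0.0306)
  # and in the tails, where decisions are made, agreement is much tighter
  a <- 1:6; b <- 7:14
  expect_lt(abs(mann_whitney_u(a, b, method = "exact")$p_value -
                mann_whitney_u(a, b, method = "normal")$p_value), 0.01)
})

test_that("ecdf_shift detects planted shifts and skips small sets", {
  set.seed(5)
  lfc <- rnorm(2000, 0, 0.5)
  names(lfc) <- sprintf("g%04d", 1:2000)
  members <- names(lfc)[1:50]
  lfc[members] <- lfc[members] + 1
  r <- ecdf_shift(members, lfc)
  expect_lt(r$p_value, 1e-6)
  expect_gt(r$median_shift, 0.5)
  expect_equal(r$n_background, 1950) # set members excluded from background
  # ECDF validity
  expect_true(all(diff(r$ecdf_set$cumulative) >= 0))
  expect_equal(range(r$ecdf_set$cumulative), c(1 / 50, 1))

  expect_warning(r1 <- ecdf_shift(names(lfc)[1], lfc), "skipped")
  expect_null(r1)
  expect_error(ecdf_shift("g1", unname(lfc)), "named")
})

test_that("null gene sets give uniform shift p-values", {
  set.seed(6)
  lfc <- rnorm(600, 0, 0.5)
  names(lfc) <- sprintf("g%03d", 1:600)
  ps <- replicate(120, ecdf_shift(sample(names(lfc), 25), lfc)$p_value)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("compare_nascent_proportions runs pairwise tests with box stats", {
  set.seed(7)
  v1 <- rbeta(300, 4, 6); v2 <- rbeta(300, 4, 6); v3 <- rbeta(300, 2, 8)
  res <- compare_nascent_proportions(c(v1, v2, v3),
                                     rep(c("a", "b", "c"), each = 300))
  expect_equal(nrow(res$pairs), 3)
  ab <- res$pairs[res$pairs$group1 == "a" & res$pairs$group2 == "b", ]
  ac <- res$pairs[res$pairs$group1 == "a" & res$pairs$group2 == "c", ]
  expect_gt(ab$p_value, 0.05) # same distribution
  expect_lt(ac$p_value, 1e-6) # shifted distribution
  expect_true(all(res$summary$median >= 0 & res$summary$median <= 1))
  # small groups are dropped
  expect_error(compare_nascent_proportions(c(v1, 0.5), c(rep("a", 300), "tiny")),
               "2 groups")
})

test_that("stratify_by_orf_length quantifies length-dependent lag", {
  set.seed(8)
  n <- 1200
  genes <- sprintf("g%04d", 1:n)
  orf <- stats::setNames(sample(300:6000, n, TRUE), genes)
  base <- rbeta(n, 5, 5)
  lag <- 1 - 0.6 * (orf - 300) / 5700 # monotone decreasing in ORF length
  props <- rbind(
    data.frame(gene_id = genes, group = "transcriptome", proportion = base),
    data.frame(gene_id = genes, group = "translatome",
               proportion = pmin(base * lag[genes] +
                                   rnorm(n, 0, 0.02), 1))
  )
  r <- stratify_by_orf_length(props, orf)
  expect_lt(r$trend_spearman, -0.8)
  expect_true(all(r$per_bin$median_diff < 0, na.rm = TRUE))

  # length-independent lag: no trend
  props0 <- props
  props0$proportion[props0$group == "translatome"] <-
    pmin(base * 0.7 + rnorm(n, 0, 0.02), 1)
  r0 <- stratify_by_orf_length(props0, orf,
                               bin_edges = quantile(orf, seq(0, 1, 1 / 8)))
  expect_lt(abs(r0$trend_spearman), 0.8)

  # single bin: per-bin test still reported, trend undefined
  r1 <- stratify_by_orf_length(props, orf, bin_edges = c(300, 6000))
  expect_true(is.na(r1$trend_spearman))
  expect_equal(nrow(r1$per_bin), 1)
  expect_lt(r1$per_bin$p_value, 0.05)

  expect_error(stratify_by_orf_length(props, orf, bin_edges = c(500, 6000)),
               "cover")
})

test_that("hypergeometric_ora matches arithmetic and enumeration", {
  universe <- sprintf("u%03d", 1:100)
  sets <- list(hit = universe[1:10], miss = universe[11:20])
  query <- universe[c(1:10, 91:100)] # overlap 10 with 'hit'
  r <- hypergeometric_ora(query, universe, sets)
  expect_equal(r$enrichment_ratio[r$set == "hit"], 5.0)
  expect_lt(r$p_value[r$set == "hit"], 1e-7)

  # overlap equal to expectation: ratio 1, unremarkable p
  q2 <- universe[c(1:2, 21:38)]
  r2 <- hypergeometric_ora(q2, universe, sets["hit"])
  expect_equal(r2$enrichment_ratio, 1.0)
  expect_gt(r2$p_value, 0.5)

  # brute-force tail enumeration on a small universe
  uni <- sprintf("v%02d", 1:30)
  set <- uni[1:8]
  q <- uni[c(1:5, 20:28)]
  k <- length(intersect(q, set))
  tail_p <- sum(vapply(k:length(q), function(i) {
    choose(8, i) * choose(22, length(q) - i) / choose(30, length(q))
  }, numeric(1)))
  r3 <- hypergeometric_ora(q, uni, list(s = set))
  expect_equal(r3$p_value, tail_p, tolerance = 1e-12)

  # self-consistency: the query's own set is the strongest hit of its size
  sets4 <- list(own = q, other = uni[c(1:5, 8:16)])
  r4 <- hypergeometric_ora(q, uni, sets4)
  expect_equal(r4$overlap[r4$set == "own"], length(q))
  expect_lt(r4$p_value[r4$set == "own"], min(r4$p_value[r4$set != "own"]))

  expect_error(hypergeometric_ora("x", character(0), sets), "universe")
  expect_error(hypergeometric_ora("x", universe, sets), "subset")
})
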