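test_that("profile correlation matches the longhand formula", {
  x <- c(g1 = 0, g2 = 1, g3 = 2, g4 = 3, g5 = 4)
  y <- c(g1 = 1, g2 = 3, g3 = 2, g4 = 5, g5 = 4)
  got <- correlate_profiles(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_hand)
  expect_equal(correlate_profiles(x, x)$r, 1)
  # symmetry and affine invariance
  expect_equal(correlate_profiles(y, x)$r, got$r)
  expect_equal(correlate_profiles(x, 3 * y + 2)$r, got$r)
  expect_error(correlate_profiles(x, setNames(rep(1, 5), names(x))),
               "zero variance")
  expect_error(correlate_profiles(x[1:2], y[1:2]), "3 shared")
})

test_that("rank-sum exact p equals exhaustive enumeration", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  got <- ranksum_test(x, y)
  expect_equal(got$statistic, 6)
  expect_equal(got$p.value, oracle_ranksum(x, y))
  expect_equal(got$p.value, 2 / 20)
  # agrees with the reference implementation when ties are absent
  expect_equal(got$p.value, stats::wilcox.test(x, y, exact = TRUE)$p.value)
  withr::with_seed(4, {
    for (i in 1:10) {
      a <- sample(1:30, sample(2:8, 1))
      b <- sample(1:30, sample(2:8, 1))
      expect_equal(ranksum_test(a, b)$p.value, oracle_ranksum(a, b))
    }
  })
  # ties are handled by midranks in both routes
  a <- c(1, 1, 2, 3); b <- c(1, 2, 2, 4)
  expect_equal(ranksum_test(a, b)$p.value, oracle_ranksum(a, b))
})

test_that("exact and normal-approximation p-values agree for n1 = n2 = 8", {
  withr::with_seed(7, {
    worst <- 0
    for (i in 1:100) {
      a <- rnorm(8); b <- rnorm(8, mean = runif(1, -1, 1))
      pe <- ranksum_test(a, b, exact = TRUE)$p.value
      pn <- ranksum_test(a, b, exact = FALSE)$p.value
      worst <- max(worst, abs(pe - pn))
    }
    expect_lt(worst, 0.02)
  })
})

test_that("EASE p-values equal the direct hypergeometric tail", {
  # full overlap: N = 20, K = 5, n = 5, k = 5 -> tail at k - 1 = 4
  got <- ease_enrichment(paste0("g", 1:5), paste0("g", 1:5), paste0("g", 1:20))
  expect_equal(got$p.value, oracle_ease(5L, 5L, 20L, 5L))
  expect_equal(got$p.value, (5 * 15 + 1) / choose(20, 5))
  # empty overlap gives p = 1 (k - 1 floored at 0)
  got0 <- ease_enrichment(paste0("g", 1:3), paste0("g", 10:12), paste0("g", 1:20))
  expect_equal(got0$p.value, 1)
  # category equal to the background is never enriched
  gotbg <- ease_enrichment(paste0("g", 1:4), paste0("g", 1:20), paste0("g", 1:20))
  expect_equal(gotbg$p.value, 1)
  # EASE is always at least the unmodified Fisher tail
  withr::with_seed(11, {
    for (i in 1:25) {
      bg <- paste0("g", 1:40)
      cat_ <- sample(bg, sample(5:20, 1))
      hits <- sample(bg, sample(3:15, 1))
      k <- length(intersect(hits, cat_))
      fisher <- stats::phyper(k - 1L, length(cat_), 40L - length(cat_),
                              length(hits), lower.tail = FALSE)
      expect_gte(ease_enrichment(hits, cat_, bg)$p.value, fisher)
      expect_equal(ease_enrichment(hits, cat_, bg)$p.value,
                   oracle_ease(k, length(cat_), 40L, length(hits)))
    }
  })
})

test_that("Benjamini-Hochberg adjustment equals the longhand recursion", {
  expect_equal(benjamini_adjust(0.05), 0.05)
  expect_equal(benjamini_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(3, {
    for (i in 1:20) {
      p <- runif(sample(1:12, 1))
      adj <- benjamini_adjust(p)
      expect_equal(adj, oracle_bh(p))
      expect_true(all(adj >= p - 1e-12))
      expect_true(all(adj <= 1))
    }
  })
})

test_that("2^-dCt ratios behave as cycle differences dictate", {
  expect_equal(delta_ct_ratio(25, 25), 1)
  expect_equal(delta_ct_ratio(26, 25), 0.5)
  expect_equal(delta_ct_ratio(23, 25), 4)
  expect_equal(delta_ct_ratio(c(25, 26), c(25, 25)), c(1, 0.5))
  expect_error(delta_ct_ratio(Inf, 25), "finite")
})

test_that("bin assignment and expression summaries are structured correctly", {
  bins <- bin_scheme()
  meth <- c(a = 0, b = 0.5, c = 2, d = 3.5, e = 7)
  expr <- c(a = 10, b = 8, c = 5, d = 3, e = 1)
  out <- methylation_expression_summary(meth, expr, bins)
  expect_equal(out$summary$bin,
               c("0", "(0,2)", "[2,3)", "[3,4)", "[4,Inf)"))
  expect_equal(out$summary$n, rep(1L, 5))
  expect_lt(out$pearson$r, 0)
  # single-bin input yields a summary but no tests
  one <- methylation_expression_summary(c(a = 0, b = 0), c(a = 1, b = 2), bins)
  expect_equal(length(one$tests), 0)
  expect_equal(one$summary$n[1], 2L)
  # normalization divides by the maximum expression value
  outn <- methylation_expression_summary(meth, expr, bins, normalize = TRUE)
  expect_equal(outn$summary$median, out$summary$median / 10)
})

test_that("simulated repression gives non-increasing medians and negative r", {
  cfg <- small_cfg(n_genes = 400, seed = 31)
  b <- run_all(cfg)
  s <- b$expr_summary
  med <- s$summary$median[s$summary$n > 0]
  expect_true(all(diff(med) <= 0))
  expect_lt(s$pearson$r, 0)
})

test_that("distance-class tabulation counts unique peaks once per class", {
  mapped <- data.frame(
    peak_id = c("p1", "p2", "p3", "p4"), chrom = "chr1",
    start = 1L, end = 10L, value = c(2.5, 3.0, 2.2, 1.5), n_probes = 2L,
    cutoff = 2, strain = "A", tissue = "heart",
    feature_id = "G1", feature_class = "TSS", signed_distance = -300,
    distance_class = c("proximal", "proximal", "distal", "distal"))
  tab <- tabulate_distance_classes(mapped, min_value = 2)
  expect_equal(tab$n[tab$distance_class == "proximal"], 2L)
  expect_equal(tab$n[tab$distance_class == "distal"], 1L)  # p4 below 2.0
  expect_equal(sum(tab$n), 3L)
  # empty when nothing reaches the threshold
  tab0 <- tabulate_distance_classes(mapped, min_value = 10)
  expect_true(all(tab0$n == 0))
  # invariant to row order and peak relabeling
  shuf <- mapped[c(3, 1, 4, 2), ]
  shuf$peak_id <- paste0("x", shuf$peak_id)
  expect_equal(tabulate_distance_classes(shuf, min_value = 2)$n, tab$n)
  # diff_only restricts to called features
  calls <- data.frame(feature_id = "G9", tissue = "heart", direction = "hyper",
                      condition = "i", test_value = 3, ref_value = 0)
  tabd <- tabulate_distance_classes(mapped, min_value = 2, diff_only = TRUE,
                                    calls = calls)
  expect_true(all(tabd$n == 0))
})
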