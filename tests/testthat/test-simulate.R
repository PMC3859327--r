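test_that("generation is deterministic and conserves planted labels", {
  cfg <- small_cfg(n_genes = 100, seed = 7, cpg_island_fraction = 0.5)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  expect_equal(nrow(a1$genes), 100)
  expect_true(nrow(a1$islands) <= 100)
  t1 <- simulate_methylomes(cfg, a1)
  t2 <- simulate_methylomes(cfg, a1)
  expect_identical(t1, t2)
  expect_equal(nrow(t1$labels), cfg$n_genes)
  expect_setequal(unique(t1$labels$label), c("none", "hypo", "hyper"))
  expect_equal(sum(t1$labels$label == "hypo"), round(100 * cfg$diff_hypo_frac))
  s1 <- simulate_probe_signals(cfg, a1, t1)
  s2 <- simulate_probe_signals(cfg, a1, t1)
  expect_identical(s1, s2)
  e1 <- simulate_expression(t1, a1)
  e2 <- simulate_expression(t1, a1)
  expect_identical(e1, e2)
})

test_that("an empty genome gives empty, well-formed objects", {
  cfg <- sim_config(n_genes = 0)
  ann <- generate_annotation(cfg)
  expect_s3_class(ann, "feature_set")
  expect_equal(nrow(ann$genes), 0)
  expect_equal(nrow(ann$islands), 0)
  truth <- simulate_methylomes(cfg, ann)
  expect_equal(nrow(truth$labels), 0)
})

test_that("genome too small for the requested gene count is an error", {
  expect_error(generate_annotation(sim_config(n_genes = 1000, chrom_length = 1e5)),
               "too small")
})

test_that("annotation geometry respects strand and containment", {
  cfg <- small_cfg(n_genes = 200, seed = 3)
  ann <- generate_annotation(cfg)
  g <- ann$genes
  expect_true(all(g$tx_start <= g$tx_end))
  expect_true(all(ifelse(g$strand == "+", g$tss == g$tx_start,
                         g$tss == g$tx_end - 1L)))
  tr <- ann$tiled_regions
  # tiled regions do not overlap
  for (ch in unique(tr$chrom)) {
    sub <- tr[tr$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
  # every planted methylated interval lies within a tiled region
  truth <- simulate_methylomes(cfg, ann)
  expect_true(all(overlaps_any(truth$regions, tr)))
  inside <- mapply(function(ch, s, e) {
    any(tr$chrom == ch & tr$start <= s & tr$end >= e)
  }, truth$regions$chrom, truth$regions$start, truth$regions$end)
  expect_true(all(inside))
})

test_that("planted labels are consistent with emitted states in all tissues", {
  cfg <- small_cfg(n_genes = 300, seed = 11)
  ann <- generate_annotation(cfg)
  truth <- simulate_methylomes(cfg, ann)
  st <- truth$states
  for (lab in c("hypo", "hyper")) {
    ids <- truth$labels$gene_id[truth$labels$label == lab]
    on_strain <- if (lab == "hypo") "A" else "B"
    off_strain <- if (lab == "hypo") "B" else "A"
    expect_true(all(st$state[st$gene_id %in% ids & st$strain == on_strain] == 1L))
    expect_true(all(st$state[st$gene_id %in% ids & st$strain == off_strain] == 0L))
  }
})

test_that("perfect tissue correlation makes tissue states identical per strain", {
  cfg <- small_cfg(n_genes = 200, seed = 5, tissue_correlation = 1.0)
  ann <- generate_annotation(cfg)
  truth <- simulate_methylomes(cfg, ann)
  st <- truth$states
  for (s in cfg$strains) {
    mats <- sapply(cfg$tissues, function(t) {
      sub <- st[st$strain == s & st$tissue == t, ]
      sub$state[order(sub$gene_id)]
    })
    expect_true(all(mats[, 1] == mats[, 2]) && all(mats[, 1] == mats[, 3]))
  }
})

test_that("configured inter-tissue correlation is recovered on emitted states", {
  cfg <- sim_config(n_genes = 5000, chrom_length = 3e7, seed = 13,
                    tissue_correlation = 0.8,
                    diff_hypo_frac = 0, diff_hyper_frac = 0)
  ann <- generate_annotation(cfg)
  truth <- simulate_methylomes(cfg, ann)
  st <- truth$states
  for (s in cfg$strains) {
    mats <- sapply(cfg$tissues, function(t) {
      sub <- st[st$strain == s & st$tissue == t, ]
      sub$state[order(sub$gene_id)]
    })
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      expect_lt(abs(cor(mats[, pair[1]], mats[, pair[2]]) - 0.8), 0.05)
    }
  }
})

test_that("no planted differentials means every label is none", {
  cfg <- small_cfg(n_genes = 80, seed = 2, diff_hypo_frac = 0, diff_hyper_frac = 0)
  truth <- simulate_methylomes(cfg, generate_annotation(cfg))
  expect_true(all(truth$labels$label == "none"))
})

test_that("noiseless emission gives exact means inside and outside regions", {
  cfg <- small_cfg(n_genes = 60, seed = 9, sigma = 0, high_boost_frac = 0)
  ann <- generate_annotation(cfg)
  truth <- simulate_methylomes(cfg, ann)
  tracks <- simulate_probe_signals(cfg, ann, truth)
  tr <- tracks[["A.heart"]]
  iv <- truth$intervals[truth$intervals$strain == "A" &
                          truth$intervals$tissue == "heart", ]
  inside <- overlaps_any(data.frame(chrom = tr$chrom, start = tr$position,
                                    end = tr$position + 1L), iv)
  expect_true(all(tr$log2_ratio[inside] == cfg$mu_methylated))
  expect_true(all(tr$log2_ratio[!inside] == cfg$mu_background))
})

test_that("background probe mean matches mu_background within sampling error", {
  cfg <- sim_config(n_genes = 250, chrom_length = 1.5e6, seed = 21,
                    p_methylated = 0, diff_hypo_frac = 0, diff_hyper_frac = 0)
  ann <- generate_annotation(cfg)
  truth <- simulate_methylomes(cfg, ann)
  tr <- simulate_probe_signals(cfg, ann, truth)[["A.heart"]]
  expect_gt(nrow(tr), 1e4)
  tol <- 3 * cfg$sigma / sqrt(nrow(tr))
  expect_lt(abs(mean(tr$log2_ratio) - cfg$mu_background), tol)
})

test_that("expression is anti-correlated with methylation as configured", {
  cfg <- sim_config(n_genes = 2000, chrom_length = 1.2e7, seed = 17,
                    high_boost_frac = 0)
  ann <- generate_annotation(cfg)
  truth <- simulate_methylomes(cfg, ann)

  # noiseless: expression difference between a methylated and an
  # unmethylated gene is exactly the slope
  e0 <- simulate_expression(truth, ann, slope = -2, noise_sd = 0)
  sub <- merge(e0, truth$states, by = c("gene_id", "strain", "tissue"))
  sub <- sub[sub$strain == "A" & sub$tissue == "heart", ]
  expect_equal(unique(sub$value[sub$state == 0]) -
                 unique(sub$value[sub$state == 1]), 2)

  # noisy: sample correlation close to the attenuated closed form
  e1 <- simulate_expression(truth, ann, slope = -2, noise_sd = 0.5)
  sub <- merge(e1, truth$states, by = c("gene_id", "strain", "tissue"))
  sub <- sub[sub$strain == "A" & sub$tissue == "heart", ]
  sd_m <- sd(sub$state)
  expected_r <- -2 * sd_m / sqrt(4 * sd_m^2 + 0.25)
  expect_lt(abs(cor(sub$state, sub$value) - expected_r), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(diff_hypo_frac = 0.7, diff_hyper_frac = 0.5), "<= 1")
  expect_error(sim_config(mu_methylated = 0, mu_background = 0), "exceed")
  expect_error(sim_config(sigma = -1), "sigma")
  expect_error(sim_config(tissue_correlation = 1.5), "\\[0, 1\\]")
})
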