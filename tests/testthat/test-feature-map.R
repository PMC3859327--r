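demo_features <- function() {
  feature_set(
    genes = data.frame(gene_id = c("Gplus", "Gminus"), chrom = "chr1",
                       strand = c("+", "-"), tss = c(10000L, 10000L),
                       tx_start = c(10000L, 6001L), tx_end = c(13000L, 10001L)),
    islands = data.frame(island_id = "I1", chrom = "chr1",
                         start = 9800L, end = 10300L),
    tiled_regions = data.frame(region_id = "T1", chrom = "chr1",
                               start = 4000L, end = 16000L))
}

peak_at <- function(anchor, id = "pk1") {
  data.frame(peak_id = id, chrom = "chr1", start = anchor - 50L,
             end = anchor + 51L, value = 3, n_probes = 2L, cutoff = 2,
             strain = "A", tissue = "heart")
}

single_gene <- function(strand = "+") {
  feature_set(genes = data.frame(
    gene_id = "G", chrom = "chr1", strand = strand, tss = 10000L,
    tx_start = if (strand == "+") 10000L else 7001L,
    tx_end = if (strand == "+") 13000L else 10001L))
}

test_that("TSS window arithmetic and strand orientation are correct", {
  cand <- map_candidates(peak_at(6000L), single_gene("+"))
  tss <- cand[cand$feature_class == "TSS", ]
  expect_equal(nrow(tss), 1)
  expect_equal(tss$signed_distance, -4000)

  # anchor past +1000 downstream: not a TSS candidate
  cand <- map_candidates(peak_at(16000L), single_gene("+"))
  expect_false("TSS" %in% cand$feature_class)

  # on the minus strand, higher coordinates are upstream
  cand <- map_candidates(peak_at(12000L), single_gene("-"))
  tss <- cand[cand$feature_class == "TSS", ]
  expect_equal(tss$signed_distance, -2000)
})

test_that("priority order selects TSS over island, island when alone", {
  fs <- demo_features()
  mp <- map_peaks(peak_at(9900L), fs)
  expect_equal(mp$feature_class, "TSS")

  # a peak only near the island (remove genes)
  fs2 <- feature_set(islands = fs$islands)
  mp2 <- map_peaks(peak_at(9900L), fs2)
  expect_equal(mp2$feature_class, "CpG_island")
  expect_equal(mp2$feature_id, "I1")
})

test_that("ties within a class go to the smallest distance then id", {
  fs <- feature_set(genes = data.frame(
    gene_id = c("Gnear", "Gfar"), chrom = "chr1", strand = "+",
    tss = c(10400L, 14400L), tx_start = c(10400L, 14400L),
    tx_end = c(30000L, 30400L)))
  mp <- map_peaks(peak_at(10000L), fs)
  expect_equal(mp$feature_id, "Gnear")
  expect_equal(mp$signed_distance, -400)

  fs_tie <- feature_set(genes = data.frame(
    gene_id = c("Gb", "Ga"), chrom = "chr1", strand = c("+", "-"),
    tss = c(10300L, 9700L), tx_start = c(10300L, 4000L),
    tx_end = c(20000L, 9701L)))
  mp <- map_peaks(peak_at(10000L), fs_tie)
  expect_equal(mp$signed_distance, -300)
  expect_equal(mp$feature_id, "Ga")
})

test_that("distance classes follow the promoter window boundaries", {
  cases <- list(list(anchor = 9700L, class = "proximal"),   # -300
                list(anchor = 9500L, class = "proximal"),   # -500 boundary
                list(anchor = 9499L, class = "distal"),     # -501 boundary
                list(anchor = 5000L, class = "distal"),     # -5000 edge
                list(anchor = 10100L, class = "proximal"),  # +100 boundary
                list(anchor = 10600L, class = "transcript"))# +600 in transcript
  for (cs in cases) {
    mp <- map_peaks(peak_at(cs$anchor), single_gene("+"))
    expect_equal(mp$distance_class, cs$class,
                 label = sprintf("anchor %d", cs$anchor))
  }
  # island-only mapping is remote
  fs2 <- feature_set(islands = data.frame(island_id = "I9", chrom = "chr1",
                                          start = 9800L, end = 10300L))
  expect_equal(map_peaks(peak_at(10000L), fs2)$distance_class, "remote")
  # unmapped peaks carry no class
  far <- map_peaks(peak_at(10000L),
                   feature_set(islands = data.frame(island_id = "I9",
                                                    chrom = "chr9",
                                                    start = 1L, end = 2L)))
  expect_equal(far$feature_class, "unmapped")
  expect_true(is.na(far$distance_class))
})

test_that("every mapped peak gets exactly one class and counts partition", {
  cfg <- small_cfg(n_genes = 150, seed = 19)
  ann <- generate_annotation(cfg)
  truth <- simulate_methylomes(cfg, ann)
  tr <- windowed_ks(simulate_probe_signals(cfg, ann, truth)[["B.liver"]])
  pk <- call_peaks(tr, peak_params(cutoff = 2))
  mp <- map_peaks(pk, ann)
  expect_equal(nrow(mp), nrow(pk))
  expect_equal(anyDuplicated(mp$peak_id), 0)
  mapped <- mp[mp$feature_class != "unmapped", ]
  expect_true(all(mapped$distance_class %in%
                    c("distal", "proximal", "transcript", "remote")))
  tab <- tabulate_distance_classes(mp, min_value = 0)
  expect_equal(sum(tab$n), nrow(mapped))
  # TSS-mapped peaks stay inside the mapping window
  tssm <- mapped[mapped$feature_class == "TSS", ]
  expect_true(all(tssm$signed_distance >= -5000 & tssm$signed_distance <= 1000))
})

test_that("mapping is invariant under genome reflection", {
  L <- 50000L
  fs <- demo_features()
  reflect_fs <- feature_set(
    genes = data.frame(gene_id = fs$genes$gene_id, chrom = fs$genes$chrom,
                       strand = ifelse(fs$genes$strand == "+", "-", "+"),
                       tss = L - 1L - fs$genes$tss,
                       tx_start = L - fs$genes$tx_end,
                       tx_end = L - fs$genes$tx_start),
    islands = data.frame(island_id = fs$islands$island_id,
                         chrom = fs$islands$chrom,
                         start = L - fs$islands$end,
                         end = L - fs$islands$start),
    tiled_regions = data.frame(region_id = fs$tiled_regions$region_id,
                               chrom = fs$tiled_regions$chrom,
                               start = L - fs$tiled_regions$end,
                               end = L - fs$tiled_regions$start))
  for (anchor in c(5200L, 9400L, 9900L, 10600L, 12000L)) {
    pk <- peak_at(anchor)
    pk_r <- pk
    pk_r$start <- L - pk$end
    pk_r$end <- L - pk$start
    a <- map_peaks(pk, fs)
    b <- map_peaks(pk_r, reflect_fs)
    expect_equal(a$feature_id, b$feature_id, label = sprintf("anchor %d", anchor))
    expect_equal(a$signed_distance, b$signed_distance,
                 label = sprintf("anchor %d", anchor))
    expect_equal(a$distance_class, b$distance_class,
                 label = sprintf("anchor %d", anchor))
  }
})
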