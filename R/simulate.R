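#' Configuration for the synthetic methylome generator
#'
#' The generator emulates the design of a two-strain, three-tissue MeDIP
#' promoter-array study: a toy genome of non-overlapping genes, each with a
#' tiled region around its TSS, promoter CpG islands for a configurable
#' fraction of genes, strain/tissue methylation states with a controllable
#' inter-tissue correlation, planted strain-differential genes, an optional
#' upstream (distal-promoter) relocation of methylated regions in the test
#' strain, an extra enrichment boost for a fraction of test-strain regions,
#' and Gaussian log2-ratio probe emissions.
#'
#' Strain ordering matters: `strains[1]` is the reference strain,
#' `strains[2]` the test ("healer"-like) strain that receives the planted
#' differentials, the upstream shift, and the high-peak boost.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of genes across the genome.
#' @param cpg_island_fraction fraction of genes with a promoter CpG island.
#' @param probe_spacing mean gap (bp) between probe centers in tiled regions.
#' @param tile_upstream,tile_downstream tiled extent (bp) upstream /
#'   downstream of each TSS, in gene orientation.
#' @param strains two strain labels (reference first).
#' @param tissues three tissue labels.
#' @param p_methylated baseline probability that a promoter region is
#'   methylated in a given strain (default 0.5: in somatic mammalian
#'   tissue most multi-kb promoter tiles contain some methylated DNA).
#' @param diff_hypo_frac,diff_hyper_frac fractions of genes planted as
#'   test-strain hypo-/hypermethylated (their sum must be <= 1).
#' @param tissue_correlation target Pearson correlation of binary
#'   methylation states across tissues, per strain (scalar or one value per
#'   strain, named or in strain order).
#' @param upstream_shift_frac fraction of test-strain methylated regions
#'   relocated from the proximal promoter window (-500..+100 bp) to the
#'   distal window (-5000..-501 bp).
#' @param high_peak_boost extra enrichment (in units of
#'   `mu_methylated - mu_background`) added to boosted test-strain regions.
#' @param high_boost_frac fraction of test-strain regions receiving the boost.
#' @param region_length length (bp) of each planted methylated region
#'   (default 900 bp, the scale of a methylated promoter CpG-island
#'   domain). Regions are placed by their midpoint: proximal regions
#'   center inside -450..-50 bp from the TSS, distal ones inside
#'   -4300..-800 bp, keeping the region midpoint clear of the distance
#'   class boundaries.
#' @param tx_length_range min/max primary-transcript length (bp).
#' @param mu_background,mu_methylated,sigma log2-ratio emission parameters;
#'   `sigma = 0` is the exact noiseless limit.
#' @param seed integer seed; identical seed + config give bit-identical
#'   output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 2L, chrom_length = 1.2e7, n_genes = 1000L,
                       cpg_island_fraction = 0.6, probe_spacing = 100L,
                       tile_upstream = 5500L, tile_downstream = 1500L,
                       strains = c("A", "B"),
                       tissues = c("heart", "liver", "spleen"),
                       p_methylated = 0.5,
                       diff_hypo_frac = 0.05, diff_hyper_frac = 0.05,
                       tissue_correlation = c(0.65, 0.85),
                       upstream_shift_frac = 0.4,
                       high_peak_boost = 1.0, high_boost_frac = 0.15,
                       region_length = 900L,
                       tx_length_range = c(1000L, 6000L),
                       mu_background = 0, mu_methylated = 1, sigma = 0.5,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.numeric(chrom_length),
              n_genes = as.integer(n_genes),
              cpg_island_fraction = cpg_island_fraction,
              probe_spacing = as.integer(probe_spacing),
              tile_upstream = as.integer(tile_upstream),
              tile_downstream = as.integer(tile_downstream),
              strains = as.character(strains), tissues = as.character(tissues),
              p_methylated = p_methylated,
              diff_hypo_frac = diff_hypo_frac, diff_hyper_frac = diff_hyper_frac,
              tissue_correlation = tissue_correlation,
              upstream_shift_frac = upstream_shift_frac,
              high_peak_boost = high_peak_boost, high_boost_frac = high_boost_frac,
              region_length = as.integer(region_length),
              tx_length_range = as.integer(tx_length_range),
              mu_background = mu_background, mu_methylated = mu_methylated,
              sigma = sigma, seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fr <- c("cpg_island_fraction", "p_methylated", "diff_hypo_frac",
          "diff_hyper_frac", "upstream_shift_frac", "high_boost_frac")
  for (f in fr) {
    assert_that(is.numeric(cfg[[f]]) && all(cfg[[f]] >= 0 & cfg[[f]] <= 1),
                sprintf("%s must lie in [0, 1]", f))
  }
  assert_that(cfg$diff_hypo_frac + cfg$diff_hyper_frac <= 1,
              "diff_hypo_frac + diff_hyper_frac must be <= 1")
  assert_that(length(cfg$strains) == 2L, "exactly two strains are required")
  assert_that(length(cfg$tissues) >= 2L, "at least two tissues are required")
  assert_that(cfg$mu_methylated > cfg$mu_background,
              "mu_methylated must exceed mu_background")
  assert_that(cfg$sigma >= 0, "sigma must be >= 0")
  assert_that(cfg$probe_spacing >= 1L, "probe_spacing must be >= 1")
  rho <- cfg$tissue_correlation
  assert_that(all(rho >= 0 & rho <= 1), "tissue_correlation must lie in [0, 1]")
  if (length(rho) == 1L) rho <- rep(rho, 2L)
  assert_that(length(rho) == 2L, "tissue_correlation needs one value per strain")
  if (is.null(names(rho))) names(rho) <- cfg$strains
  cfg$tissue_correlation <- rho
  assert_that(cfg$region_length >= 1L && cfg$region_length <= 1200L,
              "region_length must be in [1, 1200] bp")
  half <- ceiling(cfg$region_length / 2)
  assert_that(cfg$tile_upstream >= 4300L + half &&
                cfg$tile_downstream >= half,
              "tiled regions too narrow for the distal/proximal region placement")
  assert_that(all(cfg$tx_length_range >= 1L) &&
                cfg$tx_length_range[1] <= cfg$tx_length_range[2],
              "tx_length_range must be an increasing positive pair")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d genes on %d chromosome(s), %s x %s, seed %d\n",
              x$n_genes, x$n_chromosomes, paste(x$strains, collapse = "/"),
              paste(x$tissues, collapse = "/"), x$seed))
  invisible(x)
}

#' Generate the toy genome annotation
#'
#' Places `n_genes` non-overlapping genes (random strand), each with a TSS,
#' a primary transcript starting at the TSS, and a tiled region covering
#' `[TSS - tile_upstream, TSS + tile_downstream]` in gene orientation; a
#' configured fraction of genes receive a promoter CpG island overlapping
#' the TSS. Deterministic under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return A [feature_set()].
#' @export
generate_annotation <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  n <- cfg$n_genes
  if (n == 0L) return(feature_set())
  per_chrom <- ceiling(n / cfg$n_chromosomes)
  slot <- floor(cfg$chrom_length / per_chrom)
  need_up <- cfg$tile_upstream
  need_dn <- max(cfg$tile_downstream, cfg$tx_length_range[2])
  assert_that(slot >= need_up + need_dn + 2L,
              sprintf(paste("genome too small to place %d genes without overlap:",
                            "need %d bp per gene, have %d"),
                      n, need_up + need_dn + 2L, slot))
  with_seed(sub_seed(cfg$seed, 1L), {
    i <- seq_len(n)
    chrom <- sprintf("chr%d", (i - 1L) %/% per_chrom + 1L)
    slot0 <- ((i - 1L) %% per_chrom) * slot
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tx_len <- sample(seq(cfg$tx_length_range[1], cfg$tx_length_range[2]), n,
                     replace = TRUE)
    free <- slot - need_up - need_dn - 1L
    jitter <- floor(runif(n) * (free + 1L))
    tss <- ifelse(strand == "+", slot0 + need_up + jitter, slot0 + need_dn + jitter)
    tx_start <- ifelse(strand == "+", tss, tss - tx_len + 1L)
    tx_end <- ifelse(strand == "+", tss + tx_len, tss + 1L)
    has_island <- runif(n) < cfg$cpg_island_fraction
  })
  gene_id <- sprintf("G%05d", i)
  genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      tss = as.integer(tss), tx_start = as.integer(tx_start),
                      tx_end = as.integer(tx_end))
  tiv <- oriented_interval(tss, strand, -cfg$tile_upstream, cfg$tile_downstream)
  tiled <- data.frame(region_id = paste0("TR_", gene_id), chrom = chrom,
                      start = as.integer(tiv$start), end = as.integer(tiv$end))
  iiv <- oriented_interval(tss, strand, -200L, 300L)
  islands <- data.frame(island_id = paste0("CGI_", gene_id), chrom = chrom,
                        start = as.integer(iiv$start), end = as.integer(iiv$end))
  islands <- islands[has_island, , drop = FALSE]
  feature_set(genes, islands, tiled)
}

#' Simulate strain/tissue methylation states with planted structure
#'
#' Per strain, each gene has a latent methylation state (Bernoulli with
#' `p_methylated`); each tissue copies the latent state with probability
#' `q = sqrt(tissue_correlation)` and redraws it otherwise, which makes the
#' between-tissue correlation of binary states equal `q^2 =
#' tissue_correlation` exactly in expectation. Planted differential genes
#' (`diff_hypo_frac` hypo, `diff_hyper_frac` hyper in the test strain) are
#' held fixed across tissues: hypo means methylated in the reference strain
#' and unmethylated in the test strain in every tissue, and vice versa.
#'
#' Each methylated gene region occupies the proximal promoter window
#' (-500..+100 bp from the TSS, gene-oriented); in the test strain a
#' `upstream_shift_frac` fraction of regions is relocated into the distal
#' window (-5000..-501 bp), and a `high_boost_frac` fraction receives an
#' enrichment boost of `high_peak_boost`.
#'
#' @param cfg a [sim_config()].
#' @param features annotation from [generate_annotation()].
#' @return A `true_methylome`: list with `states` (long data.frame of
#'   binary states per strain/tissue/gene), `labels` (planted gene label:
#'   none/hypo/hyper), `regions` (per gene and strain: interval, enrichment
#'   level, planted distance class), and `intervals` (methylated intervals
#'   per strain/tissue sample).
#' @export
simulate_methylomes <- function(cfg, features) {
  cfg <- validate_sim_config(cfg)
  genes <- features$genes
  n <- nrow(genes)
  ref <- cfg$strains[1]; tst <- cfg$strains[2]
  if (n == 0L) {
    empty_states <- data.frame(strain = character(0), tissue = character(0),
                               gene_id = character(0), state = integer(0))
    return(structure(list(states = empty_states,
                          labels = data.frame(gene_id = character(0),
                                              label = character(0)),
                          regions = data.frame(gene_id = character(0),
                                               strain = character(0),
                                               chrom = character(0),
                                               start = integer(0),
                                               end = integer(0),
                                               level = numeric(0),
                                               planted_class = character(0)),
                          intervals = data.frame(strain = character(0),
                                                 tissue = character(0),
                                                 gene_id = character(0),
                                                 chrom = character(0),
                                                 start = integer(0), end = integer(0),
                                                 level = numeric(0))),
                     class = "true_methylome", seed = cfg$seed, config = cfg))
  }
  L <- cfg$region_length
  out <- with_seed(sub_seed(cfg$seed, 2L), {
    n_hypo <- round(n * cfg$diff_hypo_frac)
    n_hyper <- round(n * cfg$diff_hyper_frac)
    perm <- sample.int(n)
    hypo_idx <- perm[seq_len(n_hypo)]
    hyper_idx <- perm[n_hypo + seq_len(n_hyper)]
    label <- rep("none", n)
    label[hypo_idx] <- "hypo"; label[hyper_idx] <- "hyper"

    latent <- list()
    latent[[ref]] <- rbinom(n, 1L, cfg$p_methylated)
    latent[[ref]][hypo_idx] <- 1L; latent[[ref]][hyper_idx] <- 0L
    latent[[tst]] <- latent[[ref]]
    latent[[tst]][hypo_idx] <- 0L; latent[[tst]][hyper_idx] <- 1L

    planted <- label != "none"
    states <- list()
    for (s in cfg$strains) {
      q <- sqrt(cfg$tissue_correlation[[s]])
      for (t in cfg$tissues) {
        keep <- rbinom(n, 1L, q) == 1L
        st <- ifelse(keep, latent[[s]], rbinom(n, 1L, cfg$p_methylated))
        st[planted] <- latent[[s]][planted]
        states[[paste(s, t, sep = ".")]] <- as.integer(st)
      }
    }

    # Region geometry per (gene, strain): reference strain regions sit in
    # the proximal window; a fraction of test-strain regions is relocated
    # to the distal window. Regions are placed by midpoint, with margins
    # so that a called peak's anchor stays inside its planted class.
    shifted <- runif(n) < cfg$upstream_shift_frac
    mid_prox <- -450L + floor(runif(n) * (450L - 50L + 1L))
    mid_dist <- -4300L + floor(runif(n) * (4300L - 800L + 1L))
    boosted <- runif(n) < cfg$high_boost_frac
    list(label = label, states = states, shifted = shifted,
         mid_prox = mid_prox, mid_dist = mid_dist, boosted = boosted)
  })

  half_lo <- L %/% 2L
  regions <- do.call(rbind, lapply(cfg$strains, function(s) {
    is_test <- s == tst
    shifted <- if (is_test) out$shifted else rep(FALSE, n)
    mid <- ifelse(shifted, out$mid_dist, out$mid_prox)
    d_lo <- mid - half_lo
    d_hi <- mid + (L - 1L) - half_lo
    iv <- oriented_interval(genes$tss, genes$strand, d_lo, d_hi)
    level <- rep(1, n)
    if (is_test) level[out$boosted] <- 1 + cfg$high_peak_boost
    data.frame(gene_id = genes$gene_id, strain = s, chrom = genes$chrom,
               start = as.integer(iv$start), end = as.integer(iv$end),
               level = level,
               planted_class = ifelse(shifted, "distal", "proximal"))
  }))

  states_long <- do.call(rbind, lapply(names(out$states), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    data.frame(strain = parts[1], tissue = parts[2], gene_id = genes$gene_id,
               state = out$states[[key]])
  }))

  intervals <- merge(states_long[states_long$state == 1L,
                                 c("strain", "tissue", "gene_id")],
                     regions, by = c("gene_id", "strain"), sort = FALSE)
  intervals <- intervals[order(intervals$strain, intervals$tissue,
                               intervals$chrom, intervals$start),
                         c("strain", "tissue", "gene_id", "chrom",
                           "start", "end", "level")]
  rownames(intervals) <- NULL

  structure(list(states = states_long,
                 labels = data.frame(gene_id = genes$gene_id, label = out$label),
                 regions = regions, intervals = intervals),
            class = "true_methylome", seed = cfg$seed, config = cfg)
}

#' @export
print.true_methylome <- function(x, ...) {
  cat(sprintf("<true_methylome> %d genes (%d hypo, %d hyper planted), %d samples\n",
              nrow(x$labels), sum(x$labels$label == "hypo"),
              sum(x$labels$label == "hyper"),
              length(unique(paste(x$states$strain, x$states$tissue)))))
  invisible(x)
}

#' Emit noisy probe-level log2-ratio tracks
#'
#' The probe layout (the "array design") is drawn once from the tiled
#' regions -- probes every `probe_spacing` bp with a random per-region
#' phase -- and shared by every sample, as on a real array platform. A
#' probe whose center lies inside a methylated interval of a sample emits
#' `Normal(mu_background + level * (mu_methylated - mu_background), sigma)`
#' where `level` is the region's enrichment level (1, or `1 +
#' high_peak_boost` for boosted regions); other probes emit
#' `Normal(mu_background, sigma)`.
#'
#' @param cfg a [sim_config()].
#' @param features annotation from [generate_annotation()].
#' @param truth output of [simulate_methylomes()].
#' @return Named list of [probe_track()]s, one per `strain.tissue` sample.
#' @export
simulate_probe_signals <- function(cfg, features, truth) {
  cfg <- validate_sim_config(cfg)
  tiled <- features$tiled_regions
  layout <- with_seed(sub_seed(cfg$seed, 3L), {
    if (nrow(tiled) == 0L) {
      data.frame(chrom = character(0), position = integer(0))
    } else {
      off <- sample.int(cfg$probe_spacing, nrow(tiled), replace = TRUE) - 1L
      pos <- lapply(seq_len(nrow(tiled)), function(r) {
        seq.int(tiled$start[r] + off[r], tiled$end[r] - 1L, by = cfg$probe_spacing)
      })
      data.frame(chrom = rep(tiled$chrom, lengths(pos)), position = unlist(pos))
    }
  })
  layout <- layout[order(layout$chrom, layout$position), , drop = FALSE]
  layout$probe_id <- sprintf("P%07d", seq_len(nrow(layout)))
  delta <- cfg$mu_methylated - cfg$mu_background
  tracks <- list()
  k <- 0L
  for (s in cfg$strains) {
    for (t in cfg$tissues) {
      k <- k + 1L
      iv <- truth$intervals[truth$intervals$strain == s & truth$intervals$tissue == t,
                            , drop = FALSE]
      hit <- points_in_intervals(layout$chrom, layout$position, iv)
      level <- ifelse(is.na(hit), 0, iv$level[hit])
      mu <- cfg$mu_background + level * delta
      val <- with_seed(sub_seed(cfg$seed, 10L + k),
                       rnorm(nrow(layout), mean = mu, sd = cfg$sigma))
      tracks[[paste(s, t, sep = ".")]] <-
        probe_track(data.frame(probe_id = layout$probe_id, chrom = layout$chrom,
                               position = layout$position, log2_ratio = val),
                    strain = s, tissue = t)
    }
  }
  tracks
}

#' Simulate expression tables anti-correlated with promoter methylation
#'
#' Per gene and sample, expression is `baseline + slope * m + Normal(0,
#' noise_sd)` floored at zero, where `m` is the gene's promoter methylation
#' level in that sample (binary state times region enrichment level) and
#' `slope < 0` encodes promoter-methylation repression.
#'
#' @param truth a `true_methylome`.
#' @param features the matching [feature_set()].
#' @param slope regression slope of expression on methylation (negative).
#' @param noise_sd expression noise standard deviation.
#' @param baseline expression level of an unmethylated gene.
#' @param seed RNG seed; defaults to the seed the truth was built with.
#' @return data.frame(gene_id, strain, tissue, value).
#' @export
simulate_expression <- function(truth, features, slope = -2, noise_sd = 0.5,
                                baseline = 8, seed = NULL) {
  assert_that(slope < 0, "slope must be negative (methylation represses)")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  seed <- seed %||% attr(truth, "seed")
  st <- merge(truth$states, truth$regions[, c("gene_id", "strain", "level")],
              by = c("gene_id", "strain"), sort = FALSE)
  st$m <- st$state * st$level
  st <- st[order(st$strain, st$tissue, st$gene_id), , drop = FALSE]
  st$value <- with_seed(sub_seed(seed, 50L),
                        pmax(0, baseline + slope * st$m +
                               rnorm(nrow(st), 0, noise_sd)))
  rownames(st) <- NULL
  st[, c("gene_id", "strain", "tissue", "value")]
}

#' Write an expression table as TSV
#' @param expr data.frame from [simulate_expression()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(output_header(), con)
  write.table(expr, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
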