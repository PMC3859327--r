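#' Per-gene methylation vectors for profile correlation
#'
#' Follows the cross-platform recipe used for genome-wide profile
#' comparisons: only TSS-mapped peaks at cutoff 1.0 contribute; genes with
#' more than one mapped peak get the average value; genes with no peak at
#' the cutoff are assigned 0.
#'
#' @param mapped resolved mappings from [map_peaks()] over all samples.
#' @param genes optional character vector of gene ids defining the row
#'   universe (defaults to the genes observed in `mapped`).
#' @param cutoff peak cutoff whose mappings are used (default 1.0).
#' @return numeric matrix, genes x samples (`strain|tissue` columns).
#' @export
gene_meth_vector <- function(mapped, genes = NULL, cutoff = 1.0) {
  sub <- mapped[!is.na(mapped$feature_class) & mapped$feature_class == "TSS" &
                  mapped$cutoff == cutoff, , drop = FALSE]
  genes <- genes %||% sort(unique(sub$feature_id))
  samples <- unique(mapped[, c("strain", "tissue")])
  samples <- samples[order(samples$strain, samples$tissue), , drop = FALSE]
  cols <- sprintf("%s|%s", samples$strain, samples$tissue)
  m <- matrix(0, nrow = length(genes), ncol = length(cols),
              dimnames = list(genes, cols))
  if (nrow(sub)) {
    dt <- data.table::data.table(gene = sub$feature_id,
                                 col = sprintf("%s|%s", sub$strain, sub$tissue),
                                 value = sub$value)
    agg <- dt[, list(value = mean(value)), by = c("gene", "col")]
    keep <- agg$gene %in% genes
    m[cbind(match(agg$gene[keep], genes), match(agg$col[keep], cols))] <-
      agg$value[keep]
  }
  m
}

#' Pearson correlation between two gene methylation profiles
#'
#' Vectors are aligned by gene id (names); at least three shared genes and
#' nonzero variance on both sides are required.
#'
#' @param vecA,vecB named numeric vectors (gene id -> mean peak value).
#' @return list(r, p.value, n): Pearson r over the shared genes and the
#'   two-sided p-value from the t transform.
#' @export
correlate_profiles <- function(vecA, vecB) {
  assert_that(!is.null(names(vecA)) && !is.null(names(vecB)),
              "profile vectors must be named by gene id")
  shared <- intersect(names(vecA), names(vecB))
  assert_that(length(shared) >= 3L, "need at least 3 shared genes")
  x <- vecA[shared]; y <- vecB[shared]
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "undefined correlation: zero variance in a profile")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(shared))
}

#' All within-strain inter-tissue profile correlations
#'
#' @param gmm gene methylation matrix from [gene_meth_vector()].
#' @return data.frame(strain, tissue1, tissue2, r, p.value).
#' @export
profile_correlations <- function(gmm) {
  parts <- strsplit(colnames(gmm), "|", fixed = TRUE)
  strain <- vapply(parts, `[`, character(1), 1L)
  tissue <- vapply(parts, `[`, character(1), 2L)
  out <- list()
  for (s in unique(strain)) {
    cols <- which(strain == s)
    if (length(cols) < 2L) next
    for (i in seq_along(cols)[-length(cols)]) {
      for (j in seq((i + 1L), length(cols))) {
        cp <- correlate_profiles(setNames(gmm[, cols[i]], rownames(gmm)),
                                 setNames(gmm[, cols[j]], rownames(gmm)))
        out[[length(out) + 1L]] <- data.frame(strain = s,
                                              tissue1 = tissue[cols[i]],
                                              tissue2 = tissue[cols[j]],
                                              r = cp$r, p.value = cp$p.value)
      }
    }
  }
  do.call(rbind, out)
}

#' Peak-value bin scheme for methylation-expression summaries
#'
#' The default bins are `{0}`, `(0, 2)`, `[2, 3)`, `[3, 4)`, `[4, Inf)`:
#' a dedicated bin for genes with no called peak, then increasing peak
#' value ranges.
#'
#' @param edges increasing numeric vector of interior bin edges.
#' @return A `bin_scheme`.
#' @export
bin_scheme <- function(edges = c(2, 3, 4)) {
  assert_that(all(diff(edges) > 0) && all(edges > 0),
              "bin edges must be positive and strictly increasing")
  labels <- c("0", sprintf("(0,%g)", edges[1]),
              if (length(edges) > 1)
                sprintf("[%g,%g)", edges[-length(edges)], edges[-1]),
              sprintf("[%g,Inf)", edges[length(edges)]))
  structure(list(edges = edges, labels = labels), class = "bin_scheme")
}

assign_bins <- function(values, bins) {
  idx <- ifelse(values == 0, 1L, 2L + findInterval(values, bins$edges))
  factor(bins$labels[idx], levels = bins$labels)
}

#' Wilcoxon rank-sum test (exact enumeration for small samples)
#'
#' Two-tailed rank-sum test on midranks. When both samples have at most
#' `exact_max` observations the null distribution is enumerated exactly
#' over all group labelings (ties handled naturally by midranks) and the
#' p-value doubles the smaller tail (capped at 1); otherwise a normal
#' approximation with continuity and tie correction is used.
#'
#' @param x,y numeric samples.
#' @param exact logical; defaults to both sample sizes `<= exact_max`.
#' @param exact_max size bound for the exact path.
#' @return list(statistic = rank sum of `x`, p.value, method).
#' @export
ranksum_test <- function(x, y, exact = NULL, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  assert_that(n1 >= 1L && n2 >= 1L, "both samples must be non-empty")
  exact <- exact %||% (n1 <= exact_max && n2 <= exact_max)
  pooled <- c(x, y)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(n1)])
  if (exact) {
    sums <- combn(N, n1, FUN = function(i) sum(rk[i]))
    eps <- 1e-9
    p <- 2 * min(mean(sums <= W + eps), mean(sums >= W - eps))
    p <- min(p, 1)
    method <- "exact enumeration"
  } else {
    E <- n1 * (N + 1) / 2
    ties <- table(pooled)
    V <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (V <= 0) {
      p <- 1
    } else {
      z <- (W - E - sign(W - E) * 0.5) / sqrt(V)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }
  list(statistic = W, p.value = p, method = method)
}

#' Expression summaries per methylation bin
#'
#' Genes are assigned to peak-value bins; each bin's expression median and
#' quartiles are reported (optionally normalized to the highest expression
#' value in the dataset), adjacent bins are compared with two-tailed
#' rank-sum tests, and the overall Pearson correlation between methylation
#' and expression is computed.
#'
#' @param meth named numeric vector (gene -> methylation peak value) for
#'   one sample.
#' @param expr named numeric vector (gene -> expression value).
#' @param bins a [bin_scheme()].
#' @param normalize divide the bin summaries by `max(expr)`.
#' @return list(summary = per-bin data.frame, tests = adjacent-bin
#'   rank-sum results, pearson = list(r, p.value)).
#' @export
methylation_expression_summary <- function(meth, expr, bins = bin_scheme(),
                                           normalize = FALSE) {
  shared <- intersect(names(meth), names(expr))
  assert_that(length(shared) >= 1L, "no genes shared by methylation and expression")
  m <- meth[shared]; e <- expr[shared]
  bf <- assign_bins(m, bins)
  scale <- if (normalize) max(e) else 1
  qs <- tapply(e, bf, function(v) quantile(v, c(0.25, 0.5, 0.75), names = FALSE))
  summ <- data.frame(bin = levels(bf),
                     n = as.integer(table(bf)),
                     q1 = vapply(qs, function(q) if (is.null(q)) NA_real_ else q[1] / scale, 0),
                     median = vapply(qs, function(q) if (is.null(q)) NA_real_ else q[2] / scale, 0),
                     q3 = vapply(qs, function(q) if (is.null(q)) NA_real_ else q[3] / scale, 0))
  rownames(summ) <- NULL
  occupied <- which(summ$n > 0)
  tests <- list()
  if (length(occupied) >= 2L) {
    for (k in seq_len(length(occupied) - 1L)) {
      b1 <- summ$bin[occupied[k]]; b2 <- summ$bin[occupied[k + 1L]]
      rs <- ranksum_test(e[bf == b1], e[bf == b2])
      tests[[paste(b1, b2, sep = " vs ")]] <- rs
    }
  }
  pearson <- if (stats::sd(m) > 0 && stats::sd(e) > 0) {
    ct <- stats::cor.test(m, e, method = "pearson")
    list(r = unname(ct$estimate), p.value = ct$p.value)
  } else {
    list(r = NA_real_, p.value = NA_real_)
  }
  list(summary = summ, tests = tests, pearson = pearson)
}

#' Tabulate peak counts by promoter distance class
#'
#' Unique peaks with value at or above `min_value` are counted once per
#' distance class and sample. With `diff_only = TRUE`, only peaks mapped
#' to differentially methylated features (per `calls`, matched by tissue)
#' are counted.
#'
#' @param mapped resolved mappings from [map_peaks()] at a single cutoff.
#' @param min_value peak value threshold (default 2.0).
#' @param diff_only restrict to peaks on differentially called features.
#' @param calls [call_differential()] output (required when `diff_only`).
#' @return data.frame(strain, tissue, distance_class, n) with zero-filled
#'   combinations.
#' @export
tabulate_distance_classes <- function(mapped, min_value = 2.0,
                                      diff_only = FALSE, calls = NULL) {
  classes <- c("distal", "proximal", "transcript", "remote")
  sub <- mapped[!is.na(mapped$distance_class) & mapped$value >= min_value, ,
                drop = FALSE]
  if (diff_only) {
    assert_that(!is.null(calls), "diff_only requires the calls data.frame")
    key <- paste(sub$feature_id, sub$tissue)
    sub <- sub[key %in% paste(calls$feature_id, calls$tissue), , drop = FALSE]
  }
  samples <- unique(mapped[, c("strain", "tissue")])
  grid <- data.frame(samples[rep(seq_len(nrow(samples)), each = length(classes)),
                             , drop = FALSE],
                     distance_class = rep(classes, times = nrow(samples)),
                     row.names = NULL)
  if (nrow(sub)) {
    sub <- sub[!duplicated(sub[, c("peak_id", "strain", "tissue")]), , drop = FALSE]
    dt <- data.table::data.table(sub)
    cnt <- as.data.frame(dt[, list(n = .N),
                            by = c("strain", "tissue", "distance_class")])
  } else {
    cnt <- data.frame(strain = character(0), tissue = character(0),
                      distance_class = character(0), n = integer(0))
  }
  out <- merge(grid, cnt, by = c("strain", "tissue", "distance_class"),
               all.x = TRUE)
  out$n[is.na(out$n)] <- 0L
  out$distance_class <- factor(out$distance_class, levels = classes)
  out <- out[order(out$strain, out$tissue, out$distance_class), ]
  rownames(out) <- NULL
  out
}

#' EASE-score category enrichment
#'
#' One-sided Fisher's exact test made conservative by removing one gene
#' from the hit/category overlap: with `N = |background|`,
#' `K = |category|`, `n = |hits|` and overlap `k`, the p-value is the
#' hypergeometric tail `P(X >= max(k - 1, 0))`. An empty overlap therefore
#' gives p = 1, and the EASE p-value is always at least the unmodified
#' Fisher p-value.
#'
#' @param hit_set,category,background character vectors of feature ids;
#'   `hit_set` and `category` must be subsets of `background`.
#' @return list(p.value, overlap, hits, category_size, background_size).
#' @export
ease_enrichment <- function(hit_set, category, background) {
  background <- unique(background)
  hit_set <- unique(hit_set); category <- unique(category)
  assert_that(length(background) >= 1L, "background must not be empty")
  assert_that(length(hit_set) >= 1L, "hit set must not be empty")
  assert_that(all(hit_set %in% background) && all(category %in% background),
              "hit set and category must be subsets of the background")
  k <- length(intersect(hit_set, category))
  K <- length(category); N <- length(background); n <- length(hit_set)
  k_ease <- max(k - 1L, 0L)
  p <- stats::phyper(k_ease - 1L, K, N - K, n, lower.tail = FALSE)
  list(p.value = p, overlap = k, hits = n, category_size = K,
       background_size = N)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; adjusted values are capped at 1
#' and never smaller than the raw p-values.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
benjamini_adjust <- function(pvalues) {
  assert_that(all(pvalues >= 0 & pvalues <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Methylation ratio from qPCR Ct values (2^-dCt)
#'
#' Expresses a methylation-sensitive digestion qPCR readout as
#' `2^-(Ct_target - Ct_reference)`: equal Ct values give 1, each extra
#' target cycle halves the ratio.
#'
#' @param ct_target,ct_reference finite Ct values (cycles); vectorized.
#' @return numeric ratio(s).
#' @export
delta_ct_ratio <- function(ct_target, ct_reference) {
  assert_that(all(is.finite(ct_target)) && all(is.finite(ct_reference)),
              "Ct values must be finite")
  2^(-(ct_target - ct_reference))
}
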