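#' Consolidate mapped peaks into a feature-by-sample methylation matrix
#'
#' One row per feature (post-priority mapping), one column per
#' `(strain, tissue, cutoff)` combination; a cell holds the maximum value
#' among that sample/cutoff's peaks mapped to the feature, or 0 when no
#' peak maps there. Peak nesting across cutoffs guarantees that a nonzero
#' cell at cutoff 2.0 implies a nonzero cell at cutoff 1.0.
#'
#' @param mapped resolved mappings from [map_peaks()] over all samples and
#'   both cutoffs.
#' @param features optional [feature_set()]; when given, every feature id
#'   (genes, islands, tiled regions) gets a row even if no peak mapped to
#'   it. Duplicate ids across feature classes are an error.
#' @return A `meth_matrix`: numeric matrix with feature ids as rownames
#'   and `strain|tissue|cutoff` column labels.
#' @export
build_matrix <- function(mapped, features = NULL) {
  mapped <- as.data.frame(mapped)
  mapped <- mapped[!is.na(mapped$feature_id), , drop = FALSE]
  if (!is.null(features)) {
    ids <- c(features$genes$gene_id, features$islands$island_id,
             features$tiled_regions$region_id)
    assert_that(!anyDuplicated(ids), "duplicate feature ids across classes")
  } else {
    ids <- sort(unique(mapped$feature_id))
  }
  samples <- unique(mapped[, c("strain", "tissue", "cutoff"), drop = FALSE])
  samples <- samples[order(samples$strain, samples$tissue, samples$cutoff), ,
                     drop = FALSE]
  cols <- sprintf("%s|%s|%g", samples$strain, samples$tissue, samples$cutoff)
  m <- matrix(0, nrow = length(ids), ncol = length(cols),
              dimnames = list(ids, cols))
  if (nrow(mapped)) {
    col_of <- sprintf("%s|%s|%g", mapped$strain, mapped$tissue, mapped$cutoff)
    dt <- data.table::data.table(feature_id = mapped$feature_id, col = col_of,
                                 value = mapped$value)
    agg <- dt[, list(value = max(value)), by = c("feature_id", "col")]
    keep <- agg$feature_id %in% ids
    m[cbind(match(agg$feature_id[keep], ids), match(agg$col[keep], cols))] <-
      agg$value[keep]
  }
  class(m) <- c("meth_matrix", class(m))
  m
}

# Column of a meth_matrix for one (strain, tissue, cutoff); all-zero if
# the sample never produced a peak at that cutoff but others did.
mm_col <- function(mat, strain, tissue, cutoff) {
  lbl <- sprintf("%s|%s|%g", strain, tissue, cutoff)
  if (!lbl %in% colnames(mat)) {
    has_sample <- any(grepl(sprintf("^%s\\|%s\\|", strain, tissue), colnames(mat)))
    assert_that(has_sample, sprintf("sample %s/%s missing from matrix", strain, tissue))
    return(setNames(rep(0, nrow(mat)), rownames(mat)))
  }
  setNames(mat[, lbl], rownames(mat))
}

#' Two-condition differential-methylation caller
#'
#' A feature is called hypermethylated in the test strain (for a tissue)
#' when, with `test` the feature's merged peak value in the test strain
#' (max over cutoffs 1.0 and 2.0) and `ref` its value at cutoff 1.0 in the
#' reference strain, either
#' * condition **i**: `test >= 3.0` and `test >= 2 * ref`, or
#' * condition **ii**: `test >= 2.0` and `ref < 1.0`.
#'
#' Hypomethylated-in-test calls are hypermethylated calls with the strain
#' roles swapped; `test_value` always refers to the strain in which
#' methylation is present, so the condition invariants hold for both
#' directions.
#'
#' @param mat a `meth_matrix` from [build_matrix()].
#' @param test_strain,ref_strain strain labels present in the matrix.
#' @param tissue tissue label present in the matrix.
#' @return data.frame(feature_id, tissue, direction, condition,
#'   test_value, ref_value); `direction` is relative to `test_strain`.
#' @export
call_differential <- function(mat, test_strain, ref_strain, tissue) {
  one_direction <- function(hi_strain, lo_strain, direction) {
    hi <- pmax(mm_col(mat, hi_strain, tissue, 1), mm_col(mat, hi_strain, tissue, 2))
    lo <- mm_col(mat, lo_strain, tissue, 1)
    cond_i <- hi >= 3.0 & hi >= 2 * lo
    cond_ii <- !cond_i & hi >= 2.0 & lo < 1.0
    sel <- cond_i | cond_ii
    if (!any(sel)) {
      return(data.frame(feature_id = character(0), tissue = character(0),
                        direction = character(0), condition = character(0),
                        test_value = numeric(0), ref_value = numeric(0)))
    }
    data.frame(feature_id = names(hi)[sel], tissue = tissue,
               direction = direction,
               condition = ifelse(cond_i[sel], "i", "ii"),
               test_value = unname(hi[sel]), ref_value = unname(lo[sel]))
  }
  out <- rbind(one_direction(test_strain, ref_strain, "hyper"),
               one_direction(ref_strain, test_strain, "hypo"))
  rownames(out) <- NULL
  out
}

#' Tissue intersections of differential calls
#'
#' @param calls either a single data.frame of [call_differential()] output
#'   stacked over tissues, or a list of per-tissue data.frames.
#' @return A list per direction (`hyper`, `hypo`), each with
#'   `features_all` (features called in every tissue), `n_all`,
#'   `by_degree` (how many features are called in exactly 1, 2, ...
#'   tissues) and `venn` (counts per tissue combination).
#' @export
intersect_tissues <- function(calls) {
  if (is.data.frame(calls)) df <- calls else df <- do.call(rbind, calls)
  tissues <- sort(unique(df$tissue))
  k <- length(tissues)
  assert_that(k >= 2L, "intersect_tissues needs calls for at least two tissues")
  per_dir <- function(direction) {
    sub <- unique(df[df$direction == direction, c("feature_id", "tissue")])
    if (nrow(sub) == 0L) {
      return(list(features_all = character(0), n_all = 0L,
                  by_degree = setNames(rep(0L, k), as.character(seq_len(k))),
                  venn = integer(0)))
    }
    sig <- tapply(sub$tissue, sub$feature_id,
                  function(tt) paste(sort(unique(tt)), collapse = "&"))
    deg <- tapply(sub$tissue, sub$feature_id, function(tt) length(unique(tt)))
    by_degree <- setNames(rep(0L, k), as.character(seq_len(k)))
    tab <- table(factor(deg, levels = seq_len(k)))
    by_degree[names(tab)] <- as.integer(tab)
    all_sig <- paste(tissues, collapse = "&")
    list(features_all = sort(names(sig)[sig == all_sig]),
         n_all = sum(sig == all_sig),
         by_degree = by_degree,
         venn = table(sig))
  }
  list(hyper = per_dir("hyper"), hypo = per_dir("hypo"), tissues = tissues)
}

#' Cross-tissue concordance sets between two strains
#'
#' Identifies features whose methylation status in `tissue1` of strain A
#' resembles (set 2) or contrasts (set 1) the status in strain B, using
#' the differential caller's constants: "methylated" means a cutoff-1.0
#' peak value at or above `meth_threshold`, "unmethylated" below
#' `unmeth_threshold`.
#'
#' * `set1`: methylated in A/tissue1, unmethylated in A/tissue2 and in
#'   both tissues of strain B ("tissue2-like" pattern lost in B);
#' * `set2`: methylated in A/tissue1, unmethylated in A/tissue2, while
#'   methylated in both tissues of strain B.
#'
#' @param mat a `meth_matrix`.
#' @param strainA,strainB strain labels.
#' @param tissue1,tissue2 tissue labels.
#' @param meth_threshold,unmeth_threshold peak-value thresholds.
#' @return list(set1 = character vector, set2 = character vector).
#' @export
concordance_sets <- function(mat, strainA, strainB, tissue1, tissue2,
                             meth_threshold = 2.0, unmeth_threshold = 1.0) {
  a1 <- mm_col(mat, strainA, tissue1, 1); a2 <- mm_col(mat, strainA, tissue2, 1)
  b1 <- mm_col(mat, strainB, tissue1, 1); b2 <- mm_col(mat, strainB, tissue2, 1)
  set1 <- a1 >= meth_threshold & a2 < unmeth_threshold &
    b1 < unmeth_threshold & b2 < unmeth_threshold
  set2 <- a1 >= meth_threshold & a2 < unmeth_threshold &
    b1 >= meth_threshold & b2 >= meth_threshold
  list(set1 = sort(rownames(mat)[set1]), set2 = sort(rownames(mat)[set2]))
}
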