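#' Peak-to-feature mapping parameters
#'
#' @param upstream_bp,downstream_bp mapping window around a feature, in
#'   gene orientation (defaults 5000 bp upstream, 1000 bp downstream).
#' @param proximal_upstream,proximal_downstream bounds of the proximal
#'   promoter distance class (defaults -500..+100 bp from the TSS).
#' @return A `map_params` list.
#' @export
map_params <- function(upstream_bp = 5000, downstream_bp = 1000,
                       proximal_upstream = 500, proximal_downstream = 100) {
  assert_that(upstream_bp > 0 && downstream_bp > 0 &&
                proximal_upstream > 0 && proximal_downstream > 0,
              "all mapping distances must be > 0")
  assert_that(proximal_upstream <= upstream_bp,
              "proximal_upstream must not exceed upstream_bp")
  structure(list(upstream_bp = upstream_bp, downstream_bp = downstream_bp,
                 proximal_upstream = proximal_upstream,
                 proximal_downstream = proximal_downstream),
            class = "map_params")
}

feature_priority <- c(TSS = 1L, primary_transcript = 2L, CpG_island = 3L,
                      tiled_region = 4L)

#' All candidate feature assignments for each peak
#'
#' The peak anchor is its midpoint, `floor((start + end) / 2)`. A peak is a
#' candidate for:
#' * a gene **TSS** if the anchor's oriented offset from the TSS lies in
#'   `[-upstream_bp, +downstream_bp]`;
#' * a **primary transcript** if the anchor lies within the transcript
#'   extended by `upstream_bp` upstream and `downstream_bp` downstream in
#'   gene orientation;
#' * a **CpG island** or **tiled region** if the anchor lies within
#'   `[start - upstream_bp, end + downstream_bp]` (strandless).
#'
#' `signed_distance` (negative = upstream) is reported for gene-anchored
#' candidates and is `NA` for strandless features; `tie_distance` is the
#' unsigned distance used for within-class tie-breaking (distance to the
#' feature interval, 0 inside).
#'
#' @param peaks peak data.frame from [call_peaks()].
#' @param features a [feature_set()].
#' @param params a [map_params()].
#' @return data.frame of candidates, one row per (peak, feature) pair.
#' @export
map_candidates <- function(peaks, features, params = map_params()) {
  peaks <- as.data.frame(peaks)
  peaks$anchor <- floor((peaks$start + peaks$end) / 2)
  # shared seqlevel universe keeps findOverlaps quiet across feature classes
  lvls <- unique(c(peaks$chrom, features$genes$chrom, features$islands$chrom,
                   features$tiled_regions$chrom))
  agr <- GenomicRanges::GRanges(factor(peaks$chrom, levels = lvls),
                                IRanges::IRanges(peaks$anchor + 1L, width = 1L))
  up <- params$upstream_bp; dn <- params$downstream_bp
  g <- features$genes
  res <- list()

  overlap_rows <- function(win_start0, win_end0, chrom, meta) {
    keep <- win_end0 > win_start0
    if (!any(keep)) return(NULL)
    wgr <- GenomicRanges::GRanges(factor(chrom[keep], levels = lvls),
                                  IRanges::IRanges(win_start0[keep] + 1L,
                                                   win_end0[keep]))
    fo <- GenomicRanges::findOverlaps(agr, wgr)
    if (!length(fo)) return(NULL)
    cbind(peaks[S4Vectors::queryHits(fo), , drop = FALSE],
          meta[keep, , drop = FALSE][S4Vectors::subjectHits(fo), , drop = FALSE])
  }

  if (nrow(g)) {
    # TSS windows: oriented offsets -up..+dn around the TSS.
    tiv <- oriented_interval(g$tss, g$strand, -up, dn)
    meta <- data.frame(feature_id = g$gene_id, feature_class = "TSS",
                       f_tss = g$tss, f_strand = g$strand,
                       f_tx_start = g$tx_start, f_tx_end = g$tx_end,
                       f_start = g$tx_start, f_end = g$tx_end)
    res$tss <- overlap_rows(tiv$start, tiv$end, g$chrom, meta)

    # Primary-transcript windows: transcript extended -up/+dn in orientation.
    ps <- ifelse(g$strand == "+", g$tx_start - up, g$tx_start - dn)
    pe <- ifelse(g$strand == "+", g$tx_end + dn, g$tx_end + up)
    meta$feature_class <- "primary_transcript"
    res$pt <- overlap_rows(ps, pe, g$chrom, meta)
  }
  strandless <- function(df, id_col, class) {
    if (!nrow(df)) return(NULL)
    meta <- data.frame(feature_id = df[[id_col]], feature_class = class,
                       f_tss = NA_integer_, f_strand = NA_character_,
                       f_tx_start = NA_integer_, f_tx_end = NA_integer_,
                       f_start = df$start, f_end = df$end)
    overlap_rows(df$start - up, df$end + dn, df$chrom, meta)
  }
  res$island <- strandless(features$islands, "island_id", "CpG_island")
  res$tiled <- strandless(features$tiled_regions, "region_id", "tiled_region")

  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    out <- cbind(peaks[0, , drop = FALSE],
                 data.frame(feature_id = character(0), feature_class = character(0),
                            f_tss = integer(0), f_strand = character(0),
                            f_tx_start = integer(0), f_tx_end = integer(0),
                            f_start = integer(0), f_end = integer(0)))
  }
  out$signed_distance <- ifelse(is.na(out$f_strand), NA_real_,
                                oriented_offset(out$anchor, out$f_tss, out$f_strand))
  out$tie_distance <- ifelse(is.na(out$f_strand),
                             pmax(out$f_start - out$anchor,
                                  out$anchor - (out$f_end - 1L), 0),
                             abs(out$signed_distance))
  rownames(out) <- NULL
  out
}

#' Resolve each peak to a single feature by priority
#'
#' Candidate classes are ranked TSS > primary transcript > CpG island >
#' tiled region; ties within a class are broken by smallest unsigned
#' distance, then lexical feature id. The winning assignment is then given
#' a promoter distance class by [classify_distance()].
#'
#' @param candidates output of [map_candidates()].
#' @param params a [map_params()].
#' @return data.frame with one row per peak: the winning feature,
#'   `signed_distance`, and `distance_class`.
#' @export
resolve_priority <- function(candidates, params = map_params()) {
  if (nrow(candidates) == 0L) {
    out <- candidates
    out$distance_class <- character(0)
    return(out)
  }
  dt <- data.table::data.table(candidates)
  dt[, prio := feature_priority[feature_class]]
  data.table::setorder(dt, peak_id, strain, tissue, cutoff, prio, tie_distance,
                       feature_id)
  win <- as.data.frame(dt[!duplicated(dt[, c("peak_id", "strain", "tissue",
                                             "cutoff")]), ])
  win$distance_class <- classify_distance(win, params)
  win$prio <- NULL
  rownames(win) <- NULL
  win
}

#' Promoter distance class of a mapped peak
#'
#' Gene-mapped peaks (TSS or primary transcript) are classified by the
#' anchor's oriented offset `d` from the TSS: **proximal** if `d` lies in
#' `[-proximal_upstream, +proximal_downstream]` (closed; this precedes the
#' transcript class), else **distal** if in `[-upstream_bp,
#' -proximal_upstream - 1]`, else **transcript** if the anchor falls within
#' the primary transcript or up to `downstream_bp` past its 3' end.
#' Peaks mapped to CpG islands or tiled regions are **remote**.
#'
#' @param mapped data.frame of resolved mappings (from
#'   [resolve_priority()]).
#' @param params a [map_params()].
#' @return character vector of distance classes (NA for unmapped rows).
#' @export
classify_distance <- function(mapped, params = map_params()) {
  d <- mapped$signed_distance
  cls <- rep(NA_character_, nrow(mapped))
  is_gene <- mapped$feature_class %in% c("TSS", "primary_transcript")
  prox <- is_gene & d >= -params$proximal_upstream & d <= params$proximal_downstream
  distal <- is_gene & !prox & d >= -params$upstream_bp & d <= -(params$proximal_upstream + 1)
  in_tx <- ifelse(mapped$f_strand == "+",
                  mapped$anchor >= mapped$f_tx_start &
                    mapped$anchor < mapped$f_tx_end + params$downstream_bp,
                  mapped$anchor >= mapped$f_tx_start - params$downstream_bp &
                    mapped$anchor < mapped$f_tx_end)
  tx <- is_gene & !prox & !distal & in_tx
  cls[prox] <- "proximal"; cls[distal] <- "distal"; cls[tx] <- "transcript"
  cls[is_gene & is.na(cls)] <- "transcript"
  cls[!is_gene] <- "remote"
  cls
}

#' Map peaks to features and classify their promoter distance
#'
#' Convenience wrapper chaining [map_candidates()] and
#' [resolve_priority()]. Peaks with no candidate feature are returned with
#' `feature_class = "unmapped"` and no distance class.
#'
#' @inheritParams map_candidates
#' @return data.frame with one row per peak.
#' @export
map_peaks <- function(peaks, features, params = map_params()) {
  cand <- map_candidates(peaks, features, params)
  win <- resolve_priority(cand, params)
  key <- function(df) paste(df$peak_id, df$strain, df$tissue, df$cutoff)
  peaks <- as.data.frame(peaks)
  peaks$anchor <- floor((peaks$start + peaks$end) / 2)
  missing <- peaks[!(key(peaks) %in% key(win)), , drop = FALSE]
  if (nrow(missing)) {
    missing$feature_id <- NA_character_
    missing$feature_class <- "unmapped"
    missing$f_tss <- NA_integer_; missing$f_strand <- NA_character_
    missing$f_tx_start <- NA_integer_; missing$f_tx_end <- NA_integer_
    missing$f_start <- NA_integer_; missing$f_end <- NA_integer_
    missing$signed_distance <- NA_real_
    missing$tie_distance <- NA_real_
    missing$distance_class <- NA_character_
    win <- rbind(win, missing[, names(win), drop = FALSE])
  }
  win <- win[order(win$strain, win$tissue, win$cutoff, win$chrom, win$start), ]
  rownames(win) <- NULL
  win
}
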