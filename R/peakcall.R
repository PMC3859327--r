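#' Peak-calling parameters
#'
#' @param cutoff P-score cutoff(s) at which peaks are called; the pipeline
#'   conventionally uses 1.0 and 2.0.
#' @param max_spacing maximum center-to-center gap (bp) between consecutive
#'   member probes.
#' @param min_probes minimum member probes per peak.
#' @param high_threshold value at and above which a peak counts as a "high"
#'   methylation peak.
#' @return A `peak_params` list.
#' @export
peak_params <- function(cutoff = 2.0, max_spacing = 500, min_probes = 2L,
                        high_threshold = 4.0) {
  assert_that(all(cutoff > 0), "cutoff must be > 0")
  assert_that(max_spacing > 0, "max_spacing must be > 0")
  assert_that(min_probes >= 2, "min_probes must be >= 2")
  structure(list(cutoff = cutoff, max_spacing = max_spacing,
                 min_probes = as.integer(min_probes),
                 high_threshold = high_threshold),
            class = "peak_params")
}

#' Call methylation peaks from a scored track
#'
#' A peak is a maximal run of probes with `pscore >= cutoff` in which
#' consecutive member probes are separated by at most `max_spacing` bp
#' (center to center); runs with fewer than `min_probes` members are
#' discarded. The peak interval spans the first to last member probe
#' center (half-open end, +1); its value is the maximum member P-score.
#'
#' @param track a [probe_track()] with P-scores set (see [windowed_ks()]).
#' @param params a [peak_params()]; every cutoff in `params$cutoff` is
#'   called and the results are stacked with a `cutoff` column.
#' @return data.frame(peak_id, chrom, start, end, value, n_probes, cutoff,
#'   strain, tissue).
#' @export
call_peaks <- function(track, params = peak_params()) {
  assert_that(inherits(track, "probe_track"), "track must be a probe_track")
  assert_that(!any(is.na(track$pscore)), "pscores unset: run windowed_ks first")
  strain <- attr(track, "strain"); tissue <- attr(track, "tissue")
  one_cutoff <- function(co) {
    keep <- track$pscore >= co
    sub <- as.data.frame(track)[keep, , drop = FALSE]
    if (nrow(sub) == 0L) return(empty_peaks())
    new_run <- c(TRUE, sub$chrom[-1] != sub$chrom[-nrow(sub)] |
                   diff(sub$position) > params$max_spacing)
    grp <- cumsum(new_run)
    dt <- data.table::data.table(sub, grp = grp)
    pk <- dt[, list(chrom = chrom[1L], start = position[1L],
                    end = position[.N] + 1L, value = max(pscore),
                    n_probes = .N), by = "grp"]
    pk <- pk[pk$n_probes >= params$min_probes, ]
    if (nrow(pk) == 0L) return(empty_peaks())
    data.frame(peak_id = sprintf("%s.%s_c%g_pk%05d", strain, tissue, co,
                                 seq_len(nrow(pk))),
               chrom = pk$chrom, start = pk$start, end = pk$end,
               value = pk$value, n_probes = pk$n_probes, cutoff = co,
               strain = strain, tissue = tissue)
  }
  out <- do.call(rbind, lapply(sort(params$cutoff), one_cutoff))
  rownames(out) <- NULL
  out
}

empty_peaks <- function() {
  data.frame(peak_id = character(0), chrom = character(0), start = integer(0),
             end = integer(0), value = numeric(0), n_probes = integer(0),
             cutoff = numeric(0), strain = character(0), tissue = character(0))
}

#' Census of high methylation peaks
#'
#' Counts unique peaks whose value is at or above `high_threshold`
#' ("4.0 and over" at the default), per sample.
#'
#' @param peaks peak data.frame from [call_peaks()] (possibly several
#'   samples stacked), called at a single cutoff.
#' @param high_threshold inclusive value threshold.
#' @return data.frame(strain, tissue, n_high).
#' @export
count_high_peaks <- function(peaks, high_threshold = 4.0) {
  assert_that(length(unique(peaks$cutoff)) <= 1L,
              "count_high_peaks expects peaks called at a single cutoff")
  if (nrow(peaks) == 0L) {
    return(data.frame(strain = character(0), tissue = character(0),
                      n_high = integer(0)))
  }
  dt <- data.table::data.table(peaks)
  out <- dt[, list(n_high = sum(value >= high_threshold)),
            by = c("strain", "tissue")]
  as.data.frame(out)
}
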