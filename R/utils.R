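# Internal helpers shared across the pipeline stages.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Deterministic sub-stream seed for a pipeline stage. Keeps derived seeds
# inside the 32-bit integer range regardless of the user's top-level seed.
sub_seed <- function(seed, stage) {
  (as.integer(seed) %% 19997L) * 104729L + as.integer(stage)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Oriented point offsets: distance of genomic position `pos` from `tss`,
# measured along the direction of transcription (negative = upstream).
oriented_offset <- function(pos, tss, strand) {
  ifelse(strand == "+", pos - tss, tss - pos)
}

# Genomic half-open interval [start, end) covering oriented offsets
# d_lo..d_hi (inclusive, d_lo <= d_hi) around a TSS. All coordinates are
# 0-based positions of single bases.
oriented_interval <- function(tss, strand, d_lo, d_hi) {
  start <- ifelse(strand == "+", tss + d_lo, tss - d_hi)
  end <- ifelse(strand == "+", tss + d_hi + 1L, tss - d_lo + 1L)
  data.frame(start = start, end = end)
}

# Which of the points (chrom, pos) fall inside one of the half-open
# intervals in `iv` (columns chrom, start, end; assumed mutually disjoint)?
# Returns the matching interval row index, or NA.
points_in_intervals <- function(chrom, pos, iv) {
  hit <- rep(NA_integer_, length(pos))
  if (nrow(iv) == 0L || length(pos) == 0L) return(hit)
  for (ch in unique(iv$chrom)) {
    rows <- which(iv$chrom == ch)
    o <- rows[order(iv$start[rows])]
    sel <- which(chrom == ch)
    if (!length(sel)) next
    k <- findInterval(pos[sel], iv$start[o])
    ok <- k >= 1L & pos[sel] < iv$end[o][pmax(k, 1L)]
    hit[sel[ok]] <- o[k[ok]]
  }
  hit
}

# Header comment lines stamped on every text output (reproducibility).
output_header <- function(params = NULL) {
  h <- sprintf("# meditile %s", as.character(utils::packageVersion("meditile")))
  if (length(params)) {
    h <- c(h, sprintf("# %s=%s", names(params),
                      vapply(params, function(p) paste(format(p), collapse = ","),
                             character(1))))
  }
  h
}
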