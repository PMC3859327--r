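#' Probe-level signal track
#'
#' A probe track holds, for one array hybridization (one strain/tissue
#' sample), the probe center positions and log2(IP/input) ratios, plus the
#' derived KS P-scores once [windowed_ks()] has run. Coordinates are
#' 0-based probe center positions; probes are kept sorted by
#' (chrom, position) and positions must be unique within a chromosome.
#'
#' @param probes data.frame with columns `probe_id`, `chrom`, `position`,
#'   `log2_ratio` and optionally `pscore` (NA when not yet computed).
#' @param strain,tissue sample labels stored as attributes.
#' @return A `probe_track` (a data.frame subclass).
#' @export
probe_track <- function(probes, strain = NA_character_, tissue = NA_character_) {
  need <- c("probe_id", "chrom", "position", "log2_ratio")
  assert_that(all(need %in% names(probes)),
              paste("probe track needs columns:", paste(need, collapse = ", ")))
  probes <- as.data.frame(probes)[, c(need, intersect("pscore", names(probes)))]
  if (!"pscore" %in% names(probes)) probes$pscore <- rep(NA_real_, nrow(probes))
  probes$chrom <- as.character(probes$chrom)
  probes$probe_id <- as.character(probes$probe_id)
  o <- order(probes$chrom, probes$position)
  if (is.unsorted(o)) probes <- probes[o, , drop = FALSE]
  rownames(probes) <- NULL
  dup <- duplicated(probes[, c("chrom", "position")])
  assert_that(!any(dup), "duplicate (chrom, position) in probe track")
  set <- !is.na(probes$pscore)
  assert_that(all(is.finite(probes$pscore[set]) & probes$pscore[set] >= 0),
              "pscore, when set, must be finite and >= 0")
  structure(probes, class = c("probe_track", "data.frame"),
            strain = strain, tissue = tissue)
}

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf("<probe_track> %s/%s: %d probes on %d chromosome(s); pscores %s\n",
              attr(x, "strain"), attr(x, "tissue"), nrow(x),
              length(unique(x$chrom)),
              if (all(is.na(x$pscore))) "unset" else "set"))
  invisible(x)
}

#' Genome annotation used for peak mapping
#'
#' Bundles the three feature classes of a promoter tiling-array design:
#' genes (TSS, strand, primary-transcript interval), CpG islands, and the
#' tiled regions the probes were selected from. All intervals are 0-based
#' half-open internally; GFF3 output is 1-based inclusive.
#'
#' The TSS is the 0-based position of the first transcribed base:
#' `tx_start` on the + strand and `tx_end - 1` on the - strand.
#'
#' @param genes data.frame(gene_id, chrom, strand, tss, tx_start, tx_end).
#' @param islands data.frame(island_id, chrom, start, end).
#' @param tiled_regions data.frame(region_id, chrom, start, end).
#' @return A `feature_set` object.
#' @export
feature_set <- function(genes = NULL, islands = NULL, tiled_regions = NULL) {
  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    num <- setdiff(cols, c("gene_id", "island_id", "region_id", "chrom", "strand"))
    for (cc in num) df[[cc]] <- integer(0)
    df
  }
  genes <- genes %||% empty(c("gene_id", "chrom", "strand", "tss", "tx_start", "tx_end"))
  islands <- islands %||% empty(c("island_id", "chrom", "start", "end"))
  tiled_regions <- tiled_regions %||% empty(c("region_id", "chrom", "start", "end"))
  genes <- as.data.frame(genes); islands <- as.data.frame(islands)
  tiled_regions <- as.data.frame(tiled_regions)
  assert_that(!anyDuplicated(genes$gene_id) && !anyDuplicated(islands$island_id) &&
                !anyDuplicated(tiled_regions$region_id),
              "feature ids must be unique within each feature class")
  if (nrow(genes)) {
    assert_that(all(genes$strand %in% c("+", "-")), "gene strand must be + or -")
    assert_that(all(genes$tx_start <= genes$tx_end), "tx_start must be <= tx_end")
    want <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
    assert_that(all(genes$tss == want),
                "tss must equal tx_start (+) or tx_end - 1 (-): half-open convention")
  }
  rownames(genes) <- rownames(islands) <- rownames(tiled_regions) <- NULL
  structure(list(genes = genes, islands = islands, tiled_regions = tiled_regions),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d genes, %d CpG islands, %d tiled regions\n",
              nrow(x$genes), nrow(x$islands), nrow(x$tiled_regions)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Probe track TSV

#' Read a probe track from a tab-delimited file
#'
#' Expects a header line `probe_id  chrom  position  log2_ratio [pscore]`
#' preceded by optional `#` comment lines (sample labels are recovered from
#' `# strain=` / `# tissue=` comments when present). Malformed lines raise
#' an error naming the offending line; unsorted input is sorted silently
#' with a message.
#'
#' @param path file path.
#' @return A [probe_track()].
#' @export
read_track <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  lines <- readLines(path)
  meta <- grep("^#", lines)
  strain <- tissue <- NA_character_
  for (m in meta) {
    if (grepl("strain=", lines[m])) strain <- sub(".*strain=([^;[:space:]]+).*", "\\1", lines[m])
    if (grepl("tissue=", lines[m])) tissue <- sub(".*tissue=([^;[:space:]]+).*", "\\1", lines[m])
  }
  body_idx <- setdiff(seq_along(lines), meta)
  body_idx <- body_idx[nzchar(lines[body_idx])]
  assert_that(length(body_idx) >= 1L, "track file has no header line")
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  assert_that(all(c("probe_id", "chrom", "position", "log2_ratio") %in% header),
              "track header must name probe_id, chrom, position, log2_ratio")
  data_idx <- body_idx[-1]
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(header))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: expected %d fields, found %d",
                 data_idx[bad[1]], length(header), nf[bad[1]]), call. = FALSE)
  }
  if (!length(data_idx)) {
    return(probe_track(data.frame(probe_id = character(0), chrom = character(0),
                                  position = integer(0), log2_ratio = numeric(0)),
                       strain, tissue))
  }
  m <- matrix(unlist(fields), ncol = length(header), byrow = TRUE)
  colnames(m) <- header
  num_col <- function(col) {
    raw <- m[, col]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(raw %in% c("NA", "")))
    if (length(bad)) {
      stop(sprintf("parse error at line %d: non-numeric %s '%s'",
                   data_idx[bad[1]], col, raw[bad[1]]), call. = FALSE)
    }
    val
  }
  df <- data.frame(probe_id = m[, "probe_id"], chrom = m[, "chrom"],
                   position = num_col("position"),
                   log2_ratio = num_col("log2_ratio"))
  if ("pscore" %in% header) df$pscore <- num_col("pscore")
  o <- order(df$chrom, df$position)
  if (!identical(o, seq_len(nrow(df)))) message("read_track: input not sorted; sorting")
  probe_track(df, strain, tissue)
}

#' Write a probe track as tab-delimited text
#'
#' @param track a [probe_track()].
#' @param path output path.
#' @param params optional named list recorded in the header comments.
#' @export
write_track <- function(track, path, params = NULL) {
  hdr <- c(output_header(params),
           sprintf("# strain=%s tissue=%s", attr(track, "strain"), attr(track, "tissue")))
  df <- as.data.frame(track)
  if (all(is.na(df$pscore))) df$pscore <- NULL
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Annotation GFF3 / BED

gff_types <- c(gene = "gene", CpG_island = "CpG_island", tiled_region = "tiled_region")

#' Read a feature annotation from GFF3
#'
#' Recognized feature types are `gene`, `CpG_island` and `tiled_region`;
#' other types are skipped with a warning. GFF3 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return A [feature_set()].
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  unknown <- setdiff(unique(type), gff_types)
  if (length(unknown)) {
    warning(sprintf("skipping unknown feature type(s): %s",
                    paste(unknown, collapse = ", ")))
  }
  ids <- as.character(gr$ID)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  std <- as.character(GenomicRanges::strand(gr))
  gsel <- type == "gene"
  genes <- data.frame(gene_id = ids[gsel], chrom = chrom[gsel], strand = std[gsel],
                      tss = ifelse(std[gsel] == "+", start0[gsel], end0[gsel] - 1L),
                      tx_start = start0[gsel], tx_end = end0[gsel])
  isel <- type == "CpG_island"
  islands <- data.frame(island_id = ids[isel], chrom = chrom[isel],
                        start = start0[isel], end = end0[isel])
  tsel <- type == "tiled_region"
  tiled <- data.frame(region_id = ids[tsel], chrom = chrom[tsel],
                      start = start0[tsel], end = end0[tsel])
  feature_set(genes, islands, tiled)
}

#' Write a feature annotation as GFF3 (and optionally BED6)
#'
#' @param features a [feature_set()].
#' @param path output GFF3 path.
#' @param bed_path optional BED6 path (0-based half-open; strandless
#'   features carry "." strand).
#' @export
write_annotation <- function(features, path, bed_path = NULL) {
  g <- features$genes; i <- features$islands; t <- features$tiled_regions
  df <- data.frame(
    chrom = c(g$chrom, i$chrom, t$chrom),
    start0 = c(g$tx_start, i$start, t$start),
    end0 = c(g$tx_end, i$end, t$end),
    strand = c(g$strand, rep("*", nrow(i)), rep("*", nrow(t))),
    type = c(rep("gene", nrow(g)), rep("CpG_island", nrow(i)),
             rep("tiled_region", nrow(t))),
    ID = c(g$gene_id, i$island_id, t$region_id))
  if (nrow(df) == 0L) {
    writeLines("##gff-version 3", path)
  } else {
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start0 + 1L, df$end0),
                                 strand = df$strand)
    S4Vectors::mcols(gr)$type <- df$type
    S4Vectors::mcols(gr)$ID <- df$ID
    rtracklayer::export(gr, path, format = "gff3")
  }
  if (!is.null(bed_path)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", df$chrom, df$start0, df$end0,
                     df$ID, ifelse(df$strand == "*", ".", df$strand))
    writeLines(c(output_header(), lines), bed_path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Peaks

#' Write called peaks as BED6 plus a full-precision TSV
#'
#' The BED score column carries `trunc(value * 100)` saturated at 1000 per
#' the BED specification; the TSV keeps full precision and all peak
#' metadata, and is the round-trip carrier read by [read_peaks()].
#'
#' @param peaks peak data.frame from [call_peaks()].
#' @param bed_path BED6 output path (optional).
#' @param tsv_path TSV output path (optional).
#' @export
write_peaks <- function(peaks, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    score <- as.integer(pmin(trunc(peaks$value * 100), 1000))
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", peaks$chrom,
                     as.integer(peaks$start), as.integer(peaks$end),
                     peaks$peak_id, score)
    writeLines(c(output_header(), lines), bed_path)
  }
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    writeLines(output_header(), con)
    write.table(as.data.frame(peaks), con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(peaks)
}

#' Read peaks back from the full-precision TSV written by [write_peaks()]
#' @param tsv_path TSV path.
#' @return peak data.frame.
#' @export
read_peaks <- function(tsv_path) {
  read.delim(tsv_path, comment.char = "#", stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Methylation matrix TSV

#' Write / read the feature-by-sample methylation matrix
#'
#' Columns are labelled `strain|tissue|cutoff`; the first column holds the
#' feature ids. Values round-trip to at least six decimal places.
#'
#' @param mat a `meth_matrix` from [build_matrix()].
#' @param path output TSV path.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(output_header(), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  class(m) <- c("meth_matrix", class(m))
  m
}
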