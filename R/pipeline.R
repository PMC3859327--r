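#' Run the full simulate-score-call-map-diff-stats pipeline
#'
#' Chains every stage on synthetic data: annotation and methylome
#' generation, probe-signal emission, windowed-KS scoring, peak calling at
#' the configured cutoffs, feature mapping, the methylation matrix,
#' differential calls with tissue intersections, the high-peak census,
#' distance-class tabulations, inter-tissue profile correlations, and a
#' methylation-expression summary. All randomness flows from the config
#' seed, so a rerun with the same configuration is identical.
#'
#' @param cfg a [sim_config()].
#' @param ks a [ks_params()].
#' @param pk a [peak_params()]; `pk$cutoff` should hold both matrix
#'   cutoffs (default `c(1, 2)`).
#' @param mp a [map_params()].
#' @param outdir optional directory; when given, per-stage TSV/BED/GFF3
#'   outputs and a plain-text summary report are written there.
#' @param expression also simulate expression and summarize its
#'   association with methylation for the test strain's first tissue.
#' @return A list bundle with elements `annotation`, `truth`, `tracks`
#'   (scored), `peaks`, `mapped`, `matrix`, `calls`, `venn`, `high_peaks`,
#'   `distance_classes`, `correlations`, and (optionally) `expression` and
#'   `expr_summary`.
#' @export
run_all <- function(cfg = sim_config(), ks = ks_params(),
                    pk = peak_params(cutoff = c(1, 2)), mp = map_params(),
                    outdir = NULL, expression = TRUE) {
  cfg <- validate_sim_config(cfg)
  ann <- generate_annotation(cfg)
  truth <- simulate_methylomes(cfg, ann)
  tracks <- simulate_probe_signals(cfg, ann, truth)
  tracks <- lapply(tracks, function(tr) if (nrow(tr)) windowed_ks(tr, ks) else tr)
  peaks <- do.call(rbind, lapply(tracks, call_peaks, params = pk))
  rownames(peaks) <- NULL
  mapped <- map_peaks(peaks, ann, mp)
  mat <- build_matrix(mapped, ann)

  ref <- cfg$strains[1]; tst <- cfg$strains[2]
  calls <- if (ncol(mat) > 0L) {
    do.call(rbind, lapply(cfg$tissues, function(t) {
      call_differential(mat, test_strain = tst, ref_strain = ref, tissue = t)
    }))
  } else {
    data.frame(feature_id = character(0), tissue = character(0),
               direction = character(0), condition = character(0),
               test_value = numeric(0), ref_value = numeric(0))
  }
  venn <- if (nrow(calls)) intersect_tissues(calls) else NULL

  hi_cut <- max(pk$cutoff)
  high <- count_high_peaks(peaks[peaks$cutoff == hi_cut, , drop = FALSE],
                           pk$high_threshold)
  dist_all <- tabulate_distance_classes(mapped[mapped$cutoff == hi_cut, ,
                                               drop = FALSE],
                                        min_value = hi_cut)
  gmm <- gene_meth_vector(mapped, genes = ann$genes$gene_id,
                          cutoff = min(pk$cutoff))
  cors <- if (nrow(ann$genes) >= 3L && length(tracks) >= 2L)
    profile_correlations(gmm) else NULL

  bundle <- list(config = cfg, annotation = ann, truth = truth,
                 tracks = tracks, peaks = peaks, mapped = mapped,
                 matrix = mat, calls = calls, venn = venn,
                 high_peaks = high, distance_classes = dist_all,
                 gene_vectors = gmm, correlations = cors)

  if (expression) {
    expr <- simulate_expression(truth, ann)
    bundle$expression <- expr
    if (nrow(ann$genes) >= 3L) {
      sel <- expr$strain == tst & expr$tissue == cfg$tissues[1]
      ev <- setNames(expr$value[sel], expr$gene_id[sel])
      mv <- setNames(gmm[, sprintf("%s|%s", tst, cfg$tissues[1])], rownames(gmm))
      bundle$expr_summary <- methylation_expression_summary(mv, ev)
    }
  }

  if (!is.null(outdir)) write_bundle(bundle, outdir, ks, pk, mp)
  bundle
}

# Serialize a pipeline bundle as plain-text files plus a summary report.
write_bundle <- function(bundle, outdir, ks, pk, mp) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  write_annotation(bundle$annotation, file.path(outdir, "annotation.gff3"),
                   bed_path = file.path(outdir, "annotation.bed"))
  for (nm in names(bundle$tracks)) {
    write_track(bundle$tracks[[nm]],
                file.path(outdir, sprintf("%s.track.tsv", nm)),
                params = list(window_bp = ks$window_bp,
                              score_cap = ks$score_cap, seed = cfg$seed))
  }
  write_peaks(bundle$peaks, bed_path = file.path(outdir, "peaks.bed"),
              tsv_path = file.path(outdir, "peaks.tsv"))
  con <- file(file.path(outdir, "mapped.tsv"), "w")
  writeLines(output_header(list(upstream_bp = mp$upstream_bp,
                                downstream_bp = mp$downstream_bp)), con)
  write.table(bundle$mapped, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  write_matrix(bundle$matrix, file.path(outdir, "matrix.tsv"))
  con <- file(file.path(outdir, "calls.tsv"), "w")
  writeLines(output_header(), con)
  write.table(bundle$calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(bundle$expression)) {
    write_expression(bundle$expression, file.path(outdir, "expression.tsv"))
  }
  rep <- c(output_header(list(seed = cfg$seed, n_genes = cfg$n_genes)),
           sprintf("samples: %d", length(bundle$tracks)),
           sprintf("peaks called: %d", nrow(bundle$peaks)),
           sprintf("differential calls: %d", nrow(bundle$calls)))
  if (!is.null(bundle$venn)) {
    rep <- c(rep,
             sprintf("hyper in all tissues: %d", bundle$venn$hyper$n_all),
             sprintf("hypo in all tissues: %d", bundle$venn$hypo$n_all))
  }
  if (!is.null(bundle$correlations)) {
    rep <- c(rep, "inter-tissue correlations:",
             sprintf("  %s %s-%s r=%.4f", bundle$correlations$strain,
                     bundle$correlations$tissue1, bundle$correlations$tissue2,
                     bundle$correlations$r))
  }
  writeLines(rep, file.path(outdir, "report.txt"))
  invisible(outdir)
}
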