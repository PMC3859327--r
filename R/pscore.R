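#' Parameters of the sliding-window KS P-score
#'
#' @param window_bp window width in bp centered on each probe (default 750,
#'   i.e. half-width 375 bp, boundary inclusive).
#' @param min_window_probes minimum number of probes (including the center
#'   probe) a window must hold for a nonzero score.
#' @param score_cap upper cap on the P-score (-log10 p-value).
#' @return A `ks_params` list.
#' @export
ks_params <- function(window_bp = 750, min_window_probes = 2L, score_cap = 50) {
  assert_that(window_bp > 0, "window_bp must be > 0")
  assert_that(min_window_probes >= 1, "min_window_probes must be >= 1")
  assert_that(score_cap > 0, "score_cap must be > 0")
  structure(list(window_bp = window_bp,
                 min_window_probes = as.integer(min_window_probes),
                 score_cap = score_cap),
            class = "ks_params")
}

#' Sliding-window Kolmogorov-Smirnov P-scores
#'
#' For each probe, the window sample W collects the log2 ratios of all
#' probes on the same chromosome whose centers lie within `window_bp / 2`
#' of the probe center (boundary inclusive); the background sample B is the
#' whole array (the window is not excised). The one-sided, enrichment-sided
#' two-sample KS statistic is
#' \deqn{D^+ = \sup_x [F_B(x) - F_W(x)]}
#' with right-continuous empirical CDFs, and the asymptotic one-sided tail
#' \deqn{p = \exp(-2 m_{eff} (D^+)^2), \quad m_{eff} = |W||B| / (|W|+|B|)}
#' gives the P-score `min(-log10 p, score_cap)`. Probes with fewer than
#' `min_window_probes` window members, or with no enrichment
#' (`D+ <= 0`, including depletion), score 0.
#'
#' Adding a constant to every log2 ratio leaves all P-scores unchanged
#' (the statistic depends on ranks only).
#'
#' @param track a sorted [probe_track()] with finite log2 ratios.
#' @param params a [ks_params()].
#' @return The track with the `pscore` column filled in.
#' @export
windowed_ks <- function(track, params = ks_params()) {
  assert_that(inherits(track, "probe_track"), "track must be a probe_track")
  n <- nrow(track)
  assert_that(n >= 1L, "empty track")
  assert_that(all(is.finite(track$log2_ratio)), "non-finite log2 ratio in track")
  assert_that(n >= params$min_window_probes,
              "track has fewer probes than min_window_probes")
  ratio <- track$log2_ratio
  B <- sort(ratio)
  nB <- length(B)
  hw <- params$window_bp / 2

  dt <- data.table::data.table(chrom = track$chrom, pos = track$position,
                               ratio = ratio, idx = seq_len(n))
  dt[, c("lo", "hi") := {
    first <- idx[1L]
    list(findInterval(pos - hw, pos, left.open = TRUE) + first,
         findInterval(pos + hw, pos) + first - 1L)
  }, by = "chrom"]
  m <- dt$hi - dt$lo + 1L

  # Expand window membership; within each window, sorted values w_(1..m)
  # give D+ = max_i [ #{B < w_(i)}/|B| - (i-1)/m ], the supremum of
  # F_B - F_W just before each down-step of F_W.
  exp_idx <- sequence(m, from = dt$lo)
  W <- data.table::data.table(g = rep(seq_len(n), m), v = ratio[exp_idx])
  data.table::setorder(W, g, v)
  W[, r0 := seq_len(.N) - 1L, by = "g"]
  W[, mg := .N, by = "g"]
  W[, term := findInterval(v, B, left.open = TRUE) / nB - r0 / mg]
  D <- W[, list(D = max(term)), by = "g"]$D
  D <- pmax(D, 0)

  m_eff <- m * nB / (m + nB)
  score <- 2 * m_eff * D^2 * log10(exp(1))
  score[m < params$min_window_probes | D <= 0] <- 0
  track$pscore <- pmin(score, params$score_cap)
  track
}
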