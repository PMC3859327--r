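# Independent brute-force oracles and small fixtures used across the suite.
# These deliberately re-derive every quantity from first principles (explicit
# ECDFs, linear scans, exhaustive enumeration) and share no code with the
# package implementation.

# Brute-force windowed KS P-scores: per probe, explicit window collection,
# stats::ecdf for both samples, and a sup-difference scan over the pooled
# value grid (the supremum of a difference of right-continuous step
# functions is attained at one of the jump points).
oracle_pscores <- function(track, window_bp = 750, min_probes = 2, cap = 50) {
  df <- as.data.frame(track)
  n <- nrow(df)
  B <- df$log2_ratio
  FB <- stats::ecdf(B)
  nb <- length(B)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- which(df$chrom == df$chrom[i] &
                 abs(df$position - df$position[i]) <= window_bp / 2)
    W <- df$log2_ratio[w]
    m <- length(W)
    if (m < min_probes) next
    FW <- stats::ecdf(W)
    grid <- sort(unique(c(W, B)))
    D <- max(FB(grid) - FW(grid))
    if (D <= 0) next
    meff <- m * nb / (m + nb)
    out[i] <- min(-log10(exp(-2 * meff * D^2)), cap)
  }
  out
}

# Brute-force peak segmentation: a single linear scan with explicit
# gap/chromosome checks and run bookkeeping.
oracle_peaks <- function(track, cutoff, max_spacing = 500, min_probes = 2) {
  df <- as.data.frame(track)
  chroms <- character(0); firsts <- integer(0); lasts <- integer(0)
  vals <- numeric(0); ns <- integer(0)
  cur_chrom <- NA_character_; cur_first <- NA_integer_; cur_last <- NA_integer_
  cur_val <- -Inf; cur_n <- 0L
  flush <- function() {
    if (cur_n >= min_probes) {
      chroms <<- c(chroms, cur_chrom); firsts <<- c(firsts, cur_first)
      lasts <<- c(lasts, cur_last); vals <<- c(vals, cur_val); ns <<- c(ns, cur_n)
    }
  }
  for (i in seq_len(nrow(df))) {
    if (df$pscore[i] < cutoff) next
    if (cur_n > 0L && df$chrom[i] == cur_chrom &&
        df$position[i] - cur_last <= max_spacing) {
      cur_last <- df$position[i]
      cur_val <- max(cur_val, df$pscore[i])
      cur_n <- cur_n + 1L
    } else {
      flush()
      cur_chrom <- df$chrom[i]; cur_first <- df$position[i]
      cur_last <- df$position[i]; cur_val <- df$pscore[i]; cur_n <- 1L
    }
  }
  flush()
  data.frame(chrom = chroms, start = firsts, end = lasts + 1L,
             value = vals, n_probes = ns)
}

# Exhaustive rank-sum enumeration: two-tailed p over all C(N, n1) labelings.
oracle_ranksum <- function(x, y) {
  pooled <- c(x, y)
  rk <- rank(pooled)
  n1 <- length(x); N <- length(pooled)
  W <- sum(rk[seq_len(n1)])
  combos <- utils::combn(N, n1)
  sums <- apply(combos, 2, function(i) sum(rk[i]))
  eps <- 1e-9
  min(1, 2 * min(mean(sums <= W + eps), mean(sums >= W - eps)))
}

# Direct hypergeometric tail sum for the EASE statistic.
oracle_ease <- function(k, K, N, n) {
  kk <- max(k - 1L, 0L)
  xs <- kk:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Longhand Benjamini-Hochberg step-up recursion.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Interval overlap helpers (plain loops, no IRanges).
overlaps_any <- function(a, b) {
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    bi <- which(b$chrom == a$chrom[i])
    hit[i] <- length(bi) > 0 &&
      any(a$start[i] < b$end[bi] & b$start[bi] < a$end[i])
  }
  hit
}

# A compact simulation config sized for unit tests.
small_cfg <- function(n_genes = 120, seed = 1, ...) {
  sim_config(n_genes = n_genes, chrom_length = ceiling(n_genes / 2) * 12000,
             seed = seed, ...)
}

# A random pre-scored track (synthetic pscores, irregular spacing).
random_scored_track <- function(n, seed, chroms = c("chr1", "chr2")) {
  withr::with_seed(seed, {
    chrom <- sort(sample(chroms, n, replace = TRUE))
    pos <- unlist(lapply(unique(chrom), function(ch) {
      k <- sum(chrom == ch)
      sort(sample.int(k * 300, k))
    }))
    probe_track(data.frame(probe_id = sprintf("P%06d", seq_len(n)),
                           chrom = chrom, position = pos,
                           log2_ratio = rnorm(n),
                           pscore = round(runif(n, 0, 4), 3)),
                strain = "S", tissue = "T")
  })
}
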