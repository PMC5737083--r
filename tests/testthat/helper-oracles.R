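# Independent oracles used across the suite. These deliberately avoid the
# package's scanning code paths: plain loops and explicit per-character
# complement comparisons.

.oracle_comp <- c(A = "T", C = "G", G = "C", T = "A")

random_dna <- function(n, gc = 0.5, n_rate = 0) {
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  if (n_rate > 0) {
    nn <- which(runif(n) < n_rate)
    b[nn] <- "N"
  }
  paste(b, collapse = "")
}

# Cubic-time brute force: every (start, arm, spacer) window checked by
# character-wise complement comparison, then canonicalized per extent
# (smallest spacer kept).
brute_force_scan <- function(seq, config = search_config()) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  L <- length(chars)
  res <- list()
  for (start in seq_len(L)) {             # 1-based window start
    for (s in config$spacer_min:config$spacer_max) {
      for (a in config$arm_min:config$arm_max) {
        end <- start + 2L * a + s - 1L    # 1-based inclusive
        if (end > L) next
        win <- chars[start:end]
        if (any(win == "N")) next
        ok <- TRUE
        for (j in seq_len(a)) {
          lc <- .oracle_comp[[win[j]]]
          if (is.null(lc) || lc != win[2L * a + s + 1L - j]) { ok <- FALSE; break }
        }
        if (ok) res[[length(res) + 1L]] <- c(start - 1L, end, a, s)
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      arm_len = integer(0), spacer_len = integer(0)))
  m <- do.call(rbind, res)
  df <- data.frame(start = m[, 1L], end = m[, 2L],
                   arm_len = m[, 3L], spacer_len = m[, 4L])
  df <- df[order(df$start, df$end, df$spacer_len), ]
  df <- df[!duplicated(df[, c("start", "end")]), ]
  rownames(df) <- NULL
  df
}

# Greedy longest-first overlap resolution: repeatedly take the globally
# longest remaining record (ties: smaller start, then smaller spacer) and
# drop everything overlapping it.
brute_force_resolve <- function(df) {
  keep <- integer(0)
  remaining <- seq_len(nrow(df))
  while (length(remaining) > 0L) {
    len <- df$end[remaining] - df$start[remaining]
    o <- remaining[order(-len, df$start[remaining], df$spacer_len[remaining])]
    pick <- o[1L]
    keep <- c(keep, pick)
    remaining <- remaining[!(df$start[remaining] < df$end[pick] &
                               df$end[remaining] > df$start[pick])]
  }
  out <- df[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact upper-tail binomial probability by direct term-by-term summation of
# the probability mass function. The smaller tail is summed (complementing
# when k is below the mean) so the result carries no bulk accumulation error;
# the summation stops once terms stop contributing at double precision.
binom_upper_tail_sum <- function(k, n, p) {
  if (k <= 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  pmf <- function(x) exp(lchoose(n, x) + x * log(p) + (n - x) * log1p(-p))
  if (k <= n * p) {
    return(1 - sum(vapply(0:(k - 1L), pmf, numeric(1L))))
  }
  s <- 0
  t <- pmf(k)
  x <- k
  while (x <= n && (t > s * 1e-17 || x == k)) {
    s <- s + t
    t <- t * ((n - x) / (x + 1)) * (p / (1 - p))
    x <- x + 1L
  }
  s
}

# Literal BH step-up: sort, scale by m/i, cumulative minimum from the top,
# cap at 1, unsort.
bh_stepup_literal <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Build a small simulated cohort and run detection once; used by several
# test files.
make_sim <- function(seed = 1L, ...) {
  cfg <- simulation_config(seed = seed, ...)
  g <- generate_genome(cfg)
  m <- generate_mutations(cfg, g$genome, g$truth)
  c(list(config = cfg), g, m)
}

# Detected SIRs at the planted loci (exact coordinate match).
planted_subset <- function(sirs, truth) {
  key <- paste0(sirs$chrom, ":", sirs$start, "-", sirs$end)
  tk <- paste0(truth$chrom, ":", truth$start, "-", truth$end)
  sirs[key %in% tk, , drop = FALSE]
}
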