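#' One-sided binomial test of spacer mutation excess
#'
#' Exact upper-tail probability P[X >= n_muts_spacer] for
#' X ~ Binomial(spacer_len * n_samples, background_density): the spacer's
#' position-sample units are Bernoulli trials at the local control mutation
#' rate. A background density of 0 with a positive count returns p = 0.
#'
#' @param n_muts_spacer Observed spacer mutation count (vectorized).
#' @param spacer_len Spacer length in bp.
#' @param n_samples Number of sample genomes.
#' @param background_density Per-bp per-sample mutation probability from the
#'   SIR's control windows.
#' @return Upper-tail p-value(s).
#' @export
binomial_spacer_test <- function(n_muts_spacer, spacer_len, n_samples,
                                 background_density) {
  trials <- as.numeric(spacer_len) * as.numeric(n_samples)
  if (any(background_density < 0 | background_density > 1))
    stop("background_density must be in [0, 1]")
  if (any(n_muts_spacer < 0) || any(n_muts_spacer > trials))
    stop("n_muts_spacer must be between 0 and spacer_len * n_samples")
  stats::pbinom(n_muts_spacer - 1, trials, background_density,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment with enforced monotonicity, order-preserving with the
#' input.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call highly mutated SIRs
#'
#' Tests each SIR with at least one spacer mutation for an excess of spacer
#' mutations over its own local background: the per-SIR background density is
#' the mutation rate in that SIR's flanking control windows (other SIR bodies
#' carved out, N excluded). BH correction is applied across the tested family
#' and SIRs at adjusted p <= `q_threshold` are flagged as highly mutated.
#' SIRs with no usable control sequence are excluded with a message.
#'
#' @param sirs Non-overlapping SIR data frame.
#' @param assigned Mutation data frame from [assign_to_domains()]
#'   (substitutions are used).
#' @param genome Named character vector of sequences (or DNAStringSet).
#' @param n_samples Number of sample genomes.
#' @param config A [search_config()].
#' @param q_threshold Adjusted p-value threshold (default 0.01).
#' @return Data frame (`sir_index`, `chrom`, `start`, `end`, `spacer`,
#'   `n_muts_spacer`, `trials`, `background_density`, `p_value`, `q_value`,
#'   `fold`, `is_highly_mutated`), one row per tested SIR.
#' @export
call_highly_mutated <- function(sirs, assigned, genome, n_samples,
                                config = search_config(), q_threshold = 0.01) {
  empty <- data.frame(
    sir_index = integer(0), chrom = character(0), start = integer(0),
    end = integer(0), spacer = character(0), n_muts_spacer = integer(0),
    trials = numeric(0), background_density = numeric(0),
    p_value = numeric(0), q_value = numeric(0), fold = numeric(0),
    is_highly_mutated = logical(0)
  )
  if (nrow(sirs) == 0L) return(empty)
  subs <- assigned[assigned$class == "substitution", , drop = FALSE]
  sp_cnt <- tabulate(subs$sir_index[subs$domain == "spacer"], nrow(sirs))
  fam <- which(sp_cnt > 0L)
  if (length(fam) == 0L) return(empty)

  ctrl <- per_sir_controls(sirs, genome, config$control_width_sub_indel)
  usable <- ctrl$usable_bp
  no_ctrl <- fam[usable[fam] == 0]
  if (length(no_ctrl) > 0L) {
    message(length(no_ctrl),
            " SIR(s) excluded from testing: no usable control sequence")
    fam <- setdiff(fam, no_ctrl)
  }
  if (length(fam) == 0L) return(empty)

  # control mutation counts per SIR: a control base shared by two SIRs counts
  # once per SIR for these per-SIR backgrounds
  ctrl_cnt <- numeric(nrow(sirs))
  iv <- ctrl$intervals
  for (ch in unique(iv$chrom)) {
    m <- subs[subs$chrom == ch, , drop = FALSE]
    if (nrow(m) == 0L) next
    ivc <- iv[iv$chrom == ch, , drop = FALSE]
    h <- IRanges::findOverlaps(
      IRanges::IRanges(mutation_point(m), width = 1L),
      IRanges::IRanges(ivc$start + 1L, ivc$end)
    )
    if (length(h) == 0L) next
    tab <- table(ivc$sir_index[S4Vectors::subjectHits(h)])
    ctrl_cnt[as.integer(names(tab))] <- ctrl_cnt[as.integer(names(tab))] +
      as.integer(tab)
  }

  bg <- ctrl_cnt[fam] / (usable[fam] * n_samples)
  trials <- sirs$spacer_len[fam] * n_samples
  p <- binomial_spacer_test(sp_cnt[fam], sirs$spacer_len[fam], n_samples,
                            pmin(bg, 1))
  q <- bh_adjust(p)
  spacer_density <- sp_cnt[fam] / trials
  data.frame(
    sir_index = fam, chrom = sirs$chrom[fam], start = sirs$start[fam],
    end = sirs$end[fam], spacer = sirs$spacer[fam],
    n_muts_spacer = sp_cnt[fam], trials = trials,
    background_density = bg, p_value = p, q_value = q,
    fold = ifelse(bg > 0, spacer_density / bg, Inf),
    is_highly_mutated = q <= q_threshold
  )
}

#' Collapse highly mutated SIRs into hotspot sites
#'
#' Overlapping highly mutated SIRs merge into one genomic site; the longest
#' SIR (ties: leftmost) represents the site. Sites are sorted by coordinate.
#'
#' @param results Data frame from [call_highly_mutated()]; only rows with
#'   `is_highly_mutated` are used.
#' @param sirs The SIR data frame the results refer to.
#' @return Data frame (`chrom`, `start`, `end`, `spacer_seq`,
#'   `spacer_start`, `spacer_end`, `n_sirs`, `rep_sir_index`), one row per
#'   site; coordinates are those of the representative SIR.
#' @export
collapse_to_sites <- function(results, sirs) {
  hm <- results[results$is_highly_mutated, , drop = FALSE]
  empty <- data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    spacer_seq = character(0), spacer_start = integer(0),
    spacer_end = integer(0), n_sirs = integer(0), rep_sir_index = integer(0)
  )
  if (nrow(hm) == 0L) return(empty)
  sites <- do.call(rbind, lapply(split(hm, hm$chrom), function(d) {
    ir <- IRanges::IRanges(d$start + 1L, d$end)
    # min.gapwidth = 0: abutting SIRs share no base and stay separate sites
    cl <- S4Vectors::subjectHits(
      IRanges::findOverlaps(ir, IRanges::reduce(ir, min.gapwidth = 0L))
    )
    do.call(rbind, lapply(split(seq_len(nrow(d)), cl), function(g) {
      o <- g[order(-(d$end[g] - d$start[g]), d$start[g])]
      rep_i <- d$sir_index[o[1L]]
      data.frame(
        chrom = d$chrom[o[1L]],
        start = sirs$start[rep_i], end = sirs$end[rep_i],
        spacer_seq = sirs$spacer[rep_i],
        spacer_start = sirs$start[rep_i] + sirs$arm_len[rep_i],
        spacer_end = sirs$start[rep_i] + sirs$arm_len[rep_i] +
          sirs$spacer_len[rep_i],
        n_sirs = length(g), rep_sir_index = rep_i
      )
    }))
  }))
  sites <- sites[order(sites$chrom, sites$start, sites$end), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

# Genomic occurrences of a sequence and its reverse complement lying wholly
# outside every SIR interval. Returns a data frame (chrom, start, end).
.out_of_sir_occurrences <- function(seq, sirs, genome) {
  rc <- revcomp(seq)
  pats <- unique(c(seq, rc))
  out <- vector("list", 0L)
  for (ch in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ch]])
    hits <- IRanges::IRanges()
    for (p in pats) {
      m <- Biostrings::matchPattern(p, subj)
      hits <- c(hits, IRanges::IRanges(IRanges::start(m), IRanges::end(m)))
    }
    hits <- unique(hits)
    sdf <- sirs[sirs$chrom == ch, , drop = FALSE]
    if (nrow(sdf) > 0L) {
      bodies <- IRanges::IRanges(sdf$start + 1L, sdf$end)
      ov <- IRanges::overlapsAny(hits, bodies)
      hits <- hits[!ov]
    }
    if (length(hits) > 0L)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = IRanges::start(hits) - 1L, end = IRanges::end(hits)
      )
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  do.call(rbind, out)
}

#' Test spacer sequences for SIR-dependent hypermutability
#'
#' For each spacer sequence (pooled with its reverse complement -- a spacer
#' and its reverse complement are the same double-stranded sequence), compares
#' the mutation rate of its occurrences inside SIR spacers with the rate at
#' identical sequences not flanked by palindromic arms: the background is the
#' per-bp per-sample mutation rate across all exact genomic occurrences lying
#' wholly outside every SIR. Binomial upper-tail test, BH across all tested
#' sequences; sequences with no out-of-SIR occurrence are reported untestable.
#'
#' @param sirs Non-overlapping SIR data frame.
#' @param assigned Mutation data frame from [assign_to_domains()].
#' @param genome Named character vector of sequences (or DNAStringSet).
#' @param n_samples Number of sample genomes.
#' @param spacer_seqs Spacer sequences to test; default: every spacer sequence
#'   (canonicalized with its reverse complement) carrying >= 1 spacer mutation.
#' @param q_threshold Adjusted p-value threshold (default 0.01).
#' @return Data frame (`spacer_seq`, `n_occ_in`, `bp_in`, `n_muts_in`,
#'   `n_occ_out`, `bp_out`, `n_muts_out`, `background_density`, `p_value`,
#'   `q_value`, `fold`, `testable`, `is_hotspot`).
#' @export
hotspot_spacer_test <- function(sirs, assigned, genome, n_samples,
                                spacer_seqs = NULL, q_threshold = 0.01) {
  genome <- as_genome(genome)
  subs <- assigned[assigned$class == "substitution", , drop = FALSE]
  sp_cnt <- tabulate(subs$sir_index[subs$domain == "spacer"], nrow(sirs))
  canon <- pmin(sirs$spacer, revcomp(sirs$spacer))
  if (is.null(spacer_seqs)) {
    spacer_seqs <- sort(unique(canon[sp_cnt > 0L]))
  } else {
    spacer_seqs <- sort(unique(pmin(toupper(spacer_seqs),
                                    revcomp(spacer_seqs))))
  }
  if (length(spacer_seqs) == 0L) {
    return(data.frame(
      spacer_seq = character(0), n_occ_in = integer(0), bp_in = numeric(0),
      n_muts_in = integer(0), n_occ_out = integer(0), bp_out = numeric(0),
      n_muts_out = integer(0), background_density = numeric(0),
      p_value = numeric(0), q_value = numeric(0), fold = numeric(0),
      testable = logical(0), is_hotspot = logical(0)
    ))
  }
  rows <- lapply(spacer_seqs, function(sq) {
    members <- which(canon == sq)
    bp_in <- sum(sirs$spacer_len[members])
    n_in <- sum(sp_cnt[members])
    occ <- .out_of_sir_occurrences(sq, sirs, genome)
    bp_out <- sum(occ$end - occ$start)
    n_out <- 0L
    if (nrow(occ) > 0L && nrow(subs) > 0L) {
      for (ch in unique(occ$chrom)) {
        m <- subs[subs$chrom == ch, , drop = FALSE]
        if (nrow(m) == 0L) next
        oc <- occ[occ$chrom == ch, , drop = FALSE]
        ov <- IRanges::overlapsAny(
          IRanges::IRanges(mutation_point(m), width = 1L),
          IRanges::IRanges(oc$start + 1L, oc$end)
        )
        n_out <- n_out + sum(ov)
      }
    }
    data.frame(
      spacer_seq = sq, n_occ_in = length(members), bp_in = bp_in,
      n_muts_in = n_in, n_occ_out = nrow(occ), bp_out = bp_out,
      n_muts_out = n_out,
      background_density = if (bp_out > 0) n_out / (bp_out * n_samples)
                           else NA_real_,
      testable = bp_out > 0
    )
  })
  res <- do.call(rbind, rows)
  res$p_value <- NA_real_
  t_ok <- res$testable
  if (any(t_ok)) {
    res$p_value[t_ok] <- binomial_spacer_test(
      res$n_muts_in[t_ok], res$bp_in[t_ok], n_samples,
      pmin(res$background_density[t_ok], 1)
    )
  }
  res$q_value <- NA_real_
  res$q_value[t_ok] <- bh_adjust(res$p_value[t_ok])
  in_density <- res$n_muts_in / (res$bp_in * n_samples)
  res$fold <- ifelse(t_ok & res$background_density > 0,
                     in_density / res$background_density,
                     ifelse(t_ok & res$n_muts_in > 0, Inf, NA_real_))
  res$is_hotspot <- !is.na(res$q_value) & res$q_value <= q_threshold
  res
}

#' Odds ratio of spacer versus control mutability
#'
#' 2x2 table of mutated versus non-mutated position-sample units in spacer
#' versus control sequence. Haldane-Anscombe 0.5 correction when any cell is
#' zero; Wald 95% CI on the log odds ratio.
#'
#' @param spacer_count Mutated spacer position-sample units.
#' @param control_count Mutated control position-sample units.
#' @param spacer_total Total spacer position-sample units.
#' @param control_total Total control position-sample units.
#' @return List with `or`, `ci_lower`, `ci_upper`.
#' @export
odds_ratio_spacer_control <- function(spacer_count, control_count,
                                      spacer_total, control_total) {
  if (spacer_total <= 0 || control_total <= 0)
    stop("totals must be positive")
  a <- spacer_count; b <- spacer_total - spacer_count
  c_ <- control_count; d <- control_total - control_count
  if (any(c(a, b, c_, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  or <- (a / b) / (c_ / d)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(or = or,
       ci_lower = exp(log(or) - 1.96 * se),
       ci_upper = exp(log(or) + 1.96 * se))
}
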