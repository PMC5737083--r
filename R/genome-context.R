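#' Bin SIR density along the genome
#'
#' Partitions each chromosome into fixed-width bins (default 2 Mb; the last
#' bin of a chromosome may be shorter), counts SIRs by the bin containing
#' their start, and computes per-bin GC content. Density is SIRs per Mb of
#' non-N bin sequence.
#'
#' @param sirs SIR data frame.
#' @param genome Named character vector of sequences (or DNAStringSet).
#' @param bin_width Bin width in bp (default 2e6).
#' @return Data frame with columns `chrom`, `start`, `end`, `gc_fraction`,
#'   `sir_count`, `sir_density`.
#' @export
bin_sir_density <- function(sirs, genome, bin_width = 2e6) {
  genome <- as_genome(genome)
  missing_chrom <- setdiff(unique(sirs$chrom), names(genome))
  if (length(missing_chrom) > 0L)
    stop("SIRs on chromosome(s) absent from the genome: ",
         paste(missing_chrom, collapse = ", "))
  bins <- do.call(rbind, lapply(names(genome), function(ch) {
    len <- nchar(genome[[ch]])
    starts <- seq.int(0L, len - 1L, by = bin_width)
    ends <- pmin(starts + bin_width, len)
    seqs <- substring(genome[[ch]], starts + 1L, ends)
    nonn <- nchar(gsub("N", "", seqs, fixed = TRUE))
    cnt <- integer(length(starts))
    ch_sirs <- sirs$start[sirs$chrom == ch]
    if (length(ch_sirs) > 0L) {
      idx <- findInterval(ch_sirs, starts)
      tab <- tabulate(idx, nbins = length(starts))
      cnt <- tab
    }
    data.frame(
      chrom = ch, start = starts, end = ends,
      gc_fraction = gc_content(seqs),
      sir_count = cnt,
      sir_density = ifelse(nonn > 0L, cnt / (nonn / 1e6), NA_real_)
    )
  }))
  rownames(bins) <- NULL
  bins
}

#' Quadratic fit of SIR density on GC content
#'
#' Least-squares fit of per-bin SIR density on (1, gc, gc^2), the model form
#' that describes how rising local GC content depresses SIR density.
#'
#' @param bins Data frame from [bin_sir_density()].
#' @return List with `coefficients` (intercept, gc, gc^2) and `fitted`.
#' @export
fit_density_gc_quadratic <- function(bins) {
  ok <- is.finite(bins$gc_fraction) & is.finite(bins$sir_density)
  d <- bins[ok, , drop = FALSE]
  if (length(unique(d$gc_fraction)) < 3L)
    stop("need at least 3 bins with distinct GC content")
  fit <- stats::lm(sir_density ~ gc_fraction + I(gc_fraction^2), data = d)
  if (any(is.na(stats::coef(fit)))) stop("degenerate (collinear) design")
  list(coefficients = unname(stats::coef(fit)), fitted = unname(stats::fitted(fit)))
}

# 64 -> 32 pyrimidine-centered collapse map for trinucleotides.
.pyr_collapse <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  mid <- substr(all64, 2L, 2L)
  canon <- ifelse(mid %in% c("C", "T"), all64, revcomp(all64))
  stats::setNames(canon, all64)
}

#' Trinucleotide spectrum of a set of intervals
#'
#' Counts every overlapping 3-mer window fully inside an interval;
#' purine-centered 3-mers are reverse-complemented to their pyrimidine-centered
#' equivalent, giving 32 contexts (4 x {C,T} x 4). Windows containing N are
#' skipped. Frequencies are normalized to sum to 1.
#'
#' @param intervals Data frame (`chrom`, `start`, `end`), 0-based half-open.
#' @param genome Named character vector of sequences (or DNAStringSet).
#' @return Named numeric vector of 32 relative frequencies.
#' @export
trinucleotide_spectrum <- function(intervals, genome) {
  genome <- as_genome(genome)
  counts64 <- stats::setNames(numeric(64L),
    names(Biostrings::trinucleotideFrequency(Biostrings::DNAString("AAA"))))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (!ch %in% names(genome)) stop("interval on unknown chromosome: ", ch)
    iv <- iv[iv$end - iv$start >= 3L, , drop = FALSE]
    if (nrow(iv) == 0L) next
    seqs <- substring(genome[[ch]], iv$start + 1L, iv$end)
    f <- Biostrings::trinucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                            step = 1L)
    counts64 <- counts64 + colSums(f)
  }
  map <- .pyr_collapse()
  canon <- sort(unique(unname(map)))
  counts32 <- vapply(canon, function(k) sum(counts64[names(map)[map == k]]),
                     numeric(1L))
  total <- sum(counts32)
  if (total == 0) return(stats::setNames(rep(NA_real_, 32L), canon))
  counts32 / total
}

#' Cosine similarity of two spectra
#'
#' @param a,b Nonnegative numeric vectors with the same index ordering.
#' @return dot(a, b) / (||a|| * ||b||), in [0, 1] for nonnegative inputs.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("spectra must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

# Left-of-middle position of the spacer interval (0-based point).
sir_center <- function(sirs) {
  sirs$start + sirs$arm_len + (sirs$spacer_len - 1L) %/% 2L
}

#' Annotate SIRs against interval tracks
#'
#' An SIR is labelled with a track when its spacer midpoint (left-of-middle
#' position for even spacers) falls inside one of the track's merged
#' intervals; SIRs matching no track are labelled "others".
#'
#' @param sirs SIR data frame.
#' @param tracks List of tracks as returned by [read_bed_track()].
#' @return List (one element per SIR) of character vectors of track names.
#' @export
annotate_sirs <- function(sirs, tracks) {
  n <- nrow(sirs)
  labels <- vector("list", n)
  mid <- sir_center(sirs)
  for (tr in tracks) {
    for (ch in unique(tr$intervals$chrom)) {
      iv <- tr$intervals[tr$intervals$chrom == ch, , drop = FALSE]
      sel <- which(sirs$chrom == ch)
      if (length(sel) == 0L) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(mid[sel] + 1L, width = 1L),
        IRanges::IRanges(iv$start + 1L, iv$end)
      )
      for (i in unique(S4Vectors::queryHits(hits))) {
        j <- sel[i]
        labels[[j]] <- c(labels[[j]], tr$name)
      }
    }
  }
  lapply(labels, function(x) if (is.null(x)) "others" else sort(unique(x)))
}

#' Partition replication-timing intervals into deciles
#'
#' Takes a track whose interval names carry a continuous replication-timing
#' value and splits the intervals into 10 tracks (`decile_1` earliest ...
#' `decile_10` latest) by ranking values weighted by interval length.
#'
#' @param timing Data frame (`chrom`, `start`, `end`, `value`).
#' @return List of 10 tracks in [read_bed_track()] format.
#' @export
timing_deciles <- function(timing) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(timing)))
  o <- order(timing$value)
  d <- timing[o, , drop = FALSE]
  w <- cumsum(as.numeric(d$end - d$start))
  frac <- (w - (d$end - d$start) / 2) / w[length(w)]
  d$decile <- pmin(10L, 1L + floor(frac * 10))
  lapply(split(d, d$decile), function(dd) {
    list(name = paste0("decile_", dd$decile[1L]),
         intervals = dd[order(dd$chrom, dd$start), c("chrom", "start", "end")])
  })
}
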