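#' Search configuration for SIR detection
#'
#' Holds the arm/spacer length ranges used by the scanner and the control
#' window widths used downstream. Defaults correspond to hairpins expected to
#' be stable in vivo: loops (spacers) of 4-8 bp -- the steric minimum for a
#' loop is 4 bp -- and stems (arms) of 6-25 bp.
#'
#' @param spacer_min,spacer_max Spacer (loop) length range in bp.
#' @param arm_min,arm_max Arm (stem) length range in bp.
#' @param control_width_sub_indel Width in bp of each flanking control window
#'   used for substitutions and indels (default 100).
#' @param control_width_rearrangement Control width for rearrangement
#'   breakpoints (default 1000), wider because breakpoint density is low.
#' @param drop_pure_at Drop SIRs whose spacer is composed purely of A/T.
#' @return A list of class `sir_search_config`.
#' @export
search_config <- function(spacer_min = 4L, spacer_max = 8L,
                          arm_min = 6L, arm_max = 25L,
                          control_width_sub_indel = 100L,
                          control_width_rearrangement = 1000L,
                          drop_pure_at = TRUE) {
  spacer_min <- as.integer(spacer_min); spacer_max <- as.integer(spacer_max)
  arm_min <- as.integer(arm_min); arm_max <- as.integer(arm_max)
  if (spacer_min < 4L)
    stop("spacer_min must be >= 4 (steric minimum for a hairpin loop)")
  if (spacer_max < spacer_min) stop("spacer_max must be >= spacer_min")
  if (arm_min < 1L || arm_max < arm_min) stop("invalid arm length range")
  if (control_width_sub_indel <= 0L || control_width_rearrangement <= 0L)
    stop("control widths must be positive")
  structure(list(
    spacer_min = spacer_min, spacer_max = spacer_max,
    arm_min = arm_min, arm_max = arm_max,
    control_width_sub_indel = as.integer(control_width_sub_indel),
    control_width_rearrangement = as.integer(control_width_rearrangement),
    drop_pure_at = isTRUE(drop_pure_at)
  ), class = "sir_search_config")
}

#' The (spacer length, arm length) category grid
#'
#' @param config A [search_config()].
#' @return Data frame with one row per (spacer_len, arm_len) category.
#' @export
sir_categories <- function(config = search_config()) {
  expand.grid(
    spacer_len = config$spacer_min:config$spacer_max,
    arm_len = config$arm_min:config$arm_max,
    KEEP.OUT.ATTRS = FALSE
  )
}

#' Enumerate palindromic decompositions of a sequence
#'
#' Finds every split of `seq` into left arm + spacer + right arm such that the
#' right arm is the exact reverse complement of the left arm and the spacer
#' length lies within the configured range. Because one inverted repeat can be
#' read as several hairpin categories (e.g. an 18-mer as 7 bp arms with a 4 bp
#' loop, 6 bp arms with a 6 bp loop, or 5 bp arms with an 8 bp loop), the
#' arm floor is an explicit argument rather than taken from the config.
#'
#' @param seq A single DNA sequence without N.
#' @param config A [search_config()]; supplies the spacer length range.
#' @param arm_floor Minimum arm length considered; defaults to the config's
#'   arm minimum. Pass 1 to enumerate every palindromic split regardless of
#'   the detection arm range.
#' @return Data frame with columns `arm_len`, `spacer_len`, sorted by
#'   ascending spacer length; zero rows when no decomposition exists.
#' @export
enumerate_ir_decompositions <- function(seq, config = search_config(),
                                        arm_floor = config$arm_min) {
  seq <- normalize_sequence(seq)
  if (length(seq) != 1L) stop("seq must be a single sequence")
  if (grepl("N", seq, fixed = TRUE)) stop("seq must not contain N")
  if (arm_floor < 1L) stop("arm_floor must be >= 1")
  len <- nchar(seq)
  arms <- integer(0); spacers <- integer(0)
  for (s in config$spacer_min:config$spacer_max) {
    if ((len - s) %% 2L != 0L) next
    a <- (len - s) %/% 2L
    if (a < arm_floor) next
    left <- substr(seq, 1L, a)
    right <- substr(seq, a + s + 1L, 2L * a + s)
    if (right == revcomp(left)) {
      arms <- c(arms, a); spacers <- c(spacers, s)
    }
  }
  data.frame(arm_len = arms, spacer_len = spacers)
}

#' Most stable hairpin category among decompositions
#'
#' Applies the canonicalization rule: the retained category is the one whose
#' loop (spacer) is as short as possible -- but at least the configured
#' minimum -- and whose arm is as long as possible. For decompositions of one
#' sequence the two criteria coincide, since 2*arm + spacer is fixed.
#'
#' @param decomps Data frame from [enumerate_ir_decompositions()].
#' @return One-row data frame (`arm_len`, `spacer_len`), or zero rows.
#' @export
canonical_decomposition <- function(decomps) {
  if (nrow(decomps) == 0L) return(decomps)
  o <- order(decomps$spacer_len, -decomps$arm_len)
  decomps[o[1L], , drop = FALSE]
}

.empty_sirs <- function() {
  data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    arm_len = integer(0), spacer_len = integer(0),
    left_arm = character(0), spacer = character(0),
    is_pure_at_spacer = logical(0)
  )
}

#' Scan a chromosome for short inverted repeats
#'
#' Exhaustively detects every window that satisfies the arm/spacer constraints
#' with a perfect palindromic arm match, then collapses windows sharing the
#' same total extent to the single most stable hairpin category (smallest
#' spacer, hence largest arm). Windows containing N are never emitted. Only
#' the forward strand is scanned: an inverted repeat on the forward strand is
#' the same double-stranded object as on the reverse strand.
#'
#' @param seq Chromosome sequence (single string).
#' @param chrom Chromosome name recorded in the output.
#' @param config A [search_config()].
#' @return Data frame of SIR records, 0-based half-open coordinates, sorted by
#'   `start` then `end`: columns `chrom`, `start`, `end`, `arm_len`,
#'   `spacer_len`, `left_arm`, `spacer`, `is_pure_at_spacer`.
#' @export
scan_inverted_repeats <- function(seq, chrom = "chr1",
                                  config = search_config()) {
  seq <- normalize_sequence(seq)
  if (length(seq) != 1L) stop("seq must be a single sequence")
  len <- nchar(seq)
  if (len < 2L * config$arm_min + config$spacer_min) return(.empty_sirs())

  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  comp <- unname(.COMP[chars])                 # NA at N: arm pairs at N never match
  n_cum <- c(0L, cumsum(chars == "N"))

  starts <- integer(0); arms <- integer(0); spacers <- integer(0)
  for (s in config$spacer_min:config$spacer_max) {
    nm <- len - s + 1L
    if (nm < 1L) next
    m <- seq_len(nm)                            # 1-based spacer start
    spacer_has_n <- (n_cum[m + s] - n_cum[m]) > 0L
    alive <- !spacer_has_n
    armlen <- integer(nm)
    for (k in seq_len(config$arm_max)) {
      left <- m - k
      right <- m + s - 1L + k
      alive <- alive & left >= 1L & right <= len
      idx <- which(alive)
      if (length(idx) == 0L) break
      ok <- comp[left[idx]] == chars[right[idx]]
      ok[is.na(ok)] <- FALSE
      alive[idx] <- ok
      armlen[idx[ok]] <- k
    }
    hit <- which(armlen >= config$arm_min)
    if (length(hit) == 0L) next
    nrep <- armlen[hit] - config$arm_min + 1L
    a <- sequence(nrep, from = config$arm_min)  # arm_min..armlen per hit
    m_rep <- rep.int(hit, nrep)
    starts <- c(starts, m_rep - a - 1L)         # 0-based window start
    arms <- c(arms, a)
    spacers <- c(spacers, rep.int(s, length(a)))
  }
  if (length(starts) == 0L) return(.empty_sirs())

  ends <- starts + 2L * arms + spacers
  # canonicalize: among candidates spanning the identical interval, keep the
  # smallest spacer (equivalently the largest arm)
  o <- order(starts, ends, spacers)
  starts <- starts[o]; ends <- ends[o]; arms <- arms[o]; spacers <- spacers[o]
  keep <- !duplicated(cbind(starts, ends))
  starts <- starts[keep]; ends <- ends[keep]
  arms <- arms[keep]; spacers <- spacers[keep]

  spacer_seq <- substr(rep(seq, length(starts)),
                       starts + arms + 1L, starts + arms + spacers)
  data.frame(
    chrom = chrom, start = starts, end = ends,
    arm_len = arms, spacer_len = spacers,
    left_arm = substr(rep(seq, length(starts)), starts + 1L, starts + arms),
    spacer = spacer_seq,
    is_pure_at_spacer = !grepl("[CG]", spacer_seq)
  )
}

#' Remove SIRs with pure-A/T spacers
#'
#' Retains exactly the records whose spacer contains at least one C or G;
#' input order is preserved.
#'
#' @param sirs SIR data frame.
#' @return Filtered SIR data frame.
#' @export
filter_pure_at <- function(sirs) {
  sirs[grepl("[CG]", sirs$spacer), , drop = FALSE]
}

#' Resolve overlapping SIRs to the longest predicted SIR
#'
#' At low-complexity regions several SIRs may overlap. Among any chain of
#' mutually overlapping records only the longest (greatest end - start)
#' survives; ties are broken by smaller start, then smaller spacer length.
#' The output is pairwise non-overlapping.
#'
#' @param sirs SIR data frame (any chromosome mix).
#' @return Non-overlapping SIR data frame sorted by chrom, start, end.
#' @export
resolve_overlaps <- function(sirs) {
  if (nrow(sirs) <= 1L) return(sirs)
  pieces <- lapply(split(sirs, sirs$chrom), function(df) {
    n <- nrow(df)
    if (n == 1L) return(df)
    ir <- IRanges::IRanges(df$start + 1L, df$end)
    cl <- S4Vectors::subjectHits(
      IRanges::findOverlaps(ir, IRanges::reduce(ir))
    )
    keep <- logical(n)
    for (g in split(seq_len(n), cl)) {
      if (length(g) == 1L) { keep[g] <- TRUE; next }
      o <- g[order(-(df$end[g] - df$start[g]), df$start[g], df$spacer_len[g])]
      ks <- integer(0); ke <- integer(0)
      for (i in o) {
        if (!any(df$start[i] < ke & df$end[i] > ks)) {
          keep[i] <- TRUE
          ks <- c(ks, df$start[i]); ke <- c(ke, df$end[i])
        }
      }
    }
    df[keep, , drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect the final SIR set of a genome
#'
#' Full detection pipeline per chromosome: raw scan with per-extent
#' canonicalization, pure-A/T spacer filter (if configured), and overlap
#' resolution to the longest SIR.
#'
#' @param genome Named character vector of chromosome sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param config A [search_config()].
#' @return Non-overlapping SIR data frame.
#' @export
detect_sirs <- function(genome, config = search_config()) {
  genome <- as_genome(genome)
  per_chrom <- lapply(names(genome), function(ch) {
    sirs <- scan_inverted_repeats(genome[[ch]], chrom = ch, config = config)
    if (config$drop_pure_at) sirs <- filter_pure_at(sirs)
    resolve_overlaps(sirs)
  })
  out <- do.call(rbind, c(per_chrom, list(.empty_sirs())))
  rownames(out) <- NULL
  out
}

# Coerce a genome argument to a named character vector of sequences.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome must be a named character vector or DNAStringSet")
  toupper(genome)
}

#' Spacer, arm and control intervals of one SIR
#'
#' @param sir One-row SIR data frame.
#' @param control_width Width in bp of each flanking control window.
#' @param chrom_length Chromosome length used to truncate control windows.
#' @return Data frame (`domain`, `start`, `end`), 0-based half-open; empty
#'   intervals after truncation are dropped. The spacer, arm and control
#'   domains are pairwise disjoint.
#' @export
domain_intervals <- function(sir, control_width, chrom_length) {
  stopifnot(nrow(sir) == 1L, control_width > 0L)
  s0 <- sir$start; a <- sir$arm_len; sl <- sir$spacer_len; e0 <- sir$end
  iv <- data.frame(
    domain = c("control", "arm", "spacer", "arm", "control"),
    start = c(max(0L, s0 - control_width), s0, s0 + a, s0 + a + sl, e0),
    end = c(s0, s0 + a, s0 + a + sl, e0, min(chrom_length, e0 + control_width))
  )
  iv[iv$end > iv$start, , drop = FALSE]
}
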