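#' Classify substitutions on the pyrimidine strand
#'
#' Substitutions are referred to by the pyrimidine of the mutated base pair:
#' when the reference base is a purine (A or G), ref, alt and flanking bases
#' are complemented and the flanks swapped. Returns the six-class label
#' (C>A, C>G, C>T, T>A, T>C, T>G) and, when flanks are available and N-free,
#' the 96-class label in the standard "5'[ref>alt]3'" form.
#'
#' @param ref,alt Single reference/alternate bases (vectorized).
#' @param fivep,threep Single flanking bases 5' and 3' of the mutated base on
#'   the reference strand; NA or N yields a 6-class label only.
#' @return Data frame with columns `class6`, `context` (pyrimidine-strand
#'   trinucleotide) and `class96`.
#' @export
classify_substitution <- function(ref, alt, fivep = NA_character_,
                                  threep = NA_character_) {
  n <- max(length(ref), length(alt), length(fivep), length(threep))
  ref <- toupper(rep_len(ref, n)); alt <- toupper(rep_len(alt, n))
  fivep <- toupper(rep_len(as.character(fivep), n))
  threep <- toupper(rep_len(as.character(threep), n))
  if (any(!ref %in% c("A", "C", "G", "T")) || any(!alt %in% c("A", "C", "G", "T")))
    stop("ref and alt must be single A/C/G/T bases")
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, unname(.COMP[ref]), ref)
  a <- ifelse(flip, unname(.COMP[alt]), alt)
  f5 <- ifelse(flip, unname(.COMP[threep]), fivep)
  f3 <- ifelse(flip, unname(.COMP[fivep]), threep)
  class6 <- paste0(r, ">", a)
  flank_ok <- !is.na(f5) & !is.na(f3) & f5 %in% c("A", "C", "G", "T") &
    f3 %in% c("A", "C", "G", "T")
  context <- ifelse(flank_ok, paste0(f5, r, f3), NA_character_)
  class96 <- ifelse(flank_ok, paste0(f5, "[", class6, "]", f3), NA_character_)
  data.frame(class6 = class6, context = context, class96 = class96)
}

# 1-based genomic point used to place a mutation: the mutated base for
# substitutions, the first affected base (position after the anchor base) for
# indels, and the breakpoint position for rearrangements.
mutation_point <- function(muts) {
  ifelse(muts$class == "indel", muts$pos + 1L, muts$pos)
}

# Control width appropriate to a variant class.
control_width_for <- function(class, config) {
  ifelse(class == "rearrangement_breakpoint",
         config$control_width_rearrangement,
         config$control_width_sub_indel)
}

#' Assign mutations to SIR domains
#'
#' Labels each mutation spacer / arm / control / outside by point containment.
#' The control window is 100 bp each side for substitutions and indels and
#' 1000 bp for rearrangement breakpoints (configurable). A point inside any
#' SIR body takes that SIR's domain even if it also lies within another SIR's
#' control window; a point in the control windows of several SIRs is assigned
#' to the nearest SIR (ties to the leftmost).
#'
#' @param muts Mutation data frame (`sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `class`).
#' @param sirs Non-overlapping SIR data frame (after [resolve_overlaps()]).
#' @param config A [search_config()].
#' @return `muts` with added columns `domain` and `sir_index` (row index into
#'   `sirs`; NA when outside).
#' @export
assign_to_domains <- function(muts, sirs, config = search_config()) {
  n <- nrow(muts)
  domain <- rep("outside", n)
  sir_index <- rep(NA_integer_, n)
  unknown <- !muts$chrom %in% unique(sirs$chrom)
  if (any(unknown) && nrow(sirs) > 0L)
    warning("mutations on chromosome(s) without SIRs treated as outside: ",
            paste(unique(muts$chrom[unknown]), collapse = ", "))
  pt <- mutation_point(muts)          # 1-based
  cw_all <- control_width_for(muts$class, config)
  for (ch in intersect(unique(muts$chrom), unique(sirs$chrom))) {
    s <- which(sirs$chrom == ch)
    sdf <- sirs[s, , drop = FALSE]
    mi <- which(muts$chrom == ch)
    p <- pt[mi]
    bodies <- IRanges::IRanges(sdf$start + 1L, sdf$end)
    hit <- IRanges::findOverlaps(IRanges::IRanges(p, width = 1L), bodies,
                                 select = "first")
    inside <- !is.na(hit)
    if (any(inside)) {
      hs <- hit[inside]
      sp_lo <- sdf$start[hs] + sdf$arm_len[hs] + 1L
      sp_hi <- sp_lo + sdf$spacer_len[hs] - 1L
      is_sp <- p[inside] >= sp_lo & p[inside] <= sp_hi
      domain[mi[inside]] <- ifelse(is_sp, "spacer", "arm")
      sir_index[mi[inside]] <- s[hs]
    }
    # control: per variant class because widths differ
    rest <- which(!inside)
    if (length(rest) == 0L) next
    for (cw in unique(cw_all[mi[rest]])) {
      sel <- rest[cw_all[mi[rest]] == cw]
      wins <- IRanges::IRanges(
        c(sdf$start - cw + 1L, sdf$end + 1L),
        c(sdf$start, sdf$end + cw)
      )
      win_sir <- rep(seq_len(nrow(sdf)), 2L)
      h <- IRanges::findOverlaps(IRanges::IRanges(p[sel], width = 1L), wins)
      if (length(h) == 0L) next
      q <- S4Vectors::queryHits(h); sj <- win_sir[S4Vectors::subjectHits(h)]
      # distance of the point to the SIR body it would be control for
      d <- pmax(sdf$start[sj] + 1L - p[sel][q], p[sel][q] - sdf$end[sj])
      o <- order(q, d, sj)
      first <- !duplicated(q[o])
      qi <- q[o][first]; si <- sj[o][first]
      domain[mi[sel][qi]] <- "control"
      sir_index[mi[sel][qi]] <- s[si]
    }
  }
  muts$domain <- domain
  muts$sir_index <- sir_index
  muts
}

# Per-SIR usable control intervals: the SIR's own flanking windows, truncated
# at chromosome bounds and with other SIR bodies carved out. Returns a data
# frame (sir_index, start, end) plus per-SIR usable bp net of N.
per_sir_controls <- function(sirs, genome, control_width) {
  genome <- as_genome(genome)
  out <- vector("list", 0L)
  usable <- numeric(nrow(sirs))
  for (ch in unique(sirs$chrom)) {
    s <- which(sirs$chrom == ch)
    sdf <- sirs[s, , drop = FALSE]
    len <- nchar(genome[[ch]])
    chars_n <- strsplit(genome[[ch]], "", fixed = TRUE)[[1L]] == "N"
    n_cum <- c(0L, cumsum(chars_n))
    bodies <- IRanges::IRanges(sdf$start + 1L, sdf$end)
    for (i in seq_along(s)) {
      win <- IRanges::IRanges(
        c(max(0L, sdf$start[i] - control_width) + 1L, sdf$end[i] + 1L),
        c(sdf$start[i], min(len, sdf$end[i] + control_width))
      )[c(sdf$start[i] > 0L, sdf$end[i] < len)]
      if (length(win) == 0L) next
      keep <- IRanges::setdiff(win, bodies)
      if (length(keep) == 0L) next
      st <- IRanges::start(keep); en <- IRanges::end(keep)
      nn <- n_cum[en + 1L] - n_cum[st]
      usable[s[i]] <- sum(en - st + 1L - nn)
      out[[length(out) + 1L]] <- data.frame(
        sir_index = s[i], chrom = ch, start = st - 1L, end = en
      )
    }
  }
  list(
    intervals = if (length(out)) do.call(rbind, out) else
      data.frame(sir_index = integer(0), chrom = character(0),
                 start = integer(0), end = integer(0)),
    usable_bp = usable
  )
}

#' Effective domain lengths of an SIR set
#'
#' Spacer and arm lengths are summed over SIRs (SIR windows contain no N by
#' construction). The control length is the union of all flanking control
#' windows, truncated at chromosome ends, with SIR bodies carved out and N
#' positions excluded -- so overlapping control windows of adjacent SIRs are
#' counted once.
#'
#' @param sirs SIR data frame.
#' @param genome Named character vector of sequences (or DNAStringSet).
#' @param control_width Control window width in bp.
#' @return Named numeric vector (spacer, arm, control) of bp.
#' @export
domain_lengths <- function(sirs, genome, control_width) {
  genome <- as_genome(genome)
  control_bp <- 0
  for (ch in unique(sirs$chrom)) {
    sdf <- sirs[sirs$chrom == ch, , drop = FALSE]
    len <- nchar(genome[[ch]])
    bodies <- IRanges::IRanges(sdf$start + 1L, sdf$end)
    wins <- IRanges::IRanges(
      pmax(0L, c(sdf$start - control_width, sdf$end)) + 1L,
      pmin(len, c(sdf$start, sdf$end + control_width))
    )
    wins <- wins[IRanges::width(wins) > 0L]
    ctrl <- IRanges::setdiff(IRanges::reduce(wins), bodies)
    if (length(ctrl) == 0L) next
    chars_n <- strsplit(genome[[ch]], "", fixed = TRUE)[[1L]] == "N"
    n_cum <- c(0L, cumsum(chars_n))
    st <- IRanges::start(ctrl); en <- IRanges::end(ctrl)
    control_bp <- control_bp + sum(en - st + 1L - (n_cum[en + 1L] - n_cum[st]))
  }
  c(spacer = sum(sirs$spacer_len),
    arm = 2 * sum(sirs$arm_len),
    control = control_bp)
}

#' Per-domain mutation densities
#'
#' Density is mutations per Mb per sample-genome:
#' count / (effective length in bp x n_samples) x 1e6.
#'
#' @param assigned Mutation data frame from [assign_to_domains()].
#' @param sirs SIR data frame used for the assignment.
#' @param genome Named character vector of sequences (or DNAStringSet).
#' @param n_samples Number of sample genomes in the catalog.
#' @param config A [search_config()]; supplies the substitution/indel control
#'   width used for the effective control length.
#' @return Data frame (`domain`, `n_mutations`, `effective_length`,
#'   `n_samples`, `density`); density is NA where the effective length is 0.
#' @export
domain_density <- function(assigned, sirs, genome, n_samples,
                           config = search_config()) {
  lens <- domain_lengths(sirs, genome, config$control_width_sub_indel)
  doms <- c("spacer", "arm", "control")
  cnt <- vapply(doms, function(d) sum(assigned$domain == d), numeric(1L))
  data.frame(
    domain = doms,
    n_mutations = unname(cnt),
    effective_length = unname(lens[doms]),
    n_samples = n_samples,
    density = ifelse(lens[doms] > 0, cnt / (lens[doms] * n_samples) * 1e6,
                     NA_real_)
  )
}

#' Mean per-SIR spacer/arm densities by (spacer length, arm length) group
#'
#' SIRs are separated into groups by spacer and arm length (100 groups with
#' the default 4-8 bp x 6-25 bp configuration); for each group the mean and
#' standard deviation of per-SIR mutation densities are reported.
#'
#' @param assigned Mutation data frame from [assign_to_domains()].
#' @param sirs SIR data frame.
#' @param n_samples Number of sample genomes.
#' @return Data frame (`spacer_len`, `arm_len`, `domain`, `n_sirs`,
#'   `mean_density`, `sd_density`), densities per Mb per sample.
#' @export
domain_density_by_group <- function(assigned, sirs, n_samples) {
  n <- nrow(sirs)
  sp_cnt <- tabulate(assigned$sir_index[assigned$domain == "spacer"], n)
  arm_cnt <- tabulate(assigned$sir_index[assigned$domain == "arm"], n)
  per_sir <- rbind(
    data.frame(spacer_len = sirs$spacer_len, arm_len = sirs$arm_len,
               domain = "spacer",
               density = sp_cnt / (sirs$spacer_len * n_samples) * 1e6),
    data.frame(spacer_len = sirs$spacer_len, arm_len = sirs$arm_len,
               domain = "arm",
               density = arm_cnt / (2 * sirs$arm_len * n_samples) * 1e6)
  )
  agg <- do.call(rbind, lapply(
    split(per_sir, list(per_sir$spacer_len, per_sir$arm_len, per_sir$domain),
          drop = TRUE),
    function(d) data.frame(
      spacer_len = d$spacer_len[1L], arm_len = d$arm_len[1L],
      domain = d$domain[1L], n_sirs = nrow(d),
      mean_density = mean(d$density), sd_density = stats::sd(d$density)
    )
  ))
  agg <- agg[order(agg$domain, agg$spacer_len, agg$arm_len), ]
  rownames(agg) <- NULL
  agg
}

#' Mutation likelihood by distance to SIR center
#'
#' For each offset in -half_window..half_window from the SIR center (the
#' left-of-middle position of the spacer interval), the mutation count at
#' that offset divided by the number of SIRs contributing a valid genomic
#' position at that offset.
#'
#' @param muts Mutation data frame.
#' @param sirs Non-overlapping SIR data frame.
#' @param genome Named character vector of sequences (or DNAStringSet); used
#'   for chromosome lengths.
#' @param half_window Half-width of the profile in bp.
#' @return Data frame (`offset`, `n_mutations`, `n_sirs`, `likelihood`).
#' @export
distance_profile <- function(muts, sirs, genome, half_window = 100L) {
  genome <- as_genome(genome)
  offsets <- (-half_window):half_window
  n_mut <- integer(length(offsets))
  n_sir <- integer(length(offsets))
  pt <- mutation_point(muts)
  for (ch in unique(sirs$chrom)) {
    sdf <- sirs[sirs$chrom == ch, , drop = FALSE]
    centers <- sir_center(sdf)                 # 0-based
    len <- nchar(genome[[ch]])
    for (k in seq_along(offsets)) {
      pos <- centers + offsets[k]
      n_sir[k] <- n_sir[k] + sum(pos >= 0L & pos < len)
    }
    p <- pt[muts$chrom == ch] - 1L             # 0-based
    if (length(p) == 0L || length(centers) == 0L) next
    h <- IRanges::findOverlaps(
      IRanges::IRanges(p + 1L, width = 1L),
      IRanges::IRanges(centers - half_window + 1L, centers + half_window + 1L)
    )
    if (length(h) == 0L) next
    off <- p[S4Vectors::queryHits(h)] - centers[S4Vectors::subjectHits(h)]
    tab <- tabulate(off + half_window + 1L, nbins = length(offsets))
    n_mut <- n_mut + tab
  }
  data.frame(
    offset = offsets, n_mutations = n_mut, n_sirs = n_sir,
    likelihood = ifelse(n_sir > 0L, n_mut / n_sir, NA_real_)
  )
}
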