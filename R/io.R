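#' Read a genome FASTA
#'
#' Multi-record, wrapped or unwrapped, case-insensitive. Record names are
#' truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write a genome FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Write the SIR table
#'
#' Tab-separated with 1-based inclusive coordinates (the internal
#' representation is 0-based half-open). Adds spacer and arm GC content.
#'
#' @param sirs SIR data frame from [detect_sirs()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sir_table <- function(sirs, path) {
  out <- data.frame(
    chrom = sirs$chrom,
    start_1based = sirs$start + 1L,
    end_1based = sirs$end,
    arm_len = sirs$arm_len,
    spacer_len = sirs$spacer_len,
    left_arm = sirs$left_arm,
    spacer = sirs$spacer,
    gc_spacer = gc_content(sirs$spacer),
    gc_arm = gc_content(sirs$left_arm)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SIR table written by [write_sir_table()]
#'
#' @param path Path to the TSV.
#' @return SIR data frame in the internal 0-based half-open convention.
#' @export
read_sir_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  data.frame(
    chrom = x$chrom,
    start = x$start_1based - 1L,
    end = x$end_1based,
    arm_len = x$arm_len,
    spacer_len = x$spacer_len,
    left_arm = x$left_arm,
    spacer = x$spacer,
    is_pure_at_spacer = !grepl("[CG]", x$spacer)
  )
}

#' Export SIRs as BED6
#'
#' 0-based half-open per the BED standard; name = spacer sequence,
#' score = arm length.
#'
#' @param sirs SIR data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
sirs_to_bed <- function(sirs, path) {
  out <- data.frame(sirs$chrom, sirs$start, sirs$end,
                    sirs$spacer, sirs$arm_len, "+")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a somatic mutation table
#'
#' Tab-separated with columns `sample`, `chrom`, `pos` (1-based), `ref`,
#' `alt`, `class` (one of substitution, indel, rearrangement_breakpoint) and
#' optionally `signature`.
#'
#' @param path Path to the TSV.
#' @return Mutation data frame.
#' @export
read_mutation_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  req <- c("sample", "chrom", "pos", "ref", "alt", "class")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0L)
    stop("mutation table missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(x$class),
                 c("substitution", "indel", "rearrangement_breakpoint"))
  if (length(bad) > 0L)
    stop("unknown variant class: ", paste(bad, collapse = ", "))
  x
}

#' Write a mutation table
#'
#' @param muts Mutation data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mutation_table <- function(muts, path) {
  utils::write.table(muts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation track from BED4
#'
#' The 4th column carries the track name (e.g. promoter, enhancer) or a
#' numeric replication-timing value. Intervals are merged per track name.
#'
#' @param path Path to a BED file.
#' @return List of tracks; each track is a list with `name` and a data frame
#'   `intervals` (chrom, start, end; 0-based half-open, merged).
#' @export
read_bed_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4L))
    stop("malformed BED line ", which(nf < 4L)[1L], ": expected >= 4 fields")
  df <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    name = vapply(parts, `[[`, "", 4L)
  )
  if (anyNA(df$start) || anyNA(df$end) || any(df$end <= df$start)) {
    bad <- which(is.na(df$start) | is.na(df$end) | df$end <= df$start)[1L]
    stop("malformed BED line ", bad, ": bad coordinates")
  }
  lapply(split(df, df$name), function(d) {
    merged <- do.call(rbind, lapply(split(d, d$chrom), function(dd) {
      ir <- IRanges::reduce(IRanges::IRanges(dd$start + 1L, dd$end))
      data.frame(chrom = dd$chrom[1L],
                 start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }))
    rownames(merged) <- NULL
    list(name = d$name[1L], intervals = merged[order(merged$chrom, merged$start), ])
  })
}

#' Read a signature exposure matrix
#'
#' TSV of samples by signatures; first column `sample`, remaining columns one
#' per mutational signature, nonnegative.
#'
#' @param path Path to the TSV.
#' @return Data frame with `sample` plus numeric signature columns.
#' @export
read_exposures <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (names(x)[1L] != "sample") stop("first column must be 'sample'")
  num <- x[, -1L, drop = FALSE]
  if (any(vapply(num, function(v) any(v < 0), logical(1L))))
    stop("exposures must be nonnegative")
  x
}
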