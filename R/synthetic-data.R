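#' Configuration for the synthetic genome and mutation generator
#'
#' Defines a scaled-down analogue of a tumor-cohort study: one synthetic
#' chromosome with planted SIRs at well-separated loci, a cohort of sample
#' genomes mutated at a uniform background rate, a multiplicative mutability
#' fold on planted spacer (hairpin loop) sequences, optional hotspot spacer
#' sequences with their own folds, and per-sample mutational-process classes
#' (flat, APOBEC-like, MSI-like).
#'
#' @param seed Integer seed; identical config + seed gives identical output.
#' @param chrom_length Chromosome length in bp.
#' @param gc_target Background GC fraction.
#' @param n_planted_sirs Number of regular planted SIRs.
#' @param planted_spacer_lens,planted_arm_lens Length pools sampled for the
#'   planted SIRs.
#' @param n_samples Number of sample genomes in the cohort.
#' @param background_density Per-bp per-sample substitution probability.
#' @param spacer_fold Multiplicative mutability fold applied inside planted
#'   spacer intervals.
#' @param indel_density Per-bp per-sample 1-bp indel probability at A/T
#'   mononucleotide runs for MSI-like samples.
#' @param hotspot_spec Optional data frame (`spacer_seq`, `fold`,
#'   `n_locations`) of hotspot spacers to plant.
#' @param signature_mix Named proportions over classes `flat`, `apobec`,
#'   `msi` assigning samples to mutational-process classes.
#' @param breakpoint_density Per-bp per-sample rearrangement breakpoint
#'   probability, placed uniformly (0 disables).
#' @param search A [search_config()] used to screen the background.
#' @return A list of class `sir_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_length = 200000L,
                              gc_target = 0.4,
                              n_planted_sirs = 60L,
                              planted_spacer_lens = 4:8,
                              planted_arm_lens = 6:15,
                              n_samples = 60L,
                              background_density = 0.002,
                              spacer_fold = 1.35,
                              indel_density = 4e-4,
                              hotspot_spec = NULL,
                              signature_mix = c(flat = 1, apobec = 0, msi = 0),
                              breakpoint_density = 0,
                              search = search_config()) {
  stopifnot(chrom_length > 0, gc_target >= 0, gc_target <= 1,
            n_samples >= 1, background_density >= 0, spacer_fold >= 0)
  if (background_density * spacer_fold > 1)
    stop("spacer_fold too large: per-position mutation probability exceeds 1")
  if (!is.null(hotspot_spec)) {
    stopifnot(all(c("spacer_seq", "fold", "n_locations") %in%
                    names(hotspot_spec)))
    if (any(background_density * hotspot_spec$fold > 1))
      stop("hotspot fold too large: per-position mutation probability exceeds 1")
  }
  mix <- signature_mix[c("flat", "apobec", "msi")]
  mix[is.na(mix)] <- 0
  if (sum(mix) <= 0) stop("signature_mix must have positive mass")
  structure(list(
    seed = as.integer(seed), chrom_length = as.integer(chrom_length),
    gc_target = gc_target, n_planted_sirs = as.integer(n_planted_sirs),
    planted_spacer_lens = as.integer(planted_spacer_lens),
    planted_arm_lens = as.integer(planted_arm_lens),
    n_samples = as.integer(n_samples),
    background_density = background_density, spacer_fold = spacer_fold,
    indel_density = indel_density, hotspot_spec = hotspot_spec,
    signature_mix = mix / sum(mix),
    breakpoint_density = breakpoint_density,
    search = search
  ), class = "sir_sim_config")
}

.random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# A random spacer guaranteed to contain at least one C or G.
.random_spacer <- function(len, gc) {
  repeat {
    s <- paste(.random_bases(len, max(gc, 0.25)), collapse = "")
    if (grepl("[CG]", s)) return(s)
  }
}

# Draw an arm (and spacer, unless fixed) such that the assembled SIR sequence
# scans as exactly one SIR of the requested category: no internal sub-SIR and
# no same-extent relabelling to a shorter spacer. Keeps planted truth exact.
.plant_sequence <- function(arm_len, spacer_len, gc, search,
                            spacer_seq = NULL) {
  screen <- search
  screen$drop_pure_at <- FALSE
  for (try in seq_len(500L)) {
    arm <- paste(.random_bases(arm_len, gc), collapse = "")
    sp <- if (is.null(spacer_seq)) .random_spacer(spacer_len, gc) else
      spacer_seq
    full <- paste0(arm, sp, revcomp(arm))
    found <- resolve_overlaps(scan_inverted_repeats(full, "x", screen))
    if (nrow(found) == 1L && found$start == 0L &&
        found$end == nchar(full) && found$arm_len == arm_len)
      return(list(left_arm = arm, spacer = sp))
  }
  stop("could not construct a clean planted SIR (arm ", arm_len,
       ", spacer ", if (is.null(spacer_seq)) spacer_len else spacer_seq, ")")
}

#' Generate a synthetic genome with planted SIRs
#'
#' Draws i.i.d. background sequence at the target GC and plants each SIR as
#' left arm + spacer + reverse complement of the left arm at loci separated by
#' more than twice the control width, so control windows never touch another
#' plant. The background around each plant is rejection-screened: bases in the
#' neighborhood are redrawn until the only SIR whose interval comes within a
#' control width of the plant is the plant itself, recovered at exactly its
#' planted category -- keeping the ground truth unambiguous.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (named character vector, one chromosome
#'   `chr1`) and `truth` (data frame of planted SIRs: `chrom`, `start`,
#'   `end`, `arm_len`, `spacer_len`, `left_arm`, `spacer`, `fold`, `kind`).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  sc <- config$search
  cw <- sc$control_width_sub_indel
  n_hot <- if (is.null(config$hotspot_spec)) 0L else
    sum(config$hotspot_spec$n_locations)
  n_plant <- config$n_planted_sirs + n_hot

  # draw plant geometries; every planted sequence is screened so that it
  # scans as exactly its intended category
  spacer_len <- integer(0); arm_len <- integer(0)
  spacer_seq <- character(0); left_arm <- character(0)
  fold <- numeric(0); kind <- character(0)
  if (config$n_planted_sirs > 0L) {
    spacer_len <- sample(config$planted_spacer_lens, config$n_planted_sirs,
                         replace = TRUE)
    arm_len <- sample(config$planted_arm_lens, config$n_planted_sirs,
                      replace = TRUE)
    for (i in seq_len(config$n_planted_sirs)) {
      pl <- .plant_sequence(arm_len[i], spacer_len[i], config$gc_target, sc)
      left_arm <- c(left_arm, pl$left_arm)
      spacer_seq <- c(spacer_seq, pl$spacer)
    }
    fold <- rep(config$spacer_fold, config$n_planted_sirs)
    kind <- rep("planted", config$n_planted_sirs)
  }
  if (n_hot > 0L) {
    for (i in seq_len(nrow(config$hotspot_spec))) {
      h <- config$hotspot_spec[i, ]
      sq <- normalize_sequence(h$spacer_seq)
      if (nchar(sq) < sc$spacer_min || nchar(sq) > sc$spacer_max)
        stop("hotspot spacer length outside the configured spacer range: ", sq)
      for (j in seq_len(h$n_locations)) {
        a <- sample(config$planted_arm_lens, 1L)
        pl <- .plant_sequence(a, nchar(sq), config$gc_target, sc,
                              spacer_seq = sq)
        spacer_len <- c(spacer_len, nchar(sq))
        arm_len <- c(arm_len, a)
        left_arm <- c(left_arm, pl$left_arm)
        spacer_seq <- c(spacer_seq, sq)
        fold <- c(fold, h$fold)
        kind <- c(kind, "hotspot")
      }
    }
  }
  sir_len <- 2L * arm_len + spacer_len

  if (n_plant > 0L) {
    slot <- config$chrom_length %/% n_plant
    need <- max(sir_len) + 2L * cw + 40L
    if (slot < need)
      stop("chromosome too short for requested plants; need at least ",
           need * n_plant, " bp")
    starts <- (seq_len(n_plant) - 1L) * slot + cw + 20L   # 0-based
  } else {
    starts <- integer(0)
  }

  chars <- .random_bases(config$chrom_length, config$gc_target)
  for (i in seq_along(starts)) {
    sir <- paste0(left_arm[i], spacer_seq[i], revcomp(left_arm[i]))
    chars[(starts[i] + 1L):(starts[i] + sir_len[i])] <-
      strsplit(sir, "", fixed = TRUE)[[1L]]
  }

  truth <- data.frame(
    chrom = rep("chr1", n_plant), start = starts,
    end = starts + sir_len, arm_len = arm_len, spacer_len = spacer_len,
    left_arm = left_arm, spacer = spacer_seq, fold = fold, kind = kind
  )

  # rejection screen: no unplanted SIR within a control width of a plant and
  # each plant recovered at exactly its planted extent
  screen_cfg <- sc
  screen_cfg$drop_pure_at <- FALSE
  plant_bases <- unlist(mapply(function(s, e) (s + 1L):e,
                               truth$start, truth$end, SIMPLIFY = FALSE))
  for (i in seq_along(starts)) {
    win_lo <- max(0L, starts[i] - cw - 2L * sc$arm_max)
    win_hi <- min(config$chrom_length, truth$end[i] + cw + 2L * sc$arm_max)
    done <- FALSE
    for (iter in seq_len(200L)) {
      local <- paste(chars[(win_lo + 1L):win_hi], collapse = "")
      found <- resolve_overlaps(scan_inverted_repeats(local, "chr1",
                                                      screen_cfg))
      found$start <- found$start + win_lo
      found$end <- found$end + win_lo
      near <- found[found$end > truth$start[i] - cw &
                      found$start < truth$end[i] + cw, , drop = FALSE]
      if (nrow(near) == 1L && near$start == truth$start[i] &&
          near$end == truth$end[i] && near$arm_len == truth$arm_len[i]) {
        done <- TRUE
        break
      }
      redraw <- setdiff((win_lo + 1L):win_hi, plant_bases)
      chars[redraw] <- .random_bases(length(redraw), config$gc_target)
    }
    if (!done)
      stop("could not isolate planted SIR ", i, " from background SIRs")
  }

  list(genome = c(chr1 = paste(chars, collapse = "")), truth = truth)
}

# Positions (1-based) whose base is C in a TCN context or G in an NGA context
# (the reverse-strand image), i.e. the APOBEC target contexts.
.tcn_positions <- function(chars) {
  len <- length(chars)
  fwd <- which(chars == "C")
  fwd <- fwd[fwd > 1L][chars[fwd[fwd > 1L] - 1L] == "T"]
  rev <- which(chars == "G")
  rev <- rev[rev < len][chars[rev[rev < len] + 1L] == "A"]
  list(fwd = fwd, rev = rev)
}

# 1-based positions inside A/T mononucleotide runs of length >= min_run.
.at_run_positions <- function(chars, min_run = 5L) {
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("A", "T") & r$lengths >= min_run
  if (!any(keep)) return(integer(0))
  unlist(mapply(seq.int, starts[keep], ends[keep], SIMPLIFY = FALSE),
         use.names = FALSE)
}

#' Generate a somatic mutation catalog over a synthetic genome
#'
#' Per sample, substitutions are placed by independent per-position Bernoulli
#' draws at the background density, multiplied by the planted fold inside
#' planted spacer intervals. APOBEC-like samples concentrate 75% of their
#' expected substitution mass on C bases in TCN context (either strand),
#' mutated to T or G; MSI-like samples additionally emit 1-bp deletions at
#' A/T mononucleotide runs and at planted A/T-only spacers (at the planted
#' fold); flat samples are uniform. Each sample uses its own seed derived
#' from the master seed by counter, so adding samples never perturbs earlier
#' ones. At most one substitution per sample and position.
#'
#' @param config A [simulation_config()].
#' @param genome Named character vector from [generate_genome()].
#' @param truth Planted-SIR data frame from [generate_genome()].
#' @return List with `muts` (data frame: `sample`, `chrom`, `pos`, `ref`,
#'   `alt`, `class`, `signature`) and `sample_classes` (data frame `sample`,
#'   `class`).
#' @export
generate_mutations <- function(config, genome, truth) {
  chrom <- names(genome)[1L]
  chars <- strsplit(genome[[1L]], "", fixed = TRUE)[[1L]]
  len <- length(chars)

  rate <- rep(config$background_density, len)
  if (nrow(truth) > 0L) {
    for (i in seq_len(nrow(truth))) {
      sp <- (truth$start[i] + truth$arm_len[i] + 1L):
        (truth$start[i] + truth$arm_len[i] + truth$spacer_len[i])
      rate[sp] <- config$background_density * truth$fold[i]
    }
  }
  if (any(rate > 1)) stop("per-position mutation probability exceeds 1")

  mix <- config$signature_mix
  n_per <- diff(round(cumsum(c(0, mix)) * config$n_samples))
  classes <- rep(names(mix), n_per)
  if (length(classes) < config$n_samples)
    classes <- c(classes, rep("flat", config$n_samples - length(classes)))
  classes <- classes[seq_len(config$n_samples)]
  sample_ids <- sprintf("S%03d", seq_len(config$n_samples))

  tcn <- .tcn_positions(chars)
  n_tcn <- length(tcn$fwd) + length(tcn$rev)
  at_runs <- .at_run_positions(chars)
  at_spacers <- integer(0); at_spacer_fold <- numeric(0)
  if (nrow(truth) > 0L) {
    for (i in which(!grepl("[CG]", truth$spacer))) {
      sp <- (truth$start[i] + truth$arm_len[i] + 1L):
        (truth$start[i] + truth$arm_len[i] + truth$spacer_len[i])
      at_spacers <- c(at_spacers, sp)
      at_spacer_fold <- c(at_spacer_fold, rep(truth$fold[i], length(sp)))
    }
  }

  other <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))

  out <- vector("list", config$n_samples)
  for (si in seq_len(config$n_samples)) {
    set.seed((config$seed + 104729L * si) %% 2147483647L)
    cls <- classes[si]
    if (cls == "apobec" && n_tcn > 0L) {
      # 75% of the expected substitution mass rides on TCN-context C sites,
      # scaled by the local rate so planted spacer folds carry through
      tcn_all <- c(tcn$fwd, tcn$rev)
      r <- rate * 0.25
      scale <- 0.75 * sum(rate) / sum(rate[tcn_all])
      r[tcn_all] <- r[tcn_all] + rate[tcn_all] * scale
      r <- pmin(r, 0.95)
    } else {
      r <- rate
    }
    pos <- which(stats::runif(len) < r)
    ref <- chars[pos]
    is_tcn <- logical(length(pos))
    alt <- character(length(pos))
    if (cls == "apobec") {
      is_tcn <- pos %in% tcn$fwd | pos %in% tcn$rev
      fwd <- is_tcn & ref == "C"
      rev <- is_tcn & ref == "G"
      alt[fwd] <- sample(c("T", "G"), sum(fwd), replace = TRUE)
      alt[rev] <- sample(c("A", "C"), sum(rev), replace = TRUE)
    }
    plain <- !nzchar(alt)
    alt[plain] <- vapply(ref[plain], function(b) sample(other[[b]], 1L), "")
    df <- data.frame(
      sample = rep(sample_ids[si], length(pos)), chrom = chrom, pos = pos,
      ref = ref, alt = alt, class = "substitution",
      signature = ifelse(is_tcn & cls == "apobec", "APOBEC", "flat")
    )
    if (cls == "msi") {
      ipos <- sort(unique(c(
        at_runs[stats::runif(length(at_runs)) < config$indel_density],
        at_spacers[stats::runif(length(at_spacers)) <
                     config$indel_density * at_spacer_fold]
      )))
      ipos <- ipos[ipos > 1L]
      if (length(ipos) > 0L) {
        anchor <- ipos - 1L
        df <- rbind(df, data.frame(
          sample = sample_ids[si], chrom = chrom, pos = anchor,
          ref = paste0(chars[anchor], chars[ipos]), alt = chars[anchor],
          class = "indel", signature = "MSI"
        ))
      }
    }
    if (config$breakpoint_density > 0) {
      bpos <- which(stats::runif(len) < config$breakpoint_density)
      if (length(bpos) > 0L) {
        df <- rbind(df, data.frame(
          sample = sample_ids[si], chrom = chrom, pos = bpos,
          ref = chars[bpos], alt = ".", class = "rearrangement_breakpoint",
          signature = "flat"
        ))
      }
    }
    out[[si]] <- df
  }
  muts <- do.call(rbind, out)
  rownames(muts) <- NULL
  list(muts = muts,
       sample_classes = data.frame(sample = sample_ids, class = classes))
}

#' Generate a per-sample signature exposure matrix
#'
#' Emits exposures over the 12 breast-cancer substitution signatures
#' (1, 2, 3, 5, 6, 8, 13, 17, 18, 20, 26, 30) consistent with each sample's
#' generator class: APOBEC-like samples load on signatures 2/13, MSI-like on
#' 6/20/26, flat samples on the clock-like signatures 1/5, all with
#' multiplicative noise.
#'
#' @param sample_classes Data frame (`sample`, `class`) from
#'   [generate_mutations()].
#' @param seed Integer seed.
#' @param brca_fraction Fraction of flat samples re-labelled as BRCA-like
#'   (loading on signature 3) to exercise all five phenotype classes; 0
#'   disables.
#' @return Data frame `sample` plus columns `sig1` ... `sig30`.
#' @export
generate_exposures <- function(sample_classes, seed = 1L, brca_fraction = 0) {
  set.seed(seed)
  sigs <- c(1, 2, 3, 5, 6, 8, 13, 17, 18, 20, 26, 30)
  base <- stats::setNames(rep(0.01, 12L), paste0("sig", sigs))
  n <- nrow(sample_classes)
  cls <- sample_classes$class
  if (brca_fraction > 0) {
    flat_idx <- which(cls == "flat")
    nb <- floor(length(flat_idx) * brca_fraction)
    if (nb > 0L) cls[flat_idx[seq_len(nb)]] <- "brca"
  }
  mat <- matrix(rep(base, each = n), nrow = n,
                dimnames = list(NULL, names(base)))
  for (i in seq_len(n)) {
    w <- switch(cls[i],
      apobec = c(sig2 = 0.45, sig13 = 0.35),
      msi = c(sig6 = 0.35, sig20 = 0.2, sig26 = 0.25),
      brca = c(sig3 = 0.6, sig5 = 0.15),
      flat = c(sig1 = 0.4, sig5 = 0.35)
    )
    mat[i, names(w)] <- mat[i, names(w)] + w
    mat[i, ] <- mat[i, ] * stats::runif(12L, 0.8, 1.2)
    mat[i, ] <- mat[i, ] / sum(mat[i, ])
  }
  cbind(data.frame(sample = sample_classes$sample), as.data.frame(mat))
}

#' Write a simulation to disk
#'
#' FASTA genome, mutation TSV (the dialect [read_mutation_table()] reads) and
#' a JSON truth manifest.
#'
#' @param sim List with `genome`, `truth`, `muts`, `sample_classes`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_mutation_table(sim$muts, file.path(dir, "mutations.tsv"))
  jsonlite::write_json(
    list(planted = sim$truth, sample_classes = sim$sample_classes),
    file.path(dir, "truth.json"), digits = NA
  )
  invisible(dir)
}

#' Read a truth manifest written by [write_simulation()]
#'
#' @param path Path to `truth.json`.
#' @return List with `planted` and `sample_classes` data frames.
#' @export
read_truth_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(planted = as.data.frame(x$planted),
       sample_classes = as.data.frame(x$sample_classes))
}
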