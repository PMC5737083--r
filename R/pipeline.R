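#' Run configuration for the full SIR mutability pipeline
#'
#' @param fasta Path to the genome FASTA.
#' @param variants Path to the mutation TSV.
#' @param n_samples Number of sample genomes in the catalog.
#' @param out_dir Output directory.
#' @param tracks Optional path to a BED4 annotation-track file.
#' @param exposures Optional path to a signature exposure TSV.
#' @param truth Optional path to a simulation truth manifest; when present the
#'   summary also reports the spacer:control fold restricted to planted SIRs.
#' @param search A [search_config()].
#' @param q_threshold Adjusted p-value threshold for highly mutated SIRs and
#'   hotspot spacers.
#' @param msi_threshold,apobec_threshold Hotspot-count classifier thresholds.
#' @param bin_width Bin width for SIR density (bp).
#' @return A list of class `sir_run_config`.
#' @export
run_config <- function(fasta, variants, n_samples, out_dir,
                       tracks = NULL, exposures = NULL, truth = NULL,
                       search = search_config(), q_threshold = 0.01,
                       msi_threshold = 16L, apobec_threshold = 7L,
                       bin_width = 2e6) {
  structure(list(
    fasta = fasta, variants = variants, n_samples = n_samples,
    out_dir = out_dir, tracks = tracks, exposures = exposures, truth = truth,
    search = search, q_threshold = q_threshold,
    msi_threshold = as.integer(msi_threshold),
    apobec_threshold = as.integer(apobec_threshold),
    bin_width = bin_width
  ), class = "sir_run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# Spacer:control density fold for a set of SIRs.
.fold_estimate <- function(assigned, sirs, genome, n_samples, config) {
  d <- domain_density(assigned, sirs, genome, n_samples, config)
  sp <- d$density[d$domain == "spacer"]
  ct <- d$density[d$domain == "control"]
  if (is.na(sp) || is.na(ct) || ct == 0) return(NA_real_)
  sp / ct
}

#' Run the full SIR mutability pipeline
#'
#' Executes scan -> genomic context -> domain mutability -> highly mutated
#' SIRs and hotspots -> sample classification, writing every intermediate
#' table, a machine-readable JSON summary and a log under `out_dir`. Any
#' stage failure halts with the stage name; outputs of completed stages are
#' retained.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly.
#' @export
run_sir_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(..., "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("sirmut ", as.character(utils::packageVersion("sirmut")))
  logf("spacer ", config$search$spacer_min, "-", config$search$spacer_max,
       " bp, arm ", config$search$arm_min, "-", config$search$arm_max,
       " bp, control ", config$search$control_width_sub_indel, "/",
       config$search$control_width_rearrangement,
       " bp, q <= ", config$q_threshold,
       ", thresholds ", config$msi_threshold, "/", config$apobec_threshold,
       ", n_samples ", config$n_samples)

  genome <- .stage("scan", read_genome_fasta(config$fasta))
  sirs <- .stage("scan", detect_sirs(genome, config$search))
  write_sir_table(sirs, file.path(config$out_dir, "sirs.tsv"))
  logf("scan: ", nrow(sirs), " SIRs")

  context <- .stage("context", {
    bins <- bin_sir_density(sirs, genome, config$bin_width)
    utils::write.table(bins, file.path(config$out_dir, "bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sp_iv <- data.frame(chrom = sirs$chrom,
                        start = sirs$start + sirs$arm_len,
                        end = sirs$start + sirs$arm_len + sirs$spacer_len)
    spectra <- list(spacer = trinucleotide_spectrum(sp_iv, genome))
    list(bins = bins, spectra = spectra)
  })

  muts <- .stage("mutability", read_mutation_table(config$variants))
  assigned <- .stage("mutability", assign_to_domains(muts, sirs, config$search))
  densities <- .stage("mutability",
    domain_density(assigned[assigned$class == "substitution", ], sirs, genome,
                   config$n_samples, config$search))
  utils::write.table(densities, file.path(config$out_dir, "densities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fold_all <- densities$density[densities$domain == "spacer"] /
    densities$density[densities$domain == "control"]
  logf("mutability: spacer:control fold ", format(fold_all))

  fold_planted <- NA_real_
  if (!is.null(config$truth)) {
    manifest <- read_truth_manifest(config$truth)
    planted_key <- paste0(manifest$planted$chrom, ":", manifest$planted$start)
    planted_sirs <- sirs[paste0(sirs$chrom, ":", sirs$start) %in% planted_key, ]
    assigned_p <- assign_to_domains(muts, planted_sirs, config$search)
    fold_planted <- .fold_estimate(
      assigned_p[assigned_p$class == "substitution", ], planted_sirs, genome,
      config$n_samples, config$search)
    logf("mutability: planted-SIR fold ", format(fold_planted))
  }

  hm <- .stage("hotspots",
    call_highly_mutated(sirs, assigned, genome, config$n_samples,
                        config$search, config$q_threshold))
  utils::write.table(hm, file.path(config$out_dir, "highly_mutated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sites <- .stage("hotspots", collapse_to_sites(hm, sirs))
  utils::write.table(sites, file.path(config$out_dir, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hot <- .stage("hotspots",
    hotspot_spacer_test(sirs, assigned, genome, config$n_samples,
                        spacer_seqs = unique(sites$spacer_seq),
                        q_threshold = config$q_threshold))
  utils::write.table(hot, file.path(config$out_dir, "hotspot_spacers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("hotspots: ", sum(hm$is_highly_mutated), " highly mutated SIRs, ",
       nrow(sites), " sites, ", sum(hot$is_hotspot), " hotspot spacers")

  calls <- .stage("classify",
    classify_samples(muts, sites, config$msi_threshold,
                     config$apobec_threshold))
  if (!is.null(config$exposures)) {
    exp <- read_exposures(config$exposures)
    cl <- cluster_signature_classes(exp, k = min(5L, nrow(exp)))
    calls <- merge(calls, cl[, c("sample", "cluster_class")],
                   by = "sample", all.x = TRUE)
  }
  utils::write.table(calls, file.path(config$out_dir, "sample_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    n_sirs = nrow(sirs),
    densities = densities,
    spacer_control_fold = fold_all,
    planted_sir_fold = fold_planted,
    n_highly_mutated = sum(hm$is_highly_mutated),
    n_sites = nrow(sites),
    n_hotspot_spacers = sum(hot$is_hotspot),
    n_msi_flagged = sum(calls$msi_flag),
    n_apobec_flagged = sum(calls$apobec_flag)
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(summary)
}
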