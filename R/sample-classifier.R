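# Signature numbers are parsed from exposure column names ("sig2", "s13",
# "Signature.20", "2" all work).
.sig_numbers <- function(cols) {
  as.integer(sub("^\\D*", "", cols))
}

#' Cluster samples into signature phenotype classes
#'
#' Agglomerative hierarchical clustering (Ward linkage on Euclidean distance
#' of exposure proportions) cut at `k` clusters. Clusters are named by their
#' dominant mean signature content: signatures 2/13 dominant -> APOBEC,
#' 6/20/26 -> MSI, both -> APOBEC+MSI, 3 -> BRCA, none above the proportion
#' floor -> Others.
#'
#' @param exposures Data frame with a `sample` column plus one nonnegative
#'   column per signature (named with the signature number, e.g. `sig2`).
#' @param k Number of clusters (default 5).
#' @param floor Minimum mean proportion for a signature group to name its
#'   cluster (default 0.2).
#' @return Data frame (`sample`, `cluster`, `cluster_class`).
#' @export
cluster_signature_classes <- function(exposures, k = 5L, floor = 0.2) {
  if (k < 1L) stop("k must be >= 1")
  if (nrow(exposures) < k) stop("fewer samples than clusters requested")
  mat <- as.matrix(exposures[, -1L, drop = FALSE])
  rs <- rowSums(mat)
  if (any(rs == 0)) stop("sample with all-zero exposures")
  prop <- mat / rs
  if (k == 1L) {
    cl <- rep(1L, nrow(prop))
  } else {
    hc <- stats::hclust(stats::dist(prop), method = "ward.D2")
    cl <- stats::cutree(hc, k = k)
  }
  sig <- .sig_numbers(colnames(prop))
  name_cluster <- function(rows) {
    m <- colMeans(prop[rows, , drop = FALSE])
    apobec <- sum(m[sig %in% c(2L, 13L)])
    msi <- sum(m[sig %in% c(6L, 20L, 26L)])
    brca <- sum(m[sig %in% 3L])
    if (apobec >= floor && msi >= floor) "APOBEC+MSI"
    else if (apobec >= floor) "APOBEC"
    else if (msi >= floor) "MSI"
    else if (brca >= floor) "BRCA"
    else "Others"
  }
  labels <- vapply(split(seq_len(nrow(prop)), cl), name_cluster, character(1L))
  data.frame(
    sample = exposures$sample,
    cluster = cl,
    cluster_class = unname(labels[as.character(cl)])
  )
}

#' Partition hotspot sites by spacer composition
#'
#' Sites whose representative spacer contains only A/T go to `at_only`
#' (informative for mismatch-repair deficiency); the rest (GC > 0) to
#' `gc_positive` (informative for APOBEC activity). Exhaustive and disjoint.
#'
#' @param sites Data frame from [collapse_to_sites()] (needs `spacer_seq`).
#' @return List with data frames `at_only` and `gc_positive`.
#' @export
hotspot_site_partition <- function(sites) {
  at <- !grepl("[CG]", sites$spacer_seq)
  list(at_only = sites[at, , drop = FALSE],
       gc_positive = sites[!at, , drop = FALSE])
}

# Distinct sites (rows of `sites`) with >= 1 of the sample's mutations in the
# site's spacer interval; returns a per-sample named count vector.
.count_mutated_sites <- function(muts, sites, samples) {
  cnt <- stats::setNames(integer(length(samples)), samples)
  if (nrow(sites) == 0L || nrow(muts) == 0L) return(cnt)
  pairs <- vector("list", 0L)
  for (ch in unique(sites$chrom)) {
    st <- sites[sites$chrom == ch, , drop = FALSE]
    m <- muts[muts$chrom == ch, , drop = FALSE]
    if (nrow(m) == 0L) next
    h <- IRanges::findOverlaps(
      IRanges::IRanges(mutation_point(m), width = 1L),
      IRanges::IRanges(st$spacer_start + 1L, st$spacer_end)
    )
    if (length(h) == 0L) next
    pairs[[length(pairs) + 1L]] <- unique(data.frame(
      sample = m$sample[S4Vectors::queryHits(h)],
      site = paste0(ch, ":", st$spacer_start[S4Vectors::subjectHits(h)])
    ))
  }
  if (length(pairs) == 0L) return(cnt)
  tab <- table(do.call(rbind, pairs)$sample)
  cnt[names(tab)] <- as.integer(tab)
  cnt
}

#' Classify samples by hotspot mutation counts
#'
#' Per sample, counts the distinct A/T-only and GC-containing hotspot sites
#' carrying at least one of the sample's mutations within the site's spacer
#' interval (multiple mutations in one site count the site once). Samples
#' mutated at `msi_threshold` or more A/T-only sites are flagged MSI; samples
#' mutated at `apobec_threshold` or more GC-containing sites are flagged
#' APOBEC.
#'
#' @param muts Mutation data frame.
#' @param sites Data frame from [collapse_to_sites()].
#' @param msi_threshold Minimum A/T-only site count for the MSI flag
#'   (default 16).
#' @param apobec_threshold Minimum GC-containing site count for the APOBEC
#'   flag (default 7).
#' @return Data frame (`sample`, `n_at_only_sites_mutated`,
#'   `n_gc_sites_mutated`, `msi_flag`, `apobec_flag`).
#' @export
classify_samples <- function(muts, sites, msi_threshold = 16L,
                             apobec_threshold = 7L) {
  samples <- sort(unique(muts$sample))
  part <- hotspot_site_partition(sites)
  at_cnt <- .count_mutated_sites(muts, part$at_only, samples)
  gc_cnt <- .count_mutated_sites(muts, part$gc_positive, samples)
  data.frame(
    sample = samples,
    n_at_only_sites_mutated = unname(at_cnt),
    n_gc_sites_mutated = unname(gc_cnt),
    msi_flag = unname(at_cnt >= msi_threshold),
    apobec_flag = unname(gc_cnt >= apobec_threshold)
  )
}
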