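#!/usr/bin/env Rscript
# Genomic context of the detected SIRs: binned density with the quadratic
# density-GC fit, GC content by domain, and 32-trinucleotide spectra of
# spacer, arm and control sequence with cosine similarities. The spectra
# quantify how closely the flanking control windows resemble the spacers
# they stand in for.

suppressMessages(library(sirmut))

genome <- read_genome_fasta("results/sim/genome.fa")
sirs <- read_sir_table("results/sirs.tsv")

bins <- bin_sir_density(sirs, genome, bin_width = 10000L)
write.table(bins, "results/bins.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
fit <- try(fit_density_gc_quadratic(bins), silent = TRUE)
if (!inherits(fit, "try-error")) {
  # the simulated genome has uniform GC, so the bins span a narrow GC range
  # and the fit is illustrative of the interface, not of a GC effect
  cat(sprintf("density ~ GC quadratic fit over %d bins (GC range %.3f-%.3f)\n",
              nrow(bins), min(bins$gc_fraction), max(bins$gc_fraction)))
}

cat(sprintf("GC content: spacer %.3f, arm %.3f\n",
            mean(gc_content(sirs$spacer)), mean(gc_content(sirs$left_arm))))

ivs <- list(
  spacer = data.frame(chrom = sirs$chrom,
                      start = sirs$start + sirs$arm_len,
                      end = sirs$start + sirs$arm_len + sirs$spacer_len),
  arm = data.frame(chrom = rep(sirs$chrom, 2),
                   start = c(sirs$start, sirs$end - sirs$arm_len),
                   end = c(sirs$start + sirs$arm_len, sirs$end)),
  control = do.call(rbind, lapply(seq_len(nrow(sirs)), function(i)
    cbind(chrom = sirs$chrom[i],
          domain_intervals(sirs[i, ], 100L, nchar(genome[[1]]))[
            c(1, 5), c("start", "end")])))
)
spectra <- lapply(ivs, trinucleotide_spectrum, genome = genome)
spec_tab <- data.frame(context = names(spectra$spacer),
                       spacer = spectra$spacer, arm = spectra$arm,
                       control = spectra$control)
write.table(spec_tab, "results/trinucleotide_spectra.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("cosine similarity spacer vs control: %.3f; arm vs control: %.3f\n",
            cosine_similarity(spectra$spacer, spectra$control),
            cosine_similarity(spectra$arm, spectra$control)))
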