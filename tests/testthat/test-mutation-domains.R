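test_that("substitution classification follows the pyrimidine-strand convention", {
  # G>A with 5'=T, 3'=C complements to C>T with flanks swapped: G _ A
  r <- classify_substitution("G", "A", "T", "C")
  expect_equal(r$class6, "C>T")
  expect_equal(r$context, "GCA")
  expect_equal(r$class96, "G[C>T]A")

  r2 <- classify_substitution("C", "T", "T", "A")
  expect_equal(r2$class6, "C>T")
  expect_equal(r2$context, "TCA")

  # all 12 ordered ref/alt pairs land on 6 classes, two pairs each
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cl <- classify_substitution(pairs$ref, pairs$alt, "A", "A")$class6
  expect_equal(sort(unique(cl)),
               c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  expect_true(all(table(cl) == 2))

  # N in a flank drops to 6-class only; N in ref is rejected
  rn <- classify_substitution("C", "T", "N", "A")
  expect_equal(rn$class6, "C>T")
  expect_true(is.na(rn$class96))
  expect_error(classify_substitution("N", "T", "A", "A"), "ref")
})

test_that("domain assignment places points in spacer, arm, control and outside", {
  sirs <- data.frame(
    chrom = "chr1", start = c(1000L, 3000L), end = c(1018L, 3020L),
    arm_len = c(7L, 8L), spacer_len = c(4L, 4L), left_arm = "X",
    spacer = "GAAC", is_pure_at_spacer = FALSE
  )
  muts <- data.frame(
    sample = "S1", chrom = "chr1",
    pos = c(1009L, 1003L, 958L, 1500L, 3010L, 2950L),
    ref = "C", alt = "T", class = "substitution"
  )
  a <- assign_to_domains(muts, sirs)
  # spacer of SIR1 is [1007,1011) 0-based = 1008..1011 1-based
  expect_equal(a$domain,
               c("spacer", "arm", "control", "outside", "spacer", "control"))
  expect_equal(a$sir_index, c(1L, 1L, 1L, NA, 2L, 2L))
})

test_that("indels anchor at the first affected base and breakpoints use wide controls", {
  sirs <- data.frame(
    chrom = "chr1", start = 2000L, end = 2018L, arm_len = 7L,
    spacer_len = 4L, left_arm = "X", spacer = "GAAC",
    is_pure_at_spacer = FALSE
  )
  muts <- data.frame(
    sample = "S1", chrom = "chr1",
    pos = c(2007L, 2518L, 2518L),
    ref = c("AG", "C", "C"), alt = c("A", ".", "T"),
    class = c("indel", "rearrangement_breakpoint", "substitution")
  )
  a <- assign_to_domains(muts, sirs)
  # indel anchored at pos+1 = 2008, the first spacer base
  expect_equal(a$domain[1], "spacer")
  # 500 bp from the SIR: control for rearrangements, outside for substitutions
  expect_equal(a$domain[2], "control")
  expect_equal(a$domain[3], "outside")
})

test_that("domain assignment agrees with a brute-force membership oracle and conserves counts", {
  sim <- make_sim(seed = 71, chrom_length = 60000L, n_planted_sirs = 50L,
                  n_samples = 10L, background_density = 5e-4)
  sirs <- detect_sirs(sim$genome)
  set.seed(72)
  muts <- data.frame(
    sample = "S1", chrom = "chr1", pos = sample(60000L, 1000L),
    ref = "C", alt = "T", class = "substitution"
  )
  a <- assign_to_domains(muts, sirs)
  expect_equal(sum(table(a$domain)), nrow(muts))
  cw <- 100L
  for (i in seq_len(nrow(muts))) {
    p0 <- muts$pos[i] - 1L                      # 0-based
    want <- "outside"
    inside <- which(sirs$start <= p0 & p0 < sirs$end)
    if (length(inside) == 1L) {
      s <- sirs[inside, ]
      sp <- s$start + s$arm_len
      want <- if (p0 >= sp && p0 < sp + s$spacer_len) "spacer" else "arm"
    } else {
      near <- which(p0 >= sirs$start - cw & p0 < sirs$end + cw)
      if (length(near) > 0L) want <- "control"
    }
    expect_equal(a$domain[i], want)
  }
})

test_that("domain density arithmetic and null indistinguishability hold", {
  # 7 mutations over 1000 bp of spacer across 10 samples = 700 per Mb per
  # sample-genome
  assigned <- data.frame(
    sample = "S1", chrom = "chr1", pos = 1:7, ref = "C", alt = "T",
    class = "substitution", domain = "spacer", sir_index = 1L
  )
  dens <- 7 / (1000 * 10) * 1e6
  expect_equal(dens, 700)

  sim <- make_sim(seed = 81, chrom_length = 80000L, n_planted_sirs = 60L,
                  n_samples = 60L, background_density = 1e-3,
                  spacer_fold = 1)
  sirs <- detect_sirs(sim$genome)
  planted <- planted_subset(sirs, sim$truth)
  a <- assign_to_domains(sim$muts, planted)
  d <- domain_density(a[a$class == "substitution", ], planted, sim$genome, 60)
  # uniform generator: spacer count consistent with the control rate
  ctrl_rate <- d$n_mutations[d$domain == "control"] /
    (d$effective_length[d$domain == "control"] * 60)
  p <- stats::binom.test(
    d$n_mutations[d$domain == "spacer"],
    round(d$effective_length[d$domain == "spacer"] * 60),
    ctrl_rate
  )$p.value
  expect_gt(p, 0.01)

  none <- domain_density(a[0, ], planted, sim$genome, 60)
  expect_equal(none$n_mutations, c(0, 0, 0))
})

test_that("spacer fold of 2 is recovered from the planted SIR densities", {
  folds <- vapply(1:6, function(s) {
    sim <- make_sim(seed = 90 + s, chrom_length = 60000L,
                    n_planted_sirs = 60L, n_samples = 60L,
                    background_density = 1.5e-3, spacer_fold = 2)
    sirs <- detect_sirs(sim$genome)
    planted <- planted_subset(sirs, sim$truth)
    a <- assign_to_domains(sim$muts, planted)
    d <- domain_density(a[a$class == "substitution", ], planted, sim$genome, 60)
    c(d$n_mutations[d$domain == "spacer"],
      d$effective_length[d$domain == "spacer"],
      d$n_mutations[d$domain == "control"],
      d$effective_length[d$domain == "control"])
  }, numeric(4))
  pooled <- rowSums(folds)
  fold <- (pooled[1] / pooled[2]) / (pooled[3] / pooled[4])
  expect_gt(fold, 1.75)
  expect_lt(fold, 2.25)
})

test_that("distance profiles spike at planted centers and are flat under uniformity", {
  sirs <- data.frame(
    chrom = "chr1", start = as.integer(seq(500, 9500, 500)),
    end = as.integer(seq(500, 9500, 500)) + 18L, arm_len = 7L,
    spacer_len = 4L, left_arm = "X", spacer = "GAAC",
    is_pure_at_spacer = FALSE
  )
  genome <- c(chr1 = strrep("A", 10000))
  centers0 <- sirs$start + sirs$arm_len + (sirs$spacer_len - 1) %/% 2
  muts <- data.frame(sample = "S1", chrom = "chr1", pos = centers0 + 1L,
                     ref = "C", alt = "T", class = "substitution")
  prof <- distance_profile(muts, sirs, genome, half_window = 50L)
  expect_equal(prof$likelihood[prof$offset == 0], 1)
  expect_equal(sum(prof$n_mutations), nrow(muts))
  expect_true(all(prof$n_mutations[prof$offset != 0] == 0))

  set.seed(101)
  unif <- data.frame(sample = "S1", chrom = "chr1",
                     pos = sample(10000L, 3000L, replace = TRUE),
                     ref = "C", alt = "T", class = "substitution")
  prof2 <- distance_profile(unif, sirs, genome, half_window = 50L)
  expect_true(all(prof2$n_sirs == nrow(sirs)))
  expect_lt(max(prof2$likelihood), 10 * mean(prof2$likelihood))
})

test_that("per-group densities cover the planted categories with sane means", {
  sim <- make_sim(seed = 111, chrom_length = 60000L, n_planted_sirs = 50L,
                  n_samples = 20L, background_density = 1e-3)
  sirs <- detect_sirs(sim$genome)
  a <- assign_to_domains(sim$muts, sirs)
  g <- domain_density_by_group(a[a$class == "substitution", ], sirs, 20)
  expect_true(all(g$domain %in% c("spacer", "arm")))
  expect_equal(sum(g$n_sirs), 2L * nrow(sirs))
  expect_true(all(g$mean_density >= 0))
})
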