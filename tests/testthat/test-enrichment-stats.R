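test_that("binomial spacer test equals direct summation and stats::binom.test", {
  expect_equal(binomial_spacer_test(0, 4, 10, 0.01), 1)
  expect_equal(binomial_spacer_test(2, 4, 10, 0.01),
               binom_upper_tail_sum(2, 40, 0.01), tolerance = 1e-12)

  set.seed(121)
  for (i in 1:50) {
    n_trials <- sample(10:2000, 1)
    p <- runif(1, 0, 0.2)
    k <- sample(0:min(n_trials, 30), 1)
    got <- binomial_spacer_test(k, n_trials, 1, p)
    want <- binom_upper_tail_sum(k, n_trials, p)
    expect_equal(got, want, tolerance = 1e-10)
    bt <- stats::binom.test(k, n_trials, p, alternative = "greater")$p.value
    expect_equal(got, bt, tolerance = 1e-12)
  }

  # monotone non-increasing in the observed count
  p_seq <- binomial_spacer_test(0:20, 4, 10, 0.05)
  expect_true(all(diff(p_seq) <= 0))

  # conventions at the boundary of the background rate
  expect_equal(binomial_spacer_test(3, 4, 10, 0), 0)
  expect_equal(binomial_spacer_test(0, 4, 10, 0), 1)
  expect_error(binomial_spacer_test(50, 4, 10, 0.1), "between")
  expect_error(binomial_spacer_test(1, 4, 10, 1.5), "0, 1")
})

test_that("BH adjustment equals the literal step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))

  set.seed(131)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_stepup_literal(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("a planted high-fold SIR is flagged and the uniform null is controlled", {
  hs <- data.frame(spacer_seq = "CAAG", fold = 30, n_locations = 2)
  sim <- make_sim(seed = 141, chrom_length = 80000L, n_planted_sirs = 60L,
                  n_samples = 60L, background_density = 1.5e-3,
                  spacer_fold = 1, hotspot_spec = hs)
  sirs <- detect_sirs(sim$genome)
  a <- assign_to_domains(sim$muts, sirs)
  res <- call_highly_mutated(sirs, a, sim$genome, 60)
  hot_truth <- sim$truth[sim$truth$kind == "hotspot", ]
  flagged <- res[res$is_highly_mutated, ]
  planted_hot <- paste0(hot_truth$chrom, ":", hot_truth$start)
  expect_true(any(paste0(flagged$chrom, ":", flagged$start) %in% planted_hot))

  # null: nothing planted above background, flagged fraction near zero
  simnull <- make_sim(seed = 142, chrom_length = 80000L, n_planted_sirs = 60L,
                      n_samples = 60L, background_density = 1e-3,
                      spacer_fold = 1)
  sirs0 <- detect_sirs(simnull$genome)
  a0 <- assign_to_domains(simnull$muts, sirs0)
  res0 <- call_highly_mutated(sirs0, a0, simnull$genome, 60)
  expect_lte(mean(res0$is_highly_mutated), 0.02)

  empty <- call_highly_mutated(sirs[0, ], a, sim$genome, 60)
  expect_equal(nrow(empty), 0L)
})

test_that("overlapping flagged SIRs collapse to sites with the longest representative", {
  sirs <- data.frame(
    chrom = "chr1",
    start = c(100L, 105L, 110L, 500L, 1000L),
    end = c(126L, 123L, 128L, 520L, 1018L),
    arm_len = c(10L, 7L, 7L, 8L, 7L),
    spacer_len = c(6L, 4L, 4L, 4L, 4L),
    left_arm = "X",
    spacer = c("GAACAA", "GTTC", "CAAG", "TGCA", "GAAC"),
    is_pure_at_spacer = FALSE
  )
  res <- data.frame(
    sir_index = 1:5, chrom = "chr1", start = sirs$start, end = sirs$end,
    spacer = sirs$spacer, n_muts_spacer = 5L, trials = 100,
    background_density = 0.01, p_value = 0.001, q_value = 0.005,
    fold = 5, is_highly_mutated = c(TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  sites <- collapse_to_sites(res, sirs)
  expect_equal(nrow(sites), 2L)
  # the chained cluster 1-2-3 is represented by SIR 1 (longest, 26 bp)
  expect_equal(sites$rep_sir_index, c(1L, 5L))
  expect_equal(sites$spacer_seq, c("GAACAA", "GAAC"))
  expect_equal(sites$n_sirs, c(3L, 1L))

  # randomized overlap structure: site count equals connected components
  set.seed(151)
  for (rep in 1:10) {
    n <- 30
    st <- sample(0:2000, n)
    df <- data.frame(
      chrom = "chr1", start = st, end = st + sample(14:60, n, replace = TRUE),
      arm_len = 6L, spacer_len = 4L, left_arm = "X", spacer = "GAAC",
      is_pure_at_spacer = FALSE
    )
    r2 <- data.frame(
      sir_index = 1:n, chrom = "chr1", start = df$start, end = df$end,
      spacer = df$spacer, n_muts_spacer = 1L, trials = 10,
      background_density = 0.01, p_value = 0.001, q_value = 0.005,
      fold = 2, is_highly_mutated = TRUE
    )
    sites2 <- collapse_to_sites(r2, df)
    # union-find over pairwise overlaps
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (df$start[i] < df$end[j] && df$end[i] > df$start[j]) {
        parent[find(i)] <- find(j)
      }
    }
    comps <- length(unique(vapply(seq_len(n), find, integer(1))))
    expect_equal(nrow(sites2), comps)
  }
})

test_that("hotspot spacer sequences planted at fold 10 are detected with their fold", {
  hs <- data.frame(spacer_seq = "GAAC", fold = 10, n_locations = 12)
  sim <- make_sim(seed = 161, chrom_length = 100000L, n_planted_sirs = 30L,
                  n_samples = 60L, background_density = 1.5e-3,
                  spacer_fold = 1, hotspot_spec = hs)
  sirs <- detect_sirs(sim$genome)
  a <- assign_to_domains(sim$muts, sirs)
  res <- hotspot_spacer_test(sirs, a, sim$genome, 60,
                             spacer_seqs = "GAAC")
  expect_equal(nrow(res), 1L)
  expect_true(res$testable)
  expect_true(res$is_hotspot)
  expect_gt(res$fold, 5)
  expect_lt(res$fold, 20)
})

test_that("hotspot test is null-behaved for unplanted spacers", {
  sim <- make_sim(seed = 171, chrom_length = 80000L, n_planted_sirs = 40L,
                  n_samples = 60L, background_density = 1.5e-3,
                  spacer_fold = 1)
  sirs <- detect_sirs(sim$genome)
  a <- assign_to_domains(sim$muts, sirs)
  res <- hotspot_spacer_test(sirs, a, sim$genome, 60)
  expect_true(all(res$p_value[res$testable] >= 0))
  expect_lte(mean(res$is_hotspot, na.rm = TRUE), 0.05)
  # spacers with zero spacer mutations are not in the default family
  canon <- pmin(sirs$spacer, revcomp(sirs$spacer))
  expect_true(all(res$spacer_seq %in% canon))
})

test_that("odds ratios match the hand-computed 2x2 table", {
  eq <- odds_ratio_spacer_control(10, 10, 1000, 1000)
  expect_equal(eq$or, 1)
  h <- odds_ratio_spacer_control(10, 5, 1000, 1000)
  expect_equal(h$or, (10 / 990) / (5 / 995), tolerance = 1e-12)
  expect_true(h$ci_lower < h$or && h$or < h$ci_upper)
  z <- odds_ratio_spacer_control(0, 5, 1000, 1000)
  expect_true(is.finite(z$or) && z$or > 0)
  expect_error(odds_ratio_spacer_control(1, 1, 0, 10), "positive")
})
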