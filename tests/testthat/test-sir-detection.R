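test_that("the 18-bp worked example decomposes into three hairpin categories", {
  d <- enumerate_ir_decompositions("AGGCTAGCTGGCTAGCCT", arm_floor = 1L)
  expect_equal(d$arm_len, c(7L, 6L, 5L))
  expect_equal(d$spacer_len, c(4L, 6L, 8L))
  canon <- canonical_decomposition(d)
  expect_equal(canon$arm_len, 7L)
  expect_equal(canon$spacer_len, 4L)
})

test_that("decomposition enumeration matches a brute-force split check", {
  expect_equal(nrow(enumerate_ir_decompositions("ACGTACGT")), 0L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(7)
  for (i in 1:50) {
    s <- random_dna(30)
    d <- enumerate_ir_decompositions(s, arm_floor = 1L)
    expect_true(all(d$spacer_len >= 4 & d$spacer_len <= 8))
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    exp_rows <- list()
    for (sp in 4:8) {
      if ((30 - sp) %% 2 != 0) next
      a <- (30 - sp) / 2
      ok <- all(vapply(seq_len(a), function(j)
        comp[[chars[j]]] == chars[30 + 1 - j], logical(1)))
      if (ok) exp_rows[[length(exp_rows) + 1L]] <- c(a, sp)
    }
    expect_equal(nrow(d), length(exp_rows))
    if (length(exp_rows) > 0) {
      em <- do.call(rbind, exp_rows)
      em <- em[order(em[, 2]), , drop = FALSE]
      expect_equal(d$arm_len, em[, 1])
      expect_equal(d$spacer_len, em[, 2])
    }
  }
})

test_that("scanning plus overlap resolution confines the worked example to one category", {
  s <- paste0("GG", "AGGCTAGCTGGCTAGCCT", "GG")
  sirs <- resolve_overlaps(scan_inverted_repeats(s))
  expect_equal(nrow(sirs), 1L)
  expect_equal(sirs$start, 2L)
  expect_equal(sirs$end, 20L)
  expect_equal(sirs$arm_len, 7L)
  expect_equal(sirs$spacer_len, 4L)
})

test_that("scanner equals the cubic-time brute force on random sequences", {
  set.seed(11)
  for (i in 1:25) {
    s <- random_dna(300, gc = 0.4, n_rate = if (i %% 5 == 0) 0.02 else 0)
    got <- scan_inverted_repeats(s)
    want <- brute_force_scan(s)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$arm_len, want$arm_len)
    expect_equal(got$spacer_len, want$spacer_len)
  }
})

test_that("windows containing N are never emitted", {
  s <- paste0("GG", "AGGCTAGCTNGCTAGCCT", "GG")
  expect_equal(nrow(scan_inverted_repeats(s)), 0L)
  expect_equal(nrow(scan_inverted_repeats("ACG")), 0L)
})

test_that("scanning the reverse complement mirrors SIR coordinates", {
  set.seed(13)
  s <- random_dna(2000, gc = 0.4)
  fwd <- scan_inverted_repeats(s)
  rev <- scan_inverted_repeats(revcomp(s))
  L <- nchar(s)
  mirrored <- data.frame(start = L - rev$end, end = L - rev$start,
                         arm_len = rev$arm_len, spacer_len = rev$spacer_len)
  mirrored <- mirrored[order(mirrored$start, mirrored$end), ]
  expect_equal(fwd$start, mirrored$start)
  expect_equal(fwd$end, mirrored$end)
  expect_equal(fwd$arm_len, mirrored$arm_len)
  expect_equal(fwd$spacer_len, mirrored$spacer_len)
})

test_that("pure-AT spacer filter keeps exactly the spacers with a C or G", {
  sirs <- data.frame(
    chrom = "chr1", start = seq(0, 90, 10), end = seq(0, 90, 10) + 16,
    arm_len = 6L, spacer_len = 4L, left_arm = "ACGTAC",
    spacer = c("GAAC", "TTTT", "ATAT", "CGCG", "AATA", "TGCA",
               "TTAA", "GGGG", "ACCA", "GATA"),
    is_pure_at_spacer = NA
  )
  kept <- filter_pure_at(sirs)
  expect_equal(nrow(kept), 6L)
  expect_true(all(grepl("[CG]", kept$spacer)))
  expect_equal(kept$start, sirs$start[grepl("[CG]", sirs$spacer)])
})

test_that("overlap resolution keeps the longest SIR and matches the greedy oracle", {
  two <- data.frame(
    chrom = "chr1", start = c(0L, 5L), end = c(18L, 31L),
    arm_len = c(7L, 10L), spacer_len = c(4L, 6L),
    left_arm = "X", spacer = "GAAC", is_pure_at_spacer = FALSE
  )
  r <- resolve_overlaps(two)
  expect_equal(nrow(r), 1L)
  expect_equal(r$end - r$start, 26L)

  disjoint <- data.frame(
    chrom = "chr1", start = c(0L, 100L), end = c(18L, 120L),
    arm_len = 7L, spacer_len = 4L, left_arm = "X", spacer = "GAAC",
    is_pure_at_spacer = FALSE
  )
  expect_equal(resolve_overlaps(disjoint), disjoint)

  set.seed(17)
  for (rep in 1:20) {
    n <- 40
    st <- sort(sample(0:500, n, replace = TRUE))
    len <- sample(14:60, n, replace = TRUE)
    df <- data.frame(
      chrom = "chr1", start = st, end = st + len,
      arm_len = 6L, spacer_len = sample(4:8, n, replace = TRUE),
      left_arm = "X", spacer = "GAAC", is_pure_at_spacer = FALSE
    )
    df <- df[order(df$start, df$end), ]
    rownames(df) <- NULL
    got <- resolve_overlaps(df)
    want <- brute_force_resolve(df)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$spacer_len, want$spacer_len)
    # pairwise non-overlapping
    if (nrow(got) > 1) {
      expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
    }
  }
})

test_that("domain intervals follow the coordinate arithmetic and truncate at bounds", {
  sir <- data.frame(chrom = "chr1", start = 100L, end = 118L, arm_len = 7L,
                    spacer_len = 4L, left_arm = "X", spacer = "GAAC",
                    is_pure_at_spacer = FALSE)
  iv <- domain_intervals(sir, 100L, 10000L)
  expect_equal(iv$domain, c("control", "arm", "spacer", "arm", "control"))
  expect_equal(iv$start, c(0L, 100L, 107L, 111L, 118L))
  expect_equal(iv$end, c(100L, 107L, 111L, 118L, 218L))
  # conservation of total length
  expect_equal(sum(iv$end - iv$start), 2L * 7L + 4L + 2L * 100L)
  # pairwise disjoint
  expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))

  sir$start <- 30L; sir$end <- 48L
  iv2 <- domain_intervals(sir, 100L, 10000L)
  expect_equal(iv2$start[1], 0L)
  expect_equal(iv2$end[1], 30L)
})

test_that("the default configuration spans 100 hairpin categories", {
  expect_equal(nrow(sir_categories(search_config())), 100L)
})

test_that("configuration guards reject unphysical settings", {
  expect_error(search_config(spacer_min = 3), "steric")
  expect_error(search_config(control_width_sub_indel = 0), "positive")
})
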