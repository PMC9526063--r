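test_that("period representation rule applies both thresholds", {
  cen <- data.frame(period = c(7L, 29L, 31L, 151L),
                    total_copy_number = c(50000, 9000, 10000, 40),
                    n_hits = c(100L, 10L, 10L, 2L))
  p <- cluster_params(min_period = 10L, min_total_copies = 100,
                      copy_fraction = 0)
  expect_identical(select_represented_periods(cen, p), c(29L, 31L))

  cen2 <- data.frame(period = 31L, total_copy_number = 99, n_hits = 1L)
  expect_identical(length(select_represented_periods(cen2, p)), 0L)
  expect_identical(select_represented_periods(cen[0, ], p), integer(0))
})

test_that("triple concatenation contains every rotation full-length", {
  expect_identical(triple_concatenate("ACGT"), "ACGTACGTACGT")
  set.seed(40)
  m31 <- rand_seq(31)
  expect_identical(nchar(triple_concatenate(m31)), 93L)
  expect_error(triple_concatenate(""), "non-empty")

  for (i in 1:5) {
    m <- rand_seq(sample(10:50, 1))
    trip <- triple_concatenate(m)
    for (k in seq_len(nchar(m)))
      expect_true(grepl(rotate_str(m, k), trip, fixed = TRUE))
  }
})

test_that("Karlin-Altschul statistics behave as the theory requires", {
  ka <- karlin_altschul(2, 3)
  # lambda satisfies the defining equation directly
  expect_equal(0.25 * exp(2 * ka$lambda) + 0.75 * exp(-3 * ka$lambda), 1,
               tolerance = 1e-9)
  expect_gt(ka$K, 0); expect_lt(ka$K, 1)
  # closed-form anchor: +1/-1 at uniform base frequencies gives lambda ln 3
  expect_equal(karlin_altschul(1, 1)$lambda, log(3), tolerance = 1e-9)
  # degenerate scoring has no positive root
  expect_error(karlin_altschul(3, 1), "degenerate")

  # E strictly decreasing in score, exactly linear in search space
  e <- alignment_evalue(c(50, 60, 70), 1e3, 1e6)
  expect_true(all(diff(e) < 0))
  expect_equal(alignment_evalue(50, 1e3, 2e6),
               2 * alignment_evalue(50, 1e3, 1e6))
  expect_equal(alignment_evalue(60, 1e3, 1e6) /
                 alignment_evalue(50, 1e3, 1e6),
               exp(-10 * karlin_altschul(2, 3)$lambda))
})

test_that("self-match and rotations pass the E-value cutoff; noise fails", {
  set.seed(41)
  m <- rand_seq(100)
  edge <- local_align_evalue(m, triple_concatenate(m),
                             search_space = c(1e6, 1e6))
  expect_false(is.null(edge))
  expect_lte(edge$evalue, 1e-20)
  # matches the direct Karlin-Altschul evaluation for a perfect score
  ka <- karlin_altschul(2, 3)
  expect_equal(edge$evalue, ka$K * 1e12 * exp(-ka$lambda * 200),
               tolerance = 1e-9)

  # every rotation aligns full-length within the triple
  for (k in c(1, 25, 50, 99)) {
    e <- local_align_evalue(rotate_str(m, k), triple_concatenate(m))
    expect_false(is.null(e))
    expect_gte(e$length, 100)
  }

  # independent random 40-mers never link at 1e-20
  for (i in 1:10)
    expect_null(local_align_evalue(rand_seq(40), rand_seq(40)))
})

test_that("rotated diverged monomers form one family, unrelated two", {
  set.seed(42)
  m <- rand_seq(120)
  members <- vapply(1:10, function(i) {
    x <- mutate_sequence(m, 0.04, 0, seed = i)
    rotate_str(x, sample(120, 1))
  }, character(1))
  h <- hits_from_monomers(members)
  cl <- cluster_families(h, select_periods = FALSE)
  expect_identical(nrow(cl$groups), 1L)
  expect_identical(cl$groups$n_instances, 10L)

  m2 <- rand_seq(120)
  h2 <- hits_from_monomers(c(members[1:5],
                             vapply(1:5, function(i)
                               mutate_sequence(m2, 0.04, 0, seed = 100 + i),
                               character(1))))
  cl2 <- cluster_families(h2, select_periods = FALSE)
  expect_identical(nrow(cl2$groups), 2L)
  expect_setequal(
    vapply(partition_sets(h2$hit_id, cl2$families$family_id), paste,
           character(1), collapse = ","),
    c("1,2,3,4,5", "6,7,8,9,10"))

  expect_identical(nrow(cluster_families(h[0, ])$groups), 0L)
})

test_that("clustering components match exhaustive alignment components", {
  set.seed(43)
  for (trial in 1:3) {
    masters <- replicate(3, rand_seq(sample(80:150, 1)))
    seqs <- unlist(lapply(masters, function(m)
      vapply(1:4, function(i)
        rotate_str(mutate_sequence(m, 0.03, 0, seed = trial * 100 + i),
                   sample(nchar(m), 1)), character(1))))
    h <- hits_from_monomers(seqs)
    cl <- cluster_families(h, select_periods = FALSE)

    # oracle: exhaustive Smith-Waterman (Biostrings) against triples,
    # both orientations, same E-value conversion
    ka <- karlin_altschul(2, 3)
    mat <- Biostrings::nucleotideSubstitutionMatrix(2, -3, baseOnly = TRUE)
    n <- length(seqs)
    n_total <- sum(3 * nchar(unique(vapply(seqs, canonical_rotation,
                                           character(1)))))
    ea <- integer(0); eb <- integer(0)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      sc <- 0
      for (q in c(seqs[i], revcomp_str(seqs[i])))
        sc <- max(sc, Biostrings::score(Biostrings::pairwiseAlignment(
          q, triple_concatenate(seqs[j]), type = "local",
          substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)))
      for (q in c(seqs[j], revcomp_str(seqs[j])))
        sc <- max(sc, Biostrings::score(Biostrings::pairwiseAlignment(
          q, triple_concatenate(seqs[i]), type = "local",
          substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)))
      ev <- ka$K * nchar(seqs[i]) * n_total * exp(-ka$lambda * sc)
      if (ev <= 1e-20) { ea <- c(ea, i); eb <- c(eb, j) }
    }
    comp <- oracle_components(data.frame(a = ea, b = eb), n)
    expect_identical(partition_sets(h$hit_id, cl$families$family_id),
                     partition_sets(h$hit_id, comp))
  }
})

test_that("partitions are invariant to rotation and strand flips", {
  set.seed(44)
  masters <- replicate(2, rand_seq(100))
  seqs <- unlist(lapply(masters, function(m)
    vapply(1:4, function(i) mutate_sequence(m, 0.03, 0, seed = i),
           character(1))))
  h <- hits_from_monomers(seqs)
  base <- partition_sets(h$hit_id,
                         cluster_families(h,
                                          select_periods = FALSE)$families$family_id)
  for (trial in 1:5) {
    h2 <- h
    h2$base_seq <- vapply(h$base_seq, function(s) {
      s <- rotate_str(s, sample(nchar(s), 1))
      if (runif(1) < 0.5) revcomp_str(s) else s
    }, character(1))
    got <- partition_sets(h2$hit_id,
                          cluster_families(h2,
                                           select_periods = FALSE)$families$family_id)
    expect_identical(got, base)
  }
})

test_that("clustering a single family alone reproduces it (idempotence)", {
  set.seed(45)
  m <- rand_seq(90)
  seqs <- vapply(1:6, function(i) mutate_sequence(m, 0.04, 0, seed = i),
                 character(1))
  h <- hits_from_monomers(seqs)
  cl <- cluster_families(h, select_periods = FALSE)
  expect_identical(nrow(cl$groups), 1L)
  sub <- h[cl$families$family_id == "F1", ]
  cl2 <- cluster_families(sub, select_periods = FALSE)
  expect_identical(nrow(cl2$groups), 1L)
  expect_identical(sort(cl2$families$hit_id), sort(sub$hit_id))
})
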