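test_that("background generation respects length and GC composition", {
  expect_identical(generate_background(0, 0.5, 1), "")
  gc1 <- generate_background(10000, 1.0, 2)
  expect_true(grepl("^[GC]+$", gc1))
  expect_identical(nchar(gc1), 10000L)

  s <- generate_background(100000, 0.35, 3)
  obs <- sum(strsplit(s, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  sd3 <- 3 * sqrt(100000 * 0.35 * 0.65)
  expect_lt(abs(obs - 35000), sd3)

  expect_error(generate_background(-1, 0.5, 1), "non-negative")
})

test_that("mutation is rate-faithful and seed-deterministic", {
  expect_identical(mutate_sequence("ACGT", 0, 0, 1), "ACGT")
  expect_identical(mutate_sequence("", 0.1, 0.1, 1), "")

  set.seed(4)
  s <- rand_seq(10000)
  m <- mutate_sequence(s, 0.02, 0, 5)
  expect_identical(nchar(m), nchar(s))  # no indels
  hd <- sum(strsplit(s, "", fixed = TRUE)[[1]] !=
            strsplit(m, "", fixed = TRUE)[[1]])
  expect_lt(abs(hd - 200), 3 * sqrt(10000 * 0.02 * 0.98))

  expect_identical(mutate_sequence(s, 0.05, 0.05, 9),
                   mutate_sequence(s, 0.05, 0.05, 9))
  expect_error(mutate_sequence(s, 0.5, 0, 1), "rates")
})

test_that("planted arrays concatenate monomers with HOR structure", {
  fam0 <- family_spec("F", "ACG", substitution_rate = 0, indel_rate = 0)
  expect_identical(plant_array("ACG", 5, fam0, 1), strrep("ACG", 5))
  expect_error(plant_array("ACG", 1, fam0, 1), "2 copies")

  # two 3-bp variants differing at one site alternate: fundamental period 6
  fh <- family_spec("F", "ACG", substitution_rate = 0, indel_rate = 0,
                    hor_block = c("ACG", "ATG"))
  arr <- plant_array("ACG", 4, fh, 1)
  expect_identical(arr, "ACGATGACGATG")

  # divergence close to the substitution rate
  set.seed(10)
  mono <- rand_seq(31)
  fam <- family_spec("F", mono, substitution_rate = 0.02, indel_rate = 0)
  arr <- plant_array(mono, 100, fam, 7)
  expect_identical(nchar(arr), 3100L)
  mm <- sum(strsplit(arr, "", fixed = TRUE)[[1]] !=
            strsplit(strrep(mono, 100), "", fixed = TRUE)[[1]])
  expect_lt(abs(mm - 62), 3 * sqrt(3100 * 0.02 * 0.98) + 1)
})

test_that("genome building is deterministic with a faithful manifest", {
  g <- small_genome(seed = 11, periods = c(31, 55), n_arrays = 5)
  g2 <- small_genome(seed = 11, periods = c(31, 55), n_arrays = 5)
  expect_identical(as.character(g$assembly), as.character(g2$assembly))
  expect_identical(g$manifest, g2$manifest)

  m <- g$manifest
  expect_identical(nrow(m), 2L * 2L * 5L)  # families x chroms x arrays
  expect_true(all(m$start >= 0 & m$end <= 6e4))
  # no two planted intervals overlap
  for (ch in unique(m$chrom)) {
    iv <- m[m$chrom == ch, ]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1)
      expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
  }

  # zero-family spec gives pure background
  g0 <- build_genome(sim_spec(2, 1e4, 0.4, list(), seed = 3))
  expect_identical(nrow(g0$manifest), 0L)
  expect_identical(sum(Biostrings::width(g0$assembly)), 20000L)

  # localized mode plants exactly one dominant array per chromosome
  set.seed(30)
  fam <- family_spec("L", rand_seq(40), "localized",
                     n_arrays_per_chromosome = 0, dominant_copies = 50,
                     substitution_rate = 0)
  gl <- build_genome(sim_spec(3, 5e4, 0.4, list(fam), seed = 4))
  expect_identical(nrow(gl$manifest), 3L)
  expect_identical(sort(unique(gl$manifest$chrom)), paste0("chr", 1:3))
})

test_that("manifest intervals exactly delimit planted bases", {
  # zero rates: interval lengths are copies x period exactly
  set.seed(12)
  mono <- rand_seq(25)
  fam <- family_spec("Z", mono, "dispersed", 20, 5, 5,
                     substitution_rate = 0, indel_rate = 0,
                     revcomp_fraction = 0.5)
  g <- build_genome(sim_spec(2, 2e5, 0.37, list(fam), seed = 8))
  m <- g$manifest
  expect_identical(nrow(m), 40L)
  expect_true(all(m$end - m$start == 5 * 25))
  expect_equal(sum(m$end - m$start), 40 * 5 * 25)

  # the planted sequence is recoverable from the assembly at each interval
  seqs <- as.character(g$assembly)
  for (k in seq_len(nrow(m))) {
    s <- substr(seqs[[m$chrom[k]]], m$start[k] + 1, m$end[k])
    if (m$strand[k] == "-") s <- revcomp_str(s)
    expect_identical(s, strrep(mono, 5))
  }
})

test_that("mutated planted arrays keep near-rate identity to the monomer", {
  # composition invariant: re-aligning a planted interval to the monomer
  # recovers at least (1 - sub - indel) mean identity
  set.seed(13)
  mono <- rand_seq(31)
  fam <- family_spec("M", mono, "dispersed", 10, 10, 20,
                     substitution_rate = 0.03, indel_rate = 0.01)
  g <- build_genome(sim_spec(1, 1e5, 0.37, list(fam), seed = 21))
  seqs <- as.character(g$assembly)
  idents <- vapply(seq_len(nrow(g$manifest)), function(k) {
    m <- g$manifest[k, ]
    s <- substr(seqs[[m$chrom]], m$start + 1, m$end)
    if (m$strand == "-") s <- revcomp_str(s)
    wraparound_align(s, mono)$percent_identity
  }, numeric(1))
  expect_gte(mean(idents) / 100, 1 - 0.03 - 0.01)
})

test_that("sim specs validate their inputs", {
  expect_error(family_spec("F", "ACGX"), "A/C/G/T")
  expect_error(family_spec("F", ""), "non-empty")
  expect_error(family_spec("F", "ACGT", substitution_rate = 0.3), "rates")
  expect_error(family_spec("F", "ACGT", copies_min = 1), "copies_min")
  # planted bases must fit in the genome
  set.seed(14)
  big <- family_spec("B", rand_seq(100), "dispersed", 100, 50, 50)
  expect_error(sim_spec(1, 1e4, 0.4, list(big)), "planted bases")
})
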