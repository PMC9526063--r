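test_that("wraparound alignment reproduces hand-computed scores", {
  a <- wraparound_align("ACGACGACG", "ACG")
  expect_equal(a$score, 18)
  expect_equal(a$copy_number, 3.0)
  expect_equal(a$percent_identity, 100)

  b <- wraparound_align("ACG", "ACG")
  expect_equal(b$score, 6)
  expect_equal(b$copy_number, 1.0)

  c <- wraparound_align("ACGATGACG", "ACG")
  expect_equal(c$score, 18 - 2 - 7)
  expect_equal(c$percent_identity, 100 * 8 / 9)

  expect_error(wraparound_align("ACGT", ""), "non-empty")
})

test_that("wraparound alignment agrees with the full-matrix oracle", {
  set.seed(20)
  for (i in 1:15) {
    p <- sample(3:40, 1)
    mono <- rand_seq(p)
    seg <- mutate_sequence(strrep(mono, sample(3:8, 1)), 0.05, 0.02,
                           seed = i)
    mine <- wraparound_align(seg, mono)
    ref <- oracle_wrap(seg, mono)
    expect_equal(mine$score, ref$score)
    expect_equal(mine$percent_identity, ref$identity)
    expect_equal(mine$copy_number, ref$copies)
  }
})

test_that("appending an exact monomer copy adds match_score x period", {
  set.seed(21)
  for (p in c(7, 23, 50)) {
    mono <- rand_seq(p)
    s1 <- wraparound_align(strrep(mono, 4), mono)$score
    s2 <- wraparound_align(strrep(mono, 5), mono)$score
    expect_equal(s2 - s1, 2 * p)
  }
})

test_that("candidate periods are found for planted periodicities", {
  cand <- find_candidate_periods(strrep("ACG", 100),
                                 detector_params(k = 5))
  expect_true(any(cand$period %% 3 == 0))

  # homopolymer collapses to the smallest allowed period
  cand2 <- find_candidate_periods(strrep("A", 50), detector_params(k = 5))
  expect_true(nrow(cand2) >= 1)
  expect_equal(min(cand2$period), 1L)

  # short input yields nothing
  expect_identical(nrow(find_candidate_periods("ACGT")), 0L)
})

test_that("detector recovers an exact planted array almost fully", {
  set.seed(22)
  mono <- "ACGTTGCAAGGTCCAT"  # 16 bp
  bg <- rand_seq(1e5)
  arr_start <- 50000
  seq1 <- paste0(substr(bg, 1, arr_start), strrep(mono, 500),
                 substr(bg, arr_start + 1, 1e5))
  hits <- detect_tandem_repeats(c(chrA = seq1))
  expect_gte(nrow(hits), 1)
  tr_start <- arr_start; tr_end <- arr_start + 16 * 500
  ov <- pmin(hits$end, tr_end) - pmax(hits$start, tr_start)
  best <- which.max(ov)
  expect_gte(ov[best], 0.99 * (tr_end - tr_start))
  expect_true(hits$period[best] %% 16 == 0)
})

test_that("random sequence yields almost no hit bases", {
  set.seed(23)
  hits <- detect_tandem_repeats(c(null = rand_seq(2e5, gc = 0.37)))
  hit_bases <- if (nrow(hits)) sum(hits$end - hits$start) else 0
  expect_lt(hit_bases, 0.005 * 2e5)
})

test_that("diverged planted arrays are overlapped by hits", {
  g <- small_genome(seed = 31, periods = 31, n_arrays = 8, sub = 0.05,
                    copies = c(35, 60))
  hits <- detect_tandem_repeats(g$assembly)
  m <- g$manifest[g$manifest$end - g$manifest$start >= 1000, ]
  for (k in seq_len(nrow(m))) {
    h <- hits[hits$contig == m$chrom[k], ]
    ov <- pmax(0, pmin(h$end, m$end[k]) - pmax(h$start, m$start[k]))
    expect_gte(max(ov, 0), 0.8 * (m$end[k] - m$start[k]))
  }
})

test_that("planted periods dominate the census (parameter recovery)", {
  g <- small_genome(seed = 32, periods = c(31, 29), n_arrays = 8)
  hits <- detect_tandem_repeats(g$assembly)
  cen <- period_census(hits)
  top2 <- cen$period[order(-cen$total_copy_number)][1:2]
  expect_setequal(top2, c(31L, 29L))

  # modal period over hits overlapping truth equals the planted period
  for (fid in c("FAM31", "FAM29")) {
    m <- g$manifest[g$manifest$family_id == fid, ]
    per <- integer(0)
    for (k in seq_len(nrow(m))) {
      h <- hits[hits$contig == m$chrom[k] & hits$end > m$start[k] &
                hits$start < m$end[k], ]
      per <- c(per, h$period)
    }
    mode_p <- as.integer(names(sort(table(per), decreasing = TRUE))[1])
    fam <- Filter(function(f) f$family_id == fid, g$spec$families)[[1]]
    expect_identical(mode_p, nchar(fam$monomer))
  }
})

test_that("detection on the reverse complement mirrors coordinates", {
  set.seed(24)
  mono <- rand_seq(20)
  bg <- rand_seq(4e4)
  s <- paste0(substr(bg, 1, 10000), strrep(mono, 80),
              substr(bg, 10001, 25000), strrep(mono, 50),
              substr(bg, 25001, 4e4))
  L <- nchar(s)
  fwd <- detect_tandem_repeats(c(x = s))
  rev <- detect_tandem_repeats(c(x = revcomp_str(s)))
  expect_identical(sort(fwd$period), sort(rev$period))
  # coordinates mirror up to the greedy extension's edge slack
  expect_identical(nrow(fwd), nrow(rev))
  expect_lt(max(abs(sort(L - fwd$end) - sort(rev$start))), 15)
  expect_lt(max(abs(sort(L - fwd$start) - sort(rev$end))), 15)
})

test_that("period census aggregates copy numbers exactly", {
  h <- hits_from_monomers(c("A", "B", "C"), periods = c(31L, 31L, 29L))
  h$copy_number <- c(10, 5, 7)
  cen <- period_census(h)
  expect_equal(cen$period, c(29L, 31L))
  expect_equal(cen$total_copy_number, c(7, 15))
  expect_equal(cen$n_hits, c(1L, 2L))

  expect_identical(nrow(period_census(h[0, ])), 0L)

  # conservation over a large random hit set
  set.seed(25)
  hr <- hits_from_monomers(rep("A", 1000),
                           periods = sample(10:50, 1000, TRUE))
  hr$copy_number <- runif(1000, 2, 50)
  expect_equal(sum(period_census(hr)$total_copy_number),
               sum(hr$copy_number))
})

test_that("decoy dispersed identical repeats are not reported as tandem", {
  set.seed(26)
  g <- build_genome(sim_spec(2, 1e5, 0.37, list(),
                             decoy_count = 20, decoy_length = 600,
                             seed = 17))
  hits <- detect_tandem_repeats(g$assembly)
  # decoys are single-copy at any period: nothing with >= 2 copies survives
  if (nrow(hits) > 0) {
    for (k in seq_len(nrow(hits))) {
      ov <- sum(pmax(0, pmin(hits$end[k], g$decoys$end) -
                        pmax(hits$start[k], g$decoys$start)) *
                (hits$contig[k] == g$decoys$chrom))
      expect_lt(ov, 0.5 * (hits$end[k] - hits$start[k]))
    }
  } else succeed()
})
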