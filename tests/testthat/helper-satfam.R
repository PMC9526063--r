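# shared fixtures and independent oracles for the test suite

rand_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rotate_str <- function(s, k) {
  n <- nchar(s)
  k <- ((k - 1) %% n) + 1
  if (k == n) return(s)
  paste0(substr(s, k + 1, n), substr(s, 1, k))
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Independent wraparound-alignment oracle: full-matrix dynamic programming
# in R with explicit traceback (diag preferred over up over left, matching
# the stated tie convention), free start/end phase, linear gaps.
oracle_wrap <- function(segment, monomer, match = 2, mismatch = 7,
                        indel = 7) {
  s <- strsplit(segment, "", fixed = TRUE)[[1]]
  m <- strsplit(monomer, "", fixed = TRUE)[[1]]
  n <- length(s); p <- length(m)
  NEG <- -1e9
  prev <- rep(0L, p)
  tb <- matrix(0L, nrow = n, ncol = p)
  for (i in seq_len(n)) {
    cur <- rep(NEG, p)
    mv <- rep(1L, p)
    for (pass in 1:2) {
      for (j in seq_len(p)) {
        jm1 <- if (j == 1L) p else j - 1L
        sub <- if (s[i] == m[j]) match else -mismatch
        best <- prev[jm1] + sub; t <- 1L
        up <- prev[j] - indel
        if (up > best) { best <- up; t <- 2L }
        left <- cur[jm1] - indel
        if (left > best) { best <- left; t <- 3L }
        if (best > cur[j]) { cur[j] <- best; mv[j] <- t }
      }
    }
    tb[i, ] <- mv
    prev <- cur
  }
  jend <- which.max(prev)
  score <- prev[jend]
  i <- n; j <- jend; matches <- 0L; columns <- 0L; consumed <- 0L
  while (i > 0) {
    t <- tb[i, j]
    jm1 <- if (j == 1L) p else j - 1L
    if (t == 1L) {
      columns <- columns + 1L; consumed <- consumed + 1L
      if (s[i] == m[j]) matches <- matches + 1L
      i <- i - 1L; j <- jm1
    } else if (t == 2L) {
      columns <- columns + 1L; i <- i - 1L
    } else {
      columns <- columns + 1L; consumed <- consumed + 1L; j <- jm1
    }
  }
  list(score = score, matches = matches, columns = columns,
       identity = 100 * matches / columns, copies = consumed / p)
}

# union-find connected components over 1..n given an edge data.frame
oracle_components <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges[[1]][k]); rb <- find(edges[[2]][k])
    if (ra != rb) parent[rb] <- ra
  }
  vapply(seq_len(n), find, integer(1))
}

# canonical representation of a partition: sorted list of sorted member sets
partition_sets <- function(ids, groups) {
  sets <- lapply(split(ids, groups), function(x) sort(x))
  unname(sets[order(vapply(sets, `[`, ids[1] * 0L, 1))])
}

# small dispersed-genome builder used across module tests
small_genome <- function(seed = 1, periods = c(31), n_arrays = 6,
                         n_chrom = 2, chrom_len = 6e4, sub = 0.02,
                         copies = c(20, 40)) {
  set.seed(seed + 1000)
  fams <- lapply(seq_along(periods), function(i)
    family_spec(paste0("FAM", periods[i]), rand_seq(periods[i]),
                "dispersed", n_arrays, copies[1], copies[2], sub))
  build_genome(sim_spec(n_chrom, chrom_len, 0.37, fams, seed = seed))
}

# fake hit table straight from monomer sequences (bypasses detection)
hits_from_monomers <- function(base_seqs, periods = nchar(base_seqs)) {
  n <- length(base_seqs)
  data.frame(hit_id = seq_len(n), contig = "chr1",
             start = (seq_len(n) - 1) * 1000,
             end = (seq_len(n) - 1) * 1000 + periods * 3,
             period = periods, copy_number = 3,
             percent_identity = 100, score = 6 * periods,
             base_seq = base_seqs, stringsAsFactors = FALSE)
}
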