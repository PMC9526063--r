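.rotations <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  ss <- paste0(s, s)
  vapply(seq_len(n), function(i) substr(ss, i, i + n - 1L), character(1))
}

#' Canonical rotation of a monomer
#'
#' The lexicographically smallest string among all rotations of the monomer
#' and all rotations of its reverse complement, under the base order
#' A < C < G < T < N (non-ACGT characters are normalized to N).  Idempotent,
#' and identical for every rotation and for the reverse complement of a
#' monomer — the canonical form is a circular, strand-free family key.
#'
#' @param monomer Non-empty nucleotide string.
#' @return The canonical rotation.
#' @export
canonical_rotation <- function(monomer) {
  monomer <- toupper(as.character(monomer))
  if (nchar(monomer) == 0L) stop("monomer must be non-empty")
  monomer <- gsub("[^ACGT]", "N", monomer)
  cands <- c(.rotations(monomer), .rotations(revcomp(monomer)))
  # map to an alphabet where N sorts after T, compare bytewise
  mapped <- chartr("ACGTN", "abcde", cands)
  cands[order(mapped, method = "radix")][1]
}

# best rotation/strand of `member` against `center` by Hamming distance
.phase_to <- function(member, center) {
  cands <- c(.rotations(member), .rotations(revcomp(member)))
  cm <- strsplit(center, "", fixed = TRUE)[[1]]
  d <- vapply(cands, function(s) {
    sum(strsplit(s, "", fixed = TRUE)[[1]] != cm)
  }, numeric(1), USE.NAMES = FALSE)
  cands[which.min(d)]
}

#' Build a family consensus monomer
#'
#' The base period is the modal member period (ties broken toward the
#' smaller period).  Members at the modal period are reduced to canonical
#' rotations, re-phased against the most frequent canonical sequence (star
#' alignment), and the consensus is the per-column majority base (ties
#' broken A < C < G < T).  Members at higher-order multiples of the base
#' period contribute to HOR detection but not to the consensus vote.
#'
#' @param base_seqs Character vector of member monomer sequences.
#' @param periods Integer vector of member periods (same length).
#' @param hor_tolerance Tolerance in bp passed to [detect_hor()].
#' @param min_support_identity Members at the modal period count as
#'   supporting when their identity to the consensus is at least this
#'   fraction (default 0.8).
#' @return A `consensus_model` list: `base_period`, `consensus` (length =
#'   base period), `hor_periods` (data.frame `period`, `multiplier`),
#'   `support` (fraction of modal-period members consistent with the
#'   consensus), `n_members`.
#' @export
build_consensus <- function(base_seqs, periods, hor_tolerance = 2L,
                            min_support_identity = 0.8) {
  stopifnot(length(base_seqs) == length(periods), length(base_seqs) >= 1L)
  tab <- table(periods)
  modal <- min(as.integer(names(tab)[tab == max(tab)]))
  members <- base_seqs[periods == modal]
  if (length(members) == 0L)
    stop("no members at the modal period")  # unreachable given the mode
  canon <- vapply(members, canonical_rotation, character(1),
                  USE.NAMES = FALSE)
  tab_c <- table(canon)
  center <- sort(names(tab_c)[tab_c == max(tab_c)])[1]
  # re-phase every member to the center, then column-majority vote
  phased <- vapply(canon, .phase_to, character(1), center = center,
                   USE.NAMES = FALSE)
  same_len <- nchar(phased) == nchar(center)
  phased <- phased[same_len]
  mat <- do.call(rbind, strsplit(phased, "", fixed = TRUE))
  cons <- apply(mat, 2, function(col) {
    counts <- table(factor(col, levels = c(BASES, "N")))
    names(counts)[which.max(counts)]  # which.max takes first => A<C<G<T ties
  })
  consensus <- paste(cons, collapse = "")
  ident <- vapply(phased, function(s) {
    1 - sum(strsplit(s, "", fixed = TRUE)[[1]] != cons) / nchar(consensus)
  }, numeric(1), USE.NAMES = FALSE)
  support <- sum(ident >= min_support_identity) / length(members)
  # pin the reported phase/strand so the consensus is stable under
  # membership growth and rotation of the member set
  consensus <- canonical_rotation(consensus)
  structure(list(base_period = modal, consensus = consensus,
                 hor_periods = detect_hor(periods, modal, hor_tolerance),
                 support = support, n_members = length(base_seqs)),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat("consensus monomer (period ", x$base_period, " bp, support ",
      round(x$support, 2), ", ", x$n_members, " members)\n", sep = "")
  cat("  ", x$consensus, "\n", sep = "")
  if (nrow(x$hor_periods))
    cat("  HOR periods:",
        paste0(x$hor_periods$period, " (x", x$hor_periods$multiplier, ")",
               collapse = ", "), "\n")
  invisible(x)
}

#' Detect higher-order repeat periods
#'
#' Reports every distinct member period `p != base_period` lying within
#' `tolerance` bp of an integer multiple `k * base_period` with `k >= 2`,
#' together with the multiplier `k`, sorted ascending by period.
#'
#' @param periods Integer vector (or multiset) of member periods.
#' @param base_period Base (monomer) period in bp.
#' @param tolerance Tolerance in bp (default 2).
#' @return data.frame with `period` and `multiplier`.
#' @export
detect_hor <- function(periods, base_period, tolerance = 2L) {
  stopifnot(base_period >= 1)
  p <- sort(unique(as.integer(periods)))
  p <- p[p != base_period]
  k <- pmax(2L, as.integer(round(p / base_period)))
  keep <- abs(p - k * base_period) <= tolerance & k >= 2L
  data.frame(period = p[keep], multiplier = k[keep])
}
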