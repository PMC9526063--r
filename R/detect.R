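#' Tandem-repeat detector parameters
#'
#' Defaults follow the community-standard recommendation for tandem-repeat
#' scanning: match +2, mismatch 7, indel 7, minimum alignment score 50,
#' period range 1-2000 bp, at least 2 copies, 13-mer candidate seeding.
#'
#' @param k Seed k-mer length for candidate generation (<= 31).
#' @param match_score,mismatch_penalty,indel_penalty Alignment scoring
#'   (penalties as positive integers).
#' @param min_score Minimum wraparound alignment score for a reported hit.
#' @param min_period,max_period Reported period range in bp.
#' @param min_copies Minimum (possibly fractional) copy number.
#' @param xdrop Score drop-off terminating greedy array extension.
#' @param max_multiple Largest integer multiple of an already-explained
#'   period that is still evaluated as a higher-order variant of the same
#'   locus.
#' @param ident_delta A longer-period variant of an explained locus is kept
#'   only if its percent identity exceeds the covering hit's by this margin
#'   (HOR structure shows up exactly this way).
#' @return A `detector_params` list.
#' @export
detector_params <- function(k = 13L, match_score = 2L, mismatch_penalty = 7L,
                            indel_penalty = 7L, min_score = 50L,
                            min_period = 1L, max_period = 2000L,
                            min_copies = 2, xdrop = 30L, max_multiple = 8L,
                            ident_delta = 0.5) {
  stopifnot(k >= 1L, k <= 31L, min_period >= 1L, max_period >= min_period,
            min_copies >= 2, match_score > 0, mismatch_penalty >= 0,
            indel_penalty >= 0)
  structure(list(k = as.integer(k), match_score = as.integer(match_score),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 indel_penalty = as.integer(indel_penalty),
                 min_score = as.integer(min_score),
                 min_period = as.integer(min_period),
                 max_period = as.integer(max_period),
                 min_copies = min_copies, xdrop = as.integer(xdrop),
                 max_multiple = as.integer(max_multiple),
                 ident_delta = ident_delta),
            class = "detector_params")
}

#' Candidate periods from exact k-mer recurrences
#'
#' Every exact k-mer recurring at a distance `d` with
#' `min_period <= d <= max_period` yields a candidate `(pos, period = d)`
#' anchored at the earlier occurrence; candidates are deduplicated so that at
#' most one is emitted per period per monomer-length window.
#'
#' @param seq Nucleotide string.
#' @param params [detector_params()].
#' @return data.frame with 0-based `pos` and `period`.
#' @export
find_candidate_periods <- function(seq, params = detector_params()) {
  seq <- toupper(as.character(seq))
  cpp_find_candidates(seq, params$k, params$min_period, params$max_period)
}

#' Wraparound alignment of a segment against a cyclic monomer
#'
#' Globally aligns `segment` against unlimited tandem copies of `monomer`
#' by dynamic programming whose column index wraps modulo the monomer
#' length (start and end phase are free).  Scoring is additive:
#' `+match_score` per match, `-mismatch_penalty` per mismatch,
#' `-indel_penalty` per indel column.
#'
#' @param segment,monomer Nucleotide strings; `monomer` must be non-empty.
#' @param params [detector_params()] supplying the scoring.
#' @return List with `score`, `copy_number` (monomer columns consumed divided
#'   by the period), `percent_identity` (matches over aligned columns), and
#'   `consensus` (per-column majority base of the segment, length = period).
#' @export
wraparound_align <- function(segment, monomer, params = detector_params()) {
  monomer <- toupper(as.character(monomer))
  if (nchar(monomer) == 0L) stop("monomer must be non-empty")
  cpp_wrap_align(toupper(as.character(segment)), monomer,
                 params$match_score, params$mismatch_penalty,
                 params$indel_penalty)
}

#' Detect tandem repeats in an assembly
#'
#' For each k-mer candidate the array is greedily extended left and right
#' while the wraparound score improves (X-drop termination), the array
#' consensus is derived, and the segment is re-aligned against that
#' consensus.  Hits are kept when score, copy number and period pass the
#' thresholds; overlapping hits with the same period keep only the highest
#' scoring one, while distinct periods at one locus (e.g. a base period and a
#' higher-order multiple that explains the locus better) are all reported.
#'
#' @param assembly A [Biostrings::DNAStringSet], a named character vector of
#'   sequences, or a FASTA path.
#' @param params [detector_params()].
#' @return data.frame of hits: `hit_id`, `contig`, `start`, `end` (0-based
#'   half-open), `period`, `copy_number`, `percent_identity`, `score`,
#'   `base_seq` (the array consensus, length = period).
#' @export
detect_tandem_repeats <- function(assembly, params = detector_params()) {
  seqs <- .as_sequences(assembly)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    h <- cpp_detect_seq(seqs[[i]], params$k, params$match_score,
                        params$mismatch_penalty, params$indel_penalty,
                        params$min_score, params$min_period,
                        params$max_period, params$min_copies, params$xdrop,
                        params$max_multiple, params$ident_delta)
    if (nrow(h)) h <- cbind(contig = names(seqs)[i], h,
                            stringsAsFactors = FALSE)
    out[[i]] <- h
  }
  out <- out[vapply(out, nrow, integer(1)) > 0]
  hits <- if (length(out)) do.call(rbind, out) else data.frame(
    contig = character(0), start = numeric(0), end = numeric(0),
    period = integer(0), copy_number = numeric(0),
    percent_identity = numeric(0), score = numeric(0),
    base_seq = character(0), stringsAsFactors = FALSE)
  hits <- hits[order(hits$contig, hits$start, hits$period), , drop = FALSE]
  rownames(hits) <- NULL
  if (nrow(hits)) hits <- cbind(hit_id = seq_len(nrow(hits)), hits)
  else hits$hit_id <- integer(0)
  hits
}

# normalize assembly input to a named list of uppercase character sequences
.as_sequences <- function(assembly) {
  if (is.character(assembly) && length(assembly) == 1L &&
      file.exists(assembly))
    assembly <- read_genome(assembly)
  if (methods::is(assembly, "DNAStringSet")) {
    seqs <- as.list(as.character(assembly))
  } else if (is.character(assembly)) {
    seqs <- as.list(toupper(assembly))
  } else stop("assembly must be a DNAStringSet, character vector, or a ",
              "FASTA path")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  seqs
}

#' Census of total copy number per period size
#'
#' Aggregates detected hits by period: the total copy number and the number
#' of hits for each period size, sorted ascending by period.
#'
#' @param hits Hit data.frame from [detect_tandem_repeats()].
#' @return data.frame with `period`, `total_copy_number`, `n_hits`.
#' @export
period_census <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L)
    return(data.frame(period = integer(0), total_copy_number = numeric(0),
                      n_hits = integer(0)))
  periods <- sort(unique(hits$period))
  key <- as.character(periods)
  tot <- rowsum(hits$copy_number, hits$period)
  cnt <- table(hits$period)
  data.frame(period = periods,
             total_copy_number = as.numeric(tot[key, 1L]),
             n_hits = as.integer(cnt[key]))
}

#' Write detected hits as GFF3
#'
#' Records are typed `tandem_repeat` with attributes `Period=`, `Copies=`,
#' `Identity=` and `Consensus=`.
#'
#' @param hits Hit data.frame.
#' @param path Output GFF3 file.
#' @return Invisibly, `path`.
#' @export
write_hits_gff3 <- function(hits, path) {
  write_gff3(data.frame(chrom = hits$contig, start = hits$start,
                        end = hits$end, score = hits$score,
                        Period = hits$period,
                        Copies = round(hits$copy_number, 2),
                        Identity = round(hits$percent_identity, 1),
                        Consensus = hits$base_seq, stringsAsFactors = FALSE),
             path, source = "satfam", type = "tandem_repeat")
  invisible(path)
}
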