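#' Family-clustering parameters
#'
#' The E-value cutoff defaults to 1e-20; similarity-search scoring defaults
#' to the canonical nucleotide settings match +2 / mismatch -3 / gap open 5 /
#' gap extend 2 with an 11-bp exact seed word.
#'
#' @param evalue_cutoff Maximum E-value for a similarity edge.
#' @param min_period Minimum period admitted to clustering (microsatellites
#'   below this are censused but not clustered).
#' @param min_total_copies Absolute floor of the "highly represented period"
#'   rule (see [select_represented_periods()]).
#' @param copy_fraction Relative floor: a period is represented when its
#'   total copy number is at least `max(min_total_copies,
#'   copy_fraction * grand_total)`.
#' @param word_size Exact seed length of the similarity search.
#' @param match,mismatch,gap_open,gap_extend Local-alignment scoring
#'   (penalties positive).
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(evalue_cutoff = 1e-20, min_period = 10L,
                           min_total_copies = 100, copy_fraction = 0.01,
                           word_size = 11L, match = 2L, mismatch = 3L,
                           gap_open = 5L, gap_extend = 2L) {
  stopifnot(evalue_cutoff > 0, min_period >= 1L, word_size >= 1L,
            match > 0, mismatch >= 0)
  structure(list(evalue_cutoff = evalue_cutoff,
                 min_period = as.integer(min_period),
                 min_total_copies = min_total_copies,
                 copy_fraction = copy_fraction,
                 word_size = as.integer(word_size), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "cluster_params")
}

#' Select highly represented period sizes
#'
#' A period is selected when its census total copy number reaches
#' `max(min_total_copies, copy_fraction * grand total)` and the period is at
#' least `min_period`.
#'
#' @param census Output of [period_census()].
#' @param params [cluster_params()].
#' @return Integer vector of selected periods (ascending).
#' @export
select_represented_periods <- function(census, params = cluster_params()) {
  if (is.null(census) || nrow(census) == 0L) return(integer(0))
  thr <- max(params$min_total_copies,
             params$copy_fraction * sum(census$total_copy_number))
  sort(census$period[census$total_copy_number >= thr &
                     census$period >= params$min_period])
}

#' Triple self-concatenation of a monomer
#'
#' Repeats the monomer exactly three times, so that any rotation (circular
#' permutation) of a homologous monomer aligns full-length within it.
#'
#' @param base_seq Non-empty nucleotide string.
#' @return `base_seq` repeated 3 times.
#' @export
triple_concatenate <- function(base_seq) {
  base_seq <- as.character(base_seq)
  if (length(base_seq) != 1L || nchar(base_seq) == 0L)
    stop("base_seq must be a single non-empty string")
  strrep(base_seq, 3L)
}

#' Ungapped Karlin-Altschul parameters for a match/mismatch scoring
#'
#' Solves the standard ungapped Karlin-Altschul equations at uniform
#' background base frequencies (0.25 each): lambda is the unique positive
#' root of `sum_s p_s exp(lambda s) = 1`, the relative entropy H is
#' `lambda * sum_s s p_s exp(lambda s)`, and K is computed by the classical
#' convergent series over partial-sum distributions on the score lattice.
#'
#' @param match,mismatch Match score and mismatch penalty (positive).
#' @return List with `lambda` (per score unit, nats), `K` and `H`.
#' @export
karlin_altschul <- function(match = 2L, mismatch = 3L) {
  scores <- c(match, -mismatch)
  probs <- c(0.25, 0.75)
  if (sum(scores * probs) >= 0)
    stop("degenerate scoring: expected score must be negative for ",
         "Karlin-Altschul statistics")
  f <- function(l) sum(probs * exp(l * scores)) - 1
  lambda <- uniroot(f, c(1e-8, 10), tol = 1e-12)$root
  H <- lambda * sum(scores * probs * exp(lambda * scores))
  d <- .gcd_vec(abs(scores))

  # sigma = sum_j (1/j) [ E(e^{lambda S_j}; S_j < 0) + P(S_j >= 0) ]
  lo <- min(scores); hi <- max(scores)
  # distribution of the single-step score on an integer offset grid
  span <- hi - lo
  step <- setNames(numeric(span + 1L), as.character(lo:hi))
  for (i in seq_along(scores))
    step[as.character(scores[i])] <- step[as.character(scores[i])] + probs[i]
  dist <- c("0" = 1)  # S_0 = 0
  sigma <- 0
  for (j in 1:200) {
    # convolve dist with step
    vals <- as.integer(names(dist))
    newmin <- min(vals) + lo; newmax <- max(vals) + hi
    nd <- setNames(numeric(newmax - newmin + 1L),
                   as.character(newmin:newmax))
    for (v in seq_along(vals)) {
      idx <- as.character(vals[v] + (lo:hi))
      nd[idx] <- nd[idx] + dist[[v]] * step
    }
    dist <- nd[nd > 0]
    sv <- as.integer(names(dist))
    neg <- sv < 0
    term <- sum(dist[neg] * exp(lambda * sv[neg])) + sum(dist[!neg])
    sigma <- sigma + term / j
    if (term / j < 1e-12) break
  }
  K <- d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
  list(lambda = lambda, K = K, H = H)
}

.gcd_vec <- function(x) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  Reduce(g, x)
}

#' E-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with `(K, lambda)` from the ungapped
#' Karlin-Altschul solution for the configured match/mismatch scores; gapped
#' alignments reuse these constants (the standard practical approximation).
#'
#' @param score Alignment score(s).
#' @param m,n Search-space dimensions (query length and total subject
#'   length).
#' @param params [cluster_params()].
#' @param ka Optional precomputed [karlin_altschul()] constants.
#' @return Numeric E-value(s).
#' @export
alignment_evalue <- function(score, m, n, params = cluster_params(),
                             ka = NULL) {
  if (is.null(ka)) ka <- karlin_altschul(params$match, params$mismatch)
  ka$K * m * n * exp(-ka$lambda * score)
}

#' Best seeded local alignment of a monomer against a tripled monomer
#'
#' Finds the best word-seeded gapped local alignment of `query` (searched in
#' both orientations) against `subject`, converts the score to an E-value in
#' the given search space, and returns a similarity edge only if the E-value
#' passes the cutoff.
#'
#' @param query Unconcatenated monomer sequence.
#' @param subject Subject sequence (typically a [triple_concatenate()]d
#'   monomer).
#' @param params [cluster_params()].
#' @param search_space Numeric `(m, n)`: query length and total subject
#'   length of the search space used in the E-value.  Defaults to the actual
#'   sequence lengths.
#' @param ka Optional precomputed [karlin_altschul()] constants.
#' @return `NULL` when no alignment passes the cutoff, otherwise a list with
#'   `score`, `evalue`, `strand`, `length` and 1-based alignment coordinates
#'   `qstart`, `qend`, `sstart`, `send`.
#' @export
local_align_evalue <- function(query, subject, params = cluster_params(),
                               search_space = NULL, ka = NULL) {
  query <- toupper(as.character(query))
  subject <- toupper(as.character(subject))
  if (nchar(query) == 0L || nchar(subject) == 0L)
    stop("query and subject must be non-empty")
  if (is.null(search_space))
    search_space <- c(nchar(query), nchar(subject))
  if (is.null(ka)) ka <- karlin_altschul(params$match, params$mismatch)
  fwd <- cpp_seeded_local_align(query, subject, params$match,
                                params$mismatch, params$gap_open,
                                params$gap_extend, params$word_size)
  rev <- cpp_seeded_local_align(revcomp(query), subject, params$match,
                                params$mismatch, params$gap_open,
                                params$gap_extend, params$word_size)
  best <- if (rev$score > fwd$score) c(rev, strand = "-")
          else c(fwd, strand = "+")
  if (best$score <= 0) return(NULL)
  e <- alignment_evalue(best$score, search_space[1], search_space[2],
                        params, ka)
  if (e > params$evalue_cutoff) return(NULL)
  list(score = best$score, evalue = e, strand = best$strand,
       length = best$length, qstart = best$qstart, qend = best$qend,
       sstart = best$sstart, send = best$send)
}

#' Cluster detected repeats into satellite families
#'
#' Hits whose period passes [select_represented_periods()] are grouped by the
#' rotation-tolerant similarity procedure: monomers are reduced to canonical
#' rotation forms (hits with identical canonical monomers join by
#' definition), every representative monomer is aligned against every other
#' representative's triple self-concatenation in both orientations, scores
#' are converted to E-values in the database search space (m = query length,
#' n = sum of tripled subject lengths), and families are the connected
#' components of the edge graph.  Family labels `F1, F2, ...` are assigned in
#' descending order of member count.
#'
#' @param hits Hit data.frame from [detect_tandem_repeats()].
#' @param params [cluster_params()].
#' @param census Optional precomputed [period_census()]; computed from `hits`
#'   when missing.
#' @param select_periods When `FALSE`, all hits are clustered regardless of
#'   the period-representation rule (useful for testing small hit sets).
#' @return List with `families` (data.frame `hit_id`, `family_id`),
#'   `groups` (per-family data.frame: `family_id`, `n_instances`,
#'   `periods`), `edges` (data.frame of similarity edges between
#'   representative monomers) and `excluded` (hit ids dropped by period
#'   selection).
#' @export
cluster_families <- function(hits, params = cluster_params(), census = NULL,
                             select_periods = TRUE) {
  empty <- list(
    families = data.frame(hit_id = integer(0), family_id = character(0)),
    groups = data.frame(family_id = character(0), n_instances = integer(0),
                        periods = character(0)),
    edges = data.frame(rep_a = integer(0), rep_b = integer(0),
                       score = numeric(0), evalue = numeric(0)),
    excluded = integer(0))
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  if (select_periods) {
    if (is.null(census)) census <- period_census(hits)
    keep_periods <- select_represented_periods(census, params)
    sel <- hits$period %in% keep_periods
  } else sel <- rep(TRUE, nrow(hits))
  excluded <- hits$hit_id[!sel]
  hits <- hits[sel, , drop = FALSE]
  if (nrow(hits) == 0L) { empty$excluded <- excluded; return(empty) }

  canon <- vapply(hits$base_seq, canonical_rotation, character(1),
                  USE.NAMES = FALSE)
  reps <- unique(canon)
  rep_idx <- match(canon, reps)
  nrep <- length(reps)

  ka <- karlin_altschul(params$match, params$mismatch)
  n_total <- sum(3 * nchar(reps))
  ea <- integer(0); eb <- integer(0); esc <- numeric(0); eev <- numeric(0)
  if (nrep > 1) {
    for (i in seq_len(nrep - 1L)) {
      for (j in seq(i + 1L, nrep)) {
        # database search is symmetric: each monomer is both a query and
        # (as a triple) a subject, so a short monomer links to the triple of
        # its higher-order multiple through whichever direction aligns longer
        e1 <- local_align_evalue(reps[i], triple_concatenate(reps[j]),
                                 params,
                                 search_space = c(nchar(reps[i]), n_total),
                                 ka = ka)
        e2 <- local_align_evalue(reps[j], triple_concatenate(reps[i]),
                                 params,
                                 search_space = c(nchar(reps[j]), n_total),
                                 ka = ka)
        edge <- if (is.null(e1)) e2
                else if (is.null(e2) || e1$evalue <= e2$evalue) e1 else e2
        if (!is.null(edge)) {
          ea <- c(ea, i); eb <- c(eb, j)
          esc <- c(esc, edge$score); eev <- c(eev, edge$evalue)
        }
      }
    }
  }
  # connected components over representative monomers
  g <- igraph::graph_from_data_frame(
    data.frame(from = ea, to = eb),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrep)))
  comp <- igraph::components(g)$membership[as.character(seq_len(nrep))]
  hit_comp <- comp[rep_idx]

  sizes <- table(hit_comp)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  lab <- setNames(paste0("F", seq_along(ord)), names(sizes)[ord])
  family_id <- unname(lab[as.character(hit_comp)])

  groups <- do.call(rbind, lapply(unname(lab), function(fid) {
    idx <- family_id == fid
    data.frame(family_id = fid, n_instances = sum(idx),
               periods = paste(sort(unique(hits$period[idx])),
                               collapse = ","),
               stringsAsFactors = FALSE)
  }))
  groups <- groups[order(-groups$n_instances, groups$family_id), ,
                   drop = FALSE]
  rownames(groups) <- NULL
  list(families = data.frame(hit_id = hits$hit_id, family_id = family_id,
                             stringsAsFactors = FALSE),
       groups = groups,
       edges = data.frame(rep_a = ea, rep_b = eb, score = esc, evalue = eev),
       excluded = excluded)
}
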