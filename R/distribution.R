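#' Distribution-profiling parameters
#'
#' `cluster_gap` defaults to adaptive: 2% of the chromosome length, capped
#' at 500 kb — on multi-megabase chromosomes this is the fixed large-scale
#' gap, while on short test chromosomes it scales down so the
#' dispersed/localized contrast stays meaningful.
#'
#' @param cluster_gap Maximum gap (bp) joining intervals into one positional
#'   cluster, or `NA` for the adaptive default.
#' @param localized_fraction Threshold on the largest-cluster fraction of a
#'   family's bases on a chromosome.
#' @param localized_chromosome_majority Fraction of occupied chromosomes
#'   that must pass (or fail) the threshold for a global label.
#' @param coloc_window Window size (bp) for family co-localization counts.
#' @param gc_window Window size (bp) for the GC track.
#' @return A `profile_params` list.
#' @export
profile_params <- function(cluster_gap = NA_real_, localized_fraction = 0.5,
                           localized_chromosome_majority = 0.75,
                           coloc_window = 2e5, gc_window = 2e5) {
  stopifnot(is.na(cluster_gap) || cluster_gap > 0,
            localized_fraction > 0, localized_chromosome_majority > 0,
            coloc_window >= 1, gc_window >= 1)
  structure(list(cluster_gap = cluster_gap,
                 localized_fraction = localized_fraction,
                 localized_chromosome_majority = localized_chromosome_majority,
                 coloc_window = coloc_window, gc_window = gc_window),
            class = "profile_params")
}

.effective_gap <- function(params, chrom_length) {
  g <- params$cluster_gap
  if (is.null(g) || is.na(g)) min(5e5, 0.02 * chrom_length) else g
}

#' Positional clusters of merged intervals on one chromosome
#'
#' Single-linkage chaining: consecutive intervals whose start-to-previous-end
#' gap is at most `cluster_gap` join one cluster.
#'
#' @param intervals data.frame with `start`, `end` (0-based half-open),
#'   sorted and disjoint, all on one chromosome.
#' @param cluster_gap Maximum joining gap in bp.
#' @return data.frame with one row per cluster: `start`, `end` (span),
#'   `n_intervals`, `bases` (summed interval bases).
#' @export
cluster_positions <- function(intervals, cluster_gap) {
  if (is.null(intervals) || nrow(intervals) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_intervals = integer(0), bases = numeric(0)))
  iv <- intervals[order(intervals$start), , drop = FALSE]
  gap_new <- c(TRUE, iv$start[-1] - iv$end[-nrow(iv)] > cluster_gap)
  grp <- cumsum(gap_new)
  do.call(rbind, lapply(split(iv, grp), function(g)
    data.frame(start = min(g$start), end = max(g$end),
               n_intervals = nrow(g), bases = sum(g$end - g$start))))
}

#' Classify a family's chromosomal distribution
#'
#' A family is `localized` when its largest positional cluster holds at
#' least `localized_fraction` of its bases on at least
#' `localized_chromosome_majority` of the chromosomes it occupies;
#' `dispersed` when the largest-cluster fraction stays below the threshold
#' on the same majority; `mixed` otherwise.
#'
#' @param per_chrom data.frame with one row per occupied chromosome and a
#'   `largest_cluster_fraction` column.
#' @param params [profile_params()].
#' @return `"localized"`, `"dispersed"` or `"mixed"`.
#' @export
classify_distribution <- function(per_chrom, params = profile_params()) {
  if (is.null(per_chrom) || nrow(per_chrom) == 0L)
    stop("family does not occur in the assembly")
  f <- per_chrom$largest_cluster_fraction
  maj <- params$localized_chromosome_majority
  if (mean(f >= params$localized_fraction) >= maj) "localized"
  else if (mean(f < params$localized_fraction) >= maj) "dispersed"
  else "mixed"
}

#' Distribution profile of one family
#'
#' @param merged Merged intervals of the family (`chrom`, `start`, `end`).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param params [profile_params()].
#' @return A `distribution_profile` list: `per_chrom` (chromosome,
#'   n_clusters, largest_cluster_fraction, bases), `label`, `clusters`
#'   (per-chromosome cluster tables) and `params`.
#' @export
distribution_profile <- function(merged, chrom_lengths,
                                 params = profile_params()) {
  if (is.null(merged) || nrow(merged) == 0L)
    stop("family does not occur in the assembly")
  chroms <- unique(merged$chrom)
  clusters <- list()
  rows <- lapply(chroms, function(ch) {
    iv <- merged[merged$chrom == ch, , drop = FALSE]
    gap <- .effective_gap(params, chrom_lengths[[ch]])
    cl <- cluster_positions(iv, gap)
    clusters[[ch]] <<- cl
    data.frame(chrom = ch, n_clusters = nrow(cl),
               largest_cluster_fraction = max(cl$bases) / sum(cl$bases),
               bases = sum(cl$bases), stringsAsFactors = FALSE)
  })
  per_chrom <- do.call(rbind, rows)
  structure(list(per_chrom = per_chrom,
                 label = classify_distribution(per_chrom, params),
                 clusters = clusters, params = params),
            class = "distribution_profile")
}

#' @export
print.distribution_profile <- function(x, ...) {
  cat("distribution:", x$label, "over", nrow(x$per_chrom),
      "occupied chromosome(s)\n")
  print(x$per_chrom, row.names = FALSE)
  invisible(x)
}

#' Family co-localization in genomic windows
#'
#' Tiles each chromosome into `coloc_window` bins; a family occupies a bin
#' when at least 1 bp of its merged intervals overlaps it.
#'
#' @param merged_list Named list of merged-interval data.frames, one per
#'   family (>= 2 families).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param coloc_window Window size in bp.
#' @return List with `bins` (data.frame: chrom, start, end, families,
#'   n_families; only occupied bins) and `matrix` (families x families
#'   matrix of jointly occupied bin counts; diagonal = occupied bins per
#'   family).
#' @export
colocalization <- function(merged_list, chrom_lengths, coloc_window = 2e5) {
  fams <- names(merged_list)
  if (length(fams) < 2L) stop("colocalization needs at least 2 families")
  occ <- list()  # per family: character vector of bin keys
  bin_rows <- list()
  for (fid in fams) {
    m <- merged_list[[fid]]
    if (is.null(m) || nrow(m) == 0L) { occ[[fid]] <- character(0); next }
    b0 <- floor(m$start / coloc_window)
    b1 <- ceiling(m$end / coloc_window) - 1
    keys <- unique(unlist(lapply(seq_len(nrow(m)), function(i)
      paste(m$chrom[i], b0[i]:b1[i], sep = ":"))))
    occ[[fid]] <- keys
  }
  all_keys <- sort(unique(unlist(occ)))
  mat <- matrix(0L, length(fams), length(fams),
                dimnames = list(fams, fams))
  for (i in seq_along(fams)) for (j in seq_along(fams))
    mat[i, j] <- length(intersect(occ[[fams[i]]], occ[[fams[j]]]))
  bins <- if (length(all_keys)) {
    parts <- strsplit(all_keys, ":", fixed = TRUE)
    chrom <- vapply(parts, `[`, character(1), 1L)
    idx <- as.numeric(vapply(parts, `[`, character(1), 2L))
    famsets <- vapply(all_keys, function(k)
      paste(fams[vapply(fams, function(f) k %in% occ[[f]], logical(1))],
            collapse = ","), character(1), USE.NAMES = FALSE)
    data.frame(chrom = chrom, start = idx * coloc_window,
               end = pmin((idx + 1) * coloc_window,
                          as.numeric(chrom_lengths[chrom])),
               families = famsets,
               n_families = lengths(strsplit(famsets, ",", fixed = TRUE)),
               stringsAsFactors = FALSE)
  } else data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), families = character(0),
                    n_families = integer(0))
  list(bins = bins[order(bins$chrom, bins$start), , drop = FALSE],
       matrix = mat)
}

#' Windowed GC-content track
#'
#' Non-overlapping windows laid left-to-right per chromosome (final partial
#' window kept); GC = (G+C) / (A+C+G+T) per window, with ambiguous bases
#' excluded from the denominator.  Windows of only ambiguous bases report
#' `NA`.
#'
#' @param assembly A [Biostrings::DNAStringSet], named character vector, or
#'   FASTA path.
#' @param gc_window Window size in bp (>= 1).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `gc`.
#' @export
gc_track <- function(assembly, gc_window = 2e5) {
  stopifnot(gc_window >= 1)
  seqs <- .as_sequences(assembly)
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  out <- lapply(seq_along(dss), function(i) {
    L <- Biostrings::width(dss)[i]
    starts <- seq(1, L, by = gc_window)
    ends <- pmin(starts + gc_window - 1, L)
    v <- Biostrings::Views(dss[[i]], start = starts, end = ends)
    af <- Biostrings::alphabetFrequency(v, baseOnly = TRUE)
    denom <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
    gc <- ifelse(denom > 0,
                 rowSums(af[, c("C", "G"), drop = FALSE]) / denom, NA_real_)
    data.frame(chrom = names(dss)[i], start = starts - 1, end = ends,
               gc = gc, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
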