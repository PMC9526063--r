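#' Merge a family's intervals
#'
#' Overlapping and bookended (end == next start) intervals on the same
#' contig are united; output is sorted by (contig, start) and the operation
#' is idempotent.  This absorbs the redundant repeat variants that the
#' detector reports from a single genomic region.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return data.frame of merged, disjoint intervals (`chrom`, `start`,
#'   `end`), sorted.
#' @export
merge_family_intervals <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  gr <- .df_to_granges(intervals[c("chrom", "start", "end")])
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)  # merges bookended
  red <- GenomicRanges::sort(red, ignore.strand = TRUE)
  out <- .granges_to_df(red)[c("chrom", "start", "end")]
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Total bases covered by merged intervals
#'
#' @param merged Merged, disjoint intervals from [merge_family_intervals()].
#' @return Total covered bases (bp).
#' @export
family_total_bases <- function(merged) {
  if (is.null(merged) || nrow(merged) == 0L) return(0)
  sum(merged$end - merged$start)
}

#' Per-family footprint metrics
#'
#' Merges each family's member-hit intervals and reports instance counts,
#' merged-interval counts, mean instance length, total covered bases, and
#' genome fraction.
#'
#' @param hits Hit data.frame from [detect_tandem_repeats()].
#' @param families data.frame `hit_id`, `family_id` from
#'   [cluster_families()].
#' @param assembly_length Total assembly length in bp (> 0).
#' @return List with `metrics` (one row per family, descending total bases)
#'   and `merged` (named list of merged-interval data.frames per family).
#' @export
family_metrics <- function(hits, families, assembly_length) {
  if (assembly_length <= 0) stop("assembly_length must be positive")
  fams <- unique(families$family_id)
  merged <- list()
  rows <- lapply(fams, function(fid) {
    ids <- families$hit_id[families$family_id == fid]
    h <- hits[hits$hit_id %in% ids, , drop = FALSE]
    m <- merge_family_intervals(data.frame(chrom = h$contig, start = h$start,
                                           end = h$end))
    merged[[fid]] <<- m
    tb <- family_total_bases(m)
    data.frame(family_id = fid, n_instances = nrow(h),
               n_merged_intervals = nrow(m),
               mean_instance_length = mean(h$end - h$start),
               total_bases = tb,
               genome_fraction = round(100 * tb / assembly_length, 3),
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  if (is.null(metrics))
    metrics <- data.frame(family_id = character(0), n_instances = integer(0),
                          n_merged_intervals = integer(0),
                          mean_instance_length = numeric(0),
                          total_bases = numeric(0),
                          genome_fraction = numeric(0))
  metrics <- metrics[order(-metrics$total_bases, -metrics$n_instances,
                           metrics$family_id), , drop = FALSE]
  rownames(metrics) <- NULL
  list(metrics = metrics, merged = merged)
}

#' Rank families by total covered bases
#'
#' Families are sorted by `total_bases` descending, ties broken by
#' `n_instances` descending, then `family_id` lexicographic; the first
#' `top_n` are returned.
#'
#' @param metrics Metrics data.frame from [family_metrics()].
#' @param top_n Number of families to keep (>= 1).
#' @return The top `top_n` rows of `metrics`, re-ranked.
#' @export
rank_families <- function(metrics, top_n = 3L) {
  if (top_n < 1L) stop("top_n must be >= 1")
  o <- order(-metrics$total_bases, -metrics$n_instances, metrics$family_id)
  out <- metrics[o, , drop = FALSE][seq_len(min(top_n, nrow(metrics))), ,
                                    drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome fraction of selected families
#'
#' Per-family fractions are `100 * total_bases / assembly_length` (reported
#' to 3 decimals); the combined fraction uses the interval *union* across
#' the selected families, so families covering the same region are not
#' double-counted.
#'
#' @param merged_list Named list of merged-interval data.frames (one per
#'   family), as returned by [family_metrics()].
#' @param assembly_length Total assembly length in bp (> 0).
#' @return List with `per_family` (named numeric, %) and `combined` (%).
#' @export
genome_fraction <- function(merged_list, assembly_length) {
  if (assembly_length <= 0) stop("assembly_length must be positive")
  per <- vapply(merged_list, function(m)
    round(100 * family_total_bases(m) / assembly_length, 3), numeric(1))
  all_iv <- do.call(rbind, unname(merged_list))
  combined <- if (is.null(all_iv) || nrow(all_iv) == 0L) 0 else
    round(100 * family_total_bases(merge_family_intervals(all_iv)) /
            assembly_length, 3)
  list(per_family = per, combined = combined)
}
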