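#' Run the full satellite-family discovery pipeline
#'
#' Executes detection, period census, period selection, rotation-tolerant
#' family clustering, interval merging and metrics, consensus / higher-order
#' repeat inference, and chromosomal distribution profiling.  Metrics are
#' computed for the `max_groups` largest groups by instance count and the
#' top `top_n` families by total covered bases are reported, with the
#' combined genome fraction taken over the union of their intervals.
#'
#' @param assembly A [Biostrings::DNAStringSet], named character vector of
#'   sequences, or FASTA path.
#' @param config A [satfam_config()].
#' @param out_dir Optional directory; when given, all intermediate and
#'   summary files plus a JSON run manifest are written there.
#' @param quiet Suppress stage progress messages.
#' @return A `satfam_result` list with `hits`, `census`,
#'   `selected_periods`, `clustering`, `metrics` (all measured groups),
#'   `top` (ranked top families), `consensus` (per top family),
#'   `profiles` (per top family), `coloc`, `gc`, `fractions`, `summary`
#'   (one row per top family) and `config`.
#' @export
run_pipeline <- function(assembly, config = satfam_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "satfam_config"))
  say <- function(...) if (!quiet) message("[satfam] ", ...)
  set.seed(config$seed)

  seqs <- .as_sequences(assembly)
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  chrom_lengths <- setNames(as.numeric(Biostrings::width(dss)), names(dss))
  assembly_length <- sum(chrom_lengths)
  say("assembly: ", length(dss), " sequence(s), ", assembly_length, " bp")

  hits <- detect_tandem_repeats(dss, config$detector)
  say("detect: ", nrow(hits), " tandem-repeat hits")
  census <- period_census(hits)
  selected <- select_represented_periods(census, config$cluster)
  say("period selection: ", length(selected), " represented period(s): ",
      paste(selected, collapse = ", "))

  clustering <- cluster_families(hits, config$cluster, census = census)
  n_clustered <- nrow(clustering$families)
  say("cluster: ", n_clustered, " hits in ", nrow(clustering$groups),
      " families; ", length(clustering$excluded),
      " hits excluded by period selection")
  stopifnot(n_clustered + length(clustering$excluded) == nrow(hits))

  empty_summary <- data.frame(
    family_id = character(0), base_period = integer(0),
    n_instances = integer(0), mean_instance_length = numeric(0),
    total_bases = numeric(0), genome_fraction = numeric(0),
    label = character(0), hor_periods = character(0),
    consensus = character(0), stringsAsFactors = FALSE)

  if (nrow(clustering$groups) == 0L) {
    say("no satellite families found")
    res <- structure(list(
      hits = hits, census = census, selected_periods = selected,
      clustering = clustering,
      metrics = NULL, top = NULL, consensus = list(), profiles = list(),
      coloc = NULL, gc = gc_track(dss, config$profile$gc_window),
      fractions = list(per_family = numeric(0), combined = 0),
      summary = empty_summary, chrom_lengths = chrom_lengths,
      config = config), class = "satfam_result")
    if (!is.null(out_dir)) .write_outputs(res, out_dir)
    return(res)
  }

  # candidate groups: largest by instance count, then rank by total bases
  cand <- head(clustering$groups$family_id, config$max_groups)
  fam_sub <- clustering$families[clustering$families$family_id %in% cand, ,
                                 drop = FALSE]
  fm <- family_metrics(hits, fam_sub, assembly_length)
  top <- rank_families(fm$metrics, config$top_n)
  say("rank: top ", nrow(top), " families by total bases: ",
      paste(top$family_id, collapse = ", "))

  consensus <- list()
  profiles <- list()
  for (fid in top$family_id) {
    ids <- clustering$families$hit_id[clustering$families$family_id == fid]
    h <- hits[hits$hit_id %in% ids, , drop = FALSE]
    consensus[[fid]] <- build_consensus(h$base_seq, h$period)
    profiles[[fid]] <- distribution_profile(fm$merged[[fid]], chrom_lengths,
                                            config$profile)
  }
  top_merged <- fm$merged[top$family_id]
  fractions <- genome_fraction(top_merged, assembly_length)
  coloc <- if (length(top_merged) >= 2L)
    colocalization(top_merged, chrom_lengths, config$profile$coloc_window)
  else NULL
  gc <- gc_track(dss, config$profile$gc_window)

  summary_df <- do.call(rbind, lapply(seq_len(nrow(top)), function(i) {
    fid <- top$family_id[i]
    cm <- consensus[[fid]]
    data.frame(
      family_id = fid, base_period = cm$base_period,
      n_instances = top$n_instances[i],
      mean_instance_length = round(top$mean_instance_length[i], 1),
      total_bases = top$total_bases[i],
      genome_fraction = top$genome_fraction[i],
      label = profiles[[fid]]$label,
      hor_periods = paste(cm$hor_periods$period, collapse = ","),
      consensus = cm$consensus, stringsAsFactors = FALSE)
  }))

  res <- structure(list(
    hits = hits, census = census, selected_periods = selected,
    clustering = clustering, metrics = fm$metrics, merged = fm$merged,
    top = top, consensus = consensus, profiles = profiles, coloc = coloc,
    gc = gc, fractions = fractions, summary = summary_df,
    chrom_lengths = chrom_lengths, config = config),
    class = "satfam_result")
  if (!is.null(out_dir)) .write_outputs(res, out_dir)
  res
}

.write_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  if (nrow(res$hits)) write_hits_gff3(res$hits, p("hits.gff3"))
  write.table(res$hits, p("hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res$clustering$families, p("families.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$clustering$edges, p("edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(res$metrics))
    write.table(res$metrics, p("metrics.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  write.table(res$summary, p("summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bedgraph(data.frame(chrom = res$gc$chrom, start = res$gc$start,
                            end = res$gc$end, value = res$gc$gc),
                 p("gc.bedGraph"))
  if (length(res$consensus)) {
    cons <- Biostrings::DNAStringSet(vapply(res$consensus, `[[`,
                                            character(1), "consensus"))
    names(cons) <- vapply(names(res$consensus), function(fid)
      sprintf("%s period=%d support=%.2f", fid,
              res$consensus[[fid]]$base_period,
              res$consensus[[fid]]$support), character(1))
    Biostrings::writeXStringSet(cons, p("consensus.fa"), width = 60L)
    hor <- do.call(rbind, lapply(names(res$consensus), function(fid) {
      h <- res$consensus[[fid]]$hor_periods
      if (nrow(h)) cbind(family_id = fid, h) else NULL
    }))
    if (!is.null(hor))
      write.table(hor, p("hor.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    for (fid in names(res$merged)[names(res$merged) %in%
                                  res$top$family_id]) {
      m <- res$merged[[fid]]
      if (nrow(m)) write_bed(cbind(m, name = fid),
                             p(paste0("merged_", fid, ".bed")))
    }
    dist_df <- do.call(rbind, lapply(names(res$profiles), function(fid)
      cbind(family_id = fid, res$profiles[[fid]]$per_chrom,
            label = res$profiles[[fid]]$label)))
    write.table(dist_df, p("distribution.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  manifest <- list(
    package = "satfam",
    version = as.character(utils::packageVersion("satfam")),
    seed = res$config$seed,
    parameters = lapply(unclass(res$config), function(x)
      if (is.list(x)) unclass(x) else x),
    counts = list(n_hits = nrow(res$hits),
                  n_families = if (is.null(res$clustering)) 0L
                               else nrow(res$clustering$groups),
                  n_top = if (is.null(res$top)) 0L else nrow(res$top)))
  jsonlite::write_json(manifest, p("run_manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.satfam_result <- function(x, ...) {
  cat("satfam pipeline result\n")
  cat("  hits:", nrow(x$hits), " | represented periods:",
      paste(x$selected_periods, collapse = ", "), "\n")
  if (is.null(x$top) || nrow(x$summary) == 0L) {
    cat("  no satellite families found\n")
    return(invisible(x))
  }
  cat("  top families (combined genome fraction ",
      x$fractions$combined, "%):\n", sep = "")
  print(x$summary[c("family_id", "base_period", "n_instances",
                    "total_bases", "genome_fraction", "label",
                    "hor_periods")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.satfam_result <- function(object, ...) {
  object$summary
}

#' Plot family locations over a windowed GC strip
#'
#' One horizontal strip per chromosome, shaded by windowed GC content, with
#' colored ticks marking the merged intervals of each top family.
#'
#' @param x A `satfam_result`.
#' @param ... Ignored.
#' @export
plot.satfam_result <- function(x, ...) {
  chroms <- names(x$chrom_lengths)
  n <- length(chroms)
  fams <- if (!is.null(x$top)) x$top$family_id else character(0)
  cols <- grDevices::hcl.colors(max(1L, length(fams)), "Dark 3")
  graphics::plot(NULL, xlim = c(0, max(x$chrom_lengths)),
                 ylim = c(0, n + 1), xlab = "position (bp)", ylab = "",
                 yaxt = "n", bty = "n", main = "satellite families over GC")
  graphics::axis(2, at = seq_len(n), labels = chroms, las = 1, tick = FALSE)
  gcr <- range(x$gc$gc, na.rm = TRUE)
  pal <- grDevices::hcl.colors(64, "YlGnBu", rev = TRUE)
  for (i in seq_len(n)) {
    g <- x$gc[x$gc$chrom == chroms[i], , drop = FALSE]
    if (nrow(g)) {
      shade <- pal[pmax(1, pmin(64, 1 + floor(63 * (g$gc - gcr[1]) /
                                              max(1e-9, diff(gcr)))))]
      graphics::rect(g$start, i - 0.25, g$end, i + 0.05, col = shade,
                     border = NA)
    }
    for (k in seq_along(fams)) {
      m <- x$merged[[fams[k]]]
      m <- m[m$chrom == chroms[i], , drop = FALSE]
      if (nrow(m))
        graphics::segments(m$start, i + 0.1 + 0.08 * k, m$end,
                           i + 0.1 + 0.08 * k, col = cols[k], lwd = 3)
    }
  }
  if (length(fams))
    graphics::legend("topright", legend = fams, col = cols, lwd = 3,
                     bty = "n", cex = 0.8)
  invisible(x)
}
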