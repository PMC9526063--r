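#' Read a genome assembly from FASTA
#'
#' Accepts wrapped or unwrapped lines and CRLF endings; record ids are taken
#' up to the first whitespace; sequences are uppercased.
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet], in file order.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("cannot parse FASTA '", path, "': ",
                                         conditionMessage(e)))
  if (length(x) == 0L) stop("FASTA '", path, "' contains no records")
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate record ids in '", path, "': ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  af <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  frac <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE]) /
    pmax(1, Biostrings::width(x))
  if (any(frac < 0.5))
    stop("record(s) not nucleotide-majority in '", path, "': ",
         paste(names(x)[frac < 0.5], collapse = ", "))
  x
}

# internal 0-based half-open data.frame -> GRanges (1-based inclusive)
.df_to_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) && any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1]
    stop("invalid interval (start >= end) in record ", bad, ": ",
         df$chrom[bad], ":", df$start[bad], "-", df$end[bad])
  }
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand)
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(extra))
    S4Vectors::mcols(gr)[extra] <- df[extra]
  gr
}

.granges_to_df <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  df
}

#' Write genomic records as GFF3
#'
#' Internal coordinates are 0-based half-open; the GFF3 written is 1-based
#' inclusive with a `##gff-version 3` header, sorted by (contig, start).
#' Columns other than `chrom`, `start`, `end`, `strand`, `score` become GFF3
#' attributes.
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optional `strand`, `score` plus attribute columns.
#' @param path Output file.
#' @param source,type GFF3 source and type fields.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(df, path, source = "satfam", type = "feature") {
  gr <- .df_to_granges(df)
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  gr <- gr[o]
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- type
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read a GFF3 file into internal coordinates
#'
#' @param path GFF3 file.
#' @return data.frame with 0-based half-open `start`/`end`, `strand`, `type`,
#'   `source` and one column per GFF3 attribute.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  .granges_to_df(gr)
}

#' Write genomic records as BED (0-based half-open)
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `name`, `score`, `strand`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  gr <- .df_to_granges(df)
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  rtracklayer::export.bed(gr[o], path)
  invisible(path)
}

#' Write a per-window numeric track as bedGraph
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `value`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(df, path) {
  df2 <- df[!is.na(df$value), , drop = FALSE]
  gr <- .df_to_granges(df2[c("chrom", "start", "end")])
  S4Vectors::mcols(gr)$score <- df2$value
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' Bundles the parameter blocks of every stage.  Unknown keys are rejected so
#' typos cannot silently fall back to defaults.
#'
#' @param detector [detector_params()] block.
#' @param cluster [cluster_params()] block.
#' @param profile [profile_params()] block.
#' @param top_n Number of top families to report (ranked by total bases).
#' @param max_groups Number of largest groups (by instance count) for which
#'   metrics are computed before ranking by total bases.
#' @param seed Integer seed used by any randomized stage.
#' @param ... Unknown keys, rejected with an error.
#' @return A `satfam_config` list.
#' @export
satfam_config <- function(detector = detector_params(),
                          cluster = cluster_params(),
                          profile = profile_params(),
                          top_n = 3L, max_groups = 20L, seed = 1L, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration keys: ", paste(names(extra), collapse = ", "))
  stopifnot(top_n >= 1L, max_groups >= 1L)
  structure(list(detector = detector, cluster = cluster, profile = profile,
                 top_n = as.integer(top_n), max_groups = as.integer(max_groups),
                 seed = as.integer(seed)),
            class = "satfam_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The round trip `read_config(write_config(cfg, f))` reproduces `cfg`.
#'
#' @param cfg A [satfam_config()].
#' @param path YAML file.
#' @return `read_config` returns a `satfam_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "satfam_config"))
  yaml::write_yaml(unclass(lapply(cfg, function(x)
    if (is.list(x)) unclass(x) else x)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("detector", "cluster", "profile", "top_n", "max_groups", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- satfam_config()
  for (blk in c("detector", "cluster", "profile")) {
    if (!is.null(raw[[blk]])) {
      unknown <- setdiff(names(raw[[blk]]), names(cfg[[blk]]))
      if (length(unknown))
        stop("unknown keys in '", blk, "': ", paste(unknown, collapse = ", "))
      cfg[[blk]] <- modifyList(cfg[[blk]], raw[[blk]])
    }
  }
  for (k in c("top_n", "max_groups", "seed"))
    if (!is.null(raw[[k]])) cfg[[k]] <- as.integer(raw[[k]])
  cfg
}
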