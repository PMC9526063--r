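#' Specify a synthetic satellite family
#'
#' Describes one satellite family to be planted by [build_genome()]: its
#' monomer, how diverged the planted copies are, and whether its arrays are
#' scattered across chromosomes (`"dispersed"`, the holocentric-like pattern)
#' or concentrated in one dominant array per chromosome (`"localized"`, the
#' monocentric-like pattern).
#'
#' @param family_id Character label, e.g. `"FAM1"`.
#' @param monomer Monomer sequence over A/C/G/T; its length is the family's
#'   base period in bp.
#' @param spatial_mode `"dispersed"` (many small arrays per chromosome) or
#'   `"localized"` (one dominant array per chromosome plus sporadic small
#'   arrays).
#' @param n_arrays_per_chromosome Number of small arrays planted per
#'   chromosome (for `"localized"` mode these are the sporadic arrays planted
#'   in addition to the dominant one).
#' @param copies_min,copies_max Range of monomer copies per small array
#'   (uniform integer draw); both must be >= 2.
#' @param substitution_rate Per-base probability that a planted base is
#'   substituted (to a uniformly chosen different base); in `[0, 0.25]`.
#' @param indel_rate Per-base probability of a single-base indel (split
#'   evenly between insertion and deletion); in `[0, 0.25]`.
#' @param hor_block Optional character vector of monomer variants; planted
#'   copies cycle through the variants in order, producing a higher-order
#'   repeat whose fundamental period is `length(hor_block) * period`.
#' @param revcomp_fraction Fraction of arrays planted on the reverse strand.
#' @param dominant_copies Copies in the dominant array of a `"localized"`
#'   family (ignored for `"dispersed"`).
#' @return A `satfam_family_spec` list.
#' @seealso [sim_spec()], [build_genome()]
#' @export
family_spec <- function(family_id, monomer,
                        spatial_mode = c("dispersed", "localized"),
                        n_arrays_per_chromosome = 20L,
                        copies_min = 20L, copies_max = 60L,
                        substitution_rate = 0.02, indel_rate = 0,
                        hor_block = NULL, revcomp_fraction = 0.2,
                        dominant_copies = NULL) {
  spatial_mode <- match.arg(spatial_mode)
  monomer <- toupper(as.character(monomer))
  stopifnot(is.character(family_id), length(family_id) == 1L)
  if (nchar(monomer) == 0L || grepl("[^ACGT]", monomer))
    stop("monomer must be a non-empty string over A/C/G/T")
  if (substitution_rate < 0 || substitution_rate > 0.25 ||
      indel_rate < 0 || indel_rate > 0.25)
    stop("mutation rates must lie in [0, 0.25]")
  if (copies_min < 2L || copies_max < copies_min)
    stop("copies_min must be >= 2 and copies_max >= copies_min")
  if (!is.null(hor_block)) {
    hor_block <- toupper(as.character(hor_block))
    if (any(nchar(hor_block) == 0L) || any(grepl("[^ACGT]", hor_block)))
      stop("hor_block variants must be non-empty strings over A/C/G/T")
  }
  if (spatial_mode == "localized" && is.null(dominant_copies))
    dominant_copies <- 300L
  structure(list(
    family_id = family_id, monomer = monomer, spatial_mode = spatial_mode,
    n_arrays_per_chromosome = as.integer(n_arrays_per_chromosome),
    copies_min = as.integer(copies_min), copies_max = as.integer(copies_max),
    substitution_rate = substitution_rate, indel_rate = indel_rate,
    hor_block = hor_block, revcomp_fraction = revcomp_fraction,
    dominant_copies = if (is.null(dominant_copies)) NULL
                      else as.integer(dominant_copies)
  ), class = "satfam_family_spec")
}

#' Specify a synthetic genome
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of every chromosome in bp.
#' @param background_gc GC fraction of the background sequence.
#' @param families List of [family_spec()] objects.
#' @param decoy_count,decoy_length Number and length of interspersed
#'   *identical, non-tandem* copies of one random sequence — a transposon-like
#'   negative control that the tandem detector must not report.
#' @param seed Integer seed; fully determines the genome and manifest.
#' @return A `satfam_sim_spec` list.
#' @export
sim_spec <- function(n_chromosomes = 4L, chromosome_length = 5e5,
                     background_gc = 0.37, families = list(),
                     decoy_count = 0L, decoy_length = 500L, seed = 1L) {
  stopifnot(n_chromosomes >= 1L, chromosome_length >= 0,
            background_gc >= 0, background_gc <= 1)
  if (length(families) && !all(vapply(families, inherits, logical(1),
                                      "satfam_family_spec")))
    stop("families must be a list of family_spec() objects")
  planted <- 0
  for (f in families) {
    per_chrom <- f$n_arrays_per_chromosome * f$copies_max * nchar(f$monomer)
    if (f$spatial_mode == "localized")
      per_chrom <- per_chrom + f$dominant_copies * nchar(f$monomer)
    planted <- planted + per_chrom * n_chromosomes
  }
  total <- chromosome_length * n_chromosomes
  if (planted + decoy_count * decoy_length >= total)
    stop("total planted bases (", planted, ") must be smaller than the ",
         "genome (", total, ")")
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    background_gc = background_gc, families = families,
    decoy_count = as.integer(decoy_count),
    decoy_length = as.integer(decoy_length), seed = as.integer(seed)
  ), class = "satfam_sim_spec")
}

#' Generate random background sequence
#'
#' Bases are drawn independently with `P(G) + P(C) = gc`, split evenly within
#' the GC and AT pairs.
#'
#' @param length Sequence length in bp (>= 0).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return A nucleotide string of exactly `length` bases.
#' @export
generate_background <- function(length, gc, seed = NULL) {
  if (length < 0) stop("length must be non-negative")
  stopifnot(gc >= 0, gc <= 1)
  if (length == 0) return("")
  with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
  })
}

# integer-code mutation core; returns sequence plus realized event counts
.mutate_codes <- function(codes, substitution_rate, indel_rate) {
  n <- length(codes)
  if (n == 0L)
    return(list(codes = codes, n_sub = 0L, n_ins = 0L, n_del = 0L))
  del <- runif(n) < indel_rate / 2
  ins <- runif(n) < indel_rate / 2
  sub <- runif(n) < substitution_rate & !del
  if (any(sub))
    codes[sub] <- ((codes[sub] - 1L +
                    sample.int(3L, sum(sub), replace = TRUE)) %% 4L) + 1L
  insbase <- rep(NA_integer_, n)
  if (any(ins)) insbase[ins] <- sample.int(4L, sum(ins), replace = TRUE)
  m <- rbind(ifelse(del, NA_integer_, codes), insbase)
  out <- m[!is.na(m)]
  list(codes = as.integer(out), n_sub = sum(sub), n_ins = sum(ins),
       n_del = sum(del))
}

.str_to_codes <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], BASES)
}
.codes_to_str <- function(codes) paste(BASES[codes], collapse = "")

#' Mutate a sequence with independent substitutions and single-base indels
#'
#' Each base is substituted with probability `substitution_rate` (to a
#' uniformly chosen different base).  Single-base indels occur at per-base
#' rate `indel_rate`, split evenly between deletions and insertions.
#'
#' @param seq Nucleotide string.
#' @param substitution_rate,indel_rate Per-base rates in `[0, 0.25]`.
#' @param seed Optional integer seed.
#' @return The mutated nucleotide string.
#' @export
mutate_sequence <- function(seq, substitution_rate, indel_rate, seed = NULL) {
  if (substitution_rate < 0 || substitution_rate > 0.25 ||
      indel_rate < 0 || indel_rate > 0.25)
    stop("mutation rates must lie in [0, 0.25]")
  if (nchar(seq) == 0L) return("")
  with_seed(seed, {
    r <- .mutate_codes(.str_to_codes(seq), substitution_rate, indel_rate)
    .codes_to_str(r$codes)
  })
}

# plant one array; returns list(seq, divergence)
.plant_array <- function(monomer, copies, fam) {
  variants <- fam$hor_block %||% monomer
  n_var <- length(variants)
  pieces <- character(copies)
  muts <- 0L
  total <- 0L
  for (i in seq_len(copies)) {
    tpl <- .str_to_codes(variants[((i - 1L) %% n_var) + 1L])
    r <- .mutate_codes(tpl, fam$substitution_rate, fam$indel_rate)
    pieces[i] <- .codes_to_str(r$codes)
    muts <- muts + r$n_sub + r$n_ins + r$n_del
    total <- total + length(tpl)
  }
  list(seq = paste(pieces, collapse = ""),
       divergence = if (total > 0) muts / total else 0)
}

#' Build one tandem array sequence
#'
#' Concatenates `copies` (possibly mutated, possibly HOR-structured) copies
#' of the monomer.  With zero mutation rates and no `hor_block` the result is
#' the monomer repeated exactly `copies` times.
#'
#' @param monomer Monomer sequence (ignored as template when the family spec
#'   carries an `hor_block`, which then supplies the cycled variants).
#' @param copies Number of monomer copies (>= 2).
#' @param fam A [family_spec()] providing mutation rates and HOR structure.
#' @param seed Optional integer seed.
#' @return The array nucleotide string.
#' @export
plant_array <- function(monomer, copies, fam, seed = NULL) {
  stopifnot(inherits(fam, "satfam_family_spec"))
  if (copies < 2) stop("a tandem array needs at least 2 copies")
  with_seed(seed, .plant_array(monomer, as.integer(copies), fam)$seq)
}

#' Build a synthetic genome with planted satellite arrays
#'
#' Generates background chromosomes at the specified GC, plants every
#' family's arrays by non-overlapping rejection sampling (arrays replace the
#' background in place, never span chromosome ends, retry cap 1000 per
#' array), plants decoy repeats, and records every planted array in a truth
#' manifest with 0-based half-open coordinates.
#'
#' @param spec A [sim_spec()].
#' @return A `satfam_genome` list with elements `assembly` (a
#'   [Biostrings::DNAStringSet]), `manifest` (data.frame: chrom, start, end,
#'   family_id, strand, copies, divergence), `decoys` and `spec`.  The same
#'   spec (including its seed) always reproduces a byte-identical genome.
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "satfam_sim_spec"))
  with_seed(spec$seed, {
    L <- spec$chromosome_length
    chrom_names <- paste0("chr", seq_len(spec$n_chromosomes))
    chroms <- lapply(seq_len(spec$n_chromosomes), function(i)
      generate_background(L, spec$background_gc))
    names(chroms) <- chrom_names
    occupied <- lapply(chrom_names, function(x)
      data.frame(start = integer(0), end = integer(0)))
    names(occupied) <- chrom_names

    place <- function(chrom, len) {
      occ <- occupied[[chrom]]
      if (len > L) stop("array longer than chromosome on ", chrom)
      for (try in seq_len(1000L)) {
        s <- floor(runif(1, 0, L - len + 1))
        if (!any(s < occ$end & (s + len) > occ$start)) return(s)
      }
      stop("placement failed after 1000 retries on ", chrom,
           ": genome too crowded")
    }

    rows <- list()
    add_array <- function(chrom, fam, copies) {
      arr <- .plant_array(fam$monomer, copies, fam)
      strand <- if (runif(1) < fam$revcomp_fraction) "-" else "+"
      s <- arr$seq
      if (strand == "-") s <- revcomp(s)
      len <- nchar(s)
      start <- place(chrom, len)
      substr(chroms[[chrom]], start + 1L, start + len) <<- s
      occupied[[chrom]] <<- rbind(occupied[[chrom]],
                                  data.frame(start = start, end = start + len))
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = chrom, start = start, end = start + len,
        family_id = fam$family_id, strand = strand, copies = copies,
        divergence = arr$divergence, stringsAsFactors = FALSE)
    }

    for (fam in spec$families) {
      for (chrom in chrom_names) {
        if (fam$spatial_mode == "localized")
          add_array(chrom, fam, fam$dominant_copies)
        for (i in seq_len(fam$n_arrays_per_chromosome)) {
          copies <- fam$copies_min +
            sample.int(fam$copies_max - fam$copies_min + 1L, 1L) - 1L
          add_array(chrom, fam, copies)
        }
      }
    }

    decoys <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0))
    if (spec$decoy_count > 0L) {
      master <- generate_background(spec$decoy_length, spec$background_gc)
      drows <- list()
      for (i in seq_len(spec$decoy_count)) {
        chrom <- chrom_names[((i - 1L) %% spec$n_chromosomes) + 1L]
        start <- place(chrom, spec$decoy_length)
        substr(chroms[[chrom]], start + 1L, start + spec$decoy_length) <- master
        occupied[[chrom]] <- rbind(occupied[[chrom]],
          data.frame(start = start, end = start + spec$decoy_length))
        drows[[i]] <- data.frame(chrom = chrom, start = start,
                                 end = start + spec$decoy_length)
      }
      decoys <- do.call(rbind, drows)
    }

    manifest <- if (length(rows)) do.call(rbind, rows) else data.frame(
      chrom = character(0), start = integer(0), end = integer(0),
      family_id = character(0), strand = character(0), copies = integer(0),
      divergence = numeric(0), stringsAsFactors = FALSE)
    manifest <- manifest[order(manifest$chrom, manifest$start), , drop = FALSE]
    rownames(manifest) <- NULL

    assembly <- Biostrings::DNAStringSet(unlist(chroms))
    structure(list(assembly = assembly, manifest = manifest, decoys = decoys,
                   spec = spec),
              class = "satfam_genome")
  })
}

#' @export
print.satfam_genome <- function(x, ...) {
  cat("satfam synthetic genome:", length(x$assembly), "chromosomes,",
      sum(Biostrings::width(x$assembly)), "bp total\n")
  cat("  planted arrays:", nrow(x$manifest), "in",
      length(unique(x$manifest$family_id)), "families;",
      sum(x$manifest$end - x$manifest$start), "satellite bp\n")
  invisible(x)
}

#' Read a synthetic-genome specification from YAML
#'
#' The file carries the [sim_spec()] fields at top level and a `families`
#' list whose entries carry [family_spec()] fields.
#'
#' @param path YAML file.
#' @param seed Optional override of the file's seed.
#' @return A `satfam_sim_spec`.
#' @export
read_sim_spec <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  fams <- lapply(raw$families, function(f) do.call(family_spec, f))
  raw$families <- NULL
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  do.call(sim_spec, c(raw, list(families = fams)))
}

#' Write a synthetic genome to disk
#'
#' Writes `<prefix>.fa` (60-column FASTA), `<prefix>.manifest.gff3`
#' (source `satfam-sim`, type `satellite_array`, attributes `Family=` and
#' `Copies=`) and a flat `<prefix>.manifest.tsv` twin.
#'
#' @param genome A `satfam_genome` from [build_genome()].
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(genome, prefix) {
  stopifnot(inherits(genome, "satfam_genome"))
  fa <- paste0(prefix, ".fa")
  Biostrings::writeXStringSet(genome$assembly, fa, width = 60L)
  gff <- paste0(prefix, ".manifest.gff3")
  m <- genome$manifest
  write_gff3(data.frame(chrom = m$chrom, start = m$start, end = m$end,
                        strand = m$strand, Family = m$family_id,
                        Copies = m$copies, stringsAsFactors = FALSE),
             gff, source = "satfam-sim", type = "satellite_array")
  tsv <- paste0(prefix, ".manifest.tsv")
  write.table(m, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, gff, tsv))
}
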