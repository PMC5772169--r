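# On-disk formats. Every coordinate in this package is 0-based half-open
# (BED semantics); readers and writers never change convention.

#' Genome index
#'
#' A minimal sequence dictionary: ordered chromosome names and lengths.
#' Used to validate coordinates and to clip windows at chromosome ends.
#'
#' @param chrom_names character vector of unique chromosome names.
#' @param chrom_lengths integer vector of lengths in base pairs (> 0), same
#'   length as `chrom_names`.
#' @return an object of class `genome_index` with fields `chrom_names` and
#'   a named `chrom_lengths` vector.
#' @examples
#' genome_index(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_index <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths)) {
    .stop("chrom_names and chrom_lengths differ in length")
  }
  if (anyDuplicated(chrom_names)) .stop("chromosome names must be unique")
  if (any(chrom_lengths <= 0)) .stop("chromosome lengths must be > 0")
  names(chrom_lengths) <- chrom_names
  structure(list(chrom_names = chrom_names, chrom_lengths = chrom_lengths),
            class = "genome_index")
}

#' Build a genome index from a set of sequences
#'
#' @param seqs a named [Biostrings::DNAStringSet].
#' @return a [genome_index()].
#' @export
genome_index_from_seqs <- function(seqs) {
  genome_index(names(seqs), Biostrings::width(seqs))
}

.split_fields <- function(lines) {
  strsplit(trimws(lines, which = "right"), "[ \t]+")
}

.int_field <- function(fields, col, path, keep) {
  x <- suppressWarnings(as.integer(vapply(fields, `[`, "", col)))
  bad <- which(is.na(x))
  if (length(bad)) {
    .stop(sprintf("malformed row at line %d of '%s': column %d is not an integer",
                  keep[bad[1L]], path, col))
  }
  x
}

#' Read peak summits from a BED-like file
#'
#' Accepts 3+ column tab- or space-separated files. A row wider than one
#' base (`end - start > 1`) is reduced to its midpoint,
#' `floor((start + end) / 2)`; a single-base row keeps its start as the
#' summit. This accommodates both true summit files (1 bp intervals) and
#' whole-peak intervals.
#'
#' @param path file path.
#' @param sample_id label recorded for every summit in this file.
#' @param genome optional [genome_index()]; if supplied, unknown
#'   chromosomes and out-of-range positions are errors.
#' @return data frame with columns `chrom`, `pos` (0-based), `sample_id`.
#' @export
read_summits <- function(path, sample_id, genome = NULL) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !grepl("^(#|track|browser)", lines))
  if (!length(keep)) {
    return(data.frame(chrom = character(), pos = integer(),
                      sample_id = character()))
  }
  fields <- .split_fields(lines[keep])
  n <- lengths(fields)
  if (any(n < 3L)) {
    .stop(sprintf("malformed row at line %d of '%s': fewer than 3 columns",
                  keep[which(n < 3L)[1L]], path))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- .int_field(fields, 2L, path, keep)
  end <- .int_field(fields, 3L, path, keep)
  bad <- which(start >= end)
  if (length(bad)) {
    .stop(sprintf("malformed row at line %d of '%s': start >= end",
                  keep[bad[1L]], path))
  }
  pos <- ifelse(end - start > 1L, as.integer(floor((start + end) / 2)), start)
  if (!is.null(genome)) {
    .check_chroms(chrom, genome)
    if (any(pos >= genome$chrom_lengths[chrom] | pos < 0L)) {
      .stop("summit position outside chromosome in '", path, "'")
    }
  }
  data.frame(chrom = chrom, pos = pos, sample_id = sample_id)
}

#' Read BED3/BED6 intervals
#'
#' @param path file path.
#' @param genome optional [genome_index()] for validation.
#' @return data frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !grepl("^(#|track|browser)", lines))
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (!length(keep)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer())
    return(out)
  }
  fields <- .split_fields(lines[keep])
  n <- min(lengths(fields), 6L)
  if (any(lengths(fields) < 3L)) {
    .stop(sprintf("malformed row at line %d of '%s': fewer than 3 columns",
                  keep[which(lengths(fields) < 3L)[1L]], path))
  }
  out <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                    start = .int_field(fields, 2L, path, keep),
                    end = .int_field(fields, 3L, path, keep))
  if (n >= 4L) out$name <- vapply(fields, `[`, "", 4L)
  if (n >= 5L) out$score <- suppressWarnings(
    as.numeric(vapply(fields, `[`, "", 5L)))
  if (n >= 6L) out$strand <- vapply(fields, `[`, "", 6L)
  .check_intervals(out, "BED interval", genome)
  out
}

#' Read ENCODE narrowPeak intervals
#'
#' Ten-column narrowPeak. When column 10 (summit offset from `start`) is
#' present and non-negative it defines the summit; `-1` falls back to the
#' interval midpoint, matching MACS2 conventions.
#'
#' @inheritParams read_bed
#' @return data frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal`, `pvalue`, `qvalue`, `summit` (absolute 0-based
#'   position).
#' @export
read_narrowpeak <- function(path, genome = NULL) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !grepl("^(#|track|browser)", lines))
  if (!length(keep)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      strand = character(), signal = numeric(),
                      pvalue = numeric(), qvalue = numeric(),
                      summit = integer()))
  }
  fields <- .split_fields(lines[keep])
  if (any(lengths(fields) < 10L)) {
    .stop(sprintf("malformed row at line %d of '%s': narrowPeak needs 10 columns",
                  keep[which(lengths(fields) < 10L)[1L]], path))
  }
  num <- function(col) suppressWarnings(
    as.numeric(vapply(fields, `[`, "", col)))
  out <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                    start = .int_field(fields, 2L, path, keep),
                    end = .int_field(fields, 3L, path, keep),
                    name = vapply(fields, `[`, "", 4L),
                    score = num(5L),
                    strand = vapply(fields, `[`, "", 6L),
                    signal = num(7L), pvalue = num(8L), qvalue = num(9L))
  offset <- .int_field(fields, 10L, path, keep)
  out$summit <- ifelse(offset >= 0L, out$start + offset,
                       as.integer(floor((out$start + out$end) / 2)))
  .check_intervals(out, "narrowPeak interval", genome)
  out
}

#' Write intervals as BED
#'
#' Emits the columns present in `x` (up to BED6), 0-based half-open, so
#' that `read_bed(write_intervals(...))` round-trips losslessly.
#'
#' @param path output file path.
#' @param x data frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(path, x) {
  .check_intervals(x, "interval")
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED columns are positional: keep the longest unbroken prefix.
  want <- c("chrom", "start", "end", "name", "score", "strand")
  take <- want[seq_len(max(which(want %in% cols)))]
  out <- x[, intersect(take, cols), drop = FALSE]
  for (miss in setdiff(take, cols)) {
    out[[miss]] <- if (miss == "score") 0 else "."
  }
  out <- out[, take[seq_len(length(take))], drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedgraph coverage track
#'
#' @param path file path.
#' @return data frame `chrom`, `start`, `end`, `value` (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !grepl("^(#|track|browser)", lines))
  if (!length(keep)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  }
  fields <- .split_fields(lines[keep])
  if (any(lengths(fields) < 4L)) {
    .stop(sprintf("malformed row at line %d of '%s': bedgraph needs 4 columns",
                  keep[which(lengths(fields) < 4L)[1L]], path))
  }
  out <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                    start = .int_field(fields, 2L, path, keep),
                    end = .int_field(fields, 3L, path, keep),
                    value = suppressWarnings(
                      as.numeric(vapply(fields, `[`, "", 4L))))
  if (anyNA(out$value)) .stop("non-numeric coverage value in '", path, "'")
  .check_intervals(out, "bedgraph record")
  out
}

#' Write a bedgraph coverage track
#'
#' @param path output path.
#' @param track data frame `chrom`, `start`, `end`, `value`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(path, track) {
  utils::write.table(track[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

.check_track_disjoint <- function(track) {
  if (nrow(track) < 2L) return(invisible(TRUE))
  o <- order(track$chrom, track$start)
  same <- track$chrom[o][-1L] == track$chrom[o][-nrow(track)]
  clash <- same & (track$start[o][-1L] < track$end[o][-nrow(track)])
  if (any(clash)) {
    .stop("bedgraph track has overlapping records; coverage is ambiguous")
  }
  invisible(TRUE)
}

#' Overlap-weighted mean coverage of regions over a bedgraph track
#'
#' Uncovered bases count as zero, so the mean is the integral of the track
#' over the region divided by the region width.
#'
#' @param track data frame as returned by [read_bedgraph()]; records must
#'   not overlap.
#' @param regions data frame of intervals (`chrom`, `start`, `end`).
#' @return numeric vector of per-region means, in `regions` order.
#' @examples
#' track <- data.frame(chrom = "chr1", start = 0L, end = 50L, value = 2)
#' bedgraph_coverage(track, data.frame(chrom = "chr1", start = 0L, end = 100L))
#' @export
bedgraph_coverage <- function(track, regions) {
  .check_intervals(regions, "region")
  .check_track_disjoint(track)
  out <- numeric(nrow(regions))
  if (nrow(track) == 0L || nrow(regions) == 0L) return(out)
  gr_t <- .as_granges(track)
  gr_r <- .as_granges(regions)
  ov <- GenomicRanges::findOverlaps(gr_r, gr_t)
  if (length(ov)) {
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr_r)[qi], IRanges::ranges(gr_t)[si]))
    contrib <- w * track$value[si]
    sums <- tapply(contrib, qi, sum)
    out[as.integer(names(sums))] <- as.numeric(sums)
  }
  out / (regions$end - regions$start)
}

#' Read coverage for regions straight from a bedgraph file
#'
#' @inheritParams bedgraph_coverage
#' @param path bedgraph file path.
#' @return numeric vector of per-region overlap-weighted means.
#' @export
read_bedgraph_coverage <- function(path, regions) {
  bedgraph_coverage(read_bedgraph(path), regions)
}

#' Position weight matrix constructor
#'
#' Log-odds scores, one row per motif position, columns A, C, G, T.
#' Probability matrices are not accepted: conversion to log-odds is the
#' caller's responsibility, which keeps threshold semantics (score >= 6)
#' unambiguous.
#'
#' @param scores numeric matrix, width x 4.
#' @return object of class `pwm`: the score matrix with columns
#'   `A`, `C`, `G`, `T`.
#' @export
pwm <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 4L) .stop("a PWM needs exactly 4 columns (A, C, G, T)")
  if (nrow(scores) < 1L) .stop("a PWM needs at least one position")
  if (!all(is.finite(scores))) .stop("PWM scores must be finite")
  colnames(scores) <- c("A", "C", "G", "T")
  structure(scores, class = c("pwm", "matrix"))
}

#' Read a plain-text PWM
#'
#' Format: one header line naming the base order (`A C G T`), then
#' `width` rows of 4 whitespace-separated log-odds values.
#'
#' @param path file path.
#' @return a [pwm()].
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) .stop("PWM file '", path, "' has no score rows")
  hdr <- toupper(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]])
  if (!identical(hdr, c("A", "C", "G", "T"))) {
    .stop("PWM file '", path, "' must start with a header line 'A C G T'")
  }
  rows <- .split_fields(lines[-1L])
  bad <- which(lengths(rows) != 4L)
  if (length(bad)) {
    .stop(sprintf("PWM row %d of '%s' has %d values, expected 4",
                  bad[1L], path, lengths(rows)[bad[1L]]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))),
              ncol = 4L, byrow = TRUE)
  if (anyNA(m)) .stop("non-numeric PWM score in '", path, "'")
  pwm(m)
}

#' Write a PWM in the package's plain-text dialect
#'
#' @param path output path.
#' @param x a [pwm()].
#' @return `path`, invisibly.
#' @export
write_pwm <- function(path, x) {
  stopifnot(inherits(x, "pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("A C G T", con)
  utils::write.table(unclass(x), con, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.parse_sample_names <- function(nm) {
  parts <- strsplit(nm, "_", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    .stop("sample columns must be named genotype_treatment_time_rep; got: ",
          paste(nm[lengths(parts) != 4L], collapse = ", "))
  }
  time <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  if (anyNA(time)) .stop("sample time field is not numeric")
  data.frame(sample = nm,
             genotype = vapply(parts, `[`, "", 1L),
             treatment = vapply(parts, `[`, "", 2L),
             time = time,
             replicate = vapply(parts, `[`, "", 4L))
}

#' Expression table constructor
#'
#' @param fpkm numeric matrix, genes x samples, FPKM values (>= 0); column
#'   names follow `genotype_treatment_time_rep`.
#' @return object of class `expression_table` with fields `fpkm` (matrix)
#'   and `samples` (parsed design data frame).
#' @export
expression_table <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  if (is.null(rownames(fpkm))) .stop("expression matrix needs gene ids as rownames")
  if (is.null(colnames(fpkm))) .stop("expression matrix needs sample column names")
  if (any(fpkm < 0)) .stop("FPKM values must be >= 0")
  structure(list(fpkm = fpkm, samples = .parse_sample_names(colnames(fpkm))),
            class = "expression_table")
}

#' Read a tab-separated expression table
#'
#' Header row: `gene_id` then one column per sample, named
#' `genotype_treatment_time_rep` (for example `WT_IL4_6_2`).
#'
#' @param path file path.
#' @return an [expression_table()].
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "gene_id") {
    .stop("first column of '", path, "' must be 'gene_id'")
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$gene_id
  expression_table(m)
}

#' Write an expression table
#'
#' @param path output path.
#' @param x an [expression_table()] (or bare FPKM matrix with dimnames).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(path, x) {
  m <- if (inherits(x, "expression_table")) x$fpkm else as.matrix(x)
  out <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file path.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a genome FASTA
#'
#' @param path output path.
#' @param seqs named [Biostrings::DNAStringSet] or named character vector.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(path, seqs) {
  if (!inherits(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a region count table with its design
#'
#' `counts_path`: TSV with columns `region_id`, `length`, then one column
#' of raw counts per sample. `design_path`: TSV with columns `sample`,
#' `condition`, `library_size`.
#'
#' @param counts_path,design_path file paths.
#' @return a [replicate_counts()] object.
#' @export
read_counts_table <- function(counts_path, design_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE)
  des <- utils::read.delim(design_path, check.names = FALSE)
  need <- c("sample", "condition", "library_size")
  if (!all(need %in% names(des))) {
    .stop("design table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("region_id", "length") %in% names(tab))) {
    .stop("counts table needs columns region_id and length")
  }
  m <- as.matrix(tab[, as.character(des$sample), drop = FALSE])
  rownames(m) <- tab$region_id
  replicate_counts(m, condition = des$condition,
                   region_lengths = tab$length,
                   library_sizes = des$library_size)
}

#' Write a region count table and its design
#'
#' @param counts_path,design_path output paths.
#' @param rc a [replicate_counts()] object.
#' @return `counts_path`, invisibly.
#' @export
write_counts_table <- function(counts_path, design_path, rc) {
  stopifnot(inherits(rc, "replicate_counts"))
  out <- data.frame(region_id = rc$region_ids, length = rc$region_lengths,
                    rc$counts, check.names = FALSE)
  utils::write.table(out, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  des <- data.frame(sample = colnames(rc$counts),
                    condition = as.character(rc$condition),
                    library_size = rc$library_sizes)
  utils::write.table(des, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}
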