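# Consensus summit merging and insulator calling.
#
# An insulator is a CTCF consensus summit with a Cohesin consensus summit
# closer than 51 bp; its coverage is quantified on the 100 bp window around
# the CTCF position.

#' Merge per-sample summits into consensus summits
#'
#' Per chromosome, summits are sorted and chained by single linkage:
#' consecutive summits closer than `window_bp` belong to one cluster. A
#' cluster with at least `min_support` members emits a consensus summit at
#' the round-half-up mean of its member positions; smaller clusters emit
#' nothing. The result is independent of input ordering.
#'
#' @param summits data frame with `chrom`, `pos` (and optionally
#'   `sample_id`), e.g. from [read_summits()] over many samples.
#' @param window_bp chaining window; adjacent summits at distance
#'   `< window_bp` are linked (default 51).
#' @param min_support minimum cluster size to emit a consensus (default 2).
#' @param protein optional label stored in the output.
#' @return data frame `chrom`, `pos`, `support` (and `protein` if given),
#'   sorted by chromosome and position.
#' @examples
#' s <- data.frame(chrom = "chr1", pos = c(1000L, 1040L, 5000L))
#' consensus_summits(s)  # one consensus at 1020, support 2
#' @export
consensus_summits <- function(summits, window_bp = 51L, min_support = 2L,
                              protein = NULL) {
  stopifnot(window_bp > 0)
  empty <- data.frame(chrom = character(), pos = numeric(),
                      support = integer())
  if (!is.null(protein)) empty$protein <- character()
  if (nrow(summits) == 0L) return(empty)
  o <- order(summits$chrom, summits$pos)
  chrom <- as.character(summits$chrom)[o]
  pos <- summits$pos[o]
  new_cluster <- c(TRUE, chrom[-1L] != chrom[-length(chrom)] |
                     diff(pos) >= window_bp)
  cl <- cumsum(new_cluster)
  support <- tabulate(cl)
  mean_pos <- rowsum(pos, cl)[, 1L] / support  # rowsum sorts numeric groups
  first <- !duplicated(cl)
  out <- data.frame(chrom = chrom[first],
                    pos = round_half_up(mean_pos),
                    support = support)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(protein)) out$protein <- protein
  out
}

#' Call insulators from CTCF and Cohesin consensus summits
#'
#' For every CTCF consensus summit the nearest Cohesin consensus summit on
#' the same chromosome is found (equidistant neighbours resolve to the
#' lower coordinate); the pair becomes an insulator when the distance is
#' strictly below `window_bp`. The insulator position is the CTCF position
#' and its orientation starts out unknown.
#'
#' @param ctcf,cohesin consensus summit data frames from
#'   [consensus_summits()].
#' @param window_bp maximum CTCF-Cohesin distance, exclusive (default 51).
#' @return data frame `chrom`, `pos`, `cohesin_pos`, `ctcf_rpkm`,
#'   `cohesin_rpkm` (NA until quantified), `orientation`
#'   (`"unknown"`), `orientation_source` (`"none"`), `motif_score` (NA).
#' @export
call_insulators <- function(ctcf, cohesin, window_bp = 51L) {
  empty <- data.frame(chrom = character(), pos = numeric(),
                      cohesin_pos = numeric(), ctcf_rpkm = numeric(),
                      cohesin_rpkm = numeric(), orientation = character(),
                      orientation_source = character(),
                      motif_score = numeric())
  if (nrow(ctcf) == 0L || nrow(cohesin) == 0L) return(empty)
  res <- lapply(split(seq_len(nrow(ctcf)), ctcf$chrom), function(idx) {
    chrom <- as.character(ctcf$chrom[idx[1L]])
    coh <- sort(cohesin$pos[cohesin$chrom == chrom])
    if (!length(coh)) return(NULL)
    p <- ctcf$pos[idx]
    k <- findInterval(p, coh)
    left <- ifelse(k >= 1L, coh[pmax(k, 1L)], NA_real_)
    right <- ifelse(k < length(coh), coh[pmin(k + 1L, length(coh))], NA_real_)
    dl <- abs(p - left)
    dr <- abs(right - p)
    # ties break toward the lower coordinate (the left neighbour)
    use_left <- !is.na(dl) & (is.na(dr) | dl <= dr)
    partner <- ifelse(use_left, left, right)
    dist <- ifelse(use_left, dl, dr)
    ok <- !is.na(dist) & dist < window_bp
    if (!any(ok)) return(NULL)
    data.frame(chrom = chrom, pos = p[ok], cohesin_pos = partner[ok])
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0L) return(empty)
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  stopifnot(all(abs(res$pos - res$cohesin_pos) < window_bp))
  res$ctcf_rpkm <- NA_real_
  res$cohesin_rpkm <- NA_real_
  res$orientation <- "unknown"
  res$orientation_source <- "none"
  res$motif_score <- NA_real_
  res
}

#' Quantify insulator coverage from bedgraph tracks
#'
#' Mean coverage of each protein on the `2 * flank_bp` window centred on
#' the insulator (CTCF) position, `[pos - flank_bp, pos + flank_bp)`.
#' Windows are clipped at chromosome boundaries with a warning; the
#' divisor stays the clipped width. Tracks are expected to already carry
#' the producer's normalisation (RPKM).
#'
#' @param insulators data frame from [call_insulators()].
#' @param ctcf_track,cohesin_track bedgraph data frames
#'   ([read_bedgraph()]); missing bases count as zero coverage.
#' @param flank_bp half-window in bp (default 50, i.e. a 100 bp window).
#' @param genome optional [genome_index()] used for right-end clipping.
#' @return `insulators` with `ctcf_rpkm` and `cohesin_rpkm` filled in.
#' @export
quantify_insulators <- function(insulators, ctcf_track, cohesin_track,
                                flank_bp = 50L, genome = NULL) {
  if (nrow(insulators) == 0L) return(insulators)
  win <- data.frame(chrom = insulators$chrom,
                    start = insulators$pos - flank_bp,
                    end = insulators$pos + flank_bp)
  clipped <- win$start < 0
  win$start <- pmax(win$start, 0)
  if (!is.null(genome)) {
    .check_chroms(win$chrom, genome)
    len <- genome$chrom_lengths[as.character(win$chrom)]
    clipped <- clipped | win$end > len
    win$end <- pmin(win$end, len)
  }
  if (any(clipped)) {
    warning(sum(clipped), " insulator window(s) clipped at chromosome ends",
            call. = FALSE)
  }
  insulators$ctcf_rpkm <- bedgraph_coverage(ctcf_track, win)
  insulators$cohesin_rpkm <- bedgraph_coverage(cohesin_track, win)
  insulators
}

#' Write / read the insulator table
#'
#' Tab-separated with a fixed header: `chrom`, `pos`, `cohesin_pos`,
#' `ctcf_rpkm`, `cohesin_rpkm`, `orientation`, `orientation_source`,
#' `motif_score`.
#'
#' @param path file path.
#' @param insulators insulator data frame.
#' @return `path` (writer) or the insulator data frame (reader).
#' @export
write_insulators <- function(path, insulators) {
  cols <- c("chrom", "pos", "cohesin_pos", "ctcf_rpkm", "cohesin_rpkm",
            "orientation", "orientation_source", "motif_score")
  utils::write.table(insulators[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_insulators
#' @export
read_insulators <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
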