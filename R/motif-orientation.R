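# PWM scanning and insulator orientation.
#
# Orientation drives domain calling: a convergent pair is a forward
# insulator upstream of a reverse insulator. The motif is looked for in a
# window around the insulator; when several hits compete, direction
# agreement with the CTCF/Cohesin layout outranks score (configurable).

.BASE_IDX <- c(A = 1L, C = 2L, G = 3L, T = 4L)

.seq_to_idx <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)), "")[[1L]]
  idx <- .BASE_IDX[chars]
  unname(idx)  # NA for N and anything else
}

.revcomp_pwm <- function(p) {
  # scoring the reverse complement of a window with p equals scoring the
  # forward window with p row-reversed and column-complemented
  m <- unclass(p)[rev(seq_len(nrow(p))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(m) <- c("A", "C", "G", "T")
  m
}

.scan_strand <- function(idx, m) {
  w <- nrow(m)
  n <- length(idx) - w + 1L
  scores <- numeric(n)
  for (j in seq_len(w)) {
    s <- m[j, ][idx[j:(j + n - 1L)]]
    s[is.na(s)] <- -Inf  # N never matches
    scores <- scores + s
  }
  unname(scores)
}

#' Scan a sequence with a PWM on both strands
#'
#' Every start position is scored on the forward strand and on the
#' reverse strand (the reverse complement of the window); windows
#' containing `N` score `-Inf`. Hits with score `>= min_score` are
#' returned. The default threshold of 6 is the standard cut-off for CTCF
#' log-odds matrices in this pipeline.
#'
#' @param sequence character string or [Biostrings::DNAString] over
#'   `A,C,G,T,N`.
#' @param pwm a [pwm()].
#' @param min_score minimum summed log-odds score (default 6).
#' @return data frame `start`, `end` (0-based half-open, within the
#'   sequence), `strand` (`"+"`/`"-"`), `score`; empty if the sequence is
#'   shorter than the motif.
#' @examples
#' p <- pwm(matrix(c(2, -2, -2, -2, 2, -2, -2, -2), 2, 4, byrow = TRUE))
#' scan_pwm("AAT", p, min_score = 3)
#' @export
scan_pwm <- function(sequence, pwm, min_score = 6.0) {
  stopifnot(inherits(pwm, "pwm"))
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric())
  idx <- .seq_to_idx(sequence)
  w <- nrow(pwm)
  if (length(idx) < w) return(empty)
  fwd <- .scan_strand(idx, unclass(pwm))
  rev <- .scan_strand(idx, .revcomp_pwm(pwm))
  starts <- seq_along(fwd) - 1L
  out <- rbind(
    data.frame(start = starts, end = starts + w, strand = "+", score = fwd),
    data.frame(start = starts, end = starts + w, strand = "-", score = rev)
  )
  out <- out[out$score >= min_score, , drop = FALSE]
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Maximum-scoring (consensus) sequence of a PWM
#'
#' @param x a [pwm()].
#' @return character string of length `nrow(x)`.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(colnames(x)[apply(unclass(x), 1L, which.max)], collapse = "")
}

#' Maximum attainable PWM score
#'
#' @param x a [pwm()].
#' @return numeric scalar.
#' @export
pwm_max_score <- function(x) {
  stopifnot(inherits(x, "pwm"))
  sum(apply(unclass(x), 1L, max))
}

.orientation_from_strand <- function(strand) {
  c("+" = "forward", "-" = "reverse")[strand]
}

#' Assign an orientation to one insulator from motif hits
#'
#' The expected strand follows the CTCF/Cohesin layout: Cohesin downstream
#' of the CTCF summit implies a forward motif, upstream implies reverse.
#' Among hits inside `[pos - search_flank_bp, pos + search_flank_bp)` the
#' preference order is: expected-strand agreement, then score, then lowest
#' start coordinate (`prefer = "score"` swaps the first two keys). Without
#' any hit, an insulator whose Cohesin partner is at least
#' `clear_direction_min_bp` away inherits the binding-direction
#' orientation; otherwise it stays unknown.
#'
#' @param insulator one-row data frame (or list) with `pos` and
#'   `cohesin_pos`.
#' @param hits motif hit data frame (`start`, `end`, `strand`, `score`) in
#'   the same coordinate system as `pos`.
#' @param search_flank_bp half-width of the search window (default 100).
#' @param clear_direction_min_bp minimum |cohesin_pos - pos| for the
#'   binding-direction fallback (default 5).
#' @param prefer `"direction"` (default) or `"score"`: which key ranks
#'   first when hits compete.
#' @return list with `orientation` (`"forward"`, `"reverse"`,
#'   `"unknown"`), `orientation_source` (`"motif"`, `"binding_direction"`,
#'   `"none"`) and `motif_score` (NA without a motif).
#' @export
assign_orientation <- function(insulator, hits,
                               search_flank_bp = 100L,
                               clear_direction_min_bp = 5L,
                               prefer = c("direction", "score")) {
  prefer <- match.arg(prefer)
  pos <- insulator$pos
  coh <- insulator$cohesin_pos
  expected <- if (is.na(coh) || coh == pos) NA_character_
              else if (coh > pos) "+" else "-"
  if (!is.null(hits) && nrow(hits)) {
    hits <- hits[hits$start >= pos - search_flank_bp &
                   hits$start < pos + search_flank_bp, , drop = FALSE]
  }
  if (!is.null(hits) && nrow(hits)) {
    on_expected <- if (is.na(expected)) rep(FALSE, nrow(hits))
                   else hits$strand == expected
    o <- if (prefer == "direction") {
      order(-on_expected, -hits$score, hits$start)
    } else {
      order(-hits$score, -on_expected, hits$start)
    }
    best <- hits[o[1L], ]
    return(list(orientation = unname(.orientation_from_strand(best$strand)),
                orientation_source = "motif",
                motif_score = best$score))
  }
  if (!is.na(expected) && abs(coh - pos) >= clear_direction_min_bp) {
    return(list(orientation = unname(.orientation_from_strand(expected)),
                orientation_source = "binding_direction",
                motif_score = NA_real_))
  }
  list(orientation = "unknown", orientation_source = "none",
       motif_score = NA_real_)
}

#' Orient every insulator by scanning the genome around it
#'
#' Extracts `[pos - search_flank_bp, pos + search_flank_bp)` from the
#' genome (clipped at chromosome ends), scans it with the PWM on both
#' strands, and applies [assign_orientation()].
#'
#' @param insulators insulator data frame ([call_insulators()]).
#' @param genome_seqs named [Biostrings::DNAStringSet] with the
#'   chromosomes referenced by `insulators`.
#' @param pwm a [pwm()].
#' @param min_score PWM score threshold (default 6).
#' @inheritParams assign_orientation
#' @return `insulators` with `orientation`, `orientation_source` and
#'   `motif_score` filled in.
#' @export
orient_insulators <- function(insulators, genome_seqs, pwm,
                              min_score = 6.0, search_flank_bp = 100L,
                              clear_direction_min_bp = 5L,
                              prefer = c("direction", "score")) {
  prefer <- match.arg(prefer)
  if (nrow(insulators) == 0L) return(insulators)
  missing_chr <- setdiff(unique(insulators$chrom), names(genome_seqs))
  if (length(missing_chr)) {
    .stop("chromosome(s) absent from genome: ",
          paste(missing_chr, collapse = ", "))
  }
  for (i in seq_len(nrow(insulators))) {
    chrom <- as.character(insulators$chrom[i])
    pos <- insulators$pos[i]
    L <- length(genome_seqs[[chrom]])
    lo <- max(pos - search_flank_bp, 0L)
    hi <- min(pos + search_flank_bp, L)
    hits <- scan_pwm(Biostrings::subseq(genome_seqs[[chrom]], lo + 1L, hi),
                     pwm, min_score)
    if (nrow(hits)) {
      hits$start <- hits$start + lo
      hits$end <- hits$end + lo
    }
    res <- assign_orientation(insulators[i, ], hits,
                              search_flank_bp = search_flank_bp,
                              clear_direction_min_bp = clear_direction_min_bp,
                              prefer = prefer)
    insulators$orientation[i] <- res$orientation
    insulators$orientation_source[i] <- res$orientation_source
    insulators$motif_score[i] <- res$motif_score
  }
  insulators
}
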