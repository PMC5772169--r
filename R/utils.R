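# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; consensus summit positions are
#' defined as the round-half-up arithmetic mean of member summits, so a
#' deterministic half-up rule is used throughout.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop <- function(...) stop(..., call. = FALSE)

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Convert BED-style intervals to GRanges
#'
#' All public coordinates in this package are 0-based half-open (BED
#' semantics). GenomicRanges is 1-based closed; conversion happens only at
#' this internal boundary.
#'
#' @param df data frame with `chrom`, `start`, `end` columns (0-based
#'   half-open).
#' @return a [GenomicRanges::GRanges] object.
#' @keywords internal
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

.check_intervals <- function(df, what = "interval", genome = NULL) {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!(df$start < df$end))
  if (length(bad)) {
    .stop(sprintf("%s %d has start >= end (%d >= %d)",
                  what, bad[1L], df$start[bad[1L]], df$end[bad[1L]]))
  }
  if (any(df$start < 0)) .stop(what, " with negative start coordinate")
  if (!is.null(genome)) {
    .check_chroms(df$chrom, genome)
    len <- genome$chrom_lengths[as.character(df$chrom)]
    if (any(df$end > len)) .stop(what, " extends past chromosome end")
  }
  invisible(df)
}

.check_chroms <- function(chrom, genome) {
  unknown <- setdiff(unique(as.character(chrom)), genome$chrom_names)
  if (length(unknown)) {
    .stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

# Newton solver for the inverse of trigamma(), used when estimating the
# prior degrees of freedom of the variance shrinkage model.
.trigamma_inverse <- function(y) {
  stopifnot(all(y > 0))
  x <- 0.5 + 1 / y
  for (i in seq_len(60L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}
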