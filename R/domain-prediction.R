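# Domain calling: coverage filtering, convergent pairing, overlap
# resolution, and negative-domain tiling.

#' Filter insulators by relative coverage
#'
#' Per protein, the threshold is `fraction` times the summed coverage over
#' all insulators. The default mode retains insulators whose coverage
#' exceeds both thresholds ("in both samples"), i.e. removes weakly bound
#' elements so that only insulators active in the assayed cell type enter
#' domain prediction. `filter_mode = "literal"` instead discards the
#' insulators exceeding both thresholds.
#'
#' @param insulators quantified insulator data frame
#'   ([quantify_insulators()]).
#' @param fraction threshold fraction of the summed per-protein coverage
#'   (default 1e-5, one hundred-thousandth).
#' @param filter_mode `"retain"` (default) keeps insulators above both
#'   thresholds; `"literal"` removes them.
#' @return the retained insulator rows; counts are logged.
#' @export
filter_insulators_by_coverage <- function(insulators, fraction = 1e-5,
                                          filter_mode = c("retain", "literal")) {
  filter_mode <- match.arg(filter_mode)
  if (nrow(insulators) == 0L) return(insulators)
  t_ctcf <- fraction * sum(insulators$ctcf_rpkm)
  t_coh <- fraction * sum(insulators$cohesin_rpkm)
  if (t_ctcf <= 0 && t_coh <= 0) {
    warning("all insulator coverage is zero; nothing retained", call. = FALSE)
    return(insulators[0L, , drop = FALSE])
  }
  exceeds <- insulators$ctcf_rpkm > t_ctcf & insulators$cohesin_rpkm > t_coh
  keep <- if (filter_mode == "retain") exceeds else !exceeds
  .stage_log("filter", sprintf(
    "retained %d / %d insulators (ctcf threshold %.4g, cohesin threshold %.4g)",
    sum(keep), nrow(insulators), t_ctcf, t_coh))
  out <- insulators[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.fold_balanced <- function(a, b, max_fold) {
  # zero coverage on either side fails the ratio test by definition
  a > 0 & b > 0 & pmax(a, b) / pmin(a, b) < max_fold
}

#' Pair convergent insulators into candidate domains
#'
#' Each forward-oriented insulator is assigned the nearest reverse-oriented
#' insulator downstream with `min_bp < distance <= max_bp`; the pair
#' becomes a domain when the boundary coverage differs by less than
#' `max_fold` for both CTCF and Cohesin. There is no fallback to the
#' next-nearest partner when the coverage test fails. Insulators of
#' unknown orientation never pair.
#'
#' @param insulators oriented, coverage-filtered insulator data frame.
#' @param min_bp minimum summit-to-summit distance, exclusive
#'   (default 1000).
#' @param max_bp maximum distance, inclusive (default 1e6).
#' @param max_fold boundary coverage ratio bound, exclusive (default 2).
#' @return data frame of convergent domains: `chrom`, `start`, `end`
#'   (left/right insulator positions), `kind = "convergent"`,
#'   `pair_coverage` (sum of both boundaries' CTCF + Cohesin coverage),
#'   plus the four per-boundary coverages.
#' @export
call_convergent_domains <- function(insulators, min_bp = 1000L,
                                    max_bp = 1e6, max_fold = 2.0) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), kind = character(),
                      pair_coverage = numeric(),
                      left_ctcf_rpkm = numeric(), left_cohesin_rpkm = numeric(),
                      right_ctcf_rpkm = numeric(),
                      right_cohesin_rpkm = numeric())
  if (nrow(insulators) == 0L) return(empty)
  out <- lapply(split(insulators, insulators$chrom), function(ins) {
    ins <- ins[order(ins$pos), , drop = FALSE]
    fwd <- ins[ins$orientation == "forward", , drop = FALSE]
    rev <- ins[ins$orientation == "reverse", , drop = FALSE]
    if (!nrow(fwd) || !nrow(rev)) return(NULL)
    rows <- lapply(seq_len(nrow(fwd)), function(i) {
      d <- rev$pos - fwd$pos[i]
      cand <- which(d > min_bp & d <= max_bp)
      if (!length(cand)) return(NULL)
      j <- cand[which.min(d[cand])]
      ok <- .fold_balanced(fwd$ctcf_rpkm[i], rev$ctcf_rpkm[j], max_fold) &&
        .fold_balanced(fwd$cohesin_rpkm[i], rev$cohesin_rpkm[j], max_fold)
      if (!ok) return(NULL)
      data.frame(chrom = as.character(fwd$chrom[i]),
                 start = fwd$pos[i], end = rev$pos[j], kind = "convergent",
                 pair_coverage = fwd$ctcf_rpkm[i] + fwd$cohesin_rpkm[i] +
                   rev$ctcf_rpkm[j] + rev$cohesin_rpkm[j],
                 left_ctcf_rpkm = fwd$ctcf_rpkm[i],
                 left_cohesin_rpkm = fwd$cohesin_rpkm[i],
                 right_ctcf_rpkm = rev$ctcf_rpkm[j],
                 right_cohesin_rpkm = rev$cohesin_rpkm[j])
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, c(out, list(empty)))
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping candidate domains
#'
#' Greedy selection: repeatedly keep the remaining domain with the highest
#' `pair_coverage` (ties break to the leftmost, then shortest domain) and
#' reject every domain sharing at least one base with it. Touching
#' boundaries do not count as overlap. The result equals the
#' lexicographic-best non-overlapping subset under the same priority.
#'
#' @param domains data frame from [call_convergent_domains()].
#' @return non-overlapping subset, sorted by chromosome and start.
#' @export
resolve_domain_overlaps <- function(domains) {
  if (nrow(domains) <= 1L) return(domains)
  o <- order(-domains$pair_coverage, domains$chrom, domains$start,
             domains$end - domains$start)
  d <- domains[o, , drop = FALSE]
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    if (i > 1L && any(keep[seq_len(i - 1L)] &
                        d$chrom[seq_len(i - 1L)] == d$chrom[i] &
                        d$start[seq_len(i - 1L)] < d$end[i] &
                        d$end[seq_len(i - 1L)] > d$start[i])) next
    keep[i] <- TRUE
  }
  out <- d[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tile negative domains between convergent domains
#'
#' One negative domain (divergent-insulator gap) per gap between
#' consecutive final convergent domains on a chromosome; zero-length gaps
#' (touching domains) emit nothing, and no negative domains are produced
#' before the first or after the last convergent domain.
#'
#' @param convergent final non-overlapping convergent domain data frame.
#' @return data frame of `kind = "negative"` domains (coverage columns NA).
#' @export
negative_domains <- function(convergent) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), kind = character(),
                      pair_coverage = numeric())
  if (nrow(convergent) < 2L) return(empty)
  out <- lapply(split(convergent, convergent$chrom), function(d) {
    if (nrow(d) < 2L) return(NULL)
    d <- d[order(d$start), , drop = FALSE]
    gs <- d$end[-nrow(d)]
    ge <- d$start[-1L]
    ok <- ge > gs
    if (!any(ok)) return(NULL)
    data.frame(chrom = as.character(d$chrom[1L]), start = gs[ok],
               end = ge[ok], kind = "negative", pair_coverage = NA_real_)
  })
  out <- do.call(rbind, c(out, list(empty)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.check_domain_invariants <- function(convergent, min_bp, max_bp, max_fold) {
  if (nrow(convergent) == 0L) return(invisible(TRUE))
  len <- convergent$end - convergent$start
  stopifnot(all(len > min_bp), all(len <= max_bp))
  stopifnot(all(.fold_balanced(convergent$left_ctcf_rpkm,
                               convergent$right_ctcf_rpkm, max_fold)),
            all(.fold_balanced(convergent$left_cohesin_rpkm,
                               convergent$right_cohesin_rpkm, max_fold)))
  o <- order(convergent$chrom, convergent$start)
  s <- convergent[o, ]
  same <- s$chrom[-1L] == s$chrom[-nrow(s)]
  stopifnot(!any(same & s$start[-1L] < s$end[-nrow(s)]))
  invisible(TRUE)
}

#' Full domain prediction from oriented insulators
#'
#' Coverage filter, convergent pairing, greedy overlap resolution, and
#' negative-domain tiling in one call. Output invariants (length bounds,
#' coverage balance, non-overlap) are asserted before returning.
#'
#' @inheritParams filter_insulators_by_coverage
#' @inheritParams call_convergent_domains
#' @return data frame of convergent and negative domains, sorted.
#' @export
predict_domains <- function(insulators, fraction = 1e-5,
                            filter_mode = c("retain", "literal"),
                            min_bp = 1000L, max_bp = 1e6, max_fold = 2.0) {
  filter_mode <- match.arg(filter_mode)
  kept <- filter_insulators_by_coverage(insulators, fraction, filter_mode)
  conv <- resolve_domain_overlaps(
    call_convergent_domains(kept, min_bp, max_bp, max_fold))
  .check_domain_invariants(conv, min_bp, max_bp, max_fold)
  neg <- negative_domains(conv)
  for (e in setdiff(names(conv), names(neg))) {
    neg[[e]] <- rep(NA_real_, nrow(neg))
  }
  out <- rbind(conv, neg[, names(conv), drop = FALSE])
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write domains as BED
#'
#' Name field carries the domain kind (`convergent`/`negative`), score the
#' pair coverage.
#'
#' @param path output path.
#' @param domains domain data frame.
#' @return `path`, invisibly.
#' @export
write_domains <- function(path, domains) {
  bed <- data.frame(chrom = domains$chrom, start = domains$start,
                    end = domains$end, name = domains$kind,
                    score = ifelse(is.na(domains$pair_coverage), 0,
                                   domains$pair_coverage))
  write_intervals(path, bed)
}

#' Read a domain BED written by [write_domains()]
#'
#' @param path file path.
#' @return domain data frame with `chrom`, `start`, `end`, `kind`,
#'   `pair_coverage`.
#' @export
read_domains <- function(path) {
  bed <- read_bed(path)
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             kind = bed$name, pair_coverage = bed$score)
}
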