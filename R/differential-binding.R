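# Replicate read-count quantification over peak regions, the
# repressor/neutral/activator classification, and the paired region-set
# shift test used for signal-change claims over region sets.

#' Replicate counts container
#'
#' @param counts non-negative integer matrix, regions x samples.
#' @param condition condition label per sample (factor or character);
#'   exactly two levels are required for classification, the first level
#'   being the control.
#' @param region_lengths region lengths in bp (> 0).
#' @param library_sizes mapped reads per sample (> 0).
#' @param region_ids region identifiers (default: rownames of `counts`).
#' @return object of class `replicate_counts` with the validated fields
#'   and a derived `rpkm` matrix.
#' @export
replicate_counts <- function(counts, condition, region_lengths,
                             library_sizes, region_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(region_ids)) region_ids <- as.character(seq_len(nrow(counts)))
  if (any(counts < 0)) .stop("counts must be >= 0")
  if (length(region_lengths) != nrow(counts)) .stop("one length per region")
  if (length(library_sizes) != ncol(counts)) .stop("one library size per sample")
  if (length(condition) != ncol(counts)) .stop("one condition per sample")
  condition <- if (is.factor(condition)) droplevels(condition)
               else factor(condition, levels = unique(condition))
  structure(list(counts = counts,
                 condition = condition,
                 region_lengths = as.numeric(region_lengths),
                 library_sizes = as.numeric(library_sizes),
                 region_ids = as.character(region_ids),
                 rpkm = rpkm(counts, region_lengths, library_sizes)),
            class = "replicate_counts")
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm[i, j] = counts[i, j] / (length_i / 1000) / (library_j / 1e6)`.
#'
#' @param counts matrix or vector of raw counts (regions x samples).
#' @param region_lengths region lengths in bp (> 0).
#' @param library_sizes per-sample mapped read totals (> 0).
#' @return matrix of RPKM values with the dimensions of `counts`.
#' @examples
#' rpkm(100, 1000, 1e6)  # 100
#' @export
rpkm <- function(counts, region_lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (any(region_lengths <= 0)) .stop("region lengths must be > 0")
  if (any(library_sizes <= 0)) .stop("library sizes must be > 0")
  sweep(counts / (region_lengths / 1000), 2L, library_sizes / 1e6, "/")
}

#' Fraction of peaks overlapping the union of a second peak set
#'
#' A peak counts as positive when it shares at least one base with the
#' union of `peaks_b`.
#'
#' @param peaks_a,peaks_b interval data frames (`chrom`, `start`, `end`).
#' @return list with `fraction` (0-1), `positive` (logical per row of
#'   `peaks_a`), and `overlapping` (the positive subset of `peaks_a`).
#' @export
positive_overlap <- function(peaks_a, peaks_b) {
  .check_intervals(peaks_a, "peak")
  .check_intervals(peaks_b, "peak")
  if (nrow(peaks_a) == 0L) {
    return(list(fraction = NaN, positive = logical(), overlapping = peaks_a))
  }
  if (nrow(peaks_b) == 0L) {
    pos <- rep(FALSE, nrow(peaks_a))
  } else {
    union_b <- GenomicRanges::reduce(.as_granges(peaks_b))
    pos <- IRanges::overlapsAny(.as_granges(peaks_a), union_b)
  }
  list(fraction = mean(pos), positive = pos,
       overlapping = peaks_a[pos, , drop = FALSE])
}

# Empirical-Bayes variance moderation with a mean-variance trend:
# per-region residual variances are shrunk toward a loess fit of
# log-variance against average log-abundance; the prior degrees of
# freedom are estimated from the excess spread of log-variances around
# the trend (scaled-F model).
.moderate_variances <- function(s2, abund, df_resid) {
  e <- log(pmax(s2, 1e-12))
  span <- if (length(e) < 50L) 1 else 0.4
  fit <- stats::lowess(abund, e, f = span, iter = 3L)
  trend <- stats::approx(fit$x, fit$y, xout = abund, rule = 2L)$y
  bias <- digamma(df_resid / 2) - log(df_resid / 2)
  resid_var <- mean((e - trend)^2)
  excess <- resid_var - trigamma(df_resid / 2)
  if (is.na(excess) || excess < 1e-8) {
    df_prior <- Inf
    s2_prior <- exp(trend - bias)
    s2_post <- s2_prior
  } else {
    df_prior <- 2 * .trigamma_inverse(excess)
    s2_prior <- exp(trend - bias + digamma(df_prior / 2) - log(df_prior / 2))
    s2_post <- (df_prior * s2_prior + df_resid * s2) / (df_prior + df_resid)
  }
  list(s2_post = s2_post, df_prior = df_prior, df_total = df_prior + df_resid)
}

.fold_epsilon <- function(control_values) {
  nz <- control_values[control_values > 0]
  if (!length(nz)) return(1)
  as.numeric(stats::quantile(nz, 0.01, names = FALSE))
}

#' Classify factor-bound regions as repressor / neutral / activator
#'
#' Per region, control and treated co-factor RPKM (on the `log2(rpkm + 1)`
#' scale) are compared with a moderated two-sample t statistic whose
#' variance is shrunk toward the loess mean-variance trend across regions;
#' two-sided p-values come from the t reference with the total (residual +
#' prior) degrees of freedom. A region is a repressor when `p <= alpha`
#' and its fold change is below 1, an activator when `p <= alpha` and the
#' fold change is above 1, and neutral otherwise. Fold changes are
#' `(treated + eps) / (control + eps)` on mean RPKM, with `eps` the 1st
#' percentile of non-zero control RPKM.
#'
#' @param rc a [replicate_counts()] with a two-level condition (control
#'   first) and at least two replicates per condition.
#' @param alpha significance threshold on the (raw) p-value
#'   (default 0.05).
#' @param fdr apply Benjamini-Hochberg correction before thresholding
#'   (default FALSE: the classification rule is on raw p-values).
#' @return data frame `peak_id`, `class`, `p_value`, `log2_fold_change`.
#' @export
classify_peaks <- function(rc, alpha = 0.05, fdr = FALSE) {
  stopifnot(inherits(rc, "replicate_counts"))
  lev <- levels(rc$condition)
  if (length(lev) != 2L) .stop("classification needs exactly two conditions")
  i_c <- which(rc$condition == lev[1L])
  i_t <- which(rc$condition == lev[2L])
  n1 <- length(i_c); n2 <- length(i_t)
  if (n1 < 2L || n2 < 2L) {
    .stop("at least two replicates per condition are required")
  }
  y <- log2(rc$rpkm + 1)
  m_c <- rowMeans(y[, i_c, drop = FALSE])
  m_t <- rowMeans(y[, i_t, drop = FALSE])
  ss <- rowSums((y[, i_c, drop = FALSE] - m_c)^2) +
    rowSums((y[, i_t, drop = FALSE] - m_t)^2)
  df_resid <- n1 + n2 - 2L
  s2 <- ss / df_resid
  mod <- .moderate_variances(s2, rowMeans(y), df_resid)
  se <- sqrt(mod$s2_post * (1 / n1 + 1 / n2))
  tstat <- (m_t - m_c) / se
  p <- 2 * stats::pt(-abs(tstat), df = mod$df_total)
  p[se == 0] <- ifelse(m_t[se == 0] == m_c[se == 0], 1, 0)
  eps <- .fold_epsilon(rc$rpkm[, i_c])
  fold <- (rowMeans(rc$rpkm[, i_t, drop = FALSE]) + eps) /
    (rowMeans(rc$rpkm[, i_c, drop = FALSE]) + eps)
  p_rule <- if (fdr) stats::p.adjust(p, "BH") else p
  class <- ifelse(p_rule <= alpha & fold < 1, "repressor",
                  ifelse(p_rule <= alpha & fold > 1, "activator", "neutral"))
  data.frame(peak_id = rc$region_ids, class = class, p_value = p,
             log2_fold_change = log2(fold))
}

#' Paired shift test for a region set
#'
#' Paired t-test across regions between control and treated per-region
#' values, gated by an average fold-change cut-off: the shift is
#' significant only when `p < p_cut` AND the mean per-region fold change
#' is `>= fc_cut` or `<= 1 / fc_cut`. Folds are computed as
#' `(treated + eps) / (control + eps)` with `eps` the 1st percentile of
#' non-zero control values. With zero variance of the differences, p is 1
#' when all differences are zero and 0 otherwise.
#'
#' @param control,treated paired numeric vectors (same regions, same
#'   order), length >= 2.
#' @param p_cut p-value threshold, exclusive (default 1e-5).
#' @param fc_cut mean fold-change threshold, inclusive (default 1.15).
#' @return list with `significant` (logical), `p_value`, `mean_fold`, `n`.
#' @export
region_set_shift_test <- function(control, treated, p_cut = 1e-5,
                                  fc_cut = 1.15) {
  n <- length(control)
  if (length(treated) != n) .stop("control and treated must be paired")
  if (n < 2L) .stop("at least two paired regions are required")
  d <- treated - control
  sd_d <- stats::sd(d)
  p <- if (sd_d == 0) {
    if (all(d == 0)) 1 else 0
  } else {
    tstat <- mean(d) / (sd_d / sqrt(n))
    2 * stats::pt(-abs(tstat), df = n - 1L)
  }
  eps <- .fold_epsilon(control)
  mean_fold <- mean((treated + eps) / (control + eps))
  list(significant = (p < p_cut) &&
         (mean_fold >= fc_cut || mean_fold <= 1 / fc_cut),
       p_value = p, mean_fold = mean_fold, n = n)
}
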