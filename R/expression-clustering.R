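# Regulated-gene calling from FPKM time courses, trajectory clustering,
# and LPS-response sensitivity clustering.

#' Expressed-gene filter
#'
#' Retains genes with at least `min_fpkm` FPKM in at least one sample.
#'
#' @param et an [expression_table()].
#' @param min_fpkm expression threshold (default 1).
#' @return the filtered [expression_table()]; gene ids via
#'   `rownames(x$fpkm)`.
#' @export
expressed_genes <- function(et, min_fpkm = 1.0) {
  stopifnot(inherits(et, "expression_table"))
  keep <- apply(et$fpkm, 1L, max) >= min_fpkm
  out <- et
  out$fpkm <- et$fpkm[keep, , drop = FALSE]
  out
}

.check_balanced <- function(samples, alpha_cells = 2L) {
  cells <- table(samples$genotype, samples$time)
  missing <- which(cells == 0L, arr.ind = TRUE)
  if (nrow(missing)) {
    lab <- paste0(rownames(cells)[missing[, 1L]], ":t",
                  colnames(cells)[missing[, 2L]])
    .stop("design is missing cells: ", paste(lab, collapse = ", "))
  }
  thin <- which(cells < alpha_cells, arr.ind = TRUE)
  if (nrow(thin)) {
    lab <- paste0(rownames(cells)[thin[, 1L]], ":t",
                  colnames(cells)[thin[, 2L]])
    .stop("fewer than 2 replicates in cells: ", paste(lab, collapse = ", "))
  }
  invisible(TRUE)
}

.tukey_time_contrasts <- function(y, genotype, time_f, control_time) {
  if (nlevels(genotype) > 1L) {
    fit <- stats::aov(y ~ genotype * time_f)
    tk <- stats::TukeyHSD(fit, "genotype:time_f")[["genotype:time_f"]]
  } else {
    fit <- stats::aov(y ~ time_f)
    tk <- stats::TukeyHSD(fit, "time_f")[["time_f"]]
    rownames(tk) <- vapply(strsplit(rownames(tk), "-", fixed = TRUE),
                           function(h) paste0(levels(genotype)[1L], ":", h[1L],
                                              "-", levels(genotype)[1L], ":",
                                              h[2L]), "")
  }
  cmp <- rownames(tk)
  halves <- strsplit(cmp, "-", fixed = TRUE)
  g1 <- vapply(halves, function(h) strsplit(h[1L], ":")[[1L]][1L], "")
  t1 <- vapply(halves, function(h) strsplit(h[1L], ":")[[1L]][2L], "")
  g2 <- vapply(halves, function(h) strsplit(h[2L], ":")[[1L]][1L], "")
  t2 <- vapply(halves, function(h) strsplit(h[2L], ":")[[1L]][2L], "")
  ctrl <- as.character(control_time)
  sel <- g1 == g2 & ((t2 == ctrl & t1 != ctrl) | (t1 == ctrl & t2 != ctrl))
  flip <- t1 == ctrl  # make the contrast "treated - control"
  data.frame(genotype = g1[sel],
             time = ifelse(flip, t2, t1)[sel],
             diff = ifelse(flip, -tk[, "diff"], tk[, "diff"])[sel],
             p = tk[, "p adj"][sel])
}

#' Call regulated genes from a genotype x time FPKM design
#'
#' Per gene, a two-way ANOVA on `log2(FPKM + 1)` with genotype and time
#' factors is followed by Tukey post hoc contrasts of each treated time
#' point against the control time within each genotype. A gene is
#' regulated in a genotype when any contrast has `p < alpha` and a fold
#' change `>= fc_cut` (fold computed as `2^|difference of mean log2
#' expression|`). The direction is the sign at the most significant time
#' point. When a second (knockout) genotype is present, genes regulated in
#' the reference genotype but not the knockout are flagged
#' genotype-dependent.
#'
#' @param et an [expression_table()] with at least 2 replicates for every
#'   genotype x time cell.
#' @param fc_cut fold-change threshold (default 2).
#' @param alpha p-value threshold on the Tukey-adjusted contrasts
#'   (default 0.05).
#' @param control_time time point treated as the untreated control
#'   (default 0).
#' @param reference_genotype genotype whose contrasts define `regulated`
#'   (default `"WT"` when present, else the first level).
#' @return data frame with one row per gene: `gene_id`, `regulated`,
#'   `direction` (`"up"`/`"down"`/NA), `max_log2_fc` (signed, at the most
#'   significant contrast), `p_min`, and per-genotype `regulated_<g>`
#'   columns plus `genotype_dependent` when two genotypes are present.
#' @export
call_regulated <- function(et, fc_cut = 2.0, alpha = 0.05,
                           control_time = 0, reference_genotype = NULL) {
  stopifnot(inherits(et, "expression_table"))
  s <- et$samples
  .check_balanced(s)
  if (!control_time %in% s$time) {
    .stop("control time ", control_time, " absent from the design")
  }
  genos <- unique(s$genotype)
  ref <- reference_genotype %||% (if ("WT" %in% genos) "WT" else genos[1L])
  genotype <- factor(s$genotype, levels = c(ref, setdiff(genos, ref)))
  time_f <- factor(s$time)
  genes <- rownames(et$fpkm)
  res <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    y <- log2(et$fpkm[g, ] + 1)
    cc <- .tukey_time_contrasts(y, genotype, time_f, control_time)
    cc$fold <- 2^abs(cc$diff)
    hit <- cc$p < alpha & cc$fold >= fc_cut
    per_geno <- vapply(levels(genotype), function(gg) {
      any(hit[cc$genotype == gg])
    }, logical(1L))
    ref_cc <- cc[cc$genotype == ref, , drop = FALSE]
    best <- which.min(ref_cc$p)
    res[[g]] <- c(list(gene_id = genes[g],
                       regulated = unname(per_geno[ref]),
                       direction = if (per_geno[ref]) {
                         if (ref_cc$diff[best] > 0) "up" else "down"
                       } else NA_character_,
                       max_log2_fc = ref_cc$diff[best],
                       p_min = ref_cc$p[best]),
                  as.list(stats::setNames(per_geno,
                                          paste0("regulated_", levels(genotype)))))
  }
  out <- do.call(rbind, lapply(res, function(r) as.data.frame(r)))
  if (length(genos) > 1L) {
    out$genotype_dependent <- out$regulated &
      !out[[paste0("regulated_", setdiff(levels(genotype), ref)[1L])]]
  }
  rownames(out) <- NULL
  out
}

#' Per-time log2 fold-change matrix for one genotype
#'
#' `log2` ratio of mean `FPKM + 1` at each treated time point against the
#' control time.
#'
#' @inheritParams call_regulated
#' @param genotype which genotype to profile (default `"WT"`).
#' @return numeric matrix genes x treated time points, columns named
#'   `t<time>`.
#' @export
fold_change_matrix <- function(et, genotype = "WT", control_time = 0) {
  stopifnot(inherits(et, "expression_table"))
  s <- et$samples
  sel <- s$genotype == genotype
  if (!any(sel)) .stop("genotype '", genotype, "' absent from the design")
  times <- sort(unique(s$time[sel]))
  times <- times[times != control_time]
  base <- rowMeans(et$fpkm[, sel & s$time == control_time, drop = FALSE])
  fc <- vapply(times, function(tt) {
    log2((rowMeans(et$fpkm[, sel & s$time == tt, drop = FALSE]) + 1) /
           (base + 1))
  }, numeric(nrow(et$fpkm)))
  fc <- matrix(fc, nrow = nrow(et$fpkm),
               dimnames = list(rownames(et$fpkm), paste0("t", times)))
  fc
}

#' Trajectory clusters from per-time fold changes
#'
#' Genes whose strongest response is negative form the repressed cluster;
#' the remaining (induced) genes are partitioned by K-means on per-gene
#' standardised fold-change profiles (25 restarts, fixed seed). Induced
#' clusters are labelled `A`, `B`, ... ordered by centroid time of peak
#' and then by descending peak magnitude; the repressed cluster takes the
#' next letter (so the default `k_induced = 4` reproduces an A-E layout
#' with E repressed).
#'
#' @param fc matrix of per-time log2 fold changes
#'   ([fold_change_matrix()]).
#' @param k_induced number of induced clusters (default 4).
#' @param seed RNG seed for K-means restarts.
#' @return data frame `gene_id`, `cluster`, `induced`.
#' @export
trajectory_clusters <- function(fc, k_induced = 4L, seed = 1L) {
  stopifnot(is.matrix(fc))
  peak <- apply(fc, 1L, function(x) x[which.max(abs(x))])
  induced <- peak > 0
  labels <- rep(NA_character_, nrow(fc))
  repressed_label <- LETTERS[k_induced + 1L]
  labels[!induced] <- repressed_label
  if (any(induced)) {
    if (sum(induced) < k_induced) {
      .stop("k_induced (", k_induced, ") exceeds the number of induced genes (",
            sum(induced), ")")
    }
    z <- fc[induced, , drop = FALSE]
    mu <- rowMeans(z)
    sd_ <- apply(z, 1L, stats::sd)
    z <- (z - mu) / ifelse(sd_ > 0, sd_, 1)
    set.seed(seed)
    km <- stats::kmeans(z, centers = k_induced, nstart = 25L,
                        iter.max = 100L)
    cent_peak_time <- apply(km$centers, 1L, which.max)
    cent_mag <- vapply(seq_len(k_induced), function(k) {
      max(colMeans(fc[induced, , drop = FALSE][km$cluster == k, ,
                                               drop = FALSE]))
    }, numeric(1L))
    rank <- order(cent_peak_time, -cent_mag)
    relabel <- integer(k_induced)
    relabel[rank] <- seq_len(k_induced)
    labels[induced] <- LETTERS[relabel[km$cluster]]
  }
  data.frame(gene_id = rownames(fc), cluster = labels, induced = induced,
             row.names = NULL)
}

#' LPS-response sensitivity clusters
#'
#' Genes significantly induced by LPS against control (`p < alpha`,
#' two-sided t-test on `log2(FPKM + 1)`, positive shift) are split by
#' their sensitivity to IL-4 pretreatment: cluster 1 (attenuated) when the
#' pretreated LPS response is significantly below the LPS response,
#' cluster 3 (increased) when significantly above, cluster 2 (insensitive)
#' otherwise.
#'
#' @param et an [expression_table()] whose treatments include `control`,
#'   `LPS` and `IL4LPS` (IL-4 pretreatment followed by LPS).
#' @param alpha significance threshold for both tests (default 0.05).
#' @return data frame `gene_id`, `lps_induced`, `cluster` (1, 2, 3 or NA
#'   for genes not LPS-induced), `label`.
#' @export
lps_response_clusters <- function(et, alpha = 0.05) {
  stopifnot(inherits(et, "expression_table"))
  s <- et$samples
  need <- c("control", "LPS", "IL4LPS")
  miss <- setdiff(need, unique(s$treatment))
  if (length(miss)) {
    .stop("design is missing condition(s): ", paste(miss, collapse = ", "))
  }
  y <- log2(et$fpkm + 1)
  i_ctrl <- s$treatment == "control"
  i_lps <- s$treatment == "LPS"
  i_pre <- s$treatment == "IL4LPS"
  genes <- rownames(et$fpkm)
  n <- length(genes)
  induced <- logical(n); cluster <- rep(NA_integer_, n)
  for (g in seq_len(n)) {
    t1 <- stats::t.test(y[g, i_lps], y[g, i_ctrl])
    induced[g] <- t1$p.value < alpha &&
      mean(y[g, i_lps]) > mean(y[g, i_ctrl])
    if (!induced[g]) next
    t2 <- stats::t.test(y[g, i_pre], y[g, i_lps])
    cluster[g] <- if (t2$p.value < alpha) {
      if (mean(y[g, i_pre]) < mean(y[g, i_lps])) 1L else 3L
    } else 2L
  }
  data.frame(gene_id = genes, lps_induced = induced, cluster = cluster,
             label = c("attenuated", "insensitive", "increased")[cluster],
             row.names = NULL)
}

#' Write / read gene cluster assignments
#'
#' @param path file path.
#' @param x data frame with at least `gene_id` and `cluster`.
#' @return `path` (writer) or a data frame (reader).
#' @export
write_gene_clusters <- function(path, x) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_clusters
#' @export
read_gene_clusters <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
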