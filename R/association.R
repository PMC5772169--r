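# Domain-constrained association between enhancer classes and gene
# clusters: co-occurrence counts within domains, column-scaled.

.point_positions <- function(items, position) {
  switch(position,
    summit = items$summit,
    tss = {
      if (is.null(items$strand)) .stop("TSS positions need a strand column")
      ifelse(items$strand == "-", items$end - 1L, items$start)
    },
    point = items$pos,
    .stop("unknown position type: ", position)
  )
}

#' Assign point features to domains
#'
#' Peaks are located by their summit, genes by their TSS (BED6 strand
#' rules: `start` for `+`, `end - 1` for `-`). Containment is half-open:
#' a point at a domain start belongs to that domain, a point at its end
#' does not. Items outside every domain get `NA`.
#'
#' @param items data frame with `chrom` and, depending on `position`,
#'   `summit`, `pos`, or `start`/`end`/`strand` columns.
#' @param domains non-overlapping domain data frame (`chrom`, `start`,
#'   `end`).
#' @param position one of `"summit"`, `"tss"`, `"point"`.
#' @return `items` with a `domain_id` column (`chrom:start-end` or NA).
#' @export
assign_to_domains <- function(items, domains,
                              position = c("summit", "tss", "point")) {
  position <- match.arg(position)
  o <- order(domains$chrom, domains$start)
  d <- domains[o, , drop = FALSE]
  if (nrow(d) > 1L) {
    same <- d$chrom[-1L] == d$chrom[-nrow(d)]
    if (any(same & d$start[-1L] < d$end[-nrow(d)])) {
      .stop("domains must be non-overlapping for assignment")
    }
  }
  items$domain_id <- NA_character_
  if (nrow(items) == 0L || nrow(d) == 0L) return(items)
  p <- .point_positions(items, position)
  gr_p <- GenomicRanges::GRanges(as.character(items$chrom),
                                 IRanges::IRanges(p + 1L, p + 1L))
  gr_d <- .as_granges(d)
  ov <- GenomicRanges::findOverlaps(gr_p, gr_d, select = "first")
  hit <- !is.na(ov)
  items$domain_id[hit] <- paste0(d$chrom[ov[hit]], ":", d$start[ov[hit]],
                                 "-", d$end[ov[hit]])
  items
}

#' Association matrix between peak classes and gene clusters
#'
#' Raw entry `[c, g]` counts, over all domains, the (peak of class c,
#' gene of cluster g) pairs sharing a domain (`mode = "pairs"`, default)
#' or the distinct class-c peaks sharing a domain with at least one
#' cluster-g gene (`mode = "unique_peaks"`). The scaled matrix
#' standardises each gene-cluster column to mean 0 and unit variance
#' (columns with zero variance become all-zero).
#'
#' @param peak_assignments data frame with `class` and `domain_id`
#'   (from [assign_to_domains()]); NA domains are ignored.
#' @param gene_assignments data frame with `cluster` and `domain_id`.
#' @param classes,clusters optional level sets fixing row/column order
#'   (empty levels produce zero rows/columns with a warning).
#' @param mode `"pairs"` or `"unique_peaks"`.
#' @return object of class `association_matrix`: list with `raw`,
#'   `scaled`, `mode`.
#' @export
association_scores <- function(peak_assignments, gene_assignments,
                               classes = NULL, clusters = NULL,
                               mode = c("pairs", "unique_peaks")) {
  mode <- match.arg(mode)
  pk <- peak_assignments[!is.na(peak_assignments$domain_id), , drop = FALSE]
  gn <- gene_assignments[!is.na(gene_assignments$domain_id), , drop = FALSE]
  classes <- classes %||% sort(unique(as.character(peak_assignments$class)))
  clusters <- clusters %||% sort(unique(as.character(gene_assignments$cluster)))
  if (!all(as.character(pk$class) %in% classes) ||
      !all(as.character(gn$cluster) %in% clusters)) {
    .stop("classes/clusters levels do not cover the assignments")
  }
  doms <- union(pk$domain_id, gn$domain_id)
  tab_p <- table(factor(pk$domain_id, levels = doms),
                 factor(pk$class, levels = classes))
  tab_g <- table(factor(gn$domain_id, levels = doms),
                 factor(gn$cluster, levels = clusters))
  m_p <- matrix(as.numeric(tab_p), nrow = length(doms),
                dimnames = list(doms, classes))
  m_g <- matrix(as.numeric(tab_g), nrow = length(doms),
                dimnames = list(doms, clusters))
  if (mode == "unique_peaks") m_g <- (m_g > 0) + 0
  raw <- t(m_p) %*% m_g
  if (any(rowSums(raw) == 0) || any(colSums(raw) == 0)) {
    warning("association matrix has empty class rows or cluster columns",
            call. = FALSE)
  }
  scaled <- apply(raw, 2L, function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  scaled <- matrix(scaled, nrow = nrow(raw), dimnames = dimnames(raw))
  structure(list(raw = raw, scaled = scaled, mode = mode),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("Association matrix (", x$mode, " mode)\nraw counts:\n", sep = "")
  print(x$raw)
  cat("column-scaled scores:\n")
  print(round(x$scaled, 3))
  invisible(x)
}

#' Write an association matrix as TSV
#'
#' @param path output path.
#' @param x an `association_matrix`.
#' @param which `"scaled"` (default) or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_association <- function(path, x, which = c("scaled", "raw")) {
  which <- match.arg(which)
  m <- x[[which]]
  out <- data.frame(class = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
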