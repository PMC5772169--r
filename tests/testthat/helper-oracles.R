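# Independent brute-force oracles, kept deliberately naive so they share
# no code path with the implementation they check.

# Single-linkage consensus by explicit connected components of the
# all-pairs distance graph (one chromosome).
bf_consensus <- function(pos, window_bp = 51, min_support = 2) {
  n <- length(pos)
  if (!n) return(data.frame(pos = numeric(), support = integer()))
  adj <- abs(outer(pos, pos, "-")) < window_bp
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- cid
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & is.na(comp))
      frontier <- nb
    }
  }
  out <- do.call(rbind, lapply(seq_len(cid), function(k) {
    members <- pos[comp == k]
    data.frame(pos = floor(mean(members) + 0.5), support = length(members))
  }))
  out <- out[out$support >= min_support, , drop = FALSE]
  out[order(out$pos), , drop = FALSE]
}

# Exhaustive PWM scanner: loops every offset on both strands.
bf_scan <- function(sequence, mat, min_score) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  w <- nrow(mat)
  L <- length(chars)
  rc <- function(x) rev(chartr("ACGT", "TGCA", x))
  score_win <- function(win) {
    s <- 0
    for (j in seq_len(w)) {
      if (!win[j] %in% c("A", "C", "G", "T")) return(-Inf)
      s <- s + mat[j, win[j]]
    }
    s
  }
  rows <- list()
  if (L >= w) {
    for (s0 in 0:(L - w)) {
      win <- chars[(s0 + 1):(s0 + w)]
      fs <- score_win(win)
      rs <- score_win(rc(win))
      if (fs >= min_score) {
        rows[[length(rows) + 1L]] <- data.frame(start = s0, end = s0 + w,
                                                strand = "+", score = fs)
      }
      if (rs >= min_score) {
        rows[[length(rows) + 1L]] <- data.frame(start = s0, end = s0 + w,
                                                strand = "-", score = rs)
      }
    }
  }
  out <- do.call(rbind, c(rows, list(data.frame(start = integer(),
                                                end = integer(),
                                                strand = character(),
                                                score = numeric()))))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive overlap-resolution oracle: the lexicographically best valid
# subset under the greedy priority (coverage desc, chrom, start, width).
bf_resolve <- function(domains) {
  n <- nrow(domains)
  keys <- data.frame(cov = -domains$pair_coverage, chrom = domains$chrom,
                     start = domains$start,
                     width = domains$end - domains$start)
  conflict <- outer(seq_len(n), seq_len(n), function(i, j) {
    domains$chrom[i] == domains$chrom[j] &
      domains$start[i] < domains$end[j] & domains$end[i] > domains$start[j]
  })
  diag(conflict) <- FALSE
  valid <- function(idx) {
    if (length(idx) < 2L) return(TRUE)
    !any(conflict[idx, idx])
  }
  key_order <- function(idx) {
    idx[order(keys$cov[idx], keys$chrom[idx], keys$start[idx],
              keys$width[idx])]
  }
  better <- function(a, b) {
    # TRUE if sorted subset a beats b under elementwise key comparison
    if (is.null(b)) return(TRUE)
    for (k in seq_len(max(length(a), length(b)))) {
      if (k > length(a)) return(FALSE)  # a exhausted first: a worse
      if (k > length(b)) return(TRUE)
      for (col in c("cov", "chrom", "start", "width")) {
        va <- keys[[col]][a[k]]; vb <- keys[[col]][b[k]]
        if (va < vb) return(TRUE)
        if (va > vb) return(FALSE)
      }
    }
    FALSE
  }
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (!length(idx) || !valid(idx)) next
    cand <- key_order(idx)
    if (better(cand, best)) best <- cand
  }
  out <- domains[sort(best), , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_domain_set <- function(n, two_chroms = FALSE) {
  chrom <- if (two_chroms) sample(c("chrA", "chrB"), n, replace = TRUE)
           else rep("chrA", n)
  start <- sample.int(50000L, n)
  len <- sample(2000:20000, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + len,
             kind = "convergent", pair_coverage = round(runif(n, 1, 100), 6),
             left_ctcf_rpkm = 1, left_cohesin_rpkm = 1,
             right_ctcf_rpkm = 1, right_cohesin_rpkm = 1)
}

random_pwm <- function(width = 6) {
  pwm(matrix(round(runif(width * 4, -4, 4), 3), nrow = width))
}

random_dna <- function(n, with_n = FALSE) {
  alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

# Small quantified-insulator frame builder for domain tests.
make_insulators <- function(pos, orientation, ctcf, cohesin,
                            chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos,
             cohesin_pos = pos + ifelse(orientation == "forward", 30, -30),
             ctcf_rpkm = ctcf, cohesin_rpkm = cohesin,
             orientation = orientation, orientation_source = "motif",
             motif_score = 10)
}

small_sim_config <- function(seed = 7, ...) {
  args <- list(
    seed = seed, chrom_lengths = c(chr1 = 3e6, chr2 = 3e6),
    n_convergent_pairs = 10, n_divergent = 3, n_unbalanced = 3,
    n_orphan = 2, domain_len_range = c(5e3, 8e4), margin_bp = 1e5,
    n_peaks_per_class = c(repressor = 30, neutral = 30, activator = 30),
    n_genes_per_cluster = 15, n_repressed_genes = 15, n_null_genes = 20,
    n_lps_genes_per_cluster = 10)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}
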