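# Synthetic study generator with planted ground truth.
#
# Emulates the inputs of the whole pipeline: many summit samples with
# positional jitter around planted insulators, a genome with embedded
# oriented CTCF motifs, balanced coverage tracks for convergent insulator
# pairs plus decoys, negative-binomial replicate counts with planted fold
# changes at enhancer subsets, and FPKM time courses with planted
# trajectory archetypes (and a knockout genotype without response).

.default_pwm <- function() {
  consensus <- strsplit("CCAGCAGAGGGC", "")[[1L]]
  m <- matrix(-3, nrow = length(consensus), ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(consensus)) m[i, consensus[i]] <- 1.5
  pwm(m)
}

#' Simulation configuration
#'
#' Defaults describe the reference study conditions: two 10 Mb
#' chromosomes, 50 planted convergent insulator pairs and 30 decoys
#' (divergent, coverage-unbalanced, and Cohesin-less orphan CTCF sites),
#' five summit samples per protein with 10 bp positional jitter, a 30 bp
#' CTCF-Cohesin offset, NB counts with dispersion 0.1 over three
#' replicates, planted 2-fold enhancer effects, and five-point FPKM time
#' courses with four induced archetypes, one repressed archetype and a
#' non-responding knockout genotype.
#'
#' Insulator coverage levels alternate between a low and a high band
#' (more than 2-fold apart) along each chromosome while both members of a
#' pair share a band; neighbouring elements therefore always fail the
#' domain-calling balance test, which keeps planted domains identifiable
#' from decoys on a compact genome.
#'
#' @param seed RNG seed; the whole bundle is a deterministic function of
#'   the config.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_convergent_pairs planted true domains.
#' @param n_divergent,n_unbalanced,n_orphan decoy counts.
#' @param domain_len_range planted domain length range (bp).
#' @param margin_bp element-free margin at chromosome ends.
#' @param summit_samples summit files per protein.
#' @param summit_jitter_sd per-sample summit jitter (bp, normal).
#' @param cohesin_offset_bp signed CTCF-to-Cohesin offset magnitude;
#'   Cohesin sits downstream of forward insulators.
#' @param coverage_bands low/high insulator coverage band means.
#' @param coverage_cv gamma coefficient of variation for coverage draws.
#' @param unbalanced_fold per-protein mean coverage ratio planted in
#'   unbalanced decoy pairs (> 2).
#' @param pwm motif matrix to embed and scan ([pwm()]); the default is a
#'   12 bp CTCF-like log-odds matrix.
#' @param n_peaks_per_class named vector: enhancers per planted class.
#' @param peak_width enhancer width (bp).
#' @param peak_log2_fc planted absolute log2 fold change at repressor and
#'   activator enhancers.
#' @param peak_mean_range range of per-region NB base means (counts).
#' @param nb_dispersion NB dispersion (variance = mu + disp * mu^2).
#' @param n_replicates count replicates per condition.
#' @param library_size nominal mapped reads per count sample.
#' @param n_genes_per_cluster genes per induced trajectory archetype.
#' @param n_repressed_genes genes in the repressed archetype.
#' @param n_null_genes unregulated genes.
#' @param expr_times time points (h), first is the control.
#' @param expr_replicates expression replicates per genotype and time.
#' @param expr_noise_sd log2 FPKM noise standard deviation.
#' @param ko_response_multiplier scales every planted response in the
#'   knockout genotype (0 = no response).
#' @param n_lps_genes_per_cluster genes per LPS-sensitivity cluster.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                              n_convergent_pairs = 50L,
                              n_divergent = 10L,
                              n_unbalanced = 10L,
                              n_orphan = 10L,
                              domain_len_range = c(5e3, 1.5e5),
                              margin_bp = 2e5,
                              summit_samples = 5L,
                              summit_jitter_sd = 10,
                              cohesin_offset_bp = 30L,
                              coverage_bands = c(10, 45),
                              coverage_cv = 0.15,
                              unbalanced_fold = 3,
                              pwm = .default_pwm(),
                              n_peaks_per_class = c(repressor = 100L,
                                                    neutral = 100L,
                                                    activator = 100L),
                              peak_width = 500L,
                              peak_log2_fc = 1,
                              peak_mean_range = c(100, 400),
                              nb_dispersion = 0.1,
                              n_replicates = 3L,
                              library_size = 2e7,
                              n_genes_per_cluster = 60L,
                              n_repressed_genes = 60L,
                              n_null_genes = 120L,
                              expr_times = c(0, 1, 3, 6, 24),
                              expr_replicates = 3L,
                              expr_noise_sd = 0.25,
                              ko_response_multiplier = 0,
                              n_lps_genes_per_cluster = 40L) {
  cfg <- as.list(environment())
  # YAML round-trips turn named vectors into lists; accept both
  for (nm in c("chrom_lengths", "domain_len_range", "coverage_bands",
               "n_peaks_per_class", "peak_mean_range", "expr_times")) {
    cfg[[nm]] <- unlist(cfg[[nm]])
  }
  if (is.null(names(cfg$chrom_lengths))) {
    .stop("chrom_lengths must be named by chromosome")
  }
  if (is.null(names(cfg$n_peaks_per_class))) {
    .stop("n_peaks_per_class must be named by class")
  }
  stopifnot(all(cfg$chrom_lengths > 0), cfg$summit_jitter_sd >= 0,
            cfg$n_convergent_pairs >= 0, cfg$n_divergent >= 0,
            cfg$n_unbalanced >= 0, cfg$n_orphan >= 0,
            cfg$coverage_cv > 0, cfg$unbalanced_fold > 2,
            cfg$nb_dispersion >= 0, cfg$n_replicates >= 2,
            diff(cfg$domain_len_range) >= 0,
            cfg$domain_len_range[1] > 1000)
  structure(cfg, class = "simulation_config")
}

# Place insulator elements in disjoint slots along the chromosomes.
# Returns one row per insulator with its element (pair) id, type,
# orientation, true CTCF/Cohesin positions and coverage means.
.place_elements <- function(cfg) {
  types <- c(rep("convergent", cfg$n_convergent_pairs),
             rep("divergent", cfg$n_divergent),
             rep("unbalanced", cfg$n_unbalanced),
             rep("orphan", cfg$n_orphan))
  if (!length(types)) return(NULL)
  types <- sample(types)
  chroms <- names(cfg$chrom_lengths)
  chrom_of <- rep(chroms, length.out = length(types))
  chrom_of <- chrom_of[order(rep(seq_along(chroms),
                                 length.out = length(types)))]
  rows <- list()
  eid <- 0L
  for (ch in chroms) {
    idx <- which(chrom_of == ch)
    if (!length(idx)) next
    n_slots <- length(idx)
    usable <- cfg$chrom_lengths[[ch]] - 2 * cfg$margin_bp
    pitch <- floor(usable / n_slots)
    if (pitch < cfg$domain_len_range[2] + 5e4) {
      .stop("chromosome ", ch, " too short for the requested element count")
    }
    band_i <- 0L
    for (k in seq_along(idx)) {
      type <- types[idx[k]]
      eid <- eid + 1L
      slot_start <- cfg$margin_bp + (k - 1L) * pitch
      len <- round(stats::runif(1, cfg$domain_len_range[1],
                                cfg$domain_len_range[2]))
      left <- slot_start + round(stats::runif(1, 5e3, 2e4))
      right <- left + len
      if (type == "orphan") {
        level <- cfg$coverage_bands[1L + band_i %% 2L]
        rows[[length(rows) + 1L]] <- data.frame(
          element = eid, type = type, chrom = ch, pos = left,
          orientation = "forward", has_cohesin = FALSE,
          ctcf_mean = level, cohesin_mean = level)
        next
      }
      level <- cfg$coverage_bands[1L + band_i %% 2L]
      band_i <- band_i + 1L
      orient <- if (type == "divergent") c("reverse", "forward")
                else c("forward", "reverse")
      right_ctcf <- if (type == "unbalanced") level * cfg$unbalanced_fold
                    else level
      right_coh <- if (type == "unbalanced") level / cfg$unbalanced_fold
                   else level
      rows[[length(rows) + 1L]] <- data.frame(
        element = eid, type = type, chrom = ch,
        pos = c(left, right), orientation = orient, has_cohesin = TRUE,
        ctcf_mean = c(level, right_ctcf),
        cohesin_mean = c(level, right_coh))
    }
  }
  ins <- do.call(rbind, rows)
  ins$cohesin_pos <- ifelse(ins$orientation == "forward",
                            ins$pos + cfg$cohesin_offset_bp,
                            ins$pos - cfg$cohesin_offset_bp)
  # draw realised coverage around the planted means
  shape <- 1 / cfg$coverage_cv^2
  ins$ctcf_cov <- stats::rgamma(nrow(ins), shape, shape / ins$ctcf_mean)
  ins$cohesin_cov <- stats::rgamma(nrow(ins), shape, shape / ins$cohesin_mean)
  ins
}

.random_chromosome <- function(n) {
  # byte-level sampling: orders of magnitude faster than paste(collapse)
  rawToChar(sample(charToRaw("ACGT"), n, replace = TRUE))
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.embed_motifs <- function(seqs_chr, ins, cfg) {
  cons <- pwm_consensus(cfg$pwm)
  w <- nchar(cons)
  for (ch in unique(ins$chrom)) {
    sub <- ins[ins$chrom == ch, , drop = FALSE]
    starts <- sub$pos - floor(w / 2)
    if (any(diff(sort(starts)) < w)) {
      .stop("planted motifs overlap on ", ch,
            "; reduce element count or motif width")
    }
    s <- seqs_chr[[ch]]
    for (i in seq_len(nrow(sub))) {
      motif <- if (sub$orientation[i] == "forward") cons else .revcomp_chr(cons)
      substr(s, starts[i] + 1L, starts[i] + w) <- motif
    }
    seqs_chr[[ch]] <- s
  }
  seqs_chr
}

.jittered_summit_files <- function(ins, cfg, dir, protein) {
  use <- if (protein == "ctcf") rep(TRUE, nrow(ins)) else ins$has_cohesin
  truepos <- if (protein == "ctcf") ins$pos else ins$cohesin_pos
  paths <- character(cfg$summit_samples)
  for (s in seq_len(cfg$summit_samples)) {
    p <- truepos[use] +
      round(stats::rnorm(sum(use), 0, cfg$summit_jitter_sd))
    p <- pmax(p, 0)
    bed <- data.frame(chrom = ins$chrom[use], start = p, end = p + 1L)
    bed <- bed[order(bed$chrom, bed$start), ]
    paths[s] <- file.path(dir, sprintf("%s_sample%02d.bed", protein, s))
    write_intervals(paths[s], bed)
  }
  paths
}

.coverage_tracks <- function(ins, cfg, dir) {
  half <- 100L
  ctcf <- data.frame(chrom = ins$chrom, start = ins$pos - half,
                     end = ins$pos + half, value = round(ins$ctcf_cov, 4))
  coh_rows <- ins$has_cohesin
  coh <- data.frame(chrom = ins$chrom[coh_rows],
                    start = ins$cohesin_pos[coh_rows] - half,
                    end = ins$cohesin_pos[coh_rows] + half,
                    value = round(ins$cohesin_cov[coh_rows], 4))
  ctcf <- ctcf[order(ctcf$chrom, ctcf$start), ]
  coh <- coh[order(coh$chrom, coh$start), ]
  p1 <- file.path(dir, "ctcf_coverage.bedgraph")
  p2 <- file.path(dir, "cohesin_coverage.bedgraph")
  write_bedgraph(p1, ctcf)
  write_bedgraph(p2, coh)
  c(ctcf = p1, cohesin = p2)
}

.truth_domains <- function(ins) {
  conv <- ins[ins$type == "convergent", , drop = FALSE]
  if (!nrow(conv)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), element = integer(),
                      theme = character()))
  }
  out <- do.call(rbind, lapply(split(conv, conv$element), function(e) {
    data.frame(chrom = e$chrom[1L], start = min(e$pos), end = max(e$pos),
               element = e$element[1L])
  }))
  out <- out[order(out$chrom, out$start), ]
  # alternate planted regulatory themes across true domains
  out$theme <- rep(c("activated", "repressed"), length.out = nrow(out))
  rownames(out) <- NULL
  out
}

.place_in_domains <- function(n, domains, pad) {
  # round-robin placement of n points over the given domains' interiors
  dom_idx <- rep(seq_len(nrow(domains)), length.out = n)
  lo <- domains$start[dom_idx] + pad
  hi <- domains$end[dom_idx] - pad
  pos <- round(stats::runif(n, lo, hi))
  data.frame(chrom = domains$chrom[dom_idx], pos = pos,
             domain_element = domains$element[dom_idx])
}

.simulate_peaks <- function(cfg, truth_dom, dir) {
  act <- truth_dom[truth_dom$theme == "activated", , drop = FALSE]
  rep_ <- truth_dom[truth_dom$theme == "repressed", , drop = FALSE]
  pick <- function(cl) {
    d <- switch(cl, repressor = rep_, activator = act, neutral = truth_dom)
    if (nrow(d)) d else truth_dom
  }
  rows <- lapply(names(cfg$n_peaks_per_class), function(cl) {
    n <- cfg$n_peaks_per_class[[cl]]
    if (!n || !nrow(truth_dom)) return(NULL)
    pl <- .place_in_domains(n, pick(cl), pad = 1500L)
    data.frame(class = cl, chrom = pl$chrom, summit = pl$pos)
  })
  peaks <- do.call(rbind, rows)
  if (is.null(peaks) || !nrow(peaks)) {
    np_path <- file.path(dir, "peaks.narrowPeak")
    file.create(np_path)
    return(list(truth = data.frame(peak_id = character(),
                                   chrom = character(), start = integer(),
                                   end = integer(), summit = integer(),
                                   class = character()),
                narrowpeak = np_path, counts = NA_character_,
                design = NA_character_))
  }
  peaks$start <- peaks$summit - cfg$peak_width %/% 2L
  peaks$end <- peaks$start + cfg$peak_width
  peaks <- peaks[order(peaks$chrom, peaks$start), ]
  peaks$peak_id <- sprintf("peak%04d", seq_len(nrow(peaks)))
  np <- data.frame(chrom = peaks$chrom, start = peaks$start,
                   end = peaks$end, name = peaks$peak_id, score = 0,
                   strand = ".", signal = 0, pvalue = -1, qvalue = -1,
                   offset = peaks$summit - peaks$start)
  np_path <- file.path(dir, "peaks.narrowPeak")
  utils::write.table(np, np_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # replicate counts: co-factor signal at the peaks
  n <- nrow(peaks)
  mu0 <- stats::runif(n, cfg$peak_mean_range[1], cfg$peak_mean_range[2])
  effect <- c(repressor = -1, neutral = 0, activator = 1)[peaks$class] *
    cfg$peak_log2_fc
  libs <- round(cfg$library_size *
                  stats::runif(2L * cfg$n_replicates, 0.9, 1.1))
  cond <- rep(c("control", "treated"), each = cfg$n_replicates)
  counts <- matrix(0L, n, length(cond))
  for (j in seq_along(cond)) {
    mu <- mu0 * (libs[j] / cfg$library_size)
    if (cond[j] == "treated") mu <- mu * 2^effect
    counts[, j] <- stats::rnbinom(n, mu = mu,
                                  size = if (cfg$nb_dispersion > 0)
                                    1 / cfg$nb_dispersion else Inf)
  }
  colnames(counts) <- paste0(cond, "_rep", rep(seq_len(cfg$n_replicates), 2L))
  rownames(counts) <- peaks$peak_id
  rc <- replicate_counts(counts, cond, rep(cfg$peak_width, n), libs)
  write_counts_table(file.path(dir, "peak_counts.tsv"),
                     file.path(dir, "peak_design.tsv"), rc)
  list(truth = peaks[, c("peak_id", "chrom", "start", "end", "summit",
                         "class")],
       narrowpeak = np_path,
       counts = file.path(dir, "peak_counts.tsv"),
       design = file.path(dir, "peak_design.tsv"))
}

.archetype_profiles <- function(times) {
  # induced archetypes peak at successive time points; one repressed
  t_idx <- seq_along(times[-1L])
  profs <- list(
    A = c(0, 2.4, 1.2, 0.4, 0.1),
    B = c(0, 2.0, 2.3, 1.9, 1.6),
    C = c(0, 0.8, 1.8, 2.3, 1.1),
    D = c(0, 0.2, 0.8, 1.6, 2.4),
    E = c(0, -0.6, -1.6, -1.9, -1.7)
  )
  if (length(times) != 5L) {
    .stop("default archetypes are defined for five time points")
  }
  profs
}

.simulate_expression <- function(cfg, truth_dom, dir) {
  profs <- .archetype_profiles(cfg$expr_times)
  n_ind <- cfg$n_genes_per_cluster
  clusters <- c(rep(c("A", "B", "C", "D"), each = n_ind),
                rep("E", cfg$n_repressed_genes),
                rep(NA_character_, cfg$n_null_genes))
  n <- length(clusters)
  gene_id <- sprintf("gene%04d", seq_len(n))
  base <- stats::runif(n, 2, 6)  # log2 baseline FPKM
  genotypes <- c("WT", "KO")
  cols <- list(); vals <- list()
  for (gt in genotypes) {
    mult <- if (gt == "WT") 1 else cfg$ko_response_multiplier
    for (ti in seq_along(cfg$expr_times)) {
      for (r in seq_len(cfg$expr_replicates)) {
        mu <- base + mult * vapply(clusters, function(cl) {
          if (is.na(cl)) 0 else profs[[cl]][ti]
        }, numeric(1L))
        y <- mu + stats::rnorm(n, 0, cfg$expr_noise_sd)
        cols[[length(cols) + 1L]] <- sprintf("%s_IL4_%s_%d", gt,
                                             cfg$expr_times[ti], r)
        vals[[length(vals) + 1L]] <- round(2^y, 4)
      }
    }
  }
  fpkm <- do.call(cbind, vals)
  dimnames(fpkm) <- list(gene_id, unlist(cols))
  path <- file.path(dir, "expression.tsv")
  write_expression_table(path, fpkm)
  # place regulated genes inside theme-matched planted domains
  act <- truth_dom[truth_dom$theme == "activated", , drop = FALSE]
  rep_ <- truth_dom[truth_dom$theme == "repressed", , drop = FALSE]
  tss <- rep(NA_real_, n); chrom <- rep(NA_character_, n)
  ind <- which(!is.na(clusters) & clusters != "E")
  if (length(ind) && nrow(act)) {
    pl <- .place_in_domains(length(ind), act, pad = 1200L)
    tss[ind] <- pl$pos; chrom[ind] <- pl$chrom
  }
  rp <- which(clusters == "E")
  if (length(rp) && nrow(rep_)) {
    pl <- .place_in_domains(length(rp), rep_, pad = 1200L)
    tss[rp] <- pl$pos; chrom[rp] <- pl$chrom
  }
  # genes that could not be placed in a matching domain fall outside
  lost <- which(is.na(tss) & !is.na(clusters))
  if (length(lost)) {
    chrom[lost] <- sample(names(cfg$chrom_lengths), length(lost),
                          replace = TRUE)
    tss[lost] <- round(stats::runif(length(lost), 1e4, cfg$margin_bp - 1e4))
  }
  nul <- which(is.na(clusters))
  if (length(nul)) {
    # null genes live between slots, outside every planted domain
    ch <- sample(names(cfg$chrom_lengths), length(nul), replace = TRUE)
    tss[nul] <- round(stats::runif(length(nul), 1e4, cfg$margin_bp - 1e4))
    chrom[nul] <- ch
  }
  strand <- rep(c("+", "-"), length.out = n)
  genes_bed <- data.frame(chrom = chrom,
                          start = ifelse(strand == "+", tss, tss - 1999),
                          end = ifelse(strand == "+", tss + 2000, tss + 1),
                          name = gene_id, score = 0, strand = strand)
  genes_bed <- genes_bed[order(genes_bed$chrom, genes_bed$start), ]
  bed_path <- file.path(dir, "genes.bed")
  write_intervals(bed_path, genes_bed)
  list(truth = data.frame(gene_id = gene_id, cluster = clusters,
                          regulated = !is.na(clusters), chrom = chrom,
                          tss = tss, strand = strand),
       expression = path, genes_bed = bed_path)
}

.simulate_lps <- function(cfg, dir) {
  n_cl <- cfg$n_lps_genes_per_cluster
  groups <- c(rep("attenuated", n_cl), rep("insensitive", n_cl),
              rep("increased", n_cl), rep("not_induced", n_cl))
  n <- length(groups)
  gene_id <- sprintf("lps%04d", seq_len(n))
  base <- stats::runif(n, 2, 5)
  lps_eff <- ifelse(groups == "not_induced", 0, 2.5)
  pre_mult <- c(attenuated = 0.5, insensitive = 1, increased = 1.5,
                not_induced = 1)[groups]
  cols <- list(); vals <- list()
  for (tr in c("control", "LPS", "IL4LPS")) {
    eff <- switch(tr, control = 0, LPS = lps_eff, IL4LPS = lps_eff * pre_mult)
    for (r in seq_len(cfg$expr_replicates)) {
      y <- base + eff + stats::rnorm(n, 0, cfg$expr_noise_sd)
      cols[[length(cols) + 1L]] <- sprintf("WT_%s_3_%d", tr, r)
      vals[[length(vals) + 1L]] <- round(2^y, 4)
    }
  }
  fpkm <- do.call(cbind, vals)
  dimnames(fpkm) <- list(gene_id, unlist(cols))
  path <- file.path(dir, "lps_expression.tsv")
  write_expression_table(path, fpkm)
  list(truth = data.frame(gene_id = gene_id, group = groups),
       expression = path)
}

#' Generate a complete synthetic study bundle
#'
#' Writes every input the pipeline consumes into `out_dir` and returns
#' the planted ground truth. The bundle is a pure function of the
#' configuration: identical configs produce byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `paths` (named file paths), `truth` (planted
#'   domains, insulators, peaks, genes, LPS groups), and `config`.
#' @export
simulate_study <- function(config = simulation_config(), out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  ins <- .place_elements(config)
  genome <- genome_index(names(config$chrom_lengths),
                         unname(config$chrom_lengths))
  seqs_chr <- lapply(stats::setNames(nm = names(config$chrom_lengths)),
                     function(ch) .random_chromosome(config$chrom_lengths[[ch]]))
  seqs_chr <- .embed_motifs(seqs_chr, ins, config)
  fasta <- file.path(out_dir, "genome.fa")
  write_genome_fasta(fasta, unlist(seqs_chr))
  pwm_path <- file.path(out_dir, "ctcf.pwm")
  write_pwm(pwm_path, config$pwm)
  summit_dir <- file.path(out_dir, "summits")
  dir.create(summit_dir, showWarnings = FALSE)
  ctcf_beds <- .jittered_summit_files(ins, config, summit_dir, "ctcf")
  cohesin_beds <- .jittered_summit_files(ins, config, summit_dir, "cohesin")
  tracks <- .coverage_tracks(ins, config, out_dir)
  truth_dom <- .truth_domains(ins)
  pk <- .simulate_peaks(config, truth_dom, out_dir)
  ex <- .simulate_expression(config, truth_dom, out_dir)
  lps <- .simulate_lps(config, out_dir)
  truth_ins <- ins[, c("element", "type", "chrom", "pos", "cohesin_pos",
                       "orientation", "has_cohesin", "ctcf_cov",
                       "cohesin_cov")]
  truth_dir <- file.path(out_dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(truth_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(truth_dom, "domains.tsv")
  wt(truth_ins, "insulators.tsv")
  wt(pk$truth, "peaks.tsv")
  wt(ex$truth, "genes.tsv")
  wt(lps$truth, "lps_groups.tsv")
  list(paths = list(genome = fasta, pwm = pwm_path,
                    ctcf_summits = ctcf_beds, cohesin_summits = cohesin_beds,
                    ctcf_bedgraph = unname(tracks["ctcf"]),
                    cohesin_bedgraph = unname(tracks["cohesin"]),
                    peaks = pk$narrowpeak, peak_counts = pk$counts,
                    peak_design = pk$design, expression = ex$expression,
                    genes_bed = ex$genes_bed, lps_expression = lps$expression),
       truth = list(domains = truth_dom, insulators = truth_ins,
                    peaks = pk$truth, genes = ex$truth, lps = lps$truth),
       genome_index = genome,
       config = config)
}

#' Domain recovery against planted truth
#'
#' A planted domain is recovered when a predicted convergent domain on
#' the same chromosome has both boundaries within `tolerance_bp`;
#' matching is one-to-one (greedy by boundary error).
#'
#' @param predicted predicted convergent domain data frame.
#' @param truth planted domain data frame (`chrom`, `start`, `end`).
#' @param tolerance_bp boundary tolerance (default 51).
#' @return list with `recall`, `precision`, `n_truth`, `n_predicted`,
#'   `matched` (indices into `truth` per predicted row, NA if unmatched).
#' @export
evaluate_domains <- function(predicted, truth, tolerance_bp = 51) {
  n_t <- nrow(truth); n_p <- nrow(predicted)
  if (n_p == 0L || n_t == 0L) {
    return(list(recall = if (n_t) 0 else NaN,
                precision = if (n_p) 0 else NaN,
                n_truth = n_t, n_predicted = n_p,
                matched = rep(NA_integer_, n_p)))
  }
  matched <- rep(NA_integer_, n_p)
  taken <- logical(n_t)
  for (i in seq_len(n_p)) {
    cand <- which(!taken & truth$chrom == predicted$chrom[i] &
                    abs(truth$start - predicted$start[i]) <= tolerance_bp &
                    abs(truth$end - predicted$end[i]) <= tolerance_bp)
    if (length(cand)) {
      err <- abs(truth$start[cand] - predicted$start[i]) +
        abs(truth$end[cand] - predicted$end[i])
      j <- cand[which.min(err)]
      matched[i] <- j
      taken[j] <- TRUE
    }
  }
  list(recall = sum(taken) / n_t, precision = sum(!is.na(matched)) / n_p,
       n_truth = n_t, n_predicted = n_p, matched = matched)
}

#' Peak-class recovery against planted truth
#'
#' @param predicted data frame `peak_id`, `class`.
#' @param truth data frame `peak_id`, `class`.
#' @return list with the confusion `table`, per-true-class `sensitivity`,
#'   overall false-positive rate on planted-neutral peaks (`fpr`), and
#'   `sign_accuracy` (detected repressor/activator calls whose direction
#'   matches the planted one).
#' @export
evaluate_peak_classes <- function(predicted, truth) {
  m <- merge(truth, predicted, by = "peak_id", suffixes = c("_true", "_pred"))
  tab <- table(true = m$class_true, predicted = m$class_pred)
  lev <- c("repressor", "neutral", "activator")
  sens <- vapply(intersect(lev, rownames(tab)), function(cl) {
    sum(m$class_pred == cl & m$class_true == cl) / sum(m$class_true == cl)
  }, numeric(1L))
  fpr <- if (any(m$class_true == "neutral")) {
    mean(m$class_pred[m$class_true == "neutral"] != "neutral")
  } else NaN
  det <- m$class_true %in% c("repressor", "activator") &
    m$class_pred != "neutral"
  sign_acc <- if (any(det)) {
    mean(m$class_pred[det] == m$class_true[det])
  } else NaN
  list(table = tab, sensitivity = sens, fpr = fpr, sign_accuracy = sign_acc)
}

#' Gene-cluster recovery (adjusted Rand index)
#'
#' @param predicted data frame `gene_id`, `cluster`.
#' @param truth data frame `gene_id`, `cluster` (NA rows dropped).
#' @return the adjusted Rand index over the shared, labelled genes.
#' @export
evaluate_gene_clusters <- function(predicted, truth) {
  t2 <- truth[!is.na(truth$cluster), , drop = FALSE]
  m <- merge(t2, predicted, by = "gene_id", suffixes = c("_true", "_pred"))
  if (!nrow(m)) return(NaN)
  mclust::adjustedRandIndex(m$cluster_true, m$cluster_pred)
}
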