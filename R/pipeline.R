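# End-to-end orchestration: consensus -> insulators -> orient -> domains
# -> classify-peaks -> cluster-genes -> associate, with a structured run
# manifest and per-stage logging to stderr.

.pipeline_defaults <- function() {
  list(window_bp = 51L, min_support = 2L, flank_bp = 50L,
       min_score = 6.0, search_flank_bp = 100L, clear_direction_min_bp = 5L,
       prefer = "direction", coverage_fraction = 1e-5,
       filter_mode = "retain", min_bp = 1000L, max_bp = 1e6, max_fold = 2.0,
       alpha = 0.05, fdr = FALSE, fc_cut = 2.0, k_induced = 4L,
       association_mode = "pairs")
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.run_stage <- function(name, manifest, inputs, fun) {
  .stage_log(name, "starting")
  missing_in <- inputs[!vapply(inputs, function(p)
    is.na(p) || file.exists(p), logical(1L))]
  if (length(missing_in)) {
    .stop("stage '", name, "' failed: missing input(s): ",
          paste(unlist(missing_in), collapse = ", "))
  }
  res <- tryCatch(fun(), error = function(e) {
    .stop("stage '", name, "' failed: ", conditionMessage(e))
  })
  .stage_log(name, sprintf("done (%d records)", res$n %||% NA_integer_))
  manifest$stages[[name]] <- list(inputs = unlist(inputs, use.names = FALSE),
                                  outputs = res$outputs,
                                  n_records = res$n)
  manifest
}

#' Run the full sub-domain pipeline
#'
#' Executes every stage in order on the inputs named in `config` and
#' writes the outputs plus a JSON run manifest into `out_dir`. With a
#' `simulate` entry in the config, the synthetic bundle is generated
#' first and its files become the inputs. Re-running with an unchanged
#' config and seed reproduces every output byte for byte.
#'
#' Config structure (a list, or the path of a YAML file with the same
#' shape): `seed`; optional `simulate` (arguments for
#' [simulation_config()], or `TRUE` for the defaults); otherwise an
#' `inputs` list with `ctcf_summits`, `cohesin_summits` (vectors of BED
#' paths), `ctcf_bedgraph`, `cohesin_bedgraph`, `genome`, `pwm`, and
#' optionally `peak_counts` + `peak_design`, `expression`, `genes_bed`;
#' and an optional `params` list overriding the stage parameters
#' (window_bp, min_support, flank_bp, min_score, search_flank_bp,
#' clear_direction_min_bp, prefer, coverage_fraction, filter_mode,
#' min_bp, max_bp, max_fold, alpha, fdr, fc_cut, k_induced,
#' association_mode).
#'
#' @param config list or YAML file path.
#' @param out_dir output directory.
#' @return the run manifest (invisibly); also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- utils::modifyList(.pipeline_defaults(), config$params %||% list())
  seed <- config$seed %||% 1L
  manifest <- list(tool = "subtadr",
                   version = as.character(utils::packageVersion("subtadr")),
                   config_hash = .config_hash(config),
                   seed = seed, stages = list())

  inputs <- config$inputs
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- if (isTRUE(config$simulate)) list() else config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    cfg <- do.call(simulation_config, sim_args)
    sim_dir <- file.path(out_dir, "simulated")
    manifest <- .run_stage("simulate", manifest, list(), function() {
      sim <- simulate_study(cfg, sim_dir)
      inputs <<- sim$paths
      truth <<- sim$truth
      list(outputs = unlist(sim$paths, use.names = FALSE),
           n = length(unlist(sim$paths)))
    })
  }
  if (is.null(inputs)) .stop("config provides neither inputs nor simulate")

  # consensus summits per protein
  cons <- list()
  for (prot in c("ctcf", "cohesin")) {
    paths <- inputs[[paste0(prot, "_summits")]]
    out_bed <- file.path(out_dir, paste0("consensus_", prot, ".bed"))
    manifest <- .run_stage(paste0("consensus-", prot), manifest,
                           as.list(paths), function() {
      summits <- do.call(rbind, lapply(seq_along(paths), function(i) {
        read_summits(paths[i], sample_id = basename(paths[i]))
      }))
      cc <- consensus_summits(summits, window_bp = params$window_bp,
                              min_support = params$min_support)
      write_intervals(out_bed, data.frame(chrom = cc$chrom, start = cc$pos,
                                          end = cc$pos + 1L,
                                          name = paste0("c", seq_len(nrow(cc))),
                                          score = cc$support))
      cons[[prot]] <<- cc
      list(outputs = out_bed, n = nrow(cc))
    })
  }

  ins_path <- file.path(out_dir, "insulators.tsv")
  insulators <- NULL
  manifest <- .run_stage("insulators", manifest,
                         list(inputs$ctcf_bedgraph, inputs$cohesin_bedgraph),
                         function() {
    ins <- call_insulators(cons$ctcf, cons$cohesin,
                           window_bp = params$window_bp)
    ins <- quantify_insulators(ins,
                               read_bedgraph(inputs$ctcf_bedgraph),
                               read_bedgraph(inputs$cohesin_bedgraph),
                               flank_bp = params$flank_bp)
    write_insulators(ins_path, ins)
    insulators <<- ins
    list(outputs = ins_path, n = nrow(ins))
  })

  oriented_path <- file.path(out_dir, "insulators_oriented.tsv")
  manifest <- .run_stage("orient", manifest,
                         list(inputs$genome, inputs$pwm), function() {
    genome_seqs <- read_genome_fasta(inputs$genome)
    mat <- read_pwm(inputs$pwm)
    ins <- orient_insulators(insulators, genome_seqs, mat,
                             min_score = params$min_score,
                             search_flank_bp = params$search_flank_bp,
                             clear_direction_min_bp =
                               params$clear_direction_min_bp,
                             prefer = params$prefer)
    write_insulators(oriented_path, ins)
    insulators <<- ins
    list(outputs = oriented_path, n = nrow(ins))
  })

  domains_path <- file.path(out_dir, "domains.bed")
  domains <- NULL
  manifest <- .run_stage("domains", manifest, list(oriented_path),
                         function() {
    dom <- predict_domains(insulators,
                           fraction = params$coverage_fraction,
                           filter_mode = params$filter_mode,
                           min_bp = params$min_bp, max_bp = params$max_bp,
                           max_fold = params$max_fold)
    write_domains(domains_path, dom)
    domains <<- dom
    list(outputs = domains_path, n = nrow(dom))
  })

  classes <- NULL
  if (!is.null(inputs$peak_counts) && !is.na(inputs$peak_counts)) {
    classes_path <- file.path(out_dir, "peak_classes.tsv")
    manifest <- .run_stage("classify-peaks", manifest,
                           list(inputs$peak_counts, inputs$peak_design),
                           function() {
      rc <- read_counts_table(inputs$peak_counts, inputs$peak_design)
      cls <- classify_peaks(rc, alpha = params$alpha, fdr = params$fdr)
      utils::write.table(cls, classes_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      classes <<- cls
      list(outputs = classes_path, n = nrow(cls))
    })
  }

  clusters <- NULL
  if (!is.null(inputs$expression) && !is.na(inputs$expression)) {
    clusters_path <- file.path(out_dir, "gene_clusters.tsv")
    manifest <- .run_stage("cluster-genes", manifest,
                           list(inputs$expression), function() {
      et <- expressed_genes(read_expression_table(inputs$expression))
      calls <- call_regulated(et, fc_cut = params$fc_cut,
                              alpha = params$alpha)
      fc <- fold_change_matrix(et)
      reg <- calls$gene_id[calls$regulated]
      cl <- trajectory_clusters(fc[reg, , drop = FALSE],
                                k_induced = params$k_induced, seed = seed)
      out <- merge(calls, cl, by = "gene_id", all.x = TRUE)
      out <- out[order(out$gene_id), ]
      write_gene_clusters(clusters_path, out)
      clusters <<- out
      list(outputs = clusters_path, n = nrow(out))
    })
  }

  if (!is.null(classes) && !is.null(clusters) &&
      !is.null(inputs$genes_bed) && !is.na(inputs$genes_bed)) {
    assoc_path <- file.path(out_dir, "association.tsv")
    assoc_raw_path <- file.path(out_dir, "association_raw.tsv")
    manifest <- .run_stage("associate", manifest,
                           list(inputs$peaks, inputs$genes_bed), function() {
      peaks <- read_narrowpeak(inputs$peaks)
      peaks <- merge(peaks, classes, by.x = "name", by.y = "peak_id")
      conv <- domains[domains$kind == "convergent", , drop = FALSE]
      pk <- assign_to_domains(peaks, domains, position = "summit")
      genes <- read_bed(inputs$genes_bed)
      genes <- merge(genes, clusters[!is.na(clusters$cluster),
                                     c("gene_id", "cluster")],
                     by.x = "name", by.y = "gene_id")
      gn <- assign_to_domains(genes, domains, position = "tss")
      am <- association_scores(pk, gn, mode = params$association_mode)
      write_association(assoc_path, am, "scaled")
      write_association(assoc_raw_path, am, "raw")
      list(outputs = c(assoc_path, assoc_raw_path),
           n = length(am$raw))
    })
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  .stage_log("pipeline", "complete; manifest at ", manifest_path)
  invisible(manifest)
}
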