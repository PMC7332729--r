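#' Pipeline configuration
#'
#' Collects every stage threshold of the integrative analysis in one
#' validated object: the miRNA abundance filter, the DE fold-change and
#' p-value cutoffs, the duplex score and energy cutoffs, and the two
#' correlation filters (miRNA anticorrelation, TF coexpression). Input is
#' either a dataset directory (as written by [write_dataset()]) or a
#' [simulate_config()] to generate one.
#'
#' @param out_dir output directory for all stage results.
#' @param input dataset directory (`NULL` to simulate).
#' @param simulate a [simulate_config()] (`NULL` to read `input`).
#' @param min_reads miRNA abundance filter, inclusive (default 10).
#' @param fc_threshold DE fold change, strict `>` (default 2).
#' @param p_de DE p-value, strict `<` (default 0.01).
#' @param score_threshold duplex score, strict `>` (default 145).
#' @param energy_threshold duplex energy kcal/mol, strict `<`
#'   (default -10).
#' @param r_anticorr miRNA-target correlation, strict `<` (default -0.58).
#' @param p_anticorr its p-value, strict `<` (default 0.05).
#' @param r_tf TF-target correlation, strict `>` (default 0.90).
#' @param p_tf its p-value, strict `<` (default 0.01).
#' @param log_transform correlate on `log2(value + 1)` (default `TRUE`).
#' @param scan_all_genes scan the 3'-UTRs of all genes instead of only
#'   the differentially expressed ones (default `FALSE`: targets are
#'   sought among the diet-modulated mRNAs).
#' @param scheme,model optional [scoring_scheme()] / [energy_model()]
#'   overrides (thresholds above take precedence).
#' @param seed integer seed; overrides the simulate config's seed when
#'   given.
#' @return an object of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir, input = NULL, simulate = NULL,
                            min_reads = 10, fc_threshold = 2, p_de = 0.01,
                            score_threshold = 145, energy_threshold = -10,
                            r_anticorr = -0.58, p_anticorr = 0.05,
                            r_tf = 0.90, p_tf = 0.01, log_transform = TRUE,
                            scan_all_genes = FALSE,
                            scheme = NULL, model = NULL, seed = NULL) {
  if (is.null(input) && is.null(simulate)) {
    stop("either an input dataset directory or a simulate config is required")
  }
  stopifnot(min_reads >= 0, fc_threshold >= 1, p_de > 0, p_de <= 1,
            r_anticorr < 0, r_anticorr > -1, p_anticorr > 0,
            r_tf > 0, r_tf < 1, p_tf > 0)
  if (is.null(scheme)) scheme <- scoring_scheme()
  if (is.null(model)) model <- energy_model()
  scheme$score_threshold <- score_threshold
  model$energy_threshold <- energy_threshold
  if (!is.null(simulate) && !is.null(seed)) {
    simulate$seed <- as.integer(seed)
  }
  structure(
    list(out_dir = out_dir, input = input, simulate = simulate,
         min_reads = min_reads, fc_threshold = fc_threshold, p_de = p_de,
         score_threshold = score_threshold,
         energy_threshold = energy_threshold, r_anticorr = r_anticorr,
         p_anticorr = p_anticorr, r_tf = r_tf, p_tf = p_tf,
         log_transform = log_transform,
         scan_all_genes = isTRUE(scan_all_genes),
         scheme = scheme, model = model,
         seed = if (is.null(seed) && !is.null(simulate)) simulate$seed
                else seed),
    class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML tree mirrors [pipeline_config()]: top-level `out_dir`,
#' `input`, `seed`, `log_transform`, a `simulate:` section passed to
#' [simulate_config()], a `thresholds:` section (`min_reads`, `fc`,
#' `p_de`, `score`, `energy`, `r_anticorr`, `p_anticorr`, `r_tf`,
#' `p_tf`), and optional `scoring:` / `energy_model:` override sections.
#'
#' @param path YAML file.
#' @param out_dir,seed optional overrides of the file's values.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  thr <- y$thresholds
  args <- list(
    out_dir = if (!is.null(out_dir)) out_dir else y$out_dir,
    input = y$input,
    seed = if (!is.null(seed)) seed else y$seed)
  if (!is.null(y$simulate)) {
    args$simulate <- do.call(simulate_config, c(
      y$simulate,
      if (is.null(y$simulate$seed))
        list(seed = if (is.null(args$seed)) 1L else args$seed)))
  }
  thr_map <- c(min_reads = "min_reads", fc = "fc_threshold", p_de = "p_de",
               score = "score_threshold", energy = "energy_threshold",
               r_anticorr = "r_anticorr", p_anticorr = "p_anticorr",
               r_tf = "r_tf", p_tf = "p_tf")
  for (k in names(thr_map)) {
    if (!is.null(thr[[k]])) args[[thr_map[[k]]]] <- thr[[k]]
  }
  if (!is.null(y$log_transform)) args$log_transform <- y$log_transform
  if (!is.null(y$scan_all_genes)) args$scan_all_genes <- y$scan_all_genes
  if (!is.null(y$scoring)) {
    args$scheme <- do.call(scoring_scheme, y$scoring)
  }
  if (!is.null(y$energy_model)) {
    args$model <- do.call(energy_model, y$energy_model)
  }
  if (is.null(args$out_dir)) stop("config must provide out_dir")
  do.call(pipeline_config, args)
}

#' Run the integrative miRNA-TF-mRNA pipeline end-to-end
#'
#' Stages: load/simulate -> miRNA abundance filter -> RPKM/CPM
#' quantification -> sample correlation + clustering -> differential
#' expression per diet comparison (NE vs RE at each shared stage) ->
#' duplex scan of DE miRNAs against the 3'-UTRs of DE mRNAs ->
#' anticorrelation filter -> TF coexpression loop expansion -> network
#' assembly -> (when ground truth is available) recovery scoring. All
#' stage outputs are written under `config$out_dir` and checksummed into
#' a machine-readable run manifest.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list (class `RunResult`) with `network`, `de_genes`,
#'   `de_mirnas` (lists of [call_de()] tables by comparison), `hits`,
#'   `recovery` (or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- Sys.time()
  timings <- list()
  say <- function(...) if (!quiet) message("[mirloop] ", ...)
  tick <- function(stage) {
    timings[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
    t0 <<- Sys.time()
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say("thresholds: min_reads>=", config$min_reads,
      ", fc>", config$fc_threshold, ", p_de<", config$p_de,
      ", score>", config$score_threshold,
      ", energy<", config$energy_threshold,
      ", r_anticorr<", config$r_anticorr, " p<", config$p_anticorr,
      ", r_tf>", config$r_tf, " p<", config$p_tf)

  # -- load or simulate ---------------------------------------------------
  if (!is.null(config$simulate)) {
    say("simulating dataset (seed ", config$simulate$seed, ")")
    ds <- simulate_expression(config$simulate)
    write_dataset(ds, file.path(out, "dataset"), config$simulate)
  } else {
    say("reading dataset from ", config$input)
    ds <- read_dataset(config$input)
  }
  tick("load")

  # -- abundance filter and quantification -------------------------------
  mirna_f <- filter_min_reads(ds$mirna, config$min_reads)
  say(nrow(mirna_f$counts), "/", nrow(ds$mirna$counts),
      " miRNAs pass the abundance filter")
  mrna_expr <- compute_rpkm(ds$mrna)
  mirna_expr <- compute_cpm(mirna_f)
  tick("quantify")

  # -- sample correlations ------------------------------------------------
  corr_mrna <- sample_correlation_matrix(mrna_expr, config$log_transform)
  corr_mirna <- sample_correlation_matrix(mirna_expr, config$log_transform)
  write_correlation_tsv(corr_mrna, file.path(out, "corr_mrna.tsv"))
  write_correlation_tsv(corr_mirna, file.path(out, "corr_mirna.tsv"))
  clust <- tryCatch(cluster_samples(corr_mrna, mask_undefined = TRUE),
                    error = function(e) NULL)
  tick("correlate")

  # -- differential expression -------------------------------------------
  samples <- ds$samples
  stages <- sort(unique(samples$stage))
  cmp <- stages[vapply(stages, function(s) {
    all(c("NE", "RE") %in% samples$diet[samples$stage == s])
  }, logical(1))]
  de_genes <- list()
  de_mirnas <- list()
  for (s in cmp) {
    a <- samples$sample_id[samples$diet == "NE" & samples$stage == s][1]
    b <- samples$sample_id[samples$diet == "RE" & samples$stage == s][1]
    lab <- sprintf("%s_vs_%s", a, b)
    de_genes[[lab]] <- call_de(ds$mrna, a, b, config$fc_threshold,
                               config$p_de)
    de_mirnas[[lab]] <- call_de(mirna_f, a, b, config$fc_threshold,
                                config$p_de)
    write_de_tsv(de_genes[[lab]], file.path(out, paste0("de_genes_", lab, ".tsv")))
    write_de_tsv(de_mirnas[[lab]], file.path(out, paste0("de_mirnas_", lab, ".tsv")))
    say(lab, ": ", sum(de_genes[[lab]]$is_de), " DE genes, ",
        sum(de_mirnas[[lab]]$is_de), " DE miRNAs")
  }
  de_mirna_union <- unique(unlist(lapply(de_mirnas, function(d) {
    d$feature_id[d$is_de]
  }), use.names = FALSE))
  if (length(de_mirnas) >= 2) {
    sets <- lapply(de_mirnas, function(d) d$feature_id[d$is_de])
    write.table(venn_regions(sets), file.path(out, "venn_de_mirnas.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tick("de")

  # -- duplex scan: DE miRNAs vs the UTRs of diet-modulated genes --------
  de_gene_union <- unique(unlist(lapply(de_genes, function(d) {
    d$feature_id[d$is_de]
  }), use.names = FALSE))
  scan_utrs <- if (config$scan_all_genes || !length(de_gene_union)) {
    ds$utr_seqs
  } else ds$utr_seqs[de_gene_union]
  if (length(de_mirna_union)) {
    hits <- scan_targets(ds$mirna_seqs[de_mirna_union], scan_utrs,
                         config$scheme, config$model)
  } else {
    warning("no DE miRNAs; the duplex scan is empty")
    hits <- scan_targets(ds$mirna_seqs[1], ds$utr_seqs[1],
                         scoring_scheme(score_threshold = Inf),
                         config$model)
  }
  say(nrow(hits), " duplex hits pass score/energy thresholds")
  write_hits_tsv(hits, file.path(out, "duplex_hits.tsv"),
                 config$scheme, config$model)
  tick("scan")

  # -- anticorrelation filter --------------------------------------------
  mirna_edges <- filter_anticorrelated_pairs(
    hits, mirna_expr, mrna_expr, config$r_anticorr, config$p_anticorr,
    config$log_transform)
  say(nrow(mirna_edges), " miRNA->mRNA edges pass the anticorrelation filter")
  tick("anticorr")

  # -- TF loop expansion --------------------------------------------------
  tf_catalog <- if (!is.null(ds$tf_catalog) && length(ds$tf_catalog)) {
    ds$tf_catalog
  } else if (!is.null(ds$truth)) ds$truth$tf_catalog else character()
  tf_ids <- annotate_tfs(unique(mirna_edges$target_id), tf_catalog)
  tf_edges <- if (length(tf_ids)) {
    tf_target_edges(tf_ids, mrna_expr, config$r_tf, config$p_tf,
                    config$log_transform)
  } else empty_edges()
  say(length(tf_ids), " miRNA-targeted TFs; ", nrow(tf_edges),
      " TF->mRNA coexpression edges")
  tick("tf")

  # -- assembly and evaluation -------------------------------------------
  network <- assemble_network(mirna_edges, tf_edges, tf_ids)
  if (network$stats$n_mirna_mrna_pairs == 0) {
    warning("the inferred network is empty at the configured thresholds")
  }
  write_network(network,
                edges_tsv = file.path(out, "network_edges.tsv"),
                graphml = file.path(out, "network.graphml"),
                stats_json = file.path(out, "network_stats.json"))
  recovery <- NULL
  if (!is.null(ds$truth) && !is.null(ds$truth$true_edges)) {
    recovery <- evaluate_recovery(network, ds$truth)
    write.table(recovery, file.path(out, "recovery.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  tick("network")

  # -- manifest -----------------------------------------------------------
  out_files <- list.files(out, recursive = TRUE)
  out_files <- setdiff(out_files, "manifest.json")
  checksums <- lapply(setNames(out_files, out_files), function(f) {
    file_md5(file.path(out, f))
  })
  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL   # hash the parameterization, not the paths
  cfg_for_hash$scheme <- unclass(cfg_for_hash$scheme)
  cfg_for_hash$model <- unclass(cfg_for_hash$model)
  if (!is.null(cfg_for_hash$simulate)) {
    cfg_for_hash$simulate <- unclass(cfg_for_hash$simulate)
  }
  manifest <- list(
    tool = "mirloop", version = as.character(utils::packageVersion("mirloop")),
    seed = config$seed, config_hash = object_md5(cfg_for_hash),
    stage_seconds = timings, network_stats = network$stats,
    recovery = recovery, checksums = checksums)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  structure(list(network = network, de_genes = de_genes,
                 de_mirnas = de_mirnas, hits = hits,
                 mirna_edges = mirna_edges, tf_edges = tf_edges,
                 clustering = clust, recovery = recovery,
                 manifest = manifest),
            class = "RunResult")
}
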