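#' Configuration for the synthetic paired miRNA/mRNA generator
#'
#' Defines the study design the generator emulates: two maternal diets
#' (NE normal, RE calorie-restricted), one pooled library per diet at
#' each of three gestational stages (35, 55, 90 dg), with planted
#' differential expression, planted fully complementary miRNA target
#' sites, planted anticorrelated miRNA-target relations, and planted
#' TF coexpression modules.
#'
#' @param n_genes,n_mirnas,n_tfs feature counts (defaults 2000/100/40).
#' @param samples data.frame with columns `diet` (NE/RE) and `stage`;
#'   default the six-condition two-diet three-stage design.
#' @param n_true_edges planted miRNA->mRNA regulations (default 60).
#' @param n_de_genes planted DE genes per diet comparison (default 200).
#' @param n_de_mirnas planted DE miRNAs overall (default 30); planted
#'   edges draw their miRNAs from this set so that diet-responsive
#'   regulators drive the network.
#' @param de_fold planted fold change, >= 1 (default 4).
#' @param anticorr_strength target Pearson r of planted miRNA-target
#'   pairs, in (-1, 0) (default -0.95).
#' @param tf_module_r target coexpression of TF module members with their
#'   TF, in (0, 1) (default 0.97).
#' @param n_tf_modules,tf_module_size planted TF modules and members per
#'   module (defaults 10 and 8).
#' @param n_stage_genes genes with diet-shared stage-specific expression
#'   (default 300); these drive the developmental clustering structure.
#' @param utr_len,mirna_len sequence lengths in nt (defaults 1000, 22).
#' @param mirna_spread,target_spread,tf_spread dynamic range (log2 sd) of
#'   regulator/target latent profiles (default 2 = typical 4-fold swings).
#' @param de_gene_spread log2 sd of the independent variation planted DE
#'   genes receive at the samples outside their designated comparison
#'   (default 2); it leaves the planted fold change untouched while
#'   preventing all DE features from sharing a single step-like profile.
#' @param stage_sd log2 sd of stage effects on stage genes (default 1.5).
#' @param nb_dispersion negative-binomial dispersion of the count noise
#'   (default 0.05); 0 gives Poisson noise.
#' @param lib_size expected reads per library, list with `mrna` and
#'   `mirna` (defaults 5e6 and 1e6).
#' @param noise_scale multiplier on the Gaussian latent noise of planted
#'   relations (default 1); 0 gives exactly correlated latent profiles.
#' @param count_noise draw counts (TRUE, default) or return expected
#'   counts (FALSE, diagnostic noise-free mode).
#' @param seed integer seed; all randomness flows from it.
#' @return an object of class `SyntheticConfig`.
#' @export
simulate_config <- function(n_genes = 2000, n_mirnas = 100, n_tfs = 40,
                            samples = NULL, n_true_edges = 60,
                            n_de_genes = 200, n_de_mirnas = 30,
                            de_fold = 4, anticorr_strength = -0.95,
                            tf_module_r = 0.97, n_tf_modules = 10,
                            tf_module_size = 8, n_stage_genes = 300,
                            utr_len = 1000, mirna_len = 22,
                            mirna_spread = 2, target_spread = 2,
                            tf_spread = 2, de_gene_spread = 2,
                            stage_sd = 1.5,
                            nb_dispersion = 0.05,
                            lib_size = list(mrna = 5e6, mirna = 1e6),
                            noise_scale = 1, count_noise = TRUE,
                            seed = 1L) {
  if (is.null(samples)) {
    samples <- data.frame(diet = rep(c("NE", "RE"), each = 3),
                          stage = rep(c(35, 55, 90), 2))
  }
  stopifnot(n_genes > 0, n_mirnas > 0, n_tfs > 0, n_true_edges >= 0,
            n_de_genes >= 0, n_de_mirnas >= 0, de_fold >= 1,
            anticorr_strength > -1, anticorr_strength < 0,
            tf_module_r > 0, tf_module_r < 1, utr_len > 0,
            mirna_len >= 16, mirna_len <= 26, nb_dispersion >= 0,
            noise_scale >= 0, nrow(samples) >= 1)
  stopifnot(all(samples$diet %in% c("NE", "RE")))
  samples$sample_id <- paste0(samples$diet, samples$stage)
  if (anyDuplicated(samples$sample_id)) stop("samples must be unique")
  if (n_true_edges > n_genes * n_mirnas) {
    stop("infeasible config: n_true_edges exceeds n_genes * n_mirnas")
  }
  if (utr_len < mirna_len) stop("utr_len must be >= mirna_len")
  structure(
    list(n_genes = n_genes, n_mirnas = n_mirnas, n_tfs = n_tfs,
         samples = samples, n_true_edges = n_true_edges,
         n_de_genes = n_de_genes, n_de_mirnas = n_de_mirnas,
         de_fold = de_fold, anticorr_strength = anticorr_strength,
         tf_module_r = tf_module_r, n_tf_modules = n_tf_modules,
         tf_module_size = tf_module_size, n_stage_genes = n_stage_genes,
         utr_len = utr_len, mirna_len = mirna_len,
         mirna_spread = mirna_spread, target_spread = target_spread,
         tf_spread = tf_spread, de_gene_spread = de_gene_spread,
         stage_sd = stage_sd,
         nb_dispersion = nb_dispersion, lib_size = lib_size,
         noise_scale = noise_scale, count_noise = count_noise,
         seed = as.integer(seed)),
    class = "SyntheticConfig")
}

#' Plant a fully complementary miRNA target site into a UTR
#'
#' Splices the reverse complement of the miRNA into the UTR at the given
#' 0-based offset; the UTR length is unchanged. The planted site is the
#' strongest possible signal for the duplex scanner.
#'
#' @param mirna_seq miRNA sequence 5'->3' (RNA alphabet).
#' @param utr_seq UTR sequence (RNA alphabet).
#' @param position 0-based offset; `position + nchar(mirna_seq)` must not
#'   exceed the UTR length.
#' @return the modified UTR sequence.
#' @examples
#' plant_target_site("UGAGGUAG", "AAAAAAAAAAAA", 2)
#' @export
plant_target_site <- function(mirna_seq, utr_seq, position) {
  mirna_seq <- normalize_rna(mirna_seq, warn = FALSE)
  utr_seq <- normalize_rna(utr_seq, warn = FALSE)
  L <- nchar(mirna_seq)
  if (position < 0 || position + L > nchar(utr_seq)) {
    stop("site position out of UTR bounds")
  }
  site <- revcomp_rna(mirna_seq)
  paste0(substr(utr_seq, 1, position), site,
         substr(utr_seq, position + L + 1, nchar(utr_seq)))
}

random_rna <- function(n, len) {
  chars <- paste(sample(RNA_BASES, n * len, replace = TRUE), collapse = "")
  substring(chars, (seq_len(n) - 1) * len + 1, seq_len(n) * len)
}

# standardize a vector to mean 0, sd 1 (constant vectors -> zeros)
standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate paired miRNA/mRNA expression with planted ground truth
#'
#' Generates the paired count matrices, the mature miRNA and 3'-UTR
#' sequences, and the planted ground truth the analysis is scored
#' against. Latent log2 abundances are log-normal baselines plus planted
#' effects: diet fold changes on DE features, diet-shared stage effects
#' on stage genes, anticorrelated profiles on planted targets (affine
#' decreasing in their miRNA's profile plus calibrated Gaussian noise),
#' and shared profiles in TF modules. Counts are negative-binomial around
#' the abundance-proportional share of the library size. Fully
#' reproducible from the config seed.
#'
#' @param config a [simulate_config()].
#' @return list with `mrna` and `mirna` ([count_matrix()]s), `mirna_seqs`
#'   and `utr_seqs` (named character), `samples` (data.frame), and
#'   `truth` (class `GroundTruth`): `true_edges`, `planted_sites`
#'   (0-based half-open), `de_genes`, `de_mirnas` (lists keyed by
#'   comparison label), `tf_modules`, `tf_catalog`, and the latent log2
#'   matrices `latent_mrna`, `latent_mirna`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cfg <- config
  set.seed(cfg$seed)
  samples <- cfg$samples
  sample_ids <- samples$sample_id
  n_s <- nrow(samples)
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  mirna_ids <- sprintf("mir-%03d", seq_len(cfg$n_mirnas))
  stages <- sort(unique(samples$stage))
  # diet comparisons exist for stages sampled under both diets
  cmp_stages <- stages[vapply(stages, function(s) {
    all(c("NE", "RE") %in% samples$diet[samples$stage == s])
  }, logical(1))]
  cmp_labels <- sprintf("NE%s_vs_RE%s", cmp_stages, cmp_stages)

  # -- partition genes into planted roles (disjoint) ----------------------
  n_module_members <- cfg$n_tf_modules * cfg$tf_module_size
  need <- cfg$n_stage_genes + length(cmp_stages) * cfg$n_de_genes +
    cfg$n_true_edges + n_module_members
  if (need > cfg$n_genes) {
    stop("infeasible config: planted gene roles (", need,
         ") exceed n_genes (", cfg$n_genes, ")")
  }
  pool <- sample(gene_ids)
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  stage_genes <- take(cfg$n_stage_genes)
  de_genes <- setNames(
    lapply(cmp_stages, function(s) take(cfg$n_de_genes)), cmp_labels)
  edge_targets <- take(cfg$n_true_edges)
  module_members <- take(n_module_members)

  # -- miRNA roles --------------------------------------------------------
  n_de_mir <- if (length(cmp_stages)) min(cfg$n_de_mirnas, cfg$n_mirnas)
              else 0L
  de_mirna_pool <- sample(mirna_ids, n_de_mir)
  mir_stage <- if (length(cmp_stages)) {
    setNames(cmp_stages[1 + (seq_len(n_de_mir) - 1) %% length(cmp_stages)],
             de_mirna_pool)
  } else setNames(numeric(0), character(0))
  mir_sign <- setNames(sample(c(-1, 1), n_de_mir, replace = TRUE),
                       de_mirna_pool)
  de_mirnas <- setNames(lapply(cmp_stages, function(s) {
    de_mirna_pool[mir_stage[de_mirna_pool] == s]
  }), cmp_labels)
  edge_mirnas <- if (cfg$n_true_edges == 0) character(0)
  else if (n_de_mir > 0) {
    sample(de_mirna_pool, cfg$n_true_edges, replace = TRUE)
  } else sample(mirna_ids, cfg$n_true_edges, replace = TRUE)

  # -- latent miRNA log2 profiles ----------------------------------------
  # Baselines are log-normal; features that will carry planted profiles
  # are re-drawn at moderate abundance (log2 sd 1) so that no regulated
  # feature can dominate the library total: the extreme-abundance tail is
  # reserved for stable features, keeping total-count normalization
  # well-posed.
  lat_mir <- matrix(rnorm(cfg$n_mirnas, mean = 5, sd = 2),
                    nrow = cfg$n_mirnas, ncol = n_s,
                    dimnames = list(mirna_ids, sample_ids))
  mir_varying <- unique(c(de_mirna_pool, edge_mirnas))
  lat_mir[mir_varying, ] <- rnorm(length(mir_varying), mean = 5, sd = 1)
  lfc <- log2(cfg$de_fold)
  for (m in de_mirna_pool) {
    des <- samples$stage == mir_stage[[m]]   # the designated pair
    re_at <- samples$diet == "RE" & des
    lat_mir[m, re_at] <- lat_mir[m, re_at] + mir_sign[[m]] * lfc
    # diet-shared stage variation at the non-designated stages: gives each
    # regulator its own developmental profile (so distinct DE features do
    # not all share one step-like pattern) while contributing identically
    # to both libraries of every comparison — the planted fold stays exact
    # and library composition is stable within every NE-vs-RE pair
    other <- setdiff(stages, mir_stage[[m]])
    v <- setNames(rnorm(length(other), 0, cfg$mirna_spread), other)
    at <- !des
    lat_mir[m, at] <- lat_mir[m, at] + v[as.character(samples$stage[at])]
  }
  # edge miRNAs outside the DE pool still need profile variance for the
  # anticorrelation construction to standardize
  for (m in setdiff(unique(edge_mirnas), de_mirna_pool)) {
    v <- setNames(rnorm(length(stages), 0, cfg$mirna_spread), stages)
    lat_mir[m, ] <- lat_mir[m, ] + v[as.character(samples$stage)]
  }

  # -- latent gene log2 profiles -----------------------------------------
  lat_mrna <- matrix(rnorm(cfg$n_genes, mean = 5, sd = 2),
                     nrow = cfg$n_genes, ncol = n_s,
                     dimnames = list(gene_ids, sample_ids))
  gene_varying <- unique(c(unlist(de_genes, use.names = FALSE),
                           edge_targets, module_members, stage_genes))
  lat_mrna[gene_varying, ] <- rnorm(length(gene_varying), mean = 5, sd = 1)
  for (g in stage_genes) {
    v <- setNames(rnorm(length(stages), 0, cfg$stage_sd), stages)
    lat_mrna[g, ] <- lat_mrna[g, ] + v[as.character(samples$stage)]
  }
  for (lab in names(de_genes)) {
    s <- cmp_stages[match(lab, cmp_labels)]
    des <- samples$stage == s
    re_at <- samples$diet == "RE" & des
    gs <- de_genes[[lab]]
    signs <- sample(c(-1, 1), length(gs), replace = TRUE)
    lat_mrna[gs, re_at] <- lat_mrna[gs, re_at] + signs * lfc
    lat_mrna[gs, !des] <- lat_mrna[gs, !des] +
      matrix(rnorm(length(gs) * sum(!des), 0, cfg$de_gene_spread),
             nrow = length(gs))
  }
  # planted anticorrelated targets: affine decreasing in the miRNA profile
  rho <- -cfg$anticorr_strength   # magnitude of the target correlation
  for (k in seq_len(cfg$n_true_edges)) {
    z <- standardize(lat_mir[edge_mirnas[k], ])
    eps <- rnorm(n_s)
    y <- -(rho * z) + sqrt(1 - rho^2) * cfg$noise_scale * eps
    g <- edge_targets[k]
    lat_mrna[g, ] <- lat_mrna[g, 1] + cfg$target_spread * y
  }
  # TF modules: prefer miRNA-targeted TFs so miRNA->TF->mRNA loops exist
  module_tfs <- head(unique(edge_targets), cfg$n_tf_modules)
  extra_tf <- cfg$n_tf_modules - length(module_tfs)
  if (extra_tf > 0) {
    more <- take(extra_tf)
    for (g in more) {
      v <- setNames(rnorm(length(stages), 0, cfg$tf_spread), stages)
      lat_mrna[g, ] <- lat_mrna[g, ] + v[as.character(samples$stage)]
    }
    module_tfs <- c(module_tfs, more)
  }
  rho_tf <- cfg$tf_module_r
  tf_modules <- list()
  for (i in seq_along(module_tfs)) {
    tf <- module_tfs[i]
    members <- module_members[(i - 1) * cfg$tf_module_size +
                                seq_len(cfg$tf_module_size)]
    w <- standardize(lat_mrna[tf, ])
    for (g in members) {
      eps <- rnorm(n_s)
      y <- rho_tf * w + sqrt(1 - rho_tf^2) * cfg$noise_scale * eps
      lat_mrna[g, ] <- lat_mrna[g, 1] + cfg$tf_spread * y
    }
    tf_modules[[tf]] <- members
  }
  tf_catalog <- module_tfs
  if (cfg$n_tfs > length(tf_catalog)) {
    tf_catalog <- c(tf_catalog, take(cfg$n_tfs - length(tf_catalog)))
  } else {
    tf_catalog <- head(tf_catalog, cfg$n_tfs)
  }

  # -- counts -------------------------------------------------------------
  draw_counts <- function(latent, lib) {
    ab <- 2^latent
    mu <- sweep(ab, 2, colSums(ab), "/") * lib
    if (!cfg$count_noise) return(mu)
    cnt <- if (cfg$nb_dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
    matrix(cnt, nrow = nrow(mu), dimnames = dimnames(mu))
  }
  mrna_counts <- draw_counts(lat_mrna, cfg$lib_size$mrna)
  mirna_counts <- draw_counts(lat_mir, cfg$lib_size$mirna)
  gene_lengths <- setNames(round(runif(cfg$n_genes, 500, 4000)), gene_ids)

  # -- sequences and planted sites ---------------------------------------
  mirna_seqs <- setNames(random_rna(cfg$n_mirnas, cfg$mirna_len), mirna_ids)
  utr_seqs <- setNames(random_rna(cfg$n_genes, cfg$utr_len), gene_ids)
  planted_sites <- data.frame(mirna_id = character(), gene_id = character(),
                              start = integer(), end = integer(),
                              stringsAsFactors = FALSE)
  for (k in seq_len(cfg$n_true_edges)) {
    m <- edge_mirnas[k]; g <- edge_targets[k]
    pos <- sample.int(cfg$utr_len - cfg$mirna_len + 1, 1) - 1L
    utr_seqs[[g]] <- plant_target_site(mirna_seqs[[m]], utr_seqs[[g]], pos)
    planted_sites <- rbind(planted_sites, data.frame(
      mirna_id = m, gene_id = g, start = pos,
      end = pos + cfg$mirna_len, stringsAsFactors = FALSE))
  }
  true_edges <- data.frame(mirna_id = edge_mirnas, gene_id = edge_targets,
                           stringsAsFactors = FALSE)

  truth <- structure(
    list(true_edges = true_edges, planted_sites = planted_sites,
         de_genes = de_genes, de_mirnas = de_mirnas,
         tf_modules = tf_modules, tf_catalog = tf_catalog,
         latent_mrna = lat_mrna, latent_mirna = lat_mir),
    class = "GroundTruth")

  list(mrna = count_matrix(mrna_counts, lengths = gene_lengths),
       mirna = count_matrix(mirna_counts),
       mirna_seqs = mirna_seqs, utr_seqs = utr_seqs,
       samples = samples, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Writes the count TSVs, miRNA and UTR FASTA, TF catalog, sample sheet,
#' ground truth JSON (latent matrices omitted) and a manifest recording
#' the seed, the config hash, and per-file md5 checksums. Identical
#' (config, seed) runs produce identical manifests.
#'
#' @param sim result of [simulate_expression()].
#' @param out_dir output directory (created if needed).
#' @param config the [simulate_config()] used (for seed/hash recording).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
write_dataset <- function(sim, out_dir, config = NULL) {
  if (!setequal(rownames(sim$mrna$counts), names(sim$utr_seqs)) ||
      !setequal(rownames(sim$mirna$counts), names(sim$mirna_seqs))) {
    stop("inconsistent feature ids across matrices and sequences")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    mrna_counts = "mrna_counts.tsv", mirna_counts = "mirna_counts.tsv",
    mirna_fasta = "mirna.fa", utr_fasta = "utr.fa",
    tf_catalog = "tf_catalog.txt", sample_sheet = "sample_sheet.tsv",
    truth = "truth.json")
  paths <- setNames(file.path(out_dir, paths), names(paths))
  write_counts_tsv(sim$mrna, paths[["mrna_counts"]])
  write_counts_tsv(sim$mirna, paths[["mirna_counts"]])
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(sim$mirna_seqs),
                              paths[["mirna_fasta"]])
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(sim$utr_seqs),
                              paths[["utr_fasta"]])
  writeLines(sim$truth$tf_catalog, paths[["tf_catalog"]])
  write.table(sim$samples[c("sample_id", "diet", "stage")],
              paths[["sample_sheet"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_out <- sim$truth[c("true_edges", "planted_sites", "de_genes",
                           "de_mirnas", "tf_modules", "tf_catalog")]
  jsonlite::write_json(truth_out, paths[["truth"]], auto_unbox = FALSE,
                       digits = NA, dataframe = "columns")
  manifest <- list(
    seed = if (is.null(config)) NA else config$seed,
    config_hash = if (is.null(config)) NA else object_md5(unclass(config)),
    files = lapply(as.list(paths), file_md5))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a synthetic dataset back from disk
#'
#' Inverse of [write_dataset()] (latent matrices are not round-tripped).
#'
#' @param dir dataset directory.
#' @return list with `mrna`, `mirna`, `mirna_seqs`, `utr_seqs`, `samples`,
#'   `truth`.
#' @export
read_dataset <- function(dir) {
  truth <- NULL
  if (file.exists(file.path(dir, "truth.json"))) {
    truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"),
                                     simplifyVector = TRUE)
    truth <- structure(
      list(true_edges = as.data.frame(truth_raw$true_edges),
           planted_sites = as.data.frame(truth_raw$planted_sites),
           de_genes = truth_raw$de_genes, de_mirnas = truth_raw$de_mirnas,
           tf_modules = truth_raw$tf_modules,
           tf_catalog = truth_raw$tf_catalog),
      class = "GroundTruth")
  }
  tf_path <- file.path(dir, "tf_catalog.txt")
  list(
    tf_catalog = if (file.exists(tf_path)) readLines(tf_path)
                 else character(),
    mrna = read_counts_tsv(file.path(dir, "mrna_counts.tsv")),
    mirna = read_counts_tsv(file.path(dir, "mirna_counts.tsv")),
    mirna_seqs = as_rna_set(Biostrings::readRNAStringSet(
      file.path(dir, "mirna.fa")), "miRNA"),
    utr_seqs = as_rna_set(Biostrings::readRNAStringSet(
      file.path(dir, "utr.fa")), "UTR"),
    samples = read.delim(file.path(dir, "sample_sheet.tsv"),
                         stringsAsFactors = FALSE),
    truth = truth)
}
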