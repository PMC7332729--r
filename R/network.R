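#' Pearson correlation with a t-based p-value
#'
#' Product-moment correlation with the two-sided p-value from the t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. Perfect `|r| = 1` is clamped to `p = 0`; zero-variance input
#' yields an undefined (flagged) result instead of an edge.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list (class `CorrelationStat`): `r`, `n`, `t_stat`, `p`,
#'   `defined`.
#' @examples
#' pearson_with_pvalue(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
pearson_with_pvalue <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired samples")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, n = n, t_stat = NA_real_,
                          p = NA_real_, defined = FALSE),
                     class = "CorrelationStat"))
  }
  r <- cor(x, y)
  p <- cor_pvalue(r, n)
  t_stat <- if (abs(r) >= 1) Inf * sign(r)
            else r * sqrt((n - 2) / (1 - r^2))
  structure(list(r = r, n = n, t_stat = t_stat, p = p, defined = TRUE),
            class = "CorrelationStat")
}

# Vectorized two-sided p from r and n via the t transform; |r| = 1 -> 0.
cor_pvalue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  perfect <- !is.na(r) & abs(r) >= 1
  ok <- !is.na(r) & !perfect
  t_stat <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(-abs(t_stat), df = n - 2)
  p[perfect] <- 0
  p
}

empty_edges <- function() {
  data.frame(source_id = character(), target_id = character(),
             edge_type = character(), r = numeric(), p = numeric(),
             q = numeric(), score = numeric(), delta_g = numeric(),
             stringsAsFactors = FALSE)
}

#' Filter sequence-predicted pairs by expression anticorrelation
#'
#' Implements the intersection of the two evidence channels: an edge is
#' retained iff the pair has a sequence-predicted duplex hit AND its
#' expression correlation satisfies `r < r_max` (strict) and `p < p_max`
#' (strict). Correlation is computed across the shared samples, by
#' default on `log2(value + 1)`. BH-adjusted q-values are reported
#' informationally and never used for filtering.
#'
#' @param candidate_pairs data.frame from [scan_targets()] (best sites:
#'   `mirna_id`, `gene_id`, `score`, `delta_g`), or any data.frame with
#'   those columns.
#' @param mirna_expr,mrna_expr expression matrices sharing the sample
#'   axis (columns).
#' @param r_max correlation threshold, strict `<` (default -0.58).
#' @param p_max p-value threshold, strict `<` (default 0.05).
#' @param log_transform correlate `log2(value + 1)` (default `TRUE`).
#' @return data.frame of regulatory edges: `source_id` (miRNA),
#'   `target_id` (gene), `edge_type = "miRNA->mRNA"`, `r`, `p`, `q`,
#'   `score`, `delta_g`.
#' @export
filter_anticorrelated_pairs <- function(candidate_pairs, mirna_expr,
                                        mrna_expr, r_max = -0.58,
                                        p_max = 0.05,
                                        log_transform = TRUE) {
  stopifnot(r_max < 0, p_max > 0)
  shared <- intersect(colnames(mirna_expr), colnames(mrna_expr))
  if (length(shared) < 3) stop("expression matrices share fewer than 3 samples")
  me <- as.matrix(mirna_expr)[, shared, drop = FALSE]
  ge <- as.matrix(mrna_expr)[, shared, drop = FALSE]
  if (log_transform) {
    me <- log2(me + 1)
    ge <- log2(ge + 1)
  }
  if (isTRUE(nrow(candidate_pairs) > 0) && "best" %in% names(candidate_pairs)) {
    candidate_pairs <- candidate_pairs[candidate_pairs$best, , drop = FALSE]
  }
  if (!isTRUE(nrow(candidate_pairs) > 0)) return(empty_edges())
  n <- length(shared)
  known <- candidate_pairs$mirna_id %in% rownames(me) &
    candidate_pairs$gene_id %in% rownames(ge)
  if (any(!known)) {
    message("filter_anticorrelated_pairs: skipping ", sum(!known),
            " pair(s) referencing features absent from the expression data")
    candidate_pairs <- candidate_pairs[known, , drop = FALSE]
  }
  if (!nrow(candidate_pairs)) return(empty_edges())
  r <- vapply(seq_len(nrow(candidate_pairs)), function(i) {
    xs <- me[candidate_pairs$mirna_id[i], ]
    ys <- ge[candidate_pairs$gene_id[i], ]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) NA_real_ else cor(xs, ys)
  }, numeric(1))
  p <- cor_pvalue(r, n)
  keep <- !is.na(r) & r < r_max & p < p_max
  out <- data.frame(
    source_id = candidate_pairs$mirna_id[keep],
    target_id = candidate_pairs$gene_id[keep],
    edge_type = rep("miRNA->mRNA", sum(keep)),
    r = r[keep], p = p[keep],
    q = p.adjust(p, "BH")[keep],
    score = candidate_pairs$score[keep],
    delta_g = candidate_pairs$delta_g[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Identify transcription factors among a gene set
#'
#' Intersection with a TF catalog (one gene id per line when read from
#' file). Ids are normalized by upper-casing and stripping a trailing
#' `.N` version suffix before matching.
#'
#' @param gene_ids character vector of gene ids.
#' @param tf_catalog character vector of TF gene ids (the catalog).
#' @return the TF subset of `gene_ids` (original spelling preserved).
#' @export
annotate_tfs <- function(gene_ids, tf_catalog) {
  if (!length(tf_catalog)) return(character())
  norm <- function(x) toupper(sub("\\.\\d+$", "", x))
  gene_ids[norm(gene_ids) %in% norm(tf_catalog)]
}

#' TF-target coexpression edges
#'
#' For every (TF, gene != TF) pair, an edge is called iff the Pearson
#' correlation of their expression satisfies `r > r_min` (strict) and
#' `p < p_max` (strict) across samples. Computed on `log2(value + 1)` by
#' default.
#'
#' @param tf_ids TF gene ids; TFs absent from the matrix are skipped with
#'   a message.
#' @param mrna_expr expression matrix (genes x samples).
#' @param r_min correlation threshold, strict `>` (default 0.90).
#' @param p_max p-value threshold, strict `<` (default 0.01).
#' @param log_transform correlate `log2(value + 1)` (default `TRUE`).
#' @return data.frame of edges with `edge_type = "TF->mRNA"` and `r > 0`.
#' @export
tf_target_edges <- function(tf_ids, mrna_expr, r_min = 0.90, p_max = 0.01,
                            log_transform = TRUE) {
  stopifnot(r_min > 0, p_max > 0)
  ge <- as.matrix(mrna_expr)
  if (log_transform) ge <- log2(ge + 1)
  n <- ncol(ge)
  if (n < 3) stop("need at least 3 samples")
  missing_tfs <- setdiff(tf_ids, rownames(ge))
  if (length(missing_tfs)) {
    message("tf_target_edges: skipping TF(s) absent from the matrix: ",
            paste(missing_tfs, collapse = ", "))
    tf_ids <- setdiff(tf_ids, missing_tfs)
  }
  if (!length(tf_ids)) return(empty_edges())
  sds <- apply(ge, 1, stats::sd)
  r_mat <- suppressWarnings(cor(t(ge[tf_ids, , drop = FALSE]), t(ge)))
  rows <- list()
  for (tf in tf_ids) {
    r <- r_mat[tf, ]
    r[sds == 0 | sds[tf] == 0] <- NA
    r <- r[names(r) != tf]
    p <- cor_pvalue(r, n)
    keep <- !is.na(r) & r > r_min & p < p_max
    if (!any(keep)) next
    rows[[tf]] <- data.frame(
      source_id = tf, target_id = names(r)[keep],
      edge_type = "TF->mRNA", r = unname(r[keep]), p = p[keep],
      q = p.adjust(p, "BH")[keep],
      score = NA_real_, delta_g = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_edges())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the miRNA-TF-mRNA regulatory network
#'
#' Types the nodes (miRNA, TF, gene), relabels miRNA edges into TFs as
#' `miRNA->TF`, merges duplicate edges keeping the maximum-|r| support,
#' and computes summary statistics including the number of regulatory
#' loops (miRNA->TF->mRNA length-2 paths).
#'
#' @param mirna_edges edges from [filter_anticorrelated_pairs()].
#' @param tf_edges edges from [tf_target_edges()].
#' @param tf_ids the TF catalog subset used for typing.
#' @return an object of class `RegulatoryNetwork`: list with `nodes`
#'   (data.frame `id`, `type`), `edges`, and `stats` (named list).
#' @export
assemble_network <- function(mirna_edges, tf_edges = empty_edges(),
                             tf_ids = character()) {
  edges <- rbind(mirna_edges, tf_edges)
  if (nrow(edges)) {
    edges$edge_type[edges$edge_type == "miRNA->mRNA" &
                      edges$target_id %in% tf_ids] <- "miRNA->TF"
    if (any(edges$source_id == edges$target_id)) {
      stop("self-edges are not allowed")
    }
    key <- paste(edges$source_id, edges$target_id, edges$edge_type,
                 sep = "\r")
    if (anyDuplicated(key)) {
      message("assemble_network: merging ", sum(duplicated(key)),
              " duplicate edge(s) (max-|r| support kept)")
      ord <- order(key, -abs(edges$r))
      edges <- edges[ord, , drop = FALSE]
      edges <- edges[!duplicated(key[ord]), , drop = FALSE]
    }
    edges <- edges[order(edges$edge_type, edges$source_id,
                         edges$target_id), , drop = FALSE]
    rownames(edges) <- NULL
  }
  mirna_nodes <- unique(edges$source_id[grepl("^miRNA", edges$edge_type)])
  gene_nodes <- unique(c(
    edges$target_id,
    edges$source_id[edges$edge_type == "TF->mRNA"]))
  nodes <- rbind(
    data.frame(id = mirna_nodes, type = rep("miRNA", length(mirna_nodes)),
               stringsAsFactors = FALSE),
    data.frame(id = gene_nodes,
               type = ifelse(gene_nodes %in% tf_ids, "TF", "gene"),
               stringsAsFactors = FALSE))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  mir_e <- edges[grepl("^miRNA", edges$edge_type), , drop = FALSE]
  tf_e <- edges[edges$edge_type == "TF->mRNA", , drop = FALSE]
  in_mir <- table(mir_e$target_id[mir_e$edge_type == "miRNA->TF"])
  out_tf <- table(tf_e$source_id)
  shared_tfs <- intersect(names(in_mir), names(out_tf))
  stats <- list(
    n_mirna_mrna_pairs = nrow(mir_e),
    n_unique_mirnas = length(unique(mir_e$source_id)),
    n_unique_mrnas = length(unique(mir_e$target_id)),
    n_tfs_targeted = sum(nodes$type == "TF" &
                           nodes$id %in% mir_e$target_id),
    n_tf_mrna_pairs = nrow(tf_e),
    n_loops = sum(as.numeric(in_mir[shared_tfs]) *
                    as.numeric(out_tf[shared_tfs])))
  structure(list(nodes = nodes, edges = edges, stats = stats),
            class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  s <- x$stats
  cat("RegulatoryNetwork\n")
  cat(sprintf("  miRNA->mRNA/TF pairs: %d (%d miRNAs, %d targets)\n",
              s$n_mirna_mrna_pairs, s$n_unique_mirnas, s$n_unique_mrnas))
  cat(sprintf("  TFs targeted by miRNAs: %d\n", s$n_tfs_targeted))
  cat(sprintf("  TF->mRNA pairs: %d\n", s$n_tf_mrna_pairs))
  cat(sprintf("  miRNA->TF->mRNA loops: %d\n", s$n_loops))
  invisible(x)
}

#' Score network recovery against a planted ground truth
#'
#' Standard precision/recall/F1 on edge sets, per edge type. miRNA edges
#' (`miRNA->mRNA` and `miRNA->TF`) are compared with the planted
#' miRNA-target pairs; `TF->mRNA` edges with the planted TF modules.
#' An empty prediction yields precision and recall 0 with
#' `defined = FALSE`.
#'
#' @param network a `RegulatoryNetwork` (or an edge data.frame).
#' @param truth a `GroundTruth` from [simulate_expression()] (uses
#'   `true_edges` and `tf_modules`).
#' @return data.frame with one row per edge type: `edge_type`,
#'   `n_predicted`, `n_truth`, `tp`, `precision`, `recall`, `f1`,
#'   `defined`.
#' @export
evaluate_recovery <- function(network, truth) {
  edges <- if (inherits(network, "RegulatoryNetwork")) network$edges
           else network
  pair_key <- function(a, b) paste(a, b, sep = "\r")
  score_set <- function(pred, tru) {
    tp <- sum(pred %in% tru)
    defined <- length(pred) > 0
    precision <- if (defined) tp / length(pred) else 0
    recall <- if (length(tru)) tp / length(tru) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    data.frame(n_predicted = length(pred), n_truth = length(tru), tp = tp,
               precision = precision, recall = recall, f1 = f1,
               defined = defined)
  }
  mir_pred <- edges[grepl("^miRNA", edges$edge_type), , drop = FALSE]
  mir_tru <- pair_key(truth$true_edges$mirna_id, truth$true_edges$gene_id)
  res_mir <- score_set(pair_key(mir_pred$source_id, mir_pred$target_id),
                       mir_tru)
  tf_pred <- edges[edges$edge_type == "TF->mRNA", , drop = FALSE]
  tf_tru <- unlist(lapply(names(truth$tf_modules), function(tf) {
    pair_key(tf, truth$tf_modules[[tf]])
  }), use.names = FALSE)
  res_tf <- score_set(pair_key(tf_pred$source_id, tf_pred$target_id),
                      tf_tru)
  out <- cbind(data.frame(edge_type = c("miRNA->mRNA", "TF->mRNA")),
               rbind(res_mir, res_tf))
  rownames(out) <- NULL
  out
}

#' Export a regulatory network
#'
#' Writes the edge table as TSV, the graph as GraphML (node `type` and
#' edge attributes carried over), and the statistics as JSON.
#'
#' @param network a `RegulatoryNetwork`.
#' @param edges_tsv,graphml,stats_json output paths (`NULL` skips).
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, edges_tsv = NULL, graphml = NULL,
                          stats_json = NULL) {
  stopifnot(inherits(network, "RegulatoryNetwork"))
  written <- character()
  if (!is.null(edges_tsv)) {
    write.table(network$edges, edges_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, edges_tsv)
  }
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      d = transform(network$edges,
                    q = ifelse(is.na(q), -1, q),
                    score = ifelse(is.na(score), -1, score),
                    delta_g = ifelse(is.na(delta_g), 0, delta_g)),
      directed = TRUE, vertices = network$nodes)
    igraph::write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(stats_json)) {
    jsonlite::write_json(network$stats, stats_json, auto_unbox = TRUE,
                         digits = NA)
    written <- c(written, stats_json)
  }
  invisible(written)
}
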