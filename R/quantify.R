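#' RPKM normalization
#'
#' Reads per kilobase of exon model per million mapped reads:
#' `RPKM[g, s] = 1e9 * C[g, s] / (N[s] * L[g])` with C the read count,
#' N the library's mapped reads and L the feature length in nt.
#'
#' @param cm a [count_matrix()] with feature lengths.
#' @return numeric matrix of RPKM values (same dimnames as the counts),
#'   with attribute `unit = "RPKM"`.
#' @examples
#' cm <- count_matrix(matrix(10, 1, 1, dimnames = list("g", "s")),
#'   lengths = c(g = 1000), lib_sizes = c(s = 1e6))
#' compute_rpkm(cm)  # 10
#' @export
compute_rpkm <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (is.null(cm$lengths)) {
    stop("RPKM requires feature lengths; none present in this CountMatrix")
  }
  if (any(cm$lib_sizes <= 0)) {
    stop("degenerate library: zero mapped reads in sample(s) ",
         paste(names(cm$lib_sizes)[cm$lib_sizes <= 0], collapse = ", "))
  }
  v <- 1e9 * sweep(cm$counts, 2, cm$lib_sizes, "/") / cm$lengths
  attr(v, "unit") <- "RPKM"
  v
}

#' Counts-per-million normalization
#'
#' `CPM[g, s] = 1e6 * C[g, s] / N[s]`. Used for features without exon
#' models (miRNAs) and for fold-change computation.
#'
#' @inheritParams compute_rpkm
#' @return numeric matrix with attribute `unit = "CPM"`.
#' @export
compute_cpm <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (any(cm$lib_sizes <= 0)) {
    stop("degenerate library: zero mapped reads in sample(s) ",
         paste(names(cm$lib_sizes)[cm$lib_sizes <= 0], collapse = ", "))
  }
  v <- 1e6 * sweep(cm$counts, 2, cm$lib_sizes, "/")
  attr(v, "unit") <- "CPM"
  v
}

#' Abundance filter: minimum reads in at least one sample
#'
#' Retains a feature iff its maximum count over samples is at least
#' `min_reads` (inclusive threshold). Row order is preserved. Unless
#' library sizes were explicitly overridden they are recomputed as column
#' sums of the filtered matrix.
#'
#' @param cm a `CountMatrix`.
#' @param min_reads non-negative integer threshold (default 10).
#' @return the filtered `CountMatrix` (possibly with zero rows).
#' @export
filter_min_reads <- function(cm, min_reads = 10) {
  stopifnot(inherits(cm, "CountMatrix"), min_reads >= 0)
  keep <- apply(cm$counts, 1, max) >= min_reads
  if (!any(keep)) {
    message("filter_min_reads: no feature reaches ", min_reads,
            " reads; returning an empty matrix")
  }
  counts <- cm$counts[keep, , drop = FALSE]
  count_matrix(
    counts,
    lengths = if (is.null(cm$lengths)) NULL else cm$lengths[keep],
    lib_sizes = if (cm$lib_sizes_overridden) cm$lib_sizes else NULL
  )
}

#' Pairwise sample correlation matrix
#'
#' Pearson correlation between sample columns of an expression matrix,
#' optionally (default) on `log2(value + 1)`. Both r and r-squared are
#' returned; zero-variance samples yield `NA` entries and are flagged.
#'
#' @param em numeric expression matrix (features x samples), at least 3
#'   features and 2 samples.
#' @param log_transform correlate `log2(value + 1)` instead of raw values
#'   (default `TRUE`).
#' @return an object of class `sample_correlation`: list with `r`, `r_squared`
#'   (square symmetric matrices), `undefined` (character vector of
#'   zero-variance samples), `log_transform`.
#' @export
sample_correlation_matrix <- function(em, log_transform = TRUE) {
  em <- as.matrix(em)
  if (ncol(em) < 2) stop("need at least 2 samples")
  if (nrow(em) < 3) stop("need at least 3 features")
  v <- if (log_transform) log2(em + 1) else em
  sds <- apply(v, 2, stats::sd)
  undefined <- colnames(v)[sds == 0]
  r <- suppressWarnings(cor(v))
  diag(r) <- 1
  structure(
    list(r = r, r_squared = r^2, undefined = undefined,
         log_transform = log_transform),
    class = "sample_correlation"
  )
}

#' @export
print.sample_correlation <- function(x, ...) {
  cat(sprintf("sample_correlation over %d samples (log2 transform: %s)\n",
              ncol(x$r), x$log_transform))
  print(round(x$r, 3))
  if (length(x$undefined)) {
    cat("zero-variance samples:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a correlation matrix as TSV
#'
#' @param sc a `sample_correlation` (or a plain square matrix).
#' @param path output file; sample ids appear on both axes.
#' @return `path`, invisibly.
#' @export
write_correlation_tsv <- function(sc, path) {
  r <- if (inherits(sc, "sample_correlation")) sc$r else as.matrix(sc)
  df <- data.frame(sample_id = rownames(r), check.names = FALSE)
  df <- cbind(df, as.data.frame(r, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hierarchically cluster samples from a correlation matrix
#'
#' Average-linkage agglomerative clustering on the distance `1 - r`.
#' Leaf order is the deterministic order produced by [stats::hclust()]
#' (ties broken by the merge order of the distance matrix, which is fixed
#' by the input sample order).
#'
#' @param corr a `sample_correlation` or a square correlation matrix.
#' @param mask_undefined drop samples whose correlations are undefined
#'   instead of erroring.
#' @return list with the `hclust` tree (`tree`), the leaf `order`
#'   (character sample ids), and `merges` (sample-id pairs in merge order).
#' @export
cluster_samples <- function(corr, mask_undefined = FALSE) {
  r <- if (inherits(corr, "sample_correlation")) corr$r else as.matrix(corr)
  if (any(is.na(r))) {
    if (!mask_undefined) {
      stop("correlation matrix has undefined entries; ",
           "set mask_undefined = TRUE to drop the affected samples")
    }
    # greedily drop the sample contributing the most undefined entries
    while (any(is.na(r)) && nrow(r) > 2) {
      worst <- which.max(rowSums(is.na(r)))
      r <- r[-worst, -worst, drop = FALSE]
    }
    if (any(is.na(r))) r <- r[0, 0]
  }
  if (nrow(r) < 2) stop("need at least 2 samples with defined correlations")
  tree <- hclust(as.dist(1 - r), method = "average")
  ids <- rownames(r)
  merges <- apply(tree$merge, 1, function(m) {
    lab <- function(k) if (k < 0) ids[-k] else paste0("cluster", k)
    c(lab(m[1]), lab(m[2]))
  })
  list(tree = tree, order = ids[tree$order], merges = t(merges))
}
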