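#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the hypergeometric null with fixed
#' margins, using the minimum-likelihood definition: the sum of the
#' probabilities of all tables whose point probability does not exceed
#' that of the observed table. Ties are included with the same relative
#' tolerance (`1 + 1e-7`) used by [stats::fisher.test()].
#'
#' The table layout is `rbind(c(a, b), c(c, d))`: rows are the two
#' libraries, columns are (feature reads, other reads).
#'
#' @param a,b,c,d non-negative integer cell counts, or `a` may be a 2x2
#'   matrix (then `b`, `c`, `d` are ignored).
#' @return the two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(2, 8, 8, 2)   # 4252/184756
#' fisher_exact_two_sided(5, 5, 5, 5)   # 1
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("table entries must be non-negative integers")
  }
  if (sum(cells) == 0) stop("table has no positive margin")
  m <- a + c        # column-1 margin (feature reads)
  n <- b + d        # column-2 margin
  k <- a + b        # row-1 margin (library A size)
  lo <- max(0, k - n)
  hi <- min(k, m)
  if (lo == hi) return(1)
  thr <- dhyper(a, m, n, k) * (1 + 1e-7)
  # the hypergeometric pmf is log-concave (unimodal), so the acceptance
  # region {x : d(x) <= d_obs} is a union of two tails; locate each tail
  # boundary by bisection and sum the tails with phyper
  mode <- min(hi, max(lo, floor((k + 1) * (m + 1) / (m + n + 2))))
  if (dhyper(mode, m, n, k) <= thr) return(1)
  p <- 0
  if (dhyper(lo, m, n, k) <= thr) {
    l <- lo
    r <- mode  # invariant: d(l) <= thr < d(r)
    while (r - l > 1) {
      mid <- l + (r - l) %/% 2
      if (dhyper(mid, m, n, k) <= thr) l <- mid else r <- mid
    }
    p <- p + stats::phyper(l, m, n, k)
  }
  if (dhyper(hi, m, n, k) <= thr) {
    l <- mode  # invariant: d(r) <= thr < d(l)
    r <- hi
    while (r - l > 1) {
      mid <- l + (r - l) %/% 2
      if (dhyper(mid, m, n, k) <= thr) r <- mid else l <- mid
    }
    p <- p + stats::phyper(r - 1, m, n, k, lower.tail = FALSE)
  }
  min(p, 1)
}

#' Fold change on pseudocounted CPM
#'
#' `cpm_x = 1e6 * count_x / total_x`; the fold change is
#' `(cpm_a + pseudocount) / (cpm_b + pseudocount)` and `log2fc` its log2.
#' The pseudocount (default 0.5) keeps the ratio finite for zero counts.
#'
#' @param count_a,count_b feature read counts in the two libraries.
#' @param total_a,total_b library sizes (mapped reads).
#' @param pseudocount non-negative CPM pseudocount (default 0.5).
#' @return list with `cpm_a`, `cpm_b`, `fc`, `log2fc` (vectorized).
#' @export
fold_change_cpm <- function(count_a, total_a, count_b, total_b,
                            pseudocount = 0.5) {
  if (any(total_a <= 0) && any(total_b <= 0)) {
    stop("degenerate comparison: both library totals are zero")
  }
  stopifnot(pseudocount >= 0, all(total_a > 0), all(total_b > 0))
  cpm_a <- 1e6 * count_a / total_a
  cpm_b <- 1e6 * count_b / total_b
  fc <- (cpm_a + pseudocount) / (cpm_b + pseudocount)
  list(cpm_a = cpm_a, cpm_b = cpm_b, fc = fc, log2fc = log2(fc))
}

#' Call differential expression between two unreplicated libraries
#'
#' For every feature a 2x2 table (feature reads, other reads) x (library
#' A, library B) is tested with [fisher_exact_two_sided()], and the fold
#' change is computed on pseudocounted CPM. A feature is differentially
#' expressed iff `fold_change > fc_threshold` (strict, on the
#' larger/smaller-oriented ratio) and `p_value < p_threshold` (strict).
#' No multiple-testing correction enters the call; BH-adjusted p-values
#' are reported informationally in `p_adj`.
#'
#' @param cm a [count_matrix()].
#' @param sample_a,sample_b sample ids of the two libraries.
#' @param fc_threshold fold-change threshold, strict (default 2).
#' @param p_threshold p-value threshold, strict (default 0.01).
#' @param pseudocount CPM pseudocount for the fold change (default 0.5).
#' @return data.frame ordered by p-value ascending with columns
#'   `feature_id`, `count_a`, `count_b`, `cpm_a`, `cpm_b`, `fold_change`
#'   (larger/smaller orientation, direction in the sign of `log2fc`),
#'   `log2fc`, `p_value`, `p_adj`, `is_de`.
#' @export
call_de <- function(cm, sample_a, sample_b, fc_threshold = 2,
                    p_threshold = 0.01, pseudocount = 0.5) {
  stopifnot(inherits(cm, "CountMatrix"))
  for (s in c(sample_a, sample_b)) {
    if (!s %in% colnames(cm$counts)) stop("unknown sample id: ", s)
  }
  ca <- cm$counts[, sample_a]
  cb <- cm$counts[, sample_b]
  na <- cm$lib_sizes[[sample_a]]
  nb <- cm$lib_sizes[[sample_b]]
  if (na <= 0 || nb <= 0) stop("library sizes must be positive")
  fcs <- fold_change_cpm(ca, na, cb, nb, pseudocount)
  p <- vapply(seq_along(ca), function(i) {
    fisher_exact_two_sided(ca[i], na - ca[i], cb[i], nb - cb[i])
  }, numeric(1))
  fc_oriented <- pmax(fcs$fc, 1 / fcs$fc)
  res <- data.frame(
    feature_id = rownames(cm$counts),
    count_a = ca, count_b = cb,
    cpm_a = fcs$cpm_a, cpm_b = fcs$cpm_b,
    fold_change = fc_oriented,
    log2fc = fcs$log2fc,
    p_value = p,
    p_adj = p.adjust(p, "BH"),
    is_de = fc_oriented > fc_threshold & p < p_threshold,
    row.names = NULL
  )
  res[order(res$p_value, res$feature_id), , drop = FALSE]
}

#' Venn region counts for labeled DE sets
#'
#' Partitions the union of 2-4 labeled sets into its intersection regions
#' and counts members per non-empty region.
#'
#' @param de_sets named list (2-4 entries) of id vectors.
#' @return data.frame with `signature` (labels joined by `&`) and `count`;
#'   region counts sum to the size of the union.
#' @examples
#' venn_regions(list(A = c(1, 2, 3), B = c(2, 3, 4)))
#' @export
venn_regions <- function(de_sets) {
  stopifnot(is.list(de_sets), length(de_sets) >= 2, length(de_sets) <= 4,
            !is.null(names(de_sets)))
  sets <- lapply(de_sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(NULL, names(sets)))
  sig <- apply(membership, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  tab <- table(sig)
  data.frame(signature = names(tab), count = as.integer(tab),
             row.names = NULL)
}

#' Write a differential-expression table as TSV
#'
#' @param de result of [call_de()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
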