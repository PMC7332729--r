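#' Construct a count matrix container
#'
#' Holds integer read counts (features x samples) together with optional
#' per-feature lengths (needed for RPKM) and per-sample library sizes.
#' Library sizes default to column sums; an explicit override represents
#' externally supplied mapped-read totals and is preserved through
#' filtering.
#'
#' @param counts numeric matrix of non-negative counts with rownames
#'   (feature ids) and colnames (sample ids).
#' @param lengths optional named numeric vector of feature lengths in nt
#'   (mRNA only); names must cover the rownames of `counts`.
#' @param lib_sizes optional named numeric vector of mapped-read totals per
#'   sample; when `NULL`, column sums are used and are recomputed after
#'   filtering.
#' @return an object of class `CountMatrix`: a list with elements `counts`,
#'   `lengths`, `lib_sizes`, `lib_sizes_overridden`.
#' @examples
#' cm <- count_matrix(matrix(c(10, 0, 5, 3), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'   lengths = c(g1 = 1000, g2 = 500))
#' @export
count_matrix <- function(counts, lengths = NULL, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  if (!is.null(lengths)) {
    if (is.null(names(lengths)) || !all(rownames(counts) %in% names(lengths))) {
      stop("lengths must be named and cover all feature ids")
    }
    lengths <- lengths[rownames(counts)]
    if (any(lengths <= 0)) stop("feature lengths must be positive")
  }
  overridden <- !is.null(lib_sizes)
  if (overridden) {
    if (is.null(names(lib_sizes)) || !all(colnames(counts) %in% names(lib_sizes))) {
      stop("lib_sizes must be named and cover all sample ids")
    }
    lib_sizes <- lib_sizes[colnames(counts)]
  } else {
    lib_sizes <- colSums(counts)
  }
  structure(
    list(counts = counts, lengths = lengths, lib_sizes = lib_sizes,
         lib_sizes_overridden = overridden),
    class = "CountMatrix"
  )
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  lengths: %s; library sizes: %s\n",
              if (is.null(x$lengths)) "absent" else "present",
              if (x$lib_sizes_overridden) "overridden" else "column sums"))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Read a count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' An optional `length` column (any of `length`, `Length`) is used as
#' feature lengths.
#'
#' @param path TSV file path.
#' @param lib_sizes optional mapped-read totals (see [count_matrix()]).
#' @return a `CountMatrix`.
#' @export
read_counts_tsv <- function(path, lib_sizes = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  df <- df[-1]
  len_col <- intersect(c("length", "Length"), names(df))
  lengths <- NULL
  if (length(len_col)) {
    lengths <- setNames(as.numeric(df[[len_col[1]]]), ids)
    df <- df[setdiff(names(df), len_col)]
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  count_matrix(m, lengths = lengths, lib_sizes = lib_sizes)
}

#' Write a count matrix to TSV
#'
#' @param cm a `CountMatrix`.
#' @param path output file; the feature-length column is written when
#'   lengths are present.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(cm, path) {
  stopifnot(inherits(cm, "CountMatrix"))
  df <- data.frame(feature_id = rownames(cm$counts), check.names = FALSE)
  if (!is.null(cm$lengths)) df$length <- cm$lengths
  df <- cbind(df, as.data.frame(cm$counts, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
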