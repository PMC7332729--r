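# Internal helpers: RNA alphabet handling and small file utilities.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Any character outside A/C/G/U after
#' normalization is an error.
#'
#' @param x character vector of sequences.
#' @param warn warn when DNA (T) input is converted.
#' @return character vector over A/C/G/U.
#' @keywords internal
#' @noRd
normalize_rna <- function(x, warn = TRUE) {
  x <- toupper(x)
  if (any(grepl("T", x, fixed = TRUE))) {
    if (warn) warning("DNA alphabet detected; converting T to U")
    x <- gsub("T", "U", x, fixed = TRUE)
  }
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("sequence contains characters outside the RNA alphabet (A/C/G/U): ",
         substr(x[bad][1], 1, 40))
  }
  x
}

# Encode an RNA string as integers A=0 C=1 G=2 U=3 (for the C++ aligner).
encode_rna <- function(x) {
  match(strsplit(x, "", fixed = TRUE)[[1]], RNA_BASES) - 1L
}

# Reverse complement of an RNA string (A<->U, C<->G), via Biostrings.
revcomp_rna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

# Watson-Crick / wobble classification of one base pair (characters).
pair_class <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("AU", "UA", "CG", "GC")) return("wc")
  if (key %in% c("GU", "UG")) return("gu")
  "mm"
}

# md5 of a file (base tools); NA -> error.
file_md5 <- function(path) {
  h <- unname(tools::md5sum(path))
  if (is.na(h)) stop("cannot checksum file: ", path)
  h
}

# md5 hash of an arbitrary R object via canonical JSON serialization.
object_md5 <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  file_md5(tmp)
}

# Coerce named sequences (character vector or XStringSet) to a named
# character vector over the RNA alphabet.
as_rna_set <- function(x, what = "sequence") {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (length(x) == 0) return(setNames(character(0), character(0)))
  if (!is.character(x) || is.null(names(x)) || any(names(x) == "")) {
    stop(what, " input must be a named character vector or XStringSet")
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate ", what, " ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  setNames(normalize_rna(unname(x)), names(x))
}
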