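#' Scoring scheme for miRNA:UTR duplex alignment
#'
#' Parameters of the seed-weighted local complementarity alignment.
#' Watson-Crick pairs score `wc_match`, G:U wobbles `gu_wobble`,
#' mismatches `mismatch`; gaps are affine (`gap_open` for the first gapped
#' position of a run, `gap_extend` for each further one). Pair scores at
#' miRNA positions `seed_start..seed_end` (1-based from the 5' end — the
#' seed region dominant in target recognition) are multiplied by
#' `seed_scale`. Hits are retained downstream only when the alignment
#' score strictly exceeds `score_threshold`.
#'
#' @param wc_match,gu_wobble,mismatch per-position pair scores
#'   (defaults +5 / +2 / -3).
#' @param gap_open,gap_extend affine gap scores (defaults -9 / -4).
#' @param seed_start,seed_end seed region, 1-based miRNA positions
#'   (defaults 2 and 8).
#' @param seed_scale multiplier for pair scores inside the seed
#'   (default 4).
#' @param score_threshold retention threshold, strict (default 145).
#' @param strict_seed when `TRUE` (default), [scan_targets()] retains only
#'   sites whose alignment pairs every seed position contiguously by
#'   Watson-Crick base pairs (no mismatches, wobbles or gaps in the seed),
#'   mirroring the strict-seed convention of established target scanners.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(wc_match = 5, gu_wobble = 2, mismatch = -3,
                           gap_open = -9, gap_extend = -4,
                           seed_start = 2, seed_end = 8, seed_scale = 4,
                           score_threshold = 145, strict_seed = TRUE) {
  stopifnot(wc_match > gu_wobble, gu_wobble > 0, mismatch < 0,
            gap_open <= gap_extend, gap_extend < 0, seed_scale >= 1,
            seed_start >= 1, seed_end >= seed_start)
  structure(list(wc_match = wc_match, gu_wobble = gu_wobble,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, seed_start = seed_start,
                 seed_end = seed_end, seed_scale = seed_scale,
                 score_threshold = score_threshold,
                 strict_seed = isTRUE(strict_seed)),
            class = "scoring_scheme")
}

#' Is the seed region perfectly paired in an alignment?
#'
#' Checks that miRNA positions `seed_start..seed_end` (1-based from the
#' 5' end) are all covered by the alignment, Watson-Crick paired, and
#' contiguous (no intervening gap columns).
#'
#' @param alignment result of [align_duplex()].
#' @param scheme a [scoring_scheme()] (for the seed range).
#' @return logical.
#' @export
seed_intact <- function(alignment, scheme = scoring_scheme()) {
  if (!is.null(alignment$score) && alignment$score <= 0) return(FALSE)
  lo <- scheme$seed_start
  hi <- scheme$seed_end
  if (alignment$mir_start > lo || alignment$mir_end < hi) return(FALSE)
  mirc <- strsplit(alignment$aln_mir, "")[[1]]
  matc <- strsplit(alignment$aln_match, "")[[1]]
  # miRNA positions are consumed from mir_end down to mir_start
  cols <- rep(NA_integer_, length(mirc))
  pos <- alignment$mir_end
  for (k in seq_along(mirc)) {
    if (mirc[k] != "-") {
      cols[k] <- pos
      pos <- pos - 1L
    }
  }
  idx <- which(!is.na(cols) & cols >= lo & cols <= hi)
  if (length(idx) != hi - lo + 1 || any(diff(idx) != 1)) return(FALSE)
  all(matc[idx] == "|")
}

#' Nearest-neighbor duplex free-energy model
#'
#' Duplex stability is the sum of dinucleotide stacking free energies over
#' consecutive base pairs, plus `loop_penalty` per interior interrupted
#' region (mismatches/gaps between helices) and `terminal_penalty` per
#' helix end. The default stack table ships with the package
#' (`inst/extdata/stack_energies.tsv`): Turner-style Watson-Crick values
#' with a smooth approximation for G:U-containing stacks. Stack keys are
#' `XY/WZ` with `XY` the UTR dinucleotide 5'->3' and `WZ` the paired
#' miRNA dinucleotide as displayed 3'->5'.
#'
#' @param stack_table named numeric vector of stack free energies
#'   (kcal/mol, all negative); `NULL` loads the shipped defaults.
#' @param loop_penalty kcal/mol per interior interrupted region
#'   (default +3).
#' @param terminal_penalty kcal/mol per helix end (default +0.5).
#' @param energy_threshold retention threshold in kcal/mol, strict `<`
#'   (default -10).
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(stack_table = NULL, loop_penalty = 3,
                         terminal_penalty = 0.5, energy_threshold = -10) {
  if (is.null(stack_table)) {
    path <- system.file("extdata", "stack_energies.tsv", package = "mirloop")
    tab <- read.delim(path, stringsAsFactors = FALSE)
    stack_table <- setNames(tab$delta_g, tab$stack)
  }
  stopifnot(is.numeric(stack_table), !is.null(names(stack_table)),
            loop_penalty >= 0, terminal_penalty >= 0)
  if (any(stack_table >= 0)) stop("all stack free energies must be negative")
  structure(list(stack_table = stack_table, loop_penalty = loop_penalty,
                 terminal_penalty = terminal_penalty,
                 energy_threshold = energy_threshold),
            class = "energy_model")
}

#' Align a miRNA against a UTR window
#'
#' Smith-Waterman-style local alignment of the reversed miRNA (3'->5')
#' against the UTR (5'->3') under antiparallel complementarity scoring
#' (see [scoring_scheme()]). Ties are broken deterministically: smallest
#' UTR start, then shortest alignment, then smallest miRNA start.
#'
#' @param mirna_seq miRNA sequence, 5'->3' (RNA; T is accepted and
#'   normalized to U with a warning).
#' @param utr_seq UTR sequence (or window), 5'->3'.
#' @param scheme a [scoring_scheme()].
#' @return list with `score`; when positive also `utr_start`, `utr_end`
#'   (0-based half-open on the UTR), `mir_start`, `mir_end` (1-based
#'   inclusive miRNA positions from the 5' end), and the three aligned
#'   display strings `aln_mir` (3'->5'), `aln_match` (`|` WC, `:` wobble),
#'   `aln_utr` (5'->3').
#' @examples
#' align_duplex("UGAGGUAG", "AACUACCUCAAA", scoring_scheme())
#' @export
align_duplex <- function(mirna_seq, utr_seq, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  mirna_seq <- normalize_rna(mirna_seq)
  utr_seq <- normalize_rna(utr_seq)
  if (nchar(mirna_seq) < 1 || nchar(utr_seq) < 1) {
    stop("sequences must be non-empty")
  }
  res <- align_duplex_cpp(encode_rna(mirna_seq), encode_rna(utr_seq),
                          scheme$wc_match, scheme$gu_wobble,
                          scheme$mismatch, scheme$gap_open,
                          scheme$gap_extend, scheme$seed_start,
                          scheme$seed_end, scheme$seed_scale)
  if (res$empty) {
    return(list(score = 0, aln_mir = "", aln_match = "", aln_utr = ""))
  }
  n <- nchar(mirna_seq)
  mir_rev <- rev(strsplit(mirna_seq, "")[[1]])
  utr <- strsplit(utr_seq, "")[[1]]
  mi <- res$mir_rev_start
  uj <- res$utr_start
  am <- au <- ax <- character(length(res$ops))
  for (k in seq_along(res$ops)) {
    op <- res$ops[k]
    if (op == 0L) {
      mi <- mi + 1L; uj <- uj + 1L
      am[k] <- mir_rev[mi]; au[k] <- utr[uj]
      cls <- pair_class(am[k], au[k])
      ax[k] <- if (cls == "wc") "|" else if (cls == "gu") ":" else " "
    } else if (op == 1L) {
      mi <- mi + 1L
      am[k] <- mir_rev[mi]; au[k] <- "-"; ax[k] <- " "
    } else {
      uj <- uj + 1L
      am[k] <- "-"; au[k] <- utr[uj]; ax[k] <- " "
    }
  }
  list(score = res$score,
       utr_start = res$utr_start, utr_end = res$utr_end,
       mir_start = n - res$mir_rev_end + 1L,
       mir_end = n - res$mir_rev_start,
       aln_mir = paste(am, collapse = ""),
       aln_match = paste(ax, collapse = ""),
       aln_utr = paste(au, collapse = ""))
}

#' Free energy of an aligned duplex
#'
#' Decomposes the alignment into maximal helices (runs of consecutive
#' Watson-Crick or G:U paired columns; gaps and mismatches break
#' stacking). The free energy is the sum of nearest-neighbor stack terms
#' within helices, plus `loop_penalty` for every interior interrupted
#' region between helices and `terminal_penalty` for every helix end.
#'
#' @param alignment result of [align_duplex()] (needs `aln_mir` and
#'   `aln_utr`), or a list with those two elements.
#' @param model an [energy_model()].
#' @return the free energy in kcal/mol (negative = stable).
#' @export
duplex_energy <- function(alignment, model = energy_model()) {
  stopifnot(inherits(model, "energy_model"))
  mirc <- strsplit(alignment$aln_mir, "")[[1]]
  utrc <- strsplit(alignment$aln_utr, "")[[1]]
  if (length(mirc) != length(utrc)) stop("alignment strings differ in length")
  paired <- vapply(seq_along(mirc), function(i) {
    mirc[i] != "-" && utrc[i] != "-" &&
      pair_class(mirc[i], utrc[i]) != "mm"
  }, logical(1))
  # maximal runs of paired columns
  runs <- rle(paired)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  helices <- which(runs$values & runs$lengths >= 2)
  if (!length(helices)) {
    stop("undefined energy: alignment has no two consecutive base pairs")
  }
  dg <- 0
  for (h in helices) {
    for (i in starts[h]:(ends[h] - 1)) {
      key <- paste0(utrc[i], utrc[i + 1], "/", mirc[i], mirc[i + 1])
      v <- model$stack_table[[key]]
      if (is.null(v)) stop("stack table has no entry for ", key)
      dg <- dg + v
    }
  }
  # helix segments of length 1 do not stack but still delimit regions;
  # interior interrupted regions are the non-paired stretches between the
  # first and the last paired column
  pair_idx <- which(paired)
  interior <- rle(paired[min(pair_idx):max(pair_idx)])
  n_interrupt <- sum(!interior$values)
  dg <- dg + model$loop_penalty * n_interrupt
  dg <- dg + model$terminal_penalty * 2 * length(helices)
  dg
}

#' Does a duplex hit pass the retention thresholds?
#'
#' Strict-inequality semantics: retained iff `score > score_threshold`
#' and `delta_g < energy_threshold`.
#'
#' @param score alignment score(s).
#' @param delta_g duplex free energy/energies, kcal/mol.
#' @param score_threshold default 145.
#' @param energy_threshold default -10.
#' @return logical vector.
#' @export
hit_passes <- function(score, delta_g, score_threshold = 145,
                       energy_threshold = -10) {
  score > score_threshold & delta_g < energy_threshold
}

# Recursively extract non-overlapping high-scoring sites of one miRNA in
# one UTR: take the best local alignment, then recurse into the flanking
# UTR segments while scores exceed the retention threshold.
extract_sites <- function(mirna_seq, utr_seq, scheme, offset = 0L) {
  if (nchar(utr_seq) < 2) return(list())
  aln <- align_duplex(mirna_seq, utr_seq, scheme)
  if (aln$score <= scheme$score_threshold) return(list())
  aln$utr_start <- aln$utr_start + offset
  aln$utr_end <- aln$utr_end + offset
  left <- substr(utr_seq, 1, aln$utr_start - offset)
  right_from <- aln$utr_end - offset + 1
  right <- substr(utr_seq, right_from, nchar(utr_seq))
  c(list(aln),
    extract_sites(mirna_seq, left, scheme, offset),
    extract_sites(mirna_seq, right, scheme, offset + right_from - 1L))
}

#' Scan miRNAs against 3'-UTRs for target sites
#'
#' For every (miRNA, UTR) pair, finds all non-overlapping local alignment
#' maxima with score strictly above the scheme's threshold, computes each
#' site's nearest-neighbor free energy, and retains sites with
#' `score > score_threshold` and `delta_g < energy_threshold` (both
#' strict). Sites whose energy is undefined (no two consecutive pairs)
#' are discarded with a message. The maximum-score site per
#' (miRNA, gene) is flagged `best` for gene-level network use.
#'
#' @param mirnas named character vector or `RNAStringSet` of mature miRNA
#'   sequences, each 16-26 nt.
#' @param utrs named character vector or `RNAStringSet` of 3'-UTR
#'   sequences.
#' @param scheme a [scoring_scheme()].
#' @param model an [energy_model()].
#' @return data.frame of hits: `mirna_id`, `gene_id`, `start`, `end`
#'   (0-based half-open on the UTR), `score`, `delta_g`, `aln_mir`,
#'   `aln_match`, `aln_utr`, `best`.
#' @export
scan_targets <- function(mirnas, utrs, scheme = scoring_scheme(),
                         model = energy_model()) {
  mirnas <- as_rna_set(mirnas, "miRNA")
  utrs <- as_rna_set(utrs, "UTR")
  lens <- nchar(mirnas)
  if (any(lens < 16 | lens > 26)) {
    stop("miRNA length outside 16-26 nt: ",
         paste(names(mirnas)[lens < 16 | lens > 26], collapse = ", "))
  }
  if (scheme$strict_seed) {
    # a retained site must pair the whole seed by contiguous Watson-Crick
    # pairs, which requires the UTR to contain the exact reverse
    # complement of the seed; a fixed-string prefilter skips the DP for
    # the overwhelming majority of pairs
    candidates <- lapply(names(mirnas), function(mid) {
      seed_rc <- revcomp_rna(substr(mirnas[[mid]], scheme$seed_start,
                                    scheme$seed_end))
      names(utrs)[grepl(seed_rc, utrs, fixed = TRUE)]
    })
    names(candidates) <- names(mirnas)
  } else {
    # batch score pass (score-only C++ DP) prunes pairs that cannot yield
    # a passing site before the full traceback alignment is computed
    mir_enc <- lapply(unname(mirnas), encode_rna)
    utr_enc <- lapply(unname(utrs), encode_rna)
    best_scores <- scan_scores_cpp(mir_enc, utr_enc, scheme$wc_match,
                                   scheme$gu_wobble, scheme$mismatch,
                                   scheme$gap_open, scheme$gap_extend,
                                   scheme$seed_start, scheme$seed_end,
                                   scheme$seed_scale)
    dimnames(best_scores) <- list(names(mirnas), names(utrs))
    candidates <- lapply(names(mirnas), function(mid) {
      names(utrs)[best_scores[mid, ] > scheme$score_threshold]
    })
    names(candidates) <- names(mirnas)
  }
  rows <- list()
  n_undef <- 0L
  for (mid in names(mirnas)) {
    for (gid in candidates[[mid]]) {
      sites <- extract_sites(mirnas[[mid]], utrs[[gid]], scheme)
      for (s in sites) {
        if (scheme$strict_seed && !seed_intact(s, scheme)) next
        dg <- tryCatch(duplex_energy(s, model), error = function(e) NA_real_)
        if (is.na(dg)) { n_undef <- n_undef + 1L; next }
        if (!hit_passes(s$score, dg, scheme$score_threshold,
                        model$energy_threshold)) next
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mid, gene_id = gid,
          start = s$utr_start, end = s$utr_end,
          score = s$score, delta_g = dg,
          aln_mir = s$aln_mir, aln_match = s$aln_match,
          aln_utr = s$aln_utr, stringsAsFactors = FALSE)
      }
    }
  }
  if (n_undef > 0) {
    message("scan_targets: discarded ", n_undef,
            " site(s) with undefined duplex energy")
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(), gene_id = character(),
                      start = integer(), end = integer(),
                      score = numeric(), delta_g = numeric(),
                      aln_mir = character(), aln_match = character(),
                      aln_utr = character(), best = logical(),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, rows)
  # flag the max-score site per (miRNA, gene); ties -> smallest start
  ord <- order(hits$mirna_id, hits$gene_id, -hits$score, hits$start)
  hits <- hits[ord, , drop = FALSE]
  key <- paste(hits$mirna_id, hits$gene_id, sep = "\r")
  hits$best <- !duplicated(key)
  rownames(hits) <- NULL
  hits
}

#' Write a target-scan hits report as TSV
#'
#' Coordinates in the report are 1-based inclusive (stated in the file
#' header); internal coordinates are 0-based half-open.
#'
#' @param hits result of [scan_targets()].
#' @param path output file.
#' @param scheme,model the parameterization to record in the header.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path, scheme = scoring_scheme(),
                           model = energy_model()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# miRNA target scan report; coordinates 1-based inclusive on the UTR",
    sprintf("# retained at score > %g and delta_g < %g kcal/mol",
            scheme$score_threshold, model$energy_threshold)), con)
  out <- hits
  out$start <- out$start + 1L
  names(out)[names(out) == "start"] <- "start_1based"
  names(out)[names(out) == "end"] <- "end_1based"
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
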