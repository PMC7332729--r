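# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the implementation paths they
# verify.

# Maximum score over all gapped local alignments of a miRNA (reversed,
# 3'->5') against a UTR window: top-down recursive maximization over
# alignment prefixes, memoized, in plain R. Alignments start and end on a
# paired column; interior gap runs are affine with gap-state switches
# charged as openings.
oracle_align_score <- function(mirna, utr, scheme = scoring_scheme()) {
  m <- strsplit(mirna, "")[[1]]
  u <- strsplit(utr, "")[[1]]
  n <- length(m)
  nu <- length(u)
  pscore <- function(i, j) {
    pos5 <- n - i + 1
    key <- paste0(m[pos5], u[j])
    s <- if (key %in% c("AU", "UA", "CG", "GC")) scheme$wc_match
         else if (key %in% c("GU", "UG")) scheme$gu_wobble
         else scheme$mismatch
    if (pos5 >= scheme$seed_start && pos5 <= scheme$seed_end) {
      s * scheme$seed_scale
    } else s
  }
  memo <- new.env(hash = TRUE, parent = emptyenv())
  sc <- function(i, j, st) {
    if (i < 1 || j < 1) return(-Inf)
    key <- paste0(i, ",", j, ",", st)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (st == "M") {
      pscore(i, j) + max(0, sc(i - 1, j - 1, "M"), sc(i - 1, j - 1, "X"),
                         sc(i - 1, j - 1, "Y"))
    } else if (st == "X") {
      max(sc(i - 1, j, "M") + scheme$gap_open,
          sc(i - 1, j, "Y") + scheme$gap_open,
          sc(i - 1, j, "X") + scheme$gap_extend)
    } else {
      max(sc(i, j - 1, "M") + scheme$gap_open,
          sc(i, j - 1, "X") + scheme$gap_open,
          sc(i, j - 1, "Y") + scheme$gap_extend)
    }
    memo[[key]] <- val
    val
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(nu)) best <- max(best, sc(i, j, "M"))
  }
  best
}

# Literal brute-force enumeration of every gapped local alignment (no
# memoization); exponential, usable only for sequences of ~5 nt or less.
brute_align_score <- function(mirna, utr, scheme = scoring_scheme()) {
  m <- strsplit(mirna, "")[[1]]
  u <- strsplit(utr, "")[[1]]
  n <- length(m)
  nu <- length(u)
  pscore <- function(i, j) {
    pos5 <- n - i + 1
    key <- paste0(m[pos5], u[j])
    s <- if (key %in% c("AU", "UA", "CG", "GC")) scheme$wc_match
         else if (key %in% c("GU", "UG")) scheme$gu_wobble
         else scheme$mismatch
    if (pos5 >= scheme$seed_start && pos5 <= scheme$seed_end) {
      s * scheme$seed_scale
    } else s
  }
  best <- 0
  walk <- function(i, j, score, last) {
    if (last == "M" && score > best) best <<- score
    if (i <= n && j <= nu) walk(i + 1, j + 1, score + pscore(i, j), "M")
    if (i <= n) {
      walk(i + 1, j,
           score + if (last == "X") scheme$gap_extend else scheme$gap_open,
           "X")
    }
    if (j <= nu) {
      walk(i, j + 1,
           score + if (last == "Y") scheme$gap_extend else scheme$gap_open,
           "Y")
    }
  }
  for (i0 in seq_len(n)) {
    for (j0 in seq_len(nu)) {
      if (i0 < n || j0 < nu) walk(i0 + 1, j0 + 1, pscore(i0, j0), "M")
      else if (pscore(i0, j0) > best) best <- pscore(i0, j0)
    }
  }
  best
}

# Two-sided Fisher p by full enumeration of the hypergeometric support
# with probabilities from lchoose (a route independent of dhyper/phyper).
enum_fisher_p <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  supp <- max(0, k - n):min(k, m)
  dens <- exp(lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k))
  sum(dens[dens <= dens[supp == a] * (1 + 1e-7)])
}

# Two-sided correlation p-value by numerical integration of the t density
# (explicit gamma-function form, not pt).
integrate_cor_pvalue <- function(r, n) {
  df <- n - 2
  t_stat <- abs(r) * sqrt(df / (1 - r^2))
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, t_stat, Inf, rel.tol = 1e-12,
                       abs.tol = 1e-14)$value
}

# Brute-force recount of network statistics straight from an edge table.
recount_network_stats <- function(edges) {
  mir_e <- edges[edges$edge_type %in% c("miRNA->mRNA", "miRNA->TF"), ,
                 drop = FALSE]
  tf_e <- edges[edges$edge_type == "TF->mRNA", , drop = FALSE]
  loops <- 0L
  for (i in seq_len(nrow(mir_e))) {
    if (mir_e$edge_type[i] == "miRNA->TF") {
      loops <- loops + sum(tf_e$source_id == mir_e$target_id[i])
    }
  }
  list(n_mirna_mrna_pairs = nrow(mir_e),
       n_unique_mirnas = length(unique(mir_e$source_id)),
       n_unique_mrnas = length(unique(mir_e$target_id)),
       n_tf_mrna_pairs = nrow(tf_e),
       n_loops = loops)
}

# Random RNA string of length len.
rand_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Random typed edge tables for network recount checks.
random_edge_tables <- function(n_mirna = 6, n_gene = 12, n_tf = 3) {
  mirnas <- paste0("m", seq_len(n_mirna))
  genes <- paste0("g", seq_len(n_gene))
  tfs <- sample(genes, n_tf)
  n_me <- sample(3:12, 1)
  me <- data.frame(
    source_id = sample(mirnas, n_me, replace = TRUE),
    target_id = sample(genes, n_me, replace = TRUE),
    edge_type = "miRNA->mRNA",
    r = -runif(n_me, 0.82, 0.99), p = runif(n_me, 0, 0.05),
    q = NA_real_, score = runif(n_me, 146, 215),
    delta_g = -runif(n_me, 10.1, 40), stringsAsFactors = FALSE)
  me <- me[!duplicated(paste(me$source_id, me$target_id)), , drop = FALSE]
  n_te <- sample(2:10, 1)
  te <- data.frame(
    source_id = sample(tfs, n_te, replace = TRUE),
    target_id = sample(genes, n_te, replace = TRUE),
    edge_type = "TF->mRNA",
    r = runif(n_te, 0.91, 0.999), p = runif(n_te, 0, 0.01),
    q = NA_real_, score = NA_real_, delta_g = NA_real_,
    stringsAsFactors = FALSE)
  te <- te[te$source_id != te$target_id, , drop = FALSE]
  te <- te[!duplicated(paste(te$source_id, te$target_id)), , drop = FALSE]
  list(mirna_edges = me, tf_edges = te, tf_ids = tfs)
}
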