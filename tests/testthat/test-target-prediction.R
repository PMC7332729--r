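test_that("a perfect 22-nt duplex scores 15*5 + 7*5*4 = 215", {
  set.seed(2)
  mir <- rand_rna(22)
  utr <- plant_target_site(mir, rand_rna(60), 19)
  aln <- align_duplex(mir, utr)
  expect_equal(aln$score, 215)
  expect_equal(aln$utr_start, 19)
  expect_equal(aln$utr_end, 41)
  expect_equal(aln$mir_start, 1)
  expect_equal(aln$mir_end, 22)
  expect_true(seed_intact(aln))
})

test_that("no complementarity yields the local-alignment floor of zero", {
  aln <- align_duplex("AAAAAAAAAAAAAAAAAAAAAA",
                      paste(rep("A", 50), collapse = ""))
  expect_equal(aln$score, 0)
  expect_identical(aln$aln_mir, "")
})

test_that("DNA input is normalized with a warning; bad alphabet errors", {
  expect_warning(a <- align_duplex("TGAGGTAG", "AACUACCUCAAA"),
                 "converting T to U")
  expect_gt(a$score, 0)
  expect_error(align_duplex("AXGU", "AAAA"), "RNA alphabet")
})

test_that("the DP equals an independent recursive maximization over all alignments", {
  set.seed(7)
  for (i in 1:60) {
    mir <- rand_rna(sample(4:12, 1))
    utr <- rand_rna(sample(4:12, 1))
    expect_equal(align_duplex(mir, utr)$score,
                 oracle_align_score(mir, utr),
                 info = paste(mir, utr))
  }
})

test_that("the DP equals literal brute-force enumeration at tiny lengths", {
  set.seed(9)
  for (i in 1:4) {
    mir <- rand_rna(sample(4:5, 1))
    utr <- rand_rna(sample(4:5, 1))
    b <- brute_align_score(mir, utr)
    expect_equal(align_duplex(mir, utr)$score, b, info = paste(mir, utr))
    expect_equal(oracle_align_score(mir, utr), b, info = paste(mir, utr))
  }
})

test_that("jointly reversing both sequences preserves the optimal score", {
  # under position-independent scoring (no seed weighting)
  sym <- scoring_scheme(seed_scale = 1, seed_start = 1, seed_end = 1)
  revstr <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  set.seed(13)
  for (i in 1:20) {
    mir <- rand_rna(sample(6:14, 1))
    utr <- rand_rna(sample(10:30, 1))
    expect_equal(align_duplex(mir, utr, sym)$score,
                 align_duplex(revstr(mir), revstr(utr), sym)$score)
  }
})

test_that("duplex energy decomposes into stacks, loops and helix ends", {
  uniform <- setNames(rep(-2, 36),
                      names(energy_model()$stack_table))
  m0 <- energy_model(stack_table = uniform, loop_penalty = 0,
                     terminal_penalty = 0)
  # 6-bp uninterrupted helix: five -2 stacks
  helix <- list(aln_mir = "UUUUUU", aln_utr = "AAAAAA")
  expect_equal(duplex_energy(helix, m0), -10)

  # same helix split 3+3 by one mismatch, loop penalty +1
  m1 <- energy_model(stack_table = uniform, loop_penalty = 1,
                     terminal_penalty = 0)
  split <- list(aln_mir = "UUUCUUU", aln_utr = "AAACAAA")
  expect_equal(duplex_energy(split, m1), -7)

  # terminal penalty applies per helix end
  m2 <- energy_model(stack_table = uniform, loop_penalty = 1,
                     terminal_penalty = 0.5)
  expect_equal(duplex_energy(split, m2), -7 + 4 * 0.5)

  expect_error(duplex_energy(list(aln_mir = "UCU", aln_utr = "ACA"),
                             m0), "undefined energy")
})

test_that("energy is monotone non-increasing in helix length", {
  model <- energy_model()
  set.seed(19)
  prev <- 0
  mir <- rand_rna(26)
  for (len in 2:14) {
    sub <- substr(mir, 1, len)
    helix <- list(aln_mir = sub, aln_utr = chartr("ACGU", "UGCA", sub))
    dg <- duplex_energy(helix, model)
    expect_lte(dg, prev)
    prev <- dg
  }
})

test_that("default stack table is complete and negative", {
  model <- energy_model()
  expect_length(model$stack_table, 36)
  expect_true(all(model$stack_table < 0))
  expect_error(energy_model(stack_table = c("AA/UU" = 0.5)), "negative")
})

test_that("retention thresholds are strict on both score and energy", {
  expect_false(hit_passes(145, -12))
  expect_true(hit_passes(146, -10.5))
  expect_false(hit_passes(150, -10))
  expect_true(hit_passes(150, -10.01))
  expect_false(hit_passes(145, -10))
})

test_that("scan recovers every planted site and honors input contracts", {
  sim <- simulate_expression(small_sim_config(seed = 5))
  tr <- sim$truth
  hits <- scan_targets(sim$mirna_seqs[unique(tr$true_edges$mirna_id)],
                       sim$utr_seqs[unique(tr$true_edges$gene_id)])
  for (k in seq_len(nrow(tr$planted_sites))) {
    s <- tr$planted_sites[k, ]
    match <- hits[hits$mirna_id == s$mirna_id &
                    hits$gene_id == s$gene_id &
                    hits$start <= s$start & hits$end >= s$end, ]
    expect_gte(nrow(match), 1)
    expect_true(any(match$score == 215))
  }
  # one best site per pair flagged
  best <- hits[hits$best, ]
  expect_false(anyDuplicated(paste(best$mirna_id, best$gene_id)) > 0)

  expect_equal(nrow(scan_targets(sim$mirna_seqs[1], character(0))), 0)
  expect_error(scan_targets(c(x = "ACGUACGUACGU"), sim$utr_seqs[1]),
               "16-26")
  dup <- sim$mirna_seqs[c(1, 1)]
  expect_error(scan_targets(dup, sim$utr_seqs[1]), "duplicate")
})

test_that("strict seed demands contiguous Watson-Crick pairing of positions 2-8", {
  set.seed(29)
  mir <- rand_rna(22)
  utr <- plant_target_site(mir, rand_rna(100), 40)
  aln <- align_duplex(mir, utr)
  expect_true(seed_intact(aln))

  # a wobble planted inside the seed breaks strictness
  seed_chars <- strsplit(mir, "")[[1]]
  pos <- 4
  utr2 <- utr
  # UTR base pairing miRNA position 4 sits at utr index 40 + (22 - 4) + 1
  idx <- 40 + (22 - pos) + 1
  wob <- c(A = "G", C = "U", G = "U", U = "G")[[seed_chars[pos]]]
  substr(utr2, idx, idx) <- wob
  aln2 <- align_duplex(mir, utr2)
  expect_false(seed_intact(aln2))
})

test_that("hit reports are written with 1-based inclusive coordinates", {
  sim <- simulate_expression(small_sim_config(seed = 5))
  e1 <- sim$truth$true_edges[1, ]
  hits <- scan_targets(sim$mirna_seqs[e1$mirna_id],
                       sim$utr_seqs[e1$gene_id])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, path)
  back <- read.delim(path, comment.char = "#")
  expect_equal(back$start_1based, hits$start + 1)
  expect_equal(back$end_1based, hits$end)
})
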