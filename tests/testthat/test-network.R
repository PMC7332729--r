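test_that("pearson_with_pvalue reproduces the hand-worked case", {
  st <- pearson_with_pvalue(1:6, c(2, 1, 4, 3, 6, 5))
  expect_equal(st$r, 14.5 / 17.5, tolerance = 1e-12)
  expect_equal(st$t_stat, st$r * sqrt(4 / (1 - st$r^2)), tolerance = 1e-12)
  expect_equal(st$p, 0.0416, tolerance = 1e-3)
  ct <- cor.test(1:6, c(2, 1, 4, 3, 6, 5))
  expect_equal(st$p, ct$p.value, tolerance = 1e-12)

  perfect <- pearson_with_pvalue(1:6, 6:1)
  expect_equal(perfect$r, -1)
  expect_equal(perfect$p, 0)

  flat <- pearson_with_pvalue(rep(2, 6), 1:6)
  expect_false(flat$defined)
  expect_true(is.na(flat$r))

  expect_error(pearson_with_pvalue(1:5, 1:6), "length")
  expect_error(pearson_with_pvalue(1:2, 2:1), "at least 3")
})

test_that("correlation p-values match numerical t-density integration", {
  set.seed(37)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    st <- pearson_with_pvalue(x, y)
    expect_equal(st$p, integrate_cor_pvalue(st$r, n), tolerance = 1e-8)
  }
})

test_that("anticorrelation filter intersects duplex evidence with strict r and p", {
  set.seed(43)
  n <- 6
  pr_pass <- profiles_with_r(-0.9, n)     # exactly -0.9
  pr_fail <- profiles_with_r(-0.5, n)
  mirna_expr <- rbind(m1 = pr_pass$x + 10, m2 = pr_fail$x + 10,
                      m3 = pr_pass$x + 10)
  mrna_expr <- rbind(g1 = pr_pass$y + 10, g2 = pr_fail$y + 10,
                     g3 = pr_pass$y + 10)
  colnames(mirna_expr) <- colnames(mrna_expr) <- paste0("s", 1:n)
  cand <- data.frame(mirna_id = c("m1", "m2"), gene_id = c("g1", "g2"),
                     score = 150, delta_g = -12)

  # p dominates at n = 6: r = -0.9 has p < 0.05, r = -0.5 does not
  kept <- filter_anticorrelated_pairs(cand, mirna_expr, mrna_expr,
                                      log_transform = FALSE)
  expect_identical(kept$source_id, "m1")
  expect_lt(kept$r, -0.81)

  # strictness at the r boundary itself (p not binding): setting the
  # cutoff to the pair's own r must drop it, an epsilon above keeps it
  r_obs <- cor(mirna_expr["m1", ], mrna_expr["g1", ])
  kept2 <- filter_anticorrelated_pairs(cand, mirna_expr, mrna_expr,
                                       r_max = r_obs, p_max = 0.99,
                                       log_transform = FALSE)
  expect_equal(nrow(kept2), 0)
  kept3 <- filter_anticorrelated_pairs(cand, mirna_expr, mrna_expr,
                                       r_max = r_obs + 1e-9, p_max = 0.99,
                                       log_transform = FALSE)
  expect_identical(kept3$source_id, "m1")

  # an anticorrelated pair absent from the duplex candidates (m3, g3)
  # never becomes an edge
  expect_false("m3" %in% kept$source_id)

  # unknown features are skipped with a message
  cand_bad <- rbind(cand, data.frame(mirna_id = "ghost", gene_id = "g1",
                                     score = 150, delta_g = -12))
  expect_message(
    filter_anticorrelated_pairs(cand_bad, mirna_expr, mrna_expr,
                                log_transform = FALSE),
    "skipping")
})

test_that("every retained miRNA edge at defaults satisfies r < -0.81 with n = 6", {
  # with six samples, p < 0.05 under the t transform forces |r| > 0.811
  set.seed(47)
  mirna_expr <- matrix(2^rnorm(60, 6, 2), 10, 6,
                       dimnames = list(paste0("m", 1:10), paste0("s", 1:6)))
  mrna_expr <- matrix(2^rnorm(300, 6, 2), 50, 6,
                      dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  cand <- expand.grid(mirna_id = rownames(mirna_expr),
                      gene_id = rownames(mrna_expr),
                      stringsAsFactors = FALSE)
  cand$score <- 150
  cand$delta_g <- -12
  kept <- filter_anticorrelated_pairs(cand, mirna_expr, mrna_expr)
  if (nrow(kept)) expect_true(all(kept$r < -0.81))
})

test_that("edge sets shrink monotonically as thresholds tighten", {
  set.seed(53)
  mirna_expr <- matrix(2^rnorm(60, 6, 2), 10, 6,
                       dimnames = list(paste0("m", 1:10), paste0("s", 1:6)))
  mrna_expr <- matrix(2^rnorm(300, 6, 2), 50, 6,
                      dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  cand <- expand.grid(mirna_id = rownames(mirna_expr),
                      gene_id = rownames(mrna_expr),
                      stringsAsFactors = FALSE)
  cand$score <- 150
  cand$delta_g <- -12
  loose <- filter_anticorrelated_pairs(cand, mirna_expr, mrna_expr,
                                       r_max = -0.3, p_max = 0.5)
  tight <- filter_anticorrelated_pairs(cand, mirna_expr, mrna_expr,
                                       r_max = -0.6, p_max = 0.1)
  key <- function(e) paste(e$source_id, e$target_id)
  expect_true(all(key(tight) %in% key(loose)))

  tfl <- tf_target_edges(paste0("g", 1:3), mrna_expr, r_min = 0.3,
                         p_max = 0.9)
  tft <- tf_target_edges(paste0("g", 1:3), mrna_expr, r_min = 0.6,
                         p_max = 0.3)
  expect_true(all(key(tft) %in% key(tfl)))
})

test_that("TF catalog annotation normalizes case and version suffixes", {
  expect_identical(annotate_tfs(c("MYOD1", "ACTA1"), c("MYOD1", "MEF2A")),
                   "MYOD1")
  expect_identical(annotate_tfs(c("myod1.2", "ACTA1"), "MYOD1"), "myod1.2")
  expect_length(annotate_tfs(c("A", "B"), character()), 0)
})

test_that("TF-target edges apply strict coexpression thresholds", {
  set.seed(59)
  base <- rnorm(6)
  pr <- profiles_with_r(0.90, 6)
  expr <- rbind(TF1 = pr$x + 10, twin = pr$x + 10, exact90 = pr$y + 10,
                noise = rnorm(6) + 10)
  colnames(expr) <- paste0("s", 1:6)

  r_obs <- cor(expr["TF1", ], expr["exact90", ])
  kept <- tf_target_edges("TF1", expr, r_min = r_obs, p_max = 0.99,
                          log_transform = FALSE)
  expect_true("twin" %in% kept$target_id)      # r = 1
  expect_false("exact90" %in% kept$target_id)  # r == cutoff, strict
  expect_false("TF1" %in% kept$target_id)      # no self edge
  expect_true(all(kept$r > 0))
  kept_eps <- tf_target_edges("TF1", expr, r_min = r_obs - 1e-9,
                              p_max = 0.99, log_transform = FALSE)
  expect_true("exact90" %in% kept_eps$target_id)

  expect_message(out <- tf_target_edges(c("TF1", "absent"), expr,
                                        log_transform = FALSE),
                 "absent")
})

test_that("network assembly types edges, counts loops, merges duplicates", {
  me <- data.frame(source_id = "mir-1", target_id = "TF1",
                   edge_type = "miRNA->mRNA", r = -0.9, p = 0.01,
                   q = NA_real_, score = 150, delta_g = -12,
                   stringsAsFactors = FALSE)
  te <- data.frame(source_id = "TF1", target_id = c("gA", "gB"),
                   edge_type = "TF->mRNA", r = 0.95, p = 0.001,
                   q = NA_real_, score = NA_real_, delta_g = NA_real_,
                   stringsAsFactors = FALSE)
  net <- assemble_network(me, te, tf_ids = "TF1")
  expect_equal(net$stats$n_loops, 2)
  expect_equal(net$stats$n_tfs_targeted, 1)
  expect_identical(net$edges$edge_type[net$edges$target_id == "TF1"],
                   "miRNA->TF")
  expect_identical(net$nodes$type[net$nodes$id == "TF1"], "TF")

  flat <- assemble_network(me, tf_ids = character())
  expect_equal(flat$stats$n_loops, 0)
  expect_equal(flat$stats$n_tf_mrna_pairs, 0)

  dup <- rbind(me, transform(me, r = -0.95))
  expect_message(net2 <- assemble_network(dup, te, "TF1"), "duplicate")
  expect_equal(nrow(net2$edges[grepl("miRNA", net2$edges$edge_type), ]), 1)
  expect_equal(net2$edges$r[net2$edges$edge_type == "miRNA->TF"], -0.95)

  self <- transform(me, target_id = "mir-1")
  expect_error(assemble_network(self, te, "TF1"), "self-edges")
})

test_that("assembled statistics equal an independent recount on random graphs", {
  set.seed(61)
  for (i in 1:100) {
    tabs <- random_edge_tables()
    net <- suppressMessages(
      assemble_network(tabs$mirna_edges, tabs$tf_edges, tabs$tf_ids))
    rc <- recount_network_stats(net$edges)
    expect_equal(net$stats$n_mirna_mrna_pairs, rc$n_mirna_mrna_pairs)
    expect_equal(net$stats$n_unique_mirnas, rc$n_unique_mirnas)
    expect_equal(net$stats$n_unique_mrnas, rc$n_unique_mrnas)
    expect_equal(net$stats$n_tf_mrna_pairs, rc$n_tf_mrna_pairs)
    expect_equal(net$stats$n_loops, rc$n_loops)
  }
})

test_that("recovery scoring handles perfect, empty and random networks", {
  truth <- structure(list(
    true_edges = data.frame(mirna_id = c("m1", "m2"),
                            gene_id = c("g1", "g2")),
    tf_modules = list(TF1 = c("g3", "g4"))), class = "GroundTruth")
  perfect <- data.frame(
    source_id = c("m1", "m2", "TF1", "TF1"),
    target_id = c("g1", "g2", "g3", "g4"),
    edge_type = c("miRNA->mRNA", "miRNA->mRNA", "TF->mRNA", "TF->mRNA"),
    r = c(-0.9, -0.9, 0.95, 0.95), p = 0.001, q = NA_real_,
    score = c(150, 150, NA, NA), delta_g = c(-12, -12, NA, NA),
    stringsAsFactors = FALSE)
  res <- evaluate_recovery(perfect, truth)
  expect_equal(res$precision, c(1, 1))
  expect_equal(res$recall, c(1, 1))

  empty <- evaluate_recovery(perfect[0, ], truth)
  expect_equal(empty$precision, c(0, 0))
  expect_false(any(empty$defined))

  # permutation baseline: random same-size edge sets score near
  # |truth| / (n_mirnas * n_genes)
  set.seed(67)
  n_m <- 20; n_g <- 200
  truth_big <- structure(list(
    true_edges = data.frame(
      mirna_id = paste0("m", sample(n_m, 40, TRUE)),
      gene_id = paste0("g", sample(n_g, 40, TRUE))),
    tf_modules = list()), class = "GroundTruth")
  truth_big$true_edges <-
    truth_big$true_edges[!duplicated(truth_big$true_edges), ]
  n_truth <- nrow(truth_big$true_edges)
  prec <- replicate(100, {
    e <- data.frame(
      source_id = paste0("m", sample(n_m, n_truth, TRUE)),
      target_id = paste0("g", sample(n_g, n_truth, TRUE)),
      edge_type = "miRNA->mRNA", r = -0.9, p = 0.01, q = NA_real_,
      score = 150, delta_g = -12, stringsAsFactors = FALSE)
    evaluate_recovery(e, truth_big)$precision[1]
  })
  expected <- n_truth / (n_m * n_g)
  expect_lt(abs(mean(prec) - expected), 4 * sd(prec) / sqrt(100) + 1e-3)
})

test_that("networks export to edge TSV, GraphML and stats JSON", {
  tabs <- random_edge_tables()
  net <- suppressMessages(
    assemble_network(tabs$mirna_edges, tabs$tf_edges, tabs$tf_ids))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  js <- withr::local_tempfile(fileext = ".json")
  write_network(net, edges_tsv = tsv, graphml = gml, stats_json = js)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  st <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(st$n_loops, net$stats$n_loops)
})
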