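make_clusters <- function(sizes) {
  taxa <- unlist(lapply(seq_len(4), function(k)
    sprintf("g%d_s%d", k, seq_len(sizes[k]))))
  cluster_assignment(taxa, rep(1:4, sizes))
}

test_that("quartet enumeration is the full cross product, once each", {
  expect_equal(nrow(enumerate_quartets(make_clusters(c(1, 1, 1, 1)))), 1L)
  q <- enumerate_quartets(make_clusters(c(1, 2, 1, 67)))
  expect_equal(nrow(q), 134L)
  expect_equal(anyDuplicated(do.call(paste, q)), 0L)
  q2 <- enumerate_quartets(make_clusters(c(2, 3, 2, 2)))
  expect_equal(nrow(q2), 24L)
  # lexicographic: first cluster varies slowest, fourth fastest
  expect_equal(q2$t1[1:12], rep("g1_s1", 12))
  expect_equal(q2$t4[1:2], c("g4_s1", "g4_s2"))
  # one taxon from each cluster in every row
  expect_true(all(startsWith(q2$t2, "g2_")))
})

test_that("degenerate cluster assignments are rejected", {
  expect_error(cluster_assignment(c("a", "b", "c"), c(1, 2, 4)),
               "empty|least one")
  expect_error(cluster_assignment(c("a", "a", "b", "c"), c(1, 2, 3, 4)),
               "more than once")
  expect_error(cluster_assignment(c("a", "b", "c", "d"), c(1, 2, 3, 5)),
               "1..4")
})

test_that("posterior weights are a stable softmax of the triple", {
  expect_equal(posterior_weights(c(-10, -10, -10)), rep(1 / 3, 3))
  p <- posterior_weights(c(-1000, -1100, -1100))
  expect_lt(abs(p[1] - 1), 1e-40)
  # deep in the underflow regime only the differences matter
  p2 <- posterior_weights(c(-100000, -100001, -100002))
  ref <- exp(c(0, -1, -2)); ref <- ref / sum(ref)
  expect_equal(p2, ref, tolerance = 1e-12)
  expect_equal(sum(p2), 1, tolerance = 1e-12)
  expect_error(posterior_weights(c(-Inf, 0, 0)), "finite")
  expect_error(posterior_weights(c(NA, 0, 0)), "finite")
})

test_that("region classification covers corners, center, edges and ties", {
  expect_equal(classify_quartet(c(1, 0, 0), "argmax"), "T1")
  expect_equal(classify_quartet(c(1, 0, 0), "seven_region"), "corner_T1")
  expect_equal(classify_quartet(rep(1 / 3, 3), "argmax"), "tie")
  expect_equal(classify_quartet(rep(1 / 3, 3), "seven_region"), "center")
  expect_equal(classify_quartet(c(0.5, 0.45, 0.05), "seven_region"),
               "edge_T1T2")
  expect_equal(classify_quartet(c(0.05, 0.45, 0.5), "seven_region"),
               "edge_T2T3")
  expect_equal(classify_quartet(c(0.91, 0.05, 0.04), "seven_region"),
               "corner_T1")
  # constructed argmax summary: 80% / 20% / 0%
  ps <- c(rep(list(c(0.8, 0.1, 0.1)), 4), list(c(0.1, 0.8, 0.1)))
  labels <- vapply(ps, classify_quartet, character(1), mode = "argmax")
  counts <- table(factor(labels, levels = c("T1", "T2", "T3")))
  expect_equal(as.numeric(100 * counts / 5), c(80, 20, 0))
})

test_that("simplex coordinates interpolate the reference triangle", {
  expect_equal(unname(simplex_coordinates(c(1, 0, 0))), c(0, 0))
  expect_equal(unname(simplex_coordinates(c(0, 1, 0))), c(1, 0))
  expect_equal(unname(simplex_coordinates(c(0, 0, 1))),
               c(0.5, 0.8660254), tolerance = 1e-7)
  expect_equal(unname(simplex_coordinates(rep(1 / 3, 3))),
               c(0.5, sqrt(3) / 6), tolerance = 1e-12)
})

test_that("run_fclm recovers the generating split and honors relabeling", {
  fc <- four_cluster_tree(2, internal = 0.25)
  m <- substitution_model("LG", alpha = 1)
  aln <- simulate_alignment(fc$tree, m, 600, seed = 71)
  sm <- concatenate_genes(list(gene001 = aln))
  res <- run_fclm(sm, fc$clusters, model = m, alpha = "none")
  expect_equal(res$summary$n_quartets, 16L)
  am <- res$summary$argmax
  expect_gte(am$percent[am$label == "T1"], 95)
  expect_equal(sum(am$percent), 100, tolerance = 1e-9)
  expect_true(all(abs(rowSums(res$results[, c("p1", "p2", "p3")]) - 1) < 1e-12))
  # swapping cluster labels 2 and 3 turns the 12|34 signal into 13|24
  cl_sw <- cluster_assignment(unlist(fc$clusters$members),
                              rep(c(1, 3, 2, 4), each = 2))
  res_sw <- run_fclm(sm, cl_sw, model = m, alpha = "none")
  am_sw <- res_sw$summary$argmax
  expect_equal(am_sw$percent[am_sw$label == "T2"],
               am$percent[am$label == "T1"])
})

test_that("uninformative quartets get uniform weights and a flag", {
  # four taxa with pairwise disjoint coverage: no column has 2+ residues
  seqs <- c(a = "AR------", b = "--ND----", c = "----CQ--", d = "------EG")
  sm <- concatenate_genes(list(g = seqs))
  cl <- cluster_assignment(names(seqs), 1:4)
  res <- run_fclm(sm, cl, model = substitution_model("POISSON"))
  expect_true(res$results$uninformative[1])
  expect_equal(unlist(res$results[1, c("p1", "p2", "p3")]),
               rep(1 / 3, 3), ignore_attr = TRUE)
  expect_equal(res$results$argmax[1], "tie")
  expect_equal(res$results$seven_region[1], "center")
})

test_that("subsampling caps the quartet count deterministically", {
  fc <- four_cluster_tree(2, internal = 0.2)
  m <- substitution_model("POISSON")
  aln <- simulate_alignment(fc$tree, m, 40, seed = 3)
  sm <- concatenate_genes(list(g = aln))
  r1 <- run_fclm(sm, fc$clusters, model = m, alpha = "none",
                 max_quartets = 5, seed = 99)
  r2 <- run_fclm(sm, fc$clusters, model = m, alpha = "none",
                 max_quartets = 5, seed = 99)
  expect_equal(nrow(r1$results), 5L)
  expect_equal(r1$results, r2$results)
  expect_equal(r1$n_enumerated, 16L)
})

test_that("partitioned mode sums per-partition models under shared branches", {
  fc <- four_cluster_tree(1, internal = 0.3, cluster_depth = 0.05)
  m <- substitution_model("LG", alpha = 1)
  a1 <- simulate_alignment(fc$tree, m, 300, seed = 11)
  a2 <- simulate_alignment(fc$tree, m, 300, seed = 12)
  sm <- concatenate_genes(list(g1 = a1, g2 = a2))
  pm <- list(substitution_model("LG", alpha = 1),
             substitution_model("WAG", alpha = 1))
  res <- run_fclm(sm, fc$clusters, model = m, partitioned = TRUE,
                  partition_models = pm)
  expect_equal(nrow(res$results), 1L)
  # tree pairs clusters (1,2)|(3,4): T1 must win
  expect_equal(res$results$argmax[1], "T1")
  # partitioned log-likelihood must equal the sum of the blocks at the
  # optimum's branch lengths only if models matched; here just check the
  # triple is finite and ordered sensibly
  expect_true(all(is.finite(unlist(res$results[1, c("logL_T1", "logL_T2", "logL_T3")]))))
})

test_that("star-tree center fraction grows as alignments shorten", {
  fc <- four_cluster_tree(1, internal = 0, cluster_depth = 0.05,
                          tip_length = 0.05)
  m <- substitution_model("LG", alpha = 1)
  frac <- vapply(c(3000, 600, 120), function(sites) {
    center <- 0L
    for (r in 1:20) {
      aln <- simulate_alignment(fc$tree, m, sites, seed = sites * 17 + r)
      qa <- quartet_alignment(names(aln), aln)
      ev <- evaluate_three_topologies(qa, m, alpha = "none")
      p <- posterior_weights(ev$loglik)
      if (classify_quartet(p, "seven_region") == "center")
        center <- center + 1L
    }
    center / 20
  }, numeric(1))
  # less data -> flatter triples -> more quartets in the center region
  expect_true(all(diff(frac) >= 0))
  expect_lt(frac[1], frac[3])
})
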