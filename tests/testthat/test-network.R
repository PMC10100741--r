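test_that("fast-greedy recovers the two triangle communities", {
  crps <- data.frame(i = c(1, 1, 2, 4, 4, 5, 3), j = c(2, 3, 3, 5, 6, 6, 4))
  net <- residue_network(crps)
  cm <- detect_communities(net)
  expect_equal(cm$n_communities, 2)
  mem <- cm$membership
  expect_equal(length(unique(mem[c("1", "2", "3")])), 1)
  expect_equal(length(unique(mem[c("4", "5", "6")])), 1)
  expect_false(mem[["1"]] == mem[["4"]])
  # matches the brute-force optimum for this graph
  edges <- cbind(as.character(crps$i), as.character(crps$j))
  expect_equal(cm$modularity,
               oracle_best_modularity(edges, as.character(1:6)),
               tolerance = 1e-12)
})

test_that("degenerate graphs are handled", {
  one_clique <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3))
  cm <- detect_communities(residue_network(one_clique))
  expect_equal(cm$n_communities, 1)
  two_edges <- data.frame(i = c(1, 3), j = c(2, 4))
  expect_equal(detect_communities(residue_network(two_edges))$n_communities, 2)
  expect_error(detect_communities(residue_network(
    data.frame(i = integer(), j = integer()), nodes = 1:3)), "no edges")
})

test_that("CRP endpoint classification sums to one", {
  crps <- data.frame(i = c(1, 1, 3), j = c(2, 3, 4))
  cls <- classify_crps(crps, tsds = c(1, 2))
  expect_equal(unname(cls$fractions), c(1, 1, 1) / 3)
  expect_equal(sum(cls$fractions), 1)
  expect_equal(unname(classify_crps(crps, integer())$fractions), c(0, 0, 1))
  expect_equal(unname(classify_crps(crps, 1:4)$fractions), c(1, 0, 0))
})

test_that("TSDS clustering test behaves at the extremes", {
  # every edge intra-TSDS, few TSDS nodes -> smallest attainable p
  crps <- data.frame(i = c(1, 1), j = c(2, 3))
  net <- residue_network(crps, tsds = 1:3, nodes = 1:20)
  r <- tsds_clustering_test(net, n_perm = 199, seed = 1)
  expect_equal(r$observed, 1)
  expect_lt(r$p_value, 0.05)
  # zero intra-TSDS edges -> p is 1 by construction
  net0 <- residue_network(data.frame(i = 1, j = 2), tsds = c(1, 5),
                          nodes = 1:5)
  r0 <- tsds_clustering_test(net0, n_perm = 99, seed = 1)
  expect_equal(r0$observed, 0)
  expect_gte(r0$p_value, 0.5)
})

test_that("TSDS clustering test is calibrated under random labels", {
  set.seed(14)
  rejections <- replicate(60, {
    g <- igraph::sample_gnp(15, 0.3)
    el <- igraph::as_edgelist(g)
    if (nrow(el) < 2) return(NA)
    crps <- data.frame(i = el[, 1], j = el[, 2])
    tsds <- sample(15, 5)
    net <- residue_network(crps, tsds = tsds, nodes = 1:15)
    if (!length(net$tsds)) return(NA)
    tsds_clustering_test(net, n_perm = 99,
                         seed = sample.int(1e6, 1))$p_value < 0.05
  })
  rate <- mean(rejections, na.rm = TRUE)
  n <- sum(!is.na(rejections))
  se <- sqrt(0.05 * 0.95 / n)
  expect_lte(rate, 0.05 + 3 * se)
})

test_that("separation and block fractions follow the conventions", {
  blocks <- data.frame(start = c(1, 6), end = c(5, 10))
  crps <- data.frame(i = c(4, 3, 2, 2), j = c(10, 8, 4, 12))
  r <- separation_and_blocks(crps, blocks)
  # separations 6, 5, 2, 10 -> distant iff > 5
  expect_equal(r$frac_distant, 0.5)
  # (4,10) and (3,8) cross blocks; (2,12) has an endpoint outside all blocks
  expect_equal(r$frac_out_of_block, 0.75)
  expect_error(separation_and_blocks(crps,
    data.frame(start = c(1, 4), end = c(5, 8))), "disjoint")
})

test_that("default blocks split at gappy columns", {
  mat <- matrix("A", 6, 7)
  mat[, 4] <- "-"
  mat[1, 4] <- "R"
  fam <- aligned_family(mat)
  blk <- default_blocks(fam)
  expect_equal(blk$start, c(1, 5))
  expect_equal(blk$end, c(3, 7))
})

test_that("CRP-grouped motif similarity weights groups by size", {
  mk_sims <- function(v) structure(
    list(tf_ids = rownames(v), values = v),
    class = "motif_similarity_matrix")
  ids <- paste0("tf", 1:4)
  v <- diag(1, 4); dimnames(v) <- list(ids, ids)
  v["tf1", "tf2"] <- v["tf2", "tf1"] <- 0.8
  v["tf3", "tf4"] <- v["tf4", "tf3"] <- 0.4
  fam <- aligned_family(setNames(c("AR", "AR", "CK", "CK"), ids))
  sims <- mk_sims(v)
  # two groups of two at pair (1,2): weighted mean 0.5*0.8 + 0.5*0.4
  r <- crp_grouped_motif_similarity(data.frame(i = 1, j = 2),
                                    data.frame(i = integer(), j = integer()),
                                    fam, sims)
  expect_equal(unname(r$crp_scores), 0.6)
  # single eligible group
  fam1 <- aligned_family(setNames(c("AR", "AR", "C-", "-K"), ids))
  r1 <- crp_grouped_motif_similarity(data.frame(i = 1, j = 2),
                                     data.frame(i = integer(), j = integer()),
                                     fam1, sims)
  expect_equal(unname(r1$crp_scores), 0.8)
})

test_that("identical CRP and non-CRP score distributions give p near 1", {
  set.seed(15)
  ids <- paste0("tf", 1:8)
  v <- matrix(runif(64, 0.2, 0.9), 8); v <- (v + t(v)) / 2; diag(v) <- 1
  dimnames(v) <- list(ids, ids)
  sims <- structure(list(tf_ids = ids, values = v),
                    class = "motif_similarity_matrix")
  mat <- random_msa(8, 6, 3)
  rownames(mat) <- ids
  fam <- aligned_family(mat)
  pairs <- data.frame(i = c(1, 2, 3), j = c(4, 5, 6))
  r <- crp_grouped_motif_similarity(pairs, pairs, fam, sims)
  expect_gt(r$t_test$p.value, 0.99)
  expect_equal(r$crp_scores, r$non_crp_scores)
})

test_that("BH adjustment reproduces the step-up example", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.37), 0.37)
  expect_equal(adjust_fdr(c(1, 1)), c(1, 1))
  expect_error(adjust_fdr(c(0.5, 1.2)))
})
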