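test_that("worked covariation examples reproduce exactly", {
  fam <- aligned_family(c("AAA", "AAC", "CCA", "CCC"))
  r <- compute_coevolution(fam)
  expect_equal(r$matrices$MI["1", "2"], 1.0)
  expect_equal(r$matrices$MI["1", "3"], 0.0)
  expect_equal(r$matrices$OMES["1", "3"], 0.0)
  expect_equal(r$matrices$OMES["1", "2"],
               ((2 - 1)^2 + (0 - 1)^2 + (0 - 1)^2 + (2 - 1)^2) / 4)
  # APC arithmetic: row means 0.5/0.5/0, grand mean 1/3
  expect_equal(r$matrices$MIp["1", "2"], 0.25)
  expect_equal(r$matrices$MIp["1", "3"], 0.0)
  expect_equal(r$matrices$SCA["1", "3"], 0.0)
})

test_that("all four statistics match the brute-force oracle", {
  set.seed(10)
  for (rep in 1:8) {
    mat <- random_msa(sample(4:10, 1), sample(4:8, 1), sample(3:6, 1))
    fam <- aligned_family(mat)
    r <- compute_coevolution(fam, max_gap_frac = 1)
    o <- oracle_coevolution(mat)
    kept <- as.integer(rownames(r$matrices$MI))
    for (m in c("MI", "MIp", "OMES", "SCA")) {
      expect_equal(unname(r$matrices[[m]]),
                   unname(o[[m]][kept, kept, drop = FALSE]),
                   tolerance = 1e-10)
    }
  }
})

test_that("pairwise gap handling drops rows gapped at either column", {
  mat <- rbind(c("A", "A"), c("A", "-"), c("C", "C"), c("C", "C"),
               c("-", "A"), c("A", "C"))
  fam <- aligned_family(mat)
  r <- compute_coevolution(fam, methods = "MI", max_gap_frac = 0.5)
  expect_equal(r$matrices$MI["1", "2"], oracle_pair_stats(mat, 1, 2)$mi,
               tolerance = 1e-12)
})

test_that("scores are invariant to row order and alphabet relabeling", {
  set.seed(11)
  mat <- random_msa(8, 6, 5)
  fam <- aligned_family(mat)
  r1 <- compute_coevolution(fam)
  r2 <- compute_coevolution(aligned_family(mat[sample(8), , drop = FALSE]))
  expect_equal(r2$matrices, r1$matrices)
  # bijective residue relabeling
  perm <- setNames(sample(ORACLE_AA), ORACLE_AA)
  mat3 <- matrix(perm[mat], nrow(mat), dimnames = dimnames(mat))
  r3 <- compute_coevolution(aligned_family(mat3))
  expect_equal(r3$matrices, r1$matrices)
})

test_that("MI, OMES and SCA are non-negative", {
  set.seed(12)
  for (rep in 1:5) {
    fam <- aligned_family(random_msa(8, 6, 4))
    r <- compute_coevolution(fam)
    expect_true(all(r$matrices$MI >= -1e-12, na.rm = TRUE))
    expect_true(all(r$matrices$OMES >= -1e-12, na.rm = TRUE))
    expect_true(all(r$matrices$SCA >= -1e-12, na.rm = TRUE))
  }
})

test_that("column filter enforces gap fraction and diversity rules", {
  mat <- do.call(rbind, strsplit(rep("XYZ", 10), ""))
  mat[, 1] <- c(rep("-", 3), sample(c("A", "C"), 7, replace = TRUE))  # 30% gaps
  mat[, 2] <- "R"                                                     # invariant
  mat[, 3] <- rep(c("A", "C"), 5)                                     # clean
  fam <- aligned_family(mat)
  keep <- filter_columns(fam, max_gap_frac = 0.25)
  expect_false(keep[1])
  expect_false(keep[2])
  expect_true(keep[3])
  expect_error(filter_columns(aligned_family(matrix("R", 4, 3))), "filtered")
})

make_score_matrix <- function(scores, n_cols, na_pairs = 0) {
  m <- matrix(NA_real_, n_cols, n_cols,
              dimnames = list(seq_len(n_cols), seq_len(n_cols)))
  ut <- which(upper.tri(m))
  vals <- c(scores, rep(NA_real_, length(ut) - length(scores)))
  m[ut] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

test_that("top-decile candidates follow the nearest-rank tie rule", {
  # 20 distinct scores among 21 pairs (one unscored) -> exactly 2 selected
  m20 <- make_score_matrix(as.numeric(1:20), 7)
  sel <- candidate_pairs(m20, 0.10)
  expect_equal(nrow(sel), 2)
  expect_setequal(sel$score, c(19, 20))
  # 100 distinct scores -> the 10 pairs scoring >= 91
  m100 <- make_score_matrix(as.numeric(1:100), 15)
  sel100 <- candidate_pairs(m100, 0.10)
  expect_equal(sort(sel100$score), as.numeric(91:100))
  # all tied -> everything selected, with a warning
  mt <- make_score_matrix(rep(1, 21), 7)
  expect_warning(selt <- candidate_pairs(mt, 0.10), "tied")
  expect_equal(nrow(selt), 21)
})

test_that("CRP definition and Jaccard agreement follow set rules", {
  cand <- list(A = data.frame(i = c(1, 1), j = c(2, 3)),
               B = data.frame(i = c(1, 4), j = c(2, 5)),
               C = data.frame(i = 6, j = 7),
               D = data.frame(i = 8, j = 9))
  crps <- define_crps(cand, min_methods = 2)
  expect_equal(nrow(crps), 1)
  expect_equal(c(crps$i, crps$j), c(1, 2))
  # identical sets -> the full set; disjoint -> empty with warning
  same <- list(A = cand$A, B = cand$A, C = cand$A)
  expect_equal(nrow(define_crps(same)), 2)
  expect_warning(empty <- define_crps(cand[c("C", "D")]), "empty")
  expect_equal(nrow(empty), 0)

  j <- method_agreement(list(
    A = data.frame(i = c(1, 2, 3), j = c(11, 12, 13)),
    B = data.frame(i = c(2, 3, 4), j = c(12, 13, 14))))
  expect_equal(j["A", "B"], 0.5)
  expect_equal(unname(diag(j)), c(1, 1))
  expect_equal(method_agreement(list(A = cand$C, B = cand$D))["A", "B"], 0)
  expect_equal(method_agreement(list(A = cand$C, B = cand$C))["A", "B"], 1)
})

test_that("score combination follows rescale/quantile/average scheme", {
  expect_equal(rescale_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  qn <- quantile_normalize(cbind(c(1, 2, 3), c(10, 20, 30)))
  expect_equal(qn[, 1], c(5.5, 11, 16.5))
  expect_equal(qn[, 2], c(5.5, 11, 16.5))
  # four identical matrices -> combined equals the rescaled input
  m <- make_score_matrix(c(1, 3, 5, 7, 9, 11), 4)
  comb <- combine_scores(list(m, m, m, m))
  expect_equal(comb[upper.tri(comb)], rescale_minmax(m[upper.tri(m)]))
})

test_that("combined scores are monotone in shared method ranks", {
  set.seed(13)
  base_ranks <- sample(10)
  mats <- lapply(1:4, function(k) {
    # same ordering, different monotone scales
    make_score_matrix(sort(rexp(10))[base_ranks], 5)
  })
  comb <- combine_scores(mats)
  expect_equal(order(comb[upper.tri(comb)]), order(base_ranks))
})

test_that("coevolution outputs serialise to long-format TSV", {
  cfg <- synthetic_config(n_tf = 40, n_col = 12,
                          coevolving_pairs = list(c(1, 7, 0.9), c(3, 10, 0.9)),
                          seed = 1)
  gen <- generate_family(cfg)
  coe <- run_coevolution(gen$family)
  d <- withr::local_tempdir()
  write_coevolution(coe, d, seed_pos = seed_coordinates(gen$family))
  mi <- read.table(file.path(d, "coevolution_MI.tsv"), header = TRUE)
  expect_true(all(c("i", "j", "score", "seed_i", "seed_j") %in% names(mi)))
  expect_equal(nrow(mi), choose(sum(coe$column_mask), 2))
})
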