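## helix-like toy complex: protein chain A with n residues of 2 atoms each,
## DNA chain B along the x axis
toy_complex <- function(n_res = 6, resolution = 2.0, seed = 1) {
  set.seed(seed)
  prot <- do.call(rbind, lapply(seq_len(n_res), function(r) {
    ctr <- c(3 * r, 5 + 2 * (r %% 3), 4)
    data.frame(chain = "A", resno = r,
               resname = sample(c("ARG", "LYS", "ASP", "TRP", "GLU"), 1),
               elety = c("CA", "CB"),
               x = ctr[1] + c(0, runif(1, -1, 1)),
               y = ctr[2] + c(0, runif(1, -1, 1)),
               z = ctr[3] + c(0, runif(1, -1, 1)))
  }))
  dna <- data.frame(chain = "B", resno = 100 + 1:4, resname = "DA",
                    elety = "P", x = 3 * (1:4), y = 0, z = 0)
  generate_toy_complex(rbind(prot, dna), resolution = resolution)
}

test_that("PDB round trip preserves coordinates to reported precision", {
  cx <- toy_complex()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(cx, f)
  cx2 <- load_complex(f)
  expect_equal(cx2$resolution, 2.0)
  for (coord in c("x", "y", "z"))
    expect_equal(cx2$atoms[[coord]], cx$atoms[[coord]], tolerance = 1e-3)
  expect_equal(table(cx2$atoms$type), table(cx$atoms$type))
})

test_that("resolution and composition gates reject unusable structures", {
  f45 <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(toy_complex(resolution = 4.5), f45)
  expect_error(load_complex(f45), "resolution 4.50")
  expect_silent(load_complex(f45, max_resolution = 5))

  ## protein-only file
  fp <- withr::local_tempfile(fileext = ".pdb")
  cx <- toy_complex()
  cx$atoms <- cx$atoms[cx$atoms$type == "protein", ]
  write_complex_pdb(cx, fp)
  expect_error(load_complex(fp), "no DNA chain")

  ## missing resolution record
  fnr <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(toy_complex(), fnr)
  writeLines(grep("RESOLUTION", readLines(fnr), invert = TRUE, value = TRUE),
             fnr)
  expect_error(load_complex(fnr), "no resolution record")
  expect_silent(load_complex(fnr, require_resolution = FALSE))
})

test_that("minimum distances match a brute-force double loop", {
  cx <- toy_complex(seed = 3)
  mp <- data.frame(column = 1:6, chain = "A", resno = 1:6)
  dm <- residue_distances(cx, mp)
  a <- cx$atoms
  dna_xyz <- as.matrix(a[a$type == "dna", c("x", "y", "z")])
  for (i in 1:6) {
    Ai <- as.matrix(a[a$type == "protein" & a$resno == i, c("x", "y", "z")])
    expect_equal(unname(dm$dna[as.character(i)]),
                 oracle_min_dist(Ai, dna_xyz), tolerance = 1e-9)
    for (j in seq_len(6)[-i]) {
      Aj <- as.matrix(a[a$type == "protein" & a$resno == j, c("x", "y", "z")])
      expect_equal(dm$pair[as.character(i), as.character(j)],
                   oracle_min_dist(Ai, Aj), tolerance = 1e-9)
    }
  }
  expect_true(all(is.na(diag(dm$pair))))
  expect_equal(dm$pair, t(dm$pair))
})

test_that("distances are invariant under rigid motion", {
  cx <- toy_complex(seed = 4)
  mp <- data.frame(column = 1:6, chain = "A", resno = 1:6)
  dm <- residue_distances(cx, mp)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(cx$atoms[, c("x", "y", "z")]) %*% R
  cx2 <- cx
  cx2$atoms$x <- xyz[, 1] + 11.3
  cx2$atoms$y <- xyz[, 2] - 4.2
  cx2$atoms$z <- xyz[, 3] + 0.7
  dm2 <- residue_distances(cx2, mp)
  expect_equal(dm2$pair, dm$pair, tolerance = 1e-9)
  expect_equal(dm2$dna, dm$dna, tolerance = 1e-9)
})

test_that("column mapping handles substring, gaps and substitutions", {
  fam <- aligned_family(c(s1 = "RK-WD", s2 = "RKAWD"), seed_id = "s1")
  ch <- list(seq = "GGRKWDGG", resno = 11:18)
  mp <- map_columns_to_residues(fam, ch, chain_id = "A")
  expect_equal(mp$column, c(1, 2, 4, 5))
  expect_equal(mp$resno, c(13, 14, 15, 16))
  # one internal substitution: that column alone is unmapped
  fam2 <- aligned_family(c(s1 = "RKDWEFGHIL"), seed_id = "s1")
  ch2 <- list(seq = "AARKDWAFGHILAA", resno = 1:14)
  mp2 <- map_columns_to_residues(fam2, ch2, chain_id = "A")
  expect_equal(setdiff(1:10, mp2$column), 5)
  # low identity refused
  ch3 <- list(seq = "MMMMMMMMMM", resno = 1:10)
  expect_error(map_columns_to_residues(fam2, ch3), "refused")
})

test_that("f-CRP classification uses a strict 10 A endpoint rule", {
  dm <- structure(list(
    pair = matrix(NA_real_, 4, 4, dimnames = list(1:4, 1:4)),
    dna = setNames(c(12, 4, 9.9, 9.9), 1:4),
    columns = 1:4), class = "distance_map")
  crps <- data.frame(i = c(1, 3, 2), j = c(2, 4, 5))
  r <- classify_fcrps(crps, dm, cutoff = 10)
  expect_equal(r$table$fcrp, c(TRUE, FALSE))     # (12,4) yes; (9.9,9.9) no
  expect_equal(r$n_unmapped, 1)                  # column 5 has no distance
  expect_equal(r$fraction, 0.5)
  # monotone non-increasing in the cutoff
  f_lo <- classify_fcrps(crps, dm, cutoff = 5)$fraction
  f_hi <- classify_fcrps(crps, dm, cutoff = 15)$fraction
  expect_gte(f_lo, r$fraction)
  expect_lte(f_hi, r$fraction)
})

test_that("spatial comparison reports direction and degenerate groups", {
  pair <- matrix(NA_real_, 8, 8, dimnames = list(1:8, 1:8))
  crp <- data.frame(i = 1:3, j = 2:4)
  non <- data.frame(i = 5:7, j = 6:8)
  for (k in 1:3) pair[crp$i[k], crp$j[k]] <- pair[crp$j[k], crp$i[k]] <- 5
  for (k in 1:3) pair[non$i[k], non$j[k]] <- pair[non$j[k], non$i[k]] <- 20
  dm <- structure(list(pair = pair, dna = numeric(), columns = 1:8),
                  class = "distance_map")
  r <- compare_spatial(crp, non, dm)
  expect_equal(r$direction, "crp_closer")
  expect_lt(r$p_value, 0.05)
  r_same <- compare_spatial(crp, crp, dm)
  expect_equal(r_same$p_value, 1)
})

test_that("FoldX mutation lists and ddG parsing follow the contracts", {
  expect_equal(foldx_mutation_list(
    data.frame(chain = "A", resno = 49, wt = "R", mut = "G")), "RA49G;")
  cx <- toy_complex(seed = 5)
  wt1 <- bio3d::aa321(cx$atoms$resname[cx$atoms$resno == 1][1])
  expect_silent(foldx_mutation_list(
    data.frame(chain = "A", resno = 1, wt = wt1, mut = "G"), cx))
  wrong <- setdiff(c("A", "R"), wt1)[1]
  expect_error(foldx_mutation_list(
    data.frame(chain = "A", resno = 1, wt = wrong, mut = "G"), cx),
    "mismatch at A1")

  dd <- data.frame(mutant = rep(c("m1", "m2"), each = 5),
                   replicate = rep(1:5, 2),
                   ddg = c(1:5, rep(1.5, 5)),
                   group = rep(c("conserved", "crp"), each = 5))
  r <- parse_foldx_ddg(dd)
  expect_equal(r$means$mean_ddg[r$means$mutant == "m1"], 3)
  expect_true(r$means$disruptive[r$means$mutant == "m1"])    # 3 > 2 kcal/mol
  expect_false(r$means$disruptive[r$means$mutant == "m2"])
  expect_true(!is.null(r$group_tests))
  expect_warning(parse_foldx_ddg(dd[-1, ]), "replicate count")
})
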