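#' Mask invariant alignment columns
#'
#' Columns in which every non-gap residue is identical carry no subclass
#' information and are excluded from specificity scoring.  All-gap columns
#' are additionally flagged degenerate.
#'
#' @param fam an [aligned_family].
#' @return logical vector, `TRUE` where a column is masked, with attribute
#'   `degenerate` marking all-gap columns.
#' @export
exclude_invariant_columns <- function(fam) {
  meta <- column_metadata(fam)
  mask <- meta$invariant | meta$all_gap
  attr(mask, "degenerate") <- meta$all_gap
  mask
}

## ---- column scoring core ---------------------------------------------------

## Per-column subclass-specificity scores for an integer-encoded MSA.
## enc: n x L matrix over 1..20 (NA = gap); rows_by_class: list of row index
## vectors, one per retained subclass.  Returns an L x 3 matrix (re, ed, er).
## er_delta regularises the between/within substitution-distance ratio.
score_columns_core <- function(enc, rows_by_class, lambda = 0.5,
                               er_delta = 0.05) {
  K <- 20L
  L <- ncol(enc)
  S <- length(rows_by_class)
  D <- blosum_distance_matrix()
  A <- ATCHLEY_FACTORS

  count_cols <- function(rows) {
    sub <- enc[rows, , drop = FALSE]
    vapply(seq_len(L), function(j) tabulate(sub[, j], K), numeric(K))
  }
  counts <- lapply(rows_by_class, count_cols)          # each K x L
  fam_counts <- count_cols(unlist(rows_by_class))
  n_s <- lapply(counts, colSums)                       # per-class col totals
  N <- colSums(fam_counts)

  q <- sweep(fam_counts + lambda, 2L, N + lambda * K, "/")

  kl <- matrix(NA_real_, S, L)
  means <- vector("list", S)      # 5 x L Atchley mean vectors
  freqs <- vector("list", S)      # K x L frequencies
  within <- matrix(NA_real_, S, L)
  for (s in seq_len(S)) {
    ok <- n_s[[s]] > 0
    p <- sweep(counts[[s]] + lambda, 2L, n_s[[s]] + lambda * K, "/")
    term <- p * log2(p / q)
    term[p == 0] <- 0
    kl[s, ok] <- colSums(term[, ok, drop = FALSE])
    f <- sweep(counts[[s]], 2L, pmax(n_s[[s]], 1), "/")
    f[, !ok] <- NA
    freqs[[s]] <- f
    means[[s]] <- crossprod(A, f)                      # 5 x L
    within[s, ] <- colSums(f * (D %*% f))
  }

  re <- colMeans(kl, na.rm = TRUE)

  prs <- if (S >= 2) combn(S, 2) else matrix(integer(), 2, 0)
  if (ncol(prs)) {
    ed_p <- matrix(NA_real_, ncol(prs), L)
    bt_p <- matrix(NA_real_, ncol(prs), L)
    for (k in seq_len(ncol(prs))) {
      s <- prs[1, k]; t <- prs[2, k]
      ed_p[k, ] <- sqrt(colSums((means[[s]] - means[[t]])^2))
      bt_p[k, ] <- colSums(freqs[[s]] * (D %*% freqs[[t]]))
    }
    ed <- colMeans(ed_p, na.rm = TRUE)
    mb <- colMeans(bt_p, na.rm = TRUE)
  } else {
    ed <- rep(0, L)
    mb <- rep(0, L)
  }
  mw <- colMeans(within, na.rm = TRUE)
  er <- (mb + er_delta) / (mw + er_delta)

  cbind(re = re, ed = ed, er = er)
}

## Column-wise z-scores over the unmasked columns; zero-variance -> 0.
combined_z_scores <- function(scores, masked) {
  z <- apply(scores, 2L, function(x) {
    v <- x[!masked]
    mu <- mean(v, na.rm = TRUE)
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(ifelse(masked, NA_real_, 0))
    out <- (x - mu) / s
    out[masked] <- NA_real_
    out
  })
  rowMeans(z)
}

#' Subclass-specificity scores for alignment columns
#'
#' For every unmasked column, three equal-weighted measures of how strongly
#' residue composition separates the retained motif subclasses:
#' \describe{
#'   \item{re}{mean over subclasses of the Kullback-Leibler divergence
#'     (bits, pseudocount `lambda`) of the subclass residue distribution
#'     from the whole-family distribution.}
#'   \item{ed}{mean pairwise Euclidean distance between subclass mean
#'     Atchley physicochemical property vectors.}
#'   \item{er}{ratio of mean between-subclass to mean within-subclass
#'     expected residue substitution distance (1 - normalised BLOSUM62
#'     similarity), regularised by a small additive constant.}
#' }
#' The combined statistic is the mean of the three column-wise z-scores.
#'
#' @param fam an [aligned_family].
#' @param partition a [subclass_partition()]; only retained subclasses
#'   (>= `min_size` members) enter the scores.
#' @param lambda pseudocount per residue class in frequency estimates.
#' @param er_delta additive regulariser of the substitution-distance ratio.
#' @return data frame, one row per column: `column`, `seed_pos`, `re`,
#'   `ed`, `er`, `combined_z`, `excluded_invariant`.
#' @export
speer_like_scores <- function(fam, partition, lambda = 0.5, er_delta = 0.05) {
  stopifnot(inherits(fam, "aligned_family"),
            inherits(partition, "subclass_partition"))
  rows_by_class <- retained_rows(fam, partition)
  if (length(rows_by_class) < 2L)
    stop("need at least two retained subclasses for specificity scoring")
  enc <- encode_family(fam)
  masked <- exclude_invariant_columns(fam)
  sc <- score_columns_core(enc, rows_by_class, lambda = lambda,
                           er_delta = er_delta)
  sc[masked, ] <- NA_real_
  data.frame(column = seq_len(n_col(fam)),
             seed_pos = seed_coordinates(fam),
             re = sc[, "re"], ed = sc[, "ed"], er = sc[, "er"],
             combined_z = combined_z_scores(sc, masked),
             excluded_invariant = as.logical(masked))
}

## Row indices of retained-subclass members, in subclass order.
retained_rows <- function(fam, partition) {
  labs <- partition$subclass_of[fam$tf_ids]
  if (anyNA(labs)) stop("TFs missing from the subclass partition: ",
                        paste(fam$tf_ids[is.na(labs)], collapse = ", "))
  lapply(partition$retained, function(s) which(labs == s))
}

#' Permutation test for subclass-determining sites
#'
#' The observed combined z-score of every column is compared with its null
#' distribution under random permutation of the TF-to-subclass labels
#' (which preserves the column residue composition).  The p-value uses the
#' add-one convention `p = (1 + #\{perm >= obs\}) / (n_perm + 1)`, so it is
#' never zero and never exceeds one.  A column is called a TSDS when
#' `p < alpha` and it is not masked as invariant.
#'
#' @inheritParams speer_like_scores
#' @param n_perm number of label permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @param alpha call threshold on the raw permutation p-value.
#' @return a `tsds_table` data frame: the columns of [speer_like_scores()]
#'   plus `p_value`, `p_bh` (Benjamini-Hochberg adjusted) and `is_tsds`.
#' @export
tsds_permutation_test <- function(fam, partition, n_perm = 1000L, seed = 1L,
                                  alpha = 0.1, lambda = 0.5, er_delta = 0.05) {
  if (n_perm < 99L) stop("n_perm must be at least 99")
  rows_by_class <- retained_rows(fam, partition)
  if (length(rows_by_class) < 2L)
    stop("need at least two retained subclasses for specificity scoring")
  enc <- encode_family(fam)
  masked <- exclude_invariant_columns(fam)

  obs_tab <- speer_like_scores(fam, partition, lambda = lambda,
                               er_delta = er_delta)
  obs <- obs_tab$combined_z

  member_rows <- unlist(rows_by_class)
  sizes <- lengths(rows_by_class)
  set.seed(seed)
  exceed <- rep(0L, n_col(fam))
  for (b in seq_len(n_perm)) {
    perm <- sample(member_rows)
    rows_b <- split(perm, rep(seq_along(sizes), sizes))
    sc <- score_columns_core(enc, rows_b, lambda = lambda,
                             er_delta = er_delta)
    sc[masked, ] <- NA_real_
    zb <- combined_z_scores(sc, masked)
    exceed <- exceed + as.integer(!is.na(zb) & !is.na(obs) & zb >= obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  p[masked | is.na(obs)] <- NA_real_
  obs_tab$p_value <- p
  obs_tab$p_bh <- NA_real_
  ok <- !is.na(p)
  obs_tab$p_bh[ok] <- p.adjust(p[ok], method = "BH")
  obs_tab$is_tsds <- !is.na(p) & p < alpha & !obs_tab$excluded_invariant
  class(obs_tab) <- c("tsds_table", "data.frame")
  obs_tab
}

#' Write a TSDS table as TSV
#'
#' @param table a `tsds_table` from [tsds_permutation_test()].
#' @param path output path.
#' @export
write_tsds_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
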