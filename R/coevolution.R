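#' Column filter for covariation scoring
#'
#' Excludes columns whose gap fraction exceeds `max_gap_frac` and columns
#' with no residue diversity (covariation with an invariant column is
#' identically zero).
#'
#' @param fam an [aligned_family].
#' @param max_gap_frac maximum tolerated gap fraction.
#' @return logical vector, `TRUE` for retained columns.
#' @export
filter_columns <- function(fam, max_gap_frac = 0.25) {
  meta <- column_metadata(fam)
  keep <- meta$gap_frac <= max_gap_frac & !meta$invariant
  if (!any(keep)) stop("all columns filtered out")
  keep
}

## Joint residue counts for one column pair, dropping rows gapped at either
## column.  Returns NULL when fewer than 2 co-observations exist.
pair_joint_counts <- function(ai, aj, K = 20L) {
  ok <- !is.na(ai) & !is.na(aj)
  if (sum(ok) < 2L) return(NULL)
  a <- ai[ok]; b <- aj[ok]
  J <- matrix(tabulate((a - 1L) * K + b, K * K), K, K, byrow = TRUE)
  list(J = J, N = sum(ok))
}

mi_from_counts <- function(J, N) {
  P <- J / N
  pi <- rowSums(P); pj <- colSums(P)
  E <- outer(pi, pj)
  nz <- P > 0
  sum(P[nz] * log2(P[nz] / E[nz]))
}

omes_from_counts <- function(J, N) {
  E <- outer(rowSums(J), colSums(J)) / N
  sum((J - E)^2) / N
}

## SCA conservation weight for a frequency vector under uniform background.
sca_phi <- function(f, lambda = 0.03, q = 1 / 20) {
  ft <- (1 - lambda) * f + lambda * q
  abs(log(ft * (1 - q) / ((1 - ft) * q)))
}

sca_from_counts <- function(J, N, lambda = 0.03) {
  fi <- rowSums(J) / N
  fj <- colSums(J) / N
  C <- J / N - outer(fi, fj)
  W <- outer(sca_phi(fi, lambda), sca_phi(fj, lambda)) * C
  sqrt(sum(W^2))
}

#' Residue covariation matrices for an aligned family
#'
#' Computes one or more of the four covariation statistics over all pairs
#' of retained columns:
#' \describe{
#'   \item{MI}{mutual information (bits) of the joint residue distribution,
#'     over sequences ungapped at both columns.}
#'   \item{MIp}{MI minus the average product correction
#'     `APC(i,j) = MI(i,.) MI(j,.) / mean(MI)`, which removes shared
#'     background/phylogenetic signal.}
#'   \item{OMES}{`sum((N_obs - N_exp)^2) / N` over residue-pair cells, with
#'     `N_exp(a,b) = n_i(a) n_j(b) / N`.}
#'   \item{SCA}{Frobenius norm of the conservation-weighted covariance
#'     tensor `phi_i^a phi_j^b (f_ij^ab - f_i^a f_j^b)` with
#'     `phi = |ln[f~(1-q) / ((1-f~)q)]|`, `f~ = (1-lambda) f + lambda q`,
#'     uniform background `q`.}
#' }
#'
#' @param fam an [aligned_family] with >= 4 sequences.
#' @param methods subset of `c("MI", "MIp", "OMES", "SCA")`.
#' @param max_gap_frac column gap filter passed to [filter_columns()].
#' @param sca_lambda SCA frequency regularisation.
#' @return object of class `coevolution_result`: list with `matrices` (one
#'   symmetric matrix per method, rows/cols named by retained alignment
#'   column, diagonal `NA`), `column_mask` (logical over all columns) and
#'   `methods`.
#' @export
compute_coevolution <- function(fam, methods = c("MI", "MIp", "OMES", "SCA"),
                                max_gap_frac = 0.25, sca_lambda = 0.03) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_seq(fam) < 4L) stop("need at least 4 sequences")
  keep <- filter_columns(fam, max_gap_frac)
  cols <- which(keep)
  if (length(cols) < 2L) stop("need at least 2 retained columns")
  enc <- encode_family(fam)[, cols, drop = FALSE]
  n <- length(cols)
  want_mi <- any(c("MI", "MIp") %in% methods)
  empty <- matrix(NA_real_, n, n, dimnames = list(cols, cols))
  mi <- omes <- sca <- empty
  for (i in seq_len(n - 1L)) {
    ai <- enc[, i]
    for (j in (i + 1L):n) {
      pc <- pair_joint_counts(ai, enc[, j])
      if (is.null(pc)) next
      if (want_mi) mi[i, j] <- mi[j, i] <- mi_from_counts(pc$J, pc$N)
      if ("OMES" %in% methods)
        omes[i, j] <- omes[j, i] <- omes_from_counts(pc$J, pc$N)
      if ("SCA" %in% methods)
        sca[i, j] <- sca[j, i] <- sca_from_counts(pc$J, pc$N, sca_lambda)
    }
  }
  mats <- list()
  if ("MI" %in% methods) mats$MI <- mi
  if ("MIp" %in% methods) mats$MIp <- apc_correct(mi)
  if ("OMES" %in% methods) mats$OMES <- omes
  if ("SCA" %in% methods) mats$SCA <- sca
  structure(list(matrices = mats, column_mask = keep, methods = names(mats)),
            class = "coevolution_result")
}

#' Average product correction of an MI matrix
#'
#' `MIp(i,j) = MI(i,j) - MI(i,.) MI(j,.) / mean(MI)`, with row means and the
#' grand mean taken over off-diagonal scored pairs.
#'
#' @param mi symmetric MI matrix with `NA` diagonal.
#' @return the corrected matrix.
#' @export
apc_correct <- function(mi) {
  row_means <- rowMeans(mi, na.rm = TRUE)
  grand <- mean(mi[upper.tri(mi)], na.rm = TRUE)
  if (!is.finite(grand) || grand == 0) {
    apc <- matrix(0, nrow(mi), ncol(mi))
  } else {
    apc <- outer(row_means, row_means) / grand
  }
  out <- mi - apc
  dimnames(out) <- dimnames(mi)
  out
}

#' @export
print.coevolution_result <- function(x, ...) {
  cat(sprintf("coevolution_result: %s over %d columns\n",
              paste(x$methods, collapse = "/"),
              sum(x$column_mask)))
  invisible(x)
}

## Long-format upper-triangle pairs of a named score matrix.
matrix_pairs <- function(mat) {
  idx <- which(upper.tri(mat), arr.ind = TRUE)
  cols <- as.integer(rownames(mat))
  data.frame(i = cols[idx[, 1L]], j = cols[idx[, 2L]],
             score = mat[idx])
}

#' Top-decile candidate pairs of a score matrix
#'
#' Selects the top `top_fraction` of scored pairs by nearest rank: the
#' threshold is the `ceiling(top_fraction * n)`-th largest score and every
#' pair at or above it is included (ties at the threshold are kept).
#'
#' @param mat symmetric score matrix (column-named, `NA` diagonal) from
#'   [compute_coevolution()].
#' @param top_fraction fraction of pairs to select.
#' @return data frame `i`, `j`, `score` of selected pairs (alignment-column
#'   indices, `i < j`).
#' @export
candidate_pairs <- function(mat, top_fraction = 0.10) {
  pairs <- matrix_pairs(mat)
  pairs <- pairs[is.finite(pairs$score), , drop = FALSE]
  if (nrow(pairs) < 10L) stop("need at least 10 scored pairs")
  k <- ceiling(top_fraction * nrow(pairs))
  thr <- sort(pairs$score, decreasing = TRUE)[k]
  sel <- pairs[pairs$score >= thr, , drop = FALSE]
  if (nrow(sel) == nrow(pairs) && length(unique(pairs$score)) == 1L)
    warning("all scores tied: every pair selected")
  rownames(sel) <- NULL
  sel
}

#' Final coevolving residue pairs (CRPs)
#'
#' A pair is a CRP when it appears in the candidate (top-decile) sets of at
#' least `min_methods` covariation methods.
#'
#' @param candidates named list of candidate data frames from
#'   [candidate_pairs()].
#' @param min_methods minimum number of supporting methods.
#' @return data frame `i`, `j`, `n_methods`.
#' @export
define_crps <- function(candidates, min_methods = 2L) {
  if (length(candidates) < 2L) stop("need candidate sets from >= 2 methods")
  keys <- lapply(candidates, function(d) pair_key(d$i, d$j))
  tab <- table(unlist(keys))
  keep <- names(tab)[tab >= min_methods]
  if (!length(keep)) {
    warning("no pair shared by enough methods: empty CRP set")
    return(data.frame(i = integer(), j = integer(), n_methods = integer()))
  }
  ij <- do.call(rbind, strsplit(keep, "-", fixed = TRUE))
  out <- data.frame(i = as.integer(ij[, 1L]), j = as.integer(ij[, 2L]),
                    n_methods = as.integer(tab[keep]))
  out[order(out$i, out$j), , drop = FALSE]
}

#' Jaccard agreement between candidate sets
#'
#' @param candidates named list of candidate data frames.
#' @return symmetric matrix of `|A intersect B| / |A union B|` with unit
#'   diagonal.
#' @export
method_agreement <- function(candidates) {
  if (length(candidates) < 2L) stop("need >= 2 candidate sets")
  keys <- lapply(candidates, function(d) unique(pair_key(d$i, d$j)))
  m <- length(keys)
  J <- diag(1, m)
  dimnames(J) <- list(names(candidates), names(candidates))
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      u <- length(union(keys[[a]], keys[[b]]))
      J[a, b] <- J[b, a] <- if (u == 0) NA_real_ else
        length(intersect(keys[[a]], keys[[b]])) / u
    }
  }
  J
}

#' Min-max rescaling to [0, 1]
#'
#' @param x numeric vector.
#' @return `(x - min) / (max - min)`; all-equal input maps to 0.
#' @export
rescale_minmax <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (rng[1] == rng[2]) return(ifelse(is.na(x), NA_real_, 0))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Combine per-method covariation scores
#'
#' Each method's scores over the shared pair universe are min-max rescaled
#' to `[0, 1]`, quantile-normalised across methods (tied values receive the
#' mean of the tied ranks' reference values), and averaged.
#'
#' @param mats named list of symmetric score matrices on identical column
#'   sets (e.g. `$matrices` of [compute_coevolution()]).
#' @return combined symmetric matrix; pairs unscored by any method are `NA`.
#' @export
combine_scores <- function(mats) {
  stopifnot(length(mats) >= 2L)
  dims <- vapply(mats, nrow, integer(1))
  if (length(unique(dims)) != 1L) stop("matrices must share the pair universe")
  template <- mats[[1L]]
  ut <- upper.tri(template)
  vals <- vapply(mats, function(m) m[ut], numeric(sum(ut)))
  complete <- rowSums(!is.finite(vals)) == 0
  scaled <- apply(vals[complete, , drop = FALSE], 2L, rescale_minmax)
  qn <- limma::normalizeQuantiles(scaled, ties = TRUE)
  combined_vec <- rep(NA_real_, sum(ut))
  combined_vec[complete] <- rowMeans(qn)
  out <- matrix(NA_real_, nrow(template), ncol(template),
                dimnames = dimnames(template))
  out[ut] <- combined_vec
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Quantile normalisation of score vectors
#'
#' Columns of `x` are forced onto the common reference distribution given
#' by the mean of the column-sorted values; ties receive the mean of the
#' tied ranks' reference values.
#'
#' @param x numeric matrix, one column per method.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  limma::normalizeQuantiles(as.matrix(x), ties = TRUE)
}

#' Run the complete covariation stage
#'
#' [compute_coevolution()] + per-method candidates + CRP definition +
#' method agreement + combined score.
#'
#' @inheritParams compute_coevolution
#' @param top_fraction candidate decile.
#' @param min_methods CRP support threshold.
#' @return `coevolution_result` extended with `candidates`, `crps`,
#'   `agreement` and `combined`.
#' @export
run_coevolution <- function(fam, methods = c("MI", "MIp", "OMES", "SCA"),
                            max_gap_frac = 0.25, top_fraction = 0.10,
                            min_methods = 2L, sca_lambda = 0.03) {
  res <- compute_coevolution(fam, methods, max_gap_frac, sca_lambda)
  res$candidates <- lapply(res$matrices, candidate_pairs,
                           top_fraction = top_fraction)
  res$crps <- define_crps(res$candidates, min_methods)
  res$agreement <- method_agreement(res$candidates)
  res$combined <- combine_scores(res$matrices)
  res
}

#' Write covariation matrices and pair sets as TSV
#'
#' @param res a `coevolution_result`.
#' @param dir output directory (created if missing).
#' @param seed_pos optional [seed_coordinates()] vector to add seed-sequence
#'   coordinates to pair tables.
#' @export
write_coevolution <- function(res, dir, seed_pos = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  add_seed <- function(d) {
    if (!is.null(seed_pos)) {
      d$seed_i <- seed_pos[d$i]
      d$seed_j <- seed_pos[d$j]
    }
    d
  }
  for (m in names(res$matrices)) {
    write.table(add_seed(matrix_pairs(res$matrices[[m]])),
                file.path(dir, paste0("coevolution_", m, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$combined))
    write.table(add_seed(matrix_pairs(res$combined)),
                file.path(dir, "coevolution_combined.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$crps))
    write.table(add_seed(res$crps), file.path(dir, "crps.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
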