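#' Pearson similarity between two DNA motifs
#'
#' Slides one PWM along the other over all ungapped offsets with at least
#' `min_overlap` overlapping columns (optionally also on the reverse
#' complement) and returns the maximum Pearson correlation between the
#' flattened 4 x L overlapping sub-matrices.
#'
#' @param a,b [pwm] objects.
#' @param min_overlap minimum number of overlapping motif columns.
#' @param use_revcomp also search the reverse-complement orientation of `b`.
#' @return similarity in `[-1, 1]`.
#' @export
motif_similarity <- function(a, b, min_overlap = 4L, use_revcomp = TRUE) {
  stopifnot(inherits(a, "pwm"), inherits(b, "pwm"))
  if (min_overlap > min(pwm_width(a), pwm_width(b)))
    stop("min_overlap exceeds the width of a motif")
  scores <- suppressWarnings(
    best_offset_similarity(a$matrix, b$matrix, min_overlap)$score)
  if (use_revcomp) {
    scores <- c(scores, suppressWarnings(
      best_offset_similarity(a$matrix, pwm_revcomp(b)$matrix, min_overlap)$score))
  }
  scores <- scores[is.finite(scores)]
  if (!length(scores)) {
    warning("no offset with non-degenerate overlap; similarity undefined")
    return(NA_real_)
  }
  max(scores)
}

## Max Pearson correlation over offsets; offset o places column 1 of `mb`
## at column o + 1 of `ma`.  Returns the best score and offset.
best_offset_similarity <- function(ma, mb, min_overlap) {
  wa <- ncol(ma); wb <- ncol(mb)
  offsets <- seq.int(-(wb - min_overlap), wa - min_overlap)
  best <- -Inf; best_o <- NA_integer_
  for (o in offsets) {
    ia <- max(1L, o + 1L):min(wa, o + wb)
    ib <- ia - o
    if (length(ia) < min_overlap) next
    va <- as.numeric(ma[, ia]); vb <- as.numeric(mb[, ib])
    if (sd(va) == 0 || sd(vb) == 0) next
    r <- cor(va, vb)
    if (r > best) { best <- r; best_o <- o }
  }
  if (!is.finite(best)) {
    warning("no offset with non-degenerate overlap; similarity undefined")
    return(list(score = NA_real_, offset = NA_integer_))
  }
  list(score = best, offset = best_o)
}

#' Pairwise motif similarity matrix for a TF family
#'
#' @param pwms a [pwm_set] with at least two motifs.
#' @inheritParams motif_similarity
#' @return object of class `motif_similarity_matrix`: list with `tf_ids`
#'   and `values` (symmetric matrix with unit diagonal).
#' @export
similarity_matrix <- function(pwms, min_overlap = 4L, use_revcomp = TRUE) {
  if (length(pwms) < 2L) stop("need at least two PWMs")
  ids <- vapply(pwms, function(p) p$tf_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate tf_id in PWM set")
  n <- length(pwms)
  v <- diag(1, n)
  dimnames(v) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- motif_similarity(pwms[[i]], pwms[[j]], min_overlap, use_revcomp)
      v[i, j] <- v[j, i] <- s
    }
  }
  structure(list(tf_ids = ids, values = v), class = "motif_similarity_matrix")
}

#' @export
print.motif_similarity_matrix <- function(x, ...) {
  cat(sprintf("motif_similarity_matrix: %d TFs\n", length(x$tf_ids)))
  invisible(x)
}

## Within-cluster sum of squares of feature rows under a labelling.
cluster_wss <- function(features, labels) {
  sum(vapply(split(seq_along(labels), labels), function(idx) {
    x <- features[idx, , drop = FALSE]
    ctr <- colMeans(x)
    sum(sweep(x, 2L, ctr)^2)
  }, numeric(1)))
}

#' Cluster TFs into motif subclasses
#'
#' Average-linkage hierarchical clustering on distance `1 - similarity`.
#' The subclass count k is chosen by the elbow rule: the smallest k whose
#' within-cluster sum of squares (rows of the similarity matrix as feature
#' vectors) falls below `wss_frac` of the unpartitioned WSS.  Subclasses
#' with fewer than `min_size` members are flagged as excluded from
#' downstream specificity analysis.
#'
#' @param sim a [similarity_matrix()] result.
#' @param min_size minimum retained subclass size.
#' @param wss_frac elbow threshold as a fraction of WSS at k = 1.
#' @param linkage hclust linkage method.
#' @return a `subclass_partition`: list with `subclass_of` (named integer
#'   labels), `k`, `wss_curve`, `sizes`, `retained` (labels of subclasses
#'   with >= min_size members) and `min_size`.
#' @export
cluster_subclasses <- function(sim, min_size = 5L, wss_frac = 0.10,
                               linkage = "average") {
  stopifnot(inherits(sim, "motif_similarity_matrix"))
  n <- length(sim$tf_ids)
  feats <- sim$values
  if (n < min_size)
    warning("fewer TFs than min_size: single subclass, excluded downstream")
  hc <- hclust(stats::as.dist(pmax(1 - sim$values, 0)), method = linkage)
  wss1 <- cluster_wss(feats, rep(1L, n))
  wss_curve <- numeric(n)
  labels_k <- vector("list", n)
  for (k in seq_len(n)) {
    labels_k[[k]] <- cutree(hc, k = k)
    wss_curve[k] <- cluster_wss(feats, labels_k[[k]])
  }
  k <- if (wss1 == 0) 1L else which(wss_curve < wss_frac * wss1)[1L]
  labels <- setNames(as.integer(labels_k[[k]]), sim$tf_ids)
  subclass_partition(labels, min_size = min_size, k = k, wss_curve = wss_curve)
}

#' Construct a subclass partition from explicit labels
#'
#' @param labels named vector of subclass labels (names = TF ids).
#' @param min_size minimum retained subclass size.
#' @param k,wss_curve optional bookkeeping from [cluster_subclasses()].
#' @return a `subclass_partition`.
#' @export
subclass_partition <- function(labels, min_size = 5L, k = NULL,
                               wss_curve = NULL) {
  if (is.null(names(labels))) stop("labels must be named by TF id")
  labels <- setNames(as.integer(factor(labels)), names(labels))
  sizes <- table(labels)
  retained <- as.integer(names(sizes)[sizes >= min_size])
  structure(list(subclass_of = labels,
                 k = k %||% length(sizes),
                 wss_curve = wss_curve,
                 sizes = as.integer(sizes),
                 retained = retained,
                 min_size = as.integer(min_size)),
            class = "subclass_partition")
}

#' @export
print.subclass_partition <- function(x, ...) {
  cat(sprintf("subclass_partition: k = %d (%s members); retained: %s\n",
              x$k, paste(x$sizes, collapse = "/"),
              paste(x$retained, collapse = ", ")))
  invisible(x)
}

#' Write subclass assignments as TSV
#'
#' @param partition a `subclass_partition`.
#' @param path output path.
#' @export
write_subclasses <- function(partition, path) {
  df <- data.frame(tf_id = names(partition$subclass_of),
                   subclass = unname(partition$subclass_of),
                   retained = unname(partition$subclass_of) %in% partition$retained)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge the motifs of a subclass into one PWM
#'
#' Aligns every member at its best ungapped offset to the member with the
#' highest total information content and averages the aligned columns over
#' the region covered by all members, renormalising each column.
#'
#' @param pwms a [pwm_set].
#' @param members character vector of TF ids to merge.
#' @param min_overlap minimum overlap used in the offset search.
#' @return a merged [pwm].
#' @export
merge_motifs <- function(pwms, members, min_overlap = 4L) {
  if (!length(members)) stop("empty member list")
  missing <- setdiff(members, names(pwms))
  if (length(missing)) stop("members without a PWM: ",
                            paste(missing, collapse = ", "))
  mats <- lapply(pwms[members], function(p) p$matrix)
  if (length(mats) == 1L)
    return(pwm(mats[[1L]], paste0("merged_", members[[1L]])))
  ics <- vapply(pwms[members], pwm_ic, numeric(1))
  ref <- which.max(ics)
  offsets <- vapply(seq_along(mats), function(m) {
    if (m == ref) return(0L)
    as.integer(best_offset_similarity(mats[[ref]], mats[[m]], min_overlap)$offset)
  }, integer(1))
  ## region (in reference coordinates) covered by every member
  from <- max(offsets + 1L)
  to <- min(offsets + vapply(mats, ncol, integer(1)))
  if (to < from) stop("members share no common overlap region")
  cols <- from:to
  acc <- matrix(0, 4, length(cols))
  for (m in seq_along(mats)) acc <- acc + mats[[m]][, cols - offsets[m], drop = FALSE]
  pwm(acc / length(mats), paste0("merged_", length(members), "x"))
}

#' Motif diversity versus group size
#'
#' For each group, the interquartile range (IQR, linear-interpolation
#' quartiles) of the off-diagonal motif similarities, and the Spearman
#' correlation between the per-group IQR and the group sizes.
#'
#' @param sim_by_group named list of [similarity_matrix()] results.
#' @param counts named numeric vector of group sizes (same names).
#' @return list with `iqr` (per group), `rho`, `p_value` (NA when fewer
#'   than 3 groups or the correlation is undefined).
#' @export
diversity_stats <- function(sim_by_group, counts) {
  groups <- names(sim_by_group)
  stopifnot(!is.null(groups), all(groups %in% names(counts)))
  iqr <- vapply(sim_by_group, function(s) {
    v <- s$values[upper.tri(s$values)]
    IQR(v, type = 7)
  }, numeric(1))
  counts <- counts[groups]
  if (length(groups) < 3L)
    return(list(iqr = iqr, rho = NA_real_, p_value = NA_real_,
                note = "fewer than 3 groups: correlation undefined"))
  if (sd(iqr) == 0 || sd(counts) == 0)
    return(list(iqr = iqr, rho = NA_real_, p_value = NA_real_,
                note = "constant input: Spearman correlation undefined"))
  ct <- suppressWarnings(cor.test(iqr, counts, method = "spearman"))
  list(iqr = iqr, rho = unname(ct$estimate), p_value = ct$p.value)
}
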