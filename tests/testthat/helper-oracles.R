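## Independent brute-force oracles.  These share no code with the package:
## every statistic is evaluated by direct enumeration from its definition.

ORACLE_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## MI (bits), OMES and SCA for one column pair of a character MSA matrix,
## dropping rows gapped at either column.
oracle_pair_stats <- function(mat, i, j, sca_lambda = 0.03) {
  ri <- mat[, i]; rj <- mat[, j]
  ok <- ri != "-" & rj != "-"
  ri <- ri[ok]; rj <- rj[ok]
  N <- length(ri)
  q <- 1 / 20
  mi <- 0; omes <- 0; sca2 <- 0
  for (a in ORACLE_AA) {
    for (b in ORACLE_AA) {
      nab <- sum(ri == a & rj == b)
      na <- sum(ri == a); nb <- sum(rj == b)
      if (nab > 0)
        mi <- mi + (nab / N) * log2((nab / N) / ((na / N) * (nb / N)))
      omes <- omes + (nab - na * nb / N)^2 / N
      fa <- na / N; fb <- nb / N; fab <- nab / N
      fta <- (1 - sca_lambda) * fa + sca_lambda * q
      ftb <- (1 - sca_lambda) * fb + sca_lambda * q
      pa <- abs(log(fta * (1 - q) / ((1 - fta) * q)))
      pb <- abs(log(ftb * (1 - q) / ((1 - ftb) * q)))
      sca2 <- sca2 + (pa * pb * (fab - fa * fb))^2
    }
  }
  list(mi = mi, omes = omes, sca = sqrt(sca2))
}

## Full oracle matrices for an MSA matrix (no gap/diversity filtering).
oracle_coevolution <- function(mat, sca_lambda = 0.03) {
  L <- ncol(mat)
  mi <- omes <- sca <- matrix(NA_real_, L, L)
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      st <- oracle_pair_stats(mat, i, j, sca_lambda)
      mi[i, j] <- mi[j, i] <- st$mi
      omes[i, j] <- omes[j, i] <- st$omes
      sca[i, j] <- sca[j, i] <- st$sca
    }
  }
  apc <- matrix(NA_real_, L, L)
  rm_ <- sapply(seq_len(L), function(i) mean(mi[i, -i]))
  gm <- mean(mi[upper.tri(mi)])
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      apc[i, j] <- apc[j, i] <- rm_[i] * rm_[j] / gm
    }
  }
  list(MI = mi, MIp = mi - apc, OMES = omes, SCA = sca)
}

## Random gap-free MSA where every column has at least two residues.
random_msa <- function(n_seq, n_col, alphabet_size = 5) {
  aa <- sample(ORACLE_AA, alphabet_size)
  mat <- matrix("", n_seq, n_col)
  for (j in seq_len(n_col)) {
    repeat {
      col <- sample(aa, n_seq, replace = TRUE)
      if (length(unique(col)) >= 2) break
    }
    mat[, j] <- col
  }
  rownames(mat) <- paste0("s", seq_len(n_seq))
  mat
}

## Brute-force minimum atomic distance between two coordinate sets.
oracle_min_dist <- function(A, B) {
  best <- Inf
  for (p in seq_len(nrow(A))) {
    for (q in seq_len(nrow(B))) {
      d <- sqrt(sum((A[p, ] - B[q, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

## Modularity of a partition from first principles.
oracle_modularity <- function(edges, membership) {
  m <- nrow(edges)
  deg <- table(factor(c(edges[, 1], edges[, 2]), levels = names(membership)))
  q <- 0
  for (com in unique(membership)) {
    nodes <- names(membership)[membership == com]
    ec <- sum(edges[, 1] %in% nodes & edges[, 2] %in% nodes)
    dc <- sum(deg[nodes])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  q
}

## All set partitions of n items as restricted-growth label vectors.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, k) {
    pos <- length(labels) + 1
    if (pos > n) {
      out[[length(out) + 1]] <<- labels
      return()
    }
    for (lab in seq_len(k + 1)) recurse(c(labels, lab), max(k, lab))
  }
  recurse(integer(), 0)
  out
}

## Best modularity over all partitions of the nodes of an edge list.
oracle_best_modularity <- function(edges, nodes) {
  n <- length(nodes)
  best <- -Inf
  for (p in all_partitions(n)) {
    names(p) <- nodes
    q <- oracle_modularity(edges, p)
    if (q > best) best <- q
  }
  best
}

## Convenience: synthetic family config used in several recovery tests.
recovery_config <- function(seed, n_tf = 200, n_col = 60, n_pairs = 10,
                            coupling = 0.9) {
  pairs <- lapply(seq_len(n_pairs), function(k) c(2 * k - 1, 20 + 4 * k, coupling))
  synthetic_config(n_tf = n_tf, n_col = n_col, n_subclass = 1,
                   coevolving_pairs = pairs, seed = seed)
}
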