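#' Coevolution residue network
#'
#' Alignment columns as nodes, CRPs as edges; nodes carry a TSDS flag.
#'
#' @param crps data frame `i`, `j` of coevolving residue pairs.
#' @param tsds integer vector of TSDS column indices.
#' @param nodes optional full node universe (alignment columns); defaults
#'   to the union of CRP endpoints.
#' @return a `residue_network`: list with `graph` (igraph, vertex attribute
#'   `tsds`), `crps`, `tsds`.
#' @export
residue_network <- function(crps, tsds = integer(), nodes = NULL) {
  nodes <- sort(unique(c(nodes, crps$i, crps$j)))
  if (!length(nodes)) stop("empty network: no nodes")
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(crps$i), to = as.character(crps$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes),
                          tsds = nodes %in% tsds))
  structure(list(graph = g, crps = crps, tsds = intersect(tsds, nodes)),
            class = "residue_network")
}

#' Community structure by greedy modularity optimisation
#'
#' Clauset-Newman-Moore agglomerative modularity maximisation (igraph
#' fast-greedy); returns the partition at the modularity maximum of the
#' merge path.
#'
#' @param net a [residue_network()] (or an igraph graph).
#' @return list with `membership` (named by column), `modularity` and
#'   `n_communities`.
#' @export
detect_communities <- function(net) {
  g <- if (inherits(net, "residue_network")) net$graph else net
  if (igraph::ecount(g) == 0L) stop("empty graph: no edges to cluster")
  gs <- igraph::simplify(g)
  cm <- igraph::cluster_fast_greedy(gs)
  ## cut the merge path explicitly at its modularity maximum
  steps <- which.max(cm$modularity) - 1L
  mem <- igraph::cut_at(cm, steps = steps)
  list(membership = setNames(as.integer(mem), igraph::V(gs)$name),
       modularity = igraph::modularity(gs, mem),
       n_communities = length(unique(mem)))
}

#' Classify CRPs by TSDS membership of their endpoints
#'
#' @param crps data frame `i`, `j`.
#' @param tsds integer vector of TSDS columns.
#' @return list with counts and fractions `intra` (both endpoints TSDS),
#'   `between` (exactly one) and `extra` (none); fractions sum to 1.
#' @export
classify_crps <- function(crps, tsds) {
  if (!nrow(crps)) stop("no CRPs to classify")
  k <- (crps$i %in% tsds) + (crps$j %in% tsds)
  counts <- c(intra = sum(k == 2L), between = sum(k == 1L),
              extra = sum(k == 0L))
  list(counts = counts, fractions = counts / nrow(crps))
}

#' Permutation test for TSDS clustering in the coevolution network
#'
#' Observed statistic: the fraction of edges whose two endpoints are both
#' TSDSs.  Null: the TSDS labels are permuted uniformly over the network
#' nodes, preserving the number of labelled nodes and the edge structure.
#' `p = (1 + #\{perm >= obs\}) / (n_perm + 1)`.
#'
#' @param net a [residue_network()].
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list with `observed` (intra-TSDS edge fraction), `p_value`,
#'   `n_perm`.
#' @export
tsds_clustering_test <- function(net, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(net, "residue_network"))
  nodes <- as.integer(igraph::V(net$graph)$name)
  is_tsds <- igraph::V(net$graph)$tsds
  if (!any(is_tsds)) stop("no TSDS nodes in the network")
  ends <- igraph::as_edgelist(net$graph)
  ei <- match(ends[, 1L], as.character(nodes))
  ej <- match(ends[, 2L], as.character(nodes))
  frac_intra <- function(lab) mean(lab[ei] & lab[ej])
  obs <- frac_intra(is_tsds)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (frac_intra(sample(is_tsds)) >= obs) exceed <- exceed + 1L
  }
  list(observed = obs, p_value = (1 + exceed) / (n_perm + 1), n_perm = n_perm)
}

#' Sequence separation and block membership of CRPs
#'
#' @param crps data frame `i`, `j`.
#' @param blocks data frame `start`, `end` of disjoint column intervals
#'   (inclusive).  Pairs with an endpoint outside every block are counted
#'   as out-of-block.
#' @param min_separation pairs further apart than this many columns count
#'   as distant.
#' @return list with `frac_distant` (|i - j| > min_separation) and
#'   `frac_out_of_block` (endpoints in different blocks or unassigned).
#' @export
separation_and_blocks <- function(crps, blocks, min_separation = 5L) {
  if (!nrow(crps)) stop("no CRPs")
  stopifnot(all(blocks$start <= blocks$end))
  o <- order(blocks$start)
  if (any(blocks$start[o][-1L] <= blocks$end[o][-nrow(blocks)]))
    stop("blocks must be disjoint intervals")
  block_of <- function(x) {
    hit <- vapply(x, function(p) {
      w <- which(p >= blocks$start & p <= blocks$end)
      if (length(w)) w[[1L]] else NA_integer_
    }, integer(1))
    hit
  }
  bi <- block_of(crps$i); bj <- block_of(crps$j)
  out_of_block <- is.na(bi) | is.na(bj) | bi != bj
  list(frac_distant = mean(abs(crps$i - crps$j) > min_separation),
       frac_out_of_block = mean(out_of_block))
}

#' Heuristic block boundaries from alignment gap structure
#'
#' Splits the alignment into maximal runs of columns with gap fraction at
#' or below `gap_cut`; gappy columns separate blocks and belong to none.
#'
#' @param fam an [aligned_family].
#' @param gap_cut gap-fraction threshold opening a block boundary.
#' @return data frame `start`, `end`.
#' @export
default_blocks <- function(fam, gap_cut = 0.5) {
  good <- column_metadata(fam)$gap_frac <= gap_cut
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Motif similarity of TFs grouped by CRP residue combinations
#'
#' For a column pair (i, j), TFs are grouped by their ordered residue pair
#' at those columns (TFs gapped at either column are dropped).  Groups with
#' at least two members contribute their mean pairwise motif similarity,
#' weighted by group size over the eligible total; the pair score is the
#' weighted sum.  CRP and non-CRP pair score distributions are compared
#' with a Welch t-test.
#'
#' @param crps,non_crps data frames `i`, `j`.
#' @param fam an [aligned_family].
#' @param sims a [similarity_matrix()] over the family's TFs.
#' @return list with `crp_scores`, `non_crp_scores`, `t_test` (htest or
#'   NULL), `direction` (`"crp_higher"`/`"crp_lower"`/`"equal"`).
#' @export
crp_grouped_motif_similarity <- function(crps, non_crps, fam, sims) {
  stopifnot(inherits(sims, "motif_similarity_matrix"))
  if (!all(fam$tf_ids %in% sims$tf_ids))
    stop("every TF in the MSA needs a motif in the similarity matrix")
  v <- sims$values[fam$tf_ids, fam$tf_ids]
  score_pair <- function(i, j) {
    ri <- fam$seqs[, i]; rj <- fam$seqs[, j]
    ok <- ri != "-" & rj != "-"
    if (!any(ok)) return(NA_real_)
    grp <- split(which(ok), paste0(ri[ok], rj[ok]))
    grp <- grp[lengths(grp) >= 2L]
    if (!length(grp)) return(NA_real_)
    total <- sum(lengths(grp))
    sum(vapply(grp, function(idx) {
      sub <- v[idx, idx]
      (length(idx) / total) * mean(sub[upper.tri(sub)])
    }, numeric(1)))
  }
  score_set <- function(d) {
    if (!nrow(d)) return(numeric())
    s <- mapply(score_pair, d$i, d$j)
    s[is.finite(s)]
  }
  cs <- score_set(crps)
  ns <- score_set(non_crps)
  tt <- NULL
  direction <- "equal"
  if (length(cs) >= 2L && length(ns) >= 2L &&
      (sd(cs) > 0 || sd(ns) > 0)) {
    tt <- t.test(cs, ns)
    direction <- if (mean(cs) > mean(ns)) "crp_higher"
                 else if (mean(cs) < mean(ns)) "crp_lower" else "equal"
  } else if (length(cs) && length(ns)) {
    direction <- if (mean(cs) > mean(ns)) "crp_higher"
                 else if (mean(cs) < mean(ns)) "crp_lower" else "equal"
  }
  list(crp_scores = cs, non_crp_scores = ns, t_test = tt,
       direction = direction)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return BH step-up adjusted p-values.
#' @export
adjust_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Write a residue network as edge list and GraphML
#'
#' @param net a [residue_network()].
#' @param dir output directory.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(net$crps, file.path(dir, "network_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  igraph::write_graph(net$graph, file.path(dir, "network.graphml"),
                      format = "graphml")
  invisible(dir)
}
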