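## Internal constructor shared by generate_toy_complex() and load_complex().
new_structure_complex <- function(id, resolution, atoms) {
  stopifnot(all(c("chain", "resno", "resname", "elety", "x", "y", "z",
                  "type") %in% names(atoms)))
  structure(list(id = id, resolution = resolution, atoms = atoms),
            class = "structure_complex")
}

#' @export
print.structure_complex <- function(x, ...) {
  cat(sprintf("structure_complex %s (%.2f A): %d protein / %d DNA atoms\n",
              x$id, x$resolution, sum(x$atoms$type == "protein"),
              sum(x$atoms$type == "dna")))
  invisible(x)
}

## Parse "REMARK   2 RESOLUTION.  x.xx ANGSTROMS." from raw PDB lines.
parse_resolution <- function(lines) {
  r2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(r2)) return(NA_real_)
  v <- suppressWarnings(
    as.numeric(sub(".*RESOLUTION\\.\\s*([0-9]+\\.?[0-9]*).*", "\\1", r2)))
  v <- v[is.finite(v)]
  if (length(v)) v[[1L]] else NA_real_
}

#' Load a protein-DNA complex from a PDB file
#'
#' Parses coordinates with bio3d, keeps standard-residue ATOM records
#' (waters and heteroatoms excluded, highest-occupancy alternate
#' conformers only), types chains as DNA (residue names DA/DC/DG/DT/DU) or
#' protein, and enforces the resolution cutoff.
#'
#' @param path PDB file.
#' @param max_resolution reject complexes with resolution at or above this
#'   value (Angstroms).
#' @param require_resolution when `TRUE` (default) a file without a
#'   RESOLUTION remark is rejected.
#' @param id complex identifier (default: file name).
#' @return a `structure_complex`.
#' @export
load_complex <- function(path, max_resolution = 4.0,
                         require_resolution = TRUE, id = NULL) {
  lines <- readLines(path)
  res <- parse_resolution(lines)
  if (is.na(res)) {
    if (require_resolution)
      stop("rejected: no resolution record in ", path)
    res <- NA_real_
  } else if (res >= max_resolution) {
    stop(sprintf("rejected: resolution %.2f A >= cutoff %.2f A", res,
                 max_resolution))
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  a <- a[a$type == "ATOM" & !(a$resid %in% c("HOH", "WAT")), , drop = FALSE]
  if (!nrow(a)) stop("rejected: no standard ATOM records in ", path)
  ## highest-occupancy alternate conformer per atom site
  if (any(!is.na(a$alt) & a$alt != "")) {
    key <- paste(a$chain, a$resno, a$elety)
    o <- ifelse(is.na(a$o), 1, a$o)
    keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(idx) {
      idx[which.max(o[idx])]
    }), use.names = FALSE)
    a <- a[sort(keep), , drop = FALSE]
  }
  aa3 <- bio3d::aa.table$aa3
  atoms <- data.frame(chain = a$chain, resno = a$resno, resname = a$resid,
                      elety = a$elety, x = a$x, y = a$y, z = a$z)
  atoms$type <- ifelse(atoms$resname %in% DNA_RESNAMES, "dna",
                       ifelse(atoms$resname %in% aa3, "protein", "other"))
  atoms <- atoms[atoms$type != "other", , drop = FALSE]
  if (!any(atoms$type == "dna")) stop("rejected: no DNA chain in ", path)
  if (!any(atoms$type == "protein")) stop("rejected: no protein chain in ", path)
  new_structure_complex(id = id %||% basename(path), resolution = res,
                        atoms = atoms)
}

#' One-letter sequence of a protein chain
#'
#' @param complex a `structure_complex`.
#' @param chain_id chain identifier.
#' @return list with `seq` (one-letter string) and `resno` (residue numbers
#'   in chain order).
#' @export
chain_sequence <- function(complex, chain_id) {
  a <- complex$atoms
  a <- a[a$chain == chain_id & a$type == "protein", , drop = FALSE]
  if (!nrow(a)) stop("no protein residues in chain ", chain_id)
  resno <- unique(a$resno)
  resname <- a$resname[match(resno, a$resno)]
  one <- bio3d::aa321(resname)
  list(seq = paste(one, collapse = ""), resno = resno)
}

#' Map alignment columns onto structure residues
#'
#' The TF's domain sequence (gaps removed) is located in the chain sequence
#' by exact substring match or, failing that, by global alignment (BLOSUM62,
#' affine gaps); in the alignment case only columns matched to identical
#' residues are mapped.  Mapping is refused below 60% identity over the
#' domain.
#'
#' @param fam an [aligned_family].
#' @param tf_id the family row to map (default: the seed record).
#' @param chain a [chain_sequence()] result.
#' @param chain_id optional chain label stored in the output.
#' @param min_identity identity threshold for alignment-based mapping.
#' @return data frame `column`, `chain`, `resno` (one row per mapped
#'   column).
#' @export
map_columns_to_residues <- function(fam, chain, tf_id = NULL,
                                    chain_id = NA_character_,
                                    min_identity = 0.6) {
  tf_id <- tf_id %||% fam$seed_id
  row <- fam$seqs[tf_id, ]
  nongap_cols <- which(row != "-")
  dom <- paste(row[nongap_cols], collapse = "")
  hit <- regexpr(dom, chain$seq, fixed = TRUE)
  if (hit != -1L) {
    pos <- as.integer(hit) + seq_along(nongap_cols) - 1L
    return(data.frame(column = nongap_cols, chain = chain_id,
                      resno = chain$resno[pos]))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(dom), Biostrings::AAString(chain$seq),
    type = "global-local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  sub_start <- aln@subject@range@start
  pi <- 0L; si <- sub_start - 1L
  map_cols <- integer(); map_res <- integer(); n_match <- 0L
  for (k in seq_along(pa)) {
    if (pa[k] != "-") pi <- pi + 1L
    if (sa[k] != "-") si <- si + 1L
    if (pa[k] != "-" && sa[k] != "-" && pa[k] == sa[k]) {
      n_match <- n_match + 1L
      map_cols <- c(map_cols, nongap_cols[pi])
      map_res <- c(map_res, chain$resno[si])
    }
  }
  if (n_match / nchar(dom) < min_identity)
    stop(sprintf("mapping refused: identity %.1f%% below %.0f%%",
                 100 * n_match / nchar(dom), 100 * min_identity))
  data.frame(column = map_cols, chain = chain_id, resno = map_res)
}

## Minimum Euclidean distance between two atom coordinate sets (m x 3, n x 3).
min_atom_distance <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}

#' Residue-residue and residue-DNA minimum atomic distances
#'
#' Distances are the shortest Euclidean distance between any pair of atoms
#' of the two entities.  When an alignment column maps to residues in more
#' than one chain, the minimum over chains is taken.
#'
#' @param complex a `structure_complex`.
#' @param mapping data frame `column`, `chain`, `resno` from
#'   [map_columns_to_residues()] (possibly row-bound over several chains).
#' @return a `distance_map`: list with `pair` (symmetric matrix of
#'   column-pair distances, `NA` diagonal), `dna` (named vector of
#'   column-to-DNA distances) and `columns`.
#' @export
residue_distances <- function(complex, mapping) {
  if (!nrow(mapping)) stop("empty column-to-residue mapping")
  a <- complex$atoms
  dna_xyz <- as.matrix(a[a$type == "dna", c("x", "y", "z")])
  cols <- sort(unique(mapping$column))
  coord_sets <- lapply(cols, function(cl) {
    rows <- mapping[mapping$column == cl, , drop = FALSE]
    lapply(seq_len(nrow(rows)), function(r) {
      sel <- a$type == "protein" & a$resno == rows$resno[r]
      if (!is.na(rows$chain[r])) sel <- sel & a$chain == rows$chain[r]
      as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
    })
  })
  n <- length(cols)
  pair <- matrix(NA_real_, n, n, dimnames = list(cols, cols))
  dna <- setNames(rep(NA_real_, n), cols)
  for (i in seq_len(n)) {
    sets_i <- coord_sets[[i]]
    sets_i <- sets_i[vapply(sets_i, nrow, integer(1)) > 0]
    if (!length(sets_i)) next
    dna[i] <- min(vapply(sets_i, min_atom_distance, numeric(1), B = dna_xyz))
    if (i < n) {
      for (j in (i + 1L):n) {
        sets_j <- coord_sets[[j]]
        sets_j <- sets_j[vapply(sets_j, nrow, integer(1)) > 0]
        if (!length(sets_j)) next
        d <- min(vapply(sets_i, function(A)
          min(vapply(sets_j, min_atom_distance, numeric(1), A = A)),
          numeric(1)))
        pair[i, j] <- pair[j, i] <- d
      }
    }
  }
  structure(list(pair = pair, dna = dna, columns = cols),
            class = "distance_map")
}

#' Classify CRPs by distance to the DNA interface
#'
#' A CRP is an f-CRP ("far" CRP) when at least one endpoint lies more than
#' `cutoff` Angstroms from the nearest DNA atom, i.e. when the maximum of
#' the two endpoint interface distances strictly exceeds the cutoff.
#'
#' @param crps data frame `i`, `j`.
#' @param distances a [residue_distances()] result.
#' @param cutoff interface distance cutoff (Angstroms).
#' @param tsds optional TSDS column set used to label endpoints.
#' @return list with `table` (per evaluable CRP: endpoint distances,
#'   `fcrp` flag and endpoint TSDS labels), `fraction` of f-CRPs,
#'   `n_evaluable` and `n_unmapped`.
#' @export
classify_fcrps <- function(crps, distances, cutoff = 10.0, tsds = integer()) {
  di <- distances$dna[as.character(crps$i)]
  dj <- distances$dna[as.character(crps$j)]
  ok <- is.finite(di) & is.finite(dj)
  tab <- data.frame(i = crps$i[ok], j = crps$j[ok],
                    dist_i = unname(di[ok]), dist_j = unname(dj[ok]))
  tab$fcrp <- pmax(tab$dist_i, tab$dist_j) > cutoff
  tab$tsds_i <- tab$i %in% tsds
  tab$tsds_j <- tab$j %in% tsds
  list(table = tab,
       fraction = if (nrow(tab)) mean(tab$fcrp) else NA_real_,
       n_evaluable = nrow(tab), n_unmapped = sum(!ok))
}

#' Compare 3-D distances of CRPs versus non-CRPs
#'
#' Welch two-sample t-test on residue-pair minimum atomic distances.  When
#' both groups are constant the t-test degenerates; the p-value is then 1
#' for equal constants and 0 in the limit of separated constants.
#'
#' @param crps,non_crps data frames `i`, `j`.
#' @param distances a [residue_distances()] result.
#' @return list with `median_crp`, `median_non_crp`, `p_value`,
#'   `direction` (`"crp_closer"`/`"crp_farther"`/`"equal"`).
#' @export
compare_spatial <- function(crps, non_crps, distances) {
  get_d <- function(d) {
    v <- distances$pair[cbind(as.character(d$i), as.character(d$j))]
    v[is.finite(v)]
  }
  dc <- get_d(crps); dn <- get_d(non_crps)
  if (length(dc) < 2L || length(dn) < 2L)
    stop("need at least 2 mapped distances per group")
  p <- if (sd(dc) == 0 && sd(dn) == 0) {
    if (isTRUE(all.equal(mean(dc), mean(dn)))) 1 else 0
  } else {
    t.test(dc, dn)$p.value
  }
  list(median_crp = median(dc), median_non_crp = median(dn),
       p_value = p,
       direction = if (median(dc) < median(dn)) "crp_closer"
                   else if (median(dc) > median(dn)) "crp_farther" else "equal")
}

#' Write distance maps as TSV
#'
#' @param distances a [residue_distances()] result.
#' @param dir output directory.
#' @export
write_distances <- function(distances, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(matrix_pairs(distances$pair),
              file.path(dir, "residue_pair_distances.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(column = distances$columns,
                         dna_distance = unname(distances$dna)),
              file.path(dir, "interface_distances.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
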