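#' Aligned TF domain family
#'
#' Container for a multiple sequence alignment of DNA-binding-domain
#' sequences, one row per transcription factor, with a designated seed
#' (reference) record used for reporting positions in domain coordinates.
#'
#' @param seqs character vector of aligned sequences (equal lengths, gap
#'   character `-` or `.`), or a character matrix with one residue per cell.
#' @param tf_ids TF identifiers, one per sequence; defaults to names of
#'   `seqs` or `tf1..tfn`.
#' @param seed_id identifier of the seed/reference record; defaults to the
#'   first TF.
#' @return An object of class `aligned_family` with elements `seqs`
#'   (character matrix, rows named by TF), `tf_ids` and `seed_id`.
#' @export
aligned_family <- function(seqs, tf_ids = NULL, seed_id = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    tf_ids <- tf_ids %||% names(seqs)
    seqs <- toupper(as.character(seqs))
    if (length(unique(nchar(seqs))) != 1L)
      stop("all aligned sequences must have equal length")
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  tf_ids <- tf_ids %||% rownames(mat) %||% paste0("tf", seq_len(nrow(mat)))
  if (length(tf_ids) != nrow(mat)) stop("tf_ids length must match sequences")
  if (anyDuplicated(tf_ids)) stop("duplicate TF identifiers in alignment")
  mat[mat %in% GAP_CHARS] <- "-"
  rownames(mat) <- tf_ids
  seed_id <- seed_id %||% tf_ids[[1L]]
  if (!seed_id %in% tf_ids) stop("seed_id not among tf_ids: ", seed_id)
  structure(list(seqs = mat, tf_ids = tf_ids, seed_id = seed_id),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("aligned_family: %d TFs x %d columns (seed: %s)\n",
              nrow(x$seqs), ncol(x$seqs), x$seed_id))
  invisible(x)
}

#' @rdname aligned_family
#' @param x an `aligned_family`.
#' @export
n_seq <- function(x) nrow(x$seqs)

#' @rdname aligned_family
#' @export
n_col <- function(x) ncol(x$seqs)

#' Read / write an aligned FASTA family
#'
#' Thin wrappers around Biostrings FASTA I/O producing [aligned_family]
#' objects.
#'
#' @param path FASTA file path.
#' @param seed_id optional seed record id (default: first record).
#' @return `read_alignment` returns an [aligned_family].
#' @export
read_alignment <- function(path, seed_id = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  aligned_family(as.character(ss), tf_ids = names(ss), seed_id = seed_id)
}

#' @rdname read_alignment
#' @param fam an [aligned_family].
#' @export
write_alignment <- function(fam, path) {
  ss <- Biostrings::AAStringSet(apply(fam$seqs, 1L, paste, collapse = ""))
  names(ss) <- fam$tf_ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Per-column alignment metadata
#'
#' @param fam an [aligned_family].
#' @return data frame with one row per column: `column`, `gap_frac`,
#'   `invariant` (all non-gap residues identical, or no residues at all) and
#'   `all_gap`.
#' @export
column_metadata <- function(fam) {
  m <- fam$seqs
  gap <- m == "-"
  inv <- vapply(seq_len(ncol(m)), function(j) {
    r <- m[!gap[, j], j]
    length(unique(r)) <= 1L
  }, logical(1))
  data.frame(column = seq_len(ncol(m)),
             gap_frac = colMeans(gap),
             invariant = inv,
             all_gap = colMeans(gap) == 1)
}

#' Map alignment columns to seed-sequence coordinates
#'
#' @param fam an [aligned_family].
#' @return integer vector, one entry per alignment column: the position in
#'   the ungapped seed sequence, or `NA` where the seed row is gapped.
#' @export
seed_coordinates <- function(fam) {
  seed <- fam$seqs[fam$seed_id, ]
  pos <- cumsum(seed != "-")
  pos[seed == "-"] <- NA_integer_
  as.integer(pos)
}

## Integer encoding of the alignment over AA_ALPHABET; gaps/unknowns -> NA.
encode_family <- function(fam) {
  enc <- match(fam$seqs, AA_ALPHABET)
  dim(enc) <- dim(fam$seqs)
  rownames(enc) <- fam$tf_ids
  enc
}
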