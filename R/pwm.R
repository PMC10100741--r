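#' Position weight matrix
#'
#' A DNA binding motif as a 4 x w column-stochastic matrix over A, C, G, T,
#' tagged with the TF it belongs to.  Columns are motif positions.
#'
#' @param matrix numeric 4 x w matrix (rows A, C, G, T); columns are
#'   normalised to sum to one, so raw count matrices are accepted.
#' @param tf_id TF identifier.
#' @return an object of class `pwm`.
#' @export
pwm <- function(matrix, tf_id) {
  m <- as.matrix(matrix)
  if (nrow(m) != 4L) stop("a PWM must have 4 rows (A, C, G, T)")
  if (any(m < 0)) stop("PWM entries must be non-negative")
  cs <- colSums(m)
  if (any(cs <= 0)) stop("PWM columns must have positive mass")
  m <- sweep(m, 2L, cs, "/")
  rownames(m) <- DNA_BASES
  structure(list(tf_id = as.character(tf_id), matrix = m), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (width %d)\n", x$tf_id, ncol(x$matrix)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' @rdname pwm
#' @param x a `pwm`.
#' @export
pwm_width <- function(x) ncol(x$matrix)

#' Total information content of a PWM (bits)
#'
#' @param x a [pwm].
#' @return sum over positions of `2 - H(column)` in bits.
#' @export
pwm_ic <- function(x) {
  p <- x$matrix
  h <- -colSums(ifelse(p > 0, p * log2(p), 0))
  sum(2 - h)
}

#' Reverse complement of a PWM
#'
#' @param x a [pwm].
#' @return the motif read on the opposite strand: columns reversed, rows
#'   swapped A<->T and C<->G.
#' @export
pwm_revcomp <- function(x) {
  m <- x$matrix[c("T", "G", "C", "A"), rev(seq_len(ncol(x$matrix))), drop = FALSE]
  rownames(m) <- DNA_BASES
  pwm(m, x$tf_id)
}

## ---- PWM set helpers -------------------------------------------------------

#' Assemble a named PWM set
#'
#' @param ... [pwm] objects or a single list of them.
#' @return named list of `pwm` objects keyed by `tf_id`.
#' @export
pwm_set <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "pwm")) xs <- xs[[1L]]
  if (!all(vapply(xs, inherits, logical(1), "pwm")))
    stop("all elements must be pwm objects")
  ids <- vapply(xs, function(p) p$tf_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate tf_id in PWM set: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  setNames(xs, ids)
}

## ---- JASPAR-style PFM format -----------------------------------------------

#' Read and write JASPAR-style PFM files
#'
#' The JASPAR text layout: a `>id` header line followed by four rows
#' `A [ n n n ]` ... `T [ n n n ]`.  Counts are normalised to column
#' probabilities on read.
#'
#' @param path file path.
#' @return `read_jaspar` returns a [pwm_set].
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no JASPAR records in ", path)
  out <- lapply(seq_along(hdr), function(k) {
    from <- hdr[k]
    to <- if (k < length(hdr)) hdr[k + 1L] - 1L else length(lines)
    id <- sub("^>\\s*", "", lines[from])
    id <- strsplit(id, "\\s+")[[1L]][1L]
    block <- lines[(from + 1L):to]
    if (length(block) < 4L) stop("malformed JASPAR record: ", id)
    rows <- lapply(block[1:4], function(l) {
      nums <- regmatches(l, gregexpr("-?[0-9.eE+-]+", sub("^\\s*[ACGT]", "", l)))[[1L]]
      as.numeric(nums)
    })
    base <- toupper(substr(trimws(block[1:4]), 1L, 1L))
    m <- do.call(rbind, rows)
    rownames(m) <- base
    pwm(m[DNA_BASES, , drop = FALSE], id)
  })
  pwm_set(out)
}

#' @rdname read_jaspar
#' @param pwms a [pwm_set] (or single [pwm]).
#' @export
write_jaspar <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- pwm_set(list(pwms))
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$tf_id), con)
    for (b in DNA_BASES) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$matrix[b, ], digits = 6), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

## ---- MEME minimal motif format ---------------------------------------------

#' Read and write MEME minimal motif files
#'
#' @param path file path.
#' @return `read_meme` returns a [pwm_set].
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s", lines)
  if (!length(starts)) stop("no MOTIF records in ", path)
  out <- lapply(seq_along(starts), function(k) {
    id <- strsplit(trimws(lines[starts[k]]), "\\s+")[[1L]][2L]
    li <- grep("^letter-probability matrix", lines[starts[k]:length(lines)])[1L] +
      starts[k] - 1L
    w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[li]))
    rows <- lines[(li + 1L):(li + w)]
    m <- vapply(rows, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]),
                numeric(4))
    dimnames(m) <- NULL
    pwm(m, id)
  })
  pwm_set(out)
}

#' @rdname read_meme
#' @param pwms a [pwm_set] (or single [pwm]).
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- pwm_set(list(pwms))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    w <- ncol(p$matrix)
    writeLines(c(paste("MOTIF", p$tf_id),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", w)),
               con)
    for (j in seq_len(w))
      writeLines(paste0(" ", paste(sprintf("%.6f", p$matrix[, j]), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
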