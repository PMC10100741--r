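#' FoldX mutation-list export
#'
#' Formats point mutations as FoldX `individual_list` lines: wild-type
#' residue, chain, residue number, mutant residue, semicolon-terminated
#' (e.g. `RA49G;`).  When a structure is supplied the wild-type residue is
#' checked against it.
#'
#' @param mutations data frame with columns `chain`, `resno`, `wt`, `mut`
#'   (one-letter residue codes).
#' @param complex optional `structure_complex` for wild-type validation.
#' @return character vector of individual_list lines.
#' @export
foldx_mutation_list <- function(mutations, complex = NULL) {
  req <- c("chain", "resno", "wt", "mut")
  if (!all(req %in% names(mutations)))
    stop("mutations must have columns: ", paste(req, collapse = ", "))
  if (!is.null(complex)) {
    a <- complex$atoms[complex$atoms$type == "protein", , drop = FALSE]
    for (r in seq_len(nrow(mutations))) {
      sel <- a$chain == mutations$chain[r] & a$resno == mutations$resno[r]
      if (!any(sel))
        stop("no residue ", mutations$resno[r], " in chain ",
             mutations$chain[r])
      actual <- bio3d::aa321(a$resname[sel][1L])
      if (actual != mutations$wt[r])
        stop(sprintf("wild-type mismatch at %s%d: structure has %s, list has %s",
                     mutations$chain[r], mutations$resno[r], actual,
                     mutations$wt[r]))
    }
  }
  sprintf("%s%s%d%s;", mutations$wt, mutations$chain, mutations$resno,
          mutations$mut)
}

#' @rdname foldx_mutation_list
#' @param path output path for `write_foldx_individual_list`.
#' @export
write_foldx_individual_list <- function(mutations, path, complex = NULL) {
  writeLines(foldx_mutation_list(mutations, complex), path)
  invisible(path)
}

#' Parse replicate FoldX ddG output
#'
#' Reads a plain-text table (columns `mutant`, `replicate`, `ddg`, optional
#' `group`), averages the replicate interaction-energy changes per mutant,
#' flags mutants whose mean ddG exceeds `disrupt_cutoff` kcal/mol as
#' binding-disrupting, and, when groups are present, compares groups with
#' one-tailed Wilcoxon rank-sum tests.
#'
#' @param input path to a TSV/whitespace table, or a data frame.
#' @param n_runs expected replicates per mutant; a deviation warns.
#' @param disrupt_cutoff mean ddG (kcal/mol) above which a mutant is
#'   flagged disruptive.
#' @return list with `means` (per mutant: `mutant`, `n`, `mean_ddg`,
#'   `disruptive`, optional `group`) and `group_tests` (data frame of
#'   pairwise one-tailed Wilcoxon p-values, or NULL).
#' @export
parse_foldx_ddg <- function(input, n_runs = 5L, disrupt_cutoff = 2.0) {
  d <- if (is.data.frame(input)) input else
    read.table(input, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("mutant", "ddg") %in% names(d)))
    stop("ddG table needs columns 'mutant' and 'ddg'")
  sp <- split(d, d$mutant)
  means <- do.call(rbind, lapply(sp, function(x) {
    data.frame(mutant = x$mutant[[1L]], n = nrow(x),
               mean_ddg = mean(x$ddg),
               group = if ("group" %in% names(x)) x$group[[1L]] else NA)
  }))
  rownames(means) <- NULL
  if (any(means$n != n_runs))
    warning("replicate count differs from n_runs for: ",
            paste(means$mutant[means$n != n_runs], collapse = ", "))
  means$disruptive <- means$mean_ddg > disrupt_cutoff
  group_tests <- NULL
  if (!all(is.na(means$group)) && length(unique(means$group)) >= 2L) {
    gs <- split(means$mean_ddg, means$group)
    cmb <- combn(names(gs), 2)
    group_tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      a <- cmb[1, k]; b <- cmb[2, k]
      p <- suppressWarnings(
        wilcox.test(gs[[a]], gs[[b]], alternative = "greater")$p.value)
      data.frame(group_a = a, group_b = b, p_greater = p)
    }))
  }
  list(means = means, group_tests = group_tests)
}
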