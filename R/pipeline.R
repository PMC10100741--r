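#' Pipeline run configuration
#'
#' Houses the thresholds of the analysis chain with their documented
#' defaults: top covariation decile, two-method CRP support, the 0.1
#' specificity p-value cutoff, the five-member minimum subclass size, the
#' 10 Angstrom interface distance defining f-CRPs, the 4 Angstrom structure
#' resolution cutoff and the column gap filter.
#'
#' @param top_fraction candidate decile for covariation methods.
#' @param min_methods minimum methods supporting a CRP.
#' @param tsds_alpha permutation p-value cutoff calling a TSDS.
#' @param min_subclass minimum retained subclass size.
#' @param fcrp_cutoff DNA-interface distance (Angstroms) defining f-CRPs.
#' @param max_resolution structure resolution cutoff (Angstroms).
#' @param max_gap_frac column gap-fraction filter for covariation.
#' @param n_perm permutations for TSDS and network tests.
#' @param seed integer seed used by every stochastic stage.
#' @param min_separation sequence separation calling a pair distant.
#' @return a validated `run_config` list.
#' @export
run_config <- function(top_fraction = 0.10, min_methods = 2L,
                       tsds_alpha = 0.1, min_subclass = 5L,
                       fcrp_cutoff = 10.0, max_resolution = 4.0,
                       max_gap_frac = 0.25, n_perm = 1000L, seed = 1L,
                       min_separation = 5L) {
  stopifnot(top_fraction > 0, top_fraction <= 1,
            min_methods >= 1, tsds_alpha >= 0, tsds_alpha <= 1,
            min_subclass >= 1, fcrp_cutoff > 0, max_resolution > 0,
            max_gap_frac >= 0, max_gap_frac < 1, n_perm >= 99)
  structure(list(top_fraction = top_fraction,
                 min_methods = as.integer(min_methods),
                 tsds_alpha = tsds_alpha,
                 min_subclass = as.integer(min_subclass),
                 fcrp_cutoff = fcrp_cutoff,
                 max_resolution = max_resolution,
                 max_gap_frac = max_gap_frac,
                 n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 min_separation = as.integer(min_separation)),
            class = "run_config")
}

#' Run the full analysis chain on one TF family
#'
#' motif subclassing -> TSDS detection -> covariation/CRP calling ->
#' network analysis -> optional structure mapping, from a single
#' configuration.  Identical inputs, configuration and seed produce an
#' identical report.
#'
#' @param fam an [aligned_family].
#' @param pwms a [pwm_set] covering exactly the family's TFs.
#' @param config a [run_config()].
#' @param complexes optional named list of `structure_complex` objects; the
#'   seed record is mapped onto each and the first mappable complex is
#'   analysed.
#' @param blocks optional data frame `start`, `end` of residue blocks;
#'   defaults to [default_blocks()].
#' @param out_dir optional directory: stage outputs (TSV/JSON) are written
#'   eagerly so stages can be rerun from intermediates.
#' @return an `analysis_report` list; see the elements written to
#'   `report.json`.
#' @export
run_pipeline <- function(fam, pwms, config = run_config(),
                         complexes = NULL, blocks = NULL, out_dir = NULL) {
  stopifnot(inherits(fam, "aligned_family"), inherits(config, "run_config"))
  ids_msa <- fam$tf_ids
  ids_pwm <- names(pwms)
  if (!setequal(ids_msa, ids_pwm)) {
    off <- c(setdiff(ids_msa, ids_pwm), setdiff(ids_pwm, ids_msa))
    stop("TF id mismatch between MSA and motif set: ",
         paste(off, collapse = ", "))
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  report <- list(config = unclass(config), n_tf = n_seq(fam),
                 n_col = n_col(fam))

  ## 1. motif subclassing
  sims <- similarity_matrix(pwms[ids_msa])
  part <- cluster_subclasses(sims, min_size = config$min_subclass)
  report$subclassing <- list(k = part$k, sizes = part$sizes,
                             retained = part$retained)
  if (!is.null(out_dir)) write_subclasses(part, file.path(out_dir, "subclasses.tsv"))

  ## 2. TSDS detection (needs >= 2 retained subclasses)
  tsds_cols <- integer()
  if (length(part$retained) >= 2L) {
    tt <- tsds_permutation_test(fam, part, n_perm = config$n_perm,
                                seed = config$seed,
                                alpha = config$tsds_alpha)
    tsds_cols <- tt$column[tt$is_tsds]
    report$tsds <- list(n_tsds = length(tsds_cols), columns = tsds_cols)
    if (!is.null(out_dir)) write_tsds_table(tt, file.path(out_dir, "tsds.tsv"))
  } else {
    report$tsds <- list(note = "single retained subclass: no specificity stage",
                        n_tsds = 0L, columns = integer())
  }

  ## 3. covariation and CRPs
  coe <- run_coevolution(fam, max_gap_frac = config$max_gap_frac,
                         top_fraction = config$top_fraction,
                         min_methods = config$min_methods)
  report$coevolution <- list(
    n_columns = sum(coe$column_mask),
    n_crps = nrow(coe$crps),
    jaccard = coe$agreement[upper.tri(coe$agreement)])
  if (!is.null(out_dir))
    write_coevolution(coe, out_dir, seed_pos = seed_coordinates(fam))

  ## 4. network analysis
  if (nrow(coe$crps)) {
    net <- residue_network(coe$crps, tsds = tsds_cols,
                           nodes = which(coe$column_mask))
    comm <- detect_communities(net)
    cls <- classify_crps(coe$crps, tsds_cols)
    blk <- blocks %||% default_blocks(fam)
    sep <- separation_and_blocks(coe$crps, blk,
                                 min_separation = config$min_separation)
    report$network <- list(
      n_communities = comm$n_communities, modularity = comm$modularity,
      crp_fractions = as.list(cls$fractions), crp_counts = as.list(cls$counts),
      frac_distant = sep$frac_distant,
      frac_out_of_block = sep$frac_out_of_block)
    if (length(tsds_cols)) {
      ct <- tsds_clustering_test(net, n_perm = config$n_perm,
                                 seed = config$seed)
      report$network$tsds_clustering <- list(observed = ct$observed,
                                             p_value = ct$p_value)
    }
    if (!is.null(out_dir)) write_network(net, out_dir)
  } else {
    report$network <- list(note = "empty CRP set: network stage skipped")
  }

  ## 5. optional structure mapping
  if (!is.null(complexes) && length(complexes) && nrow(coe$crps)) {
    st <- NULL
    for (cx in complexes) {
      st <- tryCatch({
        ch <- chain_sequence(cx, cx$atoms$chain[cx$atoms$type == "protein"][1L])
        mp <- map_columns_to_residues(fam, ch,
                                      chain_id = cx$atoms$chain[cx$atoms$type == "protein"][1L])
        dm <- residue_distances(cx, mp)
        fc <- classify_fcrps(coe$crps, dm, cutoff = config$fcrp_cutoff,
                             tsds = tsds_cols)
        all_pairs <- matrix_pairs(dm$pair)
        crp_keys <- pair_key(coe$crps$i, coe$crps$j)
        non_crps <- all_pairs[!pair_key(all_pairs$i, all_pairs$j) %in% crp_keys,
                              c("i", "j")]
        sp <- if (sum(is.finite(dm$pair[cbind(as.character(coe$crps$i),
                                              as.character(coe$crps$j))])) >= 2 &&
                  nrow(non_crps) >= 2)
          compare_spatial(coe$crps, non_crps, dm) else NULL
        list(id = cx$id, fcrp_fraction = fc$fraction,
             n_evaluable = fc$n_evaluable, n_unmapped = fc$n_unmapped,
             spatial = sp)
      }, error = function(e) NULL)
      if (!is.null(st)) break
    }
    report$structure <- st %||% list(note = "no complex could be mapped")
  } else if (is.null(complexes)) {
    report$structure <- list(note = "no structures supplied: stage skipped")
  }

  if (!is.null(out_dir)) write_report(report, file.path(out_dir, "report.json"))
  out <- structure(report, class = "analysis_report")
  ## full stage objects for programmatic use; not part of the JSON report
  attr(out, "objects") <- list(similarity = sims, partition = part,
                               coevolution = coe)
  out
}

#' Serialise an analysis report as JSON
#'
#' @param report an `analysis_report` (any list).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Generate a synthetic family, run the pipeline and score recovery
#'
#' @param syn_config a [synthetic_config()].
#' @param config a [run_config()].
#' @param out_dir optional stage-output directory passed to
#'   [run_pipeline()].
#' @return list with `report` (the pipeline report), `tsds_recall`,
#'   `tsds_precision`, `pair_recall`, `pair_precision` and `subclass_ari`
#'   (NA where a quantity is undefined, e.g. single-subclass families).
#' @export
simulate_and_validate <- function(syn_config, config = run_config(),
                                  out_dir = NULL) {
  gen <- generate_family(syn_config)
  report <- run_pipeline(gen$family, gen$pwms, config, out_dir = out_dir)

  truth <- gen$truth
  called_tsds <- report$tsds$columns %||% integer()
  tsds_recall <- if (length(truth$true_tsds))
    mean(truth$true_tsds %in% called_tsds) else NA_real_
  tsds_precision <- if (length(called_tsds))
    mean(called_tsds %in% truth$true_tsds) else NA_real_

  objects <- attr(report, "objects")
  crp_df <- objects$coevolution$crps
  crps <- if (nrow(crp_df)) pair_key(crp_df$i, crp_df$j) else character()
  true_keys <- pair_key(truth$true_pairs[, 1], truth$true_pairs[, 2])
  pair_recall <- if (length(true_keys)) mean(true_keys %in% crps) else NA_real_
  pair_precision <- if (length(crps)) mean(crps %in% true_keys) else NA_real_

  ari <- if (syn_config$n_subclass >= 2L) {
    part_labels <- objects$partition$subclass_of
    mclust::adjustedRandIndex(part_labels[names(truth$subclass_of)],
                              truth$subclass_of)
  } else NA_real_

  list(report = report, tsds_recall = tsds_recall,
       tsds_precision = tsds_precision, pair_recall = pair_recall,
       pair_precision = pair_precision, subclass_ari = ari)
}
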