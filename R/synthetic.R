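#' Configuration for a synthetic TF family
#'
#' Describes a family of `n_tf` DNA-binding domains of aligned length
#' `n_col`, split into `n_subclass` motif subclasses.  Planted signal:
#' `tsds_columns` carry one subclass-specific residue per subclass;
#' `coevolving_pairs` are column pairs (i, j, coupling) where, with
#' probability `coupling`, the residue at j is a fixed bijective image of
#' the residue at i.  Each TF receives a PWM drawn from its subclass
#' template under per-column Dirichlet noise.
#'
#' @param n_tf number of family members.
#' @param n_col alignment length.
#' @param n_subclass number of motif subclasses (>= 1, <= n_tf).
#' @param tsds_columns integer column indices planted as subclass
#'   determining sites.
#' @param coevolving_pairs list of numeric triples `c(i, j, coupling)` with
#'   coupling in `[0, 1]`.
#' @param background_alphabet_size residues drawn uniformly from the first
#'   this-many letters of the 20-letter alphabet (<= 20).
#' @param pwm_width motif width.
#' @param pwm_noise Dirichlet concentration: each TF's PWM column is drawn
#'   from Dirichlet(pwm_noise * template + 1).  Larger = tighter around the
#'   subclass template.
#' @param tsds_noise per-cell probability that a planted TSDS residue is
#'   replaced by a random background residue.
#' @param seed integer seed; all generation is reproducible from it.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_tf, n_col, n_subclass = 1L,
                             tsds_columns = integer(),
                             coevolving_pairs = list(),
                             background_alphabet_size = 20L,
                             pwm_width = 10L, pwm_noise = 50,
                             tsds_noise = 0.05, seed = 1L) {
  stopifnot(n_tf >= 1, n_col >= 1, pwm_width >= 4, pwm_noise > 0,
            background_alphabet_size >= 2, background_alphabet_size <= 20,
            tsds_noise >= 0, tsds_noise <= 1)
  if (n_subclass < 1) stop("configuration error: n_subclass must be >= 1")
  if (n_subclass > n_tf) stop("configuration error: n_subclass > n_tf")
  tsds_columns <- as.integer(tsds_columns)
  if (any(tsds_columns < 1 | tsds_columns > n_col))
    stop("configuration error: tsds_columns outside [1, n_col]")
  pairs <- lapply(coevolving_pairs, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L) stop("each coevolving pair must be c(i, j, coupling)")
    if (p[3] < 0 || p[3] > 1) stop("configuration error: coupling outside [0, 1]")
    if (any(p[1:2] < 1 | p[1:2] > n_col) || p[1] == p[2])
      stop("configuration error: invalid pair columns")
    p
  })
  pair_cols <- unlist(lapply(pairs, function(p) p[1:2]))
  planted <- c(tsds_columns, pair_cols)
  if (anyDuplicated(planted))
    stop("configuration error: tsds_columns and coevolving-pair columns overlap")
  structure(list(n_tf = as.integer(n_tf), n_col = as.integer(n_col),
                 n_subclass = as.integer(n_subclass),
                 tsds_columns = tsds_columns, coevolving_pairs = pairs,
                 background_alphabet_size = as.integer(background_alphabet_size),
                 pwm_width = as.integer(pwm_width), pwm_noise = pwm_noise,
                 tsds_noise = tsds_noise, seed = as.integer(seed)),
            class = "synthetic_config")
}

## One Dirichlet draw via gamma variates.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic TF family with planted ground truth
#'
#' @param config a [synthetic_config].
#' @return list with elements
#'   `family` ([aligned_family]), `pwms` ([pwm_set]) and `truth` (list with
#'   `subclass_of`, `true_tsds`, `true_pairs` (2-column matrix),
#'   `pwm_templates`, `tsds_residues`).
#' @export
generate_family <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_tf
  L <- config$n_col
  S <- config$n_subclass
  alph <- AA_ALPHABET[seq_len(config$background_alphabet_size)]

  tf_ids <- sprintf("tf%03d", seq_len(n))
  subclass_of <- setNames(rep_len(seq_len(S), n), tf_ids)

  msa <- matrix("", n, L, dimnames = list(tf_ids, NULL))
  for (j in seq_len(L)) msa[, j] <- sample(alph, n, replace = TRUE)

  ## subclass-determining columns: one residue per subclass (+ noise)
  tsds_residues <- list()
  for (j in config$tsds_columns) {
    res <- sample(AA_ALPHABET, S)
    tsds_residues[[as.character(j)]] <- res
    col <- res[subclass_of]
    noisy <- runif(n) < config$tsds_noise
    col[noisy] <- sample(alph, sum(noisy), replace = TRUE)
    msa[, j] <- col
  }

  ## covarying pairs: j is the bijective image of i with prob = coupling
  for (p in config$coevolving_pairs) {
    i <- p[1]; j <- p[2]; rho <- p[3]
    bij <- setNames(sample(alph), alph)
    coupled <- runif(n) < rho
    xj <- sample(alph, n, replace = TRUE)
    xj[coupled] <- bij[msa[coupled, i]]
    msa[, j] <- xj
  }

  fam <- aligned_family(msa, tf_ids = tf_ids, seed_id = tf_ids[[1L]])

  ## subclass PWM templates: sharp random consensus per column.  Subclasses
  ## model distinct binding specificities, so templates are rejection-sampled
  ## to keep the best-offset similarity between any two below 0.5.
  draw_template <- function(s) {
    m <- matrix(0.05, 4, config$pwm_width, dimnames = list(DNA_BASES, NULL))
    cons <- sample.int(4, config$pwm_width, replace = TRUE)
    for (j in seq_len(config$pwm_width)) m[cons[j], j] <- 0.85
    pwm(m, sprintf("template%02d", s))
  }
  templates <- list()
  for (s in seq_len(S)) {
    best <- NULL
    best_sim <- Inf
    for (try in seq_len(200L)) {
      cand <- draw_template(s)
      worst <- if (length(templates)) {
        max(vapply(templates, motif_similarity, numeric(1), b = cand))
      } else -Inf
      if (worst < best_sim) {
        best_sim <- worst
        best <- cand
      }
      if (worst <= 0.5) break
    }
    templates[[s]] <- best
  }

  pwms <- pwm_set(lapply(tf_ids, function(id) {
    tm <- templates[[subclass_of[[id]]]]$matrix
    m <- vapply(seq_len(ncol(tm)),
                function(j) rdirichlet1(config$pwm_noise * tm[, j] + 1),
                numeric(4))
    pwm(m, id)
  }))

  true_pairs <- if (length(config$coevolving_pairs)) {
    t(vapply(config$coevolving_pairs, function(p) as.integer(p[1:2]), integer(2)))
  } else {
    matrix(integer(), 0, 2)
  }
  colnames(true_pairs) <- c("i", "j")

  truth <- list(subclass_of = subclass_of,
                true_tsds = config$tsds_columns,
                true_pairs = true_pairs,
                pwm_templates = templates,
                tsds_residues = tsds_residues)
  list(family = fam, pwms = pwms, truth = truth)
}

#' Write the planted ground truth of a synthetic family as JSON
#'
#' @param truth the `truth` element returned by [generate_family()].
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(subclass_of = as.list(truth$subclass_of),
              true_tsds = truth$true_tsds,
              true_pairs = apply(truth$true_pairs, 1L, function(r)
                list(i = r[[1]], j = r[[2]])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- toy protein-DNA complexes ---------------------------------------------

#' Build a toy protein-DNA complex
#'
#' Constructs an in-memory structure from explicit atom placements, for
#' exercising distance computations with known geometry.  DNA residues are
#' recognised by the names DA/DC/DG/DT/DU; everything else is treated as
#' protein.
#'
#' @param atoms data frame with columns `chain`, `resno`, `resname`,
#'   `elety`, `x`, `y`, `z` (one row per atom).
#' @param id complex identifier.
#' @param resolution nominal resolution in Angstroms recorded in the header.
#' @return a `structure_complex` (see [load_complex()]).
#' @export
generate_toy_complex <- function(atoms, id = "TOY", resolution = 2.0) {
  req <- c("chain", "resno", "resname", "elety", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  atoms <- as.data.frame(atoms)
  if (!nrow(atoms)) stop("no atoms supplied")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("all atoms need finite 3-D coordinates")
  atoms$type <- ifelse(atoms$resname %in% DNA_RESNAMES, "dna", "protein")
  if (!any(atoms$type == "dna"))
    stop("no DNA chain: a complex must contain both molecule types")
  if (!any(atoms$type == "protein"))
    stop("no protein chain: a complex must contain both molecule types")
  new_structure_complex(id = id, resolution = resolution, atoms = atoms)
}

#' Write a structure complex as a PDB file
#'
#' Emits a `REMARK   2 RESOLUTION` header followed by fixed-width ATOM
#' records, re-parsable by [load_complex()].
#'
#' @param complex a `structure_complex`.
#' @param path output path.
#' @export
write_complex_pdb <- function(complex, path) {
  a <- complex$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  body <- readLines(path)
  res <- if (is.finite(complex$resolution)) {
    sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", complex$resolution)
  } else {
    "REMARK   2 RESOLUTION. NOT APPLICABLE."
  }
  writeLines(c(sprintf("HEADER    SYNTHETIC COMPLEX %s", complex$id),
               "REMARK   2", res, body), path)
  invisible(path)
}
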