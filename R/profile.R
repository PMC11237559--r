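#' Build a position-specific scoring profile from an aligned set of proteins
#'
#' Columns with more than 50% gaps are dropped; remaining columns receive
#' log-odds emissions in bits:
#' `e[j, a] = log2((c[j, a] + pseudocount * bg[a]) / (n[j] + pseudocount) / bg[a])`
#' where `c[j, a]` counts residue `a` in column `j`, `n[j]` is the column's
#' non-gap count and `bg` the background frequencies. The conserved-cysteine
#' anchor column is located by mapping `cys_pos` (an ungapped position in the
#' reference row) through the alignment.
#'
#' @param msa named character vector of aligned sequences (equal lengths,
#'   `-` for gaps), or a character matrix of single residues.
#' @param pseudocount pseudocount weight (default 1).
#' @param background residue background frequencies (default uniform).
#' @param cys_ref name or index of the reference row carrying the conserved
#'   cysteine (default first row).
#' @param cys_pos 1-based ungapped position of the conserved cysteine in the
#'   reference row (default 110).
#' @param gap_open,gap_extend affine gap penalties in bits for alignment to
#'   the profile (defaults 4 and 0.25).
#' @param name profile name.
#' @return object of class `soxy_profile`: list with `name`, `emissions`
#'   (m x 20, bits), `background`, `gap_open`, `gap_extend`, `cys_anchor`
#'   (1-based retained-column index, NA if the anchor column was dropped),
#'   `m`.
#' @export
build_profile <- function(msa, pseudocount = 1, background = NULL,
                          cys_ref = 1L, cys_pos = 110L,
                          gap_open = 4, gap_extend = 0.25, name = "profile") {
  if (is.character(msa) && !is.matrix(msa)) {
    if (length(msa) == 0) stop("invalid-input: empty alignment")
    lens <- nchar(msa)
    if (length(unique(lens)) != 1)
      stop("invalid-input: aligned sequences must have equal lengths")
    mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
    rownames(mat) <- names(msa)
  } else {
    mat <- msa
  }
  if (is.null(mat) || nrow(mat) < 2)
    stop("invalid-input: alignment needs at least 2 rows")
  if (is.null(background)) background <- uniform_background()

  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= 0.5
  n_rows <- nrow(mat)

  # anchor bookkeeping before dropping columns
  ref_row <- mat[cys_ref, , drop = TRUE]
  ref_pos <- cumsum(ref_row != "-")
  anchor_full <- which(ref_pos == cys_pos & ref_row != "-")[1]

  kept_idx <- which(keep)
  m <- length(kept_idx)
  if (m == 0) stop("invalid-input: no columns retained")
  emis <- matrix(0, m, 20, dimnames = list(NULL, AA_ALPHABET))
  for (jj in seq_len(m)) {
    col <- mat[, kept_idx[jj]]
    col <- col[col != "-"]
    n_j <- length(col)
    cnt <- table(factor(col, levels = AA_ALPHABET))
    p <- (as.numeric(cnt) + pseudocount * background) /
      (n_j + pseudocount)
    emis[jj, ] <- unname(log2(p / background))
  }
  cys_anchor <- if (!is.na(anchor_full) && keep[anchor_full])
    match(anchor_full, kept_idx) else NA_integer_
  structure(list(name = name, emissions = emis, background = background,
                 gap_open = gap_open, gap_extend = gap_extend,
                 cys_anchor = cys_anchor, m = m),
            class = "soxy_profile")
}

# emissions padded with neutral 21st column for unknown residues
profile_emissions_padded <- function(profile) {
  cbind(profile$emissions, 0)
}

#' Globally align a protein to a profile
#'
#' Optimal global alignment of the sequence to the profile's match columns
#' under affine gap penalties (dynamic programming; gap run of length k
#' costs `open + (k - 1) * extend`). Insertions relative to the profile
#' carry no emission score.
#'
#' @param profile a `soxy_profile`.
#' @param seq protein string (length >= 1).
#' @return object of class `soxy_trace`: list with `score` (bits), `trace`
#'   (integer of length m: 1-based residue index matched to each column, NA
#'   for deletion), `seq`, `profile_name`, `m`.
#' @export
align_to_profile <- function(profile, seq) {
  stopifnot(inherits(profile, "soxy_profile"), nchar(seq) >= 1)
  res <- pssm_align_global_cpp(profile_emissions_padded(profile),
                               encode_seq(seq),
                               profile$gap_open, profile$gap_extend)
  trace <- res$trace
  trace[trace == 0L] <- NA_integer_
  structure(list(score = res$score, trace = trace, seq = seq,
                 profile_name = profile$name, m = profile$m),
            class = "soxy_trace")
}

# Score-only alignment of many sequences (used by search and calibration).
profile_scores <- function(profile, seqs) {
  codes <- lapply(seqs, encode_seq)
  pssm_score_batch_cpp(profile_emissions_padded(profile), codes,
                       profile$gap_open, profile$gap_extend)
}

#' Fit a Gumbel distribution to decoy scores by the method of moments
#'
#' `lambda = pi / (sd * sqrt(6))`, `mu = mean - gamma / lambda` with
#' Euler-Mascheroni `gamma`.
#' @param scores numeric decoy scores.
#' @return list `mu`, `lambda`.
#' @export
fit_gumbel <- function(scores) {
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0)
    stop("degenerate-calibration: zero score variance")
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.57721566490153286 / lambda
  list(mu = mu, lambda = lambda)
}

#' Calibrate a profile's score distribution on decoys
#'
#' Scores at least `n_decoys` decoy sequences against the profile and fits a
#' Gumbel location/scale by the method of moments. Decoys are either
#' Fisher-Yates shuffles of supplied sequences (`decoys` a character vector)
#' or, when `decoys` is numeric, i.i.d. draws from the profile background at
#' the given lengths (recycled as needed).
#'
#' @param profile a `soxy_profile`.
#' @param decoys character vector of sequences to shuffle, or numeric vector
#'   of decoy lengths.
#' @param n_decoys number of decoys (>= 1000).
#' @param seed integer seed.
#' @return object of class `soxy_calibration`: `mu`, `lambda`, `n_decoys`,
#'   `db_size_policy`.
#' @export
calibrate <- function(profile, decoys, n_decoys = 1000, seed = 1) {
  if (n_decoys < 1000)
    stop("invalid-parameter: calibration requires >= 1000 decoys")
  seqs <- with_seed(seed, {
    if (is.numeric(decoys)) {
      lens <- sample(rep_len(as.integer(decoys), n_decoys))
      vapply(lens, function(L) random_protein(L, profile$background), "")
    } else {
      base <- rep_len(decoys, n_decoys)
      vapply(base, function(s) paste(sample(strsplit(s, "")[[1]]),
                                     collapse = ""), "",
             USE.NAMES = FALSE)
    }
  })
  fit <- fit_gumbel(profile_scores(profile, seqs))
  structure(list(mu = fit$mu, lambda = fit$lambda, n_decoys = n_decoys,
                 db_size_policy = "n_proteins"),
            class = "soxy_calibration")
}

#' E-value of a bit score under a Gumbel calibration
#'
#' `e = db_size * (1 - exp(-exp(-lambda * (score - mu))))`: the expected
#' number of decoys in a database of `db_size` scoring at least `score`.
#' Monotone non-increasing in score and linear in `db_size` for small
#' tail probabilities.
#'
#' @param score bit score (vectorised).
#' @param cal a `soxy_calibration`.
#' @param db_size number of sequences searched (>= 1).
#' @return e-values (same length as `score`).
#' @export
evalue <- function(score, cal, db_size) {
  stopifnot(db_size >= 1)
  z <- exp(-cal$lambda * (score - cal$mu))
  db_size * -expm1(-z)
}

#' Default search configuration
#'
#' Thresholds mirror the study defaults: homolog e-value cutoff 1e-5;
#' sulfur-panel cutoffs 1e-30, relaxed to 1e-6 for panel entries shorter
#' than 120 aa; quality filter keeps sequences of length >= 140 containing
#' the "GGC" motif.
#' @return list of thresholds.
#' @export
search_config <- function() {
  list(soxy_evalue_cutoff = 1e-5,
       sulfur_evalue_cutoff = 1e-30,
       sulfur_short_evalue_cutoff = 1e-6,
       short_length_threshold = 120L,
       min_length = 140L,
       required_motif = "GGC")
}

#' Search a proteome with a calibrated profile
#'
#' Scores every protein, converts to e-values with `db_size` = number of
#' proteins searched, and returns one best-scoring hit per protein passing
#' the homolog e-value cutoff, ordered by ascending e-value with ties broken
#' by protein id. Full alignment traces for the hits are attached as the
#' `"traces"` attribute.
#'
#' @param profile a `soxy_profile`.
#' @param proteome named character vector of protein sequences.
#' @param cal a `soxy_calibration` for the profile.
#' @param cfg list of thresholds (see [search_config()]).
#' @param genome_id genome label recorded on each hit.
#' @return data.frame with columns `protein_id`, `genome_id`, `length`,
#'   `score_bits`, `evalue`, `env_start`, `env_end` (0-based half-open
#'   envelope of profile-matched residues), `sequence`.
#' @export
search_proteome <- function(profile, proteome, cal, cfg = search_config(),
                            genome_id = NA_character_) {
  empty <- data.frame(protein_id = character(), genome_id = character(),
                      length = integer(), score_bits = numeric(),
                      evalue = numeric(), env_start = integer(),
                      env_end = integer(), sequence = character(),
                      stringsAsFactors = FALSE)
  if (length(proteome) == 0) {
    attr(empty, "traces") <- list()
    return(empty)
  }
  scores <- profile_scores(profile, proteome)
  ev <- evalue(scores, cal, db_size = length(proteome))
  pass <- which(ev <= cfg$soxy_evalue_cutoff)
  if (length(pass) == 0) {
    attr(empty, "traces") <- list()
    return(empty)
  }
  ids <- names(proteome)[pass]
  traces <- lapply(proteome[pass], function(s) align_to_profile(profile, s))
  env <- vapply(traces, function(tr) {
    r <- tr$trace[!is.na(tr$trace)]
    if (length(r) == 0) c(0L, 0L) else c(min(r) - 1L, max(r))
  }, integer(2))
  hits <- data.frame(protein_id = ids, genome_id = genome_id,
                     length = nchar(proteome[pass]),
                     score_bits = scores[pass], evalue = ev[pass],
                     env_start = env[1, ], env_end = env[2, ],
                     sequence = unname(proteome[pass]),
                     stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(hits$evalue, hits$protein_id, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "traces") <- stats::setNames(traces[ord], hits$protein_id)
  hits
}

#' Apply the quality filter to homolog hits
#'
#' Retains hits whose full sequence is at least `min_length` residues
#' (boundary length exactly 140 is retained), contains the required motif
#' ("GGC") anywhere as a substring, and whose e-value passes the homolog
#' cutoff.
#'
#' @param hits hit data.frame from [search_proteome()].
#' @param cfg threshold list.
#' @return filtered hit data.frame (traces attribute subset accordingly).
#' @export
quality_filter <- function(hits, cfg = search_config()) {
  keep <- hits$length >= cfg$min_length &
    grepl(cfg$required_motif, hits$sequence, fixed = TRUE) &
    hits$evalue <= cfg$soxy_evalue_cutoff
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  tr <- attr(hits, "traces")
  if (!is.null(tr)) attr(out, "traces") <- tr[out$protein_id]
  out
}

#' Collapse identical protein sequences
#'
#' Exact full-sequence string equality collapses to one representative (the
#' lexicographically smallest protein id). Per-genome copy counting uses the
#' pre-deduplication hits; deduplication serves cross-cohort tree building.
#'
#' @param hits hit data.frame.
#' @return list with `unique` (representative hits, original ordering) and
#'   `multiplicity` (data.frame `representative`, `n`, `members`).
#' @export
deduplicate <- function(hits) {
  if (nrow(hits) == 0)
    return(list(unique = hits,
                multiplicity = data.frame(representative = character(),
                                          n = integer(),
                                          members = character())))
  grp <- split(hits$protein_id, hits$sequence)
  reps <- vapply(grp, function(ids) sort(ids)[1], "")
  mult <- data.frame(
    representative = unname(reps),
    n = vapply(grp, length, 0L),
    members = vapply(grp, function(ids) paste(sort(ids), collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL)
  keep <- hits$protein_id %in% reps
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  tr <- attr(hits, "traces")
  if (!is.null(tr)) attr(out, "traces") <- tr[out$protein_id]
  mult <- mult[order(mult$representative, method = "radix"), , drop = FALSE]
  rownames(mult) <- NULL
  list(unique = out, multiplicity = mult)
}

#' Local alignment of two proteins (Smith-Waterman)
#'
#' Optimal local alignment under BLOSUM62 with affine gaps (defaults: open
#' 11, extend 1; a gap run of length k costs `open + (k - 1) * extend`).
#' If a calibration is supplied the score is converted to an e-value for a
#' database of `db_size` targets.
#'
#' @param query,target protein strings.
#' @param gap_open,gap_extend gap penalties.
#' @param cal optional `soxy_calibration` fitted on decoy local scores.
#' @param db_size database size for the e-value (default 1).
#' @return list `score`, `evalue` (NA without calibration), `query_bounds`,
#'   `target_bounds` (0-based half-open).
#' @export
local_search <- function(query, target, gap_open = 11, gap_extend = 1,
                         cal = NULL, db_size = 1) {
  stopifnot(nchar(query) >= 1, nchar(target) >= 1)
  res <- sw_align_cpp(encode_seq(query), encode_seq(target),
                      blosum62_matrix(), gap_open, gap_extend)
  ev <- if (is.null(cal)) NA_real_ else evalue(res$score, cal, db_size)
  list(score = res$score, evalue = ev,
       query_bounds = c(res$a_start - 1L, res$a_end),
       target_bounds = c(res$b_start - 1L, res$b_end))
}

# Batch local scores of one query against many targets.
local_scores <- function(query, targets, gap_open = 11, gap_extend = 1) {
  sw_score_batch_cpp(encode_seq(query), lapply(targets, encode_seq),
                     blosum62_matrix(), gap_open, gap_extend)
}

#' Calibrate local-alignment scores for a query against shuffled decoys
#'
#' @param query protein string.
#' @param decoys character vector of sequences to shuffle into decoys.
#' @param n_decoys number of decoys (>= 1000).
#' @param seed integer seed.
#' @inheritParams local_search
#' @return a `soxy_calibration`.
#' @export
calibrate_local <- function(query, decoys, n_decoys = 1000, seed = 1,
                            gap_open = 11, gap_extend = 1) {
  if (n_decoys < 1000)
    stop("invalid-parameter: calibration requires >= 1000 decoys")
  seqs <- with_seed(seed, {
    base <- rep_len(decoys, n_decoys)
    vapply(base, function(s) paste(sample(strsplit(s, "")[[1]]),
                                   collapse = ""), "", USE.NAMES = FALSE)
  })
  fit <- fit_gumbel(local_scores(query, seqs, gap_open, gap_extend))
  structure(list(mu = fit$mu, lambda = fit$lambda, n_decoys = n_decoys,
                 db_size_policy = "n_proteins"),
            class = "soxy_calibration")
}

#' Serialize a profile to versioned JSON
#' @param profile a `soxy_profile`.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  obj <- list(format = "soxyprof-profile", version = 1L,
              name = profile$name,
              alphabet = paste(AA_ALPHABET, collapse = ""),
              emissions = unclass(profile$emissions),
              background = as.numeric(profile$background),
              gap_open = profile$gap_open, gap_extend = profile$gap_extend,
              cys_anchor = profile$cys_anchor, m = profile$m)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a profile written by [write_profile()]
#' @param path JSON file.
#' @return a `soxy_profile`.
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$format, "soxyprof-profile"))
  emis <- as.matrix(obj$emissions)
  dimnames(emis) <- list(NULL, AA_ALPHABET)
  structure(list(name = obj$name, emissions = emis,
                 background = stats::setNames(obj$background, AA_ALPHABET),
                 gap_open = obj$gap_open, gap_extend = obj$gap_extend,
                 cys_anchor = as.integer(obj$cys_anchor), m = as.integer(obj$m)),
            class = "soxy_profile")
}
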