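#' Summarise a genome's soxY repertoire
#'
#' Counts distinct soxY loci per signature from the quality-filtered,
#' pre-deduplication hits of one genome (deduplication serves cross-cohort
#' tree building, not copy counting). Classified and unclassified copies are
#' reported separately; fusions are counted from the fusion flags.
#'
#' @param hits filtered hit data.frame (one genome's rows are selected by
#'   `genome_id`).
#' @param calls classification data.frame from [classify_hits()] covering
#'   every hit.
#' @param genome_id genome to summarise.
#' @param signatures signature names defining the count columns.
#' @return one-row data.frame: `genome_id`, `soxy_total`, one `n_<sig>`
#'   column per signature, `n_unclassified`, `n_fused`.
#' @export
soxy_repertoire <- function(hits, calls, genome_id,
                            signatures = default_signature_table()$name) {
  h <- hits[hits$genome_id == genome_id, , drop = FALSE]
  missing <- setdiff(h$protein_id, calls$protein_id)
  if (length(missing) > 0)
    stop("incomplete-input: no signature call for ",
         paste(missing, collapse = ", "))
  cc <- calls[match(h$protein_id, calls$protein_id), , drop = FALSE]
  counts <- vapply(signatures, function(s) sum(cc$signature == s), 0L)
  out <- data.frame(genome_id = genome_id,
                    soxy_total = nrow(h),
                    stringsAsFactors = FALSE)
  for (s in signatures) out[[paste0("n_", s)]] <- counts[[s]]
  out$n_unclassified <- sum(cc$signature == "unclassified")
  out$n_fused <- sum(cc$fused)
  out
}

#' E-value cutoff dispatch for a sulfur-panel entry
#'
#' Panel entries shorter than the short-protein threshold (120 aa) use the
#' relaxed cutoff (1e-6); all others use the strict cutoff (1e-30).
#'
#' @param entry_length panel protein length in residues.
#' @param cfg threshold list (see [search_config()]).
#' @return numeric cutoff.
#' @export
presence_cutoff <- function(entry_length, cfg = search_config()) {
  ifelse(entry_length < cfg$short_length_threshold,
         cfg$sulfur_short_evalue_cutoff, cfg$sulfur_evalue_cutoff)
}

#' Calibrate local-search e-values for every panel entry
#'
#' Fits one Gumbel per panel protein on Smith-Waterman scores against
#' shuffled decoys, reused across genomes.
#'
#' @param panel sulfur panel from [make_sulfur_panel()].
#' @param decoys sequences to shuffle into decoys.
#' @param n_decoys decoys per entry (>= 1000).
#' @param seed integer seed.
#' @return named list of `soxy_calibration` per panel entry.
#' @export
calibrate_panel <- function(panel, decoys, n_decoys = 1000, seed = 1) {
  cals <- lapply(seq_len(nrow(panel)), function(i) {
    calibrate_local(panel$sequence[i], decoys, n_decoys,
                    seed = child_seed(seed, i))
  })
  stats::setNames(cals, panel$name)
}

#' Sulfur-gene presence/absence for one proteome
#'
#' Each panel gene is called present iff its best local-search e-value over
#' the proteome passes the length-dispatched cutoff (strict 1e-30, relaxed
#' 1e-6 for panel entries under 120 aa).
#'
#' @param proteome named character vector of proteins.
#' @param panel sulfur panel.
#' @param cals calibrations from [calibrate_panel()].
#' @param cfg threshold list.
#' @param genome_id genome label.
#' @return one-row data.frame: `genome_id`, then per gene `<name>` (logical
#'   presence) and `<name>_evalue` (best e-value).
#' @export
sulfur_presence <- function(proteome, panel, cals, cfg = search_config(),
                            genome_id = NA_character_) {
  if (nrow(panel) == 0) stop("invalid-input: empty panel")
  out <- data.frame(genome_id = genome_id, stringsAsFactors = FALSE)
  db <- length(proteome)
  for (i in seq_len(nrow(panel))) {
    nm <- panel$name[i]
    if (db == 0) {
      out[[nm]] <- FALSE
      out[[paste0(nm, "_evalue")]] <- Inf
      next
    }
    scores <- local_scores(panel$sequence[i], proteome)
    ev <- evalue(max(scores), cals[[nm]], db_size = db)
    out[[nm]] <- ev <= presence_cutoff(panel$length[i], cfg)
    out[[paste0(nm, "_evalue")]] <- ev
  }
  out
}

#' Cohort matrix of repertoires and sulfur-gene presence
#'
#' One row per genome: the soxY copy-number column first, then per-signature
#' counts, then the presence flags, ordered by genome id.
#'
#' @param repertoires row-bound output of [soxy_repertoire()].
#' @param presence_rows row-bound output of [sulfur_presence()].
#' @return merged data.frame.
#' @export
cohort_matrix <- function(repertoires, presence_rows) {
  if (!setequal(repertoires$genome_id, presence_rows$genome_id))
    stop("invalid-input: repertoire and presence genome sets differ")
  pres <- presence_rows[, !grepl("_evalue$", names(presence_rows)),
                        drop = FALSE]
  out <- merge(repertoires, pres, by = "genome_id", sort = FALSE)
  out <- out[order(out$genome_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Divergent-signature / environment association with a permutation test
#'
#' Cross-tabulates presence of any divergent signature (S1c, S2, S3 or S4)
#' against the environment label and tests association with a permutation
#' chi-square: `p = (1 + #{shuffles with statistic >= observed}) /
#' (n_permutations + 1)`. This test is an explicit package addition for
#' formalising the qualitative ecology pattern; it is labelled as such in
#' the output.
#'
#' @param matrix_tbl cohort matrix from [cohort_matrix()].
#' @param metadata data.frame `genome_id`, `environment` (and optionally
#'   `host_label`).
#' @param n_permutations number of label shuffles (>= 99; default 999).
#' @param seed integer seed.
#' @param divergent signature names counted as divergent.
#' @return list of class `soxy_association`: `table` (2 x k contingency),
#'   `statistic`, `p_value`, `n_permutations`, `seed`, `note`.
#' @export
ecology_crosstab <- function(matrix_tbl, metadata, n_permutations = 999,
                             seed = 1,
                             divergent = c("S1c", "S2", "S3", "S4")) {
  stopifnot(n_permutations >= 99)
  miss <- setdiff(matrix_tbl$genome_id, metadata$genome_id)
  if (length(miss) > 0)
    stop("invalid-input: metadata missing for ",
         paste(miss, collapse = ", "))
  md <- metadata[match(matrix_tbl$genome_id, metadata$genome_id), ,
                 drop = FALSE]
  env <- md$environment
  if (length(unique(env)) < 2)
    stop("undefined-association: a single environment label")
  cols <- paste0("n_", divergent)
  cols <- intersect(cols, names(matrix_tbl))
  has_div <- rowSums(matrix_tbl[, cols, drop = FALSE]) > 0
  tab <- table(divergent = factor(has_div, levels = c(FALSE, TRUE)),
               environment = env)
  chi_stat <- function(d, e) {
    t0 <- table(factor(d, levels = c(FALSE, TRUE)), e)
    E <- outer(rowSums(t0), colSums(t0)) / sum(t0)
    ok <- E > 0
    sum((t0[ok] - E[ok])^2 / E[ok])
  }
  obs <- chi_stat(has_div, env)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(b) {
      chi_stat(has_div, sample(env)) >= obs - 1e-12
    }, TRUE))
  })
  p <- (1 + exceed) / (n_permutations + 1)
  structure(list(table = tab, statistic = obs, p_value = p,
                 n_permutations = n_permutations, seed = seed,
                 note = paste("permutation chi-square test added by",
                              "soxyprof; not part of the original",
                              "descriptive analysis")),
            class = "soxy_association")
}
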