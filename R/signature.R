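#' Arm definition
#'
#' The sulfur-binding "swinging arm" is read as a window of profile columns
#' ending at the conserved-cysteine anchor column: columns
#' `[anchor - upstream_offset, anchor]`, with
#' `window_length = upstream_offset + 1` (default 6, the length of the
#' canonical "VTIGGC" motif).
#'
#' @param anchor conserved-cysteine column of the profile (1-based).
#' @param window_length arm window length (default 6).
#' @return list `anchor`, `window_length`, `upstream_offset`.
#' @export
arm_definition <- function(anchor, window_length = 6L) {
  stopifnot(window_length >= 1, anchor >= window_length)
  list(anchor = as.integer(anchor),
       window_length = as.integer(window_length),
       upstream_offset = as.integer(window_length) - 1L)
}

#' Extract the swinging-arm region from a profile alignment trace
#'
#' Reads the residues mapped to the arm's profile columns (gap symbol `-`
#' where the column is deleted). The cysteine is present iff the residue at
#' the anchor column is `C`; its 1-based position in the ungapped sequence is
#' then taken from the trace.
#'
#' @param trace a `soxy_trace` from [align_to_profile()].
#' @param arm_def an [arm_definition()].
#' @return list of class `soxy_arm`: `arm_string`, `cys_present`,
#'   `cys_position` (NA unless present), `resolved`.
#' @export
extract_arm <- function(trace, arm_def) {
  cols <- (arm_def$anchor - arm_def$upstream_offset):arm_def$anchor
  if (is.na(arm_def$anchor) || arm_def$anchor > trace$m || any(cols < 1)) {
    return(structure(list(arm_string = NA_character_, cys_present = FALSE,
                          cys_position = NA_integer_, resolved = FALSE),
                     class = "soxy_arm"))
  }
  chars <- strsplit(trace$seq, "", fixed = TRUE)[[1]]
  idx <- trace$trace[cols]
  arm <- ifelse(is.na(idx), "-", chars[ifelse(is.na(idx), 1L, idx)])
  anchor_idx <- trace$trace[arm_def$anchor]
  cys <- !is.na(anchor_idx) && chars[anchor_idx] == "C"
  structure(list(arm_string = paste(arm, collapse = ""),
                 cys_present = cys,
                 cys_position = if (cys) anchor_idx else NA_integer_,
                 resolved = TRUE),
            class = "soxy_arm")
}

#' Classify an arm extract against a signature table
#'
#' Hamming distance (a gap counts as a mismatch) to each entry's motif; the
#' best entry is the one with fewest mismatches, ties broken by table order
#' (priority). A named call is made iff the best distance does not exceed
#' that entry's `max_mismatch`; otherwise the call is `"unclassified"`.
#'
#' @param arm a `soxy_arm` from [extract_arm()].
#' @param table signature table (see [default_signature_table()]).
#' @return list `signature`, `mismatches` (NA when unresolved), `reason`.
#' @export
classify_arm <- function(arm, table = default_signature_table()) {
  stopifnot(nrow(table) >= 1)
  if (!isTRUE(arm$resolved))
    return(list(signature = "unclassified", mismatches = NA_integer_,
                reason = "arm-unresolved"))
  arm_chars <- strsplit(arm$arm_string, "", fixed = TRUE)[[1]]
  dists <- vapply(seq_len(nrow(table)), function(r) {
    motif <- strsplit(table$arm_motif[r], "", fixed = TRUE)[[1]]
    if (length(motif) != length(arm_chars)) return(length(motif))
    sum(motif != arm_chars | arm_chars == "-")
  }, 0L)
  ord <- order(table$priority, method = "radix")
  best <- ord[which.min(dists[ord])]
  if (dists[best] <= table$max_mismatch[best]) {
    list(signature = table$name[best], mismatches = dists[best],
         reason = NA_character_)
  } else {
    list(signature = "unclassified", mismatches = dists[best],
         reason = "no-motif-within-tolerance")
  }
}

#' Detect a SoxYZ domain fusion in a single protein
#'
#' A protein is called fused iff the best local alignment to the SoxY
#' profile and the best local alignment to the SoxZ profile each pass the
#' per-domain e-value cutoff, the two envelopes overlap by at most
#' `overlap_tolerance` residues, and the Y domain precedes the Z domain.
#'
#' @param seq protein string.
#' @param profile_y,profile_z `soxy_profile`s for the two domains.
#' @param cal_y,cal_z `soxy_calibration`s fitted on local decoy scores of
#'   the respective profiles (see [calibrate_profile_local()]).
#' @param evalue_cutoff per-domain cutoff (default 1e-5).
#' @param overlap_tolerance maximum envelope overlap in residues (default
#'   10).
#' @param protein_id optional id recorded on the call.
#' @param gap_open,gap_extend affine gap penalties in bits for the local
#'   domain alignments (defaults 8 and 1; stiffer than the global search
#'   penalties so domain envelopes stay tight). Must match the penalties
#'   used when calibrating `cal_y`/`cal_z`.
#' @return list of class `soxy_fusion`: `protein_id`, `fused`, `y_bounds`,
#'   `z_bounds` (0-based half-open), `y_evalue`, `z_evalue`.
#' @export
detect_fusion <- function(seq, profile_y, profile_z, cal_y, cal_z,
                          evalue_cutoff = 1e-5, overlap_tolerance = 10L,
                          protein_id = NA_character_,
                          gap_open = 8, gap_extend = 1) {
  y <- pssm_align_local_cpp(profile_emissions_padded(profile_y),
                            encode_seq(seq), gap_open, gap_extend)
  z <- pssm_align_local_cpp(profile_emissions_padded(profile_z),
                            encode_seq(seq), gap_open, gap_extend)
  ey <- evalue(y$score, cal_y, db_size = 1)
  ez <- evalue(z$score, cal_z, db_size = 1)
  yb <- c(y$seq_start - 1L, y$seq_end)
  zb <- c(z$seq_start - 1L, z$seq_end)
  fused <- ey <= evalue_cutoff && ez <= evalue_cutoff &&
    yb[2] <= zb[1] + overlap_tolerance &&  # envelopes barely overlap
    yb[1] < zb[1]                          # Y precedes Z
  structure(list(protein_id = protein_id, fused = fused,
                 y_bounds = yb, z_bounds = zb,
                 y_evalue = ey, z_evalue = ez),
            class = "soxy_fusion")
}

#' Calibrate a profile for local-alignment e-values
#'
#' Fits a Gumbel to local (Smith-Waterman over PSSM emissions) scores of
#' background decoys, for use in [detect_fusion()]. Gap penalties must
#' match those passed to `detect_fusion()`.
#'
#' @inheritParams calibrate
#' @param gap_open,gap_extend affine gap penalties in bits for the local
#'   alignment (defaults 8 and 1).
#' @export
calibrate_profile_local <- function(profile, decoys, n_decoys = 1000,
                                    seed = 1, gap_open = 8,
                                    gap_extend = 1) {
  if (n_decoys < 1000)
    stop("invalid-parameter: calibration requires >= 1000 decoys")
  seqs <- with_seed(seed, {
    if (is.numeric(decoys)) {
      lens <- sample(rep_len(as.integer(decoys), n_decoys))
      vapply(lens, function(L) random_protein(L, profile$background), "")
    } else {
      base <- rep_len(decoys, n_decoys)
      vapply(base, function(s) paste(sample(strsplit(s, "")[[1]]),
                                     collapse = ""), "", USE.NAMES = FALSE)
    }
  })
  emis <- profile_emissions_padded(profile)
  scores <- vapply(seqs, function(s) {
    pssm_align_local_cpp(emis, encode_seq(s), gap_open,
                         gap_extend)$score
  }, 0, USE.NAMES = FALSE)
  fit <- fit_gumbel(scores)
  structure(list(mu = fit$mu, lambda = fit$lambda, n_decoys = n_decoys,
                 db_size_policy = "per_protein"),
            class = "soxy_calibration")
}

#' Percent identity from a trimmed global alignment
#'
#' Needleman-Wunsch global alignment under BLOSUM62 (gap open 11, extend 1),
#' terminal gap columns trimmed from both ends, identity = 100 * matches /
#' remaining columns.
#'
#' @param a,b protein strings.
#' @param gap_open,gap_extend gap penalties.
#' @return list `identity` (percent), `alignment_length`, `matches`.
#' @export
global_identity <- function(a, b, gap_open = 11, gap_extend = 1) {
  stopifnot(nchar(a) >= 1, nchar(b) >= 1)
  res <- nw_align_cpp(encode_seq(a), encode_seq(b), blosum62_matrix(),
                      gap_open, gap_extend)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  A <- res$a_aln; B <- res$b_aln
  gap_col <- A == 0L | B == 0L
  inner <- which(!gap_col)
  if (length(inner) == 0)
    return(list(identity = 0, alignment_length = 0L, matches = 0L))
  lo <- min(inner); hi <- max(inner)   # trim terminal gap columns
  A <- A[lo:hi]; B <- B[lo:hi]
  matches <- sum(A != 0L & B != 0L & ca[pmax(A, 1L)] == cb[pmax(B, 1L)] &
                   A > 0L & B > 0L)
  len <- hi - lo + 1L
  list(identity = 100 * matches / len, alignment_length = len,
       matches = as.integer(matches))
}

#' Classify all hits: arm extraction, signature call, fusion call, identity
#'
#' Convenience wrapper running [extract_arm()], [classify_arm()],
#' [detect_fusion()] and [global_identity()] over a hit table.
#'
#' @param hits hit data.frame from [search_proteome()] (traces attached).
#' @param profile_y SoxY profile used for the search.
#' @param profile_z SoxZ profile.
#' @param cal_y,cal_z local calibrations for the two profiles.
#' @param reference canonical SoxY sequence for identity reporting.
#' @param table signature table.
#' @param fusion_evalue_cutoff,overlap_tolerance fusion parameters.
#' @return data.frame `protein_id`, `genome_id`, `signature`, `mismatches`,
#'   `fused`, `y_start`, `y_end`, `z_start`, `z_end`,
#'   `identity_to_canonical`, `cys_present`, `cys_position`.
#' @export
classify_hits <- function(hits, profile_y, profile_z, cal_y, cal_z,
                          reference, table = default_signature_table(),
                          fusion_evalue_cutoff = 1e-5,
                          overlap_tolerance = 10L) {
  traces <- attr(hits, "traces")
  arm_def <- arm_definition(profile_y$cys_anchor)
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    id <- hits$protein_id[i]
    tr <- traces[[id]]
    arm <- extract_arm(tr, arm_def)
    call <- classify_arm(arm, table)
    fus <- detect_fusion(hits$sequence[i], profile_y, profile_z,
                         cal_y, cal_z, fusion_evalue_cutoff,
                         overlap_tolerance, protein_id = id)
    idty <- global_identity(hits$sequence[i], reference)
    data.frame(protein_id = id, genome_id = hits$genome_id[i],
               signature = call$signature, mismatches = call$mismatches,
               fused = fus$fused,
               y_start = fus$y_bounds[1], y_end = fus$y_bounds[2],
               z_start = fus$z_bounds[1], z_end = fus$z_bounds[2],
               identity_to_canonical = idty$identity,
               cys_present = arm$cys_present,
               cys_position = arm$cys_position,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), genome_id = character(),
               signature = character(), mismatches = integer(),
               fused = logical(), y_start = integer(), y_end = integer(),
               z_start = integer(), z_end = integer(),
               identity_to_canonical = numeric(), cys_present = logical(),
               cys_position = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
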