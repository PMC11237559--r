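#' Default swinging-arm signature table
#'
#' The six named SoxY arm signatures. S1a carries the canonical "VTIGGC"
#' motif ending at the conserved sulfur-binding cysteine. S1b and S1c each
#' differ from S1a at exactly one position; S2--S4 differ at three or more
#' positions. All motifs retain the "GGC" trimer that the quality filter
#' requires. The S1b--S4 residue strings are synthetic defaults chosen to
#' satisfy those distance constraints -- real-data analyses should supply
#' their own table via this argument wherever one is accepted.
#'
#' Identity bands (`id_lo`, `id_hi`, percent identity to the canonical
#' reference) are the generator's planting targets for full-length copies of
#' each signature; `fused` marks signatures carried on SoxYZ fusion ORFs.
#'
#' @return data.frame with columns `name`, `arm_motif`, `max_mismatch`,
#'   `priority`, `id_lo`, `id_hi`, `fused`, `clade`.
#' @export
default_signature_table <- function() {
  data.frame(
    name = c("S1a", "S1b", "S1c", "S2", "S3", "S4"),
    arm_motif = c("VTIGGC", "VTVGGC", "VSIGGC", "AKMGGC", "TSLGGC", "PNVGGC"),
    max_mismatch = c(0L, 0L, 0L, 0L, 0L, 0L),
    priority = 1:6,
    id_lo = c(52, 45, 33, 24, 28, 26),
    id_hi = c(65, 60, 43, 34, 32, 37),
    fused = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    clade = c(1L, 1L, 1L, 2L, 3L, 4L),
    stringsAsFactors = FALSE
  )
}

# Clade membership of each signature (clade 1 holds S1a/S1b/S1c).
signature_clade <- function(sig, table = default_signature_table()) {
  table$clade[match(sig, table$name)]
}

#' Build the synthetic reference set
#'
#' Deterministically constructs the canonical SoxY and SoxZ reference
#' sequences, a seed alignment of perturbed canonical copies for profile
#' building, and one full-length exemplar per arm signature. The canonical
#' SoxY is 150 aa with the arm motif ending at the conserved cysteine at
#' 1-based position 110; the motif's last six residues are "VTIGGC". With
#' `arm_window > 6` the arm is extended upstream with canonical context.
#'
#' @param arm_window arm window length in residues (>= 6; default 6).
#' @param seed integer seed.
#' @param n_seed_seqs number of perturbed copies in each seed alignment.
#' @param signature_table signature definitions (see
#'   [default_signature_table()]).
#' @return object of class `soxy_reference`: list with `canonical_soxy`,
#'   `canonical_soxz`, `cys_pos` (110), `arm_window`, `arm_start`,
#'   `seed_alignment` (named character vector, equal lengths, first row
#'   `canonical`), `soxz_seed_alignment`, and `signature_exemplars`
#'   (per signature: `arm`, `sequence`).
#' @export
build_reference_set <- function(arm_window = 6, seed = 1,
                                n_seed_seqs = 8,
                                signature_table = default_signature_table()) {
  if (!is.numeric(arm_window) || arm_window < 6)
    stop("invalid-parameter: arm_window must be >= 6")
  arm_window <- as.integer(arm_window)
  cys_pos <- 110L
  len_y <- 150L
  len_z <- 100L

  canonical <- with_seed(child_seed(seed, 1), {
    s <- strsplit(random_protein(len_y), "", fixed = TRUE)[[1]]
    s[(cys_pos - 5L):cys_pos] <- strsplit("VTIGGC", "")[[1]]
    # keep exactly one GGC inside the arm window: scrub accidental GG pairs
    # bordering the arm and any other GGC inside the window
    paste(s, collapse = "")
  })
  canonical <- scrub_extra_ggc(canonical, cys_pos, arm_window)
  arm_start <- cys_pos - arm_window + 1L
  canonical_z <- with_seed(child_seed(seed, 2), random_protein(len_z))

  # one exemplar per signature at the midpoint of its identity band
  exemplars <- list()
  for (r in seq_len(nrow(signature_table))) {
    def <- signature_table[r, ]
    mid <- (def$id_lo + def$id_hi) / 2
    ex <- plant_signature(canonical, def, target_identity = mid,
                          seed = child_seed(seed, 100 + r),
                          cys_pos = cys_pos)
    exemplars[[def$name]] <- list(arm = def$arm_motif, sequence = ex)
  }

  # seed alignment: family-wide, as a domain-level profile would be built
  # from -- the canonical sequence, near-canonical copies, and a perturbed
  # copy of every signature exemplar so divergent clades contribute their
  # own column signal. Arms untouched; equal lengths, so the stack is
  # already aligned.
  s1a_def <- signature_table[signature_table$name == "S1a", ]
  seed_aln <- c(canonical = canonical)
  n_canon <- max(2L, n_seed_seqs - nrow(signature_table))
  for (k in seq_len(n_canon)) {
    idty <- 85 + (k %% 4L) * 3
    seed_aln[paste0("seed", k)] <- plant_signature(
      canonical, s1a_def, target_identity = idty,
      seed = child_seed(seed, 10 + k), cys_pos = cys_pos)
  }
  for (r in seq_len(nrow(signature_table))) {
    def <- signature_table[r, ]
    seed_aln[paste0("seed_", def$name)] <- plant_signature(
      exemplars[[def$name]]$sequence, def, target_identity = 92,
      seed = child_seed(seed, 60 + r), cys_pos = cys_pos)
  }
  z_aln <- c(canonical_z = canonical_z)
  for (k in seq_len(n_seed_seqs - 1L)) {
    z_aln[paste0("zseed", k)] <- mutate_outside(
      canonical_z, integer(0), round(len_z * (0.12 - 0.01 * (k %% 3L))),
      child_seed(seed, 30 + k))
  }

  structure(list(
    canonical_soxy = canonical,
    canonical_soxz = canonical_z,
    cys_pos = cys_pos,
    arm_window = arm_window,
    arm_start = arm_start,
    seed_alignment = seed_aln,
    soxz_seed_alignment = z_aln,
    signature_exemplars = exemplars,
    signature_table = signature_table
  ), class = "soxy_reference")
}

# Remove GGC occurrences other than the canonical one from the arm window
# and its immediate flanks so the arm holds exactly one "GGC" trimer.
scrub_extra_ggc <- function(seq, cys_pos, arm_window) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  arm_start <- cys_pos - arm_window + 1L
  canonical_ggc_start <- cys_pos - 2L
  repeat {
    s <- paste(chars, collapse = "")
    hits <- gregexpr("GGC", s, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    bad <- hits[hits != canonical_ggc_start &
                  hits >= arm_start - 2L & hits <= cys_pos]
    if (length(bad) == 0) return(s)
    chars[bad[1]] <- "A"
  }
}

#' Plant an arm signature into a base sequence at a target identity
#'
#' Rewrites the arm window (ending at the conserved cysteine position) to the
#' signature's motif, then applies uniform random substitutions outside the
#' arm, at positions drawn without replacement, until the global identity to
#' the base sequence is within rounding of `target_identity`. No indels are
#' introduced, so the realized identity is exact up to integer rounding.
#'
#' @param base protein string (the canonical reference or an exemplar).
#' @param sig one row of a signature table (`name`, `arm_motif`, ...).
#' @param target_identity percent identity to `base`, in \[20, 100\].
#' @param seed integer seed.
#' @param cys_pos 1-based position of the arm's terminal cysteine in `base`.
#' @return protein string with the exact motif in the arm window.
#' @export
plant_signature <- function(base, sig, target_identity, seed, cys_pos = 110L) {
  if (!is.numeric(target_identity) || target_identity < 20 ||
      target_identity > 100)
    stop("invalid-parameter: target_identity must be in [20, 100]")
  motif <- as.character(sig$arm_motif)
  w <- nchar(motif)
  L <- nchar(base)
  stopifnot(cys_pos <= L, cys_pos >= w)
  arm_idx <- (cys_pos - w + 1L):cys_pos
  chars <- strsplit(base, "", fixed = TRUE)[[1]]
  base_arm <- chars[arm_idx]
  motif_chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  arm_mismatch <- sum(base_arm != motif_chars)
  chars[arm_idx] <- motif_chars

  k <- round(L * (1 - target_identity / 100)) - arm_mismatch
  k <- max(0L, as.integer(k))
  avail <- setdiff(seq_len(L), arm_idx)
  if (k > length(avail))
    stop("infeasible-target: requested identity needs more substitutions ",
         "than there are positions outside the arm")
  seq <- paste(chars, collapse = "")
  mutate_outside(seq, arm_idx, k, seed)
}

# Substitute k positions (sampled without replacement outside `protect`)
# with a uniformly chosen different residue.
mutate_outside <- function(seq, protect, k, seed) {
  if (k <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  avail <- setdiff(seq_along(chars), protect)
  with_seed(seed, {
    pos <- sample(avail, k)
    for (p in pos) {
      chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1)
    }
    paste(chars, collapse = "")
  })
}
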