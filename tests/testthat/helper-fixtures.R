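# Shared fixtures, built once per test run and memoised.

.fx <- new.env(parent = emptyenv())

fx_ref <- function() {
  if (is.null(.fx$ref)) .fx$ref <- build_reference_set(seed = 1)
  .fx$ref
}

fx_profile_y <- function() {
  if (is.null(.fx$py))
    .fx$py <- build_profile(fx_ref()$seed_alignment, cys_pos = 110,
                            name = "SoxY")
  .fx$py
}

fx_profile_z <- function() {
  if (is.null(.fx$pz))
    .fx$pz <- build_profile(fx_ref()$soxz_seed_alignment, cys_ref = 1L,
                            cys_pos = 50L, name = "SoxZ")
  .fx$pz
}

fx_cal_y <- function() {
  if (is.null(.fx$cal_y))
    .fx$cal_y <- calibrate(fx_profile_y(), c(100, 150, 200, 250, 300),
                           1000, seed = 2)
  .fx$cal_y
}

fx_cal_y_local <- function() {
  if (is.null(.fx$cal_y_local))
    .fx$cal_y_local <- calibrate_profile_local(
      fx_profile_y(), c(100, 150, 200, 250, 300), 1000, seed = 3)
  .fx$cal_y_local
}

fx_cal_z_local <- function() {
  if (is.null(.fx$cal_z_local))
    .fx$cal_z_local <- calibrate_profile_local(
      fx_profile_z(), c(100, 150, 200, 250, 300), 1000, seed = 4)
  .fx$cal_z_local
}

# A small cohort reused by several files.
fx_cohort <- function() {
  if (is.null(.fx$cohort))
    .fx$cohort <- generate_cohort(8, ref = fx_ref(), seed = 5,
                                  decoy_count = 40)
  .fx$cohort
}

# Planted copy of a signature: signature exemplar -> within-clade mutant.
planted_copy <- function(sig, seed, within_identity = 90, fused = FALSE,
                         ref = fx_ref()) {
  st <- ref$signature_table
  def <- st[st$name == sig, ]
  y <- plant_signature(ref$signature_exemplars[[sig]]$sequence, def,
                       within_identity, seed = seed)
  if (fused) {
    z <- soxyprof:::mutate_outside(ref$canonical_soxz, integer(0), 12,
                                   soxyprof:::child_seed(seed, 3))
    paste0(y, z)
  } else y
}

# Clean four-clade alignment: four ancestors at moderate divergence from
# the canonical sequence (distinct arms), tight tips within each clade.
# Returns list(msa, clades) where clades maps tip id -> clade label.
clade_alignment <- function(n_per_clade = 8, seed = 17, ref = fx_ref(),
                            profile = fx_profile_y()) {
  st <- ref$signature_table
  anc_defs <- st[match(c("S1a", "S2", "S3", "S4"), st$name), ]
  ancestors <- c(
    clade1 = ref$canonical_soxy,
    clade2 = plant_signature(ref$canonical_soxy, anc_defs[2, ], 40,
                             seed = soxyprof:::child_seed(seed, 2)),
    clade3 = plant_signature(ref$canonical_soxy, anc_defs[3, ], 40,
                             seed = soxyprof:::child_seed(seed, 3)),
    clade4 = plant_signature(ref$canonical_soxy, anc_defs[4, ], 40,
                             seed = soxyprof:::child_seed(seed, 4)))
  seqs <- character(0)
  clades <- character(0)
  for (ci in seq_along(ancestors)) {
    cl <- names(ancestors)[ci]
    def <- anc_defs[ci, ]
    for (k in seq_len(n_per_clade)) {
      id <- sprintf("%s_t%02d", cl, k)
      seqs[id] <- plant_signature(
        ancestors[[ci]], def, 85 + (k %% 3) * 4,
        seed = soxyprof:::child_seed(seed, 100 * ci + k))
      clades[id] <- cl
    }
  }
  traces <- lapply(seqs, function(s) align_to_profile(profile, s))
  list(msa = stack_alignments(traces), clades = clades, seqs = seqs)
}
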