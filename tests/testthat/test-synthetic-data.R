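test_that("reference set satisfies its structural invariants and is deterministic", {
  ref <- build_reference_set(arm_window = 6, seed = 1)
  expect_equal(nchar(ref$canonical_soxy), 150)
  expect_equal(substr(ref$canonical_soxy, 105, 110), "VTIGGC")
  expect_equal(substr(ref$canonical_soxy, 110, 110), "C")
  # exactly one GGC trimer inside the arm window
  arm <- substr(ref$canonical_soxy, ref$arm_start, ref$cys_pos)
  expect_length(gregexpr("GGC", arm, fixed = TRUE)[[1]], 1)
  # every exemplar arm contains GGC and the configured motif
  for (nm in names(ref$signature_exemplars)) {
    ex <- ref$signature_exemplars[[nm]]
    expect_match(ex$arm, "GGC")
    expect_equal(substr(ex$sequence, 105, 110), ex$arm)
  }
  ref2 <- build_reference_set(arm_window = 6, seed = 1)
  expect_identical(ref, ref2)
  expect_error(build_reference_set(arm_window = 5), "invalid-parameter")
})

test_that("signature table encodes the documented motif distances", {
  st <- default_signature_table()
  ham <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  s1a <- st$arm_motif[st$name == "S1a"]
  expect_equal(s1a, "VTIGGC")
  expect_equal(ham(s1a, st$arm_motif[st$name == "S1b"]), 1)
  expect_equal(ham(s1a, st$arm_motif[st$name == "S1c"]), 1)
  for (nm in c("S2", "S3", "S4"))
    expect_gte(ham(s1a, st$arm_motif[st$name == nm]), 3)
  expect_true(all(grepl("GGC", st$arm_motif)))
})

test_that("plant_signature hits the identity target and rewrites the arm exactly", {
  ref <- fx_ref()
  st <- default_signature_table()
  for (case in list(list(sig = "S1a", t = 60), list(sig = "S2", t = 30),
                    list(sig = "S3", t = 45), list(sig = "S4", t = 80))) {
    def <- st[st$name == case$sig, ]
    out <- plant_signature(ref$canonical_soxy, def, case$t, seed = 11)
    expect_equal(substr(out, 105, 110), def$arm_motif)
    # independent hand count (sequences are equal length, no indels)
    expect_lt(abs(hand_identity(out, ref$canonical_soxy) - case$t), 3)
    # the package's aligner agrees with the hand count
    expect_lt(abs(global_identity(out, ref$canonical_soxy)$identity -
                    case$t), 3)
  }
  # 100% target: base unchanged except the arm rewrite
  s1a <- st[st$name == "S1a", ]
  out <- plant_signature(ref$canonical_soxy, s1a, 100, seed = 1)
  expect_identical(out, ref$canonical_soxy)
  expect_error(plant_signature(ref$canonical_soxy, s1a, 10, seed = 1),
               "invalid-parameter")
})

test_that("shuffle_sequence preserves composition and is uniform over positions", {
  expect_identical(shuffle_sequence("AAAA", 1), "AAAA")
  s <- soxyprof:::random_protein(200)
  sh <- shuffle_sequence(s, 42)
  expect_identical(sort(strsplit(s, "")[[1]]), sort(strsplit(sh, "")[[1]]))
  expect_identical(shuffle_sequence(s, 42), sh)
  # chi-square of where a marked residue lands over many shuffles
  base <- paste0("W", strrep("A", 9))
  pos <- vapply(1:1000, function(i) {
    regexpr("W", shuffle_sequence(base, i), fixed = TRUE)[[1]]
  }, 0L)
  tab <- tabulate(pos, nbins = 10)
  chi <- sum((tab - 100)^2 / 100)
  expect_lt(chi, qchisq(0.999, df = 9))
})

test_that("generated genomes are internally consistent with their truth table", {
  ref <- fx_ref()
  copies <- data.frame(
    signature = c("S1a", "S1a", "S2", "S3", "S4"),
    fused = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    layout = c("sedimenticola_operon", "thiodiazotropha_dispersed",
               "s2_adh", "s3_otr", "s4_c1"),
    stringsAsFactors = FALSE)
  spec <- genome_spec("T001", copies, decoy_count = 30)
  g <- generate_genome(spec, ref, seed = 9)
  expect_equal(nrow(g$truth), 5)
  expect_equal(sum(g$truth$fused), 2)
  # every truth entry is retrievable from the emitted tables by id and
  # coordinates, and coordinates match protein lengths (3L + 3 nt)
  for (r in seq_len(nrow(g$truth))) {
    gi <- match(g$truth$gene_id[r], g$genes$gene_id)
    expect_false(is.na(gi))
    expect_equal(g$genes$start[gi], g$truth$start[r])
    expect_equal(g$genes$end[gi] - g$genes$start[gi] + 1L,
                 3L * nchar(g$proteins[[g$truth$gene_id[r]]]) + 3L)
  }
  # planted copies pass the quality filter's sequence rules
  planted <- g$proteins[g$truth$gene_id]
  expect_true(all(nchar(planted) >= 140))
  expect_true(all(grepl("GGC", planted)))
  # determinism: same spec and seed give identical output
  g2 <- generate_genome(spec, ref, seed = 9)
  expect_identical(g, g2)
  # fused copy is a single CDS of about len(Y) + len(Z)
  fused_len <- unname(nchar(g$proteins[g$truth$gene_id[g$truth$fused][1]]))
  expect_equal(fused_len, 250)
  # zero copies: truth empty, decoys only
  g0 <- generate_genome(genome_spec("T002", copies[0, ], decoy_count = 20,
                                    sulfur_genes = character(0)),
                        ref, seed = 9)
  expect_equal(nrow(g0$truth), 0)
  expect_equal(length(g0$proteins), 20)
})

test_that("genome files round-trip through FASTA and GFF3", {
  cohort <- fx_cohort()
  g <- cohort$genomes[[1]]
  dir <- withr::local_tempdir()
  paths <- write_genome(g, dir)
  aa <- Biostrings::readAAStringSet(paths[["faa"]])
  expect_identical(as.character(aa)[g$genes$gene_id],
                   g$proteins[g$genes$gene_id])
  models <- read_gene_models(paths[["gff"]])
  back <- gene_models_gff(models)
  expect_identical(back$start, g$genes$start)
  expect_identical(back$end, g$genes$end)
  expect_identical(back$gene_id, g$genes$gene_id)
})

test_that("cohort ecology model yields the configured label frequencies", {
  cohort <- generate_cohort(200, ref = fx_ref(), seed = 23,
                            decoy_count = 2)
  model <- default_ecology_model()
  freq <- table(factor(cohort$metadata$environment,
                       levels = model$labels)) / 200
  for (k in seq_along(model$labels))
    expect_lt(abs(freq[[model$labels[k]]] - model$probs[k]), 0.05 + 1e-9)
  # divergent-planting rate among seagrass genomes near p_divergent
  sg <- cohort$metadata$genome_id[cohort$metadata$environment == "seagrass"]
  div <- vapply(sg, function(id) {
    any(cohort$truth$signature[cohort$truth$genome_id == id] %in%
          c("S1c", "S2", "S3", "S4"))
  }, TRUE)
  expect_lt(abs(mean(div) - model$p_divergent), 0.1)
  # every seagrass genome with divergent planting has >= 2 soxY copies
  for (id in sg[div])
    expect_gte(sum(cohort$truth$genome_id == id), 2)
  # specialist genomes carry only S1a/S1b
  sp <- cohort$metadata$genome_id[cohort$metadata$environment != "seagrass"]
  expect_true(all(cohort$truth$signature[cohort$truth$genome_id %in% sp]
                  %in% c("S1a", "S1b")))
  # copy numbers bounded by five
  expect_lte(max(table(cohort$truth$genome_id)), 5)
})

test_that("degenerate one-label model produces a single canonical genome", {
  model <- default_ecology_model()
  model$labels <- "vent"; model$probs <- 1
  model$specialist_repertoires <- list(c("S1a"))
  model$specialist_weights <- 1
  cohort <- generate_cohort(1, model = model, ref = fx_ref(), seed = 3,
                            decoy_count = 5)
  expect_equal(nrow(cohort$metadata), 1)
  expect_identical(cohort$truth$signature, "S1a")
})
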