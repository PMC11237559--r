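# A small hand-built contig: ten genes, alternating products, with one
# sox-like block in the middle.
toy_models <- function() {
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:10),
    contig = "c1",
    start = c(1, 500, 1000, 1500, 2000, 2600, 3200, 3900, 5000, 6000),
    end = c(400, 900, 1400, 1900, 2500, 3100, 3800, 4400, 5600, 6500),
    strand = c("+", "+", "+", "+", "+", "+", "+", "+", "-", "+"),
    gene = c("x1", "soxA", "soxB", "soxX", "soxY", "soxZ", "x2", "x3",
             "x4", "x5"),
    product = c("hypothetical protein",
                "sulfur oxidation c-type cytochrome SoxA",
                "sulfate thiohydrolase SoxB", "sulfur oxidation SoxX",
                "sulfur carrier protein SoxY",
                "sulfur carrier protein SoxZ",
                "LuxR family transcriptional regulator",
                "dimethyl sulfoxide reductase subunit A",
                "PQQ-dependent quinohemoprotein alcohol dehydrogenase ADH",
                "hypothetical protein"),
    stringsAsFactors = FALSE)
  gene_models(genes)
}

test_that("coordinates round-trip between GFF3 convention and internal half-open form", {
  models <- toy_models()
  expect_equal(models$start0, models$end0 - (models$end0 - models$start0))
  back <- gene_models_gff(models)
  expect_equal(back$start, c(1, 500, 1000, 1500, 2000, 2600, 3200, 3900,
                             5000, 6000))
  expect_equal(back$end, c(400, 900, 1400, 1900, 2500, 3100, 3800, 4400,
                           5600, 6500))
})

test_that("hits map to gene models with unmatched ids reported", {
  models <- toy_models()
  hits <- data.frame(protein_id = c("g05", "nope"), genome_id = "G",
                     evalue = c(1e-9, 1e-9), stringsAsFactors = FALSE)
  loci <- map_hits_to_genes(hits, models)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$gene, "soxY")
  expect_identical(attr(loci, "unmatched"), "nope")
  dup <- rbind(models, models[1, ])
  expect_error(map_hits_to_genes(hits, dup), "invalid-annotation")
  expect_equal(nrow(map_hits_to_genes(hits[0, ], models)), 0)
})

test_that("neighborhood extraction respects the radius and flags contig edges", {
  models <- toy_models()
  nm <- extract_neighborhood("g05", models, k = 4)
  expect_equal(nrow(nm$genes), 9)
  expect_equal(nm$genes$gene_id[nm$genes$offset == 0], "g05")
  expect_false(nm$truncated_up)
  # focal gene first on the contig: upstream side empty and flagged
  nm1 <- extract_neighborhood("g01", models, k = 4)
  expect_true(nm1$truncated_up)
  expect_equal(min(nm1$genes$offset), 0)
  nm5 <- extract_neighborhood("g05", models, k = 5)
  expect_equal(nrow(nm5$genes), 10)  # truncated downstream at 10 genes
  expect_error(extract_neighborhood("missing", models), "invalid-input")
})

test_that("product keywords drive gene categorization", {
  models <- toy_models()
  nm <- categorize_neighborhood(extract_neighborhood("g05", models, k = 4))
  cat_of <- function(g) nm$genes$category[nm$genes$gene_id == g]
  expect_equal(cat_of("g05"), "sulfur")       # soxY product
  expect_equal(cat_of("g07"), "regulatory")   # LuxR
  expect_equal(cat_of("g08"), "sulfur")       # DMSO reductase
  expect_equal(cat_of("g09"), "carbon")       # alcohol dehydrogenase
  expect_equal(cat_of("g01"), "hypothetical")
})

test_that("operon detection grows same-strand short-gap runs and is strand-symmetric", {
  models <- toy_models()
  # gaps within g02..g08 are all 100 bp (end0 to start0); g01->g02 gap 100
  op <- detect_operon(models, "g05", max_gap = 200)
  expect_true(op$verdict)
  expect_true(all(sprintf("g%02d", 2:6) %in% op$members))
  # tighten the gap below the layout's 99-bp spacing: the run splits
  op2 <- detect_operon(models, "g05", max_gap = 98)
  expect_false(op2$verdict)
  # strand flip + coordinate reversal leaves the verdict unchanged
  L <- max(models$end0) + 100
  flipped <- models
  flipped$start0 <- L - models$end0
  flipped$end0 <- L - models$start0
  flipped$strand <- ifelse(models$strand == "+", "-", "+")
  op3 <- detect_operon(flipped, "g05", max_gap = 200)
  expect_equal(op3$verdict, op$verdict)
  expect_setequal(op3$members, op$members)
})

test_that("planted operon and dispersed layouts are discriminated on generated genomes", {
  ref <- fx_ref()
  mk <- function(layout) {
    copies <- data.frame(signature = "S1a", fused = FALSE, layout = layout,
                         stringsAsFactors = FALSE)
    g <- generate_genome(genome_spec("T", copies, decoy_count = 30),
                         ref, seed = 15)
    models <- gene_models(g$genes)
    detect_operon(models, g$truth$gene_id[1], max_gap = 200)
  }
  expect_true(mk("sedimenticola_operon")$verdict)
  expect_false(mk("thiodiazotropha_dispersed")$verdict)
})

test_that("an intergenic gap of max_gap + 1 splits the run at the boundary", {
  genes <- data.frame(
    gene_id = c("a", "b", "c"), contig = "c1",
    start = c(1, 702, 1500), end = c(500, 1299, 2000),
    strand = "+", gene = c("soxA", "soxY", "soxB"),
    product = "p", stringsAsFactors = FALSE)
  models <- gene_models(genes)
  # gap a->b is 201 bp in half-open coordinates
  expect_equal(models$start0[2] - models$end0[1], 201)
  op <- detect_operon(models, "b", required = c("soxA", "soxY"),
                      max_gap = 201)
  expect_true(op$verdict)
  op2 <- detect_operon(models, "b", required = c("soxA", "soxY"),
                       max_gap = 200)
  expect_false(op2$verdict)
  expect_false("a" %in% op2$members)
})

test_that("synteny scores reward shared category order and ignore strand polarity", {
  models <- toy_models()
  nm <- categorize_neighborhood(extract_neighborhood("g05", models, k = 3))
  expect_equal(compare_synteny(nm, nm), 1)
  # two genomes planted with the same layout share most of their context
  ref <- fx_ref()
  mk <- function(seed) {
    copies <- data.frame(signature = "S4", fused = TRUE, layout = "s4_c1",
                         stringsAsFactors = FALSE)
    g <- generate_genome(genome_spec(paste0("T", seed), copies,
                                     decoy_count = 10), ref, seed = seed)
    models <- gene_models(g$genes)
    categorize_neighborhood(extract_neighborhood(g$truth$gene_id[1],
                                                 models, k = 3))
  }
  expect_gte(compare_synteny(mk(31), mk(32)), 0.8)
  # disjoint categories beyond the focal gene score near zero
  other <- nm
  other$genes$category <- rep("carbon", nrow(other$genes))
  expect_lte(compare_synteny(nm, other), 2 / nrow(nm$genes))
})
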