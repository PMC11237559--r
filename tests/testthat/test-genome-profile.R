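mk_hit <- function(id, genome, seq = strrep("A", 150)) {
  data.frame(protein_id = id, genome_id = genome, length = nchar(seq),
             score_bits = 10, evalue = 1e-9, env_start = 0L,
             env_end = nchar(seq), sequence = seq, stringsAsFactors = FALSE)
}

mk_call <- function(id, genome, sig, fused = FALSE) {
  data.frame(protein_id = id, genome_id = genome, signature = sig,
             mismatches = 0L, fused = fused, y_start = 0L, y_end = 150L,
             z_start = 150L, z_end = 250L, identity_to_canonical = 50,
             stringsAsFactors = FALSE)
}

test_that("repertoires count loci per signature with fusions and unclassified split out", {
  hits <- rbind(mk_hit("g1", "G1", strrep("A", 150)),
                mk_hit("g2", "G1", strrep("C", 150)),
                mk_hit("g3", "G1", strrep("D", 250)),
                mk_hit("g4", "G1", strrep("E", 150)),
                mk_hit("g5", "G1", strrep("F", 150)))
  calls <- rbind(mk_call("g1", "G1", "S1a"), mk_call("g2", "G1", "S1a"),
                 mk_call("g3", "G1", "S2", fused = TRUE),
                 mk_call("g4", "G1", "S3"), mk_call("g5", "G1", "S4"))
  rep1 <- soxy_repertoire(hits, calls, "G1")
  expect_equal(rep1$soxy_total, 5)
  expect_equal(rep1$n_S1a, 2)
  expect_equal(rep1$n_S2, 1)
  expect_equal(rep1$n_fused, 1)
  # total equals the sum over signatures plus unclassified
  sig_cols <- grep("^n_S", names(rep1))
  expect_equal(rep1$soxy_total,
               sum(unlist(rep1[sig_cols])) + rep1$n_unclassified)
  # genome with no hits: all zeros
  rep0 <- soxy_repertoire(hits, calls, "G9")
  expect_equal(rep0$soxy_total, 0)
  expect_equal(rep0$n_fused, 0)
  # missing call is an error
  expect_error(soxy_repertoire(rbind(hits, mk_hit("gX", "G1", "Y")),
                               calls, "G1"), "incomplete-input")
})

test_that("cohort repertoires agree with the generator truth table", {
  cohort <- fx_cohort()
  py <- fx_profile_y(); pz <- fx_profile_z()
  cal <- fx_cal_y(); cy <- fx_cal_y_local(); cz <- fx_cal_z_local()
  hit_list <- lapply(cohort$genomes, function(g) {
    search_proteome(py, g$proteins, cal, genome_id = g$genome_id)
  })
  hits <- do.call(rbind, hit_list)
  attr(hits, "traces") <- do.call(c, lapply(hit_list, attr, "traces"))
  hits <- quality_filter(hits)
  calls <- classify_hits(hits, py, pz, cy, cz, cohort$ref$canonical_soxy)
  reps <- do.call(rbind, lapply(cohort$genomes, function(g) {
    soxy_repertoire(hits, calls, g$genome_id)
  }))
  truth_counts <- table(factor(cohort$truth$genome_id,
                               levels = reps$genome_id))
  expect_equal(unname(reps$soxy_total), as.vector(truth_counts))
  for (sig in c("S1a", "S2", "S4")) {
    tc <- table(factor(
      cohort$truth$genome_id[cohort$truth$signature == sig],
      levels = reps$genome_id))
    expect_equal(unname(reps[[paste0("n_", sig)]]), as.vector(tc))
  }
  # repertoire conservation: signature counts sum to the filtered hits
  expect_equal(sum(reps$soxy_total), nrow(hits))
})

test_that("presence cutoffs dispatch on the 120-aa short-protein boundary", {
  cfg <- search_config()
  expect_equal(presence_cutoff(119, cfg), 1e-6)
  expect_equal(presence_cutoff(120, cfg), 1e-30)
  expect_equal(presence_cutoff(c(110, 500), cfg), c(1e-6, 1e-30))
})

test_that("sulfur presence detects planted homologs and rejects unplanted genes", {
  cohort <- fx_cohort()
  panel <- make_sulfur_panel()
  decoys <- unname(cohort$genomes[[1]]$proteins)
  cals <- calibrate_panel(panel, decoys, n_decoys = 1000, seed = 8)
  g <- cohort$genomes[[1]]
  row <- sulfur_presence(g$proteins, panel, cals, genome_id = g$genome_id)
  planted <- default_sulfur_set()
  for (nm in planted) expect_true(row[[nm]], label = nm)
  unplanted <- setdiff(panel$name, planted)
  for (nm in unplanted) expect_false(row[[nm]], label = nm)
  # relaxing the cutoff can only keep or add genes, never drop one
  cfg_relaxed <- search_config()
  cfg_relaxed$sulfur_evalue_cutoff <- 1e-10
  row2 <- sulfur_presence(g$proteins, panel, cals, cfg_relaxed,
                          genome_id = g$genome_id)
  for (nm in panel$name)
    expect_true(row2[[nm]] >= row[[nm]], label = nm)
  expect_error(sulfur_presence(g$proteins, panel[0, ], cals),
               "invalid-input")
})

test_that("the cohort matrix merges repertoires and presence stably and round-trips TSV", {
  reps <- rbind(
    data.frame(genome_id = "B", soxy_total = 2, n_S1a = 1, n_S1b = 0,
               n_S1c = 0, n_S2 = 1, n_S3 = 0, n_S4 = 0,
               n_unclassified = 0, n_fused = 1),
    data.frame(genome_id = "A", soxy_total = 1, n_S1a = 1, n_S1b = 0,
               n_S1c = 0, n_S2 = 0, n_S3 = 0, n_S4 = 0,
               n_unclassified = 0, n_fused = 0))
  pres <- data.frame(genome_id = c("A", "B"), sqr = c(TRUE, FALSE),
                     sqr_evalue = c(1e-40, 1))
  cm <- cohort_matrix(reps, pres)
  expect_identical(cm$genome_id, c("A", "B"))
  expect_identical(names(cm)[2], "soxy_total")
  expect_false("sqr_evalue" %in% names(cm))
  expect_equal(sum(cm$sqr), 1)  # column sums equal recounted prevalence
  path <- withr::local_tempfile(fileext = ".tsv")
  soxyprof:::write_tsv(cm, path)
  back <- soxyprof:::read_tsv(path)
  expect_equal(back$genome_id, cm$genome_id)
  expect_equal(back$soxy_total, cm$soxy_total)
  expect_equal(back$sqr, cm$sqr)
  expect_error(cohort_matrix(reps, pres[1, ]), "invalid-input")
})

test_that("the ecology association test gives the minimal p on perfect association", {
  n <- 50
  env <- rep(c("seagrass", "vent"), each = n / 2)
  cm <- data.frame(genome_id = sprintf("G%02d", 1:n),
                   soxy_total = 1, n_S1a = 1, n_S1b = 0, n_S1c = 0,
                   n_S2 = as.integer(env == "seagrass"), n_S3 = 0,
                   n_S4 = 0, n_unclassified = 0, n_fused = 0)
  md <- data.frame(genome_id = cm$genome_id, host_label = "h",
                   environment = env)
  res <- ecology_crosstab(cm, md, n_permutations = 999, seed = 13)
  expect_equal(res$p_value, 1 / 1000)
  expect_equal(sum(res$table), n)
  # single label is undefined
  md1 <- md; md1$environment <- "seagrass"
  expect_error(ecology_crosstab(cm, md1, 999, 1), "undefined-association")
})

test_that("permutation p-values are super-uniform under a shuffled-label null", {
  n <- 40
  set.seed(71)
  pvals <- vapply(1:200, function(b) {
    div <- rbinom(n, 1, 0.4)
    cm <- data.frame(genome_id = sprintf("G%02d", 1:n), soxy_total = 1,
                     n_S1a = 1, n_S1b = 0, n_S1c = 0, n_S2 = div,
                     n_S3 = 0, n_S4 = 0, n_unclassified = 0, n_fused = 0)
    md <- data.frame(genome_id = cm$genome_id, host_label = "h",
                     environment = sample(rep(c("a", "b"), n / 2)))
    ecology_crosstab(cm, md, n_permutations = 199, seed = 1000 + b)$p_value
  }, 0)
  for (alpha in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(pvals <= alpha), alpha + 0.07)
})
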