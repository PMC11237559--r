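test_that("profile emissions equal hand-computed log-odds on a toy alignment", {
  # two rows, uniform background, pseudocount 1
  msa <- c(a = "AC", b = "AG")
  p <- build_profile(msa, pseudocount = 1, cys_ref = 1, cys_pos = 2)
  bg <- 1 / 20
  # column 1: A twice -> p(A) = (2 + 0.05) / 3
  expect_equal(unname(p$emissions[1, "A"]), log2(((2 + bg) / 3) / bg))
  expect_equal(unname(p$emissions[1, "C"]), log2(((0 + bg) / 3) / bg))
  # column 2: C and G once each
  expect_equal(unname(p$emissions[2, "C"]), log2(((1 + bg) / 3) / bg))
  expect_equal(unname(p$emissions[2, "G"]), log2(((1 + bg) / 3) / bg))
  # per-column background-weighted expected log-odds is non-positive
  expect_true(all(rowSums(sweep(p$emissions, 2, rep(bg, 20), "*")) <=
                    1e-12))
})

test_that("columns dominated by gaps are dropped and the anchor tracks them", {
  msa <- c(a = "AC-D", b = "A--D", c = "AC-D", d = "A-CD", e = "ACCD")
  # column 3 has 60% gaps -> dropped; m decreases accordingly
  p <- build_profile(msa, cys_ref = "e", cys_pos = 4)
  expect_equal(p$m, 3)
  expect_equal(p$cys_anchor, 3)  # D column, tracked through the drop
  # identical sequences: each column's modal residue scores maximally
  p2 <- build_profile(c(x = "ACD", y = "ACD", z = "ACD"), cys_ref = "x",
                      cys_pos = 3)
  for (j in 1:3) {
    expect_equal(colnames(p2$emissions)[which.max(p2$emissions[j, ])],
                 c("A", "C", "D")[j])
    expect_gt(max(p2$emissions[j, ]), 0)
  }
  expect_error(build_profile(character(0)), "invalid-input")
})

test_that("global profile alignment matches exhaustive enumeration on small instances", {
  set.seed(101)
  for (case in 1:120) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    emis <- matrix(rnorm(m * 20, sd = 2), m, 20)
    codes <- sample(1:20, n, replace = TRUE)
    open <- runif(1, 1, 6); ext <- runif(1, 0.1, 1)
    got <- pssm_toy_score(emis, codes, open, ext)
    want <- enum_profile_global(emis, codes, open, ext)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("self-alignment of the consensus reaches the per-column maximum", {
  ref <- fx_ref()
  canon <- ref$canonical_soxy
  p <- build_profile(c(a = canon, b = canon, c = canon), cys_pos = 110)
  tr <- align_to_profile(p, canon)
  # the consensus dominates every column of its own profile
  expect_equal(tr$score, sum(apply(p$emissions, 1, max)), tolerance = 1e-6)
  expect_true(all(!is.na(tr$trace)))
  # a single residue against 150 columns: trace almost entirely deletions
  tr1 <- align_to_profile(fx_profile_y(), "A")
  expect_gte(sum(is.na(tr1$trace)), fx_profile_y()$m - 1)
  expect_lt(tr1$score, 0)
})

test_that("Gumbel fitting recovers known parameters and flags degeneracy", {
  set.seed(7)
  u <- runif(10000)
  mu <- 3; lambda <- 1.2
  scores <- mu - log(-log(u)) / lambda
  fit <- fit_gumbel(scores)
  expect_lt(abs(fit$mu - mu), 0.1)
  expect_lt(abs(fit$lambda - lambda), 0.05)
  expect_error(fit_gumbel(rep(2, 50)), "degenerate-calibration")
  expect_error(calibrate(fx_profile_y(), c(100, 150), n_decoys = 10),
               "invalid-parameter")
})

test_that("e-values are monotone in score, linear in database size, and invert the tail", {
  cal <- fx_cal_y()
  s <- seq(-30, 60, by = 1)
  e <- evalue(s, cal, 1000)
  expect_true(all(diff(e) <= 0))
  expect_lt(evalue(1e6, cal, 1000), 1e-300)
  # linearity in db size (small-e regime)
  e1 <- evalue(40, cal, 1000); e2 <- evalue(40, cal, 2000)
  expect_equal(e2 / e1, 2, tolerance = 1e-6)
  # inverse-function check: at the score whose decoy survival is
  # 1e-5 / db, the e-value is 1e-5
  db <- 5000
  target <- 1e-5 / db
  s_star <- cal$mu - log(-log(1 - target)) / cal$lambda
  expect_equal(evalue(s_star, cal, db), 1e-5, tolerance = 1e-6)
})

test_that("calibration round-trips through profile JSON serialization", {
  p <- fx_profile_y()
  path <- withr::local_tempfile(fileext = ".json")
  write_profile(p, path)
  p2 <- read_profile(path)
  expect_equal(p2$emissions, p$emissions)
  expect_equal(p2$cys_anchor, p$cys_anchor)
  s <- soxyprof:::random_protein(180)
  expect_equal(align_to_profile(p2, s)$score, align_to_profile(p, s)$score)
})

test_that("proteome search recovers planted copies and nothing from decoy-only proteomes", {
  cohort <- fx_cohort()
  p <- fx_profile_y(); cal <- fx_cal_y()
  hits <- do.call(rbind, lapply(cohort$genomes, function(g) {
    search_proteome(p, g$proteins, cal, genome_id = g$genome_id)
  }))
  truth <- cohort$truth
  idty <- vapply(truth$gene_id, function(id) {
    g <- cohort$genomes[[match(truth$genome_id[match(id, truth$gene_id)],
                               cohort$metadata$genome_id)]]
    global_identity(g$proteins[[id]], cohort$ref$canonical_soxy)$identity
  }, 0)
  recovered <- truth$gene_id %in% hits$protein_id
  expect_true(all(recovered[idty >= 40]))
  expect_true(all(recovered))  # report: at these settings even <40% recover
  # ordering: ascending e-value within the table
  one <- search_proteome(p, cohort$genomes[[1]]$proteins, cal,
                         genome_id = "g")
  expect_true(all(diff(one$evalue) >= 0))
  # decoy-only proteome yields nothing
  dec <- vapply(1:50, function(i) {
    shuffle_sequence(cohort$ref$canonical_soxy, i)
  }, "")
  names(dec) <- paste0("d", 1:50)
  expect_equal(nrow(search_proteome(p, dec, cal)), 0)
  expect_equal(nrow(search_proteome(p, character(0), cal)), 0)
})

test_that("quality filter applies the length, motif, and e-value rules", {
  cfg <- search_config()
  mk <- function(id, len, motif = TRUE, e = 1e-6) {
    seq <- strrep("A", len)
    if (motif) substr(seq, 50, 52) <- "GGC"
    data.frame(protein_id = id, genome_id = "g", length = len,
               score_bits = 10, evalue = e, env_start = 0L,
               env_end = len, sequence = seq, stringsAsFactors = FALSE)
  }
  hits <- rbind(mk("h1", 139), mk("h2", 100), mk("h3", 150, motif = FALSE),
                mk("h4", 150, e = 1e-3), mk("h5", 140), mk("h6", 200))
  out <- quality_filter(hits, cfg)
  expect_identical(out$protein_id, c("h5", "h6"))  # boundary 140 retained
  # order invariance with deduplication (both rules are per-sequence)
  hits2 <- rbind(hits, mk("h0", 200))  # duplicate sequence of h6, lower id
  a <- quality_filter(deduplicate(hits2)$unique, cfg)
  b <- deduplicate(quality_filter(hits2, cfg))$unique
  expect_equal(a[order(a$protein_id), ], b[order(b$protein_id), ],
               ignore_attr = TRUE)
})

test_that("deduplication collapses identical sequences to the smallest id and is idempotent", {
  mk <- function(id, seq) data.frame(protein_id = id, genome_id = "g",
                                     length = nchar(seq), score_bits = 1,
                                     evalue = 1e-9, env_start = 0L,
                                     env_end = nchar(seq), sequence = seq,
                                     stringsAsFactors = FALSE)
  hits <- rbind(mk("b", "AAA"), mk("a", "AAA"), mk("c", "CCC"),
                mk("d", "DDD"), mk("e", "EEE"))
  dd <- deduplicate(hits)
  expect_equal(nrow(dd$unique), 4)
  expect_true("a" %in% dd$unique$protein_id)
  expect_false("b" %in% dd$unique$protein_id)
  expect_equal(dd$multiplicity$n[dd$multiplicity$representative == "a"], 2)
  dd2 <- deduplicate(dd$unique)
  expect_identical(dd2$unique, dd$unique)
  # all distinct: identity operation
  distinct <- rbind(mk("x", "AC"), mk("y", "AD"))
  expect_equal(nrow(deduplicate(distinct)$unique), 2)
})

test_that("local search matches exhaustive enumeration and behaves on self/decoy pairs", {
  sub <- soxyprof:::blosum62_matrix()
  set.seed(202)
  for (case in 1:100) {
    n <- sample(1:4, 1); m <- sample(1:4, 1)
    a <- sample(1:20, n, replace = TRUE)
    b <- sample(1:20, m, replace = TRUE)
    open <- sample(3:11, 1); ext <- sample(1:2, 1)
    got <- sw_toy_score(a, b, sub, open, ext)
    want <- enum_pair_local(a, b, sub, open, ext)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # self alignment covers the full sequence with 100% identity score
  q <- soxyprof:::random_protein(60)
  self <- local_search(q, q)
  expect_equal(self$query_bounds, c(0L, 60L))
  codes <- soxyprof:::encode_seq(q)
  expect_equal(self$score, sum(sub[cbind(codes, codes)]))
  # query vs shuffled target is insignificant under calibration
  ref <- fx_ref()
  cal <- calibrate_local(ref$canonical_soxy,
                         vapply(1:20, function(i)
                           soxyprof:::random_protein(200), ""),
                         n_decoys = 1000, seed = 6)
  dec <- shuffle_sequence(ref$canonical_soxy, 99)
  ls <- local_search(ref$canonical_soxy, dec, cal = cal, db_size = 1)
  expect_gt(ls$evalue, 1e-3)
})
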