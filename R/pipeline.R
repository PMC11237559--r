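#' Default pipeline configuration
#'
#' All thresholds default to the study values where one exists: homolog
#' e-value cutoff 1e-5; sulfur-panel cutoffs 1e-30 and 1e-6 for panel
#' proteins under 120 aa; quality filter length 140 aa and "GGC" motif.
#'
#' @param seed integer seed used for every stochastic stage.
#' @param out_dir output directory (NULL = no files written).
#' @param n_genomes cohort size when simulating.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1, out_dir = NULL, n_genomes = 50) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(enabled = TRUE, n_genomes = n_genomes,
                    decoy_count = 60,
                    ecology_model = default_ecology_model()),
    inputs = list(proteome_files = NULL, gff_files = NULL,
                  metadata_file = NULL),
    search = c(search_config(),
               list(pseudocount = 1, gap_open = 4, gap_extend = 0.25,
                    n_decoys = 1000)),
    signature = list(table = default_signature_table(),
                     fusion_evalue_cutoff = 1e-5,
                     overlap_tolerance = 10L),
    tree = list(model = "p", bootstrap_replicates = 100L,
                min_sequences = 4L),
    neighborhood = list(k = 10L, operon_max_gap = 200L,
                        required = c("soxA", "soxB", "soxX", "soxY",
                                     "soxZ")),
    association = list(n_permutations = 999L)
  )
}

#' Validate a pipeline configuration
#'
#' Returns a character vector of violations (empty when valid), each
#' prefixed with the offending field path and carrying a hint at the
#' default value that restores the documented behaviour.
#'
#' @param config configuration list.
#' @return character vector of error messages (possibly empty).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  s <- config$search
  chk(is.numeric(s$soxy_evalue_cutoff) && s$soxy_evalue_cutoff > 0,
      "search$soxy_evalue_cutoff: must be > 0 (default 1e-5)")
  chk(is.numeric(s$sulfur_evalue_cutoff) && s$sulfur_evalue_cutoff > 0,
      "search$sulfur_evalue_cutoff: must be > 0 (default 1e-30)")
  chk(is.numeric(s$sulfur_short_evalue_cutoff) &&
        s$sulfur_short_evalue_cutoff > 0,
      "search$sulfur_short_evalue_cutoff: must be > 0 (default 1e-6)")
  chk(is.numeric(s$min_length) && s$min_length > 0,
      "search$min_length: must be > 0 (default 140)")
  chk(is.numeric(s$short_length_threshold) && s$short_length_threshold > 0,
      "search$short_length_threshold: must be > 0 (default 120)")
  chk(is.character(s$required_motif) && nchar(s$required_motif) > 0,
      "search$required_motif: must be a non-empty string (default 'GGC')")
  tab <- config$signature$table
  chk(is.data.frame(tab) && nrow(tab) > 0,
      "signature$table: must be a non-empty signature table (default default_signature_table())")
  if (is.data.frame(tab) && nrow(tab) > 0)
    chk(!anyDuplicated(tab$name),
        "signature$table: signature names must be unique")
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed: a single integer seed is required")
  chk(is.numeric(config$tree$bootstrap_replicates) &&
        config$tree$bootstrap_replicates >= 1,
      "tree$bootstrap_replicates: must be >= 1 (default 100)")
  chk(is.numeric(config$neighborhood$operon_max_gap) &&
        config$neighborhood$operon_max_gap > 0,
      "neighborhood$operon_max_gap: must be > 0 (default 200)")
  chk(is.numeric(config$association$n_permutations) &&
        config$association$n_permutations >= 99,
      "association$n_permutations: must be >= 99 (default 999)")
  if (!isTRUE(config$simulate$enabled)) {
    chk(length(config$inputs$proteome_files) > 0,
        "inputs$proteome_files: required when simulate is disabled")
  }
  errs
}

#' Run the full soxY profiling pipeline
#'
#' Stages: simulate (optional) -> profile build + calibration -> search ->
#' quality filter -> deduplicate -> signature/fusion classification ->
#' phylogeny (distances, NJ, bootstrap, clade assignment) -> repertoires and
#' sulfur presence -> neighborhoods and operon calls -> ecology association.
#' Tabular outputs, the Newick tree, the association JSON and a run manifest
#' (config echo, seed, file checksums) are written to `config$out_dir` when
#' set. Every stage logs its input/output record counts.
#'
#' @param config configuration list from [default_config()].
#' @param quiet suppress progress messages.
#' @return list of class `soxy_run` with elements `cohort`, `profile_y`,
#'   `profile_z`, `hits` (pre-filter), `filtered`, `dedup`, `calls`,
#'   `tree`, `bootstrap`, `clades`, `repertoires`, `presence`,
#'   `cohort_matrix`, `association`, `neighborhoods`, `operons`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  errs <- validate_config(config)
  if (length(errs) > 0)
    stop("config error:\n  ", paste(errs, collapse = "\n  "))
  say <- function(...) if (!quiet) message("[soxyprof] ", ...)
  seed <- config$seed
  cfg <- config$search

  # --- inputs ---------------------------------------------------------
  if (isTRUE(config$simulate$enabled)) {
    say("simulate: generating ", config$simulate$n_genomes, " genomes")
    cohort <- generate_cohort(config$simulate$n_genomes,
                              model = config$simulate$ecology_model,
                              seed = seed,
                              decoy_count = config$simulate$decoy_count)
  } else {
    say("load: reading ", length(config$inputs$proteome_files),
        " proteomes")
    cohort <- load_cohort(config$inputs)
  }
  ref <- cohort$ref
  if (is.null(ref)) ref <- build_reference_set(seed = child_seed(seed, 1))
  genomes <- cohort$genomes
  say("inputs: ", length(genomes), " genomes, ",
      sum(vapply(genomes, function(g) length(g$proteins), 0L)),
      " proteins")

  # --- profiles and calibration --------------------------------------
  profile_y <- build_profile(ref$seed_alignment,
                             pseudocount = cfg$pseudocount,
                             cys_pos = ref$cys_pos,
                             gap_open = cfg$gap_open,
                             gap_extend = cfg$gap_extend, name = "SoxY")
  profile_z <- build_profile(ref$soxz_seed_alignment,
                             pseudocount = cfg$pseudocount,
                             cys_ref = 1L, cys_pos = 50L,
                             gap_open = cfg$gap_open,
                             gap_extend = cfg$gap_extend, name = "SoxZ")
  decoy_lengths <- c(100, 150, 200, 250, 300)
  cal_y <- calibrate(profile_y, decoy_lengths, cfg$n_decoys,
                     seed = child_seed(seed, 11))
  cal_z <- calibrate(profile_z, decoy_lengths, cfg$n_decoys,
                     seed = child_seed(seed, 12))
  cal_y_local <- calibrate_profile_local(profile_y, decoy_lengths,
                                         cfg$n_decoys,
                                         seed = child_seed(seed, 13))
  cal_z_local <- calibrate_profile_local(profile_z, decoy_lengths,
                                         cfg$n_decoys,
                                         seed = child_seed(seed, 14))
  say("profiles: SoxY m=", profile_y$m, " (cys anchor ",
      profile_y$cys_anchor, "), SoxZ m=", profile_z$m)

  # --- search + filters ----------------------------------------------
  hit_list <- lapply(genomes, function(g) {
    search_proteome(profile_y, g$proteins, cal_y, cfg,
                    genome_id = g$genome_id)
  })
  hits <- do.call(rbind, lapply(hit_list, function(h) h))
  traces <- do.call(c, lapply(hit_list, function(h) attr(h, "traces")))
  attr(hits, "traces") <- traces
  rownames(hits) <- NULL
  say("search: ", nrow(hits), " hits at e <= ", cfg$soxy_evalue_cutoff)

  filtered <- quality_filter(hits, cfg)
  say("filter: ", nrow(filtered), " of ", nrow(hits), " hits retained")
  dd <- deduplicate(filtered)
  say("dedup: ", nrow(dd$unique), " unique sequences")

  # --- classification -------------------------------------------------
  calls <- classify_hits(filtered, profile_y, profile_z,
                         cal_y_local, cal_z_local, ref$canonical_soxy,
                         table = config$signature$table,
                         fusion_evalue_cutoff =
                           config$signature$fusion_evalue_cutoff,
                         overlap_tolerance =
                           config$signature$overlap_tolerance)
  say("classify: ", sum(calls$signature != "unclassified"), " classified, ",
      sum(calls$fused), " fusions")

  # --- phylogeny ------------------------------------------------------
  tree <- NULL; boot <- NULL; clades <- NULL; D <- NULL
  ex_seqs <- vapply(ref$signature_exemplars, function(e) e$sequence, "")
  names(ex_seqs) <- paste0("exemplar_", names(ref$signature_exemplars))
  tree_seqs <- c(stats::setNames(dd$unique$sequence, dd$unique$protein_id),
                 ex_seqs)
  if (length(tree_seqs) >= config$tree$min_sequences) {
    tree_traces <- c(attr(dd$unique, "traces"),
                     lapply(ex_seqs, function(s)
                       align_to_profile(profile_y, s)))
    names(tree_traces) <- names(tree_seqs)
    msa <- stack_alignments(tree_traces)
    D <- pairwise_distance(msa, config$tree$model)
    boot <- bootstrap_support(msa, config$tree$bootstrap_replicates,
                              seed = child_seed(seed, 21),
                              model = config$tree$model)
    tree <- boot$tree
    st <- config$signature$table
    exemplar_clades <- split(names(ex_seqs),
                             paste0("clade", st$clade[match(
                               sub("^exemplar_", "", names(ex_seqs)),
                               st$name)]))
    clades <- assign_clades(D, exemplar_clades, tree)
    say("tree: ", length(tree_seqs), " sequences, ",
        config$tree$bootstrap_replicates, " bootstrap replicates")
  } else {
    say("tree: skipped (fewer than ", config$tree$min_sequences,
        " sequences)")
  }

  # --- repertoires and sulfur presence -------------------------------
  panel <- make_sulfur_panel()
  pooled_decoys <- unlist(lapply(genomes[seq_len(min(3, length(genomes)))],
                                 function(g) unname(g$proteins)))
  panel_cals <- calibrate_panel(panel, pooled_decoys, cfg$n_decoys,
                                seed = child_seed(seed, 31))
  repertoires <- do.call(rbind, lapply(genomes, function(g) {
    soxy_repertoire(filtered, calls, g$genome_id,
                    signatures = config$signature$table$name)
  }))
  presence <- do.call(rbind, lapply(genomes, function(g) {
    sulfur_presence(g$proteins, panel, panel_cals, cfg,
                    genome_id = g$genome_id)
  }))
  cmat <- cohort_matrix(repertoires, presence)
  say("repertoires: ", nrow(cmat), " genomes, ",
      sum(repertoires$soxy_total), " soxY copies total")

  # --- neighborhoods --------------------------------------------------
  nbh_rows <- list(); op_rows <- list()
  for (g in genomes) {
    models <- gene_models(g$genes)
    ghits <- filtered[filtered$genome_id == g$genome_id, , drop = FALSE]
    if (nrow(ghits) == 0) next
    loci <- map_hits_to_genes(ghits, models)
    for (li in seq_len(nrow(loci))) {
      nmap <- categorize_neighborhood(
        extract_neighborhood(loci$protein_id[li], models,
                             k = config$neighborhood$k))
      op <- detect_operon(models, loci$protein_id[li],
                          required = config$neighborhood$required,
                          max_gap = config$neighborhood$operon_max_gap)
      nbh_rows[[length(nbh_rows) + 1L]] <- data.frame(
        genome_id = g$genome_id, locus = loci$protein_id[li],
        gene_id = nmap$genes$gene_id, offset = nmap$genes$offset,
        gene = nmap$genes$gene, category = nmap$genes$category,
        strand = nmap$genes$strand, stringsAsFactors = FALSE)
      op_rows[[length(op_rows) + 1L]] <- data.frame(
        genome_id = g$genome_id, locus = loci$protein_id[li],
        n_members = length(op$members), strand = op$strand,
        max_internal_gap = op$max_internal_gap,
        operon = op$verdict, stringsAsFactors = FALSE)
    }
  }
  neighborhoods <- if (length(nbh_rows)) do.call(rbind, nbh_rows) else NULL
  operons <- if (length(op_rows)) do.call(rbind, op_rows) else NULL
  say("neighborhoods: ", length(op_rows), " soxY loci mapped")

  # --- ecology association -------------------------------------------
  association <- tryCatch(
    ecology_crosstab(cmat, cohort$metadata,
                     n_permutations = config$association$n_permutations,
                     seed = child_seed(seed, 41)),
    error = function(e) {
      say("association: ", conditionMessage(e))
      NULL
    })
  if (!is.null(association))
    say("association: chi-square ", round(association$statistic, 2),
        ", p = ", association$p_value)

  result <- structure(list(
    cohort = cohort, profile_y = profile_y, profile_z = profile_z,
    hits = hits, filtered = filtered, dedup = dd, calls = calls,
    distances = D, tree = tree, bootstrap = boot, clades = clades,
    repertoires = repertoires, presence = presence, cohort_matrix = cmat,
    association = association, neighborhoods = neighborhoods,
    operons = operons, manifest = NULL), class = "soxy_run")

  if (!is.null(config$out_dir)) {
    result$manifest <- write_run_outputs(result, config)
    say("outputs written to ", config$out_dir)
  }
  result
}

# Read user-supplied proteomes/GFF3s/metadata into cohort form.
load_cohort <- function(inputs) {
  n <- length(inputs$proteome_files)
  if (n == 0) stop("missing-input: no proteome files")
  genomes <- vector("list", n)
  for (i in seq_len(n)) {
    faa <- inputs$proteome_files[i]
    if (!file.exists(faa)) stop("missing-input: ", faa)
    aa <- Biostrings::readAAStringSet(faa)
    proteins <- stats::setNames(as.character(aa),
                                sub("\\s.*$", "", names(aa)))
    gid <- sub("\\.(faa|fasta)$", "", basename(faa))
    genes <- NULL
    if (!is.null(inputs$gff_files) && !is.na(inputs$gff_files[i])) {
      models <- read_gene_models(inputs$gff_files[i])
      genes <- gene_models_gff(models)
    }
    genomes[[i]] <- structure(list(genome_id = gid, proteins = proteins,
                                   genes = genes, truth = NULL),
                              class = "soxy_genome")
  }
  metadata <- if (!is.null(inputs$metadata_file))
    read_tsv(inputs$metadata_file) else
      data.frame(genome_id = vapply(genomes, function(g) g$genome_id, ""),
                 host_label = NA_character_, environment = NA_character_,
                 stringsAsFactors = FALSE)
  structure(list(genomes = genomes, metadata = metadata, truth = NULL,
                 ref = NULL), class = "soxy_cohort")
}

# Write all tabular outputs plus the run manifest; returns the manifest.
write_run_outputs <- function(result, config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wt <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(out, name)
    write_tsv(df, p)
    paths <<- c(paths, p)
  }
  hits_out <- result$hits
  hits_out$passed_filters <- hits_out$protein_id %in%
    result$filtered$protein_id
  mult <- result$dedup$multiplicity
  rep_seq <- result$filtered$sequence[match(mult$representative,
                                            result$filtered$protein_id)]
  reps <- mult$representative[match(hits_out$sequence, rep_seq)]
  hits_out$dedup_rep <- ifelse(is.na(reps), "", reps)
  wt(hits_out[, setdiff(names(hits_out), "sequence")], "hits.tsv")
  wt(result$calls, "calls.tsv")
  wt(result$repertoires, "repertoire.tsv")
  wt(result$presence, "presence.tsv")
  wt(result$cohort_matrix, "cohort_matrix.tsv")
  wt(result$neighborhoods, "neighborhoods.tsv")
  wt(result$operons, "operons.tsv")
  if (!is.null(result$cohort$metadata))
    wt(result$cohort$metadata, "metadata.tsv")
  if (!is.null(result$cohort$truth)) wt(result$cohort$truth, "truth.tsv")
  if (!is.null(result$distances)) {
    dtab <- as.data.frame(result$distances)
    dtab <- cbind(id = rownames(result$distances), dtab)
    wt(dtab, "distances.tsv")
  }
  if (!is.null(result$tree)) {
    p <- file.path(out, "tree.nwk")
    writeLines(result$tree$newick, p)
    paths <- c(paths, p)
  }
  if (!is.null(result$bootstrap)) wt(result$bootstrap$support,
                                     "supports.tsv")
  if (!is.null(result$clades)) wt(result$clades$assignment, "clades.tsv")
  if (!is.null(result$association)) {
    p <- file.path(out, "association.json")
    jsonlite::write_json(list(
      statistic = result$association$statistic,
      p_value = result$association$p_value,
      n_permutations = result$association$n_permutations,
      table = as.data.frame(result$association$table),
      note = result$association$note), p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "soxyprof",
    version = as.character(utils::packageVersion("soxyprof")),
    seed = config$seed,
    n_genomes = length(result$cohort$genomes),
    config = config_echo(config),
    checksums = as.list(tools::md5sum(sort(paths))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  manifest
}

# Config echo with non-serialisable pieces flattened.
config_echo <- function(config) {
  e <- config
  e$simulate$ecology_model <- unclass(e$simulate$ecology_model)
  e$signature$table <- as.list(e$signature$table)
  e
}
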