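#' Default neighborhood layouts
#'
#' Ordered gene templates for the genomic contexts observed around soxY
#' loci. `sedimenticola_operon` places soxA/soxB/soxX/soxY/soxZ contiguous
#' on one strand with short gaps downstream of luxR/histidine-kinase
#' regulators; `thiodiazotropha_dispersed` splits the sox genes into three
#' clusters (soxB + regulators, soxAX, soxYZ) separated by spacer genes;
#' the divergent-signature layouts mirror the characteristic flanking genes
#' of each variant (DMSO reductase for S1c, alcohol dehydrogenase + soxH for
#' the S2 fusion, tetrathionate reductase for S3, formate/methanol
#' dehydrogenases for the S4 fusion).
#'
#' Each layout is a data.frame of gene tuples: `label`, `aa_len` (protein
#' length; NA for the focal soxY whose length depends on the planted copy),
#' `strand`, `gap` (bp to the next gene), `category`, `focal` (the soxY
#' slot), `product`.
#'
#' @return named list of layout data.frames.
#' @export
default_layouts <- function() {
  lay <- function(labels, lens, strands, gaps, cats, focal, products) {
    data.frame(label = labels, aa_len = lens, strand = strands, gap = gaps,
               category = cats, focal = focal, product = products,
               stringsAsFactors = FALSE)
  }
  list(
    sedimenticola_operon = lay(
      c("luxR", "hisK", "soxA", "soxB", "soxX", "soxY", "soxZ"),
      c(220, 300, 280, 550, 160, NA, 100),
      rep("+", 7),
      c(180, 120, 80, 60, 90, 70, 200),
      c("regulatory", "regulatory", "sulfur", "sulfur", "sulfur", "sulfur",
        "sulfur"),
      c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
      c("LuxR family transcriptional regulator", "histidine kinase",
        "sulfur oxidation c-type cytochrome SoxA",
        "sulfate thiohydrolase SoxB", "sulfur oxidation protein SoxX",
        "sulfur carrier protein SoxY", "sulfur carrier protein SoxZ")),
    thiodiazotropha_dispersed = lay(
      c("soxB", "luxR", "hisK", "spacer1", "spacer2", "soxA", "soxX",
        "spacer3", "spacer4", "soxY", "soxZ"),
      c(550, 220, 300, 250, 250, 280, 160, 250, 250, NA, 100),
      c("+", "+", "+", "+", "-", "+", "+", "-", "+", "+", "+"),
      c(150, 120, 4000, 300, 3500, 90, 5000, 280, 4000, 70, 200),
      c("sulfur", "regulatory", "regulatory", "other", "other", "sulfur",
        "sulfur", "other", "other", "sulfur", "sulfur"),
      c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
        TRUE, FALSE),
      c("sulfate thiohydrolase SoxB",
        "LuxR family transcriptional regulator", "histidine kinase",
        "hypothetical protein", "hypothetical protein",
        "sulfur oxidation c-type cytochrome SoxA",
        "sulfur oxidation protein SoxX", "hypothetical protein",
        "hypothetical protein", "sulfur carrier protein SoxY",
        "sulfur carrier protein SoxZ")),
    s1c_dms = lay(
      c("dmsA", "dmsB", "soxY", "yeeE", "dsrA", "dsrB"),
      c(750, 200, NA, 350, 420, 360),
      rep("+", 6),
      c(100, 140, 120, 90, 60, 200),
      c("sulfur", "sulfur", "sulfur", "sulfur", "sulfur", "sulfur"),
      c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
      c("dimethyl sulfoxide reductase subunit A",
        "dimethyl sulfoxide reductase subunit B",
        "sulfur carrier protein SoxY, divergent",
        "YeeE/YedE family thiosulfate transporter",
        "dissimilatory sulfite reductase subunit A",
        "dissimilatory sulfite reductase subunit B")),
    s2_adh = lay(
      c("adh", "adhAcc", "soxY", "soxH"),
      c(600, 180, NA, 300),
      rep("+", 4),
      c(110, 100, 130, 200),
      c("carbon", "carbon", "sulfur", "sulfur"),
      c(FALSE, FALSE, TRUE, FALSE),
      c("PQQ-dependent quinohemoprotein alcohol dehydrogenase ADH",
        "alcohol dehydrogenase accessory protein",
        "SoxYZ fusion sulfur carrier protein", "sulfur protein SoxH")),
    s3_otr = lay(
      c("otr", "soxY", "soxZ"),
      c(450, NA, 100),
      rep("+", 3),
      c(130, 80, 200),
      c("sulfur", "sulfur", "sulfur"),
      c(FALSE, TRUE, FALSE),
      c("octaheme tetrathionate reductase",
        "sulfur carrier protein SoxY, divergent",
        "sulfur carrier protein SoxZ")),
    s4_c1 = lay(
      c("fdhA", "fdhB", "soxY", "xoxF"),
      c(700, 250, NA, 580),
      rep("+", 4),
      c(90, 120, 140, 200),
      c("carbon", "carbon", "sulfur", "carbon"),
      c(FALSE, FALSE, TRUE, FALSE),
      c("formate dehydrogenase subunit alpha",
        "formate dehydrogenase subunit beta",
        "SoxYZ fusion sulfur carrier protein",
        "lanthanide-dependent methanol dehydrogenase XoxF"))
  )
}

# layout used by default for each signature
signature_default_layout <- function(sig) {
  switch(sig,
         S1a = "sedimenticola_operon", S1b = "thiodiazotropha_dispersed",
         S1c = "s1c_dms", S2 = "s2_adh", S3 = "s3_otr", S4 = "s4_c1",
         "thiodiazotropha_dispersed")
}

#' Specify a synthetic genome
#'
#' @param genome_id genome label.
#' @param copies data.frame with columns `signature`, `fused`, `layout`
#'   (layout name), one row per planted soxY copy (0--5 rows).
#' @param decoy_count number of decoy genes (length-matched shuffles).
#' @param ecology ecology/environment label.
#' @param host host label.
#' @param sulfur_genes names of sulfur-panel genes to plant as diverged
#'   homologs.
#' @return list of class `soxy_genome_spec`.
#' @export
genome_spec <- function(genome_id, copies, decoy_count = 60,
                        ecology = "seagrass", host = "Loripes",
                        sulfur_genes = default_sulfur_set()) {
  if (nrow(copies) > 5)
    stop("invalid-parameter: at most 5 planted copies per genome")
  structure(list(genome_id = genome_id, copies = copies,
                 decoy_count = decoy_count, ecology = ecology, host = host,
                 sulfur_genes = sulfur_genes),
            class = "soxy_genome_spec")
}

#' Default sulfur-gene complement planted in synthetic genomes
#' @return character vector of panel gene names.
#' @export
default_sulfur_set <- function() {
  c("sqr", "fccA", "fccB", "dsrA", "dsrB", "aprA", "aprB", "sat")
}

#' Synthetic sulfur-gene reference panel
#'
#' Deterministic synthetic reference proteins standing in for the classical
#' sulfur-oxidation markers (they are random sequences with realistic
#' lengths, not database proteins). `aprM` is deliberately shorter than 120
#' aa so the short-protein e-value rule is exercised.
#'
#' @param seed integer seed (default 7; the panel is a fixed reference, not
#'   per-run data).
#' @return data.frame `name`, `sequence`, `length`, `group`, `short`.
#' @export
make_sulfur_panel <- function(seed = 7) {
  def <- data.frame(
    name = c("sqr", "fccA", "fccB", "dsrA", "dsrB", "aprA", "aprB", "sat",
             "aprM", "qmoA", "qmoB", "hdrB", "hdrC"),
    length = c(430L, 250L, 420L, 420L, 360L, 650L, 150L, 400L,
               110L, 410L, 730L, 290L, 170L),
    group = c("sqr", "fccAB", "fccAB", "dsrAB", "dsrAB", "aprAB", "aprAB",
              "sat", "aprM", "qmoAB", "qmoAB", "hdrBC", "hdrBC"),
    stringsAsFactors = FALSE)
  seqs <- vapply(seq_len(nrow(def)), function(i) {
    with_seed(child_seed(seed, 500 + i), random_protein(def$length[i]))
  }, "")
  def$sequence <- seqs
  def$short <- def$length < 120L
  def[, c("name", "sequence", "length", "group", "short")]
}

# Build the protein for one planted soxY copy: a mutant of its signature
# exemplar (85-95% within-signature identity), fused copies get a diverged
# SoxZ tail so the ORF covers both domains.
planted_protein <- function(sig_name, fused, ref, seed) {
  def <- ref$signature_table[ref$signature_table$name == sig_name, ]
  if (nrow(def) == 0) stop("unknown signature: ", sig_name)
  ex <- ref$signature_exemplars[[sig_name]]$sequence
  idty <- with_seed(child_seed(seed, 1), runif(1, 85, 95))
  y <- plant_signature(ex, def, target_identity = idty,
                       seed = child_seed(seed, 2), cys_pos = ref$cys_pos)
  if (isTRUE(fused)) {
    z <- mutate_outside(ref$canonical_soxz, integer(0),
                        round(nchar(ref$canonical_soxz) * 0.12),
                        child_seed(seed, 3))
    paste0(y, z)
  } else {
    y
  }
}

#' Generate one synthetic genome with planted ground truth
#'
#' Lays out a single contig: planted soxY copies are embedded in their
#' layout's gene order (non-focal layout genes receive shuffled-decoy
#' protein sequences but informative product labels); sulfur-panel homologs
#' are planted as diverged copies (~75% identity); remaining genes are
#' length-matched shuffled decoys. Intergenic gaps outside layouts are drawn
#' uniformly from 20--400 bp; CDS coordinates are 1-based inclusive with
#' `3 * aa_len + 3` nucleotides per CDS (stop codon included).
#'
#' @param spec a [genome_spec()].
#' @param ref a [build_reference_set()] reference.
#' @param layouts named list of layouts (default [default_layouts()]).
#' @param seed integer seed.
#' @param panel sulfur panel (default [make_sulfur_panel()]).
#' @return list of class `soxy_genome`: `genome_id`, `proteins` (named
#'   character), `genes` (gene-model data.frame: `gene_id`, `contig`,
#'   `start`, `end` 1-based inclusive, `strand`, `gene`, `product`),
#'   `contig_length`, `truth` (TruthTable rows for planted copies).
#' @export
generate_genome <- function(spec, ref, layouts = default_layouts(),
                            seed = 1, panel = make_sulfur_panel()) {
  copies <- spec$copies
  if (!is.null(copies) && nrow(copies) > 0) {
    missing_layouts <- setdiff(copies$layout, names(layouts))
    if (length(missing_layouts) > 0)
      stop("invalid-parameter: unknown layout(s) ",
           paste(missing_layouts, collapse = ", "))
  }
  gid <- spec$genome_id
  blocks <- list()  # each block: data.frame(label, product, gene_label,
                    #   aa_len, strand, gap, seq, truth_sig, truth_fused,
                    #   layout_name)

  k <- 0L
  if (!is.null(copies)) for (r in seq_len(nrow(copies))) {
    k <- k + 1L
    lay <- layouts[[copies$layout[r]]]
    sig <- copies$signature[r]
    fused <- isTRUE(copies$fused[r])
    block <- lay
    block$seq <- NA_character_
    block$truth_sig <- NA_character_
    block$truth_fused <- NA
    block$layout_name <- copies$layout[r]
    for (g in seq_len(nrow(lay))) {
      if (lay$focal[g]) {
        block$seq[g] <- planted_protein(sig, fused, ref,
                                        child_seed(seed, 1000 + 10 * k))
        block$aa_len[g] <- nchar(block$seq[g])
        block$truth_sig[g] <- sig
        block$truth_fused[g] <- fused
        if (fused) block$product[g] <- "SoxYZ fusion sulfur carrier protein"
      } else if (lay$label[g] == "soxZ") {
        block$seq[g] <- mutate_outside(
          ref$canonical_soxz, integer(0),
          round(nchar(ref$canonical_soxz) * 0.15),
          child_seed(seed, 1000 + 10 * k + g))
        block$aa_len[g] <- nchar(block$seq[g])
      } else {
        # decoy body with the layout's label/product: shuffled composition
        base <- shuffle_sequence(
          paste(rep(ref$canonical_soxy,
                    ceiling(lay$aa_len[g] / nchar(ref$canonical_soxy))),
                collapse = ""),
          child_seed(seed, 2000 + 100 * k + g))
        block$seq[g] <- substr(base, 1, lay$aa_len[g])
      }
    }
    blocks[[length(blocks) + 1L]] <- block
  }

  # sulfur-panel homologs at ~75% identity
  for (sg in spec$sulfur_genes) {
    i <- match(sg, panel$name)
    if (is.na(i)) stop("invalid-model: unknown sulfur gene ", sg)
    hom <- mutate_outside(panel$sequence[i], integer(0),
                          round(panel$length[i] * 0.25),
                          child_seed(seed, 3000 + i))
    blocks[[length(blocks) + 1L]] <- data.frame(
      label = sg, aa_len = panel$length[i], strand = "+", gap = NA,
      category = "sulfur", focal = FALSE,
      product = paste("sulfur metabolism protein", sg),
      seq = hom, truth_sig = NA_character_, truth_fused = NA,
      layout_name = NA_character_, stringsAsFactors = FALSE)
  }

  # decoys: length-matched shuffles of the canonical reference
  decoys <- with_seed(child_seed(seed, 4000), {
    lens <- sample(80:400, spec$decoy_count, replace = TRUE)
    lapply(seq_along(lens), function(d) {
      base <- paste(rep(ref$canonical_soxy,
                        ceiling(lens[d] / nchar(ref$canonical_soxy))),
                    collapse = "")
      substr(shuffle_sequence(base, child_seed(seed, 4000 + d)), 1, lens[d])
    })
  })
  for (d in seq_along(decoys)) {
    blocks[[length(blocks) + 1L]] <- data.frame(
      label = paste0("decoy", d), aa_len = nchar(decoys[[d]]), strand = "+",
      gap = NA, category = "hypothetical", focal = FALSE,
      product = "hypothetical protein", seq = decoys[[d]],
      truth_sig = NA_character_, truth_fused = NA,
      layout_name = NA_character_, stringsAsFactors = FALSE)
  }

  # interleave: layout blocks stay contiguous; single-gene blocks are
  # shuffled around them
  ord <- with_seed(child_seed(seed, 5000), sample(length(blocks)))
  blocks <- blocks[ord]

  genes <- list()
  proteins <- character()
  truth <- list()
  pos <- 1L
  gene_n <- 0L
  rng_gaps <- with_seed(child_seed(seed, 6000),
                        sample(20:400, 5000, replace = TRUE))
  # separator gaps flanking multi-gene layout blocks exceed the operon
  # gap threshold so planted architectures never bridge into neighbours
  rng_seps <- with_seed(child_seed(seed, 6500),
                        sample(250:400, 5000, replace = TRUE))
  gap_i <- 0L
  sep_i <- 0L
  multi <- vapply(blocks, function(b) nrow(b) > 1, TRUE)
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    next_multi <- bi < length(blocks) && multi[bi + 1L]
    for (g in seq_len(nrow(b))) {
      gene_n <- gene_n + 1L
      gene_id <- sprintf("%s_g%03d", gid, gene_n)
      aa <- nchar(b$seq[g])
      width <- 3L * aa + 3L
      start <- pos
      end <- pos + width - 1L
      strand <- b$strand[g]
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gene_id, contig = paste0(gid, "_c1"),
        start = start, end = end, strand = strand,
        gene = b$label[g], product = b$product[g],
        stringsAsFactors = FALSE)
      proteins[gene_id] <- b$seq[g]
      if (!is.na(b$truth_sig[g])) {
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gene_id, genome_id = gid, signature = b$truth_sig[g],
          fused = b$truth_fused[g], contig = paste0(gid, "_c1"),
          start = start, end = end, strand = strand,
          layout = b$layout_name[g], stringsAsFactors = FALSE)
      }
      last_in_block <- g == nrow(b)
      gap <- b$gap[g]
      if (last_in_block && (multi[bi] || next_multi)) {
        sep_i <- sep_i + 1L
        gap <- rng_seps[sep_i]
      } else if (is.na(gap)) {
        gap_i <- gap_i + 1L
        gap <- rng_gaps[gap_i]
      }
      pos <- end + 1L + as.integer(gap)
    }
  }
  genes <- do.call(rbind, genes)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), genome_id = character(),
               signature = character(), fused = logical(),
               contig = character(), start = integer(), end = integer(),
               strand = character(), layout = character(),
               stringsAsFactors = FALSE)
  structure(list(genome_id = gid, proteins = proteins, genes = genes,
                 contig_length = pos + 200L, truth = truth,
                 ecology = spec$ecology, host = spec$host),
            class = "soxy_genome")
}

#' Default ecology model
#'
#' Environment labels with sampling probabilities and, per label, the
#' distribution over planted soxY repertoires. Specialist labels (vent,
#' mangrove, oxygen-minimum zone) receive only S1a/S1b repertoires; the
#' seagrass (generalist) label receives at least one divergent signature
#' (S1c/S2/S3/S4) with probability `p_divergent`. Divergent plantings
#' always accompany a canonical S1a copy, so divergent genomes carry at
#' least two soxY copies; total planted copies never exceed five.
#'
#' @param p_divergent probability a seagrass genome receives divergent
#'   signatures (default 0.9).
#' @return list of class `soxy_ecology_model`.
#' @export
default_ecology_model <- function(p_divergent = 0.9) {
  structure(list(
    labels = c("seagrass", "vent", "mangrove", "oxygen_minimum_zone"),
    probs = c(0.5, 0.2, 0.2, 0.1),
    hosts = list(seagrass = c("Loripes", "Codakia", "Ctena"),
                 vent = c("Bathymodiolus", "Riftia"),
                 mangrove = c("Anodontia", "Phacoides"),
                 oxygen_minimum_zone = c("Lucinoma")),
    p_divergent = p_divergent,
    specialist_repertoires = list(c("S1a"), c("S1a", "S1a"), c("S1b")),
    specialist_weights = c(0.6, 0.25, 0.15),
    divergent_pool = c("S1c", "S2", "S3", "S4")
  ), class = "soxy_ecology_model")
}

#' Generate a cohort of synthetic genomes with metadata and truth
#'
#' Samples an environment label per genome from the ecology model, a
#' repertoire per label, and generates each genome with
#' [generate_genome()]. Fusion flags follow the signature table (S2 and S4
#' are fused ORFs); layouts follow each signature's characteristic context.
#'
#' @param n_genomes number of genomes (>= 1).
#' @param model ecology model (see [default_ecology_model()]).
#' @param ref reference set (built from `seed` when NULL).
#' @param seed integer seed.
#' @param decoy_count decoy genes per genome.
#' @param layouts layout list.
#' @return list of class `soxy_cohort`: `genomes` (list of `soxy_genome`),
#'   `metadata` (data.frame `genome_id`, `host_label`, `environment`),
#'   `truth` (row-bound TruthTable), `ref`.
#' @export
generate_cohort <- function(n_genomes, model = default_ecology_model(),
                            ref = NULL, seed = 1, decoy_count = 60,
                            layouts = default_layouts()) {
  stopifnot(n_genomes >= 1)
  if (abs(sum(model$probs) - 1) > 1e-8)
    stop("invalid-model: label probabilities must sum to 1")
  if (is.null(ref)) ref <- build_reference_set(seed = child_seed(seed, 1))
  st <- ref$signature_table
  genomes <- vector("list", n_genomes)
  meta <- vector("list", n_genomes)
  for (i in seq_len(n_genomes)) {
    gid <- sprintf("G%03d", i)
    env <- with_seed(child_seed(seed, 7000 + i),
                     sample(model$labels, 1, prob = model$probs))
    if (!env %in% names(model$hosts)) stop("invalid-model: unknown label ", env)
    host <- with_seed(child_seed(seed, 7100 + i),
                      sample(model$hosts[[env]], 1))
    sigs <- with_seed(child_seed(seed, 7200 + i), {
      if (env == "seagrass" && runif(1) < model$p_divergent) {
        nd <- sample(1:4, 1)
        c("S1a", sample(model$divergent_pool, nd))
      } else {
        idx <- sample(length(model$specialist_repertoires), 1,
                      prob = model$specialist_weights)
        model$specialist_repertoires[[idx]]
      }
    })
    copies <- data.frame(
      signature = sigs,
      fused = st$fused[match(sigs, st$name)],
      layout = vapply(sigs, signature_default_layout, ""),
      stringsAsFactors = FALSE)
    spec <- genome_spec(gid, copies, decoy_count = decoy_count,
                        ecology = env, host = host)
    genomes[[i]] <- generate_genome(spec, ref, layouts,
                                    seed = child_seed(seed, 8000 + i))
    meta[[i]] <- data.frame(genome_id = gid, host_label = host,
                            environment = env, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, lapply(genomes, function(g) g$truth))
  structure(list(genomes = genomes, metadata = do.call(rbind, meta),
                 truth = truth, ref = ref),
            class = "soxy_cohort")
}

#' Write a synthetic genome's FASTA and GFF3 files
#'
#' One protein FASTA record per CDS (id = gene id) and a GFF3 of CDS
#' features (1-based inclusive coordinates; attributes `ID`, `gene`,
#' `product`).
#'
#' @param genome a `soxy_genome`.
#' @param dir output directory (created if needed).
#' @return invisible character vector of the two paths.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  faa <- file.path(dir, paste0(genome$genome_id, ".faa"))
  gff <- file.path(dir, paste0(genome$genome_id, ".gff3"))
  aa <- Biostrings::AAStringSet(genome$proteins)
  Biostrings::writeXStringSet(aa, faa)
  gr <- GenomicRanges::GRanges(
    seqnames = genome$genes$contig,
    ranges = IRanges::IRanges(start = genome$genes$start,
                              end = genome$genes$end),
    strand = genome$genes$strand,
    type = "CDS",
    phase = 0L,
    source = "soxyprof",
    ID = genome$genes$gene_id,
    gene = genome$genes$gene,
    product = genome$genes$product)
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(faa = faa, gff = gff))
}
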