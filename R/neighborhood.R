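#' Read gene models from a GFF3 file
#'
#' Imports CDS features (1-based inclusive on disk) and converts to the
#' package's internal 0-based half-open coordinates.
#'
#' @param path GFF3 file with `ID`, `gene` and `product` attributes.
#' @return data.frame `gene_id`, `contig`, `start0`, `end0` (0-based
#'   half-open), `strand`, `gene`, `product`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  mc <- S4Vectors::mcols(gr)
  get_col <- function(nm) {
    if (nm %in% names(mc)) as.character(mc[[nm]]) else
      rep(NA_character_, length(gr))
  }
  gene_models(data.frame(
    gene_id = get_col("ID"),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene = get_col("gene"),
    product = get_col("product"),
    stringsAsFactors = FALSE))
}

#' Build internal gene models from a 1-based inclusive table
#'
#' @param genes data.frame with `gene_id`, `contig`, `start`, `end`
#'   (1-based inclusive), `strand`, `gene`, `product`.
#' @return gene-model data.frame with 0-based half-open `start0`, `end0`.
#' @export
gene_models <- function(genes) {
  stopifnot(all(genes$start <= genes$end),
            all(genes$strand %in% c("+", "-")))
  out <- data.frame(gene_id = genes$gene_id, contig = genes$contig,
                    start0 = genes$start - 1L, end0 = genes$end,
                    strand = genes$strand, gene = genes$gene,
                    product = genes$product, stringsAsFactors = FALSE)
  out[order(out$contig, out$start0, method = "radix"), , drop = FALSE]
}

#' Convert internal gene models back to 1-based inclusive coordinates
#' @param models gene-model data.frame.
#' @return data.frame with `start`, `end` 1-based inclusive.
#' @export
gene_models_gff <- function(models) {
  data.frame(gene_id = models$gene_id, contig = models$contig,
             start = models$start0 + 1L, end = models$end0,
             strand = models$strand, gene = models$gene,
             product = models$product, stringsAsFactors = FALSE)
}

#' Attach homolog hits to gene models
#'
#' @param hits hit data.frame (protein ids must match gene ids).
#' @param models gene-model data.frame.
#' @return data.frame of matched loci (hit columns + model columns);
#'   unmatched protein ids reported in the `"unmatched"` attribute.
#' @export
map_hits_to_genes <- function(hits, models) {
  if (anyDuplicated(models$gene_id))
    stop("invalid-annotation: duplicate gene ids")
  idx <- match(hits$protein_id, models$gene_id)
  unmatched <- hits$protein_id[is.na(idx)]
  ok <- !is.na(idx)
  out <- cbind(hits[ok, c("protein_id", "genome_id", "evalue"),
                    drop = FALSE],
               models[idx[ok], c("contig", "start0", "end0", "strand",
                                 "gene", "product"), drop = FALSE])
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  out
}

#' Extract the gene neighborhood around a focal locus
#'
#' Up to `k` genes upstream and `k` downstream on the focal contig, in
#' genome order; truncation at a contig edge is flagged.
#'
#' @param locus_id focal gene id.
#' @param models gene-model data.frame.
#' @param k neighborhood radius in genes (>= 1; default 10).
#' @return list of class `soxy_neighborhood`: `focal`, `genes` (ordered
#'   model rows with `offset` relative to the focal gene), `truncated_up`,
#'   `truncated_down`.
#' @export
extract_neighborhood <- function(locus_id, models, k = 10L) {
  stopifnot(k >= 1)
  i <- match(locus_id, models$gene_id)
  if (is.na(i)) stop("invalid-input: locus ", locus_id, " not in models")
  contig <- models$contig[i]
  on_contig <- models[models$contig == contig, , drop = FALSE]
  on_contig <- on_contig[order(on_contig$start0, method = "radix"), ,
                         drop = FALSE]
  f <- match(locus_id, on_contig$gene_id)
  lo <- max(1L, f - k); hi <- min(nrow(on_contig), f + k)
  genes <- on_contig[lo:hi, , drop = FALSE]
  genes$offset <- seq(lo - f, hi - f)
  rownames(genes) <- NULL
  structure(list(focal = locus_id, genes = genes,
                 truncated_up = (f - lo) < k,
                 truncated_down = (hi - f) < k),
            class = "soxy_neighborhood")
}

#' Default product-keyword category map
#'
#' Case-insensitive keyword patterns matched against the product label, in
#' order (first match wins): sulfur-metabolism genes, carbon-metabolism
#' genes, transcriptional regulators, known multifunctional genes, then
#' hypothetical/unmatched.
#'
#' @return data.frame `pattern`, `category`.
#' @export
default_category_map <- function() {
  data.frame(
    pattern = c("dms", "dimethyl sulfoxide", "yeee", "dsr", "soxh", "sox",
                "sulfur", "sqr", "tetrathionate", "thiosulfate",
                "adh", "alcohol dehydrogenase", "fdh",
                "formate dehydrogenase", "xoxf", "methanol dehydrogenase",
                "luxr", "histidine kinase", "sigma-54",
                "rhd", "rhodanese",
                "hypothetical"),
    category = c(rep("sulfur", 10), rep("carbon", 6), rep("regulatory", 3),
                 rep("other", 2), "hypothetical"),
    stringsAsFactors = FALSE)
}

#' Categorize neighborhood genes by product keyword
#'
#' @param nmap a `soxy_neighborhood`.
#' @param category_map keyword table (see [default_category_map()]).
#' @return the neighborhood with a `category` column added to its genes.
#' @export
categorize_neighborhood <- function(nmap,
                                    category_map = default_category_map()) {
  if (nrow(category_map) == 0) stop("invalid-input: empty category map")
  nmap$genes$category <- vapply(nmap$genes$product, function(p) {
    if (is.na(p)) return("hypothetical")
    pl <- tolower(p)
    for (r in seq_len(nrow(category_map))) {
      if (grepl(category_map$pattern[r], pl, fixed = TRUE))
        return(category_map$category[r])
    }
    "hypothetical"
  }, "", USE.NAMES = FALSE)
  nmap
}

#' Detect operon-like organisation around a locus
#'
#' Grows the maximal run of consecutive same-strand genes around the focal
#' locus with every intergenic gap at most `max_gap` bp; the verdict is true
#' iff the required gene labels are all inside the run.
#'
#' @param models gene-model data.frame.
#' @param locus_id focal gene id.
#' @param required gene labels that must be inside the run (default the
#'   five sox structural genes).
#' @param max_gap maximum intergenic gap in bp (default 200).
#' @return list of class `soxy_operon`: `members` (gene ids in genome
#'   order), `strand`, `max_internal_gap`, `required_satisfied`, `verdict`.
#' @export
detect_operon <- function(models, locus_id,
                          required = c("soxA", "soxB", "soxX", "soxY",
                                       "soxZ"),
                          max_gap = 200L) {
  stopifnot(max_gap > 0)
  i <- match(locus_id, models$gene_id)
  if (is.na(i)) stop("invalid-input: locus ", locus_id, " not in models")
  contig <- models$contig[i]
  oc <- models[models$contig == contig, , drop = FALSE]
  oc <- oc[order(oc$start0, method = "radix"), , drop = FALSE]
  f <- match(locus_id, oc$gene_id)
  strand <- oc$strand[f]
  lo <- f
  while (lo > 1 && oc$strand[lo - 1] == strand &&
         (oc$start0[lo] - oc$end0[lo - 1]) <= max_gap) lo <- lo - 1
  hi <- f
  while (hi < nrow(oc) && oc$strand[hi + 1] == strand &&
         (oc$start0[hi + 1] - oc$end0[hi]) <= max_gap) hi <- hi + 1
  run <- oc[lo:hi, , drop = FALSE]
  gaps <- if (nrow(run) > 1)
    run$start0[-1] - run$end0[-nrow(run)] else integer(0)
  satisfied <- all(required %in% run$gene)
  structure(list(members = run$gene_id, strand = strand,
                 max_internal_gap = if (length(gaps)) max(gaps) else 0L,
                 required_satisfied = satisfied,
                 verdict = satisfied),
            class = "soxy_operon")
}

# longest common subsequence length of two character vectors
lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0L)
  prev <- integer(m + 1)
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    for (j in seq_len(m)) {
      cur[j + 1] <- if (a[i] == b[j]) prev[j] + 1L
        else max(prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[m + 1]
}

#' Synteny conservation score between two categorized neighborhoods
#'
#' Length of the longest common subsequence of category labels, after
#' normalising the two neighborhoods to the same focal-gene orientation,
#' divided by the longer neighborhood's length. Scores lie in \[0, 1\].
#'
#' @param a,b categorized `soxy_neighborhood`s.
#' @return numeric score.
#' @export
compare_synteny <- function(a, b) {
  if (is.null(a$genes$category) || is.null(b$genes$category))
    stop("invalid-input: neighborhoods must be categorized first")
  ca <- a$genes$category
  cb <- b$genes$category
  sa <- a$genes$strand[a$genes$offset == 0]
  sb <- b$genes$strand[b$genes$offset == 0]
  if (length(sa) == 1 && length(sb) == 1 && sa != sb) cb <- rev(cb)
  lcs_length(ca, cb) / max(length(ca), length(cb))
}
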