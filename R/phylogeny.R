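#' Stack profile alignment traces into a fixed-width alignment
#'
#' Residues are mapped to the profile's match columns; insertions relative
#' to the profile are discarded and deletions appear as gaps, so every row
#' has exactly `m` columns (automated trimming in profile coordinates).
#'
#' @param traces named list of `soxy_trace` objects against one profile.
#' @return character matrix (rows = sequence ids, columns = profile match
#'   columns, `-` for gaps).
#' @export
stack_alignments <- function(traces) {
  if (length(traces) == 0) stop("invalid-input: no traces")
  m <- unique(vapply(traces, function(t) t$m, 0L))
  pn <- unique(vapply(traces, function(t) t$profile_name, ""))
  if (length(m) != 1 || length(pn) != 1)
    stop("invalid-input: traces come from different profiles")
  ids <- names(traces)
  if (is.null(ids) || anyDuplicated(ids))
    stop("invalid-input: traces must have unique names")
  mat <- matrix("-", length(traces), m, dimnames = list(ids, NULL))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    chars <- strsplit(tr$seq, "", fixed = TRUE)[[1]]
    ok <- !is.na(tr$trace)
    mat[i, ok] <- chars[tr$trace[ok]]
  }
  mat
}

#' Pairwise distances from a stacked alignment
#'
#' p-distance with pairwise deletion (mismatches over columns where both
#' rows are non-gap), optionally Poisson-corrected (`d = -ln(1 - p)`).
#'
#' @param msa character matrix from [stack_alignments()].
#' @param model `"p"` or `"poisson"`.
#' @return symmetric distance matrix with zero diagonal; attribute `model`.
#' @export
pairwise_distance <- function(msa, model = c("p", "poisson")) {
  model <- match.arg(model)
  n <- nrow(msa)
  if (n < 2) stop("invalid-input: need at least 2 rows")
  ids <- rownames(msa)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  gap <- msa == "-"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !gap[i, ] & !gap[j, ]
      ns <- sum(shared)
      if (ns == 0)
        stop("incomparable-pair: no shared columns between ", ids[i],
             " and ", ids[j])
      p <- sum(msa[i, shared] != msa[j, shared]) / ns
      d <- if (model == "poisson") {
        if (p >= 1)
          stop("incomparable-pair: p-distance >= 1 under poisson model (",
               ids[i], ", ", ids[j], ")")
        -log(1 - p)
      } else p
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "model") <- model
  D
}

fmt_branch <- function(x) sprintf("%.6g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion. Ties in Q
#' are broken by the smallest (i, j) index pair in the current matrix order;
#' negative branch lengths are clamped to zero. The result is an unrooted
#' tree with a trifurcating root, serialized to Newick with 6-significant-
#' digit branch lengths.
#'
#' @param D symmetric distance matrix with labelled rows (n >= 3).
#' @return object of class `soxy_tree`: list `newick`, `phylo`
#'   (`ape::phylo`), `tip_labels`.
#' @export
neighbor_joining <- function(D) {
  n <- nrow(D)
  if (is.null(n) || n < 3) stop("invalid-input: need at least 3 taxa")
  labels <- rownames(D)
  nodes <- labels           # newick fragment per active node
  act <- D
  while (nrow(act) > 3) {
    nn <- nrow(act)
    r <- rowSums(act)
    Q <- (nn - 2) * act - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest (i, j) pair among the Q minima (deterministic tie rule)
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    dij <- act[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (nn - 2))
    lj <- dij - li
    li <- max(0, li); lj <- max(0, lj)
    newfrag <- paste0("(", nodes[i], ":", fmt_branch(li), ",",
                      nodes[j], ":", fmt_branch(lj), ")")
    dk <- (act[i, ] + act[j, ] - dij) / 2
    keep <- setdiff(seq_len(nn), c(i, j))
    new_act <- rbind(cbind(act[keep, keep, drop = FALSE], dk[keep]),
                     c(dk[keep], 0))
    nodes <- c(nodes[keep], newfrag)
    act <- new_act
  }
  d12 <- act[1, 2]; d13 <- act[1, 3]; d23 <- act[2, 3]
  l1 <- max(0, (d12 + d13 - d23) / 2)
  l2 <- max(0, (d12 + d23 - d13) / 2)
  l3 <- max(0, (d13 + d23 - d12) / 2)
  newick <- paste0("(", nodes[1], ":", fmt_branch(l1), ",",
                   nodes[2], ":", fmt_branch(l2), ",",
                   nodes[3], ":", fmt_branch(l3), ");")
  phylo <- ape::read.tree(text = newick)
  structure(list(newick = newick, phylo = phylo, tip_labels = labels),
            class = "soxy_tree")
}

#' Serialize a phylogenetic tree to Newick
#'
#' The package's canonical Newick dialect: unrooted trifurcating root,
#' branch lengths with 6 significant digits, internal node labels (e.g.
#' bootstrap supports) preserved. Deterministic, so write-read-write
#' round-trips are byte-identical.
#'
#' @param tree a `soxy_tree` or `ape::phylo`.
#' @return single Newick string.
#' @export
write_newick <- function(tree) {
  ph <- if (inherits(tree, "soxy_tree")) tree$phylo else tree
  ntip <- length(ph$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(ph$edge)), ph$edge[, 1])
  rec <- function(node, edge_idx) {
    bl <- if (is.null(edge_idx)) NULL else ph$edge.length[edge_idx]
    if (node <= ntip) {
      paste0(ph$tip.label[node],
             if (!is.null(bl)) paste0(":", fmt_branch(bl)) else "")
    } else {
      ch <- kids[[as.character(node)]]
      inner <- paste(vapply(ch, function(e) rec(ph$edge[e, 2], e), ""),
                     collapse = ",")
      lab <- if (!is.null(ph$node.label)) {
        nl <- ph$node.label[node - ntip]
        if (is.na(nl) || nl == "") "" else nl
      } else ""
      paste0("(", inner, ")", lab,
             if (!is.null(bl)) paste0(":", fmt_branch(bl)) else "")
    }
  }
  paste0(rec(root, NULL), ";")
}

# Canonical bipartition keys for every internal edge of an unrooted tree:
# the tip-set on the far side of the edge, flipped to the side NOT holding
# the overall-first tip, sorted and comma-joined.
tree_bipartitions <- function(phylo) {
  ntip <- length(phylo$tip.label)
  all_tips <- sort(phylo$tip.label)
  anchor <- all_tips[1]
  pp <- ape::prop.part(phylo)
  labs <- attr(pp, "labels")
  keys <- character(0)
  for (k in seq_along(pp)) {
    tips <- sort(labs[pp[[k]]])
    if (length(tips) == ntip || length(tips) <= 1) next
    if (anchor %in% tips) tips <- setdiff(all_tips, tips)
    if (length(tips) <= 1 || length(tips) >= ntip - 1) next
    keys <- c(keys, paste(tips, collapse = ","))
  }
  unique(keys)
}

bipartition_key <- function(tips, all_tips) {
  all_tips <- sort(all_tips)
  tips <- sort(tips)
  if (all_tips[1] %in% tips) tips <- setdiff(all_tips, tips)
  paste(tips, collapse = ",")
}

#' Bootstrap support by column resampling
#'
#' Resamples alignment columns with replacement, recomputes distances and
#' the NJ tree per replicate, and reports each base-tree internal
#' bipartition's frequency among replicates.
#'
#' @param msa stacked alignment matrix.
#' @param replicates number of bootstrap replicates (>= 1; default 100).
#' @param seed integer seed.
#' @param model distance model.
#' @return list of class `soxy_bootstrap`: `tree` (base `soxy_tree`),
#'   `support` (data.frame `bipartition`, `support`), `replicates`.
#' @export
bootstrap_support <- function(msa, replicates = 100, seed = 1,
                              model = "p") {
  stopifnot(replicates >= 1)
  base_tree <- neighbor_joining(pairwise_distance(msa, model))
  base_bip <- tree_bipartitions(base_tree$phylo)
  counts <- stats::setNames(numeric(length(base_bip)), base_bip)
  m <- ncol(msa)
  cols <- with_seed(seed, matrix(sample.int(m, m * replicates,
                                            replace = TRUE),
                                 nrow = replicates))
  for (b in seq_len(replicates)) {
    rep_msa <- msa[, cols[b, ], drop = FALSE]
    rep_tree <- tryCatch(
      neighbor_joining(pairwise_distance(rep_msa, model)),
      error = function(e) NULL)
    if (is.null(rep_tree)) next
    rb <- tree_bipartitions(rep_tree$phylo)
    hit <- base_bip %in% rb
    counts[hit] <- counts[hit] + 1
  }
  support <- data.frame(bipartition = base_bip,
                        support = unname(counts) / replicates,
                        stringsAsFactors = FALSE)
  structure(list(tree = base_tree, support = support,
                 replicates = replicates),
            class = "soxy_bootstrap")
}

#' Assign sequences to clades by exemplar distance
#'
#' Each id is assigned to the clade of its minimum mean distance to that
#' clade's exemplar set (ties go to the lowest clade number). If a tree is
#' supplied, each clade's monophyly (its assigned tip set forming a
#' bipartition of the tree) is evaluated.
#'
#' @param D distance matrix covering ids and exemplars.
#' @param exemplars named list: clade label -> character vector of exemplar
#'   ids present in `D`.
#' @param tree optional `soxy_tree` over the same ids.
#' @return list of class `soxy_clades`: `assignment` (data.frame `id`,
#'   `clade`), `monophyletic` (named logical per clade, NA without tree).
#' @export
assign_clades <- function(D, exemplars, tree = NULL) {
  if (length(exemplars) == 0) stop("invalid-input: no exemplars")
  miss <- setdiff(unlist(exemplars), rownames(D))
  if (length(miss) > 0)
    stop("invalid-input: exemplar(s) missing from distance matrix: ",
         paste(miss, collapse = ", "))
  clades <- names(exemplars)
  ord <- order(clades, method = "radix")
  clades <- clades[ord]
  ids <- rownames(D)
  mean_d <- vapply(clades, function(cl) {
    rowMeans(D[, exemplars[[cl]], drop = FALSE])
  }, numeric(length(ids)))
  assigned <- clades[apply(mean_d, 1, which.min)]  # which.min: first = lowest
  assignment <- data.frame(id = ids, clade = assigned,
                           stringsAsFactors = FALSE)
  mono <- stats::setNames(rep(NA, length(clades)), clades)
  if (!is.null(tree)) {
    ph <- if (inherits(tree, "soxy_tree")) tree$phylo else tree
    bips <- tree_bipartitions(ph)
    tips <- ph$tip.label
    for (cl in clades) {
      members <- intersect(assignment$id[assignment$clade == cl], tips)
      if (length(members) == 0) { mono[cl] <- NA; next }
      if (length(members) <= 1 || length(members) >= length(tips) - 1) {
        mono[cl] <- TRUE; next   # trivial splits are always present
      }
      mono[cl] <- bipartition_key(members, tips) %in% bips
    }
  }
  structure(list(assignment = assignment, monophyletic = mono),
            class = "soxy_clades")
}
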