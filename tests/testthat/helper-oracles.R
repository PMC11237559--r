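# Independent brute-force oracles used against the dynamic-programming
# implementations. They enumerate alignment paths explicitly (no shared
# recurrences with the package code). Gap cost model throughout:
# a run of k gaps costs open + (k - 1) * extend; I<->D transitions
# disallowed.

# Best global score of aligning codes (residues) to the columns of an
# emissions matrix, by recursive enumeration of move sequences.
enum_profile_global <- function(emis, codes, open, ext) {
  n <- length(codes); m <- nrow(emis)
  rec <- function(i, j, last) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {  # match
      s <- emis[j + 1, codes[i + 1]] + rec(i + 1, j + 1, "M")
      if (s > best) best <- s
    }
    if (i < n && last != "D") {  # insertion (consume residue)
      pen <- if (last == "I") ext else open
      s <- -pen + rec(i + 1, j, "I")
      if (s > best) best <- s
    }
    if (j < m && last != "I") {  # deletion (consume column)
      pen <- if (last == "D") ext else open
      s <- -pen + rec(i, j + 1, "D")
      if (s > best) best <- s
    }
    best
  }
  rec(0, 0, "M")
}

# Best global score of aligning two residue-code vectors under a
# substitution matrix (terminal gaps penalised).
enum_pair_global <- function(a, b, sub, open, ext) {
  n <- length(a); m <- length(b)
  rec <- function(i, j, last) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      s <- sub[a[i + 1], b[j + 1]] + rec(i + 1, j + 1, "M")
      if (s > best) best <- s
    }
    if (i < n && last != "D") {
      pen <- if (last == "I") ext else open
      s <- -pen + rec(i + 1, j, "I")
      if (s > best) best <- s
    }
    if (j < m && last != "I") {
      pen <- if (last == "D") ext else open
      s <- -pen + rec(i, j + 1, "D")
      if (s > best) best <- s
    }
    best
  }
  rec(0, 0, "M")
}

# Best local score: maximum over all substring pairs of their global
# alignment score, floored at 0 (empty alignment).
enum_pair_local <- function(a, b, sub, open, ext) {
  n <- length(a); m <- length(b)
  best <- 0
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      s <- enum_pair_global(a[i1:i2], b[j1:j2], sub, open, ext)
      if (s > best) best <- s
    }
  }
  best
}

# Best local profile score: maximum over substring x column-window pairs.
enum_profile_local <- function(emis, codes, open, ext) {
  n <- length(codes); m <- nrow(emis)
  best <- 0
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      s <- enum_profile_global(emis[j1:j2, , drop = FALSE], codes[i1:i2],
                               open, ext)
      if (s > best) best <- s
    }
  }
  best
}

# Thin wrappers over the package's DP kernels for toy inputs.
pssm_toy_score <- function(emis, codes, open, ext) {
  soxyprof:::pssm_align_global_cpp(cbind(emis, 0), as.integer(codes),
                                   open, ext)$score
}

pssm_toy_local <- function(emis, codes, open, ext) {
  soxyprof:::pssm_align_local_cpp(cbind(emis, 0), as.integer(codes),
                                  open, ext)$score
}

sw_toy_score <- function(a, b, sub, open, ext) {
  soxyprof:::sw_align_cpp(as.integer(a), as.integer(b), sub, open,
                          ext)$score
}

# Hand-count identity between equal-length sequences (no-gap oracle).
hand_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  100 * sum(ca == cb) / length(ca)
}

# Least-squares branch fit of a distance matrix on a fixed topology;
# returns the residual sum of squares (0 for the generating topology of an
# additive matrix).
ls_tree_rss <- function(phylo, D) {
  tips <- phylo$tip.label
  n <- length(tips)
  pairs <- t(combn(n, 2))
  nedge <- nrow(phylo$edge)
  # path indicator matrix via node paths from each tip to the root
  paths <- lapply(seq_len(n), function(t) {
    p <- integer(0); node <- t
    while (TRUE) {
      e <- which(phylo$edge[, 2] == node)
      if (length(e) == 0) break
      p <- c(p, e); node <- phylo$edge[e, 1]
    }
    p
  })
  X <- matrix(0, nrow(pairs), nedge)
  d <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    onpath <- union(setdiff(paths[[i]], paths[[j]]),
                    setdiff(paths[[j]], paths[[i]]))
    X[r, onpath] <- 1
    d[r] <- D[tips[i], tips[j]]
  }
  fit <- stats::lm.fit(X, d)
  sum(fit$residuals^2)
}
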