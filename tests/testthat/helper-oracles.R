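# Independent oracles used across the suite.  These deliberately do not
# share matching / clustering logic with the package implementation.

# Brute-force PROSITE matcher: enumerates every start position and every
# combination of repeat counts, and tests the resulting concrete element
# sequence literally.  Returns all (start, end) pairs; per-start shortest
# ends are what the production scanner reports by default.
brute_force_scan <- function(sequence, pattern) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  reps <- lapply(pattern, function(el) seq.int(el$min_repeat, el$max_repeat))
  combos <- expand.grid(reps, KEEP.OUT.ATTRS = FALSE)
  hits <- list()
  for (ci in seq_len(nrow(combos))) {
    counts <- as.integer(combos[ci, ])
    # concrete expansion: list of per-position residue sets
    # (character(0) is the wildcard: any residue allowed at that position)
    sets <- list()
    for (k in seq_along(pattern)) {
      el <- pattern[[k]]
      for (r in seq_len(counts[k])) {
        sets[[length(sets) + 1L]] <-
          if (el$kind == "any") character(0) else el$residues
      }
    }
    w <- length(sets)
    if (w > length(chars)) next
    for (start in seq_len(length(chars) - w + 1L)) {
      ok <- TRUE
      for (k in seq_len(w)) {
        s <- sets[[k]]
        if (length(s) && !(chars[start + k - 1L] %in% s)) { ok <- FALSE; break }
      }
      if (ok) hits[[length(hits) + 1L]] <- c(start, start + w - 1L)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  out <- unique(do.call(rbind, hits))
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  data.frame(start = out[, 1], end = out[, 2])
}

# per-start shortest ends, the default scanner policy
brute_force_shortest <- function(sequence, pattern) {
  all <- brute_force_scan(sequence, pattern)
  if (nrow(all) == 0L) return(all)
  agg <- stats::aggregate(end ~ start, data = all, FUN = min)
  agg[order(agg$start), c("start", "end")]
}

# random small pattern text for the equivalence sweep (alphabet restricted
# to a handful of residues so that matches actually occur)
random_pattern_text <- function(alphabet = c("A", "C", "G", "T")) {
  n_el <- sample(2:5, 1)
  toks <- vapply(seq_len(n_el), function(i) {
    core <- switch(sample(3, 1),
                   sample(alphabet, 1),
                   "x",
                   paste0("[", paste(sample(alphabet, sample(2:3, 1)),
                                     collapse = ""), "]"))
    if (stats::runif(1) < 0.4) {
      n <- sample(1:2, 1)
      m <- n + sample(0:2, 1)
      paste0(core, "(", n, ",", m, ")")
    } else core
  }, character(1))
  paste(toks, collapse = "-")
}

random_sequence <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Brute-force average-linkage (UPGMA) merge heights: at each step merge the
# two clusters with the smallest mean pairwise distance between their
# members.
average_linkage_heights <- function(mat) {
  d <- as.matrix(stats::dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq.int(i + 1L, length(clusters))) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# path-length (patristic) distance matrix of a phylo tree, ordered by taxa
tree_path_distances <- function(tree, taxa = tree$tip.label) {
  m <- ape::cophenetic.phylo(tree)
  m[taxa, taxa]
}

# unrooted topology equality via Robinson-Foulds distance
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
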