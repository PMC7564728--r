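# Distance-based phylogenetics over TLP proteins: pairwise distances from a
# protein MSA with pairwise gap deletion, neighbor-joining, column-resampling
# bootstrap supports, and clade-based group extraction.

#' Read an aligned protein FASTA
#'
#' @param path path to an aligned FASTA file; all sequences must have equal
#'   length (gaps as `-` or `.`).
#' @return named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned sequences have unequal lengths")
  }
  seqs
}

.alignment_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  if (methods::is(msa, "XStringSet")) msa <- as.character(msa)
  stopifnot(is.character(msa))
  if (is.null(names(msa))) names(msa) <- paste0("t", seq_along(msa))
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) stop("aligned sequences have unequal lengths")
  mat <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  rownames(mat) <- names(msa)
  mat
}

#' Pairwise distance matrix from a protein alignment
#'
#' Columns where either sequence of a pair carries a gap (`-` or `.`) are
#' deleted for that pair (pairwise deletion).  The p-distance is the
#' proportion of mismatching compared sites; the Poisson correction is
#' `d = -ln(1 - p)`, accounting for multiple substitutions per site.
#'
#' @param msa named character vector (or `AAStringSet`, or character
#'   matrix) of aligned sequences, at least 2 taxa.
#' @param model `"poisson"` (default) or `"p-distance"`.
#' @return symmetric numeric matrix with zero diagonal and taxa as
#'   dimnames.
#' @export
distance_matrix <- function(msa, model = c("poisson", "p-distance")) {
  model <- match.arg(model)
  mat <- .alignment_matrix(msa)
  n <- nrow(mat)
  if (n < 2L) stop("at least 2 taxa required")
  gap <- mat == "-" | mat == "."
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      n_sites <- sum(ok)
      if (n_sites == 0L) {
        stop("no comparable sites between ", rownames(mat)[i], " and ",
             rownames(mat)[j])
      }
      p <- sum(mat[i, ok] != mat[j, ok]) / n_sites
      if (model == "poisson") {
        if (p >= 1) {
          stop("Poisson distance is infinite between ", rownames(mat)[i],
               " and ", rownames(mat)[j], " (p = 1)")
        }
        d[i, j] <- d[j, i] <- -log(1 - p)
      } else {
        d[i, j] <- d[j, i] <- p
      }
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion over a distance
#' matrix.  Negative branch lengths, which NJ can produce on non-additive
#' input, are clamped to zero with a warning.
#'
#' @param dm symmetric distance matrix (or `dist`) over at least 3 taxa.
#' @return an unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(dm) {
  d <- stats::as.dist(dm)
  if (attr(d, "Size") < 3L) stop("neighbor-joining requires at least 3 taxa")
  tree <- ape::nj(d)
  if (any(tree$edge.length < 0)) {
    warning("negative branch length(s) clamped to zero")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' NJ tree for each replicate, and assigns each internal edge of the
#' original tree the percentage of replicate trees containing the same
#' bipartition.  Replicate `r` is seeded with `seed + r`, so runs with the
#' same root seed are identical and the resampling of each replicate does
#' not depend on `n_reps`.
#'
#' @param msa aligned sequences (see [distance_matrix()]).
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed root seed.
#' @param model distance model passed to [distance_matrix()].
#' @return the original NJ `phylo` tree with `node.label` holding support
#'   percentages for internal nodes (NA for the unrooted basal node) and an
#'   attribute `n_reps`.
#' @export
bootstrap_support <- function(msa, n_reps = 1000L, seed = 1L,
                              model = "poisson") {
  stopifnot(n_reps >= 1L)
  mat <- .alignment_matrix(msa)
  ref <- nj_tree(distance_matrix(mat, model))
  boot_trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- withr::with_seed(seed + r,
                             sample.int(ncol(mat), ncol(mat), replace = TRUE))
    boot_trees[[r]] <- suppressWarnings(
      nj_tree(distance_matrix(mat[, cols, drop = FALSE], model)))
  }
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, boot_trees, rooted = FALSE)
  support <- 100 * counts / n_reps
  ref$node.label <- support
  attr(ref, "n_reps") <- n_reps
  ref
}

# leaf labels beneath the child node of each edge (child side of the
# bipartition), used for deterministic tie-breaks
.edge_leafsets <- function(tree) {
  n_tip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    sort(unlist(lapply(children[[as.character(node)]], below)))
  }
  lapply(tree$edge[, 2], below)
}

#' Cut a tree into k groups by removing its longest edges
#'
#' Removes the `k - 1` longest internal edges of the tree (extending to
#' terminal edges when the tree has fewer than `k - 1` internal edges) and
#' assigns taxa to the connected components of what remains.  An
#' algorithmic analogue of reading clades off a drawn tree.  Ties in edge
#' length are broken by the lexicographically smallest leaf label beneath
#' the edge; groups are numbered 1..k by their smallest leaf label.
#'
#' @param tree a `phylo` tree.
#' @param k number of groups, between 1 and the number of leaves.
#' @return list with `groups` (named integer vector taxon -> group index)
#'   and `n_groups` (the number of leaf-containing components obtained,
#'   normally `k`; fewer only in degenerate cases where cutting isolates
#'   leafless internal fragments, which triggers a warning).
#' @export
extract_groups <- function(tree, k) {
  n_tip <- length(tree$tip.label)
  if (k < 1L || k > n_tip) stop("k must be between 1 and the number of leaves")
  edges <- tree$edge
  lens <- tree$edge.length
  leafsets <- .edge_leafsets(tree)
  internal <- edges[, 2] > n_tip
  tie_key <- vapply(leafsets, `[[`, character(1), 1L)
  ord <- order(!internal, -lens, tie_key)
  drop_idx <- utils::head(ord, k - 1L)
  keep <- setdiff(seq_len(nrow(edges)), drop_idx)

  # connected components over all nodes using the remaining edges
  n_nodes <- n_tip + tree$Nnode
  parent <- seq_len(n_nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in keep) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(n_tip), find, integer(1))
  comp_of_tip <- split(tree$tip.label, comp)
  comp_of_tip <- comp_of_tip[order(vapply(comp_of_tip, min, character(1)))]
  groups <- integer(n_tip)
  names(groups) <- tree$tip.label
  for (g in seq_along(comp_of_tip)) groups[comp_of_tip[[g]]] <- g
  if (length(comp_of_tip) < k) {
    warning("only ", length(comp_of_tip), " leaf-containing groups for k = ", k)
  }
  list(groups = groups, n_groups = length(comp_of_tip))
}
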