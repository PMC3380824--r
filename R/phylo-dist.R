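# Distance-based genealogy construction: uncorrected p-distance,
# neighbour-joining (delegated to ape), and column-bootstrap node support.

#' Uncorrected p-distance matrix
#'
#' `d_ij` = proportion of mismatching bases over the columns where both
#' haplotypes carry an unambiguous base (pairwise deletion of gap/N
#' columns).
#'
#' @param aln A `haplotype_alignment`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  m <- aln$mat
  n <- nrow(m)
  valid <- !(m %in% c("-", "N"))
  dim(valid) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(max(n - 1L, 1L))) {
    if (i == n) break
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      if (!any(ok)) {
        stop("no comparable columns between haplotypes ", aln$ids[i],
             " and ", aln$ids[j], call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via `ape::nj`). Negative branch lengths are
#' clamped to zero with the deficit transferred to the sister branch at the
#' same node, preserving path lengths through the cherry.
#'
#' @param dist Symmetric zero-diagonal distance matrix (or `dist` object)
#'   over at least 3 taxa.
#' @return An `ape::phylo` tree (unrooted).
#' @export
neighbor_joining <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be 0", call. = FALSE)
  tree <- ape::nj(d)
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1L]
    sisters <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sisters) > 0L) {
      s <- sisters[1L]
      tree$edge.length[s] <- tree$edge.length[s] + tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbour-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and attaches to each bipartition of the point-estimate
#' tree the percentage of replicates containing it (node labels, 0-100).
#'
#' @param aln A `haplotype_alignment`.
#' @param n_reps Number of bootstrap replicates (1000 for production runs).
#' @param seed Optional seed.
#' @param outgroup Optional tip id to root the final tree on.
#' @return An `ape::phylo` tree whose `node.label` holds support values.
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = NULL,
                              outgroup = NULL) {
  stopifnot(inherits(aln, "haplotype_alignment"), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  point <- neighbor_joining(p_distance_matrix(aln))
  L <- alignment_length(aln)
  boot_trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    baln <- haplotype_alignment(aln$mat[, cols, drop = FALSE], ids = aln$ids,
                                locus_name = aln$locus_name)
    boot_trees[[r]] <- neighbor_joining(p_distance_matrix(baln))
  }
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(point, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  point$node.label <- as.character(round(100 * counts / n_reps))
  if (!is.null(outgroup) && outgroup %in% point$tip.label) {
    point <- ape::root(point, outgroup = outgroup, resolve.root = TRUE)
  }
  point
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path, call. = FALSE)
  ape::read.tree(path)
}

#' Write a tree as Newick
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
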