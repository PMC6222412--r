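# Neighbor-joining trees with bootstrap support; thin layer over ape's
# tree machinery with the package's distance engine underneath.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape). Negative branch lengths that NJ can
#' produce are retained, so additivity checks on the returned tree are exact;
#' they are clamped to zero only when writing display output.
#'
#' @param D `distance_matrix` or a symmetric numeric matrix with dimnames
#' @return an `ape::phylo` unrooted tree
#' @export
nj_tree <- function(D) {
  m <- if (inherits(D, "distance_matrix")) D$d else as.matrix(D)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("D must be a square matrix")
  if (nrow(m) < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (any(!is.finite(m))) stop("non-finite value in distance matrix")
  ape::nj(m)
}

# distance matrix from a character alignment matrix (rows = taxa)
.dist_from_mat <- function(mat, model) {
  seqs <- apply(mat, 1L, paste, collapse = "")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- pairwise_distance(seqs[i], seqs[j], model)$d
    }
  }
  d
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the reference NJ tree from the panel's distance matrix, then
#' resamples alignment columns with replacement `n_reps` times; the support
#' of each internal bipartition of the reference tree is the percentage of
#' replicate trees containing it, stored as internal node labels.
#'
#' @param panel `species_panel`
#' @param n_reps bootstrap replicates (default 1000)
#' @param seed integer RNG seed; same seed, same supports
#' @param model distance model, `"K2P"` (default) or `"p"`
#' @return `ape::phylo` with `node.label` holding supports (percent); the
#'   root node label is empty. Attribute `n_effective` counts replicates on
#'   which a tree could be built.
#' @export
bootstrap_support <- function(panel, n_reps = 1000L, seed = 1L,
                              model = c("K2P", "p")) {
  model <- match.arg(model)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (nrow(panel$records) < 4L) stop("bootstrap needs at least 4 sequences")
  ref <- nj_tree(distance_matrix(panel, model))
  L <- panel$aligned_length
  set.seed(as.integer(seed))
  reps <- vector("list", n_reps)
  ok <- logical(n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    tr <- tryCatch(nj_tree(.dist_from_mat(panel$mat[, cols, drop = FALSE], model)),
                   error = function(e) NULL)
    if (!is.null(tr)) { reps[[b]] <- tr; ok[b] <- TRUE }
  }
  reps <- reps[ok]
  cnt <- ape::prop.clades(ref, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  support <- round(100 * cnt / length(reps))
  lab <- as.character(support)
  lab[1L] <- ""  # the basal trifurcation of an unrooted tree is not a split
  ref$node.label <- lab
  attr(ref, "n_effective") <- length(reps)
  ref
}

#' Root a tree on an outgroup for display
#'
#' Produces a rooted rendering; the underlying unrooted topology is
#' unchanged.
#'
#' @param tree `ape::phylo`
#' @param leaf_id tip label to use as outgroup
#' @return rooted `ape::phylo`
#' @export
set_outgroup <- function(tree, leaf_id) {
  if (!leaf_id %in% tree$tip.label) stop("unknown leaf: ", leaf_id)
  ape::root(tree, outgroup = leaf_id, resolve.root = TRUE)
}

#' Write a tree in Newick format
#'
#' Supports are written as internal node labels (the common dialect).
#' Negative NJ branch lengths are clamped to zero in the written file unless
#' `clamp_negative = FALSE`.
#'
#' @param tree `ape::phylo`
#' @param path output file
#' @param clamp_negative clamp negative branch lengths for display
#' @export
write_newick <- function(tree, path, clamp_negative = TRUE) {
  if (clamp_negative && !is.null(tree$edge.length)) {
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
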