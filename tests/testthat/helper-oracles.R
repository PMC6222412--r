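# Independent oracles and small fixtures shared across tests. Everything
# here re-derives expected behaviour from first principles, separately from
# the package implementation.

# IUPAC expansion sets, written out explicitly
oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_iupac_match <- function(a, b) {
  if (!a %in% names(oracle_iupac_sets) || !b %in% names(oracle_iupac_sets)) {
    return(FALSE)  # gap or unknown never matches
  }
  length(intersect(oracle_iupac_sets[[a]], oracle_iupac_sets[[b]])) > 0L
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", s),
                     "")[[1L]]), collapse = "")
}

# definition-based diagnostic-site scan: a column is diagnostic for species
# s iff all s records agree on one plain state that no other record carries
# (background ambiguity codes overlapping the state also disqualify)
oracle_diag_sites <- function(panel, target) {
  tgt <- panel$records$species == target
  found <- list()
  for (col in seq_len(panel$aligned_length)) {
    tc <- unique(panel$mat[tgt, col])
    bg <- unique(panel$mat[!tgt, col])
    if (length(tc) != 1L) next
    if (!tc %in% c("A", "C", "G", "T", "-")) next
    if (tc %in% bg) next
    if (tc != "-" && any(vapply(bg, oracle_iupac_match, NA, b = tc))) next
    found[[length(found) + 1L]] <- data.frame(
      column = col, target_state = tc,
      kind = if (tc == "-" || "-" %in% bg) "indel" else "substitution")
  }
  if (length(found)) do.call(rbind, found) else
    data.frame(column = integer(0), target_state = character(0),
               kind = character(0))
}

# all-positions binding-site scan, character by character
oracle_binding_sites <- function(primer, template, max_mismatch = 0L,
                                 forbid3 = TRUE, window = 3L,
                                 strand = "+") {
  pat <- if (strand == "+") primer else oracle_revcomp(primer)
  pc <- strsplit(pat, "")[[1L]]
  tc <- strsplit(template, "")[[1L]]
  m <- length(pc); n <- length(tc)
  hits <- list()
  for (s in seq_len(max(0L, n - m + 1L))) {
    mism <- !mapply(oracle_iupac_match, pc, tc[s:(s + m - 1L)])
    idx3 <- if (strand == "+") (m - min(window, m) + 1L):m else 1L:min(window, m)
    if (sum(mism) <= max_mismatch && (!forbid3 || !any(mism[idx3]))) {
      hits[[length(hits) + 1L]] <- data.frame(start = s, mismatches = sum(mism))
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(0), mismatches = integer(0))
}

# substring-based existence oracle for exact-match PCR: a product exists iff
# one primer and the revcomp of the other occur as exact substrings with the
# first footprint strictly upstream of the second (the pair is unordered on
# a double-stranded template)
oracle_exact_product_exists <- function(forward, reverse, template,
                                        size_limits = c(50L, 2000L)) {
  find_all <- function(pat) {
    out <- integer(0); from <- 1L
    repeat {
      i <- regexpr(pat, substring(template, from), fixed = TRUE)
      if (i < 0L) break
      out <- c(out, from + i - 1L)
      from <- from + i
    }
    out
  }
  one_way <- function(p1, p2) {
    for (f in find_all(p1)) {
      for (r in find_all(oracle_revcomp(p2))) {
        len <- r + nchar(p2) - f
        if (f + nchar(p1) - 1L < r &&
            len >= size_limits[1L] && len <= size_limits[2L]) return(TRUE)
      }
    }
    FALSE
  }
  one_way(forward, reverse) || one_way(reverse, forward)
}

# exhaustive-topology least-squares oracle for neighbor joining: fit branch
# lengths to D for every unrooted topology, return the minimum-SSE tree
oracle_ls_sse <- function(tr, D) {
  tr <- ape::unroot(tr)
  n <- length(tr$tip.label)
  desc <- phangorn::Descendants(tr, tr$edge[, 2L], type = "tips")
  Mm <- t(vapply(desc, function(t) as.numeric(seq_len(n) %in% t), numeric(n)))
  pairs <- t(utils::combn(n, 2L))
  X <- abs(Mm[, pairs[, 1L], drop = FALSE] - Mm[, pairs[, 2L], drop = FALSE])
  X <- t(X)
  Dm <- D[tr$tip.label, tr$tip.label]
  dvec <- Dm[pairs]
  fit <- stats::lm.fit(X, dvec)
  sum(fit$residuals^2)
}

oracle_best_topology <- function(D) {
  labs <- rownames(D)
  tops <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  sse <- vapply(tops, oracle_ls_sse, 0, D = D)
  tops[[which.min(sse)]]
}

# random tree with strictly positive branch lengths; its cophenetic matrix
# is additive by construction
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1)))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny three-species toy alignment with known diagnostic structure:
# column 5 separates SpA (T) from SpB/SpC (C); columns 11-12 are a SpB gap
toy_panel <- function() {
  seqs <- c(
    a1 = "ACGTTACGTAGGCCATTGCA",
    a2 = "ACGTTACGTAGGCCATTGCA",
    b1 = "ACGTCACGTA--CCATTGCA",
    b2 = "ACGTCACGTA--CCATTGCA",
    c1 = "ACGTCACGTAGGCCATTGCA"
  )
  species_panel(seq_records(names(seqs), unname(seqs),
                            species = c("SpA", "SpA", "SpB", "SpB", "SpC")))
}

table4_path <- function() {
  system.file("extdata", "qpcr_standard_curves.csv", package = "scarkit")
}

table3_path <- function() {
  system.file("extdata", "scar_primers.tsv", package = "scarkit")
}

# printed reference values for the five dilution series
table4_printed <- data.frame(
  label = c("C. militaris", "C. pruinosa", "I. cicadae", "I. tenuipes",
            "O. sinensis"),
  slope = c(-3.337, -3.364, -3.372, -2.757, -3.434),
  r_squared = c(0.99759, 0.99783, 0.99990, 0.95865, 0.99981),
  efficiency = c(99L, 98L, 98L, 131L, 96L),
  stringsAsFactors = FALSE
)

# topology distance as a bare number (Robinson-Foulds / PH85)
topo_dist <- function(t1, t2) as.numeric(ape::dist.topo(t1, t2))
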