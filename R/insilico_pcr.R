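# In-silico PCR: primer binding-site search, amplicon prediction and the
# marker x template specificity matrix (a virtual gel).

# mismatch profile of `primer` slid along `template` (both bitmask vectors):
# integer vector over all start positions, counting primer positions whose
# IUPAC sets do not intersect the template.
.slide_mismatches <- function(pmask, tmask) {
  m <- length(pmask)
  n <- length(tmask) - m + 1L
  if (n < 1L) return(integer(0))
  mism <- integer(n)
  for (j in seq_len(m)) {
    mism <- mism + as.integer(bitwAnd(pmask[j], tmask[j:(j + n - 1L)]) == 0L)
  }
  mism
}

#' Find primer binding sites on a template
#'
#' Scans both orientations: `strand = "+"` sites are where the primer anneals
#' to the minus strand and extends rightwards (the primer read 5'->3' matches
#' the template as written); `strand = "-"` sites are where the reverse
#' complement of the primer matches the template (the primer anneals to the
#' plus strand and extends leftwards). Matching is IUPAC-aware; a gap never
#' matches. Sites with a mismatch inside the 3'-terminal window are excluded
#' when `forbid_3prime_mismatch` is set.
#'
#' @param primer character scalar, ungapped
#' @param template character scalar, ungapped
#' @param max_mismatch maximum mismatches tolerated (default 0)
#' @param forbid_3prime_mismatch exclude sites with any mismatch within the
#'   3' window (default TRUE)
#' @param three_prime_window size of the 3' window in nt (default 3)
#' @param strand `"both"` (default), `"+"` or `"-"`
#' @return data.frame: `strand`, `start` (1-based leftmost template position
#'   of the footprint), `end`, `mismatches`, `three_prime_mismatch`
#' @export
find_binding_sites <- function(primer, template, max_mismatch = 0L,
                               forbid_3prime_mismatch = TRUE,
                               three_prime_window = 3L,
                               strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  tmask <- encode_iupac(template)
  m <- nchar(primer)
  if (m > length(tmask)) {
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      three_prime_mismatch = logical(0)))
  }
  scan_one <- function(pat, str) {
    pmask <- encode_iupac(pat)
    mism <- .slide_mismatches(pmask, tmask)
    # 3' terminal window: rightmost bases of the pattern for "+", leftmost
    # (the revcomp'd primer's 3' end) for "-"
    w <- min(three_prime_window, m)
    idx3 <- if (str == "+") (m - w + 1L):m else 1L:w
    m3 <- integer(length(mism))
    for (j in idx3) {
      m3 <- m3 + as.integer(bitwAnd(pmask[j], tmask[j:(j + length(mism) - 1L)]) == 0L)
    }
    keep <- mism <= max_mismatch
    if (forbid_3prime_mismatch) keep <- keep & m3 == 0L
    pos <- which(keep)
    data.frame(strand = rep(str, length(pos)), start = pos,
               end = pos + m - 1L, mismatches = mism[pos],
               three_prime_mismatch = m3[pos] > 0L,
               stringsAsFactors = FALSE)
  }
  out <- list()
  if (strand %in% c("both", "+")) out <- c(out, list(scan_one(primer, "+")))
  if (strand %in% c("both", "-")) out <- c(out, list(scan_one(revcomp(primer), "-")))
  do.call(rbind, out)
}

#' Predict PCR amplicons for a primer pair on a template
#'
#' A product forms for every (plus-strand site, minus-strand site)
#' combination where the upstream footprint lies strictly before the
#' downstream one (non-overlapping). Because the template is double-stranded
#' the pair is orientation-free: both role assignments (forward primer on
#' the plus strand with the reverse primer downstream, and vice versa) are
#' scanned, so the prediction is invariant under reverse-complementing the
#' template. The product length is the inclusive span from one primer's 5'
#' end through the other primer's 5' end on the opposite strand, i.e. both
#' primer footprints are included.
#'
#' @param forward,reverse primer sequences (5'->3')
#' @param template ungapped template sequence
#' @param size_limits numeric length-2, products outside are dropped
#'   (default c(50, 2000))
#' @param max_mismatch,forbid_3prime_mismatch,three_prime_window passed to
#'   [find_binding_sites()]
#' @return data.frame: `start`, `end` (1-based inclusive), `length`,
#'   `f_mismatches`, `r_mismatches`
#' @export
predict_amplicons <- function(forward, reverse, template,
                              size_limits = c(50L, 2000L),
                              max_mismatch = 0L,
                              forbid_3prime_mismatch = TRUE,
                              three_prime_window = 3L) {
  empty <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                      f_mismatches = integer(0), r_mismatches = integer(0))
  orientation <- function(p_plus, p_minus) {
    ps <- find_binding_sites(p_plus, template, max_mismatch,
                             forbid_3prime_mismatch, three_prime_window, "+")
    ms <- find_binding_sites(p_minus, template, max_mismatch,
                             forbid_3prime_mismatch, three_prime_window, "-")
    if (nrow(ps) == 0L || nrow(ms) == 0L) {
      return(data.frame(start = integer(0), end = integer(0),
                        length = integer(0), plus_mm = integer(0),
                        minus_mm = integer(0)))
    }
    combos <- expand.grid(pi = seq_len(nrow(ps)), mi = seq_len(nrow(ms)))
    start <- ps$start[combos$pi]
    end <- ms$end[combos$mi]
    len <- end - start + 1L
    keep <- ps$end[combos$pi] < ms$start[combos$mi] &
      len >= size_limits[1L] & len <= size_limits[2L]
    data.frame(start = start[keep], end = end[keep], length = len[keep],
               plus_mm = ps$mismatches[combos$pi][keep],
               minus_mm = ms$mismatches[combos$mi][keep])
  }
  o1 <- orientation(forward, reverse)
  o2 <- orientation(reverse, forward)
  out <- rbind(
    data.frame(start = o1$start, end = o1$end, length = o1$length,
               f_mismatches = o1$plus_mm, r_mismatches = o1$minus_mm),
    data.frame(start = o2$start, end = o2$end, length = o2$length,
               f_mismatches = o2$minus_mm, r_mismatches = o2$plus_mm))
  if (nrow(out) == 0L) return(empty)
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Marker x template specificity matrix
#'
#' Evaluates every marker against every template under exact (or configured)
#' matching and attaches a per-marker verdict: `"species_specific"` iff every
#' template of the marker's target species yields at least one product and no
#' other template yields any product in the gel-visible 50-2000 bp range;
#' `"off_target"`, `"missed_target"` or `"untested"` otherwise.
#'
#' @param markers marker table (data.frame with `marker_id`, `species`,
#'   `forward_seq`, `reverse_seq`, `expected_size`), e.g. from
#'   [design_marker_set()] or [read_primer_pairs()]
#' @param templates `seq_records` of ungapped templates (use
#'   [panel_templates()] for a panel)
#' @param max_mismatch mismatches tolerated per primer (default 0)
#' @param size_limits gel-visible product range (default c(50, 2000))
#' @return object of class `specificity_matrix`: list with `predictions`
#'   (list-matrix of amplicon data frames), `n_products` (integer matrix),
#'   `sizes` (character matrix), `verdicts` (named character), `markers`,
#'   `templates`
#' @export
specificity_matrix <- function(markers, templates, max_mismatch = 0L,
                               size_limits = c(50L, 2000L)) {
  if (inherits(templates, "species_panel")) templates <- panel_templates(templates)
  if (nrow(markers) < 1L) stop("need at least one marker")
  nm <- nrow(markers); nt <- nrow(templates)
  preds <- vector("list", nm * nt)
  dim(preds) <- c(nm, nt)
  dimnames(preds) <- list(markers$marker_id, templates$id)
  nprod <- matrix(0L, nm, nt, dimnames = dimnames(preds))
  for (i in seq_len(nm)) {
    for (j in seq_len(nt)) {
      a <- predict_amplicons(markers$forward_seq[i], markers$reverse_seq[i],
                             templates$bases[j], size_limits = size_limits,
                             max_mismatch = max_mismatch)
      preds[[i, j]] <- a
      nprod[i, j] <- nrow(a)
    }
  }
  verdicts <- vapply(seq_len(nm), function(i) {
    tgt <- templates$species == markers$species[i]
    if (!any(tgt)) return("untested")
    if (any(nprod[i, !tgt] > 0L)) return("off_target")
    if (all(nprod[i, tgt] > 0L)) "species_specific" else "missed_target"
  }, "")
  names(verdicts) <- markers$marker_id
  sizes <- matrix(vapply(preds, function(a) {
    if (nrow(a) == 0L) "-" else paste(a$length, collapse = ",")
  }, ""), nm, nt, dimnames = dimnames(preds))
  structure(
    list(predictions = preds, n_products = nprod, sizes = sizes,
         verdicts = verdicts, markers = markers, templates = templates),
    class = "specificity_matrix"
  )
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat("specificity_matrix:", nrow(x$markers), "marker(s) x",
      nrow(x$templates), "template(s)\n")
  print(x$sizes, quote = FALSE)
  cat("verdicts:\n")
  for (m in names(x$verdicts)) cat("  ", m, ": ", x$verdicts[[m]], "\n", sep = "")
  invisible(x)
}

#' Render a specificity matrix as a text virtual gel
#'
#' One block per marker; lanes are templates in the given order, showing the
#' predicted product sizes (bp) or an empty lane.
#'
#' @param specmat `specificity_matrix`
#' @return character vector of lines
#' @export
virtual_gel <- function(specmat) {
  lines <- character(0)
  lanes <- seq_len(nrow(specmat$templates))
  for (i in seq_len(nrow(specmat$markers))) {
    lines <- c(lines, paste0("marker ", specmat$markers$marker_id[i],
                             " (", specmat$markers$species[i], ", expected ",
                             specmat$markers$expected_size[i], " bp) [",
                             specmat$verdicts[i], "]"))
    for (j in lanes) {
      band <- specmat$sizes[i, j]
      lines <- c(lines, sprintf("  lane %2d %-20s | %s", j,
                                specmat$templates$id[j],
                                if (band == "-") "" else paste0(band, " bp")))
    }
  }
  lines
}

#' Cross-species specificity audit
#'
#' For each marker and each external (non-panel) template: the minimum
#' mismatch count achievable by each primer anywhere on the template, and any
#' products predicted under a relaxed mismatch policy. Templates where both
#' primers can bind with fewer than `risk_mismatch` mismatches are flagged as
#' at risk of cross-amplification.
#'
#' @param markers marker table (see [specificity_matrix()])
#' @param templates `seq_records` of external sequences
#' @param max_mismatch relaxed per-primer tolerance for product prediction
#'   (default 2)
#' @param risk_mismatch flag threshold (default 2): fewer than this many
#'   mismatches for *both* primers marks the template risky
#' @return data.frame: `marker_id`, `template_id`, `template_species`,
#'   `f_min_mismatch`, `r_min_mismatch`, `n_products`, `product_sizes`,
#'   `risky`
#' @export
audit_cross_species <- function(markers, templates, max_mismatch = 2L,
                                risk_mismatch = 2L) {
  if (inherits(templates, "species_panel")) templates <- panel_templates(templates)
  min_mm <- function(primer, template, str) {
    s <- find_binding_sites(primer, template, max_mismatch = nchar(primer),
                            forbid_3prime_mismatch = FALSE, strand = str)
    if (nrow(s) == 0L) NA_integer_ else min(s$mismatches)
  }
  rows <- list()
  for (i in seq_len(nrow(markers))) {
    for (j in seq_len(nrow(templates))) {
      fm <- min_mm(markers$forward_seq[i], templates$bases[j], "+")
      rm <- min_mm(markers$reverse_seq[i], templates$bases[j], "-")
      a <- predict_amplicons(markers$forward_seq[i], markers$reverse_seq[i],
                             templates$bases[j], max_mismatch = max_mismatch)
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = markers$marker_id[i],
        template_id = templates$id[j],
        template_species = templates$species[j],
        f_min_mismatch = fm, r_min_mismatch = rm,
        n_products = nrow(a),
        product_sizes = if (nrow(a)) paste(a$length, collapse = ",") else "",
        risky = isTRUE(fm < risk_mismatch) && isTRUE(rm < risk_mismatch),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
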