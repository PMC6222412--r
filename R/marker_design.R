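# Species-diagnostic site discovery and SCAR primer-pair design.
#
# A diagnostic site is an alignment column whose state is fixed within the
# target species and disjoint from every non-target record. Primers are
# enumerated on the ungapped reference sequence of the target species, in
# both orientations, and paired into markers under the duplex scheme: two
# markers per species with resolvably different amplicon sizes, each carrying
# at least two diagnostic substitutions in one of its primers, and validated
# by exact in-silico PCR against the whole panel.

#' Primer and marker design constraints
#'
#' Defaults reflect the dimensions of published ITS SCAR assays: primers
#' 18-23 nt with GC 0.40-0.80, Wallace Tm 48-72 degrees C, homopolymer runs
#' capped at 5, amplicons 80-400 bp, at least two diagnostic substitutions in
#' one primer, and a 20 bp minimum size difference between the two markers of
#' a duplex so a gel can resolve them.
#'
#' @param primer_length length-2 integer window (nt)
#' @param gc length-2 GC fraction window
#' @param tm length-2 Wallace Tm window (degrees C)
#' @param max_homopolymer longest allowed single-base run
#' @param amplicon length-2 amplicon size window (bp)
#' @param min_diagnostic_subs minimum diagnostic substitutions required in at
#'   least one primer of a pair
#' @param resolvable_delta minimum |size1 - size2| between duplex members (bp)
#' @param max_mismatch per-primer mismatch tolerance used in design-time
#'   specificity validation (0 = strict)
#' @param max_candidates_per_strand cap on candidates carried into pairing,
#'   keeping the highest-ranked per strand
#' @return named list of class `design_constraints`
#' @export
design_constraints <- function(primer_length = c(18L, 23L),
                               gc = c(0.40, 0.80),
                               tm = c(48, 72),
                               max_homopolymer = 5L,
                               amplicon = c(80L, 400L),
                               min_diagnostic_subs = 2L,
                               resolvable_delta = 20L,
                               max_mismatch = 0L,
                               max_candidates_per_strand = 120L) {
  structure(as.list(environment()), class = "design_constraints")
}

#' Find species-diagnostic alignment columns
#'
#' A column is diagnostic for `target_species` when (i) the target records
#' agree on one state at a frequency of at least
#' `min_intraspecific_fixation` (1 = full fixation), and (ii) that state is
#' absent from every non-target record. States are compared literally for
#' A/C/G/T and gap; a background ambiguity code blocks the column whenever
#' its expansion overlaps the target state. Columns whose target consensus is
#' itself ambiguous are skipped. Sites involving a gap on either side are of
#' kind `"indel"`, all others `"substitution"`.
#'
#' @param panel `species_panel`
#' @param target_species species label present in the panel
#' @param min_intraspecific_fixation required within-target frequency of the
#'   target state (default 1.0)
#' @return data.frame sorted by column: `column` (1-based), `target_state`,
#'   `background_states` (comma-collapsed), `kind`
#' @export
find_diagnostic_sites <- function(panel, target_species,
                                  min_intraspecific_fixation = 1.0) {
  if (!target_species %in% panel$records$species) {
    stop("target species not in panel: ", target_species)
  }
  tgt <- panel$records$species == target_species
  tmat <- panel$mat[tgt, , drop = FALSE]
  bmat <- panel$mat[!tgt, , drop = FALSE]
  plain <- c("A", "C", "G", "T", "-")
  rows <- list()
  for (col in seq_len(panel$aligned_length)) {
    tc <- tmat[, col]
    tab <- table(tc)
    state <- names(tab)[which.max(tab)]
    if (max(tab) / length(tc) < min_intraspecific_fixation) next
    if (!state %in% plain) next
    bg <- unique(bmat[, col])
    if (state %in% bg) next
    # ambiguity codes in the background: overlap with the target state blocks
    amb <- setdiff(bg, plain)
    if (length(amb) && state != "-" &&
        any(vapply(amb, iupac_match, NA, template_base = state))) next
    rows[[length(rows) + 1L]] <- data.frame(
      column = col, target_state = state,
      background_states = paste(sort(bg), collapse = ","),
      kind = if (state == "-" || "-" %in% bg) "indel" else "substitution",
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(column = integer(0), target_state = character(0),
                      background_states = character(0), kind = character(0)))
  }
  do.call(rbind, rows)
}

# reference coordinate map for the target species: ungapped sequence of the
# first target record plus the alignment column of each ungapped position
.target_reference <- function(panel, target_species, ref_id = NULL) {
  idx <- which(panel$records$species == target_species)
  if (!length(idx)) stop("target species not in panel: ", target_species)
  if (!is.null(ref_id)) {
    idx <- which(panel$records$id == ref_id)
    if (!length(idx)) stop("unknown reference id: ", ref_id)
  }
  i <- idx[1L]
  ch <- panel$mat[i, ]
  keep <- ch != "-"
  list(id = panel$records$id[i],
       seq = paste(ch[keep], collapse = ""),
       col_of = which(keep))  # ungapped position -> alignment column
}

# positions (window starts) containing a homopolymer run longer than `maxrun`
# for windows of length m over character vector ch
.homopolymer_bad_starts <- function(ch, m, maxrun) {
  r <- rle(ch)
  long <- which(r$lengths > maxrun)
  if (!length(long)) return(integer(0))
  ends <- cumsum(r$lengths)
  bad <- integer(0)
  for (k in long) {
    run_start <- ends[k] - r$lengths[k] + 1L
    # any window of length m that contains maxrun+1 consecutive bases of the run
    lo <- max(1L, run_start - (m - maxrun - 1L))
    hi <- ends[k] - maxrun
    if (hi >= lo) bad <- c(bad, lo:hi)
  }
  unique(bad)
}

#' Enumerate candidate primers over the diagnostic sites of a species
#'
#' Slides windows of every allowed length along the ungapped reference
#' sequence of the target species, on both strands, keeping windows that
#' contain at least one diagnostic site and satisfy the length, GC, Tm and
#' homopolymer constraints. Diagnostic coverage is counted over the aligned
#' columns spanned by the primer footprint, so diagnostic indels where the
#' target carries the gap are credited to the covering window.
#'
#' @param panel `species_panel`
#' @param target_species species label
#' @param constraints [design_constraints()]
#' @param sites optional precomputed [find_diagnostic_sites()] table
#' @param ref_id optional record id to use as the target reference
#' @return data.frame of candidates: `name`, `bases` (5'->3'), `strand`,
#'   `start`, `length` (1-based on the ungapped reference; `start` is the
#'   leftmost footprint position for either strand), `gc`, `tm`,
#'   `diag_count`, `diag_subs`, `three_prime_diagnostic`
#' @export
enumerate_primers <- function(panel, target_species,
                              constraints = design_constraints(),
                              sites = NULL, ref_id = NULL) {
  if (is.null(sites)) sites <- find_diagnostic_sites(panel, target_species)
  ref <- .target_reference(panel, target_species, ref_id)
  ch <- seq_chars(ref$seq)
  n <- length(ch)
  # a usable primer window must be fixed within the target species, or the
  # assay would drop conspecific templates; track polymorphic columns
  tmat <- panel$mat[panel$records$species == target_species, , drop = FALSE]
  poly <- apply(tmat, 2L, function(x) length(unique(x)) > 1L)
  cum_poly <- cumsum(as.integer(poly))
  # per-column cumulative diagnostic counts for O(1) window queries
  is_diag <- is_sub <- integer(panel$aligned_length)
  is_diag[sites$column] <- 1L
  is_sub[sites$column[sites$kind == "substitution"]] <- 1L
  cum_diag <- cumsum(is_diag)
  cum_sub <- cumsum(is_sub)
  cum_gc <- cumsum(ch %in% c("G", "C"))
  cum_unamb <- cumsum(ch %in% c("A", "C", "G", "T"))
  # window counts from cumulative sums over alignment columns, 1-based
  span <- function(cum, c1, c2) cum[c2] - c(0L, cum)[c1]
  out <- list()
  for (m in constraints$primer_length[1L]:constraints$primer_length[2L]) {
    if (m > n) next
    starts <- seq_len(n - m + 1L)
    ends <- starts + m - 1L
    gc_cnt <- span(cum_gc, starts, ends)
    amb_cnt <- m - span(cum_unamb, starts, ends)
    gcf <- gc_cnt / m
    tm <- 2 * (m - gc_cnt) + 4 * gc_cnt
    bad_hp <- .homopolymer_bad_starts(ch, m, constraints$max_homopolymer)
    c1 <- ref$col_of[starts]; c2 <- ref$col_of[ends]
    dcount <- span(cum_diag, c1, c2)
    dsubs <- span(cum_sub, c1, c2)
    keep <- dcount >= 1L & amb_cnt == 0L & span(cum_poly, c1, c2) == 0L &
      gcf >= constraints$gc[1L] & gcf <= constraints$gc[2L] &
      tm >= constraints$tm[1L] & tm <= constraints$tm[2L] &
      !(starts %in% bad_hp)
    if (!any(keep)) next
    a <- starts[keep]; b <- ends[keep]
    win <- substring(ref$seq, a, b)
    # 3'-terminal window: last 3 ungapped positions (+) / first 3 (-)
    d3_plus <- span(cum_diag, ref$col_of[pmax(a, b - 2L)], ref$col_of[b]) > 0L
    d3_minus <- span(cum_diag, ref$col_of[a], ref$col_of[pmin(b, a + 2L)]) > 0L
    out[[length(out) + 1L]] <- data.frame(
      bases = c(win, vapply(win, revcomp, "")),
      strand = rep(c("+", "-"), each = length(a)),
      start = c(a, a), length = m, gc = c(gcf[keep], gcf[keep]),
      tm = c(tm[keep], tm[keep]),
      diag_count = c(dcount[keep], dcount[keep]),
      diag_subs = c(dsubs[keep], dsubs[keep]),
      three_prime_diagnostic = c(d3_plus, d3_minus),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    warning("no primer candidates for ", target_species)
    return(data.frame(name = character(0), bases = character(0),
                      strand = character(0), start = integer(0),
                      length = integer(0), gc = numeric(0), tm = numeric(0),
                      diag_count = integer(0), diag_subs = integer(0),
                      three_prime_diagnostic = logical(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$diag_subs, -res$diag_count, res$start, res$strand,
                   res$length), , drop = FALSE]
  res$name <- sprintf("%s_%s%03d", gsub("\\s+", "", target_species),
                      ifelse(res$strand == "+", "F", "R"),
                      seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("name", "bases", "strand", "start", "length", "gc", "tm",
          "diag_count", "diag_subs", "three_prime_diagnostic")]
}

#' Pair forward and reverse candidates into SCAR markers
#'
#' All compatible forward(+)/reverse(-) combinations with non-overlapping
#' footprints, amplicon size inside the constraint window, and at least
#' `min_diagnostic_subs` diagnostic substitutions in one of the two primers.
#' The expected amplicon is the inclusive span from the forward primer's 5'
#' end through the reverse primer's 5' end on the target reference. Markers
#' are ranked by total diagnostic coverage, then number of 3'-anchored
#' primers, then Tm balance, then leftmost coordinate.
#'
#' @param candidates output of [enumerate_primers()]
#' @param target_species species label attached to the markers
#' @param constraints [design_constraints()]
#' @return data.frame of markers: `marker_id`, `species`, `forward_name`,
#'   `forward_seq`, `reverse_name`, `reverse_seq`, `f_start`, `r_end`,
#'   `expected_size`, `diag_total`, per-primer diagnostic substitution counts
#' @export
pair_primers <- function(candidates, target_species,
                         constraints = design_constraints()) {
  fwd <- candidates[candidates$strand == "+", , drop = FALSE]
  rev <- candidates[candidates$strand == "-", , drop = FALSE]
  empty <- data.frame(marker_id = character(0), species = character(0),
                      forward_name = character(0), forward_seq = character(0),
                      reverse_name = character(0), reverse_seq = character(0),
                      f_start = integer(0), r_end = integer(0),
                      expected_size = integer(0), diag_total = integer(0),
                      f_diag_subs = integer(0), r_diag_subs = integer(0))
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(empty)
  g <- expand.grid(fi = seq_len(nrow(fwd)), ri = seq_len(nrow(rev)))
  f_start <- fwd$start[g$fi]
  f_end <- f_start + fwd$length[g$fi] - 1L
  r_start <- rev$start[g$ri]
  r_end <- r_start + rev$length[g$ri] - 1L
  size <- r_end - f_start + 1L
  keep <- f_end < r_start &
    size >= constraints$amplicon[1L] & size <= constraints$amplicon[2L] &
    pmax(fwd$diag_subs[g$fi], rev$diag_subs[g$ri]) >= constraints$min_diagnostic_subs
  if (!any(keep)) return(empty)
  g <- g[keep, , drop = FALSE]
  out <- data.frame(
    species = target_species,
    forward_name = fwd$name[g$fi], forward_seq = fwd$bases[g$fi],
    reverse_name = rev$name[g$ri], reverse_seq = rev$bases[g$ri],
    f_start = f_start[keep], r_end = r_end[keep],
    expected_size = size[keep],
    diag_total = fwd$diag_count[g$fi] + rev$diag_count[g$ri],
    f_diag_subs = fwd$diag_subs[g$fi], r_diag_subs = rev$diag_subs[g$ri],
    anchored = as.integer(fwd$three_prime_diagnostic[g$fi]) +
      as.integer(rev$three_prime_diagnostic[g$ri]),
    tm_gap = abs(fwd$tm[g$fi] - rev$tm[g$ri]),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$diag_total, -out$anchored, out$tm_gap, out$f_start,
                   out$expected_size), , drop = FALSE]
  out$marker_id <- sprintf("%s_M%03d", gsub("\\s+", "", target_species),
                           seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("marker_id", "species", "forward_name", "forward_seq",
          "reverse_name", "reverse_seq", "f_start", "r_end", "expected_size",
          "diag_total", "f_diag_subs", "r_diag_subs", "anchored", "tm_gap")]
}

#' Design the duplex marker set for one species
#'
#' Enumerates and pairs primers, then walks the ranked pair list validating
#' each candidate marker by exact in-silico PCR against every panel template:
#' a marker is accepted when each target-species template yields a product
#' and no non-target template yields any. The second accepted marker must
#' differ from the first in expected size by at least `resolvable_delta`.
#'
#' @param panel `species_panel`
#' @param target_species species label
#' @param constraints [design_constraints()]
#' @param max_validate cap on the number of ranked pairs validated (default
#'   400) to bound design time
#' @return list of class `marker_set`: `species`, `markers` (data frame of
#'   0-2 accepted markers), `status` (`"ok"` or `"INFEASIBLE_DUPLEX"`)
#' @export
design_marker_set <- function(panel, target_species,
                              constraints = design_constraints(),
                              max_validate = 400L) {
  sites <- find_diagnostic_sites(panel, target_species)
  cand <- enumerate_primers(panel, target_species, constraints, sites = sites)
  # bound the candidate set carried into pairing: one (highest-ranked)
  # candidate per start position so the kept set spans every diagnostic
  # cluster instead of piling up on the richest one, then a per-strand cap
  cand <- do.call(rbind, lapply(split(cand, cand$strand), function(g) {
    g <- g[!duplicated(g$start), , drop = FALSE]
    utils::head(g, constraints$max_candidates_per_strand)
  }))
  pairs <- pair_primers(cand, target_species, constraints)
  templates <- panel_templates(panel)
  tgt <- templates$species == target_species
  accepted <- pairs[0, , drop = FALSE]
  for (k in seq_len(min(nrow(pairs), max_validate))) {
    if (nrow(accepted) == 2L) break
    if (nrow(accepted) == 1L &&
        abs(pairs$expected_size[k] - accepted$expected_size[1L]) <
          constraints$resolvable_delta) next
    nprod <- vapply(seq_len(nrow(templates)), function(j) {
      nrow(predict_amplicons(pairs$forward_seq[k], pairs$reverse_seq[k],
                             templates$bases[j],
                             max_mismatch = constraints$max_mismatch))
    }, 0L)
    if (all(nprod[tgt] > 0L) && all(nprod[!tgt] == 0L)) {
      accepted <- rbind(accepted, pairs[k, , drop = FALSE])
    }
  }
  status <- if (nrow(accepted) == 2L) "ok" else "INFEASIBLE_DUPLEX"
  if (nrow(accepted)) {
    accepted$marker_id <- sprintf("%s_SCAR%d",
                                  gsub("\\s+", "", target_species),
                                  seq_len(nrow(accepted)))
  }
  rownames(accepted) <- NULL
  structure(list(species = target_species, markers = accepted,
                 status = status),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set for", x$species, "-", x$status, "\n")
  if (nrow(x$markers)) {
    print(x$markers[, c("marker_id", "forward_seq", "reverse_seq",
                        "expected_size")])
  }
  invisible(x)
}

#' Design duplex marker sets for every species in a panel
#'
#' @param panel `species_panel`
#' @param constraints [design_constraints()]
#' @param species subset of species to design for (default: all)
#' @return named list of `marker_set` objects
#' @export
design_all_markers <- function(panel, constraints = design_constraints(),
                               species = panel_species(panel)) {
  sets <- lapply(species, function(s) design_marker_set(panel, s, constraints))
  names(sets) <- species
  sets
}

#' Flatten marker sets into one marker table
#' @param marker_sets list of `marker_set` (or a single one)
#' @return data.frame with one row per accepted marker
#' @export
marker_table <- function(marker_sets) {
  if (inherits(marker_sets, "marker_set")) marker_sets <- list(marker_sets)
  do.call(rbind, c(lapply(marker_sets, `[[`, "markers"),
                   list(make.row.names = FALSE)))
}

#' Read a primer-pair table (TSV)
#'
#' Accepts either the per-marker layout written by [write_marker_table()]
#' (columns `marker_id`, `species`, `forward_seq`, `reverse_seq`,
#' `expected_size`, ...) or the published-table layout with columns `name`,
#' `sequence`, `expected_size`, `species`, where consecutive rows form
#' forward/reverse pairs.
#'
#' @param path TSV file
#' @return per-marker data.frame usable by [specificity_matrix()]
#' @export
read_primer_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("forward_seq", "reverse_seq") %in% names(df))) return(df)
  need <- c("name", "sequence", "expected_size", "species")
  if (!all(need %in% names(df))) {
    stop("unrecognised primer table; need columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(df) %% 2L != 0L) stop("odd number of primer rows; cannot pair")
  f <- df[seq(1L, nrow(df), 2L), ]
  r <- df[seq(2L, nrow(df), 2L), ]
  if (any(f$expected_size != r$expected_size)) {
    stop("consecutive primer rows disagree on expected_size; cannot pair")
  }
  data.frame(
    marker_id = paste0(gsub("\\s+", "_", f$name), "/",
                       gsub("\\s+", "_", r$name)),
    species = f$species,
    forward_name = f$name, forward_seq = toupper(f$sequence),
    reverse_name = r$name, reverse_seq = toupper(r$sequence),
    expected_size = as.integer(f$expected_size),
    stringsAsFactors = FALSE
  )
}

#' Write a marker table as TSV
#' @param markers per-marker data.frame
#' @param path output file
#' @export
write_marker_table <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export marker footprints as BED intervals on the target reference
#'
#' BED is 0-based half-open; the package's 1-based inclusive footprints are
#' converted accordingly.
#'
#' @param markers per-marker data.frame with `f_start` and `r_end`
#' @param ref_name reference sequence name for the BED chrom column
#' @param path output file
#' @export
write_marker_bed <- function(markers, ref_name, path) {
  bed <- data.frame(chrom = ref_name,
                    start = markers$f_start - 1L,
                    end = markers$r_end,
                    name = markers$marker_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
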