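# Authentication of unknown samples: nearest-reference classification of a
# sequenced amplicon plus a virtual duplex SCAR assay.

# identity of a global alignment excluding terminal gap columns
.alignment_identity <- function(p_aln, s_aln) {
  pc <- seq_chars(p_aln); sc <- seq_chars(s_aln)
  gap <- pc == "-" | sc == "-"
  inner <- which(!gap)
  if (!length(inner)) return(0)
  keep <- inner[1L]:inner[length(inner)]
  sum(pc[keep] == sc[keep]) / length(keep)
}

#' Classify a query sequence against a reference panel
#'
#' Global (Needleman-Wunsch) alignment of the query against every ungapped
#' panel reference, scoring match +1, mismatch -1, gap -2 by default.
#' Identity is matches over aligned columns excluding terminal gaps. The
#' best-scoring species is returned; an identity below `min_identity`, or a
#' tie between two species, yields `"unresolved"`.
#'
#' @param query ungapped query sequence (character scalar or a one-row
#'   `seq_records`), at least 100 nt
#' @param panel `species_panel`
#' @param min_identity acceptance threshold (default 0.99)
#' @param match,mismatch,gap alignment scores
#' @return list of class `classification`: `species` (or `"unresolved"`),
#'   `identity`, `best_id`, `per_record` (data frame of all identities),
#'   `tie`
#' @export
classify_query <- function(query, panel, min_identity = 0.99,
                           match = 1, mismatch = -1, gap = -2) {
  if (inherits(query, "data.frame")) query <- query$bases[1L]
  query <- toupper(query)
  if (grepl("-", query, fixed = TRUE)) stop("query must be ungapped")
  if (nchar(query) < 100L) stop("query too short (< 100 nt)")
  refs <- panel_templates(panel)
  if (nrow(refs) == 0L) stop("empty panel")
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  ident <- vapply(seq_len(nrow(refs)), function(i) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(refs$bases[i]),
      type = "global", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = abs(gap))
    .alignment_identity(as.character(Biostrings::alignedPattern(aln)),
                        as.character(Biostrings::alignedSubject(aln)))
  }, 0)
  per_record <- data.frame(id = refs$id, species = refs$species,
                           identity = ident, stringsAsFactors = FALSE)
  by_species <- vapply(split(ident, refs$species), max, 0)
  best <- max(by_species)
  top <- names(by_species)[abs(by_species - best) < 1e-12]
  tie <- length(top) > 1L
  species <- if (tie || best < min_identity) "unresolved" else top[1L]
  if (tie) message("classification tie between: ", paste(top, collapse = ", "))
  structure(
    list(species = species, identity = best,
         best_id = per_record$id[which.max(ident)],
         per_record = per_record, tie = tie),
    class = "classification"
  )
}

#' @export
print.classification <- function(x, ...) {
  cat("classification:", x$species,
      sprintf("(best identity %.4f vs %s)\n", x$identity, x$best_id))
  invisible(x)
}

#' Virtual duplex SCAR assay on a sample sequence
#'
#' Runs exact in-silico PCR with every marker against the sample. A species
#' "fires" only when both members of its duplex yield a product of exactly
#' the expected size (the duplex rule). Exactly one firing species gives the
#' assignment; several give `"mixed/adulterated"`; none gives `"unresolved
#' (non-panel species)"`. When control primers (e.g. the universal barcode
#' pair) are supplied and yield no product, the sample is `"invalid sample"`.
#' When a panel is supplied, nearest-reference classification is attached for
#' cross-checking.
#'
#' @param sample_bases ungapped sample sequence
#' @param marker_sets list of `marker_set` objects (or a flat marker table)
#' @param control_primers optional list(forward=, reverse=) universal pair
#' @param panel optional `species_panel` for the classification cross-check
#' @param sample_id identifier carried into the report
#' @return list of class `assay_result`: `sample_id`, `assigned_species`,
#'   `per_marker` (data frame: marker, species, expected/observed sizes,
#'   fired), `species_fired`, `control_its_present`, `classification`
#' @export
virtual_assay <- function(sample_bases, marker_sets, control_primers = NULL,
                          panel = NULL, sample_id = "sample") {
  markers <- if (inherits(marker_sets, "data.frame")) marker_sets else marker_table(marker_sets)
  if (is.null(markers) || nrow(markers) == 0L) stop("no validated markers supplied")
  sample_bases <- toupper(sample_bases)
  per <- lapply(seq_len(nrow(markers)), function(i) {
    a <- predict_amplicons(markers$forward_seq[i], markers$reverse_seq[i],
                           sample_bases, max_mismatch = 0L)
    data.frame(marker_id = markers$marker_id[i], species = markers$species[i],
               expected_size = markers$expected_size[i],
               observed_sizes = if (nrow(a)) paste(a$length, collapse = ",") else "",
               fired = any(a$length == markers$expected_size[i]),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  fired_by_species <- vapply(split(per$fired, per$species), all, NA)
  species_fired <- names(fired_by_species)[fired_by_species]
  control_present <- NA
  if (!is.null(control_primers)) {
    ctl <- predict_amplicons(control_primers$forward, control_primers$reverse,
                             sample_bases, max_mismatch = 0L)
    control_present <- nrow(ctl) > 0L
  }
  assigned <- if (isFALSE(control_present)) {
    "invalid sample"
  } else if (length(species_fired) == 1L) {
    species_fired
  } else if (length(species_fired) > 1L) {
    "mixed/adulterated"
  } else {
    "unresolved (non-panel species)"
  }
  cls <- if (!is.null(panel) && nchar(sample_bases) >= 100L) {
    tryCatch(classify_query(sample_bases, panel), error = function(e) NULL)
  }
  structure(
    list(sample_id = sample_id, assigned_species = assigned,
         per_marker = per, species_fired = species_fired,
         control_its_present = control_present, classification = cls),
    class = "assay_result"
  )
}

#' @export
print.assay_result <- function(x, ...) {
  cat("assay_result [", x$sample_id, "]: ", x$assigned_species, "\n", sep = "")
  print(x$per_marker[, c("marker_id", "species", "expected_size",
                         "observed_sizes", "fired")])
  if (!is.na(x$control_its_present)) {
    cat("control product present:", x$control_its_present, "\n")
  }
  if (!is.null(x$classification)) {
    cat(sprintf("nearest reference: %s (identity %.4f)\n",
                x$classification$species, x$classification$identity))
  }
  invisible(x)
}
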