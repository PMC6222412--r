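# IUPAC nucleotide semantics, FASTA I/O and primer physical properties.
#
# Sequences are plain uppercase character scalars over the IUPAC alphabet
# plus '-' (gap, only meaningful inside an alignment). All coordinates in
# this package are 1-based inclusive.

# bitmask encoding: A=1, C=2, G=4, T=8; ambiguity codes are unions,
# gap encodes to 0 (matches nothing).
.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L, `-` = 0L
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
  V = "B", H = "D", D = "H", B = "V", N = "N"
)

#' Split a sequence string into single characters
#' @param bases character scalar
#' @return character vector of single bases
#' @keywords internal
seq_chars <- function(bases) {
  if (length(bases) != 1L) stop("expected a single sequence string")
  strsplit(toupper(bases), "", fixed = TRUE)[[1L]]
}

#' Encode a sequence as IUPAC bitmasks
#'
#' A=1, C=2, G=4, T=8; ambiguity codes are bitwise unions of their expansion;
#' gaps (and any unknown character) encode to 0 and therefore match nothing.
#'
#' @param bases character scalar (sequence) or character vector of single bases
#' @return integer vector of bitmasks
#' @export
encode_iupac <- function(bases) {
  ch <- if (length(bases) == 1L && nchar(bases[1L]) != 1L) seq_chars(bases) else toupper(bases)
  m <- .IUPAC_MASK[ch]
  m[is.na(m)] <- 0L
  unname(m)
}

#' Test whether a primer base can pair with a template base
#'
#' True iff the IUPAC expansion sets of the two codes intersect. A gap on
#' either side never matches (returns `FALSE`, not an error).
#'
#' @param primer_base,template_base single IUPAC characters
#' @return logical
#' @export
iupac_match <- function(primer_base, template_base) {
  bitwAnd(encode_iupac(primer_base), encode_iupac(template_base)) > 0L
}

#' Reverse complement of an IUPAC sequence
#'
#' Applies the IUPAC complement table (R<->Y, K<->M, S and W self-complementary,
#' N->N) and reverses. Gap characters are not allowed: primers and templates
#' handled here are ungapped.
#'
#' @param bases character scalar, IUPAC letters only
#' @return character scalar
#' @export
revcomp <- function(bases) {
  if (nchar(bases) == 0L) return("")
  ch <- seq_chars(bases)
  if (any(ch == "-")) stop("revcomp: gap character in sequence")
  comp <- .IUPAC_COMPLEMENT[ch]
  if (anyNA(comp)) {
    stop("revcomp: non-IUPAC character '", ch[which(is.na(comp))[1L]], "'")
  }
  paste(rev(unname(comp)), collapse = "")
}

#' GC content of a sequence
#'
#' Fraction (#G + #C + #S) / (#A + #C + #G + #T + #S + #W). Gaps, N and all
#' other ambiguity codes are excluded from numerator and denominator; S (G/C)
#' and W (A/T) are informative for GC content and are kept.
#'
#' @param bases character scalar
#' @return fraction in \[0, 1\]
#' @export
gc_content <- function(bases) {
  ch <- seq_chars(bases)
  num <- sum(ch %in% c("G", "C", "S"))
  den <- sum(ch %in% c("A", "C", "G", "T", "S", "W"))
  if (den == 0L) stop("gc_content: no unambiguous bases (all gaps or ambiguous)")
  num / den
}

#' Wallace-rule melting temperature
#'
#' Tm = 2(A+T) + 4(G+C) degrees C; the classic salt-free approximation for
#' short oligos, used here as a design-window statistic rather than a
#' thermodynamic prediction. Undefined for ambiguity codes.
#'
#' @param primer character scalar, unambiguous; meaningful for the 8-36 nt
#'   oligo range the rule was derived for
#' @return numeric, degrees C
#' @export
tm_wallace <- function(primer) {
  ch <- seq_chars(primer)
  if (length(ch) == 0L) stop("tm_wallace: empty primer")
  if (!all(ch %in% c("A", "C", "G", "T"))) {
    stop("tm_wallace: ambiguity code present; Wallace rule undefined")
  }
  2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
}

#' Construct a set of sequence records
#'
#' Records are held as a data frame with columns `id`, `species`,
#' `description`, `bases`. Sequences are uppercased and U is normalised to T.
#'
#' @param id,bases character vectors of equal length
#' @param species species labels (default `"unknown"`)
#' @param description free-text descriptions (default `""`)
#' @return data.frame of class `seq_records`
#' @export
seq_records <- function(id, bases, species = "unknown", description = "") {
  stopifnot(length(id) == length(bases))
  bases <- gsub("U", "T", toupper(bases), fixed = TRUE)
  if (any(nchar(bases) == 0L)) stop("empty sequence for record ", id[nchar(bases) == 0L][1L])
  ok <- c(names(.IUPAC_MASK))
  for (i in seq_along(bases)) {
    ch <- seq_chars(bases[i])
    bad <- which(!ch %in% ok)
    if (length(bad)) {
      stop("non-IUPAC character '", ch[bad[1L]], "' in record '", id[i],
           "' at position ", bad[1L])
    }
  }
  out <- data.frame(
    id = as.character(id),
    species = rep_len(as.character(species), length(id)),
    description = rep_len(as.character(description), length(id)),
    bases = bases,
    stringsAsFactors = FALSE
  )
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Read a FASTA file into sequence records
#'
#' The species label is parsed from the header using a delimiter-separated
#' token (default: the second `|`-delimited field); records whose header has
#' no such field get species `"unknown"`. Sequences are uppercased, U is
#' normalised to T, and every character is validated against the IUPAC
#' alphabet (plus `-`), with errors naming record and position.
#'
#' @param path FASTA file
#' @param species_delim delimiter splitting the header (default `"|"`)
#' @param species_field 1-based field index holding the species label
#' @return `seq_records` data frame, in file order
#' @export
read_fasta <- function(path, species_delim = "|", species_field = 2L) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  headers <- names(x)
  first_tok <- vapply(strsplit(headers, "[ \t]+"), `[`, "", 1L)
  fields <- strsplit(first_tok, species_delim, fixed = TRUE)
  ids <- vapply(fields, `[`, "", 1L)
  species <- vapply(fields, function(f) {
    if (length(f) >= species_field && nzchar(f[species_field])) f[species_field] else "unknown"
  }, "")
  desc <- sub("^\\S+\\s*", "", headers)
  seq_records(ids, as.character(x), species = species, description = desc)
}

#' Write sequence records to FASTA
#'
#' Headers are `id|species` (plus description when present), so
#' [read_fasta()] round-trips records exactly.
#'
#' @param records `seq_records`
#' @param path output file
#' @param width line-wrap width (default 70)
#' @export
write_fasta <- function(records, path, width = 70L) {
  hdr <- ifelse(records$species == "unknown", records$id,
                paste(records$id, records$species, sep = "|"))
  hdr <- ifelse(nzchar(records$description), paste(hdr, records$description), hdr)
  x <- Biostrings::BStringSet(records$bases)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Remove gap characters from a sequence
#' @param bases character scalar
#' @return ungapped character scalar
#' @export
degap <- function(bases) gsub("-", "", bases, fixed = TRUE)

#' Assemble a labelled species panel from an alignment
#'
#' The substrate for diagnostic-site discovery, distance summaries and tree
#' building: an alignment of reference barcode sequences with at least two
#' distinct species labels.
#'
#' @param records `seq_records`, all of equal (aligned) length
#' @return object of class `species_panel` with elements `records`,
#'   `aligned_length`, `mat` (records x columns character matrix)
#' @export
species_panel <- function(records) {
  if (!inherits(records, "data.frame")) stop("records must be a seq_records data frame")
  if (nrow(records) < 2L) stop("a panel needs at least 2 records")
  len <- unique(nchar(records$bases))
  if (length(len) != 1L) {
    stop("records are not aligned: lengths ", paste(sort(len), collapse = ", "))
  }
  if (length(unique(records$species)) < 2L) {
    stop("a panel needs at least 2 distinct species")
  }
  if (anyDuplicated(records$id)) stop("duplicate record ids in panel")
  mat <- do.call(rbind, lapply(records$bases, seq_chars))
  rownames(mat) <- records$id
  structure(
    list(records = records, aligned_length = len, mat = mat),
    class = "species_panel"
  )
}

#' @export
print.species_panel <- function(x, ...) {
  tab <- table(x$records$species)
  cat("species_panel:", nrow(x$records), "records,",
      length(tab), "species, aligned length", x$aligned_length, "bp\n")
  for (s in names(tab)) cat("  ", s, ": ", tab[[s]], " record(s)\n", sep = "")
  invisible(x)
}

#' Species labels of a panel
#' @param panel `species_panel`
#' @return character vector of distinct species, in panel order
#' @export
panel_species <- function(panel) unique(panel$records$species)

#' Ungapped template records of a panel
#'
#' Degaps every panel sequence; used when panel members serve as PCR
#' templates.
#'
#' @param panel `species_panel`
#' @return `seq_records` with gaps removed
#' @export
panel_templates <- function(panel) {
  r <- panel$records
  seq_records(r$id, vapply(r$bases, degap, ""), species = r$species,
              description = r$description)
}
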