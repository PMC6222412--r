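# Synthetic reference panels with recorded ground truth.
#
# Sequences evolve from a random ancestor along a star-of-stars genealogy:
# one branch per species (substitutions + short deletions), then one short
# branch per individual. Ground truth records every mutation, the planted
# diagnostic columns, and the conserved flanking segments that act as
# universal primer sites, so design, distance and assay code can be checked
# against a known answer without any external data.

#' Specification for a synthetic reference panel
#'
#' Defaults emulate a realistic multi-species ITS barcode panel: 6 species,
#' 2-4 sequences each, ~580 bp, near-zero intraspecific divergence,
#' interspecific divergence in the 9-21% band, occasional short indels,
#' transition/transversion ratio 2, and conserved 21-bp flanks where
#' universal primers bind.
#'
#' @param seed integer RNG seed (mandatory; same seed, same panel)
#' @param n_species number of species (default 6)
#' @param n_per_species records per species; scalar or vector (default 3)
#' @param length ancestor length in bp (default 580)
#' @param inter_divergence length-2 target band for pairwise interspecific
#'   divergence (default c(0.09, 0.21))
#' @param intra_divergence length-2 target band for pairwise intraspecific
#'   divergence (default c(0, 0.003))
#' @param indel_rate expected fraction of sites deleted per species branch
#'   (default 0.005, i.e. ~3 bp in 1-5 bp events)
#' @param tstv transition/transversion ratio of the mutation sampler
#'   (default 2)
#' @param gc ancestor GC fraction (default 0.58)
#' @param conserved_flank length of each mutation-free terminal segment
#'   (default 21)
#' @return list of class `panel_spec`
#' @export
panel_spec <- function(seed, n_species = 6L, n_per_species = 3L,
                       length = 580L, inter_divergence = c(0.09, 0.21),
                       intra_divergence = c(0, 0.003), indel_rate = 0.005,
                       tstv = 2, gc = 0.58, conserved_flank = 21L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_species >= 2L, length > 4L * conserved_flank,
            all(inter_divergence >= 0), all(inter_divergence <= 1),
            all(intra_divergence >= 0), all(intra_divergence <= 1),
            indel_rate >= 0, indel_rate <= 1)
  n_per_species <- rep_len(as.integer(n_per_species), n_species)
  # per-species branch divergence is half the pairwise target; check feasible
  if (inter_divergence[2L] / 2 * length > length - 2L * conserved_flank) {
    stop("divergence targets incompatible with sequence length")
  }
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 n_per_species = n_per_species, length = as.integer(length),
                 inter_divergence = inter_divergence,
                 intra_divergence = intra_divergence,
                 indel_rate = indel_rate, tstv = tstv, gc = gc,
                 conserved_flank = as.integer(conserved_flank)),
            class = "panel_spec")
}

# draw a substituted base: transition with probability tstv/(tstv+1)
.mutate_base <- function(base, tstv) {
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  if (stats::runif(1) < tstv / (tstv + 1)) ts_map[[base]]
  else sample(tv_map[[base]], 1L)
}

#' Generate a synthetic species panel with ground truth
#'
#' @param spec [panel_spec()]
#' @return list: `panel` (`species_panel`), `truth` (list with `ancestor`,
#'   `species_mutations`, `individual_mutations`, `diagnostic_columns` per
#'   species, `universal_primers`, `species_branch_divergence`)
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  L <- spec$length
  flank <- spec$conserved_flank
  bases4 <- c("A", "C", "G", "T")
  anc <- sample(bases4, L, replace = TRUE,
                prob = c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2,
                         (1 - spec$gc) / 2))
  mutable <- (flank + 1L):(L - flank)
  sp_names <- paste0("Species_", LETTERS[seq_len(spec$n_species)])
  sp_seqs <- list()
  sp_mut <- list()
  branch_div <- stats::runif(spec$n_species, spec$inter_divergence[1L] / 2,
                             spec$inter_divergence[2L] / 2)
  for (s in seq_len(spec$n_species)) {
    seqs <- anc
    n_sub <- round(branch_div[s] * L)
    pos <- sample(mutable, n_sub)
    for (p in pos) {
      to <- .mutate_base(seqs[p], spec$tstv)
      sp_mut[[length(sp_mut) + 1L]] <- data.frame(
        species = sp_names[s], column = p, from = seqs[p], to = to,
        kind = "substitution", stringsAsFactors = FALSE)
      seqs[p] <- to
    }
    # short deletions until ~indel_rate * L sites are gapped
    target_del <- round(spec$indel_rate * L)
    deleted <- 0L
    while (deleted < target_del) {
      w <- sample(1:5, 1L)
      a <- sample(mutable[mutable <= max(mutable) - w + 1L], 1L)
      cols <- a:(a + w - 1L)
      cols <- cols[seqs[cols] != "-"]
      if (!length(cols)) next
      for (p in cols) {
        sp_mut[[length(sp_mut) + 1L]] <- data.frame(
          species = sp_names[s], column = p, from = seqs[p], to = "-",
          kind = "indel", stringsAsFactors = FALSE)
      }
      seqs[cols] <- "-"
      deleted <- deleted + length(cols)
    }
    sp_seqs[[s]] <- seqs
  }
  sp_mut <- if (length(sp_mut)) do.call(rbind, sp_mut) else
    data.frame(species = character(0), column = integer(0),
               from = character(0), to = character(0), kind = character(0))
  # individuals: private substitutions on top of the species sequence
  ids <- character(0); species <- character(0); seq_str <- character(0)
  ind_mut <- list()
  for (s in seq_len(spec$n_species)) {
    for (k in seq_len(spec$n_per_species[s])) {
      seqs <- sp_seqs[[s]]
      rate <- stats::runif(1, spec$intra_divergence[1L],
                           spec$intra_divergence[2L]) / 2
      n_priv <- stats::rbinom(1L, L, rate)
      if (n_priv > 0L) {
        pos <- sample(mutable, n_priv)
        pos <- pos[seqs[pos] != "-"]
        for (p in pos) {
          to <- .mutate_base(seqs[p], spec$tstv)
          ind_mut[[length(ind_mut) + 1L]] <- data.frame(
            id = paste0("Sp", LETTERS[s], "_", k), column = p,
            from = seqs[p], to = to, stringsAsFactors = FALSE)
          seqs[p] <- to
        }
      }
      ids <- c(ids, paste0("Sp", LETTERS[s], "_", k))
      species <- c(species, sp_names[s])
      seq_str <- c(seq_str, paste(seqs, collapse = ""))
    }
  }
  ind_mut <- if (length(ind_mut)) do.call(rbind, ind_mut) else
    data.frame(id = character(0), column = integer(0), from = character(0),
               to = character(0))
  # planted diagnostics: columns touched by exactly one species branch and by
  # no individual branch
  col_species <- split(sp_mut$species, sp_mut$column)
  uniq_cols <- as.integer(names(col_species)[
    vapply(col_species, function(x) length(unique(x)) == 1L, NA)])
  uniq_cols <- setdiff(uniq_cols, ind_mut$column)
  diag_cols <- lapply(sp_names, function(s) {
    sort(intersect(uniq_cols, sp_mut$column[sp_mut$species == s])) })
  names(diag_cols) <- sp_names
  records <- seq_records(ids, seq_str, species = species)
  truth <- list(
    ancestor = paste(anc, collapse = ""),
    species_mutations = sp_mut,
    individual_mutations = ind_mut,
    diagnostic_columns = diag_cols,
    species_branch_divergence = stats::setNames(branch_div, sp_names),
    universal_primers = list(
      forward = paste(anc[1:flank], collapse = ""),
      reverse = revcomp(paste(anc[(L - flank + 1L):L], collapse = "")))
  )
  list(panel = species_panel(records), truth = truth)
}

#' Write a synthetic panel and its ground truth to disk
#'
#' FASTA (headers `id|species`) plus a JSON sidecar with the ground truth.
#'
#' @param generated output of [generate_panel()]
#' @param fasta_path,json_path output files
#' @export
write_panel <- function(generated, fasta_path, json_path) {
  write_fasta(generated$panel$records, fasta_path)
  jsonlite::write_json(generated$truth, json_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(fasta_path)
}

#' Generate a sample sequence from a panel species
#'
#' Draws a conspecific panel sequence (ungapped) and adds `n_private_mutations`
#' substitutions, either avoiding or restricted to the supplied footprint
#' intervals (1-based inclusive on the ungapped sequence) — for assay
#' robustness tests.
#'
#' @param panel `species_panel`
#' @param species species label to sample from
#' @param n_private_mutations substitutions to add (default 0)
#' @param seed integer RNG seed
#' @param footprints optional data.frame with `start`, `end` intervals
#' @param inside if TRUE mutations are placed inside the footprints,
#'   otherwise outside (default FALSE)
#' @return one-row `seq_records`
#' @export
generate_sample <- function(panel, species, n_private_mutations = 0L, seed = 1L,
                            footprints = NULL, inside = FALSE) {
  idx <- which(panel$records$species == species)
  if (!length(idx)) stop("species not in panel: ", species)
  set.seed(as.integer(seed))
  i <- sample(idx, 1L)
  ch <- seq_chars(degap(panel$records$bases[i]))
  pos_ok <- seq_along(ch)
  if (!is.null(footprints) && nrow(footprints)) {
    in_fp <- rep(FALSE, length(ch))
    for (k in seq_len(nrow(footprints))) {
      in_fp[footprints$start[k]:footprints$end[k]] <- TRUE
    }
    pos_ok <- if (inside) which(in_fp) else which(!in_fp)
  }
  if (n_private_mutations > 0L) {
    pos <- sample(pos_ok, min(n_private_mutations, length(pos_ok)))
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  seq_records(paste0("sample_", panel$records$id[i]),
              paste(ch, collapse = ""), species = species)
}

#' Synthetic templates embedding the binding sites of published markers
#'
#' Builds, for each species in a marker table, one synthetic template: a
#' seeded random background into which every marker's forward primer and the
#' reverse complement of its reverse primer are written at exactly the
#' spacing implied by the expected amplicon size. These stand-in templates
#' let the in-silico PCR engine be validated against a published primer
#' table when the originating reference sequences are not at hand; they
#' reproduce primer geometry, not real flanking sequence.
#'
#' @param markers per-marker table (`marker_id`, `species`, `forward_seq`,
#'   `reverse_seq`, `expected_size`)
#' @param seed RNG seed for the background sequence
#' @param margin background bases between embedded marker zones (default 60)
#' @param flank background bases before the first and after the last zone
#'   (default 150)
#' @return `seq_records`, one synthetic template per species
#' @export
embed_markers <- function(markers, seed = 1L, margin = 60L, flank = 150L) {
  set.seed(as.integer(seed))
  species <- unique(markers$species)
  recs <- lapply(species, function(s) {
    mk <- markers[markers$species == s, , drop = FALSE]
    mk <- mk[order(-mk$expected_size), , drop = FALSE]
    L <- 2L * flank + sum(mk$expected_size + margin)
    ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # placed motifs: published duplexes may share a binding site (one
    # marker's reverse site is another's forward site); anchor to an
    # existing identical motif rather than writing a duplicate occurrence
    placed <- data.frame(text = character(0), start = integer(0))
    find_placed <- function(text) {
      hit <- which(placed$text == text)
      if (length(hit)) placed$start[hit[1L]] else NA_integer_
    }
    write_motif <- function(text, at) {
      ch[at:(at + nchar(text) - 1L)] <<- seq_chars(text)
      placed[nrow(placed) + 1L, ] <<- list(text, at)
    }
    pos <- flank + 1L
    for (k in seq_len(nrow(mk))) {
      f_txt <- mk$forward_seq[k]
      r_txt <- revcomp(mk$reverse_seq[k])
      size <- mk$expected_size[k]
      f_at <- find_placed(f_txt)
      r_at <- find_placed(r_txt)
      if (!is.na(f_at)) {
        write_motif(r_txt, f_at + size - nchar(r_txt))
      } else if (!is.na(r_at)) {
        p <- r_at + nchar(r_txt) - size
        if (p < 1L) stop("embed_markers: increase flank for anchored marker ",
                         mk$marker_id[k])
        write_motif(f_txt, p)
      } else {
        write_motif(f_txt, pos)
        write_motif(r_txt, pos + size - nchar(r_txt))
        pos <- pos + size + margin
      }
    }
    seq_records(paste0("synthetic_", gsub("[^A-Za-z0-9]+", "_", s)),
                paste(ch, collapse = ""), species = s,
                description = "synthetic embedded-marker template")
  })
  do.call(rbind, recs)
}

#' Generate a dilution series with known curve parameters
#'
#' Ct = intercept + true_slope * log10(quantity) + Normal(0, noise_sd).
#'
#' @param true_slope,intercept generating parameters (cycles per log10 ng,
#'   cycles)
#' @param quantities template quantities in ng (default the 10-fold series
#'   15 ng .. 1.5 pg)
#' @param noise_sd Ct noise SD in cycles (default 0)
#' @param seed integer RNG seed
#' @param label series label
#' @return data.frame: `label`, `quantity_ng`, `ct`
#' @export
generate_dilution_series <- function(true_slope, intercept,
                                     quantities = dilution_plan(15, 10, 5L),
                                     noise_sd = 0, seed = 1L,
                                     label = "synthetic") {
  stopifnot(all(quantities > 0))
  set.seed(as.integer(seed))
  ct <- intercept + true_slope * log10(quantities) +
    stats::rnorm(length(quantities), 0, noise_sd)
  data.frame(label = label, quantity_ng = quantities, ct = ct,
             stringsAsFactors = FALSE)
}
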