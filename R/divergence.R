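# Pairwise distances (p and Kimura two-parameter) with pairwise deletion,
# and the per-species intra-/inter-specific variability summary.

.valid_base_code <- c(1L, 2L, 4L, 8L)  # A, C, G, T only; ambiguity treated as gap

#' Pairwise distance between two aligned sequences
#'
#' Distances are computed over the L columns where both sequences carry an
#' unambiguous base (pairwise deletion: gaps, N and all ambiguity codes are
#' excluded). P is the transition proportion (A<->G, C<->T), Q the
#' transversion proportion. Under the p model d = P + Q; under the Kimura
#' two-parameter (K2P) model d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q)).
#'
#' @param a,b aligned sequences (character scalars of equal length)
#' @param model `"K2P"` (default) or `"p"`
#' @return list with `d`, `P`, `Q`, `L`
#' @export
pairwise_distance <- function(a, b, model = c("K2P", "p")) {
  model <- match.arg(model)
  ca <- encode_iupac(a)
  cb <- encode_iupac(b)
  if (length(ca) != length(cb)) stop("sequences must be aligned to equal length")
  keep <- ca %in% .valid_base_code & cb %in% .valid_base_code
  L <- sum(keep)
  if (L == 0L) stop("no comparable sites")
  ca <- ca[keep]; cb <- cb[keep]
  diff <- ca != cb
  # transitions are purine<->purine (1,4) or pyrimidine<->pyrimidine (2,8)
  ts <- diff & ((ca + cb) == 5L | (ca + cb) == 10L)
  P <- sum(ts) / L
  Q <- sum(diff & !ts) / L
  d <- if (model == "p") {
    P + Q
  } else {
    if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
      stop("distance undefined (saturation)")
    }
    -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  }
  list(d = d, P = P, Q = Q, L = L)
}

#' All-pairs distance matrix for a panel
#'
#' @param panel `species_panel` (or `seq_records` alignment)
#' @param model `"K2P"` or `"p"`
#' @return object of class `distance_matrix`: list with symmetric matrices
#'   `d`, `P`, `Q`, `L`, plus `labels`, `species`, `model`
#' @export
distance_matrix <- function(panel, model = c("K2P", "p")) {
  model <- match.arg(model)
  if (!inherits(panel, "species_panel")) panel <- species_panel(panel)
  n <- nrow(panel$records)
  ids <- panel$records$id
  d <- P <- Q <- matrix(0, n, n, dimnames = list(ids, ids))
  L <- matrix(panel$aligned_length, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pd <- pairwise_distance(panel$records$bases[i], panel$records$bases[j], model)
      d[i, j] <- d[j, i] <- pd$d
      P[i, j] <- P[j, i] <- pd$P
      Q[i, j] <- Q[j, i] <- pd$Q
      L[i, j] <- L[j, i] <- pd$L
    }
  }
  structure(
    list(d = d, P = P, Q = Q, L = L, labels = ids,
         species = panel$records$species, model = model),
    class = "distance_matrix"
  )
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix (", x$model, "), ", length(x$labels), " taxa\n", sep = "")
  print(round(x$d, 4))
  invisible(x)
}

#' @export
as.matrix.distance_matrix <- function(x, ...) x$d

# population SD (n denominator), the MEGA-style convention used for the
# variability table
.sd_pop <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Intra- and inter-specific variability summary
#'
#' For each species: mean +/- SD of pairwise distances within the species
#' (undefined when the species has a single record), mean +/- SD of distances
#' against all records of other species, the ungapped sequence length and the
#' GC content. SD uses the population (n) denominator. By default the
#' inter-specific mean is over all heterospecific pairs; `inter_mode =
#' "species_means"` averages per-species-pair means instead.
#'
#' @param panel `species_panel`
#' @param model `"K2P"` or `"p"`
#' @param inter_mode `"pairs"` (default) or `"species_means"`
#' @return data.frame of class `variability_summary`, one row per species:
#'   `species`, `n`, `constant_length`, `gc_percent`, `intra_mean`,
#'   `intra_sd`, `inter_mean`, `inter_sd`
#' @export
variability_summary <- function(panel, model = c("K2P", "p"),
                                inter_mode = c("pairs", "species_means")) {
  model <- match.arg(model)
  inter_mode <- match.arg(inter_mode)
  dm <- distance_matrix(panel, model)
  sp <- dm$species
  species <- unique(sp)
  if (length(species) < 2L) stop("panel must contain at least 2 species")
  rows <- lapply(species, function(s) {
    in_s <- which(sp == s)
    out_s <- which(sp != s)
    intra <- if (length(in_s) >= 2L) {
      dm$d[in_s, in_s][upper.tri(matrix(0, length(in_s), length(in_s)))]
    } else numeric(0)
    inter <- if (inter_mode == "pairs") {
      as.vector(dm$d[in_s, out_s, drop = FALSE])
    } else {
      vapply(unique(sp[out_s]), function(t) {
        mean(dm$d[in_s, which(sp == t), drop = FALSE])
      }, 0)
    }
    lens <- nchar(vapply(panel$records$bases[in_s], degap, ""))
    gcs <- vapply(panel$records$bases[in_s], gc_content, 0)
    data.frame(
      species = s, n = length(in_s),
      constant_length = as.integer(round(mean(lens))),
      gc_percent = 100 * mean(gcs),
      intra_mean = if (length(intra)) mean(intra) else NA_real_,
      intra_sd = if (length(intra)) .sd_pop(intra) else NA_real_,
      inter_mean = mean(inter),
      inter_sd = .sd_pop(inter),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "model") <- model
  class(out) <- c("variability_summary", "data.frame")
  out
}

#' Write a distance matrix as a PHYLIP square matrix
#' @param dm `distance_matrix`
#' @param path output file
#' @export
write_phylip <- function(dm, path) {
  n <- length(dm$labels)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(formatC(dm$labels[i], width = -10),
                      paste(sprintf("%.6f", dm$d[i, ]), collapse = "  "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write a distance matrix as TSV
#' @param dm `distance_matrix`
#' @param path output file
#' @export
write_distance_tsv <- function(dm, path) {
  df <- data.frame(id = dm$labels, as.data.frame(dm$d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
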