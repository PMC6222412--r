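# Real-time PCR standard-curve analytics: slope, intercept, R^2,
# amplification efficiency and limit-of-detection bookkeeping.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(template quantity in ng). R^2 is
#' the squared Pearson correlation of (log10 quantity, Ct). The amplification
#' efficiency E = (10^(-1/slope) - 1) x 100 is attached when the slope is
#' negative, both as a percentage and as the integer value conventionally
#' reported (rounded half away from zero).
#'
#' @param quantity_ng template quantities in ng (strictly positive), or a
#'   data.frame with columns `quantity_ng` and `ct`
#' @param ct threshold-cycle values (may contain NA; such points are dropped
#'   with a warning)
#' @param label assay/species label carried into the result
#' @return list of class `standard_curve`: `label`, `slope` (cycles per
#'   log10 ng), `intercept`, `r_squared`, `efficiency_percent`,
#'   `efficiency_reported`, `n_points`
#' @export
fit_standard_curve <- function(quantity_ng, ct = NULL, label = "") {
  if (is.data.frame(quantity_ng)) {
    df <- quantity_ng
    stopifnot(all(c("quantity_ng", "ct") %in% names(df)))
    if (!nzchar(label) && "label" %in% names(df)) label <- df$label[1L]
    ct <- df$ct
    quantity_ng <- df$quantity_ng
  }
  if (any(quantity_ng <= 0)) stop("quantities must be strictly positive (ng)")
  drop <- is.na(ct)
  if (any(drop)) {
    warning(sum(drop), " point(s) with missing Ct dropped")
    quantity_ng <- quantity_ng[!drop]; ct <- ct[!drop]
  }
  if (length(unique(quantity_ng)) < 2L) stop("degenerate dilution: need >= 2 distinct quantities")
  lq <- log10(quantity_ng)
  fit <- stats::lm(ct ~ lq)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- stats::cor(lq, ct)^2
  eff <- if (slope < 0) efficiency_from_slope(slope) else NA_real_
  structure(
    list(label = label, slope = slope, intercept = intercept,
         r_squared = r2,
         efficiency_percent = eff,
         efficiency_reported = if (is.na(eff)) NA_integer_ else round_half_away(eff),
         n_points = length(ct)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("standard_curve", if (nzchar(x$label)) paste0("[", x$label, "]"), "\n",
      sprintf("  slope %.3f cycles/log10(ng), intercept %.2f, R^2 %.5f\n",
              x$slope, x$intercept, x$r_squared))
  if (!is.na(x$efficiency_percent)) {
    cat(sprintf("  efficiency %.2f%% (reported %d%%), n = %d\n",
                x$efficiency_percent, x$efficiency_reported, x$n_points))
  }
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' E = (10^(-1/slope) - 1) x 100, in percent; 100% corresponds to perfect
#' per-cycle doubling (slope = -1/log10(2) = -3.3219). Strictly decreasing in
#' |slope| for negative slopes. Undefined for non-negative slopes.
#'
#' @param slope cycles per log10(ng), must be negative
#' @return efficiency in percent
#' @export
efficiency_from_slope <- function(slope) {
  if (any(slope >= 0)) stop("efficiency undefined for slope >= 0")
  (10^(-1 / slope) - 1) * 100
}

#' Round half away from zero
#'
#' The convention of instrument-software integer reporting (99.5 -> 100,
#' 130.5 -> 131), unlike R's banker's rounding.
#'
#' @param x numeric
#' @return integer
#' @export
round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Limit of detection of a dilution series
#'
#' The smallest tested quantity whose observed Ct lies below the cutoff,
#' plus the quantity extrapolated from the fitted curve at the cutoff,
#' 10^((cutoff - intercept)/slope).
#'
#' @param quantity_ng,ct dilution series (ng, cycles)
#' @param ct_cutoff detection cutoff in cycles (default 40)
#' @param curve optional precomputed `standard_curve` (refit otherwise)
#' @return list: `lod_ng` (NA when nothing is detected), `detected` logical
#'   vector, `extrapolated_lod_ng`, `status`
#' @export
detection_limit <- function(quantity_ng, ct, ct_cutoff = 40, curve = NULL) {
  detected <- !is.na(ct) & ct < ct_cutoff
  if (is.null(curve)) {
    curve <- fit_standard_curve(quantity_ng[!is.na(ct)], ct[!is.na(ct)])
  }
  extrap <- 10^((ct_cutoff - curve$intercept) / curve$slope)
  if (!any(detected)) {
    return(list(lod_ng = NA_real_, detected = detected,
                extrapolated_lod_ng = extrap,
                status = "not detected in tested range"))
  }
  list(lod_ng = min(quantity_ng[detected]), detected = detected,
       extrapolated_lod_ng = extrap, status = "detected")
}

#' Serial dilution plan
#'
#' Geometric series `top_mass / fold^k`, k = 0..n-1 (e.g. a 10-fold series
#' from 15 ng down).
#'
#' @param top_mass highest quantity (same unit as the result)
#' @param fold dilution factor (> 1)
#' @param n number of points
#' @return numeric vector of quantities
#' @export
dilution_plan <- function(top_mass, fold = 10, n = 6L) {
  stopifnot(top_mass > 0, fold > 1, n >= 1L)
  top_mass / fold^(0:(n - 1L))
}

#' Read a dilution-series Ct table (CSV)
#'
#' Expected columns: `label`, `quantity_ng`, `ct`.
#'
#' @param path CSV file
#' @return data.frame
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "quantity_ng", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table must have columns ", paste(need, collapse = ", "))
  }
  df
}

#' Standard-curve report for a multi-assay Ct table
#'
#' Fits one standard curve per `label` and returns the conventional report
#' columns: slope, R^2, efficiencies and limit of detection.
#'
#' @param ct_table data.frame with `label`, `quantity_ng`, `ct`
#' @param ct_cutoff LOD cutoff in cycles (default 40)
#' @return data.frame, one row per label
#' @export
standard_curve_report <- function(ct_table, ct_cutoff = 40) {
  labs <- unique(ct_table$label)
  rows <- lapply(labs, function(l) {
    d <- ct_table[ct_table$label == l, ]
    sc <- fit_standard_curve(d$quantity_ng, d$ct, label = l)
    dl <- detection_limit(d$quantity_ng, d$ct, ct_cutoff, curve = sc)
    data.frame(label = l, n_points = sc$n_points,
               slope = sc$slope, intercept = sc$intercept,
               r_squared = sc$r_squared,
               efficiency_percent = sc$efficiency_percent,
               efficiency_reported = sc$efficiency_reported,
               lod_ng = dl$lod_ng,
               extrapolated_lod_ng = dl$extrapolated_lod_ng,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
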