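# Sub-grid apex estimate of a smooth spectral band: quadratic fit to
# log(loading) over the contiguous near-apex window (a Gaussian band is an
# exact parabola in log space). Falls back to the grid argmax when the
# window is too small or the fit is not concave.
refine_peak <- function(axis, v, i, frac = 0.7) {
  lo <- i
  while (lo > 1 && v[lo - 1] <= v[lo] && v[lo - 1] >= frac * v[i]) lo <- lo - 1
  hi <- i
  n <- length(v)
  while (hi < n && v[hi + 1] <= v[hi] && v[hi + 1] >= frac * v[i]) hi <- hi + 1
  win <- lo:hi
  if (length(win) < 3 || any(v[win] <= 0)) return(axis[i])
  X <- cbind(1, axis[win], axis[win]^2)
  b <- tryCatch(qr.coef(qr(X), log(v[win])), error = function(e) NULL)
  if (is.null(b) || anyNA(b) || b[3] >= 0) return(axis[i])
  apex <- -b[2] / (2 * b[3])
  if (apex < axis[lo] || apex > axis[hi]) return(axis[i])
  apex
}

#' Locate the spectral peaks of one fitted component
#'
#' The emission peak is the argmax of the emission loading, refined to a
#' sub-grid position by a quadratic fit to the log-loading around the apex
#' (exact for a Gaussian band, so the reported position is not quantized
#' by the measurement grid). Excitation peaks are the local maxima of the
#' excitation loading that reach at least `secondary_fraction` of its
#' global maximum, ordered by height (primary first) and refined the same
#' way. A maximum sitting on the first or last grid point is flagged
#' `boundary_censored` — the true band may continue beyond the measured
#' range — is not refined, and is rendered as `"<= lambda"` in printed
#' output.
#'
#' @param model a `parafac_model`.
#' @param f component index.
#' @param secondary_fraction minimum height of a reported secondary
#'   excitation peak, as a fraction of the global maximum.
#' @param refine report sub-grid apex positions (`TRUE`) or raw grid
#'   argmax positions (`FALSE`).
#' @param label optional component label (default `"C<f>"`).
#' @return An object of class `component_spectrum` with `label`,
#'   `emission_peak` (nm), `excitation_peaks` (data frame: `wavelength`,
#'   `wavelength_grid`, `height`, `boundary_censored`) and `coble_class`
#'   (filled by [classify_coble()]).
#' @export
find_component_peaks <- function(model, f, secondary_fraction = 0.5,
                                 refine = TRUE, label = NULL) {
  stopifnot(inherits(model, "parafac_model"),
            f >= 1, f <= model$n_components)
  bl <- model$emission_loadings[, f]
  cl <- model$excitation_loadings[, f]
  flat <- function(v) max(v) - min(v) <= 1e-12 * max(abs(v), 1)
  spec <- structure(list(
    label = label %||% paste0("C", f),
    emission_peak = NA_real_,
    excitation_peaks = data.frame(wavelength = numeric(0),
                                  wavelength_grid = numeric(0),
                                  height = numeric(0),
                                  boundary_censored = logical(0)),
    coble_class = "unknown"), class = "component_spectrum")
  if (flat(bl) || flat(cl)) {
    warning("component ", f, " has a flat loading; peaks unknown")
    return(spec)
  }
  spec$emission_peak <- if (refine)
    refine_peak(model$em, bl, which.max(bl)) else model$em[which.max(bl)]
  K <- length(cl)
  is_max <- logical(K)
  for (k in seq_len(K)) {
    left <- if (k == 1) -Inf else cl[k - 1]
    right <- if (k == K) -Inf else cl[k + 1]
    is_max[k] <- cl[k] >= left && cl[k] >= right && (cl[k] > left || cl[k] > right)
  }
  keep <- which(is_max & cl >= secondary_fraction * max(cl))
  if (length(keep)) {
    o <- keep[order(cl[keep], decreasing = TRUE)]
    censored <- o == 1L | o == K
    wl <- model$ex[o]
    if (refine && any(!censored))
      wl[!censored] <- vapply(o[!censored], function(k)
        refine_peak(model$ex, cl, k), numeric(1))
    spec$excitation_peaks <- data.frame(
      wavelength = wl,
      wavelength_grid = model$ex[o],
      height = cl[o],
      boundary_censored = censored)
  } else {
    warning("component ", f, " has no excitation peak above the threshold")
  }
  spec$coble_class <- classify_coble(spec)
  spec
}

#' @export
print.component_spectrum <- function(x, ...) {
  pk <- x$excitation_peaks
  fmt <- function(i) paste0(if (pk$boundary_censored[i]) "<=" else "",
                            format(round(pk$wavelength[i], 1)))
  exs <- if (nrow(pk)) {
    prim <- fmt(1)
    sec <- if (nrow(pk) > 1)
      paste0("(", paste(vapply(2:nrow(pk), fmt, character(1)),
                        collapse = ", "), ")") else ""
    paste0(prim, sec)
  } else "?"
  cat(sprintf("<component_spectrum> %s: ex %s / em %s nm -> Coble class %s\n",
              x$label, exs, format(round(x$emission_peak, 1)), x$coble_class))
  invisible(x)
}

# Coble class of a single (excitation, emission) peak pair. The emission
# windows of the five classes are mutually exclusive given the excitation
# windows, so at most one rule fires.
coble_rule <- function(ex_nm, em_nm, censored = FALSE) {
  if (is.na(ex_nm) || is.na(em_nm)) return("unknown")
  if (ex_nm >= 270 && ex_nm <= 290 && em_nm >= 320 && em_nm <= 360) return("T")
  if (ex_nm >= 265 && ex_nm <= 285 && em_nm >= 295 && em_nm < 320) return("B")
  if (((ex_nm >= 230 && ex_nm <= 275) || (censored && ex_nm <= 275)) &&
      em_nm >= 380 && em_nm <= 480) return("A")
  if (ex_nm >= 320 && ex_nm <= 380 && em_nm >= 420 && em_nm <= 490) return("C")
  if (ex_nm >= 285 && ex_nm < 320 && em_nm >= 370 && em_nm < 420) return("M")
  "unknown"
}

#' Classify a component against the conventional Coble peaks
#'
#' Assigns one of the classical fluorophore classes — B and T
#' (tyrosine-/tryptophan-like, protein-like), A and C (humic-like), M
#' (marine humic-like) — from the component's excitation and emission peak
#' positions. Every reported excitation peak is classified against the
#' emission peak; the class is chosen by majority over the classified
#' peaks, with ties broken in favor of the primary (highest) peak.
#' Boundary-censored excitation peaks count towards class A, whose
#' excitation band extends below the usual measured range.
#'
#' @param spec a `component_spectrum`.
#' @return One of `"B"`, `"T"`, `"A"`, `"C"`, `"M"`, `"unknown"`.
#' @export
classify_coble <- function(spec) {
  stopifnot(inherits(spec, "component_spectrum"))
  pk <- spec$excitation_peaks
  if (is.na(spec$emission_peak) || nrow(pk) == 0) return("unknown")
  classes <- vapply(seq_len(nrow(pk)), function(i)
    coble_rule(pk$wavelength[i], spec$emission_peak, pk$boundary_censored[i]),
    character(1))
  known <- classes[classes != "unknown"]
  if (!length(known)) return("unknown")
  tab <- table(known)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) return(top)
  # tie: the class of the highest-ranked classified peak wins
  classes[classes %in% top][1]
}

#' Modeled peak intensities (F_max) in Raman Units
#'
#' With emission and excitation loadings normalized to unit maximum, a
#' component's score is its modeled peak intensity in the (scaled) data;
#' multiplying by the per-sample scale factor stored at [scale_by_sd()]
#' returns it to Raman Units.
#'
#' @param model a `parafac_model` fitted to `dataset`.
#' @param dataset the [eem_dataset] carrying the scale factors.
#' @return Matrix sample x component of F_max values (R.U.), with sample
#'   ids as row names.
#' @export
compute_fmax <- function(model, dataset) {
  stopifnot(inherits(model, "parafac_model"), inherits(dataset, "eem_dataset"))
  if (nrow(model$scores) != length(dataset$samples))
    stop("model and dataset have different numbers of samples", call. = FALSE)
  fmax <- model$scores * dataset$scale_factors
  rownames(fmax) <- vapply(dataset$samples, `[[`, character(1), "sample_id")
  colnames(fmax) <- paste0("C", seq_len(model$n_components))
  fmax
}

#' Percent contribution of each component to total fluorescence
#'
#' @param fmax_row nonnegative per-component intensities for one sample,
#'   at least one positive.
#' @return Percentages summing to 100.
#' @export
contribution_percent <- function(fmax_row) {
  if (any(fmax_row < 0))
    stop("F_max intensities must be nonnegative", call. = FALSE)
  tot <- sum(fmax_row)
  if (tot <= 0)
    stop("undefined contribution: all intensities are zero", call. = FALSE)
  100 * fmax_row / tot
}

#' Assemble a per-sample contribution table
#'
#' Combines F_max intensities with their percent contributions and flags
#' media-blank rows, which are excluded from across-strain summaries and
#' used only to estimate the media's contribution to the final signal.
#'
#' @param fmax matrix sample x component of intensities (R.U.), e.g. from
#'   [compute_fmax()].
#' @param is_blank logical per sample; `TRUE` marks a medium blank.
#' @param sample_ids optional ids (default: row names of `fmax`).
#' @return An object of class `contribution_table` with elements `fmax`,
#'   `percent`, `is_blank`, `sample_ids`, `components`.
#' @export
contribution_table <- function(fmax, is_blank = rep(FALSE, nrow(fmax)),
                               sample_ids = rownames(fmax)) {
  fmax <- as.matrix(fmax)
  stopifnot(length(is_blank) == nrow(fmax))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(fmax)))
  pct <- t(apply(fmax, 1, contribution_percent))
  structure(list(
    fmax = fmax, percent = pct, is_blank = as.logical(is_blank),
    sample_ids = as.character(sample_ids),
    components = colnames(fmax) %||% paste0("C", seq_len(ncol(fmax)))),
    class = "contribution_table")
}

#' @export
print.contribution_table <- function(x, ...) {
  df <- data.frame(sample = x$sample_ids, blank = x$is_blank,
                   round(x$fmax, 4), round(x$percent, 1),
                   check.names = FALSE)
  names(df) <- c("sample", "blank", paste0(x$components, " (R.U.)"),
                 paste0(x$components, " (%)"))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Across-strain summary of component contributions
#'
#' Per component: mean intensity (R.U.), mean and SD (n-1) of the percent
#' shares, and their range, computed over strain samples only (media
#' blanks excluded). Optionally the range of the intensity ratio between
#' two components.
#'
#' @param table a [contribution_table].
#' @param ratio integer pair: component indices whose intensity ratio
#'   range is reported, or `NULL`.
#' @return A list with `n_strain`, `mean_ru`, `mean_pct`, `sd_pct`,
#'   `min_pct`, `max_pct`, and (if requested) `ratio` = list(components,
#'   min, max).
#' @export
summarize_contributions <- function(table, ratio = NULL) {
  stopifnot(inherits(table, "contribution_table"))
  keep <- !table$is_blank
  fm <- table$fmax[keep, , drop = FALSE]
  pc <- table$percent[keep, , drop = FALSE]
  n <- nrow(fm)
  sd_pct <- if (n >= 2) apply(pc, 2, stats::sd) else
    rep(NA_real_, ncol(pc))
  if (n < 2) warning("single strain sample: SD not available")
  out <- list(
    n_strain = n,
    components = table$components,
    mean_ru = colMeans(fm),
    mean_pct = colMeans(pc),
    sd_pct = sd_pct,
    min_pct = apply(pc, 2, min),
    max_pct = apply(pc, 2, max))
  if (!is.null(ratio)) {
    stopifnot(length(ratio) == 2)
    r <- fm[, ratio[1]] / fm[, ratio[2]]
    out$ratio <- list(components = table$components[ratio],
                      min = min(r), max = max(r))
  }
  out
}

#' Contribution of the culture media to the final fluorescence
#'
#' Under the assumption that the media's own fluorescent DOM is not
#' consumed during cultivation, the fraction of the stationary-phase
#' signal attributable to the medium is the mean blank intensity divided
#' by the across-strain mean stationary intensity, per component.
#'
#' @param media_fmax matrix medium x component of blank intensities (R.U.).
#' @param stationary_mean per-component mean stationary-phase intensity
#'   (R.U.), all positive.
#' @return Per-component percentages.
#' @export
blank_contribution <- function(media_fmax, stationary_mean) {
  media_fmax <- rbind(media_fmax)
  if (ncol(media_fmax) != length(stationary_mean))
    stop("component counts differ", call. = FALSE)
  if (any(stationary_mean <= 0))
    stop("undefined blank contribution: zero stationary mean", call. = FALSE)
  100 * colMeans(media_fmax) / stationary_mean
}
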