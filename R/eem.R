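#' Construct an excitation-emission matrix (EEM)
#'
#' An EEM holds the fluorescence intensity of one sample on a rectangular
#' excitation x emission wavelength grid, together with a per-cell mask
#' and sample metadata. Intensities are in arbitrary instrument units
#' until Raman normalization, Raman Units (R.U.) afterwards.
#'
#' @param intensity numeric matrix, rows indexed by excitation wavelength,
#'   columns by emission wavelength.
#' @param ex,em strictly ascending wavelength vectors (nm) matching the
#'   rows and columns of `intensity`.
#' @param sample_id character scalar identifying the sample.
#' @param mask character matrix of the same shape with entries `"valid"`,
#'   `"excised"` or `"undefined"`; defaults to all-valid.
#' @param meta named list of metadata. Recognized keys include `strain`,
#'   `medium` (`"WC"`, `"BBM"` or `"water-blank"`), `stage` of growth,
#'   and `units`; the preprocessing stage tag is maintained internally.
#' @return An object of class `eem`.
#' @export
eem <- function(intensity, ex, em, sample_id = "sample", mask = NULL,
                meta = list()) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (!is_ascending(ex))
    stop("excitation wavelengths must be finite and strictly ascending",
         call. = FALSE)
  if (!is_ascending(em))
    stop("emission wavelengths must be finite and strictly ascending",
         call. = FALSE)
  if (nrow(intensity) != length(ex) || ncol(intensity) != length(em))
    stop(sprintf("intensity is %d x %d but |ex| = %d, |em| = %d",
                 nrow(intensity), ncol(intensity), length(ex), length(em)),
         call. = FALSE)
  if (is.null(mask)) {
    mask <- matrix("valid", length(ex), length(em))
  } else {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(intensity)))
      stop("mask dimensions must match intensity", call. = FALSE)
    if (!all(mask %in% c("valid", "excised", "undefined")))
      stop("mask entries must be 'valid', 'excised' or 'undefined'",
           call. = FALSE)
  }
  if (any(mask == "valid" & !is.finite(intensity)))
    stop("cells flagged valid must hold finite values", call. = FALSE)
  meta$units <- meta$units %||% "raw"
  meta$pipeline_stage <- meta$pipeline_stage %||% "raw"
  structure(
    list(sample_id = as.character(sample_id),
         ex = as.numeric(ex), em = as.numeric(em),
         intensity = unname(intensity), mask = unname(mask), meta = meta),
    class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf(
    "<eem> %s: %d ex (%.4g-%.4g nm) x %d em (%.4g-%.4g nm), units %s, stage %s\n",
    x$sample_id, length(x$ex), min(x$ex), max(x$ex),
    length(x$em), min(x$em), max(x$em),
    x$meta$units, x$meta$pipeline_stage))
  tab <- table(factor(x$mask, c("valid", "excised", "undefined")))
  cat(sprintf("  cells: %d valid, %d excised, %d undefined\n",
              tab[["valid"]], tab[["excised"]], tab[["undefined"]]))
  invisible(x)
}

#' Write an EEM to a CSV matrix with a metadata sidecar
#'
#' The on-disk layout is one CSV matrix per EEM: the header row carries the
#' emission wavelengths, the first column the excitation wavelengths
#' (rows = excitation scans), matching common instrument exports. Sample id,
#' metadata and any non-valid mask cells go to a `<path>.meta.yaml` sidecar,
#' so the roundtrip is lossless for values, axes and mask states.
#'
#' @param x an [eem].
#' @param path output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_eem <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  fmt <- function(v) sprintf("%.17g", v)
  vals <- x$intensity
  vals[x$mask == "undefined" & !is.finite(vals)] <- NA
  lines <- c(
    paste(c("ex_nm/em_nm", fmt(x$em)), collapse = ","),
    vapply(seq_along(x$ex), function(i)
      paste(c(fmt(x$ex[i]), ifelse(is.na(vals[i, ]), "NA", fmt(vals[i, ]))),
            collapse = ","),
      character(1)))
  writeLines(lines, path)
  side <- list(sample_id = x$sample_id, meta = x$meta)
  nv <- which(x$mask != "valid", arr.ind = TRUE)
  if (nrow(nv) > 0) {
    side$mask <- list(row = as.integer(nv[, 1]), col = as.integer(nv[, 2]),
                      state = x$mask[nv])
  }
  yaml::write_yaml(side, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Read an EEM from a CSV matrix
#'
#' Parses the dialect written by [write_eem()]: header row = emission
#' wavelengths, first column = excitation wavelengths. If the metadata
#' sidecar is present it restores sample id, metadata and mask; otherwise
#' the mask is all-valid and units are recorded as `"raw"`.
#'
#' @param path CSV path.
#' @param dialect list of dialect options; currently `sep` (default `,`).
#' @return An [eem].
#' @export
read_eem <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- dialect$sep %||% ","
  lines <- readLines(path)
  if (length(lines) < 2) stop("EEM file has no data rows: ", path, call. = FALSE)
  split_row <- function(l) strsplit(l, sep, fixed = TRUE)[[1]]
  hdr <- split_row(lines[1])
  em <- suppressWarnings(as.numeric(hdr[-1]))
  if (anyNA(em))
    stop("non-numeric emission wavelength in header at column ",
         which(is.na(em))[1] + 1L, call. = FALSE)
  body <- lapply(lines[-1], split_row)
  ncol_expect <- length(em) + 1L
  bad <- which(lengths(body) != ncol_expect)
  if (length(bad))
    stop("row ", bad[1] + 1L, " has ", lengths(body)[bad[1]],
         " fields, expected ", ncol_expect, call. = FALSE)
  tab <- do.call(rbind, body)
  ex <- suppressWarnings(as.numeric(tab[, 1]))
  if (anyNA(ex))
    stop("non-numeric excitation wavelength at row ",
         which(is.na(ex))[1] + 1L, call. = FALSE)
  cells <- suppressWarnings(matrix(as.numeric(tab[, -1, drop = FALSE]),
                                   nrow = nrow(tab)))
  na_in <- tab[, -1, drop = FALSE] == "NA"
  if (any(is.na(cells) & !na_in)) {
    idx <- which(is.na(cells) & !na_in, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric intensity at row %d, column %d",
                 idx[1] + 1L, idx[2] + 1L), call. = FALSE)
  }
  if (!is_ascending(ex))
    stop("excitation wavelengths are not strictly ascending", call. = FALSE)
  if (!is_ascending(em))
    stop("emission wavelengths are not strictly ascending", call. = FALSE)
  sample_id <- sub("\\.[^.]*$", "", basename(path))
  meta <- list()
  mask <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    side <- yaml::read_yaml(sp)
    sample_id <- side$sample_id %||% sample_id
    meta <- side$meta %||% list()
    if (!is.null(side$mask)) {
      mask <- matrix("valid", length(ex), length(em))
      mask[cbind(side$mask$row, side$mask$col)] <- side$mask$state
    }
  }
  eem(cells, ex, em, sample_id = sample_id, mask = mask, meta = meta)
}

#' Read an absorbance spectrum
#'
#' Two-column numeric text file (wavelength nm, decadic absorbance).
#' Linear interpolation is available anywhere inside the measured range
#' via [absorbance_at()]; queries outside it raise a coverage error.
#'
#' @param path file path; comma-, tab- or whitespace-separated.
#' @param pathlength_cm cuvette path length the absorbance was measured at.
#' @return An object of class `absorbance_spectrum`.
#' @export
read_absorbance <- function(path, pathlength_cm = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.table(path, sep = "", header = FALSE,
                      colClasses = "numeric",
                      col.names = c("wavelength", "absorbance")),
    error = function(e) tryCatch(
      utils::read.table(path, sep = ",", header = FALSE,
                        colClasses = "numeric",
                        col.names = c("wavelength", "absorbance")),
      error = function(e2)
        stop("cannot parse absorbance file ", path, ": ",
             conditionMessage(e2), call. = FALSE)))
  if (nrow(tab) == 0) stop("absorbance file is empty: ", path, call. = FALSE)
  absorbance_spectrum(tab$wavelength, tab$absorbance, pathlength_cm)
}

#' @rdname read_absorbance
#' @param wavelength,absorbance numeric vectors defining the spectrum
#'   directly (wavelengths strictly ascending).
#' @export
absorbance_spectrum <- function(wavelength, absorbance, pathlength_cm = 1) {
  o <- order(wavelength)
  wavelength <- wavelength[o]
  absorbance <- absorbance[o]
  if (!is_ascending(wavelength))
    stop("absorbance wavelengths must be strictly ascending (no duplicates)",
         call. = FALSE)
  if (!all(is.finite(absorbance)))
    stop("absorbance values must be finite", call. = FALSE)
  if (!(is.numeric(pathlength_cm) && pathlength_cm > 0))
    stop("pathlength_cm must be positive", call. = FALSE)
  structure(list(wavelength = wavelength, absorbance = absorbance,
                 pathlength_cm = pathlength_cm),
            class = "absorbance_spectrum")
}

#' Interpolated absorbance at given wavelengths
#'
#' @param spec an `absorbance_spectrum`.
#' @param wl wavelengths (nm) to query.
#' @return Decadic absorbance per 1 cm path at `wl`.
#' @export
absorbance_at <- function(spec, wl) {
  stopifnot(inherits(spec, "absorbance_spectrum"))
  rng <- range(spec$wavelength)
  out <- wl < rng[1] | wl > rng[2]
  if (any(out))
    stop(sprintf(
      "absorbance spectrum (%.4g-%.4g nm) does not cover wavelength %.4g nm",
      rng[1], rng[2], wl[which(out)[1]]), call. = FALSE)
  if (length(spec$wavelength) == 1) return(rep(spec$absorbance, length(wl)) /
                                             spec$pathlength_cm)
  stats::approx(spec$wavelength, spec$absorbance, xout = wl)$y /
    spec$pathlength_cm
}

#' Construct an EEM dataset
#'
#' A dataset is an ordered collection of EEMs on one common grid plus
#' per-sample scale factors (1 until [scale_by_sd()] is applied).
#'
#' @param samples list of [eem] objects sharing identical axes.
#' @param scale_factors per-sample positive numbers.
#' @return An object of class `eem_dataset`.
#' @export
eem_dataset <- function(samples, scale_factors = rep(1, length(samples))) {
  if (length(samples) < 1) stop("dataset needs at least one EEM", call. = FALSE)
  if (!all(vapply(samples, inherits, logical(1), "eem")))
    stop("all samples must be eem objects", call. = FALSE)
  ex <- samples[[1]]$ex
  em <- samples[[1]]$em
  same <- vapply(samples, function(s)
    length(s$ex) == length(ex) && length(s$em) == length(em) &&
      all(s$ex == ex) && all(s$em == em), logical(1))
  if (!all(same))
    stop("all member EEMs must share identical excitation and emission grids",
         call. = FALSE)
  if (length(scale_factors) != length(samples) ||
      !all(is.finite(scale_factors) & scale_factors > 0))
    stop("scale_factors must be positive, one per sample", call. = FALSE)
  structure(list(samples = samples, scale_factors = as.numeric(scale_factors)),
            class = "eem_dataset")
}

#' @export
print.eem_dataset <- function(x, ...) {
  s <- x$samples[[1]]
  cat(sprintf("<eem_dataset> %d samples on %d ex x %d em grid (units %s)\n",
              length(x$samples), length(s$ex), length(s$em), s$meta$units))
  invisible(x)
}

#' @export
length.eem_dataset <- function(x) length(x$samples)

#' Align EEMs onto a common grid
#'
#' Interpolates every EEM (linearly, one axis at a time) onto the
#' intersection of all input wavelength ranges, sampled on the coarsest
#' grid among the inputs (cropped to the common range). Aligning EEMs that
#' already share a grid returns them unchanged, so the operation is
#' idempotent. Explicit target axes may be supplied, e.g. to downsample a
#' densely sampled emission axis before decomposition; EEMs carrying
#' excised/undefined cells can only be moved onto a subgrid of their own
#' axes (mask states are not interpolable).
#'
#' @param eems list of [eem] objects.
#' @param ex,em optional explicit target axes (nm) overriding the
#'   automatic choice.
#' @return An [eem_dataset] with scale factors of 1.
#' @export
align_dataset <- function(eems, ex = NULL, em = NULL) {
  if (inherits(eems, "eem")) eems <- list(eems)
  if (inherits(eems, "eem_dataset")) eems <- eems$samples
  if (length(eems) < 1) stop("need at least one EEM", call. = FALSE)
  stopifnot(all(vapply(eems, inherits, logical(1), "eem")))

  pick_axis <- function(axes, what) {
    lo <- max(vapply(axes, min, numeric(1)))
    hi <- min(vapply(axes, max, numeric(1)))
    if (lo > hi)
      stop("alignment error: ", what, " ranges do not overlap ",
           sprintf("(common range would be [%.4g, %.4g])", lo, hi),
           call. = FALSE)
    steps <- vapply(axes, function(a)
      if (length(a) > 1) stats::median(diff(a)) else Inf, numeric(1))
    coarse <- axes[[which.max(steps)]]
    out <- coarse[coarse >= lo - 1e-9 & coarse <= hi + 1e-9]
    if (length(out) == 0)
      stop("alignment error: no ", what, " grid points in the common range",
           call. = FALSE)
    out
  }
  ex_out <- ex %||% pick_axis(lapply(eems, `[[`, "ex"), "excitation")
  em_out <- em %||% pick_axis(lapply(eems, `[[`, "em"), "emission")

  out <- lapply(eems, regrid_eem, ex_out = ex_out, em_out = em_out)
  eem_dataset(out)
}

# Move one EEM onto target axes. Fully valid EEMs are interpolated
# bilinearly (separable 1-D linear interpolation); masked EEMs require the
# target to be a subgrid so mask states transfer exactly.
regrid_eem <- function(s, ex_out, em_out) {
  same_axes <- length(s$ex) == length(ex_out) && length(s$em) == length(em_out) &&
    all(s$ex == ex_out) && all(s$em == em_out)
  if (same_axes) return(s)
  if (min(ex_out) < min(s$ex) - 1e-9 || max(ex_out) > max(s$ex) + 1e-9 ||
      min(em_out) < min(s$em) - 1e-9 || max(em_out) > max(s$em) + 1e-9)
    stop("alignment error: target axes exceed the range of sample ",
         s$sample_id, call. = FALSE)
  if (all(s$mask == "valid")) {
    tmp <- t(apply(s$intensity, 1, function(row)
      stats::approx(s$em, row, xout = em_out)$y))
    vals <- apply(tmp, 2, function(col)
      stats::approx(s$ex, col, xout = ex_out)$y)
    vals <- matrix(vals, length(ex_out), length(em_out))
    return(eem(vals, ex_out, em_out, sample_id = s$sample_id, meta = s$meta))
  }
  ix <- match_subgrid(ex_out, s$ex, "excitation", s$sample_id)
  im <- match_subgrid(em_out, s$em, "emission", s$sample_id)
  eem(s$intensity[ix, im, drop = FALSE], ex_out, em_out,
      sample_id = s$sample_id, mask = s$mask[ix, im, drop = FALSE],
      meta = s$meta)
}

match_subgrid <- function(target, source, what, id) {
  idx <- vapply(target, function(w) {
    i <- which(abs(source - w) < 1e-6)
    if (length(i) != 1) NA_integer_ else i
  }, integer(1))
  if (anyNA(idx))
    stop("alignment error: masked EEM ", id, " can only be regridded onto a ",
         "subgrid of its own ", what, " axis", call. = FALSE)
  idx
}

#' Stack a dataset into a sample x excitation x emission cube
#'
#' @param dataset an [eem_dataset].
#' @return Numeric array `n x |ex| x |em|` with attribute `mask` (character
#'   array of the same shape), `ex` and `em`.
#' @export
as_cube <- function(dataset) {
  stopifnot(inherits(dataset, "eem_dataset"))
  n <- length(dataset$samples)
  s1 <- dataset$samples[[1]]
  cube <- array(NA_real_, c(n, length(s1$ex), length(s1$em)))
  mask <- array("valid", dim(cube))
  for (i in seq_len(n)) {
    cube[i, , ] <- dataset$samples[[i]]$intensity
    mask[i, , ] <- dataset$samples[[i]]$mask
  }
  attr(cube, "mask") <- mask
  attr(cube, "ex") <- s1$ex
  attr(cube, "em") <- s1$em
  cube
}
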