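#' Scatter-handling configuration
#'
#' Geometry and smoothing parameters for Rayleigh/Raman scatter excision
#' and interpolation. First-order Rayleigh and Raman ridges are excised
#' within +/- `width_first_order` nm, second-order ridges within
#' +/- `width_second_order` nm, assuming a water Raman shift of
#' `raman_shift` (cm^-1). The anti-Stokes band `undefined_band` (an open
#' interval for lambda_ex - lambda_em, nm) is left undefined and never
#' interpolated, as is the deeper non-physical region beyond it.
#'
#' Whittaker penalties control the stiffness of the two-dimensional
#' penalized least-squares fill. The penalty multiplies the squared
#' `diff_order`-th divided differences along each axis, so its value is in
#' physical (per-nm) units and carries over between instrument grids.
#' Rayleigh gaps are wide and diagonal and get a stiffer smoother than
#' the narrower Raman gaps; the defaults were chosen for fill fidelity on
#' simulated fluorophores with realistic bandwidths.
#'
#' @param raman_shift Raman shift of water, cm^-1.
#' @param width_first_order,width_second_order excision half-widths, nm.
#' @param undefined_band open interval `(lo, hi)` for lambda_ex -
#'   lambda_em in nm left undefined.
#' @param penalty_rayleigh,penalty_raman Whittaker penalty per scatter type.
#' @param diff_order order of the penalized finite differences (1, 2 or 3).
#' @return A list of class `scatter_config`.
#' @export
scatter_config <- function(raman_shift = 3400,
                           width_first_order = 18,
                           width_second_order = 30,
                           undefined_band = c(18, 30),
                           penalty_rayleigh = 1e3,
                           penalty_raman = 1e2,
                           diff_order = 2) {
  stopifnot(raman_shift > 0, width_first_order > 0, width_second_order > 0,
            length(undefined_band) == 2, undefined_band[1] < undefined_band[2],
            penalty_rayleigh > 0, penalty_raman > 0, diff_order %in% 1:3)
  structure(list(raman_shift = raman_shift,
                 width_first_order = width_first_order,
                 width_second_order = width_second_order,
                 undefined_band = as.numeric(undefined_band),
                 penalty_rayleigh = penalty_rayleigh,
                 penalty_raman = penalty_raman,
                 diff_order = as.integer(diff_order)),
            class = "scatter_config")
}

#' Water Raman integration band
#'
#' Defines the Raman-Unit normalization constant: the area under the pure
#' water Raman scatter peak in the blank, read along the emission axis at
#' a fixed excitation wavelength. Defaults to the conventional band:
#' emission 371-428 nm at 350 nm excitation.
#'
#' @param excitation_at excitation wavelength of the Raman scan, nm.
#' @param emission_lo,emission_hi integration limits along emission, nm.
#' @return A list of class `raman_band`.
#' @export
raman_band <- function(excitation_at = 350, emission_lo = 371,
                       emission_hi = 428) {
  stopifnot(emission_lo < emission_hi, excitation_at > 0)
  structure(list(excitation_at = excitation_at,
                 emission_lo = emission_lo, emission_hi = emission_hi),
            class = "raman_band")
}

#' Subtract a blank EEM from a sample EEM
#'
#' Cellwise difference against a pure-water (or medium) blank measured on
#' the identical grid. Negative results are permitted at this stage; they
#' are handled downstream.
#'
#' @param sample,blank [eem] objects on identical grids.
#' @return The blank-subtracted [eem].
#' @export
subtract_blank <- function(sample, blank) {
  stopifnot(inherits(sample, "eem"), inherits(blank, "eem"))
  check_stage(sample, "blank_subtracted")
  if (length(sample$ex) != length(blank$ex) ||
      length(sample$em) != length(blank$em) ||
      any(sample$ex != blank$ex) || any(sample$em != blank$em))
    stop("alignment error: sample and blank grids differ", call. = FALSE)
  sample$intensity <- sample$intensity - blank$intensity
  set_stage(sample, "blank_subtracted")
}

#' Absorbance-based inner-filter correction
#'
#' Corrects for attenuation of the excitation beam and re-absorption of
#' emitted light by the sample's own chromophores, using the standard
#' absorbance-based (ABA) multiplicative factor: each cell at
#' (lambda_ex, lambda_em) is multiplied by
#' `10^((A(lambda_ex) + A(lambda_em)) / 2)`, with A the decadic absorbance
#' scaled to a 1 cm path. The correction never decreases an intensity;
#' negative absorbance readings are clamped to zero with a warning.
#'
#' @param sample an [eem].
#' @param absorbance an `absorbance_spectrum` covering both wavelength axes.
#' @return The corrected [eem].
#' @export
correct_inner_filter <- function(sample, absorbance) {
  stopifnot(inherits(sample, "eem"))
  check_stage(sample, "ife_corrected")
  a_ex <- absorbance_at(absorbance, sample$ex)
  a_em <- absorbance_at(absorbance, sample$em)
  if (any(a_ex < 0) || any(a_em < 0)) {
    warning("negative absorbance clamped to 0 for inner-filter correction")
    a_ex <- pmax(a_ex, 0)
    a_em <- pmax(a_em, 0)
  }
  factor <- 10^(outer(a_ex, a_em, `+`) / 2)
  sample$intensity <- sample$intensity * factor
  set_stage(sample, "ife_corrected")
}

#' Raman-scattered emission wavelength
#'
#' Emission wavelength of water Raman scatter for a given excitation
#' wavelength and Raman shift: `1 / (1/lambda_ex - shift * 1e-7)` with
#' wavelengths in nm and the shift in cm^-1. Strictly increasing in
#' lambda_ex and above it for any positive shift.
#'
#' @param excitation excitation wavelength(s), nm.
#' @param shift Raman shift, cm^-1 (water: 3400).
#' @return Emission wavelength(s), nm.
#' @export
raman_emission_wavelength <- function(excitation, shift = 3400) {
  denom <- 1 / excitation - shift * 1e-7
  if (any(denom <= 0))
    stop(sprintf(
      "nonphysical Raman wavelength: shift %g cm^-1 at excitation %g nm",
      shift, excitation[which(denom <= 0)[1]]), call. = FALSE)
  1 / denom
}

#' Area under the water Raman peak of a blank EEM
#'
#' Trapezoidal integral of the blank's emission scan at the band's
#' excitation wavelength (nearest grid row within one grid step) over
#' `[emission_lo, emission_hi]`, in (input units) * nm. This is the
#' Raman-Unit normalization constant.
#'
#' @param blank the pure-water blank [eem].
#' @param band a [raman_band].
#' @return Positive scalar area.
#' @export
raman_area <- function(blank, band = raman_band()) {
  stopifnot(inherits(blank, "eem"), inherits(band, "raman_band"))
  d <- abs(blank$ex - band$excitation_at)
  i <- which.min(d)
  step <- if (length(blank$ex) > 1) stats::median(diff(blank$ex)) else Inf
  if (d[i] > step + 1e-9)
    stop(sprintf(
      "coverage error: no excitation row within one grid step of %g nm",
      band$excitation_at), call. = FALSE)
  if (band$emission_lo < min(blank$em) - 1e-9 ||
      band$emission_hi > max(blank$em) + 1e-9)
    stop(sprintf(
      "coverage error: Raman band %g-%g nm outside blank emission range %g-%g nm",
      band$emission_lo, band$emission_hi, min(blank$em), max(blank$em)),
      call. = FALSE)
  scan <- blank$intensity[i, ]
  inside <- blank$em >= band$emission_lo - 1e-9 &
    blank$em <= band$emission_hi + 1e-9
  xs <- blank$em[inside]
  ys <- scan[inside]
  # close the band exactly at its limits by linear interpolation
  if (length(xs) == 0 || xs[1] > band$emission_lo + 1e-9) {
    xs <- c(band$emission_lo, xs)
    ys <- c(stats::approx(blank$em, scan, band$emission_lo)$y, ys)
  }
  if (xs[length(xs)] < band$emission_hi - 1e-9) {
    xs <- c(xs, band$emission_hi)
    ys <- c(ys, stats::approx(blank$em, scan, band$emission_hi)$y)
  }
  area <- trapz(xs, ys)
  if (!is.finite(area) || area <= 0)
    stop("normalization error: water Raman area is not positive",
         call. = FALSE)
  area
}

#' Normalize an EEM to Raman Units
#'
#' Divides every cell by the water Raman peak area of the blank, turning
#' arbitrary instrument units into Raman Units (R.U.).
#'
#' @param sample an [eem].
#' @param area positive Raman area from [raman_area()].
#' @return The normalized [eem] with units `"R.U."`.
#' @export
raman_normalize <- function(sample, area) {
  stopifnot(inherits(sample, "eem"))
  check_stage(sample, "raman_normalized")
  if (!(is.numeric(area) && length(area) == 1 && is.finite(area) && area > 0))
    stop("normalization error: Raman area must be a positive number",
         call. = FALSE)
  sample$intensity <- sample$intensity / area
  sample$meta$units <- "R.U."
  set_stage(sample, "raman_normalized")
}

# Scatter-type codes used between excision and interpolation:
# 0 none, 1 Rayleigh 1st, 2 Raman 1st, 3 Rayleigh 2nd, 4 Raman 2nd.
.scatter_rayleigh <- c(1L, 3L)
.scatter_raman <- c(2L, 4L)

#' Excise Rayleigh and Raman scatter regions
#'
#' Marks cells affected by scatter as `excised` based purely on their
#' (lambda_ex, lambda_em) position:
#' first-order Rayleigh `|em - ex| <= width_first_order`;
#' first-order Raman around [raman_emission_wavelength()];
#' second-order Rayleigh `|em - 2 ex| <= width_second_order`; second-order
#' Raman around twice the Raman wavelength. The anti-Stokes band
#' `undefined_band[1] < ex - em < undefined_band[2]` is set `undefined`:
#' those cells are excluded from all later fitting and never interpolated.
#' The non-physical region `ex - em >= undefined_band[2]`, where no
#' fluorescence can occur, is set to zero and kept valid so that the
#' trilinear fit stays anchored there.
#'
#' @param sample an [eem].
#' @param cfg a [scatter_config].
#' @return The [eem] with its mask updated and the scatter type recorded
#'   for [interpolate_scatter()].
#' @export
excise_scatter <- function(sample, cfg = scatter_config()) {
  stopifnot(inherits(sample, "eem"), inherits(cfg, "scatter_config"))
  check_stage(sample, "scatter_excised")
  ex <- sample$ex
  em <- sample$em
  raman_em <- raman_emission_wavelength(ex, cfg$raman_shift)
  d_ray1 <- abs(outer(ex, em, function(x, m) m - x))
  d_ram1 <- abs(outer(raman_em, em, function(x, m) m - x))
  d_ray2 <- abs(outer(2 * ex, em, function(x, m) m - x))
  d_ram2 <- abs(outer(2 * raman_em, em, function(x, m) m - x))
  stype <- matrix(0L, length(ex), length(em))
  stype[d_ram2 <= cfg$width_second_order] <- 4L
  stype[d_ray2 <= cfg$width_second_order] <- 3L
  stype[d_ram1 <= cfg$width_first_order] <- 2L
  stype[d_ray1 <= cfg$width_first_order] <- 1L
  anti <- outer(ex, em, `-`)
  undef <- anti > cfg$undefined_band[1] & anti < cfg$undefined_band[2]
  # Fluorescence cannot occur at emission wavelengths this far below the
  # excitation wavelength: beyond the undefined anti-Stokes strip the
  # signal is physically zero, and anchoring it there keeps excitation
  # loadings of short-emission fluorophores identified at high excitation,
  # where their emission band would otherwise fall entirely in masked
  # territory.
  nonphys <- anti >= cfg$undefined_band[2]
  mask <- sample$mask
  mask[stype > 0L] <- "excised"
  mask[undef] <- "undefined"
  mask[nonphys] <- "valid"
  sample$intensity[nonphys] <- 0
  stype[undef | nonphys] <- 0L
  sample$mask <- mask
  sample$meta$scatter_type <- stype
  set_stage(sample, "scatter_excised")
}

# Divided-difference matrix of order d on a (possibly non-uniform) grid x:
# rows approximate the d-th derivative, so penalties are in physical
# (per-nm) units and independent of the sampling step.
ddmat <- function(x, d) {
  n <- length(x)
  D <- Matrix::Diagonal(n)
  if (d == 0) return(D)
  if (n <= d) return(Matrix::Matrix(0, 0, n, sparse = TRUE))
  for (k in seq_len(d)) {
    m <- nrow(D)
    D1 <- Matrix::bandSparse(m - 1, m, k = 0:1,
                             diagonals = list(rep(-1, m - 1), rep(1, m - 1)))
    h <- (x[(k + 1):n] - x[1:(n - k)]) / k
    D <- Matrix::Diagonal(x = 1 / h) %*% D1 %*% D
  }
  D
}

# Two-dimensional Whittaker smoother on the excitation x emission plane:
# minimizes sum(w * (z - y)^2) + lambda * (||d-th em-derivative||^2 +
# ||d-th ex-derivative||^2), with w = 0 on cells to be interpolated.
# Smoothness in both directions lets intact neighboring excitation scans
# reconstruct an emission peak even where a scatter band crosses it.
whittaker_fill_2d <- function(Y, W, lambda, d, ex, em) {
  K <- nrow(Y); J <- ncol(Y)
  Pex <- Matrix::crossprod(ddmat(ex, d))
  Pem <- Matrix::crossprod(ddmat(em, d))
  A <- Matrix::Diagonal(x = as.numeric(W)) +
    lambda * (Matrix::kronecker(Pem, Matrix::Diagonal(K)) +
                Matrix::kronecker(Matrix::Diagonal(J), Pex))
  y0 <- as.numeric(Y)
  y0[W == 0] <- 0
  matrix(as.numeric(Matrix::solve(A, as.numeric(W) * y0)), K, J)
}

#' Interpolate excised scatter regions by Whittaker smoothing
#'
#' Fits a two-dimensional penalized least-squares (Whittaker) smoother
#' over the excitation x emission plane with weight 1 on valid cells and
#' 0 on excised cells, then replaces the excised cells with the smoothed
#' values and flags them valid. Because the smoothness penalty acts along
#' both axes, intact neighboring excitation scans reconstruct an emission
#' band even where a scatter ridge crosses its peak — a one-dimensional
#' fill along the emission axis alone would bridge underneath it.
#' Rayleigh- and Raman-excised cells are filled in separate passes with
#' their own penalties (`penalty_rayleigh`, `penalty_raman`). Undefined
#' cells get weight 0 too but are never filled. An excitation row with no
#' valid cells is left fully undefined with a warning. Since fluorescence
#' cannot be negative, valid cells are clamped at zero afterwards.
#'
#' @param sample an [eem] previously passed through [excise_scatter()].
#' @param cfg the same [scatter_config] used for excision.
#' @return The [eem] with scatter gaps filled.
#' @export
interpolate_scatter <- function(sample, cfg = scatter_config()) {
  stopifnot(inherits(sample, "eem"), inherits(cfg, "scatter_config"))
  check_stage(sample, "interpolated", require = "scatter_excised")
  stype <- sample$meta$scatter_type
  if (is.null(stype))
    stop("no scatter-type record found; run excise_scatter() first",
         call. = FALSE)
  dead_rows <- which(apply(sample$mask, 1, function(r) !any(r == "valid")))
  for (i in dead_rows) {
    sample$mask[i, sample$mask[i, ] == "excised"] <- "undefined"
    warning(sprintf(
      "sample %s: excitation row %g nm has no valid cells; left undefined",
      sample$sample_id, sample$ex[i]))
  }
  W <- (sample$mask == "valid") * 1
  groups <- list(list(types = .scatter_rayleigh, lambda = cfg$penalty_rayleigh),
                 list(types = .scatter_raman, lambda = cfg$penalty_raman))
  for (g in groups) {
    fill <- matrix(stype %in% g$types, nrow(stype)) &
      sample$mask == "excised"
    if (!any(fill)) next
    Z <- whittaker_fill_2d(sample$intensity * W, W, g$lambda,
                           cfg$diff_order, sample$ex, sample$em)
    sample$intensity[fill] <- pmax(Z[fill], 0)
    sample$mask[fill] <- "valid"
  }
  valid <- sample$mask == "valid"
  sample$intensity[valid] <- pmax(sample$intensity[valid], 0)
  sample$meta$scatter_type <- NULL
  set_stage(sample, "interpolated")
}

#' Scale each sample by the standard deviation of its valid cells
#'
#' Divides every valid cell of each sample by that sample's standard
#' deviation (n-1 denominator, valid cells only) and records the divisor
#' in the dataset's `scale_factors`, so the scaling can be undone exactly.
#' Standardizing sample magnitudes this way keeps bright samples from
#' dominating the trilinear fit.
#'
#' @param dataset an [eem_dataset].
#' @return The scaled [eem_dataset].
#' @export
scale_by_sd <- function(dataset) {
  stopifnot(inherits(dataset, "eem_dataset"))
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    check_stage(s, "scaled")
    v <- s$intensity[s$mask == "valid"]
    if (length(v) < 2 || stats::sd(v) == 0)
      stop("scaling error: sample ", s$sample_id,
           " has fewer than 2 valid cells or zero spread", call. = FALSE)
    f <- stats::sd(v)
    s$intensity[s$mask == "valid"] <- s$intensity[s$mask == "valid"] / f
    s <- set_stage(s, "scaled")
    dataset$samples[[i]] <- s
    dataset$scale_factors[i] <- dataset$scale_factors[i] * f
  }
  dataset
}

#' Undo per-sample scaling
#'
#' @param dataset a scaled [eem_dataset].
#' @return The dataset with original intensities and unit scale factors.
#' @export
unscale <- function(dataset) {
  stopifnot(inherits(dataset, "eem_dataset"))
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    s$intensity[s$mask == "valid"] <-
      s$intensity[s$mask == "valid"] * dataset$scale_factors[i]
    if (identical(s$meta$pipeline_stage, "scaled")) s$meta$pipeline_stage <- "interpolated"
    dataset$samples[[i]] <- s
  }
  dataset$scale_factors[] <- 1
  dataset
}
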