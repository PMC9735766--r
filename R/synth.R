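#' Define a synthetic fluorophore
#'
#' A fluorophore is modeled with Gaussian spectral bands: one or more
#' excitation bands (center nm, sigma nm, relative height) and a single
#' Gaussian emission band. Loading vectors generated from it are
#' nonnegative with unit maximum.
#'
#' @param name fluorophore label.
#' @param excitation_bands matrix-like with columns `center`, `width`
#'   (Gaussian sigma, nm) and `height` (relative, >= 0); one row per band.
#' @param emission_band numeric `c(center, width)` of the emission band.
#' @return A list of class `fluorophore_spec`.
#' @export
fluorophore <- function(name, excitation_bands, emission_band) {
  excitation_bands <- matrix(unlist(excitation_bands), ncol = 3, byrow = FALSE,
                             dimnames = list(NULL, c("center", "width", "height")))
  if (is.null(dim(excitation_bands)) || nrow(excitation_bands) < 1)
    stop("at least one excitation band is required", call. = FALSE)
  stopifnot(all(excitation_bands[, "width"] > 0),
            all(excitation_bands[, "height"] >= 0),
            length(emission_band) == 2, emission_band[2] > 0)
  structure(list(name = name,
                 excitation_bands = excitation_bands,
                 emission_band = as.numeric(emission_band)),
            class = "fluorophore_spec")
}

gauss_bands <- function(axis, bands) {
  v <- numeric(length(axis))
  for (r in seq_len(nrow(bands)))
    v <- v + bands[r, "height"] *
      exp(-0.5 * ((axis - bands[r, "center"]) / bands[r, "width"])^2)
  v
}

#' Evaluate a fluorophore's loading on a wavelength axis
#'
#' Sums the Gaussian bands on the axis, clips at zero and rescales to unit
#' maximum.
#'
#' @param spec a [fluorophore()].
#' @param axis ascending wavelength vector (nm).
#' @param mode `"excitation"` or `"emission"`.
#' @return Nonnegative loading vector with maximum 1.
#' @export
make_loading <- function(spec, axis, mode = c("excitation", "emission")) {
  stopifnot(inherits(spec, "fluorophore_spec"))
  mode <- match.arg(mode)
  if (!is_ascending(axis)) stop("axis must be ascending", call. = FALSE)
  bands <- if (mode == "excitation") spec$excitation_bands else
    matrix(c(spec$emission_band, 1), 1,
           dimnames = list(NULL, c("center", "width", "height")))
  v <- pmax(gauss_bands(axis, bands), 0)
  m <- max(v)
  if (m < 1e-8)
    stop("fluorophore ", spec$name, " is essentially zero on the given ",
         mode, " axis", call. = FALSE)
  v / m
}

#' Synthetic-scenario configuration
#'
#' Describes a simulated culture experiment: how many strain samples and
#' media blanks, which fluorophores, the per-sample concentration design
#' (peak intensities in R.U.), the noise level, the scatter-ridge
#' amplitudes and the measurement grid.
#'
#' @param n_strain_samples,n_blank_samples sample counts.
#' @param fluorophores list of [fluorophore()] specs.
#' @param concentration_design optional matrix (strain sample x
#'   fluorophore) of peak intensities in R.U.; when `NULL`, intensities
#'   are drawn uniformly from `concentration_range` at simulation time.
#' @param concentration_range range the random design spans (R.U.).
#' @param blank_background fixed per-fluorophore intensity of the media
#'   blanks (R.U.), near the detection limit.
#' @param noise_sd additive homoscedastic Gaussian noise SD (R.U.).
#' @param heteroscedastic if `TRUE`, an additional noise term with SD
#'   proportional (`noise_sd`) to the signal is added.
#' @param scatter_amplitudes named vector: `rayleigh1`, `rayleigh2` peak
#'   amplitudes (R.U.) of the Gaussian scatter ridges, and `raman`, a
#'   multiplier on the water Raman ridge whose base amplitude is
#'   calibrated so that the blank's Raman band area is exactly 1
#'   R.U.-by-definition (set all three to 0 for exactly trilinear data).
#' @param scatter_width Gaussian sigma of the ridge cross-sections (nm).
#' @param raman_shift water Raman shift, cm^-1.
#' @param raw_scale raw-unit Raman area: the generator builds intensities
#'   in R.U. and multiplies by this factor so that outputs are in
#'   instrument-like arbitrary units; Raman normalization recovers R.U.
#' @param ex,em wavelength grids (nm).
#' @param seed integer seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_strain_samples = 24,
                            n_blank_samples = 3,
                            fluorophores,
                            concentration_design = NULL,
                            concentration_range = c(0.02, 0.31),
                            blank_background = NULL,
                            noise_sd = 5e-4,
                            heteroscedastic = FALSE,
                            scatter_amplitudes = c(rayleigh1 = 5,
                                                   rayleigh2 = 1,
                                                   raman = 1),
                            scatter_width = 5,
                            raman_shift = 3400,
                            raw_scale = 1200,
                            ex = seq(250, 590, by = 5),
                            em = seq(260, 800, by = 1.12),
                            seed = 7) {
  stopifnot(n_strain_samples >= 1, n_blank_samples >= 0,
            length(fluorophores) >= 1,
            all(vapply(fluorophores, inherits, logical(1), "fluorophore_spec")),
            noise_sd >= 0, scatter_width > 0, raw_scale > 0,
            is_ascending(ex), is_ascending(em))
  nf <- length(fluorophores)
  if (!is.null(concentration_design)) {
    concentration_design <- as.matrix(concentration_design)
    stopifnot(nrow(concentration_design) == n_strain_samples,
              ncol(concentration_design) == nf,
              all(concentration_design >= 0))
  }
  blank_background <- blank_background %||% rep(0.005, nf)
  stopifnot(length(blank_background) == nf, all(blank_background >= 0))
  structure(list(
    n_strain_samples = as.integer(n_strain_samples),
    n_blank_samples = as.integer(n_blank_samples),
    fluorophores = fluorophores,
    concentration_design = concentration_design,
    concentration_range = concentration_range,
    blank_background = blank_background,
    noise_sd = noise_sd,
    heteroscedastic = heteroscedastic,
    scatter_amplitudes = scatter_amplitudes,
    scatter_width = scatter_width,
    raman_shift = raman_shift,
    raw_scale = raw_scale,
    ex = as.numeric(ex), em = as.numeric(em),
    seed = as.integer(seed)), class = "scenario_config")
}

#' The default simulated culture scenario
#'
#' Emulates a stationary-phase microalgae cultivation experiment from the
#' Ob and Yenisei gulf strains: three fluorophores — a protein-like
#' (tryptophan-like, T) emitter at 278/330 nm, a terrestrial humic-like
#' (C) emitter at 376/470 nm with a sub-300 nm excitation shoulder, and a
#' humic-like (A) emitter at 315/421 nm with a sub-260 nm excitation band
#' — measured on the instrument grid (excitation 250-590 nm in 5 nm steps,
#' emission 260-800 nm in 1.12 nm steps). 24 strain samples span peak
#' intensities of 0.02-0.31 R.U.; 3 media blanks carry a fixed
#' near-detection-limit background (0.0055 / 0.003 / 0.008 R.U.).
#'
#' @param name scenario name; only `"ob_yenisei"` is defined.
#' @param ... overrides passed on to [scenario_config()].
#' @return A `scenario_config`.
#' @export
default_scenario <- function(name = "ob_yenisei", ...) {
  if (!identical(name, "ob_yenisei"))
    stop("unknown scenario name: ", name, call. = FALSE)
  fl <- list(
    fluorophore("protein_T",
                excitation_bands = rbind(c(278, 15, 1)),
                emission_band = c(330, 18)),
    fluorophore("humic_C",
                excitation_bands = rbind(c(376, 35, 1), c(265, 30, 0.65)),
                emission_band = c(470, 40)),
    fluorophore("humic_A",
                excitation_bands = rbind(c(315, 30, 1), c(240, 25, 0.6)),
                emission_band = c(421, 35)))
  scenario_config(fluorophores = fl,
                  blank_background = c(0.0055, 0.003, 0.008), ...)
}

# Scatter ridges on the (ex, em) grid: Gaussian cross-sections along the
# emission axis centered at lambda_ex (Rayleigh 1st), 2*lambda_ex
# (Rayleigh 2nd) and the water Raman wavelength.
scatter_field <- function(ex, em, amplitudes, raman_amp, width, shift) {
  ridge <- function(centers, amp) {
    amp * exp(-0.5 * outer(centers, em, function(c0, m) (m - c0) / width)^2)
  }
  ridge(ex, amplitudes[["rayleigh1"]]) +
    ridge(2 * ex, amplitudes[["rayleigh2"]]) +
    ridge(raman_emission_wavelength(ex, shift), raman_amp)
}

#' Simulate an EEM dataset with known ground truth
#'
#' Builds each strain sample as the trilinear sum of its fluorophores
#' (concentration x excitation loading x emission loading) plus Rayleigh
#' and water-Raman scatter ridges and i.i.d. Gaussian noise; media blanks
#' contain only scatter, noise and a small fixed per-fluorophore
#' background. A pure-water blank (scatter and noise only) is returned for
#' Raman normalization and blank subtraction. The Raman ridge amplitude is
#' calibrated so that the noise-free water blank has unit Raman band area
#' in R.U.; all outputs are then multiplied by `raw_scale` to mimic raw
#' instrument units, so the preprocessing chain genuinely has work to do
#' and recovers intensities in R.U.
#'
#' @param cfg a [scenario_config].
#' @return A list of class `eem_simulation`: `dataset` (an [eem_dataset]
#'   of strain samples then media blanks, raw units), `water_blank` (an
#'   [eem]), and `truth` (list: `concentrations` in R.U. for every sample
#'   including blanks, `excitation_loadings`, `emission_loadings`,
#'   `is_blank`, `raman_area_raw`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  nf <- length(cfg$fluorophores)
  K <- length(cfg$ex); J <- length(cfg$em)
  Cl <- vapply(cfg$fluorophores, make_loading, numeric(K),
               axis = cfg$ex, mode = "excitation")
  Bl <- vapply(cfg$fluorophores, make_loading, numeric(J),
               axis = cfg$em, mode = "emission")

  # calibrate the Raman ridge so the water blank's band area is 1 in R.U.
  raman_mult <- if ("raman" %in% names(cfg$scatter_amplitudes))
    cfg$scatter_amplitudes[["raman"]] else 1
  raman_amp <- 0
  if (raman_mult > 0) {
    probe <- scatter_field(cfg$ex, cfg$em,
                           c(rayleigh1 = 0, rayleigh2 = 0),
                           raman_amp = 1, width = cfg$scatter_width,
                           shift = cfg$raman_shift)
    probe_eem <- eem(probe, cfg$ex, cfg$em, "raman_probe")
    raman_amp <- raman_mult / raman_area(probe_eem, raman_band())
  }
  scat <- scatter_field(cfg$ex, cfg$em, cfg$scatter_amplitudes,
                        raman_amp, cfg$scatter_width, cfg$raman_shift)

  conc_strain <- cfg$concentration_design %||%
    matrix(stats::runif(cfg$n_strain_samples * nf,
                        cfg$concentration_range[1],
                        cfg$concentration_range[2]),
           cfg$n_strain_samples, nf)
  conc_blank <- matrix(rep(cfg$blank_background, each = cfg$n_blank_samples),
                       cfg$n_blank_samples, nf)
  conc <- rbind(conc_strain, conc_blank)
  n <- nrow(conc)
  is_blank <- c(rep(FALSE, cfg$n_strain_samples),
                rep(TRUE, cfg$n_blank_samples))
  media <- rep(c("WC", "BBM"), length.out = max(cfg$n_blank_samples, 1))

  make_sample <- function(i) {
    signal <- matrix(0, K, J)
    for (f in seq_len(nf))
      signal <- signal + conc[i, f] * tcrossprod(Cl[, f], Bl[, f])
    ru <- signal + scat
    if (cfg$noise_sd > 0) {
      ru <- ru + stats::rnorm(K * J, sd = cfg$noise_sd)
      if (cfg$heteroscedastic)
        ru <- ru + stats::rnorm(K * J, sd = cfg$noise_sd) * signal
    }
    id <- if (is_blank[i]) sprintf("MEDIA%02d", i - cfg$n_strain_samples)
      else sprintf("ALG%02d", i)
    meta <- if (is_blank[i])
      list(strain = NA_character_, medium = media[i - cfg$n_strain_samples],
           stage = "initial")
    else list(strain = id, medium = media[1 + i %% 2], stage = "stationary")
    eem(ru * cfg$raw_scale, cfg$ex, cfg$em, sample_id = id, meta = meta)
  }
  samples <- lapply(seq_len(n), make_sample)

  wb <- scat
  if (cfg$noise_sd > 0) wb <- wb + stats::rnorm(K * J, sd = cfg$noise_sd)
  water_blank <- eem(wb * cfg$raw_scale, cfg$ex, cfg$em,
                     sample_id = "WATER_BLANK",
                     meta = list(medium = "water-blank"))

  dimnames(conc) <- list(vapply(samples, `[[`, character(1), "sample_id"),
                         vapply(cfg$fluorophores, `[[`, character(1), "name"))
  structure(list(
    dataset = eem_dataset(samples),
    water_blank = water_blank,
    truth = list(concentrations = conc,
                 excitation_loadings = Cl,
                 emission_loadings = Bl,
                 is_blank = is_blank,
                 raman_area_raw = cfg$raw_scale),
    config = cfg), class = "eem_simulation")
}

#' @export
print.eem_simulation <- function(x, ...) {
  cat(sprintf(
    "<eem_simulation> %d samples (%d blanks), %d fluorophores, noise SD %g R.U.\n",
    length(x$dataset$samples), sum(x$truth$is_blank),
    length(x$config$fluorophores), x$config$noise_sd))
  invisible(x)
}
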