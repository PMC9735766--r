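#' Run the full preprocessing chain on one EEM
#'
#' Applies, in the mandatory order: blank subtraction (optional),
#' inner-filter correction (when an absorbance spectrum is given), Raman
#' normalization, scatter excision and Whittaker interpolation.
#'
#' @param sample an [eem] at stage `"raw"`.
#' @param water_blank the pure-water blank [eem] (same grid).
#' @param absorbance optional `absorbance_spectrum` for inner-filter
#'   correction.
#' @param blank_subtract subtract the water blank cellwise first?
#' @param scatter a [scatter_config].
#' @param band a [raman_band].
#' @param area Raman normalization area; computed from `water_blank` when
#'   `NULL`.
#' @return The preprocessed [eem] in Raman Units.
#' @export
preprocess_eem <- function(sample, water_blank, absorbance = NULL,
                           blank_subtract = TRUE,
                           scatter = scatter_config(),
                           band = raman_band(), area = NULL) {
  area <- area %||% raman_area(water_blank, band)
  if (blank_subtract) sample <- subtract_blank(sample, water_blank)
  if (!is.null(absorbance)) sample <- correct_inner_filter(sample, absorbance)
  sample <- raman_normalize(sample, area)
  sample <- excise_scatter(sample, scatter)
  interpolate_scatter(sample, scatter)
}

#' Preprocess and assemble a dataset for decomposition
#'
#' Runs [preprocess_eem()] on every sample, optionally downsamples the
#' (densely sampled) emission axis by an integer factor, and scales each
#' sample by its standard deviation.
#'
#' @param eems list of raw [eem] objects (or an [eem_dataset]).
#' @param water_blank pure-water blank [eem].
#' @param absorbance optional `absorbance_spectrum` (one for all samples).
#' @param downsample_emission keep every k-th emission grid point after
#'   interpolation (1 = keep all).
#' @param scale scale samples by their SD (recommended before fitting)?
#' @inheritParams preprocess_eem
#' @return A preprocessed, scaled [eem_dataset] in R.U.
#' @export
preprocess_dataset <- function(eems, water_blank, absorbance = NULL,
                               blank_subtract = TRUE,
                               scatter = scatter_config(),
                               band = raman_band(),
                               downsample_emission = 1L,
                               scale = TRUE) {
  if (inherits(eems, "eem_dataset")) eems <- eems$samples
  area <- raman_area(water_blank, band)
  pre <- lapply(eems, preprocess_eem, water_blank = water_blank,
                absorbance = absorbance, blank_subtract = blank_subtract,
                scatter = scatter, band = band, area = area)
  em <- pre[[1]]$em
  if (downsample_emission > 1L)
    em <- em[seq(1L, length(em), by = as.integer(downsample_emission))]
  ds <- align_dataset(pre, em = em)
  if (scale) ds <- scale_by_sd(ds)
  ds
}

#' Published component intensities of algae-culture FDOM
#'
#' Peak fluorescence intensities (F_max, R.U.) of three PARAFAC components
#' (C1 protein-like, C2 and C3 humic-like) measured in cultures of five
#' Arctic microalgae strains at the stationary growth phase, and in the
#' two fresh cultivation media (BBM, WC) at the start of cultivation.
#' Shipped as a plain-text fixture so the contribution arithmetic is
#' testable without any spectra.
#'
#' @return Data frame with columns `sample`, `medium`, `stage`,
#'   `is_blank`, `C1`, `C2`, `C3`.
#' @export
algal_fdom_intensities <- function() {
  path <- system.file("extdata", "algal_fdom_intensities.csv",
                      package = "eemdom", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Print the contribution summary of a culture experiment
#'
#' Emits, from a [contribution_table] of five strain samples plus two
#' media blanks (other counts produce a warning but still report):
#' per-component mean stationary intensities (R.U.), mean +/- SD percent
#' shares and their ranges, the C1/C2 intensity ratio range, and the
#' media-blank contributions under the media-not-consumed assumption.
#' Values are printed rounded half-up to the conventional precision; the
#' returned object carries the raw values.
#'
#' @param table a [contribution_table] with media blanks flagged.
#' @param ratio component index pair for the intensity ratio.
#' @return Invisibly, a list with elements `summary` (from
#'   [summarize_contributions()]), `blank_pct`, and `display` (the
#'   rounded values as printed).
#' @export
reproduce_table1_summary <- function(table, ratio = c(1, 2)) {
  stopifnot(inherits(table, "contribution_table"))
  n_strain <- sum(!table$is_blank)
  n_blank <- sum(table$is_blank)
  if (n_strain != 5 || n_blank != 2)
    warning(sprintf(
      "expected 5 strain samples and 2 media blanks, got %d and %d",
      n_strain, n_blank))
  s <- summarize_contributions(table, ratio = ratio)
  blank_pct <- blank_contribution(table$fmax[table$is_blank, , drop = FALSE],
                                  s$mean_ru)
  comp <- table$components
  display <- list(
    mean_ru = round_half_up(s$mean_ru, 3),
    mean_pct = round_half_up(s$mean_pct, 0),
    sd_pct = round_half_up(s$sd_pct, 0),
    min_pct = round_half_up(s$min_pct, 0),
    max_pct = round_half_up(s$max_pct, 0),
    ratio = round_half_up(c(s$ratio$min, s$ratio$max), 1),
    blank_pct = round_half_up(blank_pct, 1))
  cat(sprintf("Component intensities at the stationary phase (n = %d):\n",
              s$n_strain))
  for (f in seq_along(comp))
    cat(sprintf("  %s: %.3f R.U.; share %g +/- %g %% (range %g-%g %%)\n",
                comp[f], display$mean_ru[f], display$mean_pct[f],
                display$sd_pct[f], display$min_pct[f], display$max_pct[f]))
  cat(sprintf("  %s/%s intensity ratio: %.1f-%.1f\n",
              comp[ratio[1]], comp[ratio[2]],
              display$ratio[1], display$ratio[2]))
  cat("  Media contribution to the final signal (media not consumed):",
      paste(sprintf("%s %.1f%%", comp, display$blank_pct), collapse = ", "),
      "\n")
  invisible(list(summary = s, blank_pct = blank_pct, display = display))
}

#' Run the whole analysis pipeline and write its artifacts
#'
#' Drives every stage from one configuration: data input (a named
#' synthetic scenario or a directory of EEM CSV files with a manifest),
#' preprocessing, nonnegative PARAFAC at the requested rank(s), split-half
#' validation, component characterization and contribution accounting.
#' One seed governs every random draw. Writes preprocessed EEMs, the
#' model directory, the split-half report, the component table, the
#' contribution table with its summary, and a run log recording all
#' parameters.
#'
#' @param config a named list or the path of a YAML file. Recognized
#'   blocks: `seed`; `input` (either `scenario` or `dir` with a
#'   `manifest.yaml` listing `samples:` (file, is_blank), `water_blank:`
#'   and optional `absorbance:`); `preprocess` (`blank_subtract`,
#'   `downsample_emission`, scatter/band parameter overrides); `fit`
#'   (`n_components`, `tol`, `max_iter`, `n_starts`); `validation`
#'   (`n_splits`, `threshold`, `n_starts`); `report`
#'   (`secondary_fraction`, `ratio`); `output` (directory).
#' @return Invisibly, a list with the dataset, model, split-half result,
#'   component spectra, contribution table and summary, and the output
#'   directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$output %||% stop("config field 'output' is required",
                                     call. = FALSE)
  seed <- config$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- "input"
  result <- tryCatch({
    logf("seed: %d", seed)

    pp <- config$preprocess %||% list()
    scatter <- do.call(scatter_config, pp$scatter %||% list())
    band <- do.call(raman_band, pp$raman_band %||% list())
    inp <- config$input %||% stop("config field 'input' is required",
                                  call. = FALSE)
    absorb <- NULL
    truth <- NULL
    if (!is.null(inp$scenario)) {
      logf("input: synthetic scenario '%s'", inp$scenario)
      sim <- do.call(default_scenario,
                     c(list(name = inp$scenario, seed = seed),
                       inp$scenario_options %||% list()))
      sim <- simulate_dataset(sim)
      eems <- sim$dataset$samples
      water_blank <- sim$water_blank
      is_blank <- sim$truth$is_blank
      truth <- sim$truth
    } else if (!is.null(inp$dir)) {
      man <- yaml::read_yaml(file.path(inp$dir, "manifest.yaml"))
      eems <- lapply(man$samples, function(s)
        read_eem(file.path(inp$dir, s$file)))
      is_blank <- vapply(man$samples, function(s)
        isTRUE(s$is_blank), logical(1))
      water_blank <- read_eem(file.path(inp$dir, man$water_blank))
      if (!is.null(man$absorbance))
        absorb <- read_absorbance(file.path(inp$dir, man$absorbance))
      logf("input: %d EEMs from %s", length(eems), inp$dir)
    } else stop("config input must name a 'scenario' or a 'dir'",
                call. = FALSE)

    stage <- "preprocess"
    ds <- preprocess_dataset(
      eems, water_blank, absorbance = absorb,
      blank_subtract = pp$blank_subtract %||% TRUE,
      scatter = scatter, band = band,
      downsample_emission = pp$downsample_emission %||% 4L)
    logf("preprocess: %d samples, %d ex x %d em after downsampling",
         length(ds$samples), length(ds$samples[[1]]$ex),
         length(ds$samples[[1]]$em))
    pre_dir <- file.path(out_dir, "preprocessed")
    dir.create(pre_dir, showWarnings = FALSE)
    for (s in ds$samples)
      write_eem(s, file.path(pre_dir, paste0(s$sample_id, ".csv")))

    stage <- "fit"
    fit_opts <- config$fit %||% list()
    nc <- fit_opts$n_components %||% 3L
    cfg <- fit_config(tol = fit_opts$tol %||% 1e-6,
                      max_iter = fit_opts$max_iter %||% 1000,
                      n_starts = fit_opts$n_starts %||% 10,
                      seed = seed)
    model <- fit_parafac(ds, nc, cfg)
    logf("fit: F = %d, expl. var. %.6f, %d iterations, converged = %s",
         nc, model$explained_variance, model$n_iterations, model$converged)
    write_parafac(model, file.path(out_dir, "model"),
                  sample_ids = vapply(ds$samples, `[[`, character(1),
                                      "sample_id"))

    stage <- "validation"
    val_opts <- config$validation %||% list()
    vcfg <- cfg
    vcfg$n_starts <- as.integer(val_opts$n_starts %||% 2L)
    vcfg$max_iter <- as.integer(val_opts$max_iter %||% 500L)
    sh <- split_half(ds, nc, n_splits = val_opts$n_splits %||% 32,
                     cfg = vcfg, seed = seed,
                     threshold = val_opts$threshold %||% 0.95)
    logf("validation: min congruence %.4f over %d splits -> %s",
         sh$min_congruence, sh$n_splits,
         if (sh$validated) "validated" else "NOT validated")
    utils::write.csv(sh$congruence, file.path(out_dir, "splithalf.csv"),
                     row.names = FALSE)
    yaml::write_yaml(list(F = sh$F, n_splits = sh$n_splits,
                          min_congruence = sh$min_congruence,
                          threshold = sh$threshold,
                          validated = sh$validated, seed = sh$seed),
                     file.path(out_dir, "splithalf.yaml"))

    stage <- "report"
    rep_opts <- config$report %||% list()
    specs <- lapply(seq_len(nc), function(f)
      find_component_peaks(model, f,
                           rep_opts$secondary_fraction %||% 0.5))
    comp_df <- data.frame(
      component = vapply(specs, `[[`, character(1), "label"),
      emission_peak_nm = vapply(specs, `[[`, numeric(1), "emission_peak"),
      excitation_peaks_nm = vapply(specs, function(s) {
        pk <- s$excitation_peaks
        if (!nrow(pk)) return(NA_character_)
        paste(ifelse(pk$boundary_censored,
                     paste0("<=", round(pk$wavelength, 1)),
                     round(pk$wavelength, 1)), collapse = ";")
      }, character(1)),
      coble_class = vapply(specs, `[[`, character(1), "coble_class"))
    utils::write.csv(comp_df, file.path(out_dir, "components.csv"),
                     row.names = FALSE)
    for (s in specs) logf("component %s: em %.4g nm, class %s", s$label,
                          s$emission_peak, s$coble_class)

    fmax <- compute_fmax(model, ds)
    tab <- contribution_table(fmax, is_blank = is_blank)
    contrib_df <- data.frame(sample = tab$sample_ids, is_blank = tab$is_blank,
                             tab$fmax, tab$percent, check.names = FALSE)
    names(contrib_df) <- c("sample", "is_blank",
                           paste0(tab$components, "_RU"),
                           paste0(tab$components, "_pct"))
    utils::write.csv(contrib_df, file.path(out_dir, "contributions.csv"),
                     row.names = FALSE)
    ratio <- rep_opts$ratio %||% c(1, 2)
    summ <- summarize_contributions(tab, ratio = ratio)
    blank_pct <- if (any(tab$is_blank))
      blank_contribution(tab$fmax[tab$is_blank, , drop = FALSE],
                         summ$mean_ru) else NULL
    yaml::write_yaml(list(
      n_strain = summ$n_strain,
      components = summ$components,
      mean_ru = as.numeric(summ$mean_ru),
      mean_pct = as.numeric(summ$mean_pct),
      sd_pct = as.numeric(summ$sd_pct),
      min_pct = as.numeric(summ$min_pct),
      max_pct = as.numeric(summ$max_pct),
      ratio = summ$ratio,
      blank_contribution_pct = as.numeric(blank_pct)),
      file.path(out_dir, "summary.yaml"))
    logf("report: mean shares %s %%",
         paste(sprintf("%.1f", summ$mean_pct), collapse = " / "))

    list(dataset = ds, model = model, split_half = sh, components = specs,
         contributions = tab, summary = summ, blank_contribution = blank_pct,
         truth = truth, output = out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
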