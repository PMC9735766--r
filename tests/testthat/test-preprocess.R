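make_pair <- function(vals, blank_vals = NULL, ex = c(250, 255, 260),
                      em = c(300, 305, 310)) {
  s <- eem(vals, ex, em, "s")
  b <- eem(blank_vals %||% matrix(0, length(ex), length(em)), ex, em, "b")
  list(s = s, b = b)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("blank subtraction is cellwise and checks grids", {
  v <- matrix(1, 3, 3)
  p <- make_pair(v, v)
  expect_equal(subtract_blank(p$s, p$b)$intensity, matrix(0, 3, 3))

  p <- make_pair(v)
  expect_equal(subtract_blank(p$s, p$b)$intensity, v)

  p <- make_pair(matrix(1, 3, 3), matrix(0.25, 3, 3))
  expect_equal(subtract_blank(p$s, p$b)$intensity[1, 1], 0.75)

  other <- eem(matrix(0, 3, 3), c(250, 255, 260), c(301, 305, 310))
  expect_error(subtract_blank(p$s, other), "alignment error")
})

test_that("inner-filter correction applies the ABA factor", {
  ex <- c(250, 300); em <- c(350, 400)
  s <- eem(matrix(1, 2, 2), ex, em)
  a0 <- absorbance_spectrum(c(200, 500), c(0, 0))
  expect_equal(correct_inner_filter(s, a0)$intensity, matrix(1, 2, 2))

  # A(ex) = 0.2, A(em) = 0.1 -> factor 10^0.15
  a1 <- absorbance_spectrum(c(250, 300, 350, 400),
                            c(0.2, 0.2, 0.1, 0.1))
  out <- correct_inner_filter(eem(matrix(1, 2, 2), ex, em), a1)
  expect_equal(out$intensity[1, 1], 10^0.15, tolerance = 1e-10)

  a2 <- absorbance_spectrum(c(200, 500), c(0.3, 0.3))
  out2 <- correct_inner_filter(eem(matrix(2, 2, 2), ex, em), a2)
  expect_equal(out2$intensity[2, 2], 2 * 10^0.3, tolerance = 1e-10)

  # coverage error when the spectrum does not span the emission axis
  a3 <- absorbance_spectrum(c(250, 320), c(0.1, 0.1))
  expect_error(correct_inner_filter(eem(matrix(1, 2, 2), ex, em), a3),
               "does not cover")
})

test_that("inner-filter correction never decreases intensity", {
  set.seed(11)
  ex <- seq(250, 400, 25); em <- seq(300, 500, 20)
  s <- eem(matrix(runif(length(ex) * length(em)), length(ex)), ex, em)
  a <- absorbance_spectrum(c(200, 600), c(0.4, 0.01))
  out <- correct_inner_filter(s, a)
  expect_true(all(out$intensity >= s$intensity))

  aneg <- absorbance_spectrum(c(200, 600), c(-0.1, 0.2))
  expect_warning(out2 <- correct_inner_filter(s, aneg), "clamped")
  expect_true(all(out2$intensity >= s$intensity))
})

test_that("Raman emission wavelength follows the wavenumber shift", {
  expect_equal(raman_emission_wavelength(350, 3400),
               1 / (1 / 350 - 3.4e-4), tolerance = 1e-12)
  expect_equal(raman_emission_wavelength(350, 3400), 397.2758,
               tolerance = 1e-6)
  expect_equal(raman_emission_wavelength(250, 3400), 273.2240,
               tolerance = 1e-6)
  expect_equal(raman_emission_wavelength(321, 0), 321)

  # strictly increasing in excitation and above it for positive shift
  lx <- seq(250, 590, 5)
  r <- raman_emission_wavelength(lx)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > lx))

  expect_error(raman_emission_wavelength(5000, 3400), "nonphysical")
})

test_that("Raman area is the trapezoidal band integral of the blank scan", {
  ex <- seq(340, 360, 5); em <- seq(365, 435, 1)
  blank <- eem(matrix(1, length(ex), length(em)), ex, em, "water")
  expect_equal(raman_area(blank), 57)

  blank2 <- eem(matrix(2, length(ex), length(em)), ex, em, "water")
  expect_equal(raman_area(blank2), 2 * raman_area(blank))

  zero <- eem(matrix(0, length(ex), length(em)), ex, em, "water")
  expect_error(raman_area(zero), "normalization error")

  short <- eem(matrix(1, length(ex), 11), ex, seq(365, 415, 5), "water")
  expect_error(raman_area(short), "coverage error")
  far <- eem(matrix(1, 3, length(em)), c(200, 210, 220), em, "water")
  expect_error(raman_area(far), "coverage error")
})

test_that("Raman normalization rescales into R.U. and inverts exactly", {
  ex <- c(250, 255); em <- c(300, 305)
  s <- eem(matrix(c(1, 2, 3, 4), 2), ex, em)
  out <- raman_normalize(s, 2)
  expect_equal(out$intensity, s$intensity / 2)
  expect_identical(out$meta$units, "R.U.")

  one <- raman_normalize(eem(matrix(1:4, 2), ex, em), 1)
  expect_equal(one$intensity, matrix(1:4, 2))
  expect_equal(out$intensity * 2, s$intensity)

  expect_error(raman_normalize(eem(matrix(1:4, 2), ex, em), 0),
               "normalization error")
})

test_that("scatter excision marks cells by geometry alone", {
  ex <- seq(250, 590, 5); em <- seq(260, 800, 4)
  s <- eem(matrix(runif(length(ex) * length(em)), length(ex)), ex, em)
  out <- excise_scatter(s)
  cell <- function(e, m) out$mask[which(ex == e), which.min(abs(em - m))]

  expect_identical(cell(350, 360), "excised")     # 1st Rayleigh, offset 10
  expect_identical(cell(350, 396), "excised")     # 1st Raman (397.28)
  expect_identical(cell(350, 450), "valid")       # between bands
  expect_identical(cell(300, 280), "undefined")   # anti-Stokes strip
  expect_identical(cell(350, 700), "excised")     # 2nd Rayleigh
  # non-physical region is anchored at zero, not masked
  expect_identical(cell(350, 300), "valid")
  expect_equal(out$intensity[which(ex == 350), which.min(abs(em - 300))], 0)

  # mask depends only on wavelengths, never on intensity
  s2 <- eem(10 * matrix(runif(length(ex) * length(em)), length(ex)), ex, em)
  expect_identical(excise_scatter(s2)$mask, out$mask)
})

test_that("Whittaker interpolation restores a linear gap exactly", {
  ex <- c(300, 305); em <- seq(400, 500, 5)
  vals <- matrix(rep(0.01 * em + 1, each = 2), nrow = 2)
  s <- eem(vals, ex, em, meta = list(pipeline_stage = "raman_normalized"))
  s <- excise_scatter(s)  # nothing excised on this grid slice
  # carve an interior gap by hand and tag it as Raman-excised
  gap <- 8:12
  s$mask[1, gap] <- "excised"
  s$meta$scatter_type[1, gap] <- 2L
  out <- interpolate_scatter(s)
  expect_equal(out$intensity[1, gap], 0.01 * em[gap] + 1, tolerance = 1e-6)
  expect_true(all(out$mask[1, gap] == "valid"))
})

test_that("interpolation leaves untouched data unchanged and fills a masked trilinear EEM", {
  cfg <- quick_scenario(n_strain = 1, n_blank = 0, noise_sd = 0,
                        scatter_amplitudes = c(rayleigh1 = 0, rayleigh2 = 0, raman = 0))
  sim <- simulate_dataset(cfg)
  truth <- matrix(0, length(cfg$ex), length(cfg$em))
  for (f in seq_along(cfg$fluorophores))
    truth <- truth + sim$truth$concentrations[1, f] *
      tcrossprod(sim$truth$excitation_loadings[, f],
                 sim$truth$emission_loadings[, f])
  s <- eem(truth, cfg$ex, cfg$em,
           meta = list(pipeline_stage = "raman_normalized"))
  e <- excise_scatter(s)
  was_excised <- e$mask == "excised"
  stype <- e$meta$scatter_type
  out <- suppressWarnings(interpolate_scatter(e))

  # exclude the zero-anchored non-physical triangle, whose tiny band tails
  # are deliberately overwritten with zeros
  stokes <- outer(cfg$ex, cfg$em, `-`) < 18
  untouched <- e$mask == "valid" & truth > 0 & stokes
  expect_equal(out$intensity[untouched], truth[untouched])

  # relative error is meaningful where the signal is: the Rayleigh band
  # hugs the zero-anchored triangle, so its faint band tails carry large
  # relative (but negligible absolute) fill error
  filled <- was_excised & out$mask == "valid"
  sig <- filled & truth > 0.05 * max(truth)
  rel <- abs(out$intensity[sig] - truth[sig]) / truth[sig]
  expect_lt(median(rel), 0.05)
  # first-order Raman gaps cross the emission peaks; their fills must be
  # accurate even at modest signal
  raman_cells <- filled & truth > 0.01 * max(truth) & stype == 2L
  rel_raman <- abs(out$intensity[raman_cells] - truth[raman_cells]) /
    truth[raman_cells]
  expect_lt(median(rel_raman), 0.05)
})

test_that("SD scaling divides valid cells and is invertible", {
  ex <- c(250, 255); em <- c(300, 305)
  s <- eem(matrix(c(0, 2, 0, 2), 2), ex, em, "s")
  ds <- scale_by_sd(eem_dataset(list(s)))
  expect_equal(ds$scale_factors, sd(c(0, 2, 0, 2)))
  expect_equal(ds$samples[[1]]$intensity[2, 1], 2 / sd(c(0, 2, 0, 2)))

  s2 <- eem(matrix(c(0, 2), 1, 2), 250, c(300, 305), "s2")
  ds2 <- scale_by_sd(eem_dataset(list(s2)))
  expect_equal(ds2$scale_factors, sqrt(2))
  expect_equal(ds2$samples[[1]]$intensity[1, ], c(0, sqrt(2)))

  const <- eem(matrix(1, 2, 2), ex, em, "flat")
  expect_error(scale_by_sd(eem_dataset(list(const))), "flat")

  back <- unscale(ds)
  expect_equal(back$samples[[1]]$intensity, s$intensity)
  expect_equal(back$scale_factors, 1)
})

test_that("pipeline stage order is enforced", {
  ex <- c(250, 255); em <- c(300, 305)
  s <- eem(matrix(1:4, 2), ex, em)
  b <- eem(matrix(0, 2, 2), ex, em)
  s1 <- raman_normalize(s, 2)
  expect_error(subtract_blank(s1, b), "order violation")
  expect_error(raman_normalize(s1, 2), "order violation")
  expect_error(interpolate_scatter(s1), "requires an EEM at stage")
  s2 <- excise_scatter(s1)
  expect_error(excise_scatter(s2), "order violation")
})
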