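# A hand-built model wrapper for peak/classification tests.
toy_model <- function(ex, em, ex_loading, em_loading) {
  structure(list(n_components = 1L,
                 scores = matrix(1, 1, 1),
                 emission_loadings = matrix(em_loading, ncol = 1),
                 excitation_loadings = matrix(ex_loading, ncol = 1),
                 ex = ex, em = em), class = "parafac_model")
}

test_that("peak picking finds the argmax, secondaries and censored edges", {
  ex <- seq(250, 450, 5); em <- seq(300, 520, 4)
  m <- toy_model(ex, em, gauss(ex, 280, 15), gauss(em, 330, 20))
  sp <- find_component_peaks(m, 1)
  expect_equal(sp$emission_peak, 330, tolerance = 1)
  expect_equal(sp$excitation_peaks$wavelength[1], 280, tolerance = 1)
  expect_false(sp$excitation_peaks$boundary_censored[1])

  # maximal at the grid edge with a secondary interior bump
  m2 <- toy_model(ex, em, gauss(ex, 235, 25) + 0.8 * gauss(ex, 315, 20),
                  gauss(em, 421, 25))
  sp2 <- find_component_peaks(m2, 1)
  expect_true(sp2$excitation_peaks$boundary_censored[1])
  expect_equal(sp2$excitation_peaks$wavelength_grid[1], 250)
  expect_equal(sp2$excitation_peaks$wavelength[2], 315, tolerance = 1.5)

  # two-bump loading ordered by height
  m3 <- toy_model(ex, em, gauss(ex, 376, 20) + 0.8 * gauss(ex, 270, 15),
                  gauss(em, 470, 25))
  sp3 <- find_component_peaks(m3, 1)
  expect_equal(sp3$excitation_peaks$wavelength, c(376, 270), tolerance = 1.5)

  # secondary below the threshold fraction is dropped
  sp4 <- find_component_peaks(m3, 1, secondary_fraction = 0.9)
  expect_equal(nrow(sp4$excitation_peaks), 1)

  flat <- toy_model(ex, em, rep(1, length(ex)), gauss(em, 400, 20))
  expect_warning(spf <- find_component_peaks(flat, 1), "flat")
  expect_equal(nrow(spf$excitation_peaks), 0)
  expect_identical(spf$coble_class, "unknown")
})

test_that("Coble classification follows the conventional peak windows", {
  mk <- function(exp, emp, censored = FALSE) {
    structure(list(label = "C", emission_peak = emp,
                   excitation_peaks = data.frame(
                     wavelength = exp, wavelength_grid = exp,
                     height = seq(1, by = -0.1, length.out = length(exp)),
                     boundary_censored = censored),
                   coble_class = "unknown"), class = "component_spectrum")
  }
  expect_identical(classify_coble(mk(278, 330)), "T")
  expect_identical(classify_coble(mk(c(250, 315), 421, c(TRUE, FALSE))), "A")
  expect_identical(classify_coble(mk(376, 470)), "C")
  expect_identical(classify_coble(mk(300, 390)), "M")
  expect_identical(classify_coble(mk(275, 310)), "B")
  expect_identical(classify_coble(mk(500, 600)), "unknown")
  # majority vote with primary-peak tie break
  expect_identical(classify_coble(mk(c(376, 265), 470)), "C")
  expect_identical(classify_coble(mk(c(265, 250), 470, c(FALSE, TRUE))), "A")
})

test_that("F_max combines scores with the stored scale factors", {
  r1 <- rank1_dataset(scores = c(1, 2, 3, 4))
  m <- fit_parafac(r1$dataset, 1, fit_config(n_starts = 1, seed = 3))
  ds <- r1$dataset
  ds$scale_factors <- c(2, 1, 0.5, 1)
  fm <- compute_fmax(m, ds)
  expect_equal(as.numeric(fm[, 1]), c(2, 2, 1.5, 4), tolerance = 1e-6)

  fm1 <- compute_fmax(m, r1$dataset)  # unit factors: F_max equals scores
  expect_equal(unname(fm1), unname(m$scores), tolerance = 1e-12)

  short <- eem_dataset(r1$dataset$samples[1:2])
  expect_error(compute_fmax(m, short), "different numbers of samples")
})

test_that("percent contributions are normalized rows", {
  expect_equal(round(contribution_percent(c(0.173, 0.285, 0.134))[2]), 48)
  expect_equal(contribution_percent(c(3, 3, 3)), rep(100 / 3, 3))
  expect_equal(contribution_percent(c(1, 0, 0)), c(100, 0, 0))
  expect_error(contribution_percent(c(0, 0)), "undefined contribution")
  expect_error(contribution_percent(c(-1, 2)), "nonnegative")
})

test_that("contribution tables and summaries reproduce the published arithmetic", {
  tab1 <- algal_fdom_intensities()
  fmax <- as.matrix(tab1[, c("C1", "C2", "C3")])
  rownames(fmax) <- tab1$sample
  ct <- contribution_table(fmax, is_blank = tab1$is_blank)
  expect_true(all(abs(rowSums(ct$percent) - 100) < 1e-6))

  s <- summarize_contributions(ct, ratio = c(1, 2))
  expect_equal(unname(s$mean_ru), c(0.1458, 0.1078, 0.0862), tolerance = 1e-12)
  expect_equal(round(unname(s$mean_pct[3])), 27)
  expect_equal(round(unname(s$min_pct[3])), 22)
  expect_equal(round(unname(s$max_pct[3])), 33)
  expect_equal(round(unname(s$sd_pct)), c(15, 14, 5))
  expect_equal(s$ratio$min, 0.173 / 0.285, tolerance = 1e-12)

  # blanks are excluded from strain summaries
  expect_equal(s$n_strain, 5)

  two <- contribution_table(fmax[c(1, 1), ])
  s2 <- summarize_contributions(two)
  expect_equal(unname(s2$sd_pct), rep(0, 3))

  one <- contribution_table(fmax[1, , drop = FALSE])
  expect_warning(s1 <- summarize_contributions(one), "SD not available")
  expect_true(all(is.na(s1$sd_pct)))
})

test_that("media blank contributions follow the not-consumed assumption", {
  media <- rbind(c(0.005, 0.002, 0.008), c(0.006, 0.004, 0.008))
  stat_mean <- c(0.1458, 0.1078, 0.0862)
  bc <- blank_contribution(media, stat_mean)
  expect_equal(round(bc[2], 1), 2.8)
  expect_equal(blank_contribution(matrix(0, 2, 3), stat_mean), rep(0, 3))
  expect_equal(blank_contribution(rbind(stat_mean), stat_mean), rep(100, 3))
  expect_error(blank_contribution(media, c(0.1, 0, 0.1)), "zero stationary")
  expect_error(blank_contribution(media, c(0.1, 0.1)), "component counts")
})
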