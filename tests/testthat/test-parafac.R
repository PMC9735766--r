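test_that("the active-set NNLS agrees with an independent solver", {
  skip_if_not_installed("pracma")
  set.seed(42)
  for (i in 1:50) {
    f <- sample(2:6, 1)
    Z <- matrix(runif(30 * f), 30, f)
    x <- runif(30) - 0.3
    ours <- eemdom:::fnnls(crossprod(Z), crossprod(Z, x))
    ref <- pracma::lsqnonneg(Z, x)$x
    expect_equal(as.numeric(ours), as.numeric(ref), tolerance = 1e-7)
  }
})

test_that("a noise-free rank-1 cube is recovered exactly", {
  r1 <- rank1_dataset()
  m <- fit_parafac(r1$dataset, 1, fit_config(n_starts = 2, seed = 3))
  expect_gte(m$explained_variance, 1 - 1e-10)
  expect_equal(tucker_congruence(m$emission_loadings[, 1], r1$b), 1,
               tolerance = 1e-6)
  expect_equal(tucker_congruence(m$excitation_loadings[, 1], r1$c0), 1,
               tolerance = 1e-6)
  # unit-max loadings make scores the peak intensities
  expect_equal(as.numeric(m$scores[, 1]), r1$scores, tolerance = 1e-6)
})

test_that("20% random masking does not degrade rank-1 recovery", {
  r1 <- rank1_dataset(mask_frac = 0.2)
  m <- fit_parafac(r1$dataset, 1, fit_config(n_starts = 2, seed = 3))
  expect_equal(tucker_congruence(m$emission_loadings[, 1], r1$b), 1,
               tolerance = 1e-4)
  expect_equal(tucker_congruence(m$excitation_loadings[, 1], r1$c0), 1,
               tolerance = 1e-4)
})

test_that("fits are deterministic given the seed and factors nonnegative", {
  cfg <- quick_scenario(n_strain = 6, n_blank = 0)
  sim <- simulate_dataset(cfg)
  ds <- suppressWarnings(preprocess_dataset(sim$dataset, sim$water_blank))
  fc <- fit_config(n_starts = 2, seed = 5, tol = 1e-6, max_iter = 300)
  m1 <- suppressWarnings(fit_parafac(ds, 3, fc))
  m2 <- suppressWarnings(fit_parafac(ds, 3, fc))
  expect_identical(m1$scores, m2$scores)
  expect_identical(m1$emission_loadings, m2$emission_loadings)
  expect_true(all(m1$scores >= 0))
  expect_true(all(m1$emission_loadings >= 0))
  expect_true(all(m1$excitation_loadings >= 0))
  expect_equal(unname(apply(m1$emission_loadings, 2, max)), rep(1, 3))
  expect_equal(unname(apply(m1$excitation_loadings, 2, max)), rep(1, 3))
  # components ordered by ascending emission peak
  pk <- m1$em[apply(m1$emission_loadings, 2, which.max)]
  expect_true(all(diff(pk) > 0))
})

test_that("observed-cell SSE is non-increasing across ALS iterations", {
  r1 <- rank1_dataset(mask_frac = 0.15)
  m <- fit_parafac(r1$dataset, 1, fit_config(n_starts = 1, seed = 2))
  tr <- m$sse_trace
  expect_true(all(diff(tr) <= 1e-9 * pmax(tr[-length(tr)], 1e-300)))

  cfg <- quick_scenario(n_strain = 5, n_blank = 0)
  sim <- simulate_dataset(cfg)
  ds <- suppressWarnings(preprocess_dataset(sim$dataset, sim$water_blank))
  m2 <- suppressWarnings(fit_parafac(ds, 2, fit_config(n_starts = 1, seed = 2,
                                                       max_iter = 150)))
  tr2 <- m2$sse_trace
  expect_true(all(diff(tr2) <= 1e-9 * tr2[-length(tr2)]))
})

test_that("F beyond the smallest mode dimension is rejected", {
  r1 <- rank1_dataset()
  expect_error(fit_parafac(r1$dataset, 5, fit_config(n_starts = 1)),
               "between 1 and")
})

test_that("reconstruct evaluates the trilinear model", {
  r1 <- rank1_dataset()
  m <- fit_parafac(r1$dataset, 1, fit_config(n_starts = 1, seed = 3))
  cube <- as_cube(r1$dataset)
  expect_lt(sum((reconstruct(m) - cube)^2), 1e-10)

  # hand-built model: single nonzero cell
  m$scores <- matrix(2, 1, 1)
  m$emission_loadings <- matrix(c(rep(0, 4), 1,
                                  rep(0, length(r1$dataset$samples[[1]]$em) - 5)))
  m$excitation_loadings <- matrix(c(0, 0, 1,
                                    rep(0, length(r1$dataset$samples[[1]]$ex) - 3)))
  rc <- reconstruct(m)
  expect_equal(rc[1, 3, 5], 2)
  expect_equal(sum(rc != 0), 1)

  m$scores <- matrix(0, 1, 1)
  expect_true(all(reconstruct(m) == 0))
})

test_that("core consistency is 100 on exactly trilinear data and drops when over-factored", {
  r1 <- rank1_dataset()
  m1 <- fit_parafac(r1$dataset, 1, fit_config(n_starts = 1, seed = 3))
  expect_equal(corcondia(m1, r1$dataset), 100, tolerance = 0.1)

  cfg <- quick_scenario(n_strain = 8, n_blank = 0, noise_sd = 0,
                        scatter_amplitudes = c(rayleigh1 = 0, rayleigh2 = 0, raman = 0))
  sim <- simulate_dataset(cfg)
  ds <- align_dataset(sim$dataset$samples)
  m3 <- suppressWarnings(fit_parafac(ds, 3, fit_config(n_starts = 2, seed = 1,
                                                       tol = 1e-9)))
  cc3 <- corcondia(m3, ds)
  m4 <- suppressWarnings(fit_parafac(ds, 4, fit_config(n_starts = 2, seed = 1,
                                                       max_iter = 400)))
  cc4 <- corcondia(m4, ds)
  expect_gt(cc3, 99)
  expect_lt(cc4, cc3)
})

test_that("constrained SSE matches an unconstrained baseline when the truth is nonnegative", {
  # dense small cube, nonnegative rank-2 truth
  ex <- seq(300, 370, 10); em <- seq(400, 470, 10)
  b1 <- gauss(em, 420, 20); b2 <- gauss(em, 455, 15)
  c1 <- gauss(ex, 320, 15); c2 <- gauss(ex, 350, 12)
  sc <- cbind(c(1, 2, 0.5, 1.5, 1), c(0.5, 1, 2, 0.3, 1.2))
  samples <- lapply(1:5, function(i)
    eem(sc[i, 1] * outer(c1, b1) + sc[i, 2] * outer(c2, b2), ex, em,
        paste0("s", i)))
  ds <- align_dataset(samples)
  m <- fit_parafac(ds, 2, fit_config(n_starts = 3, seed = 1, tol = 1e-10))
  base <- unconstrained_parafac_sse(as_cube(ds), 2, iters = 300, seed = 1)
  expect_lte(m$sse, base + 1e-8)
})

test_that("model serialization writes all artifacts", {
  r1 <- rank1_dataset()
  m <- fit_parafac(r1$dataset, 1, fit_config(n_starts = 1, seed = 3))
  dir <- withr::local_tempdir()
  write_parafac(m, dir, sample_ids = paste0("s", 1:4))
  expect_true(all(file.exists(file.path(dir,
    c("scores.csv", "emission_loadings.csv", "excitation_loadings.csv",
      "fit.yaml", "openfluor.txt")))))
  sc <- read.csv(file.path(dir, "scores.csv"))
  expect_equal(sc$C1, as.numeric(m$scores[, 1]), tolerance = 1e-6)
  of <- readLines(file.path(dir, "openfluor.txt"))
  expect_equal(sum(startsWith(of, "Ex")), length(m$ex))
  expect_equal(sum(startsWith(of, "Em")), length(m$em))
})
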