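# Small grids and generators shared across tests. Everything is built in
# code; no binary fixtures.

small_ex <- seq(250, 400, by = 10)
small_em <- seq(300, 500, by = 5)

# A simple Gaussian band evaluated on an axis.
gauss <- function(axis, center, sigma) exp(-0.5 * ((axis - center) / sigma)^2)

# Rank-1 trilinear dataset from known nonnegative vectors, optional random
# cell masking.
rank1_dataset <- function(scores = c(2, 1, 3, 0.5),
                          ex = small_ex, em = small_em,
                          em_center = 400, em_sigma = 30,
                          ex_center = 320, ex_sigma = 25,
                          mask_frac = 0, mask_seed = 99) {
  b <- gauss(em, em_center, em_sigma)
  c0 <- gauss(ex, ex_center, ex_sigma)
  samples <- lapply(seq_along(scores), function(i) {
    mk <- NULL
    if (mask_frac > 0) {
      set.seed(mask_seed + i)
      mk <- matrix("valid", length(ex), length(em))
      mk[sample(length(mk), round(mask_frac * length(mk)))] <- "excised"
    }
    eem(scores[i] * outer(c0, b), ex, em, sample_id = paste0("s", i),
        mask = mk)
  })
  list(dataset = align_dataset(samples), scores = scores, b = b, c0 = c0)
}

# A fast low-resolution culture scenario for tests that do not need the
# instrument grid.
quick_scenario <- function(seed = 7, n_strain = 10, n_blank = 2,
                           noise_sd = 5e-4, ...) {
  default_scenario(seed = seed, n_strain_samples = n_strain,
                   n_blank_samples = n_blank, noise_sd = noise_sd,
                   ex = seq(250, 500, by = 10), em = seq(260, 620, by = 4),
                   ...)
}

# Independent unconstrained trilinear ALS baseline (no nonnegativity, no
# missing-data handling) used as an oracle for SSE comparisons on dense
# cubes. Deliberately written differently from the package: plain
# lm.fit-style normal equations per mode.
unconstrained_parafac_sse <- function(cube, F, iters = 200, seed = 1) {
  set.seed(seed)
  n <- dim(cube)[1]; K <- dim(cube)[2]; J <- dim(cube)[3]
  A <- matrix(rnorm(n * F), n, F)
  B <- matrix(rnorm(J * F), J, F)
  C <- matrix(rnorm(K * F), K, F)
  Xa <- matrix(cube, n, K * J)
  kr <- function(B, C) B[rep(seq_len(nrow(B)), each = nrow(C)), , drop = FALSE] *
    C[rep.int(seq_len(nrow(C)), nrow(B)), , drop = FALSE]
  for (it in seq_len(iters)) {
    Z <- kr(B, C)
    A <- Xa %*% Z %*% solve(crossprod(Z))
    G <- crossprod(Xa, A)
    for (f in seq_len(F)) {
      M <- matrix(G[, f], K, J)
      B[, f] <- t(M) %*% C[, f]
    }
    B <- B %*% solve(crossprod(A) * crossprod(C))
    for (f in seq_len(F)) {
      M <- matrix(G[, f], K, J)
      C[, f] <- M %*% B[, f]
    }
    C <- C %*% solve(crossprod(A) * crossprod(B))
  }
  sum((Xa - tcrossprod(A, kr(B, C)))^2)
}

# Write a tiny EEM CSV by hand (independent of write_eem) for parser tests.
write_csv_matrix <- function(path, ex, em, vals) {
  lines <- c(paste(c("ex", em), collapse = ","),
             vapply(seq_along(ex), function(i)
               paste(c(ex[i], vals[i, ]), collapse = ","), character(1)))
  writeLines(lines, path)
  path
}
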