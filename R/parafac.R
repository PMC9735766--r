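#' PARAFAC fit configuration
#'
#' @param tol relative change in SSE below which alternating least squares
#'   stops.
#' @param max_iter iteration cap per start.
#' @param n_starts number of random nonnegative initializations; the
#'   lowest-SSE solution is kept.
#' @param seed integer governing all initializations (start `s` uses
#'   `seed + s - 1`).
#' @param missing_strategy only `"em-impute"`: masked cells are replaced by
#'   the current model value at each iteration (expectation-maximization).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(tol = 1e-8, max_iter = 2000, n_starts = 10,
                       seed = 1, missing_strategy = "em-impute") {
  stopifnot(tol > 0, max_iter >= 1, n_starts >= 1,
            identical(missing_strategy, "em-impute"))
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 missing_strategy = missing_strategy),
            class = "fit_config")
}

# Fast NNLS (active set on the normal equations): minimize ||x - Z b||
# over b >= 0 given only G = Z'Z and d = Z'x. Deterministic.
fnnls <- function(G, d) {
  f <- length(d)
  P <- logical(f)
  b <- numeric(f)
  tol <- 10 * .Machine$double.eps * sum(abs(diag(G))) * f
  w <- d
  it <- 0L
  max_it <- 30L * f
  while (any(!P) && any(w[!P] > tol) && it < max_it) {
    it <- it + 1L
    cand <- which(!P)
    j <- cand[which.max(w[cand])]
    P[j] <- TRUE
    s <- numeric(f)
    s[P] <- solve_psd(G[P, P, drop = FALSE], d[P])
    inner <- 0L
    while (any(s[P] <= tol) && inner < max_it) {
      inner <- inner + 1L
      Q <- P & s <= tol
      alpha <- min(b[Q] / (b[Q] - s[Q]))
      b <- b + alpha * (s - b)
      P[P & b <= tol] <- FALSE
      s <- numeric(f)
      if (any(P)) s[P] <- solve_psd(G[P, P, drop = FALSE], d[P])
    }
    b <- s
    w <- d - G %*% b
  }
  pmax(b, 0)
}

# Solve a (possibly rank-deficient) symmetric positive-semidefinite
# system; a singular active set can arise when a component collapses.
solve_psd <- function(G, d) {
  tryCatch(solve(G, d), error = function(e) {
    z <- qr.coef(qr(G, tol = 1e-12), d)
    z[is.na(z)] <- 0
    z
  })
}

# Row-wise NNLS with a shared Gram matrix: rows whose unconstrained
# solution is already nonnegative are solved in one batched call; only the
# remainder goes through the active-set solver.
nnls_rows <- function(G, RHS) {
  sol <- tryCatch(t(solve(G, t(RHS))), error = function(e) NULL)
  if (is.null(sol)) {
    sol <- t(apply(RHS, 1, fnnls, G = G))
    return(sol)
  }
  neg <- which(apply(sol, 1, function(r) any(r < 0)))
  for (i in neg) sol[i, ] <- fnnls(G, RHS[i, ])
  sol
}

#' Fit a nonnegative PARAFAC model
#'
#' Decomposes the preprocessed sample x excitation x emission cube into
#' `F` trilinear components by alternating nonnegative least squares.
#' Each mode update solves its matricized subproblem exactly (active-set
#' NNLS on the normal equations); masked cells (excised or undefined) are
#' handled by expectation-maximization imputation, i.e. replaced by the
#' current model value before every iteration, so the observed-cell SSE is
#' non-increasing. Among `n_starts` initializations — the first a
#' deterministic nonnegative spectral start (absolute leading singular
#' vectors of each mode unfolding), the rest uniform(0,1) random draws —
#' the lowest-SSE solution is returned.
#'
#' Scale indeterminacy is resolved by rescaling every emission and
#' excitation loading column to unit maximum, absorbing magnitudes into
#' the score (sample) mode, so scores are modeled peak intensities
#' (F_max). Permutation indeterminacy is resolved by ordering components
#' by ascending emission-peak wavelength; repeated fits with the same seed
#' are identical.
#'
#' @param dataset an aligned (and normally scaled) [eem_dataset].
#' @param F number of components.
#' @param cfg a [fit_config].
#' @return An object of class `parafac_model` with elements `scores`
#'   (sample x F), `emission_loadings` (|em| x F, unit max),
#'   `excitation_loadings` (|ex| x F, unit max), `sse` (over observed
#'   cells), `explained_variance`, `n_iterations`, `converged`, `seed`,
#'   `component_order`, `sse_trace` (per-iteration SSE of the winning
#'   start), `start_sse` (final SSE of every start), and the axes.
#' @export
fit_parafac <- function(dataset, F, cfg = fit_config()) {
  stopifnot(inherits(dataset, "eem_dataset"), inherits(cfg, "fit_config"))
  cube <- as_cube(dataset)
  n <- dim(cube)[1]; K <- dim(cube)[2]; J <- dim(cube)[3]
  if (F < 1 || F > min(n, K, J))
    stop(sprintf("F = %d must be between 1 and min(samples, |ex|, |em|) = %d",
                 F, min(n, K, J)), call. = FALSE)
  mask <- attr(cube, "mask")
  obs <- mask == "valid"
  # mode-1 unfolding: n x (K*J), column index (j-1)*K + k
  Xa <- matrix(cube, n, K * J)
  Oa <- matrix(obs, n, K * J)
  Xa[!Oa] <- 0
  miss <- which(!Oa)
  # (i, k, j) coordinates of missing cells, for cheap model evaluation
  mi <- ((miss - 1L) %% n) + 1L
  rest <- (miss - 1L) %/% n
  mk <- (rest %% K) + 1L
  mj <- (rest %/% K) + 1L
  ss_obs <- sum(Xa[Oa]^2)

  # nonnegative spectral initialization: absolute leading singular vectors
  # of each mode unfolding (missing cells zero-filled); lands close to the
  # dominant trilinear structure and is deterministic
  svd_init <- function() {
    lead <- function(M) {
      s <- svd(M, nu = F, nv = 0)
      u <- abs(s$u)
      if (ncol(u) < F) u <- cbind(u, matrix(1 / nrow(u), nrow(u), F - ncol(u)))
      pmax(u, 1e-6)
    }
    Xc <- matrix(aperm(array(Xa, c(n, K, J)), c(2, 1, 3)), K, n * J)
    Xb <- matrix(aperm(array(Xa, c(n, K, J)), c(3, 1, 2)), J, n * K)
    list(A = lead(Xa), C = lead(Xc), B = lead(Xb))
  }

  run_start <- function(start_seed, use_svd = FALSE) {
    set.seed(start_seed)
    if (use_svd) {
      ini <- svd_init()
      A <- ini$A; C <- ini$C; B <- ini$B
    } else {
      A <- matrix(stats::runif(n * F), n, F)
      C <- matrix(stats::runif(K * F), K, F)
      B <- matrix(stats::runif(J * F), J, F)
    }
    X <- Xa
    sse_prev <- Inf
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    kr <- B[rep(seq_len(J), each = K), , drop = FALSE] *
      C[rep.int(seq_len(K), J), , drop = FALSE]
    for (iter in seq_len(cfg$max_iter)) {
      if (length(miss))
        X[miss] <- rowSums(A[mi, , drop = FALSE] * C[mk, , drop = FALSE] *
                             B[mj, , drop = FALSE])
      # mode A (samples)
      A <- nnls_rows(crossprod(B) * crossprod(C), X %*% kr)
      # shared cross-product for the two spectral modes
      Gm <- crossprod(X, A)                        # (K*J) x F
      GA <- crossprod(A)
      # mode B (emission)
      RHS_B <- vapply(seq_len(F), function(f)
        as.numeric(crossprod(matrix(Gm[, f], K, J), C[, f])), numeric(J))
      B <- nnls_rows(GA * crossprod(C), RHS_B)
      # mode C (excitation)
      RHS_C <- vapply(seq_len(F), function(f)
        as.numeric(matrix(Gm[, f], K, J) %*% B[, f]), numeric(K))
      C <- nnls_rows(GA * crossprod(B), RHS_C)
      kr <- B[rep(seq_len(J), each = K), , drop = FALSE] *
        C[rep.int(seq_len(K), J), , drop = FALSE]
      R <- X - tcrossprod(A, kr)
      if (length(miss)) R[miss] <- 0
      sse <- sum(R^2)
      trace <- c(trace, sse)
      if (is.finite(sse_prev) &&
          abs(sse_prev - sse) <= cfg$tol * max(sse_prev, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
      sse_prev <- sse
    }
    list(A = A, B = B, C = C, sse = sse, trace = trace,
         converged = converged, n_iterations = iter)
  }

  starts <- lapply(seq_len(cfg$n_starts), function(s)
    run_start(cfg$seed + s - 1L, use_svd = (s == 1L)))
  start_sse <- vapply(starts, `[[`, numeric(1), "sse")
  best <- starts[[which.min(start_sse)]]
  if (!best$converged)
    warning("no ALS start converged within max_iter = ", cfg$max_iter,
            "; returning the best (lowest-SSE) model")

  A <- best$A; B <- best$B; C <- best$C
  bmax <- apply(B, 2, max)
  cmax <- apply(C, 2, max)
  dead <- bmax <= 0 | cmax <= 0
  if (any(dead)) {
    warning(sum(dead), " component(s) collapsed to zero")
    bmax[dead] <- 1; cmax[dead] <- 1
    A[, dead] <- 0
  }
  A <- sweep(A, 2, bmax * cmax, `*`)
  B <- sweep(B, 2, bmax, `/`)
  C <- sweep(C, 2, cmax, `/`)
  em <- attr(cube, "em"); ex <- attr(cube, "ex")
  ord <- order(em[apply(B, 2, which.max)])
  structure(list(
    n_components = as.integer(F),
    scores = A[, ord, drop = FALSE],
    emission_loadings = B[, ord, drop = FALSE],
    excitation_loadings = C[, ord, drop = FALSE],
    ex = ex, em = em,
    sse = best$sse,
    explained_variance = max(0, min(1, 1 - best$sse / ss_obs)),
    n_iterations = best$n_iterations,
    converged = best$converged,
    seed = cfg$seed,
    component_order = ord,
    sse_trace = best$trace,
    start_sse = start_sse), class = "parafac_model")
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf(
    "<parafac_model> %d components, %d samples; expl. var. %.6f; %s in %d iterations\n",
    x$n_components, nrow(x$scores), x$explained_variance,
    if (x$converged) "converged" else "NOT converged", x$n_iterations))
  for (f in seq_len(x$n_components))
    cat(sprintf("  C%d: em peak %.4g nm, ex peak %.4g nm\n", f,
                x$em[which.max(x$emission_loadings[, f])],
                x$ex[which.max(x$excitation_loadings[, f])]))
  invisible(x)
}

#' Evaluate a PARAFAC model as a full cube
#'
#' @param model a `parafac_model`.
#' @return Array sample x excitation x emission of fitted values.
#' @export
reconstruct <- function(model) {
  stopifnot(inherits(model, "parafac_model"))
  n <- nrow(model$scores)
  K <- nrow(model$excitation_loadings)
  J <- nrow(model$emission_loadings)
  kr <- model$emission_loadings[rep(seq_len(J), each = K), , drop = FALSE] *
    model$excitation_loadings[rep.int(seq_len(K), J), , drop = FALSE]
  array(tcrossprod(model$scores, kr), c(n, K, J))
}

#' Core consistency diagnostic (CORCONDIA)
#'
#' Fits the least-squares Tucker core for the model's fixed loadings and
#' measures how close it is to the superidentity that an exactly trilinear
#' model implies: `100 * (1 - sum((G - T)^2) / F)`. 100 means perfectly
#' trilinear; values well below ~50 indicate over-factoring. Masked cells
#' are imputed from the model before computing the core.
#'
#' @param model a `parafac_model`.
#' @param dataset the [eem_dataset] the model was fitted to.
#' @return Percentage in `(-Inf, 100]`.
#' @export
corcondia <- function(model, dataset) {
  stopifnot(inherits(model, "parafac_model"), inherits(dataset, "eem_dataset"))
  cube <- as_cube(dataset)
  mask <- attr(cube, "mask")
  fit <- reconstruct(model)
  cube[mask != "valid"] <- fit[mask != "valid"]
  F <- model$n_components
  n <- dim(cube)[1]; K <- dim(cube)[2]; J <- dim(cube)[3]
  pinv <- function(M) {
    s <- svd(M)
    pos <- s$d > max(dim(M)) * .Machine$double.eps * max(s$d, 0)
    if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
    s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  }
  # G = X x_1 A^+ x_2 C^+ x_3 B^+
  g <- matrix(pinv(model$scores) %*% matrix(cube, n, K * J), F, K * J)
  arr <- array(g, c(F, K, J))
  arr <- aperm(arr, c(2, 1, 3))                        # K x F x J
  g <- pinv(model$excitation_loadings) %*% matrix(arr, K, F * J)
  arr <- array(g, c(F, F, J))
  arr <- aperm(arr, c(3, 1, 2))                        # J x F x F
  g <- pinv(model$emission_loadings) %*% matrix(arr, J, F * F)
  core <- aperm(array(g, c(F, F, F)), c(2, 3, 1))
  target <- array(0, c(F, F, F))
  for (f in seq_len(F)) target[f, f, f] <- 1
  100 * (1 - sum((core - target)^2) / F)
}

#' Serialize a PARAFAC model to a directory of text files
#'
#' Writes `scores.csv`, `emission_loadings.csv`, `excitation_loadings.csv`,
#' a `fit.yaml` report (SSE, explained variance, convergence, seed) and an
#' OpenFluor-style two-block loading table (`openfluor.txt`: excitation
#' block then emission block) for interchange with spectral databases.
#'
#' @param model a `parafac_model`.
#' @param dir output directory (created if needed).
#' @param sample_ids optional sample names for the score table.
#' @return `dir`, invisibly.
#' @export
write_parafac <- function(model, dir, sample_ids = NULL) {
  stopifnot(inherits(model, "parafac_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comp <- paste0("C", seq_len(model$n_components))
  sc <- data.frame(sample = sample_ids %||% seq_len(nrow(model$scores)),
                   model$scores)
  names(sc)[-1] <- comp
  utils::write.csv(sc, file.path(dir, "scores.csv"), row.names = FALSE)
  eml <- data.frame(emission_nm = model$em, model$emission_loadings)
  names(eml)[-1] <- comp
  utils::write.csv(eml, file.path(dir, "emission_loadings.csv"),
                   row.names = FALSE)
  exl <- data.frame(excitation_nm = model$ex, model$excitation_loadings)
  names(exl)[-1] <- comp
  utils::write.csv(exl, file.path(dir, "excitation_loadings.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(
    n_components = model$n_components,
    sse = model$sse,
    explained_variance = model$explained_variance,
    n_iterations = model$n_iterations,
    converged = model$converged,
    seed = model$seed,
    start_sse = model$start_sse), file.path(dir, "fit.yaml"))
  of <- c(
    vapply(seq_along(model$ex), function(k)
      paste(c("Ex", sprintf("%.2f", model$ex[k]),
              sprintf("%.6f", model$excitation_loadings[k, ])),
            collapse = "\t"), character(1)),
    vapply(seq_along(model$em), function(j)
      paste(c("Em", sprintf("%.2f", model$em[j]),
              sprintf("%.6f", model$emission_loadings[j, ])),
            collapse = "\t"), character(1)))
  writeLines(of, file.path(dir, "openfluor.txt"))
  invisible(dir)
}
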