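#' Tucker congruence coefficient
#'
#' Normalized inner product `sum(u*v) / sqrt(sum(u^2) * sum(v^2))` of two
#' loading vectors; 1 means identical shape, 0 orthogonal. For nonnegative
#' loadings the value lies in `[0, 1]`. Symmetric and invariant to positive
#' rescaling of either argument.
#'
#' @param u,v numeric vectors of equal length, not both all-zero.
#' @return The congruence coefficient.
#' @export
tucker_congruence <- function(u, v) {
  if (length(u) != length(v))
    stop("loading vectors must have equal length", call. = FALSE)
  su <- sum(u^2); sv <- sum(v^2)
  if (su == 0 || sv == 0)
    stop("undefined congruence: zero loading vector", call. = FALSE)
  sum(u * v) / sqrt(su * sv)
}

# Greedy matching of components across two models by the product of
# excitation and emission congruences; ties broken by emission-peak
# proximity. A component that collapsed to a zero loading (possible in
# over-factored fits) gets congruence 0 with everything, which correctly
# invalidates the rank.
match_components <- function(m1, m2) {
  F <- m1$n_components
  safe_tc <- function(u, v)
    if (sum(u^2) == 0 || sum(v^2) == 0) 0 else tucker_congruence(u, v)
  cex <- matrix(0, F, F)
  cem <- matrix(0, F, F)
  for (a in seq_len(F)) for (b in seq_len(F)) {
    cex[a, b] <- safe_tc(m1$excitation_loadings[, a],
                         m2$excitation_loadings[, b])
    cem[a, b] <- safe_tc(m1$emission_loadings[, a],
                         m2$emission_loadings[, b])
  }
  score <- cex * cem
  peaks1 <- m1$em[apply(m1$emission_loadings, 2, which.max)]
  peaks2 <- m2$em[apply(m2$emission_loadings, 2, which.max)]
  pairs <- matrix(NA_integer_, F, 2)
  avail_a <- rep(TRUE, F); avail_b <- rep(TRUE, F)
  for (step in seq_len(F)) {
    sub <- score
    sub[!avail_a, ] <- -Inf
    sub[, !avail_b] <- -Inf
    best <- max(sub)
    cand <- which(sub >= best - 1e-12, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      dpk <- abs(peaks1[cand[, 1]] - peaks2[cand[, 2]])
      cand <- cand[which.min(dpk), , drop = FALSE]
    }
    a <- cand[1, 1]; b <- cand[1, 2]
    pairs[step, ] <- c(a, b)
    avail_a[a] <- FALSE; avail_b[b] <- FALSE
  }
  list(pairs = pairs,
       congruence_ex = cex[pairs],
       congruence_em = cem[pairs])
}

#' Split-half validation of a PARAFAC model
#'
#' Randomly partitions the samples into two halves `n_splits` times, fits
#' an `F`-component model to each half, matches components across halves
#' greedily by the product of excitation and emission Tucker congruences,
#' and records both congruences per split and component. The candidate
#' rank is `validated` when the minimum congruence over all splits,
#' components and both spectral modes reaches `threshold`: stable
#' components re-emerge from independent halves, over-factored models do
#' not.
#'
#' @param dataset an [eem_dataset].
#' @param F candidate number of components.
#' @param n_splits number of random half-partitions.
#' @param cfg a [fit_config] used for every half-fit.
#' @param seed integer seed generating the partitions (and, offset per
#'   split and half, the fit initializations).
#' @param threshold minimum acceptable congruence.
#' @return An object of class `split_half_result` with `assignments` (list
#'   of index vectors for the first half of each split), a long-format
#'   `congruence` data frame, `min_congruence`, `threshold`, `validated`.
#' @export
split_half <- function(dataset, F, n_splits = 32, cfg = fit_config(),
                       seed = 1, threshold = 0.95) {
  stopifnot(inherits(dataset, "eem_dataset"))
  n <- length(dataset$samples)
  if (n < 2)
    stop("split-half validation needs at least 2 samples", call. = FALSE)
  if (floor(n / 2) < F)
    stop(sprintf(
      "cannot fit F = %d components to halves of %d samples", F, n),
      call. = FALSE)
  if (n < 2 * F)
    warning("fewer than 2F samples; split-half result is unreliable")
  set.seed(seed)
  assignments <- lapply(seq_len(n_splits), function(s)
    sort(sample(n, ceiling(n / 2))))
  rows <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    h1 <- assignments[[s]]
    h2 <- setdiff(seq_len(n), h1)
    subset_ds <- function(idx) eem_dataset(dataset$samples[idx],
                                           dataset$scale_factors[idx])
    cfg1 <- cfg; cfg1$seed <- cfg$seed + 1000L * s
    cfg2 <- cfg; cfg2$seed <- cfg$seed + 1000L * s + 500L
    m1 <- suppressWarnings(fit_parafac(subset_ds(h1), F, cfg1))
    m2 <- suppressWarnings(fit_parafac(subset_ds(h2), F, cfg2))
    m <- match_components(m1, m2)
    rows[[s]] <- data.frame(
      split = s, component = seq_len(F),
      half1 = m$pairs[, 1], half2 = m$pairs[, 2],
      congruence_ex = m$congruence_ex, congruence_em = m$congruence_em)
  }
  congruence <- do.call(rbind, rows)
  min_c <- min(congruence$congruence_ex, congruence$congruence_em)
  structure(list(
    n_splits = as.integer(n_splits),
    F = as.integer(F),
    assignments = assignments,
    congruence = congruence,
    min_congruence = min_c,
    threshold = threshold,
    validated = min_c >= threshold,
    seed = as.integer(seed)), class = "split_half_result")
}

#' @export
print.split_half_result <- function(x, ...) {
  cat(sprintf(
    "<split_half_result> F = %d, %d splits: min congruence %.4f (threshold %.2f) -> %s\n",
    x$F, x$n_splits, x$min_congruence, x$threshold,
    if (x$validated) "VALIDATED" else "not validated"))
  invisible(x)
}
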