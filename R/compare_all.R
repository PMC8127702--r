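#' Run the full suite of G-matrix comparison statistics
#'
#' Convenience wrapper applying all five comparison methods to a set of
#' per-population G posteriors: Krzanowski common subspace, covariance
#' tensor, breeder's-equation responses, R metric and random skewers.
#' Returns the individual results plus a per-method divergence call:
#'
#' * `krzanowski`: any H eigenvalue below the population count *and* below
#'   the null HPD (requires `null_G`; `NA` otherwise);
#' * `tensor`: any eigentensor's variance share above the null HPD
#'   (requires `null_G`);
#' * `response`: any trait with non-overlapping response HPDs for some
#'   population pair;
#' * `r_metric`: non-overlapping R HPDs (5th--95th percentile band) for some
#'   population pair;
#' * `skewers`: some pair's posterior of mean vector correlations entirely
#'   below the null HPD of the same statistic (requires `null_G`).
#'
#' @param G_by_pop Named list per population of G posteriors/arrays.
#' @param beta Selection gradient for responses and R (vector or
#'   `selection_gradient`). Its dimension selects the leading traits of G
#'   (fitness-proxy traits are excluded from response predictions by
#'   passing a 4-trait beta against 6-trait G: the G sub-block of those
#'   traits is used).
#' @param sds Optional per-trait SDs: when given, the G draws (assumed to be
#'   on the standardized scale of those SDs) are back-transformed to trait
#'   units before the breeder's-equation and R-metric computations, so beta
#'   (per trait unit) and G share a scale; responses are reported in trait
#'   units and SD units.
#' @param null_G Optional list over null datasets of `G_by_pop`-style lists.
#' @param k Krzanowski retention; default half the traits.
#' @param n_skewers,seed Skewer settings.
#' @param prob HPD mass.
#' @return List with elements `krzanowski`, `tensor`, `response` (per
#'   population), `r_metric` (per population), `skewers`, and
#'   `divergence_calls` (named logical vector).
#' @export
compare_populations <- function(G_by_pop, beta, sds = NULL, null_G = NULL,
                                k = NULL, n_skewers = 1000, seed = 1L,
                                prob = 0.95) {
  arrs <- lapply(G_by_pop, as_g_array)
  ntr <- dim(arrs[[1L]])[1L]
  bvec <- if (inherits(beta, "selection_gradient")) beta$beta else beta
  nb <- length(bvec)
  if (nb > ntr) stop("beta has more elements than G has traits")
  sub_idx <- seq_len(nb)
  sub_arrs <- lapply(arrs, function(a) a[sub_idx, sub_idx, , drop = FALSE])
  if (!is.null(sds)) {
    # geometry statistics stay on the standardized scale; selection-facing
    # statistics need trait units to match beta
    sm <- outer(sds[sub_idx], sds[sub_idx])
    sub_arrs <- lapply(sub_arrs, function(a) {
      for (d in seq_len(dim(a)[3L])) a[, , d] <- a[, , d] * sm
      a
    })
  }

  krz <- krzanowski_subspace(G_by_pop, k = k, null_G = null_G, prob = prob)
  tens <- covariance_tensor(G_by_pop, null_G = null_G, prob = prob)
  resp <- lapply(sub_arrs, function(a)
    predict_response(a, beta, sds = if (!is.null(sds)) sds[sub_idx] else NULL,
                     prob = prob))
  rmet <- lapply(sub_arrs, function(a) r_metric(a, beta))
  skw <- random_skewers(G_by_pop, n_skewers = n_skewers, seed = seed,
                        summary = "draws", prob = prob)

  npop <- length(G_by_pop)
  pair_idx <- which(upper.tri(diag(npop)), arr.ind = TRUE)

  # response divergence: any trait whose HPDs fail to overlap for some pair
  resp_div <- FALSE
  for (q in seq_len(nrow(pair_idx))) {
    h1 <- resp[[pair_idx[q, 1L]]]$hpd
    h2 <- resp[[pair_idx[q, 2L]]]$hpd
    sep <- h1[1L, ] > h2[2L, ] | h2[1L, ] > h1[2L, ]
    if (any(sep)) resp_div <- TRUE
  }
  # R metric divergence: non-overlapping 5th-95th percentile bands
  r_div <- FALSE
  for (q in seq_len(nrow(pair_idx))) {
    r1 <- rmet[[pair_idx[q, 1L]]]
    r2 <- rmet[[pair_idx[q, 2L]]]
    if (r1$q05 > r2$q95 || r2$q05 > r1$q95) r_div <- TRUE
  }
  krz_div <- if (all(is.na(krz$diverged))) NA else any(krz$diverged)
  tens_div <- if (all(is.na(tens$significant))) NA else any(tens$significant)

  skw_div <- NA
  if (!is.null(null_G)) {
    # identical per-draw procedure on every null dataset, summarized by its
    # posterior-mean pairwise correlations
    null_corr <- t(vapply(null_G, function(nd) {
      colMeans(random_skewers(lapply(nd, as_g_array), n_skewers = n_skewers,
                              seed = seed, summary = "draws")$draws)
    }, numeric(nrow(pair_idx))))
    if (nrow(pair_idx) == 1L) null_corr <- t(null_corr)
    skw_div <- FALSE
    for (q in seq_len(nrow(pair_idx))) {
      nh <- hpd(null_corr[, q], prob)
      if (skw$pairs$hpd_high[q] < nh[1L]) skw_div <- TRUE
    }
  }

  list(krzanowski = krz, tensor = tens, response = resp, r_metric = rmet,
       skewers = skw,
       divergence_calls = c(krzanowski = krz_div, tensor = tens_div,
                            response = resp_div, r_metric = r_div,
                            skewers = skw_div))
}
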