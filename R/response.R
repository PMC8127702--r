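#' Predicted response to selection (multivariate breeder's equation)
#'
#' Applies \eqn{\Delta\bar z = G\beta} to every retained posterior draw of
#' G, giving a posterior distribution of per-trait responses. When `beta` is
#' itself a posterior ([estimate_beta_bayes()]), its draws are paired
#' one-to-one with the G draws (counts must match), propagating uncertainty
#' in both components. Responses are returned on the scale of the G draws;
#' when per-trait SDs are supplied (the standardization record of the
#' phenotype table), responses divided by those SDs are returned as well,
#' expressing the predicted change in global-SD units.
#'
#' @param G A `g_posterior`, a `p x p x n` array, or a single matrix.
#' @param beta Numeric vector of selection gradients, or a
#'   `selection_gradient` (posterior draws are used when present).
#' @param sds Optional named per-trait SDs for SD-unit responses; defaults to
#'   the standardization record of a `g_posterior`.
#' @param prob HPD mass.
#' @return Object of class `response_prediction`: `draws` (n x p matrix),
#'   `mean`, `hpd` (2 x p), and when SDs are available `draws_sd_units`,
#'   `mean_sd_units`, `hpd_sd_units`.
#' @export
predict_response <- function(G, beta, sds = NULL, prob = 0.95) {
  a <- as_g_array(G)
  p <- dim(a)[1L]
  n <- dim(a)[3L]
  if (is.null(sds) && inherits(G, "g_posterior") &&
      !identical(G$standardization, "none"))
    sds <- G$standardization
  bdraws <- NULL
  if (inherits(beta, "selection_gradient")) {
    if (!is.null(beta$draws)) bdraws <- beta$draws
    beta <- beta$beta
  }
  if (!is.null(bdraws)) {
    if (nrow(bdraws) != n)
      stop("paired posteriors: beta has ", nrow(bdraws),
           " draws but G has ", n)
    if (ncol(bdraws) != p) stop("beta dimension must equal n_traits (", p, ")")
  } else if (length(beta) != p) {
    stop("beta dimension (", length(beta), ") must equal n_traits (", p, ")")
  }
  draws <- matrix(NA_real_, n, p)
  for (d in seq_len(n)) {
    b <- if (is.null(bdraws)) beta else bdraws[d, ]
    draws[d, ] <- a[, , d] %*% b
  }
  tn <- dimnames(a)[[1L]]
  if (!is.null(tn)) colnames(draws) <- tn
  mean_dz <- colMeans(draws)
  hpd_dz <- if (n >= 2L) apply(draws, 2L, hpd, prob = prob) else
    rbind(lower = mean_dz, upper = mean_dz)
  out <- list(draws = draws, mean = mean_dz, hpd = hpd_dz, prob = prob,
              population = if (inherits(G, "g_posterior")) G$population else NULL)
  if (!is.null(sds)) {
    if (!is.null(tn) && !is.null(names(sds))) sds <- sds[tn]
    sdm <- matrix(rep(as.numeric(sds), each = n), n, p)
    out$draws_sd_units <- draws / sdm
    out$mean_sd_units <- colMeans(out$draws_sd_units)
    out$hpd_sd_units <- if (n >= 2L)
      apply(out$draws_sd_units, 2L, hpd, prob = prob) else
        rbind(lower = out$mean_sd_units, upper = out$mean_sd_units)
  }
  structure(out, class = "response_prediction")
}

#' R metric: effect of genetic covariances on the rate of adaptation
#'
#' The rate of adaptation under directional selection is the change in mean
#' fitness \eqn{\beta^T G \beta}. The R metric compares this rate under the
#' observed G with the rate under a constraint-free G0 -- the same matrix
#' with every off-diagonal set to zero:
#' \deqn{R = \frac{\beta^T G \beta}{\beta^T G_0 \beta}.}
#' R > 1 means covariances accelerate adaptation, R < 1 that they slow it,
#' and R = 1 (any diagonal G) is the no-effect point. R is invariant to
#' positive rescaling of either `beta` or G. Computed per posterior draw;
#' draws with a non-positive denominator are flagged and excluded with a
#' count. Summaries report the mean and the 5th/95th percentiles.
#'
#' @param G As in [predict_response()].
#' @param beta Selection gradient (vector or `selection_gradient`; posterior
#'   draws are paired with G draws).
#' @return Object of class `r_metric_result`: `draws`, `mean`, `q05`, `q95`,
#'   `n_excluded`.
#' @export
r_metric <- function(G, beta) {
  a <- as_g_array(G)
  p <- dim(a)[1L]
  n <- dim(a)[3L]
  bdraws <- NULL
  if (inherits(beta, "selection_gradient")) {
    if (!is.null(beta$draws)) bdraws <- beta$draws
    beta <- beta$beta
  }
  if (!is.null(bdraws) && nrow(bdraws) != n)
    stop("paired posteriors: beta has ", nrow(bdraws), " draws but G has ", n)
  if (is.null(bdraws) && length(beta) != p)
    stop("beta dimension (", length(beta), ") must equal n_traits (", p, ")")
  vals <- numeric(n)
  ok <- logical(n)
  for (d in seq_len(n)) {
    b <- if (is.null(bdraws)) beta else bdraws[d, ]
    Gd <- a[, , d]
    num <- drop(t(b) %*% Gd %*% b)
    den <- sum(b^2 * diag(Gd))
    if (is.finite(den) && den > 0) {
      vals[d] <- num / den
      ok[d] <- TRUE
    }
  }
  if (!any(ok)) stop("denominator beta' G0 beta non-positive for every draw")
  vals <- vals[ok]
  structure(list(draws = vals, mean = mean(vals),
                 q05 = unname(quantile(vals, 0.05)),
                 q95 = unname(quantile(vals, 0.95)),
                 n_excluded = sum(!ok),
                 population = if (inherits(G, "g_posterior")) G$population else NULL),
            class = "r_metric_result")
}

#' @export
print.r_metric_result <- function(x, ...) {
  cat("R metric", if (!is.null(x$population)) paste0("(", x$population, ")"),
      ": mean", round(x$mean, 4), "[5th", round(x$q05, 4), ", 95th",
      round(x$q95, 4), "]", x$n_excluded, "draws excluded\n")
  invisible(x)
}

#' Random-skewers comparison of G matrices
#'
#' Applies a large universe of random selection vectors ("skewers", drawn
#' uniformly on the unit sphere by normalizing standard-normal vectors) to
#' every population's G matrix and compares populations by the similarity of
#' their response vectors: for each population pair, the mean vector
#' correlation and the mean angle (degrees) between `G1 s` and `G2 s` over
#' skewers.
#'
#' @param G_by_pop Named list per population (as in
#'   [krzanowski_subspace()]). By default the posterior-mean G of each
#'   population is skewed; `summary = "draws"` instead computes the
#'   per-draw mean correlation (draws paired across populations), yielding a
#'   posterior distribution per pair with an HPD interval.
#' @param n_skewers Number of skewers (default 1000).
#' @param seed Integer seed for the skewer draws.
#' @param summary `"mean"` or `"draws"` (see above).
#' @param prob HPD mass for `summary = "draws"`.
#' @return Object of class `skewer_result`: `pairs` data frame with
#'   `pop1`, `pop2`, `correlation`, `angle_deg` (and `hpd_low`/`hpd_high`
#'   for draws mode), `n_skewers`, and for draws mode `draws` (matrix,
#'   one column per pair).
#' @export
random_skewers <- function(G_by_pop, n_skewers = 1000, seed = 1L,
                           summary = c("mean", "draws"), prob = 0.95) {
  summary <- match.arg(summary)
  if (n_skewers < 1) stop("n_skewers must be >= 1")
  arrs <- lapply(G_by_pop, as_g_array)
  ntr <- dim(arrs[[1L]])[1L]
  for (a in arrs) if (dim(a)[1L] != ntr)
    stop("G matrices must share trait dimension")
  npop <- length(arrs)
  pops <- names(G_by_pop)
  if (is.null(pops)) pops <- paste0("pop", seq_len(npop))
  set.seed(as.integer(seed))
  Z <- matrix(rnorm(n_skewers * ntr), n_skewers, ntr)
  Skw <- Z / sqrt(rowSums(Z^2))

  vec_corr <- function(R1, R2) {
    num <- rowSums(R1 * R2)
    den <- sqrt(rowSums(R1^2) * rowSums(R2^2))
    num / pmax(den, 1e-300)
  }
  pair_idx <- which(upper.tri(diag(npop)), arr.ind = TRUE)
  pair_idx <- pair_idx[order(pair_idx[, 1L], pair_idx[, 2L]), , drop = FALSE]

  if (summary == "mean") {
    Gm <- lapply(arrs, function(a) apply(a, c(1L, 2L), mean))
    resp <- lapply(Gm, function(G) Skw %*% G)
    rows <- apply(pair_idx, 1L, function(ij) {
      cc <- vec_corr(resp[[ij[1L]]], resp[[ij[2L]]])
      ang <- acos(pmin(1, pmax(-1, cc))) * 180 / pi
      c(mean(cc), mean(ang))
    })
    pairs <- data.frame(pop1 = pops[pair_idx[, 1L]],
                        pop2 = pops[pair_idx[, 2L]],
                        correlation = rows[1L, ], angle_deg = rows[2L, ])
    return(structure(list(pairs = pairs, n_skewers = n_skewers),
                     class = "skewer_result"))
  }

  ndraw <- min(vapply(arrs, function(a) dim(a)[3L], 0L))
  draws <- matrix(NA_real_, ndraw, nrow(pair_idx))
  ang_mean <- numeric(nrow(pair_idx))
  for (d in seq_len(ndraw)) {
    resp <- lapply(arrs, function(a) Skw %*% a[, , d])
    for (q in seq_len(nrow(pair_idx))) {
      cc <- vec_corr(resp[[pair_idx[q, 1L]]], resp[[pair_idx[q, 2L]]])
      draws[d, q] <- mean(cc)
      ang_mean[q] <- ang_mean[q] +
        mean(acos(pmin(1, pmax(-1, cc))) * 180 / pi) / ndraw
    }
  }
  hpds <- apply(draws, 2L, hpd, prob = prob)
  pairs <- data.frame(pop1 = pops[pair_idx[, 1L]], pop2 = pops[pair_idx[, 2L]],
                      correlation = colMeans(draws), angle_deg = ang_mean,
                      hpd_low = hpds[1L, ], hpd_high = hpds[2L, ])
  structure(list(pairs = pairs, n_skewers = n_skewers, draws = draws),
            class = "skewer_result")
}

#' @export
print.skewer_result <- function(x, ...) {
  cat("Random skewers (", x$n_skewers, " skewers):\n", sep = "")
  print(x$pairs, digits = 4)
  invisible(x)
}
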