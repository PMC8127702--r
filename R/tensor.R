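#' Fourth-order genetic covariance tensor among populations
#'
#' The tensor \eqn{\Sigma_{ijkl} = cov(G_{ij}, G_{kl})} captures how a set
#' of G matrices (co)vary around their mean. Each G matrix is vectorized
#' over its `m = p(p+1)/2` unique elements with off-diagonal entries
#' weighted by \eqn{\sqrt 2} (preserving the Frobenius norm), and the tensor
#' is represented as the `m x m` matrix S: the covariance matrix, across
#' populations, of these vectors. Eigenvectors of S fold back (undoing the
#' weighting) into symmetric *eigentensors* `E_i`; the share of among-
#' population variance captured by eigentensor i is
#' \eqn{\alpha_i = \lambda_i / \sum \lambda}. The eigenvectors of each
#' eigentensor are the trait combinations driving that axis of divergence,
#' with within-eigentensor variance shares proportional to the squared
#' eigenvalues. The coordinate of population t on eigentensor i is the
#' Frobenius inner product \eqn{\langle G_t - \bar G, E_i\rangle} (centered,
#' so coordinates sum to zero across populations).
#'
#' With posterior draws, S is computed per draw (draws paired across
#' populations) and summarized on the fixed basis of the posterior-mean S's
#' eigentensors (avoiding label switching across draws): per-draw
#' eigenvalues are the quadratic forms \eqn{u_i^T S_d u_i}. Null
#' significance follows the randomization logic: an eigentensor is flagged
#' when its observed mean `alpha` exceeds the upper 95% HPD bound of the
#' null `alpha` of the same rank.
#'
#' @param G_by_pop Named list per population of G draws (as in
#'   [krzanowski_subspace()]).
#' @param null_G Optional list over null datasets of `G_by_pop`-style lists;
#'   each dataset is pushed through the identical per-draw procedure (its own
#'   posterior-mean basis) and contributes its posterior-mean `alpha` vector,
#'   so observed and null statistics are exactly comparable.
#' @param prob HPD mass.
#' @return Object of class `tensor_result`: `S_mean`, `eigentensors`
#'   (`p x p x m` array), `alpha` (draws x m matrix), `alpha_mean`,
#'   `alpha_hpd`, `eigenvalues` (draws x m), `coordinates` (populations x m),
#'   `tensor_eigen` (per-eigentensor trait-combination eigenanalysis),
#'   `null_alpha`, `null_alpha_hpd`, `significant`, `no_variation` flag.
#' @export
covariance_tensor <- function(G_by_pop, null_G = NULL, prob = 0.95) {
  if (length(G_by_pop) < 2L)
    stop("need at least 2 populations to decompose among-population variance")
  arrs <- lapply(G_by_pop, as_g_array)
  ntr <- dim(arrs[[1L]])[1L]
  for (a in arrs) if (dim(a)[1L] != ntr)
    stop("G matrices must share trait dimension")
  ndraw <- min(vapply(arrs, function(a) dim(a)[3L], 0L))
  npop <- length(arrs)
  m <- ntr * (ntr + 1L) / 2L

  core <- tensor_core(arrs, ntr, ndraw)
  S_mean <- core$S_mean
  no_variation <- core$no_variation
  U <- core$U
  eigentensors <- array(0, c(ntr, ntr, m),
                        dimnames = list(dimnames(arrs[[1L]])[[1L]],
                                        dimnames(arrs[[1L]])[[2L]], NULL))
  for (i in seq_len(m)) eigentensors[, , i] <- core$unvech(U[, i])
  eig_draws <- core$eig_draws
  alpha <- core$alpha
  alpha_mean <- colMeans(alpha)
  alpha_hpd <- if (ndraw >= 2L) apply(alpha, 2L, hpd, prob = prob) else
    rbind(lower = alpha_mean, upper = alpha_mean)

  # population coordinates on each eigentensor (posterior mean G, centered)
  Gmeans <- lapply(arrs, function(a) apply(a[, , seq_len(ndraw), drop = FALSE],
                                           c(1L, 2L), mean))
  Gbar <- Reduce(`+`, Gmeans) / npop
  coords <- matrix(NA_real_, npop, m,
                   dimnames = list(names(G_by_pop), NULL))
  for (t in seq_len(npop)) for (i in seq_len(m))
    coords[t, i] <- sum((Gmeans[[t]] - Gbar) * eigentensors[, , i])

  # trait combinations within each eigentensor
  tensor_eigen <- lapply(seq_len(m), function(i) {
    ee <- eigen(eigentensors[, , i], symmetric = TRUE)
    ord <- order(abs(ee$values), decreasing = TRUE)
    vals <- ee$values[ord]
    vecs <- fix_sign(ee$vectors[, ord, drop = FALSE])
    share <- if (sum(vals^2) > 0) vals^2 / sum(vals^2) else rep(0, ntr)
    list(values = vals, vectors = vecs, variance_share = share)
  })

  null_alpha <- null_alpha_hpd <- NULL
  significant <- rep(NA, m)
  if (!is.null(null_G)) {
    null_alpha <- t(vapply(null_G, function(nd) {
      na <- lapply(nd, as_g_array)
      nd_draw <- min(vapply(na, function(a) dim(a)[3L], 0L))
      colMeans(tensor_core(na, ntr, nd_draw)$alpha)
    }, numeric(m)))
    null_alpha_hpd <- apply(null_alpha, 2L, hpd, prob = prob)
    # significant only when the observed posterior separates from the null
    # band: its lower HPD bound exceeds the null's upper bound
    significant <- alpha_hpd[1L, ] > null_alpha_hpd[2L, ]
  }

  structure(list(S_mean = S_mean, eigentensors = eigentensors,
                 alpha = alpha, alpha_mean = alpha_mean,
                 alpha_hpd = alpha_hpd, eigenvalues = eig_draws,
                 coordinates = coords, tensor_eigen = tensor_eigen,
                 null_alpha = null_alpha, null_alpha_hpd = null_alpha_hpd,
                 significant = significant, no_variation = no_variation,
                 n_populations = npop, n_traits = ntr, prob = prob),
            class = "tensor_result")
}

# internal: per-draw S matrices, fixed-basis eigenvalue/alpha draws for a
# list of G-draw arrays (the single procedure applied to observed and null
# data alike)
tensor_core <- function(arrs, ntr, ndraw) {
  npop <- length(arrs)
  m <- ntr * (ntr + 1L) / 2L
  lower <- which(lower.tri(diag(ntr), diag = TRUE), arr.ind = TRUE)
  w <- ifelse(lower[, 1L] == lower[, 2L], 1, sqrt(2))
  vech <- function(M) M[lower] * w
  unvech <- function(v) {
    M <- matrix(0, ntr, ntr)
    M[lower] <- v / w
    M[upper.tri(M)] <- t(M)[upper.tri(M)]
    M
  }
  S_draws <- array(NA_real_, c(m, m, ndraw))
  Vmat <- matrix(NA_real_, npop, m)
  for (d in seq_len(ndraw)) {
    for (t in seq_len(npop)) Vmat[t, ] <- vech(arrs[[t]][, , d])
    S_draws[, , d] <- cov(Vmat)
  }
  S_mean <- apply(S_draws, c(1L, 2L), mean)
  no_variation <- sum(diag(S_mean)) < 1e-12
  U <- fix_sign(eigen(S_mean, symmetric = TRUE)$vectors)
  eig_draws <- matrix(NA_real_, ndraw, m)
  for (d in seq_len(ndraw))
    eig_draws[d, ] <- colSums(U * (S_draws[, , d] %*% U))
  tot <- rowSums(eig_draws)
  alpha <- eig_draws / ifelse(abs(tot) < 1e-300, 1, tot)
  alpha[abs(tot) < 1e-300, ] <- 0
  if (no_variation) alpha[] <- 0
  list(S_draws = S_draws, S_mean = S_mean, no_variation = no_variation,
       U = U, eig_draws = eig_draws, alpha = alpha,
       vech = vech, unvech = unvech)
}

#' @export
print.tensor_result <- function(x, ...) {
  cat("Genetic covariance tensor:", x$n_populations, "populations,",
      x$n_traits, "traits\n")
  if (x$no_variation) {
    cat("no variation among G matrices (S = 0)\n")
  } else {
    cat("variance shares (alpha) of leading eigentensors:\n")
    print(round(utils::head(x$alpha_mean, 4), 4))
    if (!all(is.na(x$significant)))
      cat("eigentensors above null HPD:",
          paste(which(x$significant), collapse = ", "), "\n")
  }
  invisible(x)
}
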