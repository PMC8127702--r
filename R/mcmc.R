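#' MCMC configuration for the half-sib Gibbs samplers
#'
#' Iteration accounting separates the burn-in from the post-burn-in sampling
#' phase: `post_burn_iterations / thin` draws are retained. The defaults are
#' the full production schedule for multivariate G estimation (500,000
#' burn-in, 5,000,000 post-burn iterations thinned by 500, i.e. 10,000
#' retained draws); univariate fits default to a 200,000-iteration burn-in
#' (see [fit_univariate()]). Test- and null-fit schedules should be scaled
#' down via these fields, not by thinning tricks.
#'
#' @param burn_in Burn-in iterations (discarded).
#' @param post_burn_iterations Post-burn-in iterations.
#' @param thin Thinning interval; must divide `post_burn_iterations`.
#' @param prior_scale_mode Prior expectation for the sire and dam covariance
#'   matrices: `"quarter_P"` (P/4, the default), `"half_P"` (P/2) or
#'   `"diagonal"` (diag(P)/4). The residual prior expectation is P/2
#'   (`"diagonal"`: diag(P)/2). P is the observed phenotypic covariance of
#'   the data being fitted.
#' @param prior_df_offset Degree-of-belief offset: the inverse-Wishart degree
#'   of belief is `nu = n_traits - prior_df_offset` (default 0.998, giving a
#'   minimally informative proper prior).
#' @param seed Integer seed for the sampler.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(burn_in = 500000, post_burn_iterations = 5000000,
                        thin = 500,
                        prior_scale_mode = c("quarter_P", "diagonal", "half_P"),
                        prior_df_offset = 0.998, seed = 1L) {
  prior_scale_mode <- match.arg(prior_scale_mode)
  stopifnot(burn_in >= 0, post_burn_iterations >= 1, thin >= 1)
  if (post_burn_iterations %% thin != 0)
    stop("'thin' (", thin, ") must divide 'post_burn_iterations' (",
         post_burn_iterations, ")")
  structure(list(burn_in = as.integer(burn_in),
                 post_burn_iterations = as.integer(post_burn_iterations),
                 thin = as.integer(thin),
                 prior_scale_mode = prior_scale_mode,
                 prior_df_offset = prior_df_offset,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' @export
print.mcmc_config <- function(x, ...) {
  cat("MCMC config: burn-in", x$burn_in, "| post-burn", x$post_burn_iterations,
      "| thin", x$thin, "->", x$post_burn_iterations %/% x$thin,
      "retained draws | prior", x$prior_scale_mode,
      "| nu = n_traits -", x$prior_df_offset, "\n")
  invisible(x)
}

# internal: prior expectation matrices for (sire, dam, residual) from the
# observed phenotypic covariance P
prior_scales <- function(P, mode) {
  switch(mode,
         quarter_P = list(S = P / 4, D = P / 4, E = P / 2),
         half_P = list(S = P / 2, D = P / 2, E = P / 2),
         diagonal = list(S = diag(diag(P), nrow(P)) / 4,
                         D = diag(diag(P), nrow(P)) / 4,
                         E = diag(diag(P), nrow(P)) / 2))
}

# internal: subset one population, build factors/design matrix, run sampler
run_gibbs <- function(sub, traits, config, na_action) {
  Y <- as.matrix(sub[, traits, drop = FALSE])
  storage.mode(Y) <- "double"
  miss <- is.na(Y)
  if (na_action == "complete") {
    keep <- !apply(miss, 1L, any)
    sub <- sub[keep, , drop = FALSE]
    Y <- Y[keep, , drop = FALSE]
    miss <- miss[keep, , drop = FALSE]
  } else {
    keep <- apply(!miss, 1L, any)  # rows with no data at all carry no signal
    sub <- sub[keep, , drop = FALSE]
    Y <- Y[keep, , drop = FALSE]
    miss <- miss[keep, , drop = FALSE]
    Y[miss] <- 0  # placeholder; imputed inside the sampler
  }
  p <- length(traits)
  n <- nrow(Y)
  sire_f <- factor(sub$sire)
  dam_f <- factor(paste(sub$sire, sub$dam, sep = "\r"))
  if (nlevels(sire_f) < 2L)
    stop("degenerate grouping: need at least 2 sires with data, got ",
         nlevels(sire_f))
  block_f <- factor(sub$block)
  X <- if (nlevels(block_f) > 1L)
    model.matrix(~block_f) else matrix(1, n, 1L)
  if (n < p + ncol(X))
    stop("too few usable rows (", n, ") for ", p, " traits and ",
         ncol(X), " fixed-effect columns")
  Ycc <- Y
  Ycc[miss] <- NA
  P <- cov(Ycc, use = "pairwise.complete.obs")
  P[!is.finite(P)] <- 0
  # guard against degenerate pairwise estimates
  P <- P + diag(1e-10 * max(diag(P), 1), p)
  pri <- prior_scales(P, config$prior_scale_mode)
  nu <- p - config$prior_df_offset
  set.seed(config$seed)
  fit <- gibbs_halfsib_cpp(Y, X, as.integer(sire_f) - 1L, as.integer(dam_f) - 1L,
                           miss * 1L, na_action == "impute",
                           pri$S, nu, pri$D, nu, pri$E, nu,
                           config$burn_in, config$post_burn_iterations,
                           config$thin)
  dimnames(fit$S) <- dimnames(fit$D) <- dimnames(fit$E) <-
    list(traits, traits, NULL)
  fit$n_obs <- n
  fit$n_sires <- nlevels(sire_f)
  fit$n_dams <- nlevels(dam_f)
  fit
}

#' Fit the univariate sire/dam variance-component model
#'
#' Gibbs sampler for the nested half-sib mixed model of a single trait:
#' block as fixed effect, random sire and dam-within-sire effects, conjugate
#' scaled-inverse-chi-squared updates for the three variances. Additive
#' genetic variance is `V_A = 4 V_S` (paternal half-sib covariance), and
#' narrow-sense heritability `h2 = V_A / (V_S + V_D + V_E)`.
#'
#' @param table Phenotype table.
#' @param trait Trait column name.
#' @param population Population label to fit (one population at a time).
#' @param config An [mcmc_config()]; default is the production univariate
#'   schedule (200,000 burn-in, 5,000,000 post-burn iterations, thin 500).
#' @return Object of class `vc_posterior`: a data frame of retained draws
#'   with columns `V_S`, `V_D`, `V_E`, `V_A`, `V_P`, `h2`, plus attributes
#'   `trait`, `population`, `config`.
#' @export
fit_univariate <- function(table, trait, population,
                           config = mcmc_config(burn_in = 200000)) {
  check_phenotype_table(table)
  stopifnot(inherits(config, "mcmc_config"))
  if (!trait %in% names(table)) stop("unknown trait '", trait, "'")
  sub <- table[table$population == population, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for population '", population, "'")
  sub <- sub[!is.na(sub[[trait]]), , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("trait '", trait, "' is entirely missing in population '",
         population, "'")
  fit <- run_gibbs(sub, trait, config, na_action = "complete")
  draws <- data.frame(V_S = fit$S[1, 1, ], V_D = fit$D[1, 1, ],
                      V_E = fit$E[1, 1, ])
  draws$V_A <- 4 * draws$V_S
  draws$V_P <- draws$V_S + draws$V_D + draws$V_E
  draws$h2 <- draws$V_A / draws$V_P
  structure(draws, class = c("vc_posterior", "data.frame"),
            trait = trait, population = population, config = config,
            n_obs = fit$n_obs, n_sires = fit$n_sires, n_dams = fit$n_dams)
}

#' Fit the multivariate G-matrix model for one population
#'
#' Gibbs sampler for the nested half-sib model of several traits jointly:
#' \deqn{y_{ijkl} = \mu + B_i + S_j + D_{k(j)} + e_{l(ijk)},}
#' with fixed intercept and block, multivariate-normal sire and
#' dam-within-sire effects, and conjugate inverse-Wishart updates for the
#' sire, dam and residual covariance matrices. The additive genetic
#' covariance matrix is `G = 4 x` the sire covariance per retained draw.
#' Priors put the expectation of the sire and dam covariances at P/4 (or
#' P/2 / diagonal, per the config) with degree of belief
#' `nu = n_traits - 0.998`.
#'
#' After sampling, a split-half potential-scale-reduction check is run on
#' every covariance element; apparent non-convergence raises a warning and is
#' recorded in the returned object (`converged`), never silently dropped.
#'
#' @param table Phenotype table (standardize first with
#'   [standardize_traits()] to work in global-SD units; the recorded SDs are
#'   carried into the result).
#' @param population Population label.
#' @param config An [mcmc_config()].
#' @param traits Trait columns to model; default all trait columns.
#' @param na_action `"complete"` (default) drops rows with any missing trait;
#'   `"impute"` augments missing records with conditional-normal draws inside
#'   the sampler.
#' @param psrf_threshold Split-half PSRF above which the fit is flagged.
#' @return Object of class `g_posterior` with elements `population`, `traits`,
#'   `draws` (list of `p x p x n_draws` arrays `S`, `D`, `E`, `G`),
#'   `standardization` (per-trait SDs or `"none"`), `converged`, `psrf_max`,
#'   and sampling metadata.
#' @export
fit_multivariate <- function(table, population, config = mcmc_config(),
                             traits = NULL, na_action = c("complete", "impute"),
                             psrf_threshold = 1.2) {
  check_phenotype_table(table)
  stopifnot(inherits(config, "mcmc_config"))
  na_action <- match.arg(na_action)
  if (is.null(traits)) traits <- trait_columns(table)
  if (length(traits) < 2L) stop("need at least 2 traits for a G matrix")
  missing_tr <- setdiff(traits, names(table))
  if (length(missing_tr) > 0L)
    stop("unknown trait(s): ", paste(missing_tr, collapse = ", "))
  sub <- table[table$population == population, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for population '", population, "'")
  fit <- run_gibbs(sub, traits, config, na_action)
  G <- 4 * fit$S
  std <- trait_sd(table)
  res <- structure(list(population = population, traits = traits,
                        draws = list(S = fit$S, D = fit$D, E = fit$E, G = G),
                        standardization = if (is.null(std)) "none" else std[traits],
                        n_obs = fit$n_obs, n_sires = fit$n_sires,
                        n_dams = fit$n_dams, config = config),
                   class = "g_posterior")
  # split-half convergence screen on the retained chain
  nd <- dim(G)[3]
  if (nd >= 20L) {
    half <- nd %/% 2L
    flat <- t(apply(G, 3L, function(m) m[upper.tri(m, diag = TRUE)]))
    ch <- list(flat[seq_len(half), , drop = FALSE],
               flat[(nd - half + 1L):nd, , drop = FALSE])
    dg <- diagnostics(ch)
    res$psrf_max <- max(dg$psrf, na.rm = TRUE)
    res$converged <- res$psrf_max <= psrf_threshold
    if (!res$converged)
      warning("G-matrix chain for population '", population,
              "' shows split-half PSRF ", round(res$psrf_max, 3),
              " > ", psrf_threshold, "; treat the posterior with caution")
  } else {
    res$psrf_max <- NA_real_
    res$converged <- NA
  }
  res
}

#' @export
print.g_posterior <- function(x, ...) {
  cat("G-matrix posterior for population", x$population, "\n")
  cat(" ", length(x$traits), "traits,", dim(x$draws$G)[3], "retained draws,",
      x$n_obs, "individuals /", x$n_sires, "sires\n")
  cat("  standardization:",
      if (identical(x$standardization, "none")) "none" else "global SD units",
      "\n")
  cat("posterior mean G:\n")
  print(round(posterior_mean_G(x), 4))
  invisible(x)
}

#' Posterior mean G matrix
#'
#' @param x A `g_posterior` object or a `p x p x n` array of G draws.
#' @return The element-wise posterior mean matrix.
#' @export
posterior_mean_G <- function(x) {
  a <- as_g_array(x)
  apply(a, c(1L, 2L), mean)
}

# internal: accept g_posterior | 3-d array | single matrix -> p x p x n array
as_g_array <- function(x) {
  if (inherits(x, "g_posterior")) return(x$draws$G)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.matrix(x)) return(array(x, c(dim(x), 1L), dimnames = c(dimnames(x), list(NULL))))
  stop("cannot interpret object of class '", class(x)[1L], "' as G draws")
}

#' Back-transform a G posterior to original trait units
#'
#' A G matrix estimated on globally SD-standardized traits is returned to
#' trait-unit scale using the standardization record:
#' `G_raw[i, j] = G_std[i, j] * sd_i * sd_j` (and likewise for the sire, dam
#' and residual components). Needed when combining G with selection
#' gradients estimated on raw trait scales, as in breeder's-equation
#' response predictions.
#'
#' @param x A `g_posterior` carrying a standardization record.
#' @return A `g_posterior` on trait-unit scale (`standardization = "none"`).
#' @export
unstandardize_g <- function(x) {
  stopifnot(inherits(x, "g_posterior"))
  if (identical(x$standardization, "none")) return(x)
  sds <- x$standardization[x$traits]
  scale_mat <- outer(sds, sds)
  for (comp in names(x$draws)) {
    a <- x$draws[[comp]]
    for (d in seq_len(dim(a)[3L])) a[, , d] <- a[, , d] * scale_mat
    x$draws[[comp]] <- a
  }
  x$standardization <- "none"
  x
}

#' Posterior summary table of G-matrix elements
#'
#' One row per (upper-triangle) element with posterior mean and 95% HPD
#' bounds; this is the standard flat summary written next to serialized
#' draws.
#'
#' @param x A `g_posterior` object.
#' @param prob HPD mass.
#' @return Data frame with columns `trait_i`, `trait_j`, `mean`, `hpd_low`,
#'   `hpd_high`.
#' @export
summarize_g <- function(x, prob = 0.95) {
  stopifnot(inherits(x, "g_posterior"))
  G <- x$draws$G
  p <- length(x$traits)
  rows <- list()
  for (i in seq_len(p)) for (j in i:p) {
    d <- G[i, j, ]
    h <- hpd(d, prob)
    rows[[length(rows) + 1L]] <- data.frame(
      trait_i = x$traits[i], trait_j = x$traits[j],
      mean = mean(d), hpd_low = h[1L], hpd_high = h[2L])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a G-matrix posterior to plain-text files
#'
#' Writes three artifacts sharing a basename: `<base>_draws.csv` (long format:
#' draw, component, trait_i, trait_j, value), `<base>_summary.csv` (posterior
#' mean and 95% HPD per G element) and `<base>_meta.json` (population, traits,
#' standardization record, chain schedule).
#'
#' @param x A `g_posterior`.
#' @param base Path prefix.
#' @return `base`, invisibly.
#' @export
write_g_posterior <- function(x, base) {
  stopifnot(inherits(x, "g_posterior"))
  p <- length(x$traits)
  long <- list()
  for (comp in c("S", "D", "E", "G")) {
    a <- x$draws[[comp]]
    for (i in seq_len(p)) for (j in i:p) {
      long[[length(long) + 1L]] <- data.frame(
        component = comp, trait_i = x$traits[i], trait_j = x$traits[j],
        draw = seq_len(dim(a)[3]), value = a[i, j, ])
    }
  }
  write.csv(do.call(rbind, long), paste0(base, "_draws.csv"), row.names = FALSE)
  write.csv(summarize_g(x), paste0(base, "_summary.csv"), row.names = FALSE)
  meta <- list(population = x$population, traits = x$traits,
               standardization = if (identical(x$standardization, "none"))
                 "none" else as.list(x$standardization),
               n_obs = x$n_obs, n_sires = x$n_sires, n_dams = x$n_dams,
               burn_in = x$config$burn_in,
               post_burn_iterations = x$config$post_burn_iterations,
               thin = x$config$thin, seed = x$config$seed,
               psrf_max = x$psrf_max, converged = x$converged)
  jsonlite::write_json(meta, paste0(base, "_meta.json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(base)
}
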