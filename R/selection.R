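#' Sire means of traits and fitness proxies
#'
#' Collapses a phenotype table to one row per sire with the arithmetic mean
#' of each trait over that sire's offspring (non-missing values only) and
#' the offspring count. Sires are pooled globally -- the sire-mean table
#' feeds a single selection-gradient regression across all populations, so
#' that differences in predicted responses come from G, not from
#' population-specific selection estimates.
#'
#' @param table Phenotype table.
#' @param traits Trait columns to average; default all.
#' @return Data frame of class `sire_mean_table`: `population`, `sire`, `n`
#'   (offspring count), then per-trait means (a sire with no non-missing
#'   value for a trait gets `NA` for that mean, row retained).
#' @export
sire_means <- function(table, traits = NULL) {
  check_phenotype_table(table)
  if (nrow(table) == 0L) stop("cannot summarize an empty table")
  if (is.null(traits)) traits <- trait_columns(table)
  key <- paste(table$population, table$sire, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(population = table$population[first],
                    sire = table$sire[first],
                    n = as.integer(table(key)[unique(key)]),
                    stringsAsFactors = FALSE)
  for (tr in traits)
    out[[tr]] <- as.numeric(tapply(table[[tr]], key,
                                   function(v) mean(v, na.rm = TRUE))[unique(key)])
  for (tr in traits) out[[tr]][is.nan(out[[tr]])] <- NA_real_
  rownames(out) <- NULL
  class(out) <- c("sire_mean_table", "data.frame")
  out
}

#' Composite fitness from male and female fitness proxies
#'
#' First principal component of the two fitness proxies, computed on the
#' correlation matrix (the proxies are in incommensurable units, e.g. grams
#' of seed vs. centimeters of inflorescence). The sign is fixed so the score
#' correlates positively with both proxies.
#'
#' @param sm A [sire_means()] table (or any data frame holding the proxies).
#' @param proxies The two proxy columns (female then male by convention).
#' @return Numeric vector of per-sire composite scores (`NA` where a proxy is
#'   missing), with attributes `var_explained` (proportion of variance on
#'   PC1) and `loadings`.
#' @export
composite_fitness <- function(sm, proxies = c("seed_mass", "inflorescence_length")) {
  if (length(proxies) != 2L) stop("exactly 2 fitness proxies required")
  missing_p <- setdiff(proxies, names(sm))
  if (length(missing_p) > 0L)
    stop("proxy column(s) not found: ", paste(missing_p, collapse = ", "))
  Xf <- as.matrix(sm[, proxies, drop = FALSE])
  cc <- complete.cases(Xf)
  if (sum(cc) < 3L) stop("need both proxies for at least 3 sires")
  sds <- apply(Xf[cc, , drop = FALSE], 2L, sd)
  if (any(sds == 0)) stop("zero variance in fitness proxy '",
                          proxies[which(sds == 0)[1L]], "'")
  Z <- scale(Xf[cc, , drop = FALSE])
  e <- eigen(cor(Xf[cc, , drop = FALSE]), symmetric = TRUE)
  v <- e$vectors[, 1L]
  score_cc <- drop(Z %*% v)
  if (cor(score_cc, Xf[cc, proxies[1L]]) < 0) {
    v <- -v
    score_cc <- -score_cc
  }
  score <- rep(NA_real_, nrow(sm))
  score[cc] <- score_cc
  structure(score,
            var_explained = e$values[1L] / sum(e$values),
            loadings = setNames(v, proxies))
}

# internal: pull the trait design matrix for a beta regression
beta_design <- function(sm, traits, fitness) {
  X <- as.matrix(sm[, traits, drop = FALSE])
  w <- as.numeric(fitness)
  cc <- complete.cases(X) & is.finite(w)
  list(X = X[cc, , drop = FALSE], w = w[cc], n = sum(cc))
}

# internal: relative fitness. Positive-mean metrics (seed mass, inflorescence
# length) are divided by their grand mean, the Lande-Arnold convention. A
# centered index (e.g. a composite PC1 score, mean ~ 0) cannot be divided by
# its mean; it is treated as already relative: rescaled to unit variance and
# shifted to mean 1. Both branches leave beta invariant to multiplying the
# fitness metric by a positive constant.
relativize_fitness <- function(w) {
  mw <- mean(w)
  if (mw > 0.01 * sd(w)) return(w / mw)
  message("fitness metric is centered (mean ~ 0): using a unit-variance ",
          "relative-fitness index instead of mean-relativization")
  1 + (w - mw) / sd(w)
}

#' Directional selection gradients by least squares
#'
#' Lande-Arnold point estimate: partial regression coefficients of relative
#' fitness (fitness divided by its grand mean; a centered composite index is
#' instead shifted to a unit-variance relative scale) on the trait sire
#' means, intercept included but not reported. Traits are used on their raw
#' scale (gradients in units of trait^-1) unless `standardize = TRUE`.
#'
#' @param sm A [sire_means()] table.
#' @param fitness Either the name of a fitness column in `sm` or a numeric
#'   vector aligned with its rows (e.g. a [composite_fitness()] score).
#' @param traits The (non-fitness) trait columns entering the regression;
#'   default: the first four default traits.
#' @param standardize Divide traits by their SD before regressing.
#' @param fitness_metric Label stored in the result (`"female"`, `"male"`,
#'   `"composite"`, ...).
#' @return Object of class `selection_gradient`: `beta` (named vector),
#'   `mode = "point"`, `fitness_metric`, `n`, `condition_number`.
#'   A near-collinear design (condition number above 1e8) warns but still
#'   returns coefficients.
#' @export
estimate_beta_point <- function(sm, fitness,
                                traits = default_traits()[1:4],
                                standardize = FALSE,
                                fitness_metric = "composite") {
  if (is.character(fitness) && length(fitness) == 1L) {
    fitness_metric <- fitness
    fitness <- sm[[fitness]]
    if (is.null(fitness)) stop("fitness column not found")
  }
  d <- beta_design(sm, traits, fitness)
  if (d$n <= length(traits) + 1L)
    stop("need more sires (", d$n, ") than traits + 1 (", length(traits) + 1L, ")")
  relw <- relativize_fitness(d$w)
  X <- d$X
  if (standardize) X <- scale(X, center = FALSE, scale = apply(X, 2L, sd))
  kn <- kappa(cbind(1, scale(X, scale = FALSE)), exact = TRUE)
  if (kn > 1e8)
    warning("collinear trait design (condition number ", format(kn, digits = 3),
            "); coefficients returned but unstable")
  fit <- lm(relw ~ X)
  beta <- setNames(coef(fit)[-1L], traits)
  structure(list(beta = beta, mode = "point", draws = NULL,
                 fitness_metric = fitness_metric, n = d$n,
                 condition_number = kn, standardized = standardize),
            class = "selection_gradient")
}

#' Directional selection gradients by conjugate Bayesian regression
#'
#' Posterior draws of the selection gradient under a weakly informative
#' Zellner-style g-prior (g = n, unit information) on the slopes with a flat
#' intercept and Jeffreys prior on the residual variance. The posterior is
#' available in closed form (normal--inverse-gamma), so draws are exact
#' (no chain to converge): sigma^2 from its inverse-gamma marginal, then
#' beta from its conditional normal, shrunk toward zero by n/(n+1).
#'
#' @inheritParams estimate_beta_point
#' @param n_draws Posterior draws (default 10000).
#' @param seed Integer seed.
#' @return A `selection_gradient` with `mode = "posterior"`, `draws`
#'   (n_draws x traits matrix) and `beta` = posterior means.
#' @export
estimate_beta_bayes <- function(sm, fitness,
                                traits = default_traits()[1:4],
                                n_draws = 10000, seed = 1L,
                                standardize = FALSE,
                                fitness_metric = "composite") {
  if (is.character(fitness) && length(fitness) == 1L) {
    fitness_metric <- fitness
    fitness <- sm[[fitness]]
    if (is.null(fitness)) stop("fitness column not found")
  }
  d <- beta_design(sm, traits, fitness)
  k <- length(traits)
  if (d$n <= k + 1L)
    stop("need more sires (", d$n, ") than traits + 1 (", k + 1L, ")")
  relw <- relativize_fitness(d$w)
  X <- d$X
  if (standardize) X <- scale(X, center = FALSE, scale = apply(X, 2L, sd))
  # center: intercept gets a flat prior and integrates out
  Xc <- scale(X, scale = FALSE)
  yc <- relw - mean(relw)
  XtX <- crossprod(Xc)
  XtXinv <- solve(XtX)
  bhat <- drop(XtXinv %*% crossprod(Xc, yc))
  g <- d$n
  shrink <- g / (1 + g)
  ssr <- sum(yc^2) - shrink * drop(t(bhat) %*% XtX %*% bhat)
  a_n <- (d$n - 1) / 2
  b_n <- ssr / 2
  set.seed(as.integer(seed))
  sig2 <- 1 / rgamma(n_draws, shape = a_n, rate = b_n)
  L <- chol(XtXinv)
  Z <- matrix(rnorm(n_draws * k), n_draws, k)
  draws <- matrix(rep(shrink * bhat, each = n_draws), n_draws, k) +
    sqrt(shrink * sig2) * (Z %*% L)
  colnames(draws) <- traits
  structure(list(beta = colMeans(draws), mode = "posterior", draws = draws,
                 fitness_metric = fitness_metric, n = d$n,
                 n_draws = n_draws, seed = as.integer(seed),
                 standardized = standardize),
            class = "selection_gradient")
}

#' @export
print.selection_gradient <- function(x, ...) {
  cat("Selection gradient (", x$mode, ", fitness = ", x$fitness_metric,
      ", n = ", x$n, " sires)\n", sep = "")
  print(round(x$beta, 5))
  if (!is.null(x$draws))
    cat(nrow(x$draws), "posterior draws\n")
  invisible(x)
}

#' Serialize a selection gradient
#'
#' Point gradients go to JSON; posterior gradients additionally write their
#' draws as CSV.
#'
#' @param x A `selection_gradient`.
#' @param base Path prefix.
#' @return `base`, invisibly.
#' @export
write_selection_gradient <- function(x, base) {
  stopifnot(inherits(x, "selection_gradient"))
  meta <- list(beta = as.list(x$beta), mode = x$mode,
               fitness_metric = x$fitness_metric, n = x$n)
  jsonlite::write_json(meta, paste0(base, ".json"), digits = NA,
                       auto_unbox = TRUE)
  if (!is.null(x$draws))
    write.csv(as.data.frame(x$draws), paste0(base, "_draws.csv"),
              row.names = FALSE)
  invisible(base)
}
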