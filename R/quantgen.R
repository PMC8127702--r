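#' Narrow-sense heritability from sire/dam variance components
#'
#' In a paternal half-sib design the covariance of half-sibs estimates
#' V_A/4, so `V_A = 4 V_S` and
#' \deqn{h^2 = \frac{4 V_S}{V_S + V_D + V_E}.}
#' When the sire fraction of phenotypic variance exceeds 0.25 the estimate
#' exceeds 1 -- a recognized property of half-sib heritability estimates,
#' not an error; values are therefore not truncated.
#'
#' @param vc A list/data frame with components `V_S`, `V_D`, `V_E`
#'   (vectorized over posterior draws), or a `vc_posterior`.
#' @return Numeric vector of heritabilities.
#' @export
heritability <- function(vc) {
  for (nm in c("V_S", "V_D", "V_E"))
    if (is.null(vc[[nm]])) stop("'vc' must contain ", nm)
  vp <- vc$V_S + vc$V_D + vc$V_E
  if (any(!is.finite(vp)) || any(vp <= 0))
    stop("phenotypic variance V_P = V_S + V_D + V_E must be positive")
  4 * vc$V_S / vp
}

#' Method-of-moments variance components for balanced nested designs
#'
#' Independent nested-ANOVA estimator used as a cross-check on the Gibbs
#' sampler: for a balanced design (every sire with the same number of dams,
#' every dam with the same number of offspring, trait fully observed) the
#' mean squares of the sire / dam-within-sire / within-dam strata give
#' moment estimators
#' \deqn{V_E = MS_w,\quad V_D = (MS_{dam} - MS_w)/o,\quad
#'       V_S = (MS_{sire} - MS_{dam})/(d\,o).}
#' Block means are removed first (block effects are orthogonal to family
#' structure under round-robin allocation, so this only strips the block
#' signal). Negative moment estimates are truncated at zero and flagged.
#'
#' @param table Phenotype table.
#' @param trait Trait column.
#' @param population Population label, or `NULL` if the table is a single
#'   population.
#' @return List with `V_S`, `V_D`, `V_E`, `V_A`, `V_P`, `h2`, `truncated`
#'   (logical), and the mean squares / sums of squares (`ms`, `ss`, `df`).
#' @export
anova_oracle <- function(table, trait, population = NULL) {
  check_phenotype_table(table)
  if (!is.null(population))
    table <- table[table$population == population, , drop = FALSE]
  y <- table[[trait]]
  if (any(is.na(y))) stop("anova_oracle requires a fully observed trait")
  sire <- factor(table$sire)
  dam <- factor(paste(table$sire, table$dam, sep = "\r"))
  d_per_s <- tapply(dam, sire, function(x) length(unique(x)))
  o_per_d <- tapply(y, dam, length)
  if (length(unique(d_per_s)) != 1L || length(unique(o_per_d)) != 1L)
    stop("anova_oracle requires a balanced design ",
         "(equal dams per sire and offspring per dam)")
  s <- nlevels(sire)
  d <- unname(d_per_s[1L])
  o <- unname(o_per_d[1L])
  if (s < 2L || d < 2L || o < 2L)
    stop("balanced oracle needs >= 2 sires, dams per sire and offspring per dam")
  # strip block means (orthogonal to families under round-robin allocation)
  y <- y - ave(y, table$block)
  gm <- mean(y)
  sire_mean <- ave(y, sire)
  dam_mean <- ave(y, dam)
  ss_sire <- sum((tapply(y, sire, mean) - gm)^2) * d * o
  ss_dam <- sum((dam_mean - sire_mean)^2) / 1  # row-wise sums already weighted
  ss_within <- sum((y - dam_mean)^2)
  df <- c(sire = s - 1, dam = s * (d - 1), within = s * d * (o - 1))
  ms <- c(sire = ss_sire / df[["sire"]], dam = ss_dam / df[["dam"]],
          within = ss_within / df[["within"]])
  V_E <- ms[["within"]]
  V_D <- (ms[["dam"]] - ms[["within"]]) / o
  V_S <- (ms[["sire"]] - ms[["dam"]]) / (d * o)
  truncated <- V_D < 0 || V_S < 0
  V_D <- max(V_D, 0)
  V_S <- max(V_S, 0)
  V_P <- V_S + V_D + V_E
  list(V_S = V_S, V_D = V_D, V_E = V_E, V_A = 4 * V_S, V_P = V_P,
       h2 = if (V_P > 0) 4 * V_S / V_P else NA_real_,
       truncated = truncated, ms = ms,
       ss = c(sire = ss_sire, dam = ss_dam, within = ss_within), df = df,
       design = c(sires = s, dams_per_sire = d, offspring_per_dam = o))
}

#' Convergence diagnostics for MCMC chains
#'
#' Potential scale reduction factor (PSRF), effective sample size and lag-k
#' autocorrelations for one or more chains of equal length. The PSRF is the
#' variance-ratio form
#' \deqn{\widehat{R} = \sqrt{1 + B/(nW)}}
#' (between-chain variance of chain means `B = n var(means)`, within-chain
#' variance `W`), which is exactly 1 for identical chains and never below 1.
#' Effective sample size uses the summed autocorrelation truncated at the
#' first non-positive lag, capped at the total draw count.
#'
#' @param chains A list of >= 1 chains; each chain a numeric vector or a
#'   matrix/data frame with one column per parameter. All chains must have
#'   the same length (>= 10) and parameters.
#' @param lags Lags at which autocorrelations are reported.
#' @return List of class `mcmc_diagnostics` with `psrf` (named vector; `NA`
#'   with a message when only one chain is supplied), `ess`, `autocorr`
#'   (lags x parameters matrix), `n`, `n_chains`.
#' @export
diagnostics <- function(chains, lags = c(1L, 5L, 10L, 50L)) {
  if (is.numeric(chains) || is.matrix(chains)) chains <- list(chains)
  chains <- lapply(chains, function(ch) {
    m <- as.matrix(ch)
    storage.mode(m) <- "double"
    m
  })
  n <- nrow(chains[[1L]])
  k <- ncol(chains[[1L]])
  if (n < 10L) stop("chains must have length >= 10")
  for (ch in chains)
    if (nrow(ch) != n || ncol(ch) != k)
      stop("all chains must have equal length and parameter count")
  pname <- colnames(chains[[1L]])
  if (is.null(pname)) pname <- paste0("par", seq_len(k))
  pooled <- do.call(rbind, chains)
  m <- length(chains)

  psrf <- rep(NA_real_, k)
  if (m >= 2L) {
    for (j in seq_len(k)) {
      means <- vapply(chains, function(ch) mean(ch[, j]), 0)
      W <- mean(vapply(chains, function(ch) var(ch[, j]), 0))
      B <- n * var(means)
      psrf[j] <- if (W <= 0) {
        if (B <= 1e-300) 1 else Inf
      } else sqrt(1 + B / (n * W))
    }
  } else {
    message("single chain supplied: PSRF unavailable, autocorrelation returned")
  }

  lags <- lags[lags < n]
  ac <- matrix(NA_real_, length(lags), k,
               dimnames = list(paste0("lag", lags), pname))
  ess <- numeric(k)
  for (j in seq_len(k)) {
    # average autocorrelation over chains (within-chain correlation)
    a_full <- rowMeans(vapply(chains, function(ch) {
      if (var(ch[, j]) == 0) return(rep(0, n))
      as.numeric(acf(ch[, j], lag.max = n - 1L, plot = FALSE,
                     demean = TRUE)$acf)
    }, numeric(n)))
    ac[, j] <- a_full[lags + 1L]
    rho <- a_full[-1L]
    cut <- which(rho <= 0)
    if (length(cut) > 0L) rho <- rho[seq_len(cut[1L] - 1L)]
    ess[j] <- min(m * n, m * n / (1 + 2 * sum(rho)))
  }
  structure(list(psrf = setNames(psrf, pname), ess = setNames(ess, pname),
                 autocorr = ac, n = n, n_chains = m),
            class = "mcmc_diagnostics")
}

#' @export
print.mcmc_diagnostics <- function(x, ...) {
  cat("MCMC diagnostics:", x$n_chains, "chain(s) of length", x$n, "\n")
  if (all(is.na(x$psrf))) cat("PSRF: unavailable (single chain)\n")
  else cat("PSRF: max", round(max(x$psrf, na.rm = TRUE), 4), "\n")
  cat("ESS: min", round(min(x$ess), 1), "\n")
  invisible(x)
}
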