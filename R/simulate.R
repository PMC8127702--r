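#' Build a nested paternal half-sib crossing design
#'
#' Constructs the design table for a nested paternal half-sib breeding
#' experiment: within each population, `n_sires` sires are each crossed to
#' `n_dams_per_sire` unique dams (no sire or dam reused), and each full-sib
#' family contributes `n_offspring_per_dam` offspring. Offspring are assigned
#' to field blocks in a balanced round-robin within family, so every family is
#' spread as evenly as possible across blocks. The defaults reproduce a
#' 6-population x 50-sire x 3-dam x 3-offspring experiment in 3 blocks
#' (900 families, 2700 individuals).
#'
#' @param n_populations Number of source populations.
#' @param n_sires Sires per population.
#' @param n_dams_per_sire Dams crossed to each sire (dams are unique to a sire).
#' @param n_offspring_per_dam Offspring measured per full-sib family.
#' @param n_blocks Number of field blocks.
#' @param seed Accepted for interface symmetry with the stochastic generators;
#'   the design construction is fully deterministic and ignores it.
#' @return A data frame with columns `population`, `block`, `sire`, `dam`,
#'   `individual`. Sire labels are unique within population, dam labels unique
#'   within sire, individual labels unique overall.
#' @export
make_design <- function(n_populations = 6, n_sires = 50, n_dams_per_sire = 3,
                        n_offspring_per_dam = 3, n_blocks = 3, seed = NULL) {
  counts <- c(n_populations = n_populations, n_sires = n_sires,
              n_dams_per_sire = n_dams_per_sire,
              n_offspring_per_dam = n_offspring_per_dam, n_blocks = n_blocks)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v))
      stop("'", nm, "' must be a positive integer (got ", format(v), ")")
  }
  pop <- sprintf("P%d", seq_len(n_populations))
  rows <- expand.grid(off = seq_len(n_offspring_per_dam),
                      dam = seq_len(n_dams_per_sire),
                      sire = seq_len(n_sires),
                      population = pop,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sire_id <- sprintf("%s_S%03d", rows$population, rows$sire)
  dam_id <- sprintf("%s_D%d", sire_id, rows$dam)
  individual <- sprintf("%s_O%d", dam_id, rows$off)
  # balanced round-robin across blocks within each full-sib family
  block <- ((rows$off - 1L) %% n_blocks) + 1L
  out <- data.frame(population = rows$population, block = block,
                    sire = sire_id, dam = dam_id, individual = individual,
                    stringsAsFactors = FALSE)
  out <- out[order(out$population, out$sire, out$dam, out$individual),
             DESIGN_COLS, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulation parameters for a half-sib experiment
#'
#' Bundles the generative quantitative-genetic architecture: trait means
#' `mu`, additive genetic covariance `G`, dam (maternal/dominance) covariance
#' `D`, residual covariance `E`, per-block trait offsets, and attrition /
#' missingness rates. Under the nested sire/dam model, sire effects are drawn
#' from MVN(0, G/4) (half-sib covariance = V_A/4), dam effects from MVN(0, D),
#' residuals from MVN(0, E).
#'
#' @param mu Named numeric vector of trait means (names become trait columns).
#' @param G,D,E Symmetric positive semi-definite covariance matrices of equal
#'   dimension (trait units squared).
#' @param block_effects Optional matrix (`n_blocks` x `n_traits`) of additive
#'   block offsets; `NULL` means no block effects.
#' @param attrition_rate Probability in `[0, 1]` that an individual is lost
#'   (i.i.d. across individuals).
#' @param missing_rate_per_trait Probability (scalar or per-trait vector) that
#'   a surviving individual's trait record is missing.
#' @param seed Integer seed controlling all random draws.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(mu, G, D, E, block_effects = NULL,
                       attrition_rate = 0, missing_rate_per_trait = 0,
                       seed = 1L) {
  if (is.null(names(mu))) stop("'mu' must be a named vector of trait means")
  p <- length(mu)
  for (nm in c("G", "D", "E")) {
    M <- get(nm)
    check_psd(M, nm)
    if (nrow(M) != p)
      stop("'", nm, "' dimension (", nrow(M), ") does not match length of mu (", p, ")")
  }
  if (!is.null(block_effects)) {
    block_effects <- as.matrix(block_effects)
    if (ncol(block_effects) != p)
      stop("'block_effects' must have one column per trait")
  }
  rates <- c(attrition_rate, missing_rate_per_trait)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    stop("attrition and missingness rates must lie in [0, 1]")
  structure(list(mu = mu, G = G, D = D, E = E, block_effects = block_effects,
                 attrition_rate = attrition_rate,
                 missing_rate_per_trait = missing_rate_per_trait,
                 seed = as.integer(seed), traits = names(mu)),
            class = "sim_params")
}

#' Default six-trait genetic architecture
#'
#' A realistic architecture for the default trait set: narrow-sense
#' heritabilities of 0.3 for every trait, genetic correlations of 0.3,
#' dam covariance `D = G/4` (maternal effects of the same order as the
#' sire component), and residual covariance chosen so that the phenotypic
#' covariance equals the target `P`. Means and phenotypic SDs are on
#' scales typical of an annual weed grown in a common garden.
#'
#' @param h2 Narrow-sense heritability shared by all traits.
#' @param r_g Genetic correlation shared by all trait pairs.
#' @param seed Seed stored in the parameter object.
#' @param attrition_rate,missing_rate_per_trait Passed through.
#' @return A `sim_params` object for the six default traits.
#' @export
default_sim_params <- function(h2 = 0.3, r_g = 0.3, seed = 1L,
                               attrition_rate = 0, missing_rate_per_trait = 0) {
  traits <- default_traits()
  mu <- c(15, 90, 20, 60, 30, 2)
  sdP <- c(3, 20, 6, 5, 8, 0.5)
  names(mu) <- names(sdP) <- traits
  p <- length(traits)
  corG <- matrix(r_g, p, p); diag(corG) <- 1
  P <- diag(sdP) %*% (matrix(0.2, p, p) + 0.8 * diag(p)) %*% diag(sdP)
  G <- h2 * (diag(sdP) %*% corG %*% diag(sdP))
  D <- G / 4
  E <- P - G / 4 - D
  check_psd(E, "implied residual covariance")
  dimnames(G) <- dimnames(D) <- dimnames(E) <- list(traits, traits)
  sim_params(mu = mu, G = G, D = D, E = E, seed = seed,
             attrition_rate = attrition_rate,
             missing_rate_per_trait = missing_rate_per_trait)
}

#' Simulate phenotypes on a half-sib design
#'
#' Generates trait records under the nested mixed model
#' \deqn{y = \mu + B_{block} + S_{sire} + D_{dam} + e,}
#' with one sire effect per sire drawn from MVN(0, G/4), one dam effect per
#' dam from MVN(0, D), and an individual residual from MVN(0, E). Identical
#' architectures are used in every population (populations share the true G),
#' making the output a null fixture for divergence statistics; population-
#' specific architectures can be simulated by calling this per population.
#'
#' @param design Design table from [make_design()].
#' @param params A [sim_params()] object.
#' @param keep_effects If `TRUE`, the realized sire/dam effect matrices are
#'   attached as attributes `sire_effects` and `dam_effects` (rows named by
#'   sire/dam label) for verification against the generative covariances.
#' @return A phenotype table: the design columns plus one numeric column per
#'   trait. Deterministic given `params$seed`.
#' @export
simulate_phenotypes <- function(design, params, keep_effects = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  check_phenotype_table(cbind(design))
  traits <- params$traits
  p <- length(traits)
  set.seed(params$seed)

  sires <- unique(design$sire)
  dams <- unique(design$dam)
  sire_eff <- rmvn(length(sires), params$G / 4)
  dam_eff <- rmvn(length(dams), params$D)
  resid <- rmvn(nrow(design), params$E)
  rownames(sire_eff) <- sires
  rownames(dam_eff) <- dams

  Y <- matrix(rep(params$mu, each = nrow(design)), nrow(design), p)
  if (!is.null(params$block_effects)) {
    nb <- nrow(params$block_effects)
    bi <- as.integer(factor(design$block))
    if (max(bi) > nb) stop("block_effects has fewer rows than blocks in the design")
    Y <- Y + params$block_effects[bi, , drop = FALSE]
  }
  Y <- Y + sire_eff[match(design$sire, sires), , drop = FALSE] +
    dam_eff[match(design$dam, dams), , drop = FALSE] + resid
  colnames(Y) <- traits

  out <- cbind(design, as.data.frame(Y))
  rownames(out) <- NULL
  if (keep_effects) {
    attr(out, "sire_effects") <- sire_eff
    attr(out, "dam_effects") <- dam_eff
  }
  out
}

#' Apply attrition and trait-wise missingness
#'
#' Emulates failed establishment and mortality in the field: rows are dropped
#' independently with probability `attrition_rate`, and each trait record of a
#' surviving individual is masked independently with its per-trait missing
#' rate (mimicking records that could not be taken, e.g. death before
#' flowering).
#'
#' @param table Phenotype table.
#' @param attrition_rate Probability in `[0, 1]` of losing an individual.
#' @param missing_rate_per_trait Scalar or per-trait vector of masking
#'   probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return The thinned table (possibly zero rows).
#' @export
apply_attrition <- function(table, attrition_rate, missing_rate_per_trait = 0,
                            seed = 1L) {
  check_phenotype_table(table)
  traits <- trait_columns(table)
  rates <- c(attrition_rate, missing_rate_per_trait)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    stop("attrition and missingness rates must lie in [0, 1]")
  if (length(missing_rate_per_trait) == 1L)
    missing_rate_per_trait <- rep(missing_rate_per_trait, length(traits))
  if (length(missing_rate_per_trait) != length(traits))
    stop("missing_rate_per_trait must be scalar or one rate per trait")
  set.seed(as.integer(seed))
  keep <- runif(nrow(table)) >= attrition_rate
  out <- table[keep, , drop = FALSE]
  for (i in seq_along(traits)) {
    if (missing_rate_per_trait[i] > 0 && nrow(out) > 0) {
      mask <- runif(nrow(out)) < missing_rate_per_trait[i]
      out[[traits[i]]][mask] <- NA_real_
    }
  }
  rownames(out) <- NULL
  out
}
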