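# fixture builders shared across test files; everything is generated in code

# single-trait parameter object with chosen variance components
uni_params <- function(V_S = 0.25, V_D = 0.25, V_E = 0.5, seed = 1) {
  G <- matrix(4 * V_S); D <- matrix(V_D); E <- matrix(V_E)
  dimnames(G) <- dimnames(D) <- dimnames(E) <- list("y", "y")
  sim_params(mu = c(y = 10), G = G, D = D, E = E, seed = seed)
}

# p-trait architecture with common variance v, genetic correlation r
multi_params <- function(p = 3, v = 1, r = 0.3, h2 = 0.4, seed = 1,
                         traits = paste0("t", seq_len(p))) {
  C <- matrix(r, p, p); diag(C) <- 1
  G <- h2 * v * C
  D <- G / 4
  # residual chosen so the phenotypic variance of every trait equals v
  E <- v * (1 - h2 / 2) * diag(p)
  dimnames(G) <- dimnames(D) <- dimnames(E) <- list(traits, traits)
  mu <- setNames(rep(0, p), traits)
  sim_params(mu = mu, G = G, D = D, E = E, seed = seed)
}

# small simulated phenotype table
quick_table <- function(n_pops = 2, n_sires = 10, params = multi_params(),
                        seed = NULL) {
  if (!is.null(seed)) params$seed <- seed
  des <- make_design(n_pops, n_sires, 3, 3, 3)
  simulate_phenotypes(des, params)
}

# short MCMC schedule for tests
quick_config <- function(seed = 1, burn = 300, post = 1200, thin = 2) {
  mcmc_config(burn_in = burn, post_burn_iterations = post, thin = thin,
              seed = seed)
}

# random positive-definite matrix with reproducible seed
random_pd <- function(p, seed = 1) {
  set.seed(seed)
  M <- crossprod(matrix(rnorm(p * p), p)) + diag(p) * 0.5
  (M + t(M)) / 2
}
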