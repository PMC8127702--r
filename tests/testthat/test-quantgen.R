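test_that("retained draw count follows the config arithmetic", {
  expect_error(mcmc_config(post_burn_iterations = 1000, thin = 300), "divide")
  cfg <- quick_config(post = 1000, thin = 10)
  tab <- quick_table(1, 8, seed = 12)
  fit <- fit_univariate(tab, "t1", "P1", cfg)
  expect_equal(nrow(fit), 100)
  g <- suppressWarnings(fit_multivariate(tab, "P1", cfg))
  expect_equal(dim(g$draws$G)[3], 100)
  # the production schedules resolve to 10,000 retained draws
  expect_equal(mcmc_config(burn_in = 200000)$post_burn_iterations / 500, 10000)
  expect_equal(with(mcmc_config(burn_in = 500000, post_burn_iterations = 5e6,
                                thin = 500),
                    post_burn_iterations / thin), 10000)
})

test_that("variance draws scale exactly by 4 when the trait is doubled", {
  tab <- quick_table(1, 10, seed = 13)
  cfg <- quick_config(seed = 5)
  f1 <- fit_univariate(tab, "t1", "P1", cfg)
  tab2 <- tab
  tab2$t1 <- 2 * tab2$t1
  f2 <- fit_univariate(tab2, "t1", "P1", cfg)
  expect_equal(f2$V_S, 4 * f1$V_S, tolerance = 1e-8)
  expect_equal(f2$V_E, 4 * f1$V_E, tolerance = 1e-8)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-8)
})

test_that("univariate posterior recovers generative variance components", {
  pars <- uni_params(V_S = 0.25, V_D = 0.25, V_E = 0.5, seed = 21)
  tab <- simulate_phenotypes(make_design(1, 200, 5, 10, 3), pars)
  fit <- fit_univariate(tab, "y", "P1",
                        quick_config(seed = 2, burn = 500, post = 2500, thin = 5))
  post <- colMeans(fit[, c("V_S", "V_D", "V_E")])
  expect_lt(abs(post[["V_S"]] - 0.25) / 0.25, 0.15)
  expect_lt(abs(post[["V_D"]] - 0.25) / 0.25, 0.15)
  expect_lt(abs(post[["V_E"]] - 0.50) / 0.50, 0.15)
  # cross-check against the moment oracle on the same data
  ao <- anova_oracle(tab, "y", "P1")
  expect_lt(abs(post[["V_S"]] - ao$V_S) / ao$V_S, 0.10)
})

test_that("degenerate grouping and all-missing traits are rejected", {
  tab <- quick_table(1, 6, seed = 3)
  one_sire <- tab[tab$sire == tab$sire[1], ]
  expect_error(fit_univariate(one_sire, "t1", "P1", quick_config()),
               "degenerate grouping")
  tab$t1 <- NA_real_
  expect_error(fit_univariate(tab, "t1", "P1", quick_config()),
               "entirely missing")
})

test_that("heritability formula and its boundary cases", {
  expect_equal(heritability(list(V_S = 0.25, V_D = 0.25, V_E = 0.50)), 1.0)
  expect_equal(heritability(list(V_S = 0, V_D = 0.3, V_E = 0.7)), 0)
  expect_equal(heritability(list(V_S = 0.3, V_D = 0.2, V_E = 0.5)), 1.2)
  expect_error(heritability(list(V_S = 0, V_D = 0, V_E = 0)), "positive")
  # vectorized over posterior draws
  expect_equal(heritability(list(V_S = c(0.1, 0.2), V_D = c(0.1, 0.1),
                                 V_E = c(0.8, 0.7))),
               c(0.4, 0.8))
})

test_that("anova oracle: decomposition identity, null case, balance guard", {
  pars <- uni_params(V_S = 0, V_D = 0, V_E = 1, seed = 33)
  tab <- simulate_phenotypes(make_design(1, 100, 3, 4, 1), pars)
  ao <- anova_oracle(tab, "y", "P1")
  # with no family structure, sire and dam components sit near 0
  se0 <- sqrt(2 / 100)  # crude MC scale for a variance of ~1/ (d*o) shares
  expect_lt(ao$V_S, 3 * se0)
  expect_lt(ao$V_D, 3 * se0)
  # sums of squares add to the total about the (block-adjusted) grand mean
  y <- tab$y - ave(tab$y, tab$block)
  expect_equal(unname(sum(ao$ss)), sum((y - mean(y))^2), tolerance = 1e-8)
  # unbalanced input is refused
  expect_error(anova_oracle(tab[-1, ], "y", "P1"), "balanced")
})

test_that("multivariate draws are symmetric positive definite and seeded", {
  tab <- quick_table(1, 12, multi_params(p = 3, seed = 14))
  cfg <- quick_config(seed = 8, post = 600, thin = 3)
  g <- suppressWarnings(fit_multivariate(tab, "P1", cfg))
  for (d in seq_len(dim(g$draws$G)[3])) {
    Gd <- g$draws$G[, , d]
    expect_lt(max(abs(Gd - t(Gd))), 1e-10)
    expect_gt(min(eigen(Gd, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  g2 <- suppressWarnings(fit_multivariate(tab, "P1", cfg))
  expect_identical(g$draws$G, g2$draws$G)
})

test_that("multivariate fit honours standardization record and preconditions", {
  tab <- quick_table(1, 10, seed = 15)
  std <- standardize_traits(tab)
  g <- suppressWarnings(fit_multivariate(std, "P1", quick_config(post = 400)))
  expect_equal(g$standardization, trait_sd(std))
  expect_error(fit_multivariate(tab, "P1", quick_config(), traits = "t1"),
               "at least 2 traits")
  tiny <- tab[1:4, ]
  expect_error(suppressWarnings(
    fit_multivariate(tiny, "P1", quick_config())), "degenerate|too few")
})

test_that("missing-data handling: complete-case drops rows, imputation keeps them", {
  tab <- quick_table(1, 30, multi_params(p = 2, seed = 16))
  tab <- apply_attrition(tab, 0, c(0.15, 0.15), seed = 4)
  cfg <- quick_config(seed = 9, post = 600, thin = 3)
  gcc <- suppressWarnings(fit_multivariate(tab, "P1", cfg))
  gim <- suppressWarnings(fit_multivariate(tab, "P1", cfg, na_action = "impute"))
  expect_lt(gcc$n_obs, nrow(tab))
  expect_equal(gim$n_obs, sum(!is.na(tab$t1) | !is.na(tab$t2)))
  # both recover a G in the same ballpark
  expect_lt(max(abs(posterior_mean_G(gcc) - posterior_mean_G(gim))), 0.5)
})

test_that("gibbs and moment estimates agree on a shared multivariate fixture", {
  pars <- multi_params(p = 2, v = 1, r = 0.5, h2 = 0.4, seed = 17)
  tab <- simulate_phenotypes(make_design(1, 150, 3, 3, 1), pars)
  g <- suppressWarnings(fit_multivariate(tab, "P1",
                                         quick_config(seed = 2, post = 1500, thin = 3)))
  Gm <- posterior_mean_G(g)
  for (tr in c("t1", "t2")) {
    ao <- anova_oracle(tab, tr, "P1")
    expect_lt(abs(Gm[tr, tr] - ao$V_A) / max(ao$V_A, 0.1), 0.35)
  }
})

test_that("unstandardize_g undoes the global-SD scaling element-wise", {
  tab <- quick_table(1, 10, seed = 19)
  std <- standardize_traits(tab)
  g <- suppressWarnings(fit_multivariate(std, "P1", quick_config(post = 400)))
  raw <- unstandardize_g(g)
  sds <- trait_sd(std)
  for (i in 1:3) for (j in 1:3)
    expect_equal(raw$draws$G[i, j, ], g$draws$G[i, j, ] * sds[i] * sds[j],
                 ignore_attr = TRUE)
  expect_identical(raw$standardization, "none")
  # idempotent once the record is cleared
  expect_identical(unstandardize_g(raw), raw)
})

test_that("PSRF is exactly 1 for identical chains and never below 1", {
  set.seed(5)
  ch <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  d <- diagnostics(list(ch, ch))
  expect_equal(unname(d$psrf), c(1, 1))
  for (i in 1:5) {
    c1 <- matrix(rnorm(500), ncol = 1)
    c2 <- matrix(rnorm(500, mean = i / 5), ncol = 1)
    expect_gte(diagnostics(list(c1, c2))$psrf[[1]], 1)
  }
})

test_that("iid chains show near-zero lag-1 autocorrelation and full ESS", {
  set.seed(6)
  ch <- matrix(rnorm(10000), ncol = 1)
  d <- diagnostics(list(ch), lags = 1)
  expect_lt(abs(d$autocorr["lag1", 1]), 0.03)  # 2 / sqrt(n) bound
  expect_gt(d$ess[[1]], 5000)
  expect_lte(d$ess[[1]], 10000)
})

test_that("single chain yields autocorrelation but no PSRF", {
  set.seed(7)
  expect_message(d <- diagnostics(list(rnorm(100))), "single chain")
  expect_true(is.na(d$psrf[[1]]))
  expect_false(any(is.na(d$autocorr)))
})

test_that("split-half PSRF agrees with the coda convention on long chains", {
  skip_if_not_installed("coda")
  set.seed(8)
  c1 <- as.matrix(arima.sim(list(ar = 0.5), 5000))
  c2 <- as.matrix(arima.sim(list(ar = 0.5), 5000))
  ours <- diagnostics(list(c1, c2))$psrf[[1]]
  theirs <- unname(coda::gelman.diag(coda::mcmc.list(coda::mcmc(c1), coda::mcmc(c2)),
                              autoburnin = FALSE)$psrf[1, 1])
  expect_equal(ours, theirs, tolerance = 0.01)
})
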