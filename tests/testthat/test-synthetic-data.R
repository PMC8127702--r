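test_that("design construction gives the right family and offspring counts", {
  # full experiment: 6 pops x 50 sires x 3 dams x 3 offspring in 3 blocks
  des <- make_design(6, 50, 3, 3, 3)
  expect_equal(nrow(des), 2700)
  expect_equal(length(unique(des$dam)), 900)
  expect_equal(length(unique(des$sire)), 300)
  # minimal and small product cases
  d1 <- make_design(1, 1, 1, 1, 1)
  expect_equal(nrow(d1), 1)
  expect_equal(length(unique(d1$dam)), 1)
  d2 <- make_design(1, 2, 2, 2, 1)
  expect_equal(nrow(d2), 8)
  expect_equal(length(unique(d2$dam)), 4)
})

test_that("design invariants hold: nesting, uniqueness, balanced blocks", {
  des <- make_design(2, 5, 3, 4, 3)
  # every dam appears under exactly one sire
  expect_true(all(tapply(des$sire, des$dam, function(x) length(unique(x))) == 1))
  # every sire has exactly n_dams_per_sire dams, every dam n_offspring
  expect_true(all(tapply(des$dam, des$sire, function(x) length(unique(x))) == 3))
  expect_true(all(table(des$dam) == 4))
  expect_false(any(duplicated(des$individual)))
  # round-robin block allocation is balanced within +-1 per family
  per_family_block <- table(des$dam, des$block)
  expect_true(max(per_family_block) - min(per_family_block) <= 1)
})

test_that("non-positive design counts are rejected with the parameter named", {
  expect_error(make_design(0, 5, 3, 3, 3), "n_populations")
  expect_error(make_design(2, 5, 3, 0, 3), "n_offspring_per_dam")
  expect_error(make_design(2, 5, 3, 3, 1.5), "n_blocks")
})

test_that("degenerate variances reproduce the mean vector exactly", {
  p <- multi_params(p = 2)
  p$G[] <- 0; p$D[] <- 0; p$E[] <- 0
  tab <- simulate_phenotypes(make_design(1, 3, 2, 2, 2), p)
  expect_true(all(abs(tab$t1 - p$mu["t1"]) < 1e-12))
  expect_true(all(abs(tab$t2 - p$mu["t2"]) < 1e-12))
})

test_that("simulation is bitwise reproducible under a fixed seed", {
  des <- make_design(2, 8, 3, 3, 3)
  pars <- multi_params(seed = 42)
  t1 <- simulate_phenotypes(des, pars)
  t2 <- simulate_phenotypes(des, pars)
  expect_identical(t1, t2)
  pars2 <- multi_params(seed = 43)
  expect_false(identical(simulate_phenotypes(des, pars2), t1))
})

test_that("realized sire effects have covariance G/4 at large sire counts", {
  pars <- multi_params(p = 3, v = 1, r = 0.4, h2 = 0.4, seed = 7)
  des <- make_design(1, 500, 2, 1, 1)
  tab <- simulate_phenotypes(des, pars, keep_effects = TRUE)
  se <- attr(tab, "sire_effects")
  expect_equal(nrow(se), 500)
  emp <- cov(se)
  truth <- pars$G / 4
  # Monte-Carlo error of a covariance of n draws: sd ~ sqrt((v_ii v_jj + v_ij^2)/n)
  for (i in 1:3) for (j in 1:3) {
    se_ij <- sqrt((truth[i, i] * truth[j, j] + truth[i, j]^2) / 500)
    expect_lt(abs(emp[i, j] - truth[i, j]), 3 * se_ij)
  }
})

test_that("total phenotypic covariance converges to G/4 + D + E", {
  pars <- multi_params(p = 2, v = 2, r = 0.3, h2 = 0.5, seed = 8)
  tab <- simulate_phenotypes(make_design(1, 400, 3, 3, 1), pars)
  emp <- cov(as.matrix(tab[, c("t1", "t2")]))
  truth <- pars$G / 4 + pars$D + pars$E
  expect_true(max(abs(emp - truth)) < 0.15 * max(diag(truth)))
})

test_that("block effects shift trait means per block", {
  pars <- multi_params(p = 2)
  pars$G[] <- 0; pars$D[] <- 0; pars$E[] <- 0
  pars$block_effects <- rbind(c(1, 0), c(0, -2), c(0, 0))
  tab <- simulate_phenotypes(make_design(1, 4, 3, 3, 3), pars)
  expect_equal(as.numeric(tapply(tab$t1, tab$block, mean)),
               unname(pars$mu["t1"] + c(1, 0, 0)))
  expect_equal(as.numeric(tapply(tab$t2, tab$block, mean)),
               unname(pars$mu["t2"] + c(0, -2, 0)))
})

test_that("non-PSD or mismatched covariance inputs are rejected", {
  bad <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  ok <- diag(2)
  dimnames(bad) <- dimnames(ok) <- list(c("a", "b"), c("a", "b"))
  expect_error(sim_params(c(a = 0, b = 0), bad, ok, ok), "positive semi-definite")
  expect_error(sim_params(c(a = 0, b = 0), ok, ok, diag(3)), "dimension")
  expect_error(sim_params(c(a = 0, b = 0), ok, ok, ok, attrition_rate = 1.5),
               "rates")
})

test_that("attrition identity, total-loss and binomial-survival behaviour", {
  tab <- quick_table(1, 10, seed = 3)
  expect_identical(apply_attrition(tab, 0, 0, seed = 1), tab)
  expect_equal(nrow(apply_attrition(tab, 1, 0, seed = 1)), 0)
  big <- quick_table(6, 50, multi_params(seed = 5))  # 2700 rows
  surv <- nrow(apply_attrition(big, 0.2, 0, seed = 9))
  expect_gte(surv, qbinom(0.005, 2700, 0.8))
  expect_lte(surv, qbinom(0.995, 2700, 0.8))
})

test_that("trait masking hits roughly its per-trait rate and only survivors", {
  tab <- quick_table(2, 30, seed = 4)  # 540 rows
  out <- apply_attrition(tab, 0, c(0.3, 0, 0), seed = 5)
  expect_equal(nrow(out), nrow(tab))
  n_na <- sum(is.na(out$t1))
  expect_gte(n_na, qbinom(0.005, nrow(tab), 0.3))
  expect_lte(n_na, qbinom(0.995, nrow(tab), 0.3))
  expect_equal(sum(is.na(out$t2)), 0)
  expect_error(apply_attrition(tab, 0.5, c(0.1, 0.2), seed = 1),
               "one rate per trait")
})
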