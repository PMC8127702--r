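make_sire_fixture <- function() {
  # 3 sires x 2 offspring with hand-computable means
  data.frame(population = "P1", block = 1,
             sire = rep(c("s1", "s2", "s3"), each = 2),
             dam = rep(c("d1", "d2", "d3"), each = 2),
             individual = paste0("i", 1:6),
             t1 = c(1, 3, 5, 7, 2, 4),
             t2 = c(10, 10, 20, 30, NA, 40),
             stringsAsFactors = FALSE)
}

test_that("sire means match hand-computed values and handle missing records", {
  sm <- sire_means(make_sire_fixture())
  expect_equal(sm$t1, c(2, 6, 3))
  expect_equal(sm$t2, c(10, 25, 40))  # s3 mean over the single non-missing value
  expect_equal(sm$n, c(2L, 2L, 2L))
  # single offspring per sire: means are the offspring values
  tab1 <- make_sire_fixture()[c(1, 3, 5), ]
  expect_equal(sire_means(tab1)$t1, c(1, 5, 2))
  # duplicating rows leaves means unchanged
  sm2 <- sire_means(rbind(make_sire_fixture(), make_sire_fixture()))
  expect_equal(sm2$t1, sm$t1)
  expect_equal(sm2$n, 2L * sm$n)
  # a sire with no non-missing record keeps its row with an NA mean
  tab <- make_sire_fixture()
  tab$t2[5:6] <- NA
  expect_true(is.na(sire_means(tab)$t2[3]))
})

test_that("composite fitness: rank-1, symmetric and sign-convention cases", {
  n <- 40
  set.seed(12)
  base <- data.frame(seed_mass = rnorm(n, 2, 0.5))
  # perfectly correlated proxies -> PC1 explains 100%
  d1 <- cbind(base, inflorescence_length = 3 * base$seed_mass + 5)
  s1 <- composite_fitness(d1)
  expect_equal(attr(s1, "var_explained"), 1)
  # uncorrelated equal-variance proxies -> exactly 50%
  rho_zero <- data.frame(seed_mass = rep(c(-1, 1), 20),
                         inflorescence_length = rep(c(-1, -1, 1, 1), 10))
  s2 <- composite_fitness(rho_zero)
  expect_equal(attr(s2, "var_explained"), 0.5)
  # sign convention: score correlates positively with seed mass
  d3 <- cbind(base, inflorescence_length = 0.5 * base$seed_mass + rnorm(n, 0, 0.2))
  s3 <- composite_fitness(d3)
  expect_gt(cor(s3, d3$seed_mass), 0)
  expect_gt(cor(s3, d3$inflorescence_length), 0)
  # invariance to separate proxy rescaling (correlation-matrix PCA)
  d4 <- d3
  d4$seed_mass <- d4$seed_mass * 1000   # grams -> milligrams
  expect_equal(composite_fitness(d4), composite_fitness(d3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # degenerate proxies rejected
  d5 <- d3; d5$seed_mass <- 1
  expect_error(composite_fitness(d5), "zero variance")
})

test_that("point gradients recover an exact linear fitness surface", {
  set.seed(13)
  n <- 50
  sm <- data.frame(population = "P1", sire = paste0("s", 1:n), n = 3,
                   z1 = rnorm(n), z2 = rnorm(n), z3 = rnorm(n), z4 = rnorm(n))
  w <- 1 + 0.3 * sm$z1 - 0.2 * sm$z2
  b <- estimate_beta_point(sm, w, traits = c("z1", "z2", "z3", "z4"))
  # relativization divides by mean(w), so recovered slopes scale by 1/mean(w)
  expect_equal(unname(b$beta), c(0.3, -0.2, 0, 0) / mean(w), tolerance = 1e-10)
  # fitness-scale invariance: multiplying fitness by a constant changes nothing
  b2 <- estimate_beta_point(sm, 100 * w, traits = c("z1", "z2", "z3", "z4"))
  expect_equal(b2$beta, b$beta, tolerance = 1e-12)
})

test_that("orthogonal traits make partial coefficients simple slopes", {
  set.seed(14)
  n <- 64
  z1 <- rep(c(-1, 1), n / 2)
  z2 <- rep(c(-1, -1, 1, 1), n / 4)  # exactly orthogonal to z1
  sm <- data.frame(population = "P1", sire = paste0("s", 1:n), n = 1,
                   z1 = z1, z2 = z2)
  w <- 2 + 0.5 * z1 + 0.1 * z2 + rnorm(n, 0, 0.3)
  b <- estimate_beta_point(sm, w, traits = c("z1", "z2"))
  relw <- w / mean(w)
  expect_equal(unname(b$beta["z1"]), cov(relw, z1) / var(z1), tolerance = 1e-10)
  expect_equal(unname(b$beta["z2"]), cov(relw, z2) / var(z2), tolerance = 1e-10)
})

test_that("point gradients land within sampling error of the truth", {
  set.seed(15)
  n <- 300
  X <- matrix(rnorm(n * 4), n, 4)
  colnames(X) <- paste0("z", 1:4)
  beta_true <- c(0.15, -0.1, 0.05, 0)
  w <- 1 + X %*% beta_true + rnorm(n, 0, 0.5)
  sm <- data.frame(population = "P1", sire = paste0("s", 1:n), n = 1, X, w = c(w))
  b <- estimate_beta_point(sm, "w", traits = paste0("z", 1:4))
  se <- 0.5 / sqrt(n)  # per-coefficient OLS standard error scale
  expect_true(all(abs(b$beta * mean(w) - beta_true) < 3 * se * mean(w) + 0.02))
})

test_that("bayesian gradients: draw count, OLS agreement, consistency", {
  set.seed(16)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4)
  colnames(X) <- paste0("z", 1:4)
  w <- 1 + X %*% c(0.3, -0.2, 0.1, 0) + rnorm(n, 0, 0.4)
  sm <- data.frame(population = "P1", sire = paste0("s", 1:n), n = 1, X, w = c(w))
  bb <- estimate_beta_bayes(sm, "w", traits = paste0("z", 1:4), seed = 2)
  expect_equal(nrow(bb$draws), 10000)  # production default draw count
  bp <- estimate_beta_point(sm, "w", traits = paste0("z", 1:4))
  psd <- apply(bb$draws, 2, sd)
  expect_true(all(abs(bb$beta - bp$beta) < 2 * psd))
  # near-noiseless large-n fixture: posterior concentrates on the truth
  n2 <- 10000
  X2 <- matrix(rnorm(n2 * 2), n2, 2)
  colnames(X2) <- c("z1", "z2")
  w2 <- 1 + X2 %*% c(0.25, -0.5) + rnorm(n2, 0, 0.01)
  sm2 <- data.frame(population = "P1", sire = paste0("s", 1:n2), n = 1, X2,
                    w = c(w2))
  bb2 <- estimate_beta_bayes(sm2, "w", traits = c("z1", "z2"), n_draws = 2000,
                             seed = 3)
  expect_equal(unname(bb2$beta * mean(w2)), c(0.25, -0.5), tolerance = 0.01)
  expect_lt(max(apply(bb2$draws, 2, sd)), 0.005)
})

test_that("gradient preconditions and collinearity warnings", {
  sm <- data.frame(population = "P1", sire = paste0("s", 1:5), n = 1,
                   z1 = rnorm(5), z2 = rnorm(5), z3 = rnorm(5), z4 = rnorm(5))
  expect_error(estimate_beta_point(sm, rnorm(5), traits = paste0("z", 1:4)),
               "more sires")
  set.seed(17)
  n <- 30
  smc <- data.frame(population = "P1", sire = paste0("s", 1:n), n = 1,
                    z1 = rnorm(n))
  smc$z2 <- smc$z1 + rnorm(n, 0, 1e-9)  # nearly collinear
  expect_warning(estimate_beta_point(smc, rnorm(n, 2), traits = c("z1", "z2")),
                 "collinear")
})

test_that("paired posterior responses enforce matching draw counts", {
  set.seed(18)
  arr <- array(vapply(1:50, function(i) random_pd(2, seed = i),
                      matrix(0, 2, 2)), c(2, 2, 50))
  bdraws <- matrix(rnorm(100), 50, 2)
  bobj <- structure(list(beta = colMeans(bdraws), mode = "posterior",
                         draws = bdraws, fitness_metric = "composite"),
                    class = "selection_gradient")
  r <- predict_response(arr, bobj)
  expect_equal(nrow(r$draws), 50)
  # mismatched counts rejected
  bobj$draws <- bdraws[1:20, ]
  expect_error(predict_response(arr, bobj), "paired")
  expect_error(r_metric(arr, bobj), "paired")
})
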