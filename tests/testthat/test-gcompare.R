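test_that("identical G matrices drive H eigenvalues to the population count", {
  A <- random_pd(6, seed = 1)
  Gs <- setNames(replicate(6, A, simplify = FALSE), paste0("P", 1:6))
  res <- krzanowski_subspace(Gs)  # default k = 3 for six traits
  expect_equal(res$k, 3)
  expect_equal(res$eig_mean, c(6, 6, 6, 0, 0, 0), tolerance = 1e-10)
})

test_that("orthogonal leading eigenvectors give unit H eigenvalues", {
  res <- krzanowski_subspace(list(a = diag(c(2, 0.5)), b = diag(c(0.5, 2))),
                             k = 1)
  expect_equal(res$eig_mean, c(1, 1), tolerance = 1e-12)
})

test_that("H eigenvalues are bounded by [0, n_populations] for random inputs", {
  for (s in 1:8) {
    p <- sample(3:6, 1)
    npop <- sample(2:5, 1)
    Gs <- lapply(seq_len(npop), function(i) random_pd(p, seed = 100 * s + i))
    res <- krzanowski_subspace(Gs, k = sample(seq_len(p %/% 2 + 1), 1))
    expect_true(all(res$eig_mean >= -1e-10))
    expect_true(all(res$eig_mean <= npop + 1e-10))
  }
})

test_that("krzanowski rejects bad k and too few populations", {
  A <- random_pd(4, seed = 2)
  expect_error(krzanowski_subspace(list(A), k = 2), "at least 2")
  expect_error(krzanowski_subspace(list(a = A, b = A), k = 0), "'k'")
  expect_error(krzanowski_subspace(list(a = A, b = A), k = 5), "'k'")
})

test_that("krzanowski dual criterion needs both the bound and the null", {
  # two populations sharing a subspace -> eigenvalue at p, never diverged
  A <- random_pd(4, seed = 3)
  Gs <- list(a = A, b = A)
  null_sets <- lapply(1:25, function(i)
    list(a = random_pd(4, seed = 300 + i), b = random_pd(4, seed = 600 + i)))
  res <- krzanowski_subspace(Gs, k = 2, null_G = null_sets)
  expect_false(any(res$diverged[1:2]))
})

test_that("identical matrices yield a zero tensor handled as no-variation", {
  A <- random_pd(5, seed = 4)
  res <- covariance_tensor(setNames(replicate(3, A, simplify = FALSE),
                                    c("x", "y", "z")))
  expect_true(res$no_variation)
  expect_equal(unname(res$alpha_mean), rep(0, 15))
  expect_equal(max(abs(res$S_mean)), 0)
})

test_that("tensor alphas are non-negative and sum to one when variation exists", {
  for (s in 1:5) {
    Gs <- lapply(1:4, function(i) random_pd(4, seed = 40 * s + i))
    res <- covariance_tensor(Gs)
    expect_true(all(res$alpha_mean >= -1e-12))
    expect_equal(sum(res$alpha_mean), 1, tolerance = 1e-10)
  }
})

test_that("eigentensors are orthonormal under the Frobenius inner product", {
  Gs <- lapply(1:3, function(i) random_pd(5, seed = 70 + i))
  res <- covariance_tensor(Gs)
  m <- dim(res$eigentensors)[3]
  for (i in seq_len(m)) for (j in seq_len(m)) {
    ip <- sum(res$eigentensors[, , i] * res$eigentensors[, , j])
    expect_equal(ip, as.numeric(i == j), tolerance = 1e-8)
  }
})

test_that("population coordinates on each eigentensor sum to zero", {
  Gs <- lapply(1:5, function(i) random_pd(4, seed = 90 + i))
  res <- covariance_tensor(Gs)
  expect_true(all(abs(colSums(res$coordinates)) < 1e-8))
})

test_that("a single diverging variance loads the leading eigentensor on it", {
  A <- random_pd(6, seed = 5)
  B <- A
  B[1, 1] <- B[1, 1] + 10
  res <- covariance_tensor(list(a = A, b = B))
  expect_equal(res$alpha_mean[1], 1, tolerance = 1e-10)
  lead <- res$tensor_eigen[[1]]$vectors[, 1]
  expect_gt(abs(lead[1]), 0.999)
  expect_gt(res$tensor_eigen[[1]]$variance_share[1], 0.999)
})

test_that("tensor rejects a single population", {
  expect_error(covariance_tensor(list(a = random_pd(3, 1))), "at least 2")
})

test_that("breeder's equation: hand-computed responses and linearity", {
  G <- matrix(c(1, 0.5, 0.5, 2), 2)
  expect_equal(unname(predict_response(G, c(0.1, -0.2))$mean), c(0, -0.35))
  expect_equal(unname(predict_response(G, c(0, 0))$mean), c(0, 0))
  Gd <- diag(c(2, 3, 4))
  b <- c(0.1, 0.2, -0.3)
  expect_equal(unname(predict_response(Gd, b)$mean), diag(Gd) * b)
  # linearity in beta, per draw
  arr <- array(c(G, 2 * G), c(2, 2, 2))
  b1 <- c(1, 0); b2 <- c(-0.5, 2)
  expect_equal(predict_response(arr, b1 + b2)$draws,
               predict_response(arr, b1)$draws + predict_response(arr, b2)$draws)
})

test_that("responses come back in SD units when a record is present", {
  G <- diag(c(4, 9))
  r <- predict_response(G, c(1, 1), sds = c(2, 3))
  expect_equal(unname(r$mean_sd_units), c(2, 3))
  expect_error(predict_response(G, c(1, 2, 3)), "dimension")
})

test_that("R metric: exact values, exclusion, and invariances", {
  G <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(r_metric(G, c(1, 1))$mean, 1.5)
  expect_equal(r_metric(G, c(1, -1))$mean, 0.5)
  # any diagonal G gives exactly 1 under any nonzero beta
  for (s in 1:5) {
    set.seed(s)
    Gd <- diag(runif(4, 0.1, 5))
    b <- rnorm(4)
    expect_equal(r_metric(Gd, b)$mean, 1)
  }
  # invariance to positive rescaling of beta and of G
  A <- random_pd(3, seed = 6)
  b <- c(1, -2, 0.5)
  expect_equal(r_metric(A, b)$mean, r_metric(A, 7 * b)$mean, tolerance = 1e-12)
  expect_equal(r_metric(A, b)$mean, r_metric(3 * A, b)$mean, tolerance = 1e-12)
  # zero-diagonal draws are excluded with a count
  arr <- array(c(A, matrix(0, 3, 3)), c(3, 3, 2))
  res <- r_metric(arr, b)
  expect_equal(res$n_excluded, 1)
  expect_length(res$draws, 1)
})

test_that("random skewers: identity, scale invariance, anticorrelated oracle", {
  A <- random_pd(4, seed = 7)
  res <- random_skewers(list(a = A, b = A, c = 2.5 * A), n_skewers = 200,
                        seed = 1)
  expect_equal(res$pairs$correlation, rep(1, 3), tolerance = 1e-12)
  expect_equal(res$pairs$angle_deg, rep(0, 3), tolerance = 1e-5)
  # Monte-Carlo oracle (1e6 skewers + quadrature): mean correlation 0.0675,
  # mean angle 85.9 degrees for diag(1,100) vs diag(100,1)
  res2 <- random_skewers(list(a = diag(c(1, 100)), b = diag(c(100, 1))),
                         n_skewers = 20000, seed = 2)
  expect_equal(res2$pairs$correlation, 0.0675, tolerance = 0.1)
  expect_equal(res2$pairs$angle_deg, 85.9, tolerance = 0.01)
  expect_identical(res2$pairs,
                   random_skewers(list(a = diag(c(1, 100)), b = diag(c(100, 1))),
                                  n_skewers = 20000, seed = 2)$pairs)
})

test_that("skewers in draws mode give per-pair posteriors with HPDs", {
  set.seed(11)
  arr1 <- array(vapply(1:30, function(i) random_pd(3, seed = i),
                       matrix(0, 3, 3)), c(3, 3, 30))
  arr2 <- array(vapply(31:60, function(i) random_pd(3, seed = i),
                       matrix(0, 3, 3)), c(3, 3, 30))
  res <- random_skewers(list(a = arr1, b = arr2), n_skewers = 50, seed = 3,
                        summary = "draws")
  expect_equal(nrow(res$draws), 30)
  expect_true(all(res$pairs$correlation >= -1 & res$pairs$correlation <= 1))
  expect_true(all(res$pairs$angle_deg >= 0 & res$pairs$angle_deg <= 180))
  expect_true(res$pairs$hpd_low <= res$pairs$hpd_high)
})
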