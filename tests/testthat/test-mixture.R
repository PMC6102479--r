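three_gaussian_sample <- function(n = 10000, seed = 1) {
  simulate_dscore_sample("gaussian", weights = c(0.7, 0.2, 0.1),
                         params = list(c(0.05, 0.02), c(0.25, 0.02),
                                       c(0.45, 0.02)),
                         n = n, seed = seed)
}

test_that("k-means separates trivially separable values", {
  km <- kmeans_1d(c(0, 0, 0, 10, 10, 10), k = 2, seed = 1)
  expect_equal(km$means, c(0, 10))
  expect_equal(km$wcss, 0)
  expect_equal(km$assignments, c(1, 1, 1, 2, 2, 2))
})

test_that("k-means recovers well-separated blob centers", {
  set.seed(30)
  x <- c(rnorm(300, 0, 0.01), rnorm(300, 1, 0.01), rnorm(300, 2, 0.01))
  km <- kmeans_1d(x, k = 3, seed = 2)
  expect_equal(km$means, c(0, 1, 2), tolerance = 0.05)
})

test_that("k-means is deterministic for a fixed seed and rejects degenerate input", {
  x <- three_gaussian_sample(500, seed = 3)
  a <- kmeans_1d(x, k = 3, seed = 5)
  b <- kmeans_1d(x, k = 3, seed = 5)
  expect_identical(a$assignments, b$assignments)
  expect_error(kmeans_1d(c(1, 1, 2, 2), k = 3), "degenerate")
})

test_that("single-component EM reduces to the closed-form MLE", {
  set.seed(31)
  x <- rnorm(2000, 0.3, 0.05)
  fit <- em_gaussian(x, rep(1L, length(x)))
  expect_equal(fit$k, 1)
  expect_equal(fit$weights, 1)
  expect_equal(fit$params[[1]][["mean"]], mean(x), tolerance = 1e-8)
  # biased MLE variance, 1/N denominator
  expect_equal(fit$params[[1]][["var"]], sum((x - mean(x))^2) / length(x),
               tolerance = 1e-8)
})

test_that("EM recovers the three-component gaussian benchmark", {
  x <- three_gaussian_sample()
  init <- kmeans_1d(x, k = 3, seed = 1)
  fit <- em_gaussian(x, init$assignments)
  mu <- vapply(fit$params, `[[`, 0, "mean")
  expect_equal(mu, c(0.05, 0.25, 0.45), tolerance = 0.01)
  expect_equal(fit$weights, c(0.7, 0.2, 0.1), tolerance = 0.02)
  expect_true(fit$converged)
})

test_that("gaussian EM log-likelihood is monotone and posteriors normalized", {
  x <- three_gaussian_sample(3000, seed = 4)
  init <- kmeans_1d(x, k = 3, seed = 1)
  fit <- em_gaussian(x, init$assignments)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  expect_equal(rowSums(fit$responsibilities), rep(1, length(x)),
               tolerance = 1e-9)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
})

test_that("benchmark recovery succeeds across random restarts", {
  ok <- vapply(1:20, function(s) {
    x <- three_gaussian_sample(4000, seed = s)
    init <- kmeans_1d(x, k = 3, seed = s)
    fit <- em_gaussian(x, init$assignments)
    mu <- vapply(fit$params, `[[`, 0, "mean")
    all(abs(mu - c(0.05, 0.25, 0.45)) <= 0.01)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("gamma EM recovers single- and two-component parameters", {
  x <- simulate_dscore_sample("gamma", weights = 1,
                              params = list(c(4, 0.05)), n = 10000, seed = 5)
  fit <- em_gamma(x, rep(1L, length(x)))
  expect_equal(fit$params[[1]][["shape"]], 4, tolerance = 0.3)

  x2 <- simulate_dscore_sample("gamma", weights = c(0.6, 0.4),
                               params = list(c(5, 0.01), c(80, 0.005)),
                               n = 8000, seed = 6)
  init <- kmeans_1d(x2, k = 2, seed = 1)
  fit2 <- em_gamma(x2, init$assignments)
  expect_equal(fit2$weights, c(0.6, 0.4), tolerance = 0.03)
  expect_true(all(diff(fit2$loglik_trace) >= -1e-6 * abs(fit2$loglik)))
  expect_error(em_gamma(c(-1, 1, 2), rep(1L, 3)), "positive")
})

test_that("BIC formula, penalty monotonicity, and overfit detection", {
  fit <- list(k = 2, n = 100, loglik = -50)
  class(fit) <- "mixture_model"
  expect_equal(mixture_bic(fit), (3 * 2 - 1) * log(100) + 100)
  expect_equal(mixture_bic(fit, mode = "legacy"),
               -2 * 2 * log(100) + 100)
  fit3 <- fit
  fit3$k <- 3
  expect_gt(mixture_bic(fit3), mixture_bic(fit))  # same loglik, more k
  # an overfitted k = 6 model scores worse than k = 3 on 3-component data
  x <- three_gaussian_sample(4000, seed = 7)
  f3 <- em_gaussian(x, kmeans_1d(x, k = 3, seed = 1)$assignments)
  f6 <- suppressWarnings(
    em_gaussian(x, kmeans_1d(x, k = 6, seed = 1)$assignments))
  expect_gt(mixture_bic(f6), mixture_bic(f3))
})

test_that("family selection follows the data-generating distribution", {
  x <- three_gaussian_sample(5000, seed = 8)
  init <- kmeans_1d(x, k = 3, seed = 1)
  g <- em_gaussian(x, init$assignments)
  gm <- em_gamma(pmax(x, 1e-6), init$assignments)
  expect_equal(select_best_mixture(list(g, gm))$family, "gaussian")

  xg <- simulate_dscore_sample("gamma", weights = c(0.5, 0.3, 0.2),
                               params = list(c(1.2, 0.02), c(30, 0.005),
                                             c(200, 0.002)),
                               n = 5000, seed = 9)
  initg <- kmeans_1d(xg, k = 3, seed = 1)
  g2 <- em_gaussian(xg, initg$assignments)
  gm2 <- em_gamma(xg, initg$assignments)
  expect_equal(select_best_mixture(list(g2, gm2))$family, "gamma")

  expect_identical(select_best_mixture(list(g)), g)
  expect_error(select_best_mixture(list()), "failed")
})
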