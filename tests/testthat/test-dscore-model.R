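# Closed-form oracles for the penalized regression: OLS at zero penalty,
# soft-thresholding on orthonormal designs for the pure-L1 limit, and the
# ridge normal equations for the pure-L2 limit.

make_design <- function(n = 60, p = 3, seed = 20, beta = c(0.3, 0.2, 0.1),
                        noise = 0.02, orthonormal = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(X, 2, colMeans(X))
  if (orthonormal) X <- qr.Q(qr(X))
  colnames(X) <- paste0("D", seq_len(p))
  y <- 0.1 + X %*% beta + rnorm(n, sd = noise)
  list(X = X, y = as.numeric(y))
}

enet_objective <- function(X, y, intercept, beta, lambda1, lambda2) {
  r <- y - intercept - X %*% beta
  sum(r^2) + lambda2 * sum(beta^2) + lambda1 * sum(abs(beta))
}

test_that("zero penalty reproduces ordinary least squares", {
  d <- make_design()
  fit <- fit_elastic_net(d$X, d$y, alpha = 0.5, lambda_total = 0)
  ols <- stats::lm.fit(cbind(1, d$X), d$y)$coefficients
  expect_equal(unname(fit$coefficients), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-6)
})

test_that("pure L1 on an orthonormal design soft-thresholds the OLS solution", {
  d <- make_design(orthonormal = TRUE, beta = c(0.4, 0.05, -0.2))
  lam <- 0.3
  fit <- fit_elastic_net(d$X, d$y, alpha = 0, lambda_total = lam)
  yc <- d$y - mean(d$y)
  z <- as.numeric(crossprod(d$X, yc))  # OLS coefficients (X'X = I)
  expected <- sign(z) * pmax(abs(z) - lam / 2, 0)
  expect_equal(unname(fit$coefficients), expected, tolerance = 1e-6)
})

test_that("pure L2 matches the ridge normal equations", {
  d <- make_design()
  lam <- 0.7
  fit <- fit_elastic_net(d$X, d$y, alpha = 1, lambda_total = lam)
  yc <- d$y - mean(d$y)
  ridge <- solve(crossprod(d$X) + lam * diag(ncol(d$X)),
                 crossprod(d$X, yc))
  expect_equal(unname(fit$coefficients), as.numeric(ridge),
               tolerance = 1e-6)
})

test_that("the mixed penalty agrees with glmnet under its parameterization", {
  skip_if_not_installed("glmnet")
  d <- make_design(n = 200, noise = 0.05)
  n <- nrow(d$X)
  lambda_total <- 0.8
  alpha <- 0.5  # L2 fraction in this package's convention
  lambda2 <- alpha * lambda_total
  lambda1 <- (1 - alpha) * lambda_total
  fit <- fit_elastic_net(d$X, d$y, alpha = alpha,
                         lambda_total = lambda_total)
  # glmnet standardizes y internally, which rescales its ridge (but not its
  # lasso) penalty by 1/sd(y); map both penalty weights accordingly
  s <- sqrt(mean((d$y - mean(d$y))^2))
  lam_g <- lambda1 / (2 * n) + s * lambda2 / n
  a_g <- (lambda1 / (2 * n)) / lam_g
  g <- glmnet::glmnet(d$X, d$y, alpha = a_g, lambda = lam_g,
                      standardize = FALSE, thresh = 1e-16)
  expect_equal(unname(fit$coefficients),
               as.numeric(g$beta), tolerance = 1e-6)
})

test_that("the fitted solution is single-coordinate locally optimal", {
  d <- make_design(noise = 0.1)
  fit <- fit_elastic_net(d$X, d$y, alpha = 0.5, lambda_total = 0.5)
  base <- enet_objective(d$X, d$y, fit$intercept, fit$coefficients,
                         fit$lambda1, fit$lambda2)
  for (j in seq_along(fit$coefficients)) {
    for (eps in c(-1e-4, 1e-4)) {
      b <- fit$coefficients
      b[j] <- b[j] + eps
      expect_gte(enet_objective(d$X, d$y, fit$intercept, b,
                                fit$lambda1, fit$lambda2), base - 1e-10)
    }
  }
})

test_that("the L1 norm of the solution shrinks as lambda1 grows", {
  d <- make_design(noise = 0.1)
  lambda2 <- 0.2
  l1_grid <- c(0, 0.05, 0.2, 0.5, 1, 2, 5)
  norms <- vapply(l1_grid, function(l1) {
    tot <- l1 + lambda2
    fit <- fit_elastic_net(d$X, d$y, alpha = lambda2 / tot,
                           lambda_total = tot)
    sum(abs(fit$coefficients))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("perfectly collinear features are grouped, not arbitrarily dropped", {
  set.seed(21)
  n <- 80
  x <- rnorm(n)
  X <- cbind(a = x, b = x, c = rnorm(n))
  y <- 0.5 * x + rnorm(n, sd = 0.05)
  fit <- fit_elastic_net(X, y, alpha = 0.5, lambda_total = 0.5)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["a"]] - fit$coefficients[["b"]]), 1e-4)
  expect_gt(fit$coefficients[["a"]], 0)
})

test_that("cross-validation picks small penalties for clean signal", {
  set.seed(22)
  X <- matrix(rnorm(300), 100, 3)
  y <- as.numeric(X %*% c(0.4, 0.3, 0.2))  # exactly linear, no noise
  lam <- select_lambda(X, y, alpha = 0.5, seed = 7)
  grid <- attr(lam, "grid")
  expect_lte(as.numeric(lam), grid[length(grid) - 2])
  expect_lt(min(attr(lam, "cv_error")), 1e-4)
})

test_that("cross-validation pushes pure noise to the heavy end of the grid", {
  set.seed(23)
  X <- matrix(rnorm(300), 100, 3)
  y <- rnorm(100)
  lam <- select_lambda(X, y, alpha = 0.5, seed = 7)
  grid <- attr(lam, "grid")
  expect_gte(as.numeric(lam), grid[2])  # within one grid step of lambda_max
})

test_that("penalty selection is deterministic under a fixed seed", {
  d <- make_design(noise = 0.1)
  l1 <- select_lambda(d$X, d$y, seed = 11)
  l2 <- select_lambda(d$X, d$y, seed = 11)
  expect_identical(as.numeric(l1), as.numeric(l2))
  expect_error(select_lambda(d$X[1:3, ], d$y[1:3], n_folds = 5),
               "at least")
})

test_that("D-score predictions are floored fitted values", {
  d <- make_design(noise = 0.02)
  fit <- fit_elastic_net(d$X, d$y, lambda_total = 0)
  # training residuals average zero at lambda = 0
  pred_raw <- fit$intercept + d$X %*% fit$coefficients
  expect_equal(mean(d$y - pred_raw), 0, tolerance = 1e-10)
  # flooring
  fit0 <- fit
  fit0$intercept <- 0
  expect_equal(predict_dscores(fit0, matrix(0, 1, 3,
                                            dimnames = list(NULL, colnames(d$X)))), 0)
  neg <- matrix(c(-10, -10, -10), 1, dimnames = list(NULL, colnames(d$X)))
  expect_equal(predict_dscores(fit, neg), 0)
  # with all-positive coefficients the maximal feature row scores highest
  expect_true(all(fit$coefficients > 0))
  scores <- predict_dscores(fit, d$X)
  top <- matrix(apply(d$X, 2, max), 1, dimnames = list(NULL, colnames(d$X)))
  expect_gte(predict_dscores(fit, top), max(scores))
  # column mismatch is an error
  bad <- d$X[, c(2, 1, 3)]
  expect_error(predict_dscores(fit, bad), "column")
})

test_that("coefficient report flags exact zeros and keeps signs", {
  set.seed(24)
  M <- matrix(rnorm(180), 60, 3)
  X <- qr.Q(qr(sweep(M, 2, colMeans(M))))
  colnames(X) <- c("D1", "D2", "D3")
  y <- as.numeric(X %*% c(0.5, 0.01, 0.4)) + rnorm(60, sd = 0.01)
  lasso <- fit_elastic_net(X, y, alpha = 0, lambda_total = 0.2)
  rep_l <- coefficient_report(lasso)
  expect_true(rep_l$zeroed[rep_l$term == "D2"])  # weak feature dropped
  expect_false(any(rep_l$zeroed[rep_l$term %in% c("D1", "D3")]))
  ridge <- fit_elastic_net(X, y, alpha = 1, lambda_total = 0.2)
  rep_r <- coefficient_report(ridge)
  expect_false(any(rep_r$zeroed[-1]))  # L2 never zeroes exactly
  expect_true(all(rep_r$coefficient[rep_r$term %in% c("D1", "D3")] > 0))
})
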