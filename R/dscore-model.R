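# Elastic-net regression of D4 on the normalized features, and the D-score
# (the model's fitted value, floored at 0).
#
# Objective (no 1/n scaling):
#   L(lambda1, lambda2, beta) = ||y - Xb||^2 + lambda2 ||b||_2^2
#                                            + lambda1 ||b||_1
# with an unpenalized intercept. The mixing parameter `alpha` is the L2
# FRACTION: lambda2 = alpha * lambda_total, lambda1 = (1 - alpha) *
# lambda_total, so alpha = 1 is ridge and alpha = 0 is the lasso. NOTE this
# is the REVERSE of glmnet's alpha convention.

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Fit an elastic-net regression by cyclic coordinate descent
#'
#' Minimizes `||y - Xb||^2 + lambda2 ||b||^2 + lambda1 |b|_1` with
#' `lambda2 = alpha * lambda_total` and `lambda1 = (1 - alpha) *
#' lambda_total`; the intercept is unpenalized. `alpha` is the L2 mixing
#' fraction (`alpha = 1` is ridge, `alpha = 0` the lasso) — note this is the
#' reverse of the glmnet convention.
#'
#' @param X Numeric n x p design matrix (already normalized; no intercept
#'   column).
#' @param y Numeric response vector of length n.
#' @param alpha L2 fraction of the penalty, in `[0, 1]` (default 0.5).
#' @param lambda_total Total penalty weight `lambda1 + lambda2 >= 0`.
#' @param tol Relative convergence tolerance on the coefficient updates
#'   (default 1e-7).
#' @param max_iter Maximum coordinate-descent sweeps (default 1e5).
#' @param init Optional warm-start coefficient vector of length `ncol(X)`.
#' @return An object of class `enet_fit`: list with `intercept`,
#'   `coefficients` (named), `alpha`, `lambda_total`, `lambda1`, `lambda2`,
#'   `n`, `iterations`, `converged`.
#' @export
fit_elastic_net <- function(X, y, alpha = 0.5, lambda_total = 0,
                            tol = 1e-7, max_iter = 1e5, init = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("X and y must be finite", call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)", call. = FALSE)
  if (nrow(X) < ncol(X)) stop("need n >= p", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (lambda_total < 0) stop("lambda_total must be >= 0", call. = FALSE)
  lambda2 <- alpha * lambda_total
  lambda1 <- (1 - alpha) * lambda_total
  p <- ncol(X)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  xtx <- colSums(Xc^2)
  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
  stopifnot(length(beta) == p)
  r <- yc - as.numeric(Xc %*% beta)  # residual yc - Xc %*% beta
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    delta_max <- 0
    scale_max <- 0
    for (j in seq_len(p)) {
      if (xtx[j] == 0) next  # constant column: coefficient stays 0
      zj <- sum(Xc[, j] * r) + xtx[j] * beta[j]
      bj <- soft_threshold(zj, lambda1 / 2) / (xtx[j] + lambda2)
      d <- bj - beta[j]
      if (d != 0) {
        r <- r - Xc[, j] * d
        beta[j] <- bj
      }
      delta_max <- max(delta_max, abs(d))
      scale_max <- max(scale_max, abs(bj))
    }
    if (delta_max <= tol * max(scale_max, 1)) {
      converged <- TRUE
      break
    }
  }
  intercept <- ym - sum(xm * beta)
  names(beta) <- colnames(X) %||% paste0("x", seq_len(p))
  structure(list(intercept = intercept, coefficients = beta, alpha = alpha,
                 lambda_total = lambda_total, lambda1 = lambda1,
                 lambda2 = lambda2, n = nrow(X), iterations = iter,
                 converged = converged),
            class = "enet_fit")
}

# Smallest lambda_total at which every coefficient is zero at this alpha.
lambda_max_total <- function(X, y, alpha) {
  Xc <- sweep(as.matrix(X), 2, colMeans(X))
  yc <- y - mean(y)
  zmax <- max(abs(crossprod(Xc, yc)))
  # all-zero solution needs |x_j' y_c| <= lambda1 / 2 for all j
  2 * zmax / max(1 - alpha, 1e-3)
}

#' Select the penalty weight by cross-validation
#'
#' Picks `lambda_total` minimizing the mean cross-validated squared
#' prediction error over a 50-point logarithmic grid running from the
#' smallest all-zeroing penalty down four decades. Fold assignment is seeded
#' and reproducible.
#'
#' @param X,y Design matrix and response as in [fit_elastic_net()].
#' @param alpha L2 fraction (default 0.5).
#' @param n_folds Number of CV folds (default 5, minimum 2).
#' @param seed Integer seed for the fold shuffle.
#' @param n_grid Grid resolution (default 50).
#' @return Selected `lambda_total` (scalar), with the grid and CV errors in
#'   attributes `grid` and `cv_error`.
#' @export
select_lambda <- function(X, y, alpha = 0.5, n_folds = 5L, seed = 1L,
                          n_grid = 50L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  if (n < n_folds) stop("need at least n_folds observations", call. = FALSE)
  lam_max <- lambda_max_total(X, y, alpha)
  if (lam_max <= 0) lam_max <- 1e-8
  grid <- exp(seq(log(lam_max), log(lam_max * 1e-4), length.out = n_grid))
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  # grid descends from lambda_max; warm-start each fit from the previous
  # (larger) penalty's solution, as is standard for penalty paths
  err_mat <- vapply(seq_len(n_folds), function(f) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[!tr, , drop = FALSE]
    beta <- NULL
    vapply(grid, function(lam) {
      fit <- fit_elastic_net(Xtr, y[tr], alpha = alpha, lambda_total = lam,
                             init = beta)
      beta <<- fit$coefficients
      pred <- fit$intercept + Xte %*% fit$coefficients
      mean((y[!tr] - pred)^2)
    }, numeric(1))
  }, numeric(n_grid))
  cv_err <- rowMeans(err_mat)
  best <- grid[which.min(cv_err)]
  attr(best, "grid") <- grid
  attr(best, "cv_error") <- cv_err
  best
}

#' Predict per-gene D-scores
#'
#' The D-score is the fitted value of the elastic-net regression, floored at
#' 0 (it is an uncertainty magnitude). Higher D-scores mean less reliable
#' expression estimates.
#'
#' @param model An `enet_fit` from [fit_elastic_net()].
#' @param X Feature matrix with the training column order and normalization.
#' @return Numeric vector of nonnegative D-scores.
#' @export
predict_dscores <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$coefficients)) {
    stop("feature matrix has ", ncol(X), " columns; model expects ",
         length(model$coefficients), call. = FALSE)
  }
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), names(model$coefficients))) {
    stop("feature columns do not match the training order: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }
  pmax(as.numeric(model$intercept + X %*% model$coefficients), 0)
}

#' Coefficient report for a fitted elastic net
#'
#' @param model An `enet_fit`.
#' @return A `data.frame` with one row per feature plus the intercept:
#'   `term`, `coefficient`, `sign`, `zeroed` (TRUE when shrunk exactly to
#'   zero; always FALSE for the intercept).
#' @export
coefficient_report <- function(model) {
  stopifnot(inherits(model, "enet_fit"))
  co <- c("(Intercept)" = model$intercept, model$coefficients)
  data.frame(term = names(co), coefficient = unname(co),
             sign = ifelse(co > 0, "+", ifelse(co < 0, "-", "0")),
             zeroed = c(FALSE, unname(model$coefficients) == 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.enet_fit <- function(x, ...) {
  cat("Elastic-net fit (alpha = L2 fraction = ", x$alpha,
      ", lambda_total = ", signif(x$lambda_total, 4), ")\n", sep = "")
  cat("  n =", x$n, "| sweeps =", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(c("(Intercept)" = x$intercept, x$coefficients))
  invisible(x)
}
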