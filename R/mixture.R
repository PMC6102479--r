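# Mixture modeling of the D-score distribution: k-means initialization, EM
# for Gaussian and Gamma component families, BIC model selection.

#' One-dimensional k-means with random restarts
#'
#' Clusters a numeric vector into `k` groups by Lloyd iteration from
#' `restarts` random initial groupings, keeping the solution with the lowest
#' within-cluster sum of squares. Seeded and deterministic.
#'
#' @param values Numeric vector with at least `k` distinct values.
#' @param k Number of clusters (default 3).
#' @param seed Integer seed (default 1).
#' @param restarts Number of random initializations (default 10).
#' @return List with `assignments` (integer vector, clusters relabeled in
#'   order of increasing mean), `means` (ascending), `wcss`.
#' @export
kmeans_1d <- function(values, k = 3L, seed = 1L, restarts = 10L) {
  values <- as.numeric(values)
  if (length(unique(values)) < k) {
    stop("degenerate sample: fewer than k distinct values", call. = FALSE)
  }
  km <- with_seed(seed,
                  suppressWarnings(stats::kmeans(values, centers = k,
                                                 nstart = restarts)))
  ord <- order(km$centers[, 1])
  relabel <- match(seq_len(k), ord)
  list(assignments = relabel[km$cluster],
       means = as.numeric(km$centers[ord, 1]),
       wcss = km$tot.withinss)
}

# Shared EM driver. dens_fn(x, par) -> density; mstep_fn(x, resp_k) -> par
# for one component from responsibility weights; init_fn(x_k) -> par from a
# hard cluster. `par` is a named numeric vector.
em_fit <- function(values, init, family, dens_fn, init_fn, mstep_fn,
                   sort_key, tol = 1e-6, max_iter = 500L) {
  x <- as.numeric(values)
  n <- length(x)
  ks <- sort(unique(init))
  params <- lapply(ks, function(kk) init_fn(x[init == kk]))
  weights <- vapply(ks, function(kk) sum(init == kk) / n, numeric(1))
  k <- length(params)
  loglik_trace <- numeric(0)
  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  resp <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    # E step (log space for stability)
    logd <- vapply(seq_len(k),
                   function(j) log(weights[j]) + dens_fn(x, params[[j]],
                                                         log = TRUE),
                   numeric(n))
    logd <- matrix(logd, nrow = n)
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    resp <- exp(logd - lse)
    new_loglik <- sum(lse)
    loglik_trace <- c(loglik_trace, new_loglik)
    if (is.finite(loglik) &&
        abs(new_loglik - loglik) <= tol * (abs(loglik) + tol)) {
      loglik <- new_loglik
      converged <- TRUE
      break
    }
    loglik <- new_loglik
    # M step
    weights <- colMeans(resp)
    # prune collapsed components
    keep <- weights >= 1 / (10 * n)
    if (!all(keep)) {
      warning("pruning ", sum(!keep), " collapsed mixture component(s)",
              call. = FALSE)
      resp <- resp[, keep, drop = FALSE]
      resp <- resp / rowSums(resp)
      weights <- colMeans(resp)
      params <- params[keep]
      k <- length(params)
    }
    params <- lapply(seq_len(k), function(j) mstep_fn(x, resp[, j]))
  }
  ord <- order(vapply(params, sort_key, numeric(1)))
  structure(list(family = family, k = k, weights = weights[ord],
                 params = params[ord], loglik = loglik,
                 loglik_trace = loglik_trace, n = n, converged = converged,
                 iterations = iter,
                 responsibilities = resp[, ord, drop = FALSE]),
            class = "mixture_model")
}

#' Fit a Gaussian mixture by EM
#'
#' Expectation-maximization for a mixture of normals, initialized from hard
#' cluster assignments (typically [kmeans_1d()]). Initial and M-step
#' estimates use maximum likelihood with biased (1/N_k) variance
#' denominators. Variances are floored at 1e-10; components whose weight
#' collapses below `1/(10n)` are pruned with a warning.
#'
#' @param values Numeric data vector.
#' @param init Integer cluster assignments of the same length.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @return A `mixture_model` object: `family`, `k`, `weights`, `params`
#'   (per component `c(mean, var)`), `loglik`, `loglik_trace`, `bic` fields
#'   via [mixture_bic()], `n`, `converged`, `iterations`. Components are
#'   sorted by mean, ascending.
#' @export
em_gaussian <- function(values, init, tol = 1e-6, max_iter = 500L) {
  stopifnot(length(values) == length(init))
  fit <- em_fit(
    values, init, family = "gaussian",
    dens_fn = function(x, par, log = FALSE)
      stats::dnorm(x, par[["mean"]], sqrt(par[["var"]]), log = log),
    init_fn = function(xk) {
      v <- max(sum((xk - mean(xk))^2) / length(xk), 1e-10)
      c(mean = mean(xk), var = v)
    },
    mstep_fn = function(x, r) {
      w <- sum(r)
      mu <- sum(r * x) / w
      v <- max(sum(r * (x - mu)^2) / w, 1e-10)
      c(mean = mu, var = v)
    },
    sort_key = function(par) par[["mean"]],
    tol = tol, max_iter = max_iter)
  fit$bic <- mixture_bic(fit)
  fit
}

#' Fit a Gamma mixture by EM
#'
#' Same E/M alternation as [em_gaussian()] with gamma component densities.
#' The M step uses responsibility-weighted method of moments: from weighted
#' mean m and variance v, `shape = m^2/v`, `scale = v/m`. All data must be
#' strictly positive (callers clip at a small floor).
#'
#' @inheritParams em_gaussian
#' @return A `mixture_model` with per-component parameters
#'   `c(shape, scale)`, components sorted by mean (`shape * scale`).
#' @export
em_gamma <- function(values, init, tol = 1e-6, max_iter = 500L) {
  stopifnot(length(values) == length(init))
  if (any(values <= 0)) {
    stop("gamma mixture requires strictly positive values", call. = FALSE)
  }
  moment_par <- function(m, v) {
    v <- max(v, 1e-12)
    m <- max(m, 1e-12)
    c(shape = m^2 / v, scale = v / m)
  }
  fit <- em_fit(
    values, init, family = "gamma",
    dens_fn = function(x, par, log = FALSE)
      stats::dgamma(x, shape = par[["shape"]], scale = par[["scale"]],
                    log = log),
    init_fn = function(xk) {
      moment_par(mean(xk), sum((xk - mean(xk))^2) / length(xk))
    },
    mstep_fn = function(x, r) {
      w <- sum(r)
      m <- sum(r * x) / w
      v <- sum(r * (x - m)^2) / w
      moment_par(m, v)
    },
    sort_key = function(par) par[["shape"]] * par[["scale"]],
    tol = tol, max_iter = max_iter)
  fit$bic <- mixture_bic(fit)
  fit
}

#' Bayesian information criterion of a fitted mixture
#'
#' Standard mode: `BIC = p log(n) - 2 loglik` with `p = 3k - 1` free
#' parameters (two per component plus `k - 1` independent weights); lower is
#' better. The `"legacy"` mode evaluates `-2 k log(n) - 2 loglik` instead,
#' retained for auditability against historical output.
#'
#' @param model A `mixture_model`.
#' @param mode `"standard"` (default) or `"legacy"`.
#' @return Scalar BIC.
#' @export
mixture_bic <- function(model, mode = c("standard", "legacy")) {
  mode <- match.arg(mode)
  k <- model$k
  n <- model$n
  if (mode == "standard") (3 * k - 1) * log(n) - 2 * model$loglik
  else -2 * k * log(n) - 2 * model$loglik
}

#' Select the best mixture by BIC
#'
#' Returns the candidate with the minimal BIC; ties break toward the
#' Gaussian family, whose category cutoffs have a closed form.
#'
#' @param candidates List of `mixture_model` objects.
#' @return The winning `mixture_model`.
#' @export
select_best_mixture <- function(candidates) {
  candidates <- Filter(Negate(is.null), candidates)
  if (length(candidates) == 0) {
    stop("mixture fitting failed: no candidate models", call. = FALSE)
  }
  bics <- vapply(candidates, function(m) m$bic, numeric(1))
  best <- min(bics)
  idx <- which(bics <= best + 1e-12)
  if (length(idx) > 1) {
    fam <- vapply(candidates[idx], function(m) m$family, character(1))
    if (any(fam == "gaussian")) idx <- idx[fam == "gaussian"]
  }
  candidates[[idx[1]]]
}

# Component density and CDF accessors used by the categorization module.
component_density <- function(model, j, x, weighted = FALSE) {
  par <- model$params[[j]]
  d <- if (model$family == "gaussian") {
    stats::dnorm(x, par[["mean"]], sqrt(par[["var"]]))
  } else {
    stats::dgamma(x, shape = par[["shape"]], scale = par[["scale"]])
  }
  if (weighted) model$weights[j] * d else d
}

component_cdf <- function(model, j, x) {
  par <- model$params[[j]]
  if (model$family == "gaussian") {
    stats::pnorm(x, par[["mean"]], sqrt(par[["var"]]))
  } else {
    stats::pgamma(x, shape = par[["shape"]], scale = par[["scale"]])
  }
}

component_mean <- function(model, j) {
  par <- model$params[[j]]
  if (model$family == "gaussian") par[["mean"]]
  else par[["shape"]] * par[["scale"]]
}

component_mode <- function(model, j) {
  par <- model$params[[j]]
  if (model$family == "gaussian") par[["mean"]]
  else max((par[["shape"]] - 1) * par[["scale"]], 0)
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(x$k, "-component ", x$family, " mixture (n = ", x$n, ")\n", sep = "")
  for (j in seq_len(x$k)) {
    cat(sprintf("  comp %d: weight %.4f, %s\n", j, x$weights[j],
                paste(names(x$params[[j]]), signif(x$params[[j]], 5),
                      sep = " = ", collapse = ", ")))
  }
  cat("  loglik =", signif(x$loglik, 8), "| BIC =", signif(x$bic, 8),
      "|", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}
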