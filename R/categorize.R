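# Category cutoffs from density intersections of adjacent mixture
# components, Low/Medium/High assignment, and the alternative likelihood.

# Intersection of two (by default unweighted) component densities of a
# Gaussian mixture, constrained to lie between the two means.
gaussian_pair_cutoff <- function(mu1, var1, mu2, var2, w1 = 1, w2 = 1) {
  # log f1(x) = log w1 - log sigma1 - (x - mu1)^2 / (2 var1) + const
  a <- 1 / (2 * var1) - 1 / (2 * var2)
  b <- -mu1 / var1 + mu2 / var2
  cc <- mu1^2 / (2 * var1) - mu2^2 / (2 * var2) +
    0.5 * log(var1 / var2) - log(w1) + log(w2)
  if (abs(a) < 1e-14) {
    # equal variances: linear equation; equal weights give the midpoint
    if (abs(b) < 1e-14) return(NA_real_)
    return(-cc / b)
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NA_real_)
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > min(mu1, mu2) & roots < max(mu1, mu2)]
  if (length(inside) == 0) NA_real_ else inside[1]
}

# Equal-density point located by grid search between two centers (fallback
# when the closed form yields no admissible root).
grid_equal_density <- function(model, j, lo, hi, weighted, grid_points = 10000L) {
  xs <- seq(lo, hi, length.out = grid_points)
  diff <- component_density(model, j, xs, weighted = weighted) -
    component_density(model, j + 1L, xs, weighted = weighted)
  sgn <- sign(diff)
  flips <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-1] != 0)
  if (length(flips) == 0) return((lo + hi) / 2)
  mean(xs[c(flips[1], flips[1] + 1L)])
}

#' Category cutoffs for a Gaussian mixture
#'
#' For each adjacent component pair, solves the two-density intersection
#' quadratic in closed form and keeps the root between the two component
#' means; equal-variance pairs use the linear solution (the midpoint for
#' equal weights). Densities are unweighted by default, with the
#' mixing-weighted variant behind `weighted = TRUE`.
#'
#' @param model A Gaussian `mixture_model` with components sorted by mean.
#' @param weighted Use weighted component densities (default FALSE).
#' @return Numeric vector of `k - 1` ascending cutoffs (for `k = 3`,
#'   `c1 < c2`).
#' @export
gaussian_cutoffs <- function(model, weighted = FALSE) {
  stopifnot(inherits(model, "mixture_model"), model$family == "gaussian")
  if (model$k < 2) stop("need at least 2 components for cutoffs",
                        call. = FALSE)
  cuts <- vapply(seq_len(model$k - 1L), function(j) {
    p1 <- model$params[[j]]; p2 <- model$params[[j + 1L]]
    w1 <- if (weighted) model$weights[j] else 1
    w2 <- if (weighted) model$weights[j + 1L] else 1
    x <- gaussian_pair_cutoff(p1[["mean"]], p1[["var"]],
                              p2[["mean"]], p2[["var"]], w1, w2)
    if (is.na(x) || x <= p1[["mean"]] || x >= p2[["mean"]]) {
      warning("no admissible closed-form root between components ", j,
              " and ", j + 1L, "; falling back to grid search",
              call. = FALSE)
      x <- grid_equal_density(model, j, p1[["mean"]], p2[["mean"]], weighted)
    }
    x
  }, numeric(1))
  if (is.unsorted(cuts, strictly = TRUE)) {
    stop("cutoffs are not strictly increasing; mixture components overlap ",
         "too heavily to separate categories", call. = FALSE)
  }
  cuts
}

#' Category cutoffs for a Gamma mixture
#'
#' No closed form exists for the intersection of two gamma densities, so for
#' each adjacent pair both densities are evaluated on a uniform grid between
#' the two component modes; the cutoff is the mean of the last grid point
#' where the lower component's density exceeds the upper's and the first
#' point where the order reverses. If the densities never cross on the grid
#' the midpoint of the modes is used, with a warning.
#'
#' @param model A Gamma `mixture_model` with components sorted by mean.
#' @param grid_points Grid resolution (default 10000, minimum 1000).
#' @param weighted Use weighted component densities (default FALSE).
#' @return Numeric vector of `k - 1` ascending cutoffs.
#' @export
gamma_cutoffs <- function(model, grid_points = 10000L, weighted = FALSE) {
  stopifnot(inherits(model, "mixture_model"), model$family == "gamma")
  if (grid_points < 1000L) stop("grid_points must be >= 1000", call. = FALSE)
  if (model$k < 2) stop("need at least 2 components for cutoffs",
                        call. = FALSE)
  cuts <- vapply(seq_len(model$k - 1L), function(j) {
    lo <- component_mode(model, j)
    hi <- component_mode(model, j + 1L)
    if (!(hi > lo)) {
      warning("component modes not separated for pair ", j, "/", j + 1L,
              "; using midpoint of component means", call. = FALSE)
      return((component_mean(model, j) + component_mean(model, j + 1L)) / 2)
    }
    xs <- seq(lo, hi, length.out = grid_points)
    fi <- component_density(model, j, xs, weighted = weighted)
    fj <- component_density(model, j + 1L, xs, weighted = weighted)
    above <- which(fi > fj)
    below <- which(fi < fj)
    if (length(above) == 0 || length(below) == 0) {
      warning("densities never cross between modes for pair ", j, "/",
              j + 1L, "; using midpoint of modes", call. = FALSE)
      return((lo + hi) / 2)
    }
    mean(c(xs[max(above)], xs[min(below)]))
  }, numeric(1))
  if (is.unsorted(cuts, strictly = TRUE)) {
    stop("cutoffs are not strictly increasing", call. = FALSE)
  }
  cuts
}

#' Cutoffs for any supported mixture family
#'
#' Dispatches to [gaussian_cutoffs()] or [gamma_cutoffs()].
#'
#' @param model A `mixture_model`.
#' @param grid_points Grid resolution for the gamma estimate.
#' @param weighted Use weighted component densities (default FALSE).
#' @return Ascending numeric cutoffs of length `k - 1`.
#' @export
mixture_cutoffs <- function(model, grid_points = 10000L, weighted = FALSE) {
  if (model$family == "gaussian") gaussian_cutoffs(model, weighted = weighted)
  else gamma_cutoffs(model, grid_points = grid_points, weighted = weighted)
}

#' Assign a mapping-uncertainty category to a D-score
#'
#' Low below the first cutoff, Medium in `[c1, c2)`, High at or above the
#' second. Boundary values go to the higher category (left-closed
#' intervals). Vectorized over `d`.
#'
#' @param d D-score(s).
#' @param cutoffs Ascending cutoffs `c(c1, c2)` from [mixture_cutoffs()].
#' @return Character vector in `{Low, Medium, High}`.
#' @export
assign_category <- function(d, cutoffs) {
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  ifelse(d < cutoffs[1], "Low", ifelse(d < cutoffs[2], "Medium", "High"))
}

#' Alternative likelihood of a categorized D-score
#'
#' The plausibility that a gene categorized into component `i` in fact
#' belongs to an adjacent category: `s_d = max(1 - F_{i-1}(d), F_{i+1}(d))`,
#' where `F_j` is the CDF of component `j`. The lowest and highest
#' categories use their single available neighbor term.
#'
#' @param d D-score(s).
#' @param i Component index the score was categorized into (1-based;
#'   vectorized with `d`).
#' @param model The fitted `mixture_model`.
#' @return Numeric vector in `[0, 1]`.
#' @export
alternative_likelihood <- function(d, i, model) {
  stopifnot(length(i) == 1 || length(i) == length(d))
  i <- rep_len(as.integer(i), length(d))
  vapply(seq_along(d), function(idx) {
    ii <- i[idx]
    terms <- c(
      if (ii > 1) 1 - component_cdf(model, ii - 1L, d[idx]),
      if (ii < model$k) component_cdf(model, ii + 1L, d[idx]))
    min(max(terms), 1)
  }, numeric(1))
}

#' Categorize a vector of D-scores
#'
#' Applies [assign_category()] and [alternative_likelihood()] to every
#' score. Scores of exactly 0 (genes with no evidence of mapping
#' uncertainty, which are excluded from mixture fitting) are categorized Low
#' deterministically and still receive an alternative likelihood from the
#' fitted model.
#'
#' @param d_scores Numeric vector of D-scores.
#' @param model The selected `mixture_model`.
#' @param cutoffs Cutoffs from [mixture_cutoffs()].
#' @return A `data.frame` with columns `d_score`, `category`,
#'   `alt_likelihood`.
#' @export
categorize_dscores <- function(d_scores, model, cutoffs) {
  category <- assign_category(d_scores, cutoffs)
  comp <- match(category, c("Low", "Medium", "High"))
  comp <- pmin(comp, model$k)
  alt <- alternative_likelihood(d_scores, comp, model)
  data.frame(d_score = d_scores, category = category, alt_likelihood = alt,
             stringsAsFactors = FALSE)
}
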