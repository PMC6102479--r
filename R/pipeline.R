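# Pipeline orchestration: feature extraction from SAM/FASTA/GFF3 inputs,
# D-score modeling, categorization, and report + JSON sidecar output.

#' Extract the per-gene feature table from alignment files
#'
#' Reads the three standard inputs and assembles the feature table consumed
#' by [model_dscores()].
#'
#' @param sam Path to the SAM alignment file.
#' @param fasta Path to the reference genome FASTA.
#' @param gff Path to the GFF3 annotation.
#' @param feature_types GFF3 feature types treated as genes (default
#'   `"gene"`).
#' @inheritParams build_feature_table
#' @return Feature `data.frame` (see [build_feature_table()]).
#' @export
extract_features <- function(sam, fasta, gff, feature_types = "gene",
                             min_overlap_bp = 1L, kmer_size = 15L,
                             min_shared_kmers = 3L, min_score = 20,
                             min_identity = 0.8, min_match_len = 30) {
  genome <- read_fasta(fasta)
  genes <- read_gff_genes(gff, feature_types = feature_types)
  alignments <- read_sam_alignments(sam)
  message("extract: ", nrow(genes), " genes, ", nrow(alignments),
          " alignment records")
  build_feature_table(alignments, genome, genes,
                      min_overlap_bp = min_overlap_bp,
                      kmer_size = kmer_size,
                      min_shared_kmers = min_shared_kmers,
                      min_score = min_score, min_identity = min_identity,
                      min_match_len = min_match_len)
}

#' Write / read the intermediate feature table
#'
#' The feature TSV is a stable interface between the extraction and
#' modeling stages; any file with columns `gene_id`, `D1`, `D2`, `D3`,
#' `G_size`, `U_size` is accepted by [model_dscores()].
#'
#' @param features Feature `data.frame`.
#' @param path File path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the feature `data.frame`.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  needed <- c("gene_id", "D1", "D2", "D3", "G_size", "U_size")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop("feature table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("D1", "D2", "D3")) {
    if (!is.numeric(tab[[col]])) {
      stop("feature table schema error: column ", col, " is not numeric",
           call. = FALSE)
    }
  }
  tab
}

# Low/Medium/High labels from an ascending cutoff vector of length 1 or 2
# (length 1 arises when a mixture component was pruned: no Medium band).
categories_from_cutoffs <- function(d, cutoffs) {
  if (length(cutoffs) == 2) assign_category(d, cutoffs)
  else ifelse(d < cutoffs[1], "Low", "High")
}

#' Model D-scores and categorize genes from a feature table
#'
#' Min-max normalizes D1/D2/D3 over the modeled genes (those with at least
#' one assigned read), selects the elastic-net penalty by seeded
#' cross-validation, fits the regression of D4 on the normalized features,
#' predicts D-scores, fits Gaussian and Gamma mixture candidates to the
#' positive D-scores by k-means-initialized EM, selects the family by BIC
#' and categorizes every gene at the density-intersection cutoffs.
#'
#' Genes with no assigned reads get features 0, D-score 0 and category Low;
#' D-scores of exactly 0 are excluded from mixture fitting (they form a
#' point mass) and are categorized Low deterministically.
#'
#' @param features Feature table from [extract_features()] or
#'   [read_feature_table()].
#' @param alpha Elastic-net L2 fraction (default 0.5; see
#'   [fit_elastic_net()]).
#' @param seed Integer seed for CV folds and k-means restarts (default 1).
#' @param k Mixture components (default 3).
#' @param families Mixture families to try (default gaussian and gamma).
#' @param restarts k-means restarts (default 10).
#' @param grid_points Gamma-cutoff grid resolution (default 10000).
#' @param weighted_cutoffs Use mixing-weighted densities for cutoffs
#'   (default FALSE).
#' @param n_folds CV folds for penalty selection (default 5).
#' @return List with `report` (data.frame `gene_id`, `d1`, `d2`, `d3`,
#'   `d_score`, `category`, `alt_likelihood`), `enet` (the `enet_fit`),
#'   `lambda_total`, `mixture` (selected `mixture_model` or NULL),
#'   `candidates` (BIC per family), `cutoffs`, `category_counts`.
#' @export
model_dscores <- function(features, alpha = 0.5, seed = 1L, k = 3L,
                          families = c("gaussian", "gamma"), restarts = 10L,
                          grid_points = 10000L, weighted_cutoffs = FALSE,
                          n_folds = 5L) {
  if (!"D4" %in% names(features)) {
    features$D4 <- ifelse(features$G_size >= 1,
                          1 - (features$G_size + features$U_size) /
                            (2 * pmax(features$G_size, 1)), NA_real_)
  }
  modeled <- which(features$G_size >= 1)
  if (length(modeled) < 2) {
    stop("too few genes with assigned reads to model", call. = FALSE)
  }
  X <- cbind(D1 = min_max_normalize(features$D1[modeled]),
             D2 = min_max_normalize(features$D2[modeled]),
             D3 = min_max_normalize(features$D3[modeled]))
  y <- features$D4[modeled]
  lambda <- select_lambda(X, y, alpha = alpha, n_folds = n_folds,
                          seed = seed)
  enet <- fit_elastic_net(X, y, alpha = alpha,
                          lambda_total = as.numeric(lambda))
  d_scores <- rep(0, nrow(features))
  d_scores[modeled] <- predict_dscores(enet, X)
  message("model: lambda_total = ", signif(as.numeric(lambda), 4),
          ", coefficients = ",
          paste(signif(enet$coefficients, 4), collapse = ", "))

  pos <- d_scores[d_scores > 0]
  mixture <- NULL
  cutoffs <- NULL
  candidates <- list()
  for (kk in seq(k, 2L)) {
    if (length(unique(pos)) < kk) next
    fits <- list()
    if ("gaussian" %in% families) {
      init <- kmeans_1d(pos, k = kk, seed = seed, restarts = restarts)
      fits$gaussian <- tryCatch(em_gaussian(pos, init$assignments),
                                error = function(e) NULL)
    }
    if ("gamma" %in% families) {
      clipped <- pmax(pos, 1e-6)
      init <- kmeans_1d(clipped, k = kk, seed = seed, restarts = restarts)
      fits$gamma <- tryCatch(em_gamma(clipped, init$assignments),
                             error = function(e) NULL)
    }
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0) next
    mix_try <- select_best_mixture(fits)
    cut_try <- tryCatch(
      mixture_cutoffs(mix_try, grid_points = grid_points,
                      weighted = weighted_cutoffs),
      error = function(e) NULL)
    if (!is.null(cut_try)) {
      mixture <- mix_try
      cutoffs <- cut_try
      candidates <- lapply(fits, function(m)
        list(family = m$family, k = m$k, bic = m$bic,
             loglik = m$loglik, converged = m$converged))
      break
    }
  }

  if (is.null(mixture)) {
    warning("mixture fitting degenerate (too few distinct positive ",
            "D-scores); categorizing all genes Low", call. = FALSE)
    category <- rep("Low", nrow(features))
    alt <- rep(0, nrow(features))
  } else {
    message("model: selected ", mixture$k, "-component ", mixture$family,
            " mixture (BIC ", signif(mixture$bic, 6), "), cutoffs ",
            paste(signif(cutoffs, 4), collapse = ", "))
    category <- categories_from_cutoffs(d_scores, cutoffs)
    category[d_scores == 0] <- "Low"
    comp <- pmin(match(category, c("Low", "Medium", "High")), mixture$k)
    alt <- alternative_likelihood(d_scores, comp, mixture)
  }
  report <- data.frame(gene_id = features$gene_id,
                       d1 = features$D1, d2 = features$D2, d3 = features$D3,
                       d_score = d_scores, category = category,
                       alt_likelihood = alt, stringsAsFactors = FALSE)
  list(report = report, enet = enet, lambda_total = as.numeric(lambda),
       mixture = mixture, candidates = candidates, cutoffs = cutoffs,
       category_counts = table(factor(category,
                                      levels = c("Low", "Medium", "High"))))
}

#' Run the full mapping-uncertainty pipeline
#'
#' Feature extraction, D-score modeling and categorization in one call;
#' writes the tab-separated report and a JSON sidecar
#' (`<out>.json`) recording the regression coefficients, penalty, mixture
#' candidates and selection, cutoffs, seed and per-category counts. On
#' error, partial outputs are removed.
#'
#' @param sam,fasta,gff,out Input and output file paths.
#' @param alpha Elastic-net L2 fraction (default 0.5).
#' @param seed Integer seed (default 1).
#' @param feature_types GFF3 feature types treated as genes.
#' @param min_overlap_bp,kmer_size,min_shared_kmers Read-assignment and
#'   candidate-pair parameters.
#' @param min_score,min_identity,min_match_len Similarity gates.
#' @param k,families,restarts,grid_points,weighted_cutoffs Mixture settings
#'   (see [model_dscores()]).
#' @return Invisibly, the list returned by [model_dscores()], with the
#'   feature table attached as `features`.
#' @export
run_pipeline <- function(sam, fasta, gff, out, alpha = 0.5, seed = 1L,
                         feature_types = "gene", min_overlap_bp = 1L,
                         kmer_size = 15L, min_shared_kmers = 3L,
                         min_score = 20, min_identity = 0.8,
                         min_match_len = 30, k = 3L,
                         families = c("gaussian", "gamma"), restarts = 10L,
                         grid_points = 10000L, weighted_cutoffs = FALSE) {
  sidecar <- paste0(out, ".json")
  ok <- FALSE
  on.exit({
    if (!ok) {
      if (file.exists(out)) unlink(out)
      if (file.exists(sidecar)) unlink(sidecar)
    }
  })
  features <- extract_features(sam, fasta, gff,
                               feature_types = feature_types,
                               min_overlap_bp = min_overlap_bp,
                               kmer_size = kmer_size,
                               min_shared_kmers = min_shared_kmers,
                               min_score = min_score,
                               min_identity = min_identity,
                               min_match_len = min_match_len)
  res <- model_dscores(features, alpha = alpha, seed = seed, k = k,
                       families = families, restarts = restarts,
                       grid_points = grid_points,
                       weighted_cutoffs = weighted_cutoffs)
  write_report(res$report, out)
  meta <- list(
    seed = seed, alpha = alpha, lambda_total = res$lambda_total,
    coefficients = as.list(c(intercept = res$enet$intercept,
                             res$enet$coefficients)),
    mixture = if (is.null(res$mixture)) NULL else list(
      family = res$mixture$family, k = res$mixture$k,
      weights = res$mixture$weights,
      params = lapply(res$mixture$params, as.list),
      bic = res$mixture$bic),
    candidates = res$candidates,
    cutoffs = res$cutoffs,
    category_counts = as.list(res$category_counts),
    n_genes = nrow(features),
    n_modeled = sum(features$G_size >= 1))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  message("report: ", out, " (", nrow(res$report), " genes; ",
          paste(names(res$category_counts), as.integer(res$category_counts),
                sep = "=", collapse = ", "), ")")
  ok <- TRUE
  res$features <- features
  invisible(res)
}
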