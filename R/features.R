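# Per-gene feature assembly: D1 (genomic), D2 (transcriptomic), D3 (network
# degree), the dependent variable D4, and min-max normalization.

#' Transcriptomic shared-MMR feature D2
#'
#' The maximum, over partner genes, of the fraction of this gene's assigned
#' reads that are multi-mapping reads shared with that partner:
#' `max_y |G_i intersect G_y|_MMR / |G_i|`. By convention 0 when the gene has
#' no assigned reads or no shared MMRs.
#'
#' @param gene_i Gene id.
#' @param G_size Number of reads assigned to the gene (`|G_i|`).
#' @param shared Shared-MMR counts from [shared_mmr_counts()].
#' @return Scalar in `[0, 1]`.
#' @export
compute_D2 <- function(gene_i, G_size, shared) {
  if (G_size == 0) return(0)
  cnt <- c(shared$count[shared$gene_i == gene_i],
           shared$count[shared$gene_y == gene_i])
  if (length(cnt) == 0) return(0)
  max(cnt) / G_size
}

#' Network degree feature D3
#'
#' `log10(|S union M| + 1)`, where S is the set of partner locations with a
#' significant sequence-similarity hit (D1 route) and M the set of partners
#' sharing at least one multi-mapping read (D2 route).
#'
#' @param S Character vector of similarity partners (excluding the gene).
#' @param M Character vector of shared-MMR partners (excluding the gene).
#' @return Nonnegative scalar.
#' @export
compute_D3 <- function(S, M) {
  log10(length(union(S, M)) + 1)
}

#' Dependent variable D4: approximate ambiguous-read proportion
#'
#' With G the reads assigned to a gene and U its uniquely mapped subset, the
#' true read count lies between `|U|` and `|G|`; approximating it by their
#' midpoint gives `D4 = 1 - (|G| + |U|) / (2 |G|)`, which ranges from 0
#' (all reads unique) to 0.5 (no unique reads). Vectorized over its
#' arguments.
#'
#' @param G_size Number of assigned reads (must be >= 1).
#' @param U_size Number of uniquely mapped assigned reads, `<= G_size`.
#' @return Scalar (or vector) in `[0, 0.5]`.
#' @export
compute_D4 <- function(G_size, U_size) {
  if (any(G_size < 1)) {
    stop("D4 is undefined for genes with no assigned reads", call. = FALSE)
  }
  if (any(U_size < 0) || any(U_size > G_size)) {
    stop("U_size must satisfy 0 <= U_size <= G_size", call. = FALSE)
  }
  1 - (G_size + U_size) / (2 * G_size)
}

#' Min-max normalize a numeric vector to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant vector maps to all zeros.
#'
#' @param values Nonempty numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
min_max_normalize <- function(values) {
  if (length(values) == 0) stop("empty vector", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Assemble the per-gene feature table
#'
#' Runs read classification, gene assignment, shared-MMR counting and
#' sequence similarity, and returns one row per annotated gene with the raw
#' features D1/D2/D3, the read-set sizes and the dependent variable D4
#' (NA for genes without assigned reads, which are excluded from modeling).
#'
#' @param alignments Alignment records from [read_sam_alignments()].
#' @param genome [Biostrings::DNAStringSet] from [read_fasta()].
#' @param genes Gene models from [read_gff_genes()].
#' @param min_overlap_bp Minimum read-gene overlap in bp (default 1).
#' @param kmer_size,min_shared_kmers Candidate-pair k-mer screen parameters.
#' @param min_score,min_identity,min_match_len Similarity significance gates
#'   (see [similarity_hits()]).
#' @return A `data.frame` with columns `gene_id`, `D1`, `D2`, `D3`,
#'   `G_size`, `U_size`, `D4`, `degree`.
#' @export
build_feature_table <- function(alignments, genome, genes,
                                min_overlap_bp = 1L,
                                kmer_size = 15L, min_shared_kmers = 3L,
                                min_score = 20, min_identity = 0.8,
                                min_match_len = 30) {
  mult <- classify_reads(alignments)
  assign <- assign_reads_to_genes(alignments, genes, mult,
                                  min_overlap_bp = min_overlap_bp)
  shared <- shared_mmr_counts(assign$sets, mult)
  gseqs <- gene_sequences(genome, genes)
  pairs <- find_candidate_pairs(shared, gseqs, kmer_size = kmer_size,
                                min_shared_kmers = min_shared_kmers)
  hits <- similarity_hits(pairs, gseqs, min_score = min_score,
                          min_identity = min_identity,
                          min_match_len = min_match_len)
  rows <- lapply(genes$gene_id, function(g) {
    G_size <- length(assign$sets[[g]]$G)
    U_size <- length(assign$sets[[g]]$U)
    S <- unique(hits$gene_y[hits$gene_i == g])
    M <- unique(c(shared$gene_y[shared$gene_i == g],
                  shared$gene_i[shared$gene_y == g]))
    data.frame(
      gene_id = g,
      D1 = compute_D1(g, hits),
      D2 = compute_D2(g, G_size, shared),
      D3 = compute_D3(S, M),
      G_size = G_size, U_size = U_size,
      D4 = if (G_size >= 1) compute_D4(G_size, U_size) else NA_real_,
      degree = length(union(S, M)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
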