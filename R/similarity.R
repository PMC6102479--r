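# Pairwise gene-sequence similarity: identity fraction (ss), longest
# consecutive-match run (l), and the genomic feature D1 = max_y ss * l.

#' Extract gene sequences from the genome
#'
#' @param genome A [Biostrings::DNAStringSet] from [read_fasta()].
#' @param genes Gene models from [read_gff_genes()].
#' @return A named [Biostrings::DNAStringSet], one element per gene (forward
#'   genomic strand; orientation is handled inside [align_pair()]).
#' @export
gene_sequences <- function(genome, genes) {
  missing <- setdiff(unique(genes$contig), names(genome))
  if (length(missing) > 0) {
    stop("contig(s) in annotation absent from genome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(genes)), function(i) {
    as.character(Biostrings::subseq(genome[[genes$contig[i]]],
                                    start = genes$start[i],
                                    end = genes$end[i]))
  }, character(1)))
  names(seqs) <- genes$gene_id
  seqs
}

#' Find candidate gene pairs for similarity testing
#'
#' Restricts the all-vs-all comparison to pairs that plausibly share sequence:
#' the union of (a) pairs sharing at least one multi-mapping read and (b)
#' pairs sharing at least `min_shared_kmers` exact k-mers.
#'
#' @param shared_mmr Shared-MMR pair counts from [shared_mmr_counts()].
#' @param gene_seqs Named [Biostrings::DNAStringSet] from [gene_sequences()].
#' @param kmer_size k-mer length for the sequence route (default 15).
#' @param min_shared_kmers Minimum shared exact k-mers (default 3).
#' @return A `data.frame` with columns `gene_i`, `gene_y`
#'   (`gene_i < gene_y`), no self-pairs.
#' @export
find_candidate_pairs <- function(shared_mmr, gene_seqs, kmer_size = 15L,
                                 min_shared_kmers = 3L) {
  read_pairs <- unique(shared_mmr[, c("gene_i", "gene_y"), drop = FALSE])
  ids <- names(gene_seqs)
  kmer_tab <- do.call(rbind, lapply(seq_along(gene_seqs), function(i) {
    s <- as.character(gene_seqs[[i]])
    n <- nchar(s)
    if (n < kmer_size) return(NULL)
    km <- unique(substring(s, 1:(n - kmer_size + 1), kmer_size:n))
    data.frame(kmer = km, gene = ids[i], stringsAsFactors = FALSE)
  }))
  kmer_pairs <- data.frame(gene_i = character(0), gene_y = character(0))
  if (!is.null(kmer_tab) && nrow(kmer_tab) > 0) {
    by_kmer <- split(kmer_tab$gene, kmer_tab$kmer)
    by_kmer <- by_kmer[lengths(by_kmer) > 1]
    keys <- unlist(lapply(by_kmer, function(gs) {
      gs <- sort(unique(gs))
      if (length(gs) < 2) return(character(0))
      cmb <- utils::combn(gs, 2)
      paste(cmb[1, ], cmb[2, ], sep = "\r")
    }), use.names = FALSE)
    if (length(keys) > 0) {
      tab <- table(keys)
      tab <- tab[tab >= min_shared_kmers]
      if (length(tab) > 0) {
        parts <- strsplit(names(tab), "\r", fixed = TRUE)
        kmer_pairs <- data.frame(
          gene_i = vapply(parts, `[[`, "", 1L),
          gene_y = vapply(parts, `[[`, "", 2L), stringsAsFactors = FALSE)
      }
    }
  }
  out <- unique(rbind(read_pairs, kmer_pairs))
  out <- out[out$gene_i != out$gene_y, , drop = FALSE]
  row.names(out) <- NULL
  out
}

# Longest run of identical aligned bases (no gaps, no mismatches) between two
# aligned (gapped) strings of equal width.
longest_match_run <- function(pat, sub) {
  p <- strsplit(pat, "", fixed = TRUE)[[1]]
  s <- strsplit(sub, "", fixed = TRUE)[[1]]
  eq <- p == s & p != "-" & s != "-"
  if (!any(eq)) return(0L)
  r <- rle(eq)
  max(r$lengths[r$values])
}

#' Locally align two gene sequences
#'
#' Smith-Waterman local alignment (match +1, mismatch -1, gap open -2, gap
#' extend -1) of two nucleotide sequences; both the given orientation and the
#' reverse complement of the second sequence are tried and the better-scoring
#' orientation kept. Returns the identity fraction over the aligned columns
#' (`ss`) and the longest run of consecutive identical bases (`l`). Pairs
#' whose best local score falls below `min_score` return `c(ss = 0, l = 0)`.
#'
#' @param seq_i,seq_y Nucleotide sequences (character or
#'   [Biostrings::DNAString]).
#' @param min_score Minimum local alignment score (default 20).
#' @return Named numeric vector `c(ss = , l = )`, with the best local
#'   alignment score in attribute `"score"`.
#' @export
align_pair <- function(seq_i, seq_y, min_score = 20) {
  a <- as.character(seq_i)
  b <- as.character(seq_y)
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("sequences must be nonempty", call. = FALSE)
  }
  # canonical argument order: identity and match-run length are symmetric,
  # but co-optimal alignment tie-breaks are not, so fix the orientation
  if (b < a) {
    tmp <- a
    a <- b
    b <- tmp
  }
  seq_i <- Biostrings::DNAString(a)
  seq_y <- Biostrings::DNAString(b)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln_fwd <- Biostrings::pairwiseAlignment(
    seq_i, seq_y, type = "local", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 1)
  aln_rev <- Biostrings::pairwiseAlignment(
    seq_i, Biostrings::reverseComplement(seq_y), type = "local",
    substitutionMatrix = mat, gapOpening = 2, gapExtension = 1)
  aln <- if (Biostrings::score(aln_rev) > Biostrings::score(aln_fwd))
    aln_rev else aln_fwd
  best <- Biostrings::score(aln)
  if (best < min_score) {
    return(structure(c(ss = 0, l = 0), score = best))
  }
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  width <- nchar(pat)
  ss <- Biostrings::nmatch(aln) / width
  l <- longest_match_run(pat, sub)
  structure(c(ss = ss, l = as.numeric(l)), score = best)
}

#' Compute similarity hits for candidate gene pairs
#'
#' Aligns every candidate pair and keeps the significant ones: identity
#' `ss >= min_identity` and match run `l >= min_match_len` (besides the
#' aligner's `min_score` gate). These hits define the similarity partner set
#' S of each gene and carry the products `ss * l` from which D1 is taken.
#'
#' @param pairs Candidate pairs from [find_candidate_pairs()].
#' @param gene_seqs Named [Biostrings::DNAStringSet].
#' @param min_score Minimum local alignment score (default 20).
#' @param min_identity Minimum identity fraction for a significant hit
#'   (default 0.8).
#' @param min_match_len Minimum consecutive-match run, bp (default 30).
#' @return A `data.frame` with columns `gene_i`, `gene_y`, `ss`, `l`,
#'   `product`; each significant pair appears in both orientations so that
#'   per-gene lookups are direct.
#' @export
similarity_hits <- function(pairs, gene_seqs, min_score = 20,
                            min_identity = 0.8, min_match_len = 30) {
  empty <- data.frame(gene_i = character(0), gene_y = character(0),
                      ss = numeric(0), l = numeric(0), product = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) return(empty)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs$gene_i[k]; b <- pairs$gene_y[k]
    sl <- align_pair(gene_seqs[[a]], gene_seqs[[b]], min_score = min_score)
    if (sl[["ss"]] >= min_identity && sl[["l"]] >= min_match_len) {
      data.frame(gene_i = c(a, b), gene_y = c(b, a),
                 ss = sl[["ss"]], l = sl[["l"]],
                 product = sl[["ss"]] * sl[["l"]], stringsAsFactors = FALSE)
    } else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res)) empty else res
}

#' Genomic similarity feature D1
#'
#' The maximum, over a gene's significant similarity partners, of the
#' identity fraction times the longest consecutive-match length; 0 for genes
#' without significant partners.
#'
#' @param gene_i Gene id.
#' @param hits Similarity hits from [similarity_hits()].
#' @return Nonnegative scalar.
#' @export
compute_D1 <- function(gene_i, hits) {
  own <- hits$product[hits$gene_i == gene_i]
  if (length(own) == 0) 0 else max(own)
}
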