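# Synthetic-data generator: toy genomes with controlled gene duplications,
# GFF3 annotations, and error-free SAM alignments whose NH multiplicities
# are ground truth by construction (exact occurrence counts in the genome).

#' Simulation configuration
#'
#' Bundles the generator parameters. `gene_length_bp` is the mean gene
#' length; individual genes are drawn uniformly between 0.6x and 1.4x of it
#' so that duplicated genes differ in their similarity products, as gene
#' families in real genomes do.
#'
#' @param n_genes Number of source genes (default 200).
#' @param gene_length_bp Mean gene length in bp (default 1000).
#' @param duplicate_fraction Fraction of source genes that receive a
#'   duplicated copy elsewhere in the genome, in `[0, 1]` (default 0.3).
#' @param divergence Per-base substitution rate applied to each copy, in
#'   `[0, 1]` (default 0: exact duplicates).
#' @param read_length_bp Read length in bp (default 100).
#' @param mean_depth Mean per-gene sequencing depth (default 20).
#' @param seed Integer seed (default 1).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 200L, gene_length_bp = 1000L,
                              duplicate_fraction = 0.3, divergence = 0,
                              read_length_bp = 100L, mean_depth = 20,
                              seed = 1L) {
  stopifnot(n_genes >= 1, gene_length_bp > 0,
            duplicate_fraction >= 0, duplicate_fraction <= 1,
            divergence >= 0, divergence <= 1,
            read_length_bp > 0, mean_depth > 0)
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_bp = as.integer(gene_length_bp),
                 duplicate_fraction = duplicate_fraction,
                 divergence = divergence,
                 read_length_bp = as.integer(read_length_bp),
                 mean_depth = mean_depth, seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, identity = 1))
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(bases)) < rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  list(seq = paste(bases, collapse = ""),
       identity = 1 - sum(hit) / length(bases))
}

#' Simulate a toy genome with duplicated genes
#'
#' Places `n_genes` random genes on one contig separated by 200 bp random
#' spacers, then appends a diverged copy of a `duplicate_fraction` of them
#' (copies are annotated genes too, on the same strand). Returns FASTA and
#' GFF3 text plus a truth table of duplicate pairs with realized identities.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return List with `fasta` (character scalar), `gff3` (character scalar),
#'   `truth` (`data.frame` with `source`, `copy`, `identity`), and parsed
#'   conveniences `genome` ([Biostrings::DNAStringSet]) and `genes`
#'   (`data.frame` as from [read_gff_genes()]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    lens <- as.integer(round(stats::runif(n, 0.6, 1.4) *
                               config$gene_length_bp))
    lens <- pmax(lens, config$read_length_bp)
    src_seqs <- vapply(lens, random_dna, character(1))
    src_ids <- sprintf("gene%04d", seq_len(n))
    n_dup <- as.integer(round(config$duplicate_fraction * n))
    dup_of <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
    dup_ids <- if (n_dup > 0) paste0(src_ids[dup_of], "_dup") else character(0)
    dup <- lapply(dup_of, function(i)
      mutate_sequence(src_seqs[i], config$divergence))
    all_ids <- c(src_ids, dup_ids)
    all_seqs <- c(src_seqs, vapply(dup, `[[`, "", "seq"))
    spacers <- vapply(rep(200L, length(all_seqs) + 1L), random_dna,
                      character(1))
    pieces <- character(2 * length(all_seqs) + 1L)
    pieces[seq(1, length(pieces), by = 2)] <- spacers
    pieces[seq(2, length(pieces), by = 2)] <- all_seqs
    contig <- paste(pieces, collapse = "")
    starts <- 200L + cumsum(c(0L, utils::head(nchar(all_seqs), -1) + 200L)) + 1L
    ends <- starts + nchar(all_seqs) - 1L
    genes <- data.frame(gene_id = all_ids, contig = "chr1",
                        start = starts, end = ends, strand = "+",
                        stringsAsFactors = FALSE)
    gff3 <- paste(c("##gff-version 3",
                    sprintf("chr1\tsim\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                            starts, ends, all_ids)), collapse = "\n")
    fasta_seq <- gsub("(.{70})", "\\1\n", contig)
    fasta <- paste0(">chr1 synthetic\n", sub("\n$", "", fasta_seq), "\n")
    truth <- data.frame(source = src_ids[dup_of], copy = dup_ids,
                        identity = vapply(dup, `[[`, 0, "identity"),
                        stringsAsFactors = FALSE)
    genome <- Biostrings::DNAStringSet(contig)
    names(genome) <- "chr1"
    list(fasta = fasta, gff3 = paste0(gff3, "\n"), truth = truth,
         genome = genome, genes = genes)
  })
}

#' Simulate error-free reads and their SAM alignments
#'
#' Draws reads uniformly from gene bodies at `mean_depth`. Each read's true
#' multiplicity is the exact occurrence count of its sequence (and reverse
#' complement) in the whole genome; one SAM record is emitted per
#' occurrence, with `NH` set to that count and identical `AS` scores on
#' ties (the occurrence at the read's origin is the primary record).
#'
#' @param sim Output of [simulate_genome()].
#' @param config The same `sim_config`.
#' @return List with `sam` (character scalar, header included) and `reads`
#'   (`data.frame` with `read_id`, `gene_id`, `start`, `nh`).
#' @export
simulate_reads_sam <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- sim$genome[[1]]
  genes <- sim$genes
  rl <- config$read_length_bp
  with_seed(config$seed + 1L, {
    per_gene <- pmax(1L, as.integer(round(
      config$mean_depth * (genes$end - genes$start + 1L) / rl)))
    gene_idx <- rep(seq_len(nrow(genes)), per_gene)
    max_start <- genes$end[gene_idx] - rl + 1L
    starts <- genes$start[gene_idx] +
      floor(stats::runif(length(gene_idx)) *
              (max_start - genes$start[gene_idx] + 1L))
    read_ids <- sprintf("read%06d", seq_along(gene_idx))
    seqs <- as.character(Biostrings::extractAt(
      genome, IRanges::IRanges(start = starts, width = rl)))
    uq <- unique(seqs)
    seq_idx <- match(seqs, uq)
    uq_set <- Biostrings::DNAStringSet(uq)
    pd_fwd <- Biostrings::PDict(uq_set)
    pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(uq_set))
    m_fwd <- Biostrings::matchPDict(pd_fwd, genome)
    m_rev <- Biostrings::matchPDict(pd_rev, genome)
    nil <- function(x) if (is.null(x)) integer(0) else x
    fwd_starts <- lapply(Biostrings::startIndex(m_fwd), nil)
    rev_starts <- lapply(Biostrings::startIndex(m_rev), nil)
    nh_uq <- lengths(fwd_starts) + lengths(rev_starts)
    nh <- nh_uq[seq_idx]
    # one record per occurrence; the occurrence at the read's origin is the
    # primary record (reads are extracted from the genome, so it exists)
    occ_pos <- lapply(seq_along(uq), function(i)
      c(fwd_starts[[i]], rev_starts[[i]]))
    occ_flag <- lapply(seq_along(uq), function(i)
      c(rep(256L, length(fwd_starts[[i]])),
        rep(272L, length(rev_starts[[i]]))))
    n_occ <- nh_uq[seq_idx]
    pos_all <- unlist(occ_pos[seq_idx], use.names = FALSE)
    flag_all <- unlist(occ_flag[seq_idx], use.names = FALSE)
    rid_all <- rep(read_ids, n_occ)
    origin_all <- rep(starts, n_occ)
    flag_all[flag_all == 256L & pos_all == origin_all] <- 0L
    seq_all <- rep(seqs, n_occ)
    rev_mask <- bitwAnd(flag_all, 16L) != 0L
    if (any(rev_mask)) {
      seq_all[rev_mask] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seq_all[rev_mask])))
    }
    nh_all <- rep(nh, n_occ)
    body <- sprintf("%s\t%d\tchr1\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d\tAS:i:0",
                    rid_all, flag_all, pos_all,
                    ifelse(nh_all == 1L, 60L, 1L), rl, seq_all, nh_all)
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:chr1\tLN:%d", length(genome)))
    list(sam = paste0(paste(c(header, body), collapse = "\n"), "\n"),
         reads = data.frame(read_id = read_ids,
                            gene_id = genes$gene_id[gene_idx],
                            start = starts, nh = nh,
                            stringsAsFactors = FALSE))
  })
}

#' Draw a seeded sample from a known mixture
#'
#' Test harness for the mixture-fitting module: draws `n` values from a
#' Gaussian or Gamma mixture with the given weights and per-component
#' parameters.
#'
#' @param family `"gaussian"` or `"gamma"`.
#' @param weights Component weights summing to 1.
#' @param params List of per-component parameter vectors:
#'   `c(mean, sd)` for gaussian, `c(shape, scale)` for gamma.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_dscore_sample <- function(family = c("gaussian", "gamma"),
                                   weights, params, n, seed = 1L) {
  family <- match.arg(family)
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  }
  if (length(weights) != length(params)) {
    stop("weights and params lengths differ", call. = FALSE)
  }
  with_seed(seed, {
    comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    vapply(comp, function(j) {
      p <- params[[j]]
      if (family == "gaussian") stats::rnorm(1, p[1], p[2])
      else stats::rgamma(1, shape = p[1], scale = p[2])
    }, numeric(1))
  })
}
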