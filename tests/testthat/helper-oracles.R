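# Independent oracles and small fixture builders used across the suite.

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Exhaustive Gotoh local-alignment score: match +1, mismatch -1, a gap of
# length g costs (2 + g). Independent of the Biostrings-based implementation.
oracle_local_score <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  Fm <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1] - 3, E[i, j - 1] - 1)
      Fm[i, j] <- max(H[i - 1, j] - 3, Fm[i - 1, j] - 1)
      s <- if (av[i - 1] == bv[j - 1]) 1 else -1
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], Fm[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

oracle_best_orientation_score <- function(a, b) {
  max(oracle_local_score(a, b), oracle_local_score(a, revcomp_chr(b)))
}

random_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Minimal SAM file: standard header plus the given record lines.
write_sam_fixture <- function(records, path, contig = "c1", len = 10000L) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, len),
               records), path)
  path
}

make_genes <- function(gene_id, contig, start, end, strand = "+") {
  data.frame(gene_id = gene_id, contig = contig, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

# Alignment-record data.frame in the shape produced by read_sam_alignments().
make_alignments <- function(read_id, flag = 0L, contig = "c1", pos = 1L,
                            cigar = "50M", nh = NA_integer_,
                            align_score = NA_integer_,
                            mate_index = NA_integer_) {
  data.frame(read_id = read_id, flag = flag, contig = contig, pos = pos,
             cigar = cigar, nh = nh, align_score = align_score,
             mate_index = mate_index, stringsAsFactors = FALSE)
}
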