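test_that("multiplicity uses NH when present, top-AS count otherwise", {
  aln <- rbind(
    make_alignments("r1", nh = 1L),
    make_alignments(rep("r2", 3), pos = c(1L, 100L, 200L),
                    align_score = c(-2L, 0L, 0L)),
    make_alignments(rep("r3", 2), pos = c(1L, 300L), nh = 2L))
  m <- classify_reads(aln)
  m <- m[order(m$unit_id), ]
  expect_equal(m$n_top_alignments, c(1L, 2L, 2L))
  expect_equal(m$is_mmr, c(FALSE, TRUE, TRUE))
})

test_that("records without NH or AS tie at full record count", {
  aln <- make_alignments(rep("r", 3), pos = c(1L, 50L, 90L))
  m <- classify_reads(aln)
  expect_equal(m$n_top_alignments, 3L)
})

test_that("conflicting NH values warn and take the maximum", {
  aln <- make_alignments(rep("r", 2), pos = c(1L, 50L), nh = c(2L, 3L))
  expect_warning(m <- classify_reads(aln), "conflicting NH")
  expect_equal(m$n_top_alignments, 3L)
})

test_that("paired mates are separate countable units", {
  aln <- rbind(make_alignments("frag", flag = 64L + 1L, mate_index = 1L,
                               nh = 1L),
               make_alignments("frag", flag = 128L + 1L, mate_index = 2L,
                               pos = c(200L, 400L), nh = 2L))
  m <- classify_reads(aln)
  expect_setequal(m$unit_id, c("frag/1", "frag/2"))
  expect_equal(m$n_top_alignments[m$unit_id == "frag/1"], 1L)
  expect_equal(m$n_top_alignments[m$unit_id == "frag/2"], 2L)
})

test_that("supplementary records are excluded, secondary included", {
  aln <- rbind(make_alignments("r", flag = 0L, pos = 1L),
               make_alignments("r", flag = 256L, pos = 100L),
               make_alignments("r", flag = 2048L, pos = 200L))
  m <- classify_reads(aln)
  expect_equal(m$n_top_alignments, 2L)
})

test_that("gene assignment honors overlap threshold and CIGAR blocks", {
  genes <- make_genes("g1", "c1", 11L, 110L)
  # full containment
  aln <- make_alignments("r1", pos = 11L, cigar = "50M")
  m <- classify_reads(aln)
  a <- assign_reads_to_genes(aln, genes, m)
  expect_equal(a$sets$g1$G, "r1")
  expect_equal(a$sets$g1$U, "r1")
  # 31 bp overlap at the gene tail: in at min 1, out at min 40
  aln <- make_alignments("r2", pos = 80L, cigar = "50M")
  m <- classify_reads(aln)
  expect_equal(assign_reads_to_genes(aln, genes, m)$sets$g1$G, "r2")
  expect_equal(
    assign_reads_to_genes(aln, genes, m, min_overlap_bp = 40L)$sets$g1$G,
    character(0))
  # spliced read whose N gap spans the gene entirely: not assigned
  aln <- make_alignments("r3", pos = 1L, cigar = "10M1000N10M")
  m <- classify_reads(aln)
  expect_equal(assign_reads_to_genes(aln, genes, m)$sets$g1$G, character(0))
})

test_that("alignments on unannotated contigs are skipped with a note", {
  genes <- make_genes("g1", "c1", 11L, 110L)
  aln <- rbind(make_alignments("r1", pos = 11L),
               make_alignments("r2", contig = "cX", pos = 11L))
  m <- classify_reads(aln)
  expect_message(a <- assign_reads_to_genes(aln, genes, m), "skipped")
  expect_equal(a$n_skipped, 1L)
  expect_equal(a$sets$g1$G, "r1")
})

test_that("U is always a subset of G and MMRs never enter U", {
  genes <- make_genes(c("g1", "g2"), "c1", c(11L, 200L), c(110L, 320L))
  aln <- rbind(
    make_alignments("u1", pos = 20L, nh = 1L),
    make_alignments(rep("m1", 2), pos = c(30L, 220L), nh = 2L),
    make_alignments("u2", pos = 240L, nh = 1L))
  m <- classify_reads(aln)
  a <- assign_reads_to_genes(aln, genes, m)
  for (g in names(a$sets)) {
    expect_true(all(a$sets[[g]]$U %in% a$sets[[g]]$G))
  }
  expect_equal(a$sets$g1$G, c("m1", "u1"))
  expect_equal(a$sets$g1$U, "u1")
  expect_equal(a$sets$g2$G, c("m1", "u2"))
})

test_that("shared MMR counts: simple cases", {
  mult <- data.frame(unit_id = c("r1", "r2", "r3"),
                     n_top_alignments = c(1L, 2L, 1L),
                     is_mmr = c(FALSE, TRUE, FALSE))
  sets <- list(a = list(G = c("r1", "r2"), U = "r1"),
               b = list(G = c("r2", "r3"), U = "r3"))
  sh <- shared_mmr_counts(sets, mult)
  expect_equal(nrow(sh), 1)
  expect_equal(sh$gene_i, "a")
  expect_equal(sh$gene_y, "b")
  expect_equal(sh$count, 1L)
  # disjoint G sets share nothing
  sets2 <- list(a = list(G = "r1", U = "r1"), b = list(G = "r3", U = "r3"))
  expect_equal(nrow(shared_mmr_counts(sets2, mult)), 0)
  # unique reads never contribute even when shared
  sets3 <- list(a = list(G = c("r1", "r3"), U = character(0)),
                b = list(G = c("r1", "r3"), U = character(0)))
  expect_equal(nrow(shared_mmr_counts(sets3, mult)), 0)
})

test_that("shared MMR counts agree with a brute-force double loop", {
  set.seed(42)
  n_genes <- 100
  n_reads <- 400
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  read_ids <- sprintf("r%03d", seq_len(n_reads))
  is_mmr <- runif(n_reads) < 0.4
  mult <- data.frame(unit_id = read_ids,
                     n_top_alignments = ifelse(is_mmr, 2L, 1L),
                     is_mmr = is_mmr)
  sets <- lapply(gene_ids, function(g) {
    G <- sample(read_ids, rpois(1, 8))
    list(G = sort(G), U = sort(G[!G %in% read_ids[is_mmr]]))
  })
  names(sets) <- gene_ids
  sh <- shared_mmr_counts(sets, mult)
  # brute force over all unordered pairs
  mmr_set <- read_ids[is_mmr]
  for (i in seq_len(n_genes - 1)) {
    for (j in seq(i + 1, n_genes)) {
      truth <- length(intersect(intersect(sets[[i]]$G, sets[[j]]$G),
                                mmr_set))
      row <- sh[sh$gene_i == gene_ids[i] & sh$gene_y == gene_ids[j], ]
      got <- if (nrow(row) == 0) 0L else row$count
      if (got != truth) {
        fail(sprintf("pair (%s, %s): got %d, brute force %d",
                     gene_ids[i], gene_ids[j], got, truth))
      }
    }
  }
  succeed()
})
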