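# A small end-to-end fixture (40 genes, 30% exact duplicates) built once
# per test run: genome/annotation/alignment files plus one annotated gene
# in a spacer region that no read touches.
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "mapuncert-fixture")
      dir.create(dir, showWarnings = FALSE)
      cfg <- simulation_config(n_genes = 40L, gene_length_bp = 500L,
                               duplicate_fraction = 0.3, divergence = 0,
                               read_length_bp = 80L, mean_depth = 10,
                               seed = 1L)
      sim <- simulate_genome(cfg)
      reads <- simulate_reads_sam(sim, cfg)
      fa <- file.path(dir, "genome.fa")
      gff <- file.path(dir, "genes.gff3")
      sam <- file.path(dir, "alignments.sam")
      writeLines(sub("\n$", "", sim$fasta), fa)
      gff_lines <- strsplit(sub("\n$", "", sim$gff3), "\n")[[1]]
      gff_lines <- c(gff_lines,
                     "chr1\tsim\tgene\t30\t170\t.\t+\t.\tID=gene_silent")
      writeLines(gff_lines, gff)
      writeLines(sub("\n$", "", reads$sam), sam)
      cache <<- list(dir = dir, fa = fa, gff = gff, sam = sam, sim = sim,
                     reads = reads, cfg = cfg)
    }
    cache
  }
})
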