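# Read multiplicity classification and per-gene read-set construction.
#
# A countable unit is a read for single-end data and a single mate for
# paired-end data (unit id = read_id, or read_id"/1" / "/2"). Supplementary
# records (flag 0x800) never count; secondary records (0x100) do, since they
# encode the alternative locations that make a read a multi-mapper.

unit_ids <- function(read_id, mate_index) {
  ifelse(is.na(mate_index), read_id, paste0(read_id, "/", mate_index))
}

#' Classify reads by mapping multiplicity
#'
#' Determines, for every countable unit (read, or mate of a read pair), the
#' number of best-scoring alignment locations and whether the unit is a
#' multi-mapping read (MMR). The `NH` tag takes precedence when present;
#' otherwise the unit's records with the maximal `AS` alignment score are
#' counted (all records tie when `AS` is absent).
#'
#' @param alignments Alignment records as returned by [read_sam_alignments()].
#' @return A `data.frame` with columns `unit_id`, `n_top_alignments`
#'   (integer >= 1) and `is_mmr` (`n_top_alignments > 1`).
#' @export
classify_reads <- function(alignments) {
  aln <- alignments[!is.na(alignments$contig) &
                      bitwAnd(alignments$flag, 2048L) == 0L, , drop = FALSE]
  if (nrow(aln) == 0) {
    return(data.frame(unit_id = character(0), n_top_alignments = integer(0),
                      is_mmr = logical(0)))
  }
  uid <- unit_ids(aln$read_id, aln$mate_index)
  groups <- split(seq_len(nrow(aln)), uid)
  mult <- vapply(groups, function(idx) {
    nh <- aln$nh[idx]
    nh <- nh[!is.na(nh)]
    if (length(nh) > 0) {
      if (length(unique(nh)) > 1) {
        warning("conflicting NH values for unit '",
                unit_ids(aln$read_id[idx[1]], aln$mate_index[idx[1]]),
                "'; taking the maximum", call. = FALSE)
      }
      return(max(nh))
    }
    sc <- aln$align_score[idx]
    if (all(is.na(sc))) length(idx) else sum(sc == max(sc, na.rm = TRUE),
                                             na.rm = TRUE)
  }, integer(1))
  data.frame(unit_id = names(groups), n_top_alignments = unname(mult),
             is_mmr = unname(mult) > 1L, stringsAsFactors = FALSE)
}

#' Assign reads to genes by genomic overlap
#'
#' A unit belongs to a gene's read set G when at least one of its alignments'
#' reference-aligned CIGAR blocks (runs of M/=/X/D; spliced N gaps split
#' blocks) overlaps the gene's genomic span by at least `min_overlap_bp`.
#' It additionally belongs to the unique set U when its multiplicity is 1.
#'
#' @param alignments Alignment records as returned by [read_sam_alignments()].
#' @param genes Gene models as returned by [read_gff_genes()].
#' @param multiplicity Output of [classify_reads()] on the same alignments.
#' @param min_overlap_bp Minimum aligned-block overlap, in bp (default 1).
#' @return A list with elements `sets` (named list: per gene, a list with
#'   character vectors `G` and `U`) and `n_skipped` (alignments on contigs
#'   absent from the annotation).
#' @export
assign_reads_to_genes <- function(alignments, genes, multiplicity,
                                  min_overlap_bp = 1L) {
  stopifnot(min_overlap_bp >= 1L)
  aln <- alignments[!is.na(alignments$contig) &
                      bitwAnd(alignments$flag, 2048L) == 0L, , drop = FALSE]
  known <- aln$contig %in% genes$contig
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    message(n_skipped, " alignment(s) on contigs absent from the annotation ",
            "were skipped")
  }
  aln <- aln[known, , drop = FALSE]
  unique_units <- multiplicity$unit_id[!multiplicity$is_mmr]
  sets <- stats::setNames(
    lapply(genes$gene_id, function(g) list(G = character(0), U = character(0))),
    genes$gene_id)
  if (nrow(aln) > 0) {
    uid <- unit_ids(aln$read_id, aln$mate_index)
    hit_gene <- character(0)
    hit_unit <- character(0)
    # ungapped `<n>M` CIGARs are one block; only spliced/indel records need
    # the general parser
    simple <- grepl("^[0-9]+M$", aln$cigar)
    for (ctg in unique(aln$contig)) {
      gidx <- which(genes$contig == ctg)
      ridx <- which(aln$contig == ctg)
      gene_ranges <- IRanges::IRanges(start = genes$start[gidx],
                                      end = genes$end[gidx])
      sidx <- ridx[simple[ridx]]
      cidx <- ridx[!simple[ridx]]
      bstart <- aln$pos[sidx]
      bend <- bstart + as.integer(sub("M$", "", aln$cigar[sidx])) - 1L
      baln <- sidx
      for (i in cidx) {
        blk <- cigar_aligned_blocks(aln$cigar[i], aln$pos[i])
        bstart <- c(bstart, IRanges::start(blk))
        bend <- c(bend, IRanges::end(blk))
        baln <- c(baln, rep(i, length(blk)))
      }
      if (length(bstart) == 0) next
      ov <- IRanges::findOverlaps(IRanges::IRanges(start = bstart,
                                                   end = bend),
                                  gene_ranges,
                                  minoverlap = min_overlap_bp)
      if (length(ov) == 0) next
      hit_gene <- c(hit_gene, genes$gene_id[gidx[S4Vectors::subjectHits(ov)]])
      hit_unit <- c(hit_unit, uid[baln[S4Vectors::queryHits(ov)]])
    }
    if (length(hit_gene) > 0) {
      keep <- !duplicated(paste(hit_gene, hit_unit, sep = "\r"))
      by_gene <- split(hit_unit[keep], hit_gene[keep])
      for (g in names(by_gene)) {
        units <- sort(by_gene[[g]])
        sets[[g]]$G <- units
        sets[[g]]$U <- units[units %in% unique_units]
      }
    }
  }
  list(sets = sets, n_skipped = n_skipped)
}

#' Count multi-mapping reads shared between gene pairs
#'
#' For every unordered pair of genes, counts the multi-mapping units present
#' in both genes' read sets G. Pairs sharing no MMR are omitted.
#'
#' @param gene_read_sets The `sets` element returned by
#'   [assign_reads_to_genes()].
#' @param multiplicity Output of [classify_reads()].
#' @return A `data.frame` with columns `gene_i`, `gene_y` (with
#'   `gene_i < gene_y` lexicographically) and `count` (>= 1).
#' @export
shared_mmr_counts <- function(gene_read_sets, multiplicity) {
  mmr_units <- multiplicity$unit_id[multiplicity$is_mmr]
  empty <- data.frame(gene_i = character(0), gene_y = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (length(mmr_units) == 0) return(empty)
  gene_of <- rep(names(gene_read_sets),
                 vapply(gene_read_sets, function(s)
                   sum(s$G %in% mmr_units), integer(1)))
  unit_of <- unlist(lapply(gene_read_sets, function(s)
    s$G[s$G %in% mmr_units]), use.names = FALSE)
  if (length(unit_of) == 0) return(empty)
  by_unit <- split(gene_of, unit_of)
  pair_keys <- unlist(lapply(by_unit, function(gs) {
    gs <- sort(unique(gs))
    if (length(gs) < 2) return(character(0))
    cmb <- utils::combn(gs, 2)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  }), use.names = FALSE)
  if (length(pair_keys) == 0) return(empty)
  tab <- table(pair_keys)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  data.frame(gene_i = vapply(parts, `[[`, "", 1L),
             gene_y = vapply(parts, `[[`, "", 2L),
             count = as.integer(tab), stringsAsFactors = FALSE,
             row.names = NULL)
}
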