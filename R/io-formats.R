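#' Read a reference genome from a FASTA file
#'
#' Loads every record of a (possibly multi-line) FASTA file, uppercases the
#' sequence and keys it by the first whitespace-delimited token of its header.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one element per contig.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA format error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0) stop("FASTA format error: no records in ", path,
                              call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("FASTA format error: duplicate contig id '",
         ids[duplicated(ids)][1], "'", call. = FALSE)
  }
  if (any(Biostrings::width(seqs) == 0)) {
    stop("FASTA format error: empty sequence for contig '",
         ids[Biostrings::width(seqs) == 0][1], "'", call. = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- ids
  seqs
}

#' Read gene models from a GFF3 annotation
#'
#' Extracts features of the requested types as gene models. Coordinates are
#' kept 1-based inclusive, as in GFF3. Gene ids come from the `ID` attribute,
#' falling back to a `contig:start-end` locus string.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Character vector of feature types to keep
#'   (column 3 of the GFF3). Default `"gene"`.
#' @return A `data.frame` with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` (one of `+`, `-`, `.`).
#' @export
read_gff_genes <- function(path, feature_types = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  gr <- tryCatch(
    rtracklayer::import(con = path, format = "gff3"),
    error = function(e) stop("GFF3 format error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (length(gr) == 0) {
    stop("empty annotation: no features of type ",
         paste(feature_types, collapse = "/"), " in ", path, call. = FALSE)
  }
  contig <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  ids <- as.character(gr$ID %||% rep(NA_character_, length(gr)))
  locus <- paste0(contig, ":", start, "-", end)
  ids[is.na(ids) | ids == ""] <- locus[is.na(ids) | ids == ""]
  if (anyDuplicated(ids)) {
    stop("GFF3 format error: duplicate gene id '",
         ids[duplicated(ids)][1], "'", call. = FALSE)
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(gene_id = ids, contig = contig, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Read alignment records from a SAM file
#'
#' Parses the text SAM format (mandatory columns plus the `NH` and `AS`
#' optional tags). Header lines (`@`) are skipped wherever they occur before
#' records. Unmapped records (flag bit 0x4) are kept with `contig = NA`.
#'
#' @param path Path to a SAM file.
#' @return A `data.frame` with one row per alignment record and columns
#'   `read_id`, `flag`, `contig` (NA when unmapped), `pos`, `cigar`,
#'   `nh` (NA when the tag is absent), `align_score` (NA when absent) and
#'   `mate_index` (1, 2 or NA, from flag bits 0x40/0x80).
#' @export
read_sam_alignments <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  rec_lines <- which(!is_header & nzchar(lines))
  n <- length(rec_lines)
  if (n == 0) {
    return(data.frame(read_id = character(0), flag = integer(0),
                      contig = character(0), pos = integer(0),
                      cigar = character(0), nh = integer(0),
                      align_score = integer(0), mate_index = integer(0)))
  }
  fields <- strsplit(lines[rec_lines], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11)) {
    bad <- rec_lines[which(nf < 11)[1]]
    stop("SAM format error at line ", bad, ": fewer than 11 columns",
         call. = FALSE)
  }
  read_id <- vapply(fields, `[[`, "", 1L)
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  if (anyNA(flag) || anyNA(pos)) {
    bad <- rec_lines[which(is.na(flag) | is.na(pos))[1]]
    stop("SAM format error at line ", bad, ": non-numeric FLAG or POS",
         call. = FALSE)
  }
  contig <- vapply(fields, `[[`, "", 3L)
  cigar <- vapply(fields, `[[`, "", 6L)
  unmapped <- bitwAnd(flag, 4L) != 0L
  contig[unmapped | contig == "*"] <- NA_character_
  if (any(!unmapped & pos < 1L)) {
    bad <- rec_lines[which(!unmapped & pos < 1L)[1]]
    stop("SAM format error at line ", bad, ": mapped record with POS < 1",
         call. = FALSE)
  }
  tag_value <- function(recs, tag) {
    m <- regexpr(paste0("\t", tag, ":i:(-?[0-9]+)"), recs)
    out <- rep(NA_integer_, length(recs))
    hit <- m != -1L
    out[hit] <- as.integer(substring(
      regmatches(recs, m), nchar(tag) + 5L))
    out
  }
  recs <- lines[rec_lines]
  nh <- tag_value(recs, "NH")
  as_tag <- tag_value(recs, "AS")
  mate_index <- rep(NA_integer_, n)
  mate_index[bitwAnd(flag, 64L) != 0L] <- 1L
  mate_index[bitwAnd(flag, 128L) != 0L] <- 2L
  data.frame(read_id = read_id, flag = flag, contig = contig, pos = pos,
             cigar = cigar, nh = nh, align_score = as_tag,
             mate_index = mate_index, stringsAsFactors = FALSE)
}

#' Write the per-gene mapping-uncertainty report
#'
#' Writes a tab-separated table with the columns `Gene ID`, `D1`, `D2`, `D3`,
#' `D-score`, `Category` and `Alternative likelihood`, one row per gene in
#' input order. Numeric values are rendered to 6 decimal places with
#' trailing zeros dropped.
#'
#' @param rows A `data.frame` with columns `gene_id`, `d1`, `d2`, `d3`,
#'   `d_score`, `category`, `alt_likelihood`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    stop("report rows must be a nonempty data.frame", call. = FALSE)
  }
  needed <- c("gene_id", "d1", "d2", "d3", "d_score", "category",
              "alt_likelihood")
  missing <- setdiff(needed, names(rows))
  if (length(missing) > 0) {
    stop("report rows missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fmt <- function(x) {
    vapply(x, function(v) format(round(v, 6), scientific = FALSE,
                                 trim = TRUE, drop0trailing = TRUE),
           character(1))
  }
  out <- data.frame(rows$gene_id, fmt(rows$d1), fmt(rows$d2), fmt(rows$d3),
                    fmt(rows$d_score), as.character(rows$category),
                    fmt(rows$alt_likelihood), stringsAsFactors = FALSE)
  header <- c("Gene ID", "D1", "D2", "D3", "D-score", "Category",
              "Alternative likelihood")
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write report to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a mapping-uncertainty report back into a data.frame
#'
#' Inverse of [write_report()]; used for round-trip checks and downstream
#' consumption of saved reports.
#'
#' @param path Path to a report written by [write_report()].
#' @return A `data.frame` with the same columns as the `rows` argument of
#'   [write_report()].
#' @export
read_report <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  data.frame(gene_id = as.character(tab[["Gene ID"]]),
             d1 = as.numeric(tab[["D1"]]), d2 = as.numeric(tab[["D2"]]),
             d3 = as.numeric(tab[["D3"]]),
             d_score = as.numeric(tab[["D-score"]]),
             category = as.character(tab[["Category"]]),
             alt_likelihood = as.numeric(tab[["Alternative likelihood"]]),
             stringsAsFactors = FALSE)
}
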