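# Internal helpers shared across modules.

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Parse a CIGAR string into per-operation (op, length) pairs.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(data.frame(op = character(0), len = integer(0)))
  }
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]]
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops) || length(ops) == 0 ||
      paste0(paste0(lens, ops), collapse = "") != cigar) {
    stop("malformed CIGAR string: ", cigar, call. = FALSE)
  }
  data.frame(op = ops, len = as.integer(lens))
}

# Reference-aligned blocks of an alignment starting at `pos` (1-based).
# M/=/X/D consume reference within a block; N splits blocks (spliced gap);
# I/S/H/P consume no reference. Returns an IRanges of aligned blocks.
cigar_aligned_blocks <- function(cigar, pos) {
  ops <- parse_cigar(cigar)
  starts <- integer(0)
  ends <- integer(0)
  cur_start <- NA_integer_
  ref <- pos
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]
    len <- ops$len[i]
    if (op %in% c("M", "=", "X", "D")) {
      if (is.na(cur_start)) cur_start <- ref
      ref <- ref + len
    } else if (op == "N") {
      if (!is.na(cur_start)) {
        starts <- c(starts, cur_start)
        ends <- c(ends, ref - 1L)
        cur_start <- NA_integer_
      }
      ref <- ref + len
    }
    # I, S, H, P: no reference consumption, block continues
  }
  if (!is.na(cur_start)) {
    starts <- c(starts, cur_start)
    ends <- c(ends, ref - 1L)
  }
  IRanges::IRanges(start = starts, end = ends)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
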