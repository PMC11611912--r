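# Minimal SAM text interchange: enough to hand alignments to and from other
# tools.  Internal coordinates are 0-based half-open; SAM POS is 1-based.

#' Write alignments as a minimal SAM file
#'
#' Emits a header (`@HD`, one `@SQ` per gene) and one ungapped alignment
#' line per record with a `<len>M` CIGAR.  Fragment sequences are written
#' when the alignment table carries a `frag` column.
#'
#' @param alignments data.frame with columns `read_id`, `gene_id`, `start`,
#'   `end` (0-based half-open) and `strand`; optionally `frag`.
#' @param genes a `gene_set` providing reference names and lengths.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sam <- function(alignments, genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", genes$gene_id,
                     nchar(genes$tx_seq)), con)
  len <- alignments$end - alignments$start
  seqs <- if (!is.null(alignments$frag)) alignments$frag else
    strrep("N", len)
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                     alignments$read_id, flag, alignments$gene_id,
                     alignments$start + 1L, len, seqs,
                     strrep("I", nchar(seqs))), con)
  invisible(path)
}

#' Read alignments from a SAM file
#'
#' Parses mapped primary alignments from a plain-text SAM file into the
#' package's 0-based half-open alignment table.  The reference span is
#' taken from the CIGAR (`M/D/N/=/X` operations consume reference).
#'
#' @param path SAM file.
#' @return data.frame with columns `read_id`, `gene_id`, `start`, `end`,
#'   `strand` and `status` (always `"OK"`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(read_id = character(0), gene_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), status = character(0),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  mapped <- bitwAnd(flag, 4L) == 0L
  f <- f[mapped]; flag <- flag[mapped]
  start <- vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L
  ref_len <- vapply(f, function(x) .cigar_ref_len(x[6]), integer(1))
  data.frame(read_id = vapply(f, `[`, character(1), 1L),
             gene_id = vapply(f, `[`, character(1), 3L),
             start = start,
             end = start + ref_len,
             strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
             status = "OK", stringsAsFactors = FALSE)
}

.cigar_ref_len <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops)) stop("cannot parse CIGAR: ", cigar)
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}
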