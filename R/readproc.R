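#' Read and write 4-line FASTQ files
#'
#' Thin wrappers around Biostrings' FASTQ support working on plain
#' data.frames with columns `id`, `seq` and `qual` (Phred+33).
#'
#' @param path FASTQ file.
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @return `read_fastq()` returns the data.frame; `write_fastq()` the path,
#'   invisibly.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = sub("\\s.*", "", names(x)),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Decompose raw footprint reads into fragment, UMI and barcode
#'
#' Raw reads follow the layout `QQQ | footprint | UMI(5) | barcode(5) |
#' adapter`: the first `n_untemplated` bases are removed, the adapter is
#' located (first exact occurrence anywhere; a trailing partial adapter at
#' the read end is also trimmed) and everything from it on is discarded.
#' Reads without any adapter match are rejected (`NO_ADAPTER`), reads whose
#' trimmed remainder (footprint + UMI + barcode) is shorter than
#' `min_len_after_trim` are rejected (`TOO_SHORT`), and reads too short to
#' contain the fixed-length parts at all are `MALFORMED`.  The remainder is
#' split from the 3' end as `fragment | umi | barcode`.
#'
#' @param reads data.frame with columns `id` and `seq` (e.g. from
#'   [read_fastq()]).
#' @param read a single read: character sequence, or a list/1-row data.frame
#'   with `seq` (and optionally `id`).
#' @param adapter adapter sequence (exact matching).
#' @param n_untemplated number of untemplated 5' bases to drop.
#' @param umi_len,barcode_len lengths of the UMI and sample barcode.
#' @param min_len_after_trim minimum length of the trimmed remainder; with
#'   the default 30 and 5+5 nt of UMI/barcode, fragments are >= 20 nt.
#' @return `decompose_reads()` returns a data.frame with columns `id`,
#'   `fragment`, `umi`, `barcode`, `status` (`"OK"`, `"NO_ADAPTER"`,
#'   `"TOO_SHORT"` or `"MALFORMED"`).  `decompose_read()` returns a list of
#'   class `footprint` on success, otherwise the rejection reason as a
#'   character scalar.
#' @export
decompose_reads <- function(reads, adapter = RIBOSEQ_ADAPTER,
                            n_untemplated = 3L, umi_len = 5L,
                            barcode_len = 5L, min_len_after_trim = 30L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  seq <- toupper(reads$seq)
  n <- length(seq)
  status <- rep("OK", n)
  fragment <- umi <- barcode <- rep(NA_character_, n)
  tail_len <- umi_len + barcode_len
  status[nchar(seq) < n_untemplated + tail_len] <- "MALFORMED"
  body <- substring(seq, n_untemplated + 1L)
  nb <- nchar(body)
  pos <- as.integer(regexpr(adapter, body, fixed = TRUE))
  # trailing partial adapter: longest adapter prefix that is a read suffix
  miss <- status == "OK" & pos < 0L
  if (any(miss)) {
    for (k in seq.int(nchar(adapter) - 1L, 1L)) {
      if (!any(miss)) break
      pref <- substr(adapter, 1L, k)
      hit <- miss & nb >= k & substring(body, nb - k + 1L) == pref
      pos[hit] <- nb[hit] - k + 1L
      miss <- miss & !hit
    }
  }
  status[status == "OK" & pos < 0L] <- "NO_ADAPTER"
  ok <- status == "OK"
  kept <- substr(body, 1L, pos - 1L)
  status[ok & nchar(kept) < min_len_after_trim] <- "TOO_SHORT"
  status[ok & nchar(kept) < tail_len + 1L] <- "MALFORMED"
  ok <- status == "OK"
  nk <- nchar(kept)
  fragment[ok] <- substr(kept[ok], 1L, nk[ok] - tail_len)
  umi[ok] <- substr(kept[ok], nk[ok] - tail_len + 1L, nk[ok] - barcode_len)
  barcode[ok] <- substring(kept[ok], nk[ok] - barcode_len + 1L)
  data.frame(id = if (is.null(reads$id)) as.character(seq_len(n)) else reads$id,
             fragment = fragment, umi = umi, barcode = barcode,
             status = status, stringsAsFactors = FALSE)
}

#' @rdname decompose_reads
#' @export
decompose_read <- function(read, adapter = RIBOSEQ_ADAPTER,
                           n_untemplated = 3L, umi_len = 5L,
                           barcode_len = 5L, min_len_after_trim = 30L) {
  if (is.character(read)) read <- list(id = "read", seq = read)
  res <- decompose_reads(as.data.frame(read, stringsAsFactors = FALSE),
                         adapter, n_untemplated, umi_len, barcode_len,
                         min_len_after_trim)
  if (res$status != "OK") return(res$status)
  structure(list(id = res$id, fragment = res$fragment, umi = res$umi,
                 barcode = res$barcode), class = "footprint")
}

#' @export
print.footprint <- function(x, ...) {
  cat(sprintf("footprint %s: %d nt, UMI %s, barcode %s\n",
              x$id, nchar(x$fragment), x$umi, x$barcode))
  invisible(x)
}

#' Collapse PCR duplicates by UMI
#'
#' Retains the first occurrence of each distinct (UMI, fragment sequence)
#' pair, preserving input order.  The fragment sequence is part of the key
#' so that distinct molecules that happen to share a UMI are not collapsed.
#'
#' @param footprints data.frame with columns `umi` and `fragment` (extra
#'   columns are carried through).
#' @return the deduplicated data.frame; the number of removed rows is
#'   attached as attribute `"n_removed"`.
#' @export
dedup_umi <- function(footprints) {
  stopifnot(all(c("umi", "fragment") %in% names(footprints)))
  key <- paste(footprints$umi, footprints$fragment, sep = "\r")
  keep <- !duplicated(key)
  out <- footprints[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}
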