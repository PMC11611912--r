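#' Process raw footprint reads into occupancy profiles
#'
#' Chains the preprocessing and occupancy stages: adapter/UMI decomposition,
#' UMI deduplication, contaminant filtering, unique exact mapping, A-site
#' assignment and profile construction.  Read-count bookkeeping is returned
#' alongside the profiles and balances exactly at every stage.
#'
#' @param reads raw reads: a data.frame with `id` and `seq` columns, or a
#'   FASTQ path.
#' @param genes a `gene_set`.
#' @param adapter adapter sequence for [decompose_reads()].
#' @param contaminants optional contaminant sequences for
#'   [filter_contaminants()].
#' @param offset A-site offset in nt.
#' @param min_len_after_trim minimum post-trim length (footprint + UMI +
#'   barcode).
#' @param alignments optional externally produced alignments (e.g. from
#'   [read_sam()]); when supplied, the decomposition/mapping stages are
#'   skipped and only A-site assignment and profiling run.
#' @return list of class `ribo_run` with elements `profiles`
#'   (an `occupancy_profiles`), `footprints` (deduplicated, retained),
#'   `alignments` (A-site annotated) and `tally` (named integer vector of
#'   read counts at every stage).
#' @export
footprints_to_profiles <- function(reads, genes,
                                   adapter = RIBOSEQ_ADAPTER,
                                   contaminants = NULL,
                                   offset = 11L,
                                   min_len_after_trim = 30L,
                                   alignments = NULL) {
  tally <- c()
  if (is.null(alignments)) {
    if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
    fp <- decompose_reads(reads, adapter = adapter,
                          min_len_after_trim = min_len_after_trim)
    tally["raw_reads"] <- nrow(fp)
    tally["no_adapter"] <- sum(fp$status == "NO_ADAPTER")
    tally["too_short"] <- sum(fp$status == "TOO_SHORT")
    tally["malformed"] <- sum(fp$status == "MALFORMED")
    fp <- fp[fp$status == "OK", , drop = FALSE]
    tally["footprints"] <- nrow(fp)
    fp <- dedup_umi(fp)
    tally["umi_duplicates"] <- attr(fp, "n_removed")
    tally["after_dedup"] <- nrow(fp)
    fp <- filter_contaminants(fp, contaminants)
    tally["contaminant"] <- attr(fp, "n_removed")
    aln <- map_fragments(fp, genes)
    tally["unmapped"] <- sum(aln$status == "UNMAPPED")
    tally["multimapped"] <- sum(aln$status == "MULTIMAPPED")
    aln <- aln[aln$status == "OK", , drop = FALSE]
    tally["mapped"] <- nrow(aln)
  } else {
    fp <- NULL
    aln <- alignments[alignments$status == "OK", , drop = FALSE]
    tally["mapped"] <- nrow(aln)
  }
  aln <- assign_asite(aln, genes, offset = offset)
  tally["out_of_cds"] <- sum(aln$asite_status == "OUT_OF_CDS")
  profiles <- build_profiles(aln, genes)
  tally["retained"] <- sum(vapply(profiles, `[[`, numeric(1), "total_reads"))
  structure(list(profiles = profiles, footprints = fp, alignments = aln,
                 tally = tally),
            class = "ribo_run")
}

#' @export
print.ribo_run <- function(x, ...) {
  cat("footprint processing run\n")
  for (nm in names(x$tally))
    cat(sprintf("  %-14s %d\n", nm, x$tally[[nm]]))
  invisible(x)
}
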