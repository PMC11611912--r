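#' Remove footprints matching contaminant sequences
#'
#' Discards every footprint whose fragment occurs as an exact substring of
#' any contaminant sequence (either strand), emulating the rRNA/tRNA
#' depletion step of footprint processing.
#'
#' @param footprints data.frame with a `fragment` column.
#' @param contaminants contaminant sequences: a `DNAStringSet`, a character
#'   vector, a FASTA path, or `NULL`/empty to retain everything.
#' @return the retained footprints; removed count in attribute
#'   `"n_removed"`.
#' @export
filter_contaminants <- function(footprints, contaminants = NULL) {
  if (is.null(contaminants) || length(contaminants) == 0L) {
    attr(footprints, "n_removed") <- 0L
    return(footprints)
  }
  subj <- .as_dna_set(contaminants)
  hits <- .substring_hits(footprints$fragment, subj, both_strands = TRUE)
  keep <- hits$count == 0L
  out <- footprints[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Map footprint fragments to a transcriptome by unique exact match
#'
#' Each fragment is searched as an exact substring of every transcript on
#' both strands.  Fragments with exactly one occurrence produce an
#' alignment; fragments occurring more than once anywhere are discarded as
#' `MULTIMAPPED`, absent fragments as `UNMAPPED`.  This is the package's
#' deliberate exact-match stand-in for a short-read aligner run in
#' unique-mapping mode; externally produced alignments can be supplied via
#' [read_sam()] instead.
#'
#' @param footprints data.frame with columns `id` and `fragment`.
#' @param genes a `gene_set` (uses `tx_seq` as the mapping target).
#' @param fragment a single fragment sequence for `map_unique()`.
#' @return `map_fragments()`: data.frame with columns `read_id`, `gene_id`,
#'   `start`, `end` (0-based half-open on the transcript), `strand` and
#'   `status` (`"OK"`, `"UNMAPPED"`, `"MULTIMAPPED"`).  `map_unique()`
#'   returns a one-row alignment record or the status string.
#' @export
map_fragments <- function(footprints, genes) {
  subj <- Biostrings::DNAStringSet(setNames(genes$tx_seq, genes$gene_id))
  hits <- .substring_hits(footprints$fragment, subj, both_strands = TRUE)
  status <- ifelse(hits$count == 0L, "UNMAPPED",
                   ifelse(hits$count > 1L, "MULTIMAPPED", "OK"))
  uniq <- status == "OK"
  data.frame(read_id = footprints$id,
             gene_id = ifelse(uniq, genes$gene_id[hits$subject],
                              NA_character_),
             start = ifelse(uniq, hits$start, NA_integer_),
             end = ifelse(uniq, hits$start + nchar(footprints$fragment),
                          NA_integer_),
             strand = ifelse(uniq, hits$strand, NA_character_),
             status = status, stringsAsFactors = FALSE)
}

#' @rdname map_fragments
#' @export
map_unique <- function(fragment, genes) {
  res <- map_fragments(data.frame(id = "fragment", fragment = fragment,
                                  stringsAsFactors = FALSE), genes)
  if (res$status != "OK") return(res$status)
  res
}

#' Assign ribosomal A sites to alignments by the 3'-end offset rule
#'
#' The A-site nucleotide lies `offset` nt upstream of the footprint's 3'
#' end, measured along the read's 5'->3' direction (for a minus-strand
#' alignment the 3' end is the leftmost aligned base and the offset runs
#' rightward).  The A-site codon index is `floor((asite_nt - cds_start) /
#' 3)`; A sites outside the CDS are flagged `OUT_OF_CDS`.
#'
#' @param alignments data.frame with columns `gene_id`, `start`, `end`
#'   (0-based half-open) and `strand` (e.g. from [map_fragments()] or
#'   [read_sam()]).
#' @param genes a `gene_set`.
#' @param offset A-site offset in nt (estimated per library; 11 by
#'   default).
#' @return the input with columns `asite_nt`, `asite_codon` (0-based) and
#'   `asite_status` (`"OK"` or `"OUT_OF_CDS"`) appended; rows whose mapping
#'   status is not `"OK"` get `NA` A sites.
#' @export
assign_asite <- function(alignments, genes, offset = 11L) {
  idx <- match(alignments$gene_id, genes$gene_id)
  frag_len <- alignments$end - alignments$start
  if (any(offset >= frag_len[!is.na(frag_len)]))
    stop("A-site offset must be smaller than the fragment length")
  plus <- alignments$strand == "+"
  end3 <- ifelse(plus, alignments$end - 1L, alignments$start)
  asite_nt <- ifelse(plus, end3 - offset, end3 + offset)
  cds_start <- genes$cds_start[idx]
  cds_end <- genes$cds_end[idx]
  in_cds <- !is.na(asite_nt) & asite_nt >= cds_start & asite_nt < cds_end
  alignments$asite_nt <- as.integer(ifelse(in_cds, asite_nt, NA_integer_))
  alignments$asite_codon <- as.integer(
    ifelse(in_cds, (asite_nt - cds_start) %/% 3L, NA_integer_))
  alignments$asite_status <- ifelse(is.na(asite_nt), NA_character_,
                                    ifelse(in_cds, "OK", "OUT_OF_CDS"))
  alignments
}

#' Construct an occupancy profile directly
#'
#' Builds a single-gene ribosome-density container from explicit counts;
#' mostly useful for constructing controlled inputs.  When only
#' `codon_counts` is given, counts are placed on the first nucleotide of
#' each codon (where A-site assignment puts them); when only `nt_counts` is
#' given, codon counts are derived by summing nucleotide triplets.
#'
#' @param gene_id gene identifier.
#' @param nt_counts integer vector of per-nucleotide A-site counts over the
#'   CDS (length divisible by 3), or `NULL`.
#' @param codon_counts integer vector of per-codon counts, or `NULL`.
#' @return an object of class `occupancy_profile` with elements `gene_id`,
#'   `nt_counts`, `codon_counts` and `total_reads`.
#' @export
occupancy_profile <- function(gene_id, nt_counts = NULL, codon_counts = NULL) {
  if (is.null(nt_counts) && is.null(codon_counts))
    stop("supply nt_counts or codon_counts")
  if (is.null(nt_counts)) {
    nt_counts <- integer(3L * length(codon_counts))
    nt_counts[seq_along(codon_counts) * 3L - 2L] <- codon_counts
  }
  if (length(nt_counts) %% 3L != 0L)
    stop("nt_counts length must be divisible by 3")
  if (is.null(codon_counts))
    codon_counts <- as.integer(colSums(matrix(nt_counts, nrow = 3L)))
  if (sum(codon_counts) != sum(nt_counts))
    stop("codon_counts and nt_counts disagree")
  structure(list(gene_id = gene_id,
                 nt_counts = as.integer(nt_counts),
                 codon_counts = as.integer(codon_counts),
                 total_reads = sum(as.integer(nt_counts))),
            class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat(sprintf("occupancy profile %s: %d codons, %d reads\n",
              x$gene_id, length(x$codon_counts), x$total_reads))
  invisible(x)
}

#' Build per-gene occupancy profiles from A-site assigned alignments
#'
#' Tallies A-site nucleotides and codons per gene.  Alignments whose A site
#' is outside the CDS (or that failed mapping) are excluded and counted in
#' the `"excluded"` attribute.
#'
#' @param alignments output of [assign_asite()].
#' @param genes a `gene_set`.
#' @return an object of class `occupancy_profiles`: a named list of
#'   [occupancy_profile()] objects, one per gene in `genes`.
#' @export
build_profiles <- function(alignments, genes) {
  ok <- !is.na(alignments$asite_status) & alignments$asite_status == "OK"
  excl <- nrow(alignments) - sum(ok)
  aln <- alignments[ok, , drop = FALSE]
  profs <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    n_nt <- g$cds_end - g$cds_start
    rows <- aln[aln$gene_id == g$gene_id, , drop = FALSE]
    nt_counts <- tabulate(rows$asite_nt - g$cds_start + 1L, nbins = n_nt)
    occupancy_profile(g$gene_id, nt_counts = nt_counts)
  })
  names(profs) <- genes$gene_id
  structure(profs, class = "occupancy_profiles", excluded = excl)
}

#' @export
print.occupancy_profiles <- function(x, ...) {
  tot <- sum(vapply(x, `[[`, numeric(1), "total_reads"))
  cat(sprintf("occupancy profiles: %d genes, %d assigned reads\n",
              length(x), tot))
  invisible(x)
}

#' Sum occupancy profiles across replicates
#'
#' Element-wise sum of counts over profile sets covering the same genes;
#' pause and motif statistics are computed on such aggregates.
#'
#' @param ... two or more `occupancy_profiles` objects (or a single list of
#'   them).
#' @return an `occupancy_profiles` object with summed counts.
#' @export
aggregate_replicates <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "occupancy_profiles"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  ref <- names(sets[[1]])
  for (s in sets[-1]) {
    if (!identical(names(s), ref)) stop("profile sets cover different genes")
  }
  out <- lapply(ref, function(g) {
    nt <- Reduce(`+`, lapply(sets, function(s) s[[g]]$nt_counts))
    occupancy_profile(g, nt_counts = nt)
  })
  names(out) <- ref
  structure(out, class = "occupancy_profiles",
            excluded = sum(vapply(sets, function(s)
              attr(s, "excluded") %||% 0L, numeric(1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Metagene occupancy averaged over genes
#'
#' Normalizes each qualifying gene's codon counts to mean 1 over the gene,
#' anchors the profiles at the start or stop codon, and averages across
#' genes.  Used to check that a perturbation leaves initiation and
#' termination unaffected.
#'
#' @param profiles an `occupancy_profiles` object.
#' @param anchor `"START"` (first `window` codons) or `"STOP"` (last
#'   `window` codons).
#' @param window number of codons to keep.
#' @param min_gene_reads minimum total reads for a gene to qualify.
#' @return named numeric vector of mean normalized occupancy; names are
#'   codon offsets from the anchor (0-based from the start, negative up to
#'   -1 at the stop).
#' @export
metagene <- function(profiles, anchor = c("START", "STOP"), window,
                     min_gene_reads = 1L) {
  anchor <- match.arg(anchor)
  keep <- Filter(function(p) p$total_reads >= min_gene_reads &&
                   length(p$codon_counts) >= window, profiles)
  if (!length(keep)) stop("no gene qualifies for the metagene average")
  mat <- vapply(keep, function(p) {
    norm <- p$codon_counts / mean(p$codon_counts)
    if (anchor == "START") norm[seq_len(window)]
    else norm[seq.int(length(norm) - window + 1L, length(norm))]
  }, numeric(window))
  out <- rowMeans(matrix(mat, nrow = window))
  names(out) <- if (anchor == "START") seq_len(window) - 1L
                else seq.int(-window, -1L)
  out
}
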