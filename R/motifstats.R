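#' Amino-acid trimer under a paused ribosome
#'
#' Returns the E-, P- and A-site residues of a ribosome whose A site is at
#' `asite_codon`, i.e. the amino acids at codons `asite_codon - 2 ...
#' asite_codon`.  `NA` when the A-site codon is before codon 2 or the
#' trimer would contain a stop symbol.
#'
#' @param gene one row of a `gene_set` (or any list with an `aa_seq`
#'   field).
#' @param asite_codon 0-based A-site codon index (vectorized).
#' @return character vector of trimers (`NA` where undefined).
#' @export
ribosome_trimer <- function(gene, asite_codon) {
  aa <- gene$aa_seq
  tri <- ifelse(asite_codon >= 2L & asite_codon < nchar(aa),
                substring(aa, asite_codon - 1L, asite_codon + 1L),
                NA_character_)
  tri[!is.na(tri) & grepl("\\*", tri)] <- NA_character_
  tri
}

# trimer at every codon of a gene, NA where undefined (vectorized)
.gene_trimer_track <- function(gene) {
  L <- nchar(gene$aa_seq)
  ribosome_trimer(gene, 0:(L - 1L))
}

#' Trimer enrichment at pause sites
#'
#' For each E/P/A amino-acid trimer, compares its frequency among pause
#' sites with its ribosome-occupancy-weighted background frequency.
#' `freq_pause` is the fraction of (trimer-defined) pause sites carrying
#' the trimer; `freq_background` weights every trimer-defined A-site
#' position of every gene by its codon count, so the background reflects
#' what ribosomes actually covered rather than transcript composition.
#' Enrichment is the ratio of the two; trimers observed at pause sites but
#' absent from the background are flagged (infinite enrichment).
#'
#' @param pause_sites data.frame from [call_pauses()] (`gene_id`,
#'   `asite_codon`).
#' @param profiles an `occupancy_profiles` object supplying background
#'   weights.
#' @param genes a `gene_set`.
#' @return data.frame with columns `trimer`, `n_pause`, `freq_pause`,
#'   `freq_background`, `enrichment`, `flagged`, sorted by decreasing
#'   enrichment.
#' @export
trimer_enrichment <- function(pause_sites, profiles, genes) {
  if (nrow(pause_sites) == 0L) stop("no pause sites supplied")
  gidx <- match(pause_sites$gene_id, genes$gene_id)
  tri <- vapply(seq_len(nrow(pause_sites)), function(k)
    ribosome_trimer(genes[gidx[k], ], pause_sites$asite_codon[k]),
    character(1))
  tri <- tri[!is.na(tri)]
  if (!length(tri)) stop("no pause site has a defined trimer")
  fp <- table(tri) / length(tri)

  bg <- new.env(parent = emptyenv())
  w_total <- 0
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    p <- profiles[[g$gene_id]]
    if (is.null(p)) next
    track <- .gene_trimer_track(g)
    ok <- !is.na(track) & p$codon_counts > 0L
    if (!any(ok)) next
    tab <- tapply(p$codon_counts[ok], track[ok], sum)
    for (t in names(tab)) {
      bg[[t]] <- (if (is.null(bg[[t]])) 0 else bg[[t]]) + tab[[t]]
      w_total <- w_total + tab[[t]]
    }
  }
  if (w_total == 0) stop("profiles carry no reads at trimer-defined codons")
  all_tri <- sort(union(names(fp), ls(bg)))
  freq_pause <- as.numeric(fp[all_tri])
  freq_pause[is.na(freq_pause)] <- 0
  freq_bg <- vapply(all_tri, function(t)
    if (is.null(bg[[t]])) 0 else bg[[t]] / w_total, numeric(1))
  enrich <- ifelse(freq_bg > 0, freq_pause / freq_bg,
                   ifelse(freq_pause > 0, Inf, 0))
  out <- data.frame(trimer = all_tri,
                    n_pause = as.integer(round(freq_pause * length(tri))),
                    freq_pause = freq_pause,
                    freq_background = freq_bg,
                    enrichment = enrich,
                    flagged = freq_bg == 0 & freq_pause > 0,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$enrichment, out$trimer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nucleotide bias of the E-site codon at pause sites
#'
#' Tallies the nucleotides of the E-site codon (the codon two positions
#' upstream of the pause A site) across pause sites, per codon position.
#'
#' @param pause_sites data.frame with `gene_id` and `asite_codon`.
#' @param genes a `gene_set`.
#' @return list with `freq` (4 x 3 matrix, rows A/C/G/T, columns codon
#'   positions 1-3, each column summing to 1), `counts` (same shape,
#'   integer) and `g_fraction` (guanosine fraction at codon position 1).
#' @export
esite_first_nt_bias <- function(pause_sites, genes) {
  el <- pause_sites[pause_sites$asite_codon >= 2L, , drop = FALSE]
  if (nrow(el) == 0L) stop("no pause site with asite_codon >= 2")
  gidx <- match(el$gene_id, genes$gene_id)
  e0 <- 3L * (el$asite_codon - 2L)
  codons <- substring(genes$nt_seq[gidx], e0 + 1L, e0 + 3L)
  counts <- sapply(1:3, function(p)
    table(factor(substr(codons, p, p), levels = NUCLEOTIDES)))
  dimnames(counts) <- list(NUCLEOTIDES, paste0("pos", 1:3))
  freq <- sweep(counts, 2L, colSums(counts), "/")
  list(freq = freq, counts = counts, g_fraction = unname(freq["G", 1L]))
}

#' Asymmetry score of ribosome occupancy around a motif
#'
#' Ratio of pseudocounted ribosome occupancy downstream versus upstream of
#' a motif: `AS = (sum(downstream flank) + alpha) / (sum(upstream flank) +
#' alpha)`, with the motif span itself excluded from both sums and flanks
#' clipped to the CDS.  Low AS indicates stalling at the motif (few
#' ribosomes make it past); an AS that rises when a rescue factor is
#' deleted indicates factor-dependent translation of the gene, handled by
#' [dependency_call()].
#'
#' @param profile an [occupancy_profile()].
#' @param motif_codon_span `c(start, end)`: 0-based half-open codon
#'   interval of the motif (E through A site for a planted trimer).
#' @param flank flank size in codons on each side.
#' @param pseudocount additive pseudocount `alpha` applied to both sums.
#' @return an object of class `asymmetry_result`: list with `gene_id`,
#'   `motif_codon_span`, `AS`, `log2_AS`, `upstream_sum`,
#'   `downstream_sum`, `flank_up`, `flank_down`, `pseudocount`.
#' @export
asymmetry_score <- function(profile, motif_codon_span, flank = 25L,
                            pseudocount = 0.5) {
  L <- length(profile$codon_counts)
  s <- motif_codon_span[1]
  e <- motif_codon_span[2]
  if (s < 0L || e > L || s >= e) stop("invalid motif codon span")
  up_idx <- seq.int(max(0L, s - flank), s - 1L)
  up_idx <- up_idx[up_idx >= 0L & up_idx < s]
  down_idx <- seq.int(e, min(L, e + flank) - 1L)
  down_idx <- down_idx[down_idx >= e & down_idx < L]
  if (!length(up_idx) && !length(down_idx))
    stop("both flanks empty after clipping to the CDS")
  up <- sum(profile$codon_counts[up_idx + 1L])
  down <- sum(profile$codon_counts[down_idx + 1L])
  structure(list(gene_id = profile$gene_id,
                 motif_codon_span = c(s, e),
                 AS = (down + pseudocount) / (up + pseudocount),
                 log2_AS = log2((down + pseudocount) / (up + pseudocount)),
                 upstream_sum = up, downstream_sum = down,
                 flank_up = length(up_idx), flank_down = length(down_idx),
                 pseudocount = pseudocount),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf(
    "asymmetry %s codons [%d,%d): AS = %.3f (down %d / up %d, alpha %.2f)\n",
    x$gene_id, x$motif_codon_span[1], x$motif_codon_span[2], x$AS,
    x$downstream_sum, x$upstream_sum, x$pseudocount))
  invisible(x)
}

#' Asymmetry scores for a table of motifs
#'
#' @param profiles an `occupancy_profiles` object.
#' @param motifs data.frame with columns `gene_id`, `span_start`,
#'   `span_end` (0-based half-open codon span); extra columns are carried
#'   through.
#' @param flank,pseudocount passed to [asymmetry_score()].
#' @return `motifs` with columns `AS`, `log2_AS`, `upstream_sum`,
#'   `downstream_sum` appended.
#' @export
asymmetry_table <- function(profiles, motifs, flank = 25L,
                            pseudocount = 0.5) {
  res <- lapply(seq_len(nrow(motifs)), function(k) {
    p <- profiles[[motifs$gene_id[k]]]
    if (is.null(p)) stop("no profile for gene ", motifs$gene_id[k])
    asymmetry_score(p, c(motifs$span_start[k], motifs$span_end[k]),
                    flank = flank, pseudocount = pseudocount)
  })
  motifs$AS <- vapply(res, `[[`, numeric(1), "AS")
  motifs$log2_AS <- vapply(res, `[[`, numeric(1), "log2_AS")
  motifs$upstream_sum <- vapply(res, `[[`, numeric(1), "upstream_sum")
  motifs$downstream_sum <- vapply(res, `[[`, numeric(1), "downstream_sum")
  motifs
}

#' Call elongation-factor dependency from paired asymmetry scores
#'
#' Compares the asymmetry score of a motif in a factor-deletion strain with
#' the wild type: `DEPENDENT` when the score collapses at least
#' `theta`-fold in the mutant (the stall appears when the factor is
#' absent), `INDUCED` when it rises at least `theta`-fold (the factor
#' itself caused the pause), `INDEPENDENT` otherwise.
#'
#' @param AS_wt,AS_mut positive asymmetry scores (vectorized).
#' @param theta fold-change threshold, > 1.
#' @return character vector of labels (`"DEPENDENT"`, `"INDEPENDENT"`,
#'   `"INDUCED"`).
#' @export
dependency_call <- function(AS_wt, AS_mut, theta = 2) {
  if (theta <= 1) stop("theta must exceed 1")
  if (any(AS_wt <= 0) || any(AS_mut <= 0))
    stop("asymmetry scores must be positive")
  ifelse(AS_mut <= AS_wt / theta, "DEPENDENT",
         ifelse(AS_mut >= AS_wt * theta, "INDUCED", "INDEPENDENT"))
}

#' Dependency calls for a motif table measured in two strains
#'
#' @param as_wt,as_mut outputs of [asymmetry_table()] for the wild type and
#'   the deletion strain, over the same motifs in the same order.
#' @param theta fold-change threshold passed to [dependency_call()].
#' @return data.frame with `gene_id`, motif span, `AS_wt`, `AS_mut` and
#'   `label`.
#' @export
dependency_table <- function(as_wt, as_mut, theta = 2) {
  stopifnot(identical(as_wt$gene_id, as_mut$gene_id),
            identical(as_wt$span_start, as_mut$span_start))
  data.frame(gene_id = as_wt$gene_id,
             span_start = as_wt$span_start,
             span_end = as_wt$span_end,
             AS_wt = as_wt$AS, AS_mut = as_mut$AS,
             label = dependency_call(as_wt$AS, as_mut$AS, theta),
             stringsAsFactors = FALSE)
}
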