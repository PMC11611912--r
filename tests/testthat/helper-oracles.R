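# Independent brute-force reference implementations used to pin the
# definitions of the vectorized production code.  All of them use plain
# loops over positions.

# pause score at 1-based position i1 of a count vector
oracle_pause <- function(counts, i1, w1, w2) {
  folds <- numeric(2)
  means <- numeric(2)
  sizes <- integer(2)
  covs <- numeric(2)
  ws <- c(w1, w2)
  for (k in 1:2) {
    w <- ws[k]
    lo <- max(1L, i1 - w %/% 2L)
    hi <- min(length(counts), i1 + (w + 1L) %/% 2L - 1L)
    win <- setdiff(lo:hi, i1)
    means[k] <- mean(counts[win])
    folds[k] <- counts[i1] / means[k]
    sizes[k] <- hi - lo + 1L
    covs[k] <- mean(counts[lo:hi] >= 1)
  }
  list(score = if (all(means > 0)) mean(folds) else NA_real_,
       coverage = covs[which.max(sizes)],
       defined = all(means > 0))
}

# first-occurrence deduplication on (umi, fragment) keys
oracle_dedup <- function(df) {
  seen <- character(0)
  keep <- logical(nrow(df))
  for (r in seq_len(nrow(df))) {
    key <- paste(df$umi[r], df$fragment[r], sep = "|")
    if (!(key %in% seen)) {
      keep[r] <- TRUE
      seen <- c(seen, key)
    }
  }
  df[keep, , drop = FALSE]
}

# asymmetry score around a 0-based half-open codon span
oracle_asymmetry <- function(codon_counts, span, flank, alpha) {
  L <- length(codon_counts)
  up <- 0
  down <- 0
  for (c0 in seq.int(span[1] - flank, span[1] - 1L))
    if (c0 >= 0L && c0 < L) up <- up + codon_counts[c0 + 1L]
  for (c0 in seq.int(span[2], span[2] + flank - 1L))
    if (c0 >= 0L && c0 < L) down <- down + codon_counts[c0 + 1L]
  (down + alpha) / (up + alpha)
}

# trimer pause/background frequencies by direct tallying
oracle_trimer_enrichment <- function(pause_sites, profiles, genes) {
  tri_at <- function(aa, a) {
    if (a < 2L || a >= nchar(aa)) return(NA_character_)
    t <- substr(aa, a - 1L, a + 1L)
    if (grepl("\\*", t)) NA_character_ else t
  }
  fp <- list()
  n_def <- 0L
  for (r in seq_len(nrow(pause_sites))) {
    aa <- genes$aa_seq[genes$gene_id == pause_sites$gene_id[r]]
    t <- tri_at(aa, pause_sites$asite_codon[r])
    if (is.na(t)) next
    n_def <- n_def + 1L
    fp[[t]] <- (if (is.null(fp[[t]])) 0 else fp[[t]]) + 1
  }
  fb <- list()
  wtot <- 0
  for (i in seq_len(nrow(genes))) {
    aa <- genes$aa_seq[i]
    cc <- profiles[[genes$gene_id[i]]]$codon_counts
    for (a in 0:(nchar(aa) - 1L)) {
      t <- tri_at(aa, a)
      if (is.na(t) || cc[a + 1L] == 0L) next
      fb[[t]] <- (if (is.null(fb[[t]])) 0 else fb[[t]]) + cc[a + 1L]
      wtot <- wtot + cc[a + 1L]
    }
  }
  tri <- sort(union(names(fp), names(fb)))
  data.frame(
    trimer = tri,
    freq_pause = vapply(tri, function(t)
      if (is.null(fp[[t]])) 0 else fp[[t]] / n_def, numeric(1)),
    freq_background = vapply(tri, function(t)
      if (is.null(fb[[t]])) 0 else fb[[t]] / wtot, numeric(1)),
    stringsAsFactors = FALSE)
}

# arbitrary codon string -> gene_set row helpers for constructed fixtures
aa_to_nt <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(aa, "")[[1]],
               function(a) names(gc)[gc == a][1], character(1)),
        collapse = "")
}

toy_gene <- function(gene_id, aa_seq = NULL, nt_seq = NULL, utr = 0L) {
  if (is.null(nt_seq)) nt_seq <- aa_to_nt(aa_seq)
  if (is.null(aa_seq))
    aa_seq <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nt_seq)))
  flank <- strrep("ACGT", ceiling(utr / 4))
  flank <- substr(flank, 1, utr)
  g <- data.frame(gene_id = gene_id, chrom = gene_id, strand = "+",
                  cds_start = utr, cds_end = utr + nchar(nt_seq),
                  tx_seq = paste0(flank, nt_seq, flank),
                  nt_seq = nt_seq, aa_seq = aa_seq,
                  stringsAsFactors = FALSE)
  class(g) <- c("gene_set", "data.frame")
  g
}

rbind_genes <- function(...) {
  g <- do.call(rbind, lapply(list(...), as.data.frame))
  class(g) <- c("gene_set", "data.frame")
  g
}
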