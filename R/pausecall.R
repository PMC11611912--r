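#' Parameters for sliding-window pause calling
#'
#' A position's pause score is its fold change over the mean occupancy of
#' sliding windows centred on it.  Defaults follow common practice for
#' bacterial footprint libraries: two 1000-nt windows, a minimum fold
#' change of 20, and at least 5% of window positions covered.
#'
#' @param w1,w2 window lengths in nt (both must be >= 3).
#' @param min_score minimum fold change for a site to be called (> 1).
#' @param min_cov minimum fraction of covered positions in the window,
#'   in (0, 1].
#' @return an object of class `pause_params`.
#' @export
pause_params <- function(w1 = 1000L, w2 = 1000L, min_score = 20,
                         min_cov = 0.05) {
  if (w1 < 3L || w2 < 3L) stop("window lengths must be >= 3 nt")
  if (min_score <= 1) stop("min_score must exceed 1")
  if (min_cov <= 0 || min_cov > 1) stop("min_cov must lie in (0, 1]")
  structure(list(w1 = as.integer(w1), w2 = as.integer(w2),
                 min_score = min_score, min_cov = min_cov),
            class = "pause_params")
}

#' Pause scores along a gene
#'
#' For each nucleotide position `i` of the CDS and each window length `w`,
#' the window of `w` nt centred on `i` is clipped to the gene bounds and the
#' focal position excluded; the per-window fold change is `count[i]`
#' divided by the mean count over the remaining window positions.  The
#' score is the mean of the two per-window fold changes and is defined only
#' where both window means are positive.  Coverage is the fraction of
#' positions with at least one read in the larger clipped window (focal
#' position included).
#'
#' @param profile an [occupancy_profile()].
#' @param params a [pause_params()] object.
#' @param i a single 0-based CDS nucleotide position for `pause_score()`.
#' @return `pause_scores()`: data.frame with one row per CDS position and
#'   columns `nt_position` (0-based), `count`, `score`, `coverage`,
#'   `defined`.  `pause_score()`: list with `score` and `coverage` (score
#'   `NA` where undefined).
#' @export
pause_scores <- function(profile, params = pause_params()) {
  x <- as.numeric(profile$nt_counts)
  n <- length(x)
  cs <- c(0, cumsum(x))
  cz <- c(0, cumsum(x > 0))
  i <- seq_len(n)
  win <- lapply(c(params$w1, params$w2), function(w) {
    lo <- pmax(1L, i - w %/% 2L)
    hi <- pmin(n, i + (w + 1L) %/% 2L - 1L)
    wsum <- cs[hi + 1L] - cs[lo] - x
    wmean <- wsum / (hi - lo)              # window size minus focal position
    list(fold = x / wmean, mean = wmean, size = hi - lo + 1L,
         cov = (cz[hi + 1L] - cz[lo]) / (hi - lo + 1L))
  })
  defined <- win[[1]]$mean > 0 & win[[2]]$mean > 0
  score <- (win[[1]]$fold + win[[2]]$fold) / 2
  score[!defined] <- NA_real_
  coverage <- ifelse(win[[1]]$size >= win[[2]]$size,
                     win[[1]]$cov, win[[2]]$cov)
  data.frame(nt_position = i - 1L, count = x, score = score,
             coverage = coverage, defined = defined)
}

#' @rdname pause_scores
#' @export
pause_score <- function(profile, i, params = pause_params()) {
  sc <- pause_scores(profile, params)
  row <- sc[sc$nt_position == i, , drop = FALSE]
  if (nrow(row) != 1L) stop("position out of range")
  list(score = row$score, coverage = row$coverage, defined = row$defined)
}

#' Call pause sites across a profile set
#'
#' Reports every CDS nucleotide position whose pause score and window
#' coverage meet the thresholds, annotated with its codon index.  Sites are
#' per-nucleotide; with `merge_adjacent = TRUE`, runs of consecutive
#' super-threshold positions are collapsed to the position with the highest
#' score.
#'
#' @param profiles an `occupancy_profiles` object.
#' @param params a [pause_params()] object.
#' @param merge_adjacent collapse adjacent called positions (default
#'   `FALSE`: every position is reported individually).
#' @return data.frame with columns `gene_id`, `nt_position` (0-based on the
#'   CDS), `asite_codon`, `score`, `coverage`, sorted by gene and position.
#' @export
call_pauses <- function(profiles, params = pause_params(),
                        merge_adjacent = FALSE) {
  res <- lapply(profiles, function(p) {
    sc <- pause_scores(p, params)
    sel <- sc$defined & sc$score >= params$min_score &
      sc$coverage >= params$min_cov
    sc <- sc[sel, , drop = FALSE]
    if (!nrow(sc)) return(NULL)
    if (merge_adjacent && nrow(sc) > 1L) {
      run <- cumsum(c(1L, diff(sc$nt_position) != 1L))
      sc <- do.call(rbind, lapply(split(sc, run), function(b)
        b[which.max(b$score), , drop = FALSE]))
    }
    data.frame(gene_id = p$gene_id, nt_position = sc$nt_position,
               asite_codon = sc$nt_position %/% 3L,
               score = sc$score, coverage = sc$coverage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), nt_position = integer(0),
                      asite_codon = integer(0), score = numeric(0),
                      coverage = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$nt_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
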