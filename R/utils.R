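# Internal helpers shared across modules.

NUCLEOTIDES <- c("A", "C", "G", "T")

# codon -> amino acid lookup and its inverse, from the standard genetic code
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# deterministic derived seed; keeps values in the 32-bit integer range
.derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + 7919 * as.double(k)) %% 2147483646) + 1L
}

# n random fixed-length oligonucleotides as a character vector
.rand_nt <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(NUCLEOTIDES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

.translate <- function(nt_seq) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt_seq)))
}

# Exact substring search of `frags` against `subjects` (DNAStringSet),
# optionally on both strands.  Returns, per input fragment, the total hit
# count and the first hit (subject index, 0-based start, strand).
.substring_hits <- function(frags, subjects, both_strands = TRUE) {
  uf <- unique(frags)
  nu <- length(uf)
  total <- integer(nu)
  sidx <- rep(NA_integer_, nu)
  spos <- rep(NA_integer_, nu)
  sstr <- rep(NA_character_, nu)
  if (nu > 0L && length(subjects) > 0L) {
    ws <- nchar(uf)
    slen <- Biostrings::width(subjects)
    rc <- if (both_strands) Biostrings::reverseComplement(subjects)
    strands <- c("+", if (both_strands) "-")
    for (wd in sort(unique(ws))) {
      ix <- which(ws == wd)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(uf[ix]))
      for (s in seq_along(subjects)) {
        if (slen[s] < wd) next
        for (str in strands) {
          subj <- if (str == "+") subjects[[s]] else rc[[s]]
          m <- Biostrings::matchPDict(pd, subj)
          st <- Biostrings::startIndex(m)
          cnt <- lengths(st)
          hit <- which(cnt > 0L)
          if (!length(hit)) next
          gi <- ix[hit]
          total[gi] <- total[gi] + cnt[hit]
          fresh <- is.na(sidx[gi])
          if (any(fresh)) {
            f <- gi[fresh]
            p1 <- vapply(st[hit[fresh]], `[[`, integer(1), 1L)
            spos[f] <- if (str == "+") p1 - 1L else slen[s] - (p1 - 1L) - wd
            sidx[f] <- s
            sstr[f] <- str
          }
        }
      }
    }
  }
  j <- match(frags, uf)
  data.frame(count = total[j], subject = sidx[j], start = spos[j],
             strand = sstr[j], stringsAsFactors = FALSE)
}

.as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  Biostrings::DNAStringSet(x)
}
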