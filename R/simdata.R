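#' Configuration for a synthetic footprint library
#'
#' Bundles all parameters of the footprint simulator: a toy transcriptome
#' layout, the stall motifs to plant, the dwell-time model, sequencing depth,
#' the raw-read layout, and the RNG seed.  Coordinates throughout the package
#' are 0-based (half-open for nucleotide intervals); codon indices are
#' 0-based with codon 0 the initiator.
#'
#' Each element of `planted_motifs` is a list with fields
#' \describe{
#'   \item{gene}{gene id (`"g1"`, `"g2"`, ...) carrying the motif}
#'   \item{codon_index}{A-site codon of the stall (0-based); the amino-acid
#'     trimer occupies the E, P and A sites, i.e. codons
#'     `codon_index - 2 ... codon_index`}
#'   \item{trimer}{three-letter amino-acid string (no stop symbol)}
#'   \item{s}{multiplicative dwell time at the stall codon, `s >= 1`}
#'   \item{d}{abortive drop-off probability in `[0, 1]`; ribosome density
#'     downstream of the motif is scaled by `1 - d`}
#'   \item{esite_first_nt}{optional nucleotide the E-site codon must start
#'     with (must be satisfiable by some synonymous codon)}
#' }
#'
#' @param n_genes number of independent transcripts.
#' @param gene_len_codons CDS length in codons, including the initiator and
#'   the stop codon.
#' @param planted_motifs list of planted stall motifs (see Details).
#' @param depth mean number of footprint reads per codon.
#' @param read_len_range inclusive `[min, max]` footprint length in nt
#'   (the MNase gel cut; 20--40 nt by default).
#' @param dup_rate probability that a read receives one PCR duplicate.
#' @param asite_offset distance in nt from a footprint's 3' end to its
#'   A-site nucleotide.
#' @param utr_len length of the untranslated flank simulated on each side of
#'   the CDS so that footprints over terminal codons fit on the transcript.
#' @param barcode fixed 5-nt sample barcode (libraries are demultiplexed).
#' @param adapter 3' adapter sequence appended to every raw read.
#' @param seed integer RNG seed; identical configurations give byte-identical
#'   simulator output.
#' @return an object of class `sim_config`.
#' @seealso [make_transcriptome()], [simulate_footprints()]
#' @export
sim_config <- function(n_genes = 20L,
                       gene_len_codons = 300L,
                       planted_motifs = list(),
                       depth = 50,
                       read_len_range = c(20L, 40L),
                       dup_rate = 0.2,
                       asite_offset = 11L,
                       utr_len = 60L,
                       barcode = "CTGAC",
                       adapter = RIBOSEQ_ADAPTER,
                       seed = 1L) {
  read_len_range <- as.integer(read_len_range)
  if (length(read_len_range) != 2L || read_len_range[1] > read_len_range[2])
    stop("read_len_range must be c(min, max) with min <= max")
  if (read_len_range[1] < asite_offset + 1L)
    stop("minimum read length must be >= asite_offset + 1")
  if (depth <= 0) stop("depth must be positive")
  if (dup_rate < 0 || dup_rate >= 1) stop("dup_rate must lie in [0, 1)")
  if (nchar(barcode) != 5L) stop("barcode must be 5 nt")
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  if (gene_len_codons < 10L) stop("gene_len_codons must be >= 10")
  if (utr_len < max(read_len_range[2] - asite_offset - 1L, asite_offset))
    stop("utr_len too short for the requested read lengths and A-site offset")
  planted_motifs <- lapply(planted_motifs, .validate_motif,
                           gene_len = gene_len_codons)
  structure(list(n_genes = as.integer(n_genes),
                 gene_len_codons = as.integer(gene_len_codons),
                 planted_motifs = planted_motifs,
                 depth = depth,
                 read_len_range = read_len_range,
                 dup_rate = dup_rate,
                 asite_offset = as.integer(asite_offset),
                 utr_len = as.integer(utr_len),
                 barcode = barcode,
                 adapter = adapter,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.validate_motif <- function(m, gene_len) {
  m <- as.list(m)
  for (f in c("gene", "codon_index", "trimer"))
    if (is.null(m[[f]])) stop("planted motif is missing field '", f, "'")
  if (is.null(m$s)) m$s <- 1
  if (is.null(m$d)) m$d <- 0
  if (is.null(m$esite_first_nt) || is.na(m$esite_first_nt))
    m$esite_first_nt <- NA_character_
  m$codon_index <- as.integer(m$codon_index)
  if (nchar(m$trimer) != 3L || grepl("\\*", m$trimer))
    stop("planted trimer must be three amino acids with no stop symbol")
  tbl <- .codon_table()
  aa <- strsplit(m$trimer, "")[[1]]
  if (!all(aa %in% setdiff(names(tbl), "*")))
    stop("unknown amino acid in planted trimer: ", m$trimer)
  if (m$codon_index < 2L || m$codon_index > gene_len - 2L)
    stop("planted codon_index must lie in [2, gene_len_codons - 2]")
  if (m$codon_index == 2L && aa[1] != "M")
    stop("planting at codon 2 would overwrite the ATG start codon")
  if (m$s < 1) stop("stall multiplier s must be >= 1")
  if (m$d < 0 || m$d > 1) stop("dropoff probability d must lie in [0, 1]")
  if (!is.na(m$esite_first_nt)) {
    cand <- tbl[[aa[1]]]
    if (!any(substr(cand, 1L, 1L) == m$esite_first_nt))
      stop("no codon for ", aa[1], " starts with ", m$esite_first_nt,
           ": E-site constraint unsatisfiable")
  }
  m
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Footprint simulator configuration\n")
  cat(sprintf("  %d genes x %d codons, depth %g reads/codon\n",
              x$n_genes, x$gene_len_codons, x$depth))
  cat(sprintf("  read lengths %d-%d nt, A-site offset %d nt, dup rate %.2f\n",
              x$read_len_range[1], x$read_len_range[2], x$asite_offset,
              x$dup_rate))
  cat(sprintf("  %d planted motif(s), seed %d\n",
              length(x$planted_motifs), x$seed))
  invisible(x)
}

#' Generate a toy transcriptome with planted stall motifs
#'
#' Each gene is an independent transcript: a random UTR flank, an ATG start,
#' random sense codons, a stop codon, and a second UTR flank.  Planted
#' amino-acid trimers are written into codons `codon_index - 2 ...
#' codon_index` (the E, P and A sites of the stalled ribosome), choosing a
#' synonymous codon at random, restricted to codons beginning with
#' `esite_first_nt` at the E site when that constraint is set.  Output is
#' deterministic for a given configuration.
#'
#' @param cfg a [sim_config()].
#' @return a `gene_set`: a data.frame with one row per gene and columns
#'   `gene_id`, `chrom`, `strand`, `cds_start`, `cds_end` (0-based half-open
#'   on the transcript), `tx_seq` (full transcript), `nt_seq` (CDS) and
#'   `aa_seq` (translation, terminal `*` retained).
#' @export
make_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tbl <- .codon_table()
  sense <- sort(unlist(tbl[setdiff(names(tbl), "*")], use.names = FALSE))
  stops <- tbl[["*"]]
  L <- cfg$gene_len_codons
  ids <- paste0("g", seq_len(cfg$n_genes))
  bad <- vapply(cfg$planted_motifs, function(m) !(m$gene %in% ids), logical(1))
  if (any(bad)) stop("planted motif refers to an unknown gene")
  rows <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    codons <- c("ATG",
                sample(sense, L - 2L, replace = TRUE),
                sample(stops, 1L))
    for (m in cfg$planted_motifs) {
      if (!identical(m$gene, ids[i])) next
      aa <- strsplit(m$trimer, "")[[1]]
      for (j in 0:2) {
        cand <- tbl[[aa[j + 1L]]]
        if (j == 0L && !is.na(m$esite_first_nt))
          cand <- cand[substr(cand, 1L, 1L) == m$esite_first_nt]
        codons[m$codon_index - 2L + j + 1L] <-
          if (length(cand) == 1L) cand else sample(cand, 1L)
      }
    }
    nt_seq <- paste(codons, collapse = "")
    utr5 <- paste(sample(NUCLEOTIDES, cfg$utr_len, replace = TRUE),
                  collapse = "")
    utr3 <- paste(sample(NUCLEOTIDES, cfg$utr_len, replace = TRUE),
                  collapse = "")
    rows[[i]] <- data.frame(gene_id = ids[i], chrom = ids[i], strand = "+",
                            cds_start = cfg$utr_len,
                            cds_end = cfg$utr_len + 3L * L,
                            tx_seq = paste0(utr5, nt_seq, utr3),
                            nt_seq = nt_seq, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  genes$aa_seq <- .translate(genes$nt_seq)
  class(genes) <- c("gene_set", "data.frame")
  genes
}

#' Simulate a footprint library from a toy transcriptome
#'
#' Footprint A-site codons are drawn multinomially with probability
#' proportional to a per-codon dwell time: baseline 1, multiplied by `s` at
#' each planted A-site codon, and by `1 - d` at every codon downstream of a
#' drop-off motif.  Each read's 3' end is placed exactly `asite_offset` nt
#' downstream of its A-site nucleotide and its length is uniform over
#' `read_len_range`.  Raw reads follow the library layout: 3 random
#' untemplated nt, the footprint, a random 5-nt UMI, the fixed 5-nt sample
#' barcode, and the adapter.  With probability `dup_rate` a read gains one
#' PCR duplicate identical in every field but the read id.
#'
#' @param genes a `gene_set` from [make_transcriptome()].
#' @param cfg the [sim_config()]; its `planted_motifs` define the dwell
#'   model (pass motifs with `s = 1, d = 0` to emulate a strain in which the
#'   rescue factor is active).
#' @return an object of class `sim_footprints`: a list with elements
#'   `reads` (data.frame `id`, `seq`, `qual` — the raw FASTQ records),
#'   `alignments` (data.frame of the true fragment placements, duplicates
#'   excluded), and `truth` (list with `motifs` and per-read `reads` tables;
#'   `asite_nt` is the 0-based transcript coordinate of the A-site).
#' @export
simulate_footprints <- function(genes, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.derive_seed(cfg$seed, 1L))
  off <- cfg$asite_offset
  rl_min <- cfg$read_len_range[1]
  rl_max <- cfg$read_len_range[2]
  if (any(nchar(genes$tx_seq) < rl_max))
    stop("gene shorter than the maximum read length")
  per_gene <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    L <- nchar(g$nt_seq) %/% 3L
    dwell <- rep(1, L)
    for (m in cfg$planted_motifs) {
      if (!identical(m$gene, g$gene_id)) next
      dwell[m$codon_index + 1L] <- dwell[m$codon_index + 1L] * m$s
      if (m$d > 0 && m$codon_index + 2L <= L) {
        ds <- (m$codon_index + 2L):L
        dwell[ds] <- dwell[ds] * (1 - m$d)
      }
    }
    n_reads <- as.integer(round(cfg$depth * L))
    counts <- as.vector(rmultinom(1L, n_reads, dwell))
    codon <- rep.int(0:(L - 1L), counts)
    n <- length(codon)
    rl <- sample(seq.int(rl_min, rl_max), n, replace = TRUE)
    asite_nt <- g$cds_start + 3L * codon
    end3 <- asite_nt + off                     # 0-based inclusive 3' end
    start <- end3 - rl + 1L
    per_gene[[i]] <- data.frame(
      read_id = sprintf("%s_r%06d", g$gene_id, seq_len(n)),
      gene_id = g$gene_id,
      asite_codon = codon,
      asite_nt = asite_nt,
      start = start,
      end = end3 + 1L,
      frag = substring(g$tx_seq, start + 1L, end3 + 1L),
      umi = .rand_nt(n, 5L),
      q3 = .rand_nt(n, 3L),
      stringsAsFactors = FALSE)
  }
  rd <- do.call(rbind, per_gene)
  rd$duplicate_of <- NA_character_
  dup <- rd[runif(nrow(rd)) < cfg$dup_rate, , drop = FALSE]
  if (nrow(dup)) {
    dup$duplicate_of <- dup$read_id
    dup$read_id <- paste0(dup$read_id, "_dup")
  }
  all_rd <- rbind(rd, dup)
  raw <- paste0(all_rd$q3, all_rd$frag, all_rd$umi, cfg$barcode, cfg$adapter)
  motifs <- if (length(cfg$planted_motifs)) {
    do.call(rbind, lapply(cfg$planted_motifs, function(m)
      data.frame(gene_id = m$gene, codon_index = m$codon_index,
                 trimer = m$trimer, s = m$s, d = m$d,
                 esite_first_nt = m$esite_first_nt,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(gene_id = character(0), codon_index = integer(0),
               trimer = character(0), s = numeric(0), d = numeric(0),
               esite_first_nt = character(0), stringsAsFactors = FALSE)
  }
  structure(list(
    reads = data.frame(id = all_rd$read_id, seq = raw,
                       qual = strrep("I", nchar(raw)),
                       stringsAsFactors = FALSE),
    alignments = data.frame(read_id = rd$read_id, gene_id = rd$gene_id,
                            start = rd$start, end = rd$end, strand = "+",
                            frag = rd$frag, status = "OK",
                            stringsAsFactors = FALSE),
    truth = list(
      motifs = motifs,
      reads = all_rd[, c("read_id", "gene_id", "asite_nt", "asite_codon",
                         "umi", "duplicate_of")]),
    barcode = cfg$barcode, adapter = cfg$adapter),
    class = "sim_footprints")
}

#' @export
print.sim_footprints <- function(x, ...) {
  n_dup <- sum(!is.na(x$truth$reads$duplicate_of))
  cat(sprintf(
    "Simulated footprint library: %d raw reads (%d PCR duplicates), %d genes, %d planted motif(s)\n",
    nrow(x$reads), n_dup, length(unique(x$truth$reads$gene_id)),
    nrow(x$truth$motifs)))
  invisible(x)
}

#' Write simulator outputs to disk
#'
#' `write_transcriptome()` writes the transcript sequences as FASTA,
#' `write_gene_table()` the BED-like CDS table as TSV,
#' `write_footprints_fastq()` the raw reads as 4-line FASTQ, and
#' `write_truth_tables()` the planted-motif and per-read truth tables as TSV.
#'
#' @param genes a `gene_set`.
#' @param sim a `sim_footprints` object.
#' @param path,dir output file / directory.
#' @return the written path(s), invisibly.
#' @name sim_io
NULL

#' @rdname sim_io
#' @export
write_transcriptome <- function(genes, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(genes$tx_seq, genes$gene_id)), path)
  invisible(path)
}

#' @rdname sim_io
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes[, c("gene_id", "chrom", "strand", "cds_start", "cds_end")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sim_io
#' @export
write_footprints_fastq <- function(sim, path) {
  write_fastq(sim$reads, path)
}

#' @rdname sim_io
#' @export
write_truth_tables <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "truth_motifs.tsv")
  p2 <- file.path(dir, "truth_reads.tsv")
  write.table(sim$truth$motifs, p1, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth$reads, p2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read a BED-like gene table and its transcriptome FASTA
#'
#' Reconstructs a `gene_set` from the two plain-text files written by
#' [write_gene_table()] and [write_transcriptome()]: CDS coordinates are
#' 0-based half-open on the named transcript, and the CDS is re-extracted
#' and re-translated from the sequence.
#'
#' @param table_path TSV with columns gene_id, chrom, strand, cds_start,
#'   cds_end.
#' @param fasta_path transcript FASTA whose names match `gene_id`.
#' @return a `gene_set` data.frame.
#' @export
read_gene_table <- function(table_path, fasta_path) {
  tab <- read.delim(table_path, stringsAsFactors = FALSE)
  fa <- Biostrings::readDNAStringSet(fasta_path)
  names(fa) <- sub("\\s.*", "", names(fa))
  miss <- setdiff(tab$gene_id, names(fa))
  if (length(miss)) stop("genes missing from FASTA: ",
                         paste(miss, collapse = ", "))
  tab$tx_seq <- as.character(fa[tab$gene_id])
  tab$nt_seq <- substring(tab$tx_seq, tab$cds_start + 1L, tab$cds_end)
  if (any(nchar(tab$nt_seq) %% 3L != 0L))
    stop("CDS length not divisible by 3")
  tab$aa_seq <- .translate(tab$nt_seq)
  class(tab) <- c("gene_set", "data.frame")
  tab
}
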