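test_that("contaminant filtering removes exact substrings on both strands", {
  set.seed(61)
  contam <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = "")
  inside <- substr(contam, 50, 74)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(inside)))
  mismatch <- paste0("T", substr(inside, 2, 25))
  if (mismatch == inside) mismatch <- paste0("A", substr(inside, 2, 25))
  fp <- data.frame(id = paste0("r", 1:3),
                   fragment = c(inside, rc, mismatch),
                   stringsAsFactors = FALSE)
  out <- filter_contaminants(fp, contam)
  expect_identical(out$id, "r3")
  expect_identical(attr(out, "n_removed"), 2L)
  all_kept <- filter_contaminants(fp, NULL)
  expect_identical(nrow(all_kept), 3L)
})

test_that("unique exact mapping reports coordinates and rejects others", {
  genes <- make_transcriptome(sim_config(n_genes = 2, gene_len_codons = 100,
                                         seed = 17))
  frag <- substr(genes$tx_seq[1], 121, 148)       # 0-based [120, 148)
  rec <- map_unique(frag, genes)
  expect_identical(rec$gene_id, "g1")
  expect_identical(rec$start, 120L)
  expect_identical(rec$end, 148L)
  expect_identical(rec$strand, "+")
  # a fragment present in both genes is discarded as a multi-mapper
  shared <- substr(genes$tx_seq[1], 10, 34)
  genes2 <- genes
  genes2$tx_seq[2] <- paste0(genes$tx_seq[2], shared)
  expect_identical(map_unique(shared, genes2), "MULTIMAPPED")
  absent <- strrep("ACGGT", 5)
  haystack <- paste(c(genes$tx_seq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(genes$tx_seq)))), collapse = "NN")
  stopifnot(!grepl(absent, haystack, fixed = TRUE))
  expect_identical(map_unique(absent, genes), "UNMAPPED")
  # reverse-strand occurrences are found and strand-annotated
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(frag)))
  rec_rc <- map_unique(rc, genes)
  expect_identical(rec_rc$strand, "-")
  expect_identical(rec_rc$start, 120L)
})

test_that("A sites sit offset nt upstream of the 3' end", {
  g <- toy_gene("g1", nt_seq = strrep("GCT", 120), utr = 100)  # cds [100,460)
  aln <- data.frame(gene_id = "g1",
                    start = c(100L, 87L, 85L),
                    end = c(130L, 112L, 110L),
                    strand = "+", status = "OK", stringsAsFactors = FALSE)
  res <- assign_asite(aln, g, offset = 11L)
  expect_identical(res$asite_nt[1], 118L)
  expect_identical(res$asite_codon[1], 6L)        # 3' end 129 -> A site 118
  expect_identical(res$asite_codon[2], 0L)        # 3' end at cds_start + 11
  expect_identical(res$asite_status[3], "OUT_OF_CDS")  # 3' end cds_start + 9
  expect_error(assign_asite(data.frame(gene_id = "g1", start = 0L, end = 10L,
                                       strand = "+", status = "OK"),
                            g, offset = 11L), "offset")
})

test_that("profiles tally A-site codons and conserve totals", {
  g <- toy_gene("g1", nt_seq = strrep("GCT", 30))
  aln <- data.frame(gene_id = "g1", start = 0L, end = 28L, strand = "+",
                    status = "OK", asite_nt = rep(15L, 3),
                    asite_codon = rep(5L, 3), asite_status = "OK",
                    stringsAsFactors = FALSE)
  profs <- build_profiles(aln, g)
  expect_identical(profs[["g1"]]$codon_counts[6], 3L)
  expect_identical(profs[["g1"]]$total_reads, 3L)
  expect_identical(sum(profs[["g1"]]$nt_counts),
                   sum(profs[["g1"]]$codon_counts))
  empty <- build_profiles(aln[0, ], g)
  expect_true(all(empty[["g1"]]$codon_counts == 0L))
})

test_that("profiles from true alignments equal the truth-table histogram", {
  cfg <- sim_config(n_genes = 2, gene_len_codons = 90, depth = 10,
                    dup_rate = 0, seed = 23)
  genes <- make_transcriptome(cfg)
  sim <- simulate_footprints(genes, cfg)
  run <- footprints_to_profiles(NULL, genes, alignments = sim$alignments)
  tr <- sim$truth$reads
  for (g in genes$gene_id) {
    want <- tabulate(tr$asite_codon[tr$gene_id == g] + 1L, nbins = 90)
    expect_identical(run$profiles[[g]]$codon_counts, want)
  }
  # the fastq route assigns every retained read to its true A site
  fq <- tempfile(fileext = ".fastq")
  write_footprints_fastq(sim, fq)
  run2 <- footprints_to_profiles(fq, genes)
  m <- match(run2$alignments$read_id, tr$read_id)
  expect_identical(run2$alignments$asite_nt, tr$asite_nt[m])
  unlink(fq)
})

test_that("replicate aggregation sums counts and is associative", {
  g <- toy_gene("g1", nt_seq = strrep("GCT", 20))
  p <- build_profiles(data.frame(gene_id = "g1", start = 0L, end = 28L,
                                 strand = "+", status = "OK",
                                 asite_nt = c(3L, 3L, 9L),
                                 asite_codon = c(1L, 1L, 3L),
                                 asite_status = "OK",
                                 stringsAsFactors = FALSE), g)
  doubled <- aggregate_replicates(p, p)
  expect_identical(doubled[["g1"]]$codon_counts, 2L * p[["g1"]]$codon_counts)
  expect_identical(aggregate_replicates(p)[["g1"]]$codon_counts,
                   p[["g1"]]$codon_counts)
  abc <- aggregate_replicates(aggregate_replicates(p, p), p)
  acb <- aggregate_replicates(p, aggregate_replicates(p, p))
  expect_identical(abc[["g1"]]$codon_counts, acb[["g1"]]$codon_counts)
  expect_identical(doubled[["g1"]]$total_reads, 2L * p[["g1"]]$total_reads)
  g2 <- toy_gene("gX", nt_seq = strrep("GCT", 20))
  expect_error(aggregate_replicates(p, build_profiles(
    data.frame(gene_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), status = character(0),
               asite_nt = integer(0), asite_codon = integer(0),
               asite_status = character(0)), g2)), "different genes")
})

test_that("metagene curves recover uniform and ramped occupancy", {
  flat <- structure(list(g1 = occupancy_profile(
    "g1", codon_counts = rep(7L, 50))), class = "occupancy_profiles")
  expect_equal(unname(metagene(flat, "START", 20)), rep(1, 20))
  one <- structure(list(g1 = occupancy_profile(
    "g1", codon_counts = c(1:10, rep(5L, 40)))), class = "occupancy_profiles")
  own <- one$g1$codon_counts / mean(one$g1$codon_counts)
  expect_equal(unname(metagene(one, "STOP", 15)), own[36:50])
  # a 3x dwell ramp over the first five codons shows up threefold
  set.seed(71)
  ramped <- lapply(1:20, function(i) occupancy_profile(
    paste0("g", i),
    codon_counts = stats::rpois(100, rep(c(90, 30), c(5, 95)))))
  names(ramped) <- paste0("g", 1:20)
  class(ramped) <- "occupancy_profiles"
  mg <- metagene(ramped, "START", 100)
  expect_equal(mean(mg[1:5]) / mean(mg[6:100]), 3, tolerance = 0.1)
  expect_error(metagene(flat, "START", 20, min_gene_reads = 1e9),
               "no gene")
})
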