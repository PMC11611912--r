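test_that("the ribosome trimer reads E, P and A site residues", {
  g <- list(aa_seq = "MKPPNF")
  expect_identical(ribosome_trimer(g, 4L), "PPN")
  expect_identical(ribosome_trimer(list(aa_seq = "MGDPAK"), 4L), "DPA")
  expect_true(is.na(ribosome_trimer(g, 1L)))
  expect_true(is.na(ribosome_trimer(list(aa_seq = "MK*PN"), 3L)))
})

test_that("trimer enrichment reproduces a constructed fold change", {
  g <- toy_gene("g1", aa_seq = paste0("MAPPN", strrep("A", 15)))
  counts <- integer(20)
  counts[5] <- 5L                                 # codon 4: trimer PPN
  counts[11] <- 95L                               # codon 10: trimer AAA
  profs <- structure(list(g1 = occupancy_profile("g1",
                                                 codon_counts = counts)),
                     class = "occupancy_profiles")
  sites <- data.frame(gene_id = rep("g1", 10), asite_codon = rep(4L, 10))
  tab <- trimer_enrichment(sites, profs, g)
  ppn <- tab[tab$trimer == "PPN", ]
  expect_equal(ppn$freq_pause, 1)
  expect_equal(ppn$freq_background, 0.05)
  expect_equal(ppn$enrichment, 20)
  aaa <- tab[tab$trimer == "AAA", ]
  expect_equal(aaa$freq_pause, 0)
  expect_equal(aaa$enrichment, 0)
  expect_equal(sum(tab$freq_pause), 1, tolerance = 1e-9)
  expect_equal(sum(tab$freq_background), 1, tolerance = 1e-9)
  expect_error(trimer_enrichment(sites[0, ], profs, g), "no pause sites")
})

test_that("trimer frequencies match the brute-force tally oracle", {
  set.seed(808)
  for (k in 1:100) {
    cfg <- sim_config(n_genes = 2, gene_len_codons = 40,
                      depth = 2, seed = 9000 + k)
    genes <- make_transcriptome(cfg)
    profs <- lapply(genes$gene_id, function(id)
      occupancy_profile(id, codon_counts = stats::rpois(40, 1)))
    names(profs) <- genes$gene_id
    class(profs) <- "occupancy_profiles"
    n_sites <- sample(3:12, 1)
    sites <- data.frame(
      gene_id = sample(genes$gene_id, n_sites, replace = TRUE),
      asite_codon = sample(2:38, n_sites, replace = TRUE))
    got <- trimer_enrichment(sites, profs, genes)
    want <- oracle_trimer_enrichment(sites, profs, genes)
    m <- match(got$trimer, want$trimer)
    expect_false(anyNA(m))
    expect_lt(max(abs(got$freq_pause - want$freq_pause[m])), 1e-9)
    expect_lt(max(abs(got$freq_background - want$freq_background[m])), 1e-9)
    expect_lt(abs(sum(got$freq_pause) - 1), 1e-9)
    expect_lt(abs(sum(got$freq_background) - 1), 1e-9)
  }
})

test_that("sites resampled from the background show no enrichment", {
  set.seed(212)
  aa <- vapply(1:5, function(i)
    paste0("M", paste(sample(c("A", "P", "G"), 98, replace = TRUE),
                      collapse = ""), "*"), character(1))
  genes <- do.call(rbind_genes, lapply(1:5, function(i)
    toy_gene(paste0("g", i), aa_seq = aa[i])))
  profs <- lapply(genes$gene_id, function(id)
    occupancy_profile(id, codon_counts = stats::rpois(100, 5)))
  names(profs) <- genes$gene_id
  class(profs) <- "occupancy_profiles"
  pool <- do.call(rbind, lapply(genes$gene_id, function(id)
    data.frame(gene_id = id, asite_codon = 2:98,
               w = profs[[id]]$codon_counts[3:99])))
  pick <- sample(nrow(pool), 6000, replace = TRUE, prob = pool$w)
  sites <- pool[pick, c("gene_id", "asite_codon")]
  tab <- trimer_enrichment(sites, profs, genes)
  common <- tab[tab$freq_background >= 0.02, ]
  expect_gt(nrow(common), 5)
  expect_true(all(abs(common$enrichment - 1) < 0.3))
})

test_that("E-site codon nucleotide bias is tallied per position", {
  nt <- paste0("ATG", "GAT", "CCC", "CCC", "GAA", "CCC", "CCC",
               "CCG", "CCC", "CCC", "GTT", "CCC", "CCC", "TAA")
  g <- toy_gene("g1", nt_seq = nt)
  # sites whose E-site codons are GAT, GAA, CCG, GTT
  sites <- data.frame(gene_id = "g1", asite_codon = c(3L, 6L, 9L, 12L))
  bias <- esite_first_nt_bias(sites, g)
  expect_equal(bias$g_fraction, 0.75)
  expect_equal(colSums(bias$freq), rep(1, 3), ignore_attr = TRUE)
  all_gat <- esite_first_nt_bias(
    data.frame(gene_id = "g1", asite_codon = 3L), g)
  expect_equal(all_gat$g_fraction, 1)
  expect_error(esite_first_nt_bias(
    data.frame(gene_id = "g1", asite_codon = 1L), g), "no pause site")
})

test_that("asymmetry scores follow their definition", {
  flat <- occupancy_profile("g1", codon_counts = rep(4L, 100))
  expect_equal(asymmetry_score(flat, c(48, 51))$AS, 1)
  x <- integer(100)
  x[24:48] <- 4L                                  # upstream flank sums to 100
  x[52:56] <- 4L                                  # downstream sums to 20
  p <- occupancy_profile("g1", codon_counts = x)
  res <- asymmetry_score(p, c(48, 51), flank = 25, pseudocount = 0.5)
  expect_equal(res$upstream_sum, 100)
  expect_equal(res$downstream_sum, 20)
  expect_equal(res$AS, 20.5 / 100.5)
  expect_error(asymmetry_score(p, c(0, 100)), "flanks empty")
})

test_that("asymmetry matches the brute-force oracle and scales", {
  set.seed(321)
  for (k in 1:100) {
    L <- sample(40:200, 1)
    cc <- stats::rpois(L, 3)
    p <- occupancy_profile("g", codon_counts = cc)
    s <- sample(10:(L - 10), 1)
    e <- s + sample(1:3, 1)
    fl <- sample(5:30, 1)
    al <- runif(1, 0, 2)
    got <- asymmetry_score(p, c(s, e), flank = fl, pseudocount = al)
    expect_lt(abs(got$AS - oracle_asymmetry(cc, c(s, e), fl, al)), 1e-9)
  }
  cc <- stats::rpois(120, 4) + 1L
  p1 <- occupancy_profile("g", codon_counts = cc)
  p5 <- occupancy_profile("g", codon_counts = cc * 5L)
  expect_equal(asymmetry_score(p5, c(60, 63), pseudocount = 0)$AS,
               asymmetry_score(p1, c(60, 63), pseudocount = 0)$AS)
})

test_that("simulated drop-off depresses the asymmetry score accordingly", {
  cfg <- sim_config(
    n_genes = 1, gene_len_codons = 200, depth = 30, dup_rate = 0, seed = 55,
    planted_motifs = list(list(gene = "g1", codon_index = 100,
                               trimer = "PPN", s = 50, d = 0.5)))
  sim <- simulate_footprints(make_transcriptome(cfg), cfg)
  run <- footprints_to_profiles(NULL, make_transcriptome(cfg),
                                alignments = sim$alignments)
  res <- asymmetry_score(run$profiles[["g1"]], c(98, 101))
  expect_gt(res$AS, 0.4)
  expect_lt(res$AS, 0.6)
})

test_that("dependency labels follow the fold-change rule", {
  expect_identical(dependency_call(1.0, 0.2, 2), "DEPENDENT")
  expect_identical(dependency_call(1.0, 1.05, 2), "INDEPENDENT")
  expect_identical(dependency_call(0.5, 1.2, 2), "INDUCED")
  expect_identical(dependency_call(c(1, 1), c(0.5, 2), 2),
                   c("DEPENDENT", "INDUCED"))
  expect_error(dependency_call(1, 0.5, 1), "theta")
  expect_error(dependency_call(0, 0.5, 2), "positive")
})
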