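#' Configuration of the benchmark stalling study
#'
#' Defines the simulated two-strain experiment used to validate the whole
#' pipeline: 20 genes of 300 codons at 50 reads per codon with a 20% PCR
#' duplication rate.  Ten genes carry one planted stall motif each
#' (multiplier `s`, drop-off `d` in the deletion strain; `s = 1, d = 0` in
#' the wild type, where the rescue factor neutralizes the stall); the other
#' ten are motif-free controls.  Eight of the ten motifs carry an E-site
#' residue whose codons start with guanosine (D, G, V, E) and two do not
#' (P, K), so the expected G fraction at the first E-site codon position is
#' 0.8.
#'
#' @param seed integer seed; the transcriptome and the two libraries use
#'   seeds derived from it.
#' @param depth mean reads per codon.
#' @param s stall dwell multiplier in the deletion strain.
#' @param d abortive drop-off probability in the deletion strain.
#' @param dup_rate PCR duplication probability.
#' @return list with elements `cfg_wt`, `cfg_mut` (two [sim_config()]s
#'   sharing one transcriptome seed), `motif_genes`, `control_genes` and
#'   `motifs` (the planted-motif table).
#' @export
stall_study_config <- function(seed = 1L, depth = 50, s = 50, d = 0.3,
                               dup_rate = 0.2) {
  trimers <- c(rep(c("DPA", "GPG", "VPP", "EPT"), 2L), "PPN", "KPP")
  esite_nt <- c(rep("G", 8L), "C", "A")
  motif_genes <- paste0("g", 1:10)
  control_genes <- paste0("g", 11:20)
  codon_index <- 120L + 6L * (1:10)
  motifs_mut <- lapply(1:10, function(i)
    list(gene = motif_genes[i], codon_index = codon_index[i],
         trimer = trimers[i], s = s, d = d, esite_first_nt = esite_nt[i]))
  motifs_wt <- lapply(motifs_mut, function(m) {
    m$s <- 1; m$d <- 0; m
  })
  base <- list(n_genes = 20L, gene_len_codons = 300L, depth = depth,
               dup_rate = dup_rate)
  cfg_wt <- do.call(sim_config, c(base, list(
    planted_motifs = motifs_wt, seed = seed)))
  cfg_mut <- do.call(sim_config, c(base, list(
    planted_motifs = motifs_mut, seed = seed)))
  list(cfg_wt = cfg_wt, cfg_mut = cfg_mut,
       motif_genes = motif_genes, control_genes = control_genes,
       motifs = data.frame(gene_id = motif_genes,
                           codon_index = codon_index, trimer = trimers,
                           esite_first_nt = esite_nt,
                           stringsAsFactors = FALSE))
}

#' Run the benchmark stalling study end to end
#'
#' Simulates wild-type and factor-deletion footprint libraries over a
#' shared transcriptome, round-trips the raw reads through FASTQ, runs the
#' full processing pipeline (decomposition, UMI deduplication, mapping,
#' A-site assignment, profiling), calls pauses in the deletion strain,
#' computes trimer enrichment and E-site nucleotide bias at the called
#' sites, and derives asymmetry scores and dependency calls for the motif
#' genes and for matched spans on the control genes.
#'
#' The two libraries are simulated with different library seeds but an
#' identical transcriptome.  The wild type is simulated with the stall
#' neutralized (`s = 1, d = 0`); the deletion strain with the configured
#' `s` and `d`.
#'
#' @inheritParams stall_study_config
#' @param theta dependency fold-change threshold.
#' @param flank,pseudocount asymmetry-score parameters.
#' @param params pause-calling parameters.
#' @return list of class `stall_study` with the configuration, the two
#'   `ribo_run`s, the pause/trimer/E-site/dependency tables and a `metrics`
#'   list of summary numbers (sensitivity, false-call counts, top trimer,
#'   G fraction, dependent fractions, mean asymmetry ratio).
#' @export
run_stall_study <- function(seed = 1L, depth = 50, s = 50, d = 0.3,
                            dup_rate = 0.2, theta = 2, flank = 25L,
                            pseudocount = 0.5, params = pause_params()) {
  study <- stall_study_config(seed = seed, depth = depth, s = s, d = d,
                              dup_rate = dup_rate)
  study$cfg_wt$seed <- .derive_seed(seed, 11L)
  study$cfg_mut$seed <- .derive_seed(seed, 22L)
  genes_cfg <- study$cfg_wt
  genes_cfg$seed <- as.integer(seed)
  genes <- make_transcriptome(genes_cfg)

  runs <- lapply(list(wt = study$cfg_wt, mut = study$cfg_mut), function(cfg) {
    sim <- simulate_footprints(genes, cfg)
    fq <- tempfile(fileext = ".fastq")
    on.exit(unlink(fq), add = TRUE)
    write_footprints_fastq(sim, fq)
    run <- footprints_to_profiles(fq, genes, adapter = cfg$adapter,
                                  offset = cfg$asite_offset)
    list(sim = sim, run = run)
  })

  pauses <- call_pauses(runs$mut$run$profiles, params)
  planted_nt <- 3L * study$motifs$codon_index
  hit <- mapply(function(g, nt)
    any(pauses$gene_id == g & pauses$nt_position == nt),
    study$motifs$gene_id, planted_nt)
  sensitivity <- mean(hit)
  control_calls <- sum(pauses$gene_id %in% study$control_genes)
  offtarget_calls <- sum(pauses$gene_id %in% study$motif_genes &
                           !(paste(pauses$gene_id, pauses$nt_position) %in%
                               paste(study$motifs$gene_id, planted_nt)))

  trimers <- trimer_enrichment(pauses, runs$mut$run$profiles, genes)
  esite <- esite_first_nt_bias(pauses, genes)

  spans <- data.frame(gene_id = c(study$motifs$gene_id,
                                  study$control_genes),
                      span_start = c(study$motifs$codon_index - 2L,
                                     rep(148L, length(study$control_genes))),
                      span_end = c(study$motifs$codon_index + 1L,
                                   rep(151L, length(study$control_genes))),
                      is_motif = rep(c(TRUE, FALSE),
                                     c(nrow(study$motifs),
                                       length(study$control_genes))),
                      stringsAsFactors = FALSE)
  as_wt <- asymmetry_table(runs$wt$run$profiles, spans, flank, pseudocount)
  as_mut <- asymmetry_table(runs$mut$run$profiles, spans, flank, pseudocount)
  dep <- dependency_table(as_wt, as_mut, theta)
  dep$is_motif <- spans$is_motif

  metrics <- list(
    pause_sensitivity = sensitivity,
    n_planted = nrow(study$motifs),
    control_pause_calls = control_calls,
    offtarget_pause_calls = offtarget_calls,
    top_trimer = trimers$trimer[1],
    top_trimer_is_planted = trimers$trimer[1] %in% study$motifs$trimer,
    top_trimer_enrichment = trimers$enrichment[1],
    esite_g_fraction = esite$g_fraction,
    esite_n_sites = sum(esite$counts[, 1]),
    dependent_fraction_motif = mean(dep$label[dep$is_motif] == "DEPENDENT"),
    false_dependent_controls = sum(dep$label[!dep$is_motif] == "DEPENDENT"),
    mean_as_ratio_motif = mean(dep$AS_mut[dep$is_motif] /
                                 dep$AS_wt[dep$is_motif]))

  structure(list(study = study, genes = genes, wt = runs$wt, mut = runs$mut,
                 pauses = pauses, trimers = trimers, esite = esite,
                 asymmetry_wt = as_wt, asymmetry_mut = as_mut,
                 dependency = dep, metrics = metrics),
            class = "stall_study")
}

#' @export
print.stall_study <- function(x, ...) {
  m <- x$metrics
  cat("benchmark stalling study\n")
  cat(sprintf("  pause sensitivity        %.2f (%d planted sites)\n",
              m$pause_sensitivity, m$n_planted))
  cat(sprintf("  pause calls on controls  %d\n", m$control_pause_calls))
  cat(sprintf("  top enriched trimer      %s (enrichment %.1f, planted: %s)\n",
              m$top_trimer, m$top_trimer_enrichment,
              m$top_trimer_is_planted))
  cat(sprintf("  E-site G fraction        %.2f (%d sites)\n",
              m$esite_g_fraction, m$esite_n_sites))
  cat(sprintf("  DEPENDENT motif genes    %.2f\n", m$dependent_fraction_motif))
  cat(sprintf("  false DEPENDENT controls %d\n", m$false_dependent_controls))
  cat(sprintf("  mean AS ratio (mut/wt)   %.2f\n", m$mean_as_ratio_motif))
  invisible(x)
}
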