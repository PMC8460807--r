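# Ground-truth generator: determinism, planted structure, read simulation,
# clinical and expression layers.

test_that("degenerate config gives one gene, one site, no planted shifts", {
  cfg <- apa_sim_config(n_genes = 1, multi_site_frac = 0, n_decoys = 0)
  gen <- generate_genome_annotation(cfg, seed = 7)
  expect_equal(nrow(gen$truth$genes), 1)
  expect_equal(nrow(gen$truth$sites), 1)
  expect_equal(gen$truth$sites$role, "single")
  expect_true(all(gen$truth$genes$delta_psi == 0))
})

test_that("identical config and seed reproduce byte-identical files", {
  cfg <- apa_sim_config(n_genes = 10, n_decoys = 4)
  paths <- purrr::map(1:2, function(i) {
    gen <- generate_genome_annotation(cfg, seed = 1)
    fa <- tempfile(fileext = ".fa"); gtf <- tempfile(fileext = ".gtf")
    tsv <- tempfile(fileext = ".tsv")
    write_genome_fasta(gen$genome, fa)
    write_gene_models_gtf(gen$models, gtf)
    readr::write_tsv(gen$truth$genes, tsv)
    list(fa = fa, gtf = gtf, tsv = tsv)
  })
  for (f in c("fa", "gtf", "tsv")) {
    expect_equal(unname(tools::md5sum(paths[[1]][[f]])),
                 unname(tools::md5sum(paths[[2]][[f]])))
  }
  # and a different seed changes the genome
  gen3 <- generate_genome_annotation(cfg, seed = 2)
  fa3 <- tempfile(fileext = ".fa"); write_genome_fasta(gen3$genome, fa3)
  expect_false(unname(tools::md5sum(fa3)) ==
                 unname(tools::md5sum(paths[[1]]$fa)))
})

test_that("truth invariants hold: multi sites, decoy spacing, bounded dPSI", {
  gen <- generate_genome_annotation(apa_sim_config(n_genes = 50,
                                                   n_decoys = 20),
                                    seed = 13)
  tr <- gen$truth
  n_sites <- table(tr$sites$gene_id)
  shifted <- tr$genes$gene_id[tr$genes$delta_psi != 0]
  expect_true(all(n_sites[shifted] >= 2))
  expect_true(all(abs(tr$genes$delta_psi) <= 1))
  dmin <- vapply(tr$decoys$pos, function(p) min(abs(p - tr$sites$pos)),
                 numeric(1))
  expect_true(all(dmin >= 125))
})

test_that("decoys fail the hexamer test and trip the A-run filter", {
  gen <- generate_genome_annotation(apa_sim_config(n_genes = 20,
                                                   n_decoys = 10),
                                    seed = 3)
  dec <- gen$truth$decoys
  ip <- filter_internal_priming(
    dplyr::mutate(dec, sample_id = "S1", count = 1L), gen$genome)
  expect_equal(nrow(ip$events), 0)   # every decoy removed as A-rich
  hx <- require_hexamer(dec, gen$genome)
  expect_equal(nrow(hx$sites), 0)    # and none carries a hexamer
})

test_that("planted sites carry the hexamer and survive both filters", {
  gen <- generate_genome_annotation(apa_sim_config(n_genes = 20,
                                                   n_decoys = 0),
                                    seed = 3)
  sites <- gen$truth$sites
  ip <- filter_internal_priming(
    dplyr::mutate(sites, sample_id = "S1", count = 1L), gen$genome)
  expect_equal(nrow(ip$events), nrow(sites))
  hx <- require_hexamer(sites, gen$genome)
  expect_equal(nrow(hx$sites), nrow(sites))
  expect_true(all(hx$sites$hexamer == "AATAAA"))
  expect_true(all(hx$sites$hexamer_offset == -25))
})

test_that("requesting more genes than the chromosome fits is an error", {
  expect_error(apa_sim_config(n_genes = 100, chrom_len = 1000),
               "too short")
  expect_error(apa_sim_config(n_decoys = 10, n_genes = 5), "decoy")
})

test_that("deep simulation recovers the planted PSI within binomial error", {
  cfg <- apa_sim_config(n_genes = 1, multi_site_frac = 1, switch_frac = 0,
                        n_decoys = 0, psi_range = c(0.5, 0.5),
                        psi_subject_sd = 0)
  gen <- generate_genome_annotation(cfg, seed = 1)
  sim <- simulate_reads(gen$truth,
                        apa_sim_design(n_pairs = 1, depth = 10000,
                                       jitter_sd = 0), seed = 2)
  ev <- extract_cleavage_loci(sim$alignments, "rev")
  s <- gen$truth$sites
  prox <- sum(ev$count[ev$pos == s$pos[s$role == "proximal"]])
  dist <- sum(ev$count[ev$pos == s$pos[s$role == "distal"]])
  expect_lt(abs(prox / (prox + dist) - 0.5), 0.02)
})

test_that("zero jitter puts every read exactly at a planted or decoy locus", {
  gen <- generate_genome_annotation(apa_sim_config(n_genes = 10,
                                                   n_decoys = 5),
                                    seed = 4)
  sim <- simulate_reads(gen$truth,
                        apa_sim_design(n_pairs = 2, depth = 50,
                                       jitter_sd = 0), seed = 5)
  ev <- extract_cleavage_loci(sim$alignments, "rev")
  planted <- c(gen$truth$sites$pos, gen$truth$decoys$pos)
  expect_true(all(ev$pos %in% planted))
})

test_that("zero depth yields an empty but valid alignment set", {
  gen <- generate_genome_annotation(apa_sim_config(n_genes = 5,
                                                   n_decoys = 0),
                                    seed = 6)
  sim <- simulate_reads(gen$truth, apa_sim_design(n_pairs = 1, depth = 0,
                                                  decoy_depth = 0),
                        seed = 7)
  expect_equal(nrow(sim$alignments), 0)
  expect_equal(nrow(sim$metadata), 2)
})

test_that("REV orientation: alignments are antisense with the locus at 5'", {
  gen <- generate_genome_annotation(
    apa_sim_config(n_genes = 2, multi_site_frac = 0, n_decoys = 0),
    seed = 8)
  sim <- simulate_reads(gen$truth, apa_sim_design(n_pairs = 1, depth = 30,
                                                  jitter_sd = 0), seed = 9)
  aln <- sim$alignments
  tr <- gen$truth
  for (i in seq_len(nrow(tr$genes))) {
    gstrand <- tr$genes$strand[i]
    spos <- tr$sites$pos[tr$sites$gene_id == tr$genes$gene_id[i]]
    rows <- aln[aln$start <= spos & aln$end > spos, ]
    expect_true(all(rows$strand == ifelse(gstrand == "+", "-", "+")))
    if (gstrand == "+") expect_true(all(rows$end - 1 == spos))
    else expect_true(all(rows$start == spos))
  }
})

test_that("simulated SAM round-trips through the BAM reader", {
  gen <- generate_genome_annotation(apa_sim_config(n_genes = 3,
                                                   n_decoys = 0),
                                    seed = 10)
  sim <- simulate_reads(gen$truth, apa_sim_design(n_pairs = 1, depth = 20),
                        seed = 11)
  sam <- tempfile(fileext = ".sam")
  write_alignments_sam(sim$alignments, gen$genome, sam,
                       sample_id = sim$metadata$sample_id[1])
  got <- read_cleavage_alignments(sam, sample_id = "S")
  sub <- sim$alignments[sim$alignments$sample_id ==
                          sim$metadata$sample_id[1], ]
  expect_equal(sum(got$records$count), sum(sub$count))
  ev_direct <- extract_cleavage_loci(sub, "rev")
  ev_sam <- extract_cleavage_loci(got$records, "rev")
  expect_equal(sort(unique(ev_sam$pos)), sort(unique(ev_direct$pos)))
})

test_that("survival is null when all betas are zero", {
  cfg <- apa_sim_config(n_genes = 30, multi_site_frac = 1,
                        n_prognostic = 0, n_decoys = 0)
  gen <- generate_genome_annotation(cfg, seed = 12)
  sim <- simulate_reads(gen$truth, apa_sim_design(n_pairs = 30, depth = 0,
                                                  decoy_depth = 0),
                        seed = 13)
  ps <- purrr::map_dbl(1:20, function(s) {
    cl <- simulate_clinical(gen$truth, sim$psi_true, seed = s,
                            sample_ids = grep(
                              "_T$", sim$metadata$sample_id, value = TRUE))
    g1 <- sim$psi_true$gene_id[1]
    pi_tbl <- tibble::tibble(
      sample_id = cl$sample_id,
      pi = as.numeric(sim$psi_true[sim$psi_true$gene_id == g1,
                                   cl$sample_id]))
    stratify_and_logrank(pi_tbl, cl)$p
  })
  # p roughly uniform: no excess of small values
  expect_gt(mean(ps > 0.05), 0.7)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("a strong planted coefficient drives the median split", {
  cfg <- apa_sim_config(n_genes = 10, multi_site_frac = 1,
                        n_prognostic = 1, prognostic_beta = 6,
                        psi_range = c(0.1, 0.9), psi_subject_sd = 0.25,
                        n_decoys = 0)
  gen <- generate_genome_annotation(cfg, seed = 14)
  hits <- purrr::map_lgl(1:10, function(s) {
    sim <- simulate_reads(gen$truth,
                          apa_sim_design(n_pairs = 100, depth = 0,
                                         decoy_depth = 0), seed = s)
    tum <- grep("_T$", sim$metadata$sample_id, value = TRUE)
    cl <- simulate_clinical(gen$truth, sim$psi_true, seed = s,
                            sample_ids = tum)
    g <- gen$truth$genes$gene_id[gen$truth$genes$beta != 0]
    pi_tbl <- tibble::tibble(
      sample_id = tum,
      pi = as.numeric(sim$psi_true[sim$psi_true$gene_id == g, tum]))
    stratify_and_logrank(pi_tbl, cl)$p < 0.01
  })
  expect_gte(mean(hits), 0.9)
})

test_that("all records censor when the horizon shrinks to zero", {
  gen <- generate_genome_annotation(apa_sim_config(n_genes = 5,
                                                   multi_site_frac = 1,
                                                   n_decoys = 0), seed = 1)
  sim <- simulate_reads(gen$truth, apa_sim_design(n_pairs = 5, depth = 0,
                                                  decoy_depth = 0),
                        seed = 1)
  cl <- simulate_clinical(gen$truth, sim$psi_true, seed = 1,
                          censor_horizon = 0)
  expect_true(all(cl$event == 0))
  expect_true(all(cl$time == 0))
})

test_that("expression coupling hits its Spearman target", {
  cfg <- apa_sim_config(n_genes = 40, multi_site_frac = 1,
                        switch_frac = 1, coupling_rho = 0.5, n_decoys = 0)
  gen <- generate_genome_annotation(cfg, seed = 15)
  sim <- simulate_reads(gen$truth, apa_sim_design(n_pairs = 30, depth = 0,
                                                  decoy_depth = 0),
                        seed = 16)
  ex <- simulate_expression_protein(gen$truth, sim$psi_true, seed = 17)
  rho <- correlate_psi_expression(sim$psi_true, ex$expression,
                                  min_samples = 10)$rho
  expect_lt(abs(mean(rho) - 0.5), 0.1)

  # rho = 1 makes expression ranks equal PSI ranks
  cfg1 <- apa_sim_config(n_genes = 5, multi_site_frac = 1,
                         switch_frac = 1, coupling_rho = 1, n_decoys = 0)
  gen1 <- generate_genome_annotation(cfg1, seed = 18)
  sim1 <- simulate_reads(gen1$truth,
                         apa_sim_design(n_pairs = 15, depth = 0,
                                        decoy_depth = 0), seed = 19)
  ex1 <- simulate_expression_protein(gen1$truth, sim1$psi_true, seed = 20)
  m_psi <- as.matrix(sim1$psi_true[, -1])
  m_ex <- as.matrix(ex1$expression[, -1])
  for (i in seq_len(nrow(m_psi))) {
    expect_equal(rank(m_ex[i, ]), rank(m_psi[i, ]))
  }
  expect_error(
    simulate_expression_protein(
      structure(list(genes = dplyr::mutate(gen1$truth$genes,
                                           coupling_rho = 1.5),
                     config = gen1$truth$config), class = "apa_truth"),
      sim1$psi_true, seed = 1), "rho")
})

test_that("null coupling leaves observed correlations near zero", {
  cfg <- apa_sim_config(n_genes = 100, multi_site_frac = 1,
                        switch_frac = 0, n_decoys = 0)
  gen <- generate_genome_annotation(cfg, seed = 21)
  sim <- simulate_reads(gen$truth, apa_sim_design(n_pairs = 50, depth = 0,
                                                  decoy_depth = 0),
                        seed = 22)
  ex <- simulate_expression_protein(gen$truth, sim$psi_true, seed = 23)
  rho <- correlate_psi_expression(sim$psi_true, ex$expression)$rho
  expect_gte(mean(abs(rho) < 0.25), 0.95)
})

test_that("constant concordance map leaves the deciles indistinguishable", {
  cfg <- apa_sim_config(n_genes = 60, multi_site_frac = 1, n_decoys = 0)
  gen <- generate_genome_annotation(cfg, seed = 24)
  sim <- simulate_reads(gen$truth, apa_sim_design(n_pairs = 20, depth = 0,
                                                  decoy_depth = 0),
                        seed = 25)
  ex <- simulate_expression_protein(gen$truth, sim$psi_true, seed = 26,
                                    protein_cor_range = c(0.5, 0.5),
                                    protein_cor_noise_sd = 0.05)
  r <- concordance_top_bottom(ex$protein_cor |>
                                dplyr::rename(
                                  mrna_protein_cor = mrna_protein_cor))
  expect_gt(r$p, 0.001)   # no systematic separation
  # and a monotone map does separate them
  ex2 <- simulate_expression_protein(gen$truth, sim$psi_true, seed = 27,
                                     protein_cor_range = c(0.1, 0.9),
                                     protein_cor_noise_sd = 0.02)
  r2 <- concordance_top_bottom(ex2$protein_cor)
  expect_lt(r2$p, 0.01)
  expect_gt(r2$top_median, r2$bottom_median)
})
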