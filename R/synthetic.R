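# Synthetic data with known ground truth.
#
# The generator emulates the statistical structure of a 3'-end-enriched
# (QuantSeq REV style) tumor/normal APA study: multi-polyA-site genes with
# planted tumor-vs-normal PSI shifts (predominantly shortening),
# internal-priming decoys at A-rich loci, hexamer-bearing true sites,
# same-/composite-/skipped-exon pair architectures, expression coupled to
# PSI at a target Spearman level, and exponential Cox survival driven by
# selected genes' PSI.

#' Generator settings for synthetic APA data
#'
#' Defaults mirror the proportions of a large tumor/normal 3'-end-seq
#' cohort: 46% of genes multi-site, 44% of multi-site genes with a planted
#' usage switch, 88% of switches being 3'UTR shortening. Each gene occupies
#' a fixed-length slot on a single synthetic chromosome; multi-site genes
#' realise one of the three proximal/distal pair architectures.
#'
#' @param n_genes Number of genes.
#' @param multi_site_frac Fraction of genes given two polyA sites.
#' @param switch_frac Fraction of multi-site genes with a planted non-zero
#'   tumor-normal PSI shift.
#' @param shorten_frac Fraction of planted switches that are shortenings
#'   (positive delta-PSI).
#' @param delta_psi Magnitude of the planted PSI shift.
#' @param pair_type_mix Named probabilities over
#'   `same_exon`/`composite_exon`/`skipped_exon` for multi-site genes.
#' @param n_decoys Number of internal-priming decoy loci (A-rich, no
#'   hexamer); must not exceed `n_genes`.
#' @param psi_range Range of the uniform normal-tissue baseline PSI.
#' @param psi_subject_sd Subject-level SD added to the per-sample true PSI.
#' @param hexamer Polyadenylation signal planted upstream of true sites.
#' @param hexamer_offset Transcript-orientation start offset of the planted
#'   hexamer relative to the cleavage locus (must lie in \[-30, -10\]).
#' @param gene_slot Chromosome bases reserved per gene (span + intergenic).
#' @param chrom Chromosome name.
#' @param chrom_len Chromosome length; default sized to fit all genes.
#' @param n_prognostic Number of genes given non-zero Cox coefficients.
#' @param prognostic_beta Magnitude of those coefficients (alternating sign).
#' @param coupling_rho Target Spearman correlation between PSI and
#'   expression for switched genes (0 for the rest).
#' @param base_probs Background base composition (kept A-poor so random
#'   sequence does not trip the internal-priming filter near true sites).
#' @return A list of settings (class `apa_sim_config`).
#' @export
apa_sim_config <- function(n_genes = 200,
                           multi_site_frac = 0.46,
                           switch_frac = 0.44,
                           shorten_frac = 0.88,
                           delta_psi = 0.3,
                           pair_type_mix = c(same_exon = 0.50,
                                             composite_exon = 0.29,
                                             skipped_exon = 0.21),
                           n_decoys = 40,
                           psi_range = c(0.2, 0.8),
                           psi_subject_sd = 0.05,
                           hexamer = "AATAAA",
                           hexamer_offset = -25,
                           gene_slot = 4000,
                           chrom = "chrS",
                           chrom_len = NULL,
                           n_prognostic = 3,
                           prognostic_beta = 2,
                           coupling_rho = 0.3,
                           base_probs = c(A = 0.18, C = 0.30, G = 0.30,
                                          T = 0.22)) {
  if (abs(sum(pair_type_mix) - 1) > 1e-8) {
    stop("pair_type_mix must sum to 1", call. = FALSE)
  }
  if (hexamer_offset < -30 || hexamer_offset > -10) {
    stop("hexamer_offset must lie in [-30, -10]", call. = FALSE)
  }
  if (n_decoys > n_genes) {
    stop("n_decoys must not exceed n_genes (one decoy per gene slot)",
         call. = FALSE)
  }
  gene_span <- 1600
  needed <- n_genes * gene_slot + gene_slot
  chrom_len <- chrom_len %||% needed
  if (chrom_len < needed) {
    stop(sprintf(
      "chromosome too short: %d genes with slot %d need %d bases, got %d",
      n_genes, gene_slot, needed, chrom_len), call. = FALSE)
  }
  structure(list(n_genes = n_genes, multi_site_frac = multi_site_frac,
                 switch_frac = switch_frac, shorten_frac = shorten_frac,
                 delta_psi = delta_psi, pair_type_mix = pair_type_mix,
                 n_decoys = n_decoys, psi_range = psi_range,
                 psi_subject_sd = psi_subject_sd, hexamer = hexamer,
                 hexamer_offset = hexamer_offset, gene_slot = gene_slot,
                 gene_span = gene_span, chrom = chrom, chrom_len = chrom_len,
                 n_prognostic = n_prognostic,
                 prognostic_beta = prognostic_beta,
                 coupling_rho = coupling_rho, base_probs = base_probs),
            class = "apa_sim_config")
}

# Template gene architectures in transcript-orientation coordinates on
# [0, 1600). Each returns exons/CDS per transcript and the site roles.
# Site positions: proximal placed so pairs are >125 nt apart after the
# atlas spacing filter.
gene_template <- function(config_type) {
  last_exon <- c(1000, 1600)
  cds_main <- list(c(50, 200), c(1000, 1200))   # 3'UTR = [1200, 1600)
  switch(config_type,
    single = list(
      tx = list(T1 = list(exons = list(c(0, 200), last_exon),
                          cds = cds_main)),
      sites = c(single = 1500)),
    same_exon = list(
      tx = list(T1 = list(exons = list(c(0, 200), last_exon),
                          cds = cds_main)),
      sites = c(proximal = 1250, distal = 1550)),
    composite_exon = list(
      tx = list(
        T1 = list(exons = list(c(0, 200), last_exon), cds = cds_main),
        # proximal isoform retains past the 5' splice donor at 200
        T2 = list(exons = list(c(0, 450)), cds = NULL)),
      sites = c(proximal = 420, distal = 1550)),
    skipped_exon = list(
      tx = list(
        T1 = list(exons = list(c(0, 200), last_exon), cds = cds_main),
        # proximal isoform ends in a cassette exon absent from T1
        T2 = list(exons = list(c(0, 200), c(500, 700)), cds = NULL)),
      sites = c(proximal = 650, distal = 1550)),
    stop("unknown gene architecture: ", config_type, call. = FALSE))
}

# template-coordinate interval/position -> genomic, given slot start and strand
tpl_interval <- function(iv, s0, strand, span) {
  if (strand == "+") c(s0 + iv[1], s0 + iv[2]) else
    c(s0 + span - iv[2], s0 + span - iv[1])
}
tpl_pos <- function(p, s0, strand, span) {
  if (strand == "+") s0 + p else s0 + span - 1 - p
}

#' Generate a synthetic genome, annotation and ground truth
#'
#' Lays out genes on one synthetic chromosome, writes a hexamer into the
#' \[-30, -10\] window upstream of every planted cleavage locus (transcript
#' orientation), scrubs the \[-30, +10\] context of true sites free of A-runs,
#' and plants decoy loci carrying an 8-base downstream A-run and no
#' hexamer. Identical `(config, seed)` inputs reproduce identical outputs.
#'
#' @param config An [apa_sim_config()].
#' @param seed Integer seed.
#' @return List with `genome` (named `DNAStringSet`), `models`
#'   ([gene_models()]), and `truth` (list of tibbles: `genes` with planted
#'   baseline PSI / delta-PSI / Cox beta / coupling rho, `sites`, `decoys`,
#'   plus the config echo and seed).
#' @export
generate_genome_annotation <- function(config = apa_sim_config(), seed = 1) {
  stopifnot(inherits(config, "apa_sim_config"))
  set.seed(seed)
  n <- config$n_genes
  span <- config$gene_span

  # assign architecture, strand, planted parameters per gene
  n_multi <- round(n * config$multi_site_frac)
  is_multi <- seq_len(n) <= n_multi   # deterministic block; order is arbitrary
  pair_type <- rep(NA_character_, n)
  if (n_multi > 0) {
    pair_type[is_multi] <- sample(names(config$pair_type_mix), n_multi,
                                  replace = TRUE, prob = config$pair_type_mix)
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  psi_normal <- stats::runif(n, config$psi_range[1], config$psi_range[2])
  n_switch <- round(n_multi * config$switch_frac)
  switched <- is_multi & seq_len(n) <= n_switch
  sign_up <- stats::runif(n) < config$shorten_frac
  delta <- ifelse(switched, ifelse(sign_up, 1, -1) * config$delta_psi, 0)
  delta[!is_multi] <- 0
  # record clipping against [0,1] at the truth level
  psi_tumor <- clip01(psi_normal + delta)
  clipped <- abs((psi_tumor - psi_normal) - delta) > 1e-12
  delta_eff <- psi_tumor - psi_normal

  beta <- rep(0, n)
  if (config$n_prognostic > 0) {
    idx <- which(is_multi)[seq_len(min(config$n_prognostic, n_multi))]
    beta[idx] <- config$prognostic_beta * rep_len(c(1, -1), length(idx))
  }
  rho <- ifelse(switched, config$coupling_rho, 0)

  gene_id <- sprintf("G%04d", seq_len(n))
  s0 <- (seq_len(n) - 1) * config$gene_slot + 1000

  exon_rows <- list(); cds_rows <- list(); site_rows <- list()
  for (i in seq_len(n)) {
    type_i <- if (is_multi[i]) pair_type[i] else "single"
    tpl <- gene_template(type_i)
    for (tx_name in names(tpl$tx)) {
      tid <- paste0(gene_id[i], ".", tx_name)
      for (iv in tpl$tx[[tx_name]]$exons) {
        g <- tpl_interval(iv, s0[i], strand[i], span)
        exon_rows[[length(exon_rows) + 1]] <- tibble::tibble(
          transcript_id = tid, gene_id = gene_id[i], chrom = config$chrom,
          strand = strand[i], start = g[1], end = g[2])
      }
      for (iv in tpl$tx[[tx_name]]$cds %||% list()) {
        g <- tpl_interval(iv, s0[i], strand[i], span)
        cds_rows[[length(cds_rows) + 1]] <- tibble::tibble(
          transcript_id = tid, gene_id = gene_id[i], chrom = config$chrom,
          strand = strand[i], start = g[1], end = g[2])
      }
    }
    for (role in names(tpl$sites)) {
      site_pos <- tpl_pos(tpl$sites[[role]], s0[i], strand[i], span)
      site_rows[[length(site_rows) + 1]] <- tibble::tibble(
        gene_id = gene_id[i], chrom = config$chrom, strand = strand[i],
        pos = site_pos, role = role)
    }
  }
  exons <- dplyr::bind_rows(exon_rows)
  cds <- dplyr::bind_rows(cds_rows)
  sites <- dplyr::bind_rows(site_rows)

  genes_tb <- tibble::tibble(
    gene_id = gene_id, chrom = config$chrom, strand = strand,
    start = s0, end = s0 + span,
    biotype = "coding")
  txs <- dplyr::distinct(exons, .data$transcript_id, .data$gene_id)
  models <- gene_models(genes_tb, txs, exons, cds = cds)

  # decoys: one per slot, in the intergenic margin upstream of the gene body
  decoys <- tibble::tibble(chrom = character(), strand = character(),
                           pos = numeric())
  if (config$n_decoys > 0) {
    dslots <- seq_len(config$n_decoys)
    decoys <- tibble::tibble(
      chrom = config$chrom,
      strand = sample(c("+", "-"), config$n_decoys, replace = TRUE),
      pos = (dslots - 1) * config$gene_slot + 200)
  }

  genome <- build_genome_sequence(config, sites, decoys)

  truth <- structure(list(
    genes = tibble::tibble(
      gene_id = gene_id, chrom = config$chrom, strand = strand,
      start = s0, end = s0 + span,
      pair_config = ifelse(is_multi, pair_type, "single"),
      multi_site = is_multi,
      psi_normal = psi_normal, delta_psi = delta_eff,
      delta_clipped = clipped, switched = delta_eff != 0,
      beta = beta, coupling_rho = rho),
    sites = sites, decoys = decoys,
    config = config, seed = seed), class = "apa_truth")
  check_truth(truth)
  list(genome = genome, models = models, truth = truth)
}

check_truth <- function(truth) {
  g <- truth$genes
  s <- truth$sites
  n_sites <- dplyr::count(s, .data$gene_id)
  sw <- g$gene_id[g$delta_psi != 0]
  stopifnot(all(n_sites$n[n_sites$gene_id %in% sw] >= 2))
  stopifnot(all(abs(g$delta_psi) <= 1))
  if (nrow(truth$decoys) > 0 && nrow(s) > 0) {
    dmin <- vapply(truth$decoys$pos,
                   function(p) min(abs(p - s$pos)), numeric(1))
    stopifnot(all(dmin >= 125))
  }
  invisible(truth)
}

# Random background with planted site/decoy contexts. Site context: 41 nt
# covering transcript-orientation offsets [-30, +10], A-free except the
# planted hexamer, so true sites always pass the internal-priming filter
# and carry exactly one signal in the hexamer window. Decoy context: A-free
# upstream (no hexamer possible), 8 consecutive As at offsets [+1, +8].
build_genome_sequence <- function(config, sites, decoys) {
  bases <- c("A", "C", "G", "T")
  seq_vec <- sample(bases, config$chrom_len, replace = TRUE,
                    prob = config$base_probs[bases])
  noA <- function(k) sample(c("C", "G", "T"), k, replace = TRUE)

  ctx_site <- function() {
    ctx <- noA(41)                       # offsets -30..+10 -> index 1..41
    h <- strsplit(config$hexamer, "")[[1]]
    at <- config$hexamer_offset + 31     # offset -30 -> index 1
    ctx[at:(at + 5)] <- h
    ctx
  }
  ctx_decoy <- function() {
    ctx <- noA(41)
    ctx[32:39] <- "A"                    # offsets +1..+8
    ctx
  }
  write_ctx <- function(seq_vec, pos, strand, ctx) {
    if (strand == "-") {
      ctx <- rev(chartr("ACGT", "TGCA", ctx))
      lo <- pos - 10
    } else {
      lo <- pos - 30
    }
    seq_vec[(lo + 1):(lo + 41)] <- ctx   # 0-based pos -> 1-based index
    seq_vec
  }
  for (i in seq_len(nrow(sites))) {
    seq_vec <- write_ctx(seq_vec, sites$pos[i], sites$strand[i], ctx_site())
  }
  for (i in seq_len(nrow(decoys))) {
    seq_vec <- write_ctx(seq_vec, decoys$pos[i], decoys$strand[i], ctx_decoy())
  }
  genome <- Biostrings::DNAStringSet(paste(seq_vec, collapse = ""))
  names(genome) <- config$chrom
  genome
}

#' Sample design for read simulation
#'
#' @param n_pairs Number of tumor/normal subject pairs.
#' @param depth Mean reads per gene per sample (Poisson).
#' @param jitter_sd SD (nt) of the cleavage-position jitter, truncated at
#'   +/-5 nt; 0 plants every read exactly at the true locus.
#' @param read_len Aligned read length (nt).
#' @param decoy_depth Mean reads per decoy locus per sample.
#' @return A list of settings (class `apa_sim_design`).
#' @export
apa_sim_design <- function(n_pairs = 20, depth = 200, jitter_sd = 1,
                           read_len = 80, decoy_depth = 30) {
  stopifnot(depth >= 0, n_pairs >= 1, read_len >= 20)
  structure(list(n_pairs = n_pairs, depth = depth, jitter_sd = jitter_sd,
                 read_len = read_len, decoy_depth = decoy_depth),
            class = "apa_sim_design")
}

#' Simulate 3'-end-enriched read alignments
#'
#' Draws per-sample, per-site read counts around the planted usage (tumor
#' PSI = normal PSI + planted delta, clipped to \[0, 1\], with subject-level
#' jitter), distributes cleavage positions within +/-5 nt of the planted
#' locus, gives decoy loci reads at the configured rate, and emits
#' single-end alignments in REV-protocol orientation: the read aligns
#' antisense to the transcript and the cleavage locus is the read's 5'
#' terminus.
#'
#' @param truth Ground truth from [generate_genome_annotation()].
#' @param design An [apa_sim_design()].
#' @param seed Integer seed.
#' @return List with `alignments` (tibble: `chrom, strand, start, end,
#'   cigar, sample_id, count`; aggregated identical reads), `metadata`
#'   (tibble: `sample_id, subject, tissue`), and `psi_true` (wide
#'   gene-by-sample tibble of realised per-sample usage probabilities for
#'   multi-site genes).
#' @export
simulate_reads <- function(truth, design = apa_sim_design(), seed = 1) {
  stopifnot(inherits(truth, "apa_truth"))
  set.seed(seed)
  cfg <- truth$config
  g <- truth$genes
  subjects <- sprintf("P%03d", seq_len(design$n_pairs))
  metadata <- tibble::tibble(
    sample_id = c(paste0(subjects, "_T"), paste0(subjects, "_N")),
    subject = rep(subjects, 2),
    tissue = rep(c("tumor", "normal"), each = design$n_pairs))
  metadata <- dplyr::arrange(metadata, .data$subject, .data$tissue)

  # realised per-sample true usage for multi-site genes
  n_s <- nrow(metadata)
  base <- ifelse(metadata$tissue == "tumor", 1, 0)
  psi_true <- matrix(NA_real_, nrow = nrow(g), ncol = n_s,
                     dimnames = list(g$gene_id, metadata$sample_id))
  for (i in seq_len(nrow(g))) {
    mu <- g$psi_normal[i] + base * g$delta_psi[i]
    psi_true[i, ] <- clip01(mu + stats::rnorm(n_s, 0, cfg$psi_subject_sd),
                            0.02, 0.98)
  }

  # jitter distribution over offsets -5..5 (transcript orientation;
  # symmetric, so genomic offsets are equivalent)
  offs <- -5:5
  jp <- if (design$jitter_sd <= 0) as.numeric(offs == 0) else {
    w <- stats::dnorm(offs, 0, design$jitter_sd); w / sum(w)
  }

  sites <- truth$sites
  rows <- vector("list", 0)
  emit <- function(chrom, tx_strand, locus_counts, sample_id) {
    # locus_counts: named vector, names = cleavage loci (0-based)
    loci <- as.numeric(names(locus_counts))
    keep <- locus_counts > 0
    if (!any(keep)) return(NULL)
    loci <- loci[keep]; cnt <- locus_counts[keep]
    if (tx_strand == "+") {
      tibble::tibble(chrom = chrom, strand = "-",
                     start = loci - design$read_len + 1, end = loci + 1,
                     cigar = paste0(design$read_len, "M"),
                     sample_id = sample_id, count = as.integer(cnt))
    } else {
      tibble::tibble(chrom = chrom, strand = "+",
                     start = loci, end = loci + design$read_len,
                     cigar = paste0(design$read_len, "M"),
                     sample_id = sample_id, count = as.integer(cnt))
    }
  }
  jittered <- function(pos, n_reads) {
    if (n_reads == 0) return(stats::setNames(integer(0), character(0)))
    k <- stats::rmultinom(1, n_reads, jp)[, 1]
    stats::setNames(k, pos + offs)
  }

  for (s in seq_len(n_s)) {
    sid <- metadata$sample_id[s]
    depth_g <- stats::rpois(nrow(g), design$depth)
    for (i in seq_len(nrow(g))) {
      gs <- sites[sites$gene_id == g$gene_id[i], ]
      if (depth_g[i] == 0) next
      if (g$multi_site[i]) {
        prox <- stats::rbinom(1, depth_g[i], psi_true[i, s])
        dist_n <- depth_g[i] - prox
        p_row <- gs[gs$role == "proximal", ]
        d_row <- gs[gs$role == "distal", ]
        rows[[length(rows) + 1]] <-
          emit(p_row$chrom, p_row$strand, jittered(p_row$pos, prox), sid)
        rows[[length(rows) + 1]] <-
          emit(d_row$chrom, d_row$strand, jittered(d_row$pos, dist_n), sid)
      } else {
        row1 <- gs[1, ]
        rows[[length(rows) + 1]] <-
          emit(row1$chrom, row1$strand, jittered(row1$pos, depth_g[i]), sid)
      }
    }
    if (nrow(truth$decoys) > 0 && design$decoy_depth > 0) {
      nd <- stats::rpois(nrow(truth$decoys), design$decoy_depth)
      for (j in seq_len(nrow(truth$decoys))) {
        d <- truth$decoys[j, ]
        rows[[length(rows) + 1]] <-
          emit(d$chrom, d$strand, jittered(d$pos, nd[j]), sid)
      }
    }
  }
  aln <- dplyr::bind_rows(rows)
  if (nrow(aln) > 0) {
    aln <- aln |>
      dplyr::group_by(.data$chrom, .data$strand, .data$start, .data$end,
                      .data$cigar, .data$sample_id) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  }
  psi_wide <- matrix_as_psi(psi_true[g$multi_site, , drop = FALSE])
  list(alignments = aln, metadata = metadata, psi_true = psi_wide)
}

#' Write simulated alignments to SAM
#'
#' Minimal single-end SAM emitter for the simulator's aggregated alignment
#' tibble (each row expanded to `count` records). Mapping quality is fixed;
#' sequences are written as `*`.
#'
#' @param alignments Alignment tibble from [simulate_reads()].
#' @param genome Named `DNAStringSet` (for `@SQ` header lines).
#' @param path Output path (`.sam`).
#' @param sample_id Optional filter to one sample.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(alignments, genome, path, sample_id = NULL) {
  if (!is.null(sample_id)) {
    alignments <- dplyr::filter(alignments, .data$sample_id %in% !!sample_id)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  idx <- rep(seq_len(nrow(alignments)), alignments$count)
  a <- alignments[idx, ]
  body <- sprintf("r%06d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*\tRG:Z:%s",
                  seq_len(nrow(a)),
                  ifelse(a$strand == "-", 16L, 0L),
                  a$chrom, a$start + 1, a$cigar, a$sample_id)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate survival and clinical covariates
#'
#' Event times are exponential under a Cox model whose linear predictor is
#' the sum of planted per-gene coefficients times the (centred) true PSI,
#' with administrative censoring at a fixed horizon. Covariate marginals
#' (age, sex, race, smoking, stage) default to a realistic lung-cancer
#' case-series mix and have no effect on survival unless `covariate_betas`
#' is supplied.
#'
#' @param truth Ground truth from [generate_genome_annotation()].
#' @param psi_truth Wide gene-by-sample tibble of true PSI (typically
#'   `simulate_reads()$psi_true`, tumor samples selected by `sample_ids`).
#' @param seed Integer seed.
#' @param sample_ids Samples to generate records for; defaults to all
#'   columns of `psi_truth`.
#' @param baseline_hazard Exponential baseline hazard (events per month).
#' @param censor_horizon Administrative censoring time (months); 0 censors
#'   everything.
#' @param covariate_betas Optional named vector of log-hazard effects for
#'   `age` (per year, centred) and/or `sexmale`, `raceAA`, stage terms.
#' @return Tibble: `sample_id, time, event, age, sex, race, stage, smoking`.
#' @export
simulate_clinical <- function(truth, psi_truth, seed = 1, sample_ids = NULL,
                              baseline_hazard = 0.02, censor_horizon = 60,
                              covariate_betas = NULL) {
  stopifnot(inherits(truth, "apa_truth"))
  set.seed(seed)
  m <- psi_as_matrix(psi_truth)
  sample_ids <- sample_ids %||% colnames(m)
  m <- m[, sample_ids, drop = FALSE]
  n <- length(sample_ids)

  beta <- truth$genes$beta[match(rownames(m), truth$genes$gene_id)]
  beta[is.na(beta)] <- 0
  lp <- as.numeric(crossprod(m - 0.5, beta))

  age <- round(stats::rnorm(n, 64.5, 8.9), 1)
  sex <- sample(c("male", "female"), n, TRUE, prob = c(0.28, 0.72))
  race <- sample(c("AA", "EA"), n, TRUE, prob = c(0.47, 0.53))
  stage <- sample(c("I", "II", "III"), n, TRUE, prob = c(0.62, 0.28, 0.10))
  smoking <- sample(c("never", "former", "current"), n, TRUE,
                    prob = c(0.06, 0.36, 0.58))
  if (!is.null(covariate_betas)) {
    cb <- function(nm) covariate_betas[nm] %||% 0
    lp <- lp +
      (if ("age" %in% names(covariate_betas))
         covariate_betas[["age"]] * (age - mean(age)) else 0) +
      (if ("sexmale" %in% names(covariate_betas))
         covariate_betas[["sexmale"]] * (sex == "male") else 0) +
      (if ("raceAA" %in% names(covariate_betas))
         covariate_betas[["raceAA"]] * (race == "AA") else 0)
  }
  t_event <- stats::rexp(n, rate = baseline_hazard * exp(lp))
  time <- pmin(t_event, censor_horizon)
  event <- as.integer(t_event <= censor_horizon)
  tibble::tibble(sample_id = sample_ids, time = time, event = event,
                 age = age, sex = sex, race = race, stage = stage,
                 smoking = smoking)
}

#' Simulate expression coupled to PSI, and mRNA-protein concordance
#'
#' Per gene, expression is generated with a Gaussian-copula rank coupling
#' to the gene's PSI so its Spearman correlation targets the planted rho
#' (`2*sin(pi*rho/6)` latent Pearson). A per-gene mRNA-protein correlation
#' is generated as a monotone map of the gene's median PSI plus noise,
#' emulating higher concordance for genes with more 3'UTR shortening.
#'
#' @param truth Ground truth from [generate_genome_annotation()].
#' @param psi_truth Wide gene-by-sample tibble of true (or estimated) PSI.
#' @param seed Integer seed.
#' @param protein_cor_range Length-2 range of the monotone map from median
#'   PSI to mRNA-protein correlation (constant map when equal).
#' @param protein_cor_noise_sd Noise SD added to the mapped correlation.
#' @return List with `expression` (wide gene-by-sample tibble, TPM-like)
#'   and `protein_cor` (tibble: `gene_id, median_psi, mrna_protein_cor`).
#' @export
simulate_expression_protein <- function(truth, psi_truth, seed = 1,
                                        protein_cor_range = c(0.2, 0.8),
                                        protein_cor_noise_sd = 0.05) {
  stopifnot(inherits(truth, "apa_truth"))
  set.seed(seed)
  m <- psi_as_matrix(psi_truth)
  n <- ncol(m)
  rho <- truth$genes$coupling_rho[match(rownames(m), truth$genes$gene_id)]
  rho[is.na(rho)] <- 0
  if (any(abs(rho) > 1)) stop("target |rho| > 1", call. = FALSE)
  r <- 2 * sin(pi * rho / 6)
  expr <- matrix(NA_real_, nrow(m), n, dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    z <- stats::qnorm(rank(m[i, ], ties.method = "average") / (n + 1))
    z <- (z - mean(z)) / max(stats::sd(z), 1e-12)
    x <- r[i] * z + sqrt(max(0, 1 - r[i]^2)) * stats::rnorm(n)
    expr[i, ] <- round(2^(6 + x), 4)   # TPM-like positive scale
  }
  med <- apply(m, 1, stats::median, na.rm = TRUE)
  lo <- protein_cor_range[1]; hi <- protein_cor_range[2]
  rng <- diff(range(med))
  scaled <- if (rng > 0) (med - min(med)) / rng else rep(0.5, length(med))
  pcor <- clip01(lo + (hi - lo) * scaled +
                   stats::rnorm(length(med), 0, protein_cor_noise_sd),
                 -1, 1)
  list(expression = matrix_as_psi(expr, provenance = "simulated"),
       protein_cor = tibble::tibble(gene_id = rownames(m), median_psi = med,
                                    mrna_protein_cor = pcor))
}

#' Simulate a mutation-status table for driver genes
#'
#' Bernoulli mutation calls per driver gene and sample, optionally with a
#' planted shift in a sample-level score for mutated samples (used to test
#' fold-change detection).
#'
#' @param sample_ids Character vector of samples.
#' @param driver_genes Character vector of driver gene names.
#' @param mutation_rate Per-gene mutation probability.
#' @param seed Integer seed.
#' @return Tibble: `gene, sample_id, mutated` (0/1).
#' @export
simulate_mutations <- function(sample_ids, driver_genes,
                               mutation_rate = 0.2, seed = 1) {
  set.seed(seed)
  tidyr::expand_grid(gene = driver_genes, sample_id = sample_ids) |>
    dplyr::mutate(mutated = stats::rbinom(dplyr::n(), 1, mutation_rate))
}
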