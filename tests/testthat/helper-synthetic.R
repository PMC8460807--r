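# Shared fixtures and independent oracles.

.apa_cache <- new.env(parent = emptyenv())

# One default-condition synthetic cohort (200 genes, 40 decoys, 20
# tumor/normal pairs, ~200 reads/gene/sample) run through the full
# pipeline; memoized because several suites measure different properties
# of the same run.
default_synthetic_run <- function() {
  if (!is.null(.apa_cache$run)) return(.apa_cache$run)
  cfg <- apa_sim_config()
  gen <- generate_genome_annotation(cfg, seed = 190801)
  sim <- simulate_reads(gen$truth, apa_sim_design(), seed = 190802)
  run <- run_apa_pipeline(sim$alignments, gen$genome, gen$models,
                          sim$metadata)
  .apa_cache$run <- list(gen = gen, sim = sim, run = run)
  .apa_cache$run
}

# Draw proximal/distal read counts directly from planted usage (binomial
# sampling at given depth), bypassing the read/atlas layers; used to
# calibrate the switch test at scale.
simulate_count_cohort <- function(truth, n_pairs, depth, seed) {
  set.seed(seed)
  g <- truth$genes[truth$genes$multi_site, ]
  subjects <- sprintf("S%03d", seq_len(n_pairs))
  meta <- tibble::tibble(
    sample_id = c(paste0(subjects, "_T"), paste0(subjects, "_N")),
    subject = rep(subjects, 2),
    tissue = rep(c("tumor", "normal"), each = n_pairs))
  sd0 <- truth$config$psi_subject_sd
  counts <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    mu <- g$psi_normal[i] + (meta$tissue == "tumor") * g$delta_psi[i]
    p <- pmin(pmax(mu + stats::rnorm(nrow(meta), 0, sd0), 0.02), 0.98)
    n <- stats::rpois(nrow(meta), depth)
    prox <- stats::rbinom(nrow(meta), n, p)
    tibble::tibble(gene_id = g$gene_id[i], sample_id = meta$sample_id,
                   proximal = prox, distal = n - prox)
  })
  list(counts = counts, metadata = meta, genes = g)
}

# genome from a plain character chromosome
char_genome <- function(seq, chrom = "chr1") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- chrom
  g
}

# a chromosome of background base `bg` with `pattern` written at 0-based
# position `at` (forward strand characters)
patterned_genome <- function(len, pattern, at, bg = "C", chrom = "chr1") {
  s <- rep(bg, len)
  p <- strsplit(pattern, "")[[1]]
  s[(at + 1):(at + length(p))] <- p
  char_genome(paste(s, collapse = ""), chrom)
}

one_event <- function(pos, strand = "+", chrom = "chr1", count = 10,
                      sample_id = "S1") {
  tibble::tibble(chrom = chrom, strand = strand, pos = pos,
                 sample_id = sample_id, count = count)
}

# ---- independent oracles -------------------------------------------------

# Benjamini-Hochberg step-up by definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# stated dominant-site ranking procedure, straight transliteration:
# rank all clusters by descending pooled count (5'-most first on ties),
# walk the ranking, keep those >= spacing from everything already kept
oracle_spacing <- function(pos, count, strand, spacing = 125) {
  key <- if (strand == "+") pos else -pos
  ord <- order(-count, key)
  kept <- numeric(0)
  for (i in ord) {
    if (all(abs(pos[i] - kept) >= spacing)) kept <- c(kept, pos[i])
  }
  sort(kept)
}

# two-group log-rank by the textbook hypergeometric formula
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- unique(group)[1]
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# ---- brute-force classification oracles ----------------------------------
# Work on explicit per-base sets rather than interval arithmetic.

bases_of <- function(iv) {
  if (nrow(iv) == 0) return(integer(0))
  unlist(lapply(seq_len(nrow(iv)), function(i) seq(iv$start[i],
                                                   iv$end[i] - 1)))
}

oracle_location <- function(pos, gene, exons, utr3) {
  if (pos %in% bases_of(utr3)) return("3UTR")
  if (pos %in% bases_of(exons)) return("exon")
  if (pos %in% seq(gene$start, gene$end - 1)) return("intron")
  "downstream-extension"
}

oracle_pair_type <- function(pp, dp, strand, exons) {
  txs <- unique(exons$transcript_id)
  exon_rows <- function(t) exons[exons$transcript_id == t, ]
  # same-exon
  for (t in txs) {
    e <- exon_rows(t)
    for (i in seq_len(nrow(e))) {
      b <- seq(e$start[i], e$end[i] - 1)
      if (pp %in% b && dp %in% b) return("same-exon")
    }
  }
  prox_tx <- txs[vapply(txs, function(t) pp %in% bases_of(exon_rows(t)),
                        logical(1))]
  dist_tx <- txs[vapply(txs, function(t) dp %in% bases_of(exon_rows(t)),
                        logical(1))]
  skipped <- FALSE; composite <- FALSE
  for (tp in prox_tx) {
    e <- exon_rows(tp)
    hit <- which(vapply(seq_len(nrow(e)), function(i)
      pp %in% seq(e$start[i], e$end[i] - 1), logical(1)))[1]
    pe_b <- seq(e$start[hit], e$end[hit] - 1)
    for (td in dist_tx) {
      ed <- exon_rows(td)
      ed_b <- bases_of(ed)
      span_b <- seq(min(ed$start), max(ed$end) - 1)
      if (length(intersect(pe_b, ed_b)) == 0 && all(pe_b %in% span_b)) {
        skipped <- TRUE
      }
      # 5' splice donors of td in transcript orientation
      if (strand == "+") {
        donors <- setdiff(ed$end, max(ed$end))
        if (any(donors %in% pe_b & pp >= donors)) composite <- TRUE
      } else {
        donors <- setdiff(ed$start, min(ed$start))
        for (d0 in donors) {
          if ((d0 - 1) %in% pe_b && pp < d0) composite <- TRUE
        }
      }
    }
  }
  if (skipped) return("skipped-exon")
  "composite-exon"
}

# Randomized single-gene models spanning the three pair architectures,
# with randomized exon boundaries, strand, and site placements.
random_gene_model <- function(gid = "G1") {
  arch <- sample(c("same", "skipped", "composite"), 1)
  strand <- sample(c("+", "-"), 1)
  e1_len <- sample(80:250, 1)
  i1_len <- sample(150:400, 1)
  cass_len <- sample(80:250, 1)
  i2_len <- sample(150:400, 1)
  last_len <- sample(300:700, 1)
  ext_len <- sample(60:200, 1)
  e1 <- c(0, e1_len)
  cass <- c(e1_len + i1_len, e1_len + i1_len + cass_len)
  l0 <- cass[2] + i2_len
  last <- c(l0, l0 + last_len)
  cds_end <- l0 + sample(50:(last_len - 100), 1)
  span <- last[2]
  s0 <- 1000
  g2 <- function(iv) if (strand == "+") s0 + iv else
    c(s0 + span - iv[2], s0 + span - iv[1])
  p2 <- function(p) if (strand == "+") s0 + p else s0 + span - 1 - p

  ex <- list(); cds <- list()
  add_tx <- function(tid, ivs) {
    for (iv in ivs) {
      g <- g2(iv)
      ex[[length(ex) + 1]] <<- tibble::tibble(
        transcript_id = tid, gene_id = gid, chrom = "chr1",
        strand = strand, start = g[1], end = g[2])
    }
  }
  add_tx("T1", list(e1, last))
  for (iv in list(c(e1[1] + 10, e1[2]), c(l0, cds_end))) {
    g <- g2(iv)
    cds[[length(cds) + 1]] <- tibble::tibble(
      transcript_id = "T1", gene_id = gid, chrom = "chr1",
      strand = strand, start = g[1], end = g[2])
  }
  utr_lo <- cds_end
  dp_t <- sample((utr_lo + 10):(last[2] - 5), 1)
  pp_t <- switch(arch,
    same = sample((utr_lo + 1):(dp_t - 5), 1),
    skipped = { add_tx("T2", list(e1, cass))
                sample(cass[1]:(cass[2] - 1), 1) },
    composite = { add_tx("T2", list(c(0, e1[2] + ext_len)))
                  sample(e1[2]:(e1[2] + ext_len - 1), 1) })

  genes <- tibble::tibble(gene_id = gid, chrom = "chr1", strand = strand,
                          start = s0, end = s0 + span, biotype = "coding",
                          extended_end = if (strand == "+") s0 + span + 2000
                                         else s0 - 2000)
  exons <- dplyr::bind_rows(ex)
  models <- gene_models(genes,
                        dplyr::distinct(exons, transcript_id, gene_id),
                        exons, cds = dplyr::bind_rows(cds))
  models$genes$extended_end <- genes$extended_end
  # an extra random locus anywhere in the gene span or extension, for
  # location classification
  extra_t <- sample(0:(span - 1), 1)
  list(models = models, strand = strand, arch = arch,
       proximal = p2(pp_t), distal = p2(dp_t), extra = p2(extra_t),
       gene = models$genes[1, ])
}
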