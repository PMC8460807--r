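# Count-level filtering, PSI/delta-PSI computation, tumor-normal switch
# testing, and PSI-expression correlation with a permutation null.
#
# PSI (polyA site index) for a gene in a sample is the proximal-site read
# count divided by the proximal+distal total; higher PSI means shorter
# 3'UTR usage. delta-PSI is tumor minus matched normal, so positive values
# are shortening.

#' Abundance filters on gene-assigned site counts
#'
#' Applied in order, with reasons logged:
#' 1. presence — the site is non-zero in at least `presence` of all
#'    samples;
#' 2. group-count — the summed count is at least `group_min` in the tumor
#'    group AND in the non-involved group;
#' 3. minor-fraction — the pooled count is at least `minor_frac` of the
#'    gene's best-supported surviving site.
#'
#' @param site_counts Long tibble `gene_id, chrom, strand, pos, sample_id,
#'   count` (absent rows mean zero).
#' @param metadata Sample table with `sample_id` and `tissue`
#'   (`tumor`/`normal`).
#' @param presence Minimum fraction of samples with non-zero count.
#' @param group_min Minimum per-group summed count.
#' @param minor_frac Minimum fraction of the gene's major site.
#' @return List with `counts` (surviving rows) and `removed` (site-level
#'   tibble with a `reason` column: `presence`, `group-count`, or
#'   `minor-fraction`).
#' @export
apply_abundance_filters <- function(site_counts, metadata, presence = 0.25,
                                    group_min = 10, minor_frac = 0.05) {
  md <- tibble::as_tibble(metadata)
  if (!all(c("tumor", "normal") %in% md$tissue)) {
    stop("metadata must contain both tumor and normal samples",
         call. = FALSE)
  }
  n_samples <- dplyr::n_distinct(md$sample_id)
  sc <- site_counts |>
    dplyr::inner_join(md[, c("sample_id", "tissue")], by = "sample_id")
  per_site <- sc |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand, .data$pos) |>
    dplyr::summarise(
      n_present = dplyr::n_distinct(.data$sample_id[.data$count > 0]),
      tumor_sum = sum(.data$count[.data$tissue == "tumor"]),
      normal_sum = sum(.data$count[.data$tissue == "normal"]),
      pooled = sum(.data$count), .groups = "drop")

  per_site$reason <- NA_character_
  fail1 <- per_site$n_present < presence * n_samples
  per_site$reason[fail1] <- "presence"
  fail2 <- is.na(per_site$reason) &
    (per_site$tumor_sum < group_min | per_site$normal_sum < group_min)
  per_site$reason[fail2] <- "group-count"
  surv <- is.na(per_site$reason)
  surv_rows <- per_site[surv, ]
  major <- if (nrow(surv_rows) == 0) {
    tibble::tibble(gene_id = character(), major = numeric())
  } else {
    surv_rows |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(major = max(.data$pooled), .groups = "drop")
  }
  per_site <- dplyr::left_join(per_site, major, by = "gene_id")
  fail3 <- is.na(per_site$reason) & per_site$pooled < per_site$major *
    minor_frac
  per_site$reason[fail3] <- "minor-fraction"

  removed <- per_site |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select("gene_id", "chrom", "strand", "pos", "reason")
  kept_sites <- per_site |>
    dplyr::filter(is.na(.data$reason)) |>
    dplyr::select("gene_id", "chrom", "strand", "pos")
  counts <- dplyr::semi_join(site_counts, kept_sites,
                             by = c("gene_id", "chrom", "strand", "pos"))
  list(counts = counts, removed = removed)
}

#' Per-sample proximal/distal counts for paired sites
#'
#' @param site_counts Long count tibble (`gene_id, chrom, strand, pos,
#'   sample_id, count`).
#' @param pairs Pair tibble (`gene_id, proximal_pos, distal_pos`).
#' @param sample_ids All sample ids (absent combinations count 0).
#' @return Tibble `gene_id, sample_id, proximal, distal`.
#' @export
pair_counts <- function(site_counts, pairs, sample_ids) {
  grid <- tidyr::expand_grid(gene_id = pairs$gene_id,
                             sample_id = sample_ids)
  get_role <- function(role_pos) {
    pairs |>
      dplyr::select("gene_id", pos = dplyr::all_of(role_pos)) |>
      dplyr::inner_join(site_counts, by = c("gene_id", "pos")) |>
      dplyr::select("gene_id", "sample_id", "count")
  }
  grid |>
    dplyr::left_join(get_role("proximal_pos") |>
                       dplyr::rename(proximal = "count"),
                     by = c("gene_id", "sample_id")) |>
    dplyr::left_join(get_role("distal_pos") |>
                       dplyr::rename(distal = "count"),
                     by = c("gene_id", "sample_id")) |>
    dplyr::mutate(proximal = dplyr::coalesce(.data$proximal, 0),
                  distal = dplyr::coalesce(.data$distal, 0))
}

#' Compute the PSI matrix from proximal/distal counts
#'
#' PSI = proximal / (proximal + distal) per gene per sample; a zero
#' denominator yields a missing value.
#'
#' @param pairs_long Tibble `gene_id, sample_id, proximal, distal`.
#' @return Wide gene-by-sample tibble (first column `gene_id`), attribute
#'   `provenance = "from-counts"`.
#' @export
compute_psi <- function(pairs_long) {
  if (any(pairs_long$proximal < 0 | pairs_long$distal < 0)) {
    stop("negative counts", call. = FALSE)
  }
  long <- pairs_long |>
    dplyr::mutate(total = .data$proximal + .data$distal,
                  psi = ifelse(.data$total > 0,
                               .data$proximal / .data$total, NA_real_))
  wide <- long |>
    dplyr::select("gene_id", "sample_id", "psi") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "psi")
  attr(wide, "provenance") <- "from-counts"
  wide
}

#' Per-gene tumor-normal delta-PSI over matched pairs
#'
#' For each subject with both tissues, delta-PSI = PSI(tumor) -
#' PSI(normal); the gene summary is the median over pairs where both
#' values are defined (positive = shortening).
#'
#' @param psi Wide PSI tibble.
#' @param metadata Sample table with `sample_id, subject, tissue`.
#' @return List with `per_pair` (tibble `gene_id, subject, delta_psi`) and
#'   `summary` (tibble `gene_id, n_pairs, median_delta_psi`).
#' @export
compute_delta_psi <- function(psi, metadata) {
  pairs <- matched_pairs(metadata)
  m <- psi_as_matrix(psi)
  dt <- m[, pairs$tumor, drop = FALSE] - m[, pairs$normal, drop = FALSE]
  per_pair <- tibble::as_tibble(dt) |>
    stats::setNames(pairs$subject) |>
    dplyr::mutate(gene_id = rownames(m), .before = 1) |>
    tidyr::pivot_longer(-"gene_id", names_to = "subject",
                        values_to = "delta_psi") |>
    dplyr::filter(!is.na(.data$delta_psi))
  summary <- per_pair |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     median_delta_psi = stats::median(.data$delta_psi),
                     .groups = "drop")
  list(per_pair = per_pair, summary = summary)
}

#' Test tumor-normal polyA usage switches per gene
#'
#' Two-sided paired Wilcoxon signed-rank on (PSI tumor, PSI normal) over
#' matched subjects, Benjamini-Hochberg adjusted across tested genes.
#' Direction is `shortened` when q < alpha and the median delta-PSI is
#' positive, `lengthened` when q < alpha and it is negative, `unchanged`
#' otherwise. Genes with fewer than `min_pairs` complete pairs are not
#' tested; all-zero differences give p = 1 by convention.
#'
#' @param psi Wide PSI tibble.
#' @param metadata Sample table with `sample_id, subject, tissue`.
#' @param alpha FDR level for direction calls (default 0.05).
#' @param min_pairs Minimum complete tumor/normal pairs per gene.
#' @return Tibble of class `apa_switches`: `gene_id, n_pairs, statistic,
#'   p, q, median_delta_psi, direction`.
#' @export
test_switches <- function(psi, metadata, alpha = 0.05, min_pairs = 10) {
  pairs <- matched_pairs(metadata)
  m <- psi_as_matrix(psi)
  tum <- m[, pairs$tumor, drop = FALSE]
  nor <- m[, pairs$normal, drop = FALSE]
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    ok <- !is.na(tum[i, ]) & !is.na(nor[i, ])
    n <- sum(ok)
    if (n < min_pairs) return(NULL)
    d <- tum[i, ok] - nor[i, ok]
    if (all(d == 0)) {
      stat <- NA_real_; p <- 1
    } else {
      w <- suppressWarnings(stats::wilcox.test(tum[i, ok], nor[i, ok],
                                               paired = TRUE))
      stat <- unname(w$statistic); p <- w$p.value
    }
    tibble::tibble(gene_id = rownames(m)[i], n_pairs = n, statistic = stat,
                   p = p, median_delta_psi = stats::median(d))
  })
  if (nrow(res) == 0) {
    res <- tibble::tibble(gene_id = character(), n_pairs = integer(),
                          statistic = numeric(), p = numeric(),
                          q = numeric(), median_delta_psi = numeric(),
                          direction = character())
    return(structure(res, class = c("apa_switches", class(res)),
                     alpha = alpha))
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$direction <- dplyr::case_when(
    res$q < alpha & res$median_delta_psi > 0 ~ "shortened",
    res$q < alpha & res$median_delta_psi < 0 ~ "lengthened",
    .default = "unchanged")
  res <- res[, c("gene_id", "n_pairs", "statistic", "p", "q",
                 "median_delta_psi", "direction")]
  structure(res, class = c("apa_switches", class(res)), alpha = alpha)
}

#' Gene-wise Spearman correlation between PSI and expression
#'
#' For each gene shared by both matrices, Spearman rho and p over the
#' shared samples with both values defined. Genes with a constant vector
#' or too few samples are skipped. The `beyond_threshold` flag marks genes
#' with rho greater than `rho_threshold` (`mode = "greater"`) or |rho|
#' greater than it (`mode = "abs"`).
#'
#' @param psi Wide PSI tibble.
#' @param expression Wide expression tibble (same layout).
#' @param min_samples Minimum shared samples per gene (default 10).
#' @param sig_level Significance flag level on p (default 0.05).
#' @param rho_threshold Rho threshold for `beyond_threshold` (default 0.1).
#' @param mode `"greater"` (one-sided) or `"abs"`.
#' @return Tibble `gene_id, n, rho, p, significant, beyond_threshold`.
#' @export
correlate_psi_expression <- function(psi, expression, min_samples = 10,
                                     sig_level = 0.05, rho_threshold = 0.1,
                                     mode = c("greater", "abs")) {
  mode <- match.arg(mode)
  mp <- psi_as_matrix(psi)
  me <- psi_as_matrix(expression)
  genes <- intersect(rownames(mp), rownames(me))
  samples <- intersect(colnames(mp), colnames(me))
  purrr::map_dfr(genes, function(g) {
    x <- mp[g, samples]; y <- me[g, samples]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_samples) return(NULL)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NULL)
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                           method = "spearman"))
    rho <- unname(ct$estimate)
    tibble::tibble(gene_id = g, n = sum(ok), rho = rho, p = ct$p.value,
                   significant = ct$p.value < sig_level,
                   beyond_threshold = if (mode == "greater")
                     rho > rho_threshold else abs(rho) > rho_threshold)
  })
}

#' Permutation null for the PSI-expression coupling count
#'
#' The statistic is the number of genes whose Spearman rho with expression
#' exceeds `rho_threshold`. Each permutation shuffles the sample columns of
#' the PSI matrix jointly across genes (preserving gene-gene correlation)
#' and recomputes the statistic; the empirical p is
#' `(1 + #{perm >= observed}) / (n_perm + 1)` (add-one convention, so p is
#' never 0). A per-gene independent shuffle is available via
#' `scope = "per_gene"`.
#'
#' @param psi Wide PSI tibble.
#' @param expression Wide expression tibble.
#' @param observed_count Observed number of genes beyond the threshold
#'   (e.g. `sum(correlate_psi_expression(...)$beyond_threshold)`).
#' @param rho_threshold Rho threshold (default 0.1).
#' @param mode `"greater"` or `"abs"` (match the observed statistic).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param scope `"columns"` (joint column shuffle) or `"per_gene"`.
#' @return List: `p` (empirical p), `observed`, `perm_counts` (integer
#'   vector of permuted statistics).
#' @export
permutation_empirical_p <- function(psi, expression, observed_count,
                                    rho_threshold = 0.1,
                                    mode = c("greater", "abs"),
                                    n_perm = 10000, seed = 1,
                                    scope = c("columns", "per_gene")) {
  mode <- match.arg(mode); scope <- match.arg(scope)
  if (observed_count < 0) stop("observed_count must be >= 0", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  set.seed(seed)
  mp <- psi_as_matrix(psi)
  me <- psi_as_matrix(expression)
  genes <- intersect(rownames(mp), rownames(me))
  samples <- intersect(colnames(mp), colnames(me))
  mp <- mp[genes, samples, drop = FALSE]
  me <- me[genes, samples, drop = FALSE]
  n <- length(samples)
  # standardized row ranks: per-gene Pearson on these equals Spearman
  zrank <- function(m) {
    t(apply(m, 1, function(x) {
      r <- rank(x, ties.method = "average")
      s <- stats::sd(r)
      if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }))
  }
  zp <- zrank(mp); ze <- zrank(me)
  stat <- function(z) {
    rho <- rowSums(z * ze) / (n - 1)
    if (mode == "greater") sum(rho > rho_threshold)
    else sum(abs(rho) > rho_threshold)
  }
  perm_counts <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    if (scope == "columns") {
      zperm <- zp[, sample.int(n), drop = FALSE]
    } else {
      zperm <- t(apply(zp, 1, function(x) x[sample.int(n)]))
    }
    perm_counts[b] <- stat(zperm)
  }
  p <- (1 + sum(perm_counts >= observed_count)) / (n_perm + 1)
  list(p = p, observed = observed_count, perm_counts = perm_counts)
}

#' Covariate-adjusted delta-PSI (approximate per-gene linear model)
#'
#' Regresses each gene's per-pair delta-PSI on subject-level covariates
#' with an ordinary linear model and reports the adjusted mean shift (the
#' model intercept at covariate reference levels) with its p-value and BH
#' q. This is a clearly-labelled approximation for covariate-aware
#' comparisons (e.g., between population groups); it is not a count-level
#' differential-usage model.
#'
#' @param delta_per_pair Tibble `gene_id, subject, delta_psi` (from
#'   `compute_delta_psi()$per_pair`).
#' @param subjects Tibble keyed by `subject` with covariate columns.
#' @param covariates Covariate column names (default age/sex/stage/
#'   smoking).
#' @param min_pairs Minimum pairs per gene (default 10).
#' @return Tibble `gene_id, n_pairs, adjusted_shift, p, q`.
#' @export
adjust_delta_psi_covariates <- function(delta_per_pair, subjects,
                                        covariates = c("age", "sex",
                                                       "stage",
                                                       "smoking"),
                                        min_pairs = 10) {
  dat <- dplyr::inner_join(delta_per_pair, tibble::as_tibble(subjects),
                           by = "subject")
  fml <- stats::as.formula(paste("delta_psi ~",
                                 paste(covariates, collapse = "+")))
  res <- dat |>
    dplyr::group_split(.data$gene_id) |>
    purrr::map_dfr(function(d) {
      if (nrow(d) < min_pairs) return(NULL)
      fit <- tryCatch(stats::lm(fml, data = d),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      s <- summary(fit)$coefficients
      tibble::tibble(gene_id = d$gene_id[1], n_pairs = nrow(d),
                     adjusted_shift = s["(Intercept)", "Estimate"],
                     p = s["(Intercept)", "Pr(>|t|)"])
    })
  if (nrow(res) > 0) res$q <- stats::p.adjust(res$p, method = "BH")
  res
}
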