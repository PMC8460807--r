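# Sample- and gene-level derived scores: polyadenylation-machinery activity
# index, PSI-load, mutation-status fold changes, interval read counting,
# miRNA binding-site loss, mRNA-protein concordance contrast, PDUI
# conversion.

#' Polyadenylation-machinery activity index
#'
#' Expression of each machinery gene is z-scored across samples (mean 0,
#' sd 1; constant genes get z = 0); a sample's index is the median z over
#' the gene set. The index is invariant to affine rescaling of any single
#' gene's expression row.
#'
#' @param expression Wide gene-by-sample tibble (first column `gene_id`).
#' @param gene_set Character vector of machinery gene ids (shipped lists
#'   are data: pass your catalogue of CPSF/CSTF-pathway members).
#' @return Tibble `sample_id, pa_index`.
#' @export
pa_machinery_index <- function(expression, gene_set) {
  m <- psi_as_matrix(expression)
  hit <- intersect(rownames(m), gene_set)
  if (length(hit) == 0) {
    stop("no machinery genes found in the expression matrix; missing: ",
         paste(utils::head(setdiff(gene_set, rownames(m)), 10),
               collapse = ", "), call. = FALSE)
  }
  if (ncol(m) < 2) stop("z-scores need at least 2 samples", call. = FALSE)
  z <- t(apply(m[hit, , drop = FALSE], 1, function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  tibble::tibble(sample_id = colnames(m),
                 pa_index = unname(apply(z, 2, stats::median)))
}

#' PSI-load: per-sample global 3'UTR-shortening index
#'
#' The median (or mean) of a sample's defined PSI values across genes.
#' Samples with no defined PSI get a missing load.
#'
#' @param psi Wide PSI tibble.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return Tibble `sample_id, psi_load`.
#' @export
psi_load <- function(psi, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  m <- psi_as_matrix(psi)
  if (nrow(m) == 0) stop("empty PSI matrix", call. = FALSE)
  f <- if (statistic == "median") stats::median else mean
  load <- apply(m, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else f(x)
  })
  tibble::tibble(sample_id = colnames(m), psi_load = unname(load))
}

#' PSI-load fold change by driver-gene mutation status
#'
#' For each driver gene, FC = median(load | mutated) / median(load |
#' wildtype), a two-sided Wilcoxon rank-sum p, and BH q across driver
#' genes. Genes are flagged when q < `fdr_threshold` and |FC - 1| >
#' `fc_threshold`.
#'
#' @param load Tibble `sample_id, psi_load` (from [psi_load()]).
#' @param mutations Tibble `gene, sample_id, mutated` (0/1).
#' @param min_group Minimum samples per group (default 5).
#' @param fc_threshold Flag threshold on |FC - 1| (default 0.1).
#' @param fdr_threshold Flag threshold on q (default 0.1).
#' @return Tibble `gene, n_mut, n_wt, fc, p, q, flagged`.
#' @export
mutation_psi_fold_change <- function(load, mutations, min_group = 5,
                                     fc_threshold = 0.1,
                                     fdr_threshold = 0.1) {
  dat <- dplyr::inner_join(mutations, load, by = "sample_id")
  res <- dat |>
    dplyr::group_split(.data$gene) |>
    purrr::map_dfr(function(d) {
      mut <- d$psi_load[d$mutated == 1 & !is.na(d$psi_load)]
      wt <- d$psi_load[d$mutated == 0 & !is.na(d$psi_load)]
      if (length(mut) < min_group || length(wt) < min_group) return(NULL)
      med_wt <- stats::median(wt)
      if (med_wt == 0) {
        warning("wildtype median load is 0 for ", d$gene[1],
                "; FC undefined, gene skipped")
        return(NULL)
      }
      p <- suppressWarnings(stats::wilcox.test(mut, wt)$p.value)
      if (is.na(p)) p <- 1   # fully tied groups
      tibble::tibble(gene = d$gene[1], n_mut = length(mut),
                     n_wt = length(wt), fc = stats::median(mut) / med_wt,
                     p = p)
    })
  if (nrow(res) == 0) return(res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$flagged <- res$q < fdr_threshold & abs(res$fc - 1) > fc_threshold
  res
}

#' Count reads overlapping a genomic interval
#'
#' Counts alignments whose aligned span overlaps `[start, end)` by at
#' least one base (`rule = "any"`) or is fully contained
#' (`rule = "within"`), optionally restricted by alignment strand.
#'
#' @param alignments Tibble `chrom, strand, start, end` with optional
#'   `count` (aggregated reads).
#' @param chrom,start,end The interval (0-based half-open, `start < end`).
#' @param rule `"any"` or `"within"`.
#' @param strand Optional strand filter (`"+"`/`"-"`); `NULL` ignores
#'   strand.
#' @return Integer read count.
#' @export
count_reads_in_region <- function(alignments, chrom, start, end,
                                  rule = c("any", "within"),
                                  strand = NULL) {
  rule <- match.arg(rule)
  if (end <= start) stop("inverted interval: start must be < end",
                         call. = FALSE)
  a <- tibble::as_tibble(alignments)
  if (!"count" %in% names(a)) a$count <- 1L
  a <- a[a$chrom == chrom, ]
  if (!is.null(strand)) a <- a[a$strand == strand, ]
  hit <- if (rule == "any") a$start < end & a$end > start
         else a$start >= start & a$end <= end
  as.integer(sum(a$count[hit]))
}

#' Count miRNA binding sites lost in a shortened region
#'
#' Number of binding-site intervals overlapping (any overlap) the region
#' between the proximal and distal polyA site; strand honoured when the
#' BED carries one.
#'
#' @param sites Interval tibble from [read_intervals_bed()] (`chrom,
#'   start, end, strand`).
#' @param chrom,start,end The lost region (0-based half-open).
#' @param strand Optional strand; sites with strand `*` always match.
#' @return Integer count of overlapping binding sites.
#' @export
count_lost_mirna_sites <- function(sites, chrom, start, end,
                                   strand = NULL) {
  s <- sites[sites$chrom == chrom, ]
  if (!is.null(strand) && "strand" %in% names(s)) {
    s <- s[s$strand == "*" | s$strand == strand, ]
  }
  sum(s$start < end & s$end > start)
}

#' Contrast mRNA-protein concordance between extreme PSI deciles
#'
#' Ranks genes by median PSI, compares the mRNA-protein correlation of
#' the top decile against the bottom decile with a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param gene_stats Tibble `gene_id, median_psi, mrna_protein_cor`.
#' @param decile Fraction defining the extreme groups (default 0.1).
#' @return List: `p`, `top_median`, `bottom_median`, `n_per_group`.
#' @export
concordance_top_bottom <- function(gene_stats, decile = 0.1) {
  gs <- gene_stats[!is.na(gene_stats$median_psi) &
                     !is.na(gene_stats$mrna_protein_cor), ]
  k <- floor(nrow(gs) * decile)
  if (k < 1) stop("decile group would be empty (need >= ",
                  ceiling(1 / decile), " genes)", call. = FALSE)
  ord <- order(gs$median_psi)
  bottom <- gs$mrna_protein_cor[ord[seq_len(k)]]
  top <- gs$mrna_protein_cor[rev(ord)[seq_len(k)]]
  p <- suppressWarnings(stats::wilcox.test(top, bottom)$p.value)
  list(p = p, top_median = stats::median(top),
       bottom_median = stats::median(bottom), n_per_group = k)
}

#' Convert a PDUI matrix to PSI
#'
#' PSI = 1 - PDUI elementwise (distal-usage to proximal-usage
#' convention); missing values are preserved. Values outside \[0, 1\] are
#' rejected with coordinates.
#'
#' @param pdui Wide gene-by-sample tibble of PDUI values.
#' @return Wide PSI tibble with attribute `provenance = "from-PDUI"`.
#' @export
pdui_to_psi <- function(pdui) {
  m <- psi_as_matrix(pdui)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("PDUI outside [0,1] at gene %s, sample %s",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]),
         call. = FALSE)
  }
  matrix_as_psi(1 - m, provenance = "from-PDUI")
}
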