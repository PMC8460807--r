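# End-to-end orchestration and the bookkeeping summary reporter.

#' Pipeline thresholds and settings
#'
#' Collects every stage threshold with its conventional default: hexamer
#' window \[-30, -10\], A-run >= 7, sparse-A >= 9 per 10-nt window, cluster
#' radius 5 nt, minimum site spacing 125 nt, presence 25% of samples,
#' per-group count 10, minor fraction 5%, FDR 0.05.
#'
#' @param protocol `"rev"` or `"fwd"`.
#' @param hexamers Hexamer catalogue.
#' @param cluster_radius,min_spacing Atlas thresholds (nt).
#' @param presence,group_min,minor_frac Abundance-filter thresholds.
#' @param fdr FDR level for switch direction calls.
#' @param min_pairs Minimum complete pairs per tested gene.
#' @param max_extension,near_gap Downstream-extension rule (nt).
#' @return A list of settings (class `apa_pipeline_config`).
#' @export
apa_pipeline_config <- function(protocol = "rev",
                                hexamers = pas_hexamers(),
                                cluster_radius = 5, min_spacing = 125,
                                presence = 0.25, group_min = 10,
                                minor_frac = 0.05, fdr = 0.05,
                                min_pairs = 10, max_extension = 5000,
                                near_gap = 10000) {
  stopifnot(cluster_radius > 0, min_spacing > 0, presence > 0,
            group_min > 0, minor_frac > 0, fdr > 0)
  structure(as.list(environment()), class = "apa_pipeline_config")
}

#' Run the APA pipeline end-to-end
#'
#' Stages in order: atlas construction, gene annotation, abundance
#' filtering, PSI quantification, switch statistics, and the run summary.
#' Re-running with identical inputs and config reproduces identical
#' outputs. When `out_dir` is given, every stage table is written as TSV
#' together with a YAML echo of the effective configuration.
#'
#' @param alignments Alignment tibble (or cleavage-event tibble with
#'   `input = "events"`).
#' @param genome Named `DNAStringSet`.
#' @param models A [gene_models()] object.
#' @param metadata Sample table `sample_id, subject, tissue`.
#' @param config An [apa_pipeline_config()].
#' @param input `"alignments"` or `"events"`.
#' @param out_dir Optional output directory.
#' @return Object of class `apa_run`: `atlas`, `annotation`, `filtered`,
#'   `pair_counts`, `psi`, `delta_psi`, `switches`, `summary`, `config`.
#' @export
run_apa_pipeline <- function(alignments, genome, models, metadata,
                             config = apa_pipeline_config(),
                             input = "alignments", out_dir = NULL) {
  stopifnot(inherits(config, "apa_pipeline_config"))
  chrom_lengths <- stats::setNames(Biostrings::width(genome),
                                   names(genome))
  atlas <- build_pas_atlas(alignments, genome, protocol = config$protocol,
                           input = input, hexamers = config$hexamers,
                           cluster_radius = config$cluster_radius,
                           min_spacing = config$min_spacing)
  ann <- annotate_atlas(atlas, models, chrom_lengths = chrom_lengths,
                        max_extension = config$max_extension,
                        near_gap = config$near_gap)
  counts <- atlas$counts |>
    dplyr::inner_join(
      ann$sites[, c("chrom", "strand", "pos", "gene_id")],
      by = c("chrom", "strand", "pos"))
  filt <- apply_abundance_filters(counts, metadata,
                                  presence = config$presence,
                                  group_min = config$group_min,
                                  minor_frac = config$minor_frac)
  kept_sites <- ann$sites |>
    dplyr::semi_join(dplyr::distinct(filt$counts, .data$gene_id,
                                     .data$chrom, .data$strand, .data$pos),
                     by = c("gene_id", "chrom", "strand", "pos"))
  pr <- make_site_pairs(kept_sites)
  pairs <- if (nrow(pr$pairs) > 0) classify_pair_type(pr$pairs, {
    models$genes <- ann$genes; models
  }) else pr$pairs
  pc <- pair_counts(filt$counts, pairs, unique(metadata$sample_id))
  psi <- compute_psi(pc)
  dpsi <- compute_delta_psi(psi, metadata)
  switches <- test_switches(psi, metadata, alpha = config$fdr,
                            min_pairs = config$min_pairs)
  run <- structure(list(atlas = atlas, annotation = ann,
                        filtered = filt, sites = pr$sites, pairs = pairs,
                        pair_counts = pc, psi = psi, delta_psi = dpsi,
                        switches = switches, metadata = metadata,
                        config = config), class = "apa_run")
  run$summary <- summarize_apa_run(run)
  if (!is.null(out_dir)) write_apa_run(run, out_dir)
  run
}

#' @export
print.apa_run <- function(x, ...) {
  cat("<apa_run>\n")
  print(x$summary, n = Inf)
  invisible(x)
}

write_apa_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f), na = "NA")
  w(run$atlas$sites, "atlas_sites.tsv")
  w(run$atlas$removed, "atlas_removed.tsv")
  w(run$sites, "annotated_sites.tsv")
  w(run$pairs, "site_pairs.tsv")
  write_matrix_tsv(run$psi, file.path(out_dir, "psi_matrix.tsv"))
  w(run$delta_psi$summary, "delta_psi.tsv")
  w(tibble::as_tibble(run$switches), "switches.tsv")
  w(run$summary, "summary.tsv")
  cfg <- run$config
  cfg_list <- lapply(unclass(cfg), function(v) if (is.null(v)) NA else v)
  yaml::write_yaml(cfg_list, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Bookkeeping summary from atlas/switch counts
#'
#' Recomputes the pipeline's headline arithmetic from plain counts:
#' percentages are `100 * numerator / denominator` rounded half-up to an
#' integer ([pct_half_up()]); totals are sums over direction/pair-type
#' classes. Undefined fractions (zero denominator) are reported `NA`, not
#' 0.
#'
#' @param n_sites Total polyA sites annotated to genes.
#' @param n_genes Genes with at least one site.
#' @param n_multi Genes with more than one site.
#' @param n_shortened,n_lengthened Switched genes by direction.
#' @param shortened_pair_types,lengthened_pair_types Optional named
#'   vectors (`same-exon`, `composite-exon`, `skipped-exon`) of switch
#'   counts by pair type.
#' @param location_counts Optional named vector of proximal-site location
#'   counts (`3UTR`, `intron`, `exon`).
#' @return Tibble `metric, numerator, denominator, value`.
#' @export
summarize_atlas_counts <- function(n_sites, n_genes, n_multi,
                                   n_shortened = NA, n_lengthened = NA,
                                   shortened_pair_types = NULL,
                                   lengthened_pair_types = NULL,
                                   location_counts = NULL) {
  row <- function(metric, value, num = NA, den = NA) {
    tibble::tibble(metric = metric, numerator = as.numeric(num),
                   denominator = as.numeric(den),
                   value = as.numeric(value))
  }
  out <- list(
    row("n_sites", n_sites),
    row("n_genes", n_genes),
    row("n_multi_site_genes", n_multi),
    row("pct_multi_site", pct_half_up(n_multi, n_genes), n_multi, n_genes))
  if (!is.na(n_shortened) && !is.na(n_lengthened)) {
    n_switched <- n_shortened + n_lengthened
    out <- c(out, list(
      row("n_shortened", n_shortened),
      row("n_lengthened", n_lengthened),
      row("n_switched", n_switched),
      row("pct_switched_of_multi", pct_half_up(n_switched, n_multi),
          n_switched, n_multi)))
  }
  add_pair_types <- function(out, v, prefix, total) {
    if (is.null(v)) return(out)
    c(out,
      purrr::imap(v, ~ row(paste0(prefix, "_", .y), .x)),
      list(row(paste0(prefix, "_pair_type_total"), sum(v)),
           row(paste0(prefix, "_pair_type_check"),
               as.numeric(sum(v) == total))))
  }
  out <- add_pair_types(out, shortened_pair_types, "shortened",
                        n_shortened)
  out <- add_pair_types(out, lengthened_pair_types, "lengthened",
                        n_lengthened)
  if (!is.null(location_counts)) {
    tot <- sum(location_counts)
    out <- c(out, purrr::imap(location_counts, function(v, nm) {
      row(paste0("pct_proximal_", nm), pct_half_up(v, tot), v, tot)
    }))
  }
  dplyr::bind_rows(out)
}

#' Summarize a pipeline run
#'
#' Computes the run's site/gene totals, multi-site fraction, switch totals
#' by direction and pair type, and the proximal-site location
#' distribution (downstream-extension sites counted with the 3'UTR
#' bucket), all through [summarize_atlas_counts()].
#'
#' @param run An `apa_run`.
#' @return Tibble `metric, numerator, denominator, value`.
#' @export
summarize_apa_run <- function(run) {
  sites <- run$sites
  per_gene <- dplyr::count(sites, .data$gene_id)
  sw <- tibble::as_tibble(run$switches)
  pairs <- run$pairs
  dir_of <- stats::setNames(sw$direction, sw$gene_id)
  pt_counts <- function(dir) {
    if (nrow(pairs) == 0 || nrow(sw) == 0) return(NULL)
    g <- sw$gene_id[sw$direction == dir]
    v <- table(factor(pairs$pair_type[pairs$gene_id %in% g],
                      levels = c("same-exon", "composite-exon",
                                 "skipped-exon")))
    stats::setNames(as.integer(v), names(v))
  }
  prox_loc <- NULL
  if (nrow(pairs) > 0) {
    loc <- sites |>
      dplyr::inner_join(pairs[, c("gene_id", "proximal_pos")],
                        by = "gene_id") |>
      dplyr::filter(.data$pos == .data$proximal_pos) |>
      dplyr::mutate(bucket = ifelse(
        .data$location %in% c("3UTR", "downstream-extension"),
        "3UTR", .data$location))
    v <- table(factor(loc$bucket, levels = c("3UTR", "intron", "exon")))
    prox_loc <- stats::setNames(as.integer(v), names(v))
  }
  summarize_atlas_counts(
    n_sites = nrow(sites),
    n_genes = nrow(per_gene),
    n_multi = sum(per_gene$n > 1),
    n_shortened = sum(sw$direction == "shortened"),
    n_lengthened = sum(sw$direction == "lengthened"),
    shortened_pair_types = pt_counts("shortened"),
    lengthened_pair_types = pt_counts("lengthened"),
    location_counts = prox_loc)
}
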