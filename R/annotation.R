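# Assign atlas sites to genes with downstream extension, classify genomic
# location, and type proximal/distal pairs.

#' Extend gene regions downstream
#'
#' Since 3'UTR isoforms are incompletely annotated, each gene is extended
#' past its annotated 3' end (transcript orientation) by 5 kb of intergenic
#' sequence; when the nearest downstream gene begins closer than 10 kb,
#' only half the gap is added. The neighbour search ignores strand (any
#' gene boundary beyond this gene's 3' end counts) unless
#' `same_strand_only`. Extensions are clipped at chromosome bounds when
#' `chrom_lengths` is given.
#'
#' @param genes Gene tibble (`gene_id, chrom, strand, start, end`), e.g.
#'   `models$genes`.
#' @param max_extension Maximum extension in nt (default 5000).
#' @param near_gap Gap below which only half the gap is added (default
#'   10000).
#' @param same_strand_only Restrict the neighbour search to same-strand
#'   genes.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return `genes` with an `extended_end` column: the genomic coordinate
#'   bounding the extension (exclusive beyond the 3' end for `+` genes;
#'   inclusive-start of the extended window for `-` genes).
#' @export
extend_gene_regions <- function(genes, max_extension = 5000,
                                near_gap = 10000, same_strand_only = FALSE,
                                chrom_lengths = NULL) {
  genes <- tibble::as_tibble(genes)
  ext <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    others <- genes[genes$chrom == g$chrom & genes$gene_id != g$gene_id, ]
    if (same_strand_only) others <- others[others$strand == g$strand, ]
    if (g$strand == "+") {
      starts <- others$start[others$start >= g$end]
      gap <- if (length(starts)) min(starts) - g$end else Inf
    } else {
      ends <- others$end[others$end <= g$start]
      gap <- if (length(ends)) g$start - max(ends) else Inf
    }
    e <- if (gap < near_gap) gap / 2 else max_extension
    e <- min(e, max_extension)
    if (!is.null(chrom_lengths)) {
      len <- chrom_lengths[[g$chrom]]
      e <- if (g$strand == "+") min(e, len - g$end) else min(e, g$start)
    }
    ext[i] <- e
  }
  genes$extended_end <- ifelse(genes$strand == "+",
                               genes$end + ext, genes$start - ext)
  genes
}

#' Assign polyA sites to genes
#'
#' A site is assigned to a gene iff its position lies in the gene span
#' extended downstream (transcript orientation) and its transcript strand
#' matches the gene strand. When several genes qualify, the gene whose
#' annotated 3' end is nearest wins; remaining ties go to the smaller gene
#' id. Unassigned sites are logged and excluded downstream.
#'
#' @param sites Site tibble (`chrom, strand, pos`, extra columns pass
#'   through).
#' @param genes Gene tibble with `extended_end` from
#'   [extend_gene_regions()].
#' @return List with `sites` (assigned, plus `gene_id`) and `unassigned`.
#' @export
assign_sites_to_genes <- function(sites, genes) {
  sites <- tibble::as_tibble(sites)
  if (is.na(genes$extended_end[1]) && nrow(genes) > 0) {
    stop("genes lack extended_end; run extend_gene_regions() first",
         call. = FALSE)
  }
  win_lo <- ifelse(genes$strand == "+", genes$start, genes$extended_end)
  win_hi <- ifelse(genes$strand == "+", genes$extended_end, genes$end)
  three_end <- ifelse(genes$strand == "+", genes$end, genes$start)
  gene_id <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cand <- which(genes$chrom == sites$chrom[i] &
                    genes$strand == sites$strand[i] &
                    sites$pos[i] >= win_lo & sites$pos[i] < win_hi)
    if (length(cand) == 0) next
    if (length(cand) > 1) {
      d <- abs(sites$pos[i] - three_end[cand])
      cand <- cand[order(d, genes$gene_id[cand])]
    }
    gene_id[i] <- genes$gene_id[cand[1]]
  }
  sites$gene_id <- gene_id
  list(sites = sites[!is.na(gene_id), ],
       unassigned = sites[is.na(gene_id), setdiff(names(sites), "gene_id")])
}

# point-in-interval-set helper (0-based half-open rows)
pos_in <- function(pos, iv) {
  nrow(iv) > 0 && any(pos >= iv$start & pos < iv$end)
}

#' Classify the genomic location of an assigned site
#'
#' Precedence: `3UTR` if the position falls inside any transcript's 3'UTR
#' of the assigned gene; else `exon` if inside any exon; else `intron` if
#' inside the annotated gene span; else `downstream-extension`. In summary
#' tables downstream-extension sites are counted with the 3'UTR bucket.
#'
#' @param sites Assigned site tibble (`gene_id, chrom, strand, pos`).
#' @param models A [gene_models()] object with `genes` carrying
#'   `extended_end`.
#' @return `sites` with a `location` column.
#' @export
classify_site_location <- function(sites, models) {
  sites <- tibble::as_tibble(sites)
  loc <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    gid <- sites$gene_id[i]; p <- sites$pos[i]
    g <- models$genes[models$genes$gene_id == gid, ]
    if (nrow(g) == 0) stop("site assigned to unknown gene ", gid,
                           call. = FALSE)
    utr <- models$utr3[models$utr3$gene_id == gid, ]
    ex <- models$exons[models$exons$gene_id == gid, ]
    loc[i] <- if (pos_in(p, utr)) "3UTR"
      else if (pos_in(p, ex)) "exon"
      else if (p >= g$start && p < g$end) "intron"
      else {
        inside_ext <- if (g$strand == "+") {
          p >= g$end && p < g$extended_end
        } else {
          p >= g$extended_end && p < g$start
        }
        if (!isTRUE(inside_ext)) {
          stop(sprintf("site %s:%d outside gene %s and its extension",
                       sites$chrom[i], p, gid), call. = FALSE)
        }
        "downstream-extension"
      }
  }
  sites$location <- loc
  sites
}

#' Form one proximal/distal pair per multi-site gene
#'
#' Ranks a gene's retained sites in transcript orientation (rank 1 = most
#' 5' = proximal-most) and pairs the 5'-most (proximal) with the 3'-most
#' (distal) site.
#'
#' @param sites Assigned site tibble (`gene_id, chrom, strand, pos`).
#' @return List with `sites` (plus `rank`) and `pairs` (tibble: `gene_id,
#'   chrom, strand, proximal_pos, distal_pos`), one row per gene with >= 2
#'   sites.
#' @export
make_site_pairs <- function(sites) {
  sites <- sites |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(rank = rank(tx_order_key(.data$pos, .data$strand),
                              ties.method = "first")) |>
    dplyr::ungroup()
  pairs <- sites |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      proximal_pos = .data$pos[which.min(tx_order_key(.data$pos,
                                                      .data$strand))],
      distal_pos = .data$pos[which.max(tx_order_key(.data$pos,
                                                    .data$strand))],
      .groups = "drop")
  list(sites = sites, pairs = pairs)
}

# exon containing a position among a transcript's exons, or NULL
containing_exon <- function(p, ex) {
  hit <- ex[p >= ex$start & p < ex$end, ]
  if (nrow(hit) == 0) NULL else hit[1, ]
}

#' Classify a proximal/distal pair by splice architecture
#'
#' * `same-exon`: some single transcript has one exon containing both
#'   sites.
#' * `skipped-exon`: the proximal site lies in an exon of some transcript
#'   that is fully intronic (spliced out) in a transcript containing the
#'   distal site.
#' * `composite-exon`: the proximal site lies in an exon extending past a
#'   5' splice donor used by a distal-containing transcript.
#'
#' Precedence is same-exon > skipped-exon > composite-exon; pairs matching
#' no rule are labelled `composite-exon` and flagged `unclassified`.
#'
#' @param pairs Pair tibble from [make_site_pairs()].
#' @param models A [gene_models()] object.
#' @return `pairs` with `pair_type` and `unclassified` columns.
#' @export
classify_pair_type <- function(pairs, models) {
  pairs <- tibble::as_tibble(pairs)
  type <- character(nrow(pairs)); unflag <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    gid <- pairs$gene_id[i]
    strand <- pairs$strand[i]
    pp <- pairs$proximal_pos[i]; dp <- pairs$distal_pos[i]
    if (tx_order_key(pp, strand) >= tx_order_key(dp, strand)) {
      stop("proximal site must be 5' of distal for gene ", gid,
           call. = FALSE)
    }
    ex <- models$exons[models$exons$gene_id == gid, ]
    txs <- unique(ex$transcript_id)
    extx <- split(ex, ex$transcript_id)

    same <- any(vapply(txs, function(t) {
      e <- extx[[t]]
      any(pp >= e$start & pp < e$end & dp >= e$start & dp < e$end)
    }, logical(1)))
    dist_tx <- txs[vapply(txs, function(t) pos_in(dp, extx[[t]]),
                          logical(1))]
    prox_tx <- txs[vapply(txs, function(t) pos_in(pp, extx[[t]]),
                          logical(1))]

    skipped <- FALSE; composite <- FALSE
    for (tp in prox_tx) {
      pe <- containing_exon(pp, extx[[tp]])
      for (td in dist_tx) {
        ed <- extx[[td]]
        # fully intronic in the distal transcript: overlaps no exon of td
        # but lies within td's span
        td_lo <- min(ed$start); td_hi <- max(ed$end)
        overlaps <- any(pe$start < ed$end & pe$end > ed$start)
        if (!overlaps && pe$start >= td_lo && pe$end <= td_hi) {
          skipped <- TRUE
        }
        # 5' splice donors of td (transcript orientation): exon ends that
        # are not the transcript 3' end
        donors <- if (strand == "+") setdiff(ed$end, td_hi)
                  else setdiff(ed$start, td_lo)
        past <- if (strand == "+") {
          any(donors >= pe$start & donors < pe$end & pp >= donors)
        } else {
          any(donors > pe$start & donors <= pe$end & pp < donors)
        }
        if (past) composite <- TRUE
      }
    }
    if (same) type[i] <- "same-exon"
    else if (skipped) type[i] <- "skipped-exon"
    else if (composite) type[i] <- "composite-exon"
    else { type[i] <- "composite-exon"; unflag[i] <- TRUE }
  }
  pairs$pair_type <- type
  pairs$unclassified <- unflag
  pairs
}

#' Annotate an atlas against gene models
#'
#' Convenience wrapper running [extend_gene_regions()],
#' [assign_sites_to_genes()], [classify_site_location()],
#' [make_site_pairs()] and [classify_pair_type()].
#'
#' @param atlas An `apa_atlas` from [build_pas_atlas()].
#' @param models A [gene_models()] object.
#' @param chrom_lengths Optional named chromosome lengths.
#' @param ... Passed to [extend_gene_regions()].
#' @return List with `sites` (annotated, ranked), `pairs` (typed),
#'   `unassigned`, and `genes` (with `extended_end`).
#' @export
annotate_atlas <- function(atlas, models, chrom_lengths = NULL, ...) {
  genes <- extend_gene_regions(models$genes, chrom_lengths = chrom_lengths,
                               ...)
  models$genes <- genes
  asg <- assign_sites_to_genes(atlas$sites, genes)
  sites <- classify_site_location(asg$sites, models)
  pr <- make_site_pairs(sites)
  pairs <- if (nrow(pr$pairs) > 0) classify_pair_type(pr$pairs, models)
           else dplyr::mutate(pr$pairs, pair_type = character(0),
                              unclassified = logical(0))
  list(sites = pr$sites, pairs = pairs, unassigned = asg$unassigned,
       genes = genes)
}
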