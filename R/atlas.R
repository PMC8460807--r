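# PolyA-site atlas construction: cleavage-locus extraction, internal-priming
# removal, positional clustering, hexamer requirement, minimum-spacing
# selection of dominant sites.
#
# Conventions: cleavage events live on the TRANSCRIPT strand; all window
# offsets are in transcript orientation with the cleavage locus at offset 0
# and DNA read on the transcript strand. Tie-breaks everywhere: higher count
# first, then 5'-most position in transcript orientation.

#' The 18 polyadenylation signal hexamers
#'
#' Default catalogue of characterized polyadenylation signals searched in
#' the \[-30, -10\] window upstream of a cleavage site, ordered by priority
#' (canonical AATAAA first). Fully overridable wherever used.
#'
#' @return Character vector of 18 hexamers.
#' @export
pas_hexamers <- function() {
  c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AATACA", "CATAAA",
    "AATATA", "GATAAA", "AATGAA", "AATAAT", "AAGAAA", "ACTAAA",
    "AATAGA", "ATTACA", "AACAAA", "ATTATA", "AACAAG", "AATAAG")
}

#' Extract cleavage loci from aligned reads
#'
#' Reduces each alignment to the cleavage locus — the terminal aligned base
#' corresponding to the transcript 3' end — under the stated protocol. For
#' the REV protocol (3'-end-enriched libraries read antisense to the
#' transcript) the transcript strand is the opposite of the alignment
#' strand and the locus is the read's 5' terminus: the maximum genomic
#' coordinate for minus-strand alignments, the minimum for plus-strand.
#' For the FWD protocol the transcript strand equals the alignment strand
#' and the locus is the read's 3' terminus. Soft-clipped bases never count:
#' spans must already exclude them (as [read_cleavage_alignments()]
#' guarantees). Events identical in (chrom, strand, position, sample) are
#' summed.
#'
#' @param alignments Tibble with `chrom, strand, start, end, sample_id` and
#'   optionally `count` (0-based half-open aligned spans).
#' @param protocol `"rev"` or `"fwd"`.
#' @return Tibble of cleavage events: `chrom, strand` (transcript strand),
#'   `pos, sample_id, count`.
#' @export
extract_cleavage_loci <- function(alignments, protocol = c("rev", "fwd")) {
  protocol <- match.arg(protocol)
  a <- tibble::as_tibble(alignments)
  assert_strand(a$strand, "alignment strand")
  if (!"count" %in% names(a)) a$count <- 1L
  if (protocol == "rev") {
    tx_strand <- ifelse(a$strand == "-", "+", "-")
    pos <- ifelse(a$strand == "-", a$end - 1, a$start)
  } else {
    tx_strand <- a$strand
    pos <- ifelse(a$strand == "+", a$end - 1, a$start)
  }
  tibble::tibble(chrom = a$chrom, strand = tx_strand, pos = pos,
                 sample_id = a$sample_id, count = a$count) |>
    dplyr::group_by(.data$chrom, .data$strand, .data$pos, .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

# transcript-orientation window [off_lo, off_hi] (inclusive offsets) around
# 0-based locus `pos`; returns the sequence read on the transcript strand,
# truncated at chromosome edges.
window_seq <- function(genome, chrom, strand, pos, off_lo, off_hi) {
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (strand == "+") {
    lo <- pmax(pos + off_lo, 0); hi <- pmin(pos + off_hi, len - 1)
  } else {
    lo <- pmax(pos - off_hi, 0); hi <- pmin(pos - off_lo, len - 1)
  }
  if (hi < lo) return("")
  s <- Biostrings::subseq(genome[[chrom]], start = lo + 1, end = hi + 1)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# internal-priming predicate on the [-10, +10] transcript-orientation
# window: TRUE when a run of >= 7 consecutive A exists, or any 10-nt
# subwindow contains >= 9 A. Returns the reason or NA.
internal_priming_reason <- function(s) {
  if (nchar(s) == 0) return(NA_character_)
  if (grepl("AAAAAAA", s, fixed = TRUE)) return("A-run")
  n <- nchar(s)
  if (n >= 10) {
    isA <- as.integer(strsplit(s, "")[[1]] == "A")
    cs <- cumsum(c(0L, isA))
    win <- cs[11:(n + 1)] - cs[1:(n - 9)]
    if (max(win) >= 9) return("sparse-A")
  }
  NA_character_
}

#' Remove internal-priming artefacts
#'
#' Oligo-dT priming at genomic A-rich stretches mimics true cleavage. An
#' event is removed iff, in the 21-nt transcript-orientation window
#' \[-10, +10\] around its locus (sequence read on the transcript strand),
#' there is a run of at least 7 consecutive As ("more than 6") or some
#' 10-nt subwindow contains at least 9 As ("more than 8 sparse"). Windows
#' truncated by a chromosome edge are evaluated on the available bases.
#'
#' @param events Cleavage-event tibble (`chrom, strand, pos, sample_id,
#'   count`).
#' @param genome Named `DNAStringSet` covering all event loci.
#' @return List with `events` (retained rows) and `removed` (unique removed
#'   loci with a `reason` column: `"A-run"` or `"sparse-A"`).
#' @export
filter_internal_priming <- function(events, genome) {
  loci <- dplyr::distinct(events, .data$chrom, .data$strand, .data$pos)
  if (nrow(loci) == 0) {
    return(list(events = events, removed = dplyr::mutate(loci,
                                                         reason = character(0))))
  }
  loci$reason <- vapply(seq_len(nrow(loci)), function(i) {
    s <- window_seq(genome, loci$chrom[i], loci$strand[i], loci$pos[i],
                    -10, 10)
    internal_priming_reason(s)
  }, character(1))
  removed <- dplyr::filter(loci, !is.na(.data$reason))
  kept <- dplyr::anti_join(events, removed,
                           by = c("chrom", "strand", "pos"))
  list(events = kept, removed = removed)
}

#' Require a polyadenylation hexamer upstream of a site
#'
#' A locus is retained iff one of the configured hexamers starts at a
#' transcript-orientation offset s with -30 <= s <= -10 relative to the
#' cleavage locus. The annotated hexamer is chosen by priority order of the
#' configured list, then by the most site-proximal offset.
#'
#' @param sites Tibble with `chrom, strand, pos` (one row per locus;
#'   additional columns pass through).
#' @param genome Named `DNAStringSet`.
#' @param hexamers Character vector of signals (all length 6); default
#'   [pas_hexamers()].
#' @return List with `sites` (retained, plus `hexamer` and
#'   `hexamer_offset` columns) and `removed` (loci with reason
#'   `"no-hexamer"`).
#' @export
require_hexamer <- function(sites, genome, hexamers = pas_hexamers()) {
  if (any(nchar(hexamers) != 6)) {
    stop("all configured hexamers must have length 6", call. = FALSE)
  }
  if (length(hexamers) == 0) stop("hexamer set is empty", call. = FALSE)
  sites <- tibble::as_tibble(sites)
  hex <- character(nrow(sites)); off <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    # 26-mer covering hexamer characters for starts in [-30, -10]
    s <- window_seq(genome, sites$chrom[i], sites$strand[i], sites$pos[i],
                    -30, -5)
    hex[i] <- NA_character_; off[i] <- NA_integer_
    if (nchar(s) < 6) next
    shift <- 26 - nchar(s)   # truncation at the chromosome start
    for (h in hexamers) {
      st <- gregexpr(h, s, fixed = TRUE)[[1]]
      if (st[1] == -1) next
      offs <- (st + shift) - 31          # 1-based index -> offset
      offs <- offs[offs >= -30 & offs <= -10]
      if (length(offs) > 0) {
        hex[i] <- h; off[i] <- max(offs)  # most proximal to the site
        break
      }
    }
  }
  sites$hexamer <- hex
  sites$hexamer_offset <- off
  keep <- !is.na(hex)
  removed <- sites[!keep, c("chrom", "strand", "pos")]
  removed$reason <- if (nrow(removed)) "no-hexamer" else character(0)
  list(sites = sites[keep, ], removed = removed)
}

#' Cluster cleavage events around dominant positions
#'
#' One-pass greedy clustering of pooled (across-sample) cleavage signal on
#' each (chrom, transcript strand): repeatedly seed at the unassigned
#' position with the highest pooled count (ties to the 5'-most position in
#' transcript orientation) and absorb all unassigned positions within
#' +/-5 nt (`radius`). Cluster count vectors are per-sample sums over
#' members; the representative is the seed.
#'
#' @param events Cleavage-event tibble (`chrom, strand, pos, sample_id,
#'   count`).
#' @param radius Absorption radius in nt (default 5).
#' @return List with `sites` (per-sample counts at representative
#'   positions: `chrom, strand, pos, sample_id, count`) and `clusters`
#'   (summary: `chrom, strand, pos, pooled_count, n_members, members`).
#' @export
cluster_events <- function(events, radius = 5) {
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0) {
    return(list(sites = events,
                clusters = tibble::tibble(chrom = character(),
                                          strand = character(),
                                          pos = numeric(),
                                          pooled_count = numeric(),
                                          n_members = integer(),
                                          members = list())))
  }
  pooled <- events |>
    dplyr::group_by(.data$chrom, .data$strand, .data$pos) |>
    dplyr::summarise(pooled_count = sum(.data$count), .groups = "drop")
  assign_group <- function(df) {
    ord <- order(-df$pooled_count, tx_order_key(df$pos, df$strand))
    assigned <- rep(NA_real_, nrow(df))
    for (k in ord) {
      if (!is.na(assigned[k])) next
      seedpos <- df$pos[k]
      mem <- which(is.na(assigned) & abs(df$pos - seedpos) <= radius)
      assigned[mem] <- seedpos
    }
    df$cluster_pos <- assigned
    df
  }
  pooled <- pooled |>
    dplyr::group_split(.data$chrom, .data$strand) |>
    purrr::map(assign_group) |>
    dplyr::bind_rows() |>
    dplyr::select("chrom", "strand", "pos", "pooled_count", "cluster_pos")
  ev <- events |>
    dplyr::inner_join(pooled[, c("chrom", "strand", "pos", "cluster_pos")],
                      by = c("chrom", "strand", "pos"))
  sites <- ev |>
    dplyr::group_by(.data$chrom, .data$strand, pos = .data$cluster_pos,
                    .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  clusters <- pooled |>
    dplyr::group_by(.data$chrom, .data$strand, pos2 = .data$cluster_pos) |>
    dplyr::summarise(pooled_count = sum(.data$pooled_count),
                     n_members = dplyr::n(),
                     members = list(sort(.data$pos)), .groups = "drop") |>
    dplyr::rename(pos = "pos2")
  list(sites = sites, clusters = clusters)
}

#' Select dominant sites with a minimum spacing
#'
#' Greedy by descending pooled count (count ties to the 5'-most position in
#' transcript orientation): a cluster is accepted iff its representative is
#' at least `min_spacing` nt from every previously accepted representative
#' on the same chromosome and transcript strand.
#'
#' @param clusters Cluster summary from [cluster_events()].
#' @param min_spacing Minimum pairwise distance in nt (default 125).
#' @return The accepted subset of `clusters`.
#' @export
select_dominant_sites <- function(clusters, min_spacing = 125) {
  if (min_spacing < 1) stop("min_spacing must be >= 1", call. = FALSE)
  pick_group <- function(df) {
    ord <- order(-df$pooled_count, tx_order_key(df$pos, df$strand))
    acc <- numeric(0); keep <- logical(nrow(df))
    for (k in ord) {
      if (length(acc) == 0 || all(abs(df$pos[k] - acc) >= min_spacing)) {
        keep[k] <- TRUE
        acc <- c(acc, df$pos[k])
      }
    }
    df[keep, ]
  }
  clusters |>
    dplyr::group_split(.data$chrom, .data$strand) |>
    purrr::map(pick_group) |>
    dplyr::bind_rows()
}

#' Build the polyA-site atlas from alignments or events
#'
#' Runs the full atlas stage: cleavage-locus extraction (when given
#' alignments), internal-priming removal on raw events, clustering, the
#' hexamer requirement applied to cluster representatives, and
#' minimum-spacing selection of dominant sites. The hexamer criterion is
#' applied after clustering so that jittered members of a true site are not
#' dropped individually; the internal-priming filter acts on raw events
#' because the artefact is positional.
#'
#' @param x Alignment tibble (see [extract_cleavage_loci()]) or a cleavage
#'   event tibble (`chrom, strand, pos, sample_id, count`), selected by
#'   `input`.
#' @param genome Named `DNAStringSet`.
#' @param protocol `"rev"` or `"fwd"` (used when `input = "alignments"`).
#' @param input `"alignments"` or `"events"`.
#' @param hexamers Hexamer catalogue; default [pas_hexamers()].
#' @param cluster_radius Absorption radius (nt).
#' @param min_spacing Minimum spacing between accepted sites (nt).
#' @return List of class `apa_atlas`: `sites` (accepted representatives
#'   with hexamer annotation and pooled counts), `counts` (per-sample
#'   counts at accepted sites), `removed` (loci with removal reasons), and
#'   `log` (stage counters).
#' @export
build_pas_atlas <- function(x, genome, protocol = "rev",
                            input = c("alignments", "events"),
                            hexamers = pas_hexamers(),
                            cluster_radius = 5, min_spacing = 125) {
  input <- match.arg(input)
  events <- if (input == "alignments") {
    extract_cleavage_loci(x, protocol)
  } else tibble::as_tibble(x)
  n_raw <- sum(events$count)

  ip <- filter_internal_priming(events, genome)
  cl <- cluster_events(ip$events, radius = cluster_radius)
  hx <- require_hexamer(cl$clusters, genome, hexamers)
  kept <- select_dominant_sites(hx$sites, min_spacing = min_spacing)
  dropped_spacing <- dplyr::anti_join(
    hx$sites[, c("chrom", "strand", "pos")],
    kept[, c("chrom", "strand", "pos")],
    by = c("chrom", "strand", "pos")) |>
    dplyr::mutate(reason = "spacing")
  removed <- dplyr::bind_rows(
    dplyr::mutate(ip$removed, reason = paste0("internal-priming:",
                                              .data$reason)),
    hx$removed, dropped_spacing)
  counts <- dplyr::semi_join(cl$sites, kept,
                             by = c("chrom", "strand", "pos"))
  structure(list(
    sites = kept, counts = counts, removed = removed,
    log = c(events_in = n_raw,
            loci_removed_internal_priming = nrow(ip$removed),
            clusters = nrow(cl$clusters),
            removed_no_hexamer = nrow(hx$removed),
            removed_spacing = nrow(dropped_spacing),
            sites_out = nrow(kept))), class = "apa_atlas")
}

#' @export
print.apa_atlas <- function(x, ...) {
  cat("<apa_atlas>\n")
  for (nm in names(x$log)) cat(sprintf("  %s: %s\n", nm, x$log[[nm]]))
  invisible(x)
}

#' Export an atlas as BED6
#'
#' One row per accepted site: `chrom, start, start+1, site id, pooled
#' count, transcript strand`.
#'
#' @param atlas An `apa_atlas`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_atlas_bed <- function(atlas, path) {
  s <- atlas$sites
  bed <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", s$chrom, s$pos, s$pos + 1,
                 sprintf("site_%s_%d_%s", s$chrom, s$pos,
                         ifelse(s$strand == "+", "p", "m")),
                 round(s$pooled_count), s$strand)
  writeLines(bed, path)
  invisible(path)
}
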