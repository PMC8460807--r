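# Standard-format I/O with explicit coordinate conventions.
#
# Everything internal to this package is 0-based half-open on the genomic
# forward strand; GTF I/O is 1-based inclusive (Ensembl dialect), BED is
# already 0-based half-open. Conversions happen here and nowhere else.

#' Construct a gene-model set
#'
#' Container for strand-aware gene models: genes, transcripts, exon chains,
#' optional CDS intervals and 3'UTR intervals. All coordinates are 0-based
#' half-open. When no UTR records are supplied but CDS records are, the
#' 3'UTR is derived as the exonic region 3' of the CDS end in transcript
#' orientation.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   optionally `biotype`.
#' @param transcripts Tibble with `transcript_id`, `gene_id`.
#' @param exons Tibble with `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @param cds Optional tibble like `exons`.
#' @param utr3 Optional tibble like `exons`; derived from `cds` when absent.
#' @return A `gene_models` object (list of tibbles).
#' @export
gene_models <- function(genes, transcripts, exons, cds = NULL, utr3 = NULL) {
  genes <- tibble::as_tibble(genes)
  if (!"biotype" %in% names(genes)) genes$biotype <- "coding"
  if (!"extended_end" %in% names(genes)) genes$extended_end <- NA_real_
  assert_strand(genes$strand)
  exons <- tibble::as_tibble(exons)
  stopifnot(all(exons$end > exons$start))
  cds <- if (is.null(cds)) exons[0, ] else tibble::as_tibble(cds)
  if (is.null(utr3)) utr3 <- derive_utr3(exons, cds)
  structure(list(genes = genes,
                 transcripts = tibble::as_tibble(transcripts),
                 exons = exons, cds = cds,
                 utr3 = tibble::as_tibble(utr3)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

# exonic region 3' of the CDS end, per transcript (transcript orientation)
derive_utr3 <- function(exons, cds) {
  if (nrow(cds) == 0) return(exons[0, ])
  bounds <- cds |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(cds_lo = min(.data$start), cds_hi = max(.data$end),
                     .groups = "drop")
  exons |>
    dplyr::inner_join(bounds, by = "transcript_id") |>
    dplyr::mutate(
      u_start = ifelse(.data$strand == "+",
                       pmax(.data$start, .data$cds_hi), .data$start),
      u_end = ifelse(.data$strand == "+",
                     .data$end, pmin(.data$end, .data$cds_lo))) |>
    dplyr::filter(.data$u_end > .data$u_start) |>
    dplyr::transmute(.data$transcript_id, .data$gene_id, .data$chrom,
                     .data$strand, start = .data$u_start, end = .data$u_end)
}

#' Read gene models from a GTF file
#'
#' Parses an Ensembl-style GTF (gene/transcript/exon, optional CDS and UTR
#' records) into a [gene_models()] object. GTF coordinates (1-based
#' inclusive) are converted to the package's 0-based half-open convention.
#' Three-prime UTRs are taken from `three_prime_utr`/`UTR` records when
#' present and derived from CDS ends otherwise.
#'
#' @param path Path to a GTF file.
#' @return A `gene_models` object.
#' @export
read_gene_models <- function(path) {
  has_records <- file.size(path) > 0 &&
    any(!grepl("^#|^\\s*$", readLines(path, warn = FALSE)))
  gr <- if (has_records) rtracklayer::import(path, format = "gtf")
        else GenomicRanges::GRanges()
  if (length(gr) == 0) {
    warning("empty annotation file: ", path)
    empty <- tibble::tibble(transcript_id = character(), gene_id = character(),
                            chrom = character(), strand = character(),
                            start = numeric(), end = numeric())
    return(gene_models(
      genes = tibble::tibble(gene_id = character(), chrom = character(),
                             strand = character(), start = numeric(),
                             end = numeric()),
      transcripts = empty[, c("transcript_id", "gene_id")],
      exons = empty))
  }
  tb <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,   # -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = if ("transcript_id" %in% names(S4Vectors::mcols(gr)))
      gr$transcript_id else NA_character_,
    biotype = if ("gene_biotype" %in% names(S4Vectors::mcols(gr)))
      gr$gene_biotype else NA_character_)
  assert_strand(tb$strand[tb$type %in% c("gene", "transcript", "exon", "CDS")])

  ex <- dplyr::filter(tb, .data$type == "exon")
  if (any(is.na(ex$transcript_id))) {
    stop("exon record without a parent transcript_id in ", path, call. = FALSE)
  }
  txs <- dplyr::filter(tb, .data$type == "transcript") |>
    dplyr::distinct(.data$transcript_id, .data$gene_id)
  if (nrow(txs) == 0) {
    txs <- dplyr::distinct(ex, .data$transcript_id, .data$gene_id)
  }
  gn <- dplyr::filter(tb, .data$type == "gene")
  if (nrow(gn) == 0) {
    gn <- ex |>
      dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       .groups = "drop") |>
      dplyr::mutate(biotype = NA_character_)
  }
  genes <- gn |>
    dplyr::transmute(.data$gene_id, .data$chrom, .data$strand,
                     .data$start, .data$end,
                     biotype = dplyr::coalesce(.data$biotype, "coding"))
  cds <- dplyr::filter(tb, .data$type == "CDS") |>
    dplyr::select("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  utr <- dplyr::filter(tb, .data$type %in% c("three_prime_utr", "UTR")) |>
    dplyr::select("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  gene_models(
    genes = genes,
    transcripts = txs,
    exons = dplyr::select(ex, "transcript_id", "gene_id", "chrom", "strand",
                          "start", "end"),
    cds = cds,
    utr3 = if (nrow(utr) > 0) utr else NULL)
}

#' Write gene models to a GTF file
#'
#' Emits gene/transcript/exon/CDS records, converting the internal 0-based
#' half-open coordinates back to 1-based inclusive GTF.
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  rows <- list(
    models$genes |>
      dplyr::transmute(.data$chrom, type = "gene", .data$start, .data$end,
                       .data$strand, .data$gene_id,
                       transcript_id = NA_character_,
                       biotype = .data$biotype),
    models$exons |>
      dplyr::distinct(.data$transcript_id, .data$gene_id, .data$chrom,
                      .data$strand) |>
      dplyr::inner_join(
        models$exons |>
          dplyr::group_by(.data$transcript_id) |>
          dplyr::summarise(start = min(.data$start), end = max(.data$end),
                           .groups = "drop"),
        by = "transcript_id") |>
      dplyr::transmute(.data$chrom, type = "transcript", .data$start,
                       .data$end, .data$strand, .data$gene_id,
                       .data$transcript_id, biotype = NA_character_),
    models$exons |>
      dplyr::transmute(.data$chrom, type = "exon", .data$start, .data$end,
                       .data$strand, .data$gene_id, .data$transcript_id,
                       biotype = NA_character_),
    models$cds |>
      dplyr::transmute(.data$chrom, type = "CDS", .data$start, .data$end,
                       .data$strand, .data$gene_id, .data$transcript_id,
                       biotype = NA_character_))
  tb <- dplyr::bind_rows(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tb$chrom,
    ranges = IRanges::IRanges(start = tb$start + 1, end = tb$end),
    strand = tb$strand)
  gr$type <- tb$type
  gr$gene_id <- tb$gene_id
  gr$transcript_id <- tb$transcript_id
  gr$gene_biotype <- tb$biotype
  gr$phase <- ifelse(tb$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read aligned reads for cleavage-site extraction
#'
#' Reads a SAM/BAM file (via Rsamtools; SAM files are converted on the fly)
#' or a tabular cleavage dialect. Unmapped, secondary and supplementary
#' records are skipped and counted. Aligned spans exclude soft-clipped
#' bases.
#'
#' The tabular dialect is a TSV with columns
#' `chrom, strand, position, sample_id, count` giving pre-extracted
#' cleavage events on the transcript strand; it is returned as-is with
#' `kind = "events"`.
#'
#' @param path Path to a `.bam`, `.sam` or tabular `.tsv` file.
#' @param sample_id Sample label attached to every alignment read from a
#'   SAM/BAM file (one file per sample); ignored for the tabular dialect.
#' @return A list with `kind` (`"alignments"` or `"events"`), `records`
#'   (tibble), and `skipped` (named counter vector, alignments only).
#'   Alignment records carry `chrom, strand, start, end, cigar, sample_id,
#'   count` with 0-based half-open aligned spans.
#' @export
read_cleavage_alignments <- function(path, sample_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt")) {
    rec <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("chrom", "strand", "position", "sample_id", "count")
    if (!all(need %in% names(rec))) {
      stop("tabular cleavage file must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    assert_strand(rec$strand)
    stopifnot(all(rec$count >= 1))
    return(list(kind = "events",
                records = tibble::as_tibble(rec), skipped = c(records = 0)))
  }
  bam <- path
  if (ext == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  all_n <- Rsamtools::countBam(bam)$records
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flag))
  kept <- length(ga)
  rec <- tibble::tibble(
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    strand = as.character(GenomicAlignments::strand(ga)),
    start = GenomicAlignments::start(ga) - 1,  # aligned span, soft clips excluded
    end = GenomicAlignments::end(ga),
    cigar = GenomicAlignments::cigar(ga),
    sample_id = sample_id %||% basename(path),
    count = 1L)
  list(kind = "alignments", records = rec,
       skipped = c(skipped = all_n - kept))
}

#' Read genomic intervals from a BED file
#'
#' BED3+ intervals are returned 0-based half-open; the strand column is
#' honoured when present (`*` means strand-agnostic). Overlapping rows are
#' preserved without merging.
#'
#' @param path Path to a BED file.
#' @return Tibble with `chrom, start, end, name, strand`.
#' @export
read_intervals_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tb <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    name = if ("name" %in% names(S4Vectors::mcols(gr))) gr$name
           else NA_character_,
    strand = as.character(GenomicRanges::strand(gr)))
  if (any(tb$end <= tb$start)) {
    stop("BED interval with start >= end at row(s): ",
         paste(which(tb$end <= tb$start), collapse = ", "), call. = FALSE)
  }
  tb
}

#' Read or write a feature-by-sample TSV matrix
#'
#' First column is the feature id, remaining columns are samples; missing
#' values use the literal `NA`. `read_matrix_tsv(write_matrix_tsv(m))`
#' round-trips exactly.
#'
#' @param path File path.
#' @param x Wide tibble (first column feature id) to write.
#' @return `read_matrix_tsv` returns a wide tibble; `write_matrix_tsv`
#'   returns `path` invisibly.
#' @export
read_matrix_tsv <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  if (anyDuplicated(tb[[1]])) {
    stop("duplicated feature ids in ", path, call. = FALSE)
  }
  for (j in seq_along(tb)[-1]) {
    col <- tb[[j]]
    if (nrow(tb) == 0 || (is.logical(col) && all(is.na(col)))) {
      tb[[j]] <- as.numeric(col)
    } else if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) &
                     !is.na(col))[1]
      stop(sprintf("non-numeric value at row %d, column '%s' in %s",
                   bad, names(tb)[j], path), call. = FALSE)
    }
  }
  tb
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' Write a genome to FASTA
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)
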