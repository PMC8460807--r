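# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integer percentage with half-up rounding
#'
#' Computes `100 * numerator / denominator` and rounds half-up to an integer
#' (so 45.5 -> 46, unlike [round()]'s round-half-even). Undefined fractions
#' (zero denominator) return `NA` rather than 0.
#'
#' @param numerator,denominator Non-negative numbers (vectorised).
#' @return Integer percentage vector, `NA` where the denominator is 0.
#' @examples
#' pct_half_up(7870, 17220)  # 46
#' pct_half_up(57, 231)      # 25
#' @export
pct_half_up <- function(numerator, denominator) {
  out <- ifelse(denominator > 0, floor(100 * numerator / denominator + 0.5), NA_real_)
  as.integer(out)
}

# clip a numeric vector into [lo, hi]
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# strand-aware "5'-most" comparator: for '+' smaller genomic position is 5',
# for '-' larger genomic position is 5'. Returns a key that sorts 5' -> 3'.
tx_order_key <- function(pos, strand) ifelse(strand == "+", pos, -pos)

assert_strand <- function(strand, what = "strand") {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop(sprintf("unknown %s value(s): %s", what,
                 paste(unique(strand[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(strand)
}

# wide gene x sample tibble (first column gene_id) -> numeric matrix
psi_as_matrix <- function(psi) {
  stopifnot(is.data.frame(psi), names(psi)[1] == "gene_id")
  m <- as.matrix(psi[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- psi$gene_id
  m
}

matrix_as_psi <- function(m, provenance = "from-counts") {
  out <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                          tibble::as_tibble(m))
  attr(out, "provenance") <- provenance
  out
}

# paired tumor/normal sample columns from a metadata table
matched_pairs <- function(metadata) {
  stopifnot(all(c("sample_id", "subject", "tissue") %in% names(metadata)))
  wide <- metadata |>
    dplyr::select("sample_id", "subject", "tissue") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "sample_id")
  if (!all(c("tumor", "normal") %in% names(wide))) {
    stop("metadata must contain both 'tumor' and 'normal' tissue samples",
         call. = FALSE)
  }
  wide |> dplyr::filter(!is.na(.data$tumor), !is.na(.data$normal))
}
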