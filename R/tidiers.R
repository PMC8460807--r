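# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a prognostic model
#'
#' One row per model term (gene PSI coefficients first, covariates after),
#' on the Cox log-hazard scale.
#'
#' @param x An `apa_prognostic_model`.
#' @param ... Unused.
#' @return Tibble `term, estimate, std_error, p_value, is_gene`.
#' @exportS3Method generics::tidy
tidy.apa_prognostic_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, "coef"],
                 std_error = s[, "se(coef)"],
                 p_value = s[, "Pr(>|z|)"],
                 is_gene = rownames(s) %in% x$genes)
}

#' Glance at a prognostic model
#'
#' @param x An `apa_prognostic_model`.
#' @param ... Unused.
#' @return One-row tibble: `n, n_events, n_genes, concordance,
#'   logtest_p`.
#' @exportS3Method generics::glance
glance.apa_prognostic_model <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(n = x$n, n_events = x$n_events,
                 n_genes = length(x$genes),
                 concordance = unname(s$concordance[1]),
                 logtest_p = unname(s$logtest["pvalue"]))
}

#' Tidy a risk stratification
#'
#' @param x An `apa_risk_strata`.
#' @param ... Unused.
#' @return Per-sample tibble `sample_id, pi, risk`.
#' @exportS3Method generics::tidy
tidy.apa_risk_strata <- function(x, ...) x$groups

#' Glance at a risk stratification
#'
#' @param x An `apa_risk_strata`.
#' @param ... Unused.
#' @return One-row tibble: `chisq, p, hr, hr_lo, hr_hi, orientation`.
#' @exportS3Method generics::glance
glance.apa_risk_strata <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, p = x$p, hr = x$hr$hr[1],
                 hr_lo = x$hr$lo[1], hr_hi = x$hr$hi[1],
                 orientation = x$orientation)
}

#' Glance at a switch-test result
#'
#' @param x An `apa_switches` tibble.
#' @param ... Unused.
#' @return One-row tibble: `n_tested, n_shortened, n_lengthened,
#'   n_switched`.
#' @exportS3Method generics::glance
glance.apa_switches <- function(x, ...) {
  tibble::tibble(n_tested = nrow(x),
                 n_shortened = sum(x$direction == "shortened"),
                 n_lengthened = sum(x$direction == "lengthened"),
                 n_switched = sum(x$direction != "unchanged"))
}
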