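# PSI-based prognostic modelling: L1-penalized Cox feature selection, the
# prognosis index PI = sum_i beta_i * chi_i (chi = gene PSI), leave-one-out
# cross-validation, median-split risk stratification and the log-rank test.

# complete-case design matrix: gene PSI columns + covariate dummies
build_design <- function(psi, clinical, covariates) {
  m <- t(psi_as_matrix(psi))              # samples x genes
  cl <- tibble::as_tibble(clinical)
  cl <- cl[match(rownames(m), cl$sample_id), ]
  keep <- stats::complete.cases(m) & !is.na(cl$time) & !is.na(cl$event)
  covm <- NULL
  if (length(covariates) > 0) {
    fml <- stats::as.formula(paste("~", paste(covariates, collapse = "+")))
    mf <- stats::model.frame(fml, data = cl, na.action = stats::na.pass)
    covm <- stats::model.matrix(fml, mf)[, -1, drop = FALSE]
    keep <- keep & stats::complete.cases(covm)
  }
  list(x_genes = m[keep, , drop = FALSE],
       x_cov = if (is.null(covm)) NULL else covm[keep, , drop = FALSE],
       clinical = cl[keep, ], sample_ids = rownames(m)[keep])
}

#' Lasso Cox feature selection on gene PSI
#'
#' A single multivariate L1-penalized Cox proportional-hazards fit over
#' all gene PSI columns, with clinical covariates included unpenalized;
#' the penalty is chosen by k-fold cross-validated partial likelihood and
#' the selected genes are those with a non-zero coefficient at
#' `lambda.min`. A per-gene univariate screen (`mode = "univariate"`,
#' keeping genes with Wald p below `screen_p`) is offered as an
#' alternative.
#'
#' @param psi Wide PSI tibble (genes to select among).
#' @param clinical Tibble `sample_id, time, event` plus covariate columns.
#' @param covariates Character vector of covariate column names (default
#'   age/sex/race/stage), never penalized.
#' @param nfolds Cross-validation folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param min_samples Minimum complete-case samples (default 40).
#' @param max_missing Drop genes missing in more than this fraction of
#'   samples before complete-case filtering (default 0.2).
#' @param mode `"lasso"` or `"univariate"`.
#' @param screen_p Univariate screen p threshold (default 0.05).
#' @return Character vector of selected gene ids (possibly empty).
#' @export
select_features_lasso <- function(psi, clinical,
                                  covariates = c("age", "sex", "race",
                                                 "stage"),
                                  nfolds = 5, seed = 1, min_samples = 40,
                                  max_missing = 0.2,
                                  mode = c("lasso", "univariate"),
                                  screen_p = 0.05) {
  mode <- match.arg(mode)
  m <- psi_as_matrix(psi)
  miss <- rowMeans(is.na(m))
  psi <- psi[miss <= max_missing, , drop = FALSE]
  d <- build_design(psi, clinical, covariates)
  n <- nrow(d$x_genes)
  if (n < min_samples) {
    stop(sprintf("only %d complete-case samples (< %d)", n, min_samples),
         call. = FALSE)
  }
  if (sum(d$clinical$event) == 0) stop("zero events", call. = FALSE)
  y <- survival::Surv(d$clinical$time, d$clinical$event)
  if (mode == "univariate") {
    ps <- apply(d$x_genes, 2, function(x) {
      f <- survival::coxph(y ~ x)
      summary(f)$coefficients[1, "Pr(>|z|)"]
    })
    return(colnames(d$x_genes)[ps < screen_p])
  }
  x <- cbind(d$x_genes, d$x_cov)
  pf <- c(rep(1, ncol(d$x_genes)),
          rep(0, if (is.null(d$x_cov)) 0 else ncol(d$x_cov)))
  set.seed(seed)
  cv <- glmnet::cv.glmnet(x, y, family = "cox", penalty.factor = pf,
                          nfolds = nfolds)
  beta <- as.matrix(stats::coef(cv, s = "lambda.min"))
  sel <- rownames(beta)[beta[, 1] != 0]
  intersect(sel, colnames(d$x_genes))
}

#' Fit the prognosis-index Cox model
#'
#' Unpenalized multivariate Cox proportional-hazards fit (Breslow ties) of
#' survival on the selected genes' PSI plus covariates. The prognosis
#' index of sample k is PI_k = sum_i beta_i * chi_ik over the gene terms
#' only, where beta_i is the fitted Cox log-hazard coefficient of gene i
#' and chi_ik is the sample's PSI.
#'
#' @param psi Wide PSI tibble restricted (internally) to `genes`.
#' @param clinical Tibble `sample_id, time, event` plus covariates.
#' @param genes Selected gene ids (non-empty).
#' @param covariates Covariate column names (may be empty).
#' @return Object of class `apa_prognostic_model`: `genes`, `beta` (named
#'   gene coefficients), `covariate_beta`, `pi` (tibble `sample_id, pi`),
#'   `fit` (the `coxph` object), `n`, `n_events`.
#' @export
fit_pi_model <- function(psi, clinical, genes,
                         covariates = c("age", "sex", "race", "stage")) {
  if (length(genes) == 0) stop("no genes selected", call. = FALSE)
  psi_sel <- psi[psi$gene_id %in% genes, , drop = FALSE]
  d <- build_design(psi_sel, clinical, covariates)
  x <- cbind(d$x_genes, d$x_cov)
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1) {
    drop_idx <- qrx$pivot[(qrx$rank + 1):(ncol(x) + 1)] - 1
    stop("singular design; collinear column(s): ",
         paste(colnames(x)[drop_idx], collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(time = d$clinical$time, event = d$clinical$event, x,
                    check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", colnames(x)), collapse = "+")))
  fit <- survival::coxph(fml, data = dat, ties = "breslow")
  cf <- stats::coef(fit)
  beta <- cf[colnames(d$x_genes)]
  pi_vals <- as.numeric(d$x_genes %*% beta)
  structure(list(
    genes = colnames(d$x_genes), beta = beta,
    covariate_beta = cf[setdiff(names(cf), colnames(d$x_genes))],
    pi = tibble::tibble(sample_id = d$sample_ids, pi = pi_vals),
    fit = fit, n = nrow(d$x_genes), n_events = sum(d$clinical$event)),
    class = "apa_prognostic_model")
}

#' @export
print.apa_prognostic_model <- function(x, ...) {
  cat(sprintf("<apa_prognostic_model> %d genes, n = %d (%d events)\n",
              length(x$genes), x$n, x$n_events))
  print(round(x$beta, 4))
  invisible(x)
}

#' Predict the prognosis index for new samples
#'
#' @param object An `apa_prognostic_model`.
#' @param psi Wide PSI tibble containing the model's genes.
#' @param ... Unused.
#' @return Tibble `sample_id, pi`.
#' @export
predict_pi <- function(object, psi, ...) {
  m <- psi_as_matrix(psi)
  m <- m[object$genes, , drop = FALSE]
  tibble::tibble(sample_id = colnames(m),
                 pi = as.numeric(crossprod(m, object$beta)))
}

#' Leave-one-out cross-validated prognosis index
#'
#' For each sample, the PI model is refit on all other samples and the
#' held-out sample's PI computed from that fit. Non-convergent folds leave
#' the sample's PI missing.
#'
#' @inheritParams fit_pi_model
#' @return Tibble `sample_id, pi` (held-out indices).
#' @export
loocv_prognostic_index <- function(psi, clinical, genes,
                                   covariates = c("age", "sex", "race",
                                                  "stage")) {
  cl <- tibble::as_tibble(clinical)
  samples <- intersect(cl$sample_id, colnames(psi)[-1])
  if (length(samples) < 10) stop("LOOCV needs at least 10 samples",
                                 call. = FALSE)
  pi_out <- purrr::map_dbl(samples, function(s) {
    keep_cols <- c("gene_id", setdiff(samples, s))
    out <- tryCatch({
      fit <- fit_pi_model(psi[, keep_cols],
                          cl[cl$sample_id != s, ], genes, covariates)
      predict_pi(fit, psi[, c("gene_id", s)])$pi[1]
    }, error = function(e) NA_real_, warning = function(w) {
      fit <- suppressWarnings(fit_pi_model(psi[, keep_cols],
                                           cl[cl$sample_id != s, ],
                                           genes, covariates))
      suppressWarnings(predict_pi(fit, psi[, c("gene_id", s)])$pi[1])
    })
    out
  })
  tibble::tibble(sample_id = samples, pi = pi_out)
}

#' Median-split risk stratification and log-rank test
#'
#' Samples are split at the median PI. With
#' `orientation = "as-published"`, samples with PI above the median are
#' labelled `low` and the rest `high` (the labelling used in the source
#' cohort's method description); `orientation = "conventional"` labels
#' PI above the median as `high` risk. A two-group log-rank chi-square and
#' p are reported, together with the Cox hazard ratio of the `high` group
#' (optionally covariate-adjusted, optionally within levels of
#' `group_col`).
#'
#' @param pi_tbl Tibble `sample_id, pi` (e.g. from
#'   [loocv_prognostic_index()]).
#' @param clinical Tibble `sample_id, time, event` plus covariates.
#' @param orientation `"as-published"` or `"conventional"`.
#' @param covariates Covariates for the HR model (default none).
#' @param group_col Optional clinical column for per-level HRs.
#' @return Object of class `apa_risk_strata`: `groups` (tibble
#'   `sample_id, pi, risk`), `chisq`, `p`, `hr` (tibble with the HR, CI
#'   and p; one row per `group_col` level when given), `orientation`.
#' @export
stratify_and_logrank <- function(pi_tbl, clinical,
                                 orientation = c("as-published",
                                                 "conventional"),
                                 covariates = character(),
                                 group_col = NULL) {
  orientation <- match.arg(orientation)
  dat <- dplyr::inner_join(pi_tbl, tibble::as_tibble(clinical),
                           by = "sample_id") |>
    dplyr::filter(!is.na(.data$pi))
  if (stats::sd(dat$pi) == 0) {
    stop("all prognosis indices identical; no median split possible",
         call. = FALSE)
  }
  med <- stats::median(dat$pi)
  above <- dat$pi > med
  dat$risk <- if (orientation == "as-published") {
    ifelse(above, "low", "high")
  } else {
    ifelse(above, "high", "low")
  }
  if (min(table(dat$risk)) < 2) {
    stop("median split leaves fewer than 2 samples in a group",
         call. = FALSE)
  }
  sd_fit <- survival::survdiff(
    survival::Surv(time, event) ~ risk, data = dat)
  chisq <- sd_fit$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  hr_one <- function(d, level = NA_character_) {
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~ I(risk == 'high')",
      if (length(covariates)) paste("+", paste(covariates, collapse = "+"))
      else ""))
    fit <- tryCatch(
      suppressWarnings(survival::coxph(fml, data = d, ties = "breslow")),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(group = level, hr = NA_real_, lo = NA_real_,
                            hi = NA_real_, p = NA_real_))
    }
    s <- summary(fit)
    tibble::tibble(group = level, hr = s$conf.int[1, "exp(coef)"],
                   lo = s$conf.int[1, "lower .95"],
                   hi = s$conf.int[1, "upper .95"],
                   p = s$coefficients[1, "Pr(>|z|)"])
  }
  hr <- if (is.null(group_col)) hr_one(dat) else {
    dat |>
      dplyr::group_split(.data[[group_col]]) |>
      purrr::map_dfr(~ hr_one(.x, as.character(.x[[group_col]][1])))
  }
  structure(list(groups = dat[, c("sample_id", "pi", "risk")],
                 chisq = chisq, p = p, hr = hr,
                 orientation = orientation,
                 survfit = survival::survfit(
                   survival::Surv(time, event) ~ risk, data = dat)),
            class = "apa_risk_strata")
}

#' @export
print.apa_risk_strata <- function(x, ...) {
  cat(sprintf(
    "<apa_risk_strata> log-rank chisq = %.3f, p = %.3g (orientation: %s)\n",
    x$chisq, x$p, x$orientation))
  invisible(x)
}
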