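# Lasso selection, PI arithmetic, LOOCV, median-split log-rank.

# small deterministic clinical frame with exponential survival driven by
# a linear predictor over given PSI rows
mk_surv_data <- function(n, beta, seed, baseline = 0.05, horizon = 100,
                         n_null = 0) {
  set.seed(seed)
  genes <- c(names(beta), if (n_null > 0) paste0("null", seq_len(n_null)))
  m <- matrix(runif(length(genes) * n, 0.1, 0.9), length(genes), n,
              dimnames = list(genes, paste0("S", seq_len(n))))
  lp <- as.numeric(crossprod(m[names(beta), , drop = FALSE] - 0.5, beta))
  t_ev <- rexp(n, baseline * exp(lp))
  clinical <- tibble::tibble(
    sample_id = colnames(m), time = pmin(t_ev, horizon),
    event = as.integer(t_ev <= horizon),
    age = round(rnorm(n, 65, 9), 1),
    sex = sample(c("male", "female"), n, TRUE),
    race = sample(c("AA", "EA"), n, TRUE),
    stage = sample(c("I", "II", "III"), n, TRUE))
  psi <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                          tibble::as_tibble(m))
  list(psi = psi, clinical = clinical)
}

test_that("an infinite penalty selects nothing", {
  d <- mk_surv_data(60, c(g1 = 1), seed = 41, n_null = 5)
  x <- t(as.matrix(d$psi[, -1]))
  colnames(x) <- d$psi$gene_id
  fit <- glmnet::glmnet(x, survival::Surv(d$clinical$time,
                                          d$clinical$event),
                        family = "cox")
  beta_inf <- as.matrix(stats::coef(fit, s = max(fit$lambda) * 100))
  expect_true(all(beta_inf == 0))
})

test_that("lasso recovers planted prognostic genes among nulls", {
  hits <- purrr::map_lgl(1:5, function(s) {
    d <- mk_surv_data(200, c(gA = 2, gB = -2, gC = 2), seed = 100 + s,
                      n_null = 50)
    sel <- select_features_lasso(d$psi, d$clinical, seed = s)
    all(c("gA", "gB", "gC") %in% sel)
  })
  expect_gte(mean(hits), 0.8)
})

test_that("zero-signal data selects almost nothing", {
  sizes <- purrr::map_int(1:5, function(s) {
    d <- mk_surv_data(120, c(gA = 0), seed = 200 + s, n_null = 40)
    length(select_features_lasso(d$psi, d$clinical, seed = s))
  })
  expect_lte(stats::median(sizes), 2)
})

test_that("the prognosis index is exactly the coefficient-PSI sum", {
  d <- mk_surv_data(80, c(gA = 1.2, gB = -0.8), seed = 42, n_null = 3)
  fit <- fit_pi_model(d$psi, d$clinical, genes = c("gA", "gB"))
  m <- as.matrix(d$psi[match(c("gA", "gB"), d$psi$gene_id), -1])
  manual <- as.numeric(crossprod(m, fit$beta))
  expect_equal(fit$pi$pi, manual, tolerance = 1e-12)
  # hand arithmetic on the stated formula
  expect_equal(sum(c(0.5, -1.0) * c(0.4, 0.2)), 0)
  # monotonicity: raising a positive-beta gene's PSI raises PI
  i <- which.max(fit$beta)
  psi2 <- d$psi
  psi2[psi2$gene_id == names(fit$beta)[i], "S1"] <-
    psi2[[which(psi2$gene_id == names(fit$beta)[i]), "S1"]] + 0.05
  pi2 <- predict_pi(fit, psi2)
  expect_gt(pi2$pi[pi2$sample_id == "S1"],
            fit$pi$pi[fit$pi$sample_id == "S1"])
})

test_that("empty selections and degenerate designs error cleanly", {
  d <- mk_surv_data(40, c(gA = 1), seed = 43, n_null = 2)
  expect_error(fit_pi_model(d$psi, d$clinical, genes = character(0)),
               "no genes")
  # duplicated gene column makes the design singular
  psi_dup <- dplyr::bind_rows(
    d$psi, dplyr::mutate(d$psi[d$psi$gene_id == "gA", ],
                         gene_id = "gA_copy"))
  expect_error(fit_pi_model(psi_dup, d$clinical,
                            genes = c("gA", "gA_copy"),
                            covariates = character()), "collinear")
})

test_that("LOOCV produces one held-out PI per sample", {
  d <- mk_surv_data(30, c(gA = 1.5), seed = 44, n_null = 2)
  cv <- loocv_prognostic_index(d$psi, d$clinical, genes = "gA",
                               covariates = character())
  expect_equal(nrow(cv), 30)
  expect_setequal(cv$sample_id, d$clinical$sample_id)
  expect_true(all(!is.na(cv$pi)))
  # near-duplicated data: held-out PI approximates the full fit
  full <- fit_pi_model(d$psi, d$clinical, genes = "gA",
                       covariates = character())
  expect_gt(stats::cor(cv$pi[match(full$pi$sample_id, cv$sample_id)],
                       full$pi$pi), 0.98)
})

test_that("LOOCV on duplicated rows reproduces the full fit closely", {
  d <- mk_surv_data(15, c(gA = 1), seed = 45)
  # replicate every subject eight times so that leaving one record out
  # barely moves the fit
  psi2 <- d$psi; cl2 <- d$clinical
  for (k in 1:7) {
    suffix <- paste0("d", k)
    dup_cols <- stats::setNames(d$psi[, -1],
                                paste0(names(d$psi[, -1]), suffix))
    psi2 <- dplyr::bind_cols(psi2, dup_cols)
    cl2 <- dplyr::bind_rows(cl2,
                            dplyr::mutate(d$clinical,
                                          sample_id = paste0(sample_id,
                                                             suffix)))
  }
  cv <- loocv_prognostic_index(psi2, cl2, genes = "gA",
                               covariates = character())
  full <- fit_pi_model(psi2, cl2, genes = "gA", covariates = character())
  expect_equal(cv$pi[match(full$pi$sample_id, cv$sample_id)],
               full$pi$pi, tolerance = 0.02)
})

test_that("log-rank agrees with the hand-computed 6-subject table", {
  cl <- tibble::tibble(
    sample_id = paste0("S", 1:6),
    time = c(2, 4, 5, 7, 9, 12),
    event = c(1, 1, 0, 1, 1, 0))
  pi_tbl <- tibble::tibble(sample_id = paste0("S", 1:6),
                           pi = c(5, 6, 4, 1, 2, 0))
  r <- stratify_and_logrank(pi_tbl, cl, orientation = "conventional")
  manual <- oracle_logrank(cl$time, cl$event,
                           r$groups$risk[match(cl$sample_id,
                                               r$groups$sample_id)])
  expect_equal(r$chisq, manual$chisq, tolerance = 1e-10)
  expect_equal(r$p, manual$p, tolerance = 1e-10)
})

test_that("published orientation labels PI above the median as low risk", {
  cl <- tibble::tibble(sample_id = paste0("S", 1:8),
                       time = 1:8, event = rep(1, 8))
  pi_tbl <- tibble::tibble(sample_id = paste0("S", 1:8), pi = 1:8)
  pub <- stratify_and_logrank(pi_tbl, cl)
  expect_equal(pub$orientation, "as-published")
  expect_true(all(pub$groups$risk[pub$groups$pi > stats::median(1:8)] ==
                    "low"))
  conv <- stratify_and_logrank(pi_tbl, cl, orientation = "conventional")
  expect_true(all(conv$groups$risk[conv$groups$pi > stats::median(1:8)] ==
                    "high"))
  # ties at the median go to the 'rest' group
  pi_tie <- tibble::tibble(sample_id = paste0("S", 1:8),
                           pi = c(1, 1, 1, 1, 2, 2, 2, 2))
  r <- stratify_and_logrank(pi_tie, cl, orientation = "conventional")
  expect_equal(sum(r$groups$risk == "high"), 4)
  expect_error(stratify_and_logrank(
    tibble::tibble(sample_id = paste0("S", 1:8), pi = 1), cl),
    "identical")
})

test_that("identical survival between groups gives chi-square near zero", {
  set.seed(46)
  cl <- tibble::tibble(sample_id = paste0("S", 1:100),
                       time = rep(rexp(50, 0.1), 2),
                       event = rep(rbinom(50, 1, 0.8), 2))
  pi_tbl <- tibble::tibble(sample_id = cl$sample_id,
                           pi = rep(c(0, 1), each = 50))
  r <- stratify_and_logrank(pi_tbl, cl, orientation = "conventional")
  expect_lt(r$chisq, 1e-10)
  expect_gt(r$p, 0.999)
})

test_that("a single event total does not crash the split", {
  cl <- tibble::tibble(sample_id = paste0("S", 1:10),
                       time = c(5, rep(10, 9)),
                       event = c(1, rep(0, 9)))
  pi_tbl <- tibble::tibble(sample_id = cl$sample_id, pi = 1:10)
  r <- stratify_and_logrank(pi_tbl, cl)
  expect_true(is.finite(r$p))
})

test_that("Cox fits recover planted coefficients at n = 500", {
  # bimodal usage gives the design enough spread for a tight estimate
  set.seed(47)
  n <- 500
  m <- rbind(gA = sample(c(0.15, 0.85), n, TRUE),
             gB = sample(c(0.15, 0.85), n, TRUE))
  colnames(m) <- paste0("S", 1:n)
  beta <- c(gA = 1, gB = -0.7)
  t_ev <- rexp(n, 0.05 * exp(as.numeric(crossprod(m - 0.5, beta))))
  clinical <- tibble::tibble(sample_id = colnames(m),
                             time = pmin(t_ev, 100),
                             event = as.integer(t_ev <= 100))
  psi <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                          tibble::as_tibble(m))
  fit <- fit_pi_model(psi, clinical, genes = c("gA", "gB"),
                      covariates = character())
  expect_lt(abs(fit$beta[["gA"]] - 1), 0.15)
  expect_lt(abs(fit$beta[["gB"]] + 0.7), 0.15)
})

test_that("null-model median-split p-values are approximately uniform", {
  ps <- purrr::map_dbl(1:200, function(s) {
    set.seed(1000 + s)
    n <- 40
    cl <- tibble::tibble(sample_id = paste0("S", 1:n),
                         time = pmin(rexp(n, 0.05), 100),
                         event = as.integer(rexp(n, 0.05) <= 100))
    # regenerate times so event flag matches
    t_ev <- rexp(n, 0.05)
    cl$time <- pmin(t_ev, 100); cl$event <- as.integer(t_ev <= 100)
    pi_tbl <- tibble::tibble(sample_id = cl$sample_id, pi = rnorm(n))
    stratify_and_logrank(pi_tbl, cl)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("tidiers expose coefficients and stratification summaries", {
  d <- mk_surv_data(60, c(gA = 1.5), seed = 48, n_null = 2)
  fit <- fit_pi_model(d$psi, d$clinical, genes = "gA")
  td <- generics::tidy(fit)
  expect_true("gA" %in% td$term)
  expect_true(all(td$is_gene == (td$term == "gA")))
  gl <- generics::glance(fit)
  expect_equal(gl$n, fit$n)
  r <- stratify_and_logrank(fit$pi, d$clinical)
  expect_equal(nrow(generics::tidy(r)), fit$n)
  expect_true(is.finite(generics::glance(r)$hr))
})
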