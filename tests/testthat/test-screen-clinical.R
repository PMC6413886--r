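test_that("single-stratum fit equals an unstratified two-group Cox model", {
  cl <- simulate_survival(300, 0.7, n_strata = 1, seed = 41)
  cl$sex <- "F"  # collapse the cancer_type x race x sex cross to 1 stratum
  fit <- fit_stratified_cox(cl$ind, cl)
  ref <- survival::coxph(
    survival::Surv(time_days, event) ~ ind +
      inverse_normal_transform(age) + inverse_normal_transform(gii) +
      inverse_normal_transform(tumor_purity),
    data = cl, ties = "efron")
  expect_equal(fit$beta, unname(coef(ref)["ind"]), tolerance = 1e-6)
  expect_gte(fit$lrt, 0)
})

test_that("stratified Cox recovers the planted log hazard ratio", {
  betas <- vapply(1:20, function(s) {
    cl <- simulate_survival(1000, 0.7, n_strata = 3, seed = 100 + s)
    fit_stratified_cox(cl$ind, cl)$beta
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.7), 0.15)
})

test_that("likelihood-ratio and Wald p-values agree on well-posed fits", {
  # moderate effect so both p-values sit in a regime where the ratio is
  # informative (at p ~ 1e-10 tiny absolute differences explode the ratio)
  cl <- simulate_survival(1000, 0.15, n_strata = 3, seed = 43)
  fit <- fit_stratified_cox(cl$ind, cl)
  ratio <- fit$p_lrt / fit$p_wald
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("stratified fit is invariant to relabeling strata", {
  cl <- simulate_survival(400, 0.7, n_strata = 3, seed = 44)
  fit1 <- fit_stratified_cox(cl$ind, cl)
  cl2 <- cl
  cl2$cancer_type <- c(st1 = "zebra", st2 = "alpha",
                       st3 = "mid")[cl$cancer_type]
  fit2 <- fit_stratified_cox(cl2$ind, cl2)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-8)
  expect_equal(fit1$p_lrt, fit2$p_lrt, tolerance = 1e-8)
})

test_that("null calibration: LRT rejects at close to nominal rate", {
  reject <- vapply(1:500, function(s) {
    cl <- simulate_survival(300, 0, n_strata = 3, seed = 2000 + s)
    fit_stratified_cox(cl$ind, cl)$p_lrt < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("degenerate indicators and tiny strata are handled", {
  cl <- simulate_survival(200, 0.7, seed = 45)
  expect_error(fit_stratified_cox(rep(1L, 200), cl), "degenerate indicator")
  # tiny strata get pooled rather than producing unstable baselines
  cl$race <- sprintf("r%03d", seq_len(200))  # every stratum singleton
  fit <- fit_stratified_cox(cl$ind, cl)
  expect_equal(fit$strata_used, 1L)
  expect_true(fit$converged)
})

test_that("tidy and glance expose the fitted coefficients", {
  cl <- simulate_survival(300, 0.7, seed = 46)
  fit <- fit_stratified_cox(cl$ind, cl)
  td <- tidy(fit)
  expect_true("ind" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$beta1, fit$beta)
  expect_equal(gl$n_events, sum(cl$event))
})

test_that("purity controls validate, impute, and drop columns", {
  cl <- simulate_survival(100, 0, seed = 47)
  cl$purity_absolute <- cl$tumor_purity + rnorm(100, 0, 0.02)
  cl$purity_absolute[1:5] <- NA
  cl$purity_bad <- NA_real_
  expect_warning(
    expect_warning(
      out <- add_purity_controls(cl, c("tumor_purity", "purity_absolute",
                                       "purity_bad")),
      "mean-imputed"),
    "all-missing")
  expect_setequal(out$purity_cols, c("tumor_purity", "purity_absolute"))
  expect_false(anyNA(out$clinical$purity_absolute))
})

test_that("clinical screen passes planted pairs and gates on effect sign", {
  b <- small_bundle()
  ct <- b$cohort$clinical$cancer_type
  am <- call_activity(b$cohort$mrna, ct)
  as_ <- call_activity(b$cohort$scna, ct)
  tp <- b$truth$pairs
  du <- tp[tp$sr_type == "DU", c("vulnerable", "rescuer")]
  decoys <- b$candidates[-seq_len(nrow(tp)), ][1:20, ]

  res <- screen_clinical(am, as_, b$cohort$mrna, b$cohort$scna,
                         b$cohort$clinical, rbind(du, decoys), "DU")
  expect_gte(sum(res$pass[seq_len(nrow(du))]), nrow(du) - 1)
  expect_lt(mean(res$pass[-seq_len(nrow(du))]), 0.15)
  # planted rescued states must show harm, non-rescued protection
  expect_true(all(res$beta_res_mRNA[seq_len(nrow(du))] > 0))
  expect_true(all(res$beta_non_mRNA[seq_len(nrow(du))] < 0))

  # permuted survival kills the signal
  cl_perm <- b$cohort$clinical
  set.seed(48)
  idx <- sample(nrow(cl_perm))
  cl_perm$time_days <- cl_perm$time_days[idx]
  cl_perm$event <- cl_perm$event[idx]
  res_perm <- screen_clinical(am, as_, b$cohort$mrna, b$cohort$scna,
                              cl_perm, du, "DU")
  expect_equal(sum(res_perm$pass), 0)
})
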