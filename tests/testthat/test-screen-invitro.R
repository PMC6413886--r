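test_that("conditional-essentiality fit matches lme4 and OLS references", {
  set.seed(21)
  n <- 80
  ct <- factor(sample(c("A", "B", "C"), n, TRUE))
  g <- rnorm(n)
  y <- 0.5 * g + c(-1, 0, 1)[as.integer(ct)] + rnorm(n)

  fast <- fit_conditional_essentiality(y, g, ct)
  ref <- fit_conditional_essentiality(y, g, ct, engine = "lme4")
  expect_equal(fast$beta, ref$beta, tolerance = 1e-6)
  expect_equal(fast$p, ref$p, tolerance = 1e-6)
  expect_identical(fast$method, "lmm")

  # single cancer type degrades to ordinary least squares exactly
  one <- fit_conditional_essentiality(y, g, rep("A", n))
  yin <- inverse_normal_transform(y); gin <- inverse_normal_transform(g)
  lmfit <- lm(yin ~ gin)
  expect_equal(one$beta, unname(coef(lmfit)[2]), tolerance = 1e-8)
  expect_equal(one$p, anova(lmfit)[["Pr(>F)"]][1], tolerance = 1e-8)
  expect_identical(one$method, "ols")

  expect_error(fit_conditional_essentiality(y, rep(1, n), ct),
               "constant covariate")
  expect_error(fit_conditional_essentiality(y[1:5], g[1:5], ct[1:5]),
               ">= 10")
})

test_that("mixed model recovers a planted slope and de-confounds intercepts", {
  set.seed(22)
  n <- 50
  g <- rnorm(n)
  y <- 0.5 * g + rnorm(n, sd = 0.1)
  fit <- fit_conditional_essentiality(y, g, rep("A", n), normalize = FALSE)
  expect_lt(abs(fit$beta - 0.5), 0.1)
  expect_lt(fit$p, 1e-6)

  # two cancer types with opposite intercepts confound pooled OLS; the
  # random intercept recovers the common within-type slope
  set.seed(23)
  ct <- rep(c("A", "B"), each = 60)
  g2 <- rnorm(120) + ifelse(ct == "A", -1.5, 1.5)
  y2 <- 0.5 * g2 + ifelse(ct == "A", 2, -2) + rnorm(120, sd = 0.3)
  mixed <- fit_conditional_essentiality(y2, g2, ct, normalize = FALSE)
  pooled <- unname(coef(lm(y2 ~ g2))[2])
  expect_lt(abs(mixed$beta - 0.5), 0.15)
  expect_gt(abs(pooled - 0.5), 0.3)  # pooled OLS is visibly biased here
})

test_that("mixed-model LRT p-values are calibrated under the null", {
  set.seed(24)
  n <- 60
  ct <- factor(sample(c("A", "B", "C"), n, TRUE))
  reject <- vapply(1:500, function(i) {
    y <- rnorm(n) + c(-0.5, 0, 0.5)[as.integer(ct)]
    g <- rnorm(n)
    fit_conditional_essentiality(y, g, ct)$p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("Fisher combination follows the chi-square construction", {
  expect_equal(combine_fisher(0.37), 0.37)            # k = 1 identity
  expect_equal(combine_fisher(c(0.5, 0.5)), 0.5966, tolerance = 1e-4)
  expect_equal(combine_fisher(c(1, 1)), 1)
  expect_warning(p <- combine_fisher(c(0, 0.5)), "clamped")
  expect_true(p > 0 && p < 1e-10)
})

test_that("in-vitro screen recovers planted pairs and gates on sign", {
  b <- small_bundle()
  tp <- b$truth$pairs
  du <- tp[tp$sr_type == "DU", c("vulnerable", "rescuer")]
  decoys <- b$candidates[!paste(b$candidates$vulnerable,
                                b$candidates$rescuer) %in%
                           paste(tp$vulnerable, tp$rescuer), ][1:80, ]
  cand <- rbind(du, decoys)
  res <- screen_invitro(b$panel, cand, sr_type = "DU", fdr = 0.2)
  expect_true(all(res$pass[seq_len(nrow(du))]))
  expect_lt(mean(res$pass[-seq_len(nrow(du))]), 0.2)

  # reversed pairs invert the planted signs and must fail the gate
  rev_pairs <- data.frame(vulnerable = du$rescuer, rescuer = du$vulnerable)
  res_rev <- screen_invitro(b$panel, rev_pairs, sr_type = "DD", fdr = 0.2)
  expect_false(any(res_rev$pass))

  # monotone in fdr
  res_strict <- screen_invitro(b$panel, cand, sr_type = "DU", fdr = 0.05)
  expect_true(all(which(res_strict$pass) %in% which(res$pass)))

  # empty candidate list
  empty <- screen_invitro(b$panel, cand[0, ], sr_type = "DU")
  expect_equal(nrow(empty), 0)
})

test_that("DD pairs are detected through the flipped-sign/Wilcoxon variant", {
  b <- small_bundle()
  dd <- b$truth$pairs[b$truth$pairs$sr_type == "DD",
                      c("vulnerable", "rescuer")]
  res <- screen_invitro(b$panel, dd, sr_type = "DD", fdr = 0.2)
  expect_true(all(res$pass))
})

test_that("drug readouts fan out to every non-agonist target", {
  map <- tibble::tibble(drug = c("dA", "dA", "dB"),
                        target_gene = c("g1", "g2", "g3"),
                        action = c("inhibitor", "inhibitor", "inhibitor"))
  ro <- tibble::tibble(cell_line = "cl1", cancer_type = "A",
                       perturbed_gene = c("dA", "g9"),
                       readout_kind = c("drug_logIC50", "shRNA_essentiality"),
                       value = c(1.5, 0.2))
  out <- map_drug_readouts(ro, map)
  expect_setequal(out$perturbed_gene, c("g9", "g1", "g2"))
  expect_equal(sum(out$value == 1.5), 2)
})
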