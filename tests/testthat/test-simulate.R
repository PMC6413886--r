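test_that("generators are pure functions of parameters and seed", {
  tr <- small_truth()
  c1 <- simulate_cohort(tr, n_samples = 150, n_genes = 50, seed = 5)
  c2 <- simulate_cohort(tr, n_samples = 150, n_genes = 50, seed = 5)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(unclass(c1$mrna), unclass(c2$mrna))
  c3 <- simulate_cohort(tr, n_samples = 150, n_genes = 50, seed = 6)
  expect_false(identical(unclass(c1$mrna), unclass(c3$mrna)))

  p1 <- simulate_screen_panel(tr, n_cell_lines = 40, n_genes = 50, seed = 5)
  p2 <- simulate_screen_panel(tr, n_cell_lines = 40, n_genes = 50, seed = 5)
  expect_identical(p1$readouts, p2$readouts)
  f1 <- simulate_phylo_profiles(tr, n_genes = 50, seed = 5)
  expect_identical(f1, simulate_phylo_profiles(tr, n_genes = 50, seed = 5))
  g1 <- simulate_dose_grids(3, synergy = 1.5, seed = 5)
  expect_identical(g1, simulate_dose_grids(3, synergy = 1.5, seed = 5))
})

test_that("planted truth validates its effect sizes and gene sets", {
  expect_error(small_truth(inflation = 3.5), "infeasible inflation")
  expect_error(planted_truth(tibble::tibble(
    vulnerable = c("g1", "g1"), rescuer = c("g2", "g3"),
    sr_type = c("DU", "DU"))), "distinct")
  expect_error(simulate_cohort(small_truth(n_genes = 10), n_samples = 120,
                               n_genes = 5, seed = 1), "gene universe")
  expect_error(simulate_cohort(small_truth(), n_samples = 50, seed = 1),
               ">= 100")
})

test_that("cohorts carry the planted rescued-state inflation", {
  tr <- small_truth(inflation = 2)
  co <- simulate_cohort(tr, n_samples = 1000, n_genes = 120, seed = 7)
  ct <- co$clinical$cancer_type
  am <- call_activity(co$mrna, ct)
  for (i in seq_len(nrow(tr$pairs))) {
    v <- tr$pairs$vulnerable[i]; r <- tr$pairs$rescuer[i]
    st <- pair_states(am[v, ], am[r, ], tr$pairs$sr_type[i])
    f_res <- mean(st == "rescued")
    r_state <- if (tr$pairs$sr_type[i] == "DU") 1L else -1L
    f_expected <- mean(am[v, ] == -1L) * mean(am[r, ] == r_state) * 2
    expect_lt(abs(f_res / f_expected - 1), 0.2)
  }
})

test_that("planted survival effects vanish when beta1 is zero", {
  tr0 <- small_truth(beta1 = 0)
  ps <- vapply(1:40, function(s) {
    co <- simulate_cohort(tr0, n_samples = 200, n_genes = 120, seed = 500 + s)
    v <- tr0$pairs$vulnerable[1]; r <- tr0$pairs$rescuer[1]
    st <- pair_states(co$states[v, ], co$states[r, ], "DU")
    sd <- survival::survdiff(
      survival::Surv(co$clinical$time_days, co$clinical$event) ~
        I(st == "rescued"))
    sd$pvalue
  }, numeric(1))
  expect_gt(mean(ps), 0.3)           # no systematic survival difference
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("panels plant the conditional-essentiality slope", {
  tr <- small_truth(essentiality_effect = 1)
  pan <- simulate_screen_panel(tr, n_cell_lines = 100, n_genes = 120,
                               seed = 9)
  ymat <- synrescue:::readout_matrix(pan$readouts)
  v <- tr$pairs$vulnerable[1]; r <- tr$pairs$rescuer[1]
  g <- unclass(pan$mrna)[r, colnames(ymat)]
  slope <- unname(coef(lm(ymat[v, ] ~ scale(g)))[2])
  expect_lt(abs(slope - 1), 0.35)
  # a non-planted readout shows no association
  null_slope <- unname(coef(lm(ymat["g0119", ] ~ scale(g)))[2])
  expect_lt(abs(null_slope), 0.35)
})

test_that("planted pairs dominate phylogenetic similarity", {
  tr <- small_truth()
  prof <- simulate_phylo_profiles(tr, n_genes = 120, seed = 10)
  W <- nmf_membership(prof, k = 10, seed = 1)
  planted_d <- vapply(seq_len(nrow(tr$pairs)), function(i) {
    phylo_distance(W, tr$pairs$vulnerable[i], tr$pairs$rescuer[i])
  }, numeric(1))
  set.seed(11)
  random_d <- vapply(1:300, function(i) {
    g <- sample(rownames(W), 2)
    phylo_distance(W, g[1], g[2])
  }, numeric(1))
  expect_lt(max(planted_d), quantile(random_d, 0.05))
  expect_gt(median(random_d), 0.2)   # independent genes concentrate away
})

test_that("bundles write to disk in the formats the readers accept", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  write_sr_bundle(b, dir)
  m <- read_gene_matrix(file.path(dir, "mrna.tsv"), "mRNA")
  expect_equal(dim(m), dim(b$cohort$mrna))
  expect_equal(unclass(m), unclass(b$cohort$mrna), tolerance = 1e-6)
  cl <- read_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(nrow(cl), nrow(b$cohort$clinical))
  pan <- read_screen_panel(file.path(dir, "panel.tsv"),
                           mrna = read_gene_matrix(
                             file.path(dir, "panel_mrna.tsv"), "mRNA"))
  expect_equal(nrow(pan$readouts), nrow(b$panel$readouts))
  prof <- read_phylo_profiles(file.path(dir, "phylo_profiles.tsv"))
  expect_equal(dim(prof), dim(b$profiles))
})
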