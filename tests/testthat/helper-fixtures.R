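# Shared fixtures, built in code. The small bundle is memoized so several
# test files can reuse it without regenerating.

tiny_gene_matrix <- function(modality = "mRNA", n_genes = 3, n_samples = 4,
                             seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  gene_matrix(m, modality)
}

small_truth <- function(n_du = 4, n_dd = 2, n_genes = 120, ...) {
  n <- n_du + n_dd
  planted_truth(tibble::tibble(
    vulnerable = sprintf("g%04d", seq_len(n)),
    rescuer = sprintf("g%04d", n + seq_len(n)),
    sr_type = rep(c("DU", "DD"), c(n_du, n_dd))), ...)
}

.fixture_env <- new.env(parent = emptyenv())

small_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- simulate_sr_bundle(
      n_samples = 400L, n_genes = 120L, n_cell_lines = 60L,
      n_du = 4L, n_dd = 2L, n_candidates = 200L, seed = 42L)
  }
  .fixture_env$bundle
}

# simple survival simulator for parameter-recovery and null-calibration
# tests: one binary indicator, optional strata with distinct baselines
simulate_survival <- function(n, beta1, n_strata = 3, censor_frac = 0.3,
                              prevalence = 0.2, seed = 1) {
  set.seed(seed)
  strat <- sample(paste0("st", seq_len(n_strata)), n, replace = TRUE)
  rate0 <- log(2) / 500 * exp(seq(-0.5, 0.5,
                                  length.out = n_strata))[as.integer(
                                    factor(strat))]
  ind <- rbinom(n, 1, prevalence)
  rate <- rate0 * exp(beta1 * ind)
  e1 <- rexp(n); e2 <- rexp(n)
  k <- censor_frac / (1 - censor_frac)
  tibble::tibble(
    sample_id = sprintf("s%05d", seq_len(n)),
    time_days = pmin(e1, e2 / k) / rate,
    event = as.integer(e1 <= e2 / k),
    age = rnorm(n, 60, 10),
    sex = sample(c("F", "M"), n, TRUE),
    race = "all",
    cancer_type = strat,
    tumor_purity = rbeta(n, 5, 2),
    gii = runif(n, 0, 0.4),
    ind = ind)
}
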