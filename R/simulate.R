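#' Declare planted synthetic-rescue truth for the simulators
#'
#' Bundles the list of planted vulnerable-rescuer pairs with the effect
#' sizes every generator uses: the joint-state inflation factor of the
#' rescued state in tumor cohorts, the log hazard ratio attached to the
#' rescued state (its negative to the non-rescued state), the essentiality
#' shift planted in cell-line panels (slope of knockdown fitness on the
#' partner's standardized expression), and the profile similarity of
#' planted pairs in the phylogenetic matrix. Genes may appear in at most
#' one planted pair so the planted effects stay independent.
#'
#' @param pairs tibble with columns `vulnerable`, `rescuer`, `sr_type`
#'   (`"DU"`/`"DD"`).
#' @param inflation rescued-state joint-frequency inflation over
#'   independence (default 2; feasible range (0, 3\]).
#' @param beta1 planted log hazard ratio of the rescued state (default
#'   0.7).
#' @param essentiality_effect planted in-vitro slope in readout SD units
#'   (default 1).
#' @param profile_noise relative noise on a planted rescuer's profile
#'   versus its partner's (default 0.05; smaller = more similar).
#' @return A `planted_truth` object.
#' @export
planted_truth <- function(pairs, inflation = 2, beta1 = 0.7,
                          essentiality_effect = 1, profile_noise = 0.05) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("vulnerable", "rescuer", "sr_type") %in% names(pairs)),
            all(pairs$sr_type %in% c("DU", "DD")))
  genes <- c(pairs$vulnerable, pairs$rescuer)
  if (anyDuplicated(genes)) {
    stop("planted genes must be distinct across pairs")
  }
  if (inflation <= 0) stop("inflation must be positive")
  delta <- inflation / 9 - 1 / 9
  if (delta / 2 > 1 / 9 + 1e-12) {
    stop("infeasible inflation: rescued-state frequency would exceed what ",
         "tertile marginals allow (max 3)")
  }
  structure(list(pairs = pairs, inflation = inflation, beta1 = beta1,
                 essentiality_effect = essentiality_effect,
                 profile_noise = profile_noise),
            class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf(paste0("<planted_truth> %d pairs (%d DU, %d DD); inflation ",
                     "%.2g, beta1 %.2g, essentiality %.2g\n"),
              nrow(x$pairs), sum(x$pairs$sr_type == "DU"),
              sum(x$pairs$sr_type == "DD"), x$inflation, x$beta1,
              x$essentiality_effect))
  invisible(x)
}

# 3x3 joint state table over (V, R) in {-1,0,1} with uniform tertile
# marginals and the rescued cell inflated by `inflation`; mass is moved
# within rows/columns so both marginals stay exactly 1/3.
joint_state_table <- function(inflation, sr_type) {
  p <- matrix(1 / 9, 3, 3, dimnames = list(V = c("-1", "0", "1"),
                                           R = c("-1", "0", "1")))
  res_col <- if (sr_type == "DU") "1" else "-1"
  oth_col <- setdiff(colnames(p), res_col)
  d <- inflation / 9 - 1 / 9
  p["-1", res_col] <- p["-1", res_col] + d
  p["-1", oth_col] <- p["-1", oth_col] - d / 2
  p[c("0", "1"), res_col] <- p[c("0", "1"), res_col] - d / 2
  p[c("0", "1"), oth_col] <- p[c("0", "1"), oth_col] + d / 4
  if (any(p < -1e-12)) stop("infeasible inflation")
  pmax(p, 0)
}

# Uniform draw inside the tertile interval of a state in {-1,0,1}.
tertile_uniform <- function(state) {
  lo <- c(`-1` = 0, `0` = 1 / 3, `1` = 2 / 3)[as.character(state)]
  stats::runif(length(state), lo, lo + 1 / 3)
}

#' Simulate a tumor cohort with planted rescue structure
#'
#' Generates per-cancer-type location-shifted mRNA and SCNA matrices, a
#' clinical table, and survival that carries the planted effects. For
#' planted pairs, per-sample joint activity states are drawn from a
#' marginal-preserving table whose rescued cell is inflated by
#' `truth$inflation`; values are then sampled from the matching tertile of
#' the cancer type's distribution in both modalities, so enrichment shows
#' in mRNA and SCNA alike. Survival times are exponential per cancer-type
#' stratum with log hazard shifted by `+beta1` per rescued pair state and
#' `-beta1` per non-rescued pair state; when several pairs are planted at
#' once, the shared conditional coefficient is calibrated internally so
#' that a reference pair's observable marginal rescued-state log
#' hazard-ratio equals `beta1` despite the frailty contributed by the
#' other pairs (Cox effects are non-collapsible). Censoring is independent
#' with 30% expected rate. Age, sex, race and purity come from simple documented
#' distributions; the genomic instability index is computed from the
#' simulated SCNA.
#'
#' @param truth a [planted_truth()].
#' @param n_samples cohort size (>= 100; default 1000).
#' @param n_genes gene count (default 500); planted genes must be among
#'   `paste0("g", 1:n_genes)` formatted names (see [simulate_sr_bundle()]).
#' @param n_cancer_types number of cancer types (default 3).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param scna_cor latent correlation between expression and copy number
#'   for unplanted genes (default 0.5).
#' @return List with `mrna`, `scna` ([gene_matrix()]), `clinical`
#'   (tibble), and `states` (latent planted states, genes x samples).
#' @export
simulate_cohort <- function(truth, n_samples = 1000L, n_genes = 500L,
                            n_cancer_types = 3L, seed = 1L,
                            scna_cor = 0.5) {
  if (n_samples < 100L) stop("n_samples must be >= 100")
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  genes <- gene_names(n_genes)
  miss <- setdiff(c(truth$pairs$vulnerable, truth$pairs$rescuer), genes)
  if (length(miss)) stop("planted genes outside the gene universe: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  samples <- sprintf("s%05d", seq_len(n_samples))
  cts <- paste0("ct", seq_len(n_cancer_types))
  ct <- sample(cts, n_samples, replace = TRUE)

  mu_e <- matrix(stats::rnorm(n_genes * n_cancer_types, 0, 0.5),
                 n_genes, n_cancer_types, dimnames = list(genes, cts))
  mu_s <- matrix(stats::rnorm(n_genes * n_cancer_types, 0, 0.2),
                 n_genes, n_cancer_types, dimnames = list(genes, cts))

  # latent tertile positions; planted pairs draw their joint state from
  # the inflated table through a shared per-sample "selection pressure"
  # latent: samples with high pressure sit in the rescued state of every
  # planted pair, samples with low pressure in the non-rescued states.
  # Sharing one latent couples the pairs' states, which keeps each pair's
  # survival contrast free of frailty noise from the other planted pairs
  # (the values drawn within a tertile stay independent per gene, so
  # called states and screen statistics still vary by pair).
  u_e <- matrix(stats::runif(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(genes, samples))
  states <- matrix(NA_integer_, n_genes, n_samples,
                   dimnames = list(genes, samples))
  u_sel <- stats::runif(n_samples)
  for (i in seq_len(nrow(truth$pairs))) {
    v <- truth$pairs$vulnerable[i]; r <- truth$pairs$rescuer[i]
    sr_type <- truth$pairs$sr_type[i]
    tab <- joint_state_table(truth$inflation, sr_type)
    lv <- c(-1L, 0L, 1L)
    cells <- expand.grid(V = lv, R = lv)
    cells$p <- mapply(function(a, b) tab[as.character(a), as.character(b)],
                      cells$V, cells$R)
    r_rescue <- if (sr_type == "DU") 1L else -1L
    tendency <- ifelse(cells$V == -1L & cells$R == r_rescue, 2L,
                       ifelse(cells$V == -1L, 0L, 1L))
    cells <- cells[order(tendency), ]
    cell <- findInterval(u_sel, cumsum(cells$p), left.open = TRUE) + 1L
    sv <- cells$V[cell]
    sr <- cells$R[cell]
    states[v, ] <- sv
    states[r, ] <- sr
    u_e[v, ] <- tertile_uniform(sv)
    u_e[r, ] <- tertile_uniform(sr)
  }

  z_e <- stats::qnorm(u_e)
  expr <- mu_e[, ct] + z_e
  # SCNA: same tertile state for planted genes (fresh position within the
  # tertile); correlated latent normal otherwise
  u_s <- matrix(stats::runif(n_genes * n_samples), n_genes, n_samples)
  z_s <- scna_cor * z_e + sqrt(1 - scna_cor^2) * stats::qnorm(u_s)
  planted <- which(!is.na(states[, 1L]))
  if (length(planted)) {
    z_s[planted, ] <- stats::qnorm(
      matrix(tertile_uniform(states[planted, ]), length(planted), n_samples))
  }
  scna <- mu_s[, ct] + 0.7 * z_s
  dimnames(expr) <- dimnames(scna) <- list(genes, samples)

  # survival: exponential per stratum; each planted pair shifts the log
  # hazard by +beta1 for its rescued state and -beta1 for its non-rescued
  # state. With many pairs planted in one cohort the other pairs act as an
  # unobserved frailty that attenuates every pair's *marginal* hazard
  # contrast (Cox non-collapsibility), so the shared conditional
  # coefficient is calibrated by an internal root-find until a reference
  # pair's observable rescued-state log hazard-ratio equals beta1 - the
  # condition the fixture is defined by. The calibration is a pure
  # function of the generator's own draws.
  shift_raw <- rep(0, n_samples)
  res_ind <- list()
  for (i in seq_len(nrow(truth$pairs))) {
    v <- truth$pairs$vulnerable[i]; r <- truth$pairs$rescuer[i]
    st <- pair_states(states[v, ], states[r, ], truth$pairs$sr_type[i])
    shift_raw <- shift_raw + (st == "rescued") - (st == "non_rescued")
    res_ind[[i]] <- st == "rescued"
  }
  ct_shift <- stats::setNames(seq(-0.4, 0.4, length.out = n_cancer_types),
                              cts)
  rate0 <- log(2) / 500 * exp(ct_shift[ct])
  e1 <- stats::rexp(n_samples)
  e2 <- stats::rexp(n_samples)
  event <- as.integer(e1 <= e2 * 7 / 3)  # ~30% independent censoring
  coef_use <- truth$beta1
  if (truth$beta1 != 0 && any(shift_raw != 0) && length(res_ind) > 1L) {
    refs <- res_ind[seq_len(min(3L, length(res_ind)))]
    marginal_gap <- function(cc) {
      tt <- pmin(e1, e2 * 7 / 3) / (rate0 * exp(cc * shift_raw))
      mean(vapply(refs, function(ind) {
        unname(stats::coef(suppressWarnings(survival::coxph(
          survival::Surv(tt, event) ~ ind))))
      }, numeric(1))) - truth$beta1
    }
    # search on the log scale: the contrast per unit coefficient depends
    # on how many coupled pairs share a sample's states; take the
    # coefficient whose marginal contrast is closest to beta1
    coef_use <- tryCatch(
      exp(stats::optimize(function(lc) abs(marginal_gap(exp(lc))),
                          log(truth$beta1) + c(-6, 2))$minimum),
      error = function(e) truth$beta1)
  }
  time <- pmin(e1, e2 * 7 / 3) / (rate0 * exp(coef_use * shift_raw))

  clinical <- tibble::tibble(
    sample_id = samples,
    time_days = pmax(time, 1e-3),
    event = event,
    age = stats::rnorm(n_samples, 60, 10),
    sex = sample(c("F", "M"), n_samples, replace = TRUE),
    race = sample(c("white", "black", "asian"), n_samples, replace = TRUE,
                  prob = c(0.7, 0.2, 0.1)),
    cancer_type = ct,
    tumor_purity = stats::rbeta(n_samples, 5, 2),
    gii = apply(scna, 2L, compute_gii))

  list(mrna = gene_matrix(expr, "mRNA"),
       scna = gene_matrix(scna, "SCNA"),
       clinical = clinical, states = states[planted, , drop = FALSE])
}

#' Simulate a cell-line perturbation panel with planted conditional
#' essentiality
#'
#' Every gene receives a knockdown fitness readout per cell line (higher =
#' more growth) made of a cancer-type random intercept (SD 0.5) and unit
#' noise. For a planted DU pair, the vulnerable gene's readout gains
#' `+effect` times the rescuer's standardized expression (knockdown
#' tolerated where the rescuer is high) and the rescuer's readout gains
#' `+effect` times the vulnerable gene's standardized expression (rescuer
#' knockdown lethal where the vulnerable gene is low). For DD pairs the
#' vulnerable readout's slope on the rescuer is negative instead.
#'
#' @param truth a [planted_truth()].
#' @param n_cell_lines number of cell lines (>= 30; default 100).
#' @param n_genes gene universe size (default 500).
#' @param n_cancer_types cancer types among cell lines (default 3).
#' @param seed integer seed.
#' @param scna_cor expression/copy-number latent correlation (default 0.5).
#' @return A [screen_panel()].
#' @export
simulate_screen_panel <- function(truth, n_cell_lines = 100L,
                                  n_genes = 500L, n_cancer_types = 3L,
                                  seed = 1L, scna_cor = 0.5) {
  if (n_cell_lines < 30L) stop("n_cell_lines must be >= 30")
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  genes <- gene_names(n_genes)
  lines <- sprintf("cl%04d", seq_len(n_cell_lines))
  cts <- paste0("ct", seq_len(n_cancer_types))
  ct <- sample(cts, n_cell_lines, replace = TRUE)

  mu_e <- matrix(stats::rnorm(n_genes * n_cancer_types, 0, 0.5),
                 n_genes, n_cancer_types, dimnames = list(genes, cts))
  z_e <- matrix(stats::rnorm(n_genes * n_cell_lines), n_genes, n_cell_lines)
  expr <- mu_e[, ct] + z_e
  z_s <- scna_cor * z_e + sqrt(1 - scna_cor^2) *
    matrix(stats::rnorm(n_genes * n_cell_lines), n_genes, n_cell_lines)
  scna <- 0.7 * z_s
  dimnames(expr) <- dimnames(scna) <- list(genes, lines)

  a_ct <- stats::setNames(stats::rnorm(n_cancer_types, 0, 0.5), cts)
  y <- matrix(stats::rnorm(n_genes * n_cell_lines), n_genes, n_cell_lines,
              dimnames = list(genes, lines))
  y <- sweep(y, 2L, a_ct[ct], "+")
  stdz <- function(x) (x - mean(x)) / stats::sd(x)
  eff <- truth$essentiality_effect
  for (i in seq_len(nrow(truth$pairs))) {
    v <- truth$pairs$vulnerable[i]; r <- truth$pairs$rescuer[i]
    s1 <- if (truth$pairs$sr_type[i] == "DU") 1 else -1
    y[v, ] <- y[v, ] + s1 * eff * stdz(expr[r, ])
    if (truth$pairs$sr_type[i] == "DU") {
      y[r, ] <- y[r, ] + eff * stdz(expr[v, ])
    }
  }
  readouts <- tibble::tibble(
    cell_line = rep(lines, each = n_genes),
    cancer_type = rep(ct, each = n_genes),
    perturbed_gene = rep(genes, n_cell_lines),
    readout_kind = "shRNA_essentiality",
    value = as.vector(y))
  screen_panel(readouts, mrna = gene_matrix(expr, "mRNA"),
               scna = gene_matrix(scna, "SCNA"))
}

#' Simulate co-evolving phylogenetic profiles
#'
#' Background genes follow a block model: each gene draws one dominant
#' conservation module (of `n_blocks`) whose species signature it carries,
#' plus non-negative noise. A planted rescuer copies its partner's profile
#' with relative noise `truth$profile_noise`, so planted pairs sit among
#' the most similar pairs of the universe.
#'
#' @param truth a [planted_truth()].
#' @param n_genes gene universe size (default 500).
#' @param n_species species count (default 87).
#' @param n_blocks number of conservation modules (default 10).
#' @param seed integer seed.
#' @return Non-negative genes x species matrix.
#' @export
simulate_phylo_profiles <- function(truth, n_genes = 500L, n_species = 87L,
                                    n_blocks = 10L, seed = 1L) {
  if (n_species < 10L) stop("n_species must be >= 10")
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  genes <- gene_names(n_genes)
  H <- matrix(stats::rgamma(n_blocks * n_species, shape = 0.5, rate = 0.5),
              n_blocks, n_species)
  block <- sample.int(n_blocks, n_genes, replace = TRUE)
  W <- matrix(stats::runif(n_genes * n_blocks, 0, 0.05), n_genes, n_blocks)
  W[cbind(seq_len(n_genes), block)] <- stats::runif(n_genes, 0.8, 1.2)
  A <- W %*% H +
    matrix(stats::rgamma(n_genes * n_species, 0.3, 1), n_genes, n_species)
  rownames(A) <- genes
  for (i in seq_len(nrow(truth$pairs))) {
    v <- truth$pairs$vulnerable[i]; r <- truth$pairs$rescuer[i]
    noise <- matrix(stats::rnorm(n_species, 0, truth$profile_noise),
                    1L, n_species)
    A[r, ] <- pmax(A[v, ] * (1 + noise), 0)
  }
  A
}

#' Simulate sparse 1x5 dose-response grids
#'
#' Emulates the combination design of one primary-drug dose (five
#' replicates) against five doses of a rescuer inhibitor (two replicates,
#' fourfold dilution). Counts are Bliss-independent expectations divided by
#' the planted `synergy` level, under multiplicative lognormal noise.
#'
#' @param n_grids number of (cell line, inhibitor) grids.
#' @param synergy planted synergism level: 1 = exact Bliss independence,
#'   >1 synergy, <1 antagonism.
#' @param seed integer seed.
#' @param noise_cv multiplicative coefficient of variation (default 0.05).
#' @param base_count untreated cell count (default 1000).
#' @return Long-format tibble accepted by [synergy_call()].
#' @export
simulate_dose_grids <- function(n_grids, synergy = 1, seed = 1L,
                                noise_cv = 0.05, base_count = 1000) {
  if (synergy <= 0) stop("synergy level must be > 0")
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  f_primary <- 0.5
  f_dose <- c(0.95, 0.85, 0.7, 0.5, 0.3)  # fourfold dilution series
  sdlog <- sqrt(log(1 + noise_cv^2))
  noisy <- function(x) x * stats::rlnorm(length(x), -sdlog^2 / 2, sdlog)
  purrr::map_dfr(seq_len(n_grids), function(i) {
    cl <- sprintf("cl%04d", i); ri <- sprintf("R%04d", i)
    dplyr::bind_rows(
      tibble::tibble(condition = "untreated", dose_index = NA_integer_,
                     replicate = 1:5, cell_count = noisy(rep(base_count, 5))),
      tibble::tibble(condition = "primary", dose_index = NA_integer_,
                     replicate = 1:5,
                     cell_count = noisy(rep(base_count * f_primary, 5))),
      tibble::tibble(condition = "single",
                     dose_index = rep(1:5, each = 2L), replicate = rep(1:2, 5),
                     cell_count = noisy(base_count *
                                          rep(f_dose, each = 2L))),
      tibble::tibble(condition = "combo",
                     dose_index = rep(1:5, each = 2L), replicate = rep(1:2, 5),
                     cell_count = noisy(base_count * f_primary *
                                          rep(f_dose, each = 2L) / synergy))
    ) |>
      dplyr::mutate(cell_line = cl, primary_drug = "primaryA",
                    rescuer_inhibitor = ri, .before = 1L)
  })
}

gene_names <- function(n_genes) sprintf("g%04d", seq_len(n_genes))

#' Simulate a complete desk-scale rescue-inference bundle
#'
#' Builds the default fixture the pipeline is exercised on: a tumor cohort
#' (1,000 samples, 500 genes, 3 cancer types), one cell-line panel, a
#' phylogenetic-profile matrix, 20 planted DU and 10 planted DD pairs, and
#' a candidate list of `n_candidates` ordered pairs containing the planted
#' DU pairs among random decoys (the DD pairs are included as decoys for
#' the DU run, and vice versa via `candidates_dd`).
#'
#' @param n_samples,n_genes,n_cancer_types cohort dimensions.
#' @param n_cell_lines panel size (default 100).
#' @param n_du,n_dd planted pair counts (defaults 20 and 10).
#' @param n_candidates candidate pairs per mode (default 5000).
#' @param seed integer seed driving every generator.
#' @param ... effect-size overrides passed to [planted_truth()].
#' @return List with `truth`, `cohort` (list mrna/scna/clinical), `panel`,
#'   `profiles`, `candidates` (DU mode) and `candidates_dd`.
#' @export
simulate_sr_bundle <- function(n_samples = 1000L, n_genes = 500L,
                               n_cancer_types = 3L, n_cell_lines = 100L,
                               n_du = 20L, n_dd = 10L,
                               n_candidates = 5000L, seed = 1L, ...) {
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  genes <- gene_names(n_genes)
  picked <- sample(genes, 2L * (n_du + n_dd))
  pairs <- tibble::tibble(
    vulnerable = picked[seq_len(n_du + n_dd)],
    rescuer = picked[n_du + n_dd + seq_len(n_du + n_dd)],
    sr_type = rep(c("DU", "DD"), c(n_du, n_dd)))
  truth <- planted_truth(pairs, ...)

  make_candidates <- function(planted) {
    n_decoy <- n_candidates - nrow(planted)
    decoys <- tibble::tibble(
      vulnerable = sample(genes, 3L * n_decoy, replace = TRUE),
      rescuer = sample(genes, 3L * n_decoy, replace = TRUE))
    decoys <- decoys[decoys$vulnerable != decoys$rescuer, ]
    decoys <- dplyr::anti_join(dplyr::distinct(decoys), pairs,
                               by = c("vulnerable", "rescuer"))
    dplyr::bind_rows(planted[, c("vulnerable", "rescuer")],
                     decoys[seq_len(n_decoy), ])
  }
  cand_du <- make_candidates(pairs[pairs$sr_type == "DU", ])
  cand_dd <- make_candidates(pairs[pairs$sr_type == "DD", ])

  cohort <- simulate_cohort(truth, n_samples = n_samples, n_genes = n_genes,
                            n_cancer_types = n_cancer_types, seed = seed + 1L)
  panel <- simulate_screen_panel(truth, n_cell_lines = n_cell_lines,
                                 n_genes = n_genes,
                                 n_cancer_types = n_cancer_types,
                                 seed = seed + 2L)
  profiles <- simulate_phylo_profiles(truth, n_genes = n_genes,
                                      seed = seed + 3L)
  list(truth = truth,
       cohort = cohort[c("mrna", "scna", "clinical")],
       panel = panel, profiles = profiles,
       candidates = cand_du, candidates_dd = cand_dd)
}

#' Write a simulated bundle to disk in the pipeline's input formats
#'
#' @param bundle from [simulate_sr_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sr_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_matrix(bundle$cohort$mrna, file.path(dir, "mrna.tsv"))
  write_gene_matrix(bundle$cohort$scna, file.path(dir, "scna.tsv"))
  utils::write.table(bundle$cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$panel$readouts, file.path(dir, "panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_matrix(bundle$panel$mrna, file.path(dir, "panel_mrna.tsv"))
  write_gene_matrix(bundle$panel$scna, file.path(dir, "panel_scna.tsv"))
  df <- data.frame(gene = rownames(bundle$profiles), bundle$profiles,
                   check.names = FALSE)
  utils::write.table(df, file.path(dir, "phylo_profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$pairs, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$candidates, file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
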