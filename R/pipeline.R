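#' Benjamini-Hochberg q-values
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`; `NA` entries
#' propagate and are excluded from the correction denominator.
#'
#' @param pvals numeric vector of p-values.
#' @return q-values, elementwise >= the input p-values.
#' @export
bh_fdr <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' Rank-normalize significance values to \[0, 1\]
#'
#' Maps the smallest p-value to 0 (strongest evidence) and the largest to
#' 1, linearly in rank with ties receiving the average rank. A single value
#' maps to 0 (best by definition). `NA`s stay `NA`.
#'
#' @param pvals numeric vector over all pairs tested in one screen.
#' @return Vector in \[0, 1\].
#' @export
rank_normalize <- function(pvals) {
  ok <- !is.na(pvals)
  v <- pvals[ok]
  if (!length(v)) return(pvals)
  out <- rep(NA_real_, length(pvals))
  out[ok] <- if (length(v) == 1L) 0 else
    (rank(v, ties.method = "average") - 1) / (length(v) - 1)
  out
}

#' Interaction score of a candidate pair
#'
#' Sum of the four rank-normalized per-screen significance values,
#' `r1 + r2 + r3 + r4`, ranging over \[0, 4\] with lower = stronger
#' synthetic-rescue evidence.
#'
#' @param r1,r2,r3,r4 rank-normalized screen values in \[0, 1\] (vectors
#'   recycle elementwise).
#' @return Numeric score(s) in \[0, 4\].
#' @export
interaction_score <- function(r1, r2, r3, r4) {
  rs <- cbind(r1, r2, r3, r4)
  if (any(rs < 0 | rs > 1, na.rm = TRUE)) {
    stop("rank-normalized inputs must lie in [0, 1]")
  }
  drop(rowSums(rs))
}

new_sr_network <- function(edges, audit, config) {
  structure(list(edges = tibble::as_tibble(edges), audit = audit,
                 config = config), class = "sr_network")
}

#' @export
print.sr_network <- function(x, ...) {
  cat(sprintf("<sr_network> %s: %d edges over %d genes\n",
              x$config$sr_type, nrow(x$edges),
              length(unique(c(x$edges$vulnerable, x$edges$rescuer)))))
  f <- x$audit$funnel
  if (!is.null(f)) {
    cat("  funnel:", paste(names(f), unlist(f), sep = "=", collapse = " -> "),
        "\n")
  }
  invisible(x)
}

#' @rdname run_sr_screen
#' @param x an `sr_network`.
#' @param ... unused.
#' @method tidy sr_network
#' @export
tidy.sr_network <- function(x, ...) x$edges

#' @rdname run_sr_screen
#' @method glance sr_network
#' @export
glance.sr_network <- function(x, ...) {
  tibble::tibble(sr_type = x$config$sr_type, mode = x$config$mode,
                 n_edges = nrow(x$edges),
                 n_genes = length(unique(c(x$edges$vulnerable,
                                           x$edges$rescuer))),
                 n_candidates = x$audit$funnel$candidates,
                 seed = x$config$seed)
}

#' Run the full synthetic-rescue screen
#'
#' Applies the four screens sequentially - (1) in-vitro conditional
#' essentiality, (2) tumor survival-of-the-fittest, (3) clinical survival,
#' (4) phylogenetic similarity - each consuming the survivors of the
#' previous one, and assembles the surviving pairs into a directed
#' vulnerable-to-rescuer network scored with [interaction_score()]. In
#' `mode = "ICB"` (immune-checkpoint targets, for which in-vitro panels
#' lack the immune context) step 1 is omitted and the score is rescaled by
#' 4/3 to stay on \[0, 4\].
#'
#' Pairs eliminated before a screen carry that screen's worst rank value
#' (1) in the audit table, so interaction scores remain comparable across
#' the funnel; final network edges were tested by every configured screen.
#'
#' @param candidates tibble with columns `vulnerable`, `rescuer`.
#' @param cohort list with elements `mrna`, `scna` ([gene_matrix()]),
#'   `clinical` (tibble).
#' @param panels list of [screen_panel()] (ignored in ICB mode).
#' @param profiles non-negative genes x species phylogenetic matrix.
#' @param sr_type `"DU"` or `"DD"`.
#' @param mode `"standard"` or `"ICB"`.
#' @param fdr named thresholds for steps 1-3.
#' @param phylo_quantile step-4 retained fraction (default 0.05).
#' @param nmf_rank NMF rank for step 4 (default 20).
#' @param seed integer seed controlling every stochastic element.
#' @param min_state_samples minimum rescued-state size in step 3.
#' @return An `sr_network`: `tidy()` returns the edge list with per-screen
#'   q-values and scores, `glance()` a one-row summary; `$audit` holds the
#'   per-step tables and funnel counts.
#' @export
run_sr_screen <- function(candidates, cohort, panels = NULL, profiles,
                          sr_type = c("DU", "DD"),
                          mode = c("standard", "ICB"),
                          fdr = c(invitro = 0.2, sof = 0.05, clinical = 0.05),
                          phylo_quantile = 0.05, nmf_rank = 20L, seed = 1L,
                          min_state_samples = 10L) {
  sr_type <- match.arg(sr_type)
  mode <- match.arg(mode)
  if (mode == "standard" && (is.null(panels) || !length(panels))) {
    stop("standard mode requires at least one screen panel")
  }
  for (el in c("mrna", "scna", "clinical")) {
    if (is.null(cohort[[el]])) stop("cohort is missing element '", el, "'")
  }
  candidates <- dplyr::distinct(tibble::as_tibble(candidates),
                                .data$vulnerable, .data$rescuer)
  n0 <- nrow(candidates)
  ct <- cohort$clinical$cancer_type[match(colnames(cohort$mrna),
                                          cohort$clinical$sample_id)]
  act_mrna <- call_activity(cohort$mrna, ct)
  act_scna <- call_activity(cohort$scna, ct)

  audit <- candidates
  audit$r1 <- 1; audit$r2 <- 1; audit$r3 <- 1; audit$r4 <- 1
  key <- function(df) paste(df$vulnerable, df$rescuer, sep = "\r")

  # -- step 1: in-vitro conditional essentiality ---------------------------
  if (mode == "standard") {
    s1 <- screen_invitro(panels, candidates, sr_type = sr_type,
                         fdr = fdr[["invitro"]])
    p1 <- pmin(s1$p_mRNA, s1$p_SCNA, na.rm = TRUE)
    p1[is.na(s1$p_mRNA) & is.na(s1$p_SCNA)] <- NA
    audit$r1[match(key(s1), key(audit))] <- rank_normalize(p1)
    audit$r1[is.na(audit$r1)] <- 1
    surv1 <- s1[s1$pass, c("vulnerable", "rescuer")]
  } else {
    s1 <- NULL
    surv1 <- candidates
  }

  # -- step 2: survival of the fittest -------------------------------------
  s2 <- screen_sof(act_mrna, act_scna, surv1, sr_type = sr_type,
                   fdr = fdr[["sof"]])
  if (nrow(s2)) {
    p2 <- pmax(s2$p_enrich_mRNA, s2$p_deplete_mRNA,
               s2$p_enrich_SCNA, s2$p_deplete_SCNA)
    audit$r2[match(key(s2), key(audit))] <- rank_normalize(p2)
    audit$r2[is.na(audit$r2)] <- 1
    surv2 <- s2[s2$pass, c("vulnerable", "rescuer")]
  } else {
    surv2 <- s2[, c("vulnerable", "rescuer")]
  }

  # -- step 3: clinical survival -------------------------------------------
  s3 <- screen_clinical(act_mrna, act_scna, cohort$mrna, cohort$scna,
                        cohort$clinical, surv2, sr_type = sr_type,
                        fdr = fdr[["clinical"]],
                        min_state_samples = min_state_samples)
  if (nrow(s3)) {
    p3 <- pmax(s3$p_res_mRNA, s3$p_non_mRNA, s3$p_res_SCNA, s3$p_non_SCNA)
    audit$r3[match(key(s3), key(audit))] <- rank_normalize(p3)
    audit$r3[is.na(audit$r3)] <- 1
    surv3 <- s3[s3$pass, c("vulnerable", "rescuer")]
  } else {
    surv3 <- s3[, c("vulnerable", "rescuer")]
  }

  # -- step 4: phylogenetic similarity -------------------------------------
  s4 <- screen_phylo(profiles, surv3, quantile = phylo_quantile,
                     k = nmf_rank, seed = seed)
  if (nrow(s4)) {
    audit$r4[match(key(s4), key(audit))] <- rank_normalize(s4$distance)
    audit$r4[is.na(audit$r4)] <- 1
    surv4 <- s4[s4$pass, c("vulnerable", "rescuer")]
  } else {
    surv4 <- s4[, c("vulnerable", "rescuer")]
  }

  audit$interaction_score <- if (mode == "ICB") {
    (audit$r2 + audit$r3 + audit$r4) * 4 / 3
  } else {
    interaction_score(audit$r1, audit$r2, audit$r3, audit$r4)
  }
  edges <- dplyr::left_join(surv4,
                            audit[, c("vulnerable", "rescuer",
                                      "interaction_score")],
                            by = c("vulnerable", "rescuer"))
  edges$sr_type <- sr_type
  funnel <- list(candidates = n0, step1 = nrow(surv1), step2 = nrow(surv2),
                 step3 = nrow(surv3), step4 = nrow(surv4))
  new_sr_network(edges,
                 audit = list(pairs = audit, step1 = s1, step2 = s2,
                              step3 = s3, step4 = s4, funnel = funnel),
                 config = list(sr_type = sr_type, mode = mode, fdr = fdr,
                               phylo_quantile = phylo_quantile,
                               nmf_rank = nmf_rank, seed = seed))
}

#' Write a network edge list to TSV
#'
#' @param network an `sr_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Degree-preserving shuffle of a rescue network
#'
#' Permutes the rescuer endpoints across edges while keeping every node's
#' degree, avoiding self-pairs and edges already present in the input.
#' Deterministic for a fixed seed.
#'
#' @param network an `sr_network` or an edge tibble with `vulnerable`,
#'   `rescuer`.
#' @param seed integer seed.
#' @param max_tries rejection-sampling retries (default 1000).
#' @return A shuffled `sr_network`.
#' @export
shuffle_network <- function(network, seed = 1L, max_tries = 1000L) {
  edges <- if (inherits(network, "sr_network")) network$edges else
    tibble::as_tibble(network)
  if (nrow(edges) < 2L) stop("need at least 2 edges to shuffle")
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  orig <- paste(edges$vulnerable, edges$rescuer, sep = "\r")
  for (i in seq_len(max_tries)) {
    perm <- sample.int(nrow(edges))
    newr <- edges$rescuer[perm]
    cand <- paste(edges$vulnerable, newr, sep = "\r")
    if (any(edges$vulnerable == newr) || any(cand %in% orig) ||
        anyDuplicated(cand)) next
    out <- edges
    out$rescuer <- newr
    cfg <- if (inherits(network, "sr_network")) network$config else list()
    cfg$shuffled <- TRUE
    return(new_sr_network(out, audit = list(), config = cfg))
  }
  stop("no valid degree-preserving shuffle found after ", max_tries,
       " tries")
}

#' Random degree-matched control network
#'
#' Relabels the network's genes with genes drawn at random (without
#' replacement) from a larger universe, preserving the degree sequence
#' exactly while decoupling the pairing from any real structure.
#'
#' @param network an `sr_network` or edge tibble.
#' @param gene_universe character vector of available gene names.
#' @param seed integer seed.
#' @return A control `sr_network` with the same edge count.
#' @export
random_degree_matched_network <- function(network, gene_universe, seed = 1L) {
  edges <- if (inherits(network, "sr_network")) network$edges else
    tibble::as_tibble(network)
  genes <- unique(c(edges$vulnerable, edges$rescuer))
  if (length(gene_universe) <= length(genes)) {
    stop("gene universe must be larger than the network's gene set")
  }
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  relabel <- sample(gene_universe, length(genes))
  names(relabel) <- genes
  out <- edges
  out$vulnerable <- unname(relabel[edges$vulnerable])
  out$rescuer <- unname(relabel[edges$rescuer])
  cfg <- if (inherits(network, "sr_network")) network$config else list()
  cfg$control <- "random_degree_matched"
  new_sr_network(out, audit = list(), config = cfg)
}
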