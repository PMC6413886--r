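#' Hypergeometric tail probability for state co-occurrence
#'
#' Tests the overlap `k` between two sample sets of sizes `n1` (rescuer in
#' its rescuing state) and `n2` (vulnerable gene underactive) out of `N`
#' samples. `tail = "enrich"` returns `P(X >= k)`, `tail = "deplete"`
#' returns `P(X <= k)`, with `X ~ hypergeometric(N, n1, n2)`.
#'
#' @param k overlap count.
#' @param n1,n2 marginal counts.
#' @param N total sample count.
#' @param tail `"enrich"` or `"deplete"`.
#' @return The tail probability.
#' @examples
#' hypergeom_tail(4, 4, 10, 5, "enrich") # 6/252
#' @export
hypergeom_tail <- function(k, n1, N, n2, tail = c("enrich", "deplete")) {
  tail <- match.arg(tail)
  if (k < 0 || n1 < 0 || n2 < 0 || k > min(n1, n2) || n1 > N || n2 > N) {
    stop("inconsistent counts: need 0 <= k <= min(n1, n2) <= N")
  }
  if (tail == "enrich") {
    stats::phyper(k - 1L, n1, N - n1, n2, lower.tail = FALSE)
  } else {
    stats::phyper(k, n1, N - n1, n2, lower.tail = TRUE)
  }
}

#' Survival-of-the-fittest test for one pair (step 2 statistic)
#'
#' Given activity vectors of the vulnerable and rescuer genes in one
#' modality, builds the cohort-level contingency counts and returns two
#' one-tailed hypergeometric p-values: enrichment of the rescued state and
#' depletion of the non-rescued state. Positive selection of the rescued
#' state shows as a small value in both.
#'
#' @param act_v,act_r integer activity vectors in \{-1, 0, 1\}.
#' @param sr_type `"DU"` or `"DD"`.
#' @return One-row tibble with counts and the two p-values; degenerate
#'   marginals give p = 1 and `degenerate = TRUE`.
#' @export
sof_test_pair <- function(act_v, act_r, sr_type = c("DU", "DD")) {
  sr_type <- match.arg(sr_type)
  if (length(act_v) != length(act_r)) {
    stop("activity vectors must have equal length")
  }
  N <- length(act_v)
  r_rescue <- if (sr_type == "DU") 1L else -1L
  n2 <- sum(act_v == -1L)
  n1_res <- sum(act_r == r_rescue)
  n1_non <- N - n1_res
  k_res <- sum(act_v == -1L & act_r == r_rescue)
  k_non <- n2 - k_res
  degenerate <- n2 == 0L || n1_res == 0L || n1_res == N
  p_enrich <- if (degenerate) 1 else
    hypergeom_tail(k_res, n1_res, N, n2, "enrich")
  p_deplete <- if (degenerate) 1 else
    hypergeom_tail(k_non, n1_non, N, n2, "deplete")
  tibble::tibble(N = N, n_vdown = n2, n_rstate = n1_res,
                 k_rescued = k_res, k_nonrescued = k_non,
                 p_enrich_rescued = p_enrich,
                 p_deplete_nonrescued = p_deplete,
                 degenerate = degenerate)
}

#' Tumor survival-of-the-fittest screen (step 2)
#'
#' For each candidate pair, tests in both modalities (mRNA and SCNA) that
#' the rescued state is enriched and the non-rescued state depleted across
#' the cohort. Benjamini-Hochberg correction is applied separately within
#' each of the four test families (2 states x 2 modalities); a pair passes
#' only when all four q-values clear `fdr` (AND across states and
#' modalities).
#'
#' @param act_mrna,act_scna `activity_matrix` objects from [call_activity()]
#'   on the same samples. `act_scna` may be `NULL` only with
#'   `require_both = FALSE`, in which case the screen runs on mRNA alone
#'   with a warning.
#' @param candidates tibble with columns `vulnerable`, `rescuer`.
#' @param sr_type `"DU"` or `"DD"`.
#' @param fdr per-family Benjamini-Hochberg threshold (default 0.05).
#' @param require_both error when a modality is missing (default TRUE).
#' @return Tibble: per pair, the four p's and q's and `pass`.
#' @export
screen_sof <- function(act_mrna, act_scna, candidates,
                       sr_type = c("DU", "DD"), fdr = 0.05,
                       require_both = TRUE) {
  sr_type <- match.arg(sr_type)
  candidates <- tibble::as_tibble(candidates)
  if (is.null(act_scna)) {
    if (require_both) stop("SCNA activity matrix missing; step 2 needs both ",
                           "modalities (set require_both = FALSE to override)")
    warning("running survival-of-the-fittest screen on mRNA only")
  }
  if (ncol(act_mrna) < 30L) stop("need >= 30 samples")
  empty <- tibble::tibble(vulnerable = character(), rescuer = character(),
                          pass = logical())
  if (!nrow(candidates)) return(empty)

  one_modality <- function(act) {
    res <- purrr::map(seq_len(nrow(candidates)), function(i) {
      v <- candidates$vulnerable[i]; r <- candidates$rescuer[i]
      if (!(v %in% rownames(act)) || !(r %in% rownames(act))) {
        return(tibble::tibble(p_enrich_rescued = NA_real_,
                              p_deplete_nonrescued = NA_real_))
      }
      sof_test_pair(act[v, ], act[r, ], sr_type)[
        , c("p_enrich_rescued", "p_deplete_nonrescued")]
    })
    dplyr::bind_rows(res)
  }

  m <- one_modality(act_mrna)
  out <- tibble::tibble(vulnerable = candidates$vulnerable,
                        rescuer = candidates$rescuer,
                        p_enrich_mRNA = m$p_enrich_rescued,
                        p_deplete_mRNA = m$p_deplete_nonrescued)
  out$q_enrich_mRNA <- bh_fdr(out$p_enrich_mRNA)
  out$q_deplete_mRNA <- bh_fdr(out$p_deplete_mRNA)
  if (!is.null(act_scna)) {
    s <- one_modality(act_scna)
    out$p_enrich_SCNA <- s$p_enrich_rescued
    out$p_deplete_SCNA <- s$p_deplete_nonrescued
    out$q_enrich_SCNA <- bh_fdr(out$p_enrich_SCNA)
    out$q_deplete_SCNA <- bh_fdr(out$p_deplete_SCNA)
    qcols <- c("q_enrich_mRNA", "q_deplete_mRNA",
               "q_enrich_SCNA", "q_deplete_SCNA")
  } else {
    qcols <- c("q_enrich_mRNA", "q_deplete_mRNA")
  }
  qm <- as.matrix(out[, qcols])
  out$pass <- rowSums(is.na(qm)) == 0L & rowSums(qm < fdr) == length(qcols)
  out
}
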