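#' Read a phylogenetic-profile matrix
#'
#' Genes x species matrix of non-negative phylogenetic conservation scores
#' (e.g. normalized best-hit scores across divergent eukaryotes). Negative
#' entries are shifted to zero on load with a warning; all-zero gene rows
#' are dropped.
#'
#' @param path TSV, first column gene ids, header row species ids.
#' @return Numeric matrix, genes x species.
#' @export
read_phylo_profiles <- function(path) {
  gm <- read_gene_matrix(path, modality = "mRNA")
  m <- unclass(gm)
  attr(m, "modality") <- NULL
  class(m) <- NULL
  m[is.na(m)] <- 0
  if (any(m < 0)) {
    warning("negative profile scores shifted to zero")
    m[m < 0] <- 0
  }
  keep <- rowSums(m) > 0
  if (any(!keep)) m <- m[keep, , drop = FALSE]
  m
}

#' Non-negative matrix factorization memberships
#'
#' Factorizes a non-negative genes x species matrix as `A ~ W H` with
#' multiplicative Frobenius updates (Lee-Seung), returning the gene
#' membership factor `W` with rows L2-normalized. Deterministic for a fixed
#' seed (uniform random initialization).
#'
#' @param profiles non-negative numeric matrix (genes x species).
#' @param k factorization rank (default 20); must be < min(dim).
#' @param seed integer seed for the initialization.
#' @param max_iter,tol update iterations (default 500) and relative
#'   reconstruction-error tolerance (default 1e-6).
#' @return Genes x k membership matrix with unit-L2 rows.
#' @export
nmf_membership <- function(profiles, k = 20L, seed = 1L, max_iter = 500L,
                           tol = 1e-6) {
  A <- as.matrix(profiles)
  if (any(A < 0)) stop("profile matrix must be non-negative")
  if (k < 1L || k >= min(dim(A))) stop("rank k must satisfy 1 <= k < min(dim)")
  eps <- .Machine$double.eps
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  W <- matrix(stats::runif(nrow(A) * k, 0.1, 1), nrow(A), k)
  H <- matrix(stats::runif(k * ncol(A), 0.1, 1), k, ncol(A))
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, A) / (crossprod(W) %*% H + eps))
    W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10L == 0L) {
      err <- norm(A - W %*% H, "F") / max(norm(A, "F"), eps)
      if (is.finite(err_prev) && abs(err_prev - err) < tol) break
      err_prev <- err
    }
  }
  rn <- sqrt(rowSums(W^2))
  W <- W / pmax(rn, eps)
  rownames(W) <- rownames(A)
  W
}

#' Euclidean distance between two genes' NMF membership rows
#'
#' @param memberships matrix from [nmf_membership()].
#' @param gene_a,gene_b gene identifiers.
#' @return Non-negative distance; `NA` with a warning if either gene is
#'   absent from the membership matrix.
#' @export
phylo_distance <- function(memberships, gene_a, gene_b) {
  if (!(gene_a %in% rownames(memberships)) ||
      !(gene_b %in% rownames(memberships))) {
    warning("gene(s) missing from membership matrix: ",
            paste(setdiff(c(gene_a, gene_b), rownames(memberships)),
                  collapse = ", "))
    return(NA_real_)
  }
  sqrt(sum((memberships[gene_a, ] - memberships[gene_b, ])^2))
}

#' Phylogenetic-similarity screen (step 4)
#'
#' Keeps candidate pairs whose genes co-evolve: the Euclidean distance
#' between their NMF membership rows must fall below the empirical
#' `quantile` of distances among randomly paired genes from the same
#' profile universe (an empirical-FDR background). Optionally
#' (`cap_fraction`) the passing set is additionally capped at the
#' most-similar fraction of the candidates themselves, with ties broken by
#' stable candidate order; the cap is off by default because with a small,
#' already heavily filtered candidate set it would discard pairs that are
#' unambiguously co-evolving against the genome-wide background. Pairs
#' with a gene absent from the profile matrix fail the screen by default
#' (`missing_action = "fail"`).
#'
#' @param profiles non-negative genes x species matrix.
#' @param candidates tibble with `vulnerable`, `rescuer`.
#' @param quantile background quantile defining similarity (default 0.05).
#' @param k,seed NMF rank and seed (see [nmf_membership()]).
#' @param n_background number of random background pairs (default 10000).
#' @param cap_fraction optional top fraction of candidates retained in
#'   addition to the background criterion (e.g. 0.05); `NULL` disables.
#' @param missing_action `"fail"` or `"pass"` for pairs with missing genes.
#' @param min_candidates below this many candidates the screen passes
#'   everything through with a warning (default 20).
#' @return Tibble: per pair `distance`, `bg_quantile` (position within the
#'   random background), and `pass`.
#' @export
screen_phylo <- function(profiles, candidates, quantile = 0.05, k = 20L,
                         seed = 1L, n_background = 10000L,
                         cap_fraction = NULL,
                         missing_action = c("fail", "pass"),
                         min_candidates = 20L) {
  missing_action <- match.arg(missing_action)
  candidates <- tibble::as_tibble(candidates)
  if (!nrow(candidates)) {
    return(tibble::tibble(vulnerable = character(), rescuer = character(),
                          distance = numeric(), pass = logical()))
  }
  k_use <- min(k, min(dim(profiles)) - 1L)
  if (k_use < k) message("NMF rank lowered to ", k_use,
                         " for a ", nrow(profiles), " x ", ncol(profiles),
                         " profile matrix")
  W <- nmf_membership(profiles, k = k_use, seed = seed)
  dist_i <- vapply(seq_len(nrow(candidates)), function(i) {
    suppressWarnings(phylo_distance(W, candidates$vulnerable[i],
                                    candidates$rescuer[i]))
  }, numeric(1))

  old <- withr_seed(seed + 1L)
  on.exit(restore_seed(old), add = TRUE)
  genes <- rownames(W)
  ia <- sample.int(length(genes), n_background, replace = TRUE)
  ib <- sample.int(length(genes), n_background, replace = TRUE)
  ok <- ia != ib
  bg <- sqrt(rowSums((W[ia[ok], , drop = FALSE] -
                        W[ib[ok], , drop = FALSE])^2))
  thr_bg <- stats::quantile(bg, quantile, names = FALSE)

  out <- tibble::tibble(vulnerable = candidates$vulnerable,
                        rescuer = candidates$rescuer,
                        distance = dist_i,
                        bg_quantile = vapply(dist_i, function(d) {
                          if (is.na(d)) NA_real_ else mean(bg <= d)
                        }, numeric(1)))
  if (nrow(candidates) < min_candidates) {
    warning("fewer than ", min_candidates,
            " candidates; phylogenetic screen passed through")
    out$pass <- !is.na(out$distance) | missing_action == "pass"
    return(out)
  }
  missing <- is.na(out$distance)
  out$pass <- !missing & out$distance <= thr_bg
  if (!is.null(cap_fraction)) {
    n_top <- ceiling(cap_fraction * nrow(candidates))
    ord <- order(out$distance, seq_len(nrow(out)), na.last = TRUE)
    top <- rep(FALSE, nrow(out))
    top[ord[seq_len(n_top)]] <- TRUE
    out$pass <- out$pass & top
  }
  if (missing_action == "pass") out$pass[missing] <- TRUE
  if (any(missing)) {
    message(sum(missing), " candidate pair(s) had genes missing from the ",
            "profile matrix (", missing_action, ")")
  }
  out
}
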