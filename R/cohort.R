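#' Construct a gene-by-sample matrix container
#'
#' A `gene_matrix` is a numeric matrix (genes in rows, samples in columns)
#' tagged with its molecular modality: `"mRNA"` for log-scale expression or
#' `"SCNA"` for log copy-number ratio versus matched normal. Missing entries
#' are `NA` and are excluded from all quantile computations downstream.
#'
#' @param values numeric matrix, genes x samples. Dimnames are used as gene
#'   and sample identifiers unless `gene_ids` / `sample_ids` are given.
#' @param modality `"mRNA"` or `"SCNA"`.
#' @param gene_ids,sample_ids optional character vectors overriding dimnames.
#' @return A `gene_matrix` object.
#' @export
gene_matrix <- function(values, modality = c("mRNA", "SCNA"),
                        gene_ids = NULL, sample_ids = NULL) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("gene_matrix needs gene and sample identifiers (dimnames)")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  if (any(is.infinite(values))) stop("gene_matrix values must be finite or NA")
  structure(values, modality = modality,
            class = c("gene_matrix", "matrix", "array"))
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("<gene_matrix> %d genes x %d samples, modality %s\n",
              nrow(x), ncol(x), attr(x, "modality")))
  invisible(x)
}

#' @rdname gene_matrix
#' @param x object to query.
#' @export
modality <- function(x) attr(x, "modality")

#' Read / write a gene-by-sample matrix from tab-separated text
#'
#' Expected dialect: first column holds gene symbols, header row holds sample
#' identifiers, cells are numeric with `NA` for missing. Duplicate gene rows
#' are rejected; a non-numeric cell is reported with its row and column.
#'
#' @param path file path.
#' @param modality `"mRNA"` or `"SCNA"`.
#' @return `read_gene_matrix()` returns a [gene_matrix()];
#'   `write_gene_matrix()` returns `path` invisibly.
#' @export
read_gene_matrix <- function(path, modality = c("mRNA", "SCNA")) {
  modality <- match.arg(modality)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) stop("malformed header in ", path,
                                ": need a gene column plus >=1 sample column")
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  genes <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = list(genes, colnames(vals))))
  bad <- which(is.na(num) & !(is.na(vals) | vals %in% c("NA", "", "NaN")),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at gene '%s', sample '%s' in %s",
                 genes[bad[1, 1]], colnames(vals)[bad[1, 2]], path))
  }
  gene_matrix(num, modality = modality)
}

#' @rdname read_gene_matrix
#' @param x a `gene_matrix`.
#' @export
write_gene_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Tab-separated file with columns `sample_id`, `time_days`, `event`, `age`,
#' `sex`, `race`, `cancer_type`, `tumor_purity` (and optionally `gii`; when
#' absent, compute it from SCNA with [compute_gii()] and join). Basic
#' invariants (positive times, 0/1 events, purity in \[0,1\]) are enforced.
#'
#' @param path file path.
#' @return A tibble, one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_clinical(tibble::as_tibble(df))
}

validate_clinical <- function(df) {
  need <- c("sample_id", "time_days", "event", "age", "sex", "race",
            "cancer_type", "tumor_purity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  if (any(df$time_days <= 0, na.rm = TRUE)) stop("time_days must be > 0")
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0 (censored) or 1")
  if (any(df$tumor_purity < 0 | df$tumor_purity > 1, na.rm = TRUE)) {
    stop("tumor_purity must lie in [0, 1]")
  }
  if ("gii" %in% names(df) &&
      any(df$gii < 0 | df$gii > 1, na.rm = TRUE)) stop("gii must lie in [0, 1]")
  df
}

#' Genomic instability index
#'
#' Fraction of genes in a tumor whose absolute SCNA log-ratio exceeds 1:
#' `GII = (1/N) * sum(I(|s_i| > 1))`. The inequality is strict, so a log
#' ratio of exactly +/-1 does not count.
#'
#' @param scna_profile numeric vector of per-gene log copy-number ratios for
#'   one sample; `NA` entries are dropped.
#' @return A fraction in \[0, 1\].
#' @examples
#' compute_gii(c(1.2, 0.5, -2.0, 0.8)) # 0.5
#' @export
compute_gii <- function(scna_profile) {
  scna_profile <- scna_profile[!is.na(scna_profile)]
  if (!length(scna_profile)) stop("empty SCNA profile")
  mean(abs(scna_profile) > 1)
}

#' Per-cancer-type tertile activity calling
#'
#' Calls each gene underactive (-1), normal (0) or overactive (+1) per
#' sample: within each cancer type, values strictly below that type's 33rd
#' percentile map to -1 and strictly above its 67th percentile map to +1.
#' Percentiles are linear-interpolation quantiles; values equal to a
#' threshold, missing values, and constant genes are all called 0. Cancer
#' types with fewer samples than `min_samples` are called all-normal with a
#' warning, since tertiles estimated from a handful of samples are noise.
#'
#' @param x a [gene_matrix()].
#' @param cancer_type character/factor of per-sample cancer-type labels,
#'   aligned with `colnames(x)`.
#' @param probs the two percentile cutpoints (defaults 0.33 and 0.67).
#' @param min_samples minimum samples per cancer type (default 10).
#' @return An `activity_matrix`: integer matrix in \{-1, 0, 1\} with the same
#'   dimnames and modality as `x`.
#' @export
call_activity <- function(x, cancer_type, probs = c(0.33, 0.67),
                          min_samples = 10L) {
  stopifnot(inherits(x, "gene_matrix"))
  if (length(cancer_type) != ncol(x)) {
    stop("cancer_type must have one label per sample")
  }
  cancer_type <- as.character(cancer_type)
  states <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (ct in unique(cancer_type)) {
    idx <- which(cancer_type == ct)
    if (length(idx) < min_samples) {
      warning(sprintf("cancer type '%s' has %d < %d samples; states set to 0",
                      ct, length(idx), min_samples))
      next
    }
    sub <- unclass(x)[, idx, drop = FALSE]
    qs <- t(apply(sub, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L || max(v) == min(v)) return(c(NA_real_, NA_real_))
      stats::quantile(v, probs = probs, names = FALSE, type = 7)
    }))
    lo <- sweep(sub, 1L, qs[, 1L], "<")
    hi <- sweep(sub, 1L, qs[, 2L], ">")
    st <- matrix(0L, nrow(sub), ncol(sub))
    st[which(lo)] <- -1L
    st[which(hi)] <- 1L
    st[is.na(sub)] <- 0L
    states[, idx] <- st
  }
  structure(states, modality = modality(x),
            class = c("activity_matrix", "matrix", "array"))
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("<activity_matrix> %d genes x %d samples, modality %s\n",
              nrow(x), ncol(x), attr(x, "modality")))
  invisible(x)
}

#' Rescued / non-rescued state of a gene pair across samples
#'
#' For a DU (down-up) pair, a sample is *rescued* when the vulnerable gene V
#' is underactive and the rescuer R is overactive, and *non-rescued* when V
#' is underactive but R is not overactive. For a DD (down-down) pair the
#' rescuing state of R is underactivity instead. Samples where V is not
#' underactive are *other*. The three states partition the samples.
#'
#' @param act_v,act_r integer activity vectors in \{-1, 0, 1\}, aligned on
#'   samples.
#' @param sr_type `"DU"` or `"DD"`.
#' @return Character vector over \{"rescued", "non_rescued", "other"\}.
#' @export
pair_states <- function(act_v, act_r, sr_type = c("DU", "DD")) {
  sr_type <- match.arg(sr_type)
  if (length(act_v) != length(act_r)) {
    stop("activity vectors must have equal length")
  }
  r_rescue <- if (sr_type == "DU") 1L else -1L
  out <- rep("other", length(act_v))
  vdown <- act_v == -1L
  out[vdown & act_r == r_rescue] <- "rescued"
  out[vdown & act_r != r_rescue] <- "non_rescued"
  out
}

#' Rank-based inverse-normal transform
#'
#' Maps a numeric vector to standard-normal scores through its ranks using
#' the Blom offset: `qnorm((rank - 3/8) / (n + 1/4))`, ties receiving the
#' average rank. The result is monotone in the input and has mean ~0; all
#' continuous covariates entering the survival and essentiality models are
#' passed through this transform.
#'
#' @param x numeric vector, length >= 2, not all equal. `NA`s are preserved
#'   and excluded from ranking.
#' @return Numeric vector of normal scores.
#' @export
inverse_normal_transform <- function(x) {
  ok <- !is.na(x)
  v <- x[ok]
  if (length(v) < 2L) stop("need at least 2 non-missing values")
  if (max(v) == min(v)) stop("all values equal; transform undefined")
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  out
}
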