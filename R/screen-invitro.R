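#' Assemble a cell-line perturbation screen panel
#'
#' A screen panel bundles per-cell-line fitness readouts (shRNA essentiality
#' or drug log-IC50, long format) with the molecular profiles of the same
#' cell lines. Readout values follow a growth convention: higher value =
#' more cell growth after the perturbation (for drug panels, higher log-IC50
#' = more resistant = more growth under the inhibitor).
#'
#' @param readouts tibble with columns `cell_line`, `cancer_type`,
#'   `perturbed_gene`, `readout_kind` (`"shRNA_essentiality"` or
#'   `"drug_logIC50"`), `value`.
#' @param mrna,scna [gene_matrix()] profiles for the same cell lines
#'   (`scna` may be `NULL`).
#' @return A `screen_panel` object (list).
#' @export
screen_panel <- function(readouts, mrna, scna = NULL) {
  readouts <- tibble::as_tibble(readouts)
  need <- c("cell_line", "cancer_type", "perturbed_gene", "readout_kind",
            "value")
  miss <- setdiff(need, names(readouts))
  if (length(miss)) stop("readouts missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(readouts$value))) stop("readout values must be finite")
  for (prof in list(mrna, scna)) {
    if (!is.null(prof)) {
      absent <- setdiff(unique(readouts$cell_line), colnames(prof))
      if (length(absent)) {
        stop("cell lines absent from profiles: ",
             paste(utils::head(absent, 5), collapse = ", "))
      }
    }
  }
  structure(list(readouts = readouts, mrna = mrna, scna = scna),
            class = "screen_panel")
}

#' @export
print.screen_panel <- function(x, ...) {
  cat(sprintf("<screen_panel> %d readouts, %d cell lines, %d perturbed genes\n",
              nrow(x$readouts), length(unique(x$readouts$cell_line)),
              length(unique(x$readouts$perturbed_gene))))
  invisible(x)
}

#' Read a screen panel from long-format TSV
#'
#' @param path TSV with columns `cell_line`, `cancer_type`,
#'   `perturbed_gene`, `readout_kind`, `value`.
#' @inheritParams screen_panel
#' @return A [screen_panel()].
#' @export
read_screen_panel <- function(path, mrna, scna = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  screen_panel(tibble::as_tibble(df), mrna = mrna, scna = scna)
}

#' Map drug readouts onto their target genes
#'
#' Rewrites rows with `readout_kind == "drug_logIC50"` whose
#' `perturbed_gene` is a drug name into one row per (non-agonist) target of
#' that drug, so drug panels can be screened with the same machinery as
#' shRNA panels. Drugs with several targets contribute their readout to each
#' target.
#'
#' @param readouts long-format readout tibble (see [screen_panel()]).
#' @param drug_map a drug-target map from [read_drug_target_map()] or a
#'   tibble with columns `drug`, `target_gene`.
#' @return The rewritten readout tibble.
#' @export
map_drug_readouts <- function(readouts, drug_map) {
  is_drug <- readouts$readout_kind == "drug_logIC50"
  if (!any(is_drug)) return(readouts)
  drugs <- readouts[is_drug, ]
  mapped <- dplyr::inner_join(
    drugs, dplyr::select(drug_map, drug = "drug", target = "target_gene"),
    by = c(perturbed_gene = "drug"), relationship = "many-to-many")
  mapped$perturbed_gene <- mapped$target
  mapped$target <- NULL
  dplyr::bind_rows(readouts[!is_drug, ], mapped)
}

# Profiled-ML linear mixed model with a single random intercept.
# Fits y = X beta + b[group] + e by maximizing the likelihood profiled over
# beta and the residual variance; the only free parameter is the
# variance ratio lambda = var(b)/var(e), optimized on the log scale.
# Returns the ML deviance (-2 logLik), matching lme4::lmer(REML = FALSE)
# to optimizer precision. Used for the bulk pair screen where tens of
# thousands of identical-structure fits are needed.
fast_lmm <- function(y, X, group) {
  n <- length(y)
  gi <- split(seq_len(n), group)
  nj <- lengths(gi)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y * y)
  Sx <- do.call(rbind, lapply(gi, function(i) colSums(X[i, , drop = FALSE])))
  Sy <- vapply(gi, function(i) sum(y[i]), numeric(1))

  solve_at <- function(loglam) {
    lam <- exp(loglam)
    cj <- lam / (1 + nj * lam)
    XtWX <- XtX - crossprod(Sx * sqrt(cj))
    XtWy <- Xty - drop(crossprod(Sx, cj * Sy))
    yWy <- yty - sum(cj * Sy^2)
    b <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
    if (is.null(b)) return(NULL)
    rss <- max(yWy - sum(b * XtWy), 1e-12)
    list(beta = b, dev = n * log(2 * pi * rss / n) +
           sum(log(1 + nj * lam)) + n)
  }
  obj <- function(loglam) {
    s <- solve_at(loglam)
    if (is.null(s)) return(Inf)
    s$dev
  }
  opt <- stats::optimize(obj, c(-15, 15))
  # lambda -> 0 boundary: plain least squares, still a valid ML point
  at0 <- obj(-30)
  loglam <- if (at0 < opt$objective) -30 else opt$minimum
  fit <- solve_at(loglam)
  if (is.null(fit)) return(NULL)
  c(fit, list(lambda = exp(loglam)))
}

fast_lmm_lrt <- function(y, g, group) {
  X1 <- cbind(1, g)
  full <- fast_lmm(y, X1, group)
  null <- fast_lmm(y, matrix(1, length(y), 1L), group)
  if (is.null(full) || is.null(null)) return(NULL)
  stat <- max(null$dev - full$dev, 0)
  list(beta = unname(full$beta[2L]),
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Conditional-essentiality mixed-model fit
#'
#' Models the fitness readout of one gene's knockdown as a linear function
#' of a partner gene's molecular level, with cancer type as a random
#' intercept: `y ~ g + (1 | cancer_type)`. The readout and covariate are
#' inverse-normal transformed before fitting; the fixed-effect p-value is a
#' 1-df likelihood-ratio test of the full model against the
#' intercept-plus-random-effect null (both fitted by maximum likelihood).
#' With a single cancer type the model degrades to ordinary least squares.
#'
#' @param y per-cell-line fitness readout (higher = more growth).
#' @param g per-cell-line molecular level of the partner gene.
#' @param cancer_type per-cell-line cancer-type labels.
#' @param normalize inverse-normal transform `y` and `g` first (default TRUE).
#' @param engine `"fast"` for the specialized profiled-likelihood solver,
#'   `"lme4"` for [lme4::lmer()]; the two agree to optimizer precision.
#' @return Tibble with columns `beta`, `p`, `n`, `method`.
#' @export
fit_conditional_essentiality <- function(y, g, cancer_type,
                                         normalize = TRUE,
                                         engine = c("fast", "lme4")) {
  engine <- match.arg(engine)
  ok <- is.finite(y) & is.finite(g) & !is.na(cancer_type)
  y <- y[ok]; g <- g[ok]; cancer_type <- as.character(cancer_type[ok])
  if (length(y) < 10L) stop("need >= 10 cell lines with readout and covariate")
  if (max(g) == min(g)) stop("constant covariate g: slope undefined")
  if (normalize) {
    y <- inverse_normal_transform(y)
    g <- inverse_normal_transform(g)
  }
  if (length(unique(cancer_type)) < 2L) {
    fit <- stats::lm(y ~ g)
    p <- stats::anova(fit)[["Pr(>F)"]][1L]
    return(tibble::tibble(beta = unname(stats::coef(fit)[2L]), p = p,
                          n = length(y), method = "ols"))
  }
  if (engine == "fast") {
    res <- fast_lmm_lrt(y, g, factor(cancer_type))
    if (is.null(res)) {
      warning("singular mixed-model fit; reporting p = 1")
      return(tibble::tibble(beta = NA_real_, p = 1, n = length(y),
                            method = "lmm_singular"))
    }
    return(tibble::tibble(beta = res$beta, p = res$p, n = length(y),
                          method = "lmm"))
  }
  dat <- data.frame(y = y, g = g, ct = factor(cancer_type))
  full <- lme4::lmer(y ~ g + (1 | ct), data = dat, REML = FALSE,
                     control = lme4::lmerControl(calc.derivs = FALSE))
  null <- lme4::lmer(y ~ (1 | ct), data = dat, REML = FALSE,
                     control = lme4::lmerControl(calc.derivs = FALSE))
  an <- stats::anova(null, full)
  tibble::tibble(beta = unname(lme4::fixef(full)[2L]),
                 p = an[["Pr(>Chisq)"]][2L], n = length(y), method = "lmm")
}

#' Fisher's method for combining p-values
#'
#' `X = -2 * sum(log(p))` referred to a chi-square distribution with `2k`
#' degrees of freedom. With a single p-value the combination is the
#' identity. Non-positive p-values are clamped to `1e-300` with a warning.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return Combined p-value.
#' @examples
#' combine_fisher(c(0.5, 0.5)) # 0.5966
#' @export
combine_fisher <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (!length(pvals)) return(NA_real_)
  if (any(pvals <= 0)) {
    warning("non-positive p-values clamped to 1e-300")
    pvals <- pmax(pvals, 1e-300)
  }
  stats::pchisq(-2 * sum(log(pvals)), df = 2L * length(pvals),
                lower.tail = FALSE)
}

# Readout matrix (perturbed gene x cell line) from the long format,
# averaging replicates of the same (gene, cell line).
readout_matrix <- function(readouts) {
  wide <- readouts |>
    dplyr::group_by(.data$perturbed_gene, .data$cell_line) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cell_line", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$perturbed_gene
  m
}

# One pair, one modality, one panel. Returns p-values and sign gates for
# the two rescue conditions. DU condition (i): V-knockdown growth rises
# with R's level (slope > 0); condition (ii): R-knockdown growth falls as
# V's level falls (slope > 0). DD condition (i): V-knockdown growth rises
# as R's level falls (slope < 0); condition (ii): one-sided Wilcoxon that
# V-knockdown growth is higher in R-low than R-high cell-line tertiles.
invitro_pair_stats <- function(ymat, prof, ct, v, r, sr_type) {
  if (!(v %in% rownames(ymat)) || !(r %in% rownames(prof))) {
    return(list(ok = FALSE, reason = "missing_readout_or_profile"))
  }
  yv <- ymat[v, ]
  gr <- prof[r, colnames(ymat)]
  keep <- is.finite(yv) & is.finite(gr)
  if (sum(keep) < 10L || max(gr[keep]) == min(gr[keep])) {
    return(list(ok = FALSE, reason = "too_few_lines_or_constant_covariate"))
  }
  grp <- factor(ct[keep])
  y1 <- inverse_normal_transform(yv[keep])
  g1 <- inverse_normal_transform(gr[keep])
  f1 <- if (nlevels(grp) < 2L) {
    fit <- stats::lm(y1 ~ g1)
    list(beta = unname(stats::coef(fit)[2L]),
         p = stats::anova(fit)[["Pr(>F)"]][1L])
  } else fast_lmm_lrt(y1, g1, grp)
  if (is.null(f1)) return(list(ok = FALSE, reason = "singular_fit"))
  sign1 <- if (sr_type == "DU") f1$beta > 0 else f1$beta < 0

  if (sr_type == "DU") {
    if (!(r %in% rownames(ymat)) || !(v %in% rownames(prof))) {
      return(list(ok = FALSE, reason = "missing_readout_or_profile"))
    }
    yr <- ymat[r, ]
    gv <- prof[v, colnames(ymat)]
    keep2 <- is.finite(yr) & is.finite(gv)
    if (sum(keep2) < 10L || max(gv[keep2]) == min(gv[keep2])) {
      return(list(ok = FALSE, reason = "too_few_lines_or_constant_covariate"))
    }
    grp2 <- factor(ct[keep2])
    y2 <- inverse_normal_transform(yr[keep2])
    g2 <- inverse_normal_transform(gv[keep2])
    f2 <- if (nlevels(grp2) < 2L) {
      fit <- stats::lm(y2 ~ g2)
      list(beta = unname(stats::coef(fit)[2L]),
           p = stats::anova(fit)[["Pr(>F)"]][1L])
    } else fast_lmm_lrt(y2, g2, grp2)
    if (is.null(f2)) return(list(ok = FALSE, reason = "singular_fit"))
    sign2 <- f2$beta > 0
    p2 <- f2$p
  } else {
    qs <- stats::quantile(gr[keep], c(1 / 3, 2 / 3), names = FALSE)
    lo <- yv[keep][gr[keep] < qs[1L]]
    hi <- yv[keep][gr[keep] > qs[2L]]
    if (length(lo) < 3L || length(hi) < 3L) {
      return(list(ok = FALSE, reason = "degenerate_tertiles"))
    }
    wt <- suppressWarnings(stats::wilcox.test(lo, hi, alternative = "greater"))
    p2 <- wt$p.value
    sign2 <- stats::median(lo) > stats::median(hi)
  }
  list(ok = TRUE, p1 = f1$p, sign1 = sign1, p2 = p2, sign2 = sign2)
}

#' In-vitro conditional-essentiality screen (step 1)
#'
#' Screens candidate vulnerable-rescuer pairs against one or more cell-line
#' perturbation panels. For each pair, panel and modality the two rescue
#' conditions are tested with [fit_conditional_essentiality()]'s model (see
#' `invitro_pair_stats` in the source for the DD variants); a condition
#' counts only when its effect sign matches the rescue direction. Condition
#' p-values are combined across panels with Fisher's method, the pair's
#' representative p per modality is the worse of the two conditions (the
#' gate is a conjunction), Benjamini-Hochberg correction is applied across
#' pairs within each modality, and a pair passes if it clears `fdr` in mRNA
#' OR SCNA.
#'
#' @param panels a [screen_panel()] or list of them.
#' @param candidates tibble with columns `vulnerable`, `rescuer`.
#' @param sr_type `"DU"` or `"DD"`.
#' @param fdr Benjamini-Hochberg threshold (default 0.2).
#' @return Tibble: one row per candidate with per-modality p, q, and `pass`.
#' @export
screen_invitro <- function(panels, candidates, sr_type = c("DU", "DD"),
                           fdr = 0.2) {
  sr_type <- match.arg(sr_type)
  if (inherits(panels, "screen_panel")) panels <- list(panels)
  if (!length(panels)) stop("need at least one screen panel")
  candidates <- tibble::as_tibble(candidates)
  if (!nrow(candidates)) {
    return(tibble::tibble(vulnerable = character(), rescuer = character(),
                          p_mRNA = numeric(), q_mRNA = numeric(),
                          p_SCNA = numeric(), q_SCNA = numeric(),
                          pass = logical()))
  }

  panel_data <- lapply(panels, function(pan) {
    ymat <- readout_matrix(pan$readouts)
    ct <- pan$readouts |>
      dplyr::distinct(.data$cell_line, .data$cancer_type)
    ctv <- stats::setNames(ct$cancer_type, ct$cell_line)[colnames(ymat)]
    list(ymat = ymat, ct = ctv, mrna = pan$mrna, scna = pan$scna)
  })

  per_modality <- function(mod) {
    slot <- if (mod == "mRNA") "mrna" else "scna"
    vapply(seq_len(nrow(candidates)), function(i) {
      v <- candidates$vulnerable[i]; r <- candidates$rescuer[i]
      p1s <- p2s <- numeric(0)
      for (pd in panel_data) {
        prof <- pd[[slot]]
        if (is.null(prof)) next
        st <- invitro_pair_stats(pd$ymat, unclass(prof), pd$ct, v, r, sr_type)
        if (!st$ok || !st$sign1 || !st$sign2) next
        p1s <- c(p1s, st$p1); p2s <- c(p2s, st$p2)
      }
      if (!length(p1s)) return(NA_real_)
      max(combine_fisher(p1s), combine_fisher(p2s))
    }, numeric(1))
  }

  p_mrna <- per_modality("mRNA")
  p_scna <- if (any(!vapply(panel_data, function(p) is.null(p$scna),
                            logical(1)))) per_modality("SCNA") else
    rep(NA_real_, nrow(candidates))
  q_mrna <- bh_fdr(p_mrna)
  q_scna <- bh_fdr(p_scna)
  pass <- (!is.na(q_mrna) & q_mrna < fdr) | (!is.na(q_scna) & q_scna < fdr)
  tibble::tibble(vulnerable = candidates$vulnerable,
                 rescuer = candidates$rescuer,
                 p_mRNA = p_mrna, q_mRNA = q_mrna,
                 p_SCNA = p_scna, q_SCNA = q_scna,
                 pass = pass)
}
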