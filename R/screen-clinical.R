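#' Stratified Cox proportional-hazards fit for a pair-state indicator
#'
#' Fits the hazard model
#' `h_g(t) = h_0g(t) * exp(b1*I + b2*g(V) + b3*g(R) + b4*age + b5*GII + b6*TP)`
#' where `I` is a binary per-sample state indicator (e.g. "tumor is in the
#' rescued state of pair (V, R)") and `g` indexes strata formed by the full
#' cross of cancer type, race and sex. Continuous covariates are
#' inverse-normal transformed; the indicator is left binary. Significance of
#' `b1` is a 1-df likelihood-ratio test against the same model without the
#' indicator, with a Wald p-value reported alongside. Ties use the Efron
#' approximation. Strata with fewer than `min_stratum_events` observed
#' events are merged into a single pooled stratum so their baselines remain
#' identifiable.
#'
#' @param indicator logical/0-1 vector per sample.
#' @param clinical clinical tibble (see [read_clinical()]) with `gii`.
#' @param g_v,g_r continuous molecular values of the vulnerable and rescuer
#'   genes per sample.
#' @param purity_cols names of purity columns in `clinical` to control for
#'   (default `"tumor_purity"`; see [add_purity_controls()]).
#' @param min_stratum_events strata below this event count are pooled.
#' @param min_events minimum total events required (default 10).
#' @return An `sr_cox` object; see [tidy.sr_cox()] and [glance.sr_cox()].
#' @export
fit_stratified_cox <- function(indicator, clinical, g_v = NULL, g_r = NULL,
                               purity_cols = "tumor_purity",
                               min_stratum_events = 10L, min_events = 10L) {
  indicator <- as.integer(indicator)
  if (length(unique(indicator)) < 2L) stop("degenerate indicator")
  n <- nrow(clinical)
  if (length(indicator) != n) stop("indicator length must match clinical rows")
  if (sum(clinical$event) < min_events) {
    stop("fewer than ", min_events, " events")
  }

  strat <- interaction(clinical$cancer_type, clinical$race, clinical$sex,
                       drop = TRUE)
  ev_per <- tapply(clinical$event, strat, sum)
  small <- names(ev_per)[ev_per < min_stratum_events]
  strat <- as.character(strat)
  strat[strat %in% small] <- ".pooled"
  strat <- factor(strat)

  int_or_na <- function(x) {
    if (is.null(x)) return(NULL)
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (max(x) == min(x)) return(NULL)  # constant covariate carries nothing
    inverse_normal_transform(x)
  }
  covs <- list(g_v = int_or_na(g_v), g_r = int_or_na(g_r),
               age = int_or_na(clinical$age), gii = int_or_na(clinical$gii))
  for (pc in purity_cols) {
    if (!pc %in% names(clinical)) next
    covs[[pc]] <- int_or_na(clinical[[pc]])
  }
  covs <- covs[!vapply(covs, is.null, logical(1))]

  dat <- data.frame(time = clinical$time_days, event = clinical$event,
                    ind = indicator, strat = strat)
  for (nm in names(covs)) dat[[nm]] <- covs[[nm]]
  rhs0 <- paste(c(names(covs), "strata(strat)"), collapse = " + ")
  f_full <- stats::as.formula(paste("survival::Surv(time, event) ~ ind +",
                                    rhs0))
  f_null <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs0))

  fit <- tryCatch({
    full <- survival::coxph(f_full, data = dat, ties = "efron")
    null <- survival::coxph(f_null, data = dat, ties = "efron")
    lrt <- max(2 * (full$loglik[2L] - null$loglik[2L]), 0)
    sm <- summary(full)
    list(beta = unname(stats::coef(full)["ind"]),
         se = sm$coefficients["ind", "se(coef)"],
         betas = stats::coef(full),
         lrt = lrt,
         p_lrt = stats::pchisq(lrt, 1L, lower.tail = FALSE),
         p_wald = sm$coefficients["ind", "Pr(>|z|)"],
         converged = TRUE)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || !is.finite(fit$beta)) {
    fit <- list(beta = NA_real_, se = NA_real_, betas = NULL, lrt = 0,
                p_lrt = 1, p_wald = 1, converged = FALSE)
  }
  structure(c(fit, list(n = n, n_events = sum(clinical$event),
                        strata_used = nlevels(strat))),
            class = "sr_cox")
}

#' @export
print.sr_cox <- function(x, ...) {
  cat(sprintf(paste0("<sr_cox> beta1 = %.4f, LRT p = %.3g, Wald p = %.3g ",
                     "(%d events, %d strata)%s\n"),
              x$beta, x$p_lrt, x$p_wald, x$n_events, x$strata_used,
              if (x$converged) "" else " [non-converged]"))
  invisible(x)
}

#' Tidy a stratified Cox pair-state fit
#'
#' @param x an `sr_cox` object from [fit_stratified_cox()].
#' @param ... unused.
#' @return `tidy()`: one row per model term with `estimate`;
#'   `glance()`: one-row tibble with `beta1`, `p_lrt`, `p_wald`,
#'   `n`, `n_events`, `strata_used`, `converged`.
#' @method tidy sr_cox
#' @export
tidy.sr_cox <- function(x, ...) {
  if (is.null(x$betas)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(term = names(x$betas), estimate = unname(x$betas))
}

#' @rdname tidy.sr_cox
#' @method glance sr_cox
#' @export
glance.sr_cox <- function(x, ...) {
  tibble::tibble(beta1 = x$beta, se = x$se, statistic = x$lrt,
                 p_lrt = x$p_lrt, p_wald = x$p_wald, n = x$n,
                 n_events = x$n_events, strata_used = x$strata_used,
                 converged = x$converged)
}

#' Add extra tumor-purity estimates as model covariates
#'
#' Validates up to five purity columns for use in [fit_stratified_cox()].
#' Missing entries are mean-imputed (flagged via warning); columns that are
#' entirely missing are dropped with a warning.
#'
#' @param clinical clinical tibble.
#' @param purity_cols candidate column names.
#' @return List with the augmented `clinical` and the retained
#'   `purity_cols`.
#' @export
add_purity_controls <- function(clinical, purity_cols = "tumor_purity") {
  keep <- character(0)
  for (pc in purity_cols) {
    if (!pc %in% names(clinical)) {
      warning("purity column '", pc, "' not found; dropped")
      next
    }
    x <- clinical[[pc]]
    if (all(is.na(x))) {
      warning("purity column '", pc, "' is all-missing; dropped")
      next
    }
    if (anyNA(x)) {
      warning("purity column '", pc, "' mean-imputed for ",
              sum(is.na(x)), " samples")
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      clinical[[pc]] <- x
    }
    keep <- c(keep, pc)
  }
  list(clinical = clinical, purity_cols = keep)
}

#' Clinical survival screen (step 3)
#'
#' For each surviving candidate pair, fits four stratified Cox models: the
#' rescued-state and non-rescued-state indicators, each under mRNA-derived
#' and SCNA-derived activity states. A pair passes when its rescued state
#' carries significantly *worse* survival (`beta1 > 0`) and its non-rescued
#' state significantly *better* survival (`beta1 < 0`) at Benjamini-Hochberg
#' `fdr` in both modalities. Pairs whose rescued state holds fewer than
#' `min_state_samples` samples are skipped with a reason.
#'
#' @param act_mrna,act_scna activity matrices from [call_activity()].
#' @param mrna,scna the underlying continuous [gene_matrix()] objects
#'   (used for the g(V), g(R) covariates).
#' @param clinical clinical tibble aligned to the matrix samples
#'   (matched on `sample_id`).
#' @param candidates tibble with `vulnerable`, `rescuer`.
#' @param sr_type `"DU"` or `"DD"`.
#' @param fdr per-family threshold (default 0.05).
#' @param min_state_samples minimum rescued-state count (default 10).
#' @param purity_cols purity covariates (see [add_purity_controls()]).
#' @return Tibble: per pair, betas, p/q per (state, modality), `pass`,
#'   `reason` for skipped pairs.
#' @export
screen_clinical <- function(act_mrna, act_scna, mrna, scna, clinical,
                            candidates, sr_type = c("DU", "DD"), fdr = 0.05,
                            min_state_samples = 10L,
                            purity_cols = "tumor_purity") {
  sr_type <- match.arg(sr_type)
  candidates <- tibble::as_tibble(candidates)
  samples <- colnames(act_mrna)
  clinical <- clinical[match(samples, clinical$sample_id), ]
  if (anyNA(clinical$sample_id)) {
    stop("clinical table missing some matrix samples")
  }

  fit_one <- function(ind, g_v, g_r) {
    if (sum(ind) < min_state_samples || sum(!ind) < min_state_samples) {
      return(NULL)
    }
    tryCatch(fit_stratified_cox(ind, clinical, g_v = g_v, g_r = g_r,
                                purity_cols = purity_cols),
             error = function(e) NULL)
  }

  rows <- purrr::map(seq_len(nrow(candidates)), function(i) {
    v <- candidates$vulnerable[i]; r <- candidates$rescuer[i]
    out <- tibble::tibble(vulnerable = v, rescuer = r,
                          beta_res_mRNA = NA_real_, p_res_mRNA = NA_real_,
                          beta_non_mRNA = NA_real_, p_non_mRNA = NA_real_,
                          beta_res_SCNA = NA_real_, p_res_SCNA = NA_real_,
                          beta_non_SCNA = NA_real_, p_non_SCNA = NA_real_,
                          reason = NA_character_)
    for (mod in c("mRNA", "SCNA")) {
      act <- if (mod == "mRNA") act_mrna else act_scna
      val <- if (mod == "mRNA") mrna else scna
      if (!(v %in% rownames(act)) || !(r %in% rownames(act))) {
        out$reason <- "gene_missing"
        next
      }
      st <- pair_states(act[v, ], act[r, ], sr_type)
      g_v <- unclass(val)[v, ]; g_r <- unclass(val)[r, ]
      f_res <- fit_one(st == "rescued", g_v, g_r)
      f_non <- fit_one(st == "non_rescued", g_v, g_r)
      if (is.null(f_res) || is.null(f_non)) {
        out$reason <- "state_below_minimum"
        next
      }
      out[[paste0("beta_res_", mod)]] <- f_res$beta
      out[[paste0("p_res_", mod)]] <- f_res$p_lrt
      out[[paste0("beta_non_", mod)]] <- f_non$beta
      out[[paste0("p_non_", mod)]] <- f_non$p_lrt
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(tibble::tibble(vulnerable = character(),
                                        rescuer = character(),
                                        pass = logical()))
  for (fam in c("res_mRNA", "non_mRNA", "res_SCNA", "non_SCNA")) {
    out[[paste0("q_", fam)]] <- bh_fdr(out[[paste0("p_", fam)]])
  }
  ok <- function(b, q, positive) {
    !is.na(b) & !is.na(q) & q < fdr & (if (positive) b > 0 else b < 0)
  }
  out$pass <- ok(out$beta_res_mRNA, out$q_res_mRNA, TRUE) &
    ok(out$beta_non_mRNA, out$q_non_mRNA, FALSE) &
    ok(out$beta_res_SCNA, out$q_res_SCNA, TRUE) &
    ok(out$beta_non_SCNA, out$q_non_SCNA, FALSE)
  out
}
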