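#' Read a drug-to-target map
#'
#' TSV with columns `drug`, `target_gene`, `action`. Targets whose
#' mechanism of action is annotated `"agonist"` are excluded from rescue
#' lookups; a drug left with no targets after the exclusion is an error.
#'
#' @param path file path, or a data frame with the same columns.
#' @return Tibble with columns `drug`, `target_gene`, `action`.
#' @export
read_drug_target_map <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  need <- c("drug", "target_gene", "action")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("drug map missing columns: ",
                         paste(miss, collapse = ", "))
  df <- tibble::as_tibble(df)
  kept <- df[tolower(df$action) != "agonist", ]
  lost <- setdiff(unique(df$drug), unique(kept$drug))
  if (length(lost)) {
    stop("drug(s) with only agonist-annotated targets: ",
         paste(lost, collapse = ", "))
  }
  kept
}

#' Drug-tumor synthetic-rescue score
#'
#' For each sample, the fraction `C` of the drug's rescuer genes that are
#' upregulated in the tumor, where the rescuers are the union over the
#' drug's targets of their DU rescuers in the network, and "upregulated"
#' means tertile state +1 in mRNA or SCNA (set `rule = "mRNA_only"` to use
#' expression alone). Higher `C` predicts resistance to the drug.
#'
#' @param act_mrna,act_scna activity matrices of the pre-treatment tumors
#'   (`act_scna` may be `NULL` with `rule = "mRNA_only"`).
#' @param network an `sr_network` (DU) or its edge tibble.
#' @param drug_map tibble from [read_drug_target_map()].
#' @param drug drug name.
#' @param samples sample ids to score (default: all columns).
#' @param rule `"either"` (default) or `"mRNA_only"`.
#' @return Tibble with `sample_id`, `drug`, `C`, `n_rescuers`; errors if
#'   the drug has no rescuers in the network.
#' @export
drug_sr_score <- function(act_mrna, act_scna, network, drug_map, drug,
                          samples = colnames(act_mrna),
                          rule = c("either", "mRNA_only")) {
  rule <- match.arg(rule)
  edges <- if (inherits(network, "sr_network")) network$edges else
    tibble::as_tibble(network)
  targets <- drug_map$target_gene[drug_map$drug == drug]
  if (!length(targets)) stop("drug '", drug, "' not in the drug map")
  rescuers <- unique(edges$rescuer[edges$vulnerable %in% targets])
  rescuers <- intersect(rescuers, rownames(act_mrna))
  if (!length(rescuers)) {
    stop("no rescuers of the targets of '", drug, "' in the network")
  }
  up_m <- unclass(act_mrna)[rescuers, samples, drop = FALSE] == 1L
  up <- if (rule == "either" && !is.null(act_scna)) {
    up_m | (unclass(act_scna)[rescuers, samples, drop = FALSE] == 1L)
  } else up_m
  tibble::tibble(sample_id = samples, drug = drug,
                 C = unname(colMeans(up)), n_rescuers = length(rescuers))
}

#' Survival association of the drug-tumor rescue score
#'
#' Stratified Cox model of treated patients' survival on the rescue-burden
#' score `C`: `h_g(t) = h_0g(t) * exp(b1*C + b2*age + b3*GII)`, strata =
#' cancer type x sex x race, all continuous covariates inverse-normal
#' transformed. Significance of `b1` by 1-df likelihood-ratio test.
#'
#' @param scores tibble from [drug_sr_score()] (one row per patient).
#' @param clinical clinical tibble with `gii`.
#' @param min_patients minimum treated patients (default 30).
#' @return One-row tibble with `beta1`, `p_lrt`, `p_wald`, `n`.
#' @export
survival_association <- function(scores, clinical, min_patients = 30L) {
  df <- dplyr::inner_join(scores, clinical, by = "sample_id")
  if (nrow(df) < min_patients) {
    stop("need >= ", min_patients, " treated patients with scores")
  }
  if (max(df$C) == min(df$C)) stop("constant rescue score C")
  strat <- interaction(df$cancer_type, df$race, df$sex, drop = TRUE)
  dat <- data.frame(time = df$time_days, event = df$event,
                    C = inverse_normal_transform(df$C),
                    age = inverse_normal_transform(df$age),
                    gii = inverse_normal_transform(df$gii),
                    strat = strat)
  full <- survival::coxph(survival::Surv(time, event) ~ C + age + gii +
                            strata(strat), data = dat, ties = "efron")
  null <- survival::coxph(survival::Surv(time, event) ~ age + gii +
                            strata(strat), data = dat, ties = "efron")
  lrt <- max(2 * (full$loglik[2L] - null$loglik[2L]), 0)
  sm <- summary(full)
  tibble::tibble(beta1 = unname(stats::coef(full)["C"]),
                 p_lrt = stats::pchisq(lrt, 1L, lower.tail = FALSE),
                 p_wald = sm$coefficients["C", "Pr(>|z|)"],
                 n = nrow(df))
}

#' Compare rescue scores between RECIST response groups
#'
#' Responders are CR and PR; non-responders are SD and PD. Tests the
#' one-sided alternative that non-responders carry higher rescue burden
#' `C` (Wilcoxon rank-sum, exact when sample sizes permit).
#'
#' @param scores tibble with `sample_id`, `C`.
#' @param recist tibble with `sample_id`, `response` in
#'   \{CR, PR, SD, PD\}.
#' @return One-row tibble with `p`, `direction`, group sizes and means.
#' @export
recist_compare <- function(scores, recist) {
  df <- dplyr::inner_join(scores, recist, by = "sample_id")
  if (!all(df$response %in% c("CR", "PR", "SD", "PD"))) {
    stop("response must be one of CR, PR, SD, PD")
  }
  resp <- df$C[df$response %in% c("CR", "PR")]
  nonresp <- df$C[df$response %in% c("SD", "PD")]
  if (!length(resp) || !length(nonresp)) {
    stop("both responder and non-responder groups must be non-empty")
  }
  wt <- stats::wilcox.test(nonresp, resp, alternative = "greater")
  tibble::tibble(p = wt$p.value,
                 direction = if (mean(nonresp) > mean(resp))
                   "non-responders higher" else "responders higher",
                 n_responders = length(resp),
                 n_nonresponders = length(nonresp),
                 mean_C_responders = mean(resp),
                 mean_C_nonresponders = mean(nonresp))
}

#' Unsupervised AUC of the rescue score for non-response
#'
#' Rank-based AUC (tie-corrected) of `C` for discriminating non-responders
#' from responders, with the orientation rule applied mechanically: if the
#' computed AUC exceeds 0.5 while the mean rescue fraction is higher in
#' responders, `1 - AUC` is reported instead.
#'
#' @param scores numeric rescue scores `C`.
#' @param nonresponder logical vector (TRUE = non-responder).
#' @return AUC in \[0, 1\].
#' @export
unsupervised_auc <- function(scores, nonresponder) {
  nonresponder <- as.logical(nonresponder)
  if (!any(nonresponder) || all(nonresponder)) {
    stop("both classes must be present")
  }
  pos <- scores[nonresponder]
  neg <- scores[!nonresponder]
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  if (auc > 0.5 && mean(neg) > mean(pos)) auc <- 1 - auc
  auc
}

#' Remove samples treated with a drug from a cohort
#'
#' Anti-circularity rule for drug-specific network inference: rescuers of a
#' drug's targets are inferred from patients never exposed to the drug.
#'
#' @param clinical clinical tibble.
#' @param drug drug name.
#' @param treatment tibble with `sample_id`, `drug`.
#' @return The clinical tibble without the treated samples (a message
#'   reports how many were removed).
#' @export
exclude_treated_patients <- function(clinical, drug, treatment) {
  treated <- unique(treatment$sample_id[treatment$drug == drug])
  out <- clinical[!clinical$sample_id %in% treated, ]
  message(nrow(clinical) - nrow(out), " treated sample(s) excluded for ",
          drug)
  out
}
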