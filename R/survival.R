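# Survival and association analytics: Kaplan-Meier / log-rank, Cox
# proportional hazards, likelihood-ratio comparison, bootstrap AUC,
# IPCW time-dependent AUC, Wald chi-square contribution decomposition,
# optimal-cutoff dichotomisation and responder analyses.

#' Kaplan-Meier curves and the log-rank test
#'
#' @param time,event follow-up time and event indicator (1 = event).
#' @param group grouping factor with at least 2 non-empty levels.
#' @return list: `fit` (a `survfit` for plotting), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) {
    stop("log-rank test needs at least 2 non-empty groups", call. = FALSE)
  }
  if (any(table(group) == 0L)) {
    stop("every group must contain at least one subject", call. = FALSE)
  }
  d <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd$n) - 1
  list(fit = survival::survfit(survival::Surv(time, event) ~ group,
                               data = d),
       chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Fit a Cox proportional hazards model
#'
#' Partial-likelihood maximisation with Efron tie handling. Categorical
#' terms are dummy-coded against configurable reference levels (defaults:
#' low stratum, T1, N0, age <= 75, female, MMR proficient). Returns
#' per-coefficient hazard ratios with 95% Wald intervals and per-term Wald
#' chi-square statistics (quadratic form over each term's coefficient
#' block).
#'
#' @param data data frame of survival records.
#' @param terms character vector of covariate column names.
#' @param time_col,event_col endpoint columns (e.g. `os_time`/`os_event`).
#' @param ref_levels named list of reference levels applied to factor
#'   terms when present.
#' @return object of class `sia_cox`: `coefficients` (data frame with
#'   `term`, `level`, `coef`, `se`, `hr`, `ci_lo`, `ci_hi`, `wald_p`),
#'   `loglik` (null, model), `term_chisq`, `fit` (the `coxph` object).
#' @export
cox_fit <- function(data, terms, time_col = "os_time",
                    event_col = "os_event",
                    ref_levels = list(sia_stratum = "low",
                                      is_category = "Low",
                                      t_stage = "T1", n_stage = "N0",
                                      age_group = "<=75", sex = "female",
                                      msi = "proficient")) {
  if (sum(data[[event_col]], na.rm = TRUE) < 1) {
    stop("Cox model needs at least one event", call. = FALSE)
  }
  for (tm in terms) {
    if (is.character(data[[tm]]) || is.factor(data[[tm]])) {
      data[[tm]] <- as.factor(data[[tm]])
      if (!is.null(ref_levels[[tm]]) &&
          ref_levels[[tm]] %in% levels(data[[tm]])) {
        data[[tm]] <- stats::relevel(data[[tm]], ref_levels[[tm]])
      }
    }
  }
  fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s",
                                   time_col, event_col,
                                   paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron", x = TRUE)
  if (!is.null(fit$info) && grepl("did not converge", fit$info %||% "")) {
    stop("Cox model did not converge", call. = FALSE)
  }
  s <- summary(fit)
  co <- s$coefficients
  assign_idx <- fit$assign
  term_names <- names(assign_idx)
  V <- fit$var
  term_chisq <- vapply(assign_idx, function(ix) {
    b <- fit$coefficients[ix]
    as.numeric(t(b) %*% solve(V[ix, ix, drop = FALSE]) %*% b)
  }, numeric(1))
  coef_df <- data.frame(
    term = rep(term_names, lengths(assign_idx)),
    level = rownames(co),
    coef = co[, "coef"], se = co[, "se(coef)"],
    hr = exp(co[, "coef"]),
    ci_lo = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    ci_hi = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    wald_p = co[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(coefficients = coef_df,
              loglik = c(null = fit$loglik[1], model = fit$loglik[2]),
              term_chisq = term_chisq, terms = terms, n = fit$n,
              n_event = fit$nevent, fit = fit)
  class(out) <- "sia_cox"
  out
}

#' @export
print.sia_cox <- function(x, ...) {
  cat(sprintf("Cox proportional hazards fit (%d subjects, %d events)\n",
              x$n, x$n_event))
  print(transform(x$coefficients,
                  hr = signif(hr, 3), ci_lo = signif(ci_lo, 3),
                  ci_hi = signif(ci_hi, 3), wald_p = signif(wald_p, 2),
                  coef = NULL, se = NULL), row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio comparison of nested Cox models
#'
#' @param fit_nested,fit_full `sia_cox` fits on the same records; the
#'   nested model's terms must be a subset of the full model's.
#' @return list: `statistic` = 2 (ll_full - ll_nested), `df`, `p`.
#' @export
lrt_compare <- function(fit_nested, fit_full) {
  if (!all(fit_nested$terms %in% fit_full$terms)) {
    stop("models are not nested", call. = FALSE)
  }
  if (fit_nested$n != fit_full$n) {
    stop("models were fitted on different records", call. = FALSE)
  }
  stat <- 2 * (fit_full$loglik["model"] - fit_nested$loglik["model"])
  df <- nrow(fit_full$coefficients) - nrow(fit_nested$coefficients)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = unname(max(stat, 0)), df = df, p = unname(p))
}

#' Bootstrap distribution of the AUC of a survival score
#'
#' The outcome is the event indicator over follow-up (default) or by a
#' fixed horizon (subjects censored before the horizon are dropped in that
#' mode). Each bootstrap replicate resamples patients with replacement,
#' stratified on outcome, and computes the rank-statistic AUC of the score
#' against the outcome.
#'
#' @param score per-patient score (e.g. a Cox linear predictor).
#' @param time,event follow-up and event indicator.
#' @param B bootstrap replicates.
#' @param horizon optional fixed horizon defining the outcome.
#' @param seed optional integer seed.
#' @return list: `median`, `ci` (2.5/97.5 percentiles), `aucs`.
#' @export
bootstrap_auc <- function(score, time, event, B = 1000, horizon = NULL,
                          seed = NULL) {
  set_seed_if(seed)
  if (!is.null(horizon)) {
    keep <- event == 1 | time >= horizon
    outcome <- as.integer(event[keep] == 1 & time[keep] <= horizon)
    score <- score[keep]
  } else {
    outcome <- as.integer(event == 1)
  }
  if (length(unique(outcome)) < 2L) {
    stop("outcome has a single class; AUC undefined", call. = FALSE)
  }
  cases <- which(outcome == 1L); controls <- which(outcome == 0L)
  aucs <- vapply(seq_len(B), function(b) {
    idx <- c(sample(cases, replace = TRUE), sample(controls, replace = TRUE))
    auc_rank(score[idx], outcome[idx])
  }, numeric(1))
  list(median = stats::median(aucs),
       ci = stats::quantile(aucs, c(0.025, 0.975), names = FALSE),
       aucs = aucs)
}

# Kaplan-Meier estimate of the censoring survival function G, returned as
# step functions for G(t) and the left limit G(t-).
censoring_km <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  list(G = stats::stepfun(sf$time, c(1, sf$surv), right = FALSE),
       G_left = stats::stepfun(sf$time, c(1, sf$surv), right = TRUE))
}

#' Time-dependent AUC with inverse-probability-of-censoring weighting
#'
#' Cumulative-case / dynamic-control AUC: at each evaluation time t, cases
#' are subjects with an event by t (weighted 1/G(T-)), controls those
#' still at risk beyond t (weighted 1/G(t)), with G the Kaplan-Meier
#' estimate of the censoring distribution. Without censoring this equals
#' the exhaustive proportion of concordant (case, control) score pairs.
#'
#' @param score per-patient score (higher = higher risk).
#' @param time,event follow-up and event indicator.
#' @param eval_times evaluation times; times beyond the last observed
#'   follow-up are dropped with a warning.
#' @return data frame: `t`, `auc`, `n_cases`, `n_controls`.
#' @export
time_dependent_auc <- function(score, time, event, eval_times) {
  drop <- eval_times > max(time)
  if (any(drop)) {
    warning(sprintf("dropping %d evaluation time(s) beyond follow-up",
                    sum(drop)))
    eval_times <- eval_times[!drop]
  }
  km <- censoring_km(time, event)
  rows <- lapply(eval_times, function(t0) {
    is_case <- time <= t0 & event == 1
    is_ctrl <- time > t0
    if (!any(is_case) || !any(is_ctrl)) {
      return(data.frame(t = t0, auc = NA_real_, n_cases = sum(is_case),
                        n_controls = sum(is_ctrl)))
    }
    w_case <- 1 / pmax(km$G_left(time[is_case]), .Machine$double.eps)
    w_ctrl <- rep(1 / pmax(km$G(t0), .Machine$double.eps), sum(is_ctrl))
    sc <- score[is_case]; st <- score[is_ctrl]
    # weighted concordance: sum_i sum_j w_i w_j [1(sc_i > st_j) + .5 ties]
    conc <- outer(sc, st, ">") + 0.5 * outer(sc, st, "==")
    num <- as.numeric(t(w_case) %*% conc %*% w_ctrl)
    den <- sum(w_case) * sum(w_ctrl)
    data.frame(t = t0, auc = num / den, n_cases = sum(is_case),
               n_controls = sum(is_ctrl))
  })
  do.call(rbind, rows)
}

#' Relative Wald chi-square contribution of each model term
#'
#' Per term, the Wald chi-square is the quadratic form of the term's
#' coefficient block with the inverse of its covariance block (so a
#' multi-level factor contributes through all its dummy coefficients
#' jointly); contributions are reported as proportions of the total,
#' summing to 1.
#'
#' @param fit a `sia_cox` fit with at least one term.
#' @return data frame: `term`, `chisq`, `df`, `proportion`.
#' @export
wald_contributions <- function(fit) {
  chisq <- fit$term_chisq
  if (!length(chisq)) stop("fit has no terms", call. = FALSE)
  data.frame(term = names(chisq), chisq = unname(chisq),
             df = unname(lengths(fit$fit$assign)),
             proportion = unname(chisq / sum(chisq)),
             stringsAsFactors = FALSE)
}

#' Optimal-cutoff dichotomisation against survival
#'
#' Scans every observed score value inside the configured quantile window
#' as a candidate cutoff (group = score > cutoff), computes the log-rank p
#' for each, and returns the cutoff minimising p. The minimised p is
#' optimistically biased by the scan (multiple testing is deliberately not
#' corrected, mirroring common practice); the output metadata say so.
#'
#' @param values per-patient scores.
#' @param time,event follow-up and event indicator.
#' @param window quantile window searched (default c(0.10, 0.90)); a
#'   degenerate window `c(q, q)` returns that quantile directly.
#' @return list: `cutoff`, `group` (factor low/high), `p`, `chisq`,
#'   `n_candidates`, `note`.
#' @export
optimal_cutoff_dichotomize <- function(values, time, event,
                                       window = c(0.10, 0.90)) {
  if (length(unique(values)) < 2L) {
    stop("all values identical: no cutoff exists", call. = FALSE)
  }
  if (sum(event) < 1) stop("no events observed", call. = FALSE)
  note <- paste("minimised log-rank p is optimistic: it is the minimum",
                "over all scanned cutoffs and is not corrected for",
                "multiple testing")
  qq <- stats::quantile(values, window, type = 7)
  if (window[1] == window[2]) {
    cutoff <- unname(qq[1])
  } else {
    cand <- sort(unique(values))
    cand <- cand[cand >= qq[1] & cand <= qq[2]]
    cand <- cand[cand < max(values)]   # both groups must be non-empty
    if (!length(cand)) stop("no candidate cutoffs in window", call. = FALSE)
    ps <- vapply(cand, function(ct) {
      g <- factor(ifelse(values > ct, "high", "low"),
                  levels = c("low", "high"))
      if (min(table(g)) == 0) return(NA_real_)
      km_logrank(time, event, g)$p
    }, numeric(1))
    if (all(is.na(ps))) stop("no valid cutoff in window", call. = FALSE)
    cutoff <- cand[which.min(ps)]
  }
  group <- factor(ifelse(values > cutoff, "high", "low"),
                  levels = c("low", "high"))
  lr <- km_logrank(time, event, group)
  list(cutoff = cutoff, group = group, p = lr$p, chisq = lr$chisq,
       n_candidates = if (window[1] == window[2]) 1L else length(cand),
       note = note)
}

#' Responder analyses: Mann-Whitney, ROC AUC, Spearman
#'
#' Compares a per-patient score between two response groups with the
#' Mann-Whitney U test (exact when the pooled sample size is at most 20
#' and tie-free, normal approximation with tie correction otherwise),
#' reports the ROC AUC with a bootstrap confidence interval, and - when an
#' ordinal response coding is supplied (e.g. non-responder < partial <
#' complete) - the Spearman rank correlation.
#'
#' @param scores per-patient scores.
#' @param group two-level factor; the **second** level is treated as the
#'   responder / positive class.
#' @param ordinal optional ordinal response coding for the Spearman test.
#' @param alternative passed to [stats::wilcox.test()] (U of the first
#'   group).
#' @param boot_n bootstrap replicates for the AUC confidence interval.
#' @return list: `u`, `p_mw`, `auc`, `auc_ci`, `rho`, `p_rho`.
#' @export
responder_tests <- function(scores, group, ordinal = NULL,
                            alternative = "two.sided", boot_n = 1000) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L || any(table(group) < 2L)) {
    stop("need two response groups with at least 2 patients each",
         call. = FALSE)
  }
  x <- scores[group == levels(group)[1]]
  y <- scores[group == levels(group)[2]]
  exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(scores)
  wt <- stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                           correct = !exact)
  roc <- pROC::roc(response = group, predictor = scores,
                   levels = levels(group), direction = "<", quiet = TRUE)
  ci <- pROC::ci.auc(roc, method = "bootstrap", boot.n = boot_n)
  res <- list(u = unname(wt$statistic), p_mw = wt$p.value,
              auc = as.numeric(pROC::auc(roc)),
              auc_ci = c(ci[1], ci[3]))
  if (!is.null(ordinal)) {
    ct <- suppressWarnings(
      stats::cor.test(scores, as.numeric(ordinal), method = "spearman",
                      exact = FALSE))
    res$rho <- unname(ct$estimate)
    res$p_rho <- ct$p.value
  }
  res
}
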