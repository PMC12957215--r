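# Score-stratified survival contrasts (Kaplan-Meier + log-rank + age-adjusted
# Cox hazard ratio) and the univariate Cox screen over signature genes.

#' Stratify a cohort by a score and test survival separation
#'
#' Splits samples into high/low groups at a cutpoint (ties go to low),
#' computes Kaplan-Meier curves per group, the log-rank test, and the
#' high-vs-low hazard ratio from a Cox proportional-hazards fit with patient
#' age as a covariate (the age correction accompanying the KM display).
#'
#' @param cohort a [bulk_cohort()].
#' @param score per-sample numeric vector, named by sample or aligned with
#'   `cohort$clinical$sample`.
#' @param cutpoint `"median"` (cohort median of the score) or a numeric value.
#' @return object of class `survival_result`: list with `cutpoint_value`,
#'   `group` (per-sample factor low/high), `km` (data.frame `group`, `time`,
#'   `n_risk`, `n_event`, `surv`), `logrank_chisq`, `logrank_p`, `hr`,
#'   `hr_ci` (95%), and the underlying `cox` fit.
#' @export
stratify_and_test <- function(cohort, score, cutpoint = "median") {
  if (!inherits(cohort, "bulk_cohort")) stopf("cohort must be a bulk_cohort")
  cli <- cohort$clinical
  if (!is.null(names(score))) {
    if (!all(cli$sample %in% names(score)))
      stopf("score is missing some cohort samples")
    score <- score[cli$sample]
  } else if (length(score) != nrow(cli))
    stopf("score length != number of samples")
  cut_val <- if (identical(cutpoint, "median")) stats::median(score)
             else assert_scalar_num(cutpoint, "cutpoint")
  grp <- factor(ifelse(score > cut_val, "high", "low"), levels = c("low", "high"))
  if (any(table(grp) == 0L))
    stopf("cutpoint %.6g leaves the '%s' group empty", cut_val,
          names(which(table(grp) == 0L))[1])
  if (sum(cli$event) == 0L) stopf("no events in the cohort")

  srv <- survival::Surv(cli$OS_time, cli$event)
  fit_km <- survival::survfit(srv ~ grp)
  strata_grp <- rep(sub("^grp=", "", names(fit_km$strata)), fit_km$strata)
  km <- data.frame(group = strata_grp, time = fit_km$time,
                   n_risk = fit_km$n.risk, n_event = fit_km$n.event,
                   surv = fit_km$surv, stringsAsFactors = FALSE)
  lr <- survival::survdiff(srv ~ grp)
  lr_p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  cox <- survival::coxph(srv ~ grp + age, data = data.frame(grp = grp, age = cli$age))
  hr <- unname(exp(stats::coef(cox)["grphigh"]))
  ci <- exp(stats::confint(cox)["grphigh", ])
  structure(list(cutpoint = cutpoint, cutpoint_value = cut_val, group = grp,
                 km = km, logrank_chisq = unname(lr$chisq), logrank_p = lr_p,
                 hr = hr, hr_ci = unname(ci), cox = cox),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("survival_result: high/low split at %.4g (%s cutpoint)\n",
              x$cutpoint_value, if (identical(x$cutpoint, "median")) "median" else "fixed"))
  cat(sprintf("  log-rank chisq = %.3f, p = %.3g\n", x$logrank_chisq, x$logrank_p))
  cat(sprintf("  age-adjusted HR (high vs low) = %.3f [%.3f, %.3f]\n",
              x$hr, x$hr_ci[1], x$hr_ci[2]))
  invisible(x)
}

#' Univariate Cox screen over a gene panel
#'
#' Fits a single-covariate Cox proportional-hazards model per gene on
#' standardized expression, adjusts Wald p-values by Benjamini-Hochberg
#' across the tested genes, and flags the direction of the association.
#'
#' @param cohort a [bulk_cohort()].
#' @param genes gene identifiers present in the expression matrix.
#' @return data.frame of class `univariate_screen`: `gene`, `log_hr`, `se`,
#'   `p`, `p_adj`, `direction` (`"risk"` for positive log-HR, else
#'   `"protective"`). Constant genes are excluded with a warning.
#' @export
univariate_screen <- function(cohort, genes) {
  if (!inherits(cohort, "bulk_cohort")) stopf("cohort must be a bulk_cohort")
  missing <- setdiff(genes, rownames(cohort$expression))
  if (length(missing))
    stopf("genes absent from the expression matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  cli <- cohort$clinical
  x <- cohort$expression[genes, cli$sample, drop = FALSE]
  srv <- survival::Surv(cli$OS_time, cli$event)
  const <- apply(x, 1L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warnf("excluding %d constant gene(s): %s", sum(const),
          paste(utils::head(genes[const], 5), collapse = ", "))
    x <- x[!const, , drop = FALSE]
  }
  if (!nrow(x)) stopf("no non-constant genes to screen")
  rows <- lapply(rownames(x), function(g) {
    fit <- survival::coxph(srv ~ v, data = data.frame(v = as.numeric(scale(x[g, ]))))
    s <- summary(fit)$coefficients
    data.frame(gene = g, log_hr = s[1, "coef"], se = s[1, "se(coef)"],
               p = s[1, "Pr(>|z|)"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out$direction <- ifelse(out$log_hr > 0, "risk", "protective")
  rownames(out) <- NULL
  class(out) <- c("univariate_screen", "data.frame")
  out
}
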