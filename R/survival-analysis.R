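# Development-phase prognosis analysis. Kaplan-Meier, log-rank and Cox
# fits delegate to the survival package (Efron ties); this module owns
# the stratification by prediction score, the covariate dichotomies and
# the table assembly.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator; censored times do not drop the curve. The
#' median is the first time with `S(t) <= 0.5`, or `NA` ("not
#' reached") if the curve never crosses 0.5.
#'
#' @param time event/censoring times (months), > 0.
#' @param event 1 = event observed, 0 = censored.
#' @return list with `time`, `surv`, `n_risk`, `n_event`, `median`.
#' @export
kmEstimate <- function(time, event) {
  stopifnot(length(time) >= 1, all(time > 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- unname(summary(fit)$table["median"])
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, median = med)
}

#' Log-rank test between two groups
#'
#' One-degree-of-freedom log-rank statistic over the pooled event
#' times. With no events at all the test is undefined; chi-square 0 and
#' p = 1 are returned with a warning.
#'
#' @param time,event pooled times and event flags.
#' @param group two-level grouping factor/vector.
#' @return list with `chi_square`, `p_value`.
#' @export
logrankTest <- function(time, event, group) {
  g <- factor(group)
  stopifnot(nlevels(g) == 2, all(table(g) > 0))
  if (sum(event) == 0) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(list(chi_square = 0, p_value = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(chi_square = unname(sd$chisq),
       p_value = unname(pchisq(sd$chisq, df = 1, lower.tail = FALSE)))
}

#' Cox proportional-hazards fit
#'
#' Efron tie handling, Newton-Raphson with at most 50 iterations.
#' Constant covariates are rejected (collinearity check via the design
#' matrix rank). A monotone partial likelihood (perfect separation,
#' detected as an extreme coefficient) flags the fit unstable rather
#' than failing.
#'
#' @param data data.frame with columns `time`, `event` and the
#'   covariates.
#' @param covariates character vector of covariate column names.
#' @param ties tie method, default "efron".
#' @return list with per-covariate data.frame `coef` (columns `term`,
#'   `beta`, `hr`, `ci_low`, `ci_high`, `p`), `loglik`, `converged`,
#'   `unstable`, `ties`.
#' @export
coxFit <- function(data, covariates, ties = "efron") {
  stopifnot(all(c("time", "event") %in% names(data)),
            all(covariates %in% names(data)), sum(data$event) >= 1)
  X <- stats::model.matrix(
    stats::reformulate(covariates), data = data)[, -1, drop = FALSE]
  if (any(apply(X, 2, sd) == 0) || qr(X)$rank < ncol(X))
    stop("collinear or constant covariate(s) in: ",
         paste(covariates, collapse = ", "))
  fml <- stats::reformulate(covariates,
                            response = "survival::Surv(time, event)")
  fit <- survival::coxph(fml, data = data, ties = ties,
                         control = survival::coxph.control(iter.max = 50))
  if (fit$iter >= 50)
    stop("Cox fit failed to converge in 50 iterations")
  s <- summary(fit)
  co <- data.frame(term = rownames(s$coefficients),
                   beta = s$coefficients[, "coef"],
                   hr = s$coefficients[, "exp(coef)"],
                   ci_low = s$conf.int[, "lower .95"],
                   ci_high = s$conf.int[, "upper .95"],
                   p = s$coefficients[, "Pr(>|z|)"],
                   row.names = NULL)
  unstable <- any(abs(co$beta) > 15) || any(!is.finite(co$ci_high))
  if (unstable)
    warning("monotone likelihood suspected; CI unstable")
  list(coef = co, loglik = fit$loglik[2], converged = fit$iter < 50,
       unstable = unstable, ties = ties)
}

# Dichotomize the clinical covariates the way the prognosis tables
# define them; reference level second so HR < 1 means the first-named
# level is protective (e.g. "High" score vs "Low").
.prognosisFrame <- function(clinical, scores, threshold, endpoint) {
  stopifnot(all(clinical$case_id %in% scores$case_id))
  sc <- scores$score[match(clinical$case_id, scores$case_id)]
  tm <- clinical[[paste0(endpoint, "_months")]]
  ev <- clinical[[paste0(endpoint, "_event")]]
  data.frame(
    case_id = clinical$case_id,
    time = tm, event = ev,
    age_group = factor(ifelse(clinical$age < median(clinical$age),
                              "young", "old"), c("old", "young")),
    sex = factor(clinical$sex, c("M", "F")),
    t_stage_group = factor(ifelse(clinical$t_stage <= 2, "T1-2", "T3-4"),
                           c("T3-4", "T1-2")),
    n_group = factor(ifelse(clinical$n_stage <= 1, "N0-1", "N2-4"),
                     c("N2-4", "N0-1")),
    scc_group = factor(ifelse(clinical$scc <= 1.5, "low", "high"),
                       c("high", "low")),
    location_group = factor(ifelse(clinical$location == "Ut",
                                   "upper", "mid-low"),
                            c("mid-low", "upper")),
    score_group = factor(ifelse(sc >= threshold, "High", "Low"),
                         c("Low", "High")))
}

.UNIVARIATE_VARS <- c("age_group", "sex", "t_stage_group", "n_group",
                      "scc_group", "location_group", "score_group")

#' Run the full prognosis analysis
#'
#' Stratifies cases into high/low prediction-score groups at the given
#' cutoff; for each endpoint (PFS, OS) emits Kaplan-Meier curves and
#' medians per group, the log-rank test, univariate Cox fits for the
#' seven standard variables (age, sex, T stage, lymph node metastasis,
#' SCC antigen, tumor location, prediction score), and a multivariate
#' Cox including every variable with univariate p < 0.05.
#'
#' @param scores data.frame with `case_id`, `score` (one row per case).
#' @param threshold score cutoff; score >= threshold = "High".
#' @param clinical clinical table (as written by [generateCohort()]).
#' @return nested list: per endpoint, `km` (per group), `medians`,
#'   `logrank`, `univariate` (7 rows), `multivariate`.
#' @export
runPrognosis <- function(scores, threshold, clinical) {
  need <- c("case_id", "pfs_months", "pfs_event", "os_months", "os_event")
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (endpoint in c("pfs", "os")) {
    df <- .prognosisFrame(clinical, scores, threshold, endpoint)
    for (lv in levels(df$score_group))
      if (!any(df$score_group == lv))
        stop("score stratum '", lv, "' has zero cases at cutoff ", threshold)
    km <- lapply(split(df, df$score_group), function(g)
      kmEstimate(g$time, g$event))
    lr <- logrankTest(df$time, df$event, df$score_group)
    uni <- do.call(rbind, lapply(.UNIVARIATE_VARS, function(v) {
      fit <- tryCatch(coxFit(df, v), error = function(e) NULL)
      if (is.null(fit))
        return(data.frame(term = v, beta = NA, hr = NA, ci_low = NA,
                          ci_high = NA, p = NA))
      cbind(variable = v, fit$coef)[, c("variable", "beta", "hr",
                                        "ci_low", "ci_high", "p")]
    }))
    sig <- unique(uni$variable[!is.na(uni$p) & uni$p < 0.05])
    multi <- if (length(sig) >= 2) {
      tryCatch(coxFit(df, sig)$coef, error = function(e) NULL)
    } else if (length(sig) == 1) {
      uni[uni$variable %in% sig, -1]
    } else NULL
    out[[endpoint]] <- list(
      km = km,
      medians = vapply(km, `[[`, numeric(1), "median"),
      logrank = lr,
      univariate = uni,
      multivariate = multi,
      multivariate_terms = sig)
  }
  out
}

#' Write a prognosis report as JSON + KM curve CSVs
#'
#' @param report result of [runPrognosis()].
#' @param dir output directory.
#' @param prefix filename prefix (e.g. "all_cases").
#' @return invisibly, the JSON path.
#' @export
writePrognosis <- function(report, dir, prefix = "prognosis") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (endpoint in names(report)) {
    km <- report[[endpoint]]$km
    curves <- do.call(rbind, lapply(names(km), function(g)
      data.frame(group = g, time = km[[g]]$time, surv = km[[g]]$surv,
                 n_risk = km[[g]]$n_risk)))
    write.csv(curves,
              file.path(dir, sprintf("%s_%s_km.csv", prefix, endpoint)),
              row.names = FALSE)
  }
  slim <- lapply(report, function(ep)
    list(medians = as.list(ep$medians), logrank = ep$logrank,
         univariate = ep$univariate, multivariate = ep$multivariate))
  p <- file.path(dir, paste0(prefix, "_survival_report.json"))
  jsonlite::write_json(slim, p, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(p)
}
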