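# Prognostic validation harness: Kaplan-Meier, log-rank, Cox models
# stratified by any grading system, with cohort/stage subgroup filters.
# The numerical backend is the survival package; this module contributes
# the grading-to-survival plumbing, covariate encodings and report format.

#' Validate a survival record table
#'
#' @param records data.frame with columns `case_id`, `time` (months, > 0),
#'   `event` (0/1), and optionally `endpoint` (OS/CSS/PFS), `pT` (1..4),
#'   `pN` (0..2, where 2 pools pN2-pN3), `age` (years), `stage`
#'   (I..IV), `cohort`.
#' @return the validated data.frame (class `survival_records`).
#' @export
survival_records <- function(records) {
  req <- c("case_id", "time", "event")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(records$time) | records$time <= 0))
    stop("time must be positive for all cases")
  if (!all(records$event %in% c(0, 1)))
    stop("event must be 0/1")
  if ("pT" %in% names(records) &&
      !all(is.na(records$pT) | records$pT %in% 1:4))
    stop("pT must be in 1..4 or missing")
  if ("pN" %in% names(records) &&
      !all(is.na(records$pN) | records$pN %in% 0:2))
    stop("pN must be in 0..2 (2 pools pN2-pN3) or missing")
  if ("stage" %in% names(records) &&
      !all(is.na(records$stage) | records$stage %in% c("I","II","III","IV")))
    stop("stage must be I..IV or missing")
  class(records) <- unique(c("survival_records", class(records)))
  records
}

#' Kaplan-Meier curves and log-rank test across grade groups
#'
#' Fits product-limit survival curves per grade group and computes the
#' k-sample log-rank chi-square with k - 1 degrees of freedom. Groups with
#' zero events are retained with a warning.
#'
#' @param records a [survival_records()] table (already filtered to one
#'   endpoint).
#' @param group grouping vector (e.g. grade labels) aligned with
#'   `records`, or the name of a column in `records`.
#' @return list with `fit` (a `survfit` object), `chisq`, `df`, `p`,
#'   `groups` (per-group n, events, median survival).
#' @export
km_logrank <- function(records, group) {
  if (length(group) == 1L && is.character(group) &&
      group %in% names(records)) group <- records[[group]]
  g <- factor(group)
  if (nlevels(droplevels(g)) < 2L) stop("need at least 2 non-empty groups")
  time <- records$time; event <- records$event
  ev_by_g <- tapply(event, g, sum)
  if (any(ev_by_g == 0, na.rm = TRUE))
    warning("groups with zero events: ",
            paste(names(ev_by_g)[which(ev_by_g == 0)], collapse = ", "))
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- length(sd$n) - 1
  med <- summary(fit)$table
  med <- if (is.matrix(med)) med[, "median"] else med["median"]
  names(med) <- sub("^g=", "", names(med))
  groups <- data.frame(group = levels(droplevels(g)),
                       n = as.vector(table(droplevels(g))),
                       events = as.vector(tapply(event, droplevels(g), sum)),
                       median = as.numeric(med[levels(droplevels(g))]),
                       stringsAsFactors = FALSE)
  list(fit = fit, chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       groups = groups)
}

#' Cox proportional-hazards fit of grade with clinicopathological covariates
#'
#' Fits univariate (grade only) and multivariate (grade + covariates)
#' proportional-hazards models. The grade enters as a factor with the
#' lowest grade as reference; hazard ratios with 95% confidence intervals
#' are reported per non-reference level. Covariates: `pT` ordinal-as-linear
#' by default (categorical by option), `pN` ordinal with pN2-3 pooled as 2,
#' `age` linear in years. Complete-case rows per model; counts reported.
#' Non-convergence or separation is flagged per model, not fatal.
#'
#' @param records a [survival_records()] table.
#' @param group grade vector or column name; its sorted unique values
#'   define the level order, lowest = reference.
#' @param covariates subset of `c("pT", "pN", "age")`, or `character(0)`
#'   for the univariate model only.
#' @param pT_coding "ordinal" (linear) or "categorical".
#' @param grade_coding "categorical" (factor, per-level HRs vs the lowest
#'   grade) or "ordinal" (grade rank as a linear term, one per-step HR).
#' @return data.frame with one row per grade level per model: `model`
#'   ("univariate"/"multivariate"), `term`, `coef`, `HR`, `lower`, `upper`,
#'   `p`, `n`, `flagged`.
#' @export
cox_fit <- function(records, group, covariates = c("pT", "pN", "age"),
                    pT_coding = c("ordinal", "categorical"),
                    grade_coding = c("categorical", "ordinal")) {
  pT_coding <- match.arg(pT_coding)
  grade_coding <- match.arg(grade_coding)
  if (length(group) == 1L && is.character(group) &&
      group %in% names(records)) group <- records[[group]]
  lev <- sort(unique(as.character(group)))
  grade <- factor(as.character(group), levels = lev)
  if (grade_coding == "ordinal") grade <- as.numeric(grade)
  df <- data.frame(time = records$time, event = records$event,
                   grade = grade)
  for (cv in covariates) {
    if (!cv %in% names(records)) stop("covariate absent from records: ", cv)
    df[[cv]] <- records[[cv]]
  }
  if ("pT" %in% covariates && pT_coding == "categorical")
    df$pT <- factor(df$pT)
  one_fit <- function(vars, label) {
    dat <- df[stats::complete.cases(df[, c("time", "event", "grade", vars)]),
              c("time", "event", "grade", vars), drop = FALSE]
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~ grade",
                                   if (length(vars))
                                     paste("+", paste(vars, collapse = " + "))
                                   else ""))
    flagged <- FALSE
    fit <- withCallingHandlers(
      tryCatch(survival::coxph(fml, data = dat),
               error = function(e) { flagged <<- TRUE; NULL }),
      warning = function(w) { flagged <<- TRUE
        invokeRestart("muffleWarning") })
    if (is.null(fit)) {
      return(data.frame(model = label,
                        term = if (grade_coding == "categorical")
                          paste0("grade", lev[-1]) else "grade",
                        coef = NA_real_, HR = NA_real_, lower = NA_real_,
                        upper = NA_real_, p = NA_real_, n = nrow(dat),
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    s <- summary(fit)
    ci <- s$conf.int
    data.frame(model = label, term = rownames(s$coefficients),
               coef = s$coefficients[, "coef"],
               HR = ci[, "exp(coef)"],
               lower = ci[, "lower .95"], upper = ci[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               n = nrow(dat), flagged = flagged,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- one_fit(character(0), "univariate")
  if (length(covariates))
    out <- rbind(out, one_fit(covariates, "multivariate"))
  out
}

#' Subgroup filter for survival records
#'
#' Pure filter by stage, pT and cohort (inclusion or exclusion set),
#' mirroring Stage I / pT1 subgroup analyses and merged-cohort
#' constructions such as "all cohorts minus one".
#'
#' @param records a [survival_records()] table.
#' @param stage,pT keep only rows with these values (NULL = no filter).
#' @param cohort_in keep only these cohorts; `cohort_not` drop these.
#' @return the filtered table; warns when empty.
#' @export
subset_records <- function(records, stage = NULL, pT = NULL,
                           cohort_in = NULL, cohort_not = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(stage)) keep <- keep & !is.na(records$stage) &
      records$stage %in% stage
  if (!is.null(pT)) keep <- keep & !is.na(records$pT) & records$pT %in% pT
  if (!is.null(cohort_in)) keep <- keep & records$cohort %in% cohort_in
  if (!is.null(cohort_not)) keep <- keep & !records$cohort %in% cohort_not
  out <- records[keep, , drop = FALSE]
  if (!nrow(out)) warning("subgroup filter produced an empty record set")
  out
}
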