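# Patient-cohort validation: classify patients by anchor + combined-partner
# damaging-mutation status from MAF-like input and compare survival
# (Kaplan-Meier, log-rank, Cox proportional hazards).

# MAF Variant_Classification values counted as damaging in the cohort.
maf_damaging_classes <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Splice_Site",
  "Translation_Start_Site"
)

#' Classify cohort patients into combined mutation groups
#'
#' A patient is damaging-mutated in a gene when the MAF lists any variant of
#' the four damaging classes (missense, nonsense, splice site, translation
#' start site) for it. Labels follow the combined convention: first letter =
#' anchor status, second = any partner-set gene mutated. Patients need both
#' mutation and clinical data; `drug_filter` optionally keeps only patients
#' exposed to one of the named drugs.
#'
#' @param maf Cohort variant data.frame ([read_maf()]).
#' @param clinical Clinical data.frame ([read_clinical()]).
#' @param anchor Anchor gene symbol.
#' @param partner_set Character vector of partner gene symbols.
#' @param drug_filter Optional character vector of drug names (case
#'   insensitive); default NULL keeps all patients.
#' @param damaging_classes MAF classes treated as damaging.
#' @return Data.frame of class `"cohort_table"`: `patient`, `label`
#'   (WWC/WMC/MWC/MMC), `burden`, `age`, `sex`, `cancer_type`,
#'   `cancer_type_flag` (melanoma vs other), `os_months`, `event`.
#' @export
classify_patients <- function(maf, clinical, anchor, partner_set,
                              drug_filter = NULL,
                              damaging_classes = maf_damaging_classes) {
  stopifnot(all(c("patient", "gene", "variant_classification") %in% names(maf)))
  pts <- clinical
  if (!is.null(drug_filter)) {
    keep <- vapply(pts$drugs, function(d) {
      any(tolower(d) %in% tolower(drug_filter))
    }, logical(1))
    pts <- pts[keep, , drop = FALSE]
  }
  pts <- pts[pts$patient %in% unique(maf$patient), , drop = FALSE]
  if (nrow(pts) == 0) stop("no patients with both mutation and clinical data", call. = FALSE)

  dmg <- maf[maf$variant_classification %in% damaging_classes, , drop = FALSE]
  anchor_mut <- unique(dmg$patient[dmg$gene == anchor])
  partner_tab <- dmg[dmg$gene %in% partner_set, c("patient", "gene"), drop = FALSE]
  partner_tab <- unique(partner_tab)
  burden_by <- table(factor(partner_tab$patient, levels = pts$patient))
  burden <- as.integer(burden_by[pts$patient])
  a <- pts$patient %in% anchor_mut
  label <- ifelse(a,
    ifelse(burden > 0, "MMC", "MWC"),
    ifelse(burden > 0, "WMC", "WWC")
  )
  out <- data.frame(
    patient = pts$patient, label = label, burden = burden,
    age = pts$age, sex = pts$sex, cancer_type = pts$cancer_type,
    cancer_type_flag = ifelse(pts$cancer_type == "SKCM", "melanoma", "other"),
    os_months = pts$os_months, event = pts$event,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_table", "data.frame")
  out
}

km_median <- function(fit) {
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab["median"] else tab[, "median"]
}

#' Kaplan-Meier curves and log-rank test for two patient groups
#'
#' Product-limit curves per group, median overall survival (standard
#' convention: first time the curve reaches 0.5, averaging the two
#' neighbouring event times when it sits exactly at 0.5), the log-rank
#' chi-squared P, and the hazard ratio of `group_a` vs `group_b` from a
#' two-group Cox fit.
#'
#' @param cohort A `cohort_table`.
#' @param group_a,group_b Labels to compare (e.g. "MMC", "WWC"); `group_a`
#'   is the numerator of the hazard ratio.
#' @return List with `fit` (survfit over both groups), `median_os` (named),
#'   `logrank_chisq`, `logrank_p`, `hr`, `hr_ci` (95%), `n` (named sizes).
#' @export
km_logrank <- function(cohort, group_a, group_b) {
  sub <- cohort[cohort$label %in% c(group_a, group_b), , drop = FALSE]
  n <- c(sum(sub$label == group_a), sum(sub$label == group_b))
  names(n) <- c(group_a, group_b)
  if (any(n == 0)) stop("both groups must be non-empty", call. = FALSE)
  sub$grp <- factor(sub$label, levels = c(group_b, group_a)) # reference first
  s <- survival::Surv(sub$os_months, sub$event)
  fit <- survival::survfit(s ~ grp, data = sub)
  med <- km_median(fit)
  names(med) <- sub("^grp=", "", names(med))
  sd <- survival::survdiff(s ~ grp, data = sub)
  chisq <- unname(sd$chisq)
  p <- stats::pchisq(chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  cx <- survival::coxph(s ~ grp, data = sub)
  hr <- unname(exp(stats::coef(cx)))
  ci <- exp(stats::confint(cx))
  list(
    fit = fit, median_os = med, logrank_chisq = chisq, logrank_p = p,
    hr = hr, hr_ci = c(lower = ci[1], upper = ci[2]), n = n
  )
}

#' Kaplan-Meier curve and median for a single group of survival times
#'
#' @param os_months Survival times.
#' @param event Event indicator (TRUE = death observed).
#' @return List with `fit` and `median_os`.
#' @export
km_curve <- function(os_months, event = rep(TRUE, length(os_months))) {
  fit <- survival::survfit(survival::Surv(os_months, event) ~ 1)
  list(fit = fit, median_os = unname(km_median(fit)))
}

cox_tidy <- function(fit) {
  s <- summary(fit)
  data.frame(
    term = rownames(s$coefficients),
    hr = unname(s$coefficients[, "exp(coef)"]),
    ci_lower = unname(s$conf.int[, "lower .95"]),
    ci_upper = unname(s$conf.int[, "upper .95"]),
    p = unname(s$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
}

#' Univariate and multivariate Cox proportional-hazards models
#'
#' Fits one univariate Cox model per covariate (age, sex, cancer-type flag,
#' mutation group) and one joint multivariate model. The mutation profile
#' enters as the 4-level group factor with WWC as reference; pairwise hazard
#' ratios between two specific groups come from [km_logrank()] refits. Ties
#' use Efron's method (the survival default). Monotone-likelihood /
#' separation warnings from the fitter are captured and reported in the
#' result rather than silently dropped.
#'
#' @param cohort A `cohort_table`.
#' @param covariates Character vector of clinical covariates to include
#'   alongside the group factor.
#' @return List with `univariate` (data.frame), `multivariate` (data.frame),
#'   `flags` (character vector of fitter warnings, possibly empty).
#' @export
cox_models <- function(cohort,
                       covariates = c("age", "sex", "cancer_type_flag")) {
  if (sum(cohort$event) == 0) stop("no events observed; Cox model undefined", call. = FALSE)
  if (length(unique(cohort$label)) < 2) {
    stop("need at least two mutation groups", call. = FALSE)
  }
  dat <- cohort
  dat$group <- factor(dat$label, levels = intersect(c("WWC", "WMC", "MWC", "MMC"), unique(dat$label)))
  covariates <- covariates[vapply(
    covariates,
    function(v) length(unique(dat[[v]])) > 1, logical(1)
  )]
  s <- survival::Surv(dat$os_months, dat$event)
  flags <- character()
  fit_safe <- function(formula) {
    withCallingHandlers(
      survival::coxph(formula, data = dat),
      warning = function(w) {
        flags <<- c(flags, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }
  uni <- do.call(rbind, lapply(c(covariates, "group"), function(v) {
    f <- stats::as.formula(paste("s ~", v))
    cox_tidy(fit_safe(f))
  }))
  multi <- cox_tidy(fit_safe(
    stats::as.formula(paste("s ~", paste(c(covariates, "group"), collapse = " + ")))
  ))
  list(univariate = uni, multivariate = multi, flags = unique(flags))
}
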