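# Age- and sex-adjusted association models: binary logistic regression for
# mortality by pattern, multinomial logistic regression for acute-disease
# exposure by pattern.

#' Age- and sex-adjusted mortality odds ratios by pattern
#'
#' Fits a binary logistic regression of death by a follow-up horizon on
#' pattern membership, adjusting for attained age (linear, in years) and
#' sex. The reference pattern is the one with the lowest crude mortality
#' rate at the modelled horizon (auto-selected; overridable). Patients lost
#' to follow-up by the horizon are excluded from the denominators by
#' default (treated as missing). Odds ratios are `exp(coef)` with Wald 95%
#' confidence intervals `exp(coef +/- 1.96 * SE)`.
#'
#' @param cohort an `mm_cohort`.
#' @param fit an `mm_fit` giving pattern membership (or a list with
#'   `labels`, `included_ids`, `wave`).
#' @param horizon_wave wave index at which mortality is assessed (must be
#'   later than the fit's wave); default the final wave.
#' @param exclude_lost drop patients lost to follow-up by the horizon
#'   (default `TRUE`); if `FALSE` they are treated as alive.
#' @param reference pattern index to use as reference; default the pattern
#'   with the lowest crude mortality.
#' @return an object of class `mm_assoc`: a coefficient `table`
#'   (term, level, or, ci_low, ci_high, coef, se, p), the `reference` and
#'   how it was chosen, `n`, `n_events`, convergence diagnostics, and the
#'   stripped `glm` object in `model`.
#' @export
fit_mortality_model <- function(cohort, fit, horizon_wave = 3L,
                                exclude_lost = TRUE, reference = NULL) {
  if (horizon_wave <= fit$wave) {
    stop("horizon_wave must be later than the wave of pattern assignment",
         call. = FALSE)
  }
  ids <- fit$included_ids
  st <- wave_status(cohort, horizon_wave)[match(ids, cohort$patients$patient_id)]
  keep <- if (exclude_lost) st != "lost" else rep(TRUE, length(ids))
  ids <- ids[keep]
  died <- as.integer(st[keep] == "dead")
  labels <- fit$labels[keep]
  if (length(unique(labels)) < 2L) stop("need at least two patterns", call. = FALSE)
  if (length(unique(died)) < 2L) {
    stop("outcome has a single class at this horizon", call. = FALSE)
  }

  pmeta <- cohort$patients[match(ids, cohort$patients$patient_id), , drop = FALSE]
  crude <- tapply(died, labels, mean)
  ref_how <- "lowest crude mortality rate"
  if (is.null(reference)) {
    reference <- as.integer(names(crude)[which.min(crude)])
  } else {
    ref_how <- "user-specified"
  }
  df <- data.frame(
    died = died,
    age = pmeta$age_at_baseline + 4L * (fit$wave - 1L),
    female = as.integer(pmeta$sex == "F"),
    pattern = stats::relevel(factor(labels), ref = as.character(reference))
  )
  check_separation(df$died, df$pattern, "pattern")
  check_separation(df$died, factor(df$female), "sex")

  model <- stats::glm(died ~ age + female + pattern, family = stats::binomial(),
                      data = df, model = FALSE, y = FALSE,
                      control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!model$converged) {
    stop("logistic regression did not converge after ", model$iter,
         " IRLS iterations", call. = FALSE)
  }
  sm <- summary(model)$coefficients  # aliased (collinear) terms are dropped
  tab <- wald_table(stats::setNames(sm[, "Estimate"], rownames(sm)),
                    stats::setNames(sm[, "Std. Error"], rownames(sm)))
  tab <- annotate_pattern_terms(tab, reference)
  structure(list(
    outcome = sprintf("death by wave %d (%dy horizon) given pattern at wave %s",
                      horizon_wave, 4L * (horizon_wave - fit$wave), fit$wave_label),
    reference = reference, reference_how = ref_how,
    covariates = c("age (years)", "sex"),
    table = tab, n = nrow(df), n_events = sum(df$died),
    crude_rates = crude, converged = model$converged, iterations = model$iter,
    model = model
  ), class = "mm_assoc")
}

# zero cell in the outcome x categorical-predictor table signals (quasi-)
# complete separation for that dummy; fail loudly naming the variable.
check_separation <- function(y, f, name) {
  tt <- table(f, y)
  if (any(tt == 0L)) {
    lev <- rownames(tt)[which(rowSums(tt == 0L) > 0L)][1]
    stop(sprintf("perfect separation: variable '%s' (level %s) determines the outcome",
                 name, lev), call. = FALSE)
  }
  invisible(TRUE)
}

wald_table <- function(coefs, ses, z = 1.96) {
  data.frame(
    term = names(coefs),
    coef = unname(coefs),
    se = unname(ses),
    or = exp(unname(coefs)),
    ci_low = exp(unname(coefs) - z * unname(ses)),
    ci_high = exp(unname(coefs) + z * unname(ses)),
    p = 2 * stats::pnorm(-abs(unname(coefs) / unname(ses))),
    stringsAsFactors = FALSE
  )
}

annotate_pattern_terms <- function(tab, reference) {
  ref_row <- data.frame(term = paste0("pattern", reference), coef = 0, se = NA,
                        or = 1, ci_low = NA, ci_high = NA, p = NA,
                        stringsAsFactors = FALSE)
  tab <- rbind(tab, ref_row)
  tab$reference <- tab$term == paste0("pattern", reference)
  tab
}

#' @export
print.mm_assoc <- function(x, ...) {
  cat("Age- and sex-adjusted association model\n")
  cat("  outcome:  ", x$outcome, "\n")
  cat(sprintf("  reference: pattern %s (%s); n = %d%s\n", x$reference,
              x$reference_how, x$n,
              if (!is.null(x$n_events)) sprintf(", events = %d", x$n_events) else ""))
  tab <- x$table
  or_txt <- ifelse(tab$reference %||% FALSE, "ref.",
                   sprintf("%.2f (%.2f-%.2f)", tab$or, tab$ci_low, tab$ci_high))
  print(data.frame(term = tab$term, `OR (95% CI)` = or_txt,
                   p = signif(tab$p, 3), check.names = FALSE),
        row.names = FALSE)
  invisible(x)
}

#' Acute-disease association with patterns (multinomial model)
#'
#' Fits an age- and sex-adjusted multinomial logistic regression with
#' pattern membership as the outcome and an indicator of having been
#' diagnosed with a given acute condition during the preceding follow-up
#' period as the exposure of interest. The baseline outcome category is the
#' pattern with the lowest prevalence (smallest share of the wave).
#' Reported odds ratios are for the acute indicator, per non-reference
#' pattern, with Wald 95% confidence intervals.
#'
#' @param cohort an `mm_cohort`.
#' @param fit an `mm_fit` for the wave whose patterns are modelled.
#' @param acute_label the acute-condition label of interest.
#' @param period follow-up period of exposure; defaults to the period
#'   preceding the fit's wave.
#' @param reference baseline pattern index; default the smallest pattern.
#' @return an `mm_assoc` whose `table` has one row per non-reference
#'   pattern (odds ratio of membership associated with the acute
#'   diagnosis), plus the full coefficient array in `coefficients`.
#' @export
fit_acute_model <- function(cohort, fit, acute_label, period = NULL,
                            reference = NULL) {
  if (is.null(period)) period <- max(1L, fit$wave - 1L)
  ids <- fit$included_ids
  d <- cohort$diagnoses
  exposed_ids <- unique(d$patient_id[d$kind == "acute" &
                                       d$condition_label == acute_label &
                                       d$wave_or_period == as.character(period)])
  acute <- as.integer(ids %in% exposed_ids)
  if (length(unique(acute)) < 2L) {
    stop("acute indicator '", acute_label, "' is constant in period ", period,
         call. = FALSE)
  }
  labels <- fit$labels
  sizes <- tabulate(labels, fit$k)
  if (fit$k < 2L) stop("need at least two patterns", call. = FALSE)
  ref_how <- "lowest wave prevalence (smallest size share)"
  if (is.null(reference)) {
    reference <- which.min(sizes)
  } else {
    ref_how <- "user-specified"
  }
  pmeta <- cohort$patients[match(ids, cohort$patients$patient_id), , drop = FALSE]
  df <- data.frame(
    pattern = stats::relevel(factor(labels), ref = as.character(reference)),
    age = pmeta$age_at_baseline + 4L * (fit$wave - 1L),
    female = as.integer(pmeta$sex == "F"),
    acute = acute
  )
  model <- nnet::multinom(pattern ~ age + female + acute, data = df,
                          trace = FALSE, maxit = 500, reltol = 1e-12,
                          Hess = TRUE)
  if (model$convergence != 0) {
    stop("multinomial model did not converge", call. = FALSE)
  }
  co <- stats::coef(model)
  vc <- stats::vcov(model)
  if (is.null(dim(co))) {  # two categories: coef() drops to a vector
    co <- matrix(co, 1L, dimnames = list(levels(df$pattern)[2L], names(co)))
  }
  ses <- matrix(sqrt(diag(vc)), nrow(co), ncol(co), byrow = TRUE,
                dimnames = dimnames(co))
  tab <- wald_table(stats::setNames(co[, "acute"],
                                    paste0("pattern", rownames(co))),
                    stats::setNames(ses[, "acute"], rownames(co)))
  tab <- annotate_pattern_terms(tab, reference)
  structure(list(
    outcome = sprintf("pattern membership at wave %s vs acute '%s' in period %d",
                      fit$wave_label, acute_label, period),
    reference = reference, reference_how = ref_how,
    covariates = c("age (years)", "sex"),
    table = tab, n = nrow(df), n_events = sum(df$acute),
    coefficients = co, ses = ses,
    converged = model$convergence == 0, iterations = NA_integer_,
    model = NULL
  ), class = "mm_assoc")
}
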