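# Clinical characterisation of clusters: observed/expected prevalence,
# prevalence ratios, essential conditions, naming, descriptive tables.

#' Prevalence ratio
#'
#' Ratio of a condition's observed prevalence inside a pattern (OP) to its
#' expected prevalence in the analysed population (EP): `PR = OP / EP`.
#'
#' @param op_value observed prevalence(s) in `[0, 1]`.
#' @param ep_value expected prevalence(s) in `(0, 1]`.
#' @return nonnegative ratio(s).
#' @export
prevalence_ratio <- function(op_value, ep_value) {
  if (any(op_value < 0 | op_value > 1) || any(ep_value < 0 | ep_value > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (any(ep_value == 0)) {
    stop("undefined prevalence ratio: expected prevalence is 0", call. = FALSE)
  }
  op_value / ep_value
}

#' Essential-condition rule
#'
#' A chronic condition is an essential part of a pattern's clinical profile
#' if (i) its prevalence ratio is at least `pr_high` and its observed
#' prevalence at least `op_low`, or (ii) its observed prevalence is at
#' least `op_high` and its prevalence ratio at least `pr_low`. Defaults:
#' PR >= 2.0 with OP >= 10%, or OP >= 20% with PR >= 1.5. All comparisons
#' are inclusive.
#'
#' @param pr prevalence ratio(s).
#' @param op_value observed prevalence(s) in `[0, 1]`.
#' @param pr_high,op_low thresholds of clause (i).
#' @param op_high,pr_low thresholds of clause (ii).
#' @return logical vector.
#' @export
is_essential <- function(pr, op_value, pr_high = 2.0, op_low = 0.10,
                         op_high = 0.20, pr_low = 1.5) {
  (pr >= pr_high & op_value >= op_low) | (op_value >= op_high & pr >= pr_low)
}

# OP/EP/PR per cluster over the columns of a binary matrix. EP is the
# column prevalence in the whole analysed matrix; columns with EP = 0 get
# PR = NA and can never be essential.
pattern_prevalences <- function(x, labels) {
  f <- factor(labels)
  ep <- colMeans(x)
  op <- t(vapply(levels(f),
                 function(j) colMeans(x[f == j, , drop = FALSE]),
                 numeric(ncol(x))))
  pr <- sweep(op, 2L, ep, "/")
  pr[, ep == 0] <- NA_real_
  list(ep = ep, op = op, pr = pr, levels = levels(f))
}

# Essential-condition sets per cluster (list of character vectors).
essential_sets <- function(x, labels, pr_high = 2.0, op_low = 0.10,
                           op_high = 0.20, pr_low = 1.5) {
  pp <- pattern_prevalences(x, labels)
  lapply(seq_along(pp$levels), function(i) {
    ess <- !is.na(pp$pr[i, ]) &
      is_essential(pp$pr[i, ], pp$op[i, ], pr_high, op_low, op_high, pr_low)
    colnames(x)[ess]
  })
}

# Mechanical candidate name: top-2 essential conditions by PR (ties broken
# alphabetically); "unspecific" when a cluster has no essential condition.
candidate_name <- function(conds, pr) {
  if (length(conds) == 0L) return("unspecific")
  ord <- order(-pr[conds], conds)
  paste(conds[ord][seq_len(min(2L, length(conds)))], collapse = " & ")
}

#' Clinical profiles of the multimorbidity patterns
#'
#' Characterises every cluster of a wave: size and share of the wave,
#' sex distribution (share of the wave's women belonging to the pattern),
#' mean attained age, mean chronic-disease count, per-horizon mortality,
#' mean deduplicated drug and acute-disease counts for the follow-up period
#' associated with the wave, observed and expected prevalences with their
#' ratios, the essential-condition set, and a mechanical candidate name.
#' Expected prevalence is computed on the wave's analysed population.
#'
#' @param cohort an `mm_cohort`.
#' @param wave an `mm_wave` built from the cohort.
#' @param labels integer cluster labels aligned with `wave$included_ids`,
#'   or an `mm_clust`/`mm_fit` object carrying them.
#' @param pr_high,op_low,op_high,pr_low essential-rule thresholds, see
#'   [is_essential()].
#' @return a data frame with one row per pattern (class `mm_profiles`);
#'   the long per-condition table (pattern, condition, op, ep, pr,
#'   essential) is in `attr(, "conditions")`.
#' @export
profile_patterns <- function(cohort, wave, labels, pr_high = 2.0,
                             op_low = 0.10, op_high = 0.20, pr_low = 1.5) {
  if (inherits(labels, "mm_fit")) labels <- labels$labels
  if (inherits(labels, "mm_clust")) labels <- labels$labels
  ids <- wave$included_ids
  if (length(labels) != length(ids)) {
    stop("labels must align with wave$included_ids", call. = FALSE)
  }
  if (any(tabulate(labels) == 0L)) stop("empty pattern", call. = FALSE)
  x <- wave$matrix
  pp <- pattern_prevalences(x, labels)
  k <- length(pp$levels)
  n <- length(ids)

  pmeta <- cohort$patients[match(ids, cohort$patients$patient_id), , drop = FALSE]
  age <- pmeta$age_at_baseline + 4L * (wave$wave - 1L)
  female <- pmeta$sex == "F"
  ccount <- chronic_counts(cohort, wave$wave)[ids]
  period <- max(1L, wave$wave - 1L)  # baseline profiles use the first period
  drugs <- distinct_drug_counts(cohort, ids, period)
  acute <- distinct_acute_counts(cohort, ids, period)

  horizons <- if (wave$wave < 3L) seq.int(wave$wave + 1L, 3L) else integer(0)
  dead_by <- lapply(horizons, function(h) {
    wave_status(cohort, h)[match(ids, cohort$patients$patient_id)] == "dead"
  })

  rows <- vector("list", k)
  cond_rows <- vector("list", k)
  for (i in seq_len(k)) {
    member <- labels == as.integer(pp$levels[i])
    size <- sum(member)
    ess <- !is.na(pp$pr[i, ]) &
      is_essential(pp$pr[i, ], pp$op[i, ], pr_high, op_low, op_high, pr_low)
    ess_names <- colnames(x)[ess]
    pr_named <- stats::setNames(pp$pr[i, ], colnames(x))
    row <- data.frame(
      wave_label = wave$wave_label,
      pattern = i,
      candidate_name = candidate_name(ess_names, pr_named),
      size = size,
      share_pct = pct(size, n),
      women_n = sum(female & member),
      women_distribution_pct = pct(sum(female & member), sum(female)),
      mean_age = round_half_up(mean(age[member]), 2),
      sd_age = round_half_up(stats::sd(age[member]), 2),
      mean_conditions = round_half_up(mean(ccount[member]), 2),
      sd_conditions = round_half_up(stats::sd(ccount[member]), 2),
      mean_drugs = round_half_up(mean(drugs[member]), 2),
      sd_drugs = round_half_up(stats::sd(drugs[member]), 2),
      mean_acute = round_half_up(mean(acute[member]), 2),
      sd_acute = round_half_up(stats::sd(acute[member]), 2),
      n_essential = length(ess_names),
      essential = paste(ess_names, collapse = ";"),
      stringsAsFactors = FALSE
    )
    for (hi in seq_along(horizons)) {
      hz <- 4L * (horizons[hi] - wave$wave)
      row[[sprintf("mortality_%dy_n", hz)]] <- sum(dead_by[[hi]][member])
      row[[sprintf("mortality_%dy_pct", hz)]] <- pct(sum(dead_by[[hi]][member]), size)
    }
    rows[[i]] <- row
    cond_rows[[i]] <- data.frame(
      pattern = i, condition = colnames(x),
      op = pp$op[i, ], ep = pp$ep, pr = pp$pr[i, ],
      essential = ess, row.names = NULL, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "conditions") <- do.call(rbind, cond_rows)
  class(out) <- c("mm_profiles", "data.frame")
  out
}

#' @export
print.mm_profiles <- function(x, ...) {
  cat(sprintf("Multimorbidity pattern profiles, wave %s:\n", x$wave_label[1]))
  show <- intersect(c("pattern", "candidate_name", "size", "share_pct",
                      "women_distribution_pct", "mean_age", "mean_conditions",
                      grep("^mortality_", names(x), value = TRUE)),
                    names(x))
  print.data.frame(x[, show], row.names = FALSE)
  invisible(x)
}

#' Descriptive comparisons between patterns
#'
#' Pearson's chi-squared test (uncorrected) for the sex-by-pattern table,
#' and one-way ANOVA across patterns for attained age and chronic-disease
#' count, with pairwise t-tests under a Bonferroni correction
#' (adjusted alpha = 0.05 / m for m pairwise comparisons).
#'
#' @inheritParams profile_patterns
#' @return a list of class `mm_groupcmp` with the test objects, the number
#'   of pairwise comparisons `m` and the `adjusted_alpha`.
#' @export
compare_groups <- function(cohort, wave, labels) {
  if (inherits(labels, "mm_fit")) labels <- labels$labels
  if (inherits(labels, "mm_clust")) labels <- labels$labels
  ids <- wave$included_ids
  pmeta <- cohort$patients[match(ids, cohort$patients$patient_id), , drop = FALSE]
  pattern <- factor(labels)
  k <- nlevels(pattern)
  if (k < 2L) stop("need at least two patterns to compare", call. = FALSE)
  age <- pmeta$age_at_baseline + 4L * (wave$wave - 1L)
  ccount <- as.numeric(chronic_counts(cohort, wave$wave)[ids])
  m <- choose(k, 2)

  sex_test <- stats::chisq.test(table(pmeta$sex, pattern), correct = FALSE)
  cmp_numeric <- function(y) {
    v <- tapply(y, pattern, stats::var)
    if (any(is.na(v) | v == 0)) {
      return(list(skipped = TRUE,
                  reason = "zero variance in at least one pattern"))
    }
    list(skipped = FALSE,
         anova = stats::aov(y ~ pattern),
         pairwise = stats::pairwise.t.test(y, pattern,
                                           p.adjust.method = "bonferroni"))
  }
  structure(list(sex_test = sex_test,
                 age = cmp_numeric(age),
                 conditions = cmp_numeric(ccount),
                 m = m, adjusted_alpha = 0.05 / m),
            class = "mm_groupcmp")
}

#' @export
print.mm_groupcmp <- function(x, ...) {
  cat("Between-pattern comparisons\n")
  cat(sprintf("  sex x pattern chi-squared: X2 = %.4f, df = %d, p = %.3g\n",
              unname(x$sex_test$statistic), unname(x$sex_test$parameter),
              x$sex_test$p.value))
  for (nm in c("age", "conditions")) {
    el <- x[[nm]]
    if (el$skipped) {
      cat(sprintf("  %s: skipped (%s)\n", nm, el$reason))
    } else {
      p <- summary(el$anova)[[1]][["Pr(>F)"]][1]
      cat(sprintf("  %s ANOVA: p = %.3g (Bonferroni-adjusted alpha %.4g for %d pairs)\n",
                  nm, p, x$adjusted_alpha, x$m))
    }
  }
  invisible(x)
}
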