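# The package's central model object: a fitted set of multimorbidity
# patterns for one wave.

#' Fit multimorbidity patterns to a cohort wave
#'
#' The main entry point of the package. Partitions the wave's binary
#' disease matrix with Jaccard k-means, either at a fixed `k` or — the
#' default — selecting `k` over `k_candidates` with the Calinski-Harabasz
#' index under the pattern-validity rule (every pattern must contain at
#' least one essential condition; see [select_k()]). When the parent
#' `cohort` is supplied, the fit also carries full clinical profiles
#' ([profile_patterns()]).
#'
#' @param wave an `mm_wave` from [build_wave()].
#' @param cohort optionally, the `mm_cohort` the wave was built from, to
#'   compute demographic/clinical pattern profiles.
#' @param k fixed number of patterns; if `NULL` (default) the number is
#'   selected from `k_candidates`.
#' @param k_candidates candidate cluster counts for selection, default 2:6.
#' @param seed integer seed (required).
#' @param n_init,max_iter,tol passed to [kmeans_jaccard()].
#' @param essential_params thresholds for the essential-condition rule.
#' @param ch_tolerance see [select_k()].
#' @return an object of class `mm_fit` with components `wave_label`,
#'   `wave`, `included_ids`, `condition_labels`, `k`, `labels`,
#'   `centroids`, `ch_score`, `tot_within`, `kselection` (or `NULL`),
#'   `essential`, `profiles` (or `NULL`).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_patients = 400, seed = 7))
#' wv <- build_wave(coh, wave = 1)
#' fit <- fit_patterns(wv, cohort = coh, k_candidates = 2:4, seed = 7)
#' print(fit)
#' @export
fit_patterns <- function(wave, cohort = NULL, k = NULL, k_candidates = 2:6,
                         seed, n_init = 10L, max_iter = 100L, tol = 1e-6,
                         essential_params = list(), ch_tolerance = 0.10) {
  if (!inherits(wave, "mm_wave")) stop("wave must be an mm_wave", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  ksel <- NULL
  if (is.null(k)) {
    ksel <- select_k(wave$matrix, k_candidates, seed = seed, n_init = n_init,
                     max_iter = max_iter, tol = tol,
                     essential_params = essential_params,
                     ch_tolerance = ch_tolerance)
    k <- ksel$chosen_k
    result <- ksel$fits[[as.character(k)]]
  } else {
    result <- kmeans_jaccard(wave$matrix, k, seed = seed, n_init = n_init,
                             max_iter = max_iter, tol = tol)
  }
  ess <- do.call(essential_sets,
                 c(list(x = wave$matrix, labels = result$labels),
                   essential_params))
  obj <- structure(list(
    wave_label = wave$wave_label, wave = wave$wave,
    included_ids = wave$included_ids,
    condition_labels = wave$condition_labels,
    k = result$k, labels = result$labels, centroids = result$centroids,
    ch_score = result$ch_score, tot_within = result$tot_within,
    seed = result$seed, n_iter = result$n_iter, converged = result$converged,
    kselection = ksel, essential = ess, profiles = NULL
  ), class = "mm_fit")
  if (!is.null(cohort)) {
    obj$profiles <- do.call(profile_patterns,
                            c(list(cohort = cohort, wave = wave,
                                   labels = result$labels), essential_params))
  }
  obj
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Multimorbidity patterns, wave %s: k = %d over %d patients, %d conditions\n",
              x$wave_label, x$k, length(x$labels), length(x$condition_labels)))
  sizes <- tabulate(x$labels, x$k)
  for (i in seq_len(x$k)) {
    nm <- if (!is.null(x$profiles)) x$profiles$candidate_name[i] else
      paste(utils::head(x$essential[[i]], 2L), collapse = " & ")
    if (nm == "") nm <- "unspecific"
    cat(sprintf("  pattern %d (%s): n = %d (%.2f%%), %d essential condition(s)\n",
                i, nm, sizes[i], 100 * sizes[i] / length(x$labels),
                length(x$essential[[i]])))
  }
  cat(sprintf("Calinski-Harabasz score: %s; total within-cluster Jaccard distance: %.4f\n",
              format(x$ch_score, digits = 6), x$tot_within))
  invisible(x)
}

#' @export
summary.mm_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mm_fit")
}

#' @export
print.summary.mm_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$kselection)) {
    cat("\n")
    print(x$fit$kselection)
  }
  if (!is.null(x$fit$profiles)) {
    cat("\n")
    print(x$fit$profiles)
  }
  invisible(x)
}

#' Centroid prevalence profiles of a fitted pattern model
#'
#' @param object an `mm_fit`.
#' @param ... ignored.
#' @return the `k x p` matrix of within-pattern condition prevalences.
#' @export
coef.mm_fit <- function(object, ...) {
  cen <- object$centroids
  colnames(cen) <- object$condition_labels
  rownames(cen) <- paste0("pattern_", seq_len(object$k))
  cen
}

#' Assign new patients to fitted patterns
#'
#' Assigns each row of a new binary disease matrix to the nearest fitted
#' centroid under the generalised Jaccard distance (ties to the lowest
#' pattern index). Columns are matched by condition label; conditions
#' absent from the new data are treated as zero.
#'
#' @param object an `mm_fit`.
#' @param newdata binary matrix with condition labels as column names, or
#'   an `mm_wave`.
#' @param ... ignored.
#' @return integer vector of pattern indices.
#' @export
predict.mm_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "mm_wave")) newdata <- newdata$matrix
  newdata <- assert_binary(newdata)
  x <- matrix(0, nrow(newdata), length(object$condition_labels),
              dimnames = list(rownames(newdata), object$condition_labels))
  common <- intersect(colnames(newdata), object$condition_labels)
  if (length(common) == 0L) {
    stop("newdata shares no condition labels with the fit", call. = FALSE)
  }
  x[, common] <- newdata[, common]
  d <- jaccard_dists(x, object$centroids)
  max.col(-d, ties.method = "first")
}

#' Plot the prevalence-ratio signature of each pattern
#'
#' Dot chart of the top over-represented conditions (by prevalence ratio)
#' per pattern, with the essential-rule thresholds implied by filled
#' points. Requires profiles (fit with `cohort` supplied).
#'
#' @param x an `mm_fit` with profiles.
#' @param top number of conditions to display per pattern.
#' @param ... passed to [graphics::dotchart()].
#' @export
plot.mm_fit <- function(x, top = 8L, ...) {
  if (is.null(x$profiles)) {
    stop("fit has no profiles; call fit_patterns() with cohort =", call. = FALSE)
  }
  cond <- attr(x$profiles, "conditions")
  op <- graphics::par(mfrow = c(1, x$k), mar = c(4, 6, 3, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(x$k)) {
    ci <- cond[cond$pattern == i & !is.na(cond$pr), , drop = FALSE]
    ci <- ci[order(-ci$pr), , drop = FALSE]
    ci <- utils::head(ci, top)
    graphics::dotchart(rev(ci$pr), labels = rev(ci$condition),
                       pch = rev(ifelse(ci$essential, 19, 1)),
                       xlab = "prevalence ratio (OP/EP)",
                       main = sprintf("pattern %d: %s", i,
                                      x$profiles$candidate_name[i]), ...)
    graphics::abline(v = 1, lty = 3)
  }
  invisible(x)
}
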