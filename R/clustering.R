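# Jaccard k-means and the Calinski-Harabasz model-selection machinery.

#' Jaccard distance between two profiles
#'
#' Generalised (Tanimoto) Jaccard distance
#' `1 - sum(min(a, b)) / sum(max(a, b))` between two nonnegative vectors.
#' On binary vectors this is the classic set Jaccard distance
#' `1 - |A intersect B| / |A union B|`. Two all-zero vectors are defined to
#' be at distance 0 (identical profiles).
#'
#' @param a,b numeric vectors of equal length, nonnegative.
#' @return a number in `[0, 1]`.
#' @examples
#' jaccard_distance(c(1, 1, 0), c(0, 1, 1))  # 2/3
#' @export
jaccard_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("length mismatch: ", length(a), " vs ", length(b), call. = FALSE)
  }
  if (any(a < 0) || any(b < 0)) stop("profiles must be nonnegative", call. = FALSE)
  s <- sum(pmax(a, b))
  if (s == 0) return(0)
  1 - sum(pmin(a, b)) / s
}

# n x k matrix of generalised Jaccard distances between the rows of a binary
# matrix x and centroid rows c (entries in [0,1]). For binary x,
# sum_j min(x_ij, c_kj) = x_i . c_k and
# sum_j max(x_ij, c_kj) = |x_i| + |c_k| - x_i . c_k.
jaccard_dists <- function(x, cen) {
  smin <- x %*% t(cen)
  smax <- outer(rowSums(x), rowSums(cen), "+") - smin
  d <- 1 - smin / smax
  d[smax == 0] <- 0
  d
}

# collapse rows to string keys; much faster than duplicated.matrix on
# cohort-sized inputs
row_keys <- function(x) do.call(paste, c(asplit(x, 2L), sep = "\r"))

assert_binary <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(x != 0 & x != 1)) stop("matrix must be binary (0/1)", call. = FALSE)
  x
}

#' k-means clustering under the Jaccard distance
#'
#' Lloyd-style alternation for binary disease matrices: each patient is
#' assigned to the centroid minimising the generalised Jaccard distance, and
#' centroids are updated to within-cluster column means (so centroids are
#' real-valued prevalence profiles; the generalised distance reduces to set
#' Jaccard whenever the centroid is binary). Iteration stops at an
#' assignment fixed point, when the largest centroid shift falls below
#' `tol`, or at `max_iter`. The best of `n_init` restarts (seeded
#' `seed, seed+1, ...`) by total within-cluster distance is returned. An
#' emptied cluster is re-seeded to the point farthest from its current
#' centroid. Assignment ties break to the lowest cluster index.
#'
#' @param x binary patient-by-condition matrix (or `mm_wave`).
#' @param k number of clusters (at most the number of distinct rows).
#' @param seed integer seed for the restarts (required; no global RNG use).
#' @param n_init number of random restarts, default 10.
#' @param max_iter maximum Lloyd iterations per restart, default 100.
#' @param tol centroid-shift convergence tolerance, default 1e-6.
#' @return an object of class `mm_clust`: `k`, integer `labels` (1..k),
#'   `centroids`, `tot_within` (total within-cluster Jaccard distance),
#'   `ch_score` (Calinski-Harabasz, `NA` for k = 1), `seed`, `n_init`,
#'   `n_iter`, `converged`.
#' @export
kmeans_jaccard <- function(x, k, seed, n_init = 10L, max_iter = 100L,
                           tol = 1e-6) {
  if (inherits(x, "mm_wave")) x <- x$matrix
  x <- assert_binary(x)
  n <- nrow(x)
  if (k < 1L || k != round(k)) stop("k must be a positive integer", call. = FALSE)
  ux <- x[!duplicated(row_keys(x)), , drop = FALSE]
  if (k > nrow(ux)) {
    stop(sprintf("k = %d exceeds the number of distinct rows (%d)", k, nrow(ux)),
         call. = FALSE)
  }
  if (missing(seed)) stop("seed is required", call. = FALSE)

  if (k == 1L) {
    cen <- matrix(colMeans(x), 1L, ncol(x), dimnames = list(NULL, colnames(x)))
    d <- jaccard_dists(x, cen)
    return(structure(list(k = 1L, labels = rep(1L, n), centroids = cen,
                          tot_within = sum(d), ch_score = NA_real_,
                          seed = as.integer(seed), n_init = 1L, n_iter = 1L,
                          converged = TRUE),
                     class = "mm_clust"))
  }

  best <- NULL
  for (init in seq_len(n_init)) {
    start <- with_seed(seed + init - 1L, ux[sample.int(nrow(ux), k), , drop = FALSE])
    run <- lloyd_jaccard(x, start, max_iter, tol)
    if (is.null(best) || run$tot_within < best$tot_within) best <- run
  }
  structure(c(best,
              list(k = as.integer(k),
                   ch_score = if (n > k) calinski_harabasz(x, best$labels) else NA_real_,
                   seed = as.integer(seed), n_init = as.integer(n_init))),
            class = "mm_clust")
}

lloyd_jaccard <- function(x, cen, max_iter, tol) {
  n <- nrow(x)
  k <- nrow(cen)
  lab_old <- integer(n)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- jaccard_dists(x, cen)
    lab <- max.col(-d, ties.method = "first")
    for (j in which(tabulate(lab, k) == 0L)) {
      own <- d[cbind(seq_len(n), lab)]
      own[lab %in% which(tabulate(lab, k) == 1L)] <- -Inf  # keep singletons intact
      i_star <- which.max(own)
      lab[i_star] <- j
    }
    cen_new <- cen
    for (j in seq_len(k)) {
      cen_new[j, ] <- colMeans(x[lab == j, , drop = FALSE])
    }
    shift <- max(abs(cen_new - cen))
    cen <- cen_new
    if (identical(lab, lab_old) || shift < tol) {
      converged <- TRUE
      lab_old <- lab
      break
    }
    lab_old <- lab
    if (iter >= max_iter) break
  }
  d <- jaccard_dists(x, cen)
  list(labels = lab_old, centroids = cen,
       tot_within = sum(d[cbind(seq_len(n), lab_old)]),
       n_iter = iter, converged = converged)
}

#' @export
print.mm_clust <- function(x, ...) {
  cat(sprintf("Jaccard k-means: k = %d, n = %d, total within-distance %.4f\n",
              x$k, length(x$labels), x$tot_within))
  cat(sprintf("  sizes: %s; CH = %s; converged in %d iteration(s)\n",
              paste(tabulate(x$labels, x$k), collapse = ", "),
              format(x$ch_score, digits = 6), x$n_iter))
  invisible(x)
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion normalised by degrees of
#' freedom, `[tr(B)/(k-1)] / [tr(W)/(n-k)]`, with dispersion measured about
#' Euclidean centroids of the (binary) matrix — the standard definition of
#' the index. A partition with zero within-cluster dispersion returns
#' `Inf`.
#'
#' @param x data matrix (rows = patients).
#' @param labels cluster labels (any type; at least two distinct values and
#'   fewer groups than rows).
#' @return a nonnegative number (possibly `Inf`).
#' @export
calinski_harabasz <- function(x, labels) {
  if (inherits(x, "mm_wave")) x <- x$matrix
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  f <- factor(labels)
  k <- nlevels(f)
  n <- nrow(x)
  if (k < 2L) stop("Calinski-Harabasz index undefined for k < 2", call. = FALSE)
  if (n <= k) stop("need more observations than clusters", call. = FALSE)
  g <- colMeans(x)
  ssb <- 0
  ssw <- 0
  for (j in levels(f)) {
    xj <- x[f == j, , drop = FALSE]
    cj <- colMeans(xj)
    ssb <- ssb + nrow(xj) * sum((cj - g)^2)
    ssw <- ssw + sum(sweep(xj, 2L, cj)^2)
  }
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Select the number of multimorbidity patterns
#'
#' Runs [kmeans_jaccard()] for every candidate `k`, scores each partition
#' with the Calinski-Harabasz index, and checks the pattern-validity rule:
#' every cluster must have at least one essential condition (see
#' [is_essential()]). Among valid candidates, the chosen `k` is the
#' smallest whose CH score is within `ch_tolerance` (default 10%) of the
#' best valid score — operationalising "the lowest possible number of
#' patterns" while the full score curve is reported so an analyst can
#' override the choice.
#'
#' @param x binary disease matrix (or `mm_wave`).
#' @param k_candidates integer vector of candidate cluster counts, each >= 2.
#' @param seed integer seed (shared across candidates; restarts are nested).
#' @param n_init,max_iter,tol passed to [kmeans_jaccard()].
#' @param essential_params list of thresholds for [is_essential()]
#'   (`pr_high`, `op_low`, `op_high`, `pr_low`).
#' @param ch_tolerance fraction of the maximum valid CH score within which a
#'   smaller `k` is still acceptable.
#' @return an object of class `mm_kselect`: `table` (per-k CH score,
#'   validity, minimum essential-set size), `chosen_k`, `rationale`, and the
#'   fitted `mm_clust` objects in `fits`.
#' @export
select_k <- function(x, k_candidates, seed, n_init = 10L, max_iter = 100L,
                     tol = 1e-6, essential_params = list(), ch_tolerance = 0.10) {
  if (inherits(x, "mm_wave")) x <- x$matrix
  x <- assert_binary(x)
  if (length(k_candidates) == 0L) stop("k_candidates must be non-empty", call. = FALSE)
  if (any(k_candidates < 2L)) stop("all k_candidates must be >= 2", call. = FALSE)
  k_candidates <- sort(unique(as.integer(k_candidates)))

  fits <- list()
  rows <- vector("list", length(k_candidates))
  for (i in seq_along(k_candidates)) {
    k <- k_candidates[i]
    fit <- kmeans_jaccard(x, k, seed = seed, n_init = n_init,
                          max_iter = max_iter, tol = tol)
    ess <- do.call(essential_sets,
                   c(list(x = x, labels = fit$labels), essential_params))
    n_ess <- vapply(ess, length, integer(1))
    fits[[as.character(k)]] <- fit
    rows[[i]] <- data.frame(k = k, ch_score = fit$ch_score,
                            valid = all(n_ess >= 1L),
                            min_essential = min(n_ess))
  }
  tab <- do.call(rbind, rows)
  if (!any(tab$valid)) {
    stop("no valid partition: every candidate k has a pattern without an ",
         "essential condition (",
         paste(sprintf("k=%d: min essential %d", tab$k, tab$min_essential),
               collapse = "; "), ")", call. = FALSE)
  }
  max_ch <- max(tab$ch_score[tab$valid])
  ok <- tab$valid & tab$ch_score >= (1 - ch_tolerance) * max_ch
  chosen <- min(tab$k[ok])
  rationale <- sprintf(paste0(
    "smallest valid k whose Calinski-Harabasz score (%.4g) is within %.0f%% ",
    "of the best valid score (%.4g); validity requires every pattern to have ",
    ">= 1 essential condition"),
    tab$ch_score[tab$k == chosen], 100 * ch_tolerance, max_ch)
  structure(list(table = tab, chosen_k = chosen, rationale = rationale,
                 fits = fits, ch_tolerance = ch_tolerance,
                 essential_params = essential_params, seed = as.integer(seed)),
            class = "mm_kselect")
}

#' @export
print.mm_kselect <- function(x, ...) {
  cat("Pattern-count selection (Jaccard k-means + Calinski-Harabasz):\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Chosen k = %d: %s\n", x$chosen_k, x$rationale))
  invisible(x)
}
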