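# Shared fixtures and independent oracles for the test suite.

# Config with three well-separated planted clusters: disjoint blocks of
# 30/k conditions at prevalence 0.9 over a 0.05 background.
separated_config <- function(n = 3000, seed = 1, k = 3, m = 30,
                             block_prev = 0.9, background = 0.05, ...) {
  b <- m %/% k
  prev <- matrix(background, k, m)
  for (c in seq_len(k)) prev[c, ((c - 1) * b + 1):(c * b)] <- block_prev
  cohort_config(n_patients = n, n_conditions = m, n_clusters = k,
                prevalence_matrix = prev,
                incidence_matrix = matrix(0.01, k, m),
                seed = seed, ...)
}

# A tiny hand-built cohort: explicit control over statuses, diagnoses and
# dispensations.
manual_cohort <- function(n = 6,
                          sex = rep(c("F", "M"), length.out = n),
                          age = rep(40L, n),
                          status_2015 = rep("included", n),
                          status_2019 = rep("included", n),
                          chronic = NULL, acute = NULL, disp = NULL) {
  ids <- sprintf("P%03d", seq_len(n))
  patients <- data.frame(patient_id = ids, sex = sex, age_at_baseline = age,
                         status_2015 = status_2015, status_2019 = status_2019,
                         stringsAsFactors = FALSE)
  if (is.null(chronic)) {
    chronic <- data.frame(patient_id = rep(ids, each = 2),
                          condition_label = rep(c("A", "B"), n),
                          kind = "chronic", wave_or_period = "2011",
                          stringsAsFactors = FALSE)
  }
  diagnoses <- rbind(chronic, acute)
  if (is.null(disp)) {
    disp <- data.frame(patient_id = character(), atc_code = character(),
                       period = integer(), stringsAsFactors = FALSE)
  }
  new_cohort(patients, diagnoses, disp)
}

# Minimal stand-in for a fitted pattern object, for trajectory/association
# tests with known labels.
manual_fit <- function(included_ids, labels, wave = 1L,
                       wave_label = c("2011", "2015", "2019")[wave]) {
  structure(list(wave_label = wave_label, wave = as.integer(wave),
                 included_ids = included_ids, labels = as.integer(labels),
                 k = if (length(labels)) max(labels) else 0L,
                 condition_labels = character(0),
                 centroids = NULL),
            class = "mm_fit")
}

# Adjusted Rand index via an independent implementation.
ari <- function(a, b) {
  e1071::classAgreement(table(a, b))$crand
}

# Independent Calinski-Harabasz oracle, written directly from the formula
# (per-element loops, no shared code with the package).
bf_calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  lv <- unique(labels)
  n <- nrow(x)
  k <- length(lv)
  grand <- colSums(x) / n
  ssb <- 0
  ssw <- 0
  for (l in lv) {
    rows <- which(labels == l)
    cen <- colSums(x[rows, , drop = FALSE]) / length(rows)
    ssb <- ssb + length(rows) * sum((cen - grand)^2)
    for (i in rows) ssw <- ssw + sum((x[i, ] - cen)^2)
  }
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Generalised Jaccard distance between a binary row and a real centroid,
# from the definition.
bf_jaccard <- function(a, b) {
  s <- sum(pmax(a, b))
  if (s == 0) 0 else 1 - sum(pmin(a, b)) / s
}

# Exhaustive-search k-means oracle on a tiny instance: enumerates every
# labelling with all k clusters non-empty, scores it by the total
# generalised Jaccard distance to within-cluster mean centroids, and
# returns the optimum.
bf_best_partition <- function(x, k) {
  n <- nrow(x)
  best <- list(obj = Inf, labels = NULL)
  lab <- rep(1L, n)
  repeat {
    if (length(unique(lab)) == k) {
      cen <- t(sapply(seq_len(k), function(j) colMeans(x[lab == j, , drop = FALSE])))
      obj <- sum(vapply(seq_len(n), function(i) bf_jaccard(x[i, ], cen[lab[i], ]),
                        numeric(1)))
      if (obj < best$obj) best <- list(obj = obj, labels = lab)
    }
    i <- 1L
    while (i <= n && lab[i] == k) {
      lab[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
    lab[i] <- lab[i] + 1L
  }
  best
}

# Brute-force essential-condition recount from raw counts, no shared code
# with the package (explicit loops, counts rather than prevalences).
bf_essential_sets <- function(x, labels, pr_high = 2, op_low = 0.1,
                              op_high = 0.2, pr_low = 1.5) {
  n <- nrow(x)
  lv <- sort(unique(labels))
  lapply(lv, function(l) {
    rows <- which(labels == l)
    out <- character(0)
    for (j in seq_len(ncol(x))) {
      ep <- sum(x[, j]) / n
      if (ep == 0) next
      op <- sum(x[rows, j]) / length(rows)
      pr <- op / ep
      if ((pr >= pr_high && op >= op_low) || (op >= op_high && pr >= pr_low)) {
        out <- c(out, colnames(x)[j])
      }
    }
    out
  })
}
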