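#' Configure a synthetic multimorbidity cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' generator emulates a closed cohort of multimorbid adults followed over
#' three cross-sections (baseline and two four-year periods): patients are
#' drawn from a small number of latent clinical profiles ("planted"
#' clusters), each profile being a vector of per-condition Bernoulli
#' prevalences over a catalog of chronic-condition categories. Follow-up
#' adds deaths (logistic in age, sex and cluster), losses to follow-up,
#' incident chronic conditions, repeated acute diagnoses and ATC-coded drug
#' dispensations.
#'
#' @param n_patients number of patients to simulate.
#' @param n_conditions size of the chronic-condition catalog (default 130
#'   categories, the size of a grouped chronic-condition list typical of
#'   primary-care EHR studies).
#' @param n_clusters number of planted clinical profiles.
#' @param cluster_weights probability of each profile; defaults to equal
#'   weights. Must sum to 1.
#' @param prevalence_matrix `n_clusters x n_conditions` matrix of baseline
#'   Bernoulli prevalences. Defaults to disjoint blocks of 6 conditions at
#'   prevalence 0.30 per cluster over a 0.012 background, which yields a
#'   realistic mean of roughly three chronic conditions per patient.
#' @param age_range integer age bounds at baseline; ages are uniform.
#' @param female_fraction probability that a patient is female.
#' @param mortality_coefs list with elements `intercept`, `age`, `female`
#'   and `cluster` (length `n_clusters`): log-odds of death per four-year
#'   period, evaluated at the patient's attained age.
#' @param lost_rate per-period probability of loss to follow-up among
#'   period survivors; scalar or length 2.
#' @param incidence_matrix `n_clusters x n_conditions` per-period
#'   probability of gaining a condition not yet present. Defaults to 0.04
#'   on the cluster's own block over a 0.008 background.
#' @param acute_rate_per_period mean number of acute diagnosis events per
#'   period (events, not distinct conditions; labels are sampled with
#'   replacement so repeats occur and downstream deduplication is
#'   exercised).
#' @param acute_catalog character vector of acute-condition labels.
#' @param atc4_catalog character vector of ATC level-4 codes (5 characters).
#' @param dispensation_rate mean number of dispensation events per period;
#'   full 7-character ATC codes are drawn so that distinct products sharing
#'   a level-4 subgroup occur.
#' @param seed integer RNG seed; identical configs give identical cohorts.
#' @param multimorbid_only if `TRUE` (default) baseline draws are rejected
#'   until every patient has at least two chronic conditions.
#' @param wave_labels labels of the three cross-sections.
#'
#' @return an object of class `mm_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_patients,
                          n_conditions = 130,
                          n_clusters = 3,
                          cluster_weights = NULL,
                          prevalence_matrix = NULL,
                          age_range = c(18L, 65L),
                          female_fraction = 0.58,
                          mortality_coefs = list(intercept = -7.5, age = 0.08,
                                                 female = -0.3, cluster = NULL),
                          lost_rate = 0.02,
                          incidence_matrix = NULL,
                          acute_rate_per_period = 6,
                          acute_catalog = NULL,
                          atc4_catalog = NULL,
                          dispensation_rate = 11,
                          seed = 1L,
                          multimorbid_only = TRUE,
                          wave_labels = c("2011", "2015", "2019")) {
  n_patients <- check_count(n_patients, "n_patients")
  n_conditions <- check_count(n_conditions, "n_conditions")
  n_clusters <- check_count(n_clusters, "n_clusters")

  if (is.null(cluster_weights)) cluster_weights <- rep(1 / n_clusters, n_clusters)
  check_prob(cluster_weights, "cluster_weights", n_clusters)
  if (abs(sum(cluster_weights) - 1) > 1e-9) {
    stop_field("cluster_weights", "must sum to 1")
  }

  if (is.null(prevalence_matrix)) {
    prevalence_matrix <- default_profile_matrix(n_clusters, n_conditions,
                                                block_value = 0.30,
                                                background = 0.012)
  }
  prevalence_matrix <- as.matrix(prevalence_matrix)
  if (!all(dim(prevalence_matrix) == c(n_clusters, n_conditions))) {
    stop_field("prevalence_matrix",
               sprintf("must be %d x %d", n_clusters, n_conditions))
  }
  check_prob(c(prevalence_matrix), "prevalence_matrix")
  if (n_clusters > 1L && anyDuplicated(prevalence_matrix) > 0L) {
    stop_field("prevalence_matrix", "rows must differ when n_clusters > 1")
  }

  if (length(age_range) != 2L || age_range[1] > age_range[2]) {
    stop_field("age_range", "must be two non-decreasing ages")
  }
  check_prob(female_fraction, "female_fraction", 1L)

  mc <- mortality_coefs
  for (f in c("intercept", "age", "female")) {
    if (is.null(mc[[f]]) || !is.numeric(mc[[f]]) || length(mc[[f]]) != 1L) {
      stop_field(paste0("mortality_coefs$", f), "must be a single number")
    }
  }
  if (is.null(mc$cluster)) mc$cluster <- rep(0, n_clusters)
  if (length(mc$cluster) != n_clusters || !is.numeric(mc$cluster)) {
    stop_field("mortality_coefs$cluster",
               sprintf("must be numeric of length %d", n_clusters))
  }

  if (length(lost_rate) == 1L) lost_rate <- rep(lost_rate, 2L)
  check_prob(lost_rate, "lost_rate", 2L)

  if (is.null(incidence_matrix)) {
    incidence_matrix <- default_profile_matrix(n_clusters, n_conditions,
                                               block_value = 0.04,
                                               background = 0.008)
  }
  incidence_matrix <- as.matrix(incidence_matrix)
  if (!all(dim(incidence_matrix) == c(n_clusters, n_conditions))) {
    stop_field("incidence_matrix",
               sprintf("must be %d x %d", n_clusters, n_conditions))
  }
  check_prob(c(incidence_matrix), "incidence_matrix")

  if (!is.numeric(acute_rate_per_period) || acute_rate_per_period < 0) {
    stop_field("acute_rate_per_period", "must be nonnegative")
  }
  if (is.null(acute_catalog)) acute_catalog <- sprintf("acute_%02d", 1:40)
  if (length(acute_catalog) < 1L) stop_field("acute_catalog", "must be non-empty")
  if (is.null(atc4_catalog)) atc4_catalog <- default_atc4_catalog(150L)
  if (length(atc4_catalog) < 1L) stop_field("atc4_catalog", "must be non-empty")
  if (any(nchar(atc4_catalog) != 5L)) {
    stop_field("atc4_catalog", "codes must have exactly 5 characters")
  }
  if (!is.numeric(dispensation_rate) || dispensation_rate < 0) {
    stop_field("dispensation_rate", "must be nonnegative")
  }
  if (length(wave_labels) != 3L) stop_field("wave_labels", "must have length 3")

  structure(list(
    n_patients = n_patients, n_conditions = n_conditions,
    n_clusters = n_clusters, cluster_weights = cluster_weights,
    prevalence_matrix = prevalence_matrix, age_range = as.integer(age_range),
    female_fraction = female_fraction, mortality_coefs = mc,
    lost_rate = lost_rate, incidence_matrix = incidence_matrix,
    acute_rate_per_period = acute_rate_per_period,
    acute_catalog = as.character(acute_catalog),
    atc4_catalog = as.character(atc4_catalog),
    dispensation_rate = dispensation_rate,
    seed = as.integer(seed), multimorbid_only = isTRUE(multimorbid_only),
    wave_labels = as.character(wave_labels)
  ), class = "mm_config")
}

#' Block-structured cluster profile matrix
#'
#' Convenience builder for planted-cluster prevalence or incidence matrices:
#' cluster `c` gets `block_size` consecutive conditions at `block_value`,
#' every other entry is `background`. Blocks are disjoint across clusters.
#'
#' @param n_clusters,n_conditions matrix dimensions.
#' @param block_value probability on the cluster's own block.
#' @param background probability elsewhere.
#' @param block_size conditions per block (default 6).
#' @return an `n_clusters x n_conditions` matrix.
#' @export
default_profile_matrix <- function(n_clusters, n_conditions,
                                   block_value = 0.30, background = 0.012,
                                   block_size = 6L) {
  if (n_clusters * block_size > n_conditions) {
    stop_field("n_conditions",
               "too small for disjoint cluster blocks; supply prevalence_matrix")
  }
  m <- matrix(background, n_clusters, n_conditions)
  for (c in seq_len(n_clusters)) {
    m[c, ((c - 1L) * block_size + 1L):(c * block_size)] <- block_value
  }
  m
}

# Deterministic catalog of plausible ATC level-4 codes (anatomical main
# group letter + 2-digit therapeutic subgroup + two letters).
default_atc4_catalog <- function(n = 150L) {
  main <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P", "R", "S", "V")
  g <- expand.grid(c2 = c("A", "B", "C", "D"), c1 = c("A", "B", "C"),
                   t = sprintf("%02d", 1:9), m = main,
                   stringsAsFactors = FALSE)
  codes <- paste0(g$m, g$t, g$c1, g$c2)
  codes[seq_len(min(n, length(codes)))]
}

#' Simulate a synthetic multimorbidity cohort
#'
#' Draws a closed cohort from a planted-cluster Bernoulli mixture and follows
#' it over two four-year periods. Chronic conditions are monotone over time
#' (a condition, once recorded, stays in the clinical history); deaths and
#' losses to follow-up are absorbing, with death evaluated before loss within
#' a period; acute diagnoses and drug dispensations are generated with
#' repeats so that deduplicated counting is exercised downstream.
#'
#' @param config an `mm_config` from [cohort_config()].
#' @return an object of class `mm_cohort`: a list with data frames
#'   `patients` (patient_id, sex, age_at_baseline, status_2015, status_2019),
#'   `diagnoses` (patient_id, condition_label, kind, wave_or_period; chronic
#'   rows are tagged with the wave of first record, acute rows with the
#'   follow-up period), `dispensations` (patient_id, atc_code, period), plus
#'   the planted `truth` labels (named integer vector) and the `config`.
#' @examples
#' cfg <- cohort_config(n_patients = 200, seed = 42)
#' coh <- simulate_cohort(cfg)
#' table(coh$truth)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "mm_config")) {
    stop("config must be created with cohort_config()", call. = FALSE)
  }
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_patients
  m <- config$n_conditions
  k <- config$n_clusters
  cond_labels <- sprintf("C%03d", seq_len(m))
  ids <- sprintf("P%06d", seq_len(n))
  wl <- config$wave_labels

  cl <- sample.int(k, n, replace = TRUE, prob = config$cluster_weights)
  draw <- function(rows) {
    p <- config$prevalence_matrix[cl[rows], , drop = FALSE]
    (matrix(stats::runif(length(rows) * m), length(rows), m) < p) * 1L
  }
  x <- draw(seq_len(n))
  if (config$multimorbid_only) {
    bad <- which(rowSums(x) < 2L)
    tries <- 0L
    while (length(bad) > 0L) {
      tries <- tries + 1L
      if (tries > 1000L) {
        stop("multimorbid_only: could not draw >= 2 baseline conditions; ",
             "prevalence_matrix admits too few conditions", call. = FALSE)
      }
      x[bad, ] <- draw(bad)
      bad <- bad[rowSums(x[bad, , drop = FALSE]) < 2L]
    }
  }

  female <- stats::runif(n) < config$female_fraction
  age <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)

  mc <- config$mortality_coefs
  status <- matrix("included", n, 2L)
  waves_x <- list(x)
  acute_rows <- list()
  disp_rows <- list()
  active <- rep(TRUE, n)

  for (p in 1:2) {
    at_risk <- active
    age_now <- age + 4L * (p - 1L)
    lp <- mc$intercept + mc$age * age_now + mc$female * female + mc$cluster[cl]
    dies <- at_risk & (stats::runif(n) < stats::plogis(lp))
    lost <- at_risk & !dies & (stats::runif(n) < config$lost_rate[p])
    status[dies, p] <- "dead"
    status[lost, p] <- "lost"
    if (p == 2L) status[!at_risk, 2L] <- status[!at_risk, 1L]
    active <- at_risk & !dies & !lost
    idx <- which(active)

    # incident chronic conditions among patients still under follow-up
    xw <- waves_x[[p]]
    if (length(idx) > 0L) {
      g <- (matrix(stats::runif(length(idx) * m), length(idx), m) <
              config$incidence_matrix[cl[idx], , drop = FALSE]) * 1L
      xw[idx, ] <- pmax(xw[idx, , drop = FALSE], g)
    }
    waves_x[[p + 1L]] <- xw

    # acute diagnoses and dispensations, for patients observed through the
    # whole period; labels/codes drawn with replacement so repeats occur
    if (length(idx) > 0L) {
      nev <- stats::rpois(length(idx), config$acute_rate_per_period)
      tot <- sum(nev)
      if (tot > 0L) {
        acute_rows[[p]] <- data.frame(
          patient_id = rep(ids[idx], nev),
          condition_label = sample(config$acute_catalog, tot, replace = TRUE),
          kind = "acute",
          wave_or_period = as.character(p),
          stringsAsFactors = FALSE
        )
      }
      ndis <- stats::rpois(length(idx), config$dispensation_rate)
      totd <- sum(ndis)
      if (totd > 0L) {
        atc4 <- sample(config$atc4_catalog, totd, replace = TRUE)
        disp_rows[[p]] <- data.frame(
          patient_id = rep(ids[idx], ndis),
          atc_code = paste0(atc4, sprintf("%02d", sample.int(19L, totd, replace = TRUE))),
          period = rep(p, totd),
          stringsAsFactors = FALSE
        )
      }
    }
  }

  chronic_rows <- vector("list", 3L)
  prev <- matrix(0L, n, m)
  for (w in 1:3) {
    new <- waves_x[[w]] - prev
    nz <- which(new == 1L, arr.ind = TRUE)
    if (nrow(nz) > 0L) {
      chronic_rows[[w]] <- data.frame(
        patient_id = ids[nz[, 1L]],
        condition_label = cond_labels[nz[, 2L]],
        kind = "chronic",
        wave_or_period = wl[w],
        stringsAsFactors = FALSE
      )
    }
    prev <- waves_x[[w]]
  }

  diagnoses <- do.call(rbind, c(chronic_rows, acute_rows))
  if (is.null(diagnoses)) {
    diagnoses <- data.frame(patient_id = character(), condition_label = character(),
                            kind = character(), wave_or_period = character(),
                            stringsAsFactors = FALSE)
  }
  dispensations <- do.call(rbind, disp_rows)
  if (is.null(dispensations)) {
    dispensations <- data.frame(patient_id = character(), atc_code = character(),
                                period = integer(), stringsAsFactors = FALSE)
  }

  patients <- data.frame(
    patient_id = ids,
    sex = ifelse(female, "F", "M"),
    age_at_baseline = as.integer(age),
    status_2015 = status[, 1L],
    status_2019 = status[, 2L],
    stringsAsFactors = FALSE
  )
  names(patients)[4:5] <- paste0("status_", wl[2:3])

  truth <- stats::setNames(cl, ids)
  new_cohort(patients, diagnoses, dispensations, wave_labels = wl,
             truth = truth, config = config)
}
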