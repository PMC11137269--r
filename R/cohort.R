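# Cohort container, CSV interchange, and the per-wave dataset builders.

#' Construct a cohort object
#'
#' Assembles the three long-format tables into an `mm_cohort` and validates
#' them (referential integrity, legal sex and status codes, absorbing
#' statuses). Usually called indirectly via [simulate_cohort()] or
#' [read_cohort()].
#'
#' @param patients data frame with columns `patient_id`, `sex` (`F`/`M`),
#'   `age_at_baseline`, and one status column per post-baseline wave
#'   (`status_<label>` in `{included, dead, lost}`).
#' @param diagnoses data frame with columns `patient_id`, `condition_label`,
#'   `kind` (`chronic`/`acute`) and `wave_or_period` (wave label for chronic
#'   rows — the wave of first record; `"1"`/`"2"` for acute rows).
#' @param dispensations data frame with columns `patient_id`, `atc_code`
#'   (>= 5 characters) and `period` (1 or 2).
#' @param wave_labels the three wave tags, default `c("2011","2015","2019")`.
#' @param truth optional named integer vector of planted cluster labels.
#' @param config optional `mm_config` that generated the cohort.
#' @return an object of class `mm_cohort`.
#' @export
new_cohort <- function(patients, diagnoses, dispensations,
                       wave_labels = c("2011", "2015", "2019"),
                       truth = NULL, config = NULL) {
  obj <- structure(list(patients = patients, diagnoses = diagnoses,
                        dispensations = dispensations,
                        wave_labels = as.character(wave_labels),
                        truth = truth, config = config),
                   class = "mm_cohort")
  validate_cohort(obj)
  obj
}

validate_cohort <- function(cohort) {
  p <- cohort$patients
  wl <- cohort$wave_labels
  status_cols <- paste0("status_", wl[-1])
  need <- c("patient_id", "sex", "age_at_baseline", status_cols)
  miss <- setdiff(need, names(p))
  if (length(miss) > 0L) {
    stop("patients table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dup <- p$patient_id[duplicated(p$patient_id)]
  if (length(dup) > 0L) {
    stop("duplicate patient_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- which(!p$sex %in% c("F", "M"))
  if (length(bad_sex) > 0L) {
    stop("unknown sex code in patients rows: ",
         paste(utils::head(bad_sex, 5L), collapse = ", "), call. = FALSE)
  }
  ok_status <- c("included", "dead", "lost")
  for (sc in status_cols) {
    bad <- which(!p[[sc]] %in% ok_status)
    if (length(bad) > 0L) {
      stop(sprintf("invalid %s in patients rows: %s", sc,
                   paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
  }
  # absorbing: a patient dead/lost at wave 2 keeps that status at wave 3
  if (length(status_cols) == 2L) {
    s2 <- p[[status_cols[1]]]; s3 <- p[[status_cols[2]]]
    bad <- which(s2 != "included" & s3 != s2)
    if (length(bad) > 0L) {
      stop("non-absorbing status (dead/lost returning) in patients rows: ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  d <- cohort$diagnoses
  need_d <- c("patient_id", "condition_label", "kind", "wave_or_period")
  miss <- setdiff(need_d, names(d))
  if (length(miss) > 0L) {
    stop("diagnoses table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(d$patient_id), p$patient_id)
  if (length(unknown) > 0L) {
    rows <- which(d$patient_id %in% unknown)
    stop("diagnoses reference unknown patient_id ",
         paste(utils::head(unknown, 5L), collapse = ", "),
         " (rows ", paste(utils::head(rows, 5L), collapse = ", "), ")",
         call. = FALSE)
  }
  bad_kind <- which(!d$kind %in% c("chronic", "acute"))
  if (length(bad_kind) > 0L) {
    stop("invalid diagnosis kind in rows: ",
         paste(utils::head(bad_kind, 5L), collapse = ", "), call. = FALSE)
  }
  bad_tag <- which((d$kind == "chronic" & !d$wave_or_period %in% wl) |
                     (d$kind == "acute" & !d$wave_or_period %in% c("1", "2")))
  if (length(bad_tag) > 0L) {
    stop("invalid wave_or_period in diagnoses rows: ",
         paste(utils::head(bad_tag, 5L), collapse = ", "), call. = FALSE)
  }
  dp <- cohort$dispensations
  need_dp <- c("patient_id", "atc_code", "period")
  miss <- setdiff(need_dp, names(dp))
  if (length(miss) > 0L) {
    stop("dispensations table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(dp$patient_id), p$patient_id)
  if (length(unknown) > 0L) {
    rows <- which(dp$patient_id %in% unknown)
    stop("dispensations reference unknown patient_id ",
         paste(utils::head(unknown, 5L), collapse = ", "),
         " (rows ", paste(utils::head(rows, 5L), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(cohort)
}

#' @export
print.mm_cohort <- function(x, ...) {
  cat(sprintf("Multimorbidity cohort: %d patients, %d diagnosis rows, %d dispensation rows\n",
              nrow(x$patients), nrow(x$diagnoses), nrow(x$dispensations)))
  cat("Waves:", paste(x$wave_labels, collapse = ", "), "\n")
  for (w in 2:3) {
    st <- wave_status(x, w)
    cat(sprintf("  %s: %d included, %d dead, %d lost (cumulative)\n",
                x$wave_labels[w], sum(st == "included"), sum(st == "dead"),
                sum(st == "lost")))
  }
  invisible(x)
}

# Cumulative status of every patient at a wave (1 = baseline, all included).
wave_status <- function(cohort, wave) {
  if (wave == 1L) return(rep("included", nrow(cohort$patients)))
  cohort$patients[[paste0("status_", cohort$wave_labels[wave])]]
}

# Per-patient age attained at a wave (+4 years per period).
wave_age <- function(cohort, wave) {
  cohort$patients$age_at_baseline + 4L * (wave - 1L)
}

#' Write a cohort to CSV files
#'
#' Writes `patients.csv`, `diagnoses.csv` and `dispensations.csv` (UTF-8,
#' header row, comma-separated) in a canonical row order so that
#' write/read/write round-trips are byte-identical.
#'
#' @param cohort an `mm_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- cohort$patients[order(cohort$patients$patient_id), , drop = FALSE]
  d <- cohort$diagnoses
  d <- d[order(d$patient_id, d$kind, d$wave_or_period, d$condition_label), , drop = FALSE]
  dp <- cohort$dispensations
  dp <- dp[order(dp$patient_id, dp$period, dp$atc_code), , drop = FALSE]
  paths <- file.path(dir, c("patients.csv", "diagnoses.csv", "dispensations.csv"))
  utils::write.csv(p, paths[1], row.names = FALSE)
  utils::write.csv(d, paths[2], row.names = FALSE)
  utils::write.csv(dp, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from CSV files
#'
#' Inverse of [write_cohort()]. Accepts either a directory containing the
#' three standard files or the three paths. All structural rules are
#' validated; violations raise errors naming the offending column, id or
#' row numbers.
#'
#' @param patients_path directory, or path to `patients.csv`.
#' @param diagnoses_path,dispensations_path paths, when the first argument
#'   is a file.
#' @param wave_labels the three wave tags.
#' @return an `mm_cohort`.
#' @export
read_cohort <- function(patients_path, diagnoses_path = NULL,
                        dispensations_path = NULL,
                        wave_labels = c("2011", "2015", "2019")) {
  if (dir.exists(patients_path)) {
    diagnoses_path <- file.path(patients_path, "diagnoses.csv")
    dispensations_path <- file.path(patients_path, "dispensations.csv")
    patients_path <- file.path(patients_path, "patients.csv")
  }
  read1 <- function(path, cls) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = cls)
  }
  p <- read1(patients_path, c(patient_id = "character"))
  d <- read1(diagnoses_path, c(patient_id = "character", wave_or_period = "character"))
  dp <- read1(dispensations_path, c(patient_id = "character", atc_code = "character"))
  new_cohort(p, d, dp, wave_labels = wave_labels)
}

# Number of chronic conditions recorded by `wave`, per patient (named vector,
# aligned with cohort$patients).
chronic_counts <- function(cohort, wave) {
  wl <- cohort$wave_labels
  d <- cohort$diagnoses
  d <- d[d$kind == "chronic" & d$wave_or_period %in% wl[seq_len(wave)], , drop = FALSE]
  f <- factor(d$patient_id, levels = cohort$patients$patient_id)
  stats::setNames(as.integer(table(f)), cohort$patients$patient_id)
}

#' Restrict a cohort to multimorbid patients
#'
#' Keeps exactly the patients with at least `min_conditions` chronic
#' conditions recorded at the stated wave (default: two or more at
#' baseline, the usual multimorbidity definition). The retained set defines
#' the closed cohort for all waves.
#'
#' @param cohort an `mm_cohort`.
#' @param wave wave index at which the condition count is assessed.
#' @param min_conditions minimum number of chronic conditions (default 2).
#' @return the filtered `mm_cohort`.
#' @export
multimorbidity_filter <- function(cohort, wave = 1L, min_conditions = 2L) {
  counts <- chronic_counts(cohort, wave)
  keep <- names(counts)[counts >= min_conditions]
  subset_cohort(cohort, keep)
}

subset_cohort <- function(cohort, ids) {
  p <- cohort$patients[cohort$patients$patient_id %in% ids, , drop = FALSE]
  d <- cohort$diagnoses[cohort$diagnoses$patient_id %in% ids, , drop = FALSE]
  dp <- cohort$dispensations[cohort$dispensations$patient_id %in% ids, , drop = FALSE]
  truth <- if (!is.null(cohort$truth)) cohort$truth[p$patient_id] else NULL
  new_cohort(p, d, dp, wave_labels = cohort$wave_labels,
             truth = truth, config = cohort$config)
}

# Binary patient x condition matrix at a wave, over the given patients and
# every condition recorded among them by that wave.
condition_matrix <- function(cohort, wave, ids) {
  wl <- cohort$wave_labels
  d <- cohort$diagnoses
  d <- d[d$kind == "chronic" & d$wave_or_period %in% wl[seq_len(wave)] &
           d$patient_id %in% ids, , drop = FALSE]
  conds <- sort(unique(d$condition_label))
  x <- matrix(0L, length(ids), length(conds),
              dimnames = list(ids, conds))
  if (nrow(d) > 0L) {
    x[cbind(match(d$patient_id, ids), match(d$condition_label, conds))] <- 1L
  }
  x
}

#' Build the analysis dataset for one wave
#'
#' Assembles the cross-sectional binary disease matrix for a wave of the
#' closed cohort: patients dead or lost to follow-up by the wave are
#' excluded, condition prevalence is computed as carriers divided by the
#' number of included patients, and conditions below the prevalence
#' threshold are dropped (the comparison is inclusive: prevalence equal to
#' the threshold is kept). With `prevalence_threshold = 0`, every condition
#' with at least one carrier is retained.
#'
#' @param cohort an `mm_cohort`, already restricted to the multimorbid
#'   baseline cohort.
#' @param wave wave index (1, 2 or 3).
#' @param prevalence_threshold minimum prevalence, default 0.01 (1.0%).
#' @return an object of class `mm_wave`: list with `wave_label`, `wave`,
#'   `included_ids`, binary `matrix`, retained `condition_labels` and their
#'   `prevalence`.
#' @export
build_wave <- function(cohort, wave, prevalence_threshold = 0.01) {
  if (!wave %in% 1:3) stop("wave must be 1, 2 or 3", call. = FALSE)
  if (prevalence_threshold < 0 || prevalence_threshold > 1) {
    stop("prevalence_threshold must be in [0, 1]", call. = FALSE)
  }
  st <- wave_status(cohort, wave)
  ids <- cohort$patients$patient_id[st == "included"]
  if (length(ids) == 0L) {
    stop("empty wave: no included patients at wave ", wave, call. = FALSE)
  }
  x <- condition_matrix(cohort, wave, ids)
  counts <- colSums(x)
  prev <- counts / length(ids)
  keep <- prev >= prevalence_threshold & counts >= 1L
  x <- x[, keep, drop = FALSE]
  structure(list(wave_label = cohort$wave_labels[wave], wave = as.integer(wave),
                 included_ids = ids, matrix = x,
                 condition_labels = colnames(x), prevalence = prev[keep]),
            class = "mm_wave")
}

#' @export
print.mm_wave <- function(x, ...) {
  cat(sprintf("Wave %s: %d included patients, %d conditions retained\n",
              x$wave_label, length(x$included_ids), ncol(x$matrix)))
  invisible(x)
}

#' Closed-cohort attrition accounting
#'
#' Propagates a baseline count through per-period deaths and losses to
#' follow-up: included(w+1) = included(w) - deaths(w) - lost(w). Cumulative
#' death and loss percentages use the baseline count as denominator and are
#' printed to two decimals.
#'
#' @param baseline_n baseline cohort size.
#' @param deaths integer vector of deaths per period.
#' @param lost integer vector of losses per period (same length).
#' @return data frame with one row per wave: `included`, `cum_deaths`,
#'   `cum_lost`, `pct_dead`, `pct_lost`.
#' @examples
#' cohort_accounting(293923, c(4895, 5680), c(10003, 2072))
#' @export
cohort_accounting <- function(baseline_n, deaths, lost) {
  if (length(deaths) != length(lost)) {
    stop("deaths and lost must have the same length", call. = FALSE)
  }
  if (any(c(baseline_n, deaths, lost) < 0) ||
      any(c(baseline_n, deaths, lost) != round(c(baseline_n, deaths, lost)))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  included <- baseline_n
  for (p in seq_along(deaths)) {
    nxt <- included[p] - deaths[p] - lost[p]
    if (nxt < 0) {
      stop(sprintf("inconsistent accounting: period %d removes %d from %d included",
                   p, deaths[p] + lost[p], included[p]), call. = FALSE)
    }
    included <- c(included, nxt)
  }
  data.frame(
    wave = seq_along(included),
    included = included,
    cum_deaths = c(0, cumsum(deaths)),
    cum_lost = c(0, cumsum(lost)),
    pct_dead = pct(c(0, cumsum(deaths)), baseline_n),
    pct_lost = pct(c(0, cumsum(lost)), baseline_n)
  )
}

# Level-4 prefix of ATC codes (first 5 characters); errors on short codes.
atc4 <- function(codes) {
  bad <- which(nchar(codes) < 5L)
  if (length(bad) > 0L) {
    stop("ATC code shorter than 5 characters (rows ",
         paste(utils::head(bad, 5L), collapse = ", "), ")", call. = FALSE)
  }
  substr(codes, 1L, 5L)
}

#' Deduplicated drug count for one patient and period
#'
#' Number of distinct fourth-level ATC subgroups (first five code
#' characters) among the patient's dispensations in a follow-up period;
#' repeated dispensations within the same subgroup count once.
#'
#' @param cohort an `mm_cohort`.
#' @param patient_id a patient id.
#' @param period follow-up period (1 or 2).
#' @return integer count.
#' @export
count_distinct_drugs <- function(cohort, patient_id, period) {
  dp <- cohort$dispensations
  codes <- dp$atc_code[dp$patient_id == patient_id & dp$period == period]
  if (length(codes) == 0L) return(0L)
  length(unique(atc4(codes)))
}

#' Deduplicated acute-disease count for one patient and period
#'
#' Number of distinct acute-condition labels diagnosed in a follow-up
#' period; conditions diagnosed two or more times within the period count
#' once. The scope is per period: the same condition in both periods counts
#' once in each.
#'
#' @inheritParams count_distinct_drugs
#' @return integer count.
#' @export
count_distinct_acute <- function(cohort, patient_id, period) {
  d <- cohort$diagnoses
  lab <- d$condition_label[d$kind == "acute" & d$patient_id == patient_id &
                             d$wave_or_period == as.character(period)]
  length(unique(lab))
}

# Vectorised deduplicated counts for a set of patients (used by profiles).
distinct_drug_counts <- function(cohort, ids, period) {
  dp <- cohort$dispensations
  dp <- dp[dp$period == period & dp$patient_id %in% ids, , drop = FALSE]
  if (nrow(dp) == 0L) return(stats::setNames(rep(0L, length(ids)), ids))
  key <- !duplicated(paste(dp$patient_id, atc4(dp$atc_code), sep = "\r"))
  f <- factor(dp$patient_id[key], levels = ids)
  stats::setNames(as.integer(table(f)), ids)
}

distinct_acute_counts <- function(cohort, ids, period) {
  d <- cohort$diagnoses
  d <- d[d$kind == "acute" & d$wave_or_period == as.character(period) &
           d$patient_id %in% ids, , drop = FALSE]
  if (nrow(d) == 0L) return(stats::setNames(rep(0L, length(ids)), ids))
  key <- !duplicated(paste(d$patient_id, d$condition_label, sep = "\r"))
  f <- factor(d$patient_id[key], levels = ids)
  stats::setNames(as.integer(table(f)), ids)
}
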