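# Cohort with two patterns, constant age and sex, and a planted 2x2
# exposure/outcome table: pattern 1 has a deaths among a+b members,
# pattern 2 has c deaths among c+d members.
two_by_two_cohort <- function(a, b, c, d) {
  n <- a + b + c + d
  dead <- c(rep("dead", a), rep("included", b), rep("dead", c), rep("included", d))
  coh <- manual_cohort(n = n, sex = rep("F", n), age = rep(50L, n),
                       status_2015 = dead, status_2019 = dead)
  fit <- manual_fit(coh$patients$patient_id, rep(1:2, c(a + b, c + d)), 1)
  list(cohort = coh, fit = fit)
}

test_that("with no informative covariates the OR matches the 2x2 closed form", {
  tb <- two_by_two_cohort(a = 10, b = 90, c = 30, d = 70)
  m <- fit_mortality_model(tb$cohort, tb$fit, horizon_wave = 2, reference = 2)
  row <- m$table[m$table$term == "pattern1", ]
  expect_equal(row$or, (10 * 70) / (90 * 30), tolerance = 1e-6)
  # auto-selected reference is the lowest-mortality pattern (pattern 1)
  m2 <- fit_mortality_model(tb$cohort, tb$fit, horizon_wave = 2)
  expect_equal(m2$reference, 1)
  expect_equal(m2$table$or[m2$table$term == "pattern2"],
               (30 * 90) / (70 * 10), tolerance = 1e-6)
  expect_equal(m2$table$or[m2$table$reference], 1)
})

test_that("glm coefficients match an independent likelihood maximisation", {
  set.seed(71)
  n <- 400
  age <- sample(18:65, n, replace = TRUE)
  female <- rbinom(n, 1, 0.55)
  pattern <- rbinom(n, 1, 0.4) + 1L
  lp <- -4 + 0.05 * age - 0.3 * female + 0.4 * (pattern == 2)
  died <- rbinom(n, 1, plogis(lp))
  st <- ifelse(died == 1, "dead", "included")
  coh <- manual_cohort(n = n, sex = ifelse(female == 1, "F", "M"), age = age,
                       status_2015 = st, status_2019 = st)
  fit <- manual_fit(coh$patients$patient_id, pattern, 1)
  m <- fit_mortality_model(coh, fit, horizon_wave = 2, reference = 1)

  X <- cbind(1, age, female, pattern == 2)
  negll <- function(beta) {
    eta <- X %*% beta
    -sum(died * eta - log1p(exp(eta)))
  }
  grad <- function(beta) {
    p <- plogis(X %*% beta)
    -as.numeric(t(X) %*% (died - p))
  }
  opt <- optim(rep(0, 4), negll, grad, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(m$table$coef[match(c("(Intercept)", "age", "female", "pattern2"),
                                         m$table$term)]),
               unname(opt$par), tolerance = 1e-6)
  # CI endpoints are the Wald exp(coef +/- 1.96 se)
  r <- m$table[m$table$term == "pattern2", ]
  expect_equal(r$ci_low, exp(r$coef - 1.96 * r$se))
  expect_equal(r$ci_high, exp(r$coef + 1.96 * r$se))
  expect_true(r$ci_low <= r$or && r$or <= r$ci_high)
})

test_that("shifting age by a constant only moves the intercept", {
  set.seed(72)
  n <- 300
  age <- sample(18:65, n, replace = TRUE)
  died <- rbinom(n, 1, plogis(-3 + 0.04 * age))
  st <- ifelse(died == 1, "dead", "included")
  sexes <- rep(c("F", "M"), length.out = n)
  pattern <- rep(1:2, length.out = n)
  coh1 <- manual_cohort(n = n, sex = sexes, age = age,
                        status_2015 = st, status_2019 = st)
  coh2 <- manual_cohort(n = n, sex = sexes, age = age + 10L,
                        status_2015 = st, status_2019 = st)
  fit <- manual_fit(coh1$patients$patient_id, pattern, 1)
  m1 <- fit_mortality_model(coh1, fit, horizon_wave = 2, reference = 1)
  m2 <- fit_mortality_model(coh2, fit, horizon_wave = 2, reference = 1)
  keep <- m1$table$term != "(Intercept)"
  expect_equal(m1$table$coef[keep], m2$table$coef[keep], tolerance = 1e-8)
  i1 <- m1$table$coef[m1$table$term == "(Intercept)"]
  i2 <- m2$table$coef[m2$table$term == "(Intercept)"]
  b_age <- m1$table$coef[m1$table$term == "age"]
  expect_equal(i2, i1 - 10 * b_age, tolerance = 1e-6)
})

test_that("perfect separation is reported with the separating variable", {
  tb <- two_by_two_cohort(a = 50, b = 0, c = 10, d = 40)  # pattern 1 all dead
  expect_error(fit_mortality_model(tb$cohort, tb$fit, horizon_wave = 2),
               "separation.*pattern")
})

test_that("patients lost by the horizon are excluded from the model", {
  n <- 60
  st <- rep(c("included", "lost", "dead"), each = 20)
  coh <- manual_cohort(n = n, age = sample(30:60, n, replace = TRUE),
                       status_2015 = st, status_2019 = st)
  fit <- manual_fit(coh$patients$patient_id, rep(1:2, 30), 1)
  m <- fit_mortality_model(coh, fit, horizon_wave = 2)
  expect_equal(m$n, 40)
  m_all <- fit_mortality_model(coh, fit, horizon_wave = 2, exclude_lost = FALSE)
  expect_equal(m_all$n, 60)
})

acute_cohort <- function(n, pattern, p_acute, seed) {
  set.seed(seed)
  exposed <- rbinom(n, 1, p_acute[pattern]) == 1
  ids <- sprintf("P%06d", seq_len(n))
  patients <- data.frame(patient_id = ids,
                         sex = sample(c("F", "M"), n, replace = TRUE),
                         age_at_baseline = sample(18:61, n, replace = TRUE),
                         status_2015 = "included", status_2019 = "included",
                         stringsAsFactors = FALSE)
  chronic <- data.frame(patient_id = rep(ids, each = 2),
                        condition_label = rep(c("A", "B"), n),
                        kind = "chronic", wave_or_period = "2011",
                        stringsAsFactors = FALSE)
  acute <- data.frame(patient_id = rep(ids[exposed], 2),  # duplicated diagnoses
                      condition_label = "URI", kind = "acute",
                      wave_or_period = "1", stringsAsFactors = FALSE)
  coh <- new_cohort(patients, rbind(chronic, acute),
                    data.frame(patient_id = character(), atc_code = character(),
                               period = integer(), stringsAsFactors = FALSE))
  list(cohort = coh, fit = manual_fit(ids, pattern, 2))
}

test_that("a two-category multinomial model reduces to binary logistic", {
  n <- 500
  set.seed(73)
  pattern <- rep(1:2, c(200, 300))
  ac <- acute_cohort(n, pattern, p_acute = c(0.3, 0.45), seed = 74)
  m <- fit_acute_model(ac$cohort, ac$fit, "URI", period = 1)
  expect_equal(m$reference, 1)  # pattern 1 is the smaller category

  pmeta <- ac$cohort$patients
  acute <- as.integer(pmeta$patient_id %in%
                        ac$cohort$diagnoses$patient_id[ac$cohort$diagnoses$kind == "acute"])
  df <- data.frame(y = as.integer(pattern == 2),
                   age = pmeta$age_at_baseline + 4L,
                   female = as.integer(pmeta$sex == "F"), acute = acute)
  g <- glm(y ~ age + female + acute, family = binomial(), data = df)
  expect_equal(unname(m$coefficients[1, ]), unname(coef(g)), tolerance = 1e-4)
})

test_that("a planted acute enrichment yields a significantly elevated OR", {
  n <- 20000
  set.seed(75)
  pattern <- sample(1:3, n, replace = TRUE, prob = c(0.25, 0.4, 0.35))
  ac <- acute_cohort(n, pattern, p_acute = c(0.6, 0.3, 0.3), seed = 76)
  m <- fit_acute_model(ac$cohort, ac$fit, "URI", period = 1)
  expect_equal(m$reference, 1)
  r2 <- m$table[m$table$term == "pattern2", ]
  r3 <- m$table[m$table$term == "pattern3", ]
  # membership in patterns 2/3 is negatively associated with the acute
  # diagnosis relative to the enriched reference pattern 1
  expect_lt(r2$ci_high, 1)
  expect_lt(r3$ci_high, 1)
  # true OR is (0.3/0.7)/(0.6/0.4) = 2/7
  expect_equal(r2$or, 2 / 7, tolerance = 0.08)
})
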