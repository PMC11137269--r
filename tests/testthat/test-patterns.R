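test_that("prevalence ratio is OP/EP with guarded domain", {
  expect_equal(prevalence_ratio(0.20, 0.10), 2)
  expect_equal(prevalence_ratio(0.37, 0.37), 1)
  expect_equal(prevalence_ratio(0, 0.5), 0)
  expect_error(prevalence_ratio(0.1, 0), "undefined")
  expect_error(prevalence_ratio(1.2, 0.5), "\\[0, 1\\]")
})

test_that("essential rule holds at and just below its four boundaries", {
  expect_true(is_essential(pr = 2.0, op_value = 0.10))   # clause (i) boundary
  expect_true(is_essential(pr = 1.5, op_value = 0.20))   # clause (ii) boundary
  expect_false(is_essential(pr = 1.999, op_value = 0.10))
  expect_false(is_essential(pr = 2.0, op_value = 0.0999))
  expect_false(is_essential(pr = 1.499, op_value = 0.20))
  expect_false(is_essential(pr = 1.5, op_value = 0.1999))
  expect_false(is_essential(pr = 10, op_value = 0.05))   # high PR, tiny OP
  expect_false(is_essential(pr = 1.4, op_value = 0.90))  # common but not enriched
})

test_that("increasing OP at fixed EP never de-essentialises a condition", {
  set.seed(51)
  for (rep in 1:200) {
    ep <- runif(1, 0.01, 0.5)
    op1 <- runif(1)
    op2 <- runif(1, op1, 1)
    e1 <- is_essential(op1 / ep, op1)
    e2 <- is_essential(op2 / ep, op2)
    expect_false(e1 && !e2)
  }
})

test_that("pattern profiles match a brute-force recount on a planted cohort", {
  coh <- simulate_cohort(separated_config(n = 500, seed = 52))
  wv <- build_wave(coh, 1)
  fit <- kmeans_jaccard(wv$matrix, 3, seed = 5, n_init = 5)
  prof <- profile_patterns(coh, wv, fit$labels)
  bf <- bf_essential_sets(wv$matrix, fit$labels)
  for (i in 1:3) {
    got <- strsplit(prof$essential[i], ";")[[1]]
    expect_setequal(got, bf[[i]])
  }
  # sizes, shares and women distribution recompute from raw memberships
  for (i in 1:3) {
    member <- fit$labels == i
    expect_equal(prof$size[i], sum(member))
    expect_equal(prof$share_pct[i],
                 round(100 * sum(member) / length(fit$labels), 2))
    women <- coh$patients$sex[match(wv$included_ids, coh$patients$patient_id)] == "F"
    expect_equal(prof$women_n[i], sum(women & member))
  }
  expect_equal(sum(prof$share_pct), 100, tolerance = 0.02)
})

test_that("weighted pattern prevalences reconstruct the population prevalence", {
  coh <- simulate_cohort(separated_config(n = 400, seed = 53))
  wv <- build_wave(coh, 1)
  fit <- kmeans_jaccard(wv$matrix, 3, seed = 6, n_init = 5)
  pp <- mmpatterns:::pattern_prevalences(wv$matrix, fit$labels)
  sizes <- tabulate(fit$labels, 3)
  n <- nrow(wv$matrix)
  recon <- colSums(pp$op * sizes)
  expect_true(max(abs(recon - n * pp$ep)) < 1e-12)
})

test_that("a single-pattern wave has OP = EP and PR = 1 everywhere", {
  coh <- simulate_cohort(separated_config(n = 120, seed = 54))
  wv <- build_wave(coh, 1)
  prof <- profile_patterns(coh, wv, rep(1L, length(wv$included_ids)))
  cond <- attr(prof, "conditions")
  expect_equal(cond$op, cond$ep)
  expect_true(all(cond$pr == 1))
  # with PR = 1 everywhere no condition can satisfy the essential rule
  expect_false(any(cond$essential))
  expect_equal(prof$candidate_name, "unspecific")
})

test_that("mortality percentages use the pattern size as denominator", {
  n <- 40
  st15 <- rep("included", n)
  st15[1:6] <- "dead"  # 6 deaths in pattern 1 (size 20) by wave 2
  coh <- manual_cohort(n = n, status_2015 = st15,
                       status_2019 = ifelse(st15 == "dead", "dead", "included"))
  wv <- build_wave(coh, 1, 0)
  labels <- rep(1:2, each = 20)
  prof <- profile_patterns(coh, wv, labels)
  expect_equal(prof$mortality_4y_n, c(6L, 0L))
  expect_equal(prof$mortality_4y_pct, c(30, 0))
  expect_equal(prof$mortality_8y_pct[1], round(100 * 6 / 20, 2))
})

test_that("candidate names rank essential conditions by PR with stable ties", {
  x <- cbind(hi = c(rep(1, 8), rep(0, 12)),
             mid_b = c(rep(1, 6), rep(0, 14)),
             mid_a = c(rep(1, 6), rep(0, 14)),
             base = rep(1, 20))
  labels <- rep(1:2, c(10, 10))
  ess <- mmpatterns:::essential_sets(x, labels)
  pp <- mmpatterns:::pattern_prevalences(x, labels)
  pr1 <- setNames(pp$pr[1, ], colnames(x))
  expect_equal(mmpatterns:::candidate_name(ess[[1]], pr1), "hi & mid_a")
  expect_equal(mmpatterns:::candidate_name(character(0), pr1), "unspecific")
})

test_that("group comparisons use the textbook Pearson statistic", {
  # sex x pattern table (10, 20 / 30, 40)
  sex <- c(rep("F", 10), rep("M", 20), rep("F", 30), rep("M", 40))
  n <- length(sex)
  chronic <- data.frame(patient_id = rep(sprintf("P%03d", 1:n), each = 2),
                        condition_label = rep(c("A", "B"), n),
                        kind = "chronic", wave_or_period = "2011",
                        stringsAsFactors = FALSE)
  coh <- manual_cohort(n = n, sex = sex,
                       age = sample(30:60, n, replace = TRUE), chronic = chronic)
  wv <- build_wave(coh, 1, 0)
  labels <- rep(1:2, c(30, 70))
  cmp <- compare_groups(coh, wv, labels)
  obs <- matrix(c(10, 30, 20, 40), 2, byrow = TRUE)  # rows = pattern
  expt <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  hand <- sum((obs - expt)^2 / expt)
  expect_equal(unname(cmp$sex_test$statistic), hand, tolerance = 1e-12)
  expect_equal(cmp$m, 1)
  expect_equal(cmp$adjusted_alpha, 0.05)
  # identical sex distribution across patterns: statistic 0, p = 1
  coh2 <- manual_cohort(n = 40, sex = rep(c("F", "M"), 20),
                        age = rep(c(30L, 50L), 20))
  wv2 <- build_wave(coh2, 1, 0)
  cmp2 <- compare_groups(coh2, wv2, rep(1:2, each = 20))
  expect_equal(unname(cmp2$sex_test$statistic), 0)
  expect_equal(cmp2$sex_test$p.value, 1)
  # zero-variance group is flagged and skipped
  expect_true(cmp2$conditions$skipped)
})
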