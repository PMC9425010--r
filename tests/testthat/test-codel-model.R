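# Codeletion probability models, ATRX imputation, composite classifier and
# the molecular-test triage rule.

test_that("naive Bayes age posterior matches a hand-built Gaussian Bayes", {
  co <- small_cohort()
  ages <- c(25, 40, 55, 70)
  got <- naive_bayes_codel_prob(co, data.frame(age = ages))
  # oracle: class-conditional Gaussian likelihoods (sample mean / sd with
  # n-1 denominator, as the reference implementation uses) times the prior
  lik <- function(a, cls) {
    d <- co$age[co$codel_1p19q == cls]
    stats::dnorm(a, mean(d), sd(d))
  }
  pri1 <- mean(co$codel_1p19q == 1)
  want <- vapply(ages, function(a) {
    pri1 * lik(a, 1) / (pri1 * lik(a, 1) + (1 - pri1) * lik(a, 0))
  }, 1)
  expect_equal(got, want, tolerance = 1e-6)
  # codeleted patients are older in the planted cohort: monotone posterior
  expect_true(all(diff(got) > 0))
})

test_that("naive Bayes accepts gender and degrades gracefully to the prior", {
  co <- small_cohort()
  p <- naive_bayes_codel_prob(co, data.frame(age = 50, gender = "F"))
  expect_true(p >= 0 && p <= 1)
  one <- co[co$codel_1p19q == 1, ]
  expect_warning(pp <- naive_bayes_codel_prob(one, data.frame(age = 50)),
                 "single-class")
  expect_equal(pp, 1)
})

test_that("ATRX/age model emits calibrated-direction probabilities", {
  co <- small_cohort()
  fit <- fit_atrx_age_model(co, seed = 1)
  expect_s3_class(fit, "atrx_age_model")
  expect_gte(fit$accuracy, 0.6)
  # ATRX mutation argues against codeletion at any age
  p <- predict_codel_prob(fit, data.frame(
    ATRX = c("mutant", "wildtype"), age = c(50, 50)))
  expect_lt(p[1], p[2])
  expect_true(all(p >= 0 & p <= 1))
  expect_error(fit_atrx_age_model(co[1:20, ]), "at least 50")
})

test_that("ATRX imputation recovers the planted p53/age coupling", {
  co <- make_cohort(n = 1500, seed = 9)
  set.seed(1)
  idx <- sample(nrow(co), 300)
  imputed <- impute_atrx(co[-idx, ], co[idx, ], seed = 2)
  expect_true(all(imputed %in% c("mutant", "wildtype")))
  acc <- mean(imputed == co$ATRX[idx])
  # better than always guessing the majority class
  expect_gt(acc, max(mean(co$ATRX[-idx] == "mutant"),
                     mean(co$ATRX[-idx] == "wildtype")))
})

test_that("complete_atrx fills only the missing calls", {
  co <- make_cohort(n = 800, missing_atrx_rate = 0.15, seed = 4)
  done <- complete_atrx(co, seed = 1)
  expect_false(anyNA(done$ATRX))
  obs <- !is.na(co$ATRX)
  expect_identical(done$ATRX[obs], co$ATRX[obs])
  expect_identical(done$ATRX_imputed, is.na(co$ATRX))
})

test_that("the composite model trains, predicts, and reports importance", {
  # fast stand-in case table with planted signal (the full image pipeline
  # is exercised in the acceptance suite)
  set.seed(2)
  n <- 80
  lab <- rep(0:1, each = n / 2)
  cases <- data.frame(
    mean_d10 = 2 - lab + rnorm(n, sd = 0.3),
    p53_percent = ifelse(lab == 1, runif(n, 0, 15), runif(n, 20, 95)),
    atrx_age_prob = ifelse(lab == 1, runif(n, 0.5, 1), runif(n, 0, 0.5)),
    note = "ignored",
    codel_1p19q = lab)
  fit <- train_codeletion_model(cases, seed = 3)
  expect_s3_class(fit, "codel_model")
  expect_gte(fit$accuracy, 0.9)
  expect_setequal(fit$feature_columns,
                  c("mean_d10", "p53_percent", "atrx_age_prob"))
  expect_setequal(rownames(fit$importance), fit$feature_columns)
  p <- predict_codeletion(fit, cases[1:5, ])
  expect_length(p, 5)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(train_codeletion_model(cases[lab == 1, ]), "both codeletion")
})

test_that("the triage truth table is reproduced exactly", {
  # all 8 boundary combinations of (prediction side, grade, recurrence)
  cases <- list(
    list(p = 0.2, g = "low",  r = FALSE, want = "no_further_testing"),
    list(p = 0.2, g = "low",  r = TRUE,  want = "no_further_testing"),
    list(p = 0.2, g = "high", r = FALSE, want = "no_further_testing"),
    list(p = 0.2, g = "high", r = TRUE,  want = "no_further_testing"),
    list(p = 0.8, g = "low",  r = FALSE, want = "FISH"),
    list(p = 0.8, g = "low",  r = TRUE,  want = "CMA_or_NGS"),
    list(p = 0.8, g = "high", r = FALSE, want = "CMA_or_NGS"),
    list(p = 0.8, g = "high", r = TRUE,  want = "CMA_or_NGS"))
  for (cs in cases) {
    rec <- recommend_test(cs$p, grade = cs$g, recurrent = cs$r)
    expect_equal(rec$decision, cs$want)
  }
  # threshold boundary is inclusive on the testing side
  expect_equal(recommend_test(0.5, "low")$decision, "FISH")
  expect_equal(recommend_test(0.4999, "low")$decision, "no_further_testing")
  expect_error(recommend_test(1.2, "low"), "probability")
  expect_error(recommend_test(NA_real_, "low"), "probability")
})
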