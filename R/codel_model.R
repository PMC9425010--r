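# 1p/19q codeletion probability modelling and molecular-test triage: naive
# Bayes on age (and optionally gender), the combined ATRX/age probability
# feature, ATRX imputation from age + p53, the composite codeletion
# classifier, and the clinical decision rule for ordering FISH vs CMA/NGS.

#' Naive Bayes probability of 1p/19q codeletion given age (and gender)
#'
#' Gaussian class-conditional age likelihood and categorical gender
#' likelihood with a Laplace pseudocount, normalized against the class prior.
#' If the query omits gender, the model is fitted on age alone.
#'
#' @param train Cohort data.frame with columns `age`, `gender`,
#'   `codel_1p19q` (0/1).
#' @param query A data.frame (or named list) with `age` and optionally
#'   `gender`; vectorized over rows.
#' @param laplace Laplace pseudocount (default 1).
#' @return Numeric vector of posterior P(codeleted) per query row.
#' @export
naive_bayes_codel_prob <- function(train, query, laplace = 1) {
  if (!is.data.frame(query)) query <- as.data.frame(query)
  y <- factor(train$codel_1p19q, levels = c(0, 1))
  if (nlevels(droplevels(y)) < 2) {
    warning("single-class training cohort: returning the prior")
    return(rep(as.numeric(levels(droplevels(y))), nrow(query)))
  }
  use_gender <- "gender" %in% colnames(query)
  x <- if (use_gender) {
    data.frame(age = train$age, gender = factor(train$gender))
  } else {
    data.frame(age = train$age)
  }
  fit <- e1071::naiveBayes(x = x, y = y, laplace = laplace)
  nd <- if (use_gender) {
    data.frame(age = query$age,
               gender = factor(query$gender, levels = levels(x$gender)))
  } else {
    data.frame(age = query$age)
  }
  post <- stats::predict(fit, nd, type = "raw")
  unname(post[, "1"])
}

#' Fit the combined ATRX/age codeletion probability model
#'
#' An ensemble-of-trees model of codeletion status as a function of ATRX
#' status and patient age, fitted on a global cohort; the probability it
#' emits is the "ATRX/age feature" of the composite classifier. Accuracy is
#' reported from a stratified 70/30 split; the returned model is refitted on
#' all complete rows.
#'
#' @param train Cohort with `ATRX`, `age`, `codel_1p19q`; rows with missing
#'   ATRX are ignored.
#' @param seed Integer seed.
#' @param train_frac Training fraction for the reported accuracy.
#' @return A list of class `"atrx_age_model"`: `model`, `accuracy`, `n`.
#' @export
fit_atrx_age_model <- function(train, seed = 1, train_frac = 0.7) {
  d <- train[!is.na(train$ATRX), , drop = FALSE]
  if (nrow(d) < 50) stop("need at least 50 complete rows; have ", nrow(d))
  y <- factor(d$codel_1p19q, levels = c(0, 1))
  if (nlevels(droplevels(y)) < 2) stop("both codeletion classes required")
  x <- data.frame(ATRX = factor(d$ATRX, levels = c("mutant", "wildtype")),
                  age = d$age)
  set.seed(seed)
  tr_idx <- unlist(lapply(split(seq_along(y), y), function(i) {
    sample(i, max(1L, round(train_frac * length(i))))
  }))
  fit <- randomForest::randomForest(x = x[tr_idx, ], y = y[tr_idx])
  acc <- mean(stats::predict(fit, x[-tr_idx, ]) == y[-tr_idx])
  set.seed(seed)
  full <- randomForest::randomForest(x = x, y = y)
  structure(list(model = full, accuracy = acc, n = nrow(d)),
            class = "atrx_age_model")
}

#' Codeletion probability from an ATRX/age model
#'
#' @param model An [fit_atrx_age_model()] result.
#' @param newdata Data.frame with `ATRX` (`"mutant"`/`"wildtype"`) and `age`.
#' @return Numeric vector of P(codeleted).
#' @export
predict_codel_prob <- function(model, newdata) {
  stopifnot(inherits(model, "atrx_age_model"))
  nd <- data.frame(ATRX = factor(newdata$ATRX,
                                 levels = c("mutant", "wildtype")),
                   age = newdata$age)
  unname(stats::predict(model$model, nd, type = "prob")[, "1"])
}

#' Impute missing or equivocal ATRX status from age and binary p53
#'
#' An ensemble-of-trees classifier of ATRX status as a function of age and
#' p53 (binarized at the 80% threshold when continuous), trained on the rows
#' of the global cohort with observed ATRX.
#'
#' @param train Cohort with `age`, `p53` (0/1), `ATRX`.
#' @param query Data.frame with `age` and `p53` (0/1; binarize continuous
#'   percentages with [binarize_p53()] first).
#' @param seed Integer seed.
#' @return Character vector `"mutant"`/`"wildtype"` per query row.
#' @export
impute_atrx <- function(train, query, seed = 1) {
  d <- train[!is.na(train$ATRX), , drop = FALSE]
  y <- factor(d$ATRX, levels = c("mutant", "wildtype"))
  x <- data.frame(age = d$age, p53 = factor(d$p53, levels = c(0, 1)))
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y)
  nd <- data.frame(age = query$age, p53 = factor(query$p53, levels = c(0, 1)))
  as.character(stats::predict(fit, nd))
}

#' Fill in missing ATRX calls in a cohort
#'
#' Applies [impute_atrx()] only to rows with missing (or equivocal, coded
#' `NA`) ATRX; observed calls are never overwritten.
#'
#' @param cohort Cohort with `age`, `p53`, `ATRX`.
#' @param seed Integer seed.
#' @return The cohort with `ATRX` completed and a logical `ATRX_imputed`
#'   column.
#' @export
complete_atrx <- function(cohort, seed = 1) {
  miss <- is.na(cohort$ATRX)
  cohort$ATRX_imputed <- miss
  if (any(miss)) {
    cohort$ATRX[miss] <- impute_atrx(cohort[!miss, , drop = FALSE],
                                     cohort[miss, , drop = FALSE],
                                     seed = seed)
  }
  cohort
}

#' Train the composite 1p/19q codeletion classifier
#'
#' A probability-emitting ensemble-of-trees classifier over per-case feature
#' vectors (significant Olig2 density features, continuous percent p53, and
#' the ATRX/age probability), with a stratified train/test split for the
#' reported held-out accuracy and exported feature importances.
#'
#' @param cases Data.frame of numeric case features plus a `codel_1p19q`
#'   (0/1) label column; non-numeric columns are ignored.
#' @param train_frac Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return A list of class `"codel_model"`: `model`, `accuracy` (held-out),
#'   `importance`, `test_idx`, `feature_columns`.
#' @export
train_codeletion_model <- function(cases, train_frac = 0.7, seed = 1) {
  y <- factor(cases$codel_1p19q, levels = c(0, 1))
  if (nlevels(droplevels(y)) < 2) stop("both codeletion classes required")
  num <- vapply(cases, is.numeric, TRUE)
  cols <- setdiff(colnames(cases)[num], "codel_1p19q")
  x <- cases[, cols, drop = FALSE]
  set.seed(seed)
  tr_idx <- sort(unlist(lapply(split(seq_along(y), y), function(i) {
    sample(i, max(1L, round(train_frac * length(i))))
  })))
  te_idx <- setdiff(seq_along(y), tr_idx)
  fit <- randomForest::randomForest(x = x[tr_idx, , drop = FALSE],
                                    y = y[tr_idx], importance = TRUE)
  acc <- mean(stats::predict(fit, x[te_idx, , drop = FALSE]) == y[te_idx])
  structure(list(model = fit, accuracy = acc,
                 importance = randomForest::importance(fit),
                 test_idx = te_idx, feature_columns = cols),
            class = "codel_model")
}

#' Codeletion probability from the composite model
#' @param model A [train_codeletion_model()] result.
#' @param newdata Case feature data.frame.
#' @return Numeric vector of P(codeleted).
#' @export
predict_codeletion <- function(model, newdata) {
  stopifnot(inherits(model, "codel_model"))
  unname(stats::predict(model$model,
                        newdata[, model$feature_columns, drop = FALSE],
                        type = "prob")[, "1"])
}

#' Molecular-test triage recommendation for 1p/19q status
#'
#' The clinical decision rule: a codeletion prediction below 0.5 needs no
#' confirmatory testing (diagnose astrocytoma); at or above 0.5, a low-grade
#' non-recurrent tumor is confirmed by FISH, while high-grade or recurrent
#' tumors go to chromosomal microarray or NGS to avoid FISH false positives.
#'
#' @param prediction Codeletion probability in \[0, 1\].
#' @param grade `"low"` or `"high"`.
#' @param recurrent Logical; is this a recurrence?
#' @param threshold Decision threshold (default 0.5).
#' @return A list of class `"triage_recommendation"` with `decision`
#'   (`"no_further_testing"`, `"FISH"` or `"CMA_or_NGS"`), `prediction` and
#'   `grade_context`.
#' @export
recommend_test <- function(prediction, grade = c("low", "high"),
                           recurrent = FALSE, threshold = 0.5) {
  grade <- match.arg(grade)
  if (!is.finite(prediction) || prediction < 0 || prediction > 1) {
    stop("`prediction` must be a probability in [0, 1]")
  }
  decision <- if (prediction < threshold) {
    "no_further_testing"
  } else if (grade == "low" && !recurrent) {
    "FISH"
  } else {
    "CMA_or_NGS"
  }
  structure(list(decision = decision, prediction = prediction,
                 grade_context = if (grade == "high" || recurrent) {
                   "high_grade_or_recurrent"
                 } else "low_grade"),
            class = "triage_recommendation")
}

#' @export
print.triage_recommendation <- function(x, ...) {
  cat(sprintf("triage: %s (P(codel) = %.2f, %s)\n", x$decision,
              x$prediction, x$grade_context))
  invisible(x)
}
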