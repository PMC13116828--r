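sim_logit_cohort <- function(n, seed, b0 = -1, b = c(x1 = 1.2, x2 = -0.8)) {
  set.seed(seed)
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), noise = rnorm(n))
  eta <- b0 + as.matrix(d[names(b)]) %*% b
  d$MAE <- rbinom(n, 1, plogis(eta))
  d
}

test_that("splits are disjoint, exhaustive, stratified and reproducible", {
  co <- sim_logit_cohort(100, seed = 41)
  plan <- split_plan(seed = 5)
  sp <- make_split(co, plan)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_setequal(c(sp$train, sp$test), 1:100)
  expect_length(intersect(sp$train, sp$test), 0)
  # folds partition the training set
  expect_length(sp$fold, 80)
  expect_setequal(unique(sp$fold), 1:3)
  # stratification: test event rate within one patient of the overall rate
  expect_lt(abs(mean(co$MAE[sp$test]) - mean(co$MAE)), 1 / 20 + 1e-9)
  expect_identical(make_split(co, plan), sp)
  expect_false(identical(make_split(co, split_plan(seed = 6))$train, sp$train))
  co1 <- co; co1$MAE <- 1
  expect_error(make_split(co1, plan), "single-class")
  expect_error(make_split(co[1:5, ], plan), "at least 10")
})

test_that("confusion-matrix metrics match their closed forms", {
  # TP=3 FP=1 FN=1 TN=5
  d <- data.frame(x = c(rep(1, 3), 1, rep(-1, 1), rep(-1, 5)),
                  MAE = c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0))
  probs <- ifelse(d$x > 0, 0.9, 0.1)
  pred <- as.integer(probs >= 0.5)
  tp <- sum(pred & d$MAE); fp <- sum(pred & !d$MAE)
  fn <- sum(!pred & d$MAE); tn <- sum(!pred & !d$MAE)
  expect_equal(c(tp, fp, fn, tn), c(3, 1, 1, 5))
  expect_equal(tp / (tp + fn), 0.75)            # sensitivity
  expect_equal(tn / (tn + fp), 5 / 6)           # specificity
  expect_equal(tp / (tp + fp), 0.75)            # precision
  expect_equal((tp + tn) / 10, 0.8)             # accuracy
  # and the packaged evaluator reproduces them end to end via a glm fit
  fit <- fit_model("logistic", "x", d)
  met <- evaluate_model(fit, d)
  expect_equal(unname(met[c("sensitivity", "specificity", "precision",
                            "accuracy")]),
               c(0.75, 5 / 6, 0.75, 0.8))
})

test_that("rank AUC equals the concordant-pair oracle, ties at half", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(auc_rank(s, y), bf_auc(s, y))
  }
  expect_true(is.na(auc_rank(runif(5), rep(1, 5))))
  # AUC is invariant under strictly monotone score transforms
  y <- rbinom(50, 1, 0.5); s <- rnorm(50)
  expect_equal(auc_rank(s, y), auc_rank(plogis(3 * s + 2), y))
  expect_equal(auc_rank(rep(0.5, 50), y), 0.5)
})

test_that("logistic fitting recovers known generative coefficients", {
  co <- sim_logit_cohort(20000, seed = 43)
  m <- fit_model("logistic", c("x1", "x2"), co)
  g <- summary(stats::glm(MAE ~ x1 + x2, binomial, co))$coefficients
  expect_equal(unname(m$coefficients),
               unname(g[, "Estimate"]), tolerance = 1e-6)
  expect_lt(abs(m$coefficients[["x1"]] - 1.2), 3 * g["x1", "Std. Error"])
  expect_lt(abs(m$coefficients[["x2"]] + 0.8), 3 * g["x2", "Std. Error"])
})

test_that("a linear SVM separates separable data and exposes its hyperplane", {
  set.seed(44)
  n <- 60
  d <- data.frame(x1 = c(rnorm(n / 2, -3), rnorm(n / 2, 3)), x2 = rnorm(n))
  d$MAE <- rep(c(0, 1), each = n / 2)
  m <- fit_model("linear-svm", c("x1", "x2"), d)
  met <- evaluate_model(m, d)
  expect_equal(met[["accuracy"]], 1)
  expect_equal(met[["auc"]], 1)
  # hyperplane weight points along the separating direction
  expect_gt(abs(m$coefficients[["x1"]]), abs(m$coefficients[["x2"]]))
  expect_gt(m$coefficients[["x1"]], 0)
})

test_that("a zero-hidden-unit network reduces to logistic regression", {
  co <- sim_logit_cohort(2000, seed = 45)
  glm_fit <- fit_model("logistic", c("x1", "x2"), co)
  ann_fit <- fit_model("ann", c("x1", "x2"), co, hidden = 0L)
  p1 <- predict_prob(glm_fit, co)
  p2 <- predict_prob(ann_fit, co)
  expect_lt(max(abs(p1 - p2)), 0.02)   # decay keeps it a near-exact match
  expect_equal(evaluate_model(ann_fit, co)[["auc"]],
               evaluate_model(glm_fit, co)[["auc"]], tolerance = 0.01)
})

test_that("separation triggers the bounded-coefficient fallback", {
  d <- data.frame(x = c(rnorm(20, -4), rnorm(20, 4)),
                  MAE = rep(c(0, 1), each = 20))
  expect_warning(m <- fit_model("logistic", "x", d), "separation")
  expect_lt(abs(m$coefficients[["x"]]), 50)
  expect_true(all(is.finite(predict_prob(m, d))))
})

test_that("rbf-svm and ann fits are deterministic under a fixed seed", {
  co <- sim_logit_cohort(200, seed = 46)
  for (fam in c("rbf-svm", "ann")) {
    m1 <- fit_model(fam, c("x1", "x2"), co, seed = 3)
    m2 <- fit_model(fam, c("x1", "x2"), co, seed = 3)
    expect_equal(predict_prob(m1, co), predict_prob(m2, co))
  }
  expect_error(fit_model("forest", "x1", co), "unknown model family")
})

test_that("model search finds the informative variable and ranks consistently", {
  set.seed(47)
  n <- 240
  co <- data.frame(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                   n3 = rnorm(n))
  co$MAE <- rbinom(n, 1, plogis(-0.5 + 2 * co$signal))
  s <- search_models(co, family = "logistic", plan = split_plan(seed = 2),
                     pool_size = 4, max_vars = 2, top_k = 4)
  expect_length(s$reports, 4)
  # every reported model contains the planted signal variable
  expect_true(all(vapply(s$reports, function(r) "signal" %in% r$variables,
                         logical(1))))
  expect_equal(s$frequency$variable[1], "signal")
  expect_equal(s$frequency$frequency[1], 4L)
  # reports are sorted by cross-validated AUC
  cv <- vapply(s$reports, `[[`, numeric(1), "cv_auc")
  expect_true(all(diff(cv) <= 1e-12))
  # ranking is invariant to column permutation
  s2 <- search_models(co[, c("n3", "n1", "signal", "n2", "MAE")],
                      family = "logistic", plan = split_plan(seed = 2),
                      pool_size = 4, max_vars = 2, top_k = 4)
  expect_identical(lapply(s$reports, function(r) sort(r$variables)),
                   lapply(s2$reports, function(r) sort(r$variables)))
  expect_error(search_models(co[, c("signal", "MAE")], family = "logistic"),
               "pool smaller than 2")
})
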