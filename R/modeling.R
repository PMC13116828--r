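#' Train/test split plan
#'
#' @param train_fraction fraction of patients used for training (default
#'   0.8, the 80:20 protocol).
#' @param n_folds number of cross-validation folds within the training set
#'   (default 3).
#' @param seed integer seed.
#' @param stratified preserve the outcome ratio in every part (default TRUE).
#' @return a list of class \code{split_plan}.
#' @export
split_plan <- function(train_fraction = 0.8, n_folds = 3L, seed = 1L,
                       stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_folds >= 2)
  structure(list(train_fraction = train_fraction,
                 n_folds = as.integer(n_folds),
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "split_plan")
}

# largest-remainder allocation of a total quota across strata
allocate_quota <- function(sizes, total) {
  q <- sizes * total / sum(sizes)
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Split a cohort into train/test with cross-validation folds
#'
#' Disjoint, exhaustive and reproducible under the plan seed. With
#' stratification the outcome ratio is preserved in the test set and in each
#' fold by largest-remainder allocation. The test set is never touched by
#' fitting; the folds partition the training set.
#'
#' @param cohort data.frame with the outcome column.
#' @param plan a [split_plan()].
#' @param outcome outcome column name (binary 0/1).
#' @return list with \code{train}, \code{test} (row indices) and \code{fold}
#'   (fold id per training row, parallel to \code{train}).
#' @export
make_split <- function(cohort, plan = split_plan(), outcome = "MAE") {
  n <- nrow(cohort)
  if (n < 10L) stop("need at least 10 patients to split")
  y <- cohort[[outcome]]
  if (length(unique(y)) < 2L) stop("single-class cohort cannot be split")
  set.seed(plan$seed)
  strata <- if (plan$stratified) split(seq_len(n), y) else list(seq_len(n))
  n_train <- round(plan$train_fraction * n)
  quota <- allocate_quota(lengths(strata), n_train)
  train <- integer(0); fold <- integer(0)
  for (k in seq_along(strata)) {
    idx <- sample(strata[[k]])
    tr <- idx[seq_len(quota[k])]
    train <- c(train, tr)
    fold <- c(fold, rep_len(seq_len(plan$n_folds), length(tr)))
  }
  ord <- order(train)
  list(train = train[ord], test = setdiff(seq_len(n), train),
       fold = fold[ord])
}

# L2-penalized logistic regression by direct likelihood optimization; keeps
# coefficients bounded when maximum likelihood diverges under separation
ridge_logistic <- function(X, y, lambda = 1e-2) {
  Xi <- cbind(1, X)
  p <- ncol(Xi)
  pen <- c(0, rep(lambda, p - 1))          # intercept unpenalized
  nll <- function(b) {
    eta <- drop(Xi %*% b)
    sum(log1p(exp(-(2 * y - 1) * eta))) + sum(pen * b^2) / 2
  }
  grd <- function(b) {
    mu <- stats::plogis(drop(Xi %*% b))
    drop(crossprod(Xi, mu - y)) + pen * b
  }
  opt <- stats::optim(rep(0, p), nll, grd, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  structure(list(coefficients = stats::setNames(opt$par,
                                                c("(Intercept)", colnames(X)))),
            class = "ridge_logistic")
}

predict_ridge <- function(fit, X) {
  stats::plogis(drop(cbind(1, as.matrix(X)) %*% fit$coefficients))
}

standardizer <- function(data, variables) {
  X <- data[variables]
  center <- vapply(X, mean, numeric(1))
  scale <- vapply(X, stats::sd, numeric(1))
  scale[scale == 0 | is.na(scale)] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(data, sc) {
  for (v in names(sc$center))
    data[[v]] <- (data[[v]] - sc$center[[v]]) / sc$scale[[v]]
  data
}

#' Fit one predictive model family
#'
#' Supported families: \code{"logistic"} (maximum-likelihood logistic
#' regression; \code{"linear"} gives the linear-probability variant),
#' \code{"linear-svm"} and \code{"rbf-svm"} (support vector machines with
#' Platt-scaled probability outputs) and \code{"ann"} (a single-hidden-layer
#' neural network with logistic output, default 16 units; 0 hidden units
#' reduces it to logistic regression via skip connections). Predictors are
#' standardized internally on the training data; linear families report
#' intercept and coefficients mapped back to the original variable scale.
#'
#' When a logistic fit separates (runaway coefficients), the model falls back
#' to a lightly ridge-penalized fit with a warning, keeping coefficients
#' bounded.
#'
#' @param family model family string.
#' @param variables character vector of predictor columns.
#' @param data training data.frame (no missing values among predictors).
#' @param outcome outcome column name (0/1).
#' @param seed integer seed (stochastic fitters).
#' @param hidden hidden units for \code{"ann"}.
#' @param cost,gamma SVM hyperparameters (gamma defaults to 1/p).
#' @param coef_bound absolute standardized-coefficient bound beyond which
#'   separation is assumed (default 15).
#' @return object of class \code{eam_model}.
#' @export
fit_model <- function(family, variables, data, outcome = "MAE", seed = 1L,
                      hidden = 16L, cost = 1, gamma = NULL,
                      coef_bound = 15) {
  families <- c("logistic", "linear", "linear-svm", "rbf-svm", "ann")
  if (!family %in% families)
    stop("unknown model family '", family, "' (expected one of: ",
         paste(families, collapse = ", "), ")")
  missing_vars <- setdiff(c(variables, outcome), names(data))
  if (length(missing_vars))
    stop("variable(s) not in data: ", paste(missing_vars, collapse = ", "))
  if (anyNA(data[variables])) stop("predictors contain missing values; impute first")
  y <- data[[outcome]]
  sc <- standardizer(data, variables)
  Xs <- apply_standardizer(data[variables], sc)
  df <- cbind(Xs, .y = y)
  dfc <- cbind(Xs, .y = factor(y, levels = c(0, 1)))   # classification copy
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", variables),
                                               collapse = " + ")))
  coefs <- NULL; note <- NULL
  set.seed(seed)
  fit <- switch(family,
    logistic = {
      f <- suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
      if (any(abs(stats::coef(f)[-1]) > coef_bound) || !f$converged) {
        warning("possible separation: falling back to ridge-penalized logistic fit")
        note <- "ridge fallback"
        f <- ridge_logistic(as.matrix(Xs), y, lambda = 1e-2)
      }
      f
    },
    linear = stats::lm(fml, data = df),
    `linear-svm` = e1071::svm(fml, data = dfc, kernel = "linear", cost = cost,
                              probability = TRUE, scale = FALSE),
    `rbf-svm` = e1071::svm(fml, data = dfc, kernel = "radial", cost = cost,
                           gamma = if (is.null(gamma)) 1 / length(variables) else gamma,
                           probability = TRUE, scale = FALSE),
    ann = nnet::nnet(x = as.matrix(Xs), y = as.numeric(y),
                     size = as.integer(hidden), entropy = TRUE,
                     skip = hidden == 0L, decay = 1e-3, maxit = 500,
                     trace = FALSE))

  if (family %in% c("logistic", "linear")) {
    b <- stats::coef(fit)
    # back-transform to the original variable scale
    bs <- b[-1]; names(bs) <- variables
    coefs <- c("(Intercept)" =
                 unname(b[1]) - sum(bs * sc$center / sc$scale),
               bs / sc$scale)
  }
  if (family == "linear-svm") {
    w <- drop(t(fit$coefs) %*% as.matrix(fit$SV))
    names(w) <- variables
    b0 <- -fit$rho
    # orient the hyperplane so higher decision values mean class 1
    d <- drop(as.matrix(Xs) %*% w) + b0
    if (isTRUE(auc_rank(d, y) < 0.5)) { w <- -w; b0 <- -b0 }
    coefs <- c("(Intercept)" = b0 - sum(w * sc$center / sc$scale),
               w / sc$scale)
  }
  structure(list(family = family, variables = variables, outcome = outcome,
                 fit = fit, scaler = sc, coefficients = coefs,
                 seed = seed, note = note),
            class = "eam_model")
}

#' @export
print.eam_model <- function(x, ...) {
  cat(sprintf("eam_model [%s] on %d variable(s): %s\n", x$family,
              length(x$variables), paste(x$variables, collapse = ", ")))
  if (!is.null(x$coefficients)) {
    cat("coefficients (original scale):\n")
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

#' Predicted event probabilities
#'
#' @param model an \code{eam_model}.
#' @param newdata data.frame containing the model variables.
#' @return numeric vector of probabilities in [0, 1] (linear-probability
#'   predictions are clipped).
#' @export
predict_prob <- function(model, newdata) {
  stopifnot(inherits(model, "eam_model"))
  Xs <- apply_standardizer(newdata[model$variables], model$scaler)
  p <- switch(model$family,
    logistic = {
      if (inherits(model$fit, "ridge_logistic"))
        predict_ridge(model$fit, Xs)
      else
        stats::predict(model$fit, newdata = Xs, type = "response")
    },
    linear = stats::predict(model$fit, newdata = Xs),
    `linear-svm` = ,
    `rbf-svm` = {
      pr <- stats::predict(model$fit, newdata = Xs, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    ann = drop(stats::predict(model$fit, as.matrix(Xs))))
  unname(pmin(1, pmax(0, p)))
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed from the Wilcoxon rank statistic
#' (equivalent to the fraction of concordant case/control score pairs, ties
#' counted one half).
#'
#' @param scores numeric predictions.
#' @param labels binary 0/1 outcomes.
#' @return AUC in [0, 1]; NA if only one class is present.
#' @export
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold and ranking metrics of a fitted model
#'
#' Classification metrics at the probability-0.5 threshold (accuracy,
#' precision, sensitivity, specificity) plus the rank-statistic AUC.
#'
#' @param model an \code{eam_model}.
#' @param data labeled data.frame.
#' @param threshold decision threshold (default 0.5).
#' @return named numeric vector \code{auc, accuracy, precision, sensitivity,
#'   specificity} (precision NA when nothing is called positive, AUC NA on a
#'   single-class set).
#' @export
evaluate_model <- function(model, data, threshold = 0.5) {
  p <- predict_prob(model, data)
  y <- data[[model$outcome]]
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  c(auc = auc_rank(p, y),
    accuracy = (tp + tn) / length(y),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
}

cv_performance <- function(family, variables, data, fold, outcome, seed, ...) {
  aucs <- accs <- numeric(0)
  for (f in sort(unique(fold))) {
    m <- fit_model(family, variables, data[fold != f, , drop = FALSE],
                   outcome = outcome, seed = seed, ...)
    met <- evaluate_model(m, data[fold == f, , drop = FALSE])
    aucs <- c(aucs, met[["auc"]]); accs <- c(accs, met[["accuracy"]])
  }
  c(cv_auc = mean(aucs, na.rm = TRUE), cv_accuracy = mean(accs, na.rm = TRUE))
}

#' Search variable subsets for the best predictive models
#'
#' Mirrors the model-selection protocol: candidate predictors are pre-ranked
#' by univariate training AUC, all subsets of the top \code{pool_size}
#' candidates up to \code{max_vars} variables are fitted and scored by mean
#' cross-validated AUC (ties: CV accuracy, then fewer variables), and the
#' \code{top_k} subsets are refitted on the full training set and reported
#' with train/test metrics, together with a frequency-of-occurrence table of
#' the variables across the reported models. Exhaustive enumeration is a
#' documented surrogate for an unstated search; keep
#' \code{choose(pool_size, <= max_vars)} desk-scale.
#'
#' @param cohort screened, imputed data.frame.
#' @param family model family (see [fit_model()]).
#' @param plan a [split_plan()].
#' @param outcome outcome column.
#' @param id_cols columns never used as predictors.
#' @param pool_size size of the pre-ranked candidate pool (default 20).
#' @param max_vars maximal subset size (default 8).
#' @param top_k number of models reported (default 6).
#' @param max_subsets guard on the enumeration size (default 20000).
#' @param shap_background,shap_instances sample sizes for the Shapley
#'   attribution attached to nonlinear families.
#' @param ... passed to [fit_model()].
#' @return list of class \code{model_search} with \code{reports} (one per
#'   top model: family, variables, coefficients or shap, metrics),
#'   \code{frequency} (variable occurrence across reports), \code{pool} and
#'   \code{split}.
#' @export
search_models <- function(cohort, family = "logistic", plan = split_plan(),
                          outcome = "MAE", id_cols = "patient_id",
                          pool_size = 20L, max_vars = 8L, top_k = 6L,
                          max_subsets = 20000L,
                          shap_background = 50L, shap_instances = 25L, ...) {
  families <- c("logistic", "linear", "linear-svm", "rbf-svm", "ann")
  if (!family %in% families)
    stop("unknown model family '", family, "' (expected one of: ",
         paste(families, collapse = ", "), ")")
  predictors <- setdiff(names(cohort), c(outcome, intersect(id_cols, names(cohort))))
  predictors <- predictors[vapply(cohort[predictors], is.numeric, logical(1))]
  if (length(predictors) < 2L) stop("candidate pool smaller than 2 predictors")
  split <- make_split(cohort, plan, outcome = outcome)
  train <- cohort[split$train, , drop = FALSE]
  test <- cohort[split$test, , drop = FALSE]

  uni <- vapply(predictors, function(v)
    abs(auc_rank(train[[v]], train[[outcome]]) - 0.5), numeric(1))
  pool <- predictors[order(uni, decreasing = TRUE)][seq_len(min(pool_size,
                                                                length(predictors)))]
  sizes <- seq_len(min(max_vars, length(pool)))
  n_subsets <- sum(choose(length(pool), sizes))
  if (n_subsets > max_subsets)
    stop("subset enumeration too large (", n_subsets,
         "); reduce pool_size or max_vars")
  subsets <- unlist(lapply(sizes, function(k)
    utils::combn(pool, k, simplify = FALSE)), recursive = FALSE)

  perf <- t(vapply(subsets, function(vars)
    cv_performance(family, vars, train, split$fold, outcome, plan$seed, ...),
    numeric(2)))
  key <- vapply(subsets, paste, character(1), collapse = "|")
  ord <- order(-perf[, "cv_auc"], -perf[, "cv_accuracy"],
               lengths(subsets), key)
  top <- ord[seq_len(min(top_k, length(subsets)))]

  reports <- lapply(top, function(i) {
    vars <- subsets[[i]]
    m <- fit_model(family, vars, train, outcome = outcome, seed = plan$seed, ...)
    train_met <- evaluate_model(m, train)
    test_met <- evaluate_model(m, test)
    shap <- NULL
    if (is.null(m$coefficients)) {
      set.seed(plan$seed)
      bg <- train[sample(nrow(train), min(shap_background, nrow(train))), ,
                  drop = FALSE]
      inst <- test[sample(nrow(test), min(shap_instances, nrow(test))), ,
                   drop = FALSE]
      phi <- shap_attribution(m, bg, inst, seed = plan$seed)
      shap <- colMeans(abs(phi$phi))
    }
    structure(list(family = family, variables = vars,
                   coefficients = m$coefficients, shap = shap,
                   cv_auc = perf[i, "cv_auc"],
                   metrics = c(auc_train = unname(train_met[["auc"]]),
                               auc_test = unname(test_met[["auc"]]),
                               accuracy = unname(test_met[["accuracy"]]),
                               precision = unname(test_met[["precision"]]),
                               sensitivity = unname(test_met[["sensitivity"]]),
                               specificity = unname(test_met[["specificity"]]))),
              class = "model_report")
  })
  freq <- sort(table(unlist(lapply(reports, `[[`, "variables"))),
               decreasing = TRUE)
  structure(list(reports = reports,
                 frequency = data.frame(variable = names(freq),
                                        frequency = as.integer(freq)),
                 pool = pool, split = split),
            class = "model_search")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model_report [%s]: %s\n", x$family,
              paste(x$variables, collapse = " + ")))
  print(round(x$metrics, 3))
  invisible(x)
}

#' @export
print.model_search <- function(x, ...) {
  cat(sprintf("model_search: top %d models (family %s)\n",
              length(x$reports), x$reports[[1]]$family))
  for (i in seq_along(x$reports))
    cat(sprintf("  %d. %-40s cv_auc %.3f test_auc %.3f\n", i,
                paste(x$reports[[i]]$variables, collapse = "+"),
                x$reports[[i]]$cv_auc, x$reports[[i]]$metrics[["auc_test"]]))
  invisible(x)
}
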