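#' Shapley-value feature attribution
#'
#' Decomposes individual predicted probabilities into additive per-feature
#' contributions. The value of a feature coalition S at instance x is the
#' model prediction with the features in S taken from x and the rest
#' marginalized over a background reference set. With \code{p} features at
#' most \code{exact_limit}, all \eqn{2^p} coalitions are enumerated and the
#' attributions are exact; otherwise they are estimated by permutation
#' sampling (each sampled permutation contributes a telescoping sum of
#' marginal gains against one sampled background row, so the efficiency
#' property — attributions summing to the prediction minus the background
#' expectation — holds by construction).
#'
#' @param model an \code{eam_model} (any family; typically nonlinear).
#' @param background data.frame of reference rows (e.g. training data).
#' @param instances data.frame of rows to explain.
#' @param n_samples permutations per instance in sampling mode (default 200).
#' @param seed integer seed for sampling mode.
#' @param exact_limit maximal feature count for exact enumeration
#'   (default 10).
#' @param exact force (TRUE) or forbid (FALSE) exact enumeration.
#' @return list of class \code{shap_attribution}: \code{phi} (instances x
#'   features matrix), \code{baseline} (background expectation),
#'   \code{prediction} (per-instance model output), \code{method},
#'   \code{importance} (mean absolute attribution per feature).
#' @export
shap_attribution <- function(model, background, instances, n_samples = 200L,
                             seed = 1L, exact_limit = 10L, exact = NULL) {
  stopifnot(inherits(model, "eam_model"))
  vars <- model$variables
  if (nrow(background) == 0L) stop("empty background reference set")
  bg <- background[vars]
  X <- instances[vars]
  p <- length(vars)
  use_exact <- if (is.null(exact)) p <= exact_limit else isTRUE(exact)
  baseline <- mean(predict_prob(model, bg))
  pred <- predict_prob(model, X)

  phi <- if (use_exact) shap_exact(model, bg, X)
         else shap_sample(model, bg, X, n_samples, seed)
  colnames(phi) <- vars
  structure(list(phi = phi, baseline = baseline, prediction = pred,
                 method = if (use_exact) "exact" else "sampling",
                 importance = colMeans(abs(phi))),
            class = "shap_attribution")
}

# exact Shapley by coalition enumeration; v(S) averages predictions with
# S taken from x and the complement from every background row
shap_exact <- function(model, bg, X) {
  vars <- names(bg); p <- length(vars)
  n <- nrow(X); m <- nrow(bg)
  subsets <- lapply(0:(2^p - 1), function(b) which(bitwAnd(b, 2^(0:(p - 1))) > 0))
  vS <- matrix(NA_real_, n, length(subsets))
  for (s in seq_along(subsets)) {
    S <- subsets[[s]]
    # replicate background m rows per instance, overwrite S columns from x
    mix <- bg[rep(seq_len(m), times = n), , drop = FALSE]
    for (j in S) mix[[j]] <- rep(X[[j]], each = m)
    pr <- predict_prob(model, mix)
    vS[, s] <- colMeans(matrix(pr, nrow = m))
  }
  sizes <- lengths(subsets)
  key <- vapply(subsets, function(S) sum(2^(S - 1)), numeric(1))
  idx_of <- match(0:(2^p - 1), key)
  phi <- matrix(0, n, p)
  for (j in seq_len(p)) {
    for (s in seq_along(subsets)) {
      S <- subsets[[s]]
      if (j %in% S) next
      k <- length(S)
      wgt <- factorial(k) * factorial(p - k - 1) / factorial(p)
      s_with <- idx_of[key[s] + 2^(j - 1) + 1]
      phi[, j] <- phi[, j] + wgt * (vS[, s_with] - vS[, s])
    }
  }
  phi
}

# permutation-sampling Shapley: telescoping marginal gains along random
# feature orders against sampled background rows
shap_sample <- function(model, bg, X, n_samples, seed) {
  vars <- names(bg); p <- length(vars)
  n <- nrow(X); m <- nrow(bg)
  set.seed(seed)
  phi <- matrix(0, n, p)
  for (i in seq_len(n)) {
    acc <- numeric(p)
    # build all mixed rows for this instance in one batch per permutation
    for (s in seq_len(n_samples)) {
      perm <- sample.int(p)
      b <- bg[sample.int(m, 1L), , drop = FALSE]
      cur <- b
      prev <- predict_prob(model, cur)
      steps <- cur[rep(1L, p), , drop = FALSE]
      for (k in seq_len(p)) {
        cur[[perm[k]]] <- X[[perm[k]]][i]
        steps[k, ] <- cur
      }
      val <- predict_prob(model, steps)
      gains <- diff(c(prev, val))
      acc[perm] <- acc[perm] + gains
    }
    phi[i, ] <- acc / n_samples
  }
  phi
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat(sprintf("shap_attribution (%s): %d instance(s), baseline %.4f\n",
              x$method, nrow(x$phi), x$baseline))
  print(round(sort(x$importance, decreasing = TRUE), 4))
  invisible(x)
}
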