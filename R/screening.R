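#' Screen cohort variables before modeling
#'
#' Applies the pre-modeling variable filters, outcome-blind, in a fixed
#' precedence so every dropped column is attributed to exactly one rule:
#' \enumerate{
#'   \item \code{operator_dependent}: columns flagged in
#'     \code{operator_dependent} (choices such as the mapping system or the
#'     ablation catheter, which reflect the operator, not the pathology);
#'   \item \code{missingness}: fewer than \code{min_nonmissing} (default 10\%)
#'     non-missing values — a deliberately permissive cut, taken literally;
#'   \item \code{constant}: the same value across all patients (among
#'     non-missing values);
#'   \item \code{low_heterogeneity}: fewer than \code{min_hetero} (default
#'     5\%) of values differ from the modal value.
#' }
#'
#' @param cohort data.frame; the outcome and id columns are never screened.
#' @param outcome name of the outcome column (default "MAE"; may be absent).
#' @param id_cols columns exempt from screening (default "patient_id").
#' @param operator_dependent character vector of column names to drop as
#'   operator-dependent.
#' @param min_nonmissing minimum fraction of non-missing values.
#' @param min_hetero minimum fraction of values differing from the mode.
#' @return list with \code{cohort} (screened) and \code{report} (data.frame
#'   \code{variable}, \code{rule}, one row per dropped column).
#' @export
screen_variables <- function(cohort, outcome = "MAE",
                             id_cols = "patient_id",
                             operator_dependent = character(),
                             min_nonmissing = 0.10, min_hetero = 0.05) {
  if (nrow(cohort) < 2L) stop("screening needs at least 2 patients")
  keep_always <- intersect(c(outcome, id_cols), names(cohort))
  candidates <- setdiff(names(cohort), keep_always)

  rule_of <- function(v) {
    x <- cohort[[v]]
    if (v %in% operator_dependent) return("operator_dependent")
    obs <- x[!is.na(x)]
    if (length(obs) / length(x) < min_nonmissing) return("missingness")
    if (length(unique(obs)) <= 1L) return("constant")
    tab <- table(obs)
    if (1 - max(tab) / length(obs) < min_hetero) return("low_heterogeneity")
    NA_character_
  }
  rules <- vapply(candidates, rule_of, character(1))
  dropped <- candidates[!is.na(rules)]
  report <- data.frame(variable = dropped,
                       rule = unname(rules[!is.na(rules)]),
                       stringsAsFactors = FALSE)
  list(cohort = cohort[setdiff(names(cohort), dropped)], report = report)
}

#' Impute residual missing values
#'
#' Median imputation for numeric columns, mode for categorical ones. When
#' \code{train_idx} is given the imputation statistics are computed on the
#' training rows only and applied everywhere, so no information leaks from a
#' held-out test set.
#'
#' @param cohort data.frame (already screened).
#' @param train_idx optional integer vector of training-row indices.
#' @param outcome,id_cols columns left untouched.
#' @return the cohort with missing predictor values filled in.
#' @export
impute_cohort <- function(cohort, train_idx = NULL, outcome = "MAE",
                          id_cols = "patient_id") {
  skip <- intersect(c(outcome, id_cols), names(cohort))
  if (is.null(train_idx)) train_idx <- seq_len(nrow(cohort))
  for (v in setdiff(names(cohort), skip)) {
    x <- cohort[[v]]
    miss <- is.na(x)
    if (!any(miss)) next
    ref <- x[train_idx]
    ref <- ref[!is.na(ref)]
    if (length(ref) == 0L)
      stop("column '", v, "' has no observed training values to impute from")
    fill <- if (is.numeric(x)) stats::median(ref)
            else names(sort(table(ref), decreasing = TRUE))[1L]
    x[miss] <- fill
    cohort[[v]] <- x
  }
  cohort
}
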