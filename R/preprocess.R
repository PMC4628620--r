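#' Covariate residualization by ordinary least squares
#'
#' Regresses a trait on an intercept plus the supplied covariates and returns
#' the residuals.  Used to adjust ECG traits for sex, age, BMI, height and
#' heart rate before rank transformation; heart rate must be omitted for the
#' Bazett-corrected QT, which is already rate-adjusted.
#'
#' @param y numeric trait vector (no missing values among included rows).
#' @param covariates data.frame or matrix of covariate columns (an intercept
#'   is added automatically); factors are expanded to indicators.
#' @return residual vector, same length as `y`.
#' @export
residualize <- function(y, covariates) {
  if (anyNA(y)) stop("y contains missing values; subset to complete cases first")
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  if (nrow(X) != length(y)) stop("y and covariates differ in length")
  if (anyNA(X)) stop("covariates contain missing values")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  as.vector(qr.resid(qx, y))
}

#' Rank-based inverse-normal transformation
#'
#' Maps values to standard-normal quantiles of their offset ranks,
#' \eqn{\Phi^{-1}((r - c) / (n - 2c + 1))} with the Blom offset
#' \eqn{c = 3/8} by default; ties receive their average rank.  The result is
#' invariant under any strictly monotone transformation of the input and has
#' Gaussian marginals, as the multivariate-normal likelihood of the polygenic
#' model assumes.  `NA`s are passed through (ranked among the non-missing).
#'
#' @param x numeric vector, length >= 2, not all values identical.
#' @param offset rank offset `c` (default `3/8`).
#' @return transformed vector.
#' @export
rank_inverse_normal <- function(x, offset = 3/8) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2) stop("need at least 2 non-missing values")
  if (diff(range(x[ok])) == 0)
    stop("all values identical; rank transform undefined")
  r <- rank(x[ok], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Descriptive statistics table
#'
#' Mean, SD, minimum and maximum per numeric column, with the count of
#' non-missing values.
#'
#' @param cohort data.frame; non-numeric columns are skipped.
#' @param vars optional column subset.
#' @return data.frame `variable`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
descriptives <- function(cohort, vars = NULL) {
  stopifnot(is.data.frame(cohort))
  if (is.null(vars)) vars <- names(cohort)[vapply(cohort, is.numeric, TRUE)]
  if (sum(stats::complete.cases(cohort[vars])) < 3)
    stop("need at least 3 complete rows")
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    x <- x[!is.na(x)]
    data.frame(variable = v, n = length(x), mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x))
  })
  do.call(rbind, rows)
}

#' Trait correlation matrix, unadjusted above / adjusted below the diagonal
#'
#' Pearson correlations between the analysis traits: raw values above the
#' diagonal, covariate-residualized values below (the usual two-panel
#' presentation for ECG trait tables).
#'
#' @param cohort data.frame holding the trait and covariate columns.
#' @param traits character vector of trait column names.
#' @param covariates character vector of covariate column names used for the
#'   adjusted (lower) triangle.
#' @return square correlation matrix with unit diagonal.
#' @export
trait_correlations <- function(cohort, traits,
                               covariates = c("age", "sex", "bmi", "height",
                                              "heart_rate_bpm")) {
  stopifnot(is.data.frame(cohort))
  keep <- stats::complete.cases(cohort[c(traits, covariates)])
  if (sum(keep) < 3) stop("need at least 3 complete rows")
  d <- cohort[keep, , drop = FALSE]
  con <- vapply(d[traits], function(x) stats::sd(x) == 0, TRUE)
  if (any(con))
    stop("constant trait column(s): ", paste(traits[con], collapse = ", "))
  raw <- stats::cor(d[traits])
  adj <- stats::cor(vapply(traits, function(tr)
    residualize(d[[tr]], d[covariates]), numeric(nrow(d))))
  out <- raw
  out[lower.tri(out)] <- adj[lower.tri(adj)]
  out
}

#' Build analysis-ready traits
#'
#' Runs the fixed preprocessing pipeline per trait: exclusion rules
#' ([apply_exclusions()]) -> derived trait values ([derive_traits()]) ->
#' covariate residualization ([residualize()]) -> rank-based inverse-normal
#' transformation ([rank_inverse_normal()]).  Covariates are sex, age, BMI,
#' height and heart rate, except that heart rate is dropped for QT.
#' Missingness is handled complete-case per trait; excluded or incomplete
#' rows carry `NA`.
#'
#' @param cohort raw cohort data.frame (see [read_cohort()] for the layout).
#' @param traits traits to prepare (default all six).
#' @param twelve_lead_mode passed to [derive_traits()].
#' @param blom_offset passed to [rank_inverse_normal()].
#' @return list with `traits` (data.frame: `id` plus one analysis column per
#'   trait) and `exclusions` (row-bound output of [apply_exclusions()]).
#' @export
prepare_traits <- function(cohort, traits = ECG_TRAITS,
                           twelve_lead_mode = c("sum", "difference"),
                           blom_offset = 3/8) {
  twelve_lead_mode <- match.arg(twelve_lead_mode)
  d <- derive_traits(cohort, twelve_lead_mode)
  out <- data.frame(id = d$id, stringsAsFactors = FALSE)
  excl <- list()
  for (tr in traits) {
    ex <- apply_exclusions(d, tr)
    excl[[tr]] <- ex
    covs <- c("sex", "age", "bmi", "height",
              if (tr != "QT") "heart_rate_bpm")
    ok <- ex$kept & !is.na(d[[tr]]) & stats::complete.cases(d[covs])
    val <- rep(NA_real_, nrow(d))
    if (sum(ok) >= 3) {
      res <- residualize(d[[tr]][ok], d[ok, covs, drop = FALSE])
      val[ok] <- rank_inverse_normal(res, offset = blom_offset)
    }
    out[[tr]] <- val
  }
  list(traits = out, exclusions = do.call(rbind, excl))
}
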