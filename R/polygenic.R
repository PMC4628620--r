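#' Maximum-likelihood polygenic variance-component model
#'
#' Fits the polygenic mixed model
#' \deqn{y = X\beta + g + e, \quad g \sim N(0,\, 2\Phi\,\sigma^2_g), \quad
#'       e \sim N(0,\, I\,\sigma^2_e)}
#' by maximum likelihood and reports the narrow-sense heritability
#' \eqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)} with a delta-method
#' standard error and a boundary likelihood-ratio test of \eqn{h^2 = 0}.
#'
#' The covariance \eqn{V = 2\Phi\sigma^2_g + I\sigma^2_e} shares the
#' eigenvectors of \eqn{A = 2\Phi}, so after one symmetric eigendecomposition
#' of \eqn{A} (see [kinship_eigen()]) the data are rotated into the eigenbasis,
#' \eqn{\beta} and the total variance are profiled out analytically, and the
#' likelihood is maximized over the single ratio parameter
#' \eqn{h^2 \in [0, 1]} by bounded scalar search (tolerance `1e-8`).  Each fit
#' after the first on the same pedigree is therefore a one-dimensional
#' optimization.
#'
#' @param formula model formula, e.g. `QRS ~ 1` or `QRS ~ rs1 + rs2`, whose
#'   right-hand side holds the fixed effects (SNP dosages, inbreeding-class
#'   indicators); covariate adjustment is normally done beforehand with
#'   [prepare_traits()].
#' @param data data.frame containing the response and fixed-effect columns and
#'   an `id` column (or rownames) matching the kinship ids.  Rows with missing
#'   values are dropped.
#' @param kinship a `kinship_result` or a precomputed `kinship_eigen`.
#' @param se compute the standard error of \eqn{h^2} (numeric observed
#'   information on \eqn{(\sigma^2_g, \sigma^2_e)}, central differences).
#' @param reml use residual maximum likelihood instead of ML.  ML is the
#'   default and is required for the likelihood-ratio model comparisons.
#' @param tol convergence tolerance of the scalar search on \eqn{h^2}.
#'
#' @return An object of class `polygenic`; see [polygenic_fit()] for the
#'   fields.
#' @seealso [polygenic_fit()] for the matrix interface, [lrt_nested()] /
#'   [anova.polygenic()] for model comparison, [h2_total()] for the
#'   total-variance heritability scale.
#' @examples
#' set.seed(1)
#' ped <- simulate_pedigree(n_founders = 30, n_generations = 3)
#' kin <- kinship(ped)
#' sim <- simulate_phenotype(ped, kin, sigma2_g = 0.6, sigma2_e = 0.4)
#' d <- data.frame(id = ped$id, y = sim$y)
#' fit <- polygenic(y ~ 1, data = d, kinship = kin)
#' fit
#' @export
polygenic <- function(formula, data, kinship, se = TRUE, reml = FALSE,
                      tol = 1e-8) {
  stopifnot(is.data.frame(data))
  ids_all <- if ("id" %in% names(data)) as.character(data$id) else rownames(data)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), stats::model.frame(
    formula, data, na.action = stats::na.pass))
  ok <- !is.na(y) & stats::complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]; ids <- ids_all[ok]
  eig <- as_kinship_eigen(kinship, ids)
  ord <- match(eig$ids, ids)
  fit <- polygenic_fit(y[ord], X[ord, , drop = FALSE], eig, se = se,
                       reml = reml, tol = tol)
  fit$call <- match.call()
  fit
}

as_kinship_eigen <- function(kinship, ids) {
  if (inherits(kinship, "kinship_eigen")) {
    if (!setequal(kinship$ids, ids))
      stop("kinship eigendecomposition covers a different individual set ",
           "than the data; recompute with kinship_eigen(kin, ids)")
    kinship
  } else if (inherits(kinship, "kinship_result")) {
    kinship_eigen(kinship, ids)
  } else stop("kinship must be a kinship_result or kinship_eigen object")
}

#' Low-level polygenic fitter (matrix interface)
#'
#' @param y numeric response, ordered as `eig$ids`.
#' @param X fixed-effect design matrix (including the intercept column),
#'   same row order.
#' @param eig a [kinship_eigen()] for exactly these individuals.
#' @inheritParams polygenic
#' @return list of class `polygenic` with elements `h2`, `h2_se`, `sigma2_g`,
#'   `sigma2_e`, `beta`, `loglik` (maximized criterion), `loglik_null`
#'   (\eqn{\sigma^2_g = 0} fit with the same fixed effects), `lambda_h2` and
#'   `p_h2` (boundary LRT of \eqn{h^2 = 0}), `var_fixed` (sample variance of
#'   the fitted non-constant fixed effects, used by [h2_total()]),
#'   `converged`, `n`, `ids`, `reml`, plus the rotated data needed by the
#'   methods.
#' @export
polygenic_fit <- function(y, X, eig, se = TRUE, reml = FALSE, tol = 1e-8) {
  stopifnot(inherits(eig, "kinship_eigen"))
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || length(eig$ids) != n)
    stop("y, X and the kinship eigendecomposition are not index-aligned")
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X")
  if (n <= p + 2) stop("too few individuals for ", p, " fixed effects")
  d <- eig$values
  if (diff(range(d)) < 1e-10)
    stop("relatedness matrix is (numerically) a multiple of the identity: ",
         "sigma2_g and sigma2_e are not separately identifiable")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (qr(X)$rank < p) stop("fixed-effect design matrix is rank deficient")

  U <- eig$vectors
  yt <- as.vector(crossprod(U, y))
  Xt <- crossprod(U, X)

  gls <- function(w) {
    XtW <- Xt * w
    beta <- solve(crossprod(Xt, XtW), crossprod(XtW, yt))
    r <- yt - as.vector(Xt %*% beta)
    list(beta = beta, r = r, rss = sum(w * r * r),
         ldXWX = determinant(crossprod(Xt, XtW))$modulus[1])
  }
  prof <- function(h2) {
    delta <- h2 * d + (1 - h2)
    if (min(delta) < 1e-12) return(-Inf)
    g <- gls(1 / delta)
    if (!reml) {
      s2 <- g$rss / n
      -0.5 * (n * log(2 * pi) + n * log(s2) + sum(log(delta)) + n)
    } else {
      s2 <- g$rss / (n - p)
      -0.5 * ((n - p) * (log(2 * pi) + log(s2) + 1) + sum(log(delta)) +
                g$ldXWX)
    }
  }

  opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, 0, 1)
  vals <- c(opt$objective, prof(0), prof(1))
  h2 <- cand[which.max(vals)]
  loglik <- max(vals)
  converged <- is.finite(loglik)

  delta <- h2 * d + (1 - h2)
  if (min(delta) < 1e-12) delta <- pmax(delta, 1e-12)
  g <- gls(1 / delta)
  s2p <- g$rss / (if (reml) n - p else n)
  sigma2_g <- h2 * s2p
  sigma2_e <- (1 - h2) * s2p
  beta <- as.vector(g$beta)
  names(beta) <- colnames(X)

  loglik_null <- prof(0)
  lambda <- 2 * (loglik - loglik_null)
  if (lambda < -1e-6)
    stop("optimizer failure: maximized log-likelihood below the null fit")
  lambda <- max(lambda, 0)
  p_h2 <- 0.5 * stats::pchisq(lambda, df = 1, lower.tail = FALSE)

  nonconst <- apply(X, 2, function(col) stats::sd(col) > 0)
  var_fixed <- if (any(nonconst))
    stats::var(as.vector(X[, nonconst, drop = FALSE] %*% beta[nonconst]))
  else 0

  fit <- structure(list(
    call = sys.call(), h2 = h2, h2_se = NA_real_,
    sigma2_g = sigma2_g, sigma2_e = sigma2_e, beta = beta,
    loglik = loglik, loglik_null = loglik_null,
    lambda_h2 = lambda, p_h2 = p_h2,
    var_fixed = var_fixed, converged = converged, boundary = FALSE,
    n = n, ids = eig$ids, reml = reml,
    y = y, X = X, eig = eig, yt = yt, Xt = Xt),
    class = "polygenic")

  if (se) fit$h2_se <- h2_standard_error(fit)
  fit
}

#' Delta-method standard error of the heritability estimate
#'
#' Numerically differentiates the (profile) log-likelihood in
#' \eqn{(\sigma^2_g, \sigma^2_e)} around the optimum (central differences,
#' step `1e-5` times the total-variance scale), inverts the observed
#' information, and propagates to \eqn{h^2} by the delta method.  At a
#' boundary estimate (\eqn{h^2} within `1e-6` of 0 or 1) the curvature does
#' not measure uncertainty and the SE is reported as `NA` with a warning.
#'
#' @param fit a converged `polygenic` fit.
#' @return standard error (scalar), or `NA` at a boundary.
#' @export
h2_standard_error <- function(fit) {
  stopifnot(inherits(fit, "polygenic"))
  sg <- fit$sigma2_g; se2 <- fit$sigma2_e
  if (fit$h2 < 1e-6 || fit$h2 > 1 - 1e-6) {
    warning("h2 estimate at the boundary; standard error undefined")
    return(NA_real_)
  }
  ll <- function(th) rotated_loglik(fit, th[1], th[2])
  h <- 1e-5 * (sg + se2)
  H <- matrix(NA_real_, 2, 2)
  th0 <- c(sg, se2)
  for (i in 1:2) for (j in 1:2) {
    if (j < i) { H[i, j] <- H[j, i]; next }
    ei <- ej <- c(0, 0); ei[i] <- h; ej[j] <- h
    if (i == j) {
      H[i, i] <- (ll(th0 + ei) - 2 * ll(th0) + ll(th0 - ei)) / h^2
    } else {
      H[i, j] <- (ll(th0 + ei + ej) - ll(th0 + ei - ej) -
                    ll(th0 - ei + ej) + ll(th0 - ei - ej)) / (4 * h^2)
    }
  }
  if (anyNA(H)) return(NA_real_)
  info <- -H
  cv <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cv)) return(NA_real_)
  tot <- sg + se2
  grad <- c(se2, -sg) / tot^2
  v <- drop(t(grad) %*% cv %*% grad)
  if (!is.finite(v) || v <= 0) return(NA_real_)
  sqrt(v)
}

#' Boundary likelihood-ratio test of zero heritability
#'
#' Tests \eqn{\sigma^2_g = 0} against the fitted model with identical fixed
#' effects.  Because the null value lies on the boundary of the parameter
#' space, the statistic \eqn{\Lambda = 2(\ell_{full} - \ell_{null})} follows a
#' 50:50 mixture of a point mass at zero and \eqn{\chi^2_1}, so
#' \eqn{p = \tfrac12 P(\chi^2_1 > \Lambda)}.
#'
#' @param fit a `polygenic` fit (ML).
#' @param null_loglik optional externally computed null log-likelihood;
#'   defaults to the one stored in the fit.
#' @return list with `lambda` and `p`.
#' @export
lrt_h2_zero <- function(fit, null_loglik = NULL) {
  stopifnot(inherits(fit, "polygenic"))
  ll0 <- if (is.null(null_loglik)) fit$loglik_null else null_loglik
  lambda <- 2 * (fit$loglik - ll0)
  if (lambda < -1e-6)
    stop("optimizer failure: full-model log-likelihood below the null")
  lambda <- max(lambda, 0)
  list(lambda = lambda,
       p = 0.5 * stats::pchisq(lambda, df = 1, lower.tail = FALSE))
}

#' Likelihood-ratio test between nested polygenic models
#'
#' Compares two ML fits on the identical individuals whose fixed effects are
#' nested; \eqn{\Lambda = 2\Delta\ell} is referred to \eqn{\chi^2} with
#' degrees of freedom equal to the number of added columns.
#'
#' @param fit_full,fit_reduced `polygenic` fits on the same individuals.
#' @param df degrees of freedom; defaults to the difference in the number of
#'   fixed-effect columns.
#' @return list with `lambda`, `df`, `p`.
#' @export
lrt_nested <- function(fit_full, fit_reduced, df = NULL) {
  stopifnot(inherits(fit_full, "polygenic"), inherits(fit_reduced, "polygenic"))
  if (fit_full$reml || fit_reduced$reml)
    stop("likelihood-ratio comparison of fixed effects requires ML fits")
  if (fit_full$n != fit_reduced$n || !all(fit_full$ids == fit_reduced$ids))
    stop("fits use different individual sets; refusing to compare")
  if (!all(names(fit_reduced$beta) %in% names(fit_full$beta)))
    stop("models are not nested (reduced fixed effects not a subset)")
  if (is.null(df)) df <- length(fit_full$beta) - length(fit_reduced$beta)
  if (df < 0) stop("full model has fewer fixed effects than the reduced one")
  lambda <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (lambda < -1e-6)
    stop("optimizer failure: nested model has higher log-likelihood")
  lambda <- max(lambda, 0)
  p <- if (df == 0) 1 else stats::pchisq(lambda, df = df, lower.tail = FALSE)
  list(lambda = lambda, df = df, p = p)
}

#' Variance explained by the non-constant fixed effects
#'
#' Sample variance of the fitted fixed-effect part (intercept and other
#' constant columns excluded).  The naive quantity
#' \eqn{\widehat{var}(X_s\hat\beta_s)} overstates the variance attributable to
#' the covariates, because the estimated coefficients also capture estimation
#' noise: its expectation is \eqn{var(X_s\beta_s) +
#' tr(\Sigma_s\, cov(\hat\beta_s))} with \eqn{\Sigma_s} the sample covariance
#' of the columns.  With `adjust = TRUE` (default) that trace term, evaluated
#' from the GLS coefficient covariance at the fitted variance ratio, is
#' subtracted (truncating at zero), giving an approximately unbiased estimate
#' of the explained variance.
#'
#' @param fit a `polygenic` fit.
#' @param adjust subtract the estimation-noise term.
#' @return non-negative scalar variance.
#' @export
explained_variance <- function(fit, adjust = TRUE) {
  stopifnot(inherits(fit, "polygenic"))
  X <- fit$X
  nonconst <- apply(X, 2, function(col) stats::sd(col) > 0)
  if (!any(nonconst)) return(0)
  v <- stats::var(as.vector(X[, nonconst, drop = FALSE] %*%
                              fit$beta[nonconst]))
  if (adjust) {
    delta <- fit$h2 * fit$eig$values + (1 - fit$h2)
    covb <- solve(crossprod(fit$Xt, fit$Xt / delta)) *
      (fit$sigma2_g + fit$sigma2_e)
    S <- stats::cov(X[, nonconst, drop = FALSE])
    v <- max(0, v - sum(S * covb[nonconst, nonconst]))
  }
  v
}

#' Heritability on the total-phenotypic-variance scale
#'
#' The fit's `h2` is \eqn{\sigma^2_g/(\sigma^2_g+\sigma^2_e)}, the fraction of
#' variance left after the fixed effects.  When SNP dosages are fixed effects,
#' the conditioned heritability reported by the three-model pipeline is
#' expressed relative to the total trait variance, adding the variance
#' explained by the SNPs back into the denominator:
#' \deqn{h^2_{tot} = \sigma^2_g / (\sigma^2_g + \sigma^2_e + v_s),}
#' where \eqn{v_s} is the (by default degrees-of-freedom adjusted, see
#' [explained_variance()]) variance of the fitted SNP effects.  With no
#' non-constant fixed effects the two scales coincide.
#'
#' @param fit a `polygenic` fit.
#' @param adjust passed to [explained_variance()].
#' @return heritability on the total-variance scale.
#' @export
h2_total <- function(fit, adjust = TRUE) {
  stopifnot(inherits(fit, "polygenic"))
  fit$sigma2_g / (fit$sigma2_g + fit$sigma2_e +
                    explained_variance(fit, adjust))
}
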