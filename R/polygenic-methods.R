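#' @export
print.polygenic <- function(x, digits = 3, ...) {
  cat("Polygenic variance-component model",
      if (x$reml) "(REML)" else "(ML)", "\n")
  cat(sprintf("  n = %d, fixed effects: %d\n", x$n, length(x$beta)))
  cat(sprintf("  h2 = %.*f (SE %s)   sigma2_g = %.*f   sigma2_e = %.*f\n",
              digits, x$h2,
              if (is.na(x$h2_se)) "NA" else formatC(x$h2_se, digits = digits,
                                                    format = "f"),
              digits, x$sigma2_g, digits, x$sigma2_e))
  cat(sprintf("  logLik = %.2f   P(h2 = 0) = %.3g\n", x$loglik, x$p_h2))
  invisible(x)
}

#' @export
summary.polygenic <- function(object, ...) {
  structure(list(fit = object, h2_total = h2_total(object)),
            class = "summary.polygenic")
}

#' @export
print.summary.polygenic <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  h2 on the total-variance scale: %.3f (var of fixed effects %.4f)\n",
              x$h2_total, f$var_fixed))
  cat("  Fixed effects:\n")
  print(round(f$beta, 4))
  invisible(x)
}

#' @export
coef.polygenic <- function(object, ...) object$beta

#' @export
logLik.polygenic <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 2, nobs = object$n,
            class = "logLik")
}

#' @export
nobs.polygenic <- function(object, ...) object$n

#' @export
fitted.polygenic <- function(object, ...)
  stats::setNames(as.vector(object$X %*% object$beta), object$ids)

#' Residuals of a polygenic fit
#'
#' `type = "marginal"` returns \eqn{y - X\hat\beta}; `type = "conditional"`
#' additionally subtracts the BLUP of the additive genetic effect (see
#' [predict.polygenic()]).
#'
#' @param object a `polygenic` fit.
#' @param type `"marginal"` or `"conditional"`.
#' @param ... unused.
#' @export
residuals.polygenic <- function(object, type = c("marginal", "conditional"),
                                ...) {
  type <- match.arg(type)
  r <- object$y - as.vector(object$X %*% object$beta)
  if (type == "conditional") r <- r - predict(object)
  stats::setNames(r, object$ids)
}

#' Best linear unbiased prediction of the additive genetic effects
#'
#' \eqn{\hat g = 2\Phi\sigma^2_g V^{-1} (y - X\hat\beta)}, evaluated in the
#' eigenbasis of the relationship matrix.
#'
#' @param object a `polygenic` fit.
#' @param ... unused.
#' @return named vector of predicted breeding values.
#' @export
predict.polygenic <- function(object, ...) {
  d <- object$eig$values
  delta <- object$sigma2_g * d + object$sigma2_e
  rt <- object$yt - as.vector(object$Xt %*% object$beta)
  g <- as.vector(object$eig$vectors %*% (object$sigma2_g * d / delta * rt))
  stats::setNames(g, object$ids)
}

#' Simulate responses from a fitted polygenic model
#'
#' Draws from \eqn{N(X\hat\beta,\, 2\Phi\hat\sigma^2_g + I\hat\sigma^2_e)}.
#'
#' @param object a `polygenic` fit.
#' @param nsim number of response vectors.
#' @param seed optional seed, handled as in [stats::simulate()].
#' @param ... unused.
#' @return data.frame with `nsim` columns, rows named by individual id.
#' @export
simulate.polygenic <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  d <- object$eig$values
  sdev <- sqrt(object$sigma2_g * d + object$sigma2_e)
  mu <- as.vector(object$X %*% object$beta)
  out <- vapply(seq_len(nsim), function(k)
    mu + as.vector(object$eig$vectors %*% (sdev * stats::rnorm(n))),
    numeric(n))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$ids
  out
}

#' Profile log-likelihood curve over the heritability ratio
#'
#' Plots the profile log-likelihood as a function of \eqn{h^2}, marking the
#' maximum-likelihood estimate.
#'
#' @param x a `polygenic` fit.
#' @param npoints grid resolution.
#' @param ... passed to [graphics::plot()].
#' @export
plot.polygenic <- function(x, npoints = 101, ...) {
  grid <- seq(0, 1, length.out = npoints)
  ll <- vapply(grid, function(h2) profile_loglik(x, h2), numeric(1))
  graphics::plot(grid, ll, type = "l", xlab = expression(h^2),
                 ylab = "profile log-likelihood", ...)
  graphics::abline(v = x$h2, lty = 2)
  invisible(data.frame(h2 = grid, loglik = ll))
}

# ML log-likelihood at fixed variance components, beta profiled by GLS;
# evaluated in the eigenbasis (used by the SE machinery and oracle tests)
rotated_loglik <- function(fit, sigma2_g, sigma2_e) {
  d <- fit$eig$values
  delta <- sigma2_g * d + sigma2_e
  if (min(delta) <= 0) return(NA_real_)
  w <- 1 / delta
  XtW <- fit$Xt * w
  beta <- solve(crossprod(fit$Xt, XtW), crossprod(XtW, fit$yt))
  r <- fit$yt - as.vector(fit$Xt %*% beta)
  -0.5 * (fit$n * log(2 * pi) + sum(log(delta)) + sum(w * r * r))
}

# profile ML log-likelihood at an arbitrary h2 (beta, total variance profiled)
profile_loglik <- function(fit, h2) {
  d <- fit$eig$values
  delta <- h2 * d + (1 - h2)
  if (min(delta) < 1e-12) return(-Inf)
  w <- 1 / delta
  XtW <- fit$Xt * w
  beta <- solve(crossprod(fit$Xt, XtW), crossprod(XtW, fit$yt))
  r <- fit$yt - as.vector(fit$Xt %*% beta)
  s2 <- sum(w * r * r) / fit$n
  -0.5 * (fit$n * log(2 * pi) + fit$n * log(s2) + sum(log(delta)) + fit$n)
}

#' Compare nested polygenic fits by likelihood ratio
#'
#' @param object,... two or more `polygenic` fits on the same individuals,
#'   with nested fixed effects.
#' @return data.frame with one row per model and LRT columns against the
#'   previous (smaller) model.
#' @export
anova.polygenic <- function(object, ...) {
  fits <- c(list(object), list(...))
  if (length(fits) < 2) stop("supply at least two fits to compare")
  npar <- vapply(fits, function(f) length(f$beta), integer(1))
  fits <- fits[order(npar)]
  out <- data.frame(
    n_fixed = sort(npar),
    logLik = vapply(fits, function(f) f$loglik, numeric(1)),
    lambda = NA_real_, df = NA_integer_, p = NA_real_)
  for (k in 2:length(fits)) {
    lt <- lrt_nested(fits[[k]], fits[[k - 1]])
    out$lambda[k] <- lt$lambda; out$df[k] <- lt$df; out$p[k] <- lt$p
  }
  rownames(out) <- paste0("model_", seq_along(fits))
  out
}

#' Serialize a polygenic fit to JSON
#'
#' Writes the variance components, fixed effects, log-likelihoods, h2 with SE
#' and the boundary-test p-value; numeric values keep full precision.
#'
#' @param fit a `polygenic` fit.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "polygenic"))
  obj <- fit[c("h2", "h2_se", "sigma2_g", "sigma2_e", "loglik", "loglik_null",
               "lambda_h2", "p_h2", "var_fixed", "converged", "n", "reml")]
  obj$beta <- as.list(fit$beta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
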