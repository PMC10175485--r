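poisson_loglik <- function(y, eta) {
  sum(y * eta - exp(eta) - lfactorial(y))
}

## Iteratively reweighted least squares for the log-link Poisson model.
## Converges on relative log-likelihood change < tol (default 1e-10) or
## errors after maxit iterations, reporting the last iterate.  Aliased
## (rank-deficient) columns are dropped and reported with coefficient 0
## and standard error NA, as in lm()'s aliasing convention.
irls_poisson <- function(y, X, tol = 1e-10, maxit = 100) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    fit <- irls_poisson(y, X[, keep, drop = FALSE], tol = tol, maxit = maxit)
    beta <- numeric(ncol(X)); beta[keep] <- fit$coefficients
    V <- matrix(NA_real_, ncol(X), ncol(X))
    V[keep, keep] <- fit$vcov
    return(list(coefficients = beta, loglik = fit$loglik, iter = fit$iter,
                vcov = V, aliased = setdiff(seq_len(ncol(X)), keep)))
  }
  beta <- numeric(ncol(X))
  beta[1] <- log(mean(y) + 1e-8)
  ll <- poisson_loglik(y, drop(X %*% beta))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    W <- mu
    z <- eta + (y - mu) / mu
    XtW <- t(X * W)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) stop(
                           "IRLS failed (singular information); last iterate: ",
                           paste(signif(beta, 6), collapse = ", ")))
    beta_new <- drop(beta_new)
    ll_new <- poisson_loglik(y, drop(X %*% beta_new))
    ## step-halve if the likelihood degrades (guards overshoot)
    half <- 0
    while (is.na(ll_new) || ll_new < ll - 1e-12) {
      half <- half + 1
      if (half > 30) break
      beta_new <- (beta + beta_new) / 2
      ll_new <- poisson_loglik(y, drop(X %*% beta_new))
    }
    done <- abs(ll_new - ll) < tol * (abs(ll) + 1e-8)
    beta <- beta_new; ll <- ll_new
    if (done) {
      return(list(coefficients = beta, loglik = ll, iter = it,
                  vcov = solve(t(X * exp(drop(X %*% beta))) %*% X),
                  aliased = integer(0)))
    }
  }
  stop("IRLS did not converge in ", maxit, " iterations; last iterate: ",
       paste(signif(beta, 6), collapse = ", "))
}

#' Poisson regression of mutation counts on cellular and naked CPD counts
#'
#' Fits `y ~ Poisson(exp(b0 + b_cell x_cell + b_naked x_naked))` by
#' iteratively reweighted least squares, where `y` is the per-site
#' mutation sum at the -4/-3 motif positions and `x_cell`, `x_naked` the
#' CPD count sums at the same positions in the cellular and naked-DNA
#' libraries.  Reports Wald 95% confidence intervals from the observed
#' information, a likelihood-ratio test of the full model against the
#' naked-only null (1 df), and McFadden's pseudo-R-squared against the
#' intercept-only model.
#'
#' @param y non-negative integer mutation counts, one per site.
#' @param x_cell,x_naked per-site CPD count sums (same length as `y`).
#' @param conf_level Wald confidence level.
#' @param tol,maxit IRLS convergence controls (relative log-likelihood
#'   change and iteration cap).
#' @return an object of class `cpd_glm`.
#' @export
fit_poisson_glm <- function(y, x_cell, x_naked, conf_level = 0.95,
                            tol = 1e-10, maxit = 100) {
  stopifnot(length(y) == length(x_cell), length(y) == length(x_naked))
  if (length(y) < 3) stop("need >= 3 sites after capture-efficiency exclusion")
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative integers")
  if (all(y == 0)) stop("all mutation counts are zero; model degenerate")

  X <- cbind(intercept = 1, cell = x_cell, naked = x_naked)
  fit <- irls_poisson(y, X, tol = tol, maxit = maxit)
  null_fit <- irls_poisson(y, X[, c("intercept", "naked"), drop = FALSE],
                           tol = tol, maxit = maxit)
  ll0 <- poisson_loglik(y, rep(log(mean(y)), length(y)))

  beta <- setNames(fit$coefficients, colnames(X))
  se <- sqrt(diag(fit$vcov))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- cbind(lower = beta - zq * se, upper = beta + zq * se)
  lrt <- 2 * (fit$loglik - null_fit$loglik)
  structure(list(
    coefficients = beta, se = setNames(se, colnames(X)), ci = ci,
    vcov = fit$vcov, conf_level = conf_level,
    loglik = c(model = fit$loglik, null_naked = null_fit$loglik,
               intercept = ll0),
    lrt_stat = lrt, lrt_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    pseudo_r2 = 1 - fit$loglik / ll0,
    fitted = exp(drop(X %*% beta)),
    y = y, x_cell = x_cell, x_naked = x_naked,
    iter = fit$iter, n = length(y)
  ), class = "cpd_glm")
}

#' @export
print.cpd_glm <- function(x, ...) {
  cat("Poisson regression of mutation counts on CPD counts\n")
  cat(sprintf("  n = %d sites; log-likelihood = %.3f; pseudo-R2 (McFadden) = %.4f\n",
              x$n, x$loglik[["model"]], x$pseudo_r2))
  print(signif(x$coefficients, 6))
  cat(sprintf("  LRT vs naked-only null: chi2(1) = %.3f, p = %.3g\n",
              x$lrt_stat, x$lrt_p))
  invisible(x)
}

#' @export
summary.cpd_glm <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(estimate = object$coefficients, se = object$se,
               object$ci, z = z,
               p = 2 * pnorm(-abs(z)))
  structure(list(table = tab, fit = object), class = "summary.cpd_glm")
}

#' @export
print.summary.cpd_glm <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (Wald", x$fit$conf_level * 100, "% CI):\n")
  print(signif(x$table, 6))
  invisible(x)
}

#' @export
coef.cpd_glm <- function(object, ...) object$coefficients

#' @export
confint.cpd_glm <- function(object, parm, level = 0.95, ...) {
  zq <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - zq * object$se,
              object$coefficients + zq * object$se)
  colnames(ci) <- paste0(c((1 - level) / 2, 1 - (1 - level) / 2) * 100, " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
logLik.cpd_glm <- function(object, ...) {
  structure(object$loglik[["model"]], df = 3, nobs = object$n, class = "logLik")
}

#' @export
predict.cpd_glm <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  xc <- if (is.null(newdata)) object$x_cell else newdata$x_cell
  xn <- if (is.null(newdata)) object$x_naked else newdata$x_naked
  eta <- object$coefficients[1] + object$coefficients[2] * xc +
    object$coefficients[3] * xn
  if (type == "link") unname(eta) else unname(exp(eta))
}

#' @export
residuals.cpd_glm <- function(object, type = c("pearson", "deviance", "response"), ...) {
  type <- match.arg(type)
  mu <- object$fitted; y <- object$y
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu),
    deviance = sign(y - mu) *
      sqrt(2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu)))
  )
}
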