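#' Fit a random-intercept linear mixed model
#'
#' Fits \eqn{y = X\beta + Z u + \varepsilon} with a single random intercept
#' per subject, \eqn{u_i \sim N(0, \sigma^2_u)} and
#' \eqn{\varepsilon \sim N(0, \sigma^2_e I)}, by maximum likelihood or REML.
#' The fixed effects are the generalized-least-squares estimator
#' \eqn{\hat\beta = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y} at the
#' variance-component optimum, where
#' \eqn{V = \sigma^2_u Z Z^\top + \sigma^2_e I} is the marginal covariance.
#'
#' Estimation profiles the fixed effects and the residual variance out of the
#' (restricted) likelihood and optimizes the single variance ratio
#' \eqn{\gamma = \sigma^2_u / \sigma^2_e} by bounded 1-D minimization. All
#' linear algebra exploits the block-diagonal structure of \eqn{V} by subject
#' (each block inverted analytically), so the cost is linear in the number of
#' observations; results are identical to a dense GLS solve.
#'
#' @param y numeric response vector (one entry per observation).
#' @param X fixed-effects design matrix, rows aligned with `y`; must have full
#'   column rank. Include an intercept column explicitly if wanted.
#' @param subject subject identifier per observation (coerced to factor);
#'   defines the random-intercept grouping.
#' @param method `"REML"` (default) or `"ML"`.
#' @return An object of class `lmm_ri` with components `coefficients`,
#'   `se`, `vcov`, `var_subject`, `var_residual`, `gamma`
#'   (\eqn{\sigma^2_u/\sigma^2_e}), `loglik`, `aic`
#'   (\eqn{2(p+2) - 2\,\mathrm{loglik}}), `method`, `converged`, `boundary`
#'   (`TRUE` when \eqn{\hat\sigma^2_u = 0}), `n_obs`, `n_subjects`, `p`,
#'   `fitted` (fixed part \eqn{X\hat\beta}) and `blup` (empirical Bayes
#'   subject intercepts, for diagnostics only — predictions for unseen
#'   subjects use the fixed part alone, see [predict.lmm_ri()]).
#' @examples
#' set.seed(1)
#' subj <- rep(1:20, each = 4)
#' x <- rnorm(80)
#' y <- 1 + 2 * x + rnorm(20, sd = 2)[subj] + rnorm(80)
#' fit <- lmm_ri(y, cbind(1, x), subj)
#' coef(fit)
#' @export
lmm_ri <- function(y, X, subject, method = c("REML", "ML")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  K <- length(y)
  p <- ncol(X)
  if (nrow(X) != K) stop("lmm_ri: nrow(X) must equal length(y)")
  if (anyNA(y) || anyNA(X)) stop("lmm_ri: missing values in response or design")
  subject <- factor(subject)
  if (length(subject) != K) stop("lmm_ri: subject labels must match observations")
  if (nlevels(subject) < 2L) stop("lmm_ri: need at least 2 subjects")
  if (K < p + 2L) stop("lmm_ri: need at least p + 2 observations")
  if (qr(X)$rank < p) stop("lmm_ri: fixed-effects design is rank deficient")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  idx <- split(seq_len(K), subject)
  k <- lengths(idx)
  n <- length(idx)
  # per-subject sufficient statistics
  A0 <- crossprod(X)              # X'X
  b0 <- crossprod(X, y)           # X'y
  yy <- sum(y * y)
  SX <- do.call(rbind, lapply(idx, function(ii)
    colSums(X[ii, , drop = FALSE])))          # n x p, X_i' 1
  sy <- vapply(idx, function(ii) sum(y[ii]), numeric(1))

  # profiled deviance at variance ratio gamma (up to constants)
  prof <- function(gamma) {
    cc <- gamma / (1 + gamma * k)
    A <- A0 - crossprod(SX, cc * SX)
    b <- b0 - crossprod(SX, cc * sy)
    cA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(cA)) return(list(dev = Inf))
    beta <- backsolve(cA, forwardsolve(t(cA), b))
    q <- yy - sum(cc * sy^2) - sum(b * beta)
    q <- max(q, 1e-300)
    ldV <- sum(log1p(gamma * k))
    if (method == "ML") {
      dev <- K * log(q / K) + ldV
    } else {
      ldA <- 2 * sum(log(diag(cA)))
      dev <- (K - p) * log(q / (K - p)) + ldV + ldA
    }
    list(dev = dev, beta = beta, q = q, A = A, cA = cA, ldV = ldV)
  }

  boundary <- FALSE
  converged <- TRUE
  if (max(k) == 1L) {
    gamma <- 0                     # one observation per subject: ratio unidentified
    boundary <- TRUE
  } else {
    opt <- optimize(function(t) prof(exp(t))$dev, interval = c(-12, 12),
                    tol = 1e-9)
    gamma <- exp(opt$minimum)
    if (prof(0)$dev <= opt$objective + 1e-8 || opt$minimum < -11.5) {
      gamma <- 0
      boundary <- TRUE
    }
    if (opt$minimum > 11.5) converged <- FALSE
  }

  pr <- prof(gamma)
  dfree <- if (method == "ML") K else K - p
  var_e <- pr$q / dfree
  var_u <- gamma * var_e
  if (method == "ML") {
    loglik <- -0.5 * (K * log(2 * pi) + K * log(var_e) + pr$ldV + K)
  } else {
    ldA <- 2 * sum(log(diag(pr$cA)))
    loglik <- -0.5 * ((K - p) * log(2 * pi) + (K - p) * log(var_e) +
                        pr$ldV + ldA + (K - p))
  }
  vc <- var_e * chol2inv(pr$cA)
  beta <- drop(pr$beta)
  names(beta) <- colnames(X)
  se <- sqrt(diag(vc))
  names(se) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  fitted <- drop(X %*% beta)
  # empirical Bayes subject intercepts at the estimates
  cc <- gamma / (1 + gamma * k)
  res_sums <- vapply(idx, function(ii) sum(y[ii] - fitted[ii]), numeric(1))
  blup <- gamma * res_sums / (1 + gamma * k)
  names(blup) <- names(idx)

  structure(list(
    coefficients = beta, se = se, vcov = vc,
    var_subject = var_u, var_residual = var_e, gamma = gamma,
    loglik = loglik, aic = 2 * (p + 2) - 2 * loglik,
    method = method, converged = converged, boundary = boundary,
    n_obs = K, n_subjects = n, p = p,
    fitted = fitted, residuals = y - fitted, blup = blup,
    subject = subject
  ), class = "lmm_ri")
}

#' @export
print.lmm_ri <- function(x, ...) {
  cat(sprintf("Random-intercept linear mixed model (%s)\n", x$method))
  cat(sprintf("  %d observations, %d subjects, %d fixed effects\n",
              x$n_obs, x$n_subjects, x$p))
  cat(sprintf("  var(subject) = %.4g, var(residual) = %.4g%s\n",
              x$var_subject, x$var_residual,
              if (x$boundary) "  [subject variance at boundary 0]" else ""))
  cat(sprintf("  logLik = %.3f, AIC = %.3f\n", x$loglik, x$aic))
  cat("Fixed effects:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.lmm_ri <- function(object, ...) object$coefficients

#' @export
vcov.lmm_ri <- function(object, ...) object$vcov

#' @export
logLik.lmm_ri <- function(object, ...) {
  structure(object$loglik, df = object$p + 2, class = "logLik")
}

#' @export
fitted.lmm_ri <- function(object, ...) object$fitted

#' @export
residuals.lmm_ri <- function(object, ...) object$residuals

#' Summarize a random-intercept mixed model fit
#'
#' Produces a coefficient table with Wald z statistics
#' (\eqn{p = 2\Phi(-|{\rm est}/{\rm se}|)}).
#'
#' @param object an [lmm_ri()] fit.
#' @param ... unused.
#' @export
summary.lmm_ri <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.lmm_ri"
  out
}

#' @export
print.summary.lmm_ri <- function(x, ...) {
  print(x$fit)
  cat("\nWald tests:\n")
  printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Wald test for one fixed-effect coefficient
#'
#' @param fit an [lmm_ri()] fit.
#' @param which coefficient index or name.
#' @return Named vector `c(estimate=, se=, p_value=)` with
#'   \eqn{p = 2\Phi(-|{\rm estimate}/{\rm se}|)}.
#' @export
coef_test <- function(fit, which) {
  stopifnot(inherits(fit, "lmm_ri"))
  est <- fit$coefficients[which]
  se <- fit$se[which]
  if (length(est) != 1L || is.na(est)) stop("coef_test: invalid coefficient index")
  if (se == 0) stop("coef_test: standard error is zero")
  c(estimate = unname(est), se = unname(se),
    p_value = 2 * pnorm(-abs(unname(est) / unname(se))))
}

#' Fixed-effects-only prediction from a mixed model
#'
#' Predictions for subjects not present in the training data use the fixed
#' part only, \eqn{\hat y = X_{new}\hat\beta}; the random intercept of an
#' unseen subject has expectation zero and contributes nothing.
#'
#' @param object an [lmm_ri()] fit.
#' @param newdesign matrix with the same columns as the training design.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.lmm_ri <- function(object, newdesign, ...) {
  newdesign <- as.matrix(newdesign)
  if (ncol(newdesign) != object$p)
    stop("predict.lmm_ri: newdesign must have ", object$p, " columns")
  drop(newdesign %*% object$coefficients)
}
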