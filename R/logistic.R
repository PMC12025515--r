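# Maximum-likelihood logistic regression by Newton-Raphson (IRLS), with
# Wald standard errors from the inverse observed information. Written as a
# small self-contained solver so the association stage is fully auditable;
# the deviance trace it records makes the monotone-convergence property
# directly testable.

#' Logistic regression by Newton-Raphson on a design matrix
#'
#' Fits `logit P(y = 1) = X beta` by maximum likelihood. Iteration stops
#' when the largest absolute score (gradient) component falls below `tol`
#' or the Newton step becomes numerically nil. Fits with any coefficient
#' beyond `+/- 15` on the log-odds scale are flagged as non-converged with
#' a separation warning.
#'
#' @param X numeric design matrix (include an intercept column yourself, or
#'   use the higher-level [fit_logistic()]).
#' @param y 0/1 response vector.
#' @param weights optional non-negative case weights (frequency weights).
#' @param tol convergence tolerance on the score (default 1e-8).
#' @param max_iter maximum Newton iterations (default 25).
#' @return an object of class `logistic_fit`; see [fit_logistic()].
#' @export
logistic_regression <- function(X, y, weights = NULL, tol = 1e-8,
                                max_iter = 25) {
  X <- as.matrix(X)
  if (is.logical(y)) y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  w <- weights %||% rep(1, length(y))
  stopifnot(length(w) == length(y), all(w >= 0))
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]], collapse = ", "))

  beta <- numeric(ncol(X))
  deviance_trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  repeat {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    # deviance with weights; guard exact 0/1 fitted values
    ll <- sum(w * (y * stats::plogis(eta, log.p = TRUE) +
                   (1 - y) * stats::plogis(-eta, log.p = TRUE)))
    deviance_trace <- c(deviance_trace, -2 * ll)
    score <- drop(crossprod(X, w * (y - mu)))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    wt <- w * mu * (1 - mu)
    info <- crossprod(X, X * wt)
    step <- tryCatch(solve(info, score),
                     error = function(e) stop("information matrix singular: ",
                                              conditionMessage(e)))
    if (max(abs(step)) < 1e-12) { converged <- TRUE; break }
    beta <- beta + step
    iter <- iter + 1
  }

  separated <- any(abs(beta) > 15)
  if (separated) {
    warning("possible separation: |estimate| > 15 on the log-odds scale; ",
            "fit flagged non-converged")
    converged <- FALSE
  }
  mu <- stats::plogis(drop(X %*% beta))
  info <- crossprod(X, X * (w * mu * (1 - mu)))
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  ci_lo <- beta - 1.96 * se
  ci_hi <- beta + 1.96 * se
  p <- 2 * stats::pnorm(-abs(beta / se))
  coefs <- data.frame(term = colnames(X), estimate = beta, se = se,
                      ci_lo = ci_lo, ci_hi = ci_hi, p = p,
                      row.names = NULL, stringsAsFactors = FALSE)
  ll <- sum(w * (y * log(pmax(mu, 1e-300)) +
                 (1 - y) * log(pmax(1 - mu, 1e-300))))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 table = coefs, vcov = vcov, loglik = ll,
                 deviance_trace = deviance_trace, iter = iter,
                 converged = converged, separated = separated,
                 n = sum(w)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("logistic_fit (n = ", format(x$n, big.mark = ","), ", ",
      x$iter, " Newton iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  tab <- x$table
  tab$estimate <- round(tab$estimate, 4)
  tab$se <- round(tab$se, 4)
  tab$ci_lo <- round(tab$ci_lo, 4)
  tab$ci_hi <- round(tab$ci_hi, 4)
  tab$p <- signif(tab$p, 3)
  print.data.frame(tab)
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
vcov.logistic_fit <- function(object, ...) object$vcov

#' @export
confint.logistic_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(object$vcov))
  ci <- cbind(object$coefficients - z * se, object$coefficients + z * se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
logLik.logistic_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
summary.logistic_fit <- function(object, ...) {
  print(object)
  cat("log-likelihood:", format(object$loglik), "\n")
  invisible(object)
}
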