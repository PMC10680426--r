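# Multivariable logistic NTCP model fitting.

#' Fit a logistic toxicity model on dose-bin covariates
#'
#' Maximum-likelihood logistic regression of a binary endpoint on the
#' dose-bin covariates (all bins fitted simultaneously), via iteratively
#' reweighted least squares with a tight convergence tolerance. Columns with
#' zero variance (e.g. a dose bin no patient in a stratum reaches) are
#' dropped from the design and reported with slope 0, so the model degrades
#' gracefully in per-arm sensitivity refits.
#'
#' @param covariates Numeric matrix or data frame (n x p) of dose-bin
#'   covariates; column names become coefficient names.
#' @param outcomes Binary vector (0/1 or logical), both classes present;
#'   n > 8 required.
#' @return An object of class `ntcp_fit` with `coefficients` (intercept +
#'   p slopes), `vcov`, `converged`, `fitted` (probabilities),
#'   `linear_predictors`, `n`, `n_case`, `dropped` (zero-variance columns),
#'   `loglik`.
#' @seealso [generics::tidy()] and [generics::glance()] methods;
#'   [predict.ntcp_fit()].
#' @export
fit_logistic <- function(covariates, outcomes) {
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(outcomes)
  if (!all(y %in% c(0, 1))) stop("outcomes must be binary 0/1", call. = FALSE)
  if (length(y) != nrow(X)) stop("covariates and outcomes disagree on n", call. = FALSE)
  if (nrow(X) <= 8) stop("need more than 8 subjects to fit", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  keep <- sds > 0
  Xk <- cbind(`(Intercept)` = 1, X[, keep, drop = FALSE])
  fit <- stats::glm.fit(Xk, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100))
  coefs <- stats::setNames(rep(0, ncol(X) + 1),
                           c("(Intercept)", colnames(X)))
  est <- fit$coefficients
  est[is.na(est)] <- 0
  coefs[names(est)] <- est

  p1 <- seq_len(fit$rank)
  vc_k <- matrix(NA_real_, ncol(Xk), ncol(Xk),
                 dimnames = list(colnames(Xk), colnames(Xk)))
  if (fit$rank > 0) {
    cov_unscaled <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
    piv <- fit$qr$pivot[p1]
    vc_k[piv, piv] <- cov_unscaled
  }
  vc <- matrix(0, length(coefs), length(coefs),
               dimnames = list(names(coefs), names(coefs)))
  vc[rownames(vc_k), colnames(vc_k)] <- ifelse(is.na(vc_k), 0, vc_k)

  # perfect separation shows as exploding coefficients / boundary fits
  separated <- any(abs(est) > 1e3) ||
    (fit$converged && all(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
  mu <- fit$fitted.values
  loglik <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  structure(
    list(coefficients = coefs, vcov = vc,
         converged = fit$converged && !separated,
         fitted = as.numeric(mu),
         linear_predictors = as.numeric(fit$linear.predictors),
         outcomes = y,
         n = length(y), n_case = sum(y), dropped = dropped, loglik = loglik),
    class = "ntcp_fit"
  )
}

#' Predicted event probabilities from a fitted NTCP model
#'
#' @param object An [fit_logistic()] result.
#' @param newdata Covariate matrix/data frame with the model's columns
#'   (omit for fitted values).
#' @param ... Unused.
#' @return Vector of probabilities in (0, 1).
#' @export
predict.ntcp_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- as.matrix(newdata)
  if (is.null(colnames(X))) colnames(X) <- names(object$coefficients)[-1]
  beta <- object$coefficients
  lp <- beta[1] + X[, names(beta)[-1], drop = FALSE] %*% beta[-1]
  as.numeric(stats::plogis(lp))
}

#' @export
print.ntcp_fit <- function(x, ...) {
  cat(sprintf("<ntcp_fit> n=%d (%d cases), %sconverged\n", x$n, x$n_case,
              if (x$converged) "" else "NOT "))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficient table for an NTCP fit
#'
#' @param x An [fit_logistic()] result.
#' @param ... Unused.
#' @return A tibble `term`, `estimate`, `std.error`, `statistic`, `p.value`
#'   (Wald).
#' @export
tidy.ntcp_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  se[names(se) %in% x$dropped] <- NA_real_
  z <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = as.numeric(x$coefficients),
    std.error = as.numeric(se),
    statistic = as.numeric(z),
    p.value = 2 * stats::pnorm(-abs(as.numeric(z)))
  )
}

#' One-row model summary for an NTCP fit
#'
#' @param x An [fit_logistic()] result.
#' @param ... Unused.
#' @return A tibble with `n`, `n_case`, `auc` (apparent), `logLik`,
#'   `converged`, `df`.
#' @export
glance.ntcp_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_case = x$n_case,
    auc = auc(x$fitted, x$outcomes),
    logLik = x$loglik,
    converged = x$converged,
    df = sum(!names(x$coefficients) %in% x$dropped)
  )
}
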