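#' Identity-link Poisson regression by constrained maximum likelihood
#'
#' Fits `y ~ Poisson(mu)` with `mu = X %*% beta`, i.e. a Poisson GLM whose
#' mean is a *linear* (not log-linear) function of the covariates, so that
#' coefficients are additive expected counts. Because the identity link does
#' not respect the positivity of the Poisson mean, the likelihood is
#' maximised subject to the linear constraints `X %*% beta > 0` at every
#' observed design point (barrier method via [stats::constrOptim()]); the
#' link is never silently switched.
#'
#' Covariates are rescaled internally to unit maximum absolute value for
#' optimizer stability and coefficients are reported back on the natural
#' scale. Standard errors come from the observed information
#' `t(X) %*% diag(y / mu^2) %*% X`; p-values are two-sided Wald tests.
#'
#' @param y non-negative integer response vector.
#' @param X design matrix (include an intercept column explicitly).
#' @param eps positivity floor for the fitted means, on the scaled design.
#' @return An object of class `"poisson_identity_fit"`: a list with
#'   `coefficients`, `se`, `zvalue`, `pvalue`, `vcov`, `fitted`, `loglik`,
#'   `converged`, `boundary` (TRUE when a fitted mean sits on the positivity
#'   constraint), and `degenerate` (TRUE when a covariate was constant and
#'   its slope is fixed at zero by convention).
#' @examples
#' x <- c(1, 2, 3, 4, 5, 6)
#' y <- c(2, 4, 5, 9, 10, 12)
#' fit <- poisson_identity_fit(y, cbind(1, x))
#' fit$coefficients
#' @export
poisson_identity_fit <- function(y, X, eps = 1e-10) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(y)
  stopifnot(nrow(X) == n, all(y >= 0), all(is.finite(X)))
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(p) - 1L)

  # degenerate design: a non-intercept column with no variation is
  # unidentifiable against the intercept; fix its slope at zero
  const_cols <- which(apply(X, 2, function(col) all(col == col[1])))
  intercept_col <- const_cols[which(X[1, const_cols] != 0)[1]]
  degenerate_cols <- setdiff(const_cols, intercept_col)
  keep <- setdiff(seq_len(p), degenerate_cols)
  degenerate <- length(degenerate_cols) > 0L
  is_intercept <- seq_len(p) %in% intercept_col

  Xk <- X[, keep, drop = FALSE]
  sc <- apply(abs(Xk), 2, max)
  sc[sc == 0] <- 1
  Xs <- sweep(Xk, 2, sc, "/")

  nll <- function(b) {
    mu <- drop(Xs %*% b)
    if (any(mu <= 0)) return(.Machine$double.xmax / 2)
    sum(mu - y * log(mu))
  }
  ngr <- function(b) {
    mu <- drop(Xs %*% b)
    drop(t(Xs) %*% (1 - y / mu))
  }

  # feasible starts: least squares projected to feasibility, then fallbacks
  starts <- list()
  b_ls <- tryCatch(qr.solve(Xs, y), error = function(e) NULL)
  if (!is.null(b_ls) && all(drop(Xs %*% b_ls) > 0)) starts <- c(starts, list(b_ls))
  icol <- which(is_intercept[keep])[1]
  if (!is.na(icol)) {
    b0 <- numeric(ncol(Xs))
    b0[icol] <- max(mean(y), 1) / Xs[1, icol]
    starts <- c(starts, list(b0))
  }
  if (length(starts) == 0L) starts <- list(rep(max(mean(y), 1) / max(rowSums(abs(Xs))), ncol(Xs)))

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::constrOptim(st, nll, ngr, ui = Xs, ci = rep(eps, n),
                         method = "BFGS",
                         control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    # polish with a derivative-free pass (boundary solutions stall BFGS);
    # Nelder-Mead needs at least two dimensions
    fit2 <- if (ncol(Xs) >= 2L) tryCatch(
      stats::constrOptim(fit$par, nll, grad = NULL, ui = Xs, ci = rep(eps, n),
                         control = list(maxit = 5000, reltol = 1e-14)),
      error = function(e) fit) else fit
    cand <- if (!is.null(fit2) && fit2$value <= fit$value) fit2 else fit
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best)) stop("identity-link Poisson fit failed: no feasible start")

  bs <- best$par
  mu_s <- drop(Xs %*% bs)
  info <- t(Xs) %*% (Xs * (y / mu_s^2))
  Vs <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ncol(Xs), ncol(Xs)))
  D <- diag(1 / sc, nrow = length(sc))
  Vk <- D %*% Vs %*% D

  beta <- se <- rep(0, p)
  V <- matrix(0, p, p)
  beta[keep] <- bs / sc
  se[keep] <- sqrt(diag(Vk))
  se[degenerate_cols] <- NA_real_
  V[keep, keep] <- Vk
  names(beta) <- names(se) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))

  z <- beta / se
  structure(list(
    coefficients = beta,
    se = se,
    zvalue = z,
    pvalue = 2 * stats::pnorm(-abs(z)),
    vcov = V,
    fitted = drop(X %*% beta),
    loglik = sum(stats::dpois(y, drop(X %*% beta), log = TRUE)),
    converged = best$convergence == 0,
    boundary = min(mu_s) < 1e-6 * mean(mu_s),
    degenerate = degenerate,
    y = y, X = X
  ), class = "poisson_identity_fit")
}

#' @export
print.poisson_identity_fit <- function(x, ...) {
  cat("Identity-link Poisson fit (constrained ML)\n")
  tab <- cbind(Estimate = x$coefficients, `Std.Error` = x$se,
               z = x$zvalue, `Pr(>|z|)` = x$pvalue)
  print(signif(tab, 4))
  cat(sprintf("logLik %.3f  converged %s  boundary %s\n",
              x$loglik, x$converged, x$boundary))
  invisible(x)
}

#' Likelihood-ratio test between two nested identity-link Poisson fits
#'
#' @param full,reduced objects from [poisson_identity_fit()] on the same
#'   response; `reduced` must be nested in `full`.
#' @return list with `statistic`, `df`, `pvalue`.
#' @export
poisson_identity_lrt <- function(full, reduced) {
  stat <- 2 * (full$loglik - reduced$loglik)
  df <- ncol(full$X) - ncol(reduced$X)
  list(statistic = max(stat, 0), df = df,
       pvalue = stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE))
}
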