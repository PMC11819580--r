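#' Build the per-trio design table for the parental-age models
#'
#' @param trios cohort table with `trio_id` (or `child_id`),
#'   `paternal_age`, `maternal_age`, `n_mut`, `n_paternal`, `n_maternal`,
#'   `n_phased`, and `callable_sum` (haploid callable bp).
#' @return data.frame with `trio_id`, `L` (diploid callable bp, `2 *
#'   callable_sum`), `S` (fraction of the trio's mutations that were
#'   phased), `X_P`, `X_M` (years), `N_total`, `N_pat`, `N_mat`.
#' @export
trio_design <- function(trios) {
  id <- if ("trio_id" %in% names(trios)) trios$trio_id else trios$child_id
  data.frame(trio_id = id,
             L = 2 * trios$callable_sum,
             S = trios$n_phased / trios$n_mut,
             X_P = trios$paternal_age, X_M = trios$maternal_age,
             N_total = trios$n_mut, N_pat = trios$n_paternal,
             N_mat = trios$n_maternal, stringsAsFactors = FALSE)
}

#' Identity-link Poisson regression of phased mutation counts on age
#'
#' Models the phased count for one parent as
#' `N_parent + pseudocount ~ Poisson(beta0 + beta * zeta)`, with
#' `zeta = L * S * X_parent`: diploid callable size times the trio's
#' phased fraction times that parent's age. The pseudocount (default 1)
#' avoids non-positive fitted means under the identity link. With
#' `s_convention = "count"`, `S` is instead the trio's total mutation
#' count (the literal covariate reading; the fraction is the
#' dimensionally consistent default).
#'
#' @param rows a [trio_design()] table; rows with missing ages are dropped
#'   (at least 3 complete trios required).
#' @param parent `"paternal"` or `"maternal"`.
#' @param pseudocount added to the response.
#' @param s_convention `"fraction"` (default) or `"count"`.
#' @return an `age_model_fit`: the [poisson_identity_fit()] augmented with
#'   `parent`, `pseudocount`, `zeta_per_year` (cohort mean of `L * S`,
#'   i.e. the covariate accrued per year of age) and `slope_per_year`
#'   (`beta * zeta_per_year`, expected extra phased mutations per year).
#' @export
fit_phased_regression <- function(rows, parent = c("paternal", "maternal"),
                                  pseudocount = 1,
                                  s_convention = c("fraction", "count")) {
  parent <- match.arg(parent)
  s_convention <- match.arg(s_convention)
  x <- if (parent == "paternal") rows$X_P else rows$X_M
  y <- if (parent == "paternal") rows$N_pat else rows$N_mat
  S <- if (s_convention == "fraction") rows$S else rows$N_total
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3L) stop("need at least 3 trios with ages and counts")
  zeta <- (rows$L * S * x)[keep]
  fit <- poisson_identity_fit(y[keep] + pseudocount,
                              cbind(intercept = 1, zeta = zeta))
  if (!fit$converged || any(fit$fitted <= 0))
    warning("phased ", parent, " fit flagged: ",
            if (!fit$converged) "non-convergence " else "",
            if (any(fit$fitted <= 0)) "non-positive fitted mean" else "")
  fit$parent <- parent
  fit$pseudocount <- pseudocount
  fit$s_convention <- s_convention
  fit$zeta_per_year <- mean((rows$L * S)[keep])
  fit$slope_per_year <- unname(fit$coefficients["zeta"] * fit$zeta_per_year)
  class(fit) <- c("age_model_fit", class(fit))
  fit
}

#' Identity-link Poisson regression of total mutation counts on both ages
#'
#' `N_total ~ Poisson(beta0 + betaP * L * X_P + betaM * L * X_M)`, identity
#' link, constrained ML. Collinear paternal/maternal ages are flagged but
#' the fit proceeds.
#'
#' @param rows a [trio_design()] table; at least 4 complete trios.
#' @return an `age_model_fit` with coefficients `intercept`, `zeta_P`,
#'   `zeta_M` (the latter two in mutations per bp-year) and `L_mean`, the
#'   cohort mean diploid callable size.
#' @export
fit_total_regression <- function(rows) {
  keep <- !is.na(rows$X_P) & !is.na(rows$X_M)
  if (sum(keep) < 4L) stop("need at least 4 trios with both ages")
  d <- rows[keep, ]
  if (stats::sd(d$X_P - d$X_M) < 1e-12)
    warning("paternal and maternal ages are collinear; coefficients are not separable")
  X <- cbind(intercept = 1, zeta_P = d$L * d$X_P, zeta_M = d$L * d$X_M)
  fit <- poisson_identity_fit(d$N_total, X)
  fit$parent <- "both"
  fit$L_mean <- mean(d$L)
  class(fit) <- c("age_model_fit", class(fit))
  fit
}

#' Parental-age effect in mutations per year
#'
#' For the total model this is `beta_parent * L_ref`: the expected number
#' of extra mutations in an offspring per additional year of that parent's
#' age, evaluated at a reference diploid callable genome size (default the
#' cohort mean used in the fit). The delta-method (Wald) 95% CI is
#' attached. For a phased fit the same scaling uses the fit's own
#' covariate-per-year mean.
#'
#' @param fit an `age_model_fit`.
#' @param parent `"paternal"` or `"maternal"`.
#' @param L_ref reference size (bp); defaults to the fit's cohort mean.
#' @return list: `effect`, `se`, `ci` (length 2), `parent`, `L_ref`.
#' @export
effect_per_year <- function(fit, parent = c("maternal", "paternal"),
                            L_ref = NULL) {
  parent <- match.arg(parent)
  if (identical(fit$parent, "both")) {
    cf <- if (parent == "paternal") "zeta_P" else "zeta_M"
    if (is.null(L_ref)) L_ref <- fit$L_mean
  } else {
    if (parent != fit$parent)
      stop("this phased fit models the ", fit$parent, " parent")
    cf <- "zeta"
    if (is.null(L_ref)) L_ref <- fit$zeta_per_year
  }
  eff <- unname(fit$coefficients[cf] * L_ref)
  se <- unname(fit$se[cf] * L_ref)
  list(effect = eff, se = se,
       ci = eff + c(-1, 1) * stats::qnorm(0.975) * se,
       parent = parent, L_ref = L_ref)
}

#' Regression lines and confidence bands on the phased-count scale
#'
#' Predicts the fitted phased-mutation count across an age grid from a
#' phased-model fit, with pointwise delta-method 95% bands, plus the
#' total-scale line obtained by removing the pseudocount and dividing by
#' the cohort phased fraction (the usual presentation of phased-count
#' regressions against parental age).
#'
#' @param fit a phased `age_model_fit`.
#' @param ages numeric vector of ages (years).
#' @param phased_fraction cohort fraction of mutations phased, used for
#'   the total-scale line; default 1 leaves the phased scale.
#' @return data.frame: `age`, `fit` (phased scale, pseudocount removed),
#'   `lwr`, `upr`, `fit_total`.
#' @export
predict_fig_lines <- function(fit, ages, phased_fraction = 1) {
  z <- fit$zeta_per_year * ages
  mu <- fit$coefficients["intercept"] + fit$coefficients["zeta"] * z
  V <- fit$vcov
  se <- vapply(z, function(zz) {
    g <- c(1, zz)
    sqrt(drop(t(g) %*% V %*% g))
  }, 0)
  ps <- fit$pseudocount
  data.frame(age = ages, fit = mu - ps,
             lwr = mu - ps - stats::qnorm(0.975) * se,
             upr = mu - ps + stats::qnorm(0.975) * se,
             fit_total = (mu - ps) / phased_fraction)
}

#' Equal-age parental age reproducing a target mutation sex bias
#'
#' Assuming both parents conceive at the same age `a` and that each sex's
#' mutation contribution is linear in age (the phased identity-link fits),
#' finds the age where the predicted paternal-to-maternal mutation ratio
#' equals `target_alpha`. Predictions remove the fitting pseudocount by
#' default; the search runs over the region where the maternal prediction
#' is positive, and the leftmost root is returned with a flag when the
#' ratio is degenerate (identical fits at target 1).
#'
#' @param fit_pat,fit_mat phased `age_model_fit`s for father and mother.
#' @param target_alpha target paternal/maternal ratio (> 0).
#' @param range search interval in years.
#' @param subtract_pseudocount remove the fitting pseudocount from the
#'   predicted means before forming the ratio (default TRUE).
#' @return list: `age` (years, `NA` when unattainable), `target_alpha`,
#'   `degenerate` (ratio constant over the range), `ratio_fun` (the ratio
#'   as a function of age).
#' @export
solve_equal_age_alpha <- function(fit_pat, fit_mat, target_alpha,
                                  range = c(0, 50),
                                  subtract_pseudocount = TRUE) {
  stopifnot(target_alpha > 0)
  off_p <- if (subtract_pseudocount) fit_pat$pseudocount else 0
  off_m <- if (subtract_pseudocount) fit_mat$pseudocount else 0
  pfun <- function(a) fit_pat$coefficients["intercept"] - off_p +
    fit_pat$coefficients["zeta"] * fit_pat$zeta_per_year * a
  mfun <- function(a) fit_mat$coefficients["intercept"] - off_m +
    fit_mat$coefficients["zeta"] * fit_mat$zeta_per_year * a
  rfun <- function(a) pfun(a) / mfun(a)

  grid <- seq(range[1], range[2], length.out = 5001)[-1]
  valid <- mfun(grid) > 0
  if (!any(valid))
    return(list(age = NA_real_, target_alpha = target_alpha,
                degenerate = FALSE, ratio_fun = rfun))
  g <- grid[valid]
  vals <- rfun(g) - target_alpha
  if (max(abs(vals - vals[1])) < 1e-12) {
    # constant ratio: any age works iff it equals the target
    hit <- abs(vals[1]) < 1e-9
    return(list(age = if (hit) g[1] else NA_real_,
                target_alpha = target_alpha, degenerate = TRUE,
                ratio_fun = rfun))
  }
  sgn <- which(diff(sign(vals)) != 0)
  if (!length(sgn))
    return(list(age = NA_real_, target_alpha = target_alpha,
                degenerate = FALSE, ratio_fun = rfun))
  root <- stats::uniroot(function(a) rfun(a) - target_alpha,
                         c(g[sgn[1]], g[sgn[1] + 1]), tol = 1e-10)$root
  list(age = root, target_alpha = target_alpha, degenerate = FALSE,
       ratio_fun = rfun)
}
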