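#' Male-to-female substitution rate ratio from X and autosomal branch lengths
#'
#' `alpha = (4 - 3 * X/A) / (3 * X/A - 2)`: under equal per-sex mutation
#' rates on X and autosomes, the X spends two thirds of its time in
#' females, so male-biased mutation depresses the X/A substitution ratio.
#' `X/A = 1` gives alpha 1; the ratio must lie in (2/3, 4/3) for a finite
#' positive alpha. At or below 2/3 the all-male limit is reported as `Inf`;
#' at or above 4/3 the value is undefined and returned as `NA`, both with
#' warnings.
#'
#' @param x_len X branch length (substitutions/site).
#' @param a_len autosomal branch length (same units, > 0).
#' @return alpha (vectorised).
#' @examples
#' alpha_from_branch_lengths(10.2, 12.3)  # ~3.1
#' @export
alpha_from_branch_lengths <- function(x_len, a_len) {
  stopifnot(all(a_len > 0))
  r <- x_len / a_len
  out <- (4 - 3 * r) / (3 * r - 2)
  low <- r <= 2 / 3; high <- r > 4 / 3  # exactly 4/3 is the valid alpha = 0
  if (any(low)) {
    warning("X/A <= 2/3: alpha at the all-male limit, reported Inf")
    out[low] <- Inf
  }
  if (any(high)) {
    warning("X/A > 4/3: alpha undefined (beyond the all-female limit)")
    out[high] <- NA_real_
  }
  out
}

#' Alpha point estimate with a per-chromosome confidence interval
#'
#' The point estimate uses the X branch length against the mean autosomal
#' length. Each autosome also yields its own alpha; the 95% CI is taken
#' around the mean of those per-chromosome values (Student-t with n-1 df
#' by default, normal quantiles with `ci = "z"`). Autosomes whose X/A
#' ratio falls outside the valid interval are excluded with a message.
#'
#' @param table branch-length data.frame (`branch`, `chromosome`, `is_X`,
#'   `length`).
#' @param branch branch label to estimate (default: the only one present).
#' @param ci `"t"` or `"z"`.
#' @return list of class `alpha_estimate`: `branch`, `alpha`, `x_over_a`,
#'   `ci_low`, `ci_high`, `n_autosomes`, `per_chromosome`.
#' @export
alpha_with_ci <- function(table, branch = NULL, ci = c("t", "z")) {
  ci <- match.arg(ci)
  if (is.null(branch)) {
    branch <- unique(table$branch)
    if (length(branch) != 1L) stop("specify `branch`: several present")
  }
  d <- table[table$branch == branch, , drop = FALSE]
  x <- d$length[d$is_X]
  a <- d$length[!d$is_X]
  if (length(x) != 1L) stop("exactly one X entry required per branch")
  if (length(a) < 3L) stop("need at least 3 autosomes")
  r_each <- x / a
  valid <- r_each > 2 / 3 & r_each < 4 / 3
  if (any(!valid))
    message(sum(!valid), " chromosome(s) excluded (X/A outside (2/3, 4/3))")
  a <- a[valid]
  per <- alpha_from_branch_lengths(x, a)
  point <- alpha_from_branch_lengths(x, mean(a))
  n <- length(per)
  se <- stats::sd(per) / sqrt(n)
  q <- if (ci == "t") stats::qt(0.975, n - 1) else stats::qnorm(0.975)
  m <- mean(per)
  structure(list(branch = branch, alpha = unname(point),
                 x_over_a = unname(x / mean(a)),
                 ci_low = m - q * se, ci_high = m + q * se,
                 n_autosomes = n,
                 per_chromosome = data.frame(
                   chromosome = d$chromosome[!d$is_X][valid], alpha = per)),
            class = "alpha_estimate")
}

#' Reconcile phylogenetic and pedigree estimates of mutation sex bias
#'
#' Reports the equal-sex parental age at which the pedigree phased-count
#' age models predict the phylogenetic alpha
#' ([solve_equal_age_alpha()]), and whether a pedigree alpha (e.g. one
#' computed excluding flagged outlier offspring) falls inside the
#' phylogenetic confidence interval.
#'
#' @param alpha_phylo phylogenetic point estimate.
#' @param ci_phylo length-2 confidence interval for `alpha_phylo`.
#' @param fit_pat,fit_mat phased `age_model_fit`s.
#' @param alpha_pedigree pedigree alpha to test against the CI (optional).
#' @param ... passed to [solve_equal_age_alpha()].
#' @return list: `implied_age`, `alpha_phylo`, `alpha_pedigree`,
#'   `pedigree_inside_ci`.
#' @export
reconcile_with_pedigree <- function(alpha_phylo, ci_phylo, fit_pat, fit_mat,
                                    alpha_pedigree = NULL, ...) {
  sol <- solve_equal_age_alpha(fit_pat, fit_mat, target_alpha = alpha_phylo,
                               ...)
  inside <- if (is.null(alpha_pedigree)) NA else
    alpha_pedigree >= min(ci_phylo) && alpha_pedigree <= max(ci_phylo)
  list(implied_age = sol$age, alpha_phylo = alpha_phylo,
       alpha_pedigree = alpha_pedigree, pedigree_inside_ci = inside,
       solution = sol)
}
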