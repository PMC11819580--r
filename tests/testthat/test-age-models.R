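test_that("identity-link ML matches glm and brute-force maximisation", {
  rows <- trio_design(aye_aye_trios())
  fit <- fit_total_regression(rows)

  # independent route 1: stats::glm with identity link on scaled covariates
  zP <- rows$L * rows$X_P / 1e9; zM <- rows$L * rows$X_M / 1e9
  g <- suppressWarnings(
    glm(rows$N_total ~ zP + zM, family = poisson(link = "identity"),
        start = c(mean(rows$N_total), 0.1, 0.1)))
  expect_equal(unname(fit$coefficients),
               unname(coef(g)) / c(1, 1e9, 1e9), tolerance = 1e-5)

  # independent route 2: Nelder-Mead maximisation of the log-likelihood
  nll <- function(b) {
    mu <- b[1] + b[2] * zP + b[3] * zM
    if (any(mu <= 0)) return(1e12)
    -sum(dpois(rows$N_total, mu, log = TRUE))
  }
  o <- optim(c(mean(rows$N_total), 0.1, 0.1), nll,
             control = list(maxit = 20000, reltol = 1e-14))
  o <- optim(o$par, nll, control = list(maxit = 20000, reltol = 1e-14))
  bf <- o$par / c(1, 1e9, 1e9)
  # agreement to 4 significant digits on the age coefficients
  expect_equal(signif(unname(fit$coefficients[3]), 4), signif(bf[3], 4))
  expect_equal(fit$loglik, -o$value, tolerance = 1e-8)
})

test_that("phased regressions fit the cohort table and flag degeneracy", {
  rows <- trio_design(aye_aye_trios())
  fp <- fit_phased_regression(rows, "paternal")
  fm <- fit_phased_regression(rows, "maternal")
  # maternal age association is much stronger than paternal
  expect_lt(fm$pvalue["zeta"], 0.001)
  expect_gt(fp$pvalue["zeta"], 0.05)
  expect_equal(fp$pseudocount, 1)
  # the literal covariate convention is exposed and differs
  fl <- fit_phased_regression(rows, "paternal", s_convention = "count")
  expect_false(isTRUE(all.equal(fl$coefficients, fp$coefficients)))

  # degenerate design: equal counts at equal ages -> slope exactly 0
  deg <- data.frame(trio_id = letters[1:4], L = 2e9, S = 0.5,
                    X_P = 10, X_M = 10, N_total = 20, N_pat = 5, N_mat = 5)
  fd <- fit_phased_regression(deg, "maternal")
  expect_identical(unname(fd$coefficients["zeta"]), 0)
  expect_true(fd$degenerate)
})

test_that("null slope is covered by the CI at near-nominal rate", {
  set.seed(101)
  n_seeds <- 200
  covered <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    L <- 3.7e9; S <- runif(12, 0.2, 0.5); X <- runif(12, 7, 30)
    y <- rpois(12, 8) + 1  # beta = 0 truth, pseudocount applied
    fit <- poisson_identity_fit(y, cbind(intercept = 1, zeta = L * S * X))
    ci <- fit$coefficients["zeta"] +
      c(-1.96, 1.96) * fit$se["zeta"]
    covered[s] <- ci[1] <= 0 && ci[2] >= 0
  }
  expect_gte(mean(covered), 0.93)
})

test_that("total-model parameters are recovered on simulated cohorts", {
  set.seed(7)
  b0 <- 5; bP <- 3e-10; bM <- 1.9e-9
  L <- 3.7e9
  XP <- runif(100, 7, 30); XM <- runif(100, 7, 30)
  mu <- b0 + bP * L * XP + bM * L * XM
  y <- rpois(100, mu)
  rows <- data.frame(trio_id = as.character(1:100), L = L, S = 0.3,
                     X_P = XP, X_M = XM, N_total = y, N_pat = 0, N_mat = 0)
  fit <- fit_total_regression(rows)
  expect_lt(abs(fit$coefficients["zeta_M"] - bM), 2 * fit$se["zeta_M"])
  expect_lt(abs(fit$coefficients["zeta_P"] - bP), 3 * fit$se["zeta_P"])

  # with beta = 0 truth the intercept-only model is not rejected at ~nominal
  y0 <- rpois(100, 30)
  rows0 <- within(rows, N_total <- y0)
  full <- fit_total_regression(rows0)
  red <- poisson_identity_fit(y0, cbind(intercept = rep(1, 100)))
  lrt <- poisson_identity_lrt(full, red)
  expect_gt(lrt$pvalue, 0.001)
})

test_that("median relative bias of the maternal coefficient is small", {
  set.seed(55)
  bM <- 1.9e-9; bP <- 3e-10; b0 <- 5; L <- 3.7e9
  est <- replicate(200, {
    XP <- runif(100, 7, 30); XM <- runif(100, 7, 30)
    y <- rpois(100, b0 + bP * L * XP + bM * L * XM)
    X <- cbind(1, L * XP, L * XM)
    poisson_identity_fit(y, X)$coefficients[3]
  })
  expect_lt(abs(stats::median(est) / bM - 1), 0.05)
})

test_that("effect per year scales linearly with the reference genome size", {
  rows <- trio_design(aye_aye_trios())
  fit <- fit_total_regression(rows)
  e1 <- effect_per_year(fit, "maternal")
  e2 <- effect_per_year(fit, "maternal", L_ref = 2 * fit$L_mean)
  expect_equal(e2$effect, 2 * e1$effect)
  expect_equal(e1$effect, unname(fit$coefficients["zeta_M"] * fit$L_mean))
  expect_true(e1$ci[1] < e1$effect && e1$effect < e1$ci[2])
  # zero coefficient gives zero effect
  deg <- data.frame(trio_id = letters[1:4], L = 2e9, S = 0.5,
                    X_P = 10, X_M = 10, N_total = 20, N_pat = 5, N_mat = 5)
  suppressWarnings(fd <- fit_total_regression(deg))
  expect_equal(unname(effect_per_year(fd, "maternal")$effect), 0)
})

test_that("prediction lines pass through fitted means and bands widen", {
  rows <- trio_design(aye_aye_trios())
  fm <- fit_phased_regression(rows, "maternal")
  pr <- predict_fig_lines(fm, ages = c(5, 10, 15, 25, 35))
  # at a design age the line equals the fitted mean (pseudocount removed)
  mu10 <- fm$coefficients["intercept"] +
    fm$coefficients["zeta"] * fm$zeta_per_year * 10
  expect_equal(pr$fit[pr$age == 10], unname(mu10) - 1)
  # band half-width has a single minimum (the information-weighted
  # covariate centre) and grows monotonically on either side of it
  grid <- predict_fig_lines(fm, ages = seq(0, 40, by = 0.5))
  hw <- (grid$upr - grid$lwr) / 2
  i0 <- which.min(hw)
  expect_true(all(diff(hw[seq_len(i0)]) <= 1e-9))
  expect_true(all(diff(hw[i0:length(hw)]) >= -1e-9))
  expect_gt(i0, 1); expect_lt(i0, length(hw))
  # zero-slope fit predicts a flat line
  deg <- data.frame(trio_id = letters[1:4], L = 2e9, S = 0.5,
                    X_P = 10, X_M = 10, N_total = 20, N_pat = 5, N_mat = 5)
  fd <- fit_phased_regression(deg, "maternal")
  prd <- predict_fig_lines(fd, ages = c(5, 20))
  expect_equal(prd$fit[1], prd$fit[2])
})

test_that("equal-age solver finds analytic roots and handles degeneracy", {
  mkfit <- function(b0, slope_per_year) {
    structure(list(coefficients = c(intercept = b0, zeta = slope_per_year),
                   zeta_per_year = 1, pseudocount = 0),
              class = c("age_model_fit", "poisson_identity_fit"))
  }
  # P(a) = 2 + 0.4 a, M(a) = 0.5 + 0.8 a; P/M = 2 at a = 5/6
  fp <- mkfit(2, 0.4); fm <- mkfit(0.5, 0.8)
  sol <- solve_equal_age_alpha(fp, fm, target_alpha = 2,
                               subtract_pseudocount = FALSE)
  expect_equal(sol$age, 5 / 6, tolerance = 1e-9)
  # identical fits at target 1: degenerate, leftmost age flagged
  sol1 <- solve_equal_age_alpha(fp, fp, 1, subtract_pseudocount = FALSE)
  expect_true(sol1$degenerate)
  expect_false(is.na(sol1$age))
  # unattainable target
  sol2 <- solve_equal_age_alpha(fp, fm, 1e6, subtract_pseudocount = FALSE)
  expect_true(is.na(sol2$age))
})
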