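make_missing_cohort <- function(n = 400, seed = 3, rates = c(0, 0.2, 0.15),
                                mech = "MCAR") {
  cfg <- sim_config(n_subjects = n, n_continuous = 2, n_binary = 1,
                    beta = c(0.5, -0.5, 0.3), baseline_scale = 0.05,
                    admin_censor_time = 12, missing_rates = rates,
                    missing_mechanism = mech, seed = seed)
  d <- simulate_survival(simulate_covariates(cfg), cfg)
  inject_missingness(d, cfg)
}

test_that("quickpred selects by correlation and usable cases, honours forcing", {
  set.seed(20)
  n <- 400
  z <- rnorm(n)
  d <- tibble::tibble(id = 1:n, time = rexp(n) + 0.1, event = rbinom(n, 1, 0.3),
                      a = z + rnorm(n, sd = 1),       # correlated with b
                      b = z + rnorm(n, sd = 1),
                      c = rnorm(n))                   # independent noise
  d$b[sample(n, 80)] <- NA
  pm <- quickpred(d, min_correlation = 0.1)
  expect_equal(unname(pm["b", "a"]), 1L)      # |cor| ~ 0.5 >= 0.1
  expect_equal(sum(pm["a", ]), 0L)            # fully observed: never imputed
  expect_equal(unname(pm["b", c("time", "event")]), c(1L, 1L))  # forced in
  # raising the threshold never adds predictors
  pm_hi <- quickpred(d, min_correlation = 0.4)
  expect_true(all(pm_hi <= pm))
  # forcing works regardless of correlation
  pm_f <- quickpred(d, min_correlation = 0.99, forced_in = "event")
  expect_equal(unname(pm_f["b", "event"]), 1L)
})

test_that("the imputation count follows the round-up-to-ten rule", {
  expect_equal(choose_m(33.5), 40L)
  expect_equal(choose_m(0), 5L)
  expect_equal(choose_m(71), 80L)
})

test_that("chained equations fill every cell, never touch observed data, and are seeded", {
  d <- make_missing_cohort()
  stack <- mice_impute(d, m = 4, iterations = 3, seed = 9)
  expect_equal(stack$m, 4)
  obs <- !is.na(d$cont_02)
  for (k in 1:4) {
    expect_false(anyNA(stack$data[[k]]))
    # observed cells bit-identical to the input in every completed copy
    expect_identical(stack$data[[k]]$cont_02[obs], d$cont_02[obs])
    expect_true(all(stack$data[[k]]$bin_01 %in% 0:1))
  }
  stack2 <- mice_impute(d, m = 4, iterations = 3, seed = 9)
  expect_identical(stack$data, stack2$data)
  # complete data: m identical copies with a warning
  dc <- make_missing_cohort(rates = c(0, 0, 0))
  expect_warning(sc <- mice_impute(dc, m = 3), "no missing")
  expect_identical(sc$data[[1]], sc$data[[3]])
  # empty predictor row rejected by name
  pm <- quickpred(d)
  pm["cont_02", ] <- 0L
  expect_error(mice_impute(d, pm, m = 2, iterations = 1), "cont_02")
})

test_that("imputed means are unbiased under MCAR and the bias check catches a broken imputer", {
  cfg <- sim_config(n_subjects = 1500, n_continuous = 2, n_binary = 1,
                    beta = c(0.5, -0.5, 0.3), baseline_scale = 0.05,
                    admin_censor_time = 12, missing_rates = c(0, 0.2, 0.15),
                    missing_mechanism = "MCAR", seed = 5)
  d0 <- simulate_survival(simulate_covariates(cfg), cfg)
  d0$cont_02 <- d0$cont_02 + 5   # keep the mean away from 0: percent bias
  d <- inject_missingness(d0, cfg)
  stack <- mice_impute(d, m = 6, iterations = 4, seed = 6)
  rep_ <- imputation_bias_check(d, stack)
  expect_true(all(rep_$pass))
  # pooled imputed mean within 3 SE of the observed mean
  mi <- is.na(d$cont_02)
  se <- sd(d$cont_02[!mi]) / sqrt(sum(mi))
  expect_lt(abs(rep_$imputed_mean[rep_$variable == "cont_02"] -
                rep_$observed_mean[rep_$variable == "cont_02"]), 3 * se)
  # constant-zero fill on a mean-10 column: ~100% bias, fails
  d10 <- d; d10$cont_01 <- d10$cont_01 + 10
  d10$cont_01[1:300] <- NA
  broken <- stack
  broken$incomplete <- "cont_01"
  broken$data <- lapply(stack$data, function(x) { x$cont_01 <- d10$cont_01
    x$cont_01[1:300] <- 0; x })
  rep_b <- imputation_bias_check(d10, broken)
  expect_false(rep_b$pass[rep_b$variable == "cont_01"])
  expect_gt(rep_b$bias_pct[rep_b$variable == "cont_01"], 50)
  # no missing cells: empty report
  dc <- make_missing_cohort(rates = c(0, 0, 0))
  expect_warning(sc <- mice_impute(dc, m = 2))
  expect_equal(nrow(imputation_bias_check(dc, sc)), 0)
})

test_that("Rubin pooling reproduces the worked examples and its variance identity", {
  p <- rubin_pool(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$W, 1); expect_equal(p$B, 1)
  expect_equal(p$T, 1 + (1 + 1 / 3) * 1, tolerance = 1e-12)
  p2 <- rubin_pool(c(0, 0), c(2, 4))
  expect_equal(p2$estimate, 0); expect_equal(p2$W, 3); expect_equal(p2$B, 0)
  expect_equal(p2$T, 3)
  # identical estimates: B = 0, T = W
  p3 <- rubin_pool(c(1.5, 1.5, 1.5), c(0.2, 0.3, 0.4))
  expect_equal(p3$B, 0); expect_equal(p3$T, p3$W, tolerance = 1e-12)
  # invariance to imputation order; T identity to 1e-12
  set.seed(30)
  est <- rnorm(10); va <- runif(10, 0.5, 2)
  pa <- rubin_pool(est, va); pb <- rubin_pool(rev(est), rev(va))
  expect_equal(pa, pb, tolerance = 1e-12)
  expect_equal(pa$T, pa$W + (1 + 1 / 10) * pa$B, tolerance = 1e-12)
  expect_error(rubin_pool(1, 1), "m >= 2")
})

test_that("the pooled Wald test covers its null and matches the complete-data Wald as B -> 0", {
  # all-zero extra coefficients: D1 = 0, p = 1
  est <- cbind(a = rnorm(5), b = rep(0, 5))
  vc <- replicate(5, diag(c(0.1, 0.1)), simplify = FALSE)
  r0 <- wald_compare_pooled(list(estimates = est, vcovs = vc), "a")
  expect_equal(r0$statistic, 0); expect_equal(r0$p.value, 1)

  # B -> 0 limit: D1 equals (complete-data Wald)/k within 2%
  d <- make_linear_cohort(n = 800, beta = c(0.6, -0.6, 0.3), seed = 41,
                          scale = 0.05)
  f <- fit_cox(d)
  wald <- coef(f)[3]^2 / vcov(f)[3, 3]
  m <- 30
  est_m <- matrix(rep(coef(f), each = m), m,
                  dimnames = list(NULL, names(coef(f))))
  vc_m <- replicate(m, vcov(f), simplify = FALSE)
  r1 <- wald_compare_pooled(list(estimates = est_m, vcovs = vc_m),
                            names(coef(f))[1:2])
  expect_lt(abs(r1$statistic - wald) / wald, 0.02)

  expect_error(wald_compare_pooled(list(estimates = est, vcovs = vc),
                                   c("a", "b")), "no extra")
  expect_error(wald_compare_pooled(list(estimates = est, vcovs = vc),
                                   "zz"), "subset")
})

test_that("imputed stacks round-trip through the CSV + manifest serialization", {
  d <- make_missing_cohort(n = 60)
  stack <- mice_impute(d, m = 2, iterations = 2, seed = 4)
  dir <- tempfile()
  write_imputed_stack(stack, dir)
  back <- read_imputed_stack(dir)
  expect_equal(back$m, 2); expect_equal(back$iterations, 2)
  for (k in 1:2)
    expect_equal(as.data.frame(back$data[[k]]), as.data.frame(stack$data[[k]]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
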