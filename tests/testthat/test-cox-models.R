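test_that("Cox fitting matches a 1-D grid-search oracle on enumerated risk sets", {
  tt <- c(1, 2, 3, 4); ev <- c(1L, 1L, 1L, 1L); x <- c(1, 0, 1, 0)
  d <- tibble::tibble(id = 1:4, time = tt, event = ev, x = x)
  attr(d, "feature_meta") <- tibble::tibble(name = "x", kind = "binary")
  class(d) <- c("survival_dataset", class(d))
  f <- fit_cox(d)
  grid <- seq(-3, 3, by = 1e-4)
  pl <- vapply(grid, function(b)
    -oracle_breslow(x * b, tt, ev, normalize = FALSE), numeric(1))
  expect_lt(abs(coef(f)[["x"]] - grid[which.max(pl)]), 1e-3)
  expect_lt(f$grad_norm, 1e-6)

  # constant feature rejected
  dc <- d; dc$x <- 1
  expect_error(fit_cox(dc), "constant")
  # no events rejected
  de <- d; de$event <- 0L
  expect_error(fit_cox(de), "at least 1 event")
})

test_that("Cox recovers generating coefficients within 3 SE and the likelihood is locally concave", {
  d <- make_linear_cohort(n = 2000, beta = c(0.5, -0.5, 0), seed = 51,
                          scale = 0.05)
  f <- fit_cox(d)
  se <- sqrt(diag(vcov(f)))
  expect_true(all(abs(coef(f) - c(0.5, -0.5, 0)) < 3 * se))
  # concavity along a random direction through the optimum
  x <- as.matrix(d[feature_cols(d)])
  lp_at <- function(b) -oracle_breslow(drop(x %*% b), d$time, d$event,
                                       normalize = FALSE)
  set.seed(1); dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  l0 <- lp_at(coef(f))
  expect_gt(l0, lp_at(coef(f) + 0.05 * dir))
  expect_gt(l0, lp_at(coef(f) - 0.05 * dir))
  # replication invariance: duplicating every subject leaves beta unchanged
  d2 <- dplyr::bind_rows(d, d)
  attr(d2, "feature_meta") <- feature_meta(d)
  f2 <- fit_cox(d2)
  expect_equal(coef(f2), coef(f), tolerance = 1e-6)
})

test_that("elastic net hits its limits: total shrinkage and the unpenalized fit", {
  d <- make_linear_cohort(n = 500, beta = c(0.6, -0.6, 0.4, 0, 0), seed = 52,
                          scale = 0.05)
  b_huge <- fit_coxnet(d, alpha = 0.5, lambda = 1e6)
  expect_true(all(b_huge == 0))
  b0 <- fit_coxnet(d, alpha = 0.5, lambda = 0)
  f <- fit_cox(d)
  expect_lt(max(abs(b0 - coef(f))), 1e-3)
  # pure ridge never produces exact zeros on a generic fixture
  b_r <- fit_coxnet(d, alpha = 0, lambda = 0.05)
  expect_true(all(b_r != 0))
  # lasso at moderate lambda does sparsify
  b_l <- fit_coxnet(d, alpha = 1, lambda = 0.08)
  expect_true(any(b_l == 0))
})

test_that("coefficient paths are continuous in lambda", {
  d <- make_linear_cohort(n = 400, beta = c(0.6, -0.6, 0.3, 0, 0), seed = 53,
                          scale = 0.05)
  lams <- exp(seq(log(0.2), log(0.001), length.out = 30))
  betas <- t(vapply(lams, function(l) fit_coxnet(d, alpha = 0.8, lambda = l),
                    numeric(5)))
  jumps <- apply(abs(diff(betas)), 1, max)
  expect_lt(max(jumps), 0.15)
})

test_that("tuning prefers the null model on noise and recovers informative features", {
  # pure noise: the largest grid lambda (the null model) is preferred
  lam_grid <- exp(seq(log(0.3), log(0.01), length.out = 8))
  top <- 0
  for (r in 1:25) {
    cfg <- sim_config(n_subjects = 1000, n_continuous = 5, n_binary = 0,
                      beta = rep(0, 5), baseline_scale = 0.05,
                      admin_censor_time = 12, seed = 600 + r)
    d <- simulate_survival(simulate_covariates(cfg), cfg)
    tr <- tune_coxnet(list(d), alpha_grid = c(0.8), lambda_grid = lam_grid,
                      seed = r)
    top <- top + (tr$lambda >= lam_grid[1] - 1e-12)
  }
  expect_gte(top / 25, 0.8)

  # informative features survive at the tuned optimum
  d_inf <- make_linear_cohort(n = 1500,
                              beta = c(0.5, -0.5, 0.5, -0.5, 0.5,
                                       rep(0, 10)), seed = 61, scale = 0.05)
  tr <- tune_coxnet(list(d_inf), alpha_grid = c(0.8, 1),
                    lambda_grid = lam_grid, seed = 5)
  b <- fit_coxnet(d_inf, alpha = tr$alpha, lambda = tr$lambda)
  expect_gte(sum(b[1:5] != 0), 4)
  # single-point grid: returns it
  tr1 <- tune_coxnet(list(d_inf), alpha_grid = 0.5, lambda_grid = 0.05,
                     seed = 1)
  expect_equal(tr1$alpha, 0.5); expect_equal(tr1$lambda, 0.05)
  expect_true(is.finite(tr1$deviance))
})

test_that("stability selection is reproducible and its consensus lists are nested", {
  d <- make_linear_cohort(n = 400, beta = c(0.8, -0.8, rep(0, 6)), seed = 62,
                          scale = 0.05)
  stack <- list(d, d)
  p1 <- stability_select(stack, alpha = 1, lambda = 0.05, seed = 3)
  p2 <- stability_select(stack, alpha = 1, lambda = 0.05, seed = 3)
  expect_identical(p1$split_counts, p2$split_counts)
  expect_true(all(p1$split_counts <= p1$n_splits))
  expect_true(all(p1$dataset_pass <= p1$m))
  cands <- consensus_candidates(p1, c(1, 2))
  expect_true(all(cands$t2 %in% cands$t1))
  # constructed profile: direct threshold enumeration
  prof <- structure(list(dataset_pass = c(a = 40, b = 40, c = 31, d = 30),
                         m = 40, n_splits = 10, split_keep_threshold = 8),
                    class = "selection_profile")
  cc <- consensus_candidates(prof, c(30, 31, 40))
  expect_equal(length(cc$t31), 3)
  expect_equal(length(cc$t30), 4)
  expect_equal(cc$t40, c("a", "b"))
})

test_that("model finalization keeps signal and discards pure-noise extensions", {
  set.seed(70)
  wins_small <- 0
  for (r in 1:10) {
    d <- make_linear_cohort(n = 600, beta = c(0.7, -0.7, 0, 0), seed = 700 + r,
                            scale = 0.05)
    stack <- lapply(1:3, function(k) d)   # degenerate stack is fine here
    cands <- list(small = c("cont_01", "cont_02"),
                  large = c("cont_01", "cont_02", "cont_03", "cont_04"))
    fin <- coxsf_finalize(stack, cands)
    wins_small <- wins_small + identical(sort(fin$features),
                                         sort(cands$small))
  }
  expect_gte(wins_small / 10, 0.8)

  # identical candidate lists rejected
  d <- make_linear_cohort(n = 200, seed = 71)
  expect_error(coxsf_finalize(list(d, d), list(a = "cont_01", b = "cont_01")),
               "identical|differ")
  # non-nested lists rejected
  expect_error(coxsf_finalize(list(d, d),
                              list(a = "cont_01",
                                   b = c("cont_02", "cont_03"))), "nested")
  # pooled output carries hazard ratios with CIs
  fin <- coxsf_finalize(list(d, d, d),
                        list(s = "cont_01", l = c("cont_01", "cont_02")))
  td <- tidy(fin)
  expect_true(all(c("hazard_ratio", "conf.low", "conf.high") %in% names(td)))
  expect_true(all(td$conf.low <= td$hazard_ratio + 1e-9))
})
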