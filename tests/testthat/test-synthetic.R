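test_that("simulated covariates have the configured shape, correlation and prevalence", {
  cfg <- sim_config(n_subjects = 1000, n_continuous = 2, n_binary = 1, seed = 7)
  x <- simulate_covariates(cfg)
  expect_equal(dim(x), c(1000, 3))
  expect_true(all(x[[3]] %in% 0:1))

  cfg0 <- sim_config(n_subjects = 5000, n_continuous = 2, n_binary = 1,
                     correlation = 0, prevalence = 0.3, seed = 8)
  x0 <- simulate_covariates(cfg0)
  expect_lt(abs(cor(x0[[1]], x0[[2]])), 0.1)
  expect_gt(mean(x0[[3]]), 0.25)
  expect_lt(mean(x0[[3]]), 0.35)

  cfg_bad <- sim_config(n_continuous = 5, correlation = -0.5)
  expect_error(simulate_covariates(cfg_bad), "positive-definite")
})

test_that("survival generator matches its closed forms and censoring contracts", {
  # beta = 0, k = 1: uncensored times are exponential(lambda0)
  cfg <- sim_config(n_subjects = 20000, n_continuous = 1, n_binary = 0,
                    beta = 0, baseline_shape = 1, baseline_scale = 0.1,
                    admin_censor_time = 1e6, seed = 5)
  d <- simulate_survival(simulate_covariates(cfg), cfg)
  expect_true(all(d$event == 1))      # nothing can censor
  expect_lt(abs(median(d$time) - log(2) / 0.1), 0.25)

  # wave-grid rounding is up and never changes the event indicator
  cfg_g <- sim_config(n_subjects = 500, n_continuous = 1, n_binary = 0,
                      baseline_scale = 0.05, admin_censor_time = 12,
                      wave_grid = 2, seed = 6)
  cfg_c <- cfg_g; cfg_c$wave_grid <- NULL
  d_g <- simulate_survival(simulate_covariates(cfg_g), cfg_g)
  d_c <- simulate_survival(simulate_covariates(cfg_c), cfg_c)
  expect_identical(d_g$event, d_c$event)
  expect_true(all(d_g$time >= d_c$time))
  expect_true(all(d_g$time > 0))
  expect_true(all(d_g$time %% 2 == 0))

  # exp overflow rejected with subject index
  cfg_o <- sim_config(n_subjects = 10, n_continuous = 1, n_binary = 0,
                      beta = 1000, seed = 1)
  x <- tibble::tibble(cont_01 = rep(1, 10))
  attr(x, "feature_meta") <- tibble::tibble(name = "cont_01", kind = "continuous")
  expect_error(simulate_survival(x, cfg_o), "overflow")
})

test_that("event-rate calibration hits the target and is monotone in the scale", {
  cfg <- sim_config(n_subjects = 5433, n_continuous = 5, n_binary = 3,
                    beta = c(0.5, -0.5, rep(0, 6)), baseline_shape = 1.2,
                    admin_censor_time = 12, seed = 9)
  lam <- calibrate_event_rate(cfg, 0.13)
  cfg$baseline_scale <- as.numeric(lam)
  d <- simulate_survival(simulate_covariates(cfg), cfg)
  expect_gt(mean(d$event), 0.11)
  expect_lt(mean(d$event), 0.15)

  expect_error(calibrate_event_rate(cfg, 0), "open interval")

  # doubling lambda0 never decreases the event fraction
  frac_at <- function(l) {
    c2 <- cfg; c2$baseline_scale <- l
    mean(simulate_survival(simulate_covariates(c2), c2)$event)
  }
  expect_gte(frac_at(2 * as.numeric(lam)), frac_at(as.numeric(lam)))
})

test_that("event fraction is monotone nonincreasing in the dropout rate", {
  fracs <- vapply(c(0, 0.1, 0.3), function(r) {
    cfg <- sim_config(n_subjects = 3000, n_continuous = 2, n_binary = 0,
                      baseline_scale = 0.05, admin_censor_time = 12,
                      random_censor_rate = r, seed = 21)
    mean(simulate_survival(simulate_covariates(cfg), cfg)$event)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("missingness injection hits per-feature rates, keeps outcomes, and MAR tracks its driver", {
  cfg <- sim_config(n_subjects = 5433, n_continuous = 2, n_binary = 1,
                    baseline_scale = 0.05, missing_rates = c(0, 0.335, 0.1),
                    missing_mechanism = "MCAR", seed = 10)
  d <- simulate_survival(simulate_covariates(cfg), cfg)
  dm <- inject_missingness(d, cfg)
  n_masked <- sum(is.na(dm$cont_02))
  expect_lt(abs(n_masked - 0.335 * 5433), 0.03 * 5433)
  expect_false(anyNA(dm$time)); expect_false(anyNA(dm$event))

  # all-zero rates: identity
  cfg0 <- cfg; cfg0$missing_rates <- rep(0, 3)
  expect_identical(inject_missingness(d, cfg0), d)

  # MAR: masking correlates with the driver feature
  cfg_mar <- sim_config(n_subjects = 5000, n_continuous = 2, n_binary = 0,
                        baseline_scale = 0.05, missing_rates = c(0, 0.3),
                        missing_mechanism = "MAR", seed = 11)
  d2 <- simulate_survival(simulate_covariates(cfg_mar), cfg_mar)
  dm2 <- inject_missingness(d2, cfg_mar)
  r <- cor(is.na(dm2$cont_02), d2$cont_01)
  expect_gt(abs(r), 0.05)
  expect_lt(abs(mean(is.na(dm2$cont_02)) - 0.3), 0.03)

  # MAR with no fully observed driver is rejected
  cfg_bad <- cfg_mar; cfg_bad$missing_rates <- c(0.2, 0.3)
  expect_error(inject_missingness(d2, cfg_bad), "driver")
})

test_that("the ageing-cohort preset is deterministic and matches its calibration targets", {
  d1 <- make_elsa_like(seed = 3, n = 2500)
  d2 <- make_elsa_like(seed = 3, n = 2500)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_equal(length(feature_cols(d1)), 91)
  expect_equal(sum(attr(d1, "sim_config")$beta != 0), 8)
  expect_gt(mean(d1$event), 0.10); expect_lt(mean(d1$event), 0.16)
  expect_gte(median(d1$time), 9); expect_lte(median(d1$time), 11)
  rates <- vapply(d1[feature_cols(d1)], function(x) mean(is.na(x)), numeric(1))
  expect_lt(max(rates), 0.40)
  expect_true(any(rates == 0))
})

test_that("with no signal, concordance of any score sits at 1/2", {
  cfg <- sim_config(n_subjects = 2000, n_continuous = 3, n_binary = 2,
                    beta = rep(0, 5), baseline_scale = 0.05,
                    admin_censor_time = 12, seed = 13)
  d <- simulate_survival(simulate_covariates(cfg), cfg)
  s <- drop(as.matrix(d[feature_cols(d)]) %*% c(1, -1, 0.5, 1, -0.5))
  expect_lt(abs(unos_c(s, d$time, d$event, tau = max(d$time)) - 0.5), 0.05)
})

test_that("the CSV writer and reader round-trip a dataset with missing cells", {
  d <- make_elsa_like(seed = 5, n = 120)
  path <- tempfile(fileext = ".csv")
  write_survival_data(d, path)
  d2 <- read_survival_data(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(feature_meta(d2)$kind, feature_meta(d)$kind)
  unlink(c(path, paste0(path, ".meta.json")))
})
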