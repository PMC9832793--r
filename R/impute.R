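#' Quickpred-style predictor selection for chained-equations imputation
#'
#' Builds the square 0/1 predictor matrix over all columns: `candidate` is
#' used to impute `target` iff the larger of |cor(candidate, target)| (over
#' complete pairs) and |cor(candidate, missingness indicator of target)|
#' reaches `min_correlation`, and the fraction of usable cases (candidate
#' observed where target is missing) reaches `min_usable_fraction`.
#' Variables in `forced_in` (typically the outcome columns and key
#' confounders) are always predictors for every incomplete target. Fully
#' observed variables get an all-zero row: they are never imputed.
#'
#' @param data Data frame (a `survival_dataset` works; `id` is ignored).
#' @param min_correlation Correlation threshold (default 0.1).
#' @param min_usable_fraction Minimum usable-case fraction (default 0).
#' @param forced_in Character vector of always-included predictors
#'   (default `c("time", "event")` when present).
#' @return A 0/1 matrix with target rows and candidate columns.
#' @export
quickpred <- function(data, min_correlation = 0.1, min_usable_fraction = 0,
                      forced_in = intersect(c("time", "event"), names(data))) {
  vars <- setdiff(names(data), "id")
  if (length(vars) < 2) stop_tabsurv("need at least 2 variables")
  x <- data[, vars, drop = FALSE]
  p <- length(vars)
  pm <- matrix(0L, p, p, dimnames = list(vars, vars))
  incomplete <- vars[colSums(is.na(x)) > 0]
  safe_cor <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) {
      return(0)  # undefined correlation treated as 0
    }
    abs(cor(a[ok], b[ok]))
  }
  for (tg in incomplete) {
    miss <- is.na(x[[tg]])
    for (cd in setdiff(vars, tg)) {
      r_val <- safe_cor(x[[tg]], x[[cd]])
      r_mis <- safe_cor(as.numeric(miss), x[[cd]])
      usable <- mean(!is.na(x[[cd]])[miss])
      if (max(r_val, r_mis) >= min_correlation && usable >= min_usable_fraction)
        pm[tg, cd] <- 1L
    }
    pm[tg, intersect(forced_in, setdiff(vars, tg))] <- 1L
  }
  pm
}

#' Number of imputations from the maximum missingness percentage
#'
#' Rounds the maximum per-variable missingness percentage up to the next
#' multiple of 10, with a floor of 5 (so 33.5% of missing data yields 40
#' imputations).
#'
#' @param max_missing_pct Maximum observed missingness, percent, in `[0, 100)`.
#' @return Integer number of imputations `m`.
#' @export
choose_m <- function(max_missing_pct) {
  stopifnot(max_missing_pct >= 0, max_missing_pct < 100)
  max(5L, as.integer(10 * ceiling(max_missing_pct / 10)))
}

# one proper-imputation draw for a continuous target: Bayesian linear
# regression + predictive mean matching with `donors` donors
impute_pmm <- function(y, Xmat, miss, donors = 5) {
  obs <- !miss
  X1 <- cbind(1, Xmat)
  fit <- stats::lm.fit(X1[obs, , drop = FALSE], y[obs])
  keep <- !is.na(fit$coefficients)
  beta <- fit$coefficients[keep]
  Xk <- X1[, keep, drop = FALSE]
  r <- fit$residuals
  df <- max(sum(obs) - length(beta), 1)
  sigma2 <- sum(r^2) / stats::rchisq(1, df)
  xtx <- crossprod(Xk[obs, , drop = FALSE])
  V <- tryCatch(chol2inv(chol(xtx + diag(1e-8, ncol(Xk)))) * sigma2,
                error = function(e) diag(1e-6, ncol(Xk)))
  beta_star <- beta + drop(MASS::mvrnorm(1, rep(0, length(beta)), V))
  yhat_obs <- drop(Xk[obs, , drop = FALSE] %*% beta)
  yhat_mis <- drop(Xk[miss, , drop = FALSE] %*% beta_star)
  # nearest-donor search against the sorted observed predictions
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  yo <- y[obs][ord]
  n_obs <- length(ys)
  pos <- findInterval(yhat_mis, ys)
  picks <- vapply(seq_along(yhat_mis), function(i) {
    win <- max(1, pos[i] - donors):min(n_obs, pos[i] + donors)
    d <- abs(ys[win] - yhat_mis[i])
    cand <- win[order(d)[seq_len(min(donors, length(win)))]]
    cand[sample.int(length(cand), 1)]
  }, integer(1))
  yo[picks]
}

# one draw for a binary target: logistic regression with an approximate
# posterior draw of the coefficients
impute_logreg <- function(y, Xmat, miss) {
  obs <- !miss
  X1 <- cbind(1, Xmat)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X1[obs, , drop = FALSE], y[obs],
                                    family = binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged ||
      any(abs(fit$coefficients) > 25, na.rm = TRUE)) {
    p <- mean(y[obs])
    return(rbinom(sum(miss), 1, p))
  }
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  w <- fit$weights
  xtwx <- crossprod(X1[obs, , drop = FALSE] * sqrt(w))
  V <- tryCatch(chol2inv(chol(xtwx + diag(1e-6, ncol(X1)))),
                error = function(e) diag(1e-6, ncol(X1)))
  beta_star <- beta + drop(MASS::mvrnorm(1, rep(0, length(beta)), V))
  p <- plogis(drop(X1[miss, , drop = FALSE] %*% beta_star))
  rbinom(sum(miss), 1, p)
}

#' Multiple imputation by chained equations
#'
#' Missing cells are initialized by random draws from each variable's
#' observed marginal; each of `m` independent chains then sweeps the
#' incomplete variables `iterations` times, imputing each variable from its
#' predictor-matrix row: predictive mean matching (5 donors) for continuous
#' targets, a logistic-model draw for binary targets. Observed cells are
#' never altered. The outcome columns (`time`, `event`) serve as predictors
#' but are never imputed.
#'
#' @param data A `survival_dataset` (or data frame with `time`, `event`).
#' @param predictor_matrix 0/1 matrix from [quickpred()] (default: built
#'   with its defaults).
#' @param m Number of imputations (default: [choose_m()] of the observed
#'   maximum missingness).
#' @param iterations Chained-equation sweeps per chain (default 20).
#' @param seed Seed; chains derive independent child streams.
#' @param donors Predictive-mean-matching donor count.
#' @return An `imputed_stack`: list with `data` (list of `m` completed
#'   tibbles), `m`, `iterations`, `seed`, `predictor_matrix`.
#' @export
mice_impute <- function(data, predictor_matrix = NULL, m = NULL,
                        iterations = 20, seed = 1L, donors = 5) {
  vars <- setdiff(names(data), "id")
  miss_frac <- vapply(data[vars], function(v) mean(is.na(v)), numeric(1))
  incomplete <- vars[miss_frac > 0]
  incomplete <- setdiff(incomplete, c("time", "event"))
  m <- m %||% choose_m(100 * max(miss_frac))
  if (length(incomplete) == 0) {
    rlang::warn("dataset has no missing cells; returning m identical copies")
    return(structure(list(data = replicate(m, tibble::as_tibble(data),
                                           simplify = FALSE),
                          m = m, iterations = iterations, seed = seed,
                          predictor_matrix = predictor_matrix),
                     class = "imputed_stack"))
  }
  predictor_matrix <- predictor_matrix %||% quickpred(data)
  for (tg in incomplete)
    if (sum(predictor_matrix[tg, ]) == 0)
      stop_tabsurv("incomplete variable '", tg, "' has an empty predictor row")
  binary <- vapply(data[vars], is_binary01, logical(1))
  miss_idx <- lapply(data[incomplete], is.na)
  completed <- vector("list", m)
  for (chain in seq_len(m)) {
    completed[[chain]] <- with_rng(child_seed(seed, "mice", chain), {
      d <- data
      for (tg in incomplete) {
        mi <- miss_idx[[tg]]
        d[[tg]][mi] <- sample(d[[tg]][!mi], sum(mi), replace = TRUE)
      }
      for (it in seq_len(iterations)) {
        for (tg in incomplete) {
          mi <- miss_idx[[tg]]
          preds <- names(which(predictor_matrix[tg, ] == 1))
          Xmat <- as.matrix(d[, preds, drop = FALSE])
          y <- d[[tg]]
          d[[tg]][mi] <- if (binary[tg]) impute_logreg(y, Xmat, mi)
                         else impute_pmm(y, Xmat, mi, donors)
        }
      }
      tibble::as_tibble(d)
    })
  }
  structure(list(data = completed, m = m, iterations = iterations,
                 seed = seed, predictor_matrix = predictor_matrix,
                 incomplete = incomplete),
            class = "imputed_stack")
}

#' @exportS3Method base::print
print.imputed_stack <- function(x, ...) {
  cat("Imputed stack: m =", x$m, "datasets,", x$iterations, "iterations,",
      length(x$incomplete %||% character()), "imputed variable(s)\n")
  invisible(x)
}

#' Mean-bias check of an imputation against the observed cells
#'
#' For each imputed variable, the percent bias is
#' `100 * |mean(imputed cells pooled over m) - mean(observed cells)| /
#' |mean(observed cells)|`; at most 5% is considered acceptable. When the
#' observed mean is 0 the absolute difference is reported instead.
#'
#' @param original The dataset passed to [mice_impute()].
#' @param stack The resulting `imputed_stack`.
#' @param threshold Acceptability threshold in percent (default 5).
#' @return Tibble: `variable`, `observed_mean`, `imputed_mean`, `bias_pct`,
#'   `pass`, `note`.
#' @export
imputation_bias_check <- function(original, stack, threshold = 5) {
  stopifnot(inherits(stack, "imputed_stack"))
  vars <- stack$incomplete %||% character()
  if (length(vars) == 0) {
    return(tibble::tibble(variable = character(), observed_mean = numeric(),
                          imputed_mean = numeric(), bias_pct = numeric(),
                          pass = logical(), note = character()))
  }
  rows <- lapply(vars, function(v) {
    mi <- is.na(original[[v]])
    obs_mean <- mean(original[[v]][!mi])
    imp_vals <- unlist(lapply(stack$data, function(d) d[[v]][mi]))
    imp_mean <- mean(imp_vals)
    if (abs(obs_mean) < 1e-12) {
      bias <- abs(imp_mean - obs_mean)
      note <- "observed mean ~0: absolute difference reported"
    } else {
      bias <- 100 * abs(imp_mean - obs_mean) / abs(obs_mean)
      note <- ""
    }
    tibble::tibble(variable = v, observed_mean = obs_mean,
                   imputed_mean = imp_mean, bias_pct = bias,
                   pass = bias <= threshold, note = note)
  })
  dplyr::bind_rows(rows)
}

barnard_rubin_df <- function(m, B, T_, df_com = Inf) {
  lambda <- (1 + 1 / m) * B / T_
  if (lambda < 1e-12) return(Inf)
  nu_old <- (m - 1) / lambda^2
  if (!is.finite(df_com)) return(nu_old)
  nu_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
  nu_old * nu_obs / (nu_old + nu_obs)
}

#' Pool per-imputation estimates with Rubin's rules
#'
#' `Qbar` is the mean estimate, `W` the mean within-imputation variance,
#' `B` the between-imputation sample variance, and the total variance is
#' `T = W + (1 + 1/m) B`. Degrees of freedom follow the Barnard-Rubin
#' small-sample formula given a complete-data df (default: large sample).
#'
#' @param estimates Numeric vector (one parameter) or m x k matrix of
#'   per-imputation estimates.
#' @param variances Matching vector/matrix of per-imputation variances.
#' @param df_com Complete-data degrees of freedom (default `Inf`).
#' @return Tibble with columns `term`, `estimate`, `W`, `B`, `T`, `df`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
rubin_pool <- function(estimates, variances, df_com = Inf) {
  est <- if (is.matrix(estimates)) estimates else matrix(estimates, ncol = 1)
  va <- if (is.matrix(variances)) variances else matrix(variances, ncol = 1)
  stopifnot(identical(dim(est), dim(va)))
  m <- nrow(est)
  if (m < 2) stop_tabsurv("Rubin pooling needs m >= 2 imputations")
  terms <- colnames(est) %||% paste0("q", seq_len(ncol(est)))
  rows <- lapply(seq_len(ncol(est)), function(j) {
    qbar <- mean(est[, j]); w <- mean(va[, j]); b <- var(est[, j])
    tot <- w + (1 + 1 / m) * b
    df <- barnard_rubin_df(m, b, tot, df_com)
    se <- sqrt(tot)
    stat <- if (se > 0) qbar / se else NA_real_
    p <- if (is.na(stat)) NA_real_
         else 2 * stats::pt(-abs(stat), df = if (is.finite(df)) df else 1e9)
    tibble::tibble(term = terms[j], estimate = qbar, W = w, B = b, T = tot,
                   df = df, std.error = se, statistic = stat, p.value = p)
  })
  dplyr::bind_rows(rows)
}

#' Multi-parameter Wald comparison of nested pooled models (D1)
#'
#' Tests whether the `k` coefficients present in the full model but not in
#' the nested one are jointly zero, pooling over imputations: with `Qe` the
#' mean extra-coefficient vector, `Wbar` the mean of their within-imputation
#' covariance blocks and `Bm` their between-imputation covariance, the
#' average relative increase in variance is
#' `r = (1 + 1/m) tr(Bm Wbar^-1) / k` and
#' `D1 = Qe' Wbar^-1 Qe / (k (1 + r))`, referred to an F(k, v) distribution
#' with the standard D1 denominator degrees of freedom.
#'
#' @param fits List of `m` full-model [fit_cox()] fits (one per imputation),
#'   or a list with elements `estimates` (m x p matrix, named columns) and
#'   `vcovs` (list of m p x p matrices).
#' @param nested_terms Character vector: the nested model's variables (a
#'   strict subset of the full model's).
#' @return One-row tibble: `statistic` (D1), `df1`, `df2`, `p.value`, `r`.
#' @export
wald_compare_pooled <- function(fits, nested_terms) {
  if (!is.null(fits$estimates)) {
    est <- fits$estimates; vcovs <- fits$vcovs
  } else {
    est <- do.call(rbind, lapply(fits, function(f) coef(f)))
    vcovs <- lapply(fits, function(f) vcov(f))
  }
  full_terms <- colnames(est)
  if (!all(nested_terms %in% full_terms))
    stop_tabsurv("nested model's variables must be a subset of the full model's")
  extra <- setdiff(full_terms, nested_terms)
  k <- length(extra)
  if (k < 1) stop_tabsurv("no extra parameters to test (identical models)")
  m <- nrow(est)
  ix <- match(extra, full_terms)
  qe <- colMeans(est[, ix, drop = FALSE])
  wbar <- Reduce(`+`, lapply(vcovs, function(v) v[ix, ix, drop = FALSE])) / m
  bm <- stats::cov(est[, ix, drop = FALSE])
  cond <- tryCatch(kappa(wbar, exact = TRUE), error = function(e) Inf)
  winv <- tryCatch(solve(wbar), error = function(e) NULL)
  if (is.null(winv))
    stop_tabsurv("singular within-imputation covariance (condition number ",
                 format(cond, digits = 4), ")")
  r <- (1 + 1 / m) * sum(diag(bm %*% winv)) / k
  d1 <- drop(t(qe) %*% winv %*% qe) / (k * (1 + r))
  t_ <- k * (m - 1)
  df2 <- if (r < 1e-12) Inf
         else if (t_ > 4) 4 + (t_ - 4) * (1 + (1 - 2 / t_) / r)^2
         else t_ * (1 + 1 / k) * (1 + 1 / r)^2 / 2
  p <- if (d1 <= 0) 1 else stats::pf(d1, k, min(df2, 1e9), lower.tail = FALSE)
  tibble::tibble(statistic = d1, df1 = k, df2 = df2, p.value = p, r = r)
}

#' Write / read an imputed stack as CSVs plus a JSON manifest
#' @param stack An `imputed_stack`.
#' @param dir Output directory (created if needed).
#' @export
write_imputed_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(stack$m))
    utils::write.csv(stack$data[[i]], file.path(dir, sprintf("imp_%03d.csv", i)),
                     row.names = FALSE, na = "")
  jsonlite::write_json(
    list(m = stack$m, iterations = stack$iterations, seed = stack$seed,
         incomplete = stack$incomplete,
         predictor_matrix = stack$predictor_matrix),
    file.path(dir, "manifest.json"), matrix = "rowmajor", auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_imputed_stack
#' @export
read_imputed_stack <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  data <- lapply(seq_len(man$m), function(i)
    tibble::as_tibble(utils::read.csv(file.path(dir, sprintf("imp_%03d.csv", i)),
                                      na.strings = "")))
  pm <- man$predictor_matrix
  if (!is.null(pm)) pm <- as.matrix(pm)
  structure(list(data = data, m = man$m, iterations = man$iterations,
                 seed = man$seed, predictor_matrix = pm,
                 incomplete = man$incomplete),
            class = "imputed_stack")
}
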