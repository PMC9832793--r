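#' Cox proportional-hazards fit with Breslow tie handling
#'
#' Maximizes the Cox partial likelihood (Breslow approximation for tied
#' event times). The reported convergence record includes the norm of the
#' partial-likelihood gradient at the optimum, computed with the package's
#' own Breslow score function so it is directly comparable with the network
#' loss.
#'
#' @param data A `survival_dataset` (columns `time`, `event`, features).
#' @param features Character vector of feature columns (default: all).
#' @return A `cox_fit`: coefficients, variance-covariance matrix, log
#'   partial likelihood, convergence record, tie-method tag, and the
#'   underlying `coxph` object.
#' @export
fit_cox <- function(data, features = NULL) {
  features <- features %||% feature_cols(data)
  if (sum(data$event) < 1) stop_tabsurv("need at least 1 event")
  x <- feature_matrix(data, features)
  if (anyNA(x)) stop_tabsurv("features must be complete")
  const <- features[apply(x, 2, function(v) length(unique(v)) == 1)]
  if (length(const) > 0)
    stop_tabsurv("constant feature(s): ", paste(const, collapse = ", "))
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(data$time, data$event) ~ x,
                    ties = "breslow", control = survival::coxph.control(
                      eps = 1e-12, iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        monotone <<- TRUE
        rlang::warn(paste0("possible monotone likelihood: ",
                           conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    })
  beta <- setNames(coef(fit), features)
  vc <- vcov(fit); dimnames(vc) <- list(features, features)
  # gradient of the (unnormalized) Breslow log PL at beta-hat
  grad <- breslow_score(x, data$time, data$event, beta)
  structure(list(coefficients = beta, vcov = vc,
                 loglik = fit$loglik[2], iter = fit$iter,
                 grad_norm = sqrt(sum(grad^2)),
                 converged = !monotone && fit$iter <= 100,
                 monotone_flag = monotone,
                 tie_method = "breslow", features = features,
                 n = nrow(data), n_events = sum(data$event), coxph = fit),
            class = "cox_fit")
}

# score vector of the Breslow log partial likelihood
breslow_score <- function(x, times, events, beta) {
  eta <- drop(x %*% beta)
  g <- breslow_loss_grad(eta, times, events, normalize = FALSE)
  -drop(crossprod(x, g))
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$vcov

#' @exportS3Method base::print
print.cox_fit <- function(x, ...) {
  cat("Cox fit (Breslow ties):", length(x$coefficients), "features,",
      x$n_events, "events /", x$n, "subjects\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @export
tidy.cox_fit <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = se,
                 statistic = unname(x$coefficients) / se,
                 p.value = 2 * pnorm(-abs(unname(x$coefficients) / se)),
                 hazard_ratio = exp(unname(x$coefficients)),
                 conf.low = exp(unname(x$coefficients) - z * se),
                 conf.high = exp(unname(x$coefficients) + z * se))
}

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n = x$n, n_events = x$n_events,
                 iterations = x$iter, grad_norm = x$grad_norm,
                 converged = x$converged)
}

#' Elastic-net penalized Cox regression
#'
#' Minimizes the negative log partial likelihood plus the elastic-net
#' penalty `lambda * (alpha * ||beta||_1 + (1 - alpha) * ||beta||_2^2 / 2)`
#' (glmnet's Cox objective, Breslow ties). A feature counts as *selected*
#' iff its coefficient is exactly nonzero (soft-threshold zeros, no epsilon
#' rounding). Features are expected already standardized by the
#' preprocessing step, so internal standardization is off.
#'
#' @param data A `survival_dataset`.
#' @param alpha Mixing parameter in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param lambda Penalty strength `>= 0`.
#' @param features Feature columns (default all).
#' @return Named numeric coefficient vector (exact zeros preserved).
#' @export
fit_coxnet <- function(data, alpha, lambda, features = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, lambda >= 0)
  if (sum(data$event) < 1) stop_tabsurv("need at least 1 event")
  features <- features %||% feature_cols(data)
  x <- feature_matrix(data, features)
  y <- survival::Surv(data$time, data$event)
  # descend a short path into the requested lambda for a warm-started,
  # tightly converged solution at exactly `lambda`
  lam_path <- sort(unique(c(lambda * c(64, 16, 4, 1))), decreasing = TRUE)
  if (lambda == 0) lam_path <- c(0.4, 0.1, 0.025, 0.00625, 0)
  fit <- glmnet::glmnet(x, y, family = "cox", alpha = alpha,
                        lambda = lam_path, standardize = FALSE,
                        thresh = 1e-12)
  setNames(as.numeric(coef(fit, s = lambda, exact = FALSE)), features)
}

#' Tune elastic-net parameters by repeated cross-validated deviance
#'
#' For each `(alpha, lambda)` pair, runs repeated k-fold cross-validation
#' within each imputed dataset (folds stratified by event status) and
#' averages the penalized partial-likelihood deviance over folds, repeats
#' and imputed datasets; the minimizing pair is selected.
#'
#' @param stack An `imputed_stack` (or a list of complete datasets).
#' @param alpha_grid,lambda_grid Non-empty numeric grids.
#' @param folds,repeats Cross-validation geometry (default 5-fold, twice).
#' @param seed Seed for fold assignment.
#' @param features Feature columns.
#' @return A `coxnet_tuning`: tibble `grid` (alpha, lambda, mean deviance)
#'   plus `alpha` and `lambda` at the grid minimum.
#' @export
tune_coxnet <- function(stack, alpha_grid = c(0.2, 0.5, 0.8, 1),
                        lambda_grid = NULL, folds = 5, repeats = 2,
                        seed = 1L, features = NULL) {
  datasets <- if (inherits(stack, "imputed_stack")) stack$data else stack
  stopifnot(length(alpha_grid) > 0)
  lambda_grid <- lambda_grid %||% exp(seq(log(0.2), log(0.002), length.out = 25))
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  # glmnet needs a path of >= 2 lambdas; pad a single-point grid internally
  # and report only the requested value
  lam_path <- if (length(lambda_grid) == 1) c(4 * lambda_grid, lambda_grid)
              else lambda_grid
  acc <- array(0, c(length(alpha_grid), length(lambda_grid)))
  cnt <- array(0, c(length(alpha_grid), length(lambda_grid)))
  for (d in seq_along(datasets)) {
    data <- datasets[[d]]
    features_d <- features %||% setdiff(names(data), c("id", "time", "event"))
    x <- as.matrix(data[, features_d, drop = FALSE])
    y <- survival::Surv(data$time, data$event)
    for (rep_i in seq_len(repeats)) {
      foldid <- stratified_folds(data$event, folds,
                                 child_seed(seed, "tune", d, rep_i))
      for (a in seq_along(alpha_grid)) {
        cvfit <- tryCatch(
          glmnet::cv.glmnet(x, y, family = "cox", alpha = alpha_grid[a],
                            lambda = lam_path, foldid = foldid,
                            grouped = TRUE, standardize = FALSE),
          error = function(e) NULL)
        if (is.null(cvfit)) next
        ix <- match(signif(cvfit$lambda, 8), signif(lambda_grid, 8))
        ok <- !is.na(ix) & is.finite(cvfit$cvm)
        acc[a, ix[ok]] <- acc[a, ix[ok]] + cvfit$cvm[ok]
        cnt[a, ix[ok]] <- cnt[a, ix[ok]] + 1
      }
    }
  }
  mean_dev <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  grid <- tibble::tibble(
    alpha = rep(alpha_grid, times = length(lambda_grid)),
    lambda = rep(lambda_grid, each = length(alpha_grid)),
    mean_deviance = as.numeric(mean_dev))
  if (all(is.na(grid$mean_deviance)))
    stop_tabsurv("no finite cross-validated deviance anywhere on the grid")
  best <- grid[which.min(grid$mean_deviance), ]
  structure(list(grid = grid, alpha = best$alpha, lambda = best$lambda,
                 deviance = best$mean_deviance),
            class = "coxnet_tuning")
}

#' @exportS3Method base::print
print.coxnet_tuning <- function(x, ...) {
  cat(sprintf("Elastic-net tuning: alpha* = %.3g, lambda* = %.4g (CV deviance %.4f)\n",
              x$alpha, x$lambda, x$deviance))
  invisible(x)
}

stratified_folds <- function(event, folds, seed) {
  with_rng(seed, {
    id <- integer(length(event))
    counts <- integer(folds)
    for (g in sort(unique(event), decreasing = TRUE)) {  # events first
      ix <- sample(which(event == g))
      # cycle a permutation of folds that starts with the emptiest, so the
      # strata remainders equalize the total fold sizes
      perm <- order(counts, sample.int(folds))
      fold_seq <- rep(perm, length.out = length(ix))
      id[ix] <- fold_seq
      counts <- counts + tabulate(fold_seq, folds)
    }
    id
  })
}

#' Two-level stability selection over splits and imputed datasets
#'
#' Within each imputed dataset, generates `n_splits` training datasets by
#' repeated event-stratified k-fold cross-validation (each training set is
#' the complement of one fold), fits an elastic-net Cox model on each, and
#' counts, per feature, the training sets where its coefficient is exactly
#' nonzero. A feature *passes* an imputed dataset when that count reaches
#' `split_keep_threshold`; the profile also tallies how many of the `m`
#' imputed datasets each feature passes.
#'
#' @param stack An `imputed_stack` (or list of complete datasets).
#' @param alpha,lambda Elastic-net parameters used in every split (fix them
#'   to the [tune_coxnet()] optimum of the same stack).
#' @param folds,repeats Split geometry; `n_splits = folds * repeats`
#'   (default 10).
#' @param split_keep_threshold Minimum selections among the splits
#'   (default 8).
#' @param seed Seed for the split draws.
#' @param features Feature columns.
#' @return A `selection_profile`: `split_counts` (m x p matrix),
#'   `dataset_pass` (named per-feature pass counts over datasets), `m`,
#'   `n_splits`, `split_keep_threshold`.
#' @export
stability_select <- function(stack, alpha, lambda, folds = 5, repeats = 2,
                             split_keep_threshold = 8, seed = 1L,
                             features = NULL) {
  datasets <- if (inherits(stack, "imputed_stack")) stack$data else stack
  n_splits <- folds * repeats
  stopifnot(split_keep_threshold <= n_splits)
  features <- features %||%
    setdiff(names(datasets[[1]]), c("id", "time", "event"))
  m <- length(datasets)
  split_counts <- matrix(0L, m, length(features),
                         dimnames = list(NULL, features))
  for (d in seq_len(m)) {
    data <- datasets[[d]]
    for (rep_i in seq_len(repeats)) {
      foldid <- stratified_folds(data$event, folds,
                                 child_seed(seed, "stability", d, rep_i))
      for (f in seq_len(folds)) {
        train <- data[foldid != f, , drop = FALSE]
        beta <- fit_coxnet(train, alpha = alpha, lambda = lambda,
                           features = features)
        split_counts[d, ] <- split_counts[d, ] + as.integer(beta != 0)
      }
    }
  }
  pass <- split_counts >= split_keep_threshold
  structure(list(split_counts = split_counts,
                 dataset_pass = colSums(pass),
                 m = m, n_splits = n_splits,
                 split_keep_threshold = split_keep_threshold,
                 alpha = alpha, lambda = lambda, seed = seed),
            class = "selection_profile")
}

#' @export
tidy.selection_profile <- function(x, ...) {
  tibble::tibble(feature = names(x$dataset_pass),
                 datasets_passed = as.integer(x$dataset_pass),
                 m = x$m)
}

#' @exportS3Method base::print
print.selection_profile <- function(x, ...) {
  cat("Stability selection over", x$m, "imputed datasets x", x$n_splits,
      "splits (keep >=", x$split_keep_threshold, "splits)\n")
  print(dplyr::arrange(tidy(x), dplyr::desc(.data$datasets_passed)), n = 10)
  invisible(x)
}

#' Plot the dataset-pass profile of a stability selection
#' @param object A `selection_profile`.
#' @param ... Unused.
#' @export
autoplot.selection_profile <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = stats::reorder(.data$feature,
                                                      .data$datasets_passed),
                                   y = .data$datasets_passed)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste0("imputed datasets passed (of ", object$m, ")")) +
    ggplot2::theme_minimal()
}

#' Candidate feature lists at consensus thresholds
#'
#' For each threshold `t`, the features passing at least `t` imputed
#' datasets. The lists are nested by construction: a higher threshold's list
#' is a subset of a lower threshold's.
#'
#' @param profile A `selection_profile`.
#' @param thresholds Integer vector of minimum dataset counts, within
#'   `[1, m]`.
#' @return Named list (one element per threshold) of feature vectors.
#' @export
consensus_candidates <- function(profile, thresholds) {
  stopifnot(all(thresholds >= 1), all(thresholds <= profile$m))
  out <- lapply(thresholds, function(t)
    names(profile$dataset_pass)[profile$dataset_pass >= t])
  names(out) <- paste0("t", thresholds)
  out
}

#' Final stability-selected Cox model with Rubin pooling
#'
#' Fits an unpenalized Cox model per imputed dataset for each candidate
#' feature list, pools each candidate's coefficients with Rubin's rules and
#' compares adjacent nested candidates with the pooled Wald (D1) test. The
#' default `"lowest_p"` rule picks, among candidates whose extra variables
#' test significant at `alpha_level`, the one with the smallest p-value
#' (falling back to the smallest candidate when none does);
#' `"sequential"` walks up the nested chain and stops at the first
#' non-significant extension.
#'
#' @param stack An `imputed_stack` (or list of complete datasets).
#' @param candidates Named list of nested feature vectors (>= 2, e.g. from
#'   [consensus_candidates()]).
#' @param rule `"lowest_p"` (default) or `"sequential"`.
#' @param alpha_level Significance level for the comparisons.
#' @return A `pooled_cox_fit`: pooled tibble (term, estimate, hazard ratio,
#'   95% CI, p), the chosen feature list, and the comparison table.
#' @export
coxsf_finalize <- function(stack, candidates, rule = c("lowest_p", "sequential"),
                           alpha_level = 0.05) {
  rule <- match.arg(rule)
  datasets <- if (inherits(stack, "imputed_stack")) stack$data else stack
  stopifnot(length(candidates) >= 2)
  sizes <- vapply(candidates, length, integer(1))
  ord <- order(sizes)
  candidates <- candidates[ord]; sizes <- sizes[ord]
  if (any(duplicated(sizes)))
    stop_tabsurv("candidate lists must differ (identical sizes found)")
  for (i in seq_len(length(candidates) - 1))
    if (!all(candidates[[i]] %in% candidates[[i + 1]]))
      stop_tabsurv("candidate lists are not nested")
  fits <- lapply(candidates, function(feats)
    lapply(datasets, function(d) fit_cox(d, features = feats)))
  comparisons <- dplyr::bind_rows(lapply(seq_len(length(candidates) - 1),
    function(i) {
      cmp <- wald_compare_pooled(fits[[i + 1]], candidates[[i]])
      dplyr::mutate(cmp,
                    full = names(candidates)[i + 1],
                    nested = names(candidates)[i], .before = 1)
    }))
  chosen_i <- if (rule == "sequential") {
    i <- 1L
    while (i < length(candidates) &&
           comparisons$p.value[i] < alpha_level) i <- i + 1L
    i
  } else {
    sig <- which(comparisons$p.value < alpha_level)
    if (length(sig) == 0) 1L
    else sig[which.min(comparisons$p.value[sig])] + 1L
  }
  chosen <- candidates[[chosen_i]]
  est <- do.call(rbind, lapply(fits[[chosen_i]], coef))
  va <- do.call(rbind, lapply(fits[[chosen_i]], function(f) diag(vcov(f))))
  colnames(va) <- colnames(est)
  pooled <- rubin_pool(est, va)
  pooled <- dplyr::mutate(pooled,
                          hazard_ratio = exp(.data$estimate),
                          conf.low = exp(.data$estimate - 1.96 * sqrt(.data$T)),
                          conf.high = exp(.data$estimate + 1.96 * sqrt(.data$T)))
  structure(list(pooled = pooled, features = chosen,
                 comparisons = comparisons, rule = rule,
                 per_imputation = fits[[chosen_i]], m = length(datasets)),
            class = "pooled_cox_fit")
}

#' @export
tidy.pooled_cox_fit <- function(x, ...) x$pooled

#' @export
glance.pooled_cox_fit <- function(x, ...) {
  tibble::tibble(n_features = length(x$features), m = x$m, rule = x$rule)
}

#' @exportS3Method base::print
print.pooled_cox_fit <- function(x, ...) {
  cat("Pooled Cox model (", length(x$features), " features, m = ", x$m,
      ", rule = ", x$rule, ")\n", sep = "")
  print(x$pooled[, c("term", "hazard_ratio", "conf.low", "conf.high", "p.value")])
  invisible(x)
}

#' Export a pooled Cox model as a CSV of hazard ratios
#' @param fit A `pooled_cox_fit`.
#' @param path CSV path.
#' @export
write_pooled_cox <- function(fit, path) {
  utils::write.csv(
    as.data.frame(fit$pooled[, c("term", "hazard_ratio", "conf.low",
                                 "conf.high", "p.value")]),
    path, row.names = FALSE)
  invisible(path)
}
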