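#' Dichotomize a categorical column
#'
#' Maps a categorical vector to 1 where the value equals `positive_level` and
#' 0 elsewhere; missing values stay missing.
#'
#' @param x Vector of categorical values (character, factor, or otherwise).
#' @param positive_level The level coded as 1.
#' @return Integer vector of 0/1 with `NA` preserved.
#' @export
dichotomize <- function(x, positive_level) {
  obs <- unique(x[!is.na(x)])
  if (length(obs) < 1) stop_tabsurv("column has no observed level")
  if (!positive_level %in% obs)
    rlang::warn(paste0("positive level '", positive_level,
                       "' not observed; returning an all-zero column"))
  out <- as.integer(x == positive_level)
  out[is.na(x)] <- NA_integer_
  out
}

#' Base-2 logarithmic transform for skewed positive predictors
#'
#' The default (`variant = "literal"`) computes `log2(x) + 1`, defined only
#' for strictly positive values. `variant = "shifted"` computes `log2(x + 1)`
#' instead, which tolerates zeros. Missing values stay missing.
#'
#' @param x Numeric vector.
#' @param variant `"literal"` (`log2(x) + 1`) or `"shifted"` (`log2(x + 1)`).
#' @return Transformed numeric vector.
#' @export
log2_shift <- function(x, variant = c("literal", "shifted")) {
  variant <- match.arg(variant)
  obs <- x[!is.na(x)]
  if (variant == "literal") {
    n_bad <- sum(obs <= 0)
    if (n_bad > 0)
      stop_tabsurv(n_bad, " cell(s) are <= 0; the literal form log2(x) + 1 ",
                   "is undefined there. Consider variant = \"shifted\".")
    log2(x) + 1
  } else {
    if (any(obs < 0)) stop_tabsurv("negative values not allowed for the shifted form")
    log2(x + 1)
  }
}

#' Min-max normalization fitted on training rows only
#'
#' `fit_minmax()` records each feature's minimum and maximum on the training
#' rows; `apply_minmax()` maps `(x - min) / (max - min)`. A constant training
#' column maps to 0 everywhere. Values outside the training range are NOT
#' clipped, so test rows may fall outside `[0, 1]`.
#'
#' @param data Data frame of training rows.
#' @param features Character vector of feature columns (default: all numeric
#'   columns except `id`, `time`, `event`).
#' @param split_id Optional identifier of the training split, carried in the
#'   stats for provenance.
#' @return `fit_minmax()`: a `minmax_stats` object (tibble of feature, min,
#'   max). `apply_minmax()`: `data` with the features rescaled.
#' @export
fit_minmax <- function(data, features = NULL, split_id = NA_character_) {
  if (nrow(data) == 0) stop_tabsurv("training split is empty")
  features <- features %||% setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                                    c("id", "time", "event"))
  stats <- tibble::tibble(
    feature = features,
    min = vapply(features, function(f) suppressWarnings(min(data[[f]], na.rm = TRUE)), numeric(1)),
    max = vapply(features, function(f) suppressWarnings(max(data[[f]], na.rm = TRUE)), numeric(1)))
  structure(list(stats = stats, split_id = split_id), class = "minmax_stats")
}

#' @param stats A `minmax_stats` object from [fit_minmax()].
#' @rdname fit_minmax
#' @export
apply_minmax <- function(data, stats) {
  stopifnot(inherits(stats, "minmax_stats"))
  missing_feats <- setdiff(stats$stats$feature, names(data))
  if (length(missing_feats) > 0)
    stop_tabsurv("features absent from data: ",
                 paste(missing_feats, collapse = ", "))
  for (i in seq_len(nrow(stats$stats))) {
    f <- stats$stats$feature[i]
    lo <- stats$stats$min[i]; hi <- stats$stats$max[i]
    data[[f]] <- if (hi > lo) (data[[f]] - lo) / (hi - lo) else rep(0, nrow(data)) +
      0 * data[[f]]  # keep NA pattern for constant columns
  }
  data
}

#' Serialize / restore fitted min-max stats as JSON
#' @param stats A `minmax_stats`.
#' @param path JSON file path.
#' @export
write_minmax <- function(stats, path) {
  jsonlite::write_json(list(split_id = stats$split_id, stats = stats$stats),
                       path, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_minmax
#' @export
read_minmax <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(stats = tibble::as_tibble(obj$stats),
                 split_id = obj$split_id %||% NA_character_),
            class = "minmax_stats")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing feature `j`
#' on all the others (with intercept). Computed through the inverse of the
#' feature correlation matrix, falling back to per-feature least squares when
#' that matrix is singular; exact collinearity is reported as `Inf`.
#'
#' @param features Complete numeric data frame or matrix (>= 2 columns, more
#'   rows than columns).
#' @return Named numeric vector of VIFs.
#' @export
compute_vif <- function(features) {
  x <- as.matrix(features)
  if (ncol(x) < 2) stop_tabsurv("need at least 2 features")
  if (nrow(x) <= ncol(x)) stop_tabsurv("need more rows than features")
  if (anyNA(x)) stop_tabsurv("features must be complete")
  r <- cor(x)
  inv <- tryCatch(solve(r), error = function(e) NULL)
  if (!is.null(inv) && all(diag(inv) > 0) && all(is.finite(inv)))
    return(setNames(diag(inv), colnames(x)))
  # singular: per-feature least squares, R^2 -> 1 reported as +Inf
  vifs <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    ssr <- sum(fit$residuals^2)
    sst <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(vifs, colnames(x))
}

#' Iterative multicollinearity pruning by VIF
#'
#' While any feature's VIF exceeds `threshold`, removes the single feature
#' with the largest VIF (first by column order on exact ties) and recomputes.
#'
#' @param features Complete numeric data frame or matrix.
#' @param threshold VIF threshold (default 10).
#' @return A `vif_report`: list with `log` (tibble of step, feature, vif,
#'   removed) and `retained` (character vector).
#' @export
prune_collinear <- function(features, threshold = 10) {
  x <- as.data.frame(features)
  log_rows <- list()
  step <- 0L
  repeat {
    v <- compute_vif(x)
    worst <- which.max(ifelse(is.na(v), -Inf, v))
    if (!is.finite(v[worst]) || v[worst] > threshold) {
      step <- step + 1L
      log_rows[[step]] <- tibble::tibble(step = step,
                                         feature = names(v)[worst],
                                         vif = unname(v[worst]),
                                         removed = TRUE)
      x <- x[, -worst, drop = FALSE]
      if (ncol(x) < 2) break
    } else break
  }
  final <- if (ncol(x) >= 2) compute_vif(x) else setNames(rep(NA_real_, ncol(x)), names(x))
  structure(list(
    log = dplyr::bind_rows(c(log_rows, list(
      tibble::tibble(step = step + seq_along(final), feature = names(final),
                     vif = unname(final), removed = FALSE)))),
    retained = names(x),
    threshold = threshold), class = "vif_report")
}

#' @exportS3Method base::print
print.vif_report <- function(x, ...) {
  removed <- x$log$feature[x$log$removed]
  cat("VIF pruning (threshold ", x$threshold, "): removed ",
      length(removed), " feature(s), retained ", length(x$retained), "\n", sep = "")
  if (length(removed)) cat("removed:", paste(removed, collapse = ", "), "\n")
  invisible(x)
}

#' Proportional-hazards diagnostic from scaled Schoenfeld residuals
#'
#' Tests, per covariate and globally, whether the scaled Schoenfeld residuals
#' of a fitted Cox model trend with a transform of time; a small p-value
#' flags non-proportional hazards.
#'
#' @param fit A [fit_cox()] result (or a `coxph` fit).
#' @param transform Time transform: `"km"` (default), `"identity"` or
#'   `"rank"`.
#' @return Tibble with columns `term`, `chisq`, `df`, `p`; the last row is
#'   the global test.
#' @export
schoenfeld_ph_check <- function(fit, transform = c("km", "identity", "rank")) {
  transform <- match.arg(transform)
  cfit <- if (inherits(fit, "cox_fit")) fit$coxph else fit
  if (sum(cfit$nevent %||% cfit$n) < 2 ||
      (!is.null(cfit$nevent) && cfit$nevent < 2))
    stop_tabsurv("need at least 2 events for the Schoenfeld check")
  z <- survival::cox.zph(cfit, transform = transform, global = TRUE)
  tb <- z$table
  tibble::tibble(term = rownames(tb), chisq = tb[, "chisq"],
                 df = tb[, "df"], p = tb[, "p"])
}
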