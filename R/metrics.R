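#' Harrell's concordance index for right-censored data
#'
#' Fraction of usable pairs in which the subject with the earlier event has
#' the higher risk score. A pair is usable if the earlier time is an event
#' (or the times are tied with exactly one event). Tied scores count 1/2.
#'
#' @param scores Risk scores (higher = higher risk).
#' @param times Follow-up times.
#' @param events 0/1 event indicators.
#' @return Concordance in `[0, 1]`; `NA` (with a warning) if no pair is
#'   usable.
#' @export
harrells_c <- function(scores, times, events) {
  stopifnot(length(scores) == length(times), length(times) == length(events))
  dt <- outer(times, times, "<")                # t_i < t_j
  tie_t <- outer(times, times, "==")
  ev_i <- matrix(events == 1, length(times), length(times))
  usable <- (dt & ev_i) | (tie_t & ev_i & t(!ev_i))
  diag(usable) <- FALSE
  if (!any(usable)) {
    rlang::warn("no comparable pairs; concordance undefined")
    return(NA_real_)
  }
  conc <- outer(scores, scores, ">")[usable]
  ties <- outer(scores, scores, "==")[usable]
  (sum(conc) + 0.5 * sum(ties)) / sum(usable)
}

# Kaplan-Meier estimate of the censoring survival G, returned as a
# left-continuous evaluator G(t-): product over censoring times strictly
# before t of (1 - c_s / n_s), with n_s the number still under observation.
censoring_km <- function(times, events) {
  st <- sort(times)
  n <- length(times)
  cens <- times[events == 0]
  ut <- sort(unique(cens))
  if (length(ut) == 0) return(function(t) rep(1, length(t)))
  d <- vapply(ut, function(s) sum(cens == s), numeric(1))
  nrisk <- n - findInterval(ut, st, left.open = TRUE)
  surv <- cumprod(1 - d / nrisk)
  function(t) {
    idx <- findInterval(t, ut, left.open = TRUE)  # censoring times < t
    ifelse(idx == 0, 1, surv[pmax(idx, 1)])
  }
}

#' Uno's inverse-probability-of-censoring-weighted concordance
#'
#' IPCW estimator of the concordance probability truncated at `tau`: usable
#' pairs `(i, j)` with `event_i = 1`, `t_i < t_j` and `t_i < tau` are
#' weighted by `G(t_i-)^-2`, with `G` the Kaplan-Meier estimator of the
#' censoring distribution. Unlike Harrell's C, the estimate does not depend
#' on the study-specific censoring distribution. With no censoring all
#' weights are 1 and the estimator reduces exactly to [harrells_c()].
#'
#' @inheritParams harrells_c
#' @param tau Truncation time (default: 95th percentile of observed times).
#' @param weight_data Optional data frame (`time`, `event`) on which to
#'   estimate the censoring distribution (default: the evaluation sample).
#' @return Weighted concordance in `[0, 1]`.
#' @export
unos_c <- function(scores, times, events, tau = NULL,
                   weight_data = NULL) {
  stopifnot(length(scores) == length(times), length(times) == length(events))
  tau <- tau %||% as.numeric(quantile(times, 0.95))
  G <- if (is.null(weight_data)) censoring_km(times, events)
       else censoring_km(weight_data$time, weight_data$event)
  gi <- G(times)
  usable <- outer(times, times, "<") &
    matrix(events == 1 & times < tau & gi > 0, length(times), length(times))
  if (!any(usable)) {
    rlang::warn("no comparable pairs before tau; concordance undefined")
    return(NA_real_)
  }
  n_dropped <- sum(outer(times, times, "<") &
                     matrix(events == 1 & times < tau & gi == 0,
                            length(times), length(times)))
  if (n_dropped > 0)
    rlang::inform(paste0(n_dropped, " pair(s) dropped: censoring KM is 0 at the event time"))
  w <- matrix(1 / gi^2, length(times), length(times))[usable]
  conc <- outer(scores, scores, ">")[usable]
  ties <- outer(scores, scores, "==")[usable]
  sum(w * (conc + 0.5 * ties)) / sum(w)
}

# Kaplan-Meier survival probability at time t (right-continuous), direct
# product-limit computation (no model object overhead; called in tight
# bootstrap loops)
km_surv_at <- function(times, events, t) {
  if (length(times) == 0) return(NA_real_)
  is_evt <- times <= t & events == 1
  if (!any(is_evt)) return(1)
  st <- sort(times)
  ut <- sort(unique(times[is_evt]))
  d <- vapply(ut, function(s) sum(times == s & events == 1), numeric(1))
  nrisk <- length(times) - findInterval(ut, st, left.open = TRUE)
  prod(1 - d / nrisk)
}

#' Time-dependent ROC curve (cumulative cases, dynamic controls)
#'
#' Cases at horizon `t` are subjects with an event by `t`; controls are
#' subjects event-free beyond `t`. Censoring is handled with the
#' Kaplan-Meier-based estimator of the survivalROC family:
#' `Se(c) = (1 - S(t | score > c)) P(score > c) / (1 - S(t))` and
#' `Sp(c) = S(t | score <= c) P(score <= c) / S(t)`, with the conditional
#' survival curves estimated by KM within the marker strata. Without
#' censoring before `t` this reduces exactly to the empirical ROC of the
#' binary label `[T <= t]`.
#'
#' @inheritParams harrells_c
#' @param horizon Evaluation horizon `t` (years).
#' @return Tibble with columns `cutoff`, `sensitivity`, `specificity`.
#' @export
td_roc <- function(scores, times, events, horizon) {
  if (!any(times <= horizon & events == 1) || !any(times > horizon))
    stop_tabsurv("no cases or no controls at horizon ", horizon,
                 "; time-dependent ROC undefined")
  cuts <- c(-Inf, sort(unique(scores)))
  m <- td_roc_kernel(as.numeric(times), as.integer(events),
                     as.numeric(scores), horizon, cuts)
  tibble::tibble(cutoff = cuts, sensitivity = m[, 1], specificity = m[, 2])
}

#' Time-dependent AUC by trapezoidal integration of the ROC curve
#'
#' @inheritParams td_roc
#' @return Area under the time-dependent ROC at `horizon`.
#' @export
td_auc <- function(scores, times, events, horizon) {
  auc_from_roc(td_roc(scores, times, events, horizon))
}

#' Cutoff maximizing Youden's J on a reference sample
#'
#' @inheritParams td_roc
#' @return The cutoff value maximizing `Se + Sp - 1`.
#' @export
youden_cutoff <- function(scores, times, events, horizon) {
  roc <- td_roc(scores, times, events, horizon)
  roc$cutoff[which.max(roc$sensitivity + roc$specificity)]
}

#' Time-dependent sensitivity, specificity and balanced accuracy
#'
#' Classifies subjects at `cutoff` and reports the KM-corrected sensitivity
#' and specificity at the horizon, plus balanced accuracy
#' `(Se + Sp) / 2`. The default policy derives the cutoff by maximizing
#' Youden's J on a training sample (`train`); alternatively pass a fixed
#' `cutoff`, or leave both empty to use Youden's J on the evaluation sample.
#'
#' @inheritParams td_roc
#' @param cutoff Optional fixed cutoff.
#' @param train Optional training data frame (`score`, `time`, `event`) on
#'   which the Youden cutoff is derived.
#' @return Tibble: `horizon`, `cutoff`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `cutoff_policy`.
#' @export
td_confusion <- function(scores, times, events, horizon, cutoff = NULL,
                         train = NULL) {
  policy <- if (!is.null(cutoff)) "fixed"
            else if (!is.null(train)) "youden_train" else "youden_self"
  if (is.null(cutoff)) {
    cutoff <- if (!is.null(train))
      youden_cutoff(train$score, train$time, train$event, horizon)
    else youden_cutoff(scores, times, events, horizon)
  }
  roc <- td_roc(scores, times, events, horizon)
  # Se/Sp at the largest tabulated cutoff <= requested cutoff
  i <- max(which(roc$cutoff <= cutoff))
  se <- roc$sensitivity[i]; sp <- roc$specificity[i]
  tibble::tibble(horizon = horizon, cutoff = cutoff, sensitivity = se,
                 specificity = sp, balanced_accuracy = (se + sp) / 2,
                 cutoff_policy = policy)
}

#' Percentile bootstrap confidence interval for a survival metric
#'
#' Resamples subjects with replacement `B` times; the point value is
#' computed on the original sample and the CI from the 2.5/97.5 percentiles
#' of the resampled values. Degenerate resamples (no events, or a metric
#' evaluating to `NA`) are skipped and counted.
#'
#' @param data Data frame of subjects passed to `metric_fn`.
#' @param metric_fn Function `data -> scalar`.
#' @param B Number of bootstrap replications (default 100).
#' @param seed Seed for the resampling.
#' @param conf Confidence level.
#' @param name Metric label carried in the result.
#' @return One-row tibble: `metric`, `value`, `conf_low`, `conf_high`,
#'   `n_bootstrap`, `n_skipped`, `seed`.
#' @export
bootstrap_ci <- function(data, metric_fn, B = 100, seed = 1L, conf = 0.95,
                         name = "metric") {
  stopifnot(B >= 2)
  point <- metric_fn(data)
  with_rng(seed, {
    vals <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(data), replace = TRUE)
      d <- data[idx, , drop = FALSE]
      if (!is.null(d$event) && sum(d$event) == 0) next
      vals[b] <- tryCatch(suppressWarnings(metric_fn(d)),
                          error = function(e) NA_real_)
    }
    skipped <- sum(is.na(vals))
    if (skipped > B / 2)
      stop_tabsurv("more than half of the bootstrap resamples were degenerate (",
                   skipped, "/", B, ")")
    qs <- quantile(vals, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
    tibble::tibble(metric = name, value = point,
                   conf_low = unname(qs[1]), conf_high = unname(qs[2]),
                   n_bootstrap = B, n_skipped = skipped, seed = seed)
  })
}

#' Compare models' per-dataset metrics with ANOVA + Tukey's HSD
#'
#' One-way ANOVA of the metric across models over imputed datasets, followed
#' by Tukey honest-significant-difference pairwise comparisons.
#'
#' @param metric_table Tibble with columns `model`, `dataset`, `value`.
#' @return List with `anova` (one-row tibble: statistic, p) and `pairwise`
#'   (tibble: comparison, diff, conf_low, conf_high, p_adj).
#' @export
compare_models <- function(metric_table) {
  stopifnot(all(c("model", "value") %in% names(metric_table)))
  counts <- table(metric_table$model)
  if (length(counts) < 2) stop_tabsurv("need at least 2 models to compare")
  if (any(counts < 2)) stop_tabsurv("every model needs at least 2 metric values")
  df <- data.frame(model = factor(metric_table$model),
                   value = metric_table$value)
  fit <- aov(value ~ model, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$model
  list(
    anova = tibble::tibble(statistic = an$`F value`[1], p = an$`Pr(>F)`[1]),
    pairwise = tibble::tibble(comparison = rownames(tk),
                              diff = tk[, "diff"],
                              conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
                              p_adj = tk[, "p adj"]))
}
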