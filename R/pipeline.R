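#' Event-stratified nested cross-validation splits
#'
#' `repeats` rounds of event-stratified k-fold partitioning: each (repeat,
#' fold) pair yields a training set (the complement of the fold, 80% of rows
#' at the default 5 folds) and a test set (the fold). Within a repeat the
#' test sets partition the data.
#'
#' @param data A data frame with an `event` column, or an event vector.
#' @param folds,repeats Fold count and number of repeats (default 5 x 2 =
#'   10 splits).
#' @param seed Seed for the fold draws.
#' @return A `nested_splits` object: list of `cohort_split`s, each carrying
#'   `train` and `test` row indices plus `repeat_id` and `fold`.
#' @export
nested_splits <- function(data, folds = 5, repeats = 2, seed = 1L) {
  event <- if (is.data.frame(data)) data$event else data
  n <- length(event)
  if (n < folds) stop_tabsurv("need at least `folds` rows")
  if (sum(event) < folds)
    stop_tabsurv("event count (", sum(event), ") below the fold count; ",
                 "cannot stratify")
  splits <- list()
  for (r in seq_len(repeats)) {
    foldid <- stratified_folds(event, folds, child_seed(seed, "splits", r))
    for (f in seq_len(folds)) {
      splits[[length(splits) + 1]] <- structure(
        list(train = which(foldid != f), test = which(foldid == f),
             repeat_id = r, fold = f), class = "cohort_split")
    }
  }
  structure(splits, class = "nested_splits")
}

#' @rdname nested_splits
#' @param split A `cohort_split`.
#' @export
split_train <- function(data, split) {
  stopifnot(inherits(split, "cohort_split"))
  data[split$train, , drop = FALSE]
}

#' @rdname nested_splits
#' @export
split_test <- function(data, split) {
  stopifnot(inherits(split, "cohort_split"))
  data[split$test, , drop = FALSE]
}

#' Configuration of a full five-model experiment
#'
#' @param data Optional `survival_dataset` (default: the synthetic
#'   ageing-cohort preset at size `n`).
#' @param n Cohort size when simulating.
#' @param roster Models to run, subset of `c("coxen", "coxsf",
#'   "feedforward", "densenet", "tabtransformer")`.
#' @param horizons Evaluation horizons in years, positive and sorted.
#' @param m,iterations Imputation count and chained-equation sweeps.
#' @param folds,repeats Nested-CV geometry.
#' @param bootstrap_B Bootstrap replications for metric CIs.
#' @param scale `"desk"` (reduced sizes that complete on one CPU: fewer
#'   epochs, a higher learning rate, one evaluated split, and a slimmer
#'   transformer) or `"full"` (the study-scale settings).
#' @param epochs,learning_rate Optional overrides of the scale preset.
#' @param seed Master seed; every stage derives a named child stream.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(data = NULL, n = 2000,
                              roster = c("coxen", "coxsf", "feedforward",
                                         "densenet", "tabtransformer"),
                              horizons = c(4, 6, 8, 10, 12),
                              m = 5, iterations = 5, folds = 5, repeats = 2,
                              bootstrap_B = 50,
                              scale = c("desk", "full"),
                              epochs = NULL, learning_rate = NULL,
                              seed = 1L) {
  scale <- match.arg(scale)
  roster <- match.arg(roster, several.ok = TRUE)
  if (length(horizons) == 0 || any(horizons <= 0) || is.unsorted(horizons))
    stop_tabsurv("`horizons` must be positive and sorted")
  if (length(roster) == 0) stop_tabsurv("`roster` must be non-empty")
  defaults <- if (scale == "desk") {
    list(epochs = c(feedforward = 60, densenet = 60, tabtransformer = 20),
         learning_rate = 0.01,
         tt_spec = list(embed_dim = 32, n_transformer_layers = 2, n_heads = 4,
                        batch_mode = "risk-set-batched", batch_size = 320))
  } else {
    list(epochs = c(feedforward = 300, densenet = 300, tabtransformer = 300),
         learning_rate = 1e-4, tt_spec = list())
  }
  if (!is.null(epochs))
    defaults$epochs[] <- rep_len(epochs, length(defaults$epochs))
  if (!is.null(learning_rate)) defaults$learning_rate <- learning_rate
  structure(list(data = data, n = n, roster = roster, horizons = horizons,
                 m = m, iterations = iterations, folds = folds,
                 repeats = repeats, bootstrap_B = bootstrap_B, scale = scale,
                 epochs = defaults$epochs,
                 learning_rate = defaults$learning_rate,
                 tt_spec = defaults$tt_spec, seed = as.integer(seed)),
            class = "experiment_config")
}

# one bootstrap loop computing Uno's C and all time-dependent metrics
evaluate_scores <- function(scores, times, events, horizons, B = 50,
                            seed = 1L, train = NULL, n_cutoffs = 100) {
  tau <- max(times)
  grid_cut <- function(s) {
    u <- sort(unique(s))
    if (length(u) > n_cutoffs) u <- unique(quantile(s, seq(0, 1, length.out = n_cutoffs)))
    u
  }
  # the cutoff is a fixed function of the training data: derive it once per
  # horizon, then apply it inside every bootstrap resample
  train_cuts <- if (!is.null(train)) {
    vapply(horizons, function(h) tryCatch(
      youden_from_roc(td_roc_at(train$score, train$time, train$event, h,
                                cutoffs = grid_cut(train$score))),
      error = function(e) NA_real_), numeric(1))
  }
  one <- function(sc, tt, ev) {
    out <- c(unos_c = suppressWarnings(unos_c(sc, tt, ev, tau = tau)))
    for (h in horizons) {
      vals <- tryCatch({
        roc <- td_roc_at(sc, tt, ev, h, cutoffs = grid_cut(sc))
        auc <- auc_from_roc(roc)
        cutoff <- if (!is.null(train)) train_cuts[match(h, horizons)]
        else youden_from_roc(roc)
        if (is.na(cutoff)) cutoff <- youden_from_roc(roc)
        i <- max(which(roc$cutoff <= cutoff))
        se <- roc$sensitivity[i]; sp <- roc$specificity[i]
        c(auc, (se + sp) / 2, se, sp)
      }, error = function(e) rep(NA_real_, 4))
      names(vals) <- paste0(c("td_auc", "balanced_accuracy", "sensitivity",
                              "specificity"), "@", h)
      out <- c(out, vals)
    }
    out
  }
  point <- one(scores, times, events)
  boots <- matrix(NA_real_, B, length(point))
  with_rng(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(length(scores), replace = TRUE)
      if (sum(events[idx]) == 0) next
      boots[b, ] <- tryCatch(suppressWarnings(one(scores[idx], times[idx],
                                                  events[idx])),
                             error = function(e) rep(NA_real_, ncol(boots)))
    }
  })
  lo <- apply(boots, 2, quantile, 0.025, na.rm = TRUE)
  hi <- apply(boots, 2, quantile, 0.975, na.rm = TRUE)
  nm <- names(point)
  metric <- sub("@.*$", "", nm)
  horizon <- suppressWarnings(as.numeric(sub("^.*@", "", nm)))
  tibble::tibble(metric = metric, horizon = horizon, value = unname(point),
                 conf_low = unname(lo), conf_high = unname(hi),
                 n_bootstrap = B)
}

# td_roc with an explicit cutoff grid (compiled single-pass KM kernel)
td_roc_at <- function(scores, times, events, horizon, cutoffs) {
  if (!any(times <= horizon & events == 1) || !any(times > horizon))
    stop_tabsurv("no cases or no controls at horizon ", horizon)
  cuts <- c(-Inf, cutoffs)
  m <- td_roc_kernel(as.numeric(times), as.integer(events),
                     as.numeric(scores), horizon, cuts)
  tibble::tibble(cutoff = cuts, sensitivity = m[, 1], specificity = m[, 2])
}

auc_from_roc <- function(roc) {
  # traverse the curve in decreasing-cutoff order (the natural ROC path),
  # clamping float fuzz out of [0, 1]
  o <- order(roc$cutoff, decreasing = TRUE)
  fpr <- c(0, pmin(pmax(1 - roc$specificity[o], 0), 1), 1)
  tpr <- c(0, pmin(pmax(roc$sensitivity[o], 0), 1), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

youden_from_roc <- function(roc) roc$cutoff[which.max(roc$sensitivity + roc$specificity)]

fit_roster_model <- function(name, train, test, config, dataset_id) {
  meta <- feature_meta(train)
  seed_i <- child_seed(config$seed, "model", name, dataset_id)
  if (name == "coxen") {
    beta <- fit_coxnet(train, alpha = config$tuned$alpha,
                       lambda = config$tuned$lambda)
    list(scores_test = drop(feature_matrix(test) %*% beta),
         scores_train = drop(feature_matrix(train) %*% beta))
  } else if (name == "coxsf") {
    feats <- config$coxsf_features
    fit <- fit_cox(train, features = feats)
    list(scores_test = drop(feature_matrix(test, feats) %*% coef(fit)),
         scores_train = drop(feature_matrix(train, feats) %*% coef(fit)))
  } else {
    spec_args <- list(architecture = name,
                      epochs = unname(config$epochs[name]),
                      learning_rate = config$learning_rate, seed = seed_i)
    if (name == "tabtransformer") spec_args <- c(spec_args, config$tt_spec)
    spec <- do.call(network_spec, spec_args)
    model <- switch(name,
                    feedforward = build_feedforward(spec, nrow(meta)),
                    densenet = build_densenet(spec, nrow(meta)),
                    tabtransformer = build_tabtransformer(spec, meta))
    model <- train_risk_model(model, train, valid = test)
    list(scores_test = predict(model, test),
         scores_train = predict(model, train), model = model)
  }
}

#' Run the full five-model experiment
#'
#' Executes the complete flow: simulate or load the cohort; impute missing
#' predictors by chained equations (outcome columns are predictors, never
#' imputed); tune the elastic net by repeated cross-validated deviance on
#' training rows; run two-level stability selection and finalize the pooled
#' selected-features Cox model; per imputed dataset, normalize with
#' training-split min-max statistics, fit every roster model on the
#' training split, score the test split, and evaluate Uno's C plus
#' time-dependent AUC, balanced accuracy, sensitivity and specificity at
#' every horizon with bootstrap CIs; finally compare models on Uno's C with
#' ANOVA + Tukey's HSD.
#'
#' @param config An [experiment_config()].
#' @param verbose Log stage timings to stderr.
#' @return An `experiment_result`: `report` (tidy metric tibble), `comparison`
#'   (Tukey table, when >= 2 models and >= 2 datasets), `loss_curves`,
#'   `manifest`.
#' @export
run_experiment <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()
  timers <- list()
  stage <- function(name, expr) {
    st <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop_tabsurv("stage '", name, "' failed (seed ", config$seed, "): ",
                   conditionMessage(e)))
    timers[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    if (verbose) message(sprintf("[tabsurv] %-12s %6.1fs", name, timers[[name]]))
    res
  }

  data <- stage("data", {
    config$data %||% make_elsa_like(seed = child_seed(config$seed, "data"),
                                    n = config$n)
  })
  stack <- stage("imputation", {
    if (anyNA(data[, feature_cols(data)])) {
      pm <- quickpred(data)
      mice_impute(data, pm, m = config$m, iterations = config$iterations,
                  seed = child_seed(config$seed, "impute"))
    } else {
      suppressWarnings(mice_impute(data, m = config$m,
                                   seed = child_seed(config$seed, "impute")))
    }
  })
  splits <- lapply(seq_len(stack$m), function(d)
    nested_splits(stack$data[[d]], folds = config$folds,
                  repeats = config$repeats,
                  seed = child_seed(config$seed, "split", d)))

  needs_en <- any(c("coxen", "coxsf") %in% config$roster)
  if (needs_en) {
    config$tuned <- stage("tuning", {
      train_sets <- lapply(seq_len(stack$m), function(d)
        split_train(stack$data[[d]], splits[[d]][[1]]))
      tune_coxnet(train_sets, seed = child_seed(config$seed, "tune"))
    })
  }
  if ("coxsf" %in% config$roster) {
    profile <- stage("stability", {
      train_sets <- lapply(seq_len(stack$m), function(d)
        split_train(stack$data[[d]], splits[[d]][[1]]))
      stability_select(train_sets, alpha = config$tuned$alpha,
                       lambda = config$tuned$lambda,
                       seed = child_seed(config$seed, "stability"))
    })
    config$coxsf_features <- stage("coxsf", {
      counts <- sort(unique(profile$dataset_pass), decreasing = TRUE)
      counts <- counts[counts >= max(1, ceiling(0.5 * stack$m))]
      cands <- consensus_candidates(profile, rev(counts))
      cands <- cands[!duplicated(vapply(cands, length, integer(1)))]
      if (length(cands) >= 2) {
        fin <- coxsf_finalize(stack$data, cands)
        config$coxsf_fit <- fin
        fin$features
      } else if (length(cands) == 1 && length(cands[[1]]) > 0) {
        cands[[1]]
      } else {
        rlang::warn("stability selection retained nothing; using all features")
        feature_cols(data)
      }
    })
  }

  report_rows <- list()
  curves <- list()
  stage("models", {
    for (d in seq_len(stack$m)) {
      sp <- splits[[d]][[1]]
      train <- split_train(stack$data[[d]], sp)
      test <- split_test(stack$data[[d]], sp)
      mm <- fit_minmax(train)
      train_n <- apply_minmax(train, mm)
      test_n <- apply_minmax(test, mm)
      attr(train_n, "feature_meta") <- feature_meta(data)
      attr(test_n, "feature_meta") <- feature_meta(data)
      for (mod in config$roster) {
        fitted <- fit_roster_model(mod, train_n, test_n, config, d)
        ev <- evaluate_scores(
          fitted$scores_test, test_n$time, test_n$event, config$horizons,
          B = config$bootstrap_B,
          seed = child_seed(config$seed, "boot", mod, d),
          train = tibble::tibble(score = fitted$scores_train,
                                 time = train_n$time, event = train_n$event))
        report_rows[[length(report_rows) + 1]] <-
          dplyr::mutate(ev, model = mod, dataset = d, .before = 1)
        if (!is.null(fitted$model))
          curves[[paste(mod, d, sep = "@")]] <- fitted$model
      }
    }
  })
  report <- dplyr::bind_rows(report_rows)
  comparison <- NULL
  uno <- dplyr::filter(report, .data$metric == "unos_c")
  if (length(unique(uno$model)) >= 2 && all(table(uno$model) >= 2))
    comparison <- compare_models(dplyr::select(uno, model = "model",
                                               dataset = "dataset",
                                               value = "value"))
  manifest <- list(
    config_hash = content_hash(unclass(config[c("n", "roster", "horizons",
                                                "m", "folds", "repeats",
                                                "scale", "seed")])),
    seed = config$seed, scale = config$scale,
    m = stack$m, n = nrow(data),
    roster = config$roster,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("tabsurv")),
    stage_seconds = timers,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    tuned = if (needs_en) list(alpha = config$tuned$alpha,
                               lambda = config$tuned$lambda),
    coxsf_features = config$coxsf_features)
  structure(list(report = report, comparison = comparison,
                 loss_curves = if (length(curves))
                   overfitting_curves(curves)$curves,
                 coxsf = config$coxsf_fit,
                 manifest = manifest),
            class = "experiment_result")
}

#' @exportS3Method base::print
print.experiment_result <- function(x, ...) {
  cat("tabsurv experiment:", length(unique(x$report$model)), "model(s),",
      length(unique(x$report$dataset)), "imputed dataset(s)\n")
  uno <- x$report %>% dplyr::filter(.data$metric == "unos_c") %>%
    dplyr::group_by(.data$model) %>%
    dplyr::summarise(unos_c = mean(.data$value), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$unos_c))
  print(uno)
  invisible(x)
}

#' Plot per-model metric summaries of an experiment
#' @param object An `experiment_result`.
#' @param metric Metric to plot (default `"unos_c"`).
#' @param ... Unused.
#' @export
autoplot.experiment_result <- function(object, metric = "unos_c", ...) {
  df <- dplyr::filter(object$report, .data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = metric, x = NULL) +
    ggplot2::theme_minimal()
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `impute`, `fit`, `evaluate`, `run`, `report`.
#' Flags: `--config PATH` (YAML), `--seed INT`, `--out DIR`,
#' `--models LIST`, `--horizons LIST`, `--m INT`, `--n INT`,
#' `--scale {full,desk}`. Returns the process exit code: 0 on success, 2 on
#' configuration errors, 1 on runtime failure.
#'
#' @param argv Character vector of arguments (default: the command line).
#' @return Integer exit code, invisibly.
#' @export
tabsurv_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tabsurv <simulate|impute|fit|evaluate|run|report> [options]",
    "  --config PATH   YAML experiment config",
    "  --seed INT      master seed (default 1)",
    "  --out DIR       output directory (default '.')",
    "  --models LIST   comma-separated roster",
    "  --horizons LIST comma-separated horizons (years)",
    "  --m INT         number of imputations",
    "  --n INT         cohort size for simulation",
    "  --scale S       full or desk (default desk)", sep = "\n")
  if (length(argv) == 0) { message(usage); return(invisible(2L)) }
  cmd <- argv[1]
  if (!cmd %in% c("simulate", "impute", "fit", "evaluate", "run", "report")) {
    message("unknown subcommand '", cmd, "'\n", usage); return(invisible(2L))
  }
  opts <- list(seed = 1L, out = ".", scale = "desk")
  i <- 2
  while (i <= length(argv)) {
    key <- argv[i]
    if (!grepl("^--", key) || i == length(argv)) {
      message("unknown or valueless flag '", key, "'\n", usage)
      return(invisible(2L))
    }
    val <- argv[i + 1]
    nm <- sub("^--", "", key)
    if (!nm %in% c("config", "seed", "out", "models", "horizons", "m", "n",
                   "scale")) {
      message("unknown flag '", key, "'\n", usage); return(invisible(2L))
    }
    opts[[nm]] <- val
    i <- i + 2
  }
  code <- tryCatch({
    if (!is.null(opts$config) && !file.exists(opts$config)) {
      message("config file not found: ", opts$config)
      return(invisible(2L))
    }
    dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(opts$seed)
    run_cfg <- function() {
      args <- if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
      if (!is.null(opts$models))
        args$roster <- strsplit(opts$models, ",")[[1]]
      if (!is.null(opts$horizons))
        args$horizons <- as.numeric(strsplit(opts$horizons, ",")[[1]])
      if (!is.null(opts$m)) args$m <- as.integer(opts$m)
      if (!is.null(opts$n)) args$n <- as.integer(opts$n)
      args$scale <- opts$scale
      args$seed <- seed
      do.call(experiment_config, args)
    }
    switch(cmd,
      simulate = {
        n <- as.integer(opts$n %||% 2000)
        write_survival_data(make_elsa_like(seed, n = n),
                            file.path(opts$out, "cohort.csv"))
        message("wrote ", file.path(opts$out, "cohort.csv"))
      },
      impute = {
        data <- read_survival_data(file.path(opts$out, "cohort.csv"))
        stack <- mice_impute(data, m = as.integer(opts$m %||% 5),
                             iterations = 5, seed = seed)
        write_imputed_stack(stack, file.path(opts$out, "imputed"))
        message("wrote ", file.path(opts$out, "imputed"))
      },
      report = {
        rp <- utils::read.csv(file.path(opts$out, "report.csv"))
        print(tibble::as_tibble(rp))
      },
      {
        # fit / evaluate / run all execute the experiment
        res <- run_experiment(run_cfg())
        utils::write.csv(as.data.frame(res$report),
                         file.path(opts$out, "report.csv"), row.names = FALSE)
        jsonlite::write_json(res$manifest,
                             file.path(opts$out, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, null = "null")
        message("wrote ", file.path(opts$out, "report.csv"))
      })
    0L
  }, tabsurv_error = function(e) { message(conditionMessage(e)); 1L },
     error = function(e) { message(conditionMessage(e)); 1L })
  invisible(code)
}
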