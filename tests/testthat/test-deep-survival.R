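test_that("Breslow loss matches hand-enumerated risk sets and the naive oracle", {
  # single subject with an event: log(exp(0)/exp(0)) = 0
  expect_equal(suppressWarnings(breslow_neg_log_pl(0, 1, 1)), 0)
  # two events, equal risks: first risk set has 2 members, second 1
  expect_equal(breslow_neg_log_pl(c(0, 0), c(1, 2), c(1, 1), normalize = FALSE),
               log(2))
  expect_warning(l0 <- breslow_neg_log_pl(c(1, 2), c(1, 2), c(0, 0)),
                 "no events")
  expect_equal(l0, 0)

  set.seed(100)
  for (r in 1:50) {
    n <- sample(2:8, 1)
    tt <- sample(1:4, n, replace = TRUE)   # ties injected
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[sample(n, 1)] <- 1
    h <- rnorm(n, sd = 2)
    for (norm in c(TRUE, FALSE))
      expect_equal(breslow_neg_log_pl(h, tt, ev, norm),
                   oracle_breslow(h, tt, ev, norm), tolerance = 1e-10)
    # shift invariance
    expect_equal(breslow_neg_log_pl(h + 37.5, tt, ev),
                 breslow_neg_log_pl(h, tt, ev), tolerance = 1e-8)
  }
})

test_that("censored subjects shape the loss only through risk-set membership", {
  h <- c(0.3, -0.2, 0.8, 0.1); tt <- c(1, 2, 3, 4); ev <- c(1, 1, 1, 0)
  base <- breslow_neg_log_pl(h, tt, ev, normalize = FALSE)
  # a censored subject observed LONGER than every event sits in every risk
  # set: removing it changes the loss
  drop_late <- breslow_neg_log_pl(h[-4], tt[-4], ev[-4], normalize = FALSE)
  expect_false(isTRUE(all.equal(base, drop_late)))
  # a censored subject observed SHORTER than every event joins no risk set:
  # adding or removing it leaves the loss unchanged
  h2 <- c(0.5, h); tt2 <- c(0.5, tt); ev2 <- c(0L, ev)
  expect_equal(breslow_neg_log_pl(h2, tt2, ev2, normalize = FALSE), base,
               tolerance = 1e-12)
})

test_that("loss gradient matches central finite differences", {
  set.seed(200)
  for (r in 1:10) {
    n <- sample(3:9, 1)
    tt <- sample(1:5, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.6); if (sum(ev) == 0) ev[1] <- 1
    h <- rnorm(n)
    g <- breslow_loss_grad(h, tt, ev)
    fd <- vapply(seq_len(n), function(i) {
      e <- 1e-6; hp <- h; hm <- h
      hp[i] <- h[i] + e; hm[i] <- h[i] - e
      (breslow_neg_log_pl(hp, tt, ev) - breslow_neg_log_pl(hm, tt, ev)) / (2 * e)
    }, numeric(1))
    expect_lt(max(abs(g - fd)), 1e-5)
  }
})

test_that("feedforward builder matches the closed-form parameter count and is deterministic", {
  spec <- network_spec("feedforward", seed = 4)
  m <- build_feedforward(spec, 91)
  expect_equal(count_params(m), 92 * 32 + 3 * (33 * 32) + 33)
  d <- make_mixed_cohort(n = 40, n_bin = 0, n_cont = 91)
  p1 <- predict(m, d); p2 <- predict(m, d)
  expect_identical(p1, p2)
  expect_length(p1, 40)
  expect_true(all(is.finite(p1)))
  expect_error(network_spec("feedforward", dropout_rate = 1.2), "dropout_rate")
})

test_that("densenet layer widths follow the concatenation arithmetic", {
  spec <- network_spec("densenet", seed = 4)
  m <- build_densenet(spec, 91)
  for (l in 1:4)
    expect_equal(nrow(m$params[[paste0("W", l)]]), 91 + 8 * (l - 1))
  expect_equal(nrow(m$params$W_out), 91 + 32)
  d <- make_mixed_cohort(n = 30, n_bin = 0, n_cont = 91)
  expect_identical(predict(m, d), predict(m, d))
})

test_that("tabtransformer has the stated geometry and is permutation-equivariant over tokens", {
  meta <- tibble::tibble(name = c("b1", "b2", "c1"),
                         kind = c("binary", "binary", "continuous"))
  spec <- network_spec("tabtransformer", seed = 6)
  m <- build_tabtransformer(spec, meta)
  # 2 categorical features -> token length 2, flattened width 2 * 64 = 128
  expect_equal(nrow(m$params$W_head), 2 * 64 + 1)
  expect_equal(dim(m$params$E_b1), c(2, 64))
  expect_equal(spec$embed_dim %% spec$n_heads, 0)

  d <- make_mixed_cohort(n = 25, n_bin = 2, n_cont = 1, seed = 9)
  names(d)[4:6] <- c("b1", "b2", "c1")
  attr(d, "feature_meta") <- meta
  p_ref <- predict(m, d)
  expect_identical(p_ref, predict(m, d))  # deterministic in eval mode

  # permute the categorical columns; re-index embeddings + head token blocks
  meta_p <- meta[c(2, 1, 3), ]
  m_p <- m
  m_p$info$cat_features <- c("b2", "b1")
  w <- m$params$W_head
  m_p$params$W_head <- rbind(w[65:128, , drop = FALSE],
                             w[1:64, , drop = FALSE],
                             w[129, , drop = FALSE])
  expect_equal(predict(m_p, d), p_ref, tolerance = 1e-6)

  # no categorical features degrades to an MLP with a warning
  meta_c <- tibble::tibble(name = "c1", kind = "continuous")
  expect_warning(m_c <- build_tabtransformer(spec, meta_c), "skipped")
  expect_length(predict(m_c, d), 25)
})

test_that("network parameter gradients agree with finite differences (all three architectures)", {
  meta <- tibble::tibble(name = c("b1", "b2", "c1", "c2"),
                         kind = c("binary", "binary", "continuous", "continuous"))
  d <- make_mixed_cohort(n = 12, n_bin = 2, n_cont = 2, seed = 14)
  names(d)[4:7] <- meta$name
  attr(d, "feature_meta") <- meta
  X <- as.matrix(d[, meta$name])
  models <- list(
    build_feedforward(network_spec("feedforward", hidden_width = 6, seed = 3,
                                   dropout_rate = 0, gaussian_noise_std = 0), 4),
    build_densenet(network_spec("densenet", growth_rate = 3, seed = 3,
                                dropout_rate = 0, gaussian_noise_std = 0), 4),
    build_tabtransformer(network_spec("tabtransformer", embed_dim = 8,
                                      n_transformer_layers = 2, n_heads = 2,
                                      ff_hidden = 12, head_width = 5, seed = 3,
                                      dropout_rate = 0, gaussian_noise_std = 0),
                         meta))
  for (m in models) {
    tape <- tabsurv:::new_tape()
    pn <- lapply(m$params, function(q) tabsurv:::tp_param(tape, q))
    Xm <- tabsurv:::net_feature_matrix(m, d)
    h <- tabsurv:::net_forward(m, Xm, tape, pn, training = FALSE)
    ln <- tabsurv:::tp_cox_loss(tape, h, d$time, d$event)
    tabsurv:::tape_backward(tape, ln)
    loss_at <- function(params) { m2 <- m; m2$params <- params
      tabsurv:::net_loss(m2, d) }
    set.seed(55)
    for (nm in names(m$params)) {
      g <- pn[[nm]]$grad
      expect_false(is.null(g), info = paste(m$architecture, nm))
      for (k in sample(length(m$params[[nm]]), min(2, length(m$params[[nm]])))) {
        e <- 1e-6
        qp <- m$params; qp[[nm]][k] <- qp[[nm]][k] + e
        qm <- m$params; qm[[nm]][k] <- qm[[nm]][k] - e
        fd <- (loss_at(qp) - loss_at(qm)) / (2 * e)
        expect_lt(abs(fd - g[k]), 1e-5)
      }
    }
  }
})

test_that("training reduces the loss, is seed-reproducible, and tracks overfitting curves", {
  d <- make_mixed_cohort(n = 120, n_bin = 3, n_cont = 3, seed = 18,
                         beta = c(0.6, -0.6, 0.3, 0.5, -0.5, 0))
  train <- d[1:90, ]; valid <- d[91:120, ]
  attr(train, "feature_meta") <- feature_meta(d)
  attr(valid, "feature_meta") <- feature_meta(d)
  spec <- network_spec("feedforward", epochs = 40, learning_rate = 0.01, seed = 5)
  m1 <- train_risk_model(build_feedforward(spec, 6), train, valid)
  m2 <- train_risk_model(build_feedforward(spec, 6), train, valid)
  h1 <- m1$history
  expect_identical(h1, m2$history)   # same seed, identical loss curves
  tr <- h1$loss[h1$split == "train"]
  expect_lt(tail(tr, 1), tr[1])
  expect_equal(nrow(h1), 40 * 2)     # one train + one validation entry per epoch

  oc <- overfitting_curves(list(ff = m1))
  expect_equal(nrow(oc$curves), 80)
  expect_true("gap" %in% names(oc$gap))
})

test_that("all three architectures satisfy the risk-model contract in one pipeline", {
  d <- make_mixed_cohort(n = 90, n_bin = 3, n_cont = 2, seed = 25,
                         beta = c(0.5, -0.5, 0, 0.4, 0))
  meta <- feature_meta(d)
  specs <- list(
    feedforward = build_feedforward(
      network_spec("feedforward", epochs = 3, seed = 1), nrow(meta)),
    densenet = build_densenet(
      network_spec("densenet", epochs = 3, seed = 1), nrow(meta)),
    tabtransformer = build_tabtransformer(
      network_spec("tabtransformer", embed_dim = 8, n_transformer_layers = 1,
                   n_heads = 2, epochs = 3, seed = 1), meta))
  for (nm in names(specs)) {
    m <- train_risk_model(specs[[nm]], d, epochs = 3)
    s <- predict(m, d)
    expect_length(s, nrow(d))
    expect_true(all(is.finite(s)), info = nm)
  }
})
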