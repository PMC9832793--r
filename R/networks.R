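#' Architecture and training settings for a survival network
#'
#' Defaults follow the study design this package implements: 4 hidden layers
#' of 32 SELU units with dropout 0.2 and additive Gaussian noise for the
#' feedforward net; a 4-layer dense block with growth rate 8; a transformer
#' stack of 6 layers with 8 heads over 64-dimensional categorical embeddings;
#' Adam with learning rate 1e-4. The Gaussian noise standard deviation is not
#' part of that design and defaults to 0.1.
#'
#' @param architecture `"feedforward"`, `"densenet"` or `"tabtransformer"`.
#' @param hidden_width,n_hidden Feedforward hidden layer size / count.
#' @param dropout_rate Dropout probability in `[0, 1)`.
#' @param gaussian_noise_std Train-time additive noise SD.
#' @param growth_rate Features emitted by each dense layer (densenet).
#' @param embed_dim,n_transformer_layers,n_heads Transformer geometry;
#'   `embed_dim` must be divisible by `n_heads`.
#' @param ff_hidden Width of the transformer feed-forward sublayer
#'   (default `2 * embed_dim`).
#' @param head_width Hidden width of the MLP head after the transformer.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_mode `"full"` (exact partial-likelihood risk sets) or
#'   `"risk-set-batched"` (random batches, risk sets formed within each).
#' @param batch_size Batch size for `"risk-set-batched"`.
#' @param patience Optional early-stopping patience on validation loss.
#' @param grad_clip Global gradient-norm clip (`Inf` disables).
#' @param warmup_epochs Linear learning-rate warmup over the first epochs
#'   (standard stabilizer for attention stacks; 0 disables).
#' @param seed Seed for initialization and train-time stochasticity.
#' @return A `network_spec` object.
#' @export
network_spec <- function(architecture = c("feedforward", "densenet", "tabtransformer"),
                         hidden_width = 32, n_hidden = 4, dropout_rate = 0.2,
                         gaussian_noise_std = 0.1, growth_rate = 8,
                         embed_dim = 64, n_transformer_layers = 6, n_heads = 8,
                         ff_hidden = NULL, head_width = 32,
                         learning_rate = 1e-4, epochs = 300,
                         batch_mode = c("full", "risk-set-batched"),
                         batch_size = 256, patience = NULL, grad_clip = 5,
                         warmup_epochs = 2, seed = 1L) {
  architecture <- match.arg(architecture)
  batch_mode <- match.arg(batch_mode)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_tabsurv("invalid spec field `dropout_rate`: must be in [0, 1)")
  if (embed_dim %% n_heads != 0)
    stop_tabsurv("invalid spec field `embed_dim`: must be divisible by n_heads")
  for (f in c("hidden_width", "n_hidden", "growth_rate", "embed_dim",
              "n_transformer_layers", "n_heads", "head_width", "epochs",
              "batch_size"))
    if (get(f) <= 0) stop_tabsurv("invalid spec field `", f, "`: must be positive")
  structure(list(
    architecture = architecture, hidden_width = hidden_width,
    n_hidden = n_hidden, dropout_rate = dropout_rate,
    gaussian_noise_std = gaussian_noise_std, growth_rate = growth_rate,
    embed_dim = embed_dim, n_transformer_layers = n_transformer_layers,
    n_heads = n_heads, ff_hidden = ff_hidden %||% (2L * embed_dim),
    head_width = head_width, learning_rate = learning_rate, epochs = epochs,
    batch_mode = batch_mode, batch_size = batch_size, patience = patience,
    grad_clip = grad_clip, warmup_epochs = warmup_epochs,
    seed = as.integer(seed)), class = "network_spec")
}

lecun_init <- function(nr, nc) matrix(rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)

new_risk_network <- function(arch, spec, params, info) {
  structure(list(architecture = arch, spec = spec, params = params,
                 info = info, history = NULL, trained = FALSE),
            class = "risk_network")
}

#' Build an untrained feedforward survival network
#'
#' Four fully connected SELU hidden layers of 32 units, each followed (at
#' train time) by dropout and additive Gaussian noise, and a single linear
#' output node that estimates the log-risk.
#'
#' @param spec A [network_spec()] with `architecture = "feedforward"`.
#' @param n_features Number of input features.
#' @return An untrained `risk_network`.
#' @export
build_feedforward <- function(spec, n_features) {
  stopifnot(inherits(spec, "network_spec"), n_features >= 1)
  with_rng(child_seed(spec$seed, "init", "feedforward"), {
    w <- spec$hidden_width
    params <- list()
    fan <- n_features
    for (l in seq_len(spec$n_hidden)) {
      params[[paste0("W", l)]] <- lecun_init(fan, w)
      params[[paste0("b", l)]] <- matrix(0, 1, w)
      fan <- w
    }
    params$W_out <- lecun_init(w, 1)
    params$b_out <- matrix(0, 1, 1)
    new_risk_network("feedforward", spec, params, list(n_features = n_features))
  })
}

#' Build an untrained densely connected survival network
#'
#' A 4-layer dense block: layer `l` receives the input concatenated with all
#' previous layers' outputs and emits `growth_rate` new features; the final
#' concatenation feeds the single linear Cox output node. Activation,
#' dropout and noise policy match the feedforward network.
#'
#' @param spec A [network_spec()] with `architecture = "densenet"`.
#' @inheritParams build_feedforward
#' @return An untrained `risk_network`.
#' @export
build_densenet <- function(spec, n_features) {
  stopifnot(inherits(spec, "network_spec"), n_features >= 1)
  with_rng(child_seed(spec$seed, "init", "densenet"), {
    g <- spec$growth_rate
    params <- list()
    for (l in seq_len(spec$n_hidden)) {
      fan <- n_features + g * (l - 1)
      params[[paste0("W", l)]] <- lecun_init(fan, g)
      params[[paste0("b", l)]] <- matrix(0, 1, g)
    }
    params$W_out <- lecun_init(n_features + g * spec$n_hidden, 1)
    params$b_out <- matrix(0, 1, 1)
    new_risk_network("densenet", spec, params, list(n_features = n_features))
  })
}

#' Build an untrained TabTransformer survival network
#'
#' Each categorical (binary) feature gets a learned per-level embedding of
#' dimension `embed_dim`, tied to the column's identity. The token sequence
#' passes through `n_transformer_layers` transformer layers (multi-head
#' self-attention and a feed-forward sublayer, each with residual connection
#' and layer normalization). Contextual embeddings are flattened and
#' concatenated with layer-normalized continuous features; an MLP head feeds
#' the single linear Cox output node. With no categorical features the model
#' degrades to an MLP on the continuous block, with a warning.
#'
#' @param spec A [network_spec()] with `architecture = "tabtransformer"`.
#' @param feature_meta Tibble with columns `name` and `kind`
#'   (`"continuous"`/`"binary"`), as from [feature_meta()].
#' @return An untrained `risk_network`.
#' @export
build_tabtransformer <- function(spec, feature_meta) {
  stopifnot(inherits(spec, "network_spec"))
  cat_feats <- feature_meta$name[feature_meta$kind == "binary"]
  cont_feats <- feature_meta$name[feature_meta$kind == "continuous"]
  d <- spec$embed_dim
  if (length(cat_feats) == 0)
    rlang::warn("no categorical features: transformer stack skipped, using an MLP on the continuous block")
  with_rng(child_seed(spec$seed, "init", "tabtransformer"), {
    params <- list()
    for (f in cat_feats)
      params[[paste0("E_", f)]] <- matrix(rnorm(2 * d, sd = 0.05), 2, d)
    if (length(cat_feats) > 0) {
      for (l in seq_len(spec$n_transformer_layers)) {
        pfx <- paste0("L", l, "_")
        for (nm in c("Wq", "Wk", "Wv", "Wo"))
          params[[paste0(pfx, nm)]] <- lecun_init(d, d)
        for (nm in c("bq", "bk", "bv", "bo"))
          params[[paste0(pfx, nm)]] <- matrix(0, 1, d)
        params[[paste0(pfx, "ln1_g")]] <- matrix(1, 1, d)
        params[[paste0(pfx, "ln1_b")]] <- matrix(0, 1, d)
        params[[paste0(pfx, "W1")]] <- lecun_init(d, spec$ff_hidden)
        params[[paste0(pfx, "b1")]] <- matrix(0, 1, spec$ff_hidden)
        params[[paste0(pfx, "W2")]] <- lecun_init(spec$ff_hidden, d)
        params[[paste0(pfx, "b2")]] <- matrix(0, 1, d)
        params[[paste0(pfx, "ln2_g")]] <- matrix(1, 1, d)
        params[[paste0(pfx, "ln2_b")]] <- matrix(0, 1, d)
      }
    }
    if (length(cont_feats) > 0) {
      params$cont_ln_g <- matrix(1, 1, length(cont_feats))
      params$cont_ln_b <- matrix(0, 1, length(cont_feats))
    }
    head_in <- length(cat_feats) * d + length(cont_feats)
    params$W_head <- lecun_init(head_in, spec$head_width)
    params$b_head <- matrix(0, 1, spec$head_width)
    params$W_out <- lecun_init(spec$head_width, 1)
    params$b_out <- matrix(0, 1, 1)
    new_risk_network("tabtransformer", spec, params,
                     list(cat_features = cat_feats, cont_features = cont_feats,
                          n_features = nrow(feature_meta)))
  })
}

#' Number of learnable parameters of a network
#' @param model A `risk_network`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) sum(vapply(model$params, length, integer(1)))

# dropout + gaussian noise applied to a hidden activation (train time only)
regularize_node <- function(tape, node, spec, training) {
  if (!training) return(node)
  if (spec$dropout_rate > 0) {
    keep <- 1 - spec$dropout_rate
    mask <- matrix(rbinom(length(node$value), 1, keep) / keep,
                   nrow(node$value), ncol(node$value))
    node <- tp_mul_const(tape, node, mask)
  }
  if (spec$gaussian_noise_std > 0) {
    noise <- matrix(rnorm(length(node$value), sd = spec$gaussian_noise_std),
                    nrow(node$value), ncol(node$value))
    node <- tp_add_const(tape, node, noise)
  }
  node
}

dense_layer <- function(tape, x, pnodes, wname, bname, spec, training,
                        activation = TRUE) {
  z <- tp_bias(tape, tp_matmul(tape, x, pnodes[[wname]]), pnodes[[bname]])
  if (activation) z <- tp_selu(tape, z)
  regularize_node(tape, z, spec, training)
}

forward_feedforward <- function(model, X, tape, pnodes, training) {
  h <- tp_const(tape, X)
  for (l in seq_len(model$spec$n_hidden))
    h <- dense_layer(tape, h, pnodes, paste0("W", l), paste0("b", l),
                     model$spec, training)
  tp_bias(tape, tp_matmul(tape, h, pnodes$W_out), pnodes$b_out)
}

forward_densenet <- function(model, X, tape, pnodes, training) {
  acc <- list(tp_const(tape, X))
  for (l in seq_len(model$spec$n_hidden)) {
    inp <- if (length(acc) == 1) acc[[1]] else tp_cbind(tape, acc)
    out <- dense_layer(tape, inp, pnodes, paste0("W", l), paste0("b", l),
                       model$spec, training)
    acc <- c(acc, list(out))
  }
  final <- tp_cbind(tape, acc)
  tp_bias(tape, tp_matmul(tape, final, pnodes$W_out), pnodes$b_out)
}

# reshape (B*T) x d token matrix (subject-major blocks) to B x (T*d), with
# token-major column layout (column (t-1)*d + k holds token t, channel k)
tp_flatten_tokens <- function(tape, a, B, T_, d) {
  val <- matrix(aperm(array(a$value, c(T_, B, d)), c(2, 3, 1)), B, T_ * d)
  tp_node(tape, val, list(a), function(g) {
    tp_accum(a, matrix(aperm(array(g, c(B, d, T_)), c(3, 1, 2)), B * T_, d))
  })
}

forward_tabtransformer <- function(model, X, tape, pnodes, training) {
  spec <- model$spec
  cat_feats <- model$info$cat_features
  cont_feats <- model$info$cont_features
  B <- nrow(X)
  parts <- list()
  if (length(cat_feats) > 0) {
    d <- spec$embed_dim; H <- spec$n_heads; dh <- d %/% H
    T_ <- length(cat_feats)
    # fused embedding lookup, already subject-major: rows (b-1)*T + t
    levels <- (X[, cat_feats, drop = FALSE] != 0) + 0L
    x <- tp_embed(tape, levels, lapply(cat_feats, function(f)
      pnodes[[paste0("E_", f)]]))
    for (l in seq_len(spec$n_transformer_layers)) {
      pfx <- paste0("L", l, "_")
      o <- tp_attention(tape, x,
                        pnodes[[paste0(pfx, "Wq")]], pnodes[[paste0(pfx, "bq")]],
                        pnodes[[paste0(pfx, "Wk")]], pnodes[[paste0(pfx, "bk")]],
                        pnodes[[paste0(pfx, "Wv")]], pnodes[[paste0(pfx, "bv")]],
                        H, T_)
      o <- tp_bias(tape, tp_matmul(tape, o, pnodes[[paste0(pfx, "Wo")]]), pnodes[[paste0(pfx, "bo")]])
      x <- tp_layernorm(tape, tp_add(tape, x, o),
                        pnodes[[paste0(pfx, "ln1_g")]], pnodes[[paste0(pfx, "ln1_b")]])
      ffn <- tp_selu(tape, tp_bias(tape, tp_matmul(tape, x, pnodes[[paste0(pfx, "W1")]]),
                                   pnodes[[paste0(pfx, "b1")]]))
      ffn <- tp_bias(tape, tp_matmul(tape, ffn, pnodes[[paste0(pfx, "W2")]]),
                     pnodes[[paste0(pfx, "b2")]])
      x <- tp_layernorm(tape, tp_add(tape, x, ffn),
                        pnodes[[paste0(pfx, "ln2_g")]], pnodes[[paste0(pfx, "ln2_b")]])
    }
    parts <- c(parts, list(tp_flatten_tokens(tape, x, B, T_, d)))
  }
  if (length(cont_feats) > 0) {
    xc <- tp_const(tape, X[, cont_feats, drop = FALSE])
    parts <- c(parts, list(tp_layernorm(tape, xc, pnodes$cont_ln_g, pnodes$cont_ln_b)))
  }
  inp <- if (length(parts) == 1) parts[[1]] else tp_cbind(tape, parts)
  h <- tp_selu(tape, tp_bias(tape, tp_matmul(tape, inp, pnodes$W_head), pnodes$b_head))
  h <- regularize_node(tape, h, spec, training)
  tp_bias(tape, tp_matmul(tape, h, pnodes$W_out), pnodes$b_out)
}

net_forward <- function(model, X, tape, pnodes, training = FALSE) {
  switch(model$architecture,
         feedforward = forward_feedforward(model, X, tape, pnodes, training),
         densenet = forward_densenet(model, X, tape, pnodes, training),
         tabtransformer = forward_tabtransformer(model, X, tape, pnodes, training))
}

net_feature_matrix <- function(model, data) {
  if (model$architecture == "tabtransformer") {
    cols <- c(model$info$cat_features, model$info$cont_features)
    m <- as.matrix(data[, cols, drop = FALSE])
  } else {
    m <- feature_matrix(data)
  }
  if (anyNA(m)) stop_tabsurv("network input must be complete (impute first)")
  m
}

#' Predict log-risk scores
#'
#' Evaluation mode: dropout and noise are off, so predictions are
#' deterministic.
#'
#' @param object A `risk_network`.
#' @param newdata A data frame containing the feature columns.
#' @param ... Unused.
#' @return Numeric vector of log-risks, one per row.
#' @export
predict.risk_network <- function(object, newdata, ...) {
  X <- net_feature_matrix(object, newdata)
  chunk <- if (object$architecture == "tabtransformer") 512L else nrow(X)
  starts <- seq(1, nrow(X), by = chunk)
  out <- lapply(starts, function(s0) {
    idx <- s0:min(s0 + chunk - 1, nrow(X))
    tape <- new_tape()
    pnodes <- lapply(object$params, function(p) tp_const(tape, p))
    as.numeric(net_forward(object, X[idx, , drop = FALSE], tape, pnodes,
                           training = FALSE)$value)
  })
  unlist(out)
}

net_loss <- function(model, data, normalize = TRUE) {
  h <- predict(model, data)
  suppressWarnings(breslow_neg_log_pl(h, data$time, data$event, normalize))
}

#' Train a survival network with the Breslow partial-likelihood loss
#'
#' Minimizes [breslow_neg_log_pl()] by Adam. `batch_mode = "full"` computes
#' the exact loss over the full training risk sets once per epoch;
#' `"risk-set-batched"` partitions the subjects into random batches anew
#' each epoch and forms risk sets within each batch, sorted by follow-up
#' time (an approximation that trades exactness for more optimizer steps).
#' Training and validation losses are recorded each
#' epoch in evaluation mode. Fully deterministic under the `network_spec()` seed.
#'
#' @param model An untrained `risk_network`.
#' @param train Training `survival_dataset` (complete features).
#' @param valid Optional validation dataset for loss tracking/early stopping.
#' @param epochs,learning_rate Optional overrides of the spec.
#' @param verbose Print a line every 25 epochs.
#' @return The trained `risk_network`, with a `history` tibble
#'   (`epoch`, `split`, `loss`).
#' @export
train_risk_model <- function(model, train, valid = NULL, epochs = NULL,
                             learning_rate = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "risk_network"))
  if (sum(train$event) < 1) stop_tabsurv("training data has no events")
  spec <- model$spec
  epochs <- epochs %||% spec$epochs
  lr <- learning_rate %||% spec$learning_rate
  X <- net_feature_matrix(model, train)
  tt <- train$time; ev <- train$event
  params <- model$params
  m_adam <- lapply(params, function(p) p * 0)
  v_adam <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  full_batch <- spec$batch_mode == "full"
  n_tr <- nrow(X)
  hist_rows <- list()
  batch_losses <- list()
  best <- Inf; wait <- 0L
  with_rng(child_seed(spec$seed, "train"), {
    for (ep in seq_len(epochs)) {
      batches <- if (full_batch) list(seq_len(n_tr)) else {
        # fresh random partition each epoch; risk sets form within each
        # batch (the loss sorts by time internally)
        split(sample.int(n_tr), ceiling(seq_len(n_tr) / spec$batch_size))
      }
      for (idx in batches) {
        if (sum(ev[idx]) == 0) next
        tape <- new_tape()
        pnodes <- lapply(params, function(p) tp_param(tape, p))
        h <- net_forward(model, X[idx, , drop = FALSE], tape, pnodes,
                         training = TRUE)
        loss_node <- tp_cox_loss(tape, h, tt[idx], ev[idx], normalize = TRUE)
        if (!is.finite(loss_node$value[1]))
          stop_tabsurv("non-finite training loss at epoch ", ep)
        batch_losses[[length(batch_losses) + 1]] <- loss_node$value[1]
        tape_backward(tape, loss_node)
        step <- step + 1L
        lr_t <- lr * if (spec$warmup_epochs %||% 0 > 0)
          min(1, ep / (spec$warmup_epochs + 1)) else 1
        clip <- spec$grad_clip %||% Inf
        if (is.finite(clip)) {
          gnorm <- sqrt(sum(vapply(pnodes, function(p)
            if (is.null(p$grad)) 0 else sum(p$grad^2), numeric(1))))
          if (gnorm > clip)
            for (nm in names(params))
              if (!is.null(pnodes[[nm]]$grad))
                pnodes[[nm]]$grad <- pnodes[[nm]]$grad * (clip / gnorm)
        }
        for (nm in names(params)) {
          g <- pnodes[[nm]]$grad
          if (is.null(g)) next
          m_adam[[nm]] <- b1 * m_adam[[nm]] + (1 - b1) * g
          v_adam[[nm]] <- b2 * v_adam[[nm]] + (1 - b2) * g^2
          mhat <- m_adam[[nm]] / (1 - b1^step)
          vhat <- v_adam[[nm]] / (1 - b2^step)
          params[[nm]] <- params[[nm]] - lr_t * mhat / (sqrt(vhat) + eps)
        }
      }
      model$params <- params
      tr_loss <- if (spec$batch_mode == "full") net_loss(model, train)
                 else mean(unlist(batch_losses))
      batch_losses <- list()
      hist_rows[[length(hist_rows) + 1]] <-
        tibble::tibble(epoch = ep, split = "train", loss = tr_loss)
      if (!is.null(valid)) {
        va_loss <- net_loss(model, valid)
        hist_rows[[length(hist_rows) + 1]] <-
          tibble::tibble(epoch = ep, split = "validation", loss = va_loss)
        if (!is.null(spec$patience)) {
          if (va_loss < best - 1e-8) { best <- va_loss; wait <- 0L }
          else { wait <- wait + 1L; if (wait >= spec$patience) break }
        }
      }
      if (verbose && ep %% 25 == 0)
        message(sprintf("[%s] epoch %d loss %.4f", model$architecture, ep, tr_loss))
    }
  })
  model$params <- params
  model$history <- dplyr::bind_rows(hist_rows)
  model$trained <- TRUE
  model
}

#' Tidy per-epoch loss curves for overfitting assessment
#'
#' @param models A named list of trained `risk_network`s (names become the
#'   model labels), or a single model.
#' @return List with `curves`, a tibble (`model`, `epoch`, `split`, `loss`),
#'   and `gap`, a tibble of each model's final validation-minus-train loss.
#' @export
overfitting_curves <- function(models) {
  if (inherits(models, "risk_network")) models <- list(model = models)
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m$architecture, character(1))
  curves <- dplyr::bind_rows(lapply(names(models), function(nm) {
    h <- models[[nm]]$history
    if (is.null(h)) stop_tabsurv("model '", nm, "' has no training history")
    dplyr::mutate(h, model = nm, .before = 1)
  }))
  gap <- curves %>%
    dplyr::group_by(.data$model) %>%
    dplyr::filter(.data$epoch == max(.data$epoch)) %>%
    tidyr::pivot_wider(names_from = "split", values_from = "loss") %>%
    dplyr::ungroup()
  if ("validation" %in% names(gap))
    gap$gap <- gap$validation - gap$train
  list(curves = curves, gap = gap)
}

#' Plot training/validation loss curves
#' @param object Output of [overfitting_curves()] or a trained model list.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_network <- function(object, ...) {
  stopifnot(!is.null(object$history))
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = paste(object$architecture, "training"),
                  y = "Breslow partial-likelihood loss") +
    ggplot2::theme_minimal()
}

#' @rdname overfitting_curves
#' @param curves The `curves` tibble from [overfitting_curves()].
#' @export
plot_loss_curves <- function(curves) {
  if (is.list(curves) && !is.data.frame(curves)) curves <- curves$curves
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                       colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~model, scales = "free_y") +
    ggplot2::theme_minimal()
}
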