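# A minimal reverse-mode tape over dense matrices, sized for the three
# survival networks. Each node holds a value, its parents, and a backward
# closure that scatters the incoming gradient to the parents. Parameters are
# leaf nodes flagged `param`; `tape_backward()` accumulates their gradients.
#
# Not exported: the networks are the public surface.

new_tape <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env
}

tp_node <- function(tape, value, parents = list(), backward = NULL,
                    param = FALSE) {
  # force the arguments BEFORE claiming an id: `value` may itself build
  # nested nodes on the tape (R evaluates arguments lazily)
  force(value); force(parents); force(backward)
  id <- length(tape$nodes) + 1L
  node <- new.env(parent = emptyenv())
  node$id <- id
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$param <- param
  node$grad <- NULL
  tape$nodes[[id]] <- node
  node
}

tp_const <- function(tape, value) tp_node(tape, value)
tp_param <- function(tape, value) tp_node(tape, value, param = TRUE)

tp_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

tape_backward <- function(tape, loss_node) {
  loss_node$grad <- matrix(1, 1, 1)
  for (i in rev(seq_along(tape$nodes))) {
    node <- tape$nodes[[i]]
    if (!is.null(node$grad) && !is.null(node$backward)) node$backward(node$grad)
  }
}

tp_matmul <- function(tape, a, b) {
  tp_node(tape, a$value %*% b$value, list(a, b), function(g) {
    tp_accum(a, tcrossprod(g, b$value))
    tp_accum(b, crossprod(a$value, g))
  })
}

# add a 1 x k bias row to every row of a
tp_bias <- function(tape, a, bias) {
  tp_node(tape,
          a$value + rep(as.numeric(bias$value), each = nrow(a$value)),
          list(a, bias),
          function(g) {
            tp_accum(a, g)
            tp_accum(bias, matrix(colSums(g), 1))
          })
}

tp_add <- function(tape, a, b) {
  tp_node(tape, a$value + b$value, list(a, b), function(g) {
    tp_accum(a, g); tp_accum(b, g)
  })
}

# elementwise product with a constant matrix (dropout masks, noise gates)
tp_mul_const <- function(tape, a, m) {
  tp_node(tape, a$value * m, list(a), function(g) tp_accum(a, g * m))
}

tp_add_const <- function(tape, a, m) {
  tp_node(tape, a$value + m, list(a), function(g) tp_accum(a, g))
}

tp_scale <- function(tape, a, s) {
  tp_node(tape, a$value * s, list(a), function(g) tp_accum(a, g * s))
}

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

tp_selu <- function(tape, a) {
  val <- selu_fwd(a$value)
  tp_node(tape, val, list(a), function(g) {
    tp_accum(a, selu_bwd(val, g))
  })
}

tp_rows <- function(tape, a, idx) {
  tp_node(tape, a$value[idx, , drop = FALSE], list(a), function(g) {
    full <- matrix(0, nrow(a$value), ncol(a$value))
    full[idx, ] <- g
    tp_accum(a, full)
  })
}

tp_cols <- function(tape, a, idx) {
  tp_node(tape, a$value[, idx, drop = FALSE], list(a), function(g) {
    full <- matrix(0, nrow(a$value), ncol(a$value))
    full[, idx] <- g
    tp_accum(a, full)
  })
}

tp_rbind <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) n$value)
  nr <- vapply(vals, nrow, integer(1))
  offs <- cumsum(c(0L, nr[-length(nr)]))
  tp_node(tape, do.call(rbind, vals), nodes, function(g) {
    for (i in seq_along(nodes))
      tp_accum(nodes[[i]], g[(offs[i] + 1):(offs[i] + nr[i]), , drop = FALSE])
  })
}

tp_cbind <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) n$value)
  nc <- vapply(vals, ncol, integer(1))
  offs <- cumsum(c(0L, nc[-length(nc)]))
  tp_node(tape, do.call(cbind, vals), nodes, function(g) {
    for (i in seq_along(nodes))
      tp_accum(nodes[[i]], g[, (offs[i] + 1):(offs[i] + nc[i]), drop = FALSE])
  })
}

# row-wise softmax (attention weights over the token axis)
tp_softmax_rows <- function(tape, a) {
  x <- a$value
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  p <- e / rowSums(e)
  tp_node(tape, p, list(a), function(g) {
    tp_accum(a, p * (g - rowSums(g * p)))
  })
}

# row-wise layer normalization with learned gain/shift (1 x k each)
tp_layernorm <- function(tape, a, gain, shift, eps = 1e-5) {
  fw <- layernorm_fwd(a$value, as.numeric(gain$value),
                      as.numeric(shift$value), eps)
  tp_node(tape, fw$val, list(a, gain, shift), function(g) {
    bw <- layernorm_bwd(g, fw$xhat, fw$inv, as.numeric(gain$value))
    tp_accum(a, bw$gx)
    tp_accum(gain, matrix(bw$ggain, 1))
    tp_accum(shift, matrix(bw$gshift, 1))
  })
}

# batched block products via the compiled kernel; groups stacked vertically
tp_bmm <- function(tape, a, b, groups, op = c("nt", "nn")) {
  op <- match.arg(op)
  code <- if (op == "nt") 0L else 1L
  val <- bmm_blocks(a$value, b$value, groups, code)
  tp_node(tape, val, list(a, b), function(g) {
    if (op == "nt") {
      # out = A B^T : dA = g B ; dB = g^T A (per block)
      tp_accum(a, bmm_blocks(g, b$value, groups, 1L))
      tp_accum(b, bmm_blocks(g, a$value, groups, 2L))
    } else {
      # out = A B : dA = g B^T ; dB = A^T g (per block)
      tp_accum(a, bmm_blocks(g, b$value, groups, 0L))
      tp_accum(b, bmm_blocks(a$value, g, groups, 2L))
    }
  })
}

# terminal node: Breslow negative log partial likelihood of a column of
# log-risks; hand-coded gradient (validated against finite differences)
tp_cox_loss <- function(tape, h, times, events, normalize = TRUE) {
  hv <- as.numeric(h$value)
  val <- suppressWarnings(breslow_neg_log_pl(hv, times, events, normalize))
  tp_node(tape, matrix(val, 1, 1), list(h), function(g) {
    tp_accum(h, matrix(breslow_loss_grad(hv, times, events, normalize) *
                         as.numeric(g), ncol = 1))
  })
}

# fused multi-head self-attention (compiled kernel); parents: the token
# matrix and the six projection parameters
tp_attention <- function(tape, x, wq, bq, wk, bk, wv, bv, H, T_) {
  fw <- attn_forward(x$value, wq$value, as.numeric(bq$value),
                     wk$value, as.numeric(bk$value),
                     wv$value, as.numeric(bv$value), H, T_)
  tp_node(tape, fw$O, list(x, wq, bq, wk, bk, wv, bv), function(g) {
    bw <- attn_backward(g, fw$Q, fw$K, fw$V, x$value,
                        wq$value, wk$value, wv$value, H, T_)
    tp_accum(x, bw$gX)
    tp_accum(wq, bw$gWq); tp_accum(bq, matrix(bw$gbq, 1))
    tp_accum(wk, bw$gWk); tp_accum(bk, matrix(bw$gbk, 1))
    tp_accum(wv, bw$gWv); tp_accum(bv, matrix(bw$gbv, 1))
  })
}

# fused per-column embedding lookup: levels is a B x T 0/1 matrix, embeds a
# list of 2 x d parameter nodes (one per categorical column); the output is
# the subject-major (B*T) x d token stack
tp_embed <- function(tape, levels, embeds) {
  B <- nrow(levels); T_ <- ncol(levels)
  d <- ncol(embeds[[1]]$value)
  val <- matrix(0, B * T_, d)
  for (t in seq_len(T_)) {
    idx <- (seq_len(B) - 1L) * T_ + t
    val[idx, ] <- embeds[[t]]$value[levels[, t] + 1L, , drop = FALSE]
  }
  tp_node(tape, val, embeds, function(g) {
    for (t in seq_len(T_)) {
      idx <- (seq_len(B) - 1L) * T_ + t
      gt <- g[idx, , drop = FALSE]
      lev1 <- levels[, t] == 1
      ge <- rbind(colSums(gt[!lev1, , drop = FALSE]),
                  colSums(gt[lev1, , drop = FALSE]))
      tp_accum(embeds[[t]], ge)
    }
  })
}
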