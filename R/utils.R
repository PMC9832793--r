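# Internal helpers: deterministic seed fan-out and RNG isolation.
#
# Every stochastic operation draws its seed from a single master seed through
# a named child stream, so any stage of a run can be replayed in isolation.

# Deterministic child seed from a master seed and a path of labels.
# Kept strictly below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, ...) {
  label <- paste(c(...), collapse = "/")
  h <- 0
  for (cc in utf8ToInt(label)) h <- (h * 131 + cc) %% 2147483587
  as.integer((abs(as.numeric(seed)) %% 2147483587 * 48271 + h * 69621 + 11) %%
               2147483587 + 1)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_rng <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tabsurv <- function(...) rlang::abort(paste0(...), class = "tabsurv_error")

# log-sum-exp of a numeric vector, stable
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  all(x %in% c(0, 1))
}

# Simple stable content hash (FNV-1a over the serialized object), hex string.
content_hash <- function(object) {
  bytes <- as.integer(serialize(object, NULL, ascii = TRUE))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
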