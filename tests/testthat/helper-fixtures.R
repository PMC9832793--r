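# Shared fixtures, all built in code under fixed seeds.

# small complete survival dataset with a known linear hazard
make_linear_cohort <- function(n = 500, beta = c(0.8, -0.8, 0.5, -0.5, 0),
                               seed = 1, censor = 12, scale = 0.03) {
  cfg <- sim_config(n_subjects = n, n_continuous = length(beta), n_binary = 0,
                    beta = beta, baseline_scale = scale,
                    admin_censor_time = censor, seed = seed)
  simulate_survival(simulate_covariates(cfg), cfg)
}

# tiny mixed-type dataset for network shape tests
make_mixed_cohort <- function(n = 80, n_bin = 4, n_cont = 3, seed = 2,
                              beta = NULL) {
  cfg <- sim_config(n_subjects = n, n_continuous = n_cont, n_binary = n_bin,
                    beta = beta %||% rep(0, n_cont + n_bin),
                    baseline_scale = 0.1, admin_censor_time = 12, seed = seed)
  simulate_survival(simulate_covariates(cfg), cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Breslow loss: explicit risk-set enumeration
oracle_breslow <- function(h, tt, ev, normalize = TRUE) {
  s <- 0
  for (i in which(ev == 1)) {
    rs <- which(tt >= tt[i])
    s <- s - (h[i] - log(sum(exp(h[rs]))))
  }
  if (normalize) s / sum(ev) else s
}

# brute-force concordance: all-pairs double loop
oracle_harrell <- function(s, tt, ev) {
  num <- 0; den <- 0
  n <- length(s)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    usable <- (tt[i] < tt[j] && ev[i] == 1) ||
      (tt[i] == tt[j] && ev[i] == 1 && ev[j] == 0)
    if (!usable) next
    den <- den + 1
    if (s[i] > s[j]) num <- num + 1
    else if (s[i] == s[j]) num <- num + 0.5
  }
  if (den == 0) NA_real_ else num / den
}

# plain binary ROC / AUC oracle for the uncensored reduction
oracle_binary_roc <- function(scores, label, cutoffs) {
  se <- vapply(cutoffs, function(c) mean(scores[label == 1] > c), numeric(1))
  sp <- vapply(cutoffs, function(c) mean(scores[label == 0] <= c), numeric(1))
  list(se = se, sp = sp)
}

oracle_binary_auc <- function(scores, label) {
  pos <- scores[label == 1]; neg <- scores[label == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}
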