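#' Negative log Breslow-approximation Cox partial likelihood
#'
#' The training loss of the survival networks and the objective matched by
#' the Cox baselines. For log-risks `h`, observed times `t` and event
#' indicators `d`,
#' `L = -sum over events i of [ h_i - log sum_{j: t_j >= t_i} exp(h_j) ]`,
#' where tied event times share the full risk set (Breslow approximation).
#' Computed with log-sum-exp stabilization. With `normalize = TRUE`
#' (default) the loss is divided by the number of events so its scale does
#' not depend on the batch size.
#'
#' @param log_risks Numeric vector of log-risk scores.
#' @param times Follow-up times.
#' @param events 0/1 event indicators.
#' @param normalize Divide by the number of events (default `TRUE`).
#' @return Scalar loss. A batch with zero events returns 0 with a warning.
#' @export
breslow_neg_log_pl <- function(log_risks, times, events, normalize = TRUE) {
  stopifnot(length(log_risks) == length(times),
            length(times) == length(events))
  d <- sum(events)
  if (d == 0) {
    rlang::warn("batch contains no events; loss is uninformative (0)")
    return(0)
  }
  ord <- order(times, decreasing = TRUE)
  h <- log_risks[ord]; tt <- times[ord]; ev <- events[ord]
  m <- max(h)
  cum <- cumsum(exp(h - m))          # prefix over descending time
  # risk set of time t = all j with t_j >= t: last index of each tie group
  last_of_group <- cummax_by_time(tt)
  log_denom <- m + log(cum[last_of_group])
  loss <- -sum((h - log_denom)[ev == 1])
  if (normalize) loss / d else loss
}

# For times sorted in decreasing order, index of the last element of each
# element's tie group (so cum[idx] sums exp(h) over all t_j >= t_i).
cummax_by_time <- function(tt_desc) {
  runs <- rle(tt_desc)
  ends <- cumsum(runs$lengths)
  rep(ends, runs$lengths)
}

#' Gradient of the Breslow loss with respect to the log-risks
#'
#' `dL/dh_i = -(d_i - exp(h_i) * sum over event times s <= t_i of d_s / S_s)`
#' with `S_s` the risk-set sum of `exp(h)` at event time `s` (divided by the
#' event count when `normalize = TRUE`). Used by the network training loop;
#' validated against central finite differences in the test suite.
#'
#' @inheritParams breslow_neg_log_pl
#' @return Numeric gradient vector, same length as `log_risks`.
#' @export
breslow_loss_grad <- function(log_risks, times, events, normalize = TRUE) {
  d_tot <- sum(events)
  if (d_tot == 0) return(rep(0, length(log_risks)))
  ord <- order(times, decreasing = TRUE)
  h <- log_risks[ord]; tt <- times[ord]; ev <- events[ord]
  n <- length(h)
  m <- max(h)
  eh <- exp(h - m)
  cum <- cumsum(eh)
  last <- cummax_by_time(tt)
  s <- cum[last] # scaled risk-set sums, aligned to each subject's time
  # events grouped by tie group: d_s / S_s accumulated over event times
  # with t_s <= t_i  <=>  positions at or after i in descending order
  contrib <- ifelse(ev == 1, 1 / s, 0)
  # subject i is in the risk set of event s iff t_i >= t_s, i.e. s at or
  # after i's tie-group start. Accumulate suffix sums then align per group.
  suffix <- rev(cumsum(rev(contrib)))
  first <- first_of_group(tt)
  g <- eh * suffix[first]
  grad_sorted <- -(ev - g)
  grad <- numeric(n)
  grad[ord] <- grad_sorted
  if (normalize) grad / d_tot else grad
}

first_of_group <- function(tt_desc) {
  runs <- rle(tt_desc)
  starts <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  rep(starts, runs$lengths)
}
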