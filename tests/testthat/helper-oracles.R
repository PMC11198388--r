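# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force (enumeration, direct likelihood evaluation)
# rather than calling package internals.

# all permutations of 1..n (simple recursion; n <= 8 in tests)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# exact permutation distribution of T = sum(g * a[pi])
perm_enum_oracle <- function(g, a) {
  pm <- all_perms(length(a))
  vals <- apply(pm, 1, function(pp) sum(g * a[pp]))
  list(mean = mean(vals),
       var = sum((vals - mean(vals))^2) / length(vals),
       vals = vals)
}

# direct O(n^2) Cox log partial likelihood (Breslow or Efron ties)
cox_ll_bruteforce <- function(beta, x, time, event, ties = "efron") {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(event == 1 & time == t)
    risk <- which(time >= t)
    d <- length(dead)
    s0r <- sum(exp(eta[risk]))
    s0d <- sum(exp(eta[dead]))
    ll <- ll + sum(eta[dead])
    for (k in seq_len(d) - 1) {
      frac <- if (ties == "efron") k / d else 0
      ll <- ll - log(s0r - frac * s0d)
    }
  }
  ll
}

# random right-censored sample with events and censorings interleaved
random_censored_sample <- function(n, event_rate = 0.3, censor_rate = 0.2) {
  t_event <- rexp(n, event_rate)
  t_cens <- rexp(n, censor_rate)
  list(time = pmin(t_event, t_cens),
       event = as.integer(t_event <= t_cens))
}
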