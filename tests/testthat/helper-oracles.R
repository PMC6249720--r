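# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Direct Riemann-sum quadrature of the CWT integral with the sampled Morlet
# wavelet: coef(a, tau_j) = dt / sqrt(a) * sum_i x_i Psi*((t_i - tau_j)/a).
riemann_cwt <- function(x, fs, scales, omega0 = 6) {
  n <- length(x)
  dt <- 1 / fs
  tt <- (0:(n - 1)) * dt
  psi <- function(u) pi^(-0.25) * exp(1i * omega0 * u) * exp(-u^2 / 2)
  out <- matrix(0 + 0i, length(scales), n)
  for (s in seq_along(scales)) {
    for (j in seq_len(n)) {
      out[s, j] <- sum(x * Conj(psi((tt - tt[j]) / scales[s]))) * dt / sqrt(scales[s])
    }
  }
  out
}

# Minimum expected code length over all prefix-free binary codes, by
# exhaustive top-down partitioning (every split adds one bit to each symbol
# in the subtree): cost(S) = freq(S) + min over bipartitions cost(A)+cost(B).
min_prefix_code_cost <- function(freq) {
  n <- length(freq)
  memo <- new.env()
  cost <- function(idx) {
    if (length(idx) == 1) return(0)
    key <- paste(idx, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- Inf
    rest <- idx[-1]
    # enumerate bipartitions; fix idx[1] in A to avoid double counting
    for (mask in 0:(2^length(rest) - 1)) {
      a <- c(idx[1], rest[bitwAnd(mask, 2^(seq_along(rest) - 1)) > 0])
      b <- setdiff(idx, a)
      if (length(b) == 0) next
      best <- min(best, cost(a) + cost(b))
    }
    memo[[key]] <- best + sum(freq[idx])
    best + sum(freq[idx])
  }
  cost(seq_len(n))
}

# ROC AUC as the pairwise concordance statistic (ties count 1/2).
concordance_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  total <- 0
  for (p in sp) total <- total + sum(p > sn) + 0.5 * sum(p == sn)
  total / (length(sp) * length(sn))
}

# Small multi-channel record with one seizure, cheap enough for unit tests.
tiny_record <- function(seed = 1, fs = 64, duration_s = 20, n_channels = 2,
                        interval = c(0.3, 0.6) * duration_s) {
  generate_record(synth_config(fs = fs, n_channels = n_channels,
                               duration_s = duration_s,
                               ictal_intervals = rbind(interval),
                               seed = seed),
                  record_id = sprintf("tiny-%d", seed))
}

# Fast wavelet settings for pipeline-level tests.
tiny_wavelet <- function() wavelet_config(n_scales = 12, freq_min_hz = 1)
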