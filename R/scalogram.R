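#' Wavelet configuration for scalogram computation
#'
#' @param mother Mother wavelet; only `"morlet"` is implemented. `"morse"`
#'   and `"bump"` are recognised names but raise an unsupported error.
#' @param omega0 Morlet centre-frequency parameter (dimensionless,
#'   default 6) -- the standard trade-off between time and frequency
#'   localisation. The pseudo-frequency of scale `a` is
#'   `f = omega0 / (2 * pi * a)`.
#' @param n_scales Number of scales (>= 2, default 32).
#' @param freq_min_hz,freq_max_hz Pseudo-frequency range; `freq_max_hz = NULL`
#'   means the Nyquist frequency `fs/2` at transform time.
#' @param scale_spacing `"log"` (default) or `"linear"` spacing of the
#'   pseudo-frequency grid.
#' @return An object of class `wavelet_config`.
#' @export
wavelet_config <- function(mother = c("morlet", "morse", "bump"), omega0 = 6,
                           n_scales = 32, freq_min_hz = 1, freq_max_hz = NULL,
                           scale_spacing = c("log", "linear")) {
  mother <- match.arg(mother)
  scale_spacing <- match.arg(scale_spacing)
  if (mother != "morlet") {
    stop(sprintf("mother wavelet '%s' is not supported by this backend; use 'morlet'",
                 mother))
  }
  if (n_scales < 2) stop("n_scales must be >= 2")
  if (freq_min_hz <= 0) stop("freq_min_hz must be positive")
  if (!is.null(freq_max_hz) && freq_min_hz >= freq_max_hz) {
    stop("freq_min_hz must be below freq_max_hz")
  }
  structure(list(mother = mother, omega0 = omega0,
                 n_scales = as.integer(n_scales),
                 freq_min_hz = freq_min_hz, freq_max_hz = freq_max_hz,
                 scale_spacing = scale_spacing),
            class = "wavelet_config")
}

# Complex Morlet wavelet sampled at (dimensionless) argument u.
morlet_psi <- function(u, omega0) {
  pi^(-0.25) * exp(1i * omega0 * u) * exp(-u^2 / 2)
}

# Frequency grid and the matching scales for a given sampling rate.
cwt_freq_grid <- function(cfg, fs) {
  fmax <- if (is.null(cfg$freq_max_hz)) fs / 2 else cfg$freq_max_hz
  if (fmax > fs / 2 + 1e-9) stop("freq_max_hz exceeds the Nyquist frequency")
  if (cfg$freq_min_hz >= fmax) stop("freq_min_hz must be below freq_max_hz")
  freqs <- switch(cfg$scale_spacing,
    log = exp(seq(log(cfg$freq_min_hz), log(fmax), length.out = cfg$n_scales)),
    linear = seq(cfg$freq_min_hz, fmax, length.out = cfg$n_scales)
  )
  list(freqs = freqs, scales = cfg$omega0 / (2 * pi * freqs))
}

# FFT kernels for the cross-correlation form of the CWT:
#   coef[s, j] = dt / sqrt(a_s) * sum_i x[i] Conj(psi((t_i - t_j) / a_s)).
# Kernels cover lags -(n-1)..(n-1), i.e. exact linear correlation with the
# zero-padded signal (no truncation of the wavelet support within the
# record), wrapped into an FFT of length L >= 2n - 1.
cwt_kernels <- function(n, fs, cfg) {
  g <- cwt_freq_grid(cfg, fs)
  L <- 2^ceiling(log2(max(2 * n, 4)))
  dt <- 1 / fs
  m <- c(0:(n - 1), -(L - n):-1)      # lag of each wrapped FFT bin
  keep <- abs(m) <= n - 1
  K <- matrix(0 + 0i, nrow = L, ncol = cfg$n_scales)
  for (s in seq_along(g$scales)) {
    a <- g$scales[s]
    v <- complex(length.out = L)
    v[keep] <- Conj(morlet_psi(-m[keep] * dt / a, cfg$omega0))
    K[, s] <- stats::fft(v) * dt / sqrt(a)
  }
  list(K = K, L = L, freqs = g$freqs, scales = g$scales)
}

apply_cwt_kernels <- function(x, ker) {
  n <- length(x)
  xf <- stats::fft(c(x, rep(0, ker$L - n)))
  cf <- ker$K * xf
  # inverse FFT column-wise; mvfft(inverse) returns unnormalised transform
  full <- stats::mvfft(cf, inverse = TRUE) / ker$L
  coefs <- t(full[seq_len(n), , drop = FALSE])
  attr(coefs, "scales") <- ker$scales
  attr(coefs, "freqs") <- ker$freqs
  coefs
}

#' Continuous wavelet transform of a single-channel fragment
#'
#' Computes Morlet CWT coefficients
#' `CWT(a, tau) = a^{-1/2} * integral x(t) Psi*((t - tau)/a) dt`
#' on the discrete time grid, one row per scale, evaluated at every sample
#' position tau. The integral is discretised as a Riemann sum over the
#' sampled record (zero outside its support) and computed exactly by FFT
#' cross-correlation; rows are ordered by increasing pseudo-frequency.
#'
#' @param x Numeric sample vector (length >= 2, no NA/NaN).
#' @param fs Sampling rate in Hz.
#' @param cfg A [wavelet_config()].
#' @return Complex matrix `n_scales x length(x)` with attributes `scales`
#'   (dilation values) and `freqs` (pseudo-frequency per row, Hz).
#' @export
cwt_transform <- function(x, fs, cfg = wavelet_config()) {
  if (!is.numeric(x) || length(x) < 2) stop("x must be a numeric vector of length >= 2")
  if (anyNA(x) || any(!is.finite(x))) stop("x contains NA/NaN/Inf; reject before transforming")
  stopifnot(inherits(cfg, "wavelet_config"))
  apply_cwt_kernels(x, cwt_kernels(length(x), fs, cfg))
}

#' Scalogram: squared magnitude of CWT coefficients
#'
#' @param coeffs Complex coefficient matrix from [cwt_transform()].
#' @return An `eeg_scalogram`: list with `power` (non-negative matrix,
#'   rows ordered by frequency), `scales`, `freqs`.
#' @export
scalogram_power <- function(coeffs) {
  if (any(!is.finite(Re(coeffs))) || any(!is.finite(Im(coeffs)))) {
    stop("coefficients must be finite")
  }
  structure(list(power = matrix(Mod(coeffs)^2, nrow(coeffs)),
                 scales = attr(coeffs, "scales"),
                 freqs = attr(coeffs, "freqs")),
            class = "eeg_scalogram")
}

# contiguous, near-equal index groups for mean pooling
pool_groups <- function(n, k) {
  cuts <- floor(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(g) (cuts[g] + 1):cuts[g + 1])
}

#' Pool and normalize a scalogram into a fixed-size vector
#'
#' Mean-pools the power matrix onto a `rows x cols` grid, flattens it
#' row-major, then min-max normalizes the result into `[0, 1]` per fragment
#' so it can feed the sigmoid/cross-entropy denoising autoencoders. A
#' constant scalogram (max == min) maps to the all-zero vector with a
#' warning rather than dividing by zero.
#'
#' @param s An `eeg_scalogram` (or a bare numeric matrix of powers).
#' @param grid Integer pair `c(rows, cols)`; both must not exceed the
#'   scalogram dimensions. Default 16 x 16 (vector length 256).
#' @return A `scalogram_vector`: list with `values` (in `[0,1]`) and `grid`.
#' @export
vectorize_scalogram <- function(s, grid = c(16, 16)) {
  power <- if (inherits(s, "eeg_scalogram")) s$power else s
  stopifnot(is.matrix(power))
  grid <- as.integer(grid)
  if (length(grid) != 2 || any(grid < 1)) stop("grid must be two positive integers")
  if (grid[1] > nrow(power) || grid[2] > ncol(power)) {
    stop("grid dimensions must not exceed the scalogram dimensions")
  }
  rg <- pool_groups(nrow(power), grid[1])
  cg <- pool_groups(ncol(power), grid[2])
  pooled <- matrix(0, grid[1], grid[2])
  for (i in seq_len(grid[1])) {
    sub <- power[rg[[i]], , drop = FALSE]
    cm <- colMeans(sub)
    for (j in seq_len(grid[2])) pooled[i, j] <- mean(cm[cg[[j]]])
  }
  v <- as.vector(t(pooled))  # row-major flatten
  rng <- range(v)
  if (rng[2] - rng[1] < .Machine$double.eps * max(1, abs(rng[2]))) {
    warning("constant scalogram: returning all-zero vector")
    v <- rep(0, length(v))
  } else {
    v <- (v - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(values = v, grid = grid), class = "scalogram_vector")
}

#' Scalogram vectors for a collection of fragments
#'
#' Computes, per channel, the pooled/normalized scalogram vector of every
#' fragment, reusing one set of FFT wavelet kernels across all fragments.
#'
#' @param fragments List of fragments (all with identical channel count and
#'   window length) from [segment_record()].
#' @param fs Sampling rate in Hz.
#' @param cfg A [wavelet_config()].
#' @param grid Pooling grid passed to [vectorize_scalogram()].
#' @return List with `per_channel` (list over channels of
#'   `n_fragments x (rows*cols)` matrices) and `concat`
#'   (`n_fragments x (C*rows*cols)` matrix of all-channel concatenations).
#' @export
scalogram_features <- function(fragments, fs, cfg = wavelet_config(),
                               grid = c(16, 16)) {
  stopifnot(length(fragments) > 0)
  C <- nrow(fragments[[1]]$samples)
  n <- ncol(fragments[[1]]$samples)
  ker <- cwt_kernels(n, fs, cfg)
  d <- prod(grid)
  per_channel <- lapply(seq_len(C), function(c) matrix(0, length(fragments), d))
  for (i in seq_along(fragments)) {
    for (c in seq_len(C)) {
      coefs <- apply_cwt_kernels(fragments[[i]]$samples[c, ], ker)
      sv <- suppressWarnings(vectorize_scalogram(scalogram_power(coefs), grid))
      per_channel[[c]][i, ] <- sv$values
    }
  }
  list(per_channel = per_channel, concat = do.call(cbind, per_channel))
}
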