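# Daubechies filters and the maximal-overlap (non-decimated) wavelet transform.
# Implemented here because the band-power mapping onto physiological LF/HF
# bands needs direct access to the filter cascade.

#' Daubechies scaling (lowpass) filter
#'
#' Generates the extremal-phase Daubechies scaling filter with `p` vanishing
#' moments (2p taps) by spectral factorization of the half-band polynomial:
#' the binomial polynomial P(y) is rooted with [polyroot()], each root mapped
#' to its minimum-modulus z-plane partner, and the filter assembled as
#' (1+z)^p times the minimum-phase root product, normalised to sum sqrt(2).
#'
#' @param p Number of vanishing moments (filter has `2p` taps). The filter the
#'   field labels "db12" corresponds to `p = 12`.
#' @return Numeric vector of length `2p`; sums to `sqrt(2)`, unit energy.
#' @examples
#' g <- daubechies_filter(4)
#' sum(g)       # sqrt(2)
#' sum(g^2)     # 1
#' @export
daubechies_filter <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 1, p <= 20, p == round(p))
  p <- as.integer(p)
  if (p == 1L) return(rep(1 / sqrt(2), 2L))
  k <- 0:(p - 1L)
  Pc <- choose(p - 1L + k, k)          # P(y), ascending powers
  yr <- polyroot(Pc)
  zr <- complex(0)
  for (y0 in yr) {
    # y = (2 - z - 1/z)/4  =>  z^2 - (2 - 4 y) z + 1 = 0
    b <- 2 - 4 * y0
    disc <- sqrt(b^2 - 4 + 0i)
    z1 <- (b + disc) / 2
    z2 <- (b - disc) / 2
    zr <- c(zr, if (Mod(z1) < 1) z1 else z2)
  }
  coefs <- 1 + 0i
  for (i in seq_len(p)) coefs <- .poly_mult(coefs, c(1, 1))
  for (z0 in zr) coefs <- .poly_mult(coefs, c(-z0, 1))
  g <- Re(coefs)
  g * sqrt(2) / sum(g)
}

.poly_mult <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- rep(0 + 0i, n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Quadrature-mirror wavelet (highpass) filter from a scaling filter
#' @param g Scaling filter.
#' @return Wavelet filter of the same length.
#' @keywords internal
qmf <- function(g) {
  L <- length(g)
  (-1)^(0:(L - 1L)) * rev(g)
}

# circular filtering with a filter upsampled by `up` (zeros inserted):
# y_t = sum_l f_l x_{t - up*(l-1) mod M}
.circ_filter <- function(x, f, up) {
  M <- length(x)
  y <- numeric(M)
  idx0 <- seq_len(M) - 1L
  for (l in seq_along(f)) {
    s <- (as.integer(up) * (l - 1L)) %% M
    y <- y + f[l] * x[((idx0 - s) %% M) + 1L]
  }
  y
}

#' MODWT wavelet-packet band powers
#'
#' Decomposes a uniformly sampled series with the shift-invariant (maximal
#' overlap) discrete wavelet transform and attributes coefficient variances to
#' the requested frequency bands. The dyadic tree is refined adaptively: any
#' node whose nominal band straddles a target band edge is split further
#' (sequency-ordered wavelet packet), so a sinusoid close to a dyadic band
#' edge is not mis-attributed by the quadrature-mirror 50/50 split. Terminal
#' node variances are mapped to bands by fractional overlap of the node's
#' nominal band with each target band.
#'
#' Boundary handling: the series is mean-detrended and reflected to twice its
#' length, filtering is circular, and coefficients whose filter support
#' reaches back across the reflection junction are excluded from variances
#' whenever the level's support leaves any interior coefficient (at depths
#' where the support exceeds the window every coefficient is kept). Packet
#' depth is capped so the cumulative filter support fits the reflected series.
#'
#' @param x Numeric series (uniform sampling).
#' @param fs_hz Sampling rate in Hz.
#' @param bands Named list of `c(lo, hi)` band edges in Hz.
#' @param p Daubechies vanishing moments (default 12, the "db12" filter).
#' @param max_level Maximum packet depth (default 6; additionally capped by
#'   filter support).
#' @return Named numeric vector of band powers (variance units of `x`).
#' @export
modwt_band_power <- function(x, fs_hz, bands, p = 12L, max_level = 6L) {
  stopifnot(is.numeric(x), length(x) >= 32L, fs_hz > 0)
  if (is.null(names(bands)) || any(!nzchar(names(bands))))
    stop("`bands` must be a named list of c(lo, hi) pairs")
  for (b in bands) {
    if (length(b) != 2L || b[1] < 0 || b[2] <= b[1] || b[2] > fs_hz / 2)
      stop("band edges must satisfy 0 <= lo < hi <= fs/2")
  }
  g <- daubechies_filter(p) / sqrt(2)   # MODWT-rescaled filters
  h <- qmf(g * sqrt(2)) / sqrt(2)
  L <- length(g)

  N <- length(x)
  xr <- c(x, rev(x))
  xr <- xr - mean(xr)
  M <- length(xr)

  # deepest level whose cumulative support (2^j - 1)(L - 1) + 1 stays within
  # twice the reflected length; variance estimates degrade gracefully once the
  # support exceeds the window, and one extra refinement level is worth more
  # than it costs for tones near dyadic edges
  support_ok <- function(j) (2^j - 1) * (L - 1) + 1 <= 2 * M
  jmax <- 0L
  while (support_ok(jmax + 1L)) jmax <- jmax + 1L
  if (jmax < 3L)
    stop("window too short for the filter support at the depth the bands require")
  jmax <- min(jmax, as.integer(max_level))

  edges <- sort(unique(unlist(bands)))
  straddles <- function(a, b) any(edges > a + 1e-12 & edges < b - 1e-12)

  powers <- stats::setNames(numeric(length(bands)), names(bands))
  assign_var <- function(v, a, b) {
    for (nm in names(bands)) {
      lo <- bands[[nm]][1]; hi <- bands[[nm]][2]
      ov <- max(0, min(hi, b) - max(lo, a)) / (b - a)
      powers[[nm]] <<- powers[[nm]] + v * ov
    }
  }
  node_var <- function(coef, j) {
    Lj <- (2^j - 1) * (L - 1) + 1
    keep <- if (Lj < N) Lj:N else seq_len(N)
    mean(coef[keep]^2)
  }

  # stack of packet nodes: coefficients, depth, band [a,b] Hz, sequency flip
  stack <- list(list(c = xr, j = 0L, a = 0, b = fs_hz / 2, flip = FALSE))
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    terminal <- nd$j > 0L && (nd$j >= jmax || !straddles(nd$a, nd$b))
    if (terminal) {
      ov_any <- any(vapply(bands, function(bb)
        min(bb[2], nd$b) > max(bb[1], nd$a), logical(1)))
      if (ov_any) assign_var(node_var(nd$c, nd$j), nd$a, nd$b)
      next
    }
    lo <- .circ_filter(nd$c, g, 2^nd$j)
    hi <- .circ_filter(nd$c, h, 2^nd$j)
    mid <- (nd$a + nd$b) / 2
    if (!nd$flip) {
      stack[[length(stack) + 1L]] <- list(c = lo, j = nd$j + 1L, a = nd$a, b = mid, flip = nd$flip)
      stack[[length(stack) + 1L]] <- list(c = hi, j = nd$j + 1L, a = mid, b = nd$b, flip = !nd$flip)
    } else {
      stack[[length(stack) + 1L]] <- list(c = lo, j = nd$j + 1L, a = mid, b = nd$b, flip = nd$flip)
      stack[[length(stack) + 1L]] <- list(c = hi, j = nd$j + 1L, a = nd$a, b = mid, flip = !nd$flip)
    }
  }
  powers
}

#' Welch periodogram band powers
#'
#' Welch-averaged modified periodogram, used as the Fourier cross-check for
#' the wavelet band powers. Hann-tapered segments with 50\% overlap; the
#' one-sided PSD integrates to the series variance, so a sinusoid of amplitude
#' A contributes A^2/2 to its band.
#'
#' @param x Numeric series.
#' @param fs_hz Sampling rate (Hz).
#' @param bands Named list of `c(lo, hi)` edges in Hz.
#' @param nseg Segment length (default `min(256, length(x))`).
#' @return Named numeric vector of band powers.
#' @export
welch_band_power <- function(x, fs_hz, bands, nseg = min(256L, length(x))) {
  ps <- welch_psd(x, fs_hz, nseg = nseg)
  df <- ps$freq[2] - ps$freq[1]
  vapply(bands, function(b) {
    sel <- ps$freq >= b[1] & ps$freq < b[2]
    sum(ps$psd[sel]) * df
  }, numeric(1))
}

#' Welch power spectral density
#' @inheritParams welch_band_power
#' @return List with `freq` (Hz) and `psd` (one-sided density).
#' @export
welch_psd <- function(x, fs_hz, nseg = min(256L, length(x))) {
  stopifnot(length(x) >= 16L, fs_hz > 0)
  nseg <- min(as.integer(nseg), length(x))
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1L)) / (nseg - 1L))  # Hann
  U <- sum(w^2)
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    pxx <- (Mod(X)^2) / (fs_hz * U)
    scale2 <- rep(2, nfreq)
    scale2[1] <- 1
    if (nseg %% 2L == 0L) scale2[nfreq] <- 1
    acc <- acc + pxx * scale2
  }
  list(freq = (0:(nfreq - 1L)) * fs_hz / nseg, psd = acc / length(starts))
}
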