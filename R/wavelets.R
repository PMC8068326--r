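# Filter banks for the four supported wavelets. Standard published
# decomposition/reconstruction coefficients (orthogonal: haar, db2, sym2;
# biorthogonal: bior1.3). sym2 and db2 coincide at this filter length.

.SQRT2I <- 1 / sqrt(2)

.WAVELET_FILTERS <- list(
  haar = list(
    dec_lo = c(.SQRT2I, .SQRT2I),
    dec_hi = c(-.SQRT2I, .SQRT2I),
    rec_lo = c(.SQRT2I, .SQRT2I),
    rec_hi = c(.SQRT2I, -.SQRT2I)
  ),
  db2 = list(
    dec_lo = c(-0.12940952255126037, 0.22414386804201339,
               0.83651630373780790, 0.48296291314453416),
    dec_hi = c(-0.48296291314453416, 0.83651630373780790,
               -0.22414386804201339, -0.12940952255126037),
    rec_lo = c(0.48296291314453416, 0.83651630373780790,
               0.22414386804201339, -0.12940952255126037),
    rec_hi = c(-0.12940952255126037, -0.22414386804201339,
               0.83651630373780790, -0.48296291314453416)
  ),
  bior1.3 = list(
    dec_lo = c(-0.08838834764831845, 0.08838834764831845, .SQRT2I, .SQRT2I,
               0.08838834764831845, -0.08838834764831845),
    dec_hi = c(0, 0, -.SQRT2I, .SQRT2I, 0, 0),
    rec_lo = c(0, 0, .SQRT2I, .SQRT2I, 0, 0),
    rec_hi = c(-0.08838834764831845, -0.08838834764831845, .SQRT2I, -.SQRT2I,
               0.08838834764831845, 0.08838834764831845)
  )
)
.WAVELET_FILTERS$sym2 <- .WAVELET_FILTERS$db2

#' Supported wavelet names
#'
#' The four wavelet families used for level-1 stationary decomposition:
#' `"haar"`, `"sym2"`, `"db2"` and `"bior1.3"`.
#'
#' @return Character vector of supported wavelet names.
#' @export
supported_wavelets <- function() c("haar", "sym2", "db2", "bior1.3")

#' Filter bank for a supported wavelet
#'
#' Returns the analysis and synthesis filters together with the group delay
#' of the combined analysis/synthesis cascade, which the inverse transform
#' compensates so that reconstruction is exact under periodic extension.
#'
#' @param wavelet One of [supported_wavelets()].
#' @return List with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` (numeric filters)
#'   and `delay` (integer, samples).
#' @export
swt_filters <- function(wavelet) {
  if (!is.character(wavelet) || length(wavelet) != 1L ||
      !(wavelet %in% supported_wavelets())) {
    stop("unsupported wavelet: ", paste(wavelet, collapse = ", "),
         " (supported: ", paste(supported_wavelets(), collapse = ", "), ")",
         call. = FALSE)
  }
  f <- .WAVELET_FILTERS[[wavelet]]
  # combined lowpass+highpass cascade must be 2*delta at lag `delay`
  p <- .conv_full(f$dec_lo, f$rec_lo) + .conv_full(f$dec_hi, f$rec_hi)
  delay <- which.max(abs(p)) - 1L
  stopifnot(abs(p[delay + 1L] - 2) < 1e-12, sum(abs(p[-(delay + 1L)])) < 1e-12)
  c(f, list(delay = delay, wavelet = wavelet))
}

# plain full linear convolution of two short filters
.conv_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Circular convolution of every column of matrix `x` with filter `h`:
# y[i, ] = sum_j h[j] * x[(i - j) mod n + 1, ], j = 0 .. L-1 (0-based lags).
# FFT-based; filter taps folded modulo n so short signals remain correct.
.circ_filter_cols <- function(x, h) {
  n <- nrow(x)
  hp <- numeric(n)
  for (j in seq_along(h)) {
    k <- (j - 1L) %% n + 1L
    hp[k] <- hp[k] + h[j]
  }
  Re(stats::mvfft(stats::mvfft(x) * stats::fft(hp), inverse = TRUE)) / n
}

# circularly shift columns of x down by s (s may be negative)
.circ_shift_cols <- function(x, s) {
  n <- nrow(x)
  s <- ((s %% n) + n) %% n
  if (s == 0) return(x)
  x[c((n - s + 1L):n, 1L:(n - s)), , drop = FALSE]
}
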