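# Flat-spectrum luminance sequences and circular lag machinery.
#
# Each memorized item is tagged by a flickering disk whose luminance follows a
# 5 s noise sequence with equal Fourier power at every nonzero frequency. The
# Leader sequence is drawn fresh per trial; Follower sequences are exact
# circular time-shifts of it (200 ms in the two-item design, 150/300 ms in the
# three-item design), so the only difference between conditions is temporal
# lag, never spectral content.

#' Luminance sequence objects
#'
#' A `lum_sequence` is a frame-by-frame luminance trace in cd/m^2 together
#' with the frame rate, the sequence role (`"Leader"`, `"Follower1"` or
#' `"Follower2"`) and its nominal lag in milliseconds relative to the Leader.
#'
#' @param samples Numeric vector of luminance values in cd/m^2.
#' @param frame_rate Frames per second (default 100, a CRT/LCD refresh rate).
#' @param role One of `"Leader"`, `"Follower1"`, `"Follower2"`.
#' @param lag_ms Nominal lag in ms relative to the Leader; 0 for the Leader.
#'   Must be a nonnegative integer multiple of the frame duration.
#' @return An object of class `lum_sequence`.
#' @export
lum_sequence <- function(samples, frame_rate = 100, role = "Leader", lag_ms = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 1, is.finite(samples))
  role <- match.arg(role, c("Leader", "Follower1", "Follower2"))
  frame_ms <- 1000 / frame_rate
  if (lag_ms < 0 || abs(lag_ms / frame_ms - round(lag_ms / frame_ms)) > 1e-9) {
    stop("lag_ms must be a nonnegative integer multiple of the frame duration (",
         frame_ms, " ms)")
  }
  structure(
    list(samples = as.numeric(samples), frame_rate = frame_rate,
         role = role, lag_ms = lag_ms),
    class = "lum_sequence"
  )
}

#' @export
print.lum_sequence <- function(x, ...) {
  cat(sprintf("<lum_sequence> %s, %d frames @ %g Hz, lag %g ms, range [%.3f, %.3f] cd/m^2\n",
              x$role, length(x$samples), x$frame_rate, x$lag_ms,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.lum_sequence <- function(x) length(x$samples)

#' Generate a flat-power-spectrum luminance sequence
#'
#' Draws Gaussian white noise, normalizes the amplitude of every nonzero
#' Fourier component to a common constant while preserving phases (the DC
#' component keeps the pre-normalization mean), inverse-transforms, and
#' min-max rescales the result to `[lum_min, lum_max]`. The output has
#' identical Fourier amplitude at every nonzero frequency bin; the rescaling
#' is affine, so flatness survives it exactly (only the DC bin changes).
#'
#' @param n_frames Number of frames (>= 4); the default 500 is 5 s at 100 Hz.
#' @param lum_min,lum_max Luminance range in cd/m^2 (defaults 0 and 15).
#' @param frame_rate Frames per second (default 100).
#' @param seed Optional integer seed; a fresh random phase spectrum per call
#'   otherwise.
#' @return A `lum_sequence` with role `"Leader"` and lag 0.
#' @examples
#' leader <- generate_flat_spectrum_sequence(seed = 1)
#' range(leader$samples)
#' @export
generate_flat_spectrum_sequence <- function(n_frames = 500, lum_min = 0,
                                            lum_max = 15, frame_rate = 100,
                                            seed = NULL) {
  if (!is.numeric(n_frames) || length(n_frames) != 1 || n_frames < 4 ||
      n_frames != round(n_frames)) {
    stop("n_frames must be a single integer >= 4")
  }
  if (!is.numeric(lum_min) || !is.numeric(lum_max) || lum_min >= lum_max) {
    stop("degenerate luminance range: lum_min must be strictly below lum_max")
  }
  if (!is.null(seed)) set.seed(seed)
  z <- stats::rnorm(n_frames)
  spec <- stats::fft(z)
  amp <- Mod(spec)
  nz <- seq_len(n_frames)[-1]
  # Unit amplitude at every nonzero bin, phases untouched; conjugate symmetry
  # of the real input is preserved, so the inverse transform is real.
  flat <- spec
  safe <- amp[nz] > 0
  flat[nz][safe] <- spec[nz][safe] / amp[nz][safe]
  flat[nz][!safe] <- 1
  y <- Re(stats::fft(flat, inverse = TRUE)) / n_frames
  y <- (y - min(y)) / (max(y) - min(y)) * (lum_max - lum_min) + lum_min
  lum_sequence(y, frame_rate = frame_rate, role = "Leader", lag_ms = 0)
}

#' Circularly shift a luminance sequence
#'
#' Shifts the sequence rightward in time by `lag_ms`, moving the final
#' `lag_ms` segment to the beginning: `output[t] = input[(t - k) mod T]` with
#' `k = lag_ms * frame_rate / 1000` frames. This is how Follower sequences are
#' constructed from the Leader.
#'
#' @param seq A `lum_sequence`.
#' @param lag_ms Shift in ms; must map to a whole number of frames in
#'   `[0, T)`. All lags used in the designs (200, 150, 300 ms at 100 Hz) do.
#' @param role Role label for the shifted copy (default `"Follower1"`).
#' @return A `lum_sequence` whose `lag_ms` is the total lag relative to the
#'   input's own lag.
#' @export
circular_shift <- function(seq, lag_ms, role = "Follower1") {
  stopifnot(inherits(seq, "lum_sequence"))
  n <- length(seq$samples)
  if (lag_ms < 0) stop("lag_ms must be nonnegative")
  k <- lag_ms * seq$frame_rate / 1000
  if (abs(k - round(k)) > 1e-9) {
    stop("lag_ms = ", lag_ms, " ms is not a whole number of frames at ",
         seq$frame_rate, " Hz")
  }
  k <- as.integer(round(k)) %% n
  idx <- ((seq_len(n) - 1 - k) %% n) + 1
  lum_sequence(seq$samples[idx], frame_rate = seq$frame_rate, role = role,
               lag_ms = (seq$lag_ms + lag_ms) %% (n * 1000 / seq$frame_rate))
}

#' Circular cross-correlation between two luminance sequences
#'
#' The coefficient at lag `k` frames is the Pearson correlation between `a`
#' circularly shifted by `k` and `b`. Because a circular shift leaves the mean
#' and variance untouched, every lag is on an equal footing and the whole
#' correlogram reduces to one circular convolution, computed via the FFT.
#' For a Follower constructed as `circular_shift(leader, lag)`, the peak sits
#' exactly at `lag`.
#'
#' @param a,b `lum_sequence` objects of equal length and frame rate.
#' @return An object of class `xcorr`: `lags_ms` (one full period),
#'   `coefficients`, and `peak_lag_ms` (ties broken toward the smallest lag).
#' @examples
#' leader <- generate_flat_spectrum_sequence(seed = 7)
#' follower <- circular_shift(leader, 200)
#' cross_correlation(leader, follower)$peak_lag_ms
#' @export
cross_correlation <- function(a, b) {
  stopifnot(inherits(a, "lum_sequence"), inherits(b, "lum_sequence"))
  n <- length(a$samples)
  if (length(b$samples) != n) stop("sequences have mismatched lengths")
  if (a$frame_rate != b$frame_rate) stop("sequences have mismatched frame rates")
  ca <- a$samples - mean(a$samples)
  cb <- b$samples - mean(b$samples)
  sa <- sqrt(sum(ca^2))
  sb <- sqrt(sum(cb^2))
  if (sa == 0 || sb == 0) stop("constant sequence: cross-correlation undefined")
  # s[k] = sum_t a[t] * b[t + k] for k = 0..n-1 (circular), via FFT.
  s <- Re(stats::fft(Conj(stats::fft(ca)) * stats::fft(cb), inverse = TRUE)) / n
  coef <- s / (sa * sb)
  lags_ms <- (seq_len(n) - 1) * 1000 / a$frame_rate
  peak <- which.max(coef)  # which.max returns the first maximum: smallest lag
  structure(
    list(lags_ms = lags_ms, coefficients = coef, peak_lag_ms = lags_ms[peak]),
    class = "xcorr"
  )
}

#' @export
print.xcorr <- function(x, ...) {
  cat(sprintf("<xcorr> %d lags, peak %g ms (r = %.4f)\n",
              length(x$lags_ms), x$peak_lag_ms,
              x$coefficients[which.max(x$coefficients)]))
  invisible(x)
}

#' Read and write luminance sequences as delimited text
#'
#' One row per frame with mandatory header `frame_index`, `time_ms`,
#' `luminance_cd_m2`. Frame indices are zero-based.
#'
#' @param seq A `lum_sequence`.
#' @param path File path.
#' @param role,lag_ms Role and lag to attach on read (the table itself stores
#'   only the trace).
#' @param frame_rate Frame rate on read; inferred from `time_ms` when `NULL`.
#' @return `write_sequence` returns `path` invisibly; `read_sequence` a
#'   `lum_sequence`.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "lum_sequence"))
  n <- length(seq$samples)
  df <- data.frame(
    frame_index = seq_len(n) - 1L,
    time_ms = (seq_len(n) - 1) * 1000 / seq$frame_rate,
    luminance_cd_m2 = seq$samples
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path, role = "Leader", lag_ms = 0, frame_rate = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("frame_index", "time_ms", "luminance_cd_m2")
  if (!all(need %in% names(df))) {
    stop("sequence file must have header columns: ", paste(need, collapse = ", "))
  }
  df <- df[order(df$frame_index), ]
  if (is.null(frame_rate)) {
    dt <- diff(df$time_ms)
    frame_rate <- 1000 / stats::median(dt)
  }
  lum_sequence(df$luminance_cd_m2, frame_rate = frame_rate, role = role,
               lag_ms = lag_ms)
}
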