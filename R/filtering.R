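# Zero-phase low-pass filtering of kinematic series.
#
# Contact times are read off the filtered curve, so the filter must not lag
# events: a forward-backward (zero-phase) Butterworth pass is used, order 4
# by default (order 2 per direction).

#' Zero-phase Butterworth low-pass
#'
#' @param series numeric vector.
#' @param cutoff_hz cutoff frequency; must satisfy `fps > 2 * cutoff_hz`.
#' @param fps sampling rate.
#' @param order filter order (split over the two passes).
#' @return Filtered series; inputs shorter than the filter warm-up
#'   (3 x (order + 1) samples) are returned unfiltered with attribute
#'   `filtered = FALSE`.
#' @export
lowpass <- function(series, cutoff_hz, fps, order = 4) {
  stopifnot(fps > 2 * cutoff_hz, cutoff_hz > 0)
  n <- length(series)
  warmup <- 3 * (order + 1)
  if (n < warmup) {
    warning("series shorter than filter warm-up; returned unfiltered")
    return(structure(series, filtered = FALSE))
  }
  bf <- signal::butter(order / 2, cutoff_hz / (fps / 2), type = "low")
  # odd-reflection padding: filtfilt alone assumes zero initial conditions
  # and corrupts both ends of short kinematic series
  p <- min(n - 1L, max(warmup, ceiling(3 * fps / cutoff_hz)))
  head_pad <- 2 * series[1L] - series[(p + 1L):2L]
  tail_pad <- 2 * series[n] - series[(n - 1L):(n - p)]
  padded <- c(head_pad, series, tail_pad)
  out <- as.numeric(signal::filtfilt(bf, padded))[(p + 1L):(p + n)]
  structure(out, filtered = TRUE)
}

#' Spectral-energy cutoff selection
#'
#' Returns the frequency below which `energy_frac` of the non-DC spectral
#' energy lies, times a 1.5 margin so the passband keeps the signal's own
#' harmonics, clamped to `[0.5, fps/4]` Hz (the plausible bandwidth of limb
#' motion at typical recording rates).
#'
#' @param series numeric vector.
#' @param fps sampling rate.
#' @param energy_frac energy fraction (default 0.95).
#' @return Cutoff frequency in Hz.
#' @export
auto_cutoff <- function(series, fps, energy_frac = 0.95) {
  n <- length(series)
  if (n < 8L) return(fps / 4)
  x <- series - mean(series)
  spec <- Mod(fft(x))^2
  half <- spec[2:(floor(n / 2) + 1L)]
  freqs <- (seq_along(half)) * fps / n
  cum <- cumsum(half) / sum(half)
  f95 <- freqs[which(cum >= energy_frac)[1L]]
  min(max(1.5 * f95, 0.5), fps / 4)
}
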