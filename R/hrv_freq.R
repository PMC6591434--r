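#' Beat-domain FFT power spectrum of an RR segment
#'
#' Transforms a fixed-length set of RR intervals with a fast Fourier
#' transform, squares the coefficient magnitudes and divides by the average
#' interval length, then folds the spectrum one-sided and sums it into
#' very-low- (0-0.4 Hz), low- (0.4-1.5 Hz) and high-frequency (1.5-5.0 Hz)
#' bands. Ectopic positions enter as literal zeros (the zero-replace cleaning
#' mode); the mean interval is computed over the non-zero entries only and is
#' subtracted from them before the transform, so the DC term does not swamp
#' the physiological bands.
#'
#' The transform lives in the beat domain: bin k corresponds to
#' `k / n_fft` cycles per beat, mapped to Hz by dividing by the mean RR in
#' seconds. For a mouse at ~10 beats/s this puts the per-beat Nyquist near
#' 5 Hz, matching the upper edge of the HF band. Band intervals are half-open
#' `[low, high)` with HF closed at its upper edge; the DC bin belongs to no
#' band. No taper is applied (rectangular window); `window = "hann"` is
#' available for leakage-sensitive use.
#'
#' @param seg a `clean_segment` with `cleaning_mode = "zero_replace"` (or
#'   `"none"`), or a numeric vector; exactly `n_fft` positions.
#' @param n_fft transform length (default 2048).
#' @param band_edges_hz numeric vector of band boundaries in Hz; default
#'   `c(0, 0.4, 1.5, 5.0)` delimiting VLF/LF/HF.
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return List of class `spectral_summary`: `freq_hz` and one-sided `power`
#'   (DC included as the first element), band powers `vlf`, `lf`, `hf`,
#'   `total_power` (all bins in (0, max band edge]), `band_edges_hz`,
#'   `mean_rr_s`, `n_fft`.
#' @export
rr_power_spectrum <- function(seg, n_fft = 2048L,
                              band_edges_hz = c(0, 0.4, 1.5, 5.0),
                              window = c("rectangular", "hann")) {
  window <- match.arg(window)
  x <- segment_values(seg, require_mode = c("zero_replace", "none"),
                      caller = "rr_power_spectrum")
  n_fft <- as.integer(n_fft)
  if (length(x) != n_fft) {
    stop("segment has ", length(x), " positions; rr_power_spectrum needs exactly ",
         n_fft)
  }
  if (length(band_edges_hz) < 2 || is.unsorted(band_edges_hz, strictly = TRUE)) {
    stop("band_edges_hz must be strictly increasing")
  }
  nz <- x != 0
  if (!any(nz) || mean(x[nz]) <= 0) {
    stop("segment must contain positive intervals")
  }
  t_bar <- mean(x[nz]) / 1000  # mean interval, seconds
  y <- x
  y[nz] <- x[nz] - mean(x[nz])
  if (window == "hann") {
    y <- y * (0.5 - 0.5 * cos(2 * pi * seq(0, n_fft - 1) / n_fft))
  }

  X <- stats::fft(y)
  p2 <- Mod(X)^2 / t_bar                 # two-sided, per-bin
  half <- n_fft %/% 2                    # Nyquist bin for even n_fft
  power <- p2[seq_len(half + 1L)]        # bins 0..N/2
  if (half >= 2) power[2:half] <- 2 * power[2:half]  # fold; DC & Nyquist once
  freq_hz <- (seq(0, half) / n_fft) / t_bar

  band_sum <- function(lo, hi, close_hi = FALSE) {
    inb <- if (close_hi) freq_hz >= lo & freq_hz <= hi else freq_hz >= lo & freq_hz < hi
    inb[1L] <- FALSE  # DC excluded from every band
    sum(power[inb])
  }
  ne <- length(band_edges_hz)
  bands <- vapply(seq_len(ne - 1L), function(i) {
    band_sum(band_edges_hz[i], band_edges_hz[i + 1L], close_hi = (i == ne - 1L))
  }, numeric(1))
  total <- band_sum(0, band_edges_hz[ne], close_hi = TRUE)

  structure(list(freq_hz = freq_hz,
                 power = power,
                 vlf = bands[1L],
                 lf = if (ne >= 3) bands[2L] else NA_real_,
                 hf = if (ne >= 4) bands[3L] else NA_real_,
                 total_power = total,
                 band_powers = bands,
                 band_edges_hz = band_edges_hz,
                 mean_rr_s = t_bar,
                 n_fft = n_fft,
                 window = window),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf(paste0("<spectral_summary> n_fft %d, mean RR %.1f ms\n",
                     "  VLF %.3g | LF %.3g | HF %.3g | total %.3g\n"),
              x$n_fft, 1000 * x$mean_rr_s, x$vlf, x$lf, x$hf, x$total_power))
  invisible(x)
}
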