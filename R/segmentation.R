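#' Segment-selection criteria
#'
#' Bundles the thresholds used to pick analyzable RR segments: a minimum
#' number of usable intervals, the ectopic-beat outlier multiplier (intervals
#' beyond `outlier_sd` standard deviations of the window mean are ectopic),
#' and the stationarity screen (a significant linear trend in RR is only
#' disqualifying if the fitted drift over the window also exceeds
#' `max_relative_drift` of the mean interval).
#'
#' @param min_intervals minimum usable intervals per segment (>= 16).
#' @param outlier_sd SD multiplier for the ectopic rule (> 0).
#' @param stationarity_alpha two-sided significance level for the trend test.
#' @param max_relative_drift maximum tolerated fitted drift as a fraction of
#'   the mean RR.
#' @return An object of class `segment_criteria`.
#' @export
segment_criteria <- function(min_intervals = 2048L, outlier_sd = 2,
                             stationarity_alpha = 0.05,
                             max_relative_drift = 0.05) {
  min_intervals <- as.integer(min_intervals)
  if (is.na(min_intervals) || min_intervals < 16L) {
    stop("min_intervals must be an integer >= 16")
  }
  if (!is.numeric(outlier_sd) || outlier_sd <= 0) stop("outlier_sd must be > 0")
  if (stationarity_alpha <= 0 || stationarity_alpha >= 1) {
    stop("stationarity_alpha must lie in (0, 1)")
  }
  if (max_relative_drift < 0) stop("max_relative_drift must be >= 0")
  structure(list(min_intervals = min_intervals,
                 outlier_sd = as.numeric(outlier_sd),
                 stationarity_alpha = as.numeric(stationarity_alpha),
                 max_relative_drift = as.numeric(max_relative_drift)),
            class = "segment_criteria")
}

#' Flag ectopic intervals by the k-SD rule
#'
#' An interval is ectopic when it lies more than `k` standard deviations from
#' the mean of the candidate window. Mean and SD are computed once on the raw
#' window (no re-estimation after removal). A constant window (SD = 0) flags
#' nothing.
#'
#' @param rr an [rr_series()] or numeric vector of intervals (length >= 3).
#' @param k SD multiplier, > 0 (the conventional rule uses 2).
#' @return Logical vector, `TRUE` at ectopic positions.
#' @export
detect_ectopics <- function(rr, k = 2) {
  x <- rr_values(rr)
  if (length(x) < 3) stop("need at least 3 intervals to estimate dispersion")
  if (!is.numeric(k) || k <= 0) stop("k must be > 0")
  s <- stats::sd(x)
  if (s == 0) return(rep(FALSE, length(x)))
  abs(x - mean(x)) > k * s
}

#' Screen a candidate window for stationarity
#'
#' Fits an ordinary least-squares line of RR against beat index. The window
#' fails only when the slope is statistically significant at
#' `stationarity_alpha` AND the fitted drift across the window exceeds
#' `max_relative_drift` of the mean RR — a significant but physiologically
#' negligible trend does not disqualify a long window.
#'
#' @param rr numeric vector or [rr_series()], length >= 16.
#' @param criteria a [segment_criteria()].
#' @return List with `pass` (logical), `slope` (ms/beat), `p_value`, and
#'   `drift_fraction` (|slope| * (n-1) / mean RR).
#' @export
assess_stationarity <- function(rr, criteria = segment_criteria()) {
  x <- rr_values(rr)
  n <- length(x)
  if (n < 16) stop("need at least 16 intervals to assess stationarity")
  idx <- seq_len(n)
  fit <- stats::lm(x ~ idx)
  # a perfectly flat window triggers lm's "essentially perfect fit" warning;
  # that case is legitimate here and handled via the NaN p-value below
  co <- suppressWarnings(stats::coef(summary(fit)))
  slope <- co["idx", "Estimate"]
  p <- co["idx", "Pr(>|t|)"]
  if (is.nan(p)) p <- 1  # zero residual variance: perfectly flat window
  drift_fraction <- abs(slope) * (n - 1) / mean(x)
  fail <- (p < criteria$stationarity_alpha) &&
    (drift_fraction > criteria$max_relative_drift)
  list(pass = !fail, slope = unname(slope), p_value = unname(p),
       drift_fraction = drift_fraction)
}

#' Select clean, stationary RR segments
#'
#' Partitions the series left-to-right into `floor(N / min_intervals)`
#' non-overlapping candidate windows (the last window absorbs the remainder).
#' Each window is kept only if it passes the stationarity screen and still
#' holds at least `min_intervals` non-ectopic intervals after applying the
#' k-SD ectopic rule; kept windows are truncated to exactly `min_intervals`
#' usable intervals from the window start.
#'
#' Cleaning modes follow the two downstream analysis families:
#' `"remove"` drops ectopic intervals (time-domain and nonlinear metrics),
#' `"zero_replace"` overwrites them with 0 and returns the first
#' `min_intervals` positions so the spectral stage receives a fixed-length
#' vector, `"none"` applies no cleaning.
#'
#' @param rr an [rr_series()] or numeric vector with at least
#'   `min_intervals` intervals.
#' @param criteria a [segment_criteria()].
#' @param mode cleaning mode: `"remove"`, `"zero_replace"` or `"none"`.
#' @return List of `clean_segment` objects (possibly empty). The
#'   `"rejections"` attribute is a data frame logging one reason per
#'   rejected window.
#' @export
select_segments <- function(rr, criteria = segment_criteria(),
                            mode = c("remove", "zero_replace", "none")) {
  mode <- match.arg(mode)
  x <- rr_values(rr)
  meta_id <- if (inherits(rr, "rr_series")) rr$animal_id else "series"
  n <- length(x)
  m <- criteria$min_intervals
  if (n < m) {
    stop("series has ", n, " intervals; at least ", m, " required")
  }
  k_blocks <- n %/% m
  starts <- (seq_len(k_blocks) - 1L) * m + 1L
  ends <- c(starts[-1L] - 1L, n)

  segments <- list()
  rejections <- data.frame(start = integer(), end = integer(),
                           reason = character(), stringsAsFactors = FALSE)
  for (b in seq_len(k_blocks)) {
    win <- x[starts[b]:ends[b]]
    stat <- assess_stationarity(win, criteria)
    if (!stat$pass) {
      rejections <- rbind(rejections, data.frame(
        start = starts[b], end = ends[b],
        reason = sprintf("non-stationary (slope %.3g ms/beat, p = %.3g, drift %.1f%%)",
                         stat$slope, stat$p_value, 100 * stat$drift_fraction),
        stringsAsFactors = FALSE))
      next
    }
    mask <- detect_ectopics(win, criteria$outlier_sd)
    n_clean <- sum(!mask)
    if (n_clean < m) {
      rejections <- rbind(rejections, data.frame(
        start = starts[b], end = ends[b],
        reason = sprintf("only %d clean intervals after ectopic masking (need %d)",
                         n_clean, m),
        stringsAsFactors = FALSE))
      next
    }
    seg_rr <- switch(mode,
      remove = win[!mask][seq_len(m)],
      zero_replace = { z <- win; z[mask] <- 0; z[seq_len(m)] },
      none = win[seq_len(m)]
    )
    segments[[length(segments) + 1L]] <- structure(
      list(rr = seg_rr,
           ectopic_mask = mask,
           cleaning_mode = mode,
           criteria = criteria,
           stationarity = stat,
           provenance = list(series_id = meta_id,
                             offset = starts[b] - 1L,
                             window_length = length(win))),
      class = "clean_segment")
  }
  attr(segments, "rejections") <- rejections
  segments
}

#' @export
print.clean_segment <- function(x, ...) {
  cat(sprintf("<clean_segment> %s+%d: %d intervals (%s), %d ectopic in window\n",
              x$provenance$series_id, x$provenance$offset, length(x$rr),
              x$cleaning_mode, sum(x$ectopic_mask)))
  invisible(x)
}

# Pull the interval vector out of a clean_segment, enforcing the cleaning
# mode the downstream metric requires.
segment_values <- function(seg, require_mode = NULL, caller = "metric") {
  if (inherits(seg, "clean_segment")) {
    if (!is.null(require_mode) && !(seg$cleaning_mode %in% require_mode)) {
      stop(caller, " requires a segment cleaned with mode ",
           paste(sQuote(require_mode), collapse = " or "),
           ", got ", sQuote(seg$cleaning_mode))
    }
    return(seg$rr)
  }
  rr_values(seg)
}
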