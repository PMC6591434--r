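#' Time-domain HRV summary
#'
#' Mean RR, range of RR, SDRR (sample standard deviation, n-1 denominator)
#' and the coefficient of variation CV = SDRR / mean RR, computed on a
#' segment cleaned by ectopic removal. A zero-replaced segment is refused:
#' the injected zeros would corrupt every time-domain statistic.
#'
#' @param seg a `clean_segment` with `cleaning_mode = "remove"` (or `"none"`),
#'   or a numeric vector of intervals already free of artifacts; length >= 2.
#' @return List of class `time_domain_summary`: `mean_rr`, `range_rr`,
#'   `sdrr`, `cv` (all ms except `cv`), and `n`.
#' @export
time_domain_summary <- function(seg) {
  x <- segment_values(seg, require_mode = c("remove", "none"),
                      caller = "time_domain_summary")
  if (length(x) < 2) stop("need at least 2 intervals")
  m <- mean(x)
  s <- stats::sd(x)
  structure(list(mean_rr = m,
                 range_rr = max(x) - min(x),
                 sdrr = s,
                 cv = s / m,
                 n = length(x)),
            class = "time_domain_summary")
}

#' @export
print.time_domain_summary <- function(x, ...) {
  cat(sprintf("mean RR %.2f ms | range %.2f ms | SDRR %.3f ms | CV %.4f | n = %d\n",
              x$mean_rr, x$range_rr, x$sdrr, x$cv, x$n))
  invisible(x)
}
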