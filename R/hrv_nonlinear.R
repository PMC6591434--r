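#' Poincaré plot dispersions SD1 and SD2
#'
#' Dispersions of the lag-1 return map of RR intervals, computed from the
#' successive-interval differences and sums: with `d_i = rr[i+1] - rr[i]` and
#' `s_i = rr[i+1] + rr[i]`, `SD1 = sqrt(var(d)/2)` (short-axis, beat-to-beat
#' variability) and `SD2 = sqrt(var(s)/2)` (long-axis, longer-term
#' variability). Sample variance (n-1) throughout, consistent with SDRR, so
#' the identity `SD1^2 + SD2^2 = 2 SDRR^2` holds up to an O(1/n) edge term.
#'
#' `convention = "literal"` swaps the two formulas (SD1 from sums), for
#' compatibility with sources that describe the computation the other way
#' round; the default follows the universal Poincaré convention.
#'
#' @param seg a `clean_segment` with `cleaning_mode = "remove"` (or `"none"`),
#'   or a numeric vector; length >= 3.
#' @param convention `"standard"` (default; SD1 from differences) or
#'   `"literal"`.
#' @return List of class `poincare_summary`: `sd1`, `sd2` (ms), `ratio`
#'   (SD1/SD2, `NA` with `ratio_undefined = TRUE` when SD2 = 0).
#' @export
poincare_summary <- function(seg, convention = c("standard", "literal")) {
  convention <- match.arg(convention)
  x <- segment_values(seg, require_mode = c("remove", "none"),
                      caller = "poincare_summary")
  n <- length(x)
  if (n < 3) stop("need at least 3 intervals")
  d <- x[-1L] - x[-n]
  s <- x[-1L] + x[-n]
  sd_diff <- sqrt(stats::var(d) / 2)
  sd_sum <- sqrt(stats::var(s) / 2)
  if (convention == "standard") {
    sd1 <- sd_diff; sd2 <- sd_sum
  } else {
    sd1 <- sd_sum; sd2 <- sd_diff
  }
  structure(list(sd1 = sd1, sd2 = sd2,
                 ratio = if (sd2 > 0) sd1 / sd2 else NA_real_,
                 ratio_undefined = sd2 == 0,
                 convention = convention, n = n),
            class = "poincare_summary")
}

#' @export
print.poincare_summary <- function(x, ...) {
  cat(sprintf("SD1 %.3f ms | SD2 %.3f ms | SD1/SD2 %s (n = %d)\n",
              x$sd1, x$sd2,
              if (x$ratio_undefined) "undefined" else sprintf("%.3f", x$ratio),
              x$n))
  invisible(x)
}

# Unordered template-pair match counts for sample entropy, Richman-Moorman
# convention: the N-m templates that possess an (m+1)-length continuation are
# compared pairwise (i < j, self-matches excluded) under the Chebyshev
# distance; B counts m-length matches, A counts (m+1)-length matches.
# Vectorised over j for O(n) memory.
sampen_counts <- function(x, m, r) {
  n <- length(x)
  np <- n - m          # templates with an (m+1)-continuation
  A <- 0; B <- 0
  if (np < 2) return(list(A = 0, B = 0))
  for (i in seq_len(np - 1L)) {
    js <- (i + 1L):np
    d <- abs(x[js] - x[i])
    if (m >= 2L) {
      for (k in seq_len(m - 1L)) {
        d <- pmax(d, abs(x[js + k] - x[i + k]))
      }
    }
    hit <- d <= r
    B <- B + sum(hit)
    if (any(hit)) {
      jh <- js[hit]
      A <- A + sum(pmax(d[hit], abs(x[jh + m] - x[i + m])) <= r)
    }
  }
  list(A = A, B = B)
}

#' Sample entropy of an RR segment
#'
#' SampEn(m, r) = -ln(A / B), where B is the number of template pairs that
#' match within tolerance `r` (Chebyshev distance) at length `m` and A the
#' number still matching at length `m + 1`; self-matches are excluded. The
#' tolerance is relative: `r = r_fraction * sd(segment)`, recomputed per
#' segment, which makes the statistic invariant under affine rescaling of
#' the series. A constant segment yields r = 0 with every pair matching
#' (A = B), hence SampEn 0 — a perfectly regular series.
#'
#' @param seg a `clean_segment` with `cleaning_mode = "remove"` (or `"none"`),
#'   or a numeric vector; length >= m + 2.
#' @param m template length (default 2).
#' @param r_fraction tolerance as a fraction of the segment SD (default 0.2).
#' @param r optional absolute tolerance in ms; overrides `r_fraction` (used
#'   by [multiscale_entropy_e1()] to hold the tolerance fixed across
#'   coarse-graining scales).
#' @return List of class `entropy_summary`: `e1` (the SampEn value; `NA` with
#'   `undefined = TRUE` when no templates match), `m`, `r` (absolute
#'   tolerance, ms), `r_fraction`, match counts `n_templates_a`,
#'   `n_templates_b`, `scale`, `n`.
#' @export
sample_entropy <- function(seg, m = 2L, r_fraction = 0.2, r = NULL) {
  x <- segment_values(seg, require_mode = c("remove", "none"),
                      caller = "sample_entropy")
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  if (r_fraction <= 0) stop("r_fraction must be > 0")
  n <- length(x)
  if (n < m + 2L) stop("need at least m + 2 = ", m + 2L, " intervals")
  if (is.null(r)) r <- r_fraction * stats::sd(x)
  if (r < 0) stop("r must be >= 0")
  cnt <- sampen_counts(x, m, r)
  undefined <- cnt$B == 0 || cnt$A == 0
  e1 <- if (cnt$B == 0) {
    NA_real_
  } else if (cnt$A == 0) {
    NA_real_
  } else {
    -log(cnt$A / cnt$B)
  }
  structure(list(e1 = e1, m = m, r = r, r_fraction = r_fraction,
                 n_templates_a = cnt$A, n_templates_b = cnt$B,
                 undefined = undefined, scale = 1L, n = n),
            class = "entropy_summary")
}

#' Multiscale entropy, scale-s sample entropy (E1 at scale 1)
#'
#' Coarse-grains the segment into non-overlapping means of length `scale`,
#' then computes [sample_entropy()] on the coarse series. The tolerance is
#' fixed at `r_fraction * sd` of the original (scale-1) series for every
#' scale — the convention of the multiscale-entropy literature, under which
#' white noise loses entropy with coarse-graining as averaging shrinks its
#' variance relative to the fixed tolerance. At `scale = 1` the result is
#' identical to [sample_entropy()]; the scale-1 value is the E1 statistic of
#' the multiscale entropy curve.
#'
#' @inheritParams sample_entropy
#' @param scale coarse-graining factor (>= 1).
#' @return An `entropy_summary` (see [sample_entropy()]) with `scale` set.
#' @export
multiscale_entropy_e1 <- function(seg, m = 2L, r_fraction = 0.2, scale = 1L) {
  x <- segment_values(seg, require_mode = c("remove", "none"),
                      caller = "multiscale_entropy_e1")
  scale <- as.integer(scale)
  if (scale < 1L) stop("scale must be >= 1")
  if (scale == 1L) return(sample_entropy(x, m = m, r_fraction = r_fraction))
  r_abs <- r_fraction * stats::sd(x)
  n2 <- length(x) %/% scale
  if (n2 < m + 2L) {
    stop("coarse-grained length ", n2, " is below m + 2 = ", m + 2L)
  }
  y <- colMeans(matrix(x[seq_len(n2 * scale)], nrow = scale))
  out <- sample_entropy(y, m = m, r_fraction = r_fraction, r = r_abs)
  out$scale <- scale
  out
}

#' @export
print.entropy_summary <- function(x, ...) {
  cat(sprintf("SampEn(m = %d, r = %.3f ms, scale %d) = %s  [A = %d, B = %d]\n",
              x$m, x$r, x$scale,
              if (x$undefined) "undefined" else sprintf("%.4f", x$e1),
              x$n_templates_a, x$n_templates_b))
  invisible(x)
}
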