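#' Full HRV metric panel for one or more RR series
#'
#' Runs the whole analysis chain on each series: segment selection (same
#' windows for every metric family), ectopic removal for the time-domain and
#' nonlinear metrics, zero-replacement for the spectral metrics, then one
#' tidy row per (segment, metric). Metrics reported: `mean_rr`, `range_rr`,
#' `sdrr`, `cv`, `total_power`, `vlf`, `lf`, `hf`, `sd1`, `sd2`, and
#' `mse_e1` (scale-1 multiscale sample entropy).
#'
#' @param x an [rr_series()], a [beat_series()], or a list of either.
#' @param criteria a [segment_criteria()].
#' @param m,r_fraction sample-entropy parameters (see [sample_entropy()]).
#' @return Data frame with columns `animal_id`, `genotype`, `condition`,
#'   `epoch`, `segment` (window offset), `metric`, `value`. Series with no
#'   qualifying window contribute no rows.
#' @export
hrv_metrics <- function(x, criteria = segment_criteria(), m = 2L,
                        r_fraction = 0.2) {
  if (inherits(x, c("rr_series", "beat_series"))) x <- list(x)
  rows <- lapply(x, function(s) {
    if (inherits(s, "beat_series")) s <- beats_to_rr(s)
    if (!inherits(s, "rr_series")) {
      stop("hrv_metrics expects rr_series or beat_series objects")
    }
    segs_rm <- select_segments(s, criteria, mode = "remove")
    segs_z <- select_segments(s, criteria, mode = "zero_replace")
    if (!length(segs_rm)) return(NULL)
    do.call(rbind, lapply(seq_along(segs_rm), function(i) {
      td <- time_domain_summary(segs_rm[[i]])
      sp <- rr_power_spectrum(segs_z[[i]], n_fft = criteria$min_intervals)
      pc <- poincare_summary(segs_rm[[i]])
      en <- multiscale_entropy_e1(segs_rm[[i]], m = m,
                                  r_fraction = r_fraction, scale = 1L)
      vals <- c(mean_rr = td$mean_rr, range_rr = td$range_rr, sdrr = td$sdrr,
                cv = td$cv, total_power = sp$total_power, vlf = sp$vlf,
                lf = sp$lf, hf = sp$hf, sd1 = pc$sd1, sd2 = pc$sd2,
                mse_e1 = en$e1)
      data.frame(animal_id = s$animal_id, genotype = s$genotype,
                 condition = s$condition, epoch = s$epoch,
                 segment = segs_rm[[i]]$provenance$offset,
                 metric = names(vals), value = unname(vals),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(animal_id = character(), genotype = character(),
                      condition = character(), epoch = character(),
                      segment = integer(), metric = character(),
                      value = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
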