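#' Beat-time series for one animal and condition
#'
#' A `beat_series` holds the ordered beat occurrence times (seconds) of one
#' telemetric recording epoch, together with the animal's identity, genotype
#' and experimental condition (e.g. `"basal"`, `"atropine"`).
#'
#' @param beat_times numeric vector of beat occurrence times in seconds,
#'   strictly increasing, length >= 2.
#' @param animal_id label identifying the animal.
#' @param genotype genotype label; `"WT"` and `"TGAC8"` are recognised by the
#'   genotype presets, any other label is carried through unchanged.
#' @param condition condition label (drug or `"basal"`).
#' @param epoch optional epoch label (e.g. a pre/post-drug window tag).
#' @return An object of class `beat_series`.
#' @seealso [beats_to_rr()], [load_beat_table()]
#' @export
beat_series <- function(beat_times, animal_id = "animal", genotype = "WT",
                        condition = "basal", epoch = NA_character_) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2) {
    stop("a beat series needs at least 2 beats, got ", length(beat_times))
  }
  if (anyNA(beat_times) || any(!is.finite(beat_times))) {
    stop("beat_times must be finite and non-missing")
  }
  d <- diff(beat_times)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L] + 1L
    stop("beat_times must be strictly increasing; violation at position ", bad,
         " (t = ", beat_times[bad], " s follows t = ", beat_times[bad - 1L], " s)")
  }
  structure(
    list(animal_id = as.character(animal_id),
         genotype = as.character(genotype),
         condition = as.character(condition),
         epoch = as.character(epoch),
         beat_times = beat_times),
    class = "beat_series"
  )
}

#' RR-interval series for one animal and condition
#'
#' Inter-beat (RR) intervals in milliseconds with the same metadata as a
#' [beat_series()].
#'
#' @param rr numeric vector of RR intervals in milliseconds, all > 0.
#' @inheritParams beat_series
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(rr, animal_id = "animal", genotype = "WT",
                      condition = "basal", epoch = NA_character_) {
  rr <- as.numeric(rr)
  if (length(rr) < 1) stop("rr must be non-empty")
  if (anyNA(rr) || any(!is.finite(rr))) stop("rr must be finite and non-missing")
  if (any(rr <= 0)) {
    stop("all RR intervals must be positive; first violation at position ",
         which(rr <= 0)[1L])
  }
  structure(
    list(animal_id = as.character(animal_id),
         genotype = as.character(genotype),
         condition = as.character(condition),
         epoch = as.character(epoch),
         rr = rr),
    class = "rr_series"
  )
}

#' Convert beat times to RR intervals
#'
#' `rr[i] = (beat_times[i+1] - beat_times[i]) * 1000` ms, so an n-beat series
#' yields n-1 intervals. The cumulative sum of the result recovers the beat
#' times up to the offset of the first beat.
#'
#' @param b a [beat_series()].
#' @return An [rr_series()] with the same metadata.
#' @export
beats_to_rr <- function(b) {
  if (!inherits(b, "beat_series")) stop("`b` must be a beat_series")
  rr_series(diff(b$beat_times) * 1000,
            animal_id = b$animal_id, genotype = b$genotype,
            condition = b$condition, epoch = b$epoch)
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %s | %s | %s: %d beats over %.1f s\n",
              x$animal_id, x$genotype, x$condition,
              length(x$beat_times),
              diff(range(x$beat_times))))
  invisible(x)
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %s | %s | %s: %d intervals, mean RR %.1f ms\n",
              x$animal_id, x$genotype, x$condition,
              length(x$rr), mean(x$rr)))
  invisible(x)
}

# Accept an rr_series or a bare numeric vector of intervals.
rr_values <- function(x) {
  if (inherits(x, "rr_series")) return(x$rr)
  if (is.numeric(x)) return(as.numeric(x))
  stop("expected an rr_series or a numeric vector of RR intervals")
}
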