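#' Read a beat-annotation or RR-interval table
#'
#' Reads a delimited text table with one row per beat and returns one series
#' per (animal, condition) group. The table may carry either beat occurrence
#' times (seconds) or ready-made RR intervals (milliseconds) — never both:
#' `column_map` states which column plays which role.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named character vector or list mapping roles to column
#'   names. Required: `id`; exactly one of `time` (beat times, s) or
#'   `rr` (intervals, ms). Optional: `genotype`, `condition`, `epoch`.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return A list of [beat_series()] (when a `time` column is mapped) or
#'   [rr_series()] (when an `rr` column is mapped), one per
#'   (animal_id, condition) group; rows must already be time-ordered within
#'   each group (an out-of-order or duplicate time is reported as an error
#'   naming the offending row).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(animal_id = "m1", genotype = "WT",
#'                      condition = "basal", time_s = c(0, 0.1, 0.2)),
#'           tf, row.names = FALSE)
#' load_beat_table(tf)
#' @export
load_beat_table <- function(path,
                            column_map = c(id = "animal_id",
                                           genotype = "genotype",
                                           condition = "condition",
                                           time = "time_s"),
                            sep = ",") {
  column_map <- as.list(column_map)
  if (is.null(column_map$id)) stop("column_map must name an `id` column")
  has_time <- !is.null(column_map$time)
  has_rr <- !is.null(column_map$rr)
  if (has_time && has_rr) {
    stop("column_map maps both `time` and `rr`; a table carries one or the other")
  }
  if (!has_time && !has_rr) {
    stop("column_map must name either a `time` (s) or an `rr` (ms) column")
  }

  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  needed <- unlist(column_map, use.names = FALSE)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }

  get_col <- function(role, default) {
    if (!is.null(column_map[[role]])) df[[column_map[[role]]]] else default
  }
  id <- as.character(df[[column_map$id]])
  genotype <- as.character(get_col("genotype", "WT"))
  condition <- as.character(get_col("condition", "basal"))
  epoch <- as.character(get_col("epoch", NA_character_))

  key <- interaction(id, condition, drop = TRUE, lex.order = TRUE)
  out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    g <- genotype[idx][1L]
    cnd <- condition[idx][1L]
    ep <- epoch[idx][1L]
    if (has_time) {
      tm <- as.numeric(df[[column_map$time]][idx])
      if (any(diff(tm) <= 0)) {
        bad <- idx[which(diff(tm) <= 0)[1L] + 1L]
        stop("non-monotone beat times for animal ", id[idx][1L],
             " (", cnd, "): duplicate or reversed time at input row ", bad)
      }
      beat_series(tm, animal_id = id[idx][1L], genotype = g,
                  condition = cnd, epoch = ep)
    } else {
      rr_series(as.numeric(df[[column_map$rr]][idx]),
                animal_id = id[idx][1L], genotype = g,
                condition = cnd, epoch = ep)
    }
  })
  names(out) <- levels(key)
  out
}

#' Write a tidy HRV metrics table
#'
#' Writes one row per (segment, metric) with full double precision, so that
#' [read_metrics_table()] recovers the values exactly.
#'
#' @param records data frame of HRV records (metadata + `metric`, `value`).
#' @param path output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("`records` must be a non-empty data frame of HRV records")
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      # %.17g round-trips IEEE doubles exactly through text
      out[[j]] <- ifelse(is.na(out[[j]]), NA, sprintf("%.17g", out[[j]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Read a metrics table written by [write_metrics_table()]
#'
#' @param path path to the CSV file.
#' @return data frame with numeric columns restored to machine precision.
#' @export
read_metrics_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
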