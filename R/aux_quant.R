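#' Corrected total cell fluorescence (CTCF)
#'
#' Background-corrected integrated intensity of a cell region of interest:
#' `CTCF = integrated_density - cell_area * mean(background_means)`. With
#' several background readings per image, their mean fluorescence is used.
#'
#' @param integrated_density integrated density of the cell ROI (arbitrary
#'   fluorescence units); may be a vector of cells.
#' @param cell_area area of the cell ROI (same length as
#'   `integrated_density`).
#' @param background_means numeric vector of background mean-fluorescence
#'   readings shared by all cells, or a list with one numeric vector per
#'   cell.
#' @return Numeric vector of CTCF values.
#' @examples
#' ctcf(1000, 50, 2)  # 900
#' @export
ctcf <- function(integrated_density, cell_area, background_means) {
  if (length(integrated_density) != length(cell_area)) {
    stop("integrated_density and cell_area must have equal length")
  }
  if (any(cell_area <= 0)) stop("cell_area must be > 0")
  bg <- if (is.list(background_means)) {
    if (length(background_means) != length(integrated_density)) {
      stop("per-cell background list must match the number of cells")
    }
    vapply(background_means, function(b) {
      if (!length(b)) stop("each cell needs at least one background reading")
      mean(as.numeric(b))
    }, numeric(1))
  } else {
    if (!length(background_means)) stop("at least one background reading required")
    mean(as.numeric(background_means))
  }
  integrated_density - cell_area * bg
}

#' Comparative-Ct (ddCt) relative quantification
#'
#' Computes relative expression normalized to a reference gene (e.g. HPRT):
#' per sample, replicate wells are first averaged to a single Ct
#' (average-Ct-first convention), then `dCt = Ct_target - Ct_reference`,
#' `ddCt = dCt - mean(dCt of the calibrator group)`, and
#' `RQ = 2^(-ddCt)` (amplification efficiency fixed at 2). The calibrator
#' group's RQ values have geometric mean 1 by construction.
#'
#' @param wells data frame with columns `sample_id`, `group`, `target_ct`,
#'   `reference_ct`; one row per well, replicates sharing a `sample_id`.
#' @param calibrator_group value of `group` defining the calibrator samples.
#' @return Data frame with one row per sample: `sample_id`, `group`,
#'   `target_ct`, `reference_ct` (replicate means), `delta_ct`,
#'   `delta_delta_ct`, `rq`.
#' @examples
#' w <- data.frame(sample_id = c("a", "b"), group = c("WT", "TG"),
#'                 target_ct = c(24, 23), reference_ct = c(20, 20))
#' ddct_rq(w, calibrator_group = "WT")  # b: RQ = 2
#' @export
ddct_rq <- function(wells, calibrator_group) {
  need <- c("sample_id", "group", "target_ct", "reference_ct")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stop("wells lack column(s): ", paste(miss, collapse = ", "))
  no_ref <- unique(wells$sample_id[is.na(wells$reference_ct)])
  if (length(no_ref)) {
    stop("missing reference-gene Ct for sample(s): ",
         paste(no_ref, collapse = ", "))
  }
  no_tgt <- unique(wells$sample_id[is.na(wells$target_ct)])
  if (length(no_tgt)) {
    stop("missing target Ct for sample(s): ", paste(no_tgt, collapse = ", "))
  }

  agg <- stats::aggregate(cbind(target_ct, reference_ct) ~ sample_id + group,
                          data = wells, FUN = mean)
  if (!any(agg$group == calibrator_group)) {
    stop("calibrator group ", sQuote(calibrator_group), " not present")
  }
  agg$delta_ct <- agg$target_ct - agg$reference_ct
  cal_mean <- mean(agg$delta_ct[agg$group == calibrator_group])
  agg$delta_delta_ct <- agg$delta_ct - cal_mean
  agg$rq <- 2^(-agg$delta_delta_ct)
  agg[order(agg$group != calibrator_group, agg$sample_id), , drop = FALSE]
}
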