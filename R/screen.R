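#' OD-normalized GFP fold change for screen colonies
#'
#' The reporter screen compares GFP fluorescence per unit cell density
#' between a treated culture (glycerol + test sugar) and the glycerol-only
#' control: fold = (gfp_treated / od_treated) / (gfp_control / od_control).
#' Vectorized over colonies.
#'
#' @param od_control,gfp_control,od_treated,gfp_treated Plate-reader
#'   readings; OD values must be > 0 and the normalized control signal
#'   non-zero.
#' @return Fold change per colony.
#' @export
fluorescence_fold_change <- function(od_control, gfp_control, od_treated,
                                     gfp_treated) {
  if (any(od_control <= 0) || any(od_treated <= 0)) {
    stop("OD readings must be positive")
  }
  if (any(gfp_control < 0) || any(gfp_treated < 0)) {
    stop("GFP readings must be non-negative")
  }
  ctrl <- gfp_control / od_control
  if (any(ctrl == 0)) stop("zero normalized control signal: fold undefined")
  (gfp_treated / od_treated) / ctrl
}

#' Filter and rank screen positives
#'
#' Computes each colony's fold change and keeps those strictly above
#' `fold_threshold`, ranked by fold descending. The screen's ">1-fold
#' increase" wording is ambiguous between "ratio > 1" and "an increase of
#' 100%, i.e. ratio > 2"; the default threshold of 2 takes the stricter
#' reading, and passing `fold_threshold = 1` selects the other.
#'
#' @param records Data frame with columns `colony_id`, `od_control`,
#'   `gfp_control`, `od_treated`, `gfp_treated`.
#' @param fold_threshold Colonies with fold strictly above this are positive
#'   (default 2).
#' @return The positive subset of `records` with an added `fold` column,
#'   sorted by decreasing fold (ties by `colony_id`).
#' @export
screen_positives <- function(records, fold_threshold = 2) {
  req <- c("colony_id", "od_control", "gfp_control", "od_treated",
           "gfp_treated")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop("screen records need columns: ", paste(req, collapse = ", "))
  }
  if (nrow(records) == 0) stop("need at least one record")
  records$fold <- fluorescence_fold_change(
    records$od_control, records$gfp_control,
    records$od_treated, records$gfp_treated
  )
  pos <- records[records$fold > fold_threshold, , drop = FALSE]
  pos <- pos[order(-pos$fold, pos$colony_id), , drop = FALSE]
  rownames(pos) <- NULL
  pos
}

#' Keep the k colonies with the largest fold change
#'
#' @param positives Ranked data frame from [screen_positives()] (must have a
#'   `fold` column).
#' @param k Number of colonies to keep (> 0); fewer are returned when the
#'   list is shorter. Ties at the boundary are broken by `colony_id`.
#' @return The first `min(k, n)` rows.
#' @export
top_k <- function(positives, k) {
  if (!is.data.frame(positives) || !"fold" %in% names(positives)) {
    stop("'positives' must be a ranked data frame with a 'fold' column")
  }
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    stop("'k' must be a positive number")
  }
  ord <- order(-positives$fold, positives$colony_id)
  out <- positives[ord, , drop = FALSE][seq_len(min(k, nrow(positives))), ,
                                        drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scatter-gate flow events and summarize GFP
#'
#' Emulates the "tight forward- and side-scatter gate" used to read reporter
#' levels from a flow cytometer: events whose FSC and SSC both lie within
#' their respective sample quantile band are kept, and the median FL1 (GFP)
#' intensity of the kept events is reported. The median is robust to the
#' long fluorescence tails typical of reporter distributions.
#'
#' @param events Data frame with columns `fsc`, `ssc`, `fl1` (>= 100 rows).
#' @param gate_quantiles Length-2 vector `(low, high)` with
#'   `0 <= low < high <= 1` (default `c(0.25, 0.75)`).
#' @return A list with `median_fl1`, `gated_fraction`, `n_events`,
#'   `n_gated`.
#' @export
gate_and_summarize <- function(events, gate_quantiles = c(0.25, 0.75)) {
  req <- c("fsc", "ssc", "fl1")
  if (!is.data.frame(events) || !all(req %in% names(events))) {
    stop("flow events need columns: ", paste(req, collapse = ", "))
  }
  if (nrow(events) < 100) {
    stop("need at least 100 events for a stable gate, got ", nrow(events))
  }
  if (length(gate_quantiles) != 2 || gate_quantiles[1] < 0 ||
      gate_quantiles[2] > 1 || gate_quantiles[1] >= gate_quantiles[2]) {
    stop("gate_quantiles must satisfy 0 <= low < high <= 1")
  }
  if (any(!is.finite(as.matrix(events[req]))) ||
      any(as.matrix(events[req]) < 0)) {
    stop("event measurements must be finite and non-negative")
  }
  qf <- stats::quantile(events$fsc, gate_quantiles, names = FALSE)
  qs <- stats::quantile(events$ssc, gate_quantiles, names = FALSE)
  keep <- events$fsc >= qf[1] & events$fsc <= qf[2] &
    events$ssc >= qs[1] & events$ssc <= qs[2]
  if (!any(keep)) stop("scatter gate removed every event")
  list(
    median_fl1 = stats::median(events$fl1[keep]),
    gated_fraction = mean(keep),
    n_events = nrow(events),
    n_gated = sum(keep)
  )
}

#' Fold repression of a reporter between treated and control cultures
#'
#' Ratio of the treated median reporter level to the control median, exactly
#' as assayed for repair mutants: values below 1 indicate repression under
#' treatment. Despite its name the statistic is the plain treated/control
#' ratio; set `invert = TRUE` for the reciprocal (a "times repressed"
#' number).
#'
#' @param gfp_treated_median,gfp_control_median Median reporter intensities
#'   (> 0).
#' @param invert Return `control/treated` instead.
#' @return The ratio.
#' @export
fold_repression <- function(gfp_treated_median, gfp_control_median,
                            invert = FALSE) {
  if (any(gfp_treated_median <= 0) || any(gfp_control_median <= 0)) {
    stop("medians must be positive")
  }
  r <- gfp_treated_median / gfp_control_median
  if (invert) 1 / r else r
}
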