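#' Maximum specific growth rate from an OD600 time series
#'
#' Slides a window of `window` consecutive readings along the curve,
#' restricted to readings above `od_floor` (blank-level noise makes
#' log(OD) meaningless near zero), fits ln(OD) against time by ordinary
#' least squares in each window, and returns the steepest slope. The result
#' is floored at 0: a culture that never grows has mu_max = 0, not a
#' negative rate.
#'
#' @param times Numeric vector of times in hours, strictly increasing.
#' @param od Numeric vector of OD600 readings (same length, >= 0).
#' @param window Number of consecutive points per fit (default 5, i.e. 1 h
#'   at 15-min sampling).
#' @param od_floor Minimum OD for a reading to be used (default 0.01).
#' @return Maximum specific growth rate in 1/h.
#' @examples
#' t <- seq(0, 10, by = 0.25)
#' mu_max(t, 0.01 * exp(0.5 * t))  # 0.5
#' @export
mu_max <- function(times, od, window = 5, od_floor = 0.01) {
  if (length(times) != length(od)) stop("times and od must match in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(od < 0)) stop("od must be non-negative")
  if (window < 2) stop("window must be at least 2")
  usable <- od > od_floor
  n <- length(od)
  if (sum(usable) < window) {
    stop("fewer than ", window, " readings above od_floor = ", od_floor)
  }
  best <- -Inf
  for (i in seq_len(n - window + 1)) {
    idx <- i:(i + window - 1)
    if (!all(usable[idx])) next
    tt <- times[idx]
    ly <- log(od[idx])
    # closed-form OLS slope; lm() per window would dominate the runtime
    slope <- sum((tt - mean(tt)) * (ly - mean(ly))) /
      sum((tt - mean(tt))^2)
    if (slope > best) best <- slope
  }
  if (!is.finite(best)) {
    stop("no run of ", window, " consecutive readings above od_floor")
  }
  max(best, 0)
}

#' Choose the carbon-source concentration with the highest growth rate
#'
#' Concentration screens (e.g. 5 / 10 / 20 mM) pick the concentration whose
#' replicate mu_max values have the highest mean; ties go to the lower
#' concentration, the conservative choice when higher concentrations exert
#' metabolic pressure.
#'
#' @param mu_by_concentration Named list (names = concentrations, numeric)
#'   of replicate mu_max vectors, each non-empty.
#' @return The selected concentration (numeric).
#' @export
pick_optimal_concentration <- function(mu_by_concentration) {
  if (length(mu_by_concentration) == 0) stop("empty input")
  if (length(mu_by_concentration) < 2) {
    stop("need at least 2 concentrations to compare")
  }
  if (any(vapply(mu_by_concentration, length, integer(1)) == 0)) {
    stop("every concentration needs at least one replicate")
  }
  conc <- as.numeric(names(mu_by_concentration))
  if (any(is.na(conc))) stop("names must be numeric concentrations")
  means <- vapply(mu_by_concentration, function(v) mean(as.numeric(v)),
                  numeric(1))
  best <- max(means)
  min(conc[means == best])
}

#' mu_max for every curve in a long-format growth table
#'
#' @param growth Data frame with columns `time_h`, `od` and grouping columns
#'   `source_id`, `concentration_mM`, `replicate`.
#' @inheritParams mu_max
#' @return A data frame with one `mu_max` per (source, concentration,
#'   replicate) curve.
#' @export
growth_rates <- function(growth, window = 5, od_floor = 0.01) {
  req <- c("time_h", "od", "source_id", "concentration_mM", "replicate")
  if (!is.data.frame(growth) || !all(req %in% names(growth))) {
    stop("growth table needs columns: ", paste(req, collapse = ", "))
  }
  key <- interaction(growth$source_id, growth$concentration_mM,
                     growth$replicate, drop = TRUE)
  out <- lapply(split(growth, key), function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    data.frame(source_id = g$source_id[1],
               concentration_mM = g$concentration_mM[1],
               replicate = g$replicate[1],
               mu_max = mu_max(g$time_h, g$od, window = window,
                               od_floor = od_floor),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
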