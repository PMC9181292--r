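#' Normalize a raw concentration-versus-position profile
#'
#' Literature tables report carbon-source abundance against intestinal
#' position in heterogeneous units (concentrations, enzyme activities used as
#' proxies, arbitrary gut lengths). Both axes are therefore mapped affinely so
#' that the minimum becomes 0 and the maximum becomes 1, making profiles from
#' different studies comparable. Duplicate positions are averaged first and
#' rows are sorted by position.
#'
#' @param raw A data frame with numeric columns `position` and `value`;
#'   additional columns (`source_id`, `is_proxy`) are carried through.
#' @return A data frame of the same shape with both axes on `[0, 1]`.
#'   Applying the function twice gives the same result as applying it once.
#' @examples
#' normalize_profile(data.frame(position = c(0, 5, 10), value = c(2, 4, 6)))
#' @export
normalize_profile <- function(raw) {
  raw <- validate_raw_profile(raw)
  pos <- raw$position
  val <- raw$value
  if (max(pos) == min(pos)) {
    stop("cannot normalize: position axis is degenerate (max == min)")
  }
  if (max(val) == min(val)) {
    stop("cannot normalize: value axis is degenerate (max == min)")
  }
  raw$position <- (pos - min(pos)) / (max(pos) - min(pos))
  raw$value <- (val - min(val)) / (max(val) - min(val))
  raw
}

# Shared raw-table checks: >= 3 points after duplicate-position averaging,
# finite non-negative values, sorted strictly increasing positions.
validate_raw_profile <- function(raw) {
  if (!is.data.frame(raw) || !all(c("position", "value") %in% names(raw))) {
    stop("raw profile must be a data frame with 'position' and 'value' columns")
  }
  if (!is.numeric(raw$position) || !is.numeric(raw$value)) {
    stop("'position' and 'value' must be numeric")
  }
  if (any(!is.finite(raw$position)) || any(!is.finite(raw$value))) {
    stop("raw profile contains non-finite positions or values")
  }
  if (any(raw$value < 0)) {
    stop("raw profile values must be non-negative")
  }
  raw <- raw[order(raw$position), , drop = FALSE]
  if (anyDuplicated(raw$position)) {
    agg <- stats::aggregate(value ~ position, data = raw, FUN = mean)
    keep <- raw[!duplicated(raw$position), setdiff(names(raw), "value"),
                drop = FALSE]
    raw <- cbind(keep, value = agg$value[match(keep$position, agg$position)])
  }
  if (nrow(raw) < 3) {
    stop("raw profile needs at least 3 distinct positions, got ", nrow(raw))
  }
  rownames(raw) <- NULL
  raw
}

#' Loess-smooth a normalized profile onto a fixed evaluation grid
#'
#' Fits a locally weighted degree-1 (linear) regression with tricube weights
#' through the normalized points and evaluates it at `grid_size` evenly spaced
#' positions spanning `[0, 1]` inclusive. Exact local fits are used (no
#' interpolation surface), so each grid value is the solution of the weighted
#' least-squares problem at that point. Smoothed values are not clipped to
#' `[0, 1]`: local linear fits may slightly overshoot near steep flanks, and
#' downstream operations tolerate this.
#'
#' @param normalized A profile as returned by [normalize_profile()].
#' @param span Fraction of points entering each local fit, in `(0, 1]`.
#' @param grid_size Number of evaluation points (default 1000).
#' @param source_id Identifier attached to the result; defaults to the
#'   `source_id` column of `normalized` when present.
#' @return A `smoothed_profile`: a list with `source_id`, `grid` (length
#'   `grid_size`, from 0 to 1) and `values`.
#' @examples
#' raw <- normalize_profile(data.frame(position = 0:10, value = 0:10))
#' sp <- loess_smooth(raw, span = 1, grid_size = 11)
#' all.equal(sp$values, sp$grid)
#' @export
loess_smooth <- function(normalized, span = 0.5, grid_size = 1000,
                         source_id = NULL) {
  normalized <- validate_raw_profile(normalized)
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1) {
    stop("'span' must be a single number in (0, 1]")
  }
  if (grid_size < 2) stop("'grid_size' must be at least 2")
  n <- nrow(normalized)
  if (floor(span * n) < 2) {
    stop("span ", span, " leaves fewer than 2 points per local fit (n = ",
         n, ")")
  }
  fit <- stats::loess(
    value ~ position, data = normalized, span = span, degree = 1,
    family = "gaussian",
    control = stats::loess.control(surface = "direct")
  )
  grid <- seq(0, 1, length.out = grid_size)
  values <- as.numeric(stats::predict(fit, data.frame(position = grid)))
  if (any(!is.finite(values))) {
    stop("Loess fit produced non-finite values; increase 'span'")
  }
  smoothed_profile(
    source_id = source_id %||% as.character(normalized$source_id[1] %||% NA),
    grid = grid, values = values
  )
}

#' Construct a smoothed profile object
#'
#' @param source_id Carbon-source identifier.
#' @param grid Evaluation positions, evenly spaced from 0 to 1.
#' @param values Smoothed normalized abundance at each grid position.
#' @return An object of class `smoothed_profile`.
#' @export
smoothed_profile <- function(source_id, grid, values) {
  if (length(grid) != length(values)) {
    stop("grid and values must have the same length")
  }
  if (length(grid) < 2 || grid[1] != 0 || grid[length(grid)] != 1) {
    stop("grid must span [0, 1] inclusive")
  }
  if (any(!is.finite(values))) stop("smoothed values must be finite")
  structure(
    list(source_id = as.character(source_id), grid = as.numeric(grid),
         values = as.numeric(values)),
    class = "smoothed_profile"
  )
}

#' @export
print.smoothed_profile <- function(x, ...) {
  cat(sprintf("<smoothed_profile> %s: %d grid points, peak at %.3f\n",
              x$source_id, length(x$grid), peak_position(x)))
  invisible(x)
}

#' Grid position of a profile's maximum
#'
#' Ties (including plateaus of equal maxima) are broken toward the smallest
#' position, i.e. the anterior end. A completely flat profile has no
#' meaningful peak; it returns 0 with a warning.
#'
#' @param profile A [smoothed_profile()].
#' @return A position in `[0, 1]`.
#' @export
peak_position <- function(profile) {
  stopifnot(inherits(profile, "smoothed_profile"))
  v <- profile$values
  if (max(v) == min(v)) {
    warning("flat profile for '", profile$source_id,
            "': peak position undefined, returning 0")
    return(0)
  }
  profile$grid[which.max(v)]
}

#' Pearson similarity of two smoothed profiles
#'
#' Operationalizes "similar pattern of a concentration gradient" as the
#' Pearson correlation of the smoothed values on the shared grid.
#'
#' @param a,b [smoothed_profile()] objects on identical grids.
#' @return A correlation in `[-1, 1]`.
#' @export
profile_similarity <- function(a, b) {
  stopifnot(inherits(a, "smoothed_profile"), inherits(b, "smoothed_profile"))
  if (length(a$grid) != length(b$grid) || any(a$grid != b$grid)) {
    stop("profiles must share an identical grid")
  }
  if (stats::sd(a$values) == 0 || stats::sd(b$values) == 0) {
    stop("correlation undefined: at least one profile is constant")
  }
  stats::cor(a$values, b$values)
}

#' Normalize and smooth every source in a raw profile table
#'
#' Convenience wrapper: splits a combined table on `source_id`, applies
#' [normalize_profile()] then [loess_smooth()] to each source.
#'
#' @param raw_table Data frame with columns `source_id`, `position`, `value`
#'   (and optionally `is_proxy`).
#' @inheritParams loess_smooth
#' @return A named list of [smoothed_profile()] objects.
#' @export
smooth_profiles <- function(raw_table, span = 0.5, grid_size = 1000) {
  stopifnot(is.data.frame(raw_table), "source_id" %in% names(raw_table))
  ids <- unique(as.character(raw_table$source_id))
  out <- lapply(ids, function(id) {
    sub <- raw_table[raw_table$source_id == id, , drop = FALSE]
    loess_smooth(normalize_profile(sub), span = span, grid_size = grid_size,
                 source_id = id)
  })
  names(out) <- ids
  out
}

#' Summaries of a set of smoothed profiles
#'
#' @param profiles Named list of [smoothed_profile()] objects on a shared
#'   grid.
#' @return A list with `peaks` (named vector of peak positions) and
#'   `similarity` (symmetric correlation matrix with unit diagonal).
#' @export
profile_summaries <- function(profiles) {
  ids <- vapply(profiles, function(p) p$source_id, character(1))
  peaks <- vapply(profiles, peak_position, numeric(1))
  names(peaks) <- ids
  n <- length(profiles)
  sim <- diag(1, n)
  dimnames(sim) <- list(ids, ids)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        sim[i, j] <- sim[j, i] <- profile_similarity(profiles[[i]],
                                                     profiles[[j]])
      }
    }
  }
  list(peaks = peaks, similarity = sim)
}
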