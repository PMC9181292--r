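#' Percentage fitness loss from a blue/white competition replicate
#'
#' In the competition assay the wild type carries lacZ (blue colonies on
#' X-gal/IPTG plates) and the mutant is a lacZ deletion (white). With
#' x = blue/white at t = 0 and y = blue/white at t = 12 h, the mutant's
#' percentage loss in fitness is 100 (y - x) / x: positive when the white
#' mutant loses ground to the blue wild type.
#'
#' All arguments are vectorized over replicates.
#'
#' @param blue_t0,white_t0,blue_t12,white_t12 Colony-forming-unit counts.
#' @return Percentage loss in fitness (one value per replicate).
#' @examples
#' fitness_loss(100, 100, 120, 100)  # 20
#' @export
fitness_loss <- function(blue_t0, white_t0, blue_t12, white_t12) {
  counts <- cbind(blue_t0, white_t0, blue_t12, white_t12)
  if (any(counts < 0)) stop("colony counts must be non-negative")
  if (any(white_t0 == 0) || any(white_t12 == 0)) {
    stop("white CFU count of zero: blue/white ratio undefined")
  }
  if (any(blue_t0 == 0)) {
    stop("blue CFU count of zero at t = 0: x undefined as denominator")
  }
  x <- blue_t0 / white_t0
  y <- blue_t12 / white_t12
  100 * (y - x) / x
}

#' Fitness statistics for a table of competition replicates
#'
#' @param counts Data frame with columns `blue_t0`, `white_t0`, `blue_t12`,
#'   `white_t12` and optionally `replicate_id`.
#' @return A data frame with per-replicate `x`, `y` and `loss_percent`.
#' @export
competition_fitness <- function(counts) {
  req <- c("blue_t0", "white_t0", "blue_t12", "white_t12")
  if (!is.data.frame(counts) || !all(req %in% names(counts))) {
    stop("counts needs columns: ", paste(req, collapse = ", "))
  }
  data.frame(
    replicate_id = counts$replicate_id %||% seq_len(nrow(counts)),
    x = counts$blue_t0 / counts$white_t0,
    y = counts$blue_t12 / counts$white_t12,
    loss_percent = fitness_loss(counts$blue_t0, counts$white_t0,
                                counts$blue_t12, counts$white_t12),
    stringsAsFactors = FALSE
  )
}

#' Mean and standard error over replicates
#'
#' @param losses Numeric vector of per-replicate fitness-loss percentages
#'   (or any replicate statistic); at least 2 values.
#' @return A list with `mean`, `se` (sample sd / sqrt(n)) and `n`.
#' @export
summarize_fitness <- function(losses) {
  losses <- as.numeric(losses)
  if (length(losses) < 2) {
    stop("need at least 2 replicates to compute a standard error")
  }
  list(mean = mean(losses), se = stats::sd(losses) / sqrt(length(losses)),
       n = length(losses))
}

#' Two-sample t-test between replicate groups
#'
#' Welch's unequal-variance form by default; set `pooled = TRUE` for the
#' classical equal-variance test. When both groups are constant with equal
#' means the statistic is taken as t = 0, p = 1 by convention (with a
#' warning); constant groups with different means give t = +/-Inf, p = 0.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values.
#' @param pooled Use the pooled-variance (equal variance) form.
#' @return A list with `t`, `df` and `p` (two-sided).
#' @export
two_sample_t <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      warning("both groups constant with equal means: t = 0, p = 1 by ",
              "convention")
      return(list(t = 0, df = NA_real_, p = 1))
    }
    warning("both groups constant with different means: p = 0")
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = NA_real_, p = 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
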