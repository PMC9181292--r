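#' Thresholds for the expected cross-regulation rule
#'
#' The decision rule needs two cutoffs that the underlying biology does not
#' pin down exactly: how correlated two gradients must be before the sugars
#' are considered to share a pattern (`rho_homeo`), and how far apart two
#' peaks must be before one sugar genuinely precedes the other along the
#' intestine (`delta_peak`). Both are recorded in every downstream report.
#'
#' @param rho_homeo Similarity cutoff in `[-1, 1]` above which a pair is
#'   homeostatic (default 0.7).
#' @param delta_peak Minimum peak separation on the normalized `[0, 1]` axis
#'   for an anticipatory ordering (default 0.2).
#' @return A list of class `expectation_thresholds`.
#' @export
expectation_thresholds <- function(rho_homeo = 0.7, delta_peak = 0.2) {
  stopifnot(is.numeric(rho_homeo), length(rho_homeo) == 1,
            rho_homeo >= -1, rho_homeo <= 1,
            is.numeric(delta_peak), length(delta_peak) == 1, delta_peak >= 0)
  structure(list(rho_homeo = rho_homeo, delta_peak = delta_peak),
            class = "expectation_thresholds")
}

#' Classify one ordered pair of carbon sources
#'
#' Applies the expectation rule to the ordered pair (a, b), asking: growing
#' on `a`, what should happen to the catabolic genes of `b`?
#'
#' 1. If the two gradients are similar (`similarity >= rho_homeo`), the pair
#'    is *homeostatic*: the sugars co-occur, so their catabolic genes should
#'    be co-regulated (expected sign +1 by default; see
#'    [compare_maps()]'s `homeostatic_match` for the sign-agnostic reading).
#' 2. Otherwise, if `b` peaks at least `delta_peak` further down the
#'    intestine than `a`, the pair is *anticipatory*: `a` should pre-induce
#'    `b`'s genes (expected +1).
#' 3. Otherwise, if `a` peaks at least `delta_peak` below `b`'s, the pair is
#'    a *random-response candidate*: inducing the genes of an upstream sugar
#'    while sitting downstream has no anticipatory rationale (expected 0; a
#'    measured induction here is a "random response").
#' 4. Otherwise (dissimilar but peaks too close to order) the pair is
#'    homeostatic with expected sign 0.
#'
#' Similarity is evaluated before peak ordering, so homeostatic labeling is
#' symmetric in a and b, and the anticipatory / random-candidate labels are
#' mutually converse.
#'
#' @param a,b [smoothed_profile()] objects on the same grid; `a` is the
#'   growth (treatment) sugar, `b` the target sugar.
#' @param thresholds An [expectation_thresholds()] object.
#' @return A list with `expected_sign` (+1, 0) and `category`
#'   (`"anticipatory"`, `"homeostatic"`, or `"random_candidate"`).
#' @export
classify_pair <- function(a, b, thresholds = expectation_thresholds()) {
  stopifnot(inherits(thresholds, "expectation_thresholds"))
  sim <- profile_similarity(a, b)
  pa <- peak_position(a)
  pb <- peak_position(b)
  if (sim >= thresholds$rho_homeo) {
    list(expected_sign = 1L, category = "homeostatic")
  } else if (pb - pa >= thresholds$delta_peak) {
    list(expected_sign = 1L, category = "anticipatory")
  } else if (pa - pb >= thresholds$delta_peak) {
    list(expected_sign = 0L, category = "random_candidate")
  } else {
    list(expected_sign = 0L, category = "homeostatic")
  }
}

#' Build the expected cross-regulation map
#'
#' Applies [classify_pair()] to every ordered pair of distinct sources.
#' Optional overrides let curated knowledge pin individual cells: the rule is
#' a reconstruction from gradient shape alone, and published regulation for a
#' specific sugar pair takes precedence where available.
#'
#' @param profiles Named list of [smoothed_profile()] objects on a common
#'   grid.
#' @param thresholds An [expectation_thresholds()] object.
#' @param overrides Optional data frame with columns `from`, `to`,
#'   `expected_sign` whose entries replace the rule's sign for those cells
#'   (category is kept).
#' @return An `expected_map`: a data frame with columns `from`, `to`,
#'   `expected_sign`, `category`, one row per ordered pair of distinct
#'   sources, with the thresholds attached as attribute `"thresholds"`.
#' @export
build_expected_map <- function(profiles, thresholds = expectation_thresholds(),
                               overrides = NULL) {
  if (length(profiles) < 2) stop("need at least 2 profiles")
  ids <- vapply(profiles, function(p) p$source_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate source_id: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  pairs <- expand.grid(to = ids, from = ids, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)[, c("from", "to")]
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  cls <- Map(function(f, t) {
    classify_pair(profiles[[match(f, ids)]], profiles[[match(t, ids)]],
                  thresholds)
  }, pairs$from, pairs$to)
  map <- data.frame(
    from = pairs$from,
    to = pairs$to,
    expected_sign = vapply(cls, function(x) x$expected_sign, integer(1)),
    category = vapply(cls, function(x) x$category, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(map) <- NULL
  if (!is.null(overrides)) {
    stopifnot(all(c("from", "to", "expected_sign") %in% names(overrides)))
    for (k in seq_len(nrow(overrides))) {
      i <- which(map$from == overrides$from[k] & map$to == overrides$to[k])
      if (length(i) != 1) {
        stop("override for unknown pair ", overrides$from[k], " -> ",
             overrides$to[k])
      }
      map$expected_sign[i] <- as.integer(overrides$expected_sign[k])
    }
  }
  structure(map, thresholds = thresholds, sources = ids,
            class = c("expected_map", "data.frame"))
}

#' Construct an expected map directly from per-cell entries
#'
#' Used for worked examples and tests where the map is specified by hand
#' rather than derived from gradient profiles.
#'
#' @param from,to Character vectors naming the ordered pairs.
#' @param expected_sign Integer vector in `{-1, 0, 1}`.
#' @param category Character vector of pair categories.
#' @param thresholds Optional [expectation_thresholds()] for provenance.
#' @return An `expected_map` data frame.
#' @export
expected_map <- function(from, to, expected_sign, category,
                         thresholds = NULL) {
  stopifnot(length(from) == length(to),
            length(from) == length(expected_sign),
            length(from) == length(category),
            all(expected_sign %in% c(-1L, 0L, 1L)),
            all(category %in% c("anticipatory", "homeostatic",
                                "random_candidate")),
            all(from != to))
  if (anyDuplicated(paste(from, to))) stop("duplicate (from, to) pair")
  structure(
    data.frame(from = as.character(from), to = as.character(to),
               expected_sign = as.integer(expected_sign),
               category = as.character(category), stringsAsFactors = FALSE),
    thresholds = thresholds, sources = unique(c(from, to)),
    class = c("expected_map", "data.frame")
  )
}
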