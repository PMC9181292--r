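#' Score agreement between an expected and a measured relation map
#'
#' For each pair category of the expected map (anticipatory, homeostatic,
#' random candidate), counts the measured cells whose sign equals the
#' expected sign and reports the match percentage, both raw and rounded
#' half-up to the nearest integer. Cells the experiment did not measure
#' (`NA`) never enter a denominator.
#'
#' With `homeostatic_match = "same_sign"`, a homeostatic cell instead counts
#' as a match when its measured sign is non-zero and equal to the measured
#' sign of the reverse cell -- the reading under which co-occurring sugars
#' may be either co-induced or co-repressed, as long as both directions
#' agree.
#'
#' @param expected An [expected_map()] / [build_expected_map()] result.
#' @param measured A [measured_map()] / [build_measured_map()] result.
#' @param homeostatic_match `"expected_sign"` (default) or `"same_sign"`.
#' @return A list of class `concordance_report` with elements `categories`
#'   (data frame: `category`, `n_cells`, `n_match`, `percent_match`,
#'   `percent_match_rounded`), `audit` (cell-level table), and `thresholds`.
#' @export
compare_maps <- function(expected, measured,
                         homeostatic_match = c("expected_sign", "same_sign")) {
  homeostatic_match <- match.arg(homeostatic_match)
  stopifnot(inherits(expected, "expected_map"),
            inherits(measured, "measured_map"))
  if (length(intersect(unique(expected$from), unique(measured$from))) == 0 &&
      length(intersect(unique(expected$to), unique(measured$to))) == 0) {
    stop("expected and measured maps share no sources")
  }
  key_e <- paste(expected$from, expected$to, sep = "\r")
  key_m <- paste(measured$from, measured$to, sep = "\r")
  idx <- match(key_e, key_m)
  msign <- measured$sign[idx]
  rev_sign <- measured$sign[match(paste(expected$to, expected$from,
                                        sep = "\r"), key_m)]
  match_cell <- msign == expected$expected_sign
  if (homeostatic_match == "same_sign") {
    hom <- expected$category == "homeostatic"
    match_cell[hom] <- !is.na(msign[hom]) & msign[hom] != 0L &
      !is.na(rev_sign[hom]) & msign[hom] == rev_sign[hom]
    match_cell[hom & is.na(msign[hom])] <- NA
  }
  audit <- data.frame(
    from = expected$from, to = expected$to, category = expected$category,
    expected = expected$expected_sign, measured = msign,
    match = match_cell, stringsAsFactors = FALSE
  )
  cats <- c("anticipatory", "homeostatic", "random_candidate")
  rows <- lapply(cats, function(cat) {
    cells <- audit[audit$category == cat & !is.na(audit$measured), ,
                   drop = FALSE]
    n <- nrow(cells)
    m <- sum(cells$match, na.rm = TRUE)
    pct <- if (n > 0) 100 * m / n else NA_real_
    data.frame(category = cat, n_cells = n, n_match = m,
               percent_match = pct,
               percent_match_rounded = if (is.na(pct)) NA_real_ else
                 round_half_up(pct),
               stringsAsFactors = FALSE)
  })
  structure(
    list(categories = do.call(rbind, rows), audit = audit,
         thresholds = attr(expected, "thresholds")),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance between expected and measured cross-regulation\n")
  for (i in seq_len(nrow(x$categories))) {
    r <- x$categories[i, ]
    cat(sprintf("  %-17s %2d/%2d match  (%s%%)\n", r$category, r$n_match,
                r$n_cells,
                if (is.na(r$percent_match_rounded)) "NA" else
                  format(r$percent_match_rounded)))
  }
  invisible(x)
}

#' Classify measured relations as symmetric or asymmetric
#'
#' A cross-regulation is *symmetric* when both directions of a sugar pair
#' are non-zero (the pair regulates each other) and *asymmetric* when only
#' one direction is. Responses are counted per relation: a mutually
#' regulating pair is one symmetric response, a one-way cell is one
#' asymmetric response; pairs with no regulation in either direction are not
#' counted. `NA` cells are treated as unmeasured (no regulation evidence).
#'
#' @param measured A [measured_map()].
#' @return A list with `n_relations`, `n_asymmetric`, `n_symmetric`,
#'   `percent_asymmetric`, `percent_symmetric` (percentages are `NA` when no
#'   relation is counted), and `symmetric_pairs` (data frame of the mutual
#'   pairs with both signs).
#' @export
classify_symmetry <- function(measured) {
  stopifnot(inherits(measured, "measured_map"))
  key <- paste(measured$from, measured$to, sep = "\r")
  sgn <- function(f, t) {
    s <- measured$sign[match(paste(f, t, sep = "\r"), key)]
    if (length(s) == 0 || is.na(s)) 0L else s
  }
  ids <- sort(unique(c(measured$from, measured$to)))
  n_asym <- 0L
  sym <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        s_ab <- sgn(ids[i], ids[j])
        s_ba <- sgn(ids[j], ids[i])
        if (s_ab != 0L && s_ba != 0L) {
          sym[[length(sym) + 1]] <- data.frame(
            a = ids[i], b = ids[j], sign_ab = s_ab, sign_ba = s_ba,
            stringsAsFactors = FALSE
          )
        } else if (s_ab != 0L || s_ba != 0L) {
          n_asym <- n_asym + 1L
        }
      }
    }
  }
  n_sym <- length(sym)
  n <- n_asym + n_sym
  list(
    n_relations = n,
    n_asymmetric = n_asym,
    n_symmetric = n_sym,
    percent_asymmetric = if (n > 0) 100 * n_asym / n else NA_real_,
    percent_symmetric = if (n > 0) 100 * n_sym / n else NA_real_,
    symmetric_pairs = if (n_sym > 0) do.call(rbind, sym) else
      data.frame(a = character(), b = character(), sign_ab = integer(),
                 sign_ba = integer(), stringsAsFactors = FALSE)
  )
}

#' Fraction of symmetric responses that are mutual inductions
#'
#' Among the symmetric (mutually regulating) sugar pairs of a measured map,
#' the percentage in which both directions are inductions (+1), i.e. each
#' sugar induces the catabolic genes of the other.
#'
#' @param measured A [measured_map()].
#' @return A percentage in `[0, 100]`, or `NA` if the map has no symmetric
#'   relation.
#' @export
symmetric_induction_fraction <- function(measured) {
  sym <- classify_symmetry(measured)$symmetric_pairs
  if (nrow(sym) == 0) return(NA_real_)
  100 * mean(sym$sign_ab == 1L & sym$sign_ba == 1L)
}

#' Agreement between two measured maps (e.g. RNA-Seq versus RT-PCR)
#'
#' Restricted to cells measured (non-`NA`) on both platforms; the percentage
#' of those cells on which the two signed calls are equal.
#'
#' @param a,b [measured_map()] objects over the same sources.
#' @return A percentage, or `NA` if no cell is co-measured.
#' @export
cross_platform_agreement <- function(a, b) {
  stopifnot(inherits(a, "measured_map"), inherits(b, "measured_map"))
  key_a <- paste(a$from, a$to, sep = "\r")
  key_b <- paste(b$from, b$to, sep = "\r")
  idx <- match(key_a, key_b)
  sb <- b$sign[idx]
  both <- !is.na(a$sign) & !is.na(sb)
  if (!any(both)) return(NA_real_)
  100 * mean(a$sign[both] == sb[both])
}

#' Full concordance report
#'
#' Convenience wrapper assembling the category-agreement part
#' ([compare_maps()]), the symmetry statistics ([classify_symmetry()],
#' [symmetric_induction_fraction()]) and, when an RT-PCR map is supplied,
#' the cross-platform agreement ([cross_platform_agreement()]).
#'
#' @inheritParams compare_maps
#' @param rtpcr Optional second [measured_map()] (provenance `"rt_pcr"`).
#' @return A list of class `concordance_report` with the extra elements
#'   `symmetry`, `symmetric_induction_percent` and (optionally)
#'   `cross_platform_percent`.
#' @export
concordance_report <- function(expected, measured, rtpcr = NULL,
                               homeostatic_match = "expected_sign") {
  rep <- compare_maps(expected, measured,
                      homeostatic_match = homeostatic_match)
  rep$symmetry <- classify_symmetry(measured)
  rep$symmetry$symmetric_pairs <- NULL
  rep$symmetric_induction_percent <- symmetric_induction_fraction(measured)
  if (!is.null(rtpcr)) {
    rep$cross_platform_percent <- cross_platform_agreement(measured, rtpcr)
  }
  rep
}
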