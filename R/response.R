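#' Call a signed relation from a differential-expression table
#'
#' Restricts a DEG table (one treatment sugar versus the glycerol background)
#' to the catabolic gene set of a target sugar and reduces it to a single
#' signed relation: +1 if the significant set genes are mostly induced, -1 if
#' mostly repressed, 0 if none is significant or the vote ties. Genes in the
#' set but absent from the table are treated as not significant (with a
#' message), since an uncalled gene carries no evidence either way.
#'
#' @param deg Data frame with columns `gene`, `log2fc`, `pvalue`, `padj`. If
#'   `padj` is missing it is computed from `pvalue` by Benjamini-Hochberg
#'   across the supplied table.
#' @param geneset Character vector of catabolic gene identifiers (non-empty).
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @param lfc_min Minimum absolute log2 fold change (default 1).
#' @return An integer relation sign: -1, 0, or +1.
#' @export
call_relation_from_deg <- function(deg, geneset, alpha = 0.05, lfc_min = 1) {
  deg <- validate_deg_table(deg)
  if (length(geneset) == 0) stop("geneset must be non-empty")
  geneset <- unique(as.character(geneset))
  missing <- setdiff(geneset, deg$gene)
  if (length(missing) > 0) {
    message("genes not in DEG table, treated as not significant: ",
            paste(missing, collapse = ", "))
  }
  sub <- deg[deg$gene %in% geneset, , drop = FALSE]
  sig <- sub[sub$padj < alpha & abs(sub$log2fc) >= lfc_min, , drop = FALSE]
  if (nrow(sig) == 0) return(0L)
  n_up <- sum(sig$log2fc > 0)
  n_dn <- sum(sig$log2fc < 0)
  if (n_up > n_dn) 1L else if (n_dn > n_up) -1L else 0L
}

validate_deg_table <- function(deg) {
  if (!is.data.frame(deg) ||
      !all(c("gene", "log2fc", "pvalue") %in% names(deg))) {
    stop("DEG table needs columns 'gene', 'log2fc', 'pvalue' (and ideally 'padj')")
  }
  if (any(!is.finite(deg$log2fc))) stop("log2fc must be finite")
  if (any(deg$pvalue < 0 | deg$pvalue > 1, na.rm = TRUE)) {
    stop("pvalue outside [0, 1]")
  }
  if (!"padj" %in% names(deg) || all(is.na(deg$padj))) {
    deg$padj <- stats::p.adjust(deg$pvalue, method = "BH")
  }
  if (any(deg$padj < 0 | deg$padj > 1, na.rm = TRUE)) {
    stop("padj outside [0, 1]")
  }
  deg$gene <- as.character(deg$gene)
  deg
}

#' Build the measured relation map from DEG tables
#'
#' One DEG table per treatment sugar; entry (treatment, target) is the
#' majority-sign relation of the target sugar's catabolic gene set in that
#' table. Treatments without a table yield `NA` cells (not measured).
#'
#' @param deg_tables Named list of DEG data frames, one per treatment sugar.
#'   Names must be a subset of `sources`.
#' @param genesets Named list mapping each source to its catabolic gene set.
#' @param sources Character vector of all carbon sources in the map; defaults
#'   to the geneset names.
#' @param alpha,lfc_min Significance cutoffs, as in
#'   [call_relation_from_deg()].
#' @param provenance Label recorded on the map (default `"rna_seq"`).
#' @return A `measured_map`: data frame with columns `from`, `to`, `sign`
#'   (integer, `NA` allowed), one row per ordered pair of distinct sources.
#' @export
build_measured_map <- function(deg_tables, genesets, sources = names(genesets),
                               alpha = 0.05, lfc_min = 1,
                               provenance = "rna_seq") {
  stopifnot(is.list(deg_tables), is.list(genesets))
  if (is.null(names(deg_tables)) || any(names(deg_tables) == "")) {
    stop("deg_tables must be a named list (one table per treatment sugar)")
  }
  unknown <- setdiff(names(deg_tables), sources)
  if (length(unknown) > 0) {
    stop("treatment not in source list: ", paste(unknown, collapse = ", "))
  }
  if (!all(sources %in% names(genesets))) {
    stop("every source needs a gene set")
  }
  pairs <- expand.grid(to = sources, from = sources, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)[, c("from", "to")]
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  sign <- mapply(function(f, t) {
    if (!f %in% names(deg_tables)) return(NA_integer_)
    call_relation_from_deg(deg_tables[[f]], genesets[[t]],
                           alpha = alpha, lfc_min = lfc_min)
  }, pairs$from, pairs$to)
  measured_map(pairs$from, pairs$to, as.integer(sign), provenance = provenance)
}

#' Construct a measured relation map from per-cell entries
#'
#' @param from,to Character vectors of ordered source pairs.
#' @param sign Integer vector in `{-1, 0, 1, NA}` (`NA` = not measured).
#' @param provenance Label, e.g. `"rna_seq"` or `"rt_pcr"`.
#' @return A `measured_map` data frame.
#' @export
measured_map <- function(from, to, sign, provenance = "rna_seq") {
  stopifnot(length(from) == length(to), length(from) == length(sign),
            all(sign %in% c(-1L, 0L, 1L) | is.na(sign)), all(from != to))
  if (anyDuplicated(paste(from, to))) stop("duplicate (from, to) pair")
  structure(
    data.frame(from = as.character(from), to = as.character(to),
               sign = as.integer(sign), stringsAsFactors = FALSE),
    provenance = provenance, sources = unique(c(from, to)),
    class = c("measured_map", "data.frame")
  )
}

#' qPCR fold change by the delta-delta-Ct method
#'
#' For one target gene, computes per-condition delta-Ct = Ct(target) -
#' Ct(reference) (averaged over samples), then delta-delta-Ct =
#' dCt(treated) - dCt(control) and returns the linear fold change
#' 2^(-ddCt). A constitutively expressed transcript (here typically *ihfB*)
#' serves as the reference.
#'
#' @param ct Data frame with columns `sample`, `condition` (`"control"` /
#'   `"treated"`), `target_gene`, `ct_target`, `ct_reference`.
#' @param target_gene Gene to quantify; both conditions must be present.
#' @return Linear fold change (treated relative to control).
#' @export
ddct_fold_change <- function(ct, target_gene) {
  req <- c("sample", "condition", "target_gene", "ct_target", "ct_reference")
  if (!is.data.frame(ct) || !all(req %in% names(ct))) {
    stop("Ct table needs columns: ", paste(req, collapse = ", "))
  }
  sub <- ct[ct$target_gene == target_gene, , drop = FALSE]
  if (any(!is.finite(sub$ct_target)) || any(!is.finite(sub$ct_reference)) ||
      any(sub$ct_target <= 0) || any(sub$ct_reference <= 0)) {
    stop("Ct values must be positive and finite")
  }
  dct <- function(cond) {
    rows <- sub[sub$condition == cond, , drop = FALSE]
    if (nrow(rows) == 0) {
      stop("missing condition '", cond, "' for target gene '", target_gene,
           "'")
    }
    mean(rows$ct_target - rows$ct_reference)
  }
  ddct <- dct("treated") - dct("control")
  2^(-ddct)
}

#' Signed relation from RT-PCR fold changes
#'
#' Reduces per-gene qPCR fold changes for a catabolic gene set to one signed
#' relation: +1 when a strict majority of the genes are at or above
#' `up_threshold`, -1 when a strict majority are at or below
#' `down_threshold`, 0 otherwise.
#'
#' @param fold_changes Numeric vector of linear fold changes (> 0), one per
#'   set gene.
#' @param up_threshold Fold at or above which a gene counts as induced
#'   (default 2).
#' @param down_threshold Fold at or below which a gene counts as repressed
#'   (default 0.5).
#' @return An integer relation sign: -1, 0, or +1.
#' @export
relation_from_rtpcr <- function(fold_changes, up_threshold = 2,
                                down_threshold = 0.5) {
  if (length(fold_changes) == 0) stop("need at least one fold change")
  if (any(!is.finite(fold_changes)) || any(fold_changes <= 0)) {
    stop("fold changes must be positive and finite")
  }
  n <- length(fold_changes)
  if (sum(fold_changes >= up_threshold) > n / 2) return(1L)
  if (sum(fold_changes <= down_threshold) > n / 2) return(-1L)
  0L
}
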