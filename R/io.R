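# Validated table readers and writers. Every reader names the file, row and
# column in its error messages so malformed literature tables fail loudly.

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
}

check_numeric <- function(df, cols, path) {
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(v2 <- as.numeric(as.character(v)))
      bad <- which(is.na(v2) & !is.na(v))
      if (length(bad) > 0) {
        stop("file '", path, "', column '", col, "': non-numeric value at ",
             "row ", bad[1])
      }
      df[[col]] <- v2
    }
    if (anyNA(df[[col]])) {
      stop("file '", path, "', column '", col, "': missing value at row ",
           which(is.na(df[[col]]))[1])
    }
  }
  df
}

#' Read a combined raw gradient profile table
#'
#' CSV with header `source_id,position,value,is_proxy`; one file may hold
#' all carbon sources.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("source_id", "position", "value"), path)
  df <- check_numeric(df, c("position", "value"), path)
  neg <- which(df$value < 0)
  if (length(neg) > 0) {
    stop("file '", path, "': negative concentration at row ", neg[1])
  }
  if (!"is_proxy" %in% names(df)) df$is_proxy <- FALSE
  df$source_id <- as.character(df$source_id)
  df
}

#' Read a differential-expression table
#'
#' TSV with header `gene,log2fc,pvalue,padj` (`padj` optional; computed by
#' Benjamini-Hochberg from `pvalue` when absent).
#'
#' @param path TSV file path.
#' @return A validated DEG data frame.
#' @export
read_deg_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("gene", "log2fc", "pvalue"), path)
  df <- check_numeric(df, intersect(c("log2fc", "pvalue", "padj"),
                                    names(df)), path)
  if (anyDuplicated(df$gene)) {
    stop("file '", path, "': duplicate gene at row ",
         which(duplicated(df$gene))[1])
  }
  validate_deg_table(df)
}

#' Read a gene-set map
#'
#' TSV with header `source_id,gene`, one row per (source, gene).
#'
#' @param path TSV file path.
#' @return A named list of character vectors.
#' @export
read_genesets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("source_id", "gene"), path)
  sets <- split(as.character(df$gene), df$source_id)
  for (s in names(sets)) {
    if (anyDuplicated(sets[[s]])) {
      stop("file '", path, "': duplicate gene '",
           sets[[s]][duplicated(sets[[s]])][1], "' in set '", s, "'")
    }
    if (length(sets[[s]]) == 0) stop("empty gene set for '", s, "'")
  }
  sets
}

#' Read competition colony counts
#'
#' CSV with header
#' `replicate_id,blue_t0,white_t0,blue_t12,white_t12[,condition]`.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_competition_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("replicate_id", "blue_t0", "white_t0", "blue_t12",
                      "white_t12"), path)
  df <- check_numeric(df, c("blue_t0", "white_t0", "blue_t12", "white_t12"),
                      path)
  neg <- which(df$blue_t0 < 0 | df$white_t0 < 0 | df$blue_t12 < 0 |
                 df$white_t12 < 0)
  if (length(neg) > 0) {
    stop("file '", path, "': negative colony count at row ", neg[1])
  }
  df
}

#' Read OD600 growth curves
#'
#' CSV with header `time_h,od,source_id,concentration_mM,replicate`.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_growth_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("time_h", "od", "source_id", "concentration_mM",
                      "replicate"), path)
  df <- check_numeric(df, c("time_h", "od", "concentration_mM"), path)
  neg <- which(df$od < 0)
  if (length(neg) > 0) {
    stop("file '", path, "': negative OD at row ", neg[1])
  }
  df
}

#' Read a qPCR Ct table
#'
#' CSV with header `sample,condition,target_gene,ct_target,ct_reference`.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample", "condition", "target_gene", "ct_target",
                      "ct_reference"), path)
  df <- check_numeric(df, c("ct_target", "ct_reference"), path)
  bad <- which(!df$condition %in% c("control", "treated"))
  if (length(bad) > 0) {
    stop("file '", path, "', column 'condition': expected 'control' or ",
         "'treated' at row ", bad[1])
  }
  df
}

#' Read a reporter-screen plate table
#'
#' CSV with header `colony_id,od_control,gfp_control,od_treated,gfp_treated`.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_screen_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("colony_id", "od_control", "gfp_control", "od_treated",
                      "gfp_treated"), path)
  df <- check_numeric(df, c("od_control", "gfp_control", "od_treated",
                            "gfp_treated"), path)
  if (anyDuplicated(df$colony_id)) {
    stop("file '", path, "': duplicate colony_id at row ",
         which(duplicated(df$colony_id))[1])
  }
  df
}

#' Read flow-cytometry events
#'
#' CSV with header `fsc,ssc,fl1` (plain tables, no FCS binary parsing).
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_flow_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("fsc", "ssc", "fl1"), path)
  check_numeric(df, c("fsc", "ssc", "fl1"), path)
}

#' Write smoothed profiles as a long TSV
#'
#' Columns `source_id,grid_position,smoothed_value`.
#'
#' @param profiles Named list of [smoothed_profile()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_smoothed_tsv <- function(profiles, path) {
  long <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(source_id = p$source_id, grid_position = p$grid,
               smoothed_value = p$values, stringsAsFactors = FALSE)
  }))
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read smoothed profiles written by [write_smoothed_tsv()]
#'
#' @param path TSV path.
#' @return Named list of [smoothed_profile()] objects.
#' @export
read_smoothed_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("source_id", "grid_position", "smoothed_value"), path)
  out <- lapply(split(df, df$source_id), function(sub) {
    sub <- sub[order(sub$grid_position), , drop = FALSE]
    smoothed_profile(sub$source_id[1], sub$grid_position,
                     sub$smoothed_value)
  })
  out[unique(df$source_id)]
}

#' Write a relation map as TSV
#'
#' Expected maps get columns `from_source,to_source,expected_sign,category`;
#' measured maps get `from_source,to_source,sign,provenance`.
#'
#' @param map An [expected_map()] or [measured_map()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_map_tsv <- function(map, path) {
  if (inherits(map, "expected_map")) {
    out <- data.frame(from_source = map$from, to_source = map$to,
                      expected_sign = map$expected_sign,
                      category = map$category, stringsAsFactors = FALSE)
  } else if (inherits(map, "measured_map")) {
    out <- data.frame(from_source = map$from, to_source = map$to,
                      sign = map$sign,
                      provenance = attr(map, "provenance"),
                      stringsAsFactors = FALSE)
  } else {
    stop("not a relation map")
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
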