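#' Default pipeline configuration
#'
#' All tunable parameters of the analysis in one list: Loess span and grid
#' size, expectation thresholds, DEG significance cutoffs, RT-PCR fold
#' thresholds, screen threshold interpretation, flow gate quantiles, growth
#' window, and the seed recorded in reports.
#'
#' @param ... Named overrides of any default entry.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    span = 0.5,
    grid_size = 1000,
    rho_homeo = 0.7,
    delta_peak = 0.2,
    alpha = 0.05,
    lfc_min = 1,
    homeostatic_match = "expected_sign",
    rtpcr_up = 2,
    rtpcr_down = 0.5,
    screen_fold_threshold = 2,
    screen_top_k = 20,
    gate_quantiles = c(0.25, 0.75),
    mu_window = 5,
    od_floor = 0.01,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the [pipeline_config()] keys.
#' @return A full config list (missing keys at their defaults).
#' @export
read_pipeline_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(pipeline_config, over)
}

#' Write a scenario's input tables to a directory
#'
#' Materializes every generated input as the plain-text format the readers
#' consume, plus a `ground_truth.json` recording the scenario parameters
#' and planted relation map.
#'
#' @param scenario A [synthetic_scenario()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
simulate_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- generate_scenario(scenario)
  utils::write.csv(gen$gradients, file.path(dir, "gradients.csv"),
                   row.names = FALSE, quote = FALSE)
  deg_dir <- file.path(dir, "deg")
  if (!dir.exists(deg_dir)) dir.create(deg_dir)
  for (trt in names(gen$deg_tables)) {
    fname <- paste0(gsub("[^A-Za-z0-9]+", "_", trt), ".tsv")
    utils::write.table(gen$deg_tables[[trt]], file.path(deg_dir, fname),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  gs <- do.call(rbind, lapply(names(gen$genesets), function(s) {
    data.frame(source_id = s, gene = gen$genesets[[s]],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(gs, file.path(dir, "genesets.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(gen$competition, file.path(dir, "competition.csv"),
                   row.names = FALSE, quote = FALSE)
  growth <- gen$growth
  growth$source_id <- "D-galactose"
  growth$concentration_mM <- 10
  utils::write.csv(growth[, c("time_h", "od", "source_id",
                              "concentration_mM", "replicate")],
                   file.path(dir, "growth.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(gen$screen_plate, file.path(dir, "screen_plate.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(gen$flow_events, file.path(dir, "flow_events.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- list(
    seed = scenario$seed,
    epsilon = scenario$epsilon,
    sources = scenario$sources,
    planted_map = as.data.frame(gen$truth$planted_measured),
    expected_map = as.data.frame(gen$truth$expected),
    competition = scenario$competition,
    growth = scenario$growth,
    screen_positives = attr(gen$screen_plate, "positives")
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Run the gradient-to-concordance pipeline on a scenario directory
#'
#' Chains the full analysis: read and smooth the gradient tables, build the
#' expected cross-regulation map, call the measured map from the DEG
#' tables, and score concordance. When the directory also holds
#' competition, growth, screen or flow tables, the corresponding summary
#' statistics are appended. Every output is stamped with the resolved
#' configuration.
#'
#' @param dir Directory holding `gradients.csv`, `genesets.tsv` and a
#'   `deg/` subdirectory (as produced by [simulate_scenario()] or by hand).
#' @param config A [pipeline_config()] list.
#' @param out_dir Optional directory for TSV/JSON outputs; `NULL` writes
#'   nothing.
#' @return A list of class `pipeline_result` with `profiles`, `expected`,
#'   `measured`, `report`, optional extra summaries, and `config`.
#' @export
run_pipeline <- function(dir, config = pipeline_config(), out_dir = NULL) {
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  gradients <- run_stage("gradients",
                         read_profiles(file.path(dir, "gradients.csv")))
  profiles <- run_stage("gradients",
                        smooth_profiles(gradients, span = config$span,
                                        grid_size = config$grid_size))
  thresholds <- expectation_thresholds(config$rho_homeo, config$delta_peak)
  expected <- run_stage("expect", build_expected_map(profiles, thresholds))
  genesets <- run_stage("respond",
                        read_genesets(file.path(dir, "genesets.tsv")))
  deg_dir <- file.path(dir, "deg")
  deg_files <- if (dir.exists(deg_dir)) {
    list.files(deg_dir, pattern = "\\.tsv$", full.names = TRUE)
  } else character()
  sources <- names(profiles)
  slug <- gsub("[^A-Za-z0-9]+", "_", sources)
  measured <- NULL
  report <- NULL
  if (length(deg_files) > 0) {
    deg_tables <- run_stage("respond", {
      tabs <- lapply(deg_files, read_deg_table)
      got <- sub("\\.tsv$", "", basename(deg_files))
      idx <- match(got, slug)
      if (anyNA(idx)) {
        stop("DEG table '", got[is.na(idx)][1],
             "' does not match any gradient source")
      }
      names(tabs) <- sources[idx]
      tabs
    })
    measured <- run_stage("respond",
                          build_measured_map(deg_tables, genesets,
                                             sources = sources,
                                             alpha = config$alpha,
                                             lfc_min = config$lfc_min))
    report <- run_stage("concord",
                        concordance_report(
                          expected, measured,
                          homeostatic_match = config$homeostatic_match))
  }
  result <- list(profiles = profiles, expected = expected,
                 measured = measured, report = report)
  comp_path <- file.path(dir, "competition.csv")
  if (file.exists(comp_path)) {
    counts <- run_stage("fitness", read_competition_counts(comp_path))
    fit <- run_stage("fitness", competition_fitness(counts))
    result$fitness <- c(list(per_replicate = fit),
                        summarize_fitness(fit$loss_percent))
  }
  growth_path <- file.path(dir, "growth.csv")
  if (file.exists(growth_path)) {
    growth <- run_stage("growth", read_growth_curves(growth_path))
    result$growth <- run_stage("growth",
                               growth_rates(growth,
                                            window = config$mu_window,
                                            od_floor = config$od_floor))
  }
  screen_path <- file.path(dir, "screen_plate.csv")
  if (file.exists(screen_path)) {
    plate <- run_stage("screen", read_screen_plate(screen_path))
    pos <- run_stage("screen",
                     screen_positives(plate,
                                      config$screen_fold_threshold))
    result$screen <- list(n_screened = nrow(plate), n_positive = nrow(pos),
                          top = top_k(pos, config$screen_top_k))
  }
  flow_path <- file.path(dir, "flow_events.csv")
  if (file.exists(flow_path)) {
    events <- run_stage("screen", read_flow_events(flow_path))
    result$flow <- run_stage("screen",
                             gate_and_summarize(events,
                                                config$gate_quantiles))
  }
  result$config <- config
  class(result) <- "pipeline_result"
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_smoothed_tsv(profiles, file.path(out_dir, "smoothed.tsv"))
    write_map_tsv(expected, file.path(out_dir, "expected_map.tsv"))
    if (!is.null(measured)) {
      write_map_tsv(measured, file.path(out_dir, "measured_map.tsv"))
    }
    if (!is.null(report)) {
      utils::write.table(report$audit, file.path(out_dir, "audit.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      json <- list(config = config,
                   categories = report$categories,
                   symmetry = report$symmetry,
                   symmetric_induction_percent =
                     report$symmetric_induction_percent)
      jsonlite::write_json(json, file.path(out_dir, "concordance.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
    }
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", length(x$profiles), "profiles,",
      nrow(x$expected), "expected-map cells\n")
  if (!is.null(x$report)) print(x$report)
  if (!is.null(x$fitness)) {
    cat(sprintf("Fitness loss: mean %.1f%% (SE %.2f, n = %d)\n",
                x$fitness$mean, x$fitness$se, x$fitness$n))
  }
  invisible(x)
}
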