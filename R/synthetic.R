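#' Generate a raw concentration-versus-position table
#'
#' Emulates a literature gradient table: a Gaussian bump of abundance
#' centered on the planted peak, sampled at irregular positions (the two
#' intestinal extremes plus uniformly scattered interior sites, mimicking
#' studies that report a handful of unevenly spaced segments), with additive
#' Gaussian noise clipped at zero.
#'
#' All `gen_*` generators are pure functions of their arguments and `seed`:
#' the same call yields the identical table.
#'
#' @param source_id Carbon-source identifier.
#' @param peak Planted peak position in `[0, 1]`.
#' @param width Bump standard deviation (default 0.15).
#' @param n Number of sampled positions (>= 3, default 25).
#' @param noise_sd Additive Gaussian noise sd (default 0.05).
#' @param seed Integer seed.
#' @param is_proxy Mark the values as an enzyme-activity proxy.
#' @return A data frame with columns `source_id`, `position`, `value`,
#'   `is_proxy`.
#' @export
gen_gradient_table <- function(source_id, peak, width = 0.15, n = 25,
                               noise_sd = 0.05, seed = 1, is_proxy = FALSE) {
  if (n < 3) stop("need at least 3 sampled positions")
  stopifnot(peak >= 0, peak <= 1, width > 0, noise_sd >= 0)
  withr::with_seed(seed, {
    pos <- sort(c(0, 1, stats::runif(n - 2)))
    val <- exp(-((pos - peak)^2) / (2 * width^2)) +
      stats::rnorm(n, 0, noise_sd)
  })
  data.frame(source_id = as.character(source_id), position = pos,
             value = pmax(val, 0), is_proxy = is_proxy,
             stringsAsFactors = FALSE)
}

#' Generate a differential-expression table for one treatment sugar
#'
#' Plants the signed relations of one row of a relation map into a DEG
#' table: catabolic genes of a target with planted sign s != 0 receive
#' log2 fold changes ~ Normal(s * effect, sd) and near-zero p-values; genes
#' of targets with planted sign 0, and `n_null` filler genes, receive
#' null-like effects ~ Normal(0, sd) and uniform p-values. Adjusted
#' p-values are computed across the whole table by Benjamini-Hochberg.
#'
#' @param planted_signs Named integer vector: target source -> sign in
#'   `{-1, 0, 1}`.
#' @param genesets Named list mapping each target source to its catabolic
#'   genes; must cover `names(planted_signs)`.
#' @param effect Planted absolute log2 fold change (>= 0, default 2).
#' @param sd Within-set log2fc standard deviation (default 0.25).
#' @param n_null Number of unrelated null genes (default 500).
#' @param seed Integer seed.
#' @return A DEG data frame: `gene`, `log2fc`, `pvalue`, `padj`.
#' @export
gen_deg_table <- function(planted_signs, genesets, effect = 2, sd = 0.25,
                          n_null = 500, seed = 1) {
  if (effect < 0) stop("effect must be non-negative")
  if (!all(names(planted_signs) %in% names(genesets))) {
    stop("genesets must cover every planted target")
  }
  withr::with_seed(seed, {
    rows <- lapply(names(planted_signs), function(target) {
      genes <- genesets[[target]]
      s <- planted_signs[[target]]
      k <- length(genes)
      if (s != 0) {
        data.frame(gene = genes,
                   log2fc = stats::rnorm(k, s * effect, sd),
                   pvalue = stats::runif(k, 1e-10, 1e-6),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(gene = genes,
                   log2fc = stats::rnorm(k, 0, sd),
                   pvalue = stats::runif(k),
                   stringsAsFactors = FALSE)
      }
    })
    null <- data.frame(
      gene = sprintf("null_%04d", seq_len(n_null)),
      log2fc = stats::rnorm(n_null, 0, sd),
      pvalue = stats::runif(n_null),
      stringsAsFactors = FALSE
    )
  })
  deg <- rbind(do.call(rbind, rows), null)
  deg$padj <- stats::p.adjust(deg$pvalue, method = "BH")
  rownames(deg) <- NULL
  deg
}

#' Generate blue/white competition colony counts
#'
#' Models the mutant's planted fractional fitness deficit `d` as the
#' wild-type/mutant CFU ratio growing by the factor 1/(1 - d) between t = 0
#' and t = 12 h, so the expected value of the fitness-loss statistic is
#' 100 d / (1 - d) in closed form. Counts are Poisson-sampled around their
#' expectations; t = 12 h expectations carry an overall growth factor that
#' cancels from the ratio.
#'
#' @param d Planted fractional deficit of the white mutant, `0 <= d < 1`.
#' @param n0 Expected CFU count per class at t = 0 (default 500; a warning
#'   is issued below 50, where sampling noise dominates).
#' @param replicates Number of biological replicates (default 4).
#' @param growth Overall CFU growth factor between the time points
#'   (default 4).
#' @param seed Integer seed.
#' @return A data frame with columns `replicate_id`, `blue_t0`, `white_t0`,
#'   `blue_t12`, `white_t12`.
#' @export
gen_competition_counts <- function(d, n0 = 500, replicates = 4, growth = 4,
                                   seed = 1) {
  stopifnot(d >= 0, d < 1, replicates >= 1, growth > 0)
  if (n0 < 50) {
    warning("n0 < 50: Poisson sampling noise will dominate the loss estimate")
  }
  withr::with_seed(seed, {
    out <- data.frame(
      replicate_id = seq_len(replicates),
      blue_t0 = stats::rpois(replicates, n0),
      white_t0 = stats::rpois(replicates, n0),
      blue_t12 = stats::rpois(replicates, growth * n0 / (1 - d)),
      white_t12 = stats::rpois(replicates, growth * n0)
    )
  })
  # zero counts break the ratio; at the intended scales (n0 >= 50) a zero
  # draw is practically impossible, but guard anyway
  out$blue_t0 <- pmax(out$blue_t0, 1L)
  out$white_t0 <- pmax(out$white_t0, 1L)
  out$white_t12 <- pmax(out$white_t12, 1L)
  out
}

#' Generate logistic OD600 growth curves
#'
#' Logistic trajectories sampled every `dt` hours over `hours` hours (the
#' default 15-min spacing over 24 h gives 97 readings), with additive
#' Gaussian noise clipped at zero.
#'
#' @param rate Intrinsic growth rate in 1/h (> 0).
#' @param capacity Carrying capacity (OD units, > od0).
#' @param od0 Inoculum OD (> 0, default 0.01).
#' @param noise_sd Additive noise sd (default 0).
#' @param hours Total duration (default 24).
#' @param dt Sampling interval in hours (default 0.25).
#' @param replicates Number of replicate curves (default 1).
#' @param seed Integer seed.
#' @return A data frame with columns `time_h`, `od`, `replicate`.
#' @export
gen_growth_curves <- function(rate, capacity = 1, od0 = 0.01, noise_sd = 0,
                              hours = 24, dt = 0.25, replicates = 1,
                              seed = 1) {
  stopifnot(rate > 0, capacity > od0, od0 > 0, noise_sd >= 0)
  times <- seq(0, hours, by = dt)
  clean <- capacity / (1 + ((capacity - od0) / od0) * exp(-rate * times))
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      data.frame(time_h = times,
                 od = pmax(clean + stats::rnorm(length(times), 0, noise_sd),
                           0),
                 replicate = r)
    }))
  })
  out
}

#' Generate a reporter-screen plate with planted positives
#'
#' Colony OD and GFP readings are lognormal; a planted subset of colonies
#' has its treated GFP signal multiplied by `effect_fold`, while the rest
#' fluctuate around fold 1 with lognormal noise of log-sd `noise_sd`. The
#' planted positive colony ids are attached as attribute `"positives"`.
#'
#' @param n Number of colonies (default 455).
#' @param n_positive Number of planted positives (default 31, `<= n`).
#' @param effect_fold Planted fold change of positives (default 4).
#' @param noise_sd Lognormal log-sd of the colony-to-colony fold noise
#'   (default 0.05).
#' @param seed Integer seed.
#' @return A data frame with columns `colony_id`, `od_control`,
#'   `gfp_control`, `od_treated`, `gfp_treated`; planted ids in
#'   `attr(, "positives")`.
#' @export
gen_screen_plate <- function(n = 455, n_positive = 31, effect_fold = 4,
                             noise_sd = 0.05, seed = 1) {
  stopifnot(n >= 1, n_positive >= 0, n_positive <= n, effect_fold > 0,
            noise_sd >= 0)
  ids <- sprintf("C%04d", seq_len(n))
  withr::with_seed(seed, {
    pos <- sort(sample(n, n_positive))
    od_c <- stats::rlnorm(n, log(0.5), 0.05)
    od_t <- stats::rlnorm(n, log(0.5), 0.05)
    gfp_c <- stats::rlnorm(n, log(1000), 0.1)
    fold <- stats::rlnorm(n, 0, noise_sd)
    fold[pos] <- fold[pos] * effect_fold
    gfp_t <- (gfp_c / od_c) * fold * od_t
  })
  structure(
    data.frame(colony_id = ids, od_control = od_c, gfp_control = gfp_c,
               od_treated = od_t, gfp_treated = gfp_t,
               stringsAsFactors = FALSE),
    positives = ids[pos]
  )
}

#' Generate flow-cytometry events
#'
#' Draws a main cell population with lognormal forward scatter, side
#' scatter and FL1 (GFP) intensity, plus an optional outlier population
#' (debris / aggregates) with shifted scatter and its own fluorescence,
#' shuffled together.
#'
#' @param n Number of events (default 20000).
#' @param fl1_meanlog,fl1_sdlog Main-population FL1 log-mean and log-sd.
#' @param fsc_meanlog,ssc_meanlog Main-population scatter log-means.
#' @param scatter_sdlog Scatter log-sd (default 0.15).
#' @param outlier_frac Fraction of events from the outlier population
#'   (default 0).
#' @param outlier_shift Added to the outlier population's scatter log-means
#'   (default 1.5).
#' @param outlier_fl1_meanlog Outlier FL1 log-mean (default
#'   `fl1_meanlog + 2`).
#' @param seed Integer seed.
#' @return A data frame with columns `fsc`, `ssc`, `fl1`.
#' @export
gen_flow_events <- function(n = 20000, fl1_meanlog = log(500),
                            fl1_sdlog = 0.3, fsc_meanlog = log(5e4),
                            ssc_meanlog = log(2e4), scatter_sdlog = 0.15,
                            outlier_frac = 0, outlier_shift = 1.5,
                            outlier_fl1_meanlog = fl1_meanlog + 2,
                            seed = 1) {
  stopifnot(n >= 1, outlier_frac >= 0, outlier_frac < 1)
  withr::with_seed(seed, {
    n_out <- round(n * outlier_frac)
    n_main <- n - n_out
    main <- data.frame(
      fsc = stats::rlnorm(n_main, fsc_meanlog, scatter_sdlog),
      ssc = stats::rlnorm(n_main, ssc_meanlog, scatter_sdlog),
      fl1 = stats::rlnorm(n_main, fl1_meanlog, fl1_sdlog)
    )
    if (n_out > 0) {
      out <- data.frame(
        fsc = stats::rlnorm(n_out, fsc_meanlog + outlier_shift,
                            scatter_sdlog),
        ssc = stats::rlnorm(n_out, ssc_meanlog + outlier_shift,
                            scatter_sdlog),
        fl1 = stats::rlnorm(n_out, outlier_fl1_meanlog, fl1_sdlog)
      )
      main <- rbind(main, out)
    }
    main <- main[sample(nrow(main)), , drop = FALSE]
  })
  rownames(main) <- NULL
  main
}

#' Generate a Ct table consistent with a planted fold change
#'
#' Reference-gene Ct values are drawn around `ct_reference`; the target's
#' control delta-Ct is `dct_control`, and the treated delta-Ct is shifted by
#' -log2(fold) so that the delta-delta-Ct fold change recovers `fold` in
#' expectation.
#'
#' @param target_gene Gene name.
#' @param fold Planted linear fold change (> 0).
#' @param samples Samples per condition (default 3).
#' @param ct_reference Mean reference Ct (default 18).
#' @param dct_control Control delta-Ct (default 4).
#' @param noise_sd Ct measurement noise sd (default 0).
#' @param seed Integer seed.
#' @return A Ct data frame as consumed by [ddct_fold_change()].
#' @export
gen_ct_table <- function(target_gene, fold, samples = 3, ct_reference = 18,
                         dct_control = 4, noise_sd = 0, seed = 1) {
  stopifnot(fold > 0, samples >= 1, noise_sd >= 0)
  withr::with_seed(seed, {
    conds <- rep(c("control", "treated"), each = samples)
    ref <- ct_reference + stats::rnorm(2 * samples, 0, noise_sd)
    dct <- ifelse(conds == "control", dct_control,
                  dct_control - log2(fold))
    tgt <- ref + dct + stats::rnorm(2 * samples, 0, noise_sd)
  })
  data.frame(
    sample = sprintf("S%d", seq_len(2 * samples)),
    condition = conds, target_gene = target_gene,
    ct_target = tgt, ct_reference = ref, stringsAsFactors = FALSE
  )
}

#' Randomly perturb the cells of a relation map
#'
#' With probability `epsilon`, each non-`NA` cell's sign is replaced by one
#' of the two other signs (chosen uniformly), guaranteeing the perturbed
#' cell no longer matches. Used to study how concordance degrades with
#' measurement error.
#'
#' @param map An [expected_map()] or [measured_map()].
#' @param epsilon Per-cell flip probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param provenance Provenance tag of the returned measured map.
#' @return A [measured_map()] whose signs are the (possibly flipped)
#'   expected signs.
#' @export
perturb_map <- function(map, epsilon, seed = 1, provenance = "rna_seq") {
  stopifnot(epsilon >= 0, epsilon <= 1)
  sign <- if (inherits(map, "expected_map")) map$expected_sign else map$sign
  withr::with_seed(seed, {
    flip <- stats::runif(length(sign)) < epsilon
    pick <- stats::runif(length(sign))
    for (i in which(flip & !is.na(sign))) {
      others <- setdiff(c(-1L, 0L, 1L), sign[i])
      sign[i] <- others[1 + (pick[i] > 0.5)]
    }
  })
  measured_map(map$from, map$to, sign, provenance = provenance)
}

#' Default seven-source panel for synthetic scenarios
#'
#' Seven carbon sources with planted gradient peaks along the normalized
#' intestine (0 = anterior), arranged as three spatial clusters: an
#' anterior cluster (lactose, galactose), a mid-intestinal cluster
#' (glucose, fructose) and a distal cluster (trehalose, oleic acid,
#' maltose). The placements are synthetic choices consistent with lactose
#' and galactose peaking anteriorly and maltose distally; clustering keeps
#' every pair far from the classification boundaries (within-cluster
#' similarity above 0.9, between-cluster peak separation at least 0.34),
#' so the planted cross-regulation map is identifiable from the sampled
#' tables themselves.
#'
#' @return A data frame with columns `source_id`, `peak`, `width`, `n`,
#'   `noise_sd`.
#' @export
default_source_specs <- function() {
  data.frame(
    source_id = c("D-lactose", "D-galactose", "D-glucose", "D-fructose",
                  "D-trehalose", "Oleic acid", "D-maltose"),
    peak = c(0.06, 0.10, 0.44, 0.48, 0.82, 0.86, 0.90),
    width = 0.15, n = 25, noise_sd = 0.05,
    stringsAsFactors = FALSE
  )
}

#' Default catabolic gene sets
#'
#' Standard operon members for each carbon source's catabolism. Set
#' membership is data, not code: the same table ships as the editable
#' fixture `catabolic_gene_sets.tsv` under `inst/extdata`.
#'
#' @return A named list of character vectors.
#' @export
default_genesets <- function() {
  list(
    "D-lactose" = c("lacZ", "lacY", "lacA"),
    "D-galactose" = c("galE", "galT", "galK", "galM"),
    "D-glucose" = c("ptsG", "crr", "glk"),
    "D-fructose" = c("fruA", "fruB", "fruK"),
    "D-trehalose" = c("treB", "treC"),
    "Oleic acid" = c("fadL", "fadD", "fadE"),
    "D-maltose" = c("malE", "malF", "malG", "malP", "malQ", "malT")
  )
}

#' Parameterize a complete synthetic study
#'
#' Bundles every generator's parameters, with defaults emulating the study
#' design: seven carbon sources with spatially ordered gradient peaks,
#' catabolic gene sets per sugar, DEG effect sizes, competition deficits,
#' logistic growth, a 455-colony screen with 31 planted positives, and
#' 20000 flow events. The planted cross-regulation map is the expected map
#' computed from the noiseless bump profiles, optionally perturbed by a
#' cellwise flip probability `epsilon`.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param sources Data frame of source specs (`source_id`, `peak`, `width`,
#'   `n`, `noise_sd`); defaults to the seven-source panel.
#' @param genesets Named list of catabolic gene sets.
#' @param thresholds [expectation_thresholds()] used for the planted map.
#' @param epsilon Cellwise flip probability applied to the planted map
#'   before DEG generation (default 0).
#' @param deg List of DEG-generator parameters (`effect`, `sd`, `n_null`).
#' @param competition List of competition parameters (`d`, `n0`,
#'   `replicates`, `growth`).
#' @param growth List of growth parameters (`rate`, `capacity`, `od0`,
#'   `noise_sd`).
#' @param screen List of screen parameters (`n`, `n_positive`,
#'   `effect_fold`, `noise_sd`).
#' @param flow List of flow parameters passed to [gen_flow_events()].
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1,
                               sources = default_source_specs(),
                               genesets = default_genesets(),
                               thresholds = expectation_thresholds(),
                               epsilon = 0,
                               deg = list(effect = 2, sd = 0.25,
                                          n_null = 500),
                               competition = list(d = 0.15, n0 = 500,
                                                  replicates = 4,
                                                  growth = 4),
                               growth = list(rate = 0.5, capacity = 1,
                                             od0 = 0.01, noise_sd = 0),
                               screen = list(n = 455, n_positive = 31,
                                             effect_fold = 4,
                                             noise_sd = 0.05),
                               flow = list(n = 20000)) {
  stopifnot(is.data.frame(sources),
            all(sources$source_id %in% names(genesets)))
  structure(
    list(seed = as.integer(seed), sources = sources, genesets = genesets,
         thresholds = thresholds, epsilon = epsilon, deg = deg,
         competition = competition, growth = growth, screen = screen,
         flow = flow),
    class = "synthetic_scenario"
  )
}

# Deterministic per-stage seed derived from the master seed. Kept well
# below .Machine$integer.max.
stage_seed <- function(seed, stage, k = 0L) {
  (as.integer(seed) * 97L + stage * 1009L + k) %% 2147483581L
}

#' Planted ideal profiles and relation map of a scenario
#'
#' The scenario's ground truth: each source's noiseless Gaussian bump
#' evaluated directly on the smoothing grid (min-max normalized), the
#' expected map those ideal profiles imply, and the planted measured map
#' (the expected map after the scenario's `epsilon` cellwise flips).
#'
#' @param scenario A [synthetic_scenario()].
#' @param grid_size Grid resolution (default 1000).
#' @return A list with `profiles`, `expected`, `planted_measured`.
#' @export
scenario_ground_truth <- function(scenario, grid_size = 1000) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  grid <- seq(0, 1, length.out = grid_size)
  profiles <- lapply(seq_len(nrow(scenario$sources)), function(i) {
    s <- scenario$sources[i, ]
    v <- exp(-((grid - s$peak)^2) / (2 * s$width^2))
    v <- (v - min(v)) / (max(v) - min(v))
    smoothed_profile(s$source_id, grid, v)
  })
  names(profiles) <- scenario$sources$source_id
  expected <- build_expected_map(profiles, scenario$thresholds)
  planted <- perturb_map(expected, scenario$epsilon,
                         seed = stage_seed(scenario$seed, 2L))
  list(profiles = profiles, expected = expected, planted_measured = planted)
}

#' Generate every input table of a scenario
#'
#' Runs all generators with seeds derived from the scenario's master seed
#' and returns the tables in memory, together with the ground truth.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list with `gradients` (combined raw profile table),
#'   `deg_tables` (one per treatment sugar), `genesets`, `competition`,
#'   `growth`, `screen_plate`, `flow_events`, and `truth`
#'   (see [scenario_ground_truth()]).
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  truth <- scenario_ground_truth(scenario)
  gradients <- do.call(rbind, lapply(seq_len(nrow(scenario$sources)),
                                     function(i) {
    s <- scenario$sources[i, ]
    gen_gradient_table(s$source_id, s$peak, width = s$width, n = s$n,
                       noise_sd = s$noise_sd,
                       seed = stage_seed(scenario$seed, 1L, i))
  }))
  planted <- truth$planted_measured
  srcs <- scenario$sources$source_id
  deg_tables <- lapply(seq_along(srcs), function(i) {
    trt <- srcs[i]
    rows <- planted[planted$from == trt, , drop = FALSE]
    signs <- stats::setNames(as.integer(rows$sign), rows$to)
    signs[is.na(signs)] <- 0L
    gen_deg_table(signs, scenario$genesets,
                  effect = scenario$deg$effect, sd = scenario$deg$sd,
                  n_null = scenario$deg$n_null,
                  seed = stage_seed(scenario$seed, 3L, i))
  })
  names(deg_tables) <- srcs
  competition <- gen_competition_counts(
    d = scenario$competition$d, n0 = scenario$competition$n0,
    replicates = scenario$competition$replicates,
    growth = scenario$competition$growth,
    seed = stage_seed(scenario$seed, 4L)
  )
  growth <- gen_growth_curves(
    rate = scenario$growth$rate, capacity = scenario$growth$capacity,
    od0 = scenario$growth$od0, noise_sd = scenario$growth$noise_sd,
    seed = stage_seed(scenario$seed, 5L)
  )
  screen_plate <- gen_screen_plate(
    n = scenario$screen$n, n_positive = scenario$screen$n_positive,
    effect_fold = scenario$screen$effect_fold,
    noise_sd = scenario$screen$noise_sd,
    seed = stage_seed(scenario$seed, 6L)
  )
  flow_events <- do.call(gen_flow_events,
                         c(scenario$flow,
                           list(seed = stage_seed(scenario$seed, 7L))))
  list(gradients = gradients, deg_tables = deg_tables,
       genesets = scenario$genesets, competition = competition,
       growth = growth, screen_plate = screen_plate,
       flow_events = flow_events, truth = truth)
}
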