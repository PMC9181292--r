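# Shared fixtures built in code.

# A smoothed profile from a Gaussian bump evaluated directly on the grid.
bump_profile <- function(id, peak, width = 0.1, grid_size = 201) {
  grid <- seq(0, 1, length.out = grid_size)
  v <- exp(-((grid - peak)^2) / (2 * width^2))
  smoothed_profile(id, grid, (v - min(v)) / (max(v) - min(v)))
}

# Worked-example maps over seven sources: 18 homeostatic cells (3 measured
# mismatches), 3 random-candidate cells (none matching), 21 anticipatory
# cells (all matching).
worked_example_maps <- function() {
  ids <- paste0("s", 1:7)
  pairs <- expand.grid(to = ids, from = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, c("from", "to")]
  n <- nrow(pairs) # 42
  category <- c(rep("homeostatic", 18), rep("random_candidate", 3),
                rep("anticipatory", n - 21))
  expected_sign <- ifelse(category == "random_candidate", 0L, 1L)
  exp_map <- expected_map(pairs$from, pairs$to, expected_sign, category)
  sign <- expected_sign
  sign[1:3] <- 0L     # three homeostatic mismatches
  sign[19:21] <- 1L   # random-candidate cells measured as inductions
  list(expected = exp_map,
       measured = measured_map(pairs$from, pairs$to, sign))
}

# Map with 11 one-way non-zero cells and 5 mutually non-zero pairs, of
# which 4 are mutual inductions: the smallest integer composition that
# yields a 68.75% / 31.25% symmetry split and an 80% induction fraction.
symmetry_example_map <- function() {
  ids <- paste0("s", 1:7)
  pairs <- expand.grid(to = ids, from = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, c("from", "to")]
  key <- paste(pairs$from, pairs$to)
  sign <- rep(0L, nrow(pairs))
  sym <- list(c("s1", "s2"), c("s1", "s3"), c("s1", "s4"), c("s2", "s3"))
  for (p in sym) {
    sign[key == paste(p[1], p[2])] <- 1L
    sign[key == paste(p[2], p[1])] <- 1L
  }
  sign[key == "s2 s4"] <- 1L  # fifth symmetric pair, mixed signs
  sign[key == "s4 s2"] <- -1L
  oneway <- list(c("s1", "s5"), c("s1", "s6"), c("s1", "s7"), c("s2", "s5"),
                 c("s2", "s6"), c("s3", "s5"), c("s3", "s6"), c("s4", "s5"),
                 c("s5", "s6"), c("s6", "s7"), c("s7", "s5"))
  for (p in oneway) sign[key == paste(p[1], p[2])] <- 1L
  measured_map(pairs$from, pairs$to, sign)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "anticipatr", mustWork = TRUE)
}
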