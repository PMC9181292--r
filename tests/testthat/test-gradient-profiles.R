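test_that("normalize_profile maps both axes affinely onto [0, 1]", {
  out <- normalize_profile(data.frame(position = c(0, 5, 10),
                                      value = c(2, 4, 6)))
  expect_equal(out$position, c(0, 0.5, 1))
  expect_equal(out$value, c(0, 0.5, 1))

  # any valid input: min exactly 0, max exactly 1, elementwise equal to the
  # direct (v - min) / (max - min) formula
  withr::with_seed(11, {
    for (k in 1:5) {
      raw <- data.frame(position = sort(sample(100, 10)),
                        value = runif(10, 2, 9))
      out <- normalize_profile(raw)
      expect_identical(min(out$value), 0)
      expect_identical(max(out$value), 1)
      oracle <- function(v) (v - min(v)) / (max(v) - min(v))
      expect_equal(out$position, oracle(raw$position), tolerance = 1e-12)
      expect_equal(out$value, oracle(raw$value), tolerance = 1e-12)
    }
  })
})

test_that("normalize_profile is idempotent and rejects degenerate input", {
  raw <- data.frame(position = c(1, 4, 7, 9), value = c(3, 8, 5, 6))
  once <- normalize_profile(raw)
  expect_equal(normalize_profile(once), once, tolerance = 1e-12)
  expect_error(normalize_profile(data.frame(position = c(1, 1, 1),
                                            value = c(1, 2, 3))),
               "position")
  expect_error(normalize_profile(data.frame(position = 1:3,
                                            value = c(2, 2, 2))),
               "value")
  expect_error(normalize_profile(data.frame(position = 1:2, value = 1:2)),
               "at least 3")
})

test_that("duplicate raw positions are averaged before use", {
  raw <- data.frame(position = c(0, 5, 5, 10), value = c(0, 2, 4, 10))
  out <- normalize_profile(raw)
  expect_equal(nrow(out), 3)
  expect_equal(out$value[out$position == 0.5], 0.3) # mean(2, 4) / 10
})

test_that("loess_smooth hits the requested grid and is exact on lines", {
  raw <- normalize_profile(data.frame(position = seq(0, 10),
                                      value = seq(0, 10)))
  sp <- loess_smooth(raw, span = 1, grid_size = 1000)
  expect_length(sp$values, 1000)
  expect_identical(sp$grid[1], 0)
  expect_identical(sp$grid[1000], 1)

  sp11 <- loess_smooth(raw, span = 1, grid_size = 11)
  expect_equal(sp11$values, sp11$grid, tolerance = 1e-6)
})

test_that("loess_smooth agrees with a brute-force tricube WLS oracle", {
  # independent oracle: at one evaluation point, tricube-weight the
  # floor(span * n) nearest points and solve weighted least squares
  tricube_fit <- function(x, y, x0, span) {
    n <- length(x)
    d <- abs(x - x0)
    dq <- sort(d)[floor(span * n)]
    w <- ifelse(d <= dq, (1 - (d / dq)^3)^3, 0)
    X <- cbind(1, x[w > 0])
    W <- diag(w[w > 0])
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y[w > 0])
    beta[1] + beta[2] * x0
  }
  withr::with_seed(4, {
    x <- sort(runif(19))
    x <- (x - min(x)) / (max(x) - min(x))
    y <- sin(4 * x) + rnorm(19, 0, 0.1)
    y <- (y - min(y)) / (max(y) - min(y))
  })
  raw <- data.frame(position = x, value = y)
  for (span in c(0.4, 0.6, 1)) {
    sp <- loess_smooth(raw, span = span, grid_size = 21)
    for (i in c(1, 6, 13, 21)) {
      expect_equal(sp$values[i], tricube_fit(x, y, sp$grid[i], span),
                   tolerance = 1e-9)
    }
  }
})

test_that("loess_smooth rejects spans leaving fewer than 2 local points", {
  raw <- normalize_profile(data.frame(position = 0:9, value = (0:9)^2))
  expect_error(loess_smooth(raw, span = 0.1), "span")
})

test_that("peak_position takes the argmax with anterior tie-break", {
  expect_equal(peak_position(bump_profile("a", 0.25, grid_size = 401)), 0.25)

  inc <- smoothed_profile("inc", seq(0, 1, length.out = 101),
                          seq_len(101))
  expect_equal(peak_position(inc), 1.0)

  # plateau of equal maxima on [0.4, 0.6]: exhaustive scan confirms the
  # smallest-position tie-break
  grid <- seq(0, 1, by = 0.1)
  vals <- ifelse(grid >= 0.4 & grid <= 0.6, 1, 0.2)
  plateau <- smoothed_profile("p", grid, vals)
  expect_equal(peak_position(plateau), min(grid[vals == max(vals)]))
  expect_equal(peak_position(plateau), 0.4)
})

test_that("peak_position warns and returns 0 on flat profiles", {
  flat <- smoothed_profile("f", seq(0, 1, length.out = 11), rep(1, 11))
  expect_warning(p <- peak_position(flat), "flat")
  expect_equal(p, 0)
})

test_that("peak_position is invariant to positive value scaling", {
  p <- bump_profile("a", 0.37)
  scaled <- smoothed_profile("a", p$grid, p$values * 17.3)
  expect_equal(peak_position(p), peak_position(scaled))
})

test_that("profile_similarity is a Pearson correlation on the grid", {
  a <- bump_profile("a", 0.3)
  expect_equal(profile_similarity(a, a), 1.0)

  refl <- smoothed_profile("r", a$grid, 2 * mean(a$values) - a$values)
  expect_equal(profile_similarity(a, refl), -1.0)

  withr::with_seed(8, {
    u <- smoothed_profile("u", a$grid, runif(length(a$grid)))
    v <- smoothed_profile("v", a$grid, runif(length(a$grid)))
  })
  # direct covariance / (sd * sd) by explicit summation
  x <- u$values; y <- v$values; n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2))
  expect_equal(profile_similarity(u, v), num / den, tolerance = 1e-12)
  expect_equal(profile_similarity(u, v), profile_similarity(v, u),
               tolerance = 1e-12)
})

test_that("profile_similarity rejects constant profiles and grid mismatch", {
  a <- bump_profile("a", 0.3)
  flat <- smoothed_profile("f", a$grid, rep(1, length(a$grid)))
  expect_error(profile_similarity(a, flat), "constant")
  b <- bump_profile("b", 0.3, grid_size = 101)
  expect_error(profile_similarity(a, b), "grid")
})
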