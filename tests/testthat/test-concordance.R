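test_that("compare_maps reproduces the printed worked example", {
  maps <- worked_example_maps()
  rep <- compare_maps(maps$expected, maps$measured)
  hom <- rep$categories[rep$categories$category == "homeostatic", ]
  expect_equal(hom$n_cells, 18)
  expect_equal(hom$n_match, 15)
  expect_equal(hom$percent_match_rounded, 83)
  rnd <- rep$categories[rep$categories$category == "random_candidate", ]
  expect_equal(rnd$n_cells, 3)
  expect_equal(rnd$n_match, 0)
  expect_equal(rnd$percent_match_rounded, 0)
})

test_that("perfect agreement scores 100% in every category", {
  maps <- worked_example_maps()
  perfect <- measured_map(maps$expected$from, maps$expected$to,
                          maps$expected$expected_sign)
  rep <- compare_maps(maps$expected, perfect)
  expect_true(all(rep$categories$percent_match == 100))
})

test_that("NA cells never enter a denominator", {
  maps <- worked_example_maps()
  sgn <- maps$measured$sign
  sgn[1:10] <- NA
  with_na <- measured_map(maps$measured$from, maps$measured$to, sgn)
  rep <- compare_maps(maps$expected, with_na)
  expect_equal(sum(rep$categories$n_cells), sum(!is.na(sgn)))
})

test_that("category percentages are invariant under source relabeling", {
  maps <- worked_example_maps()
  relabel <- function(v) chartr("1234567", "4712365", v)
  exp2 <- expected_map(relabel(maps$expected$from),
                       relabel(maps$expected$to),
                       maps$expected$expected_sign,
                       maps$expected$category)
  mea2 <- measured_map(relabel(maps$measured$from),
                       relabel(maps$measured$to), maps$measured$sign)
  expect_equal(compare_maps(exp2, mea2)$categories,
               compare_maps(maps$expected, maps$measured)$categories)
})

test_that("agreement degrades as 100(1 - eps) under cellwise flips", {
  maps <- worked_example_maps()
  for (eps in c(0, 0.1, 0.3)) {
    agree <- rowMeans(vapply(1:1000, function(s) {
      flipped <- perturb_map(maps$expected, eps, seed = s)
      compare_maps(maps$expected, flipped)$categories$percent_match
    }, numeric(3)))
    expect_true(all(abs(agree - 100 * (1 - eps)) <= 3))
  }
})

test_that("classify_symmetry counts one-way cells and mutual pairs", {
  one_way <- measured_map(c("a", "b"), c("b", "a"), c(1L, 0L))
  sym <- classify_symmetry(one_way)
  expect_equal(sym$n_asymmetric, 1)
  expect_equal(sym$n_symmetric, 0)

  m <- symmetry_example_map()
  sym <- classify_symmetry(m)
  expect_equal(sym$n_relations, 16)
  expect_equal(sym$n_asymmetric, 11)
  expect_equal(sym$n_symmetric, 5)
  expect_equal(sym$percent_asymmetric, 68.75)
  expect_equal(sym$percent_symmetric, 31.25)
  # rounded, these are the printed 69% / 31%
  expect_equal(anticipatr:::round_half_up(sym$percent_asymmetric), 69)
  expect_equal(anticipatr:::round_half_up(sym$percent_symmetric), 31)
  expect_equal(sym$n_asymmetric + sym$n_symmetric, sym$n_relations)
})

test_that("classify_symmetry reports NA percentages on an empty map", {
  empty <- measured_map(c("a", "b"), c("b", "a"), c(0L, 0L))
  sym <- classify_symmetry(empty)
  expect_equal(sym$n_relations, 0)
  expect_true(is.na(sym$percent_asymmetric))
  expect_true(is.na(sym$percent_symmetric))
})

test_that("symmetry counts always add up over random maps", {
  withr::with_seed(55, {
    for (k in 1:20) {
      ids <- paste0("s", 1:5)
      pairs <- expand.grid(to = ids, from = ids,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$from != pairs$to, ]
      m <- measured_map(pairs$from, pairs$to,
                        sample(c(-1L, 0L, 1L), nrow(pairs), replace = TRUE))
      sym <- classify_symmetry(m)
      expect_equal(sym$n_asymmetric + sym$n_symmetric, sym$n_relations)
    }
  })
})

test_that("symmetric induction fraction counts mutual inductions", {
  expect_equal(symmetric_induction_fraction(symmetry_example_map()), 80.0)

  both_up <- measured_map(c("a", "b"), c("b", "a"), c(1L, 1L))
  expect_equal(symmetric_induction_fraction(both_up), 100)
  both_dn <- measured_map(c("a", "b"), c("b", "a"), c(-1L, -1L))
  expect_equal(symmetric_induction_fraction(both_dn), 0)
  none <- measured_map(c("a", "b"), c("b", "a"), c(1L, 0L))
  expect_true(is.na(symmetric_induction_fraction(none)))
})

test_that("cross-platform agreement counts co-measured equal calls", {
  m <- symmetry_example_map()
  expect_equal(cross_platform_agreement(m, m), 100)

  ids <- paste0("s", 1:4)
  pairs <- expand.grid(to = ids, from = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ] # 12 cells
  a_sign <- rep(1L, 12); a_sign[10:12] <- NA
  b_sign <- rep(1L, 12); b_sign[1] <- 0L  # one disagreement in 9 co-measured
  a <- measured_map(pairs$from, pairs$to, a_sign)
  b <- measured_map(pairs$from, pairs$to, b_sign,
                    provenance = "rt_pcr")
  expect_equal(cross_platform_agreement(a, b), 100 * 8 / 9,
               tolerance = 1e-12)

  b_disjoint <- measured_map(pairs$from, pairs$to,
                             c(rep(NA_integer_, 9), 1L, 1L, 1L))
  expect_true(is.na(cross_platform_agreement(a, b_disjoint)))
})

test_that("concordance_report assembles category, symmetry and platform parts", {
  maps <- worked_example_maps()
  rtpcr <- measured_map(maps$measured$from, maps$measured$to,
                        maps$measured$sign, provenance = "rt_pcr")
  rep <- concordance_report(maps$expected, maps$measured, rtpcr = rtpcr)
  expect_s3_class(rep, "concordance_report")
  expect_named(rep$symmetry,
               c("n_relations", "n_asymmetric", "n_symmetric",
                 "percent_asymmetric", "percent_symmetric"))
  expect_equal(rep$cross_platform_percent, 100)
})

test_that("same_sign homeostatic matching accepts mutual repression", {
  exp_map <- expected_map(c("a", "b"), c("b", "a"), c(1L, 1L),
                          c("homeostatic", "homeostatic"))
  both_dn <- measured_map(c("a", "b"), c("b", "a"), c(-1L, -1L))
  strict <- compare_maps(exp_map, both_dn)
  relaxed <- compare_maps(exp_map, both_dn, homeostatic_match = "same_sign")
  hom <- function(r) r$categories[r$categories$category == "homeostatic", ]
  expect_equal(hom(strict)$n_match, 0)
  expect_equal(hom(relaxed)$n_match, 2)
})
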