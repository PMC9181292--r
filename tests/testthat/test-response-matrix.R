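deg_row <- function(gene, log2fc, padj = 0.001) {
  data.frame(gene = gene, log2fc = log2fc, pvalue = padj, padj = padj,
             stringsAsFactors = FALSE)
}

test_that("call_relation_from_deg follows the significant majority sign", {
  deg <- deg_row(c("g1", "g2", "g3"), c(2, 2, 2))
  expect_equal(call_relation_from_deg(deg, c("g1", "g2", "g3")), 1L)

  ns <- deg_row(c("g1", "g2"), c(2, -2), padj = 0.5)
  expect_equal(call_relation_from_deg(ns, c("g1", "g2")), 0L)

  mixed <- deg_row(c("g1", "g2", "g3"), c(-2, -2, 2))
  expect_equal(call_relation_from_deg(mixed, c("g1", "g2", "g3")), -1L)
})

test_that("relation calls match an enumeration oracle on random tables", {
  # independent oracle: count significant up/down genes explicitly
  oracle <- function(deg, set, alpha, lfc) {
    sig <- deg[deg$gene %in% set & deg$padj < alpha &
                 abs(deg$log2fc) >= lfc, ]
    up <- sum(sig$log2fc > 0); dn <- sum(sig$log2fc < 0)
    if (up == dn) 0L else if (up > dn) 1L else -1L
  }
  withr::with_seed(31, {
    for (k in 1:25) {
      n <- sample(3:8, 1)
      deg <- data.frame(gene = paste0("g", 1:n),
                        log2fc = round(runif(n, -3, 3), 2),
                        pvalue = runif(n),
                        padj = runif(n), stringsAsFactors = FALSE)
      set <- paste0("g", sample(n, sample(2:n, 1)))
      expect_identical(call_relation_from_deg(deg, set),
                       oracle(deg, set, 0.05, 1))
    }
  })
})

test_that("relation calls ignore gene order and genes outside the set", {
  deg <- deg_row(c("g1", "g2", "g3", "x1", "x2"), c(2, 2, -2, -3, -3))
  set <- c("g1", "g2", "g3")
  expect_equal(call_relation_from_deg(deg, set), 1L)
  expect_equal(call_relation_from_deg(deg[sample(5), ], rev(set)), 1L)
})

test_that("set genes absent from the table count as not significant", {
  deg <- deg_row("g1", 2)
  expect_message(r <- call_relation_from_deg(deg, c("g1", "ghost")),
                 "ghost")
  expect_equal(r, 1L)
})

test_that("raw p-values get Benjamini-Hochberg adjustment when padj absent", {
  deg <- data.frame(gene = c("g1", "g2"), log2fc = c(3, 0.1),
                    pvalue = c(1e-6, 0.9), stringsAsFactors = FALSE)
  expect_equal(call_relation_from_deg(deg, c("g1", "g2")), 1L)
})

test_that("build_measured_map recovers a planted map and handles nulls", {
  sc <- synthetic_scenario(seed = 5)
  gen <- generate_scenario(sc)
  mm <- suppressMessages(build_measured_map(gen$deg_tables, gen$genesets))
  planted <- gen$truth$planted_measured
  idx <- match(paste(mm$from, mm$to), paste(planted$from, planted$to))
  expect_identical(mm$sign, planted$sign[idx])

  # planted strong repression (galactose treatment, maltose operon) -> -1
  signs <- c("D-maltose" = -1L)
  deg <- gen_deg_table(signs, gen$genesets, seed = 9)
  expect_equal(call_relation_from_deg(deg, gen$genesets[["D-maltose"]]),
               -1L)

  # all-null tables -> all-zero map
  null_signs <- stats::setNames(rep(0L, length(gen$genesets)),
                                names(gen$genesets))
  null_tabs <- lapply(1:2, function(i)
    gen_deg_table(null_signs, gen$genesets, seed = i))
  names(null_tabs) <- names(gen$genesets)[1:2]
  nm <- build_measured_map(null_tabs, gen$genesets)
  measured <- nm$sign[nm$from %in% names(null_tabs)]
  expect_true(all(measured == 0L))
  # treatments without a table are NA rows
  expect_true(all(is.na(nm$sign[!nm$from %in% names(null_tabs)])))
})

test_that("build_measured_map rejects treatments outside the source list", {
  gs <- list(a = "g1", b = "g2")
  tabs <- list(zz = deg_row("g1", 2))
  expect_error(build_measured_map(tabs, gs), "zz")
})

test_that("ddct_fold_change implements 2^(-ddCt)", {
  ct0 <- data.frame(sample = c("s1", "s2"),
                    condition = c("control", "treated"),
                    target_gene = "malP", ct_target = c(20, 20),
                    ct_reference = c(15, 15), stringsAsFactors = FALSE)
  expect_equal(ddct_fold_change(ct0, "malP"), 1.0)

  ct1 <- ct0
  ct1$ct_target[2] <- 19
  expect_equal(ddct_fold_change(ct1, "malP"), 2.0)

  withr::with_seed(13, {
    for (k in 1:10) {
      ct <- data.frame(
        sample = paste0("s", 1:6),
        condition = rep(c("control", "treated"), each = 3),
        target_gene = "g", ct_target = runif(6, 15, 30),
        ct_reference = runif(6, 14, 20), stringsAsFactors = FALSE)
      dctc <- mean(ct$ct_target[1:3] - ct$ct_reference[1:3])
      dctt <- mean(ct$ct_target[4:6] - ct$ct_reference[4:6])
      expect_equal(ddct_fold_change(ct, "g"), 2^(-(dctt - dctc)),
                   tolerance = 1e-12)
    }
  })
})

test_that("ddct_fold_change errors when a condition is missing", {
  ct <- data.frame(sample = "s1", condition = "control",
                   target_gene = "g", ct_target = 20, ct_reference = 15,
                   stringsAsFactors = FALSE)
  expect_error(ddct_fold_change(ct, "g"), "treated")
})

test_that("relation_from_rtpcr applies the fold-threshold majority rule", {
  expect_equal(relation_from_rtpcr(c(3.1, 2.4)), 1L)
  expect_equal(relation_from_rtpcr(c(1.1, 0.9)), 0L)
  # enumeration: 2 of 3 at or below 0.5 is a strict repression majority
  expect_equal(relation_from_rtpcr(c(0.4, 0.45, 1.2)), -1L)
  expect_error(relation_from_rtpcr(c(1, -2)), "positive")
  expect_error(relation_from_rtpcr(numeric(0)), "at least one")
})
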