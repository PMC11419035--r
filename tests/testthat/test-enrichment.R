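make_assignments <- function(genes, cohorts, classes) {
  data.frame(sequence_id = sprintf("r%03d", seq_along(genes)),
             v_call = genes, locus = ifelse(grepl("^IGK", genes), "IGK", "IGL"),
             coverage_class = classes, cohort = cohorts,
             stringsAsFactors = FALSE)
}

test_that("usage counts include complete+incomplete and never excluded", {
  a <- make_assignments(rep("IGKV1-33", 9), rep("A", 9),
                        c(rep("complete", 3), rep("incomplete", 2),
                          rep("excluded", 4)))
  tab <- tabulate_usage(a, "A")
  expect_equal(tab$A[tab$v_gene == "IGKV1-33"], 5L)
  expect_equal(unname(attr(tab, "totals")["A"]), 5L)
  expect_equal(nrow(tabulate_usage(a[a$coverage_class == "excluded", ], "A")),
               0L)
  genes <- sprintf("IGKV1-%d", 1:10)
  tab2 <- tabulate_usage(make_assignments(genes, rep("A", 10),
                                          rep("complete", 10)), "A")
  expect_true(all(tab2$A == 1L))
  expect_equal(sum(tab2$A), 10L)
  expect_error(tabulate_usage(a, c("A", "missing_cohort")), "absent")
})

test_that("gene_enrichment reproduces the hand-computed 2x2 odds ratio", {
  tab <- structure(data.frame(v_gene = c("g1", "g2"),
                              AL = c(50L, 731L), MM = c(5L, 1117L)),
                   totals = c(AL = 781L, MM = 1122L),
                   class = c("GeneUsageTable", "data.frame"))
  e <- gene_enrichment(tab, "AL", "MM")
  r <- e[e$v_gene == "g1", ]
  expect_equal(r$odds_ratio, (50 * 1117) / (5 * 731), tolerance = 1e-12)
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
  expect_identical(r$direction, "over")
  expect_error(gene_enrichment(tab, "AL", "nope"), "nope")
})

test_that("identical usage proportions give OR = 1 for every gene", {
  tab <- structure(data.frame(v_gene = paste0("g", 1:4),
                              A = c(10L, 20L, 30L, 40L),
                              B = c(20L, 40L, 60L, 80L)),
                   totals = c(A = 100L, B = 200L),
                   class = c("GeneUsageTable", "data.frame"))
  e <- gene_enrichment(tab, "A", "B")
  expect_equal(e$odds_ratio, rep(1, 4))
  expect_true(all(e$direction == "none"))
})

test_that("case/control swap inverts the odds ratio when no cell is zero", {
  withr::local_seed(12)
  tab <- sim_usage_table(setNames(rep(0.1, 10), paste0("g", 1:10)),
                         setNames(rep(0.1, 10), paste0("g", 1:10)),
                         500, 700)
  expect_true(all(tab$case > 0 & tab$ctrl > 0))  # seed chosen accordingly
  f <- gene_enrichment(tab, "case", "ctrl")
  r <- gene_enrichment(tab, "ctrl", "case")
  expect_equal(f$odds_ratio[order(f$v_gene)] * r$odds_ratio[order(r$v_gene)],
               rep(1, 10), tolerance = 1e-12)
})

test_that("zero cells trigger the Haldane-Anscombe correction, not NaN", {
  tab <- structure(data.frame(v_gene = c("rare", "common"),
                              A = c(5L, 95L), B = c(0L, 200L)),
                   totals = c(A = 100L, B = 200L),
                   class = c("GeneUsageTable", "data.frame"))
  e <- gene_enrichment(tab, "A", "B")
  r <- e[e$v_gene == "rare", ]
  expect_true(is.finite(r$odds_ratio) && is.finite(r$ci_high))
  expect_true(r$continuity_corrected)
  expect_equal(r$odds_ratio, (5.5 * 200.5) / (0.5 * 95.5), tolerance = 1e-12)
})

test_that("bh_adjust matches hand evaluation and preserves ranked order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.07), 0.07)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::local_seed(8)
  for (i in 1:10) {
    p <- stats::runif(12)
    q <- bh_adjust(p)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    expect_equal(q, stats::p.adjust(p, "BH"))
  }
})

test_that("usage_correlation handles the boundary geometries", {
  x <- setNames((1:10) / 55, paste0("g", 1:10))
  expect_equal(usage_correlation(x, x)$r, 1)
  expect_equal(usage_correlation(x, setNames(rev(unname(x)), names(x)))$r, -1)
  # union-of-genes semantics: a gene absent from one profile counts as 0
  y <- setNames(c(0.5, 0.5), c("g1", "g11"))
  expect_silent(usage_correlation(x, y))
  expect_error(usage_correlation(setNames(rep(0.1, 10), paste0("g", 1:10)), x),
               "zero-variance")
  expect_error(usage_correlation(x[1:2], x[1:2]), "at least 3")
})

test_that("usage_correlation matches the direct covariance formula", {
  a <- setNames(c(12, 7, 33, 2, 9, 14, 21, 5, 8, 19), paste0("g", 1:10))
  b <- setNames(c(10, 9, 28, 4, 7, 16, 18, 6, 11, 15), paste0("g", 1:10))
  got <- usage_correlation(a, b)
  x <- a / sum(a); y <- b / sum(b)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_hand, tolerance = 1e-12)
})
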