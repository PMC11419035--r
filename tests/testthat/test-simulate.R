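test_that("simulate_shm respects rate boundaries", {
  withr::local_seed(1)
  g <- random_aa(100)
  m0 <- simulate_shm(g, 0, 0, 0)
  expect_identical(m0$seq, g)
  expect_equal(c(m0$substitutions, m0$insertions, m0$deletions), c(0L, 0L, 0L))
  m1 <- simulate_shm(g, 1 - 1e-12, 0, 0)
  expect_equal(m1$substitutions, 100L)
  expect_equal(hamming(m1$seq, g), 100L)
  expect_error(simulate_shm("", 0.1), "non-empty")
})

test_that("substitution counts follow the binomial oracle", {
  # mean of Binomial(100, 0.1) is 10 with se sqrt(100 * .1 * .9 / reps)
  withr::local_seed(42)
  g <- random_aa(100)
  reps <- 10000L
  subs <- vapply(seq_len(reps),
                 function(i) simulate_shm(g, 0.1)$substitutions, integer(1))
  se <- sqrt(100 * 0.1 * 0.9 / reps)
  expect_lt(abs(mean(subs) - 10), 3 * se)
})

test_that("edit scripts replay to the emitted sequence", {
  withr::local_seed(7)
  g <- random_aa(120)
  for (i in 1:50) {
    m <- simulate_shm(g, 0.08, 0.5, 0.5)
    expect_identical(replay_edits(g, m$edits), m$seq)
    expect_equal(length(m$edits$sub_pos), m$substitutions)
    expect_equal(length(m$edits$ins_pos), m$insertions)
    expect_equal(length(m$edits$del_pos), m$deletions)
  }
})

test_that("generate_cohort handles n = 0 and draws genes multinomially", {
  ref <- make_test_reference()
  vg <- assignment_candidates(ref, "V")$gene_id[1:2]
  usage <- setNames(c(0.5, 0.5), vg)
  j <- setNames(c(0.5, 0.5), assignment_candidates(ref, "J")$gene_id)
  empty <- generate_cohort(cohort_spec("e", 0, usage, j, seed = 1), ref)
  expect_length(empty$sequences, 0L)
  expect_equal(nrow(empty$metadata), 0L)
  co <- generate_cohort(cohort_spec("c", 1000, usage, j, seed = 5), ref)
  counts <- table(co$truth$true_v_gene)
  expect_true(all(abs(counts - 500) <= 3 * sqrt(1000 * 0.25)))
})

test_that("generation is byte-identical under a fixed seed, distinct across seeds", {
  ref <- make_test_reference()
  vg <- assignment_candidates(ref, "V")$gene_id[1:2]
  usage <- setNames(c(0.3, 0.7), vg)
  j <- setNames(c(0.5, 0.5), assignment_candidates(ref, "J")$gene_id)
  spec <- cohort_spec("d", 60, usage, j, sub_rate = 0.1, ins_rate = 0.1,
                      del_rate = 0.1, truncate_prob = 0.1, exclude_prob = 0.05,
                      duplicate_prob = 0.1, seed = 11)
  d1 <- withr::local_tempdir()
  f1 <- write_cohort(generate_cohort(spec, ref), file.path(d1, "a"))
  f2 <- write_cohort(generate_cohort(spec, ref), file.path(d1, "b"))
  for (k in 1:3)
    expect_identical(readLines(f1[k]), readLines(f2[k]))
  spec2 <- spec; spec2$seed <- 12L
  other <- generate_cohort(spec2, ref)
  expect_false(identical(other$sequences,
                         generate_cohort(spec, ref)$sequences))
})

test_that("empirical gene usage passes a chi-squared goodness-of-fit sweep", {
  # 20 seeds at n = 10,000, alpha = 0.01, at most one rejection allowed
  ref <- make_test_reference(n_v = 3L)
  vg <- assignment_candidates(ref, "V")$gene_id
  usage <- setNames(c(0.4, 0.25, 0.15, 0.1, 0.06, 0.04), vg)
  j <- setNames(c(0.5, 0.5), assignment_candidates(ref, "J")$gene_id)
  fails <- 0L
  for (s in 1:20) {
    co <- generate_cohort(cohort_spec("g", 10000, usage, j, sub_rate = 0,
                                      seed = 1000 + s), ref)
    counts <- table(factor(co$truth$true_v_gene, levels = names(usage)))
    p <- stats::chisq.test(counts, p = usage)$p.value
    if (p < 0.01) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("unknown genes in a spec fail before any output", {
  ref <- make_test_reference()
  j <- setNames(c(0.5, 0.5), assignment_candidates(ref, "J")$gene_id)
  spec <- cohort_spec("bad", 10, c(NOSUCH = 1), j, seed = 1)
  expect_error(generate_cohort(spec, ref), "NOSUCH")
  expect_error(cohort_spec("bad", 10, c(a = 0.5, b = 0.4), j), "sum to 1")
})

test_that("back_translate round-trips through the nucleotide path", {
  aa <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  nt <- back_translate(aa)
  expect_equal(nchar(nt), 3L * nchar(aa))
  tr <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  expect_identical(tr, aa)
  expect_error(back_translate("MKX"), "X")
})
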