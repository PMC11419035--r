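test_that("exact germline concatenations assign with zero edits", {
  ref <- bundled_reference()
  q <- germline_of(ref, "IGKV1-33", "IGKJ1")
  a <- assign_germline(q, ref)
  expect_identical(a$v_call, "IGKV1-33")
  expect_identical(a$j_call, "IGKJ1")
  expect_equal(c(a$substitutions, a$insertions, a$deletions), c(0L, 0L, 0L))
  expect_identical(a$coverage_class, "complete")
  # a distal-paralog match reports the proximal gene
  a2 <- assign_germline(germline_of(ref, "IGKV1D-33", "IGKJ2"), ref)
  expect_identical(a2$v_call, "IGKV1-33")
  # the IGLJ2/IGLJ3 ambiguity reports the merged label
  a3 <- assign_germline(germline_of(ref, "IGLV6-57", "IGLJ3"), ref)
  expect_identical(a3$j_call, "IGLJ2/IGLJ3")
})

test_that("assignment is invariant to reference row order", {
  ref <- bundled_reference()
  withr::local_seed(3)
  q <- simulate_shm(germline_of(ref, "IGLV2-14", "IGLJ2"), 0.08, 0.3, 0.3)$seq
  a1 <- assign_germline(q, ref)
  perm <- ref
  perm$genes <- perm$genes[rev(seq_len(nrow(perm$genes))), ]
  a2 <- assign_germline(q, perm)
  expect_identical(a1[, c("v_call", "j_call", "substitutions", "insertions",
                          "deletions", "score")],
                   a2[, c("v_call", "j_call", "substitutions", "insertions",
                          "deletions", "score")])
})

test_that("substitution counts equal the Hamming oracle without indels", {
  ref <- make_test_reference(n_v = 2L)
  vg <- assignment_candidates(ref, "V")$gene_id[c(1, 3)]
  usage <- setNames(c(0.5, 0.5), vg)
  j <- setNames(c(0.5, 0.5), assignment_candidates(ref, "J")$gene_id)
  co <- generate_cohort(cohort_spec("h", 60, usage, j, sub_rate = 0.06,
                                    seed = 21), ref)
  aln <- assign_repertoire(co$sequences, ref, co$metadata)
  for (i in seq_len(nrow(aln))) {
    tt <- co$truth[co$truth$record_id == aln$sequence_id[i], ]
    germ <- germline_of(ref, tt$emitting_v_copy,
                        sub("/.*$", "", tt$true_j_gene))
    expect_equal(aln$substitutions[i], hamming(co$sequences[[i]], germ))
    expect_equal(aln$substitutions[i], tt$true_substitutions)
  }
})

test_that("junk queries fall below the identity floor", {
  ref <- bundled_reference()
  withr::local_seed(9)
  # shuffled germline: same composition, no alignable signal at 50% identity
  junk <- paste(sample(strsplit(germline_of(ref, "IGKV1-33", "IGKJ1"),
                                "")[[1]]), collapse = "")
  a <- assign_germline(junk, ref)
  expect_identical(a$coverage_class, "excluded")
  expect_identical(a$exclusion_reason, "unassignable")
  short <- assign_germline("ACDEFGHIK", ref)
  expect_identical(short$exclusion_reason, "too short")
})

test_that("coverage classification implements the 80-residue / CDR rule", {
  # narrow windows (with CDR3 crossing the V-J junction) so an 85-residue
  # truncation can still span all CDRs and reach the J segment
  windows <- list(cdr1 = c(10L, 20L), cdr2 = c(40L, 50L), cdr3 = c(60L, 75L))
  ref <- make_test_reference(v_len = 70L, j_len = 50L, cdr_windows = windows)
  q <- germline_of(ref, assignment_candidates(ref, "V")$gene_id[1], "IGKJ1")
  expect_identical(assign_germline(q, ref)$coverage_class, "complete")
  # ambiguity residue defeats the complete class but not the incomplete one
  qx <- sub("^(.{30}).", "\\1X", q)
  expect_identical(assign_germline(qx, ref)$coverage_class, "incomplete")
  # 85 contiguous residues spanning all three CDR windows
  expect_identical(assign_germline(substr(q, 1, 85), ref)$coverage_class,
                   "incomplete")
  # 79 contiguous residues: below the floor
  expect_identical(assign_germline(substr(q, 1, 79), ref)$coverage_class,
                   "excluded")
  # 85 residues that miss CDR1 entirely
  expect_identical(assign_germline(substr(q, 36, 120), ref)$coverage_class,
                   "excluded")
})

test_that("every record lands in exactly one coverage class", {
  ref <- bundled_reference()
  vg <- c("IGKV1-33", "IGLV6-57")
  usage <- setNames(c(0.5, 0.5), vg)
  j <- setNames(rep(0.25, 4), assignment_candidates(ref, "J")$gene_id)
  co <- generate_cohort(cohort_spec("p", 80, usage, j, sub_rate = 0.08,
                                    ins_rate = 0.1, del_rate = 0.1,
                                    truncate_prob = 0.2, exclude_prob = 0.1,
                                    seed = 33), ref)
  aln <- assign_repertoire(co$sequences, ref, co$metadata)
  expect_true(all(aln$coverage_class %in% c("complete", "incomplete",
                                            "excluded")))
  expect_equal(nrow(aln), length(co$sequences))
  # intended coverage classes are recovered
  tt <- co$truth[match(aln$sequence_id, co$truth$record_id), ]
  expect_gte(mean(aln$coverage_class == tt$true_coverage_class), 0.95)
})

test_that("nucleotide records translate in the scoring frame; stops exclude", {
  ref <- bundled_reference()
  q <- germline_of(ref, "IGLV6-57", "IGLJ2")
  for (shift in 0:2) {
    a <- assign_germline(back_translate(q, frame_shift = shift), ref,
                         molecule = "nucleotide")
    expect_identical(a$v_call, "IGLV6-57")
    expect_equal(a$substitutions, 0L)
  }
  # stop codons in every frame: non-productive
  nt <- back_translate(q)
  ntstop <- paste0(substr(nt, 1, 150), "TAATAATAA", substring(nt, 151))
  a2 <- assign_germline(ntstop, ref, molecule = "nucleotide")
  expect_identical(a2$exclusion_reason, "non-productive")
})

test_that("duplicate collapsing follows the consensus rules", {
  withr::local_seed(17)
  base <- random_aa(110)
  # three identical records collapse to one kept representative
  r <- collapse_duplicates(c(a = base, b = base, c = base))
  expect_length(r$kept, 1L)
  expect_identical(unname(r$kept[1]), base)
  expect_equal(nrow(r$consensus), 0L)
  # a 1-1 tie cannot form an unambiguous consensus
  var1 <- sub("^.", ifelse(startsWith(base, "A"), "C", "A"), base)
  r2 <- collapse_duplicates(c(x = base, y = var1))
  expect_length(r2$kept, 0L)
  expect_setequal(r2$log$fate, "excluded")
  expect_setequal(r2$log$reason, "ambiguous consensus")
  # longest record retained; nucleotide-derived preferred over protein
  r3 <- collapse_duplicates(
    c(nt = base, pr = substr(base, 1, 108)),
    metadata = data.frame(record_id = c("nt", "pr"),
                          molecule = c("nucleotide", "protein")))
  expect_identical(names(r3$kept), "nt")
  # 2-vs-1 majority resolves to the majority sequence
  r4 <- collapse_duplicates(c(p = base, q = base, z = var1))
  expect_identical(unname(r4$kept[1]), base)
  # conservation: every input id appears exactly once in the log
  for (r_ in list(r, r2, r3, r4))
    expect_false(anyDuplicated(r_$log$record_id) > 0)
  expect_error(collapse_duplicates(c(a = base), identity_threshold = 0.5))
})

test_that("unrelated records are never merged", {
  withr::local_seed(23)
  seqs <- setNames(replicate(12, random_aa(110)), paste0("r", 1:12))
  r <- collapse_duplicates(seqs)
  expect_length(r$kept, 12L)
  expect_identical(sort(names(r$kept)), sort(names(seqs)))
})
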