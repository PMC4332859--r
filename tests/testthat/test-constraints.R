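# Sequence- and set-level constraint mathematics.

test_that("edit distance reproduces the worked three-tag example", {
  expect_identical(edit_distance("ACTG", "CAGT"), 3L)
  expect_identical(edit_distance("ACTG", "GAGT"), 3L)
  expect_identical(edit_distance("CAGT", "GAGT"), 1L)
  expect_identical(edit_distance("ACTG", "ACTG"), 0L)
})

test_that("edit distance rejects non-ACGT characters", {
  expect_error(edit_distance("ACGN", "ACGT"), "alphabet")
  expect_error(tte("ACGU", c("ACGT")), "alphabet")
  expect_error(gc_content("AC-G"), "alphabet")
})

test_that("edit distance matches the recursive oracle exhaustively on short words", {
  # all pairs of words of length 1..4 over a 2-letter alphabet (plain
  # recursion over every edit script), including unequal lengths
  words <- unlist(lapply(1:4, all_words, alphabet = c("A", "C")))
  for (a in words) for (b in words)
    expect_identical(edit_distance(a, b), lev_recursive(a, b))
})

test_that("edit distance matches the memoized recursive oracle on random pairs", {
  set.seed(42)
  for (i in 1:200) {
    a <- random_tags(1, sample(2:8, 1))
    b <- random_tags(1, sample(2:8, 1))
    expect_identical(edit_distance(a, b), lev_recursive_memo(a, b))
  }
})

test_that("edit distance satisfies the metric axioms and the Hamming bound", {
  set.seed(7)
  tags <- random_tags(12, 6)
  for (i in 1:40) {
    trio <- sample(tags, 3)
    dab <- edit_distance(trio[1], trio[2])
    dba <- edit_distance(trio[2], trio[1])
    dbc <- edit_distance(trio[2], trio[3])
    dac <- edit_distance(trio[1], trio[3])
    expect_identical(dab, dba)
    expect_lte(dac, dab + dbc)                    # triangle inequality
    expect_identical(dab == 0L, trio[1] == trio[2])
    expect_lte(dab, hamming(trio[1], trio[2]))    # edit <= Hamming <= n
    expect_lte(hamming(trio[1], trio[2]), 6L)
  }
})

test_that("TTE reproduces the worked example and the vacuous cases", {
  trio <- c("ACTG", "CAGT", "GAGT")
  expect_equal(tte("ACTG", trio), 3)
  expect_equal(tte("CAGT", trio), 1)
  expect_equal(tte("GAGT", trio), 1)
  expect_identical(tte("ACTG", character(0)), Inf)
  expect_identical(tte("ACTG", "ACTG"), Inf)  # only itself in the set
})

test_that("GC content and the two GC modes behave as defined", {
  expect_equal(gc_content("ACTG"), 50)
  expect_equal(gc_content("AATT"), 0)
  expect_equal(gc_content("GCGC"), 100)
  range_p <- constraint_profile(1, gc_mode = "range")
  fixed_p <- constraint_profile(1, gc_mode = "fixed")  # floor(n/2) G/C
  off_p <- constraint_profile(1, gc_mode = "off")
  expect_true(gc_satisfied("GTCAA", range_p))   # 40% inclusive at the edge
  expect_true(gc_satisfied("GTCAA", fixed_p))   # floor(5/2) = 2 G/C
  expect_false(gc_satisfied("GGCAA", fixed_p))  # 3 != 2
  expect_false(gc_satisfied("AAAAT", range_p))
  expect_true(gc_satisfied("AAAAT", off_p))
  expect_true(gc_satisfied("GGGGG",
    constraint_profile(1, gc_mode = "fixed", gc_fixed_count = 5)))
})

test_that("longest run and continuity reproduce the worked example", {
  expect_identical(longest_run("AATGC"), 2L)
  expect_identical(longest_run("AAATTG"), 3L)
  expect_identical(longest_run("TCGTCA"), 1L)
  expect_identical(continuity(c("AATGC", "AAATTG", "TCGTCA")), 3L)
  expect_identical(continuity("TCGTCA"), 1L)
  expect_identical(continuity(c("ACACAC", "GTGTGT")), 1L)
  expect_error(continuity(character(0)), "empty")
})

test_that("removing a tag never increases continuity", {
  set.seed(11)
  tags <- random_tags(8, 7)
  full <- continuity(tags)
  for (i in seq_along(tags))
    expect_lte(continuity(tags[-i]), full)
})

test_that("reverse complement matches the worked examples and is an involution", {
  expect_identical(reverse_complement("GTCAA"), "TTGAC")
  expect_identical(reverse_complement("AATT"), "AATT")
  set.seed(5)
  tags <- random_tags(25, 8)
  expect_identical(reverse_complement(reverse_complement(tags)), tags)
  expect_identical(nchar(reverse_complement(tags)), nchar(tags))
  # reverse complement preserves the G/C count
  expect_equal(gc_content(reverse_complement(tags)), gc_content(tags))
})

test_that("base-swapped word complements the GC content", {
  # swapping A<->G and C<->T maps every A/T base to a G/C base and vice
  # versa, so the GC percentages of a word and its swap sum to 100
  set.seed(6)
  tags <- random_tags(20, 9)
  swapped <- chartr("ACGT", "GTAC", tags)
  expect_equal(gc_content(tags) + gc_content(swapped), rep(100, 20))
})

test_that("self-complementarity detection is exact", {
  expect_true(is_self_complementary("AATT"))
  expect_false(is_self_complementary("GTCAA"))
  set.seed(9)
  # no odd-length word can equal its reverse complement
  expect_false(any(is_self_complementary(random_tags(50, 7))))
})

test_that("cross-complement violations are enumerated including the self case", {
  v <- cross_complement_violations(c("GTCAA", "TTGAC", "ACCTA"))
  expect_identical(nrow(v), 2L)  # both orders of the mutual pair
  expect_true(all(c("GTCAA", "TTGAC") %in% v$tag))
  v2 <- cross_complement_violations(c("AATT", "ACGG"))
  expect_identical(v2$tag, "AATT")
  expect_identical(v2$complement_of, "AATT")
  # direct check by enumeration for a clean set
  set.seed(3)
  tags <- c("ACACA", "GACGT")
  manual <- sum(outer(tags, reverse_complement(tags), "=="))
  expect_identical(nrow(cross_complement_violations(tags)), as.integer(manual))
})

test_that("validate_tag applies the distance threshold of the worked example", {
  S <- c("ACTG", "CAGT")
  only_d <- function(d) constraint_profile(d, gc_mode = "off",
                                           continuity_max = 4,
                                           complementarity = "none")
  expect_false(validate_tag("GAGT", S, only_d(2))$ok)   # TTE = 1 < 2
  expect_identical(validate_tag("GAGT", S, only_d(2))$reasons, "distance")
  expect_true(validate_tag("GAGT", S, only_d(1))$ok)
  dup <- validate_tag("ACTG", S, only_d(1))
  expect_false(dup$ok)
  expect_true("duplicate" %in% dup$reasons)
  expect_error(validate_tag("ACTGA", S, only_d(1)), "length")
})

test_that("validate_tag reports every failed rule", {
  p <- constraint_profile(3, gc_mode = "fixed", complementarity = "cross")
  # AAAA: 0 G/C (needs 2), run of 4, and TTE 1 to AAAT
  r <- validate_tag("AAAA", c("AAAT", "GGCC"), p)
  expect_false(r$ok)
  expect_setequal(r$reasons, c("distance", "gc", "continuity"))
  # reverse complement of a member, cross mode
  r2 <- validate_tag("ACCT", "AGGT", p)
  expect_true("cross_complement" %in% r2$reasons)
})

test_that("validate_set detects sub-threshold pairs and passes singletons", {
  p3 <- constraint_profile(3, gc_mode = "off", continuity_max = 4,
                           complementarity = "none")
  rep3 <- validate_set(c("ACTG", "CAGT", "GAGT"), p3)
  expect_false(rep3$pass)
  expect_identical(rep3$min_pairwise_distance, 1L)
  expect_true(validate_set("TCGTCA", constraint_profile(6))$pass)
  expect_error(validate_set(c("ACGT", "ACGTA"), p3), "length")
})

test_that("lowercase input is canonicalized to uppercase", {
  expect_identical(check_tags("acgt"), "ACGT")
  expect_identical(edit_distance("acgt", "ACGT"), 0L)
})
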