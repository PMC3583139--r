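state <- function(x, ...) as_ancestral_state(x, ...)

test_that("observed distance counts positions with disjoint nucleotide sets", {
  a <- state("ACG")          # {A} {C} {G}
  b <- state("ATS")          # {A} {T} {C,G}; only position 2 is disjoint
  expect_identical(observed_distance(a, b), 1L)
  expect_identical(observed_distance(state("ACGT"), state("ACGT")), 0L)
  expect_identical(observed_distance(state("AAAA"), state("CCCC")), 4L)
  # mask mismatch is an error
  expect_error(observed_distance(state("ACG", mask = 1:2), state("ACG")),
               "masks")
  expect_error(observed_distance(state("ACG"), state("ACGT")), "site counts")
})

test_that("null disjoint probability enumerates all ordered cross pairs", {
  # hand enumeration of the 4 ordered pairs: (A,A) meet, (A,C) disjoint,
  # (C,A) disjoint, (C,C) meet -> 0.5
  expect_equal(null_disjoint_probability(state("AC"), state("AC")), 0.5)
  expect_equal(null_disjoint_probability(state("AA"), state("AA")), 0)
  # a full-ambiguity column intersects everything
  a <- state("AC")
  b <- state("NC")  # {ACGT} {C}
  expect_equal(null_disjoint_probability(a, b), 0.25) # only (A, {C}) disjoint
})

test_that("the analytic null equals the permutation-oracle mean", {
  set.seed(37)
  sites_a <- sample(1:15, 60, replace = TRUE, prob = c(rep(0.2, 2), 0.02,
                                                       0.2, rep(0.02, 3),
                                                       0.2, rep(0.02, 6),
                                                       0.06))
  sites_b <- sample(1:15, 60, replace = TRUE)
  a <- ancestral_state(sites_a)
  b <- ancestral_state(sites_b)
  p_analytic <- null_disjoint_probability(a, b)
  perm <- replicate(1000, {
    bp <- ancestral_state(sample(sites_b))
    observed_distance(a, bp) / 60
  })
  mc_sd <- sd(perm) / sqrt(length(perm))
  expect_lt(abs(mean(perm) - p_analytic), 3 * mc_sd + 1e-12)
})

test_that("relatedness summaries reproduce published worked examples", {
  # z = 1.6 exactly -> one-tailed p = 0.0548
  expect_equal(round(relatedness_probability(68, 78.4, 6.5), 4), 0.0548)
  expect_equal(relatedness_probability(87, 105.8, 6.4), 0.0016, tolerance = 0.1)
  # symmetric null: observed equal to expected
  expect_equal(relatedness_probability(50, 50, 5), 0.5)
  # binomial SD identity
  expect_equal(round(null_sd(80.1, 172), 1), 6.5)
})

test_that("the full test composes distance, null and normal tail", {
  set.seed(41)
  # identical singleton states: strong relatedness signal
  x <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  rt <- relatedness_test(state(x), state(x))
  expect_identical(rt$observed, 0L)
  expect_lt(rt$p.value, 1e-10)
  expect_true(rt$significant)
  # invariants O <= L, E = L p, S^2 = E(1-p)
  y <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  rt <- relatedness_test(state(x), state(y))
  expect_lte(rt$observed, rt$L)
  expect_equal(rt$expected, rt$L * rt$p_disjoint)
  expect_equal(rt$sd^2, rt$expected * (1 - rt$p_disjoint))
  expect_equal(unname(rt$statistic), (rt$expected - rt$observed) / rt$sd)
  # degenerate null rejected
  expect_error(relatedness_test(state("AAAA"), state("AAAA")), "degenerate")
})

test_that("the relatedness test is symmetric in its two states", {
  set.seed(43)
  for (rep in 1:5) {
    a <- ancestral_state(sample(1:15, 80, replace = TRUE))
    b <- ancestral_state(sample(1:15, 80, replace = TRUE))
    r1 <- relatedness_test(a, b)
    r2 <- relatedness_test(b, a)
    expect_identical(r1$observed, r2$observed)
    expect_equal(r1$expected, r2$expected)
    expect_equal(r1$sd, r2$sd)
    expect_equal(r1$p.value, r2$p.value)
  }
})

test_that("independent singleton states reject near the nominal rate", {
  set.seed(47)
  L <- 172
  rej <- 0L
  n_rep <- 400
  for (r in seq_len(n_rep)) {
    a <- ancestral_state(sample(c(1L, 2L, 4L, 8L), L, replace = TRUE))
    b <- ancestral_state(sample(c(1L, 2L, 4L, 8L), L, replace = TRUE))
    if (relatedness_test(a, b)$significant) rej <- rej + 1L
  }
  expect_gt(rej / n_rep, 0.02)
  expect_lt(rej / n_rep, 0.10)
})

test_that("quantile screening selects rows strictly above the threshold", {
  # type-7 interpolation by hand: h = 0.95*(4-1)+1 = 3.85 -> 0 + 0.85*20 = 17
  counts <- c(r1 = 0, r2 = 0, r3 = 0, r4 = 20)
  sel <- screen_by_quantile(counts)
  expect_identical(as.character(sel), "r4")
  expect_equal(attr(sel, "threshold"), 17)
  # equal counts: nothing exceeds the quantile
  expect_length(screen_by_quantile(c(a = 3, b = 3, c = 3)), 0)
  # a single row never exceeds its own quantile
  expect_length(screen_by_quantile(c(solo = 12)), 0)
  expect_error(screen_by_quantile(numeric(0)), "empty")
})

test_that("the screen matrix counts significant references per query", {
  set.seed(53)
  base <- sample(c("A", "C", "G", "T"), 120, replace = TRUE)
  refs <- list(
    ref1 = state(paste(base, collapse = "")),
    ref2 = state(paste(base, collapse = "")))
  # q_near shares the reference sequence; q_far is its fixed-point-free
  # base swap, so every site pair is disjoint and p is near 1
  q_near <- paste(base, collapse = "")
  q_far <- chartr("ACGT", "CATG", q_near)
  scr <- relatedness_screen(c(near = q_near, far = q_far), refs)
  expect_identical(dim(scr$p), c(2L, 2L))
  expect_identical(unname(scr$counts["near"]), 2)
  expect_identical(unname(scr$counts["far"]), 0)
  expect_identical(scr$selected, "near")
})
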