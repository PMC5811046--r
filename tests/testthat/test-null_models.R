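test_that("shuffle preserves composition and is uniform over permutations", {
  expect_equal(shuffle_sequence("AAAA", 99), "AAAA")
  s <- shuffle_sequence("MAPPG", 5)
  expect_equal(sort(strsplit(s, "")[[1]]), sort(strsplit("MAPPG", "")[[1]]))
  expect_identical(shuffle_sequence("MAPPG", 5), shuffle_sequence("MAPPG", 5))
  expect_error(shuffle_sequence("", 1), "non-empty")

  # each of the 6 permutations of ABC appears with frequency 1/6 +- 3 SE
  n <- 10000
  perms <- vapply(seq_len(n), function(i) shuffle_sequence("ABC", i),
                  character(1))
  freq <- table(perms) / n
  expect_equal(length(freq), 6)
  se <- sqrt((1 / 6) * (5 / 6) / n)
  expect_true(all(abs(freq - 1 / 6) < 3.5 * se))
})

test_that("shuffle fold change arithmetic and p-values follow the contract", {
  # stateful counter: 80 for the observed set, 100 for every replicate
  calls <- 0
  counter <- function(seqs) {
    calls <<- calls + 1
    if (calls == 1) 80 else 100
  }
  fc <- shuffle_fold_change(c(a = "APPA"), counter, replicates = 50, seed = 1)
  expect_equal(fc$fold_change, 0.8)
  expect_equal(fc$n_exp, 100)
  expect_equal(fc$p_deplete, 1 / 51)
  expect_equal(fc$p_enrich, 1)
  expect_equal(length(fc$replicate_counts), 50)

  # replicate seeds derive from (seed, r, i): same seed reproduces exactly
  seqs <- random_aa_seqs(5, 100, f_p = 0.1, seed = 3)
  f1 <- shuffle_fold_change(seqs, count_motifs, 20, seed = 7)
  f2 <- shuffle_fold_change(seqs, count_motifs, 20, seed = 7)
  expect_identical(f1$replicate_counts, f2$replicate_counts)
})

test_that("unplanted i.i.d. sequences give fold change near 1", {
  seqs <- random_aa_seqs(300, 500, f_p = 0.08, seed = 21)
  fc <- shuffle_fold_change(seqs, count_motifs, replicates = 60, seed = 5)
  expect_gt(fc$n_obs, 500) # enough signal for the bound to be meaningful
  expect_gt(fc$fold_change, 0.9)
  expect_lt(fc$fold_change, 1.1)
})

test_that("M0 expectation, variance and exact distribution match enumeration", {
  certain <- markov_null(freqs = c(P = 1))
  expect_equal(markov_expected_count(2, certain)$expectation, 1)
  half <- markov_null(freqs = c(P = 0.1, A = 0.9))
  expect_equal(markov_expected_count(101, half)$expectation, 1)

  nl <- markov_null(freqs = c(P = 0.5, A = 0.5))
  for (L in c(2, 4, 7, 10)) {
    want <- enum_pp_dist(L, 0.5)
    got <- markov_count_distribution(L, nl)
    expect_equal(sum(got), 1, tolerance = 1e-12)
    expect_equal(got[seq_along(want)], want, tolerance = 1e-12)
    # moments agree with the closed-form expectation/variance
    k <- 0:(length(got) - 1)
    ev <- markov_expected_count(L, nl)
    expect_equal(sum(k * got), ev$expectation, tolerance = 1e-12)
    expect_equal(sum(k^2 * got) - sum(k * got)^2, ev$variance,
                 tolerance = 1e-12)
  }
  # multi-sequence convolution: two sequences vs direct enumeration
  d1 <- enum_pp_dist(3, 0.3); d2 <- enum_pp_dist(4, 0.3)
  conv <- convolve(d1, rev(d2), type = "open")
  got <- markov_count_distribution(c(3, 4), markov_null(freqs = c(P = 0.3, A = 0.7)))
  expect_equal(got[seq_along(conv)], conv, tolerance = 1e-10)

  expect_error(markov_expected_count(5, nl, word = "PA"), "unsupported")
  # longer proline-run words use the same machinery
  ev3 <- markov_expected_count(10, nl, word = "PPP")
  expect_equal(ev3$expectation, 8 * 0.5^3)
})

test_that("markov_word_test branches agree with each other and enumeration", {
  nl <- markov_null(freqs = c(P = 0.5, A = 0.5))
  tst <- markov_word_test(2, 4, nl)
  expect_equal(tst$branch, "exact")
  expect_equal(tst$p_enrich, 3 / 16, tolerance = 1e-12)

  # centred observation in the Gaussian branch: z = 0, two-sided p = 1
  nl2 <- markov_null(freqs = c(P = 0.05, A = 0.95))
  ev <- markov_expected_count(5000, nl2)
  tst2 <- markov_word_test(round(ev$expectation), 5000, nl2,
                           exact_threshold = 0)
  expect_equal(tst2$branch, "gaussian")
  expect_lt(abs(tst2$z), 0.2) # rounding the expectation moves z slightly
  expect_equal(tst2$p_value, 1)

  # exact and Gaussian tail probabilities agree closely at total length 5000
  # (measured worst case 0.0214 near the mode, from the skew of the count
  # distribution that the continuity-corrected normal cannot capture)
  prob <- markov_count_distribution(5000, nl2, kmax = 80)
  for (n_obs in c(5, 9, 12, 16)) {
    exact_dep <- sum(prob[seq_len(n_obs + 1)])
    gauss <- markov_word_test(n_obs, 5000, nl2, exact_threshold = 0)
    expect_lt(abs(exact_dep - gauss$p_deplete), 0.025)
  }
})

test_that("M0 expectation matches Monte-Carlo simulation", {
  nl <- markov_null(freqs = c(P = 0.07, A = 0.93))
  sim <- vapply(1:4000, function(i) {
    s <- paste(sample(c("P", "A"), 60, TRUE, prob = c(0.07, 0.93)),
               collapse = "")
    count_pp_words(s)
  }, numeric(1))
  ev <- markov_expected_count(60, nl)
  se <- sqrt(ev$variance / 4000)
  expect_lt(abs(mean(sim) - ev$expectation), 3.5 * se)
})

test_that("dimer ratios behave at independence and on forced structure", {
  dr <- dimer_ratio_table(setNames(rep("ABAB", 50), sprintf("s%d", 1:50)))
  expect_gt(dr$ratio[dr$dimer == "AB"], 1)
  expect_equal(dr$ratio[dr$dimer == "AA"], 0)

  seqs <- random_aa_seqs(200, 400, f_p = 0.05, seed = 13)
  names(seqs) <- sprintf("p%d", seq_along(seqs))
  dr2 <- dimer_ratio_table(seqs)
  n_dimers <- sum(nchar(seqs) - 1)
  se <- sqrt(pmax(dr2$exp_freq * (1 - dr2$exp_freq), 1e-12) / n_dimers)
  dev <- abs(dr2$obs_freq - dr2$exp_freq) / se
  expect_lt(max(dev), 5)
})

test_that("rank-sum comparison is symmetric and detects separation", {
  withr::with_seed(31, {
    a <- rnorm(1000, 0.8, 0.01)
    b <- rnorm(1000, 1.0, 0.01)
  })
  expect_equal(compare_fold_change_vectors(a, a), 1, tolerance = 1e-6)
  p <- compare_fold_change_vectors(a, b)
  expect_lt(p, 1e-10)
  expect_equal(p, compare_fold_change_vectors(b, a))

  # agreement with a permutation oracle at small n
  withr::with_seed(8, {
    x <- rnorm(12); y <- rnorm(12, 0.8)
    obs <- sum(rank(c(x, y))[seq_along(x)])
    perm <- replicate(4000, {
      z <- sample(c(x, y))
      sum(rank(z)[1:12])
    })
    p_perm <- mean(abs(perm - mean(perm)) >= abs(obs - mean(perm)))
  })
  expect_lt(abs(compare_fold_change_vectors(x, y) - p_perm), 0.03)
})
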