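test_that("scan_motifs finds maximal stretches with correct flanks", {
  m <- scan_motifs("MAPPG")
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 3)
  expect_equal(m$n, 2)
  expect_equal(c(m$x_m2, m$x_m1, m$x_p1), c("M", "A", "G"))

  m <- scan_motifs("PPPPK")
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1)
  expect_equal(m$n, 4)
  expect_true(is.na(m$x_m2) && is.na(m$x_m1))
  expect_equal(m$x_p1, "K")

  expect_equal(nrow(scan_motifs("MAPG")), 0)
  expect_error(scan_motifs(""), "non-empty")
})

test_that("scanner agrees with the regex oracle on random sequences", {
  seqs <- random_aa_seqs(1000, 500, f_p = 0.05, seed = 42)
  for (i in seq_along(seqs)) {
    got <- scan_motifs(seqs[i])
    want <- regex_scan_oracle(seqs[i])
    expect_equal(got$start, want$start)
    expect_equal(got$n, want$n)
  }
})

test_that("maximality and proline conservation hold on random sequences", {
  seqs <- random_aa_seqs(200, 300, f_p = 0.08, seed = 7)
  for (s in seqs) {
    m <- scan_motifs(s)
    chars <- strsplit(s, "")[[1]]
    if (nrow(m)) {
      before <- m$start - 1
      after <- m$start + m$n
      expect_true(all(chars[before[before >= 1]] != "P"))
      expect_true(all(chars[after[after <= length(chars)]] != "P"))
      # motifs never overlap
      expect_true(all(diff(m$start) > m$n[-nrow(m)]))
    }
    expect_lte(sum(m$n), sum(chars == "P"))
  }
})

test_that("classification follows the arrest-context hierarchy", {
  rules <- default_rule_table()
  mk <- function(n, x_m2, x_m1, x_p1)
    data.frame(protein_id = "x", start = 3, n = n, x_m2 = x_m2,
               x_m1 = x_m1, x_p1 = x_p1, strength = NA_character_,
               stringsAsFactors = FALSE)
  # APP context with neutral other flanks stalls strongly
  expect_equal(classify_motif(mk(2, "V", "A", "K"), rules), "STRONG")
  # L/PP/L is a weak pause
  expect_equal(classify_motif(mk(2, "V", "L", "L"), rules), "WEAK")
  # three or more prolines always arrest strongly
  expect_equal(classify_motif(mk(3, "V", "L", "L"), rules), "STRONG")
  # ambiguous letters exclude the motif from classification
  expect_equal(classify_motif(mk(2, "V", "A", "X"), rules), "UNCLASSIFIED")
  # upstream promoters and attenuators shift the class by one rank
  expect_equal(classify_motif(mk(2, "K", "V", "K"), rules), "STRONG")
  expect_equal(classify_motif(mk(2, "G", "V", "K"), rules), "WEAK")
  # pure function: repeated calls agree
  expect_identical(classify_motif(mk(2, "V", "A", "K"), rules),
                   classify_motif(mk(2, "V", "A", "K"), rules))
})

test_that("missing flanks are neutral by default and excludable by policy", {
  rules <- default_rule_table()
  m <- scan_motifs("PPK") # both upstream flanks missing
  # missing X(-1) contributes the weak-effect base; X(+1)=K is neutral
  expect_equal(classify_motifs(m, rules)$strength, "MEDIUM")
  m2 <- scan_motifs("PPL") # weak-effect X(+1)
  expect_equal(classify_motifs(m2, rules)$strength, "WEAK")
  expect_equal(classify_motifs(m, rules, missing_policy = "exclude")$strength,
               "UNCLASSIFIED")
  expect_error(classify_motifs(m, structure(list(), class = "strength_rule_table")),
               "validated")
})

test_that("scan_proteome aggregates counts and rejects duplicate ids", {
  mt <- scan_proteome(c(a = "MAPPG", b = "AAAAA", c = "PPMPP"))
  expect_equal(unname(motif_counts(mt)), c(1, 0, 2))
  expect_equal(nrow(mt), 3)
  expect_equal(mt$start, c(3, 1, 4))

  empty <- scan_proteome(setNames(character(0), character(0)))
  expect_equal(nrow(empty), 0)

  expect_error(scan_proteome(setNames(c("APPA", "APPA"), c("a", "a"))),
               "duplicate")
})

test_that("planted stretches are recovered exactly", {
  gen <- generate_proteome(n_proteins = 30, plant = data.frame(
    class = "STRONG", density = 0.8), seed = 11)
  pl <- gen$planted
  mt <- gen$motif_table
  found <- paste(mt$protein_id, mt$start)
  expect_true(all(paste(pl$protein_id, pl$start) %in% found))
  hit <- mt[match(paste(pl$protein_id, pl$start), found), ]
  expect_true(all(hit$strength == pl$class))
})

test_that("the packaged rule table loads, is total, and round-trips", {
  path <- system.file("extdata", "stalling_rules.yaml", package = "ppstall")
  rules <- load_rule_table(path)
  for (pos in c("x_m2", "x_m1", "x_p1"))
    expect_setequal(names(rules$flank_effect[[pos]]),
                    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(nrow(rules$combination_rules), 54)

  tmp <- tempfile(fileext = ".yaml")
  write_rule_table(rules, tmp)
  rules2 <- load_rule_table(tmp)
  expect_identical(rules$flank_effect, rules2$flank_effect)
  expect_identical(rules$combination_rules$strength,
                   rules2$combination_rules$strength)

  # a table with a missing rule key fails validation naming the gap
  broken <- rules
  broken$combination_rules <- rules$combination_rules[-1, ]
  expect_error(validate_rule_table(broken), "missing keys")
  broken2 <- rules
  broken2$flank_effect$x_m1 <- broken2$flank_effect$x_m1[-1]
  expect_error(validate_rule_table(broken2), "x_m1")
})
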