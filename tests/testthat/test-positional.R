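test_that("linker construction follows the downstream-extension rule", {
  doms <- data.frame(start = c(1, 111), end = c(100, 200))
  expect_equal(define_linkers(doms, 250), data.frame(start = 101, end = 110))

  doms2 <- data.frame(start = c(1, 103), end = c(100, 200))
  expect_equal(define_linkers(doms2, 250), data.frame(start = 101, end = 105))

  doms3 <- data.frame(start = c(1, 101), end = c(100, 200))
  expect_equal(define_linkers(doms3, 250), data.frame(start = 101, end = 105))

  # clipped at the protein end; overlapping domains rejected
  expect_equal(define_linkers(doms3, 103)$end, 103)
  expect_error(define_linkers(data.frame(start = c(1, 50), end = c(60, 90)),
                              100), "overlap")
  expect_error(define_linkers(doms3[1, , drop = FALSE], 100), "at least 2")

  # every emitted linker has length >= 5 unless clipped
  withr::with_seed(3, {
    for (i in 1:20) {
      s1 <- sample(1:50, 1); e1 <- s1 + sample(20:80, 1)
      s2 <- e1 + sample(1:12, 1); e2 <- s2 + sample(20:80, 1)
      lk <- define_linkers(data.frame(start = c(s1, s2), end = c(e1, e2)),
                           e2 + 50)
      expect_gte(lk$end - lk$start + 1, 5)
    }
  })
})

test_that("N-terminal ramp test attributes motifs by anchor", {
  # a protein shorter than the split contributes only to the N-terminal set
  prot <- c(short = "MAPPGAKLVDKSAGLKVDAGLKVDSAGLKVDASAGLKVDK") # length 40
  expect_equal(nchar(prot[[1]]), 40)
  res <- nterminal_ramp_test(prot, split = 50, replicates = 30, seed = 2)
  expect_equal(res$n_nterm, 1)
  expect_equal(res$n_rest, 0)
})

test_that("uniform motif placement gives a null ramp comparison", {
  seqs <- random_aa_seqs(120, 300, f_p = 0.08, seed = 44)
  names(seqs) <- sprintf("p%d", seq_along(seqs))
  res <- nterminal_ramp_test(seqs, split = 50, replicates = 80, seed = 3)
  expect_gt(res$p_value, 0.01)
  expect_lt(abs(res$nterm$fold_change - 1), 0.2)
  expect_lt(abs(res$rest$fold_change - 1), 0.1)
})

test_that("region enrichment calibrates on i.i.d. segments and forced cases", {
  segs <- random_aa_seqs(150, 200, f_p = 0.06, seed = 51)
  fc <- region_enrichment(segs)
  expect_equal(fc$null_kind, "MARKOV_M0")
  se_rel <- sqrt(fc$variance) / fc$n_exp
  expect_lt(abs(fc$fold_change - 1), 4 * se_rel)

  # removing every proline forces zero observation and near-minimal p
  nop <- gsub("P", "A", segs)
  fc0 <- region_enrichment(nop, null = markov_null(segs))
  expect_equal(fc0$n_obs, 0)
  expect_lt(fc0$p_deplete, 1e-6)

  # thinning half the stretches halves the word count
  thin <- thin_motifs(setNames(segs, sprintf("s%d", seq_along(segs))),
                      q = 0.5, seed = 7)
  fc5 <- region_enrichment(unname(thin$proteome), null = markov_null(segs))
  expect_lt(abs(fc5$fold_change - 0.5), 0.12)

  expect_error(region_enrichment(character(0)), "empty")
})

test_that("boundary profiles count offsets, normalise and smooth correctly", {
  prot <- c(p1 = paste(rep("A", 200), collapse = ""))
  substr(prot["p1"], 95, 96) <- "PP"
  track <- data.frame(protein_id = "p1", kind = "DOMAIN",
                      start = 100, end = 150)
  mt <- scan_proteome(prot)
  prof <- boundary_profile(prot, mt, track, "DOMAIN_START", offsets = -25:25)
  expect_equal(prof$raw_count[prof$offset == -5], 1)
  expect_equal(sum(prof$raw_count), 1)
  expect_true(all(prof$n_contributing == 1))

  # no motifs -> all-zero profile
  prof0 <- boundary_profile(c(q = "AGAGAGAGAG"), scan_proteome(c(q = "AGAGAGAGAG")),
                            NULL, "PROTEIN_START", offsets = 0:9)
  expect_true(all(prof0$raw_count == 0))

  # smoothing: linear, idempotent on constants, edge-aware
  x <- c(1, 1, 1, 1)
  expect_equal(ppstall:::smooth3(x), x)
  expect_equal(ppstall:::smooth3(c(0, 3, 0)), c(1.5, 1, 1.5))
})

test_that("TMH site intervals and location labels follow the site table", {
  # TMH at [10,30]: site II (+23..+32, 1-based from the start) is [32,41]
  expect_equal(ppstall:::site_absolute(10, c(23, 32)), c(32, 41))
  # site I abuts the start: [-17,-1] relative to start 100 is [83,99]
  expect_equal(ppstall:::site_absolute(100, c(-17, -1)), c(83, 99))

  # a site instance whose midpoint lies in a downstream TMH is labelled TMH
  prot <- c(tp = paste(rep("A", 200), collapse = ""))
  track <- data.frame(protein_id = "tp", kind = "TMH",
                      start = c(10, 55), end = c(30, 75))
  res <- tmh_site_analysis(prot, track)
  # site III of TMH1 = [58,68], midpoint 63 inside TMH2 [55,75]
  expect_true(any(res$site == "III" & res$location == "TMH"))
  expect_error(tmh_site_analysis(prot, track[0, ]), "empty")
})

test_that("TP proportion test matches its contingency arithmetic", {
  withr::with_seed(6, {
    tp <- sprintf("tp%d", 1:912)
    sol <- sprintf("s%d", 1:3000)
    with_tp <- sample(tp, 358)
    with_sol <- sample(sol, round(0.326 * 3000))
  })
  mt <- data.frame(protein_id = c(with_tp, with_sol), start = 1, n = 2,
                   stringsAsFactors = FALSE)
  res <- tp_proportion_test(tp, sol, mt)
  expect_equal(res$prop_tp, 358 / 912)
  expect_equal(round(100 * res$prop_tp, 1), 39.3)
  expect_lt(res$p_value, 0.01)

  # doubling every cell keeps proportions, decreases p
  mt2 <- data.frame(protein_id = c(paste0(c(with_tp, with_sol), "_b"),
                                   c(with_tp, with_sol)),
                    start = 1, n = 2)
  tp2 <- c(tp, paste0(tp, "_b")); sol2 <- c(sol, paste0(sol, "_b"))
  res2 <- tp_proportion_test(tp2, sol2, mt2)
  expect_equal(res2$prop_tp, res$prop_tp)
  expect_lt(res2$p_value, res$p_value)

  expect_error(tp_proportion_test(character(0), sol, mt), "non-empty")
  expect_error(tp_proportion_test(tp, c(sol, tp[1]), mt), "disjoint")
})

test_that("equal planted proportions give a null TP comparison", {
  withr::with_seed(29, {
    tp <- sprintf("tp%d", 1:500); sol <- sprintf("s%d", 1:500)
    hit <- c(sample(tp, 170), sample(sol, 170))
  })
  mt <- data.frame(protein_id = hit, start = 1, n = 2)
  expect_gt(tp_proportion_test(tp, sol, mt)$p_value, 0.01)
})
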