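test_that("motif regions map through gaps and carry max-rank leaf states", {
  proteome <- c(s1 = "MAPPG", s2 = "MAPPG", s3 = "MAPPG")
  mt <- scan_proteome(proteome)
  msa <- c(s1 = "MAPPG", s2 = "MAPPG", s3 = "MAPPG")
  regions <- map_motifs_to_alignment(msa, mt, "og1", proteome)
  expect_length(regions, 1)
  expect_equal(regions[[1]]$columns, c(3, 4))
  expect_true(all(regions[[1]]$leaf_states == "STRONG"))

  # one motif-bearing sequence among motif-free orthologs
  proteome2 <- c(a = "MAPPGK", b = "MAGLGK", c = "MAGLGK")
  mt2 <- scan_proteome(proteome2)
  regions2 <- map_motifs_to_alignment(proteome2, mt2, "og2", proteome2)
  expect_length(regions2, 1)
  st <- regions2[[1]]$leaf_states
  expect_equal(unname(st[c("a", "b", "c")]), c("STRONG", "NONE", "NONE"))

  # gap bookkeeping round-trip: columns map back to the residue span
  msa3 <- c(x = "MA--PPG", y = "MAKL--G")
  prot3 <- c(x = "MAPPG", y = "MAKLG")
  mt3 <- scan_proteome(prot3)
  r3 <- map_motifs_to_alignment(msa3, mt3, "og3", prot3)
  expect_length(r3, 1)
  expect_equal(r3[[1]]$columns, c(5, 6))
  cols_x <- which(strsplit(msa3[["x"]], "")[[1]] != "-")
  expect_equal(which(cols_x %in% 5:6), 3:4) # residues 3..4 of x

  # de-gap mismatch is an error naming the sequence
  expect_error(map_motifs_to_alignment(msa3, mt3, "og3",
                                       c(x = "MAPPG", y = "MAKLA")), "y")
})

test_that("region extraction and re-scanning reproduce leaf states", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      prot <- setNames(random_aa_seqs(4, 80, f_p = 0.08,
                                      seed = sample.int(1e6, 1)),
                       paste0("t", 1:4))
      mt <- scan_proteome(prot)
      ## align trivially (ungapped, equal lengths)
      regions <- map_motifs_to_alignment(prot, mt, "og", prot)
      for (rg in regions) {
        for (id in names(prot)) {
          sub <- mt[mt$protein_id == id &
                      mt$start <= rg$columns[2] &
                      (mt$start + mt$n - 1) >= rg$columns[1] &
                      mt$strength != "UNCLASSIFIED", ]
          want <- if (nrow(sub)) STATES4[max(strength_rank(sub$strength)) + 1]
                  else "NONE"
          expect_equal(unname(rg$leaf_states[id]), want)
        }
      }
    }
  })
})

test_that("midpoint rooting splits the longest path and preserves distances", {
  tr2 <- ape::read.tree(text = "(A:2,B:4);")
  m2 <- midpoint_root(tr2)
  d <- ape::cophenetic.phylo(m2)
  expect_equal(unname(d["A", "B"]), 6)
  depths <- ape::node.depth.edgelength(m2)[1:2]
  expect_equal(unname(depths), c(3, 3))

  withr::with_seed(5, {
    for (i in 1:15) {
      tr <- ape::rtree(20)
      m <- midpoint_root(tr)
      d1 <- ape::cophenetic.phylo(tr); d2 <- ape::cophenetic.phylo(m)
      expect_lt(max(abs(d1[rownames(d2), colnames(d2)] - d2)), 1e-9)
      dep <- ape::node.depth.edgelength(m)[1:ape::Ntip(m)]
      # the two ends of the longest path are equidistant from the root
      expect_lt(abs(max(dep) - max(d1) / 2), 1e-9)
      expect_true(ape::is.rooted(m))
    }
  })
})

test_that("midpoint rooting agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  withr::with_seed(9, {
    for (i in 1:8) {
      tr <- ape::rtree(12)
      m <- midpoint_root(tr)
      p <- phangorn::midpoint(tr)
      dep_m <- sort(ape::node.depth.edgelength(m)[1:12])
      dep_p <- sort(ape::node.depth.edgelength(p)[1:12])
      expect_equal(dep_m, dep_p, tolerance = 1e-9)
    }
  })
})

test_that("pruning likelihood and marginal posteriors match brute force", {
  withr::with_seed(23, {
    for (i in 1:8) {
      n <- sample(4:6, 1)
      tr <- ape::rcoal(n)
      ls <- random_states(tr$tip.label, seed = sample.int(1e6, 1))
      alpha <- runif(1, 0.05, 2)
      st <- reconstruct_ancestral_states(tr, ls, rate = alpha)
      bf <- brute_force_mk(tr, ls, alpha)
      expect_lt(abs(st$loglik - bf$loglik), 1e-9)
      expect_lt(max(abs(st$posteriors - bf$posteriors)), 1e-9)
    }
  })
})

test_that("reconstruction handles invariant data and the 3-leaf star", {
  tr <- ape::read.tree(text = "(a:1,b:1,c:1);")
  tr <- ape::root(tr, outgroup = "a", resolve.root = TRUE)
  all_s <- setNames(rep("STRONG", 3), c("a", "b", "c"))
  st <- reconstruct_ancestral_states(tr, all_s)
  expect_true(all(st$node_states == "STRONG"))

  star <- ape::read.tree(text = "((a:1,b:1):1e-9,c:1):0;")
  ls <- c(a = "STRONG", b = "STRONG", c = "NONE")
  st2 <- reconstruct_ancestral_states(star, ls, rate = 0.3)
  bf <- brute_force_mk(star, ls, 0.3)
  # majority state wins at the root, matching direct summation
  expect_equal(which.max(bf$posteriors[1, ]), 4L)
  root_state <- st2$node_states[ape::Ntip(star) + 1]
  expect_equal(root_state, "STRONG")

  expect_error(reconstruct_ancestral_states(star, ls[-1]), "missing")
})

test_that("events and PSEC follow their definitions", {
  # hand-built two-branch tree: root W, children S (gain) and W
  tr <- ape::read.tree(text = "(a:1,b:5);")
  st <- structure(list(tree = tr,
                       node_states = c("STRONG", "WEAK", "WEAK")),
                  class = "state_tree")
  ev <- count_events(st)
  expect_equal(ev$event[ev$child == 1], "GAIN")
  expect_true(is.na(ev$event[ev$child == 2]))
  ps <- compute_psec(st)
  # gain on branch length 1; gains possible on both branches (parent W)
  expect_equal(ps$b_g, 1); expect_equal(ps$b_cg, 6)
  expect_equal(ps$b_l, 0); expect_equal(ps$b_cl, 6)
  expect_equal(ps$psec, 1 / 6)
  expect_equal(ps$gains + ps$losses,
               sum(ev$parent_state != ev$child_state))

  # parent STRONG above weaker children: both branches are losses
  st2 <- structure(list(tree = tr,
                        node_states = c("NONE", "MEDIUM", "STRONG")),
                   class = "state_tree")
  ev2 <- count_events(st2)
  expect_equal(sort(ev2$event), c("LOSS", "LOSS"))
  st3 <- structure(list(tree = tr, node_states = rep("MEDIUM", 3)),
                   class = "state_tree")
  expect_equal(compute_psec(st3)$psec, 0)
})

test_that("PSEC stays in [-1, 1] and books branches consistently", {
  withr::with_seed(41, {
    for (i in 1:25) {
      sim <- simulate_state_evolution(n_leaves = 8, alpha = runif(1, 0.05, 1),
                                      seed = sample.int(1e6, 1))
      st <- reconstruct_ancestral_states(sim$tree, sim$leaf_states)
      ev <- count_events(st)
      ps <- compute_psec(st, ev)
      expect_gte(ps$psec, -1); expect_lte(ps$psec, 1)
      expect_lte(ps$b_g, ps$b_cg + 1e-12)
      expect_lte(ps$b_l, ps$b_cl + 1e-12)
      expect_equal(ps$gains + ps$losses,
                   sum(ev$parent_state != ev$child_state))
    }
  })
})

test_that("og_psec runs end-to-end on a synthetic group", {
  prot <- c(t1 = "MAPPGKL", t2 = "MAPPGKL", t3 = "MAGLGKL", t4 = "MAGLGKL")
  mt <- scan_proteome(prot)
  tree <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  res <- og_psec(prot, tree, mt, og_id = "og9")
  expect_equal(nrow(res), 1)
  expect_true(res$psec >= -1 && res$psec <= 1)
  summ <- psec_cohort_summary(c(res$psec, -0.2, 0.3, 0))
  expect_equal(summ$n_zero, sum(c(res$psec, -0.2, 0.3, 0) == 0))
})
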