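test_that("yule trees are seeded, labelled, and match the analytic height", {
  t2 <- simulate_yule_tree(2, 1, seed = 1)
  expect_identical(sort(t2$tip.label), c("T1", "T2"))
  expect_identical(ape::Ntip(t2), 2L)

  expect_identical(write_newick(simulate_yule_tree(8, 1, seed = 3)),
                   write_newick(simulate_yule_tree(8, 1, seed = 3)))
  expect_false(identical(write_newick(simulate_yule_tree(8, 1, seed = 3)),
                         write_newick(simulate_yule_tree(8, 1, seed = 4))))

  # expected tree height (sum of internode intervals, 2..n lineages) is
  # sum_{k=2}^{n} 1/(k * lambda); Monte Carlo over many seeds
  n <- 8L
  lambda <- 2
  heights <- vapply(1:400, function(s) {
    tr <- simulate_yule_tree(n, lambda, seed = 10000 + s)
    max(ape::node.depth.edgelength(tr))
  }, 0)
  expected <- sum(1 / ((2:n) * lambda))
  se <- stats::sd(heights) / sqrt(length(heights))
  expect_lt(abs(mean(heights) - expected), 4 * se)
})

test_that("random root structures hit the exact pair count and invariants", {
  s0 <- simulate_root_structure(100, 0, seed = 2)
  expect_identical(n_pairs(s0$pairs), 0L)
  for (seed in 1:6) {
    len <- sample(60:200, 1)
    pf <- runif(1, 0.1, 0.4)
    s <- simulate_root_structure(len, pf, seed = 1000 + seed)
    expect_identical(n_pairs(s$pairs), as.integer(floor(pf * len)))
    expect_s3_class(s$pairs, "pair_table")   # involution + nesting enforced
    expect_silent(structured_seq(s$record, s$pairs, strict = TRUE))
  }
  expect_error(simulate_root_structure(10, 0.5, seed = 1),
               class = "rnaphylo_invalid")
})

test_that("evolution conserves structure and respects the rate limits", {
  tree <- simulate_yule_tree(6, 1, seed = 5)
  root <- simulate_root_structure(200, 0.3, seed = 6)

  frozen <- evolve_alignment(tree, root, c = 1, rate = 0, seed = 7)
  for (s in frozen) {
    expect_identical(s$record$residues, root$record$residues)
    expect_identical(unclass(s$pairs), unclass(root$pairs))
  }

  evolved <- evolve_alignment(tree, root, c = 1, rate = 0.3, seed = 8)
  for (s in evolved) {
    expect_identical(unclass(s$pairs), unclass(root$pairs))  # conserved
    expect_silent(structured_seq(s$record, s$pairs, strict = TRUE))  # c = 1
  }

  # with c = 0 and long branches, pair validity decays to the stationary
  # expectation: two independent uniform residues pair in 6/16 of cases
  long_tree <- simulate_yule_tree(40, 1, seed = 9)
  long_tree$edge.length <- long_tree$edge.length * 0 + 5
  big_root <- simulate_root_structure(600, 0.3, seed = 10)
  leaves <- evolve_alignment(long_tree, big_root, c = 0, rate = 3, seed = 11)
  pr <- pairs_of(big_root$pairs)
  frac <- mean(vapply(leaves, function(s) {
    res <- strsplit(s$record$residues, "")[[1]]
    mean(paste0(res[pr[, 1]], res[pr[, 2]]) %in%
           c("AU", "UA", "GC", "CG", "GU", "UG"))
  }, 0))
  expect_lt(abs(frac - 6 / 16), 0.02)
})

test_that("defect injection hits exact counts and reports ground truth", {
  sim <- simulate_dataset(n_taxa = 8, seq_length = 200, rate = 0.2, seed = 12)
  none <- degrade_dataset(sim$clean, seed = 13)
  expect_identical(vapply(none$records, function(s) s$record$residues, ""),
                   vapply(sim$clean, function(s) s$record$residues, ""))
  expect_true(all(none$truth$defect == "none"))

  deg <- degrade_dataset(sim$clean, frac_short = 0.25, short_factor = 0.4,
                         frac_structure_noise = 0.25,
                         noise_pair_rewire_fraction = 0.6, seed = 14)
  expect_identical(sum(deg$truth$defect == "short"), 2L)
  expect_identical(sum(deg$truth$defect == "structure_noise"), 2L)
  shorts <- which(deg$truth$defect == "short")
  for (k in shorts)
    expect_identical(length(deg$records[[k]]$pairs), 80L)
  noisy <- which(deg$truth$defect == "structure_noise")
  for (k in noisy) {
    expect_identical(deg$records[[k]]$record$residues,
                     sim$clean[[k]]$record$residues)  # sequence kept
    expect_false(identical(unclass(deg$records[[k]]$pairs),
                           unclass(sim$clean[[k]]$pairs)))
  }

  expect_error(degrade_dataset(sim$clean, frac_short = 0.7,
                               frac_structure_noise = 0.7, seed = 1),
               class = "rnaphylo_invalid")
})

test_that("the curation filter recovers the injected truth table exactly", {
  sim <- simulate_dataset(n_taxa = 12, seq_length = 300, rate = 0.15,
                          frac_short = 0.25, short_factor = 0.4,
                          frac_structure_noise = 0.25,
                          noise_pair_rewire_fraction = 0.8, seed = 15)
  results <- list()
  cfg <- filter_config(min_length = 200, min_transfer_pct = 65)
  recs <- lapply(sim$records, function(s) s$record)
  for (s in sim$records) {
    if (nchar(s$record$residues) < cfg$min_length) next
    # records carry their own (possibly scrambled) structures: structural
    # homology to the known template is the filter statistic
    results[[s$record$id]] <- structural_homology(sim$root, s)
  }
  flt <- filter_dataset(recs, results, cfg)
  truth <- sim$truth
  expect_setequal(flt$kept, truth$id[truth$defect == "none"])
  short_ids <- flt$discarded$id[flt$discarded$reason == "too short"]
  expect_setequal(short_ids, truth$id[truth$defect == "short"])
  noise_ids <- flt$discarded$id[flt$discarded$reason == "low transfer"]
  expect_setequal(noise_ids, truth$id[truth$defect == "structure_noise"])
})
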