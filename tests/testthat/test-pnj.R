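pnj_fixture <- function(seed = 9, n = 6, L = 300, rate = 0.3) {
  sim <- simulate_dataset(n_taxa = n, seq_length = L, rate = rate, seed = seed)
  list(sim = sim,
       aln = as_alignment(vapply(sim$clean, function(s)
         encode_structured(s)$letters, "")))
}

test_that("a degenerate collapse threshold reduces PNJ to plain NJ", {
  fx <- pnj_fixture()
  res <- profile_nj(fx$aln, pnj_config(bootstrap_replicates = 10,
                                       collapse_threshold = 100,
                                       iterations = 1, seed = 5))
  expect_length(res$profiles, 0L)
  nj <- neighbor_joining(matrix_from_alignment(fx$aln, "jc12"))
  stripped <- res$tree
  stripped$node.label <- NULL
  expect_identical(write_newick(stripped), write_newick(nj))
})

test_that("well-separated clusters collapse into profiles and expand back", {
  fx <- pnj_fixture(seed = 9)
  res <- profile_nj(fx$aln, pnj_config(bootstrap_replicates = 30,
                                       iterations = 2, seed = 5))
  expect_gte(length(res$profiles), 1L)
  # expansion restores every sequence exactly once
  expect_setequal(res$tree$tip.label, names(fx$aln))
  # profiles transferred a support value from the overview bootstrap
  sup <- vapply(res$profiles, function(p) p$support, 1L)
  expect_true(all(is.na(sup) | (sup >= 0 & sup <= 100)))
  # the final unit tree has the profiles as leaves
  expect_true(all(names(res$profiles) %in%
                    c(res$unit_tree$tip.label,
                      unlist(lapply(res$profiles, function(p) p$label)))))
  # determinism
  res2 <- profile_nj(fx$aln, pnj_config(bootstrap_replicates = 30,
                                        iterations = 2, seed = 5))
  expect_identical(write_newick(res2$tree), write_newick(res$tree))
})

test_that("profile frequency distances reduce to sequence distances", {
  # a profile of identical rows is an indicator profile: its generalized p
  # to any sequence equals the plain sequence p distance
  lets <- encoding_table()$letters
  set.seed(44)
  s1 <- paste(sample(lets, 200, TRUE), collapse = "")
  s2 <- paste(sample(lets, 200, TRUE), collapse = "")
  aln <- as_alignment(c(a = s1, b = s1, c = s1, d = s2, e = s2))
  units <- list(list(label = "P", ids = c("a", "b", "c")),
                list(label = "d", ids = "d"))
  D <- rnaphylo:::unit_dist_matrix(units, aln, lets, "p")
  expect_equal(unname(D["P", "d"]), p_distance(s1, s2))
})

test_that("manual initial profiles seed the iteration", {
  fx <- pnj_fixture(seed = 12, n = 6)
  ids <- names(fx$aln)
  res <- profile_nj(fx$aln,
                    pnj_config(bootstrap_replicates = 10, iterations = 1,
                               seed = 3,
                               initial_profiles = list(M1 = ids[1:2])))
  expect_true("M1" %in% names(res$profiles))
  expect_setequal(res$tree$tip.label, ids)
})

test_that("a profile swallowing every row raises the degenerate error", {
  lets <- encoding_table()$letters
  rows <- setNames(rep(paste(rep("A", 50), collapse = ""), 3),
                   c("a", "b", "c"))
  aln <- as_alignment(rows)
  expect_error(
    profile_nj(aln, pnj_config(bootstrap_replicates = 2, iterations = 1,
                               seed = 1,
                               initial_profiles = list(P = c("a", "b", "c")))),
    class = "rnaphylo_degenerate")
})
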