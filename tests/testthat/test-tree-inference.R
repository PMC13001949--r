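make_additive <- function(tree, labs = tree$tip.label) {
  D <- ape::cophenetic.phylo(tree)[labs, labs]
  dist_matrix(D)
}

test_that("neighbor joining recovers the worked additive example exactly", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(dist_matrix(D))
  # AB|CD split, with the generating branch lengths
  expect_identical(unname(bipartitions(tr)),
                   split_key(c("A", "B"), c("A", "B", "C", "D")))
  expect_equal(unname(make_additive(tr, c("A", "B", "C", "D"))), unname(D))
  # least-squares oracle over all three quartet topologies picks AB too
  expect_identical(ls_best_quartet(D), c("A", "B"))
})

test_that("neighbor joining recovers random additive matrices (n <= 12)", {
  for (seed in 1:10) {
    n <- sample(4:12, 1)
    tr <- simulate_yule_tree(n, 1, seed = 400 + seed)
    D <- make_additive(tr)
    rec <- neighbor_joining(D)
    expect_identical(robinson_foulds(rec, tr), 0L)
    # branch lengths are reproduced: the path metric matches
    expect_equal(unclass(make_additive(rec, rownames(D))), unclass(D),
                 tolerance = 1e-8)
  }
})

test_that("three-taxon and tie cases are deterministic", {
  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(dist_matrix(D3))
  expect_identical(write_newick(tr), "(x:1,y:1,z:3);")

  Deq <- matrix(1, 5, 5,
                dimnames = list(letters[1:5], letters[1:5]))
  diag(Deq) <- 0
  t1 <- write_newick(neighbor_joining(dist_matrix(Deq)))
  t2 <- write_newick(neighbor_joining(dist_matrix(Deq)))
  expect_identical(t1, t2)
  # lexicographically smallest pair is joined first
  expect_match(t1, "\\(a:[0-9.]+,b:[0-9.]+\\)")

  expect_error(neighbor_joining(dist_matrix(
    matrix(c(0, Inf, Inf, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))),
    class = "rnaphylo_numeric")
})

test_that("robinson-foulds agrees with the reference implementation", {
  expect_identical(robinson_foulds(read_newick("((A,B),(C,D));"),
                                   read_newick("((A,C),(B,D));")), 2L)
  for (seed in 1:6) {
    t1 <- simulate_yule_tree(8, 1, seed = 500 + seed)
    t2 <- simulate_yule_tree(8, 1, seed = 600 + seed)
    expect_identical(robinson_foulds(t1, t2),
                     as.integer(phangorn::RF.dist(t1, t2)))
    expect_identical(robinson_foulds(t1, t1), 0L)
  }
})

test_that("outgroup rooting places the root on the outgroup edge", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  rooted <- root_with_outgroup(tr, "A")
  expect_true(ape::is.rooted(rooted))
  kids <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1L, 2]
  expect_true(which(rooted$tip.label == "A") %in% kids)

  rooted2 <- root_with_outgroup(tr, c("C", "D"))
  expect_true(ape::is.rooted(rooted2))

  expect_error(root_with_outgroup(tr, c("A", "C")),
               class = "rnaphylo_invalid")   # not a clade
  expect_error(root_with_outgroup(tr, "Z"), class = "rnaphylo_lookup")
})

test_that("bootstrap support is deterministic, bounded, and column-based", {
  sim <- simulate_dataset(n_taxa = 6, seq_length = 400, seed = 31)
  aln <- as_alignment(vapply(sim$clean, function(s)
    encode_structured(s)$letters, ""))
  b1 <- bootstrap_support(aln, nj_builder("jc12"), B = 15, seed = 99)
  b2 <- bootstrap_support(aln, nj_builder("jc12"), B = 15, seed = 99)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 100))
  expect_identical(b1$B_effective, 15L)

  one <- bootstrap_support(aln, nj_builder("jc12"), B = 1, seed = 7)
  expect_true(all(one$support %in% c(0L, 100L)))

  # row order must not matter: same seed, permuted rows
  perm <- as_alignment(unclass(aln)[sample(names(aln))])
  b3 <- bootstrap_support(perm, nj_builder("jc12"), B = 15, seed = 99)
  k1 <- setNames(b1$support, bipartitions(ape::unroot(b1$tree)))
  k3 <- setNames(b3$support, bipartitions(ape::unroot(b3$tree)))
  expect_identical(k1[sort(names(k1))], k3[sort(names(k3))])
})

test_that("fitch score matches exhaustive enumeration (n = 4, short columns)", {
  aln1 <- as_alignment(c(a = "A", b = "A", c = "F", d = "F"))
  res <- mp_search(aln1, strategy = "exhaustive")
  expect_identical(res$score, 1L)
  expect_identical(unname(bipartitions(res$tree)),
                   split_key(c("a", "b"), letters[1:4]))

  expect_identical(fitch_score(read_newick("((a,b),(c,d));"),
                               as_alignment(c(a = "AAA", b = "AAA",
                                              c = "AAA", d = "AAA"))), 0L)

  set.seed(32)
  lets <- encoding_table()$letters
  quartets <- phangorn::allTrees(4, rooted = FALSE,
                                 tip.label = c("a", "b", "c", "d"))
  for (rep in 1:12) {
    L <- sample(1:3, 1)
    rows <- setNames(vapply(1:4, function(k)
      paste(sample(c(lets, "-"), L, TRUE, prob = c(rep(1, 12), 0.5)),
            collapse = ""), ""), c("a", "b", "c", "d"))
    aln <- as_alignment(rows)
    tr <- quartets[[sample(3, 1)]]
    mine <- fitch_score(tr, aln)
    states <- do.call(rbind, strsplit(rows, ""))
    oracle <- sum(vapply(seq_len(L), function(col) {
      st <- setNames(match(states[, col], lets), names(rows))
      brute_fitch_column(ape::reorder.phylo(tr, "postorder"), st)
    }, 0))
    expect_identical(mine, as.integer(oracle))
  }
})

test_that("pruning log-likelihood equals brute-force state summation", {
  set.seed(33)
  lets <- encoding_table()$letters
  for (rep in 1:3) {
    n <- sample(3:4, 1)
    tr <- simulate_yule_tree(n, 2, seed = 700 + rep)
    L <- sample(3:8, 1)
    rows <- setNames(vapply(seq_len(n), function(k)
      paste(sample(c(lets, "-"), L, TRUE, prob = c(rep(1, 12), 0.3)),
            collapse = ""), ""), tr$tip.label)
    aln <- as_alignment(rows)
    for (model in list(subst_model_12(),
                       subst_model_12(gamma_alpha = 0.7, p_inv = 0.15))) {
      expect_equal(ml_loglik(tr, aln, model), brute_loglik(tr, aln, model),
                   tolerance = 1e-9)
    }
  }
})

test_that("likelihood is invariant under re-rooting (reversibility)", {
  sim <- simulate_dataset(n_taxa = 5, seq_length = 120, seed = 34)
  aln <- as_alignment(vapply(sim$clean, function(s)
    encode_structured(s)$letters, ""))
  tr <- ape::unroot(sim$tree)
  model <- subst_model_12(gamma_alpha = 1.2)
  base <- ml_loglik(tr, aln, model)
  for (og in tr$tip.label[1:3]) {
    rer <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(ml_loglik(rer, aln, model), base, tolerance = 1e-8)
  }
})

test_that("likelihood of identical sequences peaks at zero branch length", {
  aln <- as_alignment(c(x = "ACGTDFIK", y = "ACGTDFIK"))
  m <- subst_model_12()
  ll_small <- ml_loglik(read_newick("(x:1e-8,y:1e-8);"), aln, m)
  expect_equal(ll_small, 8 * log(1 / 12), tolerance = 1e-5)
  expect_lt(ml_loglik(read_newick("(x:0.3,y:0.3);"), aln, m), ll_small)
})

test_that("ml search improves on its starting tree and finds the true split", {
  sim <- simulate_dataset(n_taxa = 5, seq_length = 300, seed = 35)
  aln <- as_alignment(vapply(sim$clean, function(s)
    encode_structured(s)$letters, ""))
  fit <- ml_search(aln)
  start <- ape::unroot(neighbor_joining(matrix_from_alignment(aln, "jc12")))
  expect_gte(fit$loglik, ml_loglik(start, aln, fit$model) - 1e-6)
  expect_identical(robinson_foulds(fit$tree, sim$tree), 0L)
})
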