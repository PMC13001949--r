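test_that("dot-bracket parsing matches bracket matching and flags errors", {
  pt <- parse_dotbracket("((..))")
  expect_identical(unname(pairs_of(pt)), cbind(c(1L, 2L), c(6L, 5L)))
  expect_identical(unclass(parse_dotbracket("()")), c(2L, 1L))
  expect_error(parse_dotbracket("(."), class = "rnaphylo_parse")
  expect_error(parse_dotbracket(").("), class = "rnaphylo_parse")
  expect_identical(n_pairs(parse_dotbracket("....")), 0L)
})

test_that("parse/serialize is the identity on random nested structures", {
  for (seed in 1:8) {
    st <- random_structured(30 + 7 * seed, 0.3, seed = seed)
    db <- write_dotbracket(st$pairs)
    expect_identical(unclass(parse_dotbracket(db)), unclass(st$pairs))
  }
})

test_that("pair tables enforce involution and nesting", {
  expect_error(pair_table(c(2L, 3L, 0L)), class = "rnaphylo_invalid")
  expect_error(pair_table(c(1L, 0L)), class = "rnaphylo_invalid")  # self pair
  # crossing pairs rejected unless pseudoknot
  crossing <- c(3L, 4L, 1L, 2L)
  expect_error(pair_table(crossing), class = "rnaphylo_invalid")
  expect_silent(pair_table(crossing, pseudoknot = TRUE))
  expect_silent(parse_dotbracket("([)]", pseudoknot = TRUE))
  expect_error(parse_dotbracket("([)]"), class = "rnaphylo_parse")
})

test_that("helix enumeration partitions pairs and respects the merge limit", {
  expect_length(enumerate_helices(parse_dotbracket("((((...))))"),
                                  merge_limit = 2L), 1L)
  h <- enumerate_helices(parse_dotbracket("((..((...))..((...))..))"),
                         merge_limit = 0L)
  expect_length(h, 3L)
  expect_identical(vapply(h, `[[`, 0L, "parent"), c(0L, 1L, 1L))
  expect_length(enumerate_helices(parse_dotbracket("....")), 0L)

  expect_length(root_level_helices(parse_dotbracket("((...))..((...))")), 2L)
  expect_length(root_level_helices(parse_dotbracket("((((...))))")), 1L)

  # partition: pair counts over helices sum to the total, at any merge limit;
  # helix count is monotone non-increasing in the merge limit
  for (seed in 1:6) {
    st <- random_structured(80, 0.35, seed = 30 + seed)
    prev <- Inf
    for (ml in 0:4) {
      hs <- enumerate_helices(st$pairs, merge_limit = ml)
      expect_identical(sum(vapply(hs, function(h) nrow(h$pairs), 0L)),
                       n_pairs(st$pairs))
      expect_lte(length(hs), prev)
      prev <- length(hs)
    }
  }
})

test_that("a merge limit of zero never merges across any interruption", {
  pt <- parse_dotbracket("((.((...))))")  # bulge of 1 between stacks
  expect_length(enumerate_helices(pt, merge_limit = 0L), 2L)
  expect_length(enumerate_helices(pt, merge_limit = 1L), 1L)
})

test_that("shared pair fraction counts co-aligned pairs", {
  st <- random_structured(50, 0.3, seed = 77)
  idmap <- seq_len(length(st$pairs))
  expect_identical(shared_pair_fraction(st, st, idmap), 1)

  # two pairs; breaking one in b halves the fraction
  a <- structured_seq(seq_record("a", "GGAACC"), parse_dotbracket("((..))"))
  b <- structured_seq(seq_record("b", "GGAACC"), parse_dotbracket("(....)"))
  expect_identical(shared_pair_fraction(a, b, 1:6), 0.5)

  # unpaired a: 1 by convention, error in strict mode
  u <- structured_seq(seq_record("u", "ACGU"), parse_dotbracket("...."))
  expect_identical(shared_pair_fraction(u, u, 1:4), 1)
  expect_error(shared_pair_fraction(u, u, 1:4, strict = TRUE),
               class = "rnaphylo_invalid")

  expect_error(shared_pair_fraction(a, b, c(1:5, 9L)),
               class = "rnaphylo_contract")
})
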