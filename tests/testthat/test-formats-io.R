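test_that("FASTA reading normalizes, preserves order, and rejects bad input", {
  f <- withr::local_tempfile(lines = c(">x first", "ACGT", ">y", "ggnu"))
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_identical(recs[[1]]$id, "x")
  expect_identical(recs[[1]]$description, "first")
  expect_identical(recs[[1]]$residues, "ACGU")   # T -> U, upper case
  expect_identical(recs[[2]]$residues, "GGNU")

  dup <- withr::local_tempfile(lines = c(">x", "AC", ">x", "GG"))
  expect_error(read_fasta(dup), class = "rnaphylo_format")

  gap <- withr::local_tempfile(lines = c(">x", "acgu", ">y", "GG-N"))
  expect_error(read_fasta(gap), class = "rnaphylo_format")
  expect_silent(read_fasta(gap, allow_gap = TRUE))

  iupac <- withr::local_tempfile(lines = c(">x", "ACGR"))
  expect_error(read_fasta(iupac), class = "rnaphylo_format")
})

test_that("FASTA round-trips through write_fasta", {
  recs <- lapply(1:5, function(k)
    seq_record(paste0("s", k),
               paste(sample(c("A", "C", "G", "U"), 40 + k, TRUE), collapse = "")))
  f <- withr::local_tempfile()
  write_fasta(recs, f, width = 17L)
  back <- read_fasta(f)
  expect_identical(lapply(back, `[[`, "residues"),
                   lapply(recs, `[[`, "residues"))
  expect_identical(vapply(back, `[[`, "", "id"), vapply(recs, `[[`, "", "id"))
})

test_that("Vienna files parse, validate lengths, and round-trip", {
  f <- withr::local_tempfile(lines = c(">x", "GGAACC", "((..))"))
  ss <- read_vienna(f)
  expect_length(ss[[1]]$pairs, 6L)
  expect_identical(n_pairs(ss[[1]]$pairs), 2L)

  bad <- withr::local_tempfile(lines = c(">x", "GGAACC", "((..)"))
  expect_error(read_vienna(bad), class = "rnaphylo_format")

  nop <- withr::local_tempfile(lines = c(">x", "GG", ".."))
  expect_identical(n_pairs(read_vienna(nop)[[1]]$pairs), 0L)

  out <- withr::local_tempfile()
  write_vienna(ss, out)
  expect_identical(readLines(out), c(">x", "GGAACC", "((..))"))
})

test_that("CT files parse with involution checking", {
  f <- withr::local_tempfile(lines = c(
    "2 tiny", "1 G 0 2 2 1", "2 C 1 0 1 2"))
  s <- read_ct(f)
  expect_identical(unclass(s$pairs), c(2L, 1L))
  expect_identical(s$record$residues, "GC")

  asym <- withr::local_tempfile(lines = c(
    "2 tiny", "1 G 0 2 2 1", "2 C 1 0 0 2"))
  expect_error(read_ct(asym), class = "rnaphylo_consistency")

  zeros <- withr::local_tempfile(lines = c(
    "3 t", "1 A 0 2 0 1", "2 C 1 3 0 2", "3 G 2 0 0 3"))
  expect_identical(n_pairs(read_ct(zeros)$pairs), 0L)

  # write -> read round trip on a generated structure
  st <- random_structured(60, 0.3, seed = 5)
  out <- withr::local_tempfile()
  write_ct(st, out)
  back <- read_ct(out)
  expect_identical(unclass(back$pairs), unclass(st$pairs))
  expect_identical(back$record$residues, st$record$residues)
})

test_that("Newick round-trips preserve topology, lengths, and supports", {
  txt <- "((A:1,B:2):1,C:3);"
  tr <- read_newick(txt)
  expect_identical(length(tr$tip.label), 3L)
  expect_identical(write_newick(read_newick(write_newick(tr))),
                   write_newick(tr))

  sup <- read_newick("((A,B)95,C);")
  expect_true("95" %in% sup$node.label)

  expect_error(read_newick("((A,B,C);"), class = "rnaphylo_parse")
})

test_that("score matrix files parse with symmetry and dimension checks", {
  m <- default_score_matrix()[1:12, 1:12]
  f <- withr::local_tempfile()
  write_score_matrix(m, f)
  back <- read_score_matrix(f)
  expect_equal(unname(back), unname(m))
  expect_identical(colnames(back), colnames(m))
  expect_identical(back["A", "A"], 4)

  lines <- readLines(f)
  small <- withr::local_tempfile(lines = lines[1:12])  # 11 rows
  expect_error(read_score_matrix(small), class = "rnaphylo_format")

  asym <- m
  asym[1, 2] <- 99
  f2 <- withr::local_tempfile()
  write_score_matrix(asym, f2)
  expect_error(read_score_matrix(f2), class = "rnaphylo_format")
})

test_that("structural-token corruption is rejected by the readers (fuzz)", {
  set.seed(41)
  for (rep in 1:5) {
    st <- random_structured(40, 0.3, seed = 100 + rep)
    f <- withr::local_tempfile()
    write_vienna(list(st), f)
    lines <- readLines(f)
    # delete one bracket from the structure line: lengths now disagree
    db <- lines[3]
    pos <- regexpr("(", db, fixed = TRUE)
    lines[3] <- paste0(substr(db, 1, pos - 1), substr(db, pos + 1, nchar(db)))
    f2 <- withr::local_tempfile(lines = lines)
    expect_error(read_vienna(f2), class = "rnaphylo_error")
  }
})
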