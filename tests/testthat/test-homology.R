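test_that("structure transfer reproduces the worked examples", {
  # self-transfer is always 100%
  tmpl <- random_structured(80, 0.3, seed = 51)
  self <- transfer_structure(tmpl, tmpl$record)
  expect_identical(self$transfer_pct, 100)
  expect_identical(unclass(self$target$pairs), unclass(tmpl$pairs))

  # GGGAAACCC with three nested pairs against GGAAAACCC: the G->A change
  # breaks one pair, the other two survive -> 66.7%
  t1 <- structured_seq(seq_record("t1", "GGGAAACCC"),
                       pair_table(c(9L, 8L, 7L, 0L, 0L, 0L, 3L, 2L, 1L)))
  r1 <- transfer_structure(t1, seq_record("g1", "GGAAAACCC"))
  expect_equal(r1$transfer_pct, 100 * 2 / 3, tolerance = 1e-9)

  # a C.A combination at one of two pairs drops it -> 50%
  t2 <- structured_seq(seq_record("t2", "GGAAGC"),
                       pair_table(c(6L, 5L, 0L, 0L, 2L, 1L)))
  r2 <- transfer_structure(t2, seq_record("g2", "GGAAAC"))
  expect_identical(r2$transfer_pct, 50)
  # ...unless pairability is not required
  r2b <- transfer_structure(t2, seq_record("g2", "GGAAAC"),
                            require_pairable = FALSE)
  expect_identical(r2b$transfer_pct, 100)

  unpaired <- structured_seq(seq_record("u", "ACGU"), parse_dotbracket("...."))
  expect_error(transfer_structure(unpaired, seq_record("g", "ACGU")),
               class = "rnaphylo_invalid")
})

test_that("transferred structures are valid and flank-truncation invariant", {
  for (seed in 1:5) {
    tmpl <- random_structured(120, 0.3, seed = 60 + seed)
    sim <- simulate_dataset(n_taxa = 2, seq_length = 120, rate = 0.2,
                            seed = 70 + seed)
    tgt <- sim$clean[[1]]$record
    res <- transfer_structure(tmpl, tgt)
    expect_s3_class(res$target$pairs, "pair_table")
    expect_silent(structured_seq(res$target$record, res$target$pairs,
                                 strict = TRUE))
    expect_true(res$transfer_pct >= 0 && res$transfer_pct <= 100)
  }

  # simultaneous trimming of unpaired 5' flanks leaves the percentage alone
  tmpl <- structured_seq(seq_record("t", "AAAAGGGCUUCGCCC"),
                         parse_dotbracket("....((((...))))"))
  tgt <- seq_record("g", "AAAAGGGCUUCGCCC")
  full <- transfer_structure(tmpl, tgt)
  trim_t <- structured_seq(seq_record("t", substr(tmpl$record$residues, 5, 15)),
                           parse_dotbracket("((((...))))"))
  trim_g <- seq_record("g", substr(tgt$residues, 5, 15))
  expect_identical(transfer_structure(trim_t, trim_g)$transfer_pct,
                   full$transfer_pct)
})

test_that("best_template maximizes transfer with library-order ties", {
  lib <- list(random_structured(90, 0.3, seed = 81),
              random_structured(90, 0.3, seed = 82))
  hit <- best_template(lib, lib[[2]]$record)
  expect_identical(hit$template_id, lib[[2]]$record$id)
  expect_identical(hit$transfer_pct, 100)

  one <- best_template(lib[1], lib[[1]]$record)
  expect_identical(one$transfer_pct,
                   transfer_structure(lib[[1]], lib[[1]]$record)$transfer_pct)

  # exact tie: identical templates under different ids -> first wins
  dup <- lib[[1]]
  dup$record$id <- "dup"
  tie <- best_template(list(lib[[1]], dup), lib[[1]]$record)
  expect_identical(tie$template_id, lib[[1]]$record$id)

  expect_error(best_template(list(), seq_record("g", "ACGU")),
               class = "rnaphylo_invalid")
})

test_that("dataset filtering applies length first, then strict transfer cutoff", {
  mk_res <- function(id, pct) structure(list(transfer_pct = pct,
                                             template_id = "t"),
                                        class = "transfer_result")
  recs <- lapply(1:10, function(k)
    seq_record(paste0("r", k), strrep("A", if (k <= 3) 40L else 200L)))
  results <- setNames(lapply(4:10, function(k)
    mk_res(paste0("r", k), c(60, 64, 65, 80, 90, 95, 99)[k - 3])),
    paste0("r", 4:10))
  flt <- filter_dataset(recs, results, filter_config(min_length = 100,
                                                     min_transfer_pct = 65))
  expect_identical(flt$kept, paste0("r", 6:10))
  expect_identical(flt$discarded$reason,
                   c(rep("too short", 3), rep("low transfer", 2)))
  expect_identical(flt$table$id, paste0("r", 1:10))  # order preserved

  # exactly at the threshold is kept; zero thresholds keep everything
  expect_true("r6" %in% flt$kept)  # r6 sits exactly at 65
  full_results <- c(setNames(lapply(1:3, function(k)
    mk_res(paste0("r", k), 50)), paste0("r", 1:3)), results)
  all_kept <- filter_dataset(recs, full_results, filter_config(0, 0))
  expect_length(all_kept$discarded$id, 0L)

  # a record passing the length check with no transfer result is an error
  expect_error(filter_dataset(recs, results[-1],
                              filter_config(min_length = 100,
                                            min_transfer_pct = 65)),
               class = "rnaphylo_invalid")
})
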