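test_that("p distance uses pairwise deletion", {
  expect_identical(p_distance("AAAA", "AAAA"), 0)
  expect_identical(p_distance("AAAA", "AAAF"), 0.25)
  expect_identical(p_distance("A-AA", "AG-A"), 0)
  expect_error(p_distance("--", "AA"), class = "rnaphylo_undefined")
})

test_that("jc12 matches its closed form and saturates at 11/12", {
  expect_identical(jc12(0), 0)
  expect_equal(jc12(0.1), -(11 / 12) * log(1 - (12 / 11) * 0.1))
  expect_equal(jc12(0.1), 0.1058868, tolerance = 1e-6)
  expect_warning(d <- jc12(11 / 12), "saturated")
  expect_identical(d, Inf)
  expect_identical(jc12(0.95, cap = TRUE), 40)

  # strictly increasing, and always >= p
  p <- seq(0, 0.9, by = 0.01)
  d <- jc12(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("transition matrices are stochastic and stationary under pi", {
  set.seed(21)
  for (rep in 1:5) {
    pi <- runif(12); pi <- pi / sum(pi)
    m <- subst_model_12(pi = pi)
    for (t in c(0.01, 0.5, 3)) {
      P <- transition_matrix(m, t)
      expect_equal(unname(rowSums(P)), rep(1, 12), tolerance = 1e-10)
      expect_equal(as.numeric(m$pi %*% P), unname(m$pi), tolerance = 1e-9)
    }
  }
  # normalization: one expected substitution per unit time
  m <- subst_model_12()
  expect_equal(-sum(m$pi * diag(m$Q)), 1)
})

test_that("rate-matrix files load as valid models", {
  R <- matrix(1, 12, 12)
  diag(R) <- 0
  dimnames(R) <- list(encoding_table()$letters, encoding_table()$letters)
  f <- withr::local_tempfile()
  write_score_matrix(R, f)
  m <- read_rate_matrix(f, gamma_alpha = 0.5, p_inv = 0.1)
  expect_s3_class(m, "subst_model_12")
  expect_equal(-sum(m$pi * diag(m$Q)), 1)
  expect_identical(m$p_inv, 0.1)
})

test_that("ml distance equals jc12 under the equal-rates model", {
  set.seed(22)
  lets <- encoding_table()$letters
  m <- subst_model_12()
  for (rep in 1:4) {
    a <- sample(lets, 800, TRUE)
    b <- a
    flip <- sample(800, 120)
    b[flip] <- sample(lets, 120, TRUE)
    sa <- paste(a, collapse = "")
    sb <- paste(b, collapse = "")
    p <- p_distance(sa, sb)
    expect_equal(ml_distance(sa, sb, m), jc12(p), tolerance = 1e-4)
  }
  expect_identical(ml_distance("AAAA", "AAAA", m), 0)
})

test_that("ml distance saturates gracefully at p >= 11/12", {
  lets <- encoding_table()$letters
  a <- paste(rep(lets[1], 120), collapse = "")
  b <- paste(rep(lets[2:11], 12), collapse = "")  # every site differs: p = 1
  expect_warning(d <- ml_distance(a, b, subst_model_12()), "t_max|saturat")
  expect_identical(d, 40)
})

test_that("ml distance recovers the generating branch length (seeded)", {
  # pair of sequences at known distance under the 12-state equal-rates
  # process; the estimate must fall within 3 binomial standard errors
  set.seed(24)
  lets <- encoding_table()$letters
  m <- subst_model_12()
  for (t_true in c(0.1, 0.4)) {
    L <- 2000L
    a <- sample(12L, L, TRUE)
    P <- transition_matrix(m, t_true)
    b <- vapply(a, function(x) sample.int(12L, 1L, prob = P[x, ]), 0L)
    sa <- paste(lets[a], collapse = "")
    sb <- paste(lets[b], collapse = "")
    t_hat <- ml_distance(sa, sb, m)
    p_exp <- (11 / 12) * (1 - exp(-(12 / 11) * t_true))
    se_p <- sqrt(p_exp * (1 - p_exp) / L)
    se_d <- se_p / (1 - (12 / 11) * p_exp)
    expect_lt(abs(t_hat - t_true), 3 * se_d)
  }
})

test_that("alignment distance matrices are consistent across methods", {
  set.seed(25)
  lets <- encoding_table()$letters
  rows <- setNames(vapply(1:4, function(k)
    paste(sample(lets, 300, TRUE), collapse = ""), ""), paste0("s", 1:4))
  rows[2] <- rows[1]
  aln <- as_alignment(rows)
  Dp <- matrix_from_alignment(aln, "p")
  Dj <- matrix_from_alignment(aln, "jc12")
  expect_identical(Dp["s1", "s2"], 0)
  expect_equal(unname(Dp["s1", "s3"]), p_distance(rows[[1]], rows[[3]]))
  expect_true(all(unclass(Dj) >= unclass(Dp)))   # correction only stretches
  expect_equal(unclass(Dj), t(unclass(Dj)))
})

test_that("discrete gamma categories agree with the reference implementation", {
  for (alpha in c(0.3, 1, 4)) {
    mine <- rnaphylo:::discrete_gamma_rates(alpha, 4L)
    ref <- phangorn::discrete.gamma(alpha, 4L)
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})
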