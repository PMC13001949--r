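# Independent oracles and fixture builders shared across the test files.
# Oracles are deliberately naive (enumeration / brute force) and share no
# code with the package implementations they check.

# ---- brute-force global alignment (affine gaps, cost open + k*ext) --------

# enumerate all global alignments of a and b as move strings (M/U/L),
# score each by scanning runs; returns the maximum score
brute_align_score <- function(a, b, scores, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  # recursion over (position in a, position in b, current gap state)
  rec2 <- function(i, j, state, sc) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec2(i + 1, j + 1, "M", sc + scores[ca[i], cb[j]])
    if (i <= length(ca))
      rec2(i + 1, j, "U",
           sc - gap_extend - if (state == "U") 0 else gap_open)
    if (j <= length(cb))
      rec2(i, j + 1, "L",
           sc - gap_extend - if (state == "L") 0 else gap_open)
  }
  rec2(1, 1, "M", 0)
  best
}

# ---- least-squares additive fit over 4-taxon topologies --------------------

# OLS branch lengths for each of the 3 resolved quartet topologies; returns
# the split (as sorted pair of labels grouped together) with lowest RSS
ls_best_quartet <- function(D) {
  labs <- rownames(D)
  stopifnot(length(labs) == 4)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  rss <- sapply(splits, function(grp) {
    # design: pendant edges e1..e4 + internal e5
    pairs <- t(combn(4, 2))
    X <- matrix(0, 6, 5)
    y <- numeric(6)
    other <- setdiff(1:4, grp)
    for (r in 1:6) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      X[r, i] <- 1; X[r, j] <- 1
      same <- (all(c(i, j) %in% grp)) || (all(c(i, j) %in% other))
      if (!same) X[r, 5] <- 1
      y[r] <- D[i, j]
    }
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  })
  grp <- splits[[which.min(rss)]]
  sort(labs[grp])
}

# ---- brute-force Fitch over all internal labelings -------------------------

# minimum changes for one column on an unrooted 4-taxon tree ((a,b),(c,d))
# topology given as a list of two pairs of tip states; enumerate the two
# internal node states over `nstates`
brute_fitch_column <- function(tree, states, nstates = 12) {
  # tree: ape phylo (4 tips); states: named integer vector (NA = missing)
  # enumerate assignments to all internal nodes
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(nstates)), nint)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign_ <- grid[g, ]
    changes <- 0
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; kid <- tree$edge[e, 2]
      sp <- assign_[par - ntip]
      sk <- if (kid <= ntip) states[tree$tip.label[kid]] else assign_[kid - ntip]
      if (!is.na(sk) && sp != sk) changes <- changes + 1
    }
    best <- min(best, changes)
  }
  best
}

# ---- brute-force likelihood: sum over internal states ----------------------

brute_loglik <- function(tree, aln, model) {
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  idx <- matrix(match(m, model$letters), nrow = nrow(m),
                dimnames = dimnames(m))
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  mix_r <- if (!is.null(model$gamma_alpha)) {
    k <- model$n_rate_categories
    br <- qgamma(seq(0, 1, length.out = k + 1), model$gamma_alpha, model$gamma_alpha)
    r <- k * diff(pgamma(br, model$gamma_alpha + 1, model$gamma_alpha))
    r / mean(r)
  } else 1
  mix_w <- rep(1 / length(mix_r), length(mix_r))
  if (model$p_inv > 0) {
    mix_r <- c(0, mix_r)
    mix_w <- c(model$p_inv, (1 - model$p_inv) * mix_w)
  }
  total <- 0
  for (site in seq_len(ncol(idx))) {
    site_lik <- 0
    for (rc in seq_along(mix_r)) {
      P <- lapply(seq_len(nrow(tree$edge)), function(e)
        if (mix_r[rc] == 0) diag(12) else
          transition_matrix(model, tree$edge.length[e], mix_r[rc]))
      grid <- as.matrix(expand.grid(rep(list(1:12), nint)))
      lk <- 0
      for (g in seq_len(nrow(grid))) {
        assign_ <- grid[g, ]
        pr <- unname(model$pi[assign_[1]])  # root = first internal node
        for (e in seq_len(nrow(tree$edge))) {
          par <- tree$edge[e, 1]; kid <- tree$edge[e, 2]
          sp <- assign_[par - ntip]
          sk <- if (kid <= ntip) idx[tree$tip.label[kid], site] else
            assign_[kid - ntip]
          if (is.na(sk)) next  # missing tip: sums to 1
          pr <- pr * P[[e]][sp, sk]
        }
        lk <- lk + pr
      }
      site_lik <- site_lik + mix_w[rc] * lk
    }
    total <- total + log(site_lik)
  }
  total
}

# ---- fixture builders ------------------------------------------------------

# random nested structured sequence via the package generator (seeded)
random_structured <- function(len, pf, seed) {
  simulate_root_structure(len, pf, seed = seed, id = paste0("r", seed))
}

# canonical synthetic ITS2 exemplar (see ?example_its2_structure)
synthetic_its2 <- function(fifth = FALSE) {
  example_its2_structure(if (fifth) "long" else "canonical")
}

expect_no_gap_mismatch <- function(aln) {
  for (id in names(aln))
    testthat::expect_identical(nchar(aln[[id]]), nchar(aln[[1]]))
}
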