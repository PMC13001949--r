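## 12-state maximum likelihood: Felsenstein pruning with per-node scaling,
## Gamma(4)+I rate mixture, branch-length optimization and NNI search.

## site patterns: list(states = ntaxa x npat integer matrix (NA = missing),
## weights)
site_patterns <- function(aln, letters) {
  m <- alignment_matrix(aln)
  idx <- matrix(match(m, letters), nrow = nrow(m), dimnames = dimnames(m))
  key <- apply(idx, 2L, paste, collapse = ",")
  tab <- table(factor(key, levels = unique(key)))
  first <- match(names(tab), key)
  list(states = idx[, first, drop = FALSE], weights = as.numeric(tab))
}

## pruning partials for one rate category; returns list(root_partials (npat x
## 12), log_scale (npat))
prune_category <- function(tr, states, model, rate, ntip) {
  npat <- ncol(states)
  k <- 12L
  nnode <- max(tr$edge)
  partial <- vector("list", nnode)
  logscale <- matrix(0, nnode, npat)
  Pmats <- vector("list", nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge)))
    Pmats[[e]] <- if (rate == 0) diag(k) else
      transition_matrix(model, tr$edge.length[e], rate)
  for (tp in seq_len(ntip)) {
    lab <- tr$tip.label[tp]
    st <- states[lab, ]
    pm <- matrix(0, npat, k)
    pm[cbind(seq_len(npat), st)[!is.na(st), , drop = FALSE]] <- 1
    pm[is.na(st), ] <- 1  # gap / wildcard: missing data
    partial[[tp]] <- pm
  }
  for (nd in unique(tr$edge[, 1L])) {
    eidx <- which(tr$edge[, 1L] == nd)
    acc <- matrix(1, npat, k)
    sc <- rep(0, npat)
    for (e in eidx) {
      kid <- tr$edge[e, 2L]
      acc <- acc * (partial[[kid]] %*% t(Pmats[[e]]))
      sc <- sc + logscale[kid, ]
    }
    mx <- pmax(apply(acc, 1L, max), .Machine$double.xmin)
    partial[[nd]] <- acc / mx
    logscale[nd, ] <- sc + log(mx)
  }
  root <- ape::Ntip(tr) + 1L
  list(root_partials = partial[[root]], log_scale = logscale[root, ])
}

#' Log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning over the 12-state model with the model's
#' Gamma-plus-invariant rate mixture; gaps and wildcards are missing data
#' (all-ones partials). Numerical underflow is guarded by per-node scaling,
#' so long trees and many taxa stay finite.
#'
#' @param tree `ape::phylo` with branch lengths (>= 0); rooted or unrooted.
#' @param aln alignment (named character vector of gapped rows).
#' @param model a [subst_model_12()].
#' @return Log-likelihood (a single number).
#' @export
ml_loglik <- function(tree, aln, model = subst_model_12()) {
  if (!setequal(tree$tip.label, names(aln)))
    abort_fmt("rnaphylo_invalid", "tree tip labels do not match alignment rows")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    abort_fmt("rnaphylo_invalid", "tree must have nonnegative branch lengths")
  pat <- site_patterns(aln, model$letters)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  mix <- model_rate_mixture(model)
  npat <- ncol(pat$states)
  site_lik <- rep(0, npat)
  ## accumulate in likelihood space per category with shared scaling trick:
  ## categories have different scale factors, so combine via logs
  cat_loglik <- matrix(NA_real_, length(mix$rates), npat)
  for (kk in seq_along(mix$rates)) {
    pr <- prune_category(tr, pat$states, model, mix$rates[kk], ntip)
    lik <- as.numeric(pr$root_partials %*% model$pi)
    cat_loglik[kk, ] <- log(pmax(lik, .Machine$double.xmin)) + pr$log_scale
  }
  mx <- apply(cat_loglik, 2L, max)
  site_log <- mx + log(colSums(mix$weights * exp(sweep(cat_loglik, 2L, mx))))
  ll <- sum(pat$weights * site_log)
  if (!is.finite(ll))
    abort_fmt("rnaphylo_numeric", "non-finite log-likelihood")
  ll
}

## optimize every branch length in turn, <= `sweeps` passes
optimize_branch_lengths <- function(tree, aln, model, sweeps = 20L,
                                    tol = 1e-6, t_upper = 10) {
  cur <- ml_loglik(tree, aln, model)
  for (s in seq_len(sweeps)) {
    prev <- cur
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tree$edge.length[e] <- x
        -ml_loglik(tree, aln, model)
      }
      opt <- optimize(f, c(0, t_upper), tol = tol)
      if (-opt$objective > cur) {
        tree$edge.length[e] <- opt$minimum
        cur <- -opt$objective
      }
    }
    if (cur - prev < tol) break
  }
  list(tree = tree, loglik = cur)
}

#' Maximum-likelihood tree search
#'
#' Starts from the neighbor-joining tree on corrected distances, then
#' alternates per-branch one-dimensional branch-length optimization
#' (tolerance `1e-6`, at most 20 sweeps) with rounds of NNI rearrangement.
#' Equal-likelihood moves keep the incumbent so the search terminates.
#' The stationary distribution is taken from empirical alignment letter
#' frequencies; the Gamma shape and invariant proportion can be optimized by
#' bounded one-dimensional search.
#'
#' @param aln alignment (named character vector of gapped rows).
#' @param model a [subst_model_12()]; its `pi` is replaced by empirical
#'   frequencies unless `empirical_pi = FALSE`.
#' @param optimize_alpha,optimize_pinv optimize the Gamma shape / invariant
#'   fraction (bounded 1-D search) after the first branch-length pass.
#' @param empirical_pi use empirical letter frequencies as `pi`.
#' @param max_nni_rounds cap on NNI improvement rounds.
#' @return List with `tree` (branch-length-optimized `phylo`), `loglik`, and
#'   the final `model`.
#' @export
ml_search <- function(aln, model = subst_model_12(), optimize_alpha = FALSE,
                      optimize_pinv = FALSE, empirical_pi = TRUE,
                      max_nni_rounds = 10L) {
  if (empirical_pi) {
    m <- alignment_matrix(aln)
    cnt <- table(factor(m[m %in% model$letters], levels = model$letters))
    pi <- (as.numeric(cnt) + 1e-6)
    pi <- pi / sum(pi)
    model <- subst_model_12(pi = pi, gamma_alpha = model$gamma_alpha,
                            p_inv = model$p_inv,
                            n_rate_categories = model$n_rate_categories,
                            letters = model$letters)
  }
  start <- ape::unroot(neighbor_joining(matrix_from_alignment(aln, "jc12")))
  start$edge.length[start$edge.length <= 0] <- 1e-6
  fit <- optimize_branch_lengths(start, aln, model)
  if (optimize_alpha) {
    f <- function(a) {
      m2 <- subst_model_12(pi = model$pi, gamma_alpha = a, p_inv = model$p_inv,
                           n_rate_categories = model$n_rate_categories,
                           letters = model$letters)
      -ml_loglik(fit$tree, aln, m2)
    }
    opt <- optimize(f, c(0.05, 50), tol = 1e-3)
    model <- subst_model_12(pi = model$pi, gamma_alpha = opt$minimum,
                            p_inv = model$p_inv,
                            n_rate_categories = model$n_rate_categories,
                            letters = model$letters)
    fit$loglik <- ml_loglik(fit$tree, aln, model)
  }
  if (optimize_pinv) {
    f <- function(p) {
      m2 <- subst_model_12(pi = model$pi, gamma_alpha = model$gamma_alpha,
                           p_inv = p, n_rate_categories = model$n_rate_categories,
                           letters = model$letters)
      -ml_loglik(fit$tree, aln, m2)
    }
    opt <- optimize(f, c(0, 0.99), tol = 1e-3)
    model <- subst_model_12(pi = model$pi, gamma_alpha = model$gamma_alpha,
                            p_inv = opt$minimum,
                            n_rate_categories = model$n_rate_categories,
                            letters = model$letters)
    fit$loglik <- ml_loglik(fit$tree, aln, model)
  }
  for (round in seq_len(max_nni_rounds)) {
    improved <- FALSE
    nbrs <- phangorn::nni(fit$tree)
    for (kk in seq_along(nbrs)) {
      nb <- nbrs[[kk]]
      if (is.null(nb$edge.length)) nb$edge.length <- rep(0.1, nrow(nb$edge))
      nb$edge.length[nb$edge.length <= 0] <- 1e-6
      cand <- optimize_branch_lengths(nb, aln, model, sweeps = 2L)
      if (cand$loglik > fit$loglik + 1e-9) {
        fit <- optimize_branch_lengths(cand$tree, aln, model)
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(tree = fit$tree, loglik = fit$loglik, model = model)
}
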