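## Evolutionary distances over the 12-letter alphabet: proportion of
## differing sites (pairwise deletion), the 12-state generalization of the
## Jukes-Cantor correction, and maximum-likelihood distances under a
## loadable 12x12 reversible rate matrix with optional Gamma rate
## heterogeneity and invariant sites.

T_MAX <- 20
SATURATION_CAP <- 2 * T_MAX

#' Proportion of differing sites between two aligned rows
#'
#' Columns where either row carries a gap are skipped (pairwise deletion).
#'
#' @param a,b equal-length gapped strings.
#' @return `p` in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b))
    abort_fmt("rnaphylo_invalid", "rows have unequal lengths (%d vs %d)",
              nchar(a), nchar(b))
  ca <- chars(a); cb <- chars(b)
  use <- ca != "-" & cb != "-"
  if (!any(use))
    abort_fmt("rnaphylo_undefined", "no usable (gap-free) columns between rows")
  sum(ca[use] != cb[use]) / sum(use)
}

#' 12-state Jukes-Cantor distance correction
#'
#' For a uniform-rate process over `k = 12` states,
#' `d = -(11/12) * log(1 - (12/11) * p)`. Saturated inputs
#' (`p >= 11/12`) return `Inf`, or a large finite cap (`2 * t_max = 40`)
#' with `cap = TRUE` so downstream tree building stays finite.
#'
#' @param p proportion of differing sites.
#' @param cap return the finite saturation cap instead of `Inf`.
#' @return Corrected distance `d >= p`.
#' @export
jc12 <- function(p, cap = FALSE) {
  stopifnot(all(p >= 0), all(p <= 1))
  sat <- p >= 11 / 12
  d <- ifelse(sat, Inf, -(11 / 12) * log(1 - (12 / 11) * p))
  if (any(sat & !cap))
    warning("saturated distance (p >= 11/12); returning Inf")
  if (cap) d[sat] <- SATURATION_CAP
  d
}

## ---- substitution models ---------------------------------------------------

#' Construct a 12-state substitution model
#'
#' A reversible continuous-time Markov model over the 12 encoded letters.
#' The rate matrix is normalized so the expected number of substitutions per
#' unit time at stationarity is 1 (`-sum(pi * diag(Q)) = 1`), making branch
#' lengths substitutions per site.
#'
#' @param Q 12x12 rate matrix (rows sum to 0, nonnegative off-diagonal), or
#'   `NULL` for the equal-rates (JC-12) default.
#' @param pi stationary distribution (length 12, sums to 1); default uniform;
#'   ignored (recomputed) when `Q` is supplied.
#' @param gamma_alpha Gamma shape for among-site rate variation, or `NULL`.
#' @param p_inv invariant-site proportion in `[0, 1)`.
#' @param n_rate_categories discrete Gamma categories (default 4,
#'   equal-probability categories represented by their means).
#' @param letters the 12 encoded letters (default from [encoding_table()]).
#' @return A list of class `subst_model_12`.
#' @export
subst_model_12 <- function(Q = NULL, pi = NULL, gamma_alpha = NULL,
                           p_inv = 0, n_rate_categories = 4L,
                           letters = encoding_table()$letters) {
  k <- 12L
  if (is.null(Q)) {
    pi <- pi %||% rep(1 / k, k)
    Q <- matrix(1, k, k)
    diag(Q) <- 0
    Q <- Q %*% diag(pi) # equal exchangeabilities, general pi
    diag(Q) <- -rowSums(Q)
  } else {
    Q <- as.matrix(Q)
    if (!all(dim(Q) == k))
      abort_fmt("rnaphylo_invalid", "Q must be 12x12")
    if (any(Q[row(Q) != col(Q)] < 0))
      abort_fmt("rnaphylo_invalid", "Q off-diagonal entries must be >= 0")
    if (max(abs(rowSums(Q))) > 1e-8)
      abort_fmt("rnaphylo_invalid", "Q rows must sum to 0")
    pi <- stationary_dist(Q)
  }
  if (abs(sum(pi) - 1) > 1e-8 || any(pi < 0))
    abort_fmt("rnaphylo_invalid", "pi must be a probability distribution")
  ## normalize expected rate to 1
  mu <- -sum(pi * diag(Q))
  if (mu <= 0)
    abort_fmt("rnaphylo_invalid", "degenerate rate matrix (zero total rate)")
  Q <- Q / mu
  if (!is.null(gamma_alpha)) stopifnot(gamma_alpha > 0)
  stopifnot(p_inv >= 0, p_inv < 1, n_rate_categories >= 1L)
  dimnames(Q) <- list(letters, letters)
  eig <- reversible_eigen(Q, pi)
  structure(list(Q = Q, pi = setNames(pi, letters),
                 gamma_alpha = gamma_alpha, p_inv = p_inv,
                 n_rate_categories = as.integer(n_rate_categories),
                 letters = letters, eigen = eig),
            class = "subst_model_12")
}

#' @export
print.subst_model_12 <- function(x, ...) {
  cat(sprintf("<subst_model_12> %s%s%s\n",
              if (all(abs(x$Q[row(x$Q) != col(x$Q)] -
                            x$Q[1, 2]) < 1e-12)) "equal rates (JC-12)" else "general Q",
              if (!is.null(x$gamma_alpha))
                sprintf(", +G(alpha=%.3g, %d cat)", x$gamma_alpha,
                        x$n_rate_categories) else "",
              if (x$p_inv > 0) sprintf(", +I(%.3g)", x$p_inv) else ""))
  invisible(x)
}

stationary_dist <- function(Q) {
  ## left null vector of Q
  ns <- eigen(t(Q))
  v <- Re(ns$vectors[, which.min(abs(ns$values))])
  v <- v / sum(v)
  if (any(v < -1e-8))
    abort_fmt("rnaphylo_invalid", "Q has no nonnegative stationary distribution")
  pmax(v, 0) / sum(pmax(v, 0))
}

## symmetric eigendecomposition of a reversible Q: B = D^{1/2} Q D^{-1/2}
reversible_eigen <- function(Q, pi) {
  s <- sqrt(pi)
  B <- diag(s) %*% Q %*% diag(1 / s)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       right = diag(1 / s) %*% e$vectors,   # columns: right eigenvectors of Q
       left = t(e$vectors) %*% diag(s))     # rows: left eigenvectors
}

#' Transition probability matrix `P(t) = expm(Q t)`
#'
#' @param model a [subst_model_12()].
#' @param t branch length (>= 0).
#' @param rate rate multiplier (Gamma category rate).
#' @return 12x12 stochastic matrix.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  e <- model$eigen
  P <- e$right %*% (exp(e$values * t * rate) * e$left)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(model$Q)
  P
}

## discrete Gamma rates: K equal-probability categories, category means
## (mean-one parameterization: shape = rate = alpha)
discrete_gamma_rates <- function(alpha, k) {
  if (k == 1L) return(1)
  breaks <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  ## category mean via the incomplete-gamma identity
  cdf1 <- pgamma(breaks, shape = alpha + 1, rate = alpha)
  r <- k * diff(cdf1)
  r / (sum(r) / k) # guard tiny numeric drift; mean exactly 1
}

## per-category rates and weights including the invariant class
model_rate_mixture <- function(model) {
  if (!is.null(model$gamma_alpha)) {
    r <- discrete_gamma_rates(model$gamma_alpha, model$n_rate_categories)
    w <- rep(1 / model$n_rate_categories, model$n_rate_categories)
  } else {
    r <- 1
    w <- 1
  }
  if (model$p_inv > 0) {
    r <- c(0, r)
    w <- c(model$p_inv, (1 - model$p_inv) * w)
  }
  list(rates = r, weights = w)
}

#' Read a 12x12 rate matrix file as a substitution model
#'
#' Same file dialect as [read_score_matrix()] but interpreted as symmetric
#' exchangeabilities `R`; the model rate matrix is `Q[i,j] = R[i,j] * pi[j]`
#' with `pi` either supplied on a final line `pi v1 ... v12` or uniform.
#'
#' @param path file path.
#' @inheritParams subst_model_12
#' @return A [subst_model_12()].
#' @export
read_rate_matrix <- function(path, gamma_alpha = NULL, p_inv = 0) {
  lines <- trimws(readLines(path, warn = FALSE))
  pi_line <- grep("^pi\\b", lines, value = TRUE)
  pi <- NULL
  if (length(pi_line)) {
    pi <- as.numeric(strsplit(pi_line[1], "[ \t]+")[[1]][-1L])
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(lines[!grepl("^pi\\b", lines)], tmp)
    path <- tmp
  }
  R <- read_score_matrix(path)
  if (any(R[row(R) != col(R)] < 0))
    abort_fmt("rnaphylo_format", "exchangeabilities must be nonnegative")
  pi <- pi %||% rep(1 / 12, 12)
  Q <- R %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  subst_model_12(Q = Q, gamma_alpha = gamma_alpha, p_inv = p_inv,
                 letters = colnames(R))
}

## ---- ML distance -----------------------------------------------------------

#' Maximum-likelihood distance between two aligned rows
#'
#' Maximizes `sum(log(pi[x] * P(t)[x, y]))` over the gap-free columns, with
#' the model's Gamma/invariant rate mixture, by bounded one-dimensional
#' optimization of `t` on `[0, 20]` (tolerance `1e-8`). Distances at the
#' upper bound are reported as saturated via the finite cap.
#'
#' @param a,b equal-length gapped strings over the model's letters.
#' @param model a [subst_model_12()].
#' @return Distance `t >= 0`.
#' @export
ml_distance <- function(a, b, model = subst_model_12()) {
  ca <- chars(a); cb <- chars(b)
  use <- ca != "-" & cb != "-"
  if (!any(use))
    abort_fmt("rnaphylo_undefined", "no usable (gap-free) columns between rows")
  ia <- match(ca[use], model$letters)
  ib <- match(cb[use], model$letters)
  if (anyNA(ia) || anyNA(ib))
    abort_fmt("rnaphylo_scoring", "letter not covered by the model alphabet")
  ## site pattern counts
  pat <- paste(ia, ib)
  cnt <- table(pat)
  upat <- strsplit(names(cnt), " ", fixed = TRUE)
  ui <- as.integer(vapply(upat, `[`, "", 1L))
  uj <- as.integer(vapply(upat, `[`, "", 2L))
  w <- as.numeric(cnt)
  mix <- model_rate_mixture(model)
  nll <- function(t) {
    lik <- numeric(length(ui))
    for (k in seq_along(mix$rates)) {
      P <- if (mix$rates[k] == 0) diag(12L) else transition_matrix(model, t, mix$rates[k])
      lik <- lik + mix$weights[k] * model$pi[ui] * P[cbind(ui, uj)]
    }
    if (any(lik <= 0) || any(!is.finite(lik))) return(1e18)
    -sum(w * log(lik))
  }
  if (all(ia == ib)) return(0)
  opt <- optimize(nll, c(0, T_MAX), tol = 1e-8)
  if (!is.finite(opt$objective))
    abort_fmt("rnaphylo_numeric", "non-finite likelihood in ml_distance")
  t_hat <- opt$minimum
  ## boundary checks: the optimizer never samples the exact endpoints
  if (nll(0) <= opt$objective) return(0)
  if (t_hat > T_MAX - 1e-4 || nll(T_MAX) <= opt$objective) {
    warning("ml_distance hit t_max; reporting saturation cap")
    return(SATURATION_CAP)
  }
  t_hat
}

## ---- distance matrices -----------------------------------------------------

#' Construct a distance matrix object
#'
#' @param d symmetric numeric matrix with zero diagonal and labels as
#'   dimnames.
#' @return `d` with class `dist_matrix`.
#' @export
dist_matrix <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d)))
    abort_fmt("rnaphylo_invalid", "distance matrix needs labels")
  dd <- d - t(d)
  dd[is.infinite(d) & is.infinite(t(d))] <- 0  # Inf sentinels compare equal
  if (any(is.nan(dd)) || max(abs(dd)) > 1e-9 || any(diag(d) != 0))
    abort_fmt("rnaphylo_invalid",
              "distance matrix must be symmetric with zero diagonal")
  if (any(d < 0))
    abort_fmt("rnaphylo_invalid", "distances must be nonnegative")
  structure(d, class = c("dist_matrix", "matrix"))
}

#' Pairwise distance matrix from an alignment
#'
#' @param aln alignment (named character vector of gapped rows; see
#'   [as_alignment()]).
#' @param method `"p"`, `"jc12"` or `"ml"`.
#' @param model [subst_model_12()] for `method = "ml"`.
#' @return A [dist_matrix()].
#' @export
matrix_from_alignment <- function(aln, method = c("jc12", "p", "ml"),
                                  model = subst_model_12()) {
  method <- match.arg(method)
  ids <- names(aln)
  n <- length(aln)
  if (n < 2L) abort_fmt("rnaphylo_invalid", "need at least 2 rows")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- tryCatch({
      switch(method,
             p = p_distance(aln[[i]], aln[[j]]),
             jc12 = jc12(p_distance(aln[[i]], aln[[j]]), cap = TRUE),
             ml = ml_distance(aln[[i]], aln[[j]], model))
    }, rnaphylo_undefined = function(cond)
      abort_fmt("rnaphylo_undefined", "undefined distance for pair (%s, %s): %s",
                ids[i], ids[j], conditionMessage(cond)))
    d[i, j] <- d[j, i] <- v
  }
  dist_matrix(d)
}
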