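## Saitou-Nei neighbor joining with deterministic tie-breaking.  Trees are
## assembled as Newick fragments and returned as ape "phylo" objects.

fmt_bl <- function(x) sprintf("%.10g", max(x, 0))

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with the rate-corrected selection
#' criterion `Q[i,j] = (n-2) d[i,j] - R[i] - R[j]`. Negative estimated branch
#' lengths are clamped to zero. Ties in the selection criterion are broken by
#' the lexicographically smallest label pair, where a cluster is labelled by
#' its smallest member label, so the output is deterministic. The result is
#' unrooted (basal trifurcation) for `n >= 3`; `n = 2` yields a single edge
#' split evenly.
#'
#' @param D a [dist_matrix()] (or plain symmetric labelled matrix).
#' @return An `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (!inherits(D, "dist_matrix")) D <- dist_matrix(D)
  if (any(!is.finite(D)))
    abort_fmt("rnaphylo_numeric", "non-finite distances in neighbor_joining")
  labs <- rownames(D)
  n <- length(labs)
  if (n < 2L) abort_fmt("rnaphylo_invalid", "need at least 2 taxa")
  frag <- setNames(labs, labs)       # newick fragment per active unit
  key <- setNames(labs, labs)        # tie-break label (smallest member)
  d <- unclass(D)
  while (nrow(d) > 3L) {
    m <- nrow(d)
    R <- rowSums(d)
    Qc <- (m - 2) * d - outer(R, R, `+`)
    diag(Qc) <- Inf
    qmin <- min(Qc)
    cand <- which(Qc - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pairkey <- apply(cand, 1L, function(ij) {
      ks <- sort(c(key[ij[1]], key[ij[2]]))
      paste(ks, collapse = "\r")
    })
    sel <- cand[order(pairkey)[1L], ]
    i <- sel[1L]; j <- sel[2L]
    vi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_bl(vi), frag[j], fmt_bl(vj))
    newkey <- min(key[i], key[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    dk <- pmax(dk, 0)
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nm <- c(rownames(d)[keep], newkey)
    dimnames(d2) <- list(nm, nm)
    frag <- c(frag[keep], setNames(newfrag, newkey))
    key <- c(key[keep], setNames(newkey, newkey))
    d <- d2
  }
  nwk <- if (nrow(d) == 2L) {
    h <- d[1, 2] / 2
    sprintf("(%s:%s,%s:%s);", frag[1], fmt_bl(h), frag[2], fmt_bl(h))
  } else {
    ## closed three-point formulas for the final star
    v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt_bl(v1), frag[2], fmt_bl(v2),
            frag[3], fmt_bl(v3))
  }
  read_newick(nwk)
}
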