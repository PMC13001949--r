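## Fitch parsimony over the 12-letter alphabet, with exhaustive search for
## small taxon sets and NNI hill climbing otherwise.

## bitmask per letter; gap / wildcard / unknown = all states (missing data)
fitch_masks <- function(aln, letters = encoding_table()$letters) {
  m <- alignment_matrix(aln)
  full <- bitwShiftL(1L, length(letters)) - 1L
  idx <- match(m, letters)
  mask <- ifelse(is.na(idx), full, bitwShiftL(1L, idx - 1L))
  matrix(mask, nrow = nrow(m), dimnames = dimnames(m))
}

#' Fitch parsimony score
#'
#' Minimum number of state changes over the tree, summed over columns, with
#' the 12 encoded letters as states. Gaps and wildcards are treated as
#' missing data (any state).
#'
#' @param tree `ape::phylo`; tip labels must match alignment row names.
#' @param aln alignment (named character vector of gapped rows).
#' @param letters state alphabet.
#' @return Integer parsimony score.
#' @export
fitch_score <- function(tree, aln, letters = encoding_table()$letters) {
  if (!setequal(tree$tip.label, names(aln)))
    abort_fmt("rnaphylo_invalid", "tree tip labels do not match alignment rows")
  masks <- fitch_masks(aln, letters)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- max(tr$edge)
  L <- ncol(masks)
  node_mask <- matrix(0L, nnode, L)
  node_mask[seq_len(ntip), ] <- masks[tr$tip.label, , drop = FALSE]
  score <- 0L
  for (nd in unique(tr$edge[, 1L])) {
    kids <- tr$edge[tr$edge[, 1L] == nd, 2L]
    acc <- node_mask[kids[1L], ]
    for (kid in kids[-1L]) {
      inter <- bitwAnd(acc, node_mask[kid, ])
      zero <- inter == 0L
      score <- score + sum(zero)
      acc <- ifelse(zero, bitwOr(acc, node_mask[kid, ]), inter)
    }
    node_mask[nd, ] <- acc
  }
  as.integer(score)
}

#' Maximum-parsimony tree search
#'
#' Exhaustive enumeration of all unrooted topologies for up to 8 taxa
#' (first-found tie-breaking in enumeration order); otherwise NNI hill
#' climbing from the neighbor-joining tree, keeping the incumbent on ties so
#' the search terminates.
#'
#' @param aln alignment (named character vector of gapped rows).
#' @param strategy `"auto"`, `"exhaustive"` or `"nni"`.
#' @param letters state alphabet.
#' @return List with `tree` (`phylo`, no branch lengths from parsimony) and
#'   `score`.
#' @export
mp_search <- function(aln, strategy = c("auto", "exhaustive", "nni"),
                      letters = encoding_table()$letters) {
  strategy <- match.arg(strategy)
  n <- length(aln)
  if (n < 3L) abort_fmt("rnaphylo_invalid", "need at least 3 taxa")
  if (strategy == "auto")
    strategy <- if (n <= 8L) "exhaustive" else "nni"
  if (strategy == "exhaustive") {
    trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = names(aln))
    best <- NULL
    best_score <- Inf
    for (k in seq_along(trees)) {
      tr <- trees[[k]]  # [[ decompresses shared tip labels of a multiPhylo
      sc <- fitch_score(tr, aln, letters)
      if (sc < best_score) {
        best_score <- sc
        best <- tr
      }
    }
    return(list(tree = best, score = best_score))
  }
  cur <- ape::unroot(neighbor_joining(matrix_from_alignment(aln, "jc12")))
  cur_score <- fitch_score(cur, aln, letters)
  repeat {
    nbrs <- phangorn::nni(cur)
    scores <- vapply(seq_along(nbrs), function(k)
      fitch_score(nbrs[[k]], aln, letters), integer(1))
    if (min(scores) < cur_score) {
      cur <- nbrs[[which.min(scores)]]
      cur_score <- min(scores)
    } else break
  }
  list(tree = cur, score = cur_score)
}
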