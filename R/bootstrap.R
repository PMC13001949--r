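## Column-resampling bootstrap support for any deterministic tree builder.

resample_columns <- function(aln, idx) {
  m <- alignment_matrix(aln)
  as_alignment(setNames(apply(m[, idx, drop = FALSE], 1L, paste, collapse = ""),
                        rownames(m)))
}

#' Bootstrap support for a reference tree
#'
#' Columns are resampled with replacement (by column index, so supports are
#' invariant under row reordering); support for each internal edge of the
#' reference tree is the percentage of replicate trees containing the same
#' bipartition, reported as an integer 0-100. Replicates on which the
#' builder fails (e.g. an undefined distance pair) are dropped with a
#' message; the effective replicate count is reported.
#'
#' @param aln alignment (named character vector of gapped rows).
#' @param tree_builder function `aln -> phylo`, deterministic per replicate.
#' @param B number of pseudo-replicates (default 100).
#' @param seed integer seed; all resampling derives from it.
#' @param reference optional precomputed reference tree (default
#'   `tree_builder(aln)`).
#' @return List with `tree` (reference, supports in `node.label`), `support`
#'   (named integer vector keyed by internal node number) and `B_effective`.
#' @export
bootstrap_support <- function(aln, tree_builder, B = 100L, seed,
                              reference = NULL) {
  B <- as.integer(B)
  stopifnot(B >= 1L)
  if (missing(seed)) abort_fmt("rnaphylo_invalid", "seed is required")
  reference <- reference %||% tree_builder(aln)
  ref_bip <- bipartitions(ape::unroot(reference))
  L <- nchar(aln[[1]])
  counts <- setNames(rep(0L, length(ref_bip)), names(ref_bip))
  dropped <- 0L
  idx_mat <- with_seed(derive_seed(seed, 101L),
                       matrix(sample.int(L, L * B, replace = TRUE), nrow = B))
  for (b in seq_len(B)) {
    rep_aln <- resample_columns(aln, idx_mat[b, ])
    tr <- tryCatch(tree_builder(rep_aln), rnaphylo_error = function(cond) {
      message(sprintf("bootstrap replicate %d dropped: %s", b,
                      conditionMessage(cond)))
      NULL
    })
    if (is.null(tr)) {
      dropped <- dropped + 1L
      next
    }
    hit <- ref_bip %in% bipartitions(ape::unroot(tr))
    counts[hit] <- counts[hit] + 1L
  }
  B_eff <- B - dropped
  if (B_eff < 1L)
    abort_fmt("rnaphylo_numeric", "all %d bootstrap replicates failed", B)
  support <- as.integer(round(100 * counts / B_eff))
  names(support) <- names(ref_bip)
  tree <- attach_support(reference, support)
  list(tree = tree, support = support, B_effective = B_eff)
}

## write integer supports into node.label by internal node number
attach_support <- function(tree, support) {
  n <- length(tree$tip.label)
  lab <- rep("", tree$Nnode)
  for (nm in names(support))
    lab[as.integer(nm) - n] <- as.character(support[[nm]])
  tree$node.label <- lab
  tree
}

#' Neighbor-joining builder factory
#'
#' Convenience wrapper producing an alignment-to-tree function for
#' [bootstrap_support()] and the searches.
#'
#' @param method distance method (see [matrix_from_alignment()]).
#' @param model substitution model for `method = "ml"`.
#' @return Function `aln -> phylo`.
#' @export
nj_builder <- function(method = "jc12", model = subst_model_12()) {
  function(aln) neighbor_joining(matrix_from_alignment(aln, method, model))
}
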