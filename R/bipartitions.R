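## Bipartitions (splits), Robinson-Foulds distance and outgroup rooting.

#' Canonical key of a bipartition
#'
#' A tip-label set is normalized to the side not containing the reference
#' (alphabetically smallest) label, sorted, and collapsed to a single string,
#' so bipartitions of different trees over the same tips compare directly.
#'
#' @param labels tip labels on one side of the split.
#' @param all_labels all tip labels of the tree.
#' @return A single string key.
#' @export
split_key <- function(labels, all_labels) {
  ref <- min(all_labels)
  side <- if (ref %in% labels) setdiff(all_labels, labels) else labels
  paste(sort(side), collapse = "\r")
}

#' Non-trivial bipartitions of a tree
#'
#' @param tree an `ape::phylo`.
#' @return Character vector of canonical split keys, one per internal edge;
#'   names are the tree's internal node numbers.
#' @export
bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  pp <- ape::prop.part(tree)
  nodes <- seq_len(tree$Nnode) + n
  out <- character(0)
  for (k in seq_along(pp)) {
    clade <- tips[pp[[k]]]
    sz <- length(clade)
    if (sz <= 1L || sz >= n - 1L) next
    out[as.character(nodes[k])] <- split_key(clade, tips)
  }
  out
}

#' Robinson-Foulds distance
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' trees (symmetric difference).
#'
#' @param t1,t2 `ape::phylo` trees over the same tip set.
#' @return Integer RF distance.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    abort_fmt("rnaphylo_invalid", "trees have different tip sets")
  b1 <- bipartitions(ape::unroot(t1))
  b2 <- bipartitions(ape::unroot(t2))
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Root a tree with an outgroup
#'
#' The outgroup must be a single tip or form a clade in the unrooted tree;
#' the root is placed at the midpoint of the edge separating outgroup from
#' ingroup.
#'
#' @param tree an `ape::phylo`.
#' @param labels outgroup tip labels.
#' @return A rooted `ape::phylo`.
#' @export
root_with_outgroup <- function(tree, labels) {
  tips <- tree$tip.label
  missing <- setdiff(labels, tips)
  if (length(missing))
    abort_fmt("rnaphylo_lookup", "outgroup tip '%s' not in tree", missing[1])
  un <- ape::unroot(tree)
  if (length(labels) > 1L && length(labels) < length(tips) - 1L) {
    key <- split_key(labels, tips)
    if (!(key %in% bipartitions(un)))
      abort_fmt("rnaphylo_invalid",
                "outgroup {%s} is not monophyletic in the unrooted tree",
                paste(sort(labels), collapse = ", "))
  }
  rooted <- ape::root(un, outgroup = labels, resolve.root = TRUE)
  ## midpoint the split edge: the two basal edges share the original length
  root_node <- length(rooted$tip.label) + 1L
  basal <- which(rooted$edge[, 1L] == root_node)
  if (length(basal) == 2L && !is.null(rooted$edge.length)) {
    tot <- sum(rooted$edge.length[basal])
    rooted$edge.length[basal] <- tot / 2
  }
  rooted
}
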