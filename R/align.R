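## Structure-aware alignment over the 12-letter alphabet: default scoring
## matrix, optimal global pairwise alignment (affine gaps, C++ kernel), and
## a guide-tree progressive multiple aligner.

#' Default 12x12 sequence-structure score matrix
#'
#' Scores reward sequence and structure agreement independently:
#' `+4` identical letter (same nucleotide and pairing state), `+1` same
#' nucleotide in a different pairing state, `0` same pairing state with a
#' different nucleotide, `-2` otherwise. The wildcard `X` (ambiguous
#' nucleotide) scores `-2` against everything including itself.
#'
#' @param table an [encoding_table()].
#' @param same_letter,same_nuc,same_state,other the four score levels.
#' @return Symmetric 13x13 numeric matrix (12 letters + `X`).
#' @export
default_score_matrix <- function(table = encoding_table(), same_letter = 4,
                                 same_nuc = 1, same_state = 0, other = -2) {
  lc <- letter_components(table)
  n <- nrow(lc)
  m <- matrix(other, n + 1L, n + 1L,
              dimnames = list(c(lc$letter, "X"), c(lc$letter, "X")))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- if (i == j) same_letter
    else if (lc$nuc[i] == lc$nuc[j]) same_nuc
    else if (lc$state[i] == lc$state[j]) same_state
    else other
  }
  m
}

#' Nucleotide score matrix for structure-transfer alignments
#'
#' @param match,mismatch scores; `N` is scored as a mismatch against
#'   everything, including itself.
#' @return Symmetric 5x5 matrix over `A`,`C`,`G`,`U`,`N`.
#' @export
nucleotide_score_matrix <- function(match = 2, mismatch = -1) {
  l <- c("A", "C", "G", "U", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(l, l))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

letters_string <- function(m) paste(colnames(m), collapse = "")

#' Optimal global pairwise alignment
#'
#' Three-state affine-gap dynamic program; a gap run of length `k` costs
#' `gap_open + k * gap_extend`. The traceback is deterministic, preferring
#' diagonal over up (gap in `b`) over left (gap in `a`) moves.
#'
#' @param a,b [encoded_seq][encode_structured()] objects or plain strings.
#' @param scores symmetric letter score matrix (see
#'   [default_score_matrix()]); every letter of the inputs must be covered.
#' @param gap_open,gap_extend nonnegative gap penalties.
#' @param free_ends score leading/trailing gap runs as zero (semi-global).
#' @return List with gapped strings `a`, `b` and the alignment `score`.
#' @export
pairwise_align <- function(a, b, scores = default_score_matrix(),
                           gap_open = 6, gap_extend = 1, free_ends = FALSE) {
  sa <- if (inherits(a, "encoded_seq")) a$letters else a
  sb <- if (inherits(b, "encoded_seq")) b$letters else b
  stopifnot(is.character(sa), is.character(sb), gap_open >= 0, gap_extend >= 0)
  if (!nchar(sa) && !nchar(sb)) return(list(a = "", b = "", score = 0))
  if (!nchar(sa) || !nchar(sb)) {
    k <- max(nchar(sa), nchar(sb))
    cost <- if (free_ends) 0 else -(gap_open + k * gap_extend)
    return(list(a = if (nchar(sa)) sa else strrep("-", k),
                b = if (nchar(sb)) sb else strrep("-", k),
                score = cost))
  }
  res <- tryCatch(
    .cpp_align_affine(sa, sb, scores, letters_string(scores),
                      gap_open, gap_extend, free_ends),
    error = function(cond) abort_fmt("rnaphylo_scoring", "%s",
                                     conditionMessage(cond)))
  res
}

## ---- alignment container ---------------------------------------------------

#' Build a multiple alignment object
#'
#' An alignment is a named character vector of equal-length gapped rows.
#'
#' @param rows named character vector (or list) of gapped strings.
#' @return Named character vector of class `msa`.
#' @export
as_alignment <- function(rows) {
  rows <- unlist(rows)
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    abort_fmt("rnaphylo_invalid", "alignment rows must be named")
  if (anyDuplicated(names(rows)))
    abort_fmt("rnaphylo_invalid", "duplicate alignment row id '%s'",
              names(rows)[duplicated(names(rows))][1])
  if (length(unique(nchar(rows))) > 1L)
    abort_fmt("rnaphylo_invalid", "alignment rows have unequal lengths")
  structure(rows, class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d rows x %d columns\n", length(x), nchar(x[1])))
  invisible(x)
}

#' Alignment as a character matrix
#' @param aln an [as_alignment()] object (or named character vector).
#' @return Character matrix, rows = sequences, one character per cell.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Ungapped length of an alignment row
#'
#' @param id row identifier.
#' @param aln alignment (named character vector of gapped rows).
#' @return Number of non-gap characters in that row.
#' @export
ungapped_length <- function(id, aln) {
  if (!(id %in% names(aln)))
    abort_fmt("rnaphylo_lookup", "id '%s' not in alignment", id)
  row <- aln[[id]]
  nchar(gsub("-", "", row, fixed = TRUE))
}

degap <- function(row) gsub("-", "", row, fixed = TRUE)

## ---- progressive MSA -------------------------------------------------------

## column frequency matrix (L x nletters+gap) of a set of gapped rows
profile_freqs <- function(rows, letters) {
  syms <- c(letters, "-")
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  f <- vapply(syms, function(s) colMeans(m == s), numeric(ncol(m)))
  if (ncol(m) == 1L) f <- matrix(f, nrow = 1L, dimnames = list(NULL, syms))
  f
}

#' Progressive multiple alignment of encoded sequences
#'
#' Guide tree: neighbor joining on 12-state Jukes-Cantor-corrected distances
#' from all pairwise alignments. Profiles are merged leaf to root, scoring
#' column pairs by the expected pairwise letter score (gaps score zero);
#' once a gap is introduced it is never removed. Output row order equals
#' input order.
#'
#' @param seqs list of [encoded_seq][encode_structured()] objects (>= 2) or
#'   a named character vector.
#' @inheritParams pairwise_align
#' @return An [as_alignment()] object (input order).
#' @export
progressive_msa <- function(seqs, scores = default_score_matrix(),
                            gap_open = 6, gap_extend = 1) {
  if (!is.list(seqs)) {
    seqs <- Map(function(id, s) structure(list(id = id, letters = s),
                                          class = "encoded_seq"),
                names(seqs), unname(seqs))
  }
  ids <- vapply(seqs, function(s) s$id, character(1))
  if (length(seqs) < 2L)
    abort_fmt("rnaphylo_invalid", "progressive_msa needs at least 2 sequences")
  strs <- setNames(vapply(seqs, function(s) s$letters, character(1)), ids)
  if (length(seqs) == 2L) {
    pw <- pairwise_align(strs[[1]], strs[[2]], scores, gap_open, gap_extend)
    return(as_alignment(setNames(c(pw$a, pw$b), ids)))
  }
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pw <- pairwise_align(strs[[i]], strs[[j]], scores, gap_open, gap_extend)
    p <- p_distance(pw$a, pw$b)
    D[i, j] <- D[j, i] <- jc12(p, cap = TRUE)
  }
  guide <- neighbor_joining(dist_matrix(D))
  ## merge order: postorder over a rooted version of the guide tree
  rt <- ape::root(guide, outgroup = guide$tip.label[1], resolve.root = TRUE)
  rt <- ape::reorder.phylo(rt, "postorder")
  letters <- colnames(scores)
  node_group <- vector("list", max(rt$edge))
  for (k in seq_along(rt$tip.label))
    node_group[[k]] <- setNames(strs[rt$tip.label[k]], rt$tip.label[k])
  for (nd in unique(rt$edge[, 1L])) {
    kids <- rt$edge[rt$edge[, 1L] == nd, 2L]
    acc <- node_group[[kids[1L]]]
    for (kid in kids[-1L]) {
      acc <- merge_profiles(acc, node_group[[kid]], scores, letters,
                            gap_open, gap_extend)
    }
    node_group[[nd]] <- acc
  }
  rows <- node_group[[ape::Ntip(rt) + 1L]]
  as_alignment(rows[ids])
}

## align two groups of already-aligned rows by expected-score profile DP
merge_profiles <- function(rows1, rows2, scores, letters, gap_open, gap_extend) {
  f1 <- profile_freqs(unname(rows1), letters)
  f2 <- profile_freqs(unname(rows2), letters)
  ## expected pairwise score; gap symbol scores 0 against everything
  s13 <- rbind(cbind(scores, 0), 0)
  S <- (f1 %*% s13) %*% t(f2)
  path <- .cpp_align_profile(S, gap_open, gap_extend)
  expand <- function(rows, idx, len) {
    vapply(rows, function(r) {
      cs <- chars(r)
      out <- rep("-", len)
      out[idx > 0L] <- cs[idx[idx > 0L]]
      paste(out, collapse = "")
    }, character(1))
  }
  len <- length(path$ia)
  c(expand(rows1, path$ia, len), expand(rows2, path$ib, len))
}
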