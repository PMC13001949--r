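## Pair tables: integer vector p with p[i] = 1-based partner of position i,
## 0 = unpaired.  The canonical in-memory representation of a secondary
## structure; dot-bracket and CT files both reduce to it.

#' Construct a pair table
#'
#' @param partner integer vector; `partner[i]` is the 1-based partner of
#'   position `i`, `0` for unpaired.
#' @param pseudoknot allow crossing pairs (default `FALSE`; the templates and
#'   the canonical ITS2 core are fully nested).
#' @return An integer vector of class `pair_table`.
#' @export
pair_table <- function(partner, pseudoknot = FALSE) {
  partner <- as.integer(partner)
  n <- length(partner)
  if (any(is.na(partner)) || any(partner < 0L) || any(partner > n))
    abort_fmt("rnaphylo_invalid", "pair table entries must be in 0..%d", n)
  idx <- which(partner > 0L)
  if (any(partner[idx] == idx))
    abort_fmt("rnaphylo_invalid", "position %d pairs with itself",
              idx[which(partner[idx] == idx)[1]])
  bad <- idx[partner[partner[idx]] != idx]
  if (length(bad))
    abort_fmt("rnaphylo_invalid",
              "pair table is not an involution at position %d", bad[1])
  if (!pseudoknot && !is_nested(partner))
    abort_fmt("rnaphylo_invalid",
              "pair table contains crossing pairs (pseudoknot not allowed)")
  structure(partner, class = "pair_table")
}

is_nested <- function(partner) {
  op <- which(partner > seq_along(partner))
  if (length(op) < 2L) return(TRUE)
  i <- op
  j <- partner[op]
  ## pairs sorted by opening position: each must nest inside or follow its
  ## predecessor on a stack
  stack_j <- integer(0)
  for (k in seq_along(i)) {
    while (length(stack_j) && stack_j[length(stack_j)] < i[k])
      stack_j <- stack_j[-length(stack_j)]
    if (length(stack_j) && j[k] > stack_j[length(stack_j)]) return(FALSE)
    stack_j <- c(stack_j, j[k])
  }
  TRUE
}

#' Parse dot-bracket notation into a pair table
#'
#' @param text dot-bracket string over `(`, `)`, `.`; with
#'   `pseudoknot = TRUE` the bracket pairs `[]` and `{}` are also accepted and
#'   may cross the round brackets.
#' @param pseudoknot allow extended brackets and crossing pairs.
#' @return A [pair_table()].
#' @export
parse_dotbracket <- function(text, pseudoknot = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  cs <- chars(text)
  openers <- c("(" = ")", "[" = "]", "{" = "}")
  if (!pseudoknot) openers <- openers["("]
  allowed <- c(names(openers), unname(openers), ".")
  bad <- which(!(cs %in% allowed))
  if (length(bad))
    abort_fmt("rnaphylo_parse", "invalid dot-bracket character '%s' at position %d",
              cs[bad[1]], bad[1])
  partner <- integer(length(cs))
  for (br in names(openers)) {
    stack <- integer(0)
    close <- openers[[br]]
    for (i in seq_along(cs)) {
      if (cs[i] == br) stack <- c(stack, i)
      else if (cs[i] == close) {
        if (!length(stack))
          abort_fmt("rnaphylo_parse", "unbalanced '%s' at position %d", close, i)
        j <- stack[length(stack)]
        stack <- stack[-length(stack)]
        partner[i] <- j
        partner[j] <- i
      }
    }
    if (length(stack))
      abort_fmt("rnaphylo_parse", "unbalanced '%s' at position %d (end of input)",
                br, stack[length(stack)])
  }
  pair_table(partner, pseudoknot = pseudoknot)
}

#' Serialize a pair table to dot-bracket notation
#'
#' @param pt a [pair_table()].
#' @return Single dot-bracket string.
#' @export
write_dotbracket <- function(pt) {
  out <- rep(".", length(pt))
  out[pt > seq_along(pt)] <- "("
  out[pt > 0L & pt < seq_along(pt)] <- ")"
  paste(out, collapse = "")
}

#' Base pairs of a pair table
#'
#' @param pt a [pair_table()].
#' @return Two-column integer matrix `(i, j)` with `i < j`, ordered by `i`.
#' @export
pairs_of <- function(pt) {
  i <- which(pt > seq_along(pt))
  cbind(i = i, j = as.integer(pt[i]))
}

#' Number of base pairs
#' @param pt a [pair_table()].
#' @return Integer pair count.
#' @export
n_pairs <- function(pt) sum(pt > seq_along(pt))

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("<pair_table> %d positions, %d pairs\n", length(x), n_pairs(x)))
  cat(write_dotbracket(x), "\n")
  invisible(x)
}

## ---- helices ---------------------------------------------------------------

#' Decompose a structure into helices
#'
#' Consecutive stacked pairs are grouped into helices; two adjacent pairs stay
#' in the same helix when the interruption (bulge or interior loop) between
#' them is at most `merge_limit` unpaired nucleotides on each strand.
#'
#' @param pt a [pair_table()].
#' @param merge_limit maximum interruption per strand, in nucleotides
#'   (default 2: small bulges and 1x1 interior loops stay within one helix).
#' @return A list of helices, each a list with elements `pairs` (two-column
#'   matrix), `fiveprime`/`threeprime` (closed position ranges) and `parent`
#'   (index of the enclosing helix, or `0` for the exterior loop), ordered by
#'   5' start. Class `helix_list`.
#' @export
enumerate_helices <- function(pt, merge_limit = 2L) {
  stopifnot(merge_limit >= 0L)
  pr <- pairs_of(pt)
  if (!nrow(pr)) return(structure(list(), class = "helix_list"))
  pr <- pr[order(pr[, 1L]), , drop = FALSE]
  helices <- list()
  cur <- pr[1L, , drop = FALSE]
  for (k in seq_len(nrow(pr))[-1L]) {
    i <- pr[k, 1L]; j <- pr[k, 2L]
    pi <- cur[nrow(cur), 1L]; pj <- cur[nrow(cur), 2L]
    gap5 <- if (i - pi > 1L) (pi + 1L):(i - 1L) else integer(0)
    gap3 <- if (pj - j > 1L) (j + 1L):(pj - 1L) else integer(0)
    ## (i,j) continues the helix if nested directly inside (pi,pj), the
    ## interruptions are short, and contain no paired position (a paired
    ## position means a branching sibling helix, never merged)
    if (i > pi && j < pj &&
        length(gap5) <= merge_limit && length(gap3) <= merge_limit &&
        all(pt[c(gap5, gap3)] == 0L)) {
      cur <- rbind(cur, pr[k, ])
    } else {
      helices[[length(helices) + 1L]] <- cur
      cur <- pr[k, , drop = FALSE]
    }
  }
  helices[[length(helices) + 1L]] <- cur
  out <- lapply(helices, function(h) {
    list(pairs = unname(h),
         fiveprime = c(h[1L, 1L], h[nrow(h), 1L]),
         threeprime = c(h[nrow(h), 2L], h[1L, 2L]),
         parent = 0L)
  })
  ## parent: the innermost helix strictly enclosing this helix's outer pair
  outer_i <- vapply(out, function(h) h$fiveprime[1L], integer(1))
  outer_j <- vapply(out, function(h) h$threeprime[2L], integer(1))
  for (a in seq_along(out)) {
    enclosing <- which(outer_i < outer_i[a] & outer_j > outer_j[a])
    if (length(enclosing)) {
      ## innermost = largest opening position among enclosing helices
      out[[a]]$parent <- enclosing[which.max(outer_i[enclosing])]
    }
  }
  structure(out, class = "helix_list")
}

#' Root-level helices (exterior-loop children)
#'
#' Returns only the helices whose enclosing loop is the exterior loop, in
#' 5' to 3' order; these are the helices numbered I, II, ... in ITS2
#' structure diagrams.
#'
#' @inheritParams enumerate_helices
#' @return A `helix_list` of root-level helices.
#' @export
root_level_helices <- function(pt, merge_limit = 2L) {
  hs <- enumerate_helices(pt, merge_limit)
  structure(hs[vapply(hs, function(h) h$parent == 0L, logical(1))],
            class = "helix_list")
}

#' @export
print.helix_list <- function(x, ...) {
  cat(sprintf("<helix_list> %d helices\n", length(x)))
  for (k in seq_along(x)) {
    h <- x[[k]]
    cat(sprintf("  [%d] 5' %d..%d / 3' %d..%d  %d pairs, parent %d\n", k,
                h$fiveprime[1], h$fiveprime[2], h$threeprime[1],
                h$threeprime[2], nrow(h$pairs), h$parent))
  }
  invisible(x)
}
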