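## Structured sequences: a nucleotide sequence together with its pair table.

#' Construct a sequence record
#'
#' @param id nonempty accession-like identifier.
#' @param residues nucleotide string; `T` is normalized to `U` and case folded
#'   to upper. Allowed letters after normalization: `A`, `C`, `G`, `U`, `N`.
#' @param description free-text description (optional).
#' @param allow_gap permit `-` characters (aligned rows).
#' @return A list of class `seq_record` with `id`, `description`, `residues`.
#' @export
seq_record <- function(id, residues, description = "", allow_gap = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    abort_fmt("rnaphylo_invalid", "record id must be a nonempty string")
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    abort_fmt("rnaphylo_format", "record '%s' has an empty sequence", id)
  residues <- toupper(residues)
  residues <- gsub("T", "U", residues, fixed = TRUE)
  alpha <- c("A", "C", "G", "U", "N", if (allow_gap) "-")
  cs <- chars(residues)
  bad <- which(!(cs %in% alpha))
  if (length(bad))
    abort_fmt("rnaphylo_format",
              "record '%s': unsupported residue '%s' at position %d",
              id, cs[bad[1]], bad[1])
  structure(list(id = id, description = description, residues = residues),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d nt)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Construct a structured sequence
#'
#' @param record a [seq_record()] (or a list coercible to one).
#' @param pairs a [pair_table()] of the same length.
#' @param strict require every pair to be canonical or wobble
#'   (`AU`,`UA`,`GC`,`CG`,`GU`,`UG`); `N` never satisfies strict pairing.
#' @return A list of class `structured_seq` with `record` and `pairs`.
#' @export
structured_seq <- function(record, pairs, strict = FALSE) {
  if (!inherits(record, "seq_record"))
    record <- seq_record(record$id, record$residues, record$description %||% "")
  if (!inherits(pairs, "pair_table")) pairs <- pair_table(pairs)
  if (nchar(record$residues) != length(pairs))
    abort_fmt("rnaphylo_invalid",
              "record '%s': sequence length %d != structure length %d",
              record$id, nchar(record$residues), length(pairs))
  if (strict) {
    cs <- chars(record$residues)
    pr <- pairs_of(pairs)
    if (nrow(pr)) {
      ok <- is_allowed_pair(cs[pr[, 1L]], cs[pr[, 2L]])
      if (!all(ok))
        abort_fmt("rnaphylo_invalid",
                  "record '%s': non-canonical pair %s-%s at (%d,%d)",
                  record$id, cs[pr[!ok, 1L][1]], cs[pr[!ok, 2L][1]],
                  pr[!ok, 1L][1], pr[!ok, 2L][1])
    }
  }
  structure(list(record = record, pairs = pairs), class = "structured_seq")
}

#' @export
print.structured_seq <- function(x, ...) {
  cat(sprintf("<structured_seq> %s (%d nt, %d pairs)\n",
              x$record$id, length(x$pairs), n_pairs(x$pairs)))
  invisible(x)
}

#' Fraction of base pairs shared through a position mapping
#'
#' The proportion of `a`'s base pairs whose two endpoints map (through a
#' pairwise-alignment position map) onto a base pair of `b`. With no pairs in
#' `a` the fraction is 1 by convention unless `strict = TRUE`, in which case
#' an error is raised.
#'
#' @param a,b [structured_seq()] objects.
#' @param mapping integer vector of length `length(a)`: `mapping[i]` is the
#'   position of `b` aligned to position `i` of `a`, `NA` where `i` aligns to
#'   a gap.
#' @param strict error when `a` has no pairs (instead of returning 1).
#' @return Fraction in `[0, 1]`.
#' @export
shared_pair_fraction <- function(a, b, mapping, strict = FALSE) {
  stopifnot(inherits(a, "structured_seq"), inherits(b, "structured_seq"))
  if (length(mapping) != length(a$pairs))
    abort_fmt("rnaphylo_contract", "mapping length %d != length of a (%d)",
              length(mapping), length(a$pairs))
  mm <- mapping[!is.na(mapping)]
  if (length(mm) && (any(mm < 1L) || any(mm > length(b$pairs))))
    abort_fmt("rnaphylo_contract", "mapping position out of range of b")
  if (anyDuplicated(mm))
    abort_fmt("rnaphylo_contract", "mapping is not injective")
  pr <- pairs_of(a$pairs)
  if (!nrow(pr)) {
    if (strict)
      abort_fmt("rnaphylo_invalid", "'%s' has no pairs to compare", a$record$id)
    return(1)
  }
  mi <- mapping[pr[, 1L]]
  mj <- mapping[pr[, 2L]]
  both <- !is.na(mi) & !is.na(mj)
  shared <- both
  shared[both] <- unclass(b$pairs)[mi[both]] == mj[both]
  sum(shared) / nrow(pr)
}

#' Truncate a structured sequence
#'
#' Keeps the first `k` positions; pairs with a partner beyond `k` are opened.
#'
#' @param s a [structured_seq()].
#' @param k number of leading positions to keep.
#' @return A [structured_seq()] of length `k`.
#' @export
truncate_structured <- function(s, k) {
  stopifnot(inherits(s, "structured_seq"), k >= 1L, k <= length(s$pairs))
  p <- unclass(s$pairs)[seq_len(k)]
  p[p > k] <- 0L
  structured_seq(seq_record(s$record$id, substr(s$record$residues, 1L, k),
                            s$record$description),
                 pair_table(p))
}
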