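## External formats: FASTA (plain and gapped), Vienna dot-bracket triplets,
## CT (RNAstructure dialect, 1-based), Newick, and plain-text 12x12 score
## matrices.  FASTA parsing is delegated to Biostrings; Newick to ape.

#' Read a FASTA file
#'
#' @param path file path.
#' @param allow_gap accept `-` characters (gapped/aligned FASTA).
#' @return List of [seq_record()], input order preserved; `T` is normalized
#'   to `U` and case folded. Duplicate ids are rejected.
#' @export
read_fasta <- function(path, allow_gap = FALSE) {
  if (!file.exists(path))
    abort_fmt("rnaphylo_format", "FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(cond)
                    abort_fmt("rnaphylo_format", "malformed FASTA '%s': %s",
                              path, conditionMessage(cond)))
  hdr <- names(set)
  recs <- vector("list", length(set))
  ids <- character(length(set))
  for (k in seq_along(set)) {
    if (is.null(hdr[k]) || !nzchar(trimws(hdr[k])))
      abort_fmt("rnaphylo_format", "record %d: empty FASTA header", k)
    id <- strsplit(trimws(hdr[k]), "[ \t]+")[[1]][1]
    desc <- sub("^\\S+\\s*", "", trimws(hdr[k]))
    body <- as.character(set[[k]])
    if (!nzchar(body))
      abort_fmt("rnaphylo_format", "record %d ('%s'): empty sequence", k, id)
    recs[[k]] <- seq_record(id, body, desc, allow_gap = allow_gap)
    ids[k] <- id
  }
  if (anyDuplicated(ids))
    abort_fmt("rnaphylo_format", "duplicate record id '%s'",
              ids[duplicated(ids)][1])
  recs
}

#' Write records to FASTA
#'
#' Emits upper-case `U` (RNA) regardless of input conventions.
#'
#' @param records list of [seq_record()] (or objects with `id`, `residues`).
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  lines <- unlist(lapply(records, function(r) {
    body <- r$residues
    starts <- seq(1L, nchar(body), by = width)
    hdr <- if (nzchar(r$description %||% "")) paste(r$id, r$description) else r$id
    c(paste0(">", hdr), substring(body, starts, pmin(starts + width - 1L, nchar(body))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Vienna (dot-bracket) structure file
#'
#' Records are header/sequence/structure line triplets
#' (`>id`, nucleotides, dot-bracket).
#'
#' @param path file path.
#' @param pseudoknot passed to [parse_dotbracket()].
#' @return List of [structured_seq()].
#' @export
read_vienna <- function(path, pseudoknot = FALSE) {
  if (!file.exists(path))
    abort_fmt("rnaphylo_format", "Vienna file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3L != 0L)
    abort_fmt("rnaphylo_format",
              "Vienna file '%s': %d non-empty lines, not header/sequence/structure triplets",
              path, length(lines))
  out <- vector("list", length(lines) %/% 3L)
  for (k in seq_along(out)) {
    hdr <- lines[3L * k - 2L]
    seq <- lines[3L * k - 1L]
    db <- lines[3L * k]
    if (!startsWith(hdr, ">"))
      abort_fmt("rnaphylo_format", "record %d: expected '>' header, got '%s'",
                k, substr(hdr, 1L, 20L))
    id <- strsplit(sub("^>", "", hdr), "[ \t]+")[[1]][1]
    desc <- sub("^\\S+\\s*", "", sub("^>", "", hdr))
    if (nchar(seq) != nchar(db))
      abort_fmt("rnaphylo_format",
                "record %d ('%s'): sequence length %d != structure length %d",
                k, id, nchar(seq), nchar(db))
    out[[k]] <- structured_seq(seq_record(id, seq, desc),
                               parse_dotbracket(db, pseudoknot = pseudoknot))
  }
  ids <- vapply(out, function(s) s$record$id, character(1))
  if (anyDuplicated(ids))
    abort_fmt("rnaphylo_format", "duplicate record id '%s'",
              ids[duplicated(ids)][1])
  out
}

#' Write structured sequences as a Vienna file
#'
#' @param ss list of [structured_seq()].
#' @param path output path.
#' @export
write_vienna <- function(ss, path) {
  if (inherits(ss, "structured_seq")) ss <- list(ss)
  lines <- unlist(lapply(ss, function(s)
    c(paste0(">", s$record$id,
             if (nzchar(s$record$description %||% "")) paste0(" ", s$record$description)),
      s$record$residues,
      write_dotbracket(s$pairs))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a CT structure file (RNAstructure dialect)
#'
#' First line: position count (optionally followed by a title); then one row
#' per position with 6 whitespace-delimited fields
#' `index base prev next partner index`, partner `0` meaning unpaired,
#' all indices 1-based.
#'
#' @param path file path.
#' @return A [structured_seq()].
#' @export
read_ct <- function(path) {
  if (!file.exists(path))
    abort_fmt("rnaphylo_format", "CT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(n) || n < 1L)
    abort_fmt("rnaphylo_format", "CT header must start with the position count")
  title <- if (length(hdr) > 1L) paste(hdr[-1L], collapse = " ") else "ct"
  if (length(lines) - 1L < n)
    abort_fmt("rnaphylo_format", "CT file declares %d rows but has %d", n,
              length(lines) - 1L)
  res <- character(n)
  partner <- integer(n)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(lines[k + 1L]), "[ \t]+")[[1]]
    if (length(f) < 6L)
      abort_fmt("rnaphylo_format", "CT row %d has %d fields, expected 6", k,
                length(f))
    idx <- as.integer(f[1]); p <- suppressWarnings(as.integer(f[5]))
    if (is.na(idx) || idx != k)
      abort_fmt("rnaphylo_format", "CT row %d has index %s", k, f[1])
    if (is.na(p) || p < 0L || p > n)
      abort_fmt("rnaphylo_format", "CT row %d: partner '%s' out of range", k, f[5])
    res[k] <- f[2]
    partner[k] <- p
  }
  idx <- which(partner > 0L)
  bad <- idx[partner[partner[idx]] != idx]
  if (length(bad))
    abort_fmt("rnaphylo_consistency",
              "CT pairing asymmetry: row %d names partner %d but row %d names %d",
              bad[1], partner[bad[1]], partner[bad[1]], partner[partner[bad[1]]])
  structured_seq(seq_record(strsplit(title, "[ \t]+")[[1]][1],
                            paste(res, collapse = "")),
                 pair_table(partner))
}

#' Write a structured sequence as a CT file
#'
#' @param s a [structured_seq()].
#' @param path output path.
#' @export
write_ct <- function(s, path) {
  n <- length(s$pairs)
  cs <- chars(s$record$residues)
  rows <- sprintf("%5d %s %7d %4d %4d %4d", seq_len(n), cs,
                  seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L),
                  unclass(s$pairs), seq_len(n))
  writeLines(c(sprintf("%5d %s", n, s$record$id), rows), path)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over `ape`: trees are `phylo` objects, internal-node support
#' labels land in `node.label`. Canonical output rounds branch lengths to six
#' decimals so write-read round trips are byte stable.
#'
#' @param text Newick string, or a path to a file containing one.
#' @return [read_newick()]: an `ape::phylo`; [write_newick()]: a Newick string.
#' @export
read_newick <- function(text) {
  tr <- tryCatch(
    if (length(text) == 1L && !grepl("(", text, fixed = TRUE) && file.exists(text))
      ape::read.tree(text)
    else ape::read.tree(text = text),
    error = function(cond)
      abort_fmt("rnaphylo_parse", "Newick parse error: %s", conditionMessage(cond)))
  if (is.null(tr))
    abort_fmt("rnaphylo_parse", "Newick parse error (unbalanced or empty input)")
  tr
}

#' @param tree an `ape::phylo` tree.
#' @param digits branch-length precision.
#' @rdname read_newick
#' @export
write_newick <- function(tree, digits = 6L) {
  ape::write.tree(tree, digits = digits)
}

#' Read a 12x12 score matrix file
#'
#' Format: a header row listing the 12 encoded letters, then 12
#' whitespace-delimited numeric rows (an optional leading row label is
#' accepted). The matrix must be symmetric to within `1e-9`.
#'
#' @param path file path.
#' @return Numeric 12x12 matrix with letter dimnames.
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path))
    abort_fmt("rnaphylo_format", "score matrix file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- strsplit(lines[1], "[ \t]+")[[1]]
  if (length(hdr) != 12L || anyDuplicated(hdr) || any(nchar(hdr) != 1L))
    abort_fmt("rnaphylo_format",
              "score matrix header must list 12 distinct letters, got %d fields",
              length(hdr))
  if (length(lines) - 1L != 12L)
    abort_fmt("rnaphylo_format", "score matrix must have 12 rows, got %d",
              length(lines) - 1L)
  m <- matrix(NA_real_, 12L, 12L, dimnames = list(hdr, hdr))
  for (k in 1:12) {
    f <- strsplit(lines[k + 1L], "[ \t]+")[[1]]
    if (length(f) == 13L) {
      if (f[1] != hdr[k])
        abort_fmt("rnaphylo_format", "row %d labelled '%s', expected '%s'",
                  k, f[1], hdr[k])
      f <- f[-1L]
    }
    if (length(f) != 12L)
      abort_fmt("rnaphylo_format", "score matrix row %d has %d values, expected 12",
                k, length(f))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      abort_fmt("rnaphylo_format", "non-numeric value in score matrix row %d", k)
    m[k, ] <- v
  }
  if (max(abs(m - t(m))) > 1e-9)
    abort_fmt("rnaphylo_format", "score matrix is asymmetric (max |S - t(S)| = %g)",
              max(abs(m - t(m))))
  m
}

#' Write a 12x12 score matrix file
#'
#' @param m symmetric numeric matrix with letter dimnames.
#' @param path output path.
#' @export
write_score_matrix <- function(m, path) {
  stopifnot(nrow(m) == 12L, ncol(m) == 12L)
  lines <- c(paste(colnames(m), collapse = " "),
             vapply(seq_len(12L), function(k)
               paste(c(rownames(m)[k], format(m[k, ], trim = TRUE)), collapse = " "),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
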