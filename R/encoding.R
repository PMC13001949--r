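## 12-letter sequence-structure encoding: each position becomes one letter
## coding (nucleotide, structural state) with states unpaired / paired-left
## (opening) / paired-right (closing).  Letters are drawn from the standard
## amino-acid one-letter codes so amino-acid tooling can consume the data.

NUCS <- c("A", "C", "G", "U")
STATES <- c("unpaired", "left", "right")

#' Construct a 12-letter encoding table
#'
#' Maps each (nucleotide, structural state) combination to one amino-acid
#' one-letter code, bijectively. The default maps unpaired A,C,G,U to
#' A,C,G,T; paired-left (opening) A,C,G,U to D,E,F,H; paired-right (closing)
#' A,C,G,U to I,K,L,M. Any bijection is equivalent for downstream analysis;
#' the table in force is serialized into run manifests so outputs are
#' self-describing.
#'
#' @param unpaired,left,right character vectors of 4 letters each, in
#'   nucleotide order A, C, G, U.
#' @return A list of class `encoding_table`.
#' @export
encoding_table <- function(unpaired = c("A", "C", "G", "T"),
                           left = c("D", "E", "F", "H"),
                           right = c("I", "K", "L", "M")) {
  letters12 <- c(unpaired, left, right)
  aa <- chars("ACDEFGHIKLMNPQRSTVWY")
  if (length(letters12) != 12L || anyDuplicated(letters12) ||
      !all(letters12 %in% aa))
    abort_fmt("rnaphylo_invalid",
              "encoding must be a bijection onto 12 distinct amino-acid letters")
  enc <- matrix(letters12, nrow = 4L,
                dimnames = list(NUCS, STATES))
  structure(list(map = enc, letters = letters12), class = "encoding_table")
}

#' @export
print.encoding_table <- function(x, ...) {
  cat("<encoding_table>\n")
  print(x$map)
  invisible(x)
}

## structural state per position: 1 unpaired, 2 left/opening, 3 right/closing
state_codes <- function(pt) {
  idx <- seq_along(pt)
  ifelse(pt == 0L, 1L, ifelse(pt > idx, 2L, 3L))
}

#' Encode a structured sequence into the 12-letter alphabet
#'
#' @param s a [structured_seq()].
#' @param table an [encoding_table()].
#' @param n_action how to treat residue `N`: `"error"` (strict) or `"X"`
#'   (emit the wildcard letter `X`, scored as mismatch everywhere).
#' @return A list of class `encoded_seq` with `id` and `letters` (string).
#' @export
encode_structured <- function(s, table = encoding_table(),
                              n_action = c("error", "X")) {
  n_action <- match.arg(n_action)
  stopifnot(inherits(s, "structured_seq"), inherits(table, "encoding_table"))
  cs <- chars(s$record$residues)
  st <- state_codes(s$pairs)
  out <- character(length(cs))
  is_n <- cs == "N"
  if (any(is_n)) {
    if (n_action == "error")
      abort_fmt("rnaphylo_invalid",
                "record '%s': residue N at position %d not encodable in strict mode",
                s$record$id, which(is_n)[1])
    out[is_n] <- "X"
  }
  ok <- !is_n
  out[ok] <- table$map[cbind(match(cs[ok], NUCS), st[ok])]
  structure(list(id = s$record$id, letters = paste(out, collapse = "")),
            class = "encoded_seq")
}

#' Decode a 12-letter encoded sequence
#'
#' Reconstructs residues and the pair table by matching paired-left and
#' paired-right states as brackets.
#'
#' @param e an [encoded_seq][encode_structured()] or a plain letter string.
#' @param table the [encoding_table()] used to encode.
#' @param id identifier when `e` is a plain string.
#' @return A [structured_seq()].
#' @export
decode_encoded <- function(e, table = encoding_table(), id = NULL) {
  if (is.character(e)) e <- structure(list(id = id %||% "decoded", letters = e),
                                      class = "encoded_seq")
  cs <- chars(e$letters)
  if (!length(cs))
    return(structure(list(record = structure(list(id = e$id, description = "",
                                                  residues = ""),
                                             class = "seq_record"),
                          pairs = pair_table(integer(0))),
                     class = "structured_seq"))
  hit <- match(cs, table$letters)
  if (anyNA(hit))
    abort_fmt("rnaphylo_decode", "letter '%s' at position %d not in encoding table",
              cs[is.na(hit)][1], which(is.na(hit))[1])
  nuc <- NUCS[(hit - 1L) %% 4L + 1L]
  st <- (hit - 1L) %/% 4L + 1L  # 1 unpaired, 2 left, 3 right
  db <- c(".", "(", ")")[st]
  pt <- tryCatch(parse_dotbracket(paste(db, collapse = "")),
                 rnaphylo_parse = function(cond)
                   abort_fmt("rnaphylo_decode",
                             "unbalanced structural states: %s",
                             conditionMessage(cond)))
  structured_seq(seq_record(e$id, paste(nuc, collapse = "")), pt)
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat(sprintf("<encoded_seq> %s (%d letters)\n", x$id, nchar(x$letters)))
  invisible(x)
}

#' Encode many structured sequences
#'
#' @param ss list of [structured_seq()].
#' @inheritParams encode_structured
#' @return List of `encoded_seq`.
#' @export
encode_all <- function(ss, table = encoding_table(), n_action = "error") {
  lapply(ss, encode_structured, table = table, n_action = n_action)
}

## nucleotide / state of each encoded letter, for score-matrix construction
letter_components <- function(table = encoding_table()) {
  data.frame(letter = table$letters,
             nuc = rep(NUCS, 3L),
             state = rep(STATES, each = 4L),
             stringsAsFactors = FALSE)
}
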