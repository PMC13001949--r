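## Annotation of the canonical ITS2 structural hallmarks: the proximal stem
## with its two unpaired nucleotides, the A-rich spacer between helices II
## and III, the U-U mismatch in helix II, the UGGU motif near the 5' apex of
## helix III, and helix numbering with fifth helices and side arms.

#' ITS2 annotation parameters
#'
#' @param proximal_unpaired unpaired nucleotides the proximal stem must
#'   contain between its first and last pair (default 2).
#' @param a_frac minimum A fraction of the A-rich window (default 0.5).
#' @param a_minlen minimum A-rich window length in nt (default 3).
#' @param apex_window how far below the apical loop of helix III (in nt
#'   along the 5' strand) the UGGU motif is searched (default 20).
#' @param merge_limit helix decomposition merge limit (see
#'   [enumerate_helices()]).
#' @return List of class `its2_params`.
#' @export
its2_params <- function(proximal_unpaired = 2L, a_frac = 0.5, a_minlen = 3L,
                        apex_window = 20L, merge_limit = 2L) {
  structure(list(proximal_unpaired = as.integer(proximal_unpaired),
                 a_frac = a_frac, a_minlen = as.integer(a_minlen),
                 apex_window = as.integer(apex_window),
                 merge_limit = as.integer(merge_limit)),
            class = "its2_params")
}

## core helices for numbering: when one root helix encloses two or more
## child helices it is the proximal stem and its children are numbered;
## otherwise the root-level helices are numbered directly
its2_core <- function(pt, merge_limit) {
  hs <- enumerate_helices(pt, merge_limit)
  roots <- which(vapply(hs, function(h) h$parent == 0L, logical(1)))
  if (length(roots) == 1L) {
    kids <- which(vapply(hs, function(h) h$parent == roots, logical(1)))
    if (length(kids) >= 2L)
      return(list(helices = hs, core = kids, proximal = roots))
  }
  list(helices = hs, core = roots, proximal = NA_integer_)
}

## unpaired positions strictly inside a helix (between first and last pair,
## both strands combined) -- bulges and interior loops, not the closed loop
helix_internal_unpaired <- function(pt, h) {
  p <- h$pairs
  i1 <- p[1L, 1L]; j1 <- p[1L, 2L]
  ik <- p[nrow(p), 1L]; jk <- p[nrow(p), 2L]
  span <- c(if (ik > i1) i1:ik else integer(0),
            if (j1 > jk) jk:j1 else integer(0))
  span[unclass(pt)[span] == 0L]
}

#' Annotate canonical ITS2 structural hallmarks
#'
#' Detects, where applicable: the proximal stem (a single root helix
#' enclosing the numbered core helices, with a configured number of unpaired
#' nucleotides between its first and last pair); the A-rich spacer between
#' helices II and III; a U-U one-by-one interior loop in helix II; the UGGU
#' motif on the 5' strand of helix III near its apical loop; and the core
#' helix count with fifth helices and helical side arms. Features whose
#' reference helix does not exist are reported absent, never as an error.
#'
#' @param s a [structured_seq()].
#' @param params an [its2_params()].
#' @return List of class `its2_annotation`: `helix_count`, `helices`
#'   (per-core-helix roman numeral, span, side-arm count), `proximal_stem`
#'   (`present`, `unpaired`), `arich` (`start`, `end`, `a_fraction` or
#'   absent), `uu_mismatch` (positions or absent), `uggu` (position or
#'   absent).
#' @export
annotate_its2 <- function(s, params = its2_params()) {
  stopifnot(inherits(s, "structured_seq"))
  pt <- s$pairs
  res <- chars(s$record$residues)
  dec <- its2_core(pt, params$merge_limit)
  hs <- dec$helices
  core <- dec$core
  ## order core helices 5' -> 3'
  core <- core[order(vapply(hs[core], function(h) h$fiveprime[1L], integer(1)))]
  romans <- as.character(utils::as.roman(seq_along(core)))

  helices <- lapply(seq_along(core), function(k) {
    h <- hs[[core[k]]]
    arms <- which(vapply(hs, function(x) x$parent == core[k], logical(1)))
    list(numeral = romans[k],
         span = c(h$fiveprime[1L], h$threeprime[2L]),
         n_pairs = nrow(h$pairs),
         side_arms = length(arms))
  })
  names(helices) <- romans

  proximal <- if (!is.na(dec$proximal)) {
    up <- helix_internal_unpaired(pt, hs[[dec$proximal]])
    list(present = length(up) == params$proximal_unpaired, unpaired = length(up))
  } else list(present = FALSE, unpaired = NA_integer_)

  arich <- NULL
  if (length(core) >= 3L) {
    h2 <- hs[[core[2L]]]; h3 <- hs[[core[3L]]]
    lo <- h2$threeprime[2L] + 1L
    hi <- h3$fiveprime[1L] - 1L
    if (hi >= lo) {
      spacer <- lo:hi
      spacer <- spacer[unclass(pt)[spacer] == 0L]
      arich <- best_a_window(res, spacer, params$a_frac, params$a_minlen)
    }
  }

  uu <- NULL
  if (length(core) >= 2L) {
    h2 <- hs[[core[2L]]]
    p <- h2$pairs
    if (nrow(p) >= 2L) {
      for (k in seq_len(nrow(p) - 1L)) {
        i1 <- p[k, 1L]; j1 <- p[k, 2L]
        i2 <- p[k + 1L, 1L]; j2 <- p[k + 1L, 2L]
        if (i2 == i1 + 2L && j2 == j1 - 2L &&
            unclass(pt)[i1 + 1L] == 0L && unclass(pt)[j1 - 1L] == 0L &&
            res[i1 + 1L] == "U" && res[j1 - 1L] == "U") {
          uu <- c(i1 + 1L, j1 - 1L)
          break
        }
      }
    }
  }

  uggu <- NULL
  if (length(core) >= 3L) {
    h3 <- hs[[core[3L]]]
    strand5_end <- h3$fiveprime[2L]      # innermost 5' paired position
    lo <- max(h3$fiveprime[1L], strand5_end - params$apex_window + 1L)
    region <- substr(s$record$residues, lo, strand5_end)
    hit <- regexpr("UGGU", region, fixed = TRUE)
    if (hit > 0L) uggu <- lo + as.integer(hit) - 1L
  }

  structure(list(helix_count = length(core), helices = helices,
                 proximal_stem = proximal, arich = arich,
                 uu_mismatch = uu, uggu = uggu),
            class = "its2_annotation")
}

## longest window over `positions` (contiguous runs only) with A fraction >=
## frac and length >= minlen; ties to the leftmost window
best_a_window <- function(res, positions, frac, minlen) {
  if (!length(positions)) return(NULL)
  runs <- split(positions, cumsum(c(1L, diff(positions) != 1L)))
  best <- NULL
  best_len <- 0L
  for (run in runs) {
    n <- length(run)
    if (n < minlen) next
    isa <- cumsum(c(0L, res[run] == "A"))
    for (st in seq_len(n - minlen + 1L)) {
      for (en in seq(st + minlen - 1L, n)) {
        len <- en - st + 1L
        f <- (isa[en + 1L] - isa[st]) / len
        if (f >= frac && len > best_len) {
          best <- list(start = run[st], end = run[en], a_fraction = f)
          best_len <- len
        }
      }
    }
  }
  best
}

#' Synthetic exemplar ITS2 structures
#'
#' Hand-built structures displaying the canonical hallmarks: a proximal stem
#' with two unpaired nucleotides enclosing four core helices, a U-U
#' one-by-one interior loop in helix II, an A-rich spacer between helices II
#' and III, and a UGGU motif just below the apex of helix III. The `"long"`
#' variant adds a fifth helix and a side arm branching off helix III, and
#' carries no UGGU motif — the shape reported for unusually long ITS2
#' sequences. These are synthetic constructions for demonstrations and
#' validation, not database records.
#'
#' @param variant `"canonical"` (four helices) or `"long"` (fifth helix,
#'   side arms, no UGGU).
#' @return A [structured_seq()].
#' @export
example_its2_structure <- function(variant = c("canonical", "long")) {
  variant <- match.arg(variant)
  fifth <- variant == "long"
  seg <- function(s, d) list(s = s, d = d)
  hp <- function(stem5, loop, stem3)
    seg(paste0(stem5, loop, stem3),
        paste0(strrep("(", nchar(stem5)), strrep(".", nchar(loop)),
               strrep(")", nchar(stem3))))
  helix3 <- if (!fifth) {
    hp("GGCGCUGGU", "GAAA", "ACCAGCGCC")
  } else {
    seg(paste0("GGCGC", "GGGC", "UUCG", "GCCC", "CACGC", "GAAA", "GCGUG",
               "GCGCC"),
        paste0("(((((", "((((", "....", "))))", "(((((", "....", ")))))",
               ")))))"))
  }
  parts <- list(
    seg("GGC", "((("),                      # proximal stem, outer
    seg("U", "."),                          # bulge nt 1
    seg("GG", "(("),                        # proximal stem, inner
    seg("AC", ".."),
    hp("GGCG", "UUCG", "CGCC"),             # helix I
    seg("UCU", "..."),
    seg("GCGUGCGGAAACGCUCGC", "(((.(((....))).)))"),  # helix II, U-U loop
    seg("CAAAAAC", "......."),              # A-rich spacer
    helix3,
    seg("C", "."),
    hp("GGGC", "GCAA", "GCCC"),             # helix IV
    if (fifth) hp("GCGG", "UUCG", "CCGC") else NULL,  # helix V
    seg("A", "."),
    seg("CC", "))"),                        # proximal stem, inner 3'
    seg("A", "."),                          # bulge nt 2
    seg("GCC", ")))"))                      # proximal stem, outer 3'
  parts <- Filter(Negate(is.null), parts)
  s <- paste(vapply(parts, `[[`, "", "s"), collapse = "")
  d <- paste(vapply(parts, `[[`, "", "d"), collapse = "")
  structured_seq(seq_record(paste0("synthetic_its2_", variant), s),
                 parse_dotbracket(d))
}

#' @export
print.its2_annotation <- function(x, ...) {
  cat(sprintf("<its2_annotation> %d core helices (%s)\n", x$helix_count,
              paste(names(x$helices), collapse = ", ")))
  cat(sprintf("  proximal stem: %s (unpaired: %s)\n",
              if (x$proximal_stem$present) "present" else "absent",
              x$proximal_stem$unpaired))
  cat(sprintf("  A-rich spacer: %s\n",
              if (is.null(x$arich)) "absent"
              else sprintf("%d-%d (A fraction %.2f)", x$arich$start,
                           x$arich$end, x$arich$a_fraction)))
  cat(sprintf("  U-U mismatch in helix II: %s\n",
              if (is.null(x$uu_mismatch)) "absent"
              else paste(x$uu_mismatch, collapse = "/")))
  cat(sprintf("  UGGU near apex of helix III: %s\n",
              if (is.null(x$uggu)) "absent" else x$uggu))
  invisible(x)
}
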