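## Template-based secondary-structure homology modeling: a template's base
## pairs are transferred onto a target through a global pairwise nucleotide
## alignment; the percentage of transferred pairs scores the model, selects
## among templates, and drives dataset curation filters.

#' Alignment parameters for structure transfer
#'
#' @param match,mismatch nucleotide scores (`N` is always a mismatch).
#' @param gap_open,gap_extend nonnegative affine gap penalties (a gap run of
#'   length `k` costs `gap_open + k * gap_extend`).
#' @return List of class `transfer_params`.
#' @export
transfer_params <- function(match = 2, mismatch = -1, gap_open = 6,
                            gap_extend = 1) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "transfer_params")
}

#' Transfer a template structure onto a target sequence
#'
#' The template and target nucleotide sequences are aligned globally
#' (affine gaps); a template pair `(i, j)` is transferred iff both `i` and
#' `j` align to ungapped target positions whose residues can themselves form
#' a canonical or wobble pair. With `require_pairable = FALSE` only the
#' co-alignment condition is applied (the transferred pair may then be
#' non-canonical in the target). The transfer percentage is
#' `100 * transferred / n_template_pairs`.
#'
#' @param template a [structured_seq()] with at least one pair.
#' @param target a [seq_record()] (or structured_seq; its pairs are ignored).
#' @param params a [transfer_params()].
#' @param require_pairable require target residues to form an allowed pair.
#' @return List of class `transfer_result`: `target` ([structured_seq()]
#'   with the transferred pairs), `template_id`, `transfer_pct`, and
#'   `alignment` (gapped template/target strings).
#' @export
transfer_structure <- function(template, target, params = transfer_params(),
                               require_pairable = TRUE) {
  stopifnot(inherits(template, "structured_seq"))
  if (inherits(target, "structured_seq")) target <- target$record
  if (!inherits(target, "seq_record"))
    target <- seq_record(target$id, target$residues, target$description %||% "")
  npair <- n_pairs(template$pairs)
  if (npair == 0L)
    abort_fmt("rnaphylo_invalid",
              "template '%s' has no pairs; transfer cannot be scored",
              template$record$id)
  sm <- nucleotide_score_matrix(params$match, params$mismatch)
  pw <- pairwise_align(template$record$residues, target$residues, sm,
                       params$gap_open, params$gap_extend)
  ## position map template -> target through the alignment
  ca <- chars(pw$a)
  cb <- chars(pw$b)
  tpos <- cumsum(ca != "-")
  gpos <- cumsum(cb != "-")
  map <- rep(NA_integer_, nchar(template$record$residues))
  hit <- ca != "-" & cb != "-"
  map[tpos[hit]] <- gpos[hit]
  pr <- pairs_of(template$pairs)
  mi <- map[pr[, 1L]]
  mj <- map[pr[, 2L]]
  ok <- !is.na(mi) & !is.na(mj)
  if (require_pairable && any(ok)) {
    res <- chars(target$residues)
    ok[ok] <- is_allowed_pair(res[mi[ok]], res[mj[ok]])
  }
  partner <- integer(nchar(target$residues))
  partner[mi[ok]] <- mj[ok]
  partner[mj[ok]] <- mi[ok]
  structure(list(target = structured_seq(target, pair_table(partner)),
                 template_id = template$record$id,
                 transfer_pct = 100 * sum(ok) / npair,
                 alignment = list(template = pw$a, target = pw$b,
                                  score = pw$score)),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result> %s <- template %s: %.1f%% of pairs transferred\n",
              x$target$record$id, x$template_id, x$transfer_pct))
  invisible(x)
}

#' Structural homology of a structured record to a template
#'
#' For records that already carry a structure (e.g. curated or simulated
#' datasets), the homology score is the percentage of template base pairs
#' whose endpoints co-align with positions that are also paired with each
#' other in the record's own structure — the agreement between the record's
#' structure and the template, measured through the same global alignment
#' used for transfer.
#'
#' @param template a [structured_seq()] with pairs.
#' @param target a [structured_seq()] carrying its own structure.
#' @param params a [transfer_params()].
#' @return A `transfer_result` whose `transfer_pct` is the homology
#'   percentage and whose `target` is the record unchanged.
#' @export
structural_homology <- function(template, target, params = transfer_params()) {
  stopifnot(inherits(template, "structured_seq"),
            inherits(target, "structured_seq"))
  if (n_pairs(template$pairs) == 0L)
    abort_fmt("rnaphylo_invalid", "template '%s' has no pairs",
              template$record$id)
  sm <- nucleotide_score_matrix(params$match, params$mismatch)
  pw <- pairwise_align(template$record$residues, target$record$residues, sm,
                       params$gap_open, params$gap_extend)
  ca <- chars(pw$a)
  cb <- chars(pw$b)
  tpos <- cumsum(ca != "-")
  gpos <- cumsum(cb != "-")
  map <- rep(NA_integer_, nchar(template$record$residues))
  hit <- ca != "-" & cb != "-"
  map[tpos[hit]] <- gpos[hit]
  pct <- 100 * shared_pair_fraction(template, target, map)
  structure(list(target = target, template_id = template$record$id,
                 transfer_pct = pct,
                 alignment = list(template = pw$a, target = pw$b,
                                  score = pw$score)),
            class = "transfer_result")
}

#' Best template for a target
#'
#' Runs [transfer_structure()] against every template in the library and
#' returns the result with maximal transfer percentage; exact ties go to the
#' earlier template in library order.
#'
#' @param library list of [structured_seq()] templates (nonempty, each with
#'   pairs).
#' @inheritParams transfer_structure
#' @return A `transfer_result`.
#' @export
best_template <- function(library, target, params = transfer_params(),
                          require_pairable = TRUE) {
  if (!length(library))
    abort_fmt("rnaphylo_invalid", "template library is empty")
  best <- NULL
  for (tm in library) {
    res <- transfer_structure(tm, target, params, require_pairable)
    if (is.null(best) || res$transfer_pct > best$transfer_pct) best <- res
  }
  best
}

#' Curation filter configuration
#'
#' @param min_length minimum ungapped sequence length (nt).
#' @param min_transfer_pct records strictly below this transfer percentage
#'   are discarded (a record exactly at the threshold is kept).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_length = 0L, min_transfer_pct = 0) {
  stopifnot(min_transfer_pct >= 0, min_transfer_pct <= 100, min_length >= 0)
  structure(list(min_length = as.integer(min_length),
                 min_transfer_pct = min_transfer_pct),
            class = "filter_config")
}

#' Filter a dataset on length and structural transfer
#'
#' The length check applies first: records shorter than `cfg$min_length` are
#' discarded as `"too short"` (and need no transfer result). Of the
#' remaining records, those with transfer percentage strictly below
#' `cfg$min_transfer_pct` are discarded as `"low transfer"`. Input order is
#' preserved on both sides.
#'
#' @param records list of [seq_record()] (or structured_seq).
#' @param results named list of `transfer_result` keyed by record id; only
#'   consulted for records that pass the length check.
#' @param cfg a [filter_config()].
#' @return List with `kept` (record ids), `discarded` (data.frame `id`,
#'   `reason`), and `table` (data.frame `id`, `length`, `transfer_pct`,
#'   `status`, `reason` mirroring a curation supplement).
#' @export
filter_dataset <- function(records, results, cfg) {
  ids <- vapply(records, function(r)
    if (inherits(r, "structured_seq")) r$record$id else r$id, character(1))
  lens <- vapply(records, function(r) {
    res <- if (inherits(r, "structured_seq")) r$record$residues else r$residues
    nchar(res)
  }, integer(1))
  status <- character(length(ids))
  reason <- rep(NA_character_, length(ids))
  pct <- rep(NA_real_, length(ids))
  for (k in seq_along(ids)) {
    if (lens[k] < cfg$min_length) {
      status[k] <- "discarded"
      reason[k] <- "too short"
      next
    }
    res <- results[[ids[k]]]
    if (is.null(res))
      abort_fmt("rnaphylo_invalid",
                "no transfer result for record '%s' passing the length check",
                ids[k])
    pct[k] <- res$transfer_pct
    if (res$transfer_pct < cfg$min_transfer_pct) {
      status[k] <- "discarded"
      reason[k] <- "low transfer"
    } else status[k] <- "kept"
  }
  tab <- data.frame(id = ids, length = lens, transfer_pct = pct,
                    status = status, reason = reason,
                    stringsAsFactors = FALSE)
  list(kept = ids[status == "kept"],
       discarded = tab[status == "discarded", c("id", "reason")],
       table = tab)
}

#' Write transfer results as a TSV curation table
#'
#' Columns: id, template_id, transfer_pct, reason (empty for kept records).
#'
#' @param table the `table` element of [filter_dataset()].
#' @param results named list of `transfer_result` by id.
#' @param path output path.
#' @export
write_transfer_tsv <- function(table, results, path) {
  template <- vapply(table$id, function(id) {
    r <- results[[id]]
    if (is.null(r)) NA_character_ else r$template_id
  }, character(1))
  out <- data.frame(id = table$id, template_id = template,
                    transfer_pct = ifelse(is.na(table$transfer_pct), "",
                                          sprintf("%.2f", table$transfer_pct)),
                    reason = ifelse(is.na(table$reason), "", table$reason),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
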