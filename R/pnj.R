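## Iterated profile neighbor joining (PNJ).  Well-supported clades are
## collapsed into frequency profiles ("super-profiles" when profiles merge),
## distances between units are generalized p distances between column
## frequency vectors, and after the final iteration each profile is expanded
## back to the NJ subtree it had when collapsed.  Profile support values are
## transferred from a bootstrap of the sequence-level overview NJ tree.

#' PNJ configuration
#'
#' @param bootstrap_replicates pseudo-replicates per iteration (default 100).
#' @param collapse_threshold collapse clades with support strictly greater
#'   than this (default 75).
#' @param iterations collapse iterations (default 3).
#' @param initial_profiles optional named list of row-id vectors: manual
#'   starting profiles (must be disjoint).
#' @param seed integer seed (required; drives every resampling).
#' @return List of class `pnj_config`.
#' @export
pnj_config <- function(bootstrap_replicates = 100L, collapse_threshold = 75,
                       iterations = 3L, initial_profiles = NULL, seed) {
  if (missing(seed)) abort_fmt("rnaphylo_invalid", "seed is required")
  stopifnot(collapse_threshold >= 0, collapse_threshold <= 100,
            iterations >= 1L, bootstrap_replicates >= 1L)
  if (!is.null(initial_profiles)) {
    all_ids <- unlist(initial_profiles)
    if (anyDuplicated(all_ids))
      abort_fmt("rnaphylo_invalid", "initial profiles overlap on '%s'",
                all_ids[duplicated(all_ids)][1])
    if (is.null(names(initial_profiles)))
      names(initial_profiles) <- paste0("P", seq_along(initial_profiles))
  }
  structure(list(bootstrap_replicates = as.integer(bootstrap_replicates),
                 collapse_threshold = collapse_threshold,
                 iterations = as.integer(iterations),
                 initial_profiles = initial_profiles,
                 seed = as.integer(seed)),
            class = "pnj_config")
}

## generalized p distance between two units from 13-symbol frequency
## matrices (12 letters + gap): columns where either unit has gap frequency
## > 0.5 are excluded; p = mean over used columns of 1 - sum_k f1k * f2k
unit_p_distance <- function(f1, f2) {
  gap1 <- f1[, ncol(f1)]
  gap2 <- f2[, ncol(f2)]
  use <- gap1 <= 0.5 & gap2 <= 0.5
  if (!any(use))
    abort_fmt("rnaphylo_undefined", "no usable columns between units")
  mean(1 - rowSums(f1[use, , drop = FALSE] * f2[use, , drop = FALSE]))
}

unit_freqs <- function(rows, letters) profile_freqs(unname(rows), letters)

unit_dist_matrix <- function(units, aln, letters, method, col_idx = NULL) {
  rowsets <- lapply(units, function(u) {
    r <- unclass(aln)[u$ids]
    if (!is.null(col_idx)) {
      m <- do.call(rbind, strsplit(r, "", fixed = TRUE))
      r <- apply(m[, col_idx, drop = FALSE], 1L, paste, collapse = "")
    }
    r
  })
  fr <- lapply(rowsets, unit_freqs, letters = letters)
  n <- length(units)
  labs <- vapply(units, function(u) u$label, character(1))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- unit_p_distance(fr[[i]], fr[[j]])
    d[i, j] <- d[j, i] <- if (method == "jc12") jc12(p, cap = TRUE) else p
  }
  dist_matrix(d)
}

## maximal ("outermost-first") clades of `tree` with support > threshold
collapsible_clades <- function(tree, support, threshold) {
  ntip <- length(tree$tip.label)
  cl <- list()
  good <- as.integer(names(support)[support > threshold])
  if (!length(good)) return(cl)
  sets <- lapply(good, function(nd)
    tree$tip.label[ape::prop.part(tree)[[nd - ntip]]])
  ## keep only sets not contained in another good set (outermost first)
  keep <- vapply(seq_along(sets), function(a)
    !any(vapply(seq_along(sets), function(b)
      b != a && all(sets[[a]] %in% sets[[b]]) &&
        length(sets[[b]]) > length(sets[[a]]), logical(1))), logical(1))
  sets[keep]
}

## newick fragment (with branch lengths) of the clade below `labels` in
## `tree`, leaves labelled by unit labels
clade_fragment <- function(tree, labels) {
  sub <- ape::keep.tip(tree, labels)
  txt <- write_newick(sub)
  sub("^\\(", "(", sub(";$", "", txt))
}

#' Iterated profile neighbor joining
#'
#' Each iteration builds an NJ tree on the current units (sequences and
#' profiles), bootstraps it, and collapses every maximal clade whose support
#' strictly exceeds the threshold into a profile whose columns are member
#' frequency vectors; profiles caught in a later collapse merge into
#' super-profiles. Unit-to-unit distances are generalized p distances over
#' the 13-symbol frequency vectors (columns with gap frequency above one
#' half in either unit are skipped), corrected by the chosen method. After
#' the final iteration the tree over units is expanded: each profile is
#' replaced by the NJ subtree it had when collapsed, and its support is the
#' bootstrap value of the matching clade in the sequence-level overview NJ
#' tree.
#'
#' @param aln alignment (named character vector of gapped rows).
#' @param cfg a [pnj_config()].
#' @param dist_method `"jc12"` (default) or `"p"`.
#' @param letters encoded alphabet (12 letters; gap handled internally).
#' @return List with `tree` (expanded `phylo` with supports), `profiles`
#'   (member ids and transferred support per profile), `overview` (the
#'   bootstrapped sequence-level NJ result), and `unit_tree` (final tree
#'   over collapsed units).
#' @export
profile_nj <- function(aln, cfg, dist_method = c("jc12", "p"),
                       letters = encoding_table()$letters) {
  dist_method <- match.arg(dist_method)
  aln <- as_alignment(aln)
  ids <- names(aln)
  ## overview: sequence-level NJ + bootstrap (source of profile supports)
  overview <- bootstrap_support(aln, nj_builder(dist_method),
                                B = cfg$bootstrap_replicates,
                                seed = derive_seed(cfg$seed, 1L))
  overview_keys <- bipartitions(ape::unroot(overview$tree))
  overview_supp <- setNames(overview$support[names(overview_keys)],
                            overview_keys)

  units <- lapply(ids, function(id) list(label = id, ids = id, fragment = id))
  names(units) <- ids
  profiles <- list()
  pcount <- 0L
  if (!is.null(cfg$initial_profiles)) {
    for (nm in names(cfg$initial_profiles)) {
      member <- cfg$initial_profiles[[nm]]
      if (!all(member %in% ids))
        abort_fmt("rnaphylo_lookup", "initial profile '%s' names unknown rows", nm)
      pcount <- pcount + 1L
      ## manual profiles have no collapse-time subtree; expand as a star
      frag <- sprintf("(%s)", paste(sprintf("%s:0", member), collapse = ","))
      units <- units[setdiff(names(units), member)]
      units[[nm]] <- list(label = nm, ids = member, fragment = frag)
      profiles[[nm]] <- list(label = nm, members = member, fragment = frag)
    }
  }

  for (it in seq_len(cfg$iterations)) {
    if (length(units) < 3L)
      abort_fmt("rnaphylo_degenerate",
                "profiles cover (almost) all rows; cannot iterate NJ on %d units",
                length(units))
    D <- unit_dist_matrix(units, aln, letters, dist_method)
    utree <- neighbor_joining(D)
    ## bootstrap over columns, rebuilding unit distances per replicate
    L <- nchar(aln[[1]])
    idx_mat <- with_seed(derive_seed(cfg$seed, 10L + it),
                         matrix(sample.int(L, L * cfg$bootstrap_replicates,
                                           replace = TRUE),
                                nrow = cfg$bootstrap_replicates))
    ref_bip <- bipartitions(ape::unroot(utree))
    counts <- setNames(rep(0L, length(ref_bip)), names(ref_bip))
    dropped <- 0L
    for (b in seq_len(cfg$bootstrap_replicates)) {
      tr <- tryCatch(
        neighbor_joining(unit_dist_matrix(units, aln, letters, dist_method,
                                          col_idx = idx_mat[b, ])),
        rnaphylo_error = function(cond) NULL)
      if (is.null(tr)) { dropped <- dropped + 1L; next }
      hit <- ref_bip %in% bipartitions(ape::unroot(tr))
      counts[hit] <- counts[hit] + 1L
    }
    B_eff <- cfg$bootstrap_replicates - dropped
    if (B_eff < 1L)
      abort_fmt("rnaphylo_numeric", "all PNJ bootstrap replicates failed")
    supp <- as.integer(round(100 * counts / B_eff))
    names(supp) <- names(ref_bip)
    ## collapse maximal clades with support strictly > threshold
    clades <- collapsible_clades(utree, setNames(supp, names(ref_bip)),
                                 cfg$collapse_threshold)
    for (cl in clades) {
      if (length(cl) >= length(units))
        abort_fmt("rnaphylo_degenerate", "collapse would swallow every unit")
      pcount <- pcount + 1L
      plab <- paste0("P", pcount)
      frag <- clade_fragment(utree, cl)
      members <- unlist(lapply(units[cl], function(u) u$ids), use.names = FALSE)
      units <- units[setdiff(names(units), cl)]
      units[[plab]] <- list(label = plab, ids = members, fragment = frag)
      profiles[[plab]] <- list(label = plab, members = members, fragment = frag)
    }
  }

  ## final tree over units + expansion
  if (length(units) < 2L)
    abort_fmt("rnaphylo_degenerate", "fewer than 2 units after collapsing")
  D <- unit_dist_matrix(units, aln, letters, dist_method)
  final_units <- neighbor_joining(D)
  ## bootstrap supports for the final unit tree
  fb <- bootstrap_support(aln, function(a) {
    neighbor_joining(unit_dist_matrix(units, a, letters, dist_method))
  }, B = cfg$bootstrap_replicates, seed = derive_seed(cfg$seed, 99L),
  reference = final_units)
  unit_tree <- fb$tree

  ## transferred support per profile from the overview bootstrap
  for (nm in names(profiles)) {
    key <- split_key(profiles[[nm]]$members, ids)
    profiles[[nm]]$support <-
      if (key %in% names(overview_supp)) unname(overview_supp[[key]]) else NA_integer_
  }

  ## expand profiles (newest first, so nested profile labels resolve)
  nwk <- write_newick(unit_tree)
  for (nm in rev(names(profiles))) {
    pr <- profiles[[nm]]
    sup <- if (is.na(pr$support)) "" else as.character(pr$support)
    repl <- sprintf("%s%s", pr$fragment, sup)
    nwk <- sub(paste0("(?<![A-Za-z0-9_])", nm, "(?![A-Za-z0-9_])"),
               repl, nwk, perl = TRUE)
  }
  tree <- read_newick(nwk)
  list(tree = tree, profiles = profiles, overview = overview,
       unit_tree = unit_tree, final_units = units)
}
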