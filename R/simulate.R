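## Seeded synthetic structured-sequence datasets with known ground truth:
## Yule trees, random nested structures, 12-state sequence evolution with a
## conserved structure and optional compensatory pair substitutions, and
## curation-style defect injection (truncation, structure rewiring).

#' Simulate a pure-birth (Yule) tree
#'
#' Waiting times between successive splits are exponential with rate
#' `k * birth_rate` while `k` lineages exist; after the n-th lineage is born
#' a final waiting interval is appended so tips are contemporaneous. Leaves
#' are labelled `T1..Tn`.
#'
#' @param n number of tips (>= 2).
#' @param birth_rate speciation rate (per lineage per unit time).
#' @param seed integer seed.
#' @return An `ape::phylo`, ultrametric, rooted.
#' @export
simulate_yule_tree <- function(n, birth_rate = 1, seed) {
  stopifnot(n >= 2L, birth_rate > 0)
  if (missing(seed)) abort_fmt("rnaphylo_invalid", "seed is required")
  with_seed(derive_seed(seed, 7L), {
    ## grow lineages; track birth time of each active lineage tip
    parent <- integer(0)
    birth <- numeric(0)
    ## active lineages indexed into node table; node 1 = root
    n_nodes <- 1L
    active <- 1L
    birth_t <- c(0)
    t_now <- 0
    children <- vector("list", 1L)
    while (length(active) < n) {
      k <- length(active)
      t_now <- t_now + rexp(1L, rate = k * birth_rate)
      who <- active[sample.int(k, 1L)]
      kid1 <- n_nodes + 1L
      kid2 <- n_nodes + 2L
      n_nodes <- n_nodes + 2L
      children[[who]] <- c(kid1, kid2)
      children[[kid1]] <- integer(0)
      children[[kid2]] <- integer(0)
      birth_t[kid1] <- birth_t[kid2] <- t_now
      active <- c(setdiff(active, who), kid1, kid2)
    }
    t_now <- t_now + rexp(1L, rate = n * birth_rate)
    ## build newick: leaf labels T1..Tn in order of leaf creation
    leaf_no <- 0L
    build <- function(v) {
      if (!length(children[[v]])) {
        leaf_no <<- leaf_no + 1L
        sprintf("T%d", leaf_no)
      } else {
        kids <- vapply(children[[v]], function(k) {
          end_t <- if (length(children[[k]])) birth_t[children[[k]][1L]] else t_now
          sprintf("%s:%s", build(k), fmt_bl(end_t - birth_t[k]))
        }, character(1))
        sprintf("(%s)", paste(kids, collapse = ","))
      }
    }
    nwk <- if (length(children[[1L]])) paste0(build(1L), ";") else "(T1);"
    read_newick(nwk)
  })
}

#' Simulate a random nested secondary structure with its sequence
#'
#' Draws exactly `floor(pair_fraction * length)` nested base pairs (hairpin
#' loops of at least 3 nt are respected), then samples residues: paired
#' positions get a canonical or wobble pair (GC/CG/AU/UA twice as likely as
#' GU/UG), unpaired positions a uniform nucleotide.
#'
#' @param length sequence length (nt).
#' @param pair_fraction fraction of positions that open a pair, in
#'   `[0, 0.5]`.
#' @param seed integer seed.
#' @param id record id.
#' @return A [structured_seq()] (strict-mode valid).
#' @export
simulate_root_structure <- function(length, pair_fraction = 0.25, seed,
                                    id = "root") {
  stopifnot(length >= 1L, pair_fraction >= 0, pair_fraction <= 0.5)
  if (missing(seed)) abort_fmt("rnaphylo_invalid", "seed is required")
  target <- floor(pair_fraction * length)
  with_seed(derive_seed(seed, 11L), {
    ## helix-biased growth: mostly stack onto existing pairs (as real rRNA
    ## helices do), occasionally open a new helix; restart on the rare
    ## deadlock, declare the count infeasible after repeated failures
    draw_structure <- function() {
      partner <- integer(length)
      made <- 0L
      n_helices <- 0L
      ## every helix costs >= 3 unpaired loop nt plus spacing, so the
      ## unpaired budget bounds how many separate helices can be opened
      max_helices <- max(1L, (length - 2L * target) %/% 5L)
      while (made < target) {
        placed <- FALSE
        want_new <- n_helices < max_helices &&
          (made == 0L || runif(1L) < 0.2)
        if (made > 0L && !want_new) {
          op <- which(partner > seq_len(length))
          js <- partner[op]
          ## stack inward: (i+1, j-1), keeping the closed loop >= 3 nt
          ok_in <- partner[op + 1L] == 0L & partner[js - 1L] == 0L &
            (js - op - 2L > 3L | vapply(seq_along(op), function(k)
              any(partner[(op[k] + 1L):(js[k] - 1L)] > 0L), logical(1)))
          ## stack outward: (i-1, j+1); always nesting-safe when both
          ## flanking positions exist and are unpaired
          ok_out <- op > 1L & js < length & partner[pmax(op - 1L, 1L)] == 0L &
            partner[pmin(js + 1L, length)] == 0L
          moves <- rbind(cbind(op + 1L, js - 1L)[ok_in, , drop = FALSE],
                         cbind(op - 1L, js + 1L)[ok_out, , drop = FALSE])
          if (nrow(moves)) {
            k <- sample.int(nrow(moves), 1L)
            partner[moves[k, 1L]] <- moves[k, 2L]
            partner[moves[k, 2L]] <- moves[k, 1L]
            made <- made + 1L
            placed <- TRUE
          }
        }
        if (!placed) {
          pool <- which(partner == 0L)
          while (base::length(pool)) {
            i <- pool[sample.int(base::length(pool), 1L)]
            js <- valid_partners(partner, i, min_loop = 3L)
            if (base::length(js)) {
              j <- js[sample.int(base::length(js), 1L)]
              partner[i] <- j
              partner[j] <- i
              made <- made + 1L
              n_helices <- n_helices + 1L
              placed <- TRUE
              break
            }
            pool <- pool[pool != i]
          }
        }
        if (!placed) return(NULL)
      }
      partner
    }
    partner <- NULL
    for (attempt in 1:50) {
      partner <- draw_structure()
      if (!is.null(partner)) break
    }
    if (is.null(partner))
      abort_fmt("rnaphylo_invalid",
                "cannot place %d pairs in %d nt (infeasible pair count)",
                target, length)
    pt <- pair_table(partner)
    res <- character(length)
    unp <- which(partner == 0L)
    res[unp] <- sample(NUCS, base::length(unp), replace = TRUE)
    pr <- pairs_of(pt)
    if (nrow(pr)) {
      kinds <- sample(ALLOWED_PAIRS, nrow(pr), replace = TRUE,
                      prob = c(2, 2, 2, 2, 1, 1))
      res[pr[, 1L]] <- substr(kinds, 1L, 1L)
      res[pr[, 2L]] <- substr(kinds, 2L, 2L)
    }
    structured_seq(seq_record(id, paste(res, collapse = "")), pt, strict = TRUE)
  })
}

## unpaired positions j that can pair with i without crossing an existing
## pair and with at least `min_loop` nt between them: scan outward from i,
## stopping where the enclosing region ends
valid_partners <- function(partner, i, min_loop = 3L) {
  L <- base::length(partner)
  out <- integer(0)
  ## rightward: skip over complete sub-helices; stop at a closing partner
  j <- i + 1L
  while (j <= L) {
    p <- partner[j]
    if (p == 0L) {
      if (j - i > min_loop) out <- c(out, j)
      j <- j + 1L
    } else if (p > j) {
      j <- p + 1L  # jump over the nested helix
    } else break    # closing bracket of an enclosing pair: region ends
  }
  ## leftward, symmetric
  j <- i - 1L
  while (j >= 1L) {
    p <- partner[j]
    if (p == 0L) {
      if (i - j > min_loop) out <- c(out, j)
      j <- j - 1L
    } else if (p < j) {
      j <- p - 1L
    } else break
  }
  out
}

## one substitution event: new nucleotide uniform among the other three
sub_event <- function(cur) sample(setdiff(NUCS, cur), 1L)

## partner residue restoring an allowed pair with `nuc`
compensating_partner <- function(nuc) {
  switch(nuc, A = "U", U = sample(c("A", "G"), 1L),
         G = sample(c("C", "U"), 1L), C = "G")
}

#' Evolve sequences along a tree under a conserved structure
#'
#' The root structure is held fixed across the whole tree (every taxon
#' shares the root pair table); residues evolve site-independently by a
#' jump process with one expected substitution per site per unit branch
#' length, restricted to the site's structural state (a paired site stays
#' paired). At paired sites, each substitution is compensated with
#' probability `c`: the partner is immediately replaced by a residue
#' restoring a canonical or wobble pair.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param root a [structured_seq()] (the template/ancestral structure).
#' @param c compensation probability in `[0, 1]`.
#' @param rate substitutions per site per unit branch length (default 1).
#' @param seed integer seed.
#' @return Named list of [structured_seq()], one per tip (tip-label order).
#' @export
evolve_alignment <- function(tree, root, c = 1, rate = 1, seed) {
  stopifnot(inherits(root, "structured_seq"), c >= 0, c <= 1, rate >= 0)
  if (missing(seed)) abort_fmt("rnaphylo_invalid", "seed is required")
  L <- base::length(root$pairs)
  pr <- pairs_of(root$pairs)
  open_i <- pr[, 1L]
  unp <- which(unclass(root$pairs) == 0L)
  with_seed(derive_seed(seed, 13L), {
    tr <- ape::reorder.phylo(tree, "cladewise")
    ntip <- base::length(tr$tip.label)
    rootn <- ntip + 1L
    seqs <- vector("list", max(tr$edge))
    seqs[[rootn]] <- chars(root$record$residues)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]
      kid <- tr$edge[e, 2L]
      t <- tr$edge.length[e] * rate
      cur <- seqs[[par]]
      if (t > 0) {
        ## unpaired sites: Poisson number of uniform jumps
        nev <- stats::rpois(base::length(unp), t)
        for (kx in which(nev > 0L)) {
          pos <- unp[kx]
          for (dummy in seq_len(nev[kx])) cur[pos] <- sub_event(cur[pos])
        }
        ## paired sites: joint jump process on the pair; the event rate is
        ## normalized by (1 + c) so compensation does not inflate the
        ## expected per-site substitution rate
        nev2 <- stats::rpois(base::length(open_i), 2 * t / (1 + c))
        for (kx in which(nev2 > 0L)) {
          i <- open_i[kx]; j <- pr[kx, 2L]
          for (dummy in seq_len(nev2[kx])) {
            if (runif(1L) < 0.5) {
              cur[i] <- sub_event(cur[i])
              if (runif(1L) < c) cur[j] <- compensating_partner(cur[i])
            } else {
              cur[j] <- sub_event(cur[j])
              if (runif(1L) < c) cur[i] <- compensating_partner(cur[j])
            }
          }
        }
      }
      seqs[[kid]] <- cur
    }
    out <- lapply(seq_len(ntip), function(tp)
      structured_seq(seq_record(tr$tip.label[tp],
                                paste(seqs[[tp]], collapse = "")),
                     root$pairs))
    names(out) <- tr$tip.label
    out
  })
}

#' Inject curation-style defects into a dataset
#'
#' A seeded random `frac_short` of the records is truncated to
#' `short_factor` of its length; a disjoint `frac_structure_noise` fraction
#' has `noise_pair_rewire_fraction` of its base pairs rewired (structure
#' scrambled, sequence untouched). Counts are `round(frac * n)`.
#'
#' @param records named list of [structured_seq()].
#' @param frac_short,short_factor truncation fraction of records and kept
#'   length fraction per truncated record.
#' @param frac_structure_noise,noise_pair_rewire_fraction structure-noise
#'   fraction of records and fraction of pairs rewired per noisy record.
#' @param seed integer seed.
#' @return List with `records` (modified, same order/names) and `truth`
#'   (data.frame `id`, `defect` in `none`/`short`/`structure_noise`).
#' @export
degrade_dataset <- function(records, frac_short = 0, short_factor = 0.5,
                            frac_structure_noise = 0,
                            noise_pair_rewire_fraction = 0.5, seed) {
  stopifnot(frac_short >= 0, frac_short <= 1, frac_structure_noise >= 0,
            frac_structure_noise <= 1, short_factor > 0, short_factor <= 1,
            noise_pair_rewire_fraction >= 0, noise_pair_rewire_fraction <= 1)
  if (frac_short + frac_structure_noise > 1)
    abort_fmt("rnaphylo_invalid", "defect fractions sum to more than 1")
  if (missing(seed)) abort_fmt("rnaphylo_invalid", "seed is required")
  n <- base::length(records)
  ids <- vapply(records, function(s) s$record$id, character(1))
  n_short <- round(frac_short * n)
  n_noise <- round(frac_structure_noise * n)
  with_seed(derive_seed(seed, 17L), {
    perm <- sample.int(n)
    short_idx <- perm[seq_len(n_short)]
    noise_idx <- perm[n_short + seq_len(n_noise)]
    out <- records
    for (k in short_idx) {
      keep <- max(1L, floor(short_factor * base::length(out[[k]]$pairs)))
      out[[k]] <- truncate_structured(out[[k]], keep)
    }
    for (k in noise_idx) {
      out[[k]] <- rewire_pairs(out[[k]], noise_pair_rewire_fraction)
    }
    defect <- rep("none", n)
    defect[short_idx] <- "short"
    defect[noise_idx] <- "structure_noise"
    list(records = out,
         truth = data.frame(id = ids, defect = defect, stringsAsFactors = FALSE))
  })
}

## scramble a fraction of the pairs: remove them, then re-pair the freed
## positions among themselves in a random (nested) way elsewhere
rewire_pairs <- function(s, fraction) {
  pr <- pairs_of(s$pairs)
  if (!nrow(pr) || fraction == 0) return(s)
  nmove <- max(1L, round(fraction * nrow(pr)))
  sel <- sample.int(nrow(pr), nmove)
  partner <- unclass(s$pairs)
  freed <- as.vector(pr[sel, , drop = FALSE])
  partner[freed] <- 0L
  ## re-pair freed positions with random valid partners, keeping nesting
  for (i in sample(freed)) {
    if (partner[i] != 0L) next
    js <- setdiff(valid_partners(partner, i, min_loop = 3L), freed[freed == i])
    ## prefer partners that change the structure (not the original partner)
    js <- setdiff(js, unclass(s$pairs)[i])
    if (!base::length(js)) next
    j <- js[sample.int(base::length(js), 1L)]
    partner[i] <- j
    partner[j] <- i
  }
  structured_seq(s$record, pair_table(partner))
}

#' Generate a complete synthetic study dataset
#'
#' Convenience wrapper tying the generator together: Yule tree, root
#' structure, evolution with conserved structure, and defect injection.
#'
#' @param n_taxa,seq_length,birth_rate,pair_fraction tree and structure
#'   parameters.
#' @param c compensation probability (default 1: structure-conserving).
#' @param rate substitutions per site per unit branch length.
#' @param frac_short,short_factor,frac_structure_noise,noise_pair_rewire_fraction
#'   defect parameters (see [degrade_dataset()]).
#' @param seed integer seed (required).
#' @return List with `tree`, `root`, `clean` (undegraded records),
#'   `records` (degraded), `truth` (defect table).
#' @export
simulate_dataset <- function(n_taxa = 8L, seq_length = 1500L, birth_rate = 1,
                             pair_fraction = 0.25, c = 1, rate = 0.25,
                             frac_short = 0, short_factor = 0.5,
                             frac_structure_noise = 0,
                             noise_pair_rewire_fraction = 0.5, seed) {
  if (missing(seed)) abort_fmt("rnaphylo_invalid", "seed is required")
  tree <- simulate_yule_tree(n_taxa, birth_rate, seed = derive_seed(seed, 1L))
  root <- simulate_root_structure(seq_length, pair_fraction,
                                  seed = derive_seed(seed, 2L))
  clean <- evolve_alignment(tree, root, c = c, rate = rate,
                            seed = derive_seed(seed, 3L))
  deg <- degrade_dataset(clean, frac_short, short_factor,
                         frac_structure_noise, noise_pair_rewire_fraction,
                         seed = derive_seed(seed, 4L))
  list(tree = tree, root = root, clean = clean, records = deg$records,
       truth = deg$truth)
}
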