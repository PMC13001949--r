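## Pipeline orchestration: each stage reads standard files, writes standard
## files plus a JSON manifest echoing configuration (encoding table,
## thresholds, seeds) and reconciled record counts, so runs are
## self-describing and reproducible.

pkg_version <- function() as.character(utils::packageVersion("rnaphylo"))

manifest_skeleton <- function(stage, config, inputs = character(0)) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(tool = "rnaphylo", version = pkg_version(), stage = stage,
       config = config, input_md5 = sums,
       encoding = as.list(setNames(encoding_table()$letters,
                                   paste(rep(STATES, each = 4L),
                                         rep(NUCS, 3L), sep = "_"))))
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read / write encoded sequences as FASTA-like files
#'
#' Encoded (12-letter) sequences use amino-acid codes, so they bypass the
#' nucleotide validation of [read_fasta()].
#'
#' @param path file path.
#' @return Named character vector of letter strings (gapped rows allowed).
#' @export
read_encoded_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(cond)
                    abort_fmt("rnaphylo_format", "malformed FASTA '%s': %s",
                              path, conditionMessage(cond)))
  ids <- vapply(strsplit(trimws(names(set)), "[ \t]+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    abort_fmt("rnaphylo_format", "duplicate record id '%s'",
              ids[duplicated(ids)][1])
  setNames(toupper(as.character(set)), ids)
}

#' @param seqs named character vector (or list of `encoded_seq`).
#' @rdname read_encoded_fasta
#' @export
write_encoded_fasta <- function(seqs, path) {
  if (is.list(seqs))
    seqs <- setNames(vapply(seqs, function(s) s$letters, character(1)),
                     vapply(seqs, function(s) s$id, character(1)))
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}

#' Homology-modeling pipeline stage
#'
#' Reads targets (FASTA) and templates (Vienna), predicts each target's
#' structure from its best template, applies the length and transfer
#' filters, and writes predicted structures (Vienna), a curation TSV and a
#' manifest.
#'
#' @param fasta path to target sequences (FASTA).
#' @param templates path to the template library (multi-record Vienna).
#' @param min_length,min_transfer curation thresholds (see
#'   [filter_config()]).
#' @param out_dir output directory (created if needed).
#' @param params [transfer_params()].
#' @return The manifest (invisibly written to `manifest.json`).
#' @export
pipeline_model <- function(fasta, templates, min_length = 0L,
                           min_transfer = 0, out_dir = ".",
                           params = transfer_params()) {
  records <- read_fasta(fasta)
  lib <- read_vienna(templates)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- filter_config(min_length, min_transfer)
  results <- list()
  for (r in records) {
    if (nchar(r$residues) < cfg$min_length) next
    results[[r$id]] <- best_template(lib, r, params)
  }
  flt <- filter_dataset(records, results, cfg)
  kept_structs <- lapply(flt$kept, function(id) results[[id]]$target)
  write_vienna(kept_structs, file.path(out_dir, "structures.vienna"))
  write_transfer_tsv(flt$table, results, file.path(out_dir, "transfer.tsv"))
  counts <- list(compiled = length(records),
                 discarded_short = sum(flt$table$reason %in% "too short"),
                 discarded_low_transfer = sum(flt$table$reason %in% "low transfer"),
                 retained = length(flt$kept))
  stopifnot(counts$compiled == counts$retained + counts$discarded_short +
              counts$discarded_low_transfer)
  manifest <- manifest_skeleton("model",
                                list(min_length = cfg$min_length,
                                     min_transfer_pct = cfg$min_transfer_pct,
                                     align = unclass(params)),
                                c(fasta, templates))
  manifest$counts <- counts
  manifest$outputs <- list(structures = file.path(out_dir, "structures.vienna"),
                           table = file.path(out_dir, "transfer.tsv"))
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Encode pipeline stage: Vienna structures to 12-letter FASTA
#'
#' @param vienna path to structures (Vienna).
#' @param out output FASTA path.
#' @return Output path, invisibly.
#' @export
pipeline_encode <- function(vienna, out) {
  ss <- read_vienna(vienna)
  enc <- encode_all(ss, n_action = "X")
  write_encoded_fasta(enc, out)
  invisible(out)
}

#' Alignment pipeline stage: encoded FASTA to aligned encoded FASTA
#'
#' @param encoded_fasta path to unaligned encoded sequences.
#' @param out output path.
#' @inheritParams progressive_msa
#' @return Output path, invisibly.
#' @export
pipeline_align <- function(encoded_fasta, out, scores = default_score_matrix(),
                           gap_open = 6, gap_extend = 1) {
  seqs <- read_encoded_fasta(encoded_fasta)
  aln <- progressive_msa(seqs, scores, gap_open, gap_extend)
  write_encoded_fasta(unclass(aln), out)
  invisible(out)
}

#' Tree-inference pipeline stage
#'
#' @param aligned_fasta path to an aligned encoded FASTA.
#' @param method `"nj"`, `"pnj"`, `"mp"` or `"ml"`.
#' @param dist distance method for nj/pnj (`"p"`, `"jc12"`).
#' @param bootstrap pseudo-replicates for nj support / pnj iterations.
#' @param seed integer seed (required for bootstrap/pnj).
#' @param outgroup optional outgroup tip labels for rooting.
#' @param out output Newick path.
#' @param iterations,collapse_threshold PNJ settings.
#' @return Manifest, invisibly; the tree is written to `out`.
#' @export
pipeline_tree <- function(aligned_fasta, method = c("nj", "pnj", "mp", "ml"),
                          dist = "jc12", bootstrap = 100L, seed = 1L,
                          outgroup = NULL, out = "tree.nwk",
                          iterations = 3L, collapse_threshold = 75) {
  method <- match.arg(method)
  aln <- as_alignment(read_encoded_fasta(aligned_fasta))
  tree <- switch(method,
    nj = {
      bs <- bootstrap_support(aln, nj_builder(dist), B = bootstrap, seed = seed)
      bs$tree
    },
    pnj = {
      cfg <- pnj_config(bootstrap_replicates = bootstrap,
                        collapse_threshold = collapse_threshold,
                        iterations = iterations, seed = seed)
      profile_nj(aln, cfg, dist_method = dist)$tree
    },
    mp = mp_search(aln)$tree,
    ml = ml_search(aln)$tree)
  if (!is.null(outgroup)) tree <- root_with_outgroup(tree, outgroup)
  writeLines(write_newick(tree), out)
  manifest <- manifest_skeleton("tree",
                                list(method = method, dist = dist,
                                     bootstrap = bootstrap, seed = seed,
                                     iterations = iterations,
                                     collapse_threshold = collapse_threshold,
                                     outgroup = outgroup),
                                aligned_fasta)
  manifest$outputs <- list(tree = out)
  write_manifest(manifest, paste0(out, ".manifest.json"))
  invisible(manifest)
}

#' ITS2 annotation pipeline stage
#'
#' @param vienna path to structures (Vienna).
#' @param out output JSON path.
#' @param params [its2_params()].
#' @return The annotations (named list), invisibly; JSON written to `out`.
#' @export
pipeline_annotate <- function(vienna, out, params = its2_params()) {
  ss <- read_vienna(vienna)
  ann <- lapply(ss, annotate_its2, params = params)
  names(ann) <- vapply(ss, function(s) s$record$id, character(1))
  jsonlite::write_json(lapply(ann, unclass), out, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(ann)
}

#' Simulation pipeline stage
#'
#' Writes the synthetic dataset (FASTA, Vienna structures, true tree,
#' defect truth table) plus a manifest.
#'
#' @param config list of [simulate_dataset()] arguments (must include
#'   `seed`).
#' @param out_dir output directory.
#' @return Manifest, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir = ".") {
  if (is.null(config$seed))
    abort_fmt("rnaphylo_invalid", "simulation config requires a seed")
  sim <- do.call(simulate_dataset, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(lapply(sim$records, function(s) s$record),
              file.path(out_dir, "sequences.fasta"))
  write_vienna(sim$records, file.path(out_dir, "structures.vienna"))
  write_vienna(list(sim$root), file.path(out_dir, "template.vienna"))
  writeLines(write_newick(sim$tree), file.path(out_dir, "true_tree.nwk"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- manifest_skeleton("simulate", config)
  manifest$counts <- list(records = length(sim$records),
                          short = sum(sim$truth$defect == "short"),
                          structure_noise = sum(sim$truth$defect == "structure_noise"))
  manifest$outputs <- list(fasta = file.path(out_dir, "sequences.fasta"),
                           vienna = file.path(out_dir, "structures.vienna"),
                           template = file.path(out_dir, "template.vienna"),
                           tree = file.path(out_dir, "true_tree.nwk"),
                           truth = file.path(out_dir, "truth.tsv"))
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Full pipeline from a YAML configuration
#'
#' Runs simulate (optional) -> model -> encode -> align (optional; simulated
#' records share coordinates already) -> tree, as configured. See the
#' methods vignette for the configuration keys.
#'
#' @param config_path YAML file.
#' @param out_dir output directory.
#' @return Named list of stage manifests, invisibly.
#' @export
pipeline_run <- function(config_path, out_dir = ".") {
  cfg <- yaml::read_yaml(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifests <- list()
  if (!is.null(cfg$simulate)) {
    manifests$simulate <- pipeline_simulate(cfg$simulate, out_dir)
    cfg$model$fasta <- cfg$model$fasta %||% file.path(out_dir, "sequences.fasta")
    cfg$model$templates <- cfg$model$templates %||%
      file.path(out_dir, "template.vienna")
  }
  if (!is.null(cfg$model)) {
    manifests$model <- do.call(pipeline_model,
                               c(cfg$model, list(out_dir = out_dir)))
  }
  enc_path <- file.path(out_dir, "encoded.fasta")
  pipeline_encode(file.path(out_dir, "structures.vienna"), enc_path)
  aln_path <- enc_path
  if (isTRUE(cfg$align$run)) {
    aln_path <- file.path(out_dir, "aligned.fasta")
    pipeline_align(enc_path, aln_path)
  }
  if (!is.null(cfg$tree)) {
    cfg$tree$aligned_fasta <- aln_path
    cfg$tree$out <- cfg$tree$out %||% file.path(out_dir, "tree.nwk")
    manifests$tree <- do.call(pipeline_tree, cfg$tree)
  }
  invisible(manifests)
}
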