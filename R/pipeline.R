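# End-to-end experiment driver: one call from network (+ attribute data)
# to the behavior-vs-attribute cross-validated comparison.

resolve_classifier <- function(classifier) {
  if (inherits(classifier, "dti_classifier")) return(classifier)
  switch(match.arg(classifier, c("rf", "svm", "logistic")),
         rf = classifier_random_forest(),
         svm = classifier_svm(),
         logistic = classifier_logistic())
}

#' Run the behavior-vs-attribute comparison experiment
#'
#' Builds the balanced labeled pair table from the network's drug-target
#' edges, assembles both feature representations, and evaluates each under
#' the same stratified k-fold plan and classifier. In `leakage = "strict"`
#' (the default) the behavior features are re-derived for every fold from
#' a network with that fold's positive interactions removed before
#' walking and embedding; `leakage = "global"` embeds the full network
#' once, the cheaper protocol a one-shot embedding of a complete database
#' snapshot corresponds to.
#'
#' @param g a `man_graph`.
#' @param proteins named character vector of protein sequences (see
#'   [read_protein_fasta()]); `NULL` to skip the attribute arm.
#' @param fingerprints binary drug fingerprint matrix (see
#'   [load_fingerprints()]); `NULL` to skip the attribute arm.
#' @param classifier `"rf"`, `"svm"`, `"logistic"`, or a
#'   `dti_classifier` contract.
#' @param k number of cross-validation folds.
#' @param seed master seed; sub-seeds for negative sampling, fold
#'   assignment, walking, training and fitting are derived from it.
#' @param leakage `"strict"` or `"global"`.
#' @param negative_ratio negatives per positive.
#' @param walk_cfg a [walk_config()] (its seed is overridden by a derived
#'   sub-seed).
#' @param sg_cfg a [skipgram_config()] (same).
#' @return list of class `dti_experiment` with elements `behavior` and
#'   (if attribute inputs were given) `attribute`, each a
#'   `metrics_report`, plus the `pairs` table and `folds` plan.
#' @export
run_dti_experiment <- function(g, proteins = NULL, fingerprints = NULL,
                               classifier = "rf", k = 5L, seed = 1L,
                               leakage = c("strict", "global"),
                               negative_ratio = 1,
                               walk_cfg = walk_config(),
                               sg_cfg = skipgram_config()) {
  leakage <- match.arg(leakage)
  clf <- resolve_classifier(classifier)
  walk_cfg$seed <- derive_seed(seed, "walks")
  sg_cfg$seed <- derive_seed(seed, "skipgram")
  pairs <- make_pair_table(g, seed = derive_seed(seed, "negatives"),
                           negative_ratio = negative_ratio)
  plan <- make_fold_plan(pairs$label, k = k,
                         seed = derive_seed(seed, "folds"))
  out <- list(pairs = pairs, folds = plan, leakage = leakage)

  if (leakage == "strict") {
    ds_beh <- structure(
      list(pairs = pairs, features = NULL, tag = "behavior", n_dropped = 0L),
      class = "pair_dataset")
    builder <- behavior_feature_builder(g, pairs, walk_cfg, sg_cfg)
    out$behavior <- run_cv(ds_beh, plan, clf, feature_builder = builder,
                           seed = derive_seed(seed, "fit_behavior"))
  } else {
    emb <- train_embeddings(generate_walks(g, walk_cfg), sg_cfg)
    ds_beh <- build_pair_features(pairs, emb, emb, tag = "behavior")
    plan_beh <- restrict_plan(plan, which(
      paste(pairs$drug, pairs$protein) %in%
        paste(ds_beh$pairs$drug, ds_beh$pairs$protein)))
    out$behavior <- run_cv(ds_beh, plan_beh, clf,
                           seed = derive_seed(seed, "fit_behavior"))
  }

  if (!is.null(proteins) && !is.null(fingerprints)) {
    prot_feat <- protein_kmer_matrix(proteins)
    ds_att <- build_pair_features(pairs, fingerprints, prot_feat,
                                  tag = "attribute")
    plan_att <- restrict_plan(plan, which(
      paste(pairs$drug, pairs$protein) %in%
        paste(ds_att$pairs$drug, ds_att$pairs$protein)))
    out$attribute <- run_cv(ds_att, plan_att, clf,
                            seed = derive_seed(seed, "fit_attribute"))
  }
  structure(out, class = "dti_experiment")
}

restrict_plan <- function(plan, idx) {
  structure(plan[idx], class = "fold_plan", k = attr(plan, "k"))
}

#' @export
print.dti_experiment <- function(x, ...) {
  cat(sprintf("DTI experiment (%s leakage mode)\n", x$leakage))
  for (arm in intersect(c("behavior", "attribute"), names(x))) {
    cat("\n")
    print(x[[arm]])
  }
  if (all(c("behavior", "attribute") %in% names(x))) {
    cat(sprintf("\nmean AUC: behavior %.4f vs attribute %.4f\n",
                x$behavior$mean[["AUC"]], x$attribute$mean[["AUC"]]))
  }
  invisible(x)
}

#' Write a reproducibility manifest
#'
#' Records the configuration, the seed, package version and md5 checksums
#' of the input files, so two runs can be compared end to end.
#'
#' @param path output JSON path.
#' @param config named list of configuration values.
#' @param inputs character vector of input file paths to checksum.
#' @export
write_manifest <- function(path, config, inputs = character()) {
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mandti")),
    r_version = as.character(getRversion()),
    config = config,
    config_md5 = unname(tools::md5sum(cfg_file)),
    inputs = lapply(stats::setNames(inputs, basename(inputs)),
                    function(f) list(path = f,
                                     md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a fixture directory into pipeline inputs
#'
#' Reads the nine relation TSVs, the protein FASTA and the fingerprint
#' TSV emitted by [write_synthetic_fixture()] (or assembled by hand in
#' the same layout).
#'
#' @param dir fixture directory.
#' @param fingerprint_dialect passed to [load_fingerprints()].
#' @return list with `graph`, `proteins`, `fingerprints`.
#' @export
load_fixture <- function(dir, fingerprint_dialect = "maccs") {
  edge_lists <- lapply(names(RELATION_ENDPOINTS), function(rel) {
    f <- file.path(dir, paste0(gsub("-", "_", rel), ".tsv"))
    if (!file.exists(f)) {
      stop("missing edge list for relation '", rel, "': ", f, call. = FALSE)
    }
    load_edge_list(f, rel)
  })
  list(graph = assemble_man(edge_lists),
       proteins = read_protein_fasta(file.path(dir, "proteins.fasta")),
       fingerprints = load_fingerprints(file.path(dir, "fingerprints.tsv"),
                                        dialect = fingerprint_dialect))
}
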