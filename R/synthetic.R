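# Seedable synthetic molecular associations networks with planted
# community structure, plus matching protein sequences and drug
# fingerprints, so the whole pipeline is testable without external data.

#' Synthetic network configuration
#'
#' Nodes of all five types are assigned uniformly to `communities` latent
#' blocks; every type-compatible node pair is linked independently with
#' probability `p_in` (same block) or `p_out` (different blocks) for each
#' of the nine relation types — a planted-partition model, the minimal
#' generator whose random walks can learn community structure the way the
#' real network's embeddings learn association neighborhoods. `signal`
#' (rho) interpolates the attribute generators between community-blind
#' (0) and fully community-informative (1): attribute features are meant
#' to carry weaker signal than the topology, mirroring the behavior
#' vs. attribute comparison on real data.
#'
#' @param n_per_type named integer vector of node counts for drug,
#'   protein, disease, lncRNA, miRNA. Default 80 each (400 nodes).
#' @param communities number of latent blocks B.
#' @param p_in within-block edge probability.
#' @param p_out between-block edge probability.
#' @param seq_length length-2 vector: protein sequence length range.
#' @param fingerprint_dialect `"maccs"` (166 bits) or `"circular"`.
#' @param nbits bit count for the circular dialect.
#' @param signal rho in \[0, 1\]: strength of the community signal in
#'   sequences and fingerprints.
#' @param holdout_fraction fraction of drug-target edges withheld from the
#'   emitted graph and recorded as test positives.
#' @param seed master seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_per_type = c(drug = 80L, protein = 80L,
                                        disease = 80L, lncRNA = 80L,
                                        miRNA = 80L),
                         communities = 4L, p_in = 0.25, p_out = 0.01,
                         seq_length = c(200L, 400L),
                         fingerprint_dialect = c("maccs", "circular"),
                         nbits = 1024L, signal = 0.4,
                         holdout_fraction = 0.1, seed = 1L) {
  fingerprint_dialect <- match.arg(fingerprint_dialect)
  stopifnot(setequal(names(n_per_type), NODE_TYPES), all(n_per_type >= 1L),
            p_in > p_out, p_out >= 0, p_in <= 1,
            length(seq_length) == 2L, seq_length[1L] >= 3L,
            seq_length[1L] <= seq_length[2L],
            signal >= 0, signal <= 1,
            holdout_fraction >= 0, holdout_fraction < 1)
  structure(list(
    n_per_type = vapply(NODE_TYPES, function(t) as.integer(n_per_type[[t]]),
                        integer(1L)),
    communities = assert_scalar_int(communities, "communities"),
    p_in = p_in, p_out = p_out,
    seq_length = as.integer(seq_length),
    fingerprint_dialect = fingerprint_dialect,
    nbits = assert_scalar_int(nbits, "nbits"),
    signal = signal, holdout_fraction = holdout_fraction,
    seed = assert_scalar_int(seed, "seed", min = -.Machine$integer.max)
  ), class = "synth_config")
}

synth_node_ids <- function(cfg) {
  prefix <- c(drug = "D", protein = "P", disease = "S", lncRNA = "L",
              miRNA = "M")
  lapply(stats::setNames(NODE_TYPES, NODE_TYPES), function(t) {
    make_node_id(t, sprintf("%s%04d", prefix[[t]],
                            seq_len(cfg$n_per_type[[t]])))
  })
}

#' Generate a synthetic molecular associations network
#'
#' @param cfg a [synth_config()].
#' @return list with `graph` (a `man_graph` with the held-out drug-target
#'   edges removed) and `truth` (list: `communities` — named block id per
#'   node; `edges` — every generated edge; `heldout_dti` — data.frame of
#'   withheld positive pairs).
#' @export
generate_man <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  ids <- synth_node_ids(cfg)
  all_ids <- unlist(ids, use.names = FALSE)
  with_seed(derive_seed(cfg$seed, "man"), {
    comm <- stats::setNames(
      sample.int(cfg$communities, length(all_ids), replace = TRUE), all_ids)
    edge_frames <- lapply(names(RELATION_ENDPOINTS), function(rel) {
      ends <- RELATION_ENDPOINTS[[rel]]
      a <- ids[[ends[1L]]]; b <- ids[[ends[2L]]]
      if (ends[1L] == ends[2L]) {
        pair_idx <- utils::combn(length(a), 2L)
        u <- a[pair_idx[1L, ]]; v <- a[pair_idx[2L, ]]
      } else {
        grid <- expand.grid(i = seq_along(a), j = seq_along(b),
                            KEEP.OUT.ATTRS = FALSE)
        u <- a[grid$i]; v <- b[grid$j]
      }
      p <- ifelse(comm[u] == comm[v], cfg$p_in, cfg$p_out)
      keep <- stats::runif(length(p)) < p
      data.frame(u = u[keep], v = v[keep], relation = rel,
                 stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, edge_frames)
    if (nrow(edges) == 0L) {
      warning("synthetic configuration produced no edges")
    }
    is_dti <- edges$relation == "drug-target"
    n_hold <- as.integer(floor(cfg$holdout_fraction * sum(is_dti)))
    hold_rows <- if (n_hold > 0L) {
      sample(which(is_dti), n_hold)
    } else integer()
    heldout <- data.frame(
      drug = edges$u[hold_rows], protein = edges$v[hold_rows],
      stringsAsFactors = FALSE)
    kept <- edges[setdiff(seq_len(nrow(edges)), hold_rows), , drop = FALSE]
    g <- assemble_man(kept)
    # isolated nodes would otherwise vanish: re-register the full node set
    missing <- setdiff(all_ids, g$nodes$id)
    if (length(missing) > 0L) {
      nodes <- data.frame(id = sort(c(g$nodes$id, missing)),
                          stringsAsFactors = FALSE)
      nodes$type <- node_type_of(nodes$id)
      adj <- build_adjacency(nodes$id, g$edges)
      g <- structure(list(nodes = nodes, edges = g$edges, adjacency = adj),
                     class = "man_graph")
    }
    list(graph = g,
         truth = list(communities = comm, edges = edges,
                      heldout_dti = heldout))
  })
}

# Dirichlet-style community composition profiles (normalized gamma draws).
community_profiles <- function(n_communities, n_categories, concentration) {
  t(vapply(seq_len(n_communities), function(b) {
    x <- stats::rgamma(n_categories, shape = concentration)
    x / sum(x)
  }, numeric(n_categories)))
}

#' Generate synthetic protein sequences
#'
#' Each protein draws i.i.d. residues over the 20 standard letters with
#' composition `(1 - rho) * uniform + rho * profile(community)`; at
#' `signal = 0` all communities share the uniform composition and
#' sequence features carry no link information.
#'
#' @param protein_ids namespaced protein node ids.
#' @param communities named block assignment (from [generate_man()]'s
#'   truth).
#' @param cfg a [synth_config()].
#' @return named character vector of sequences.
#' @export
generate_proteins <- function(protein_ids, communities,
                              cfg = synth_config()) {
  letters20 <- names(reduced_alphabet())
  with_seed(derive_seed(cfg$seed, "proteins"), {
    prof <- community_profiles(cfg$communities, 20L, concentration = 0.8)
    lens <- sample(seq(cfg$seq_length[1L], cfg$seq_length[2L]),
                   length(protein_ids), replace = TRUE)
    seqs <- vapply(seq_along(protein_ids), function(i) {
      b <- communities[[protein_ids[i]]]
      p <- (1 - cfg$signal) / 20 + cfg$signal * prof[b, ]
      paste(sample(letters20, lens[i], replace = TRUE, prob = p),
            collapse = "")
    }, character(1L))
    stats::setNames(seqs, protein_ids)
  })
}

#' Generate synthetic drug fingerprints
#'
#' Bit f of a drug in block b switches on with probability
#' `(1 - rho) * q_f + rho * q_{f,b}`, where the base rates `q_f` and the
#' block-specific rates `q_{f,b}` are themselves drawn once per run; at
#' `signal = 0` all blocks share the base rates.
#'
#' @param drug_ids namespaced drug node ids.
#' @param communities named block assignment.
#' @param cfg a [synth_config()].
#' @return binary matrix, one row per drug.
#' @export
generate_fingerprints <- function(drug_ids, communities,
                                  cfg = synth_config()) {
  f_len <- if (cfg$fingerprint_dialect == "maccs") 166L else cfg$nbits
  with_seed(derive_seed(cfg$seed, "fingerprints"), {
    base_q <- stats::runif(f_len, 0.05, 0.60)
    block_q <- matrix(stats::rbeta(cfg$communities * f_len, 0.4, 0.4),
                      nrow = cfg$communities)
    m <- t(vapply(drug_ids, function(id) {
      b <- communities[[id]]
      p <- (1 - cfg$signal) * base_q + cfg$signal * block_q[b, ]
      as.integer(stats::runif(f_len) < p)
    }, integer(f_len)))
    rownames(m) <- drug_ids
    m
  })
}

write_fasta <- function(seqs, path) {
  ids <- sub("^protein:", "", names(seqs))
  writeLines(paste0(">", ids, "\n", unname(seqs)), path)
  invisible(path)
}

write_fingerprint_tsv <- function(m, path) {
  ids <- sub("^drug:", "", rownames(m))
  bits <- apply(m, 1L, paste, collapse = "")
  writeLines(paste(ids, bits, sep = "\t"), path)
  invisible(path)
}

#' Write a complete synthetic fixture directory
#'
#' Emits exactly the formats the pipeline consumes: one two-column TSV per
#' relation type, a protein FASTA, a fingerprint TSV, and the ground truth
#' as JSON.
#'
#' @param dir output directory (created if needed).
#' @param cfg a [synth_config()].
#' @return (invisibly) list with the generated `graph`, `truth`, and file
#'   paths.
#' @export
write_synthetic_fixture <- function(dir, cfg = synth_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- generate_man(cfg)
  ids <- synth_node_ids(cfg)
  edge_paths <- stats::setNames(
    file.path(dir, paste0(gsub("-", "_", names(RELATION_ENDPOINTS)), ".tsv")),
    names(RELATION_ENDPOINTS))
  for (rel in names(RELATION_ENDPOINTS)) {
    e <- man$graph$edges[man$graph$edges$relation == rel, , drop = FALSE]
    utils::write.table(
      data.frame(sub("^[^:]+:", "", e$u), sub("^[^:]+:", "", e$v)),
      edge_paths[[rel]], sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  seqs <- generate_proteins(ids$protein, man$truth$communities, cfg)
  fasta_path <- file.path(dir, "proteins.fasta")
  write_fasta(seqs, fasta_path)
  fp <- generate_fingerprints(ids$drug, man$truth$communities, cfg)
  fp_path <- file.path(dir, "fingerprints.tsv")
  write_fingerprint_tsv(fp, fp_path)
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(communities = as.list(man$truth$communities),
         heldout_dti = man$truth$heldout_dti,
         n_edges_generated = nrow(man$truth$edges)),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(graph = man$graph, truth = man$truth,
                 files = c(edge_paths, fasta = fasta_path,
                           fingerprints = fp_path, truth = truth_path)))
}
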