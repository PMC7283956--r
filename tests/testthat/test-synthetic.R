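small_cfg <- function(...) {
  synth_config(n_per_type = c(drug = 25, protein = 25, disease = 25,
                              lncRNA = 25, miRNA = 25), ...)
}

test_that("degenerate probabilities confine edges to communities", {
  cfg <- synth_config(n_per_type = c(drug = 15, protein = 15, disease = 15,
                                     lncRNA = 15, miRNA = 15),
                      communities = 2L, p_in = 0.999999, p_out = 0,
                      holdout_fraction = 0, seed = 5)
  man <- generate_man(cfg)
  comm <- man$truth$communities
  expect_true(all(comm[man$truth$edges$u] == comm[man$truth$edges$v]))
})

test_that("per-relation edge counts concentrate at the binomial expectation", {
  cfg <- small_cfg(p_in = 0.3, p_out = 0.02, holdout_fraction = 0, seed = 9)
  man <- generate_man(cfg)
  comm <- man$truth$communities
  for (rel in relation_types()) {
    ends <- mandti:::RELATION_ENDPOINTS[[rel]]
    ids <- mandti:::synth_node_ids(cfg)
    if (ends[1L] == ends[2L]) {
      pr <- utils::combn(ids[[ends[1L]]], 2L)
      u <- pr[1L, ]; v <- pr[2L, ]
    } else {
      grid <- expand.grid(u = ids[[ends[1L]]], v = ids[[ends[2L]]],
                          stringsAsFactors = FALSE)
      u <- grid$u; v <- grid$v
    }
    p <- ifelse(comm[u] == comm[v], cfg$p_in, cfg$p_out)
    expectation <- sum(p)
    sdev <- sqrt(sum(p * (1 - p)))
    observed <- sum(man$truth$edges$relation == rel)
    expect_lt(abs(observed - expectation), 4 * sdev + 1)
  }
})

test_that("held-out interactions are true edges absent from the graph", {
  cfg <- small_cfg(holdout_fraction = 0.2, seed = 13)
  man <- generate_man(cfg)
  hold <- man$truth$heldout_dti
  expect_gt(nrow(hold), 0L)
  gen_key <- paste(man$truth$edges$u, man$truth$edges$v,
                   man$truth$edges$relation)
  expect_true(all(paste(hold$drug, hold$protein, "drug-target") %in%
                    gen_key))
  emitted <- mandti:::canonical_edge_key(man$graph$edges)
  hold_key <- paste(pmin(hold$drug, hold$protein),
                    pmax(hold$drug, hold$protein), "drug-target",
                    sep = "\r")
  expect_length(intersect(hold_key, emitted), 0L)
  # all nodes stay registered even if isolated by the holdout
  expect_equal(nrow(man$graph$nodes), sum(cfg$n_per_type))
})

test_that("generation is seed-deterministic", {
  cfg <- small_cfg(seed = 31)
  m1 <- generate_man(cfg); m2 <- generate_man(cfg)
  expect_identical(m1$truth, m2$truth)
  expect_identical(m1$graph$edges, m2$graph$edges)
  ids <- mandti:::synth_node_ids(cfg)
  expect_identical(generate_proteins(ids$protein, m1$truth$communities, cfg),
                   generate_proteins(ids$protein, m1$truth$communities, cfg))
  expect_identical(
    generate_fingerprints(ids$drug, m1$truth$communities, cfg),
    generate_fingerprints(ids$drug, m1$truth$communities, cfg))
})

test_that("sequence lengths and fingerprint dimensions follow the config", {
  cfg <- small_cfg(seq_length = c(50L, 80L), seed = 17)
  man <- generate_man(cfg)
  ids <- mandti:::synth_node_ids(cfg)
  seqs <- generate_proteins(ids$protein, man$truth$communities, cfg)
  expect_true(all(nchar(seqs) >= 50L & nchar(seqs) <= 80L))
  expect_true(all(strsplit(paste(seqs, collapse = ""), "")[[1L]] %in%
                    names(reduced_alphabet())))
  fp <- generate_fingerprints(ids$drug, man$truth$communities, cfg)
  expect_equal(dim(fp), c(25L, 166L))
  expect_true(all(fp %in% c(0L, 1L)))
})

test_that("signal = 0 makes community compositions indistinguishable", {
  cfg <- small_cfg(signal = 0, communities = 2L, seq_length = c(300L, 300L),
                   seed = 23)
  man <- generate_man(cfg)
  ids <- mandti:::synth_node_ids(cfg)
  seqs <- generate_proteins(ids$protein, man$truth$communities, cfg)
  comm <- man$truth$communities[names(seqs)]
  # pooled residue counts per community; chi-square homogeneity test
  count_letters <- function(ss) {
    table(factor(strsplit(paste(ss, collapse = ""), "")[[1L]],
                 levels = names(reduced_alphabet())))
  }
  tab <- rbind(count_letters(seqs[comm == 1L]),
               count_letters(seqs[comm == 2L]))
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
  # and with full signal the compositions do differ
  cfg1 <- small_cfg(signal = 1, communities = 2L,
                    seq_length = c(300L, 300L), seed = 23)
  man1 <- generate_man(cfg1)
  seqs1 <- generate_proteins(ids$protein, man1$truth$communities, cfg1)
  comm1 <- man1$truth$communities[names(seqs1)]
  tab1 <- rbind(count_letters(seqs1[comm1 == 1L]),
                count_letters(seqs1[comm1 == 2L]))
  p1 <- suppressWarnings(stats::chisq.test(tab1)$p.value)
  expect_lt(p1, 1e-6)
})

test_that("attribute informativeness is monotone in the signal dial", {
  # drug fingerprints at rho = 0, 0.5, 1: community recoverability from
  # the bits should increase (measured by a logistic separator's CV AUC
  # on community-1 membership)
  # measured as the gap between mean between-community and mean
  # within-community Hamming distance of the bit vectors
  gaps <- vapply(c(0, 0.5, 1), function(rho) {
    cfg <- small_cfg(signal = rho, communities = 2L, seed = 29)
    man <- generate_man(cfg)
    ids <- mandti:::synth_node_ids(cfg)
    fp <- generate_fingerprints(ids$drug, man$truth$communities, cfg)
    comm <- man$truth$communities[rownames(fp)]
    d <- as.matrix(stats::dist(fp, method = "manhattan"))
    same <- outer(comm, comm, "==") & upper.tri(d)
    diff_c <- (!outer(comm, comm, "==")) & upper.tri(d)
    mean(d[diff_c]) - mean(d[same])
  }, numeric(1L))
  expect_true(all(diff(gaps) > 0))
  expect_lt(abs(gaps[1L]), 5)             # near zero when rho = 0
})

test_that("fixture directories contain exactly what the pipeline consumes", {
  dir <- tempfile("fixture")
  cfg <- small_cfg(seed = 41)
  fix <- write_synthetic_fixture(dir, cfg)
  expect_true(all(file.exists(fix$files)))
  loaded <- load_fixture(dir)
  s <- summarize_man(loaded$graph)
  expect_equal(s$n_edges, nrow(fix$graph$edges))
  prot_nodes <- loaded$graph$nodes$id[loaded$graph$nodes$type == "protein"]
  expect_true(all(prot_nodes %in% names(loaded$proteins)))
  expect_equal(ncol(loaded$fingerprints), 166L)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(length(truth$communities), sum(cfg$n_per_type))
})
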