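# Shared in-code fixtures: tiny graphs and edge-list files built at test
# time, plus brute-force oracles used across test files.

edge_df <- function(u, v, relation) {
  data.frame(u = u, v = v, relation = relation, stringsAsFactors = FALSE)
}

# A small hand-made MAN: 2 drugs, 2 proteins, 1 disease.
tiny_man <- function() {
  assemble_man(list(
    edge_df(c("drug:d1", "drug:d2"), c("protein:p1", "protein:p2"),
            "drug-target"),
    edge_df("protein:p1", "disease:s1", "protein-disease"),
    edge_df("drug:d1", "disease:s1", "drug-disease")))
}

# Two-block planted-partition graph exposed as a MAN (all protein nodes,
# protein-protein edges), with known block labels.
two_block_man <- function(n_per_block = 50L, p_in = 0.3, p_out = 0.01,
                          seed = 1L) {
  n <- 2L * n_per_block
  ids <- sprintf("protein:B%03d", seq_len(n))
  block <- rep(1:2, each = n_per_block)
  set.seed(seed)
  pairs <- utils::combn(n, 2L)
  p <- ifelse(block[pairs[1L, ]] == block[pairs[2L, ]], p_in, p_out)
  keep <- stats::runif(length(p)) < p
  g <- assemble_man(edge_df(ids[pairs[1L, keep]], ids[pairs[2L, keep]],
                            "protein-protein"))
  list(graph = g, block = stats::setNames(block, ids))
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# Brute-force (center, context) window enumeration for one walk.
pairs_oracle <- function(walk, window) {
  out <- NULL
  L <- length(walk)
  for (i in seq_len(L)) {
    for (k in seq(max(1L, i - window), min(L, i + window))) {
      if (k != i) out <- rbind(out, c(walk[i], walk[k]))
    }
  }
  out
}

# Independent loop-based confusion tally.
confusion_oracle <- function(labels, predicted) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == 1L && predicted[i] == 1L) tp <- tp + 1L
    if (labels[i] == 0L && predicted[i] == 1L) fp <- fp + 1L
    if (labels[i] == 0L && predicted[i] == 0L) tn <- tn + 1L
    if (labels[i] == 1L && predicted[i] == 0L) fn <- fn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# O(P*N) pairwise Mann-Whitney AUC with ties counted one half.
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (sp in pos) for (sn in neg) {
    total <- total + (sp > sn) + 0.5 * (sp == sn)
  }
  total / (length(pos) * length(neg))
}

# Central finite differences of a scalar function.
finite_diff <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1L))
}

# Naive dictionary-counting 3-mer oracle over the reduced alphabet.
kmer_oracle <- function(seq) {
  alpha <- reduced_alphabet()
  chars <- strsplit(gsub("*", "", toupper(seq), fixed = TRUE), "")[[1L]]
  counts <- stats::setNames(numeric(64L), apply(
    expand.grid(0:3, 0:3, 0:3)[, 3:1], 1L, paste, collapse = ""))
  n_valid <- 0L
  if (length(chars) >= 3L) {
    for (i in seq_len(length(chars) - 2L)) {
      w <- chars[i:(i + 2L)]
      if (all(w %in% names(alpha))) {
        key <- paste(alpha[w], collapse = "")
        counts[key] <- counts[key] + 1
        n_valid <- n_valid + 1L
      }
    }
  }
  if (n_valid == 0L) return(NULL)
  unname(counts / n_valid)
}
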