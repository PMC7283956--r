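# Truncated uniform random walks over the MAN; the resulting corpus plays
# the role of sentences for the skip-gram model.

#' Random-walk configuration
#'
#' @param walks_per_node number of walks rooted at every node (gamma).
#' @param walk_length maximum walk length, counted in nodes (t).
#' @param seed integer seed for the walk RNG.
#' @return a `walk_config` list.
#' @export
walk_config <- function(walks_per_node = 10L, walk_length = 40L, seed = 1L) {
  structure(list(
    walks_per_node = assert_scalar_int(walks_per_node, "walks_per_node"),
    walk_length = assert_scalar_int(walk_length, "walk_length"),
    seed = assert_scalar_int(seed, "seed", min = -.Machine$integer.max)
  ), class = "walk_config")
}

#' Generate the truncated random-walk corpus
#'
#' Performs `walks_per_node` passes; each pass visits every node of the
#' graph in a freshly shuffled order and starts one walk there, so every
#' molecule — however peripheral — roots exactly `walks_per_node` walks.
#' Each step moves uniformly at random to a neighbor of the current node;
#' a walk that reaches a node with no neighbors stops early.
#'
#' @param g a `man_graph`.
#' @param cfg a [walk_config()].
#' @return a `walk_corpus`: list of integer vectors (1-based vocabulary
#'   indices) with attribute `vocab` giving the node ids. A fixed seed
#'   yields an identical corpus.
#' @export
generate_walks <- function(g, cfg = walk_config()) {
  stopifnot(inherits(g, "man_graph"), inherits(cfg, "walk_config"))
  ids <- g$nodes$id
  if (length(ids) == 0L) {
    stop("cannot walk an empty graph", call. = FALSE)
  }
  idx <- stats::setNames(seq_along(ids), ids)
  # 0-based CSR adjacency for the C++ walker
  adj <- g$adjacency[ids]
  deg <- lengths(adj)
  ptr <- c(0L, cumsum(deg))
  nb <- if (sum(deg) > 0L) idx[unlist(adj, use.names = FALSE)] - 1L else integer()
  walks <- with_seed(cfg$seed, {
    roots <- unlist(lapply(seq_len(cfg$walks_per_node), function(p) {
      sample.int(length(ids))
    }), use.names = FALSE) - 1L
    cpp_generate_walks(nb, ptr, roots, cfg$walk_length)
  })
  structure(walks, vocab = ids, class = "walk_corpus")
}

#' Summary statistics of a walk corpus
#'
#' @param corpus a `walk_corpus`.
#' @return list with `n_walks`, `length_histogram` (table of walk lengths),
#'   and `node_coverage` (named vector counting each node's occurrences).
#' @export
corpus_stats <- function(corpus) {
  stopifnot(inherits(corpus, "walk_corpus"))
  vocab <- attr(corpus, "vocab")
  counts <- tabulate(unlist(corpus, use.names = FALSE), nbins = length(vocab))
  list(n_walks = length(corpus),
       length_histogram = table(lengths(corpus)),
       node_coverage = stats::setNames(counts, vocab))
}

#' Write a walk corpus as plain text
#'
#' One walk per line, space-separated node ids (the word2vec corpus
#' convention).
#'
#' @param corpus a `walk_corpus`.
#' @param path output file path.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "walk_corpus"))
  vocab <- attr(corpus, "vocab")
  lines <- vapply(corpus, function(w) paste(vocab[w], collapse = " "),
                  character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a walk corpus from plain text
#'
#' @param path file written by [write_corpus()].
#' @return a `walk_corpus`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(lines, " ", fixed = TRUE)
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  idx <- stats::setNames(seq_along(vocab), vocab)
  walks <- lapply(toks, function(t) unname(idx[t]))
  structure(walks, vocab = vocab, class = "walk_corpus")
}
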