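# Skip-gram training on the walk corpus: node "behavior" vectors.

#' Vocabulary index of a walk corpus
#'
#' @param corpus a `walk_corpus`.
#' @return list with `ids` (node id per vocabulary index) and `freq`
#'   (corpus occurrence count per index).
#' @export
vocab_index <- function(corpus) {
  stopifnot(inherits(corpus, "walk_corpus"))
  ids <- attr(corpus, "vocab")
  freq <- tabulate(unlist(corpus, use.names = FALSE), nbins = length(ids))
  list(ids = ids, freq = freq)
}

#' Enumerate (center, context) training pairs
#'
#' For position i of a walk, every position within `window` on either side
#' (clipped at the walk boundaries) contributes one pair — the
#' independence factorization of the window co-occurrence probability.
#' Pairs are emitted walk by walk, position by position, context in
#' left-to-right order.
#'
#' @param corpus a `walk_corpus`.
#' @param window window half-width c (>= 1).
#' @return integer matrix with columns `center`, `context` (vocabulary
#'   indices).
#' @export
extract_pairs <- function(corpus, window) {
  stopifnot(inherits(corpus, "walk_corpus"))
  window <- assert_scalar_int(window, "window")
  res <- vector("list", length(corpus))
  for (wi in seq_along(corpus)) {
    walk <- corpus[[wi]]
    L <- length(walk)
    if (L < 2L) next
    centers <- integer(); contexts <- integer()
    for (i in seq_len(L)) {
      ks <- max(1L, i - window):min(L, i + window)
      ks <- ks[ks != i]
      centers <- c(centers, rep(walk[i], length(ks)))
      contexts <- c(contexts, walk[ks])
    }
    res[[wi]] <- cbind(centers, contexts)
  }
  out <- do.call(rbind, c(res, list(matrix(integer(), ncol = 2L))))
  colnames(out) <- c("center", "context")
  out
}

#' Skip-gram training configuration
#'
#' @param dimension embedding dimension d. The default 64 puts behavior
#'   vectors on the same scale as the 64-dimensional protein 3-mer
#'   attribute vectors.
#' @param window context window half-width c.
#' @param epochs passes over the walk corpus.
#' @param learning_rate initial SGD step size, decayed linearly per
#'   processed pair down to `min_learning_rate`.
#' @param min_learning_rate floor of the decayed step size.
#' @param objective `"negative_sampling"` (default) or
#'   `"hierarchical_softmax"`.
#' @param negative number k of noise words per pair (negative sampling
#'   only), drawn from the unigram distribution raised to 3/4.
#' @param seed seed for initialization and noise draws.
#' @return a `skipgram_config` list.
#' @export
skipgram_config <- function(dimension = 64L, window = 5L, epochs = 5L,
                            learning_rate = 0.025, min_learning_rate = 1e-4,
                            objective = c("negative_sampling",
                                          "hierarchical_softmax"),
                            negative = 5L, seed = 1L) {
  objective <- match.arg(objective)
  stopifnot(learning_rate > 0, min_learning_rate > 0,
            min_learning_rate <= learning_rate)
  structure(list(
    dimension = assert_scalar_int(dimension, "dimension"),
    window = assert_scalar_int(window, "window"),
    epochs = assert_scalar_int(epochs, "epochs"),
    learning_rate = learning_rate,
    min_learning_rate = min_learning_rate,
    objective = objective,
    negative = assert_scalar_int(negative, "negative"),
    seed = assert_scalar_int(seed, "seed", min = -.Machine$integer.max)
  ), class = "skipgram_config")
}

#' Train node embeddings on a walk corpus
#'
#' Stochastic gradient descent on the per-pair skip-gram loss (see
#' [ns_pair_objective()] and [hs_pair_objective()] for the exact
#' formulas), single-threaded with a fixed pair order, so a fixed seed
#' reproduces the matrix bit for bit. Input vectors are initialized
#' uniformly in `[-0.5/d, 0.5/d]`; output/inner vectors start at zero.
#'
#' @param corpus a `walk_corpus`.
#' @param cfg a [skipgram_config()].
#' @return numeric matrix `V x d` of input ("behavior") vectors with node
#'   ids as row names; the context-side matrix is attached as attribute
#'   `context_vectors`.
#' @export
train_embeddings <- function(corpus, cfg = skipgram_config()) {
  stopifnot(inherits(corpus, "walk_corpus"), inherits(cfg, "skipgram_config"))
  if (length(corpus) == 0L) stop("empty walk corpus", call. = FALSE)
  vocab <- vocab_index(corpus)
  v_size <- length(vocab$ids)
  walks1 <- unclass(corpus)              # 1-based vocabulary indices
  attributes(walks1) <- NULL

  if (cfg$objective == "negative_sampling") {
    p <- vocab$freq^0.75
    unigram_cdf <- cumsum(p) / sum(p)
    hs_path <- integer(); hs_code <- integer()
    hs_off <- integer(v_size + 1L)
    mode <- 0L
  } else {
    tree <- build_huffman(vocab$freq)
    hs_path <- unlist(tree$paths, use.names = FALSE) - 1L
    hs_code <- unlist(tree$codes, use.names = FALSE)
    hs_off <- c(0L, cumsum(lengths(tree$paths)))
    unigram_cdf <- numeric()
    mode <- 1L
  }
  res <- cpp_train_skipgram(
    walks1, v_size, cfg$dimension, cfg$window, cfg$epochs,
    cfg$learning_rate, cfg$min_learning_rate, mode, cfg$negative,
    unigram_cdf, hs_path, hs_code, hs_off, cfg$seed)
  emb <- res$input
  if (any(!is.finite(emb))) {
    stop("non-finite values in trained embedding; try a smaller learning rate",
         call. = FALSE)
  }
  rownames(emb) <- vocab$ids
  rownames(res$context) <- if (mode == 0L) vocab$ids else NULL
  attr(emb, "context_vectors") <- res$context
  emb
}

#' Save embeddings in word2vec text format
#'
#' Header line `"V d"`, then one row per node: the id followed by d
#' coordinates. Values are written with 17 significant digits so a save /
#' load round trip is exact.
#'
#' @param m embedding matrix with row names.
#' @param path output path.
#' @export
save_embeddings <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], formatC(m[i, ], format = "g", digits = 17)),
          collapse = " ")
  }, character(1L))
  writeLines(rows, con)
  invisible(path)
}

#' Load embeddings from word2vec text format
#'
#' @param path file written by [save_embeddings()] (or any word2vec-format
#'   text embedding).
#' @return numeric matrix with node ids as row names.
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty embedding file: ", path, call. = FALSE)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("malformed word2vec header in ", path, call. = FALSE)
  }
  v_size <- as.integer(hdr[1L]); d <- as.integer(hdr[2L])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != v_size) {
    stop(sprintf("header promises %d rows but file has %d", v_size,
                 length(body)), call. = FALSE)
  }
  toks <- strsplit(trimws(body), "\\s+")
  if (any(lengths(toks) != d + 1L)) {
    i <- which(lengths(toks) != d + 1L)[1L]
    stop(sprintf("row %d has %d fields, expected %d", i,
                 lengths(toks)[i], d + 1L), call. = FALSE)
  }
  ids <- vapply(toks, `[[`, character(1L), 1L)
  vals <- vapply(toks, function(t) as.numeric(t[-1L]), numeric(d))
  m <- if (d == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(m)) stop("non-numeric coordinate in ", path, call. = FALSE)
  rownames(m) <- ids
  m
}
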