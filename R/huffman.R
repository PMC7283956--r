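# Huffman coding of the vocabulary by corpus frequency, used by the
# hierarchical-softmax objective: each vocabulary word becomes a leaf whose
# root-to-leaf path of binary decisions replaces the flat softmax.

#' Build a Huffman tree over the vocabulary
#'
#' Uses the two-queue construction (O(V) after one sort), merging the two
#' lowest-frequency subtrees at each step; ties broken by construction
#' order so the tree is deterministic for a given frequency vector.
#'
#' @param freq positive numeric vector of corpus frequencies, optionally
#'   named by node id; position i is vocabulary index i.
#' @return list of class `huffman_tree` with `paths` (per leaf, the
#'   1-based indices of the inner nodes on the root-to-leaf path) and
#'   `codes` (per leaf, the 0/1 branch decisions taken at those inner
#'   nodes), plus `n_inner = V - 1`.
#' @export
build_huffman <- function(freq) {
  v <- length(freq)
  if (v == 0L) stop("empty vocabulary", call. = FALSE)
  if (any(!is.finite(freq)) || any(freq <= 0)) {
    stop("all frequencies must be positive and finite", call. = FALSE)
  }
  if (v == 1L) {
    return(structure(list(paths = list(integer()), codes = list(integer()),
                          n_inner = 0L), class = "huffman_tree"))
  }
  ord <- order(freq, seq_len(v))          # ascending; stable tie-break
  n_total <- 2L * v - 1L
  weight <- c(freq[ord], rep(NA_real_, v - 1L))
  parent <- integer(n_total)
  side <- integer(n_total)                # 0 = first-merged child, 1 = second
  q1 <- 1L                                 # front of sorted-leaf queue
  q2_head <- v + 1L                        # front of merged-node queue
  next_new <- v + 1L
  pop_min <- function() {
    take_leaf <- q1 <= v &&
      (q2_head >= next_new || weight[q1] <= weight[q2_head])
    if (take_leaf) { i <- q1; q1 <<- q1 + 1L } else {
      i <- q2_head; q2_head <<- q2_head + 1L
    }
    i
  }
  for (m in seq_len(v - 1L)) {
    a <- pop_min()
    b <- pop_min()
    node <- next_new
    weight[node] <- weight[a] + weight[b]
    parent[a] <- node; side[a] <- 0L
    parent[b] <- node; side[b] <- 1L
    next_new <- next_new + 1L
  }
  # map queue positions back to original vocabulary indices
  leaf_pos <- integer(v)
  leaf_pos[ord] <- seq_len(v)
  paths <- vector("list", v)
  codes <- vector("list", v)
  for (w in seq_len(v)) {
    node <- leaf_pos[w]
    p <- integer(); s <- integer()
    while (parent[node] != 0L) {
      p <- c(parent[node], p)              # root first
      s <- c(side[node], s)
      node <- parent[node]
    }
    paths[[w]] <- p - v                    # inner nodes numbered 1..V-1
    codes[[w]] <- s
  }
  structure(list(paths = paths, codes = codes, n_inner = v - 1L),
            class = "huffman_tree")
}

#' Hierarchical-softmax leaf probabilities
#'
#' For a center vector `v` and inner-node matrix `W`, the probability of
#' leaf w is the product over its path of `sigmoid((1 - 2 b_j) w_j . v)`;
#' summed over all leaves this is exactly 1 for any `W`, `v`.
#'
#' @param tree a [build_huffman()] tree.
#' @param W numeric matrix `(V - 1) x d` of inner-node vectors.
#' @param v numeric center vector of length d.
#' @return numeric vector of leaf probabilities (sums to 1).
#' @export
hs_leaf_probs <- function(tree, W, v) {
  stopifnot(inherits(tree, "huffman_tree"))
  vapply(seq_along(tree$paths), function(w) {
    p <- tree$paths[[w]]
    if (length(p) == 0L) return(1)
    s <- 1 - 2 * tree$codes[[w]]
    prod(plogis(s * as.numeric(W[p, , drop = FALSE] %*% v)))
  }, numeric(1L))
}
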