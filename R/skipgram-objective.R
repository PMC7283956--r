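# Per-pair skip-gram losses and analytic gradients, written out in plain R.
# These are the formulas the compiled trainer applies update-by-update;
# keeping them here makes them unit-testable against finite differences.

sigmoid <- function(x) stats::plogis(x)

#' Negative-sampling loss and gradients for one training pair
#'
#' The pair loss is `-log sigmoid(u_pos . v) - sum_j log sigmoid(-u_j . v)`
#' over the k noise vectors `u_j`: the observed context is pushed towards
#' the center vector while sampled noise words are pushed away.
#'
#' @param v center (input) vector, length d.
#' @param u_pos context (output) vector of the observed context word.
#' @param U_neg matrix `k x d` of noise-word output vectors.
#' @return list with `loss`, `grad_v`, `grad_u_pos`, `grad_U_neg`.
#' @export
ns_pair_objective <- function(v, u_pos, U_neg) {
  U_neg <- matrix(U_neg, ncol = length(v))
  s_pos <- sum(u_pos * v)
  s_neg <- as.numeric(U_neg %*% v)
  loss <- -log(sigmoid(s_pos)) - sum(log(sigmoid(-s_neg)))
  g_pos <- sigmoid(s_pos) - 1          # d loss / d s_pos
  g_neg <- sigmoid(s_neg)              # d loss / d s_neg
  list(loss = loss,
       grad_v = g_pos * u_pos + as.numeric(t(U_neg) %*% g_neg),
       grad_u_pos = g_pos * v,
       grad_U_neg = outer(g_neg, v))
}

#' Hierarchical-softmax loss and gradients for one training pair
#'
#' The context word's probability is a product of sigmoid branch decisions
#' along its Huffman path; with branch codes `b_j` in {0, 1} and inner
#' vectors `w_j`, the loss is `-sum_j log sigmoid((1 - 2 b_j) w_j . v)`.
#'
#' @param v center (input) vector, length d.
#' @param W_path matrix `m x d`: inner-node vectors along the path.
#' @param code integer vector of the m branch decisions (0/1).
#' @return list with `loss`, `grad_v`, `grad_W` (`m x d`).
#' @export
hs_pair_objective <- function(v, W_path, code) {
  W_path <- matrix(W_path, ncol = length(v))
  stopifnot(nrow(W_path) == length(code), all(code %in% c(0L, 1L)))
  s <- 1 - 2 * code
  x <- as.numeric(W_path %*% v)
  loss <- -sum(log(sigmoid(s * x)))
  g <- sigmoid(x) - (1 - code)         # d loss / d x_j
  list(loss = loss,
       grad_v = as.numeric(t(W_path) %*% g),
       grad_W = outer(g, v))
}
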