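# Graph encoder: L rounds of message passing over the molecular graph
# followed by scaled-dot-product attention over all nodes and a mean-pool
# readout to a fixed-length embedding.
#
# Message passing (round l):
#   m_i = sum_{j in N(i)} (A_l h_j + B_l e_ij)        (edge-conditioned map)
#   h_i = sigma(W_l m_i + b_l)
# Attention (after round L): queries/keys/values are linear projections of
# h^(L); each node attends over ALL nodes (the attention stage deliberately
# ignores graph edges, extending the receptive field beyond bonded
# neighborhoods). The encoder is used frozen: a seeded random
# initialization provides fixed structural features to the predictor, and a
# plug-in slot accepts precomputed per-molecule embedding tables instead.

.encoder_activations <- list(
  relu = function(x) pmax(x, 0),
  tanh = tanh,
  identity = identity
)

#' Graph encoder parameterization
#'
#' @param n_node_feat,n_edge_feat feature widths of the molecular graph
#'   (6 and 3 for [mol_to_graph()] output).
#' @param L message-passing rounds (>= 0; 0 skips message passing).
#' @param hidden_dim node-state width.
#' @param d attention embedding width (the encoder output length); must be
#'   divisible by `n_heads`.
#' @param n_heads attention heads.
#' @param activation nonlinearity for the message-passing update.
#' @param attn_scale `"sqrt_d"` (standard scaled dot product, the default)
#'   or `"d"` (divide raw scores by the head width instead of its square
#'   root).
#' @param seed RNG seed for weight initialization.
#' @param init `"random"` or `"identity"`. Identity initialization requires
#'   `hidden_dim == n_node_feat` and `d == hidden_dim`; it sets the input map
#'   and value projection to the identity and queries/keys to zero, so with
#'   `L = 0` the encoder reduces to mean-pooled raw atom features.
#' @return an `EncoderParams` object.
#' @export
encoder_params <- function(n_node_feat = 6L, n_edge_feat = 3L, L = 3L,
                           hidden_dim = 128L, d = 128L, n_heads = 4L,
                           activation = c("relu", "tanh", "identity"),
                           attn_scale = c("sqrt_d", "d"),
                           seed = 1L, init = c("random", "identity")) {
  activation <- match.arg(activation)
  attn_scale <- match.arg(attn_scale)
  init <- match.arg(init)
  stopifnot(L >= 0L, d %% n_heads == 0L, hidden_dim >= 1L)
  set.seed(seed)
  rmat <- function(r, c) matrix(stats::rnorm(r * c, sd = 1 / sqrt(c)), r, c)
  if (init == "identity") {
    stopifnot(hidden_dim == n_node_feat, d == hidden_dim)
    W0 <- diag(hidden_dim); b0 <- rep(0, hidden_dim)
    Wq <- matrix(0, d, hidden_dim); Wk <- matrix(0, d, hidden_dim)
    Wv <- diag(d)
  } else {
    W0 <- rmat(hidden_dim, n_node_feat); b0 <- rep(0, hidden_dim)
    Wq <- rmat(d, hidden_dim); Wk <- rmat(d, hidden_dim)
    Wv <- rmat(d, hidden_dim)
  }
  layers <- lapply(seq_len(L), function(l) {
    if (init == "identity") {
      list(A = diag(hidden_dim), B = matrix(0, hidden_dim, n_edge_feat),
           W = diag(hidden_dim), b = rep(0, hidden_dim))
    } else {
      list(A = rmat(hidden_dim, hidden_dim),
           B = rmat(hidden_dim, n_edge_feat),
           W = rmat(hidden_dim, hidden_dim),
           b = stats::rnorm(hidden_dim, sd = 0.1))
    }
  })
  structure(
    list(n_node_feat = n_node_feat, n_edge_feat = n_edge_feat, L = L,
         hidden_dim = hidden_dim, d = d, n_heads = n_heads,
         activation = activation, attn_scale = attn_scale, seed = seed,
         W0 = W0, b0 = b0, layers = layers, Wq = Wq, Wk = Wk, Wv = Wv),
    class = "EncoderParams"
  )
}

#' Initial node states from atom features
#'
#' `h^(0)` is a linear map of the atom-feature vectors; deterministic given
#' the seed the parameters were built with.
#'
#' @param g a `MolGraph`.
#' @param p `EncoderParams`.
#' @return a `NodeStates` object (`h`: n x hidden matrix).
#' @export
init_states <- function(g, p) {
  stopifnot(inherits(g, "MolGraph"), inherits(p, "EncoderParams"))
  if (ncol(g$nodes) != p$n_node_feat) {
    stop("node feature width does not match encoder configuration")
  }
  h <- g$nodes %*% t(p$W0) + matrix(p$b0, g$n_nodes, p$hidden_dim,
                                    byrow = TRUE)
  structure(list(h = h, m = NULL), class = "NodeStates")
}

#' One message-passing round
#'
#' Aggregates inbound messages `m_i = sum_j (A h_j + B e_ij)` over one-hop
#' neighborhoods (sum aggregation) and applies the dense update
#' `h_i = sigma(W m_i + b)`. On an edgeless graph every `m_i` is zero, so
#' every node state becomes `sigma(b)`.
#'
#' @param g a `MolGraph`.
#' @param s `NodeStates` from the previous round.
#' @param layer round index in 1..L.
#' @param p `EncoderParams`.
#' @return updated `NodeStates` (fields `h` and the aggregate `m`).
#' @export
message_step <- function(g, s, layer, p) {
  stopifnot(inherits(s, "NodeStates"), layer >= 1L, layer <= p$L)
  ly <- p$layers[[layer]]
  n <- g$n_nodes
  m <- matrix(0, n, p$hidden_dim)
  if (nrow(g$edges) > 0L) {
    ef <- as.matrix(g$edges[, c("order", "aromatic", "ring")])
    contrib <- s$h[g$edges$j, , drop = FALSE] %*% t(ly$A) + ef %*% t(ly$B)
    m <- rowsum(contrib, group = g$edges$i, reorder = FALSE)
    # rowsum drops nodes with no inbound edges; scatter back
    idx <- as.integer(rownames(m))
    full <- matrix(0, n, p$hidden_dim)
    full[idx, ] <- m
    m <- full
  }
  act <- .encoder_activations[[p$activation]]
  h <- act(m %*% t(ly$W) + matrix(ly$b, n, p$hidden_dim, byrow = TRUE))
  structure(list(h = h, m = m), class = "NodeStates")
}

.softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Scaled-dot-product attention over all nodes
#'
#' Projects the final node states to queries, keys and values, and returns
#' each node's attention-weighted sum of values over all nodes (multi-head;
#' heads are concatenated). Scaling divides raw scores by `sqrt(d_head)`
#' (default) or by `d_head`.
#'
#' @param s `NodeStates` after the final message-passing round.
#' @param p `EncoderParams`.
#' @return an `AttentionOutput`: `A` (n x d attended vectors) and
#'   `attn_weights` (list, one n x n row-stochastic matrix per head).
#' @export
attend <- function(s, p) {
  stopifnot(inherits(s, "NodeStates"))
  H <- s$h
  Q <- H %*% t(p$Wq); K <- H %*% t(p$Wk); V <- H %*% t(p$Wv)
  dh <- p$d / p$n_heads
  scale <- if (p$attn_scale == "sqrt_d") sqrt(dh) else dh
  A <- matrix(0, nrow(H), p$d)
  weights <- vector("list", p$n_heads)
  for (h in seq_len(p$n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / scale
    W <- .softmax_rows(S)
    A[, cols] <- W %*% V[, cols, drop = FALSE]
    weights[[h]] <- W
  }
  structure(list(A = A, attn_weights = weights), class = "AttentionOutput")
}

#' Encode a molecular graph to a fixed-length embedding
#'
#' Runs initialization, `L` message-passing rounds, the attention block, and
#' mean-pools the attended node vectors. Permutation-invariant: relabeling
#' the atoms changes the embedding only by floating-point noise.
#'
#' @param g a `MolGraph`.
#' @param p `EncoderParams`.
#' @return numeric embedding of length `p$d`.
#' @export
encode_graph <- function(g, p) {
  s <- init_states(g, p)
  for (l in seq_len(p$L)) s <- message_step(g, s, l, p)
  out <- attend(s, p)
  colMeans(out$A)
}

#' Embedding provider for a set of molecules
#'
#' @param mols list of `Molecule` objects.
#' @param p `EncoderParams`.
#' @return numeric matrix (n x d), rownames = molecule ids.
#' @export
encode_molecules <- function(mols, p) {
  E <- t(vapply(mols, function(m) encode_graph(m$graph, p),
                numeric(p$d)))
  rownames(E) <- vapply(mols, function(m) m$id, "")
  E
}

#' Precomputed-embedding provider
#'
#' Substitutes [encode_graph()] with stored per-molecule vectors (e.g. an
#' externally trained embedder run offline). The provider returns the stored
#' rows verbatim and errors on unknown ids, naming them.
#'
#' @param table numeric matrix with rownames = molecule ids, or a data.frame
#'   whose first column is `id` followed by numeric embedding columns.
#' @return function `(ids) -> matrix` of embeddings.
#' @export
load_external_embeddings <- function(table) {
  if (is.data.frame(table)) {
    ids <- as.character(table[[1L]])
    M <- as.matrix(table[, -1L, drop = FALSE])
    rownames(M) <- ids
  } else {
    M <- as.matrix(table)
    if (is.null(rownames(M))) stop("embedding table needs row ids")
  }
  storage.mode(M) <- "double"
  function(ids) {
    hit <- match(ids, rownames(M))
    if (anyNA(hit)) {
      stop("missing embedding id(s): ",
           paste(ids[is.na(hit)], collapse = ", "))
    }
    M[hit, , drop = FALSE]
  }
}
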