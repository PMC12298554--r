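#' Relational graph convolution and multi-head graph attention
#'
#' Two stacked message-passing layers update the node (utterance) features:
#'
#' 1. **RGCN** — relation-specific linear maps aggregate each node's FFC and
#'    BFC neighbourhoods, weighted by the initialised edge weights divided
#'    by the neighbourhood size, plus a self term:
#'    `h_i^(1) = act( sum_r sum_{j in N_i^r} (alpha_ij / |N_i^r|) W_r c_j
#'    + alpha_ii W_0 c_i )`, with `alpha_ii = 1` (singleton SELF softmax).
#' 2. **GAT** — K independent attention heads re-weight the (union of the)
#'    FFC/BFC neighbourhoods from the updated features:
#'    `e_ij = a' LeakyReLU(W [h_i , h_j])`, soft-maxed per (destination,
#'    relation, head), then aggregate `h_i^(2,k) = W^k h_i +
#'    sum_j alpha'_ij W^k h_j` and concatenate the K head outputs.
#'
#' All backward passes are exact analytic gradients, validated against
#' finite differences and against dense adjacency-matrix oracles in the
#' test-suite.
#'
#' @name graph_layers
NULL

#' Initialise RGCN parameters
#'
#' @param d_node input (node feature) dimension.
#' @param d_h output dimension.
#' @param act activation, `"relu"` (default) or `"tanh"`.
#' @param degree_norm divide each edge weight by its neighbourhood size
#'   `|N_i^r|` as well as softmax-normalising (default `TRUE`).
#' @param relations character vector of non-self relations with their own
#'   weight matrix.
#' @export
rgcn_init <- function(d_node, d_h, act = "relu", degree_norm = TRUE,
                      relations = c("FFC", "BFC")) {
  Wr <- lapply(relations, function(r) glorot(d_h, d_node))
  names(Wr) <- relations
  list(Wr = Wr, W0 = glorot(d_h, d_node), act = act,
       degree_norm = degree_norm)
}

#' Relational graph convolution forward pass
#'
#' @param g a weighted graph from [init_edge_weights()].
#' @param C node features (n x d_node).
#' @param params from [rgcn_init()].
#' @param keep_cache retain intermediates for backpropagation.
#' @return Matrix (n x d_h); with `keep_cache`, the cache is attached as an
#'   attribute.
#' @export
rgcn_forward <- function(g, C, params, keep_cache = FALSE) {
  if (is.null(g$alpha)) stopf("graph has no edge weights; run init_edge_weights first")
  n <- g$n_nodes
  deg <- edge_degree(g)
  pre <- C %*% t(params$W0)          # alpha_ii = 1 exactly
  agg <- list()
  for (r in names(params$Wr)) {
    ri <- match(r, REL_NAMES)
    e <- which(g$rel == ri)
    if (!length(e)) next
    coef <- g$alpha[e] / (if (params$degree_norm) deg[e] else 1)
    agg[[r]] <- scatter_rowsum(coef * C[g$src[e], , drop = FALSE], g$dst[e], n)
    pre <- pre + agg[[r]] %*% t(params$Wr[[r]])
  }
  H1 <- apply_act(pre, params$act)
  if (keep_cache)
    attr(H1, "cache") <- list(pre = pre, agg = agg, deg = deg)
  H1
}

## Backward for rgcn_forward.  Returns parameter gradients plus dC and the
## gradient on the edge weights (propagated further into Eq. 3).
rgcn_backward <- function(dH1, g, C, params, cache) {
  n <- g$n_nodes
  dpre <- dH1 * act_grad(cache$pre, params$act)
  dC <- dpre %*% params$W0
  dW0 <- crossprod(dpre, C)
  dWr <- lapply(params$Wr, function(W) matrix(0, nrow(W), ncol(W)))
  dalpha <- numeric(length(g$src))
  for (r in names(params$Wr)) {
    ri <- match(r, REL_NAMES)
    e <- which(g$rel == ri)
    if (!length(e)) next
    dWr[[r]] <- crossprod(dpre, cache$agg[[r]])
    dagg <- dpre %*% params$Wr[[r]]                 # (n x d_node)
    dmsg <- dagg[g$dst[e], , drop = FALSE]          # per-edge upstream
    coef_den <- if (params$degree_norm) cache$deg[e] else 1
    Cs <- C[g$src[e], , drop = FALSE]
    dalpha[e] <- rowSums(dmsg * Cs) / coef_den
    dC <- dC + scatter_rowsum(dmsg * (g$alpha[e] / coef_den), g$src[e], n)
  }
  list(dC = dC, dW0 = dW0, dWr = dWr, dalpha = dalpha)
}

#' Initialise multi-head graph-attention parameters
#'
#' @param d_h input dimension (RGCN output).
#' @param d_head per-head output dimension; final width is `K * d_head`.
#' @param K number of attention heads (>= 1).
#' @param leaky_slope negative slope of the LeakyReLU inside the logit.
#' @export
gat_init <- function(d_h, d_head, K = 4L, leaky_slope = 0.2) {
  if (K < 1L) stopf("K must be >= 1")
  heads <- lapply(seq_len(K), function(k)
    list(W = glorot(d_head, d_h), a = runif(2 * d_head, -0.1, 0.1)))
  list(heads = heads, K = as.integer(K), leaky_slope = leaky_slope)
}

#' Attention re-weighting for one head
#'
#' Computes the new edge weights `alpha'` of one attention head from the
#' RGCN output: `e_ij = a' LeakyReLU(W [h_i , h_j])` (i = destination),
#' soft-maxed per (destination, relation).  SELF edges are singleton
#' groups, weight exactly 1.
#'
#' @param g the (weighted or unweighted) graph; only the edge structure is
#'   used.
#' @param H1 node features (n x d_h).
#' @param params from [gat_init()].
#' @param head head index in `1:K`.
#' @return Numeric vector of new weights, one per edge of `g`.
#' @export
gat_reweight <- function(g, H1, params, head = 1L) {
  hp <- params$heads[[head]]
  if (ncol(H1) != ncol(hp$W))
    stopf("H1 has %d columns but head W expects %d", ncol(H1), ncol(hp$W))
  Hw <- H1 %*% t(hp$W)
  ns <- which(g$rel != REL_SELF)
  alpha <- numeric(length(g$src))
  alpha[g$rel == REL_SELF] <- 1
  if (length(ns)) {
    u <- cbind(Hw[g$dst[ns], , drop = FALSE], Hw[g$src[ns], , drop = FALSE])
    v <- leaky_relu(u, params$leaky_slope)
    e <- as.numeric(v %*% hp$a)
    alpha[ns] <- group_softmax(e, edge_group(g)[ns])
  }
  alpha
}

#' Multi-head graph attention forward pass
#'
#' @param g graph (edge structure).
#' @param H1 node features (n x d_h), the RGCN output.
#' @param params from [gat_init()].
#' @param keep_cache retain intermediates for backpropagation.
#' @return Matrix (n x K*d_head), the concatenation of all head outputs.
#' @export
gat_forward <- function(g, H1, params, keep_cache = FALSE) {
  n <- g$n_nodes
  K <- params$K
  d_head <- nrow(params$heads[[1]]$W)
  ns <- which(g$rel != REL_SELF)
  key <- edge_group(g)[ns]
  H2 <- matrix(0, n, K * d_head)
  caches <- vector("list", K)
  for (k in seq_len(K)) {
    hp <- params$heads[[k]]
    Hw <- H1 %*% t(hp$W)
    out <- Hw                                     # self term, alpha'_ii = 1
    ck <- list(Hw = Hw)
    if (length(ns)) {
      u <- cbind(Hw[g$dst[ns], , drop = FALSE], Hw[g$src[ns], , drop = FALSE])
      v <- leaky_relu(u, params$leaky_slope)
      e <- as.numeric(v %*% hp$a)
      al <- group_softmax(e, key)
      out <- out + scatter_rowsum(al * Hw[g$src[ns], , drop = FALSE],
                                  g$dst[ns], n)
      ck$u <- u; ck$v <- v; ck$alpha <- al
    }
    H2[, (k - 1L) * d_head + seq_len(d_head)] <- out
    caches[[k]] <- ck
  }
  if (keep_cache) attr(H2, "cache") <- list(heads = caches, ns = ns, key = key)
  H2
}

## Backward for gat_forward: parameter gradients and dH1.
gat_backward <- function(dH2, g, H1, params, cache) {
  n <- g$n_nodes
  K <- params$K
  d_head <- nrow(params$heads[[1]]$W)
  ns <- cache$ns; key <- cache$key
  dH1 <- matrix(0, nrow(H1), ncol(H1))
  dheads <- vector("list", K)
  for (k in seq_len(K)) {
    hp <- params$heads[[k]]
    ck <- cache$heads[[k]]
    dOut <- dH2[, (k - 1L) * d_head + seq_len(d_head), drop = FALSE]
    dHw <- dOut                                   # self term
    da <- numeric(length(hp$a))
    if (length(ns)) {
      src <- g$src[ns]; dst <- g$dst[ns]
      dmsg <- dOut[dst, , drop = FALSE]
      dalpha <- rowSums(dmsg * ck$Hw[src, , drop = FALSE])
      dHw <- dHw + scatter_rowsum(dmsg * ck$alpha, src, n)
      de <- group_softmax_grad(ck$alpha, dalpha, key)
      da <- colSums(de * ck$v)
      dv <- de %o% hp$a
      du <- dv * ifelse(ck$u > 0, 1, params$leaky_slope)
      dHw <- dHw + scatter_rowsum(du[, seq_len(d_head), drop = FALSE], dst, n)
      dHw <- dHw + scatter_rowsum(du[, d_head + seq_len(d_head), drop = FALSE], src, n)
    }
    dheads[[k]] <- list(W = crossprod(dHw, H1), a = da)
    dH1 <- dH1 + dHw %*% hp$W
  }
  list(dH1 = dH1, dheads = dheads)
}
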