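#' Model configuration
#'
#' Collects every architectural and optimisation hyperparameter.  The
#' defaults are the full-scale settings (GRU hidden size 200, node
#' dimension 160, window 20, 4 attention heads, learning rate 1e-4, weight
#' decay 1e-8, 500 epochs, batch size 50); [desk_config()] provides a small
#' configuration for fast experimentation.
#'
#' @param hidden_units GRU hidden size per direction.
#' @param node_dim node feature dimension after projection.
#' @param project apply the linear projection after modality concatenation.
#' @param Nw total context window (even); Nw/2 neighbours per side.
#' @param heads number of attention heads K.
#' @param d_h RGCN output dimension.
#' @param d_head per-head GAT output dimension (final width K*d_head).
#' @param rgcn_act RGCN activation, `"relu"` or `"tanh"`.
#' @param rgcn_degree_norm divide edge weights by `|N_i^r|` (as well as the
#'   softmax normalisation).
#' @param leaky_slope LeakyReLU slope inside the attention logit.
#' @param head_activation output activation of the scoring head.
#' @param loss `"ccc"` (default) or `"mse"`.
#' @param lr,weight_decay,epochs,batch_size optimiser settings.
#' @param seed integer seed controlling initialisation and batch order.
#' @param variant one of `"full"`, `"no_mil"`, `"no_gnn"`, `"gcn_only"`,
#'   `"no_bfc"`, `"mha_fusion"`.
#' @param modalities modality subset the model consumes.
#' @return An `mignn_config` list.
#' @export
mignn_config <- function(hidden_units = 200L, node_dim = 160L, project = TRUE,
                         Nw = 20L, heads = 4L, d_h = 160L, d_head = 40L,
                         rgcn_act = "relu", rgcn_degree_norm = TRUE,
                         leaky_slope = 0.2,
                         head_activation = "identity",
                         loss = c("ccc", "mse"),
                         lr = 1e-4, weight_decay = 1e-8,
                         epochs = 500L, batch_size = 50L, seed = 1L,
                         variant = c("full", "no_mil", "no_gnn", "gcn_only",
                                     "no_bfc", "mha_fusion"),
                         modalities = c("A", "V", "T")) {
  variant <- match.arg(variant)
  loss <- match.arg(loss)
  stopifnot(hidden_units >= 1, node_dim >= 1, heads >= 1, d_h >= 1,
            d_head >= 1, lr > 0, epochs >= 1, batch_size >= 2,
            Nw >= 0, Nw %% 2 == 0, all(modalities %in% MODALITIES))
  structure(
    list(hidden_units = as.integer(hidden_units),
         node_dim = as.integer(node_dim), project = project,
         Nw = as.integer(Nw), heads = as.integer(heads),
         d_h = as.integer(d_h), d_head = as.integer(d_head),
         rgcn_act = rgcn_act, rgcn_degree_norm = rgcn_degree_norm,
         leaky_slope = leaky_slope, head_activation = head_activation,
         loss = loss, lr = lr, weight_decay = weight_decay,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         seed = as.integer(seed), variant = variant,
         modalities = MODALITIES[MODALITIES %in% modalities]),
    class = "mignn_config")
}

#' Desk-scale configuration
#'
#' A small, fast configuration for synthetic-data experiments: GRU hidden
#' size 8, node dimension 16, RGCN width 16, 4 heads of width 4, learning
#' rate 0.01.  Architecture is unchanged, only widths shrink.
#'
#' @param ... overrides passed to [mignn_config()].
#' @export
desk_config <- function(...) {
  args <- list(...)
  defaults <- list(hidden_units = 8L, node_dim = 16L, d_h = 16L,
                   d_head = 4L, heads = 4L, lr = 0.01, epochs = 60L)
  do.call(mignn_config, utils::modifyList(defaults, args))
}

variant_uses_graph <- function(v) v %in% c("full", "no_mil", "no_bfc", "gcn_only")
variant_uses_gat <- function(v) v %in% c("full", "no_mil", "no_bfc")

head_width <- function(config) {
  config$node_dim + switch(config$variant,
    no_gnn = 0L,
    gcn_only = config$d_h,
    mha_fusion = config$heads * config$d_head,
    config$heads * config$d_head)
}

#' Initialise all trainable parameters
#'
#' Builds the parameter container for the configured variant: per-modality
#' bidirectional GRU weights, the fusion projection, per-relation edge-score
#' matrices, RGCN and GAT weights (or multi-head-attention Q/K/V maps for
#' the `mha_fusion` variant) and the scoring head.  Initialisation is
#' Glorot-uniform for dense maps, orthogonal for recurrent matrices, zero
#' biases; deterministic given `config$seed`.
#'
#' @param config an [mignn_config()].
#' @param dims named per-modality input feature dimensions.
#' @param y_max label-range upper bound (for the `sigmoid_scaled` head).
#' @return An `mignn_params` nested list.
#' @export
mignn_init <- function(config, dims, y_max = 24) {
  stopifnot(inherits(config, "mignn_config"))
  dims <- dims[config$modalities[config$modalities %in% names(dims)]]
  if (!length(dims)) stopf("no overlap between config modalities and data modalities")
  with_seed(config$seed, {
    p <- list()
    p$encoder <- encoder_init(dims, config$hidden_units, config$node_dim,
                              project = config$project)
    v <- config$variant
    rels <- if (v == "no_bfc") "FFC" else c("FFC", "BFC")
    if (variant_uses_graph(v)) {
      p$edge <- list(Wer = setNames(
        lapply(rels, function(r) glorot(config$node_dim, config$node_dim)),
        rels))
      p$rgcn <- rgcn_init(config$node_dim, config$d_h, act = config$rgcn_act,
                          degree_norm = config$rgcn_degree_norm,
                          relations = rels)
    }
    if (variant_uses_gat(v))
      p$gat <- gat_init(config$d_h, config$d_head, K = config$heads,
                        leaky_slope = config$leaky_slope)
    if (v == "mha_fusion")
      p$mha <- list(heads = lapply(seq_len(config$heads), function(k)
        list(Wq = glorot(config$d_head, config$node_dim),
             Wk = glorot(config$d_head, config$node_dim),
             Wv = glorot(config$d_head, config$node_dim))))
    p$head <- head_init(head_width(config), config$head_activation, y_max)
    structure(p, class = "mignn_params")
  })
}

#' Count trainable parameters
#'
#' @param params an `mignn_params` container.
#' @return Integer number of scalar parameters.
#' @export
n_parameters <- function(params) {
  length(params_flatten(params))
}

## Flatten/restore the numeric leaves of the parameter container, skipping
## metadata fields (activation names, flags, head counts, slopes).
NON_TRAINABLE <- c("K", "leaky_slope", "y_max", "act", "activation",
                   "degree_norm")

params_skeleton <- function(params) {
  strip <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[!(names(x) %in% NON_TRAINABLE)]
      kept <- lapply(x, strip)
      kept[!vapply(kept, is.null, logical(1))]
    } else if (is.numeric(x)) x else NULL
  }
  strip(unclass(params))
}

params_flatten <- function(params) {
  as.numeric(unlist(params_skeleton(params), use.names = FALSE))
}

params_unflatten <- function(flat, template) {
  skel <- params_skeleton(template)
  filled <- utils::relist(flat, skel)
  graft <- function(orig, new) {
    if (is.list(orig)) {
      nms <- names(orig)
      j <- 0L                       # position in `new` (stripped structure)
      for (i in seq_along(orig)) {
        nm <- if (is.null(nms)) "" else nms[i]
        if (nm %in% NON_TRAINABLE) next
        if (is.list(orig[[i]]) || is.numeric(orig[[i]])) {
          j <- j + 1L
          orig[[i]] <- graft(orig[[i]], new[[j]])
        }
      }
      orig
    } else if (is.numeric(orig)) {
      dim(new) <- dim(orig)
      new
    } else orig
  }
  out <- graft(unclass(template), filled)
  class(out) <- class(template)
  out
}

## Assemble a batch: stacked per-modality feature matrices + session sizes.
## For the no_mil variant each session collapses to one mean-pooled
## instance before encoding.
make_batch <- function(cohort, variant = "full", modalities = NULL) {
  stopifnot(length(cohort) >= 1)
  mods <- modalities %||% cohort_modalities(cohort)
  mods <- mods[mods %in% cohort_modalities(cohort)]
  sessions <- cohort
  if (variant == "no_mil") {
    sessions <- lapply(cohort, function(s) {
      s$features <- lapply(s$features, function(m)
        matrix(colMeans(m), 1L, ncol(m)))
      s$n_utterances <- 1L
      s
    })
  }
  ns <- vapply(sessions, `[[`, integer(1), "n_utterances")
  off <- c(0L, cumsum(ns))[seq_along(ns)]
  X <- lapply(mods, function(m)
    do.call(rbind, lapply(sessions, function(s) s$features[[m]])))
  names(X) <- mods
  list(X = X, ns = ns, off = off,
       sess_of_row = rep(seq_along(ns), ns),
       labels = cohort_labels(cohort), ids = cohort_ids(cohort),
       modalities = mods)
}

## Multi-head scaled dot-product self-attention over each session's
## utterances (dense within the session) -- the attention-fusion baseline
## that replaces the graph stage in the mha_fusion variant.
mha_forward <- function(batch, C, params, d_head, keep_cache = FALSE) {
  K <- length(params$heads)
  N <- nrow(C)
  H2 <- matrix(0, N, K * d_head)
  caches <- if (keep_cache) vector("list", K) else NULL
  scale <- 1 / sqrt(d_head)
  for (k in seq_len(K)) {
    hp <- params$heads[[k]]
    Q <- C %*% t(hp$Wq); Kmat <- C %*% t(hp$Wk); V <- C %*% t(hp$Wv)
    out <- matrix(0, N, d_head)
    sc <- if (keep_cache) vector("list", length(batch$ns)) else NULL
    for (s in seq_along(batch$ns)) {
      idx <- batch$off[s] + seq_len(batch$ns[s])
      S <- (Q[idx, , drop = FALSE] %*% t(Kmat[idx, , drop = FALSE])) * scale
      S <- S - apply(S, 1, max)
      A <- exp(S); A <- A / rowSums(A)
      out[idx, ] <- A %*% V[idx, , drop = FALSE]
      if (keep_cache) sc[[s]] <- A
    }
    H2[, (k - 1L) * d_head + seq_len(d_head)] <- out
    if (keep_cache) caches[[k]] <- list(Q = Q, Km = Kmat, V = V, A = sc)
  }
  if (keep_cache) attr(H2, "cache") <- caches
  H2
}

mha_backward <- function(dH2, batch, C, params, d_head, cache) {
  K <- length(params$heads)
  dC <- matrix(0, nrow(C), ncol(C))
  dheads <- vector("list", K)
  scale <- 1 / sqrt(d_head)
  for (k in seq_len(K)) {
    hp <- params$heads[[k]]
    ck <- cache[[k]]
    dOut <- dH2[, (k - 1L) * d_head + seq_len(d_head), drop = FALSE]
    dQ <- matrix(0, nrow(C), d_head); dK <- dQ; dV <- dQ
    for (s in seq_along(batch$ns)) {
      idx <- batch$off[s] + seq_len(batch$ns[s])
      A <- ck$A[[s]]
      dO <- dOut[idx, , drop = FALSE]
      dV[idx, ] <- crossprod(A, dO)
      dA <- dO %*% t(ck$V[idx, , drop = FALSE])
      dS <- A * (dA - rowSums(A * dA))
      dQ[idx, ] <- (dS %*% ck$Km[idx, , drop = FALSE]) * scale
      dK[idx, ] <- (crossprod(dS, ck$Q[idx, , drop = FALSE])) * scale
    }
    dheads[[k]] <- list(Wq = crossprod(dQ, C), Wk = crossprod(dK, C),
                        Wv = crossprod(dV, C))
    dC <- dC + dQ %*% hp$Wq + dK %*% hp$Wk + dV %*% hp$Wv
  }
  list(dC = dC, dheads = dheads)
}

#' Full forward pass over a batch of sessions
#'
#' Encodes every modality with the bidirectional GRU, fuses and projects to
#' node features, builds the per-session temporal graphs, runs the
#' variant's graph stage, scores utterances and aggregates bag means.
#'
#' @param params an [mignn_init()] container.
#' @param batch output of `make_batch()` (internal) or a cohort, which is
#'   converted automatically.
#' @param config the [mignn_config()].
#' @param keep_cache retain every intermediate for backpropagation.
#' @return List with `Ybag` (subject scores), `yhat` (utterance scores),
#'   `batch`, and (with `keep_cache`) the cache.
#' @export
mignn_forward <- function(params, batch, config, keep_cache = FALSE) {
  if (is.null(batch$X))                      # a cohort, not a prepared batch
    batch <- make_batch(batch, config$variant, config$modalities)
  v <- config$variant
  cache <- list()
  ## 1. per-modality bidirectional encoding
  ctx <- list(); enc_cache <- list()
  for (m in batch$modalities) {
    prm <- params$encoder$enc[[m]]
    fw <- gru_dir_forward(batch$X[[m]], batch$off, batch$ns, prm$f, reverse = FALSE)
    bw <- gru_dir_forward(batch$X[[m]], batch$off, batch$ns, prm$b, reverse = TRUE)
    ctx[[m]] <- cbind(fw$H, bw$H)
    if (keep_cache) enc_cache[[m]] <- list(f = fw$cache, b = bw$cache)
  }
  fused <- fuse_context(ctx, params$encoder)
  C <- fused$C
  ## 2. graph stage (variant-dependent)
  H2 <- NULL; g <- NULL; H1 <- NULL
  if (variant_uses_graph(v)) {
    g <- build_batch_graph(batch$ns, config$Nw, include_bfc = v != "no_bfc")
    g <- init_edge_weights(g, C, params$edge)
    H1 <- rgcn_forward(g, C, params$rgcn, keep_cache = keep_cache)
    if (variant_uses_gat(v)) {
      H2 <- gat_forward(g, H1, params$gat, keep_cache = keep_cache)
    } else {
      H2 <- H1                                   # gcn_only
    }
  } else if (v == "mha_fusion") {
    H2 <- mha_forward(batch, C, params$mha, config$d_head, keep_cache = keep_cache)
  } else {
    H2 <- matrix(0, nrow(C), 0L)                  # no_gnn
  }
  ## 3. head + bag mean
  Z <- cbind(C, H2)
  lin <- as.numeric(Z %*% t(params$head$Wc)) + params$head$bc
  yhat <- head_act(lin, params$head)
  Ybag <- as.numeric(rowsum(yhat, batch$sess_of_row)) / batch$ns
  out <- list(Ybag = Ybag, yhat = yhat, batch = batch)
  if (keep_cache)
    out$cache <- list(ctx = ctx, enc = enc_cache, pre = fused$pre, C = C,
                      g = g, H1 = H1, H2 = H2, Z = Z, lin = lin)
  out
}

#' Backward pass: exact gradients of the loss in every parameter
#'
#' @param fw output of [mignn_forward()] with `keep_cache = TRUE`.
#' @param dYbag gradient of the loss in the subject-level scores.
#' @param params,config as in [mignn_forward()].
#' @return Gradient container with the same structure as `params`.
#' @export
mignn_backward <- function(fw, dYbag, params, config) {
  v <- config$variant
  batch <- fw$batch; cache <- fw$cache
  grads <- list()
  ## head
  dyhat <- dYbag[batch$sess_of_row] / batch$ns[batch$sess_of_row]
  dlin <- dyhat * head_act_grad(cache$lin, params$head)
  grads$head <- list(Wc = matrix(dlin, 1) %*% cache$Z, bc = sum(dlin))
  dZ <- dlin %o% as.numeric(params$head$Wc)
  d_node <- ncol(cache$C)
  dC <- dZ[, seq_len(d_node), drop = FALSE]
  dH2 <- dZ[, -seq_len(d_node), drop = FALSE]
  ## graph stage
  if (variant_uses_graph(v)) {
    g <- cache$g
    if (variant_uses_gat(v)) {
      gb <- gat_backward(dH2, g, cache$H1, params$gat,
                         attr(cache$H2, "cache"))
      dH1 <- gb$dH1
      grads$gat <- list(heads = gb$dheads)
    } else {
      dH1 <- dH2
    }
    rb <- rgcn_backward(dH1, g, cache$C, params$rgcn,
                        attr(cache$H1, "cache"))
    grads$rgcn <- list(Wr = rb$dWr, W0 = rb$dW0)
    eb <- edge_weights_backward(g, cache$C, params$edge, rb$dalpha)
    grads$edge <- list(Wer = eb$dWer)
    dC <- dC + rb$dC + eb$dC
  } else if (v == "mha_fusion") {
    mb <- mha_backward(dH2, batch, cache$C, params$mha, config$d_head,
                       attr(cache$H2, "cache"))
    grads$mha <- list(heads = mb$dheads)
    dC <- dC + mb$dC
  }
  ## fusion projection
  if (!is.null(params$encoder$Wp)) {
    grads$encoder <- list(Wp = crossprod(dC, cache$pre))
    dpre <- dC %*% params$encoder$Wp
  } else {
    grads$encoder <- list()
    dpre <- dC
  }
  ## split into per-modality context grads, then BPTT
  H2w <- 2L * config$hidden_units
  enc_grads <- list()
  col0 <- 0L
  for (m in batch$modalities) {
    dcm <- dpre[, col0 + seq_len(H2w), drop = FALSE]
    col0 <- col0 + H2w
    prm <- params$encoder$enc[[m]]
    Hu <- config$hidden_units
    gf <- gru_dir_backward(dcm[, seq_len(Hu), drop = FALSE],
                           batch$X[[m]], batch$off, batch$ns,
                           prm$f, cache$enc[[m]]$f)
    gb <- gru_dir_backward(dcm[, Hu + seq_len(Hu), drop = FALSE],
                           batch$X[[m]], batch$off, batch$ns,
                           prm$b, cache$enc[[m]]$b)
    enc_grads[[m]] <- list(f = gf[c("W", "U", "b")], b = gb[c("W", "U", "b")])
  }
  grads$encoder$enc <- enc_grads
  ## order fields to mirror the parameter container exactly
  out <- list()
  out$encoder <- grads$encoder[intersect(names(params$encoder), names(grads$encoder))]
  for (nm in c("edge", "rgcn", "gat", "mha", "head"))
    if (!is.null(grads[[nm]])) out[[nm]] <- grads[[nm]]
  structure(out, class = "mignn_params")
}

#' Predict subject-level scores for a cohort
#'
#' @param params trained parameters.
#' @param cohort an `mignn_cohort`.
#' @param config the model configuration.
#' @return Data frame with session_id, y_true, y_pred.
#' @export
mignn_predict <- function(params, cohort, config) {
  fw <- mignn_forward(params, cohort, config, keep_cache = FALSE)
  data.frame(session_id = fw$batch$ids, y_true = fw$batch$labels,
             y_pred = fw$Ybag, stringsAsFactors = FALSE)
}
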