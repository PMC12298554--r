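#' Multimodal context encoding
#'
#' Each modality's utterance sequence is encoded with an independent
#' single-layer bidirectional gated recurrent unit (GRU): the forward and
#' backward passes are concatenated channel-wise, so row i of the output
#' depends on the whole sequence.  The per-modality contexts are then
#' concatenated in the fixed order (A, V, T) and linearly projected to the
#' node dimension, giving the multimodal context matrix C whose rows become
#' the graph nodes.
#'
#' The GRU cell uses reset/update sigmoid gates and a tanh candidate,
#' `n_t = tanh(W_n x_t + r_t * (U_n h_{t-1}))`,
#' `h_t = (1 - z_t) * n_t + z_t * h_{t-1}`,
#' with unshared weights per modality and per direction.  All gradients are
#' exact analytic backpropagation-through-time, implemented batched over
#' sessions (step t updates every active session at once).
#'
#' @name context_encoder
NULL

## One direction's weight set: W (3H x d) input weights, U (3H x H)
## recurrent weights, b (3H) bias; gate row blocks ordered [r; z; n].
gru_dir_init <- function(d, H) {
  list(W = glorot(3 * H, d), U = orthogonal(3 * H, H), b = numeric(3 * H))
}

#' Initialise encoder parameters
#'
#' @param dims named integer vector of input feature dimensions per modality
#'   (names a subset of A, V, T).
#' @param hidden_units GRU hidden size H per direction (default 200).
#' @param node_dim output node dimension after projection (default 160).
#' @param project add the learned linear projection from the concatenated
#'   width `length(dims) * 2H` down to `node_dim`; if `FALSE`, `node_dim`
#'   must equal the concatenated width.
#' @return Parameter list with one weight set per modality per direction
#'   and, when projecting, the projection matrix `Wp`.
#' @export
encoder_init <- function(dims, hidden_units = 200L, node_dim = 160L,
                         project = TRUE) {
  stopifnot(length(dims) >= 1, all(names(dims) %in% MODALITIES))
  H <- as.integer(hidden_units)
  total <- length(dims) * 2L * H
  if (!project && node_dim != total)
    stopf("without projection node_dim must equal %d (= %d modalities x 2H)",
          total, length(dims))
  enc <- lapply(dims, function(d) list(f = gru_dir_init(d, H),
                                       b = gru_dir_init(d, H)))
  prm <- list(enc = enc)
  if (project) prm$Wp <- glorot(node_dim, total)
  attr(prm, "hidden_units") <- H
  attr(prm, "node_dim") <- if (project) as.integer(node_dim) else total
  prm
}

## Batched single-direction GRU over concatenated sessions.
## X: (N x d) stacked rows; off: 0-based row offset per session; ns: lengths.
gru_dir_forward <- function(X, off, ns, prm, reverse = FALSE) {
  H <- ncol(prm$U) / 1L
  N <- nrow(X)
  XW <- X %*% t(prm$W)
  XW <- XW + rep(prm$b, each = N)
  Hout <- matrix(0, N, H)
  hstate <- matrix(0, length(ns), H)
  tU <- t(prm$U)
  i_r <- seq_len(H); i_z <- H + i_r; i_n <- 2L * H + i_r
  Tmax <- max(ns)
  cache <- vector("list", Tmax)
  for (t in seq_len(Tmax)) {
    act <- which(ns >= t)
    idx <- if (reverse) off[act] + ns[act] - t + 1L else off[act] + t
    hprev <- hstate[act, , drop = FALSE]
    Uh <- hprev %*% tU
    g <- XW[idx, , drop = FALSE]
    r <- sigmoid(g[, i_r, drop = FALSE] + Uh[, i_r, drop = FALSE])
    z <- sigmoid(g[, i_z, drop = FALSE] + Uh[, i_z, drop = FALSE])
    Un <- Uh[, i_n, drop = FALSE]
    nb <- tanh(g[, i_n, drop = FALSE] + r * Un)
    hnew <- (1 - z) * nb + z * hprev
    Hout[idx, ] <- hnew
    hstate[act, ] <- hnew
    cache[[t]] <- list(act = act, idx = idx, hprev = hprev,
                       r = r, z = z, nb = nb, Un = Un)
  }
  list(H = Hout, cache = cache)
}

## Exact BPTT for one direction; returns parameter gradients (and the input
## gradient when need_dx, used only for completeness/testing).
gru_dir_backward <- function(dHout, X, off, ns, prm, cache, need_dx = FALSE) {
  H <- ncol(prm$U)
  dW <- matrix(0, 3 * H, ncol(X)); dU <- matrix(0, 3 * H, H)
  db <- numeric(3 * H)
  dX <- if (need_dx) matrix(0, nrow(X), ncol(X)) else NULL
  dhstate <- matrix(0, length(ns), H)
  for (t in rev(seq_along(cache))) {
    cc <- cache[[t]]
    dh <- dHout[cc$idx, , drop = FALSE] + dhstate[cc$act, , drop = FALSE]
    dz <- dh * (cc$hprev - cc$nb)
    dnb <- dh * (1 - cc$z)
    dhprev <- dh * cc$z
    dn_pre <- dnb * (1 - cc$nb^2)
    dr <- dn_pre * cc$Un
    dUn <- dn_pre * cc$r
    dz_pre <- dz * cc$z * (1 - cc$z)
    dr_pre <- dr * cc$r * (1 - cc$r)
    dG <- cbind(dr_pre, dz_pre, dn_pre)
    dUh <- cbind(dr_pre, dz_pre, dUn)
    dW <- dW + crossprod(dG, X[cc$idx, , drop = FALSE])
    db <- db + colSums(dG)
    dU <- dU + crossprod(dUh, cc$hprev)
    dhprev <- dhprev + dUh %*% prm$U
    if (need_dx) dX[cc$idx, ] <- dG %*% prm$W
    dhstate[cc$act, ] <- dhprev
  }
  list(W = dW, U = dU, b = db, dX = dX)
}

#' Encode one modality's utterance sequence
#'
#' Runs the bidirectional GRU for a single session and modality; the output
#' row i is the channel-wise concatenation of the forward pass at step i and
#' the backward pass at step i, so it depends on the entire sequence.
#'
#' @param X_m numeric matrix (n x d_m), one row per utterance.
#' @param params output of [encoder_init()].
#' @param modality one of `"A"`, `"V"`, `"T"` (must be in `params`).
#' @return Matrix (n x 2H).
#' @export
encode_modality <- function(X_m, params, modality) {
  X_m <- as.matrix(X_m)
  if (nrow(X_m) < 1L) stopf("empty sequence")
  if (!all(is.finite(X_m))) stopf("non-finite input features")
  prm <- params$enc[[modality]]
  if (is.null(prm)) stopf("no encoder weights for modality %s", modality)
  off <- 0L; ns <- nrow(X_m)
  fw <- gru_dir_forward(X_m, off, ns, prm$f, reverse = FALSE)
  bw <- gru_dir_forward(X_m, off, ns, prm$b, reverse = TRUE)
  cbind(fw$H, bw$H)
}

#' Fuse per-modality contexts into the multimodal context matrix
#'
#' Concatenates the per-modality context matrices in the fixed (A, V, T)
#' order restricted to the declared modality set, then applies the linear
#' projection to the node dimension when present.
#'
#' @param contexts named list of (n x 2H) matrices.
#' @param params output of [encoder_init()].
#' @return List with `C` (n x node_dim) and the pre-projection
#'   concatenation `pre`.
#' @export
fuse_context <- function(contexts, params) {
  ord <- MODALITIES[MODALITIES %in% names(contexts)]
  ns <- vapply(contexts, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stopf("row counts differ across modalities: %s", paste(ns, collapse = " vs "))
  pre <- do.call(cbind, contexts[ord])
  C <- if (is.null(params$Wp)) pre else pre %*% t(params$Wp)
  list(C = C, pre = pre)
}
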