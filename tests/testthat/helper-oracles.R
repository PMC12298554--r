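# Independent brute-force oracles: dense adjacency-matrix implementations of
# the edge-weight softmax, the relational graph convolution and the
# attention layer, written with explicit per-node loops.  They share no code
# with the package's sparse edge-list implementations.

leaky <- function(x, s = 0.2) ifelse(x > 0, x, s * x)

# neighbourhood indices of destination i under a relation, window Nw/2
nbr_ffc <- function(i, n, half) {
  lo <- max(1, i - half)
  if (half == 0 || lo > i - 1) integer(0) else lo:(i - 1)
}
nbr_bfc <- function(i, n, half) {
  hi <- min(n, i + half)
  if (half == 0 || hi < i + 1) integer(0) else (i + 1):hi
}

dense_edge_softmax <- function(C, Wer, Nw) {
  n <- nrow(C); half <- Nw / 2
  A <- list(FFC = matrix(0, n, n), BFC = matrix(0, n, n))
  for (i in seq_len(n)) {
    for (r in c("FFC", "BFC")) {
      J <- if (r == "FFC") nbr_ffc(i, n, half) else nbr_bfc(i, n, half)
      if (!length(J)) next
      s <- vapply(J, function(j)
        as.numeric(t(C[i, ]) %*% Wer[[r]] %*% C[j, ]), numeric(1))
      w <- exp(s - max(s)); w <- w / sum(w)
      A[[r]][i, J] <- w
    }
  }
  A
}

dense_rgcn <- function(C, A, Wr, W0, act = "relu", degree_norm = TRUE) {
  n <- nrow(C)
  H <- matrix(0, n, nrow(W0))
  for (i in seq_len(n)) {
    acc <- as.numeric(W0 %*% C[i, ])
    for (r in names(Wr)) {
      J <- which(A[[r]][i, ] > 0)
      if (!length(J)) next
      for (j in J) {
        coef <- A[[r]][i, j] / (if (degree_norm) length(J) else 1)
        acc <- acc + coef * as.numeric(Wr[[r]] %*% C[j, ])
      }
    }
    H[i, ] <- if (act == "relu") pmax(acc, 0) else if (act == "tanh") tanh(acc) else acc
  }
  H
}

# one attention head; returns both the reweighted alphas and the output
dense_gat_head <- function(H1, W, a, Nw, slope = 0.2) {
  n <- nrow(H1); half <- Nw / 2
  Hw <- t(apply(H1, 1, function(h) as.numeric(W %*% h)))
  if (nrow(W) == 1) Hw <- matrix(Hw, ncol = 1)        # apply() drops dims
  out <- Hw                                            # self, alpha = 1
  AL <- list(FFC = matrix(0, n, n), BFC = matrix(0, n, n))
  for (i in seq_len(n)) {
    for (r in c("FFC", "BFC")) {
      J <- if (r == "FFC") nbr_ffc(i, n, half) else nbr_bfc(i, n, half)
      if (!length(J)) next
      e <- vapply(J, function(j)
        sum(a * leaky(c(Hw[i, ], Hw[j, ]))), numeric(1))
      w <- exp(e - max(e)); w <- w / sum(w)
      AL[[r]][i, J] <- w
      for (k in seq_along(J)) out[i, ] <- out[i, ] + w[k] * Hw[J[k], ]
    }
  }
  list(alpha = AL, out = out)
}

# enumeration-based edge counting for the closed-form check
count_pairs <- function(n, Nw) {
  half <- Nw / 2
  ffc <- 0; bfc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j < i && i - j <= half) ffc <- ffc + 1
    if (j > i && j - i <= half) bfc <- bfc + 1
  }
  c(FFC = ffc, BFC = bfc, SELF = n)
}

# small random cohort builder used across tests
tiny_cohort <- function(n_sessions = 3, n_range = c(3, 6),
                        dims = c(A = 3, V = 4, T = 2), scale = "PHQ8",
                        seed = 1) {
  cfg <- synthetic_config(n_subjects = n_sessions, n_utterances = n_range,
                          dims = dims, scale = scale, seed = seed)
  generate_cohort(cfg)$cohort
}

tiny_config <- function(...) {
  desk_config(hidden_units = 3L, node_dim = 5L, d_h = 4L, d_head = 3L,
              heads = 2L, Nw = 4L, ...)
}
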