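#' Windowed dual-relation temporal graph
#'
#' The temporal graph over a session's utterances has one node per
#' utterance and three edge relations:
#'
#' * **FFC** (forward-full-connection): edges j -> i from each of the Nw/2
#'   utterances *before* i, carrying information forward in time;
#' * **BFC** (backward-full-connection): edges j -> i from each of the Nw/2
#'   utterances *after* i, carrying information backward;
#' * **SELF**: exactly one self-loop per node, treated as its own relation.
#'
#' `Nw` is the *total* context window, split Nw/2 per side; windows truncate
#' at the sequence boundaries.  Sliding the window along the sequence with
#' step 1 yields exactly this edge set, so a single graph per session
#' suffices.  Edge weights are initialised with a bilinear attention score
#' `s_ij = c_i' W_er c_j` soft-maxed per (destination, relation); since SELF
#' is a singleton relation its weight is exactly 1.
#'
#' @name graph_builder
NULL

REL_FFC <- 1L
REL_BFC <- 2L
REL_SELF <- 3L
REL_NAMES <- c("FFC", "BFC", "SELF")

#' Build the edge structure for one session
#'
#' @param n number of utterances (nodes), >= 1.
#' @param Nw even non-negative total window size; Nw/2 neighbours per side.
#' @param include_bfc drop the BFC relation when `FALSE` (ablation).
#' @return An `mignn_graph`: integer vectors `src`, `dst`, `rel`
#'   (1 = FFC, 2 = BFC, 3 = SELF), `n_nodes`, `Nw`, and unset weights
#'   `alpha = NULL`.
#' @export
build_edges <- function(n, Nw, include_bfc = TRUE) {
  if (length(n) != 1L || n < 1L || n != round(n)) stopf("n must be a positive integer")
  if (length(Nw) != 1L || Nw < 0L || Nw %% 2L != 0L)
    stopf("Nw must be even and non-negative (got %s); it is halved per side", Nw)
  n <- as.integer(n); half <- as.integer(Nw / 2)
  src <- integer(0); dst <- integer(0); rel <- integer(0)
  if (half > 0L && n > 1L) {
    for (d in seq_len(min(half, n - 1L))) {
      i <- (d + 1L):n                      # FFC: j = i - d -> i
      src <- c(src, i - d); dst <- c(dst, i); rel <- c(rel, rep(REL_FFC, length(i)))
      if (include_bfc) {                   # BFC: j = i + d -> i
        i2 <- seq_len(n - d)
        src <- c(src, i2 + d); dst <- c(dst, i2); rel <- c(rel, rep(REL_BFC, length(i2)))
      }
    }
  }
  src <- c(src, seq_len(n)); dst <- c(dst, seq_len(n))
  rel <- c(rel, rep(REL_SELF, n))
  o <- order(rel, dst, src)
  structure(list(src = src[o], dst = dst[o], rel = rel[o],
                 n_nodes = n, Nw = as.integer(Nw), alpha = NULL),
            class = "mignn_graph")
}

#' @export
print.mignn_graph <- function(x, ...) {
  cnt <- tabulate(x$rel, 3L)
  cat(sprintf("<mignn_graph> %d nodes, Nw=%d: %d FFC, %d BFC, %d SELF edges%s\n",
              x$n_nodes, x$Nw, cnt[1], cnt[2], cnt[3],
              if (is.null(x$alpha)) " (weights unset)" else " (weighted)"))
  invisible(x)
}

## Per-(destination, relation) group key; unique across relations.
edge_group <- function(g) g$dst + as.numeric(g$n_nodes) * (g$rel - 1L)

## |N_i^r| for every edge's (dst, rel) group (SELF included, degree 1).
edge_degree <- function(g) {
  f <- group_id(edge_group(g))
  cnt <- tabulate(f)
  cnt[f]
}

#' Initialise edge weights from node features
#'
#' Scores every non-self edge with the bilinear form
#' `s_ij = c_i' W_er c_j` (i = destination, j = source, W_er per relation)
#' and normalises by softmax within each (destination, relation) group.
#' SELF edges form singleton groups, so their weight is exactly 1.
#'
#' @param g an unweighted [build_edges()] graph.
#' @param C node feature matrix (n x d).
#' @param params list with `Wer`, a list of (d x d) matrices named
#'   `FFC`/`BFC`.
#' @return The graph with `alpha` set (and the raw scores cached for
#'   backpropagation).
#' @export
init_edge_weights <- function(g, C, params) {
  stopifnot(inherits(g, "mignn_graph"))
  if (nrow(C) != g$n_nodes)
    stopf("C has %d rows but graph has %d nodes", nrow(C), g$n_nodes)
  scores <- numeric(length(g$src))
  for (r in c(REL_FFC, REL_BFC)) {
    e <- which(g$rel == r)
    if (!length(e)) next
    W <- params$Wer[[REL_NAMES[r]]]
    if (is.null(W)) stopf("missing Wer for relation %s", REL_NAMES[r])
    if (ncol(W) != ncol(C) || nrow(W) != ncol(C))
      stopf("Wer[%s] is %dx%d but node features have %d columns",
            REL_NAMES[r], nrow(W), ncol(W), ncol(C))
    scores[e] <- rowSums((C[g$dst[e], , drop = FALSE] %*% W) *
                           C[g$src[e], , drop = FALSE])
  }
  key <- edge_group(g)
  ns <- which(g$rel != REL_SELF)
  alpha <- numeric(length(scores))
  alpha[ns] <- group_softmax(scores[ns], key[ns])
  alpha[g$rel == REL_SELF] <- 1
  g$alpha <- alpha
  attr(g, "scores") <- scores
  g
}

## Backward through init_edge_weights: given d(alpha) for every edge,
## returns dC and dWer.  SELF weights are constant (singleton softmax), so
## their gradient is identically zero.
edge_weights_backward <- function(g, C, params, dalpha) {
  key <- edge_group(g)
  ns <- which(g$rel != REL_SELF)
  dC <- matrix(0, nrow(C), ncol(C))
  dWer <- lapply(params$Wer, function(W) matrix(0, nrow(W), ncol(W)))
  if (!length(ns)) return(list(dC = dC, dWer = dWer))
  dscore <- numeric(length(dalpha))
  dscore[ns] <- group_softmax_grad(g$alpha[ns], dalpha[ns], key[ns])
  for (r in c(REL_FFC, REL_BFC)) {
    e <- which(g$rel == r)
    if (!length(e)) next
    W <- params$Wer[[REL_NAMES[r]]]
    ds <- dscore[e]
    Cd <- C[g$dst[e], , drop = FALSE]; Cs <- C[g$src[e], , drop = FALSE]
    dWer[[REL_NAMES[r]]] <- dWer[[REL_NAMES[r]]] + crossprod(Cd * ds, Cs)
    dC <- dC + scatter_rowsum((Cs %*% t(W)) * ds, g$dst[e], nrow(C))
    dC <- dC + scatter_rowsum((Cd %*% W) * ds, g$src[e], nrow(C))
  }
  list(dC = dC, dWer = dWer)
}

## Concatenate per-session graphs into one block-diagonal batch graph with
## 0-based node offsets; group keys stay disjoint across sessions.
build_batch_graph <- function(ns, Nw, include_bfc = TRUE) {
  off <- c(0L, cumsum(ns))[seq_along(ns)]
  parts <- lapply(seq_along(ns), function(s) {
    g <- build_edges(ns[s], Nw, include_bfc = include_bfc)
    list(src = g$src + off[s], dst = g$dst + off[s], rel = g$rel,
         sess = rep(s, length(g$src)))
  })
  structure(list(src = unlist(lapply(parts, `[[`, "src")),
                 dst = unlist(lapply(parts, `[[`, "dst")),
                 rel = unlist(lapply(parts, `[[`, "rel")),
                 sess = unlist(lapply(parts, `[[`, "sess")),
                 n_nodes = sum(ns), Nw = as.integer(Nw), alpha = NULL),
            class = "mignn_graph")
}

#' Dump a weighted graph's edge list
#'
#' @param g a weighted graph.
#' @param path optional TSV output path; when `NULL` the data frame is
#'   returned only.
#' @return Data frame with columns src, dst, relation, alpha.
#' @export
dump_graph <- function(g, path = NULL) {
  stopifnot(inherits(g, "mignn_graph"))
  df <- data.frame(src = g$src, dst = g$dst,
                   relation = REL_NAMES[g$rel],
                   alpha = if (is.null(g$alpha)) NA_real_ else g$alpha)
  if (!is.null(path))
    data.table::fwrite(df, path, sep = "\t")
  df
}
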