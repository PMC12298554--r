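#' @importFrom stats rnorm runif setNames cor sd
#' @importFrom utils relist
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

relu <- function(x) pmax(x, 0)

#' Apply an activation function by name
#'
#' @param x numeric vector/matrix
#' @param act one of "relu", "tanh", "identity"
#' @keywords internal
apply_act <- function(x, act) {
  switch(act,
    relu = pmax(x, 0),
    tanh = tanh(x),
    identity = x,
    stop("unknown activation: ", act)
  )
}

act_grad <- function(pre, act) {
  switch(act,
    relu = (pre > 0) * 1,
    tanh = 1 - tanh(pre)^2,
    identity = array(1, dim = dim(pre)),
    stop("unknown activation: ", act)
  )
}

## Map arbitrary group labels to dense 1..k integer ids (first-appearance
## order), so per-group reductions can use integer indexing.
group_id <- function(group) match(group, unique(group))

## max per group, expanded back to element order (f must be dense 1..k ids)
group_expand <- function(stat, f) stat[f]

## softmax within groups: x is a numeric vector, group a vector of equal
## length; returns weights summing to 1 within each group.  Max-shifted for
## numerical stability.
group_softmax <- function(x, group) {
  if (length(x) == 0L) return(numeric(0))
  f <- group_id(group)
  k <- max(f)
  gmax <- rep(-Inf, k)
  ## vapply over split is slower than this two-pass trick for small groups
  o <- order(f, x)
  gmax[f[o]] <- x[o]            # last write per group = group max
  ex <- exp(x - gmax[f])
  gsum <- as.numeric(rowsum(ex, f, reorder = TRUE))
  ex / gsum[f]
}

## Backward through group_softmax: given alpha (the softmax output) and
## upstream gradients dalpha, returns dx for the pre-softmax scores.
group_softmax_grad <- function(alpha, dalpha, group) {
  if (length(alpha) == 0L) return(numeric(0))
  f <- group_id(group)
  gdot <- as.numeric(rowsum(alpha * dalpha, f, reorder = TRUE))
  alpha * (dalpha - gdot[f])
}

## Sum rows of `x` into `n_out` rows indexed by `index` (1-based); rows of x
## with the same index accumulate.  Deterministic (rowsum is).
scatter_rowsum <- function(x, index, n_out) {
  out <- matrix(0, n_out, ncol(x))
  if (nrow(x) == 0L) return(out)
  rs <- rowsum(x, group = index)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

## Glorot-uniform matrix (nrow = fan_out, ncol = fan_in)
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

## Orthogonal init for recurrent weights (rows >= cols assumed square here)
orthogonal <- function(nr, nc) {
  a <- matrix(rnorm(max(nr, nc)^2), max(nr, nc))
  q <- qr.Q(qr(a))
  q[seq_len(nr), seq_len(nc), drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
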