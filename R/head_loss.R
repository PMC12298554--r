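#' Utterance scoring head, bag-mean aggregation and CCC loss
#'
#' Every utterance gets a scalar score from a linear head over the
#' concatenation of its contextual embedding and its graph-updated feature,
#' `yhat_i = act(W_c [c_i , h_i^(2)] + b_c)`.  Supervision is
#' multiple-instance: only the subject (bag) carries a label, and the
#' subject-level prediction is *exactly* the arithmetic mean of the
#' utterance scores.  Training minimises `1 - CCC` over the subject-level
#' predictions of a batch, where CCC is the concordance correlation
#' coefficient computed with population (1/N) moments:
#' `CCC = 2 cov(f, y) / (var(f) + var(y) + (mean(f) - mean(y))^2)`.
#'
#' @name head_and_loss
NULL

#' Initialise head parameters
#'
#' @param width input width (`d_node + K*d_head` for the full model).
#' @param activation `"identity"` (default), `"relu"`, or
#'   `"sigmoid_scaled"` (sigmoid times `y_max`, constraining scores to the
#'   label range).
#' @param y_max label-range upper bound, used by `sigmoid_scaled` only.
#' @export
head_init <- function(width, activation = "identity", y_max = 24) {
  list(Wc = glorot(1, width), bc = 0,
       activation = activation, y_max = y_max)
}

head_act <- function(lin, params) {
  switch(params$activation,
    identity = lin,
    relu = pmax(lin, 0),
    sigmoid_scaled = params$y_max * sigmoid(lin),
    stop("unknown head activation: ", params$activation))
}

head_act_grad <- function(lin, params) {
  switch(params$activation,
    identity = rep(1, length(lin)),
    relu = as.numeric(lin > 0),
    sigmoid_scaled = {
      s <- sigmoid(lin); params$y_max * s * (1 - s)
    })
}

#' Score a session's utterances and aggregate to a subject score
#'
#' @param C contextual embeddings (n x d_node).
#' @param H2 graph-updated features (n x d), or a zero-column matrix when
#'   the graph stage is ablated.
#' @param params from [head_init()].
#' @return List with `per_utterance` (length-n scores) and `subject_score`
#'   (their arithmetic mean, exactly).
#' @export
predict_session <- function(C, H2, params) {
  if (nrow(C) != nrow(H2))
    stopf("C has %d rows but H2 has %d", nrow(C), nrow(H2))
  Z <- cbind(C, H2)
  if (ncol(Z) != ncol(params$Wc))
    stopf("head expects width %d but got %d", ncol(params$Wc), ncol(Z))
  lin <- as.numeric(Z %*% t(params$Wc)) + params$bc
  y <- head_act(lin, params)
  list(per_utterance = y, subject_score = mean(y))
}

#' Concordance correlation coefficient
#'
#' Population-moment form: `2 cov(f,y) / (var f + var y + (mu_f - mu_y)^2)`.
#' Equals 1 for identical non-constant vectors, 0 when one vector is
#' constant and the other varies, and -1 under perfect anticorrelation with
#' matched means and variances.  For two identical constant vectors (zero
#' denominator) it returns 1 by continuity.
#'
#' @param preds,labels numeric vectors of equal length >= 2.
#' @return CCC in `[-1, 1]`.
#' @export
ccc <- function(preds, labels) {
  if (length(preds) != length(labels))
    stopf("length mismatch: %d predictions vs %d labels",
          length(preds), length(labels))
  if (length(preds) < 2L) stopf("CCC needs at least 2 pairs")
  n <- length(preds)
  mf <- mean(preds); my <- mean(labels)
  vf <- mean((preds - mf)^2); vy <- mean((labels - my)^2)
  cfy <- mean((preds - mf) * (labels - my))
  den <- vf + vy + (mf - my)^2
  if (den == 0) return(1)     # both constant with equal means
  2 * cfy / den
}

#' CCC loss
#'
#' `1 - CCC`; ranges over `[0, 2]` and is differentiable in the predictions
#' wherever the denominator is positive.
#'
#' @inheritParams ccc
#' @export
ccc_loss <- function(preds, labels) 1 - ccc(preds, labels)

## Analytic gradient of ccc_loss w.r.t. preds:
## dCCC/df_i = (2/n) [ (y_i - mu_y) - CCC ((f_i - mu_f) + (mu_f - mu_y)) ] / den
ccc_loss_grad <- function(preds, labels) {
  n <- length(preds)
  mf <- mean(preds); my <- mean(labels)
  vf <- mean((preds - mf)^2); vy <- mean((labels - my)^2)
  cfy <- mean((preds - mf) * (labels - my))
  den <- vf + vy + (mf - my)^2
  if (den == 0) return(rep(0, n))
  val <- 2 * cfy / den
  dccc <- (2 / n) * ((labels - my) - val * ((preds - mf) + (mf - my))) / den
  -dccc
}

mse_loss <- function(preds, labels) mean((preds - labels)^2)

mse_loss_grad <- function(preds, labels) 2 * (preds - labels) / length(preds)

#' Cohort-level metrics
#'
#' @param preds subject-level predictions.
#' @param labels subject-level ground-truth severities.
#' @return A `MetricsReport` list: `mae`, `rmse`, `ccc`, `n_subjects`.
#' @export
evaluate <- function(preds, labels) {
  if (!length(preds)) stopf("empty cohort")
  if (length(preds) != length(labels))
    stopf("length mismatch: %d predictions vs %d labels",
          length(preds), length(labels))
  list(mae = mean(abs(preds - labels)),
       rmse = sqrt(mean((preds - labels)^2)),
       ccc = if (length(preds) >= 2) ccc(preds, labels) else NA_real_,
       n_subjects = length(preds))
}
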