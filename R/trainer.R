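#' Training, ablation and sweep harness
#'
#' Sessions (bags) are the batch unit; each optimisation step runs the full
#' forward/backward over one batch of sessions and minimises the configured
#' loss (CCC by default, computed over the batch's subject-level scores —
#' batch moments are meaningful at the default batch size of 50).  The
#' optimiser is Adam with L2 weight decay added to the gradient.  Batch
#' order is reshuffled every epoch from the seeded RNG, so two runs with
#' the same seed produce identical loss trajectories on one platform.
#' Model selection keeps the parameters with the best development-set CCC.
#'
#' @name trainer
NULL

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

batch_loss_and_grad <- function(params, batch, config, labels) {
  fw <- mignn_forward(params, batch, config, keep_cache = TRUE)
  if (config$loss == "ccc") {
    loss <- ccc_loss(fw$Ybag, labels)
    dY <- ccc_loss_grad(fw$Ybag, labels)
  } else {
    loss <- mse_loss(fw$Ybag, labels)
    dY <- mse_loss_grad(fw$Ybag, labels)
  }
  grads <- mignn_backward(fw, dY, params, config)
  list(loss = loss, grads = grads)
}

#' Train the model
#'
#' @param cohort_train,cohort_dev training and development cohorts.
#' @param config an [mignn_config()]; `config$seed` controls
#'   initialisation and batch order.
#' @param params optional warm-start parameters.
#' @param verbose print one line per `verbose` epochs (0 = silent).
#' @return List with `params` (best by dev CCC), `final_params`, `log`
#'   (data frame: epoch, train_loss, dev_ccc, dev_rmse, dev_mae),
#'   `best_epoch` and the `config`.
#' @export
mignn_train <- function(cohort_train, cohort_dev, config, params = NULL,
                        verbose = 0L) {
  stopifnot(length(cohort_train) >= 2, length(cohort_dev) >= 2)
  dims <- cohort_dims(cohort_train)
  y_max <- SCALE_RANGE[[cohort_train[[1]]$scale]][2]
  if (is.null(params)) params <- mignn_init(config, dims, y_max = y_max)
  theta <- params_flatten(params)
  st <- adam_state(length(theta))
  dev_batch <- make_batch(cohort_dev, config$variant, config$modalities)
  dev_labels <- dev_batch$labels
  n_tr <- length(cohort_train)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    dev_ccc = numeric(0), dev_rmse = numeric(0),
                    dev_mae = numeric(0))
  best <- list(ccc = -Inf, theta = theta, epoch = 0L)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = config$batch_size)
      ## merge a trailing singleton into the previous batch (CCC needs >= 2)
      if (length(starts) > 1L && n_tr - starts[length(starts)] + 1L < 2L)
        starts <- starts[-length(starts)]
      ep_losses <- numeric(0)
      for (b in seq_along(starts)) {
        take <- ord[starts[b]:min(n_tr, if (b < length(starts))
          starts[b + 1L] - 1L else n_tr)]
        sub <- cohort_train[take]
        batch <- make_batch(sub, config$variant, config$modalities)
        lg <- batch_loss_and_grad(params, batch, config,
                                  cohort_labels(sub))
        if (!is.finite(lg$loss))
          stopf("non-finite loss at epoch %d, batch %d", ep, b)
        grad <- params_flatten(lg$grads) + config$weight_decay * theta
        upd <- adam_step(theta, grad, st, config$lr)
        theta <- upd$theta; st <- upd$state
        params <- params_unflatten(theta, params)
        ep_losses <- c(ep_losses, lg$loss)
      }
      fw_dev <- mignn_forward(params, dev_batch, config)
      mr <- evaluate(fw_dev$Ybag, dev_labels)
      log <- rbind(log, data.frame(epoch = ep,
                                   train_loss = mean(ep_losses),
                                   dev_ccc = mr$ccc, dev_rmse = mr$rmse,
                                   dev_mae = mr$mae))
      if (is.finite(mr$ccc) && mr$ccc > best$ccc)
        best <- list(ccc = mr$ccc, theta = theta, epoch = ep)
      if (verbose > 0 && ep %% verbose == 0)
        message(sprintf("epoch %3d  loss %.4f  dev CCC %.3f  RMSE %.3f",
                        ep, mean(ep_losses), mr$ccc, mr$rmse))
    }
  })
  list(params = params_unflatten(best$theta, params),
       final_params = params, log = log, best_epoch = best$epoch,
       config = config)
}

#' Train and evaluate one model variant
#'
#' Variant semantics: `no_mil` collapses each session to a single
#' mean-pooled instance; `no_gnn` predicts from the context matrix alone;
#' `gcn_only` skips the attention stage; `no_bfc` drops the
#' backward-full-connection relation; `mha_fusion` replaces the graph
#' layers with dense multi-head self-attention over utterances.
#'
#' @param cohort_train,cohort_dev,cohort_test cohorts; `cohort_test` may be
#'   `NULL`, in which case metrics are reported on the dev set.
#' @param config configuration carrying `variant`.
#' @return A `MetricsReport` list with the fitted model attached as
#'   attribute `"fit"`.
#' @export
run_variant <- function(cohort_train, cohort_dev, cohort_test = NULL,
                        config) {
  fit <- mignn_train(cohort_train, cohort_dev, config)
  eval_cohort <- cohort_test %||% cohort_dev
  pred <- mignn_predict(fit$params, eval_cohort, config)
  mr <- evaluate(pred$y_pred, pred$y_true)
  attr(mr, "fit") <- fit
  mr
}

#' Window / heads sweep
#'
#' Runs a grid over the context window `Nw` and the number of attention
#' heads with shared seeds, mirroring the window-size and head-count
#' experiments.  Per-cell failures are recorded, not propagated.
#'
#' @param cohort_train,cohort_dev,cohort_test cohorts.
#' @param config base configuration.
#' @param nw_grid,heads_grid integer grids; the default grids are
#'   `c(0, 10, 16, 20, 24, 30, 40)` and `3:6`.
#' @param out_csv optional path for the result table.
#' @return Data frame with one row per (Nw, heads) cell: metrics or the
#'   error message.
#' @export
mignn_sweep <- function(cohort_train, cohort_dev, cohort_test = NULL, config,
                        nw_grid = c(0L, 10L, 16L, 20L, 24L, 30L, 40L),
                        heads_grid = 3:6, out_csv = NULL) {
  rows <- list()
  for (nw in nw_grid) for (k in heads_grid) {
    cfg <- config
    cfg$Nw <- as.integer(nw); cfg$heads <- as.integer(k)
    res <- tryCatch({
      mr <- run_variant(cohort_train, cohort_dev, cohort_test, cfg)
      data.frame(Nw = nw, heads = k, mae = mr$mae, rmse = mr$rmse,
                 ccc = mr$ccc, error = NA_character_)
    }, error = function(e)
      data.frame(Nw = nw, heads = k, mae = NA_real_, rmse = NA_real_,
                 ccc = NA_real_, error = conditionMessage(e)))
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) data.table::fwrite(out, out_csv)
  out
}
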