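# End-to-end forward/backward assembly across ablation variants.

test_that("parameter containers flatten and restore losslessly", {
  cfg <- tiny_config()
  p <- mignn_init(cfg, c(A = 3, V = 4, T = 2))
  th <- mignn:::params_flatten(p)
  p2 <- mignn:::params_unflatten(th + 1, p)
  expect_equal(mignn:::params_flatten(p2), th + 1)
  expect_equal(p2$gat$K, p$gat$K)                 # metadata untouched
  expect_equal(p2$head$activation, p$head$activation)
  p3 <- mignn:::params_unflatten(th, p)
  expect_equal(p3, p, tolerance = 0)
})

test_that("head width tracks the variant architecture", {
  dims <- c(A = 3, V = 4, T = 2)
  widths <- vapply(c(full = "full", no_gnn = "no_gnn", gcn_only = "gcn_only",
                     mha = "mha_fusion"), function(v) {
    cfg <- tiny_config(variant = v)
    p <- mignn_init(cfg, dims)
    ncol(p$head$Wc)
  }, integer(1))
  expect_equal(unname(widths), c(5 + 2 * 3, 5, 5 + 4, 5 + 2 * 3))
})

test_that("no_gnn prediction is exactly the head applied to the context matrix", {
  cfg <- tiny_config(variant = "no_gnn")
  cohort <- tiny_cohort(2, seed = 21)
  p <- mignn_init(cfg, c(A = 3, V = 4, T = 2))
  fw <- mignn_forward(p, cohort, cfg)
  batch <- mignn:::make_batch(cohort, "no_gnn")
  ctx <- lapply(setNames(nm = names(batch$X)), function(m)
    do.call(rbind, lapply(cohort, function(s)     # per-session encoding
      encode_modality(s$features[[m]], p$encoder, m))))
  C <- fuse_context(ctx, p$encoder)$C
  manual <- vapply(seq_along(cohort), function(s) {
    idx <- batch$off[s] + seq_len(batch$ns[s])
    predict_session(C[idx, , drop = FALSE],
                    matrix(0, batch$ns[s], 0), p$head)$subject_score
  }, numeric(1))
  expect_equal(fw$Ybag, manual, tolerance = 1e-12)
})

test_that("no_bfc builds graphs without BFC edges but with unchanged FFC edges", {
  g_full <- mignn:::build_batch_graph(c(5L, 7L), 4L, include_bfc = TRUE)
  g_nb <- mignn:::build_batch_graph(c(5L, 7L), 4L, include_bfc = FALSE)
  expect_equal(sum(g_nb$rel == 2L), 0L)
  expect_equal(sum(g_nb$rel == 1L), sum(g_full$rel == 1L))
  expect_equal(sum(g_nb$rel == 3L), 12L)
})

test_that("ablations strictly shrink the parameter count in the documented order", {
  dims <- c(A = 3, V = 4, T = 2)
  n_par <- function(v) n_parameters(mignn_init(tiny_config(variant = v), dims))
  expect_lt(n_par("no_bfc"), n_par("full"))
  expect_lt(n_par("gcn_only"), n_par("full"))
  expect_lt(n_par("no_gnn"), n_par("gcn_only"))
})

test_that("analytic gradients match finite differences for every variant", {
  for (v in c("full", "no_bfc", "gcn_only", "no_gnn", "mha_fusion", "no_mil")) {
    cfg <- tiny_config(variant = v, seed = 5L)
    cohort <- tiny_cohort(2, seed = 31)
    labels <- mignn:::cohort_labels(cohort)
    p <- mignn_init(cfg, c(A = 3, V = 4, T = 2))
    batch <- mignn:::make_batch(cohort, cfg$variant, cfg$modalities)
    fw <- mignn_forward(p, batch, cfg, keep_cache = TRUE)
    gr <- mignn_backward(fw, mignn:::ccc_loss_grad(fw$Ybag, labels), p, cfg)
    ga <- mignn:::params_flatten(gr)
    th <- mignn:::params_flatten(p)
    f <- function(vv) ccc_loss(
      mignn_forward(mignn:::params_unflatten(vv, p), batch, cfg)$Ybag, labels)
    set.seed(7)
    idx <- sample(length(th), 40)
    h <- 1e-6
    gn <- vapply(idx, function(i) {
      e <- numeric(length(th)); e[i] <- h
      (f(th + e) - f(th - e)) / (2 * h)
    }, numeric(1))
    expect_equal(ga[idx], gn, tolerance = 1e-5,
                 label = sprintf("analytic grad (%s)", v))
  }
})

test_that("the forward pass is deterministic for fixed parameters", {
  cfg <- tiny_config()
  cohort <- tiny_cohort(3, seed = 41)
  p <- mignn_init(cfg, c(A = 3, V = 4, T = 2))
  expect_identical(mignn_forward(p, cohort, cfg)$Ybag,
                   mignn_forward(p, cohort, cfg)$Ybag)
})

test_that("no_mil collapses every session to a single mean-pooled instance", {
  cohort <- tiny_cohort(2, seed = 51)
  batch <- mignn:::make_batch(cohort, "no_mil")
  expect_equal(batch$ns, c(1L, 1L))
  expect_equal(batch$X$A[1, ], colMeans(cohort[[1]]$features$A))
})
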