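weighted_graph <- function(n, Nw, d, seed = 1) {
  set.seed(seed)
  C <- matrix(rnorm(n * d), n)
  Wer <- list(FFC = matrix(rnorm(d * d), d), BFC = matrix(rnorm(d * d), d))
  g <- init_edge_weights(build_edges(n, Nw), C, list(Wer = Wer))
  list(g = g, C = C, Wer = Wer)
}

test_that("a single-node graph reduces RGCN to the activated self term", {
  wg <- weighted_graph(1, 4, 3)
  prm <- rgcn_init(3, 2, act = "relu")
  H1 <- rgcn_forward(wg$g, wg$C, prm)
  expect_equal(H1, pmax(wg$C %*% t(prm$W0), 0))
})

test_that("identity weights with uniform alpha equal neighbourhood means plus self", {
  n <- 5
  wg <- weighted_graph(n, 4, 3, seed = 2)
  g <- wg$g
  g$alpha[g$rel != 3L] <- 1 / mignn:::edge_degree(g)[g$rel != 3L]  # uniform
  prm <- list(Wr = list(FFC = diag(3), BFC = diag(3)), W0 = diag(3),
              act = "identity", degree_norm = FALSE)
  H1 <- rgcn_forward(g, wg$C, prm)
  manual <- wg$C
  for (i in seq_len(n)) {
    for (r in 1:2) {
      J <- g$src[g$rel == r & g$dst == i]
      if (length(J)) manual[i, ] <- manual[i, ] + colMeans(wg$C[J, , drop = FALSE])
    }
  }
  expect_equal(H1, manual, tolerance = 1e-12)
})

test_that("zero RGCN weights give the activated zero matrix", {
  wg <- weighted_graph(4, 2, 3, seed = 3)
  prm <- list(Wr = list(FFC = matrix(0, 2, 3), BFC = matrix(0, 2, 3)),
              W0 = matrix(0, 2, 3), act = "relu", degree_norm = TRUE)
  expect_equal(rgcn_forward(wg$g, wg$C, prm), matrix(0, 4, 2))
})

test_that("RGCN requires an initialised (weighted) graph", {
  g <- build_edges(3, 2)
  expect_error(rgcn_forward(g, matrix(0, 3, 3), rgcn_init(3, 2)), "weights")
})

test_that("RGCN matches the dense adjacency oracle on random instances", {
  for (seed in 1:4) {
    n <- 6; Nw <- 4
    wg <- weighted_graph(n, Nw, 3, seed = seed)
    prm <- rgcn_init(3, 4, act = "relu")
    H1 <- rgcn_forward(wg$g, wg$C, prm)
    A <- dense_edge_softmax(wg$C, wg$Wer, Nw)
    expect_equal(H1, dense_rgcn(wg$C, A, prm$Wr, prm$W0, "relu", TRUE),
                 tolerance = 1e-5)
  }
})

test_that("a singleton attention neighbourhood gets weight 1; a = 0 gives uniform", {
  wg <- weighted_graph(2, 2, 3, seed = 5)
  prm <- gat_init(3, 2, K = 1)
  expect_equal(gat_reweight(wg$g, wg$C, prm, 1), rep(1, length(wg$g$src)))
  wg6 <- weighted_graph(6, 4, 3, seed = 6)
  prm$heads[[1]]$a <- prm$heads[[1]]$a * 0
  al <- gat_reweight(wg6$g, wg6$C, prm, 1)
  expect_equal(al, 1 / mignn:::edge_degree(wg6$g), tolerance = 1e-12)
})

test_that("multi-head attention matches the dense oracle head by head", {
  set.seed(9)
  n <- 5; Nw <- 4
  wg <- weighted_graph(n, Nw, 3, seed = 9)
  H1 <- matrix(rnorm(n * 4), n)
  prm <- gat_init(4, 3, K = 2)
  H2 <- gat_forward(wg$g, H1, prm)
  for (k in 1:2) {
    dk <- dense_gat_head(H1, prm$heads[[k]]$W, prm$heads[[k]]$a, Nw)
    expect_equal(H2[, (k - 1) * 3 + 1:3], dk$out, tolerance = 1e-5)
    al <- gat_reweight(wg$g, H1, prm, k)
    for (e in which(wg$g$rel != 3L)) {
      r <- c("FFC", "BFC")[wg$g$rel[e]]
      expect_equal(al[e], dk$alpha[[r]][wg$g$dst[e], wg$g$src[e]],
                   tolerance = 1e-6)
    }
  }
})

test_that("K=1 output equals the single head; K=4 x d_head=40 gives width 160", {
  wg <- weighted_graph(4, 2, 3, seed = 10)
  H1 <- matrix(rnorm(4 * 4), 4)
  prm1 <- gat_init(4, 3, K = 1)
  expect_equal(ncol(gat_forward(wg$g, H1, prm1)), 3L)
  prm4 <- gat_init(4, 40, K = 4)
  expect_equal(ncol(gat_forward(wg$g, H1, prm4)), 160L)
  expect_error(gat_init(4, 3, K = 0), "K")
})

test_that("attention weights sum to 1 per (destination, relation, head)", {
  wg <- weighted_graph(8, 6, 3, seed = 11)
  H1 <- matrix(rnorm(8 * 4), 8)
  prm <- gat_init(4, 3, K = 3)
  for (k in 1:3) {
    al <- gat_reweight(wg$g, H1, prm, k)
    sums <- tapply(al, mignn:::edge_group(wg$g), sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
})

test_that("both layers are permutation-equivariant under consistent relabeling", {
  set.seed(12)
  n <- 6
  wg <- weighted_graph(n, 4, 3, seed = 12)
  perm <- sample(n)
  inv <- order(perm)
  # relabel nodes: node i becomes perm[i]; rows of C permuted accordingly
  g2 <- wg$g
  g2$src <- perm[wg$g$src]; g2$dst <- perm[wg$g$dst]
  C2 <- wg$C[inv, , drop = FALSE]      # C2[perm[i], ] == C[i, ]
  prm_e <- list(Wer = wg$Wer)
  g1w <- init_edge_weights(wg$g, wg$C, prm_e)
  g2w <- init_edge_weights(g2, C2, prm_e)
  rp <- rgcn_init(3, 4)
  H1a <- rgcn_forward(g1w, wg$C, rp)
  H1b <- rgcn_forward(g2w, C2, rp)
  expect_equal(H1b[perm, , drop = FALSE], H1a, tolerance = 1e-12)
  gp <- gat_init(4, 3, K = 2)
  H2a <- gat_forward(g1w, H1a, gp)
  H2b <- gat_forward(g2w, H1b, gp)
  expect_equal(H2b[perm, , drop = FALSE], H2a, tolerance = 1e-12)
})

test_that("node updates are local: features beyond the 2-hop window do not leak", {
  set.seed(13)
  n <- 12; Nw <- 2                       # 1-hop radius 1, 2-hop radius 2
  C <- matrix(rnorm(n * 3), n)
  Wer <- list(FFC = matrix(rnorm(9), 3), BFC = matrix(rnorm(9), 3))
  rp <- rgcn_init(3, 4); gp <- gat_init(4, 3, K = 2)
  run <- function(C) {
    g <- init_edge_weights(build_edges(n, Nw), C, list(Wer = Wer))
    gat_forward(g, rgcn_forward(g, C, rp), gp)
  }
  base <- run(C)
  C2 <- C; C2[12, ] <- C2[12, ] + 5       # far from node 1 (distance 11)
  pert <- run(C2)
  expect_equal(pert[1, ], base[1, ], tolerance = 1e-12)
  expect_gt(max(abs(pert[12, ] - base[12, ])), 0)
})
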