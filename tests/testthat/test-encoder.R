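test_that("single-utterance sequences produce one (1 x 2H) context row", {
  set.seed(1)
  p <- encoder_init(c(A = 4), hidden_units = 3, node_dim = 6)
  out <- encode_modality(matrix(rnorm(4), 1), p, "A")
  expect_equal(dim(out), c(1L, 6L))
  expect_true(all(is.finite(out)))
})

test_that("reversing the input and swapping direction halves reverses the output rows", {
  # the forward pass on reversed input equals the reversed backward pass:
  # encode(rev(X)) with halves swapped == row-reversed encode(X)
  set.seed(7)
  p <- encoder_init(c(A = 3), hidden_units = 4, node_dim = 8)
  H <- 4
  for (n in 2:5) {
    X <- matrix(rnorm(n * 3), n)
    out <- encode_modality(X, p, "A")
    # swap the f/b weight sets instead of post-hoc column swapping
    p_sw <- p
    p_sw$enc$A <- list(f = p$enc$A$b, b = p$enc$A$f)
    out_rev <- encode_modality(X[n:1, , drop = FALSE], p_sw, "A")
    swapped <- cbind(out_rev[, H + 1:H, drop = FALSE],
                     out_rev[, 1:H, drop = FALSE])
    expect_equal(swapped, out[n:1, , drop = FALSE], tolerance = 1e-5)
  }
})

test_that("all-zero weights yield the zero context (gate fixed point)", {
  p <- encoder_init(c(A = 3), hidden_units = 2, node_dim = 4)
  p$enc$A <- lapply(p$enc$A, function(d)
    list(W = d$W * 0, U = d$U * 0, b = d$b * 0))
  out <- encode_modality(matrix(rnorm(12), 4), p, "A")
  expect_equal(out, matrix(0, 4, 4))
})

test_that("every output row depends on the whole sequence (bidirectionality)", {
  set.seed(3)
  p <- encoder_init(c(A = 2), hidden_units = 3, node_dim = 6)
  X <- matrix(rnorm(10), 5)
  base <- encode_modality(X, p, "A")
  X2 <- X; X2[5, ] <- X2[5, ] + 1          # perturb the last utterance
  expect_gt(max(abs(encode_modality(X2, p, "A")[1, ] - base[1, ])), 0)
  X3 <- X; X3[1, ] <- X3[1, ] + 1          # perturb the first
  expect_gt(max(abs(encode_modality(X3, p, "A")[5, ] - base[5, ])), 0)
})

test_that("modalities are encoded independently (unshared weights)", {
  set.seed(5)
  p <- encoder_init(c(A = 3, T = 2), hidden_units = 3, node_dim = 6)
  XT <- matrix(rnorm(8), 4)
  before <- encode_modality(XT, p, "T")
  p$enc$A$f$W <- p$enc$A$f$W + 1           # perturb only modality A
  expect_identical(encode_modality(XT, p, "T"), before)
})

test_that("full-scale fusion widths match: 3 x 2x200 = 1200 concatenated, 160 projected", {
  set.seed(11)
  p <- encoder_init(c(A = 100, V = 2048, T = 768), hidden_units = 200,
                    node_dim = 160)
  n <- 2
  ctx <- list(A = matrix(rnorm(n * 400), n), V = matrix(rnorm(n * 400), n),
              T = matrix(rnorm(n * 400), n))
  fused <- fuse_context(ctx, p)
  expect_equal(ncol(fused$pre), 1200L)
  expect_equal(ncol(fused$C), 160L)
})

test_that("identity projection leaves the concatenation untouched", {
  set.seed(2)
  p <- encoder_init(c(A = 3, T = 2), hidden_units = 2, node_dim = 8,
                    project = FALSE)
  ctx <- list(A = matrix(rnorm(12), 3), T = matrix(rnorm(12), 3))
  fused <- fuse_context(ctx, p)
  expect_identical(fused$C, fused$pre)
  expect_equal(fused$C, cbind(ctx$A, ctx$T))   # fixed (A, V, T) order
})

test_that("single declared modality fuses to its own projected context", {
  set.seed(4)
  p <- encoder_init(c(T = 3), hidden_units = 2, node_dim = 3)
  ctx <- list(T = matrix(rnorm(8), 2))
  fused <- fuse_context(ctx, p)
  expect_equal(fused$C, ctx$T %*% t(p$Wp))
})

test_that("row-count mismatches and degenerate inputs error", {
  p <- encoder_init(c(A = 2, T = 2), hidden_units = 2, node_dim = 8)
  expect_error(fuse_context(list(A = matrix(0, 2, 4), T = matrix(0, 3, 4)), p),
               "2 vs 3")
  expect_error(encode_modality(matrix(numeric(0), 0, 2), p, "A"), "empty")
  expect_error(encode_modality(matrix(c(1, Inf), 1), p, "A"), "finite")
  expect_error(encoder_init(c(A = 2), 2, node_dim = 5, project = FALSE),
               "node_dim")
})

test_that("encoding is bitwise deterministic for fixed parameters and input", {
  set.seed(6)
  p <- encoder_init(c(A = 3), hidden_units = 4, node_dim = 8)
  X <- matrix(rnorm(15), 5)
  expect_identical(encode_modality(X, p, "A"), encode_modality(X, p, "A"))
})
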