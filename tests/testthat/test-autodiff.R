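# Finite-difference verification of the reverse-mode engine. Each op is
# wrapped in a scalar objective sum(R * f(X)) with a fixed random weighting
# R, and analytic gradients are compared to central differences.

fd_check <- function(build, inputs, tol = 1e-5, h = 1e-6) {
  # build: function(tp, leaves) -> output node
  tp <- actimodal:::tp_tape()
  leaves <- lapply(inputs, function(x) actimodal:::tp_leaf(tp, x))
  out <- build(tp, leaves)
  R <- matrix(seq_len(length(out$value)) %% 7 - 3, nrow(out$value))
  loss <- actimodal:::tp_mean_all(tp, actimodal:::tp_mul(
    tp, out, actimodal:::tp_const(tp, R)))
  actimodal:::tape_backward(tp, loss)
  f <- function(ins) {
    tp2 <- actimodal:::tp_tape()
    lv <- lapply(ins, function(x) actimodal:::tp_leaf(tp2, x, needs = FALSE))
    mean(build(tp2, lv)$value * R)
  }
  for (k in seq_along(inputs)) {
    g <- leaves[[k]]$grad
    expect_false(is.null(g), info = paste("no grad for input", k))
    idx <- seq_len(min(6L, length(inputs[[k]])))
    for (i in idx) {
      ip <- inputs; ip[[k]][i] <- ip[[k]][i] + h; up <- f(ip)
      ip[[k]][i] <- ip[[k]][i] - 2 * h; dn <- f(ip)
      fd <- (up - dn) / (2 * h)
      expect_equal(g[i], fd, tolerance = tol,
                   info = sprintf("input %d entry %d", k, i))
    }
  }
}

test_that("primitive op gradients match finite differences", {
  withr::with_seed(31, {
    A <- matrix(rnorm(12), 3); B <- matrix(rnorm(20), 4)
    fd_check(function(tp, l) actimodal:::tp_mm(tp, l[[1]], l[[2]]),
             list(A, B))
    fd_check(function(tp, l) actimodal:::tp_add_rowvec(tp, l[[1]], l[[2]]),
             list(A, matrix(rnorm(4), 1)))
    fd_check(function(tp, l) actimodal:::tp_mul(tp, l[[1]], l[[2]]),
             list(A, matrix(rnorm(12), 3)))
    fd_check(function(tp, l) actimodal:::tp_tanh(tp, l[[1]]), list(A))
    fd_check(function(tp, l) actimodal:::tp_sigmoid(tp, l[[1]]), list(A))
    fd_check(function(tp, l) actimodal:::tp_gelu(tp, l[[1]]), list(A))
    fd_check(function(tp, l) actimodal:::tp_softmax_rows(tp, l[[1]]), list(A))
    fd_check(function(tp, l) actimodal:::tp_layernorm(tp, l[[1]], l[[2]], l[[3]]),
             list(A, matrix(runif(4, 0.5, 2), 1), matrix(rnorm(4), 1)),
             tol = 1e-4)
    fd_check(function(tp, l) actimodal:::tp_rows(tp, l[[1]], c(3, 1)), list(A))
    fd_check(function(tp, l) actimodal:::tp_cols(tp, l[[1]], c(2, 4)), list(A))
    fd_check(function(tp, l) actimodal:::tp_cbind2(tp, l[[1]], l[[2]]),
             list(A, matrix(rnorm(6), 3)))
    fd_check(function(tp, l) actimodal:::tp_rbind_list(tp, l), list(A, A + 1))
    fd_check(function(tp, l) actimodal:::tp_mul_scalar(tp, l[[1]], l[[2]]),
             list(A, matrix(0.7, 1, 1)))
    fd_check(function(tp, l) actimodal:::tp_affine(tp, l[[1]], -2, 0.5), list(A))
  })
})

test_that("fused block gradients match finite differences", {
  withr::with_seed(32, {
    # class-token prepend and tiled positional add (2 frames, 3 patches, d=4)
    P6 <- matrix(rnorm(24), 6)
    fd_check(function(tp, l) actimodal:::tp_prepend_cls(tp, l[[1]], l[[2]], 3L),
             list(P6, matrix(rnorm(4), 1)))
    X8 <- matrix(rnorm(32), 8)
    fd_check(function(tp, l) actimodal:::tp_add_tiled(tp, l[[1]], l[[2]], 2L),
             list(X8, matrix(rnorm(16), 4)))
    # multi-head self-attention: 2 frames of 4 tokens, d = 6, 2 heads
    X <- matrix(rnorm(48, sd = 0.7), 8, 6)
    fd_check(function(tp, l)
      actimodal:::tp_block_mhsa(tp, l[[1]], l[[2]], l[[3]], l[[4]], l[[5]],
                                n_tok = 4L, heads = 2L),
      list(X, matrix(rnorm(18 * 6, sd = 0.3), 6), matrix(rnorm(18), 1),
           matrix(rnorm(36, sd = 0.3), 6), matrix(rnorm(6), 1)),
      tol = 1e-4)
    # cross-attention: batch 3, 5 tokens, d_k = 4, 2 heads
    Q <- matrix(rnorm(12), 3)
    K <- matrix(rnorm(60, sd = 0.6), 15, 4)
    V <- matrix(rnorm(60), 15, 4)
    fd_check(function(tp, l)
      actimodal:::tp_cross_attn(tp, l[[1]], l[[2]], l[[3]], heads = 2L,
                                n_tok = 5L),
      list(Q, K, V), tol = 1e-4)
  })
})

test_that("focal loss node gradient matches finite differences", {
  withr::with_seed(33, {
    logits <- matrix(rnorm(10), 5)
    labels <- c(0L, 1L, 1L, 0L, 1L)
    w <- c(0.8, 1.2)
    for (gamma in c(0, 2)) {
      tp <- actimodal:::tp_tape()
      lg <- actimodal:::tp_leaf(tp, logits)
      pr <- actimodal:::tp_softmax_rows(tp, lg)
      loss <- actimodal:::tp_focal_loss(tp, pr, labels, w, gamma)
      actimodal:::tape_backward(tp, loss)
      g <- lg$grad
      f <- function(x) focal_loss(actimodal:::softmax_rows(x), labels, w, gamma)
      for (i in 1:6) {
        h <- 1e-6
        xp <- logits; xp[i] <- xp[i] + h
        xm <- logits; xm[i] <- xm[i] - h
        expect_equal(g[i], (f(xp) - f(xm)) / (2 * h), tolerance = 1e-5)
      }
      # tape value agrees with the numeric implementation
      expect_equal(loss$value[1],
                   focal_loss(actimodal:::softmax_rows(logits), labels, w,
                              gamma),
                   tolerance = 1e-9)
    }
  })
})

test_that("end-to-end model gradient flows to the patch projection", {
  samples <- random_samples(n = 4)
  model <- build_model(tiny_model_config(6), seed = 7)
  model$cfg$fusion$dropout <- 0
  b <- actimodal:::collate_batch(samples)
  fw <- model_forward(model, b, train = TRUE)
  loss <- actimodal:::tp_focal_loss(fw$tape, fw$prob_node, b$labels, c(1, 1), 2)
  actimodal:::tape_backward(fw$tape, loss)
  grads <- lapply(fw$param_nodes, function(nd) nd$grad)
  expect_false(is.null(grads$patch_W))
  expect_gt(max(abs(grads$patch_W)), 0)
  # spot-check representative parameters against central differences
  lossfun <- function(params) {
    m2 <- model; m2$params <- params
    fw2 <- model_forward(m2, b, train = FALSE)
    focal_loss(fw2$probs, b$labels, c(1, 1), 2)
  }
  withr::with_seed(34, {
    for (nm in c("patch_W", "L1_qkv_W", "lstm1f_Wx", "lstm2b_Wh", "fus_Wq",
                 "head_W")) {
      i <- sample(length(model$params[[nm]]), 1)
      h <- 1e-5
      pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + h; up <- lossfun(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * h; dn <- lossfun(pp)
      fd <- (up - dn) / (2 * h)
      expect_equal(grads[[nm]][i], fd, tolerance = 1e-3,
                   info = nm)
    }
  })
})
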