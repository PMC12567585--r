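test_that("configuration invariants are enforced", {
  expect_error(vit_config(image_size = 30, patch_size = 8), "divisible")
  expect_error(vit_config(embed_dim = 70, heads = 12), "divisible")
  expect_error(fusion_config(d_k = 30, heads = 4), "divisible")
  expect_error(model_config(vit_config_tiny(), bilstm_config(input_dim = 768),
                            fusion_config(), d_tab = 5),
               "input_dim")
  expect_error(build_model(model_config(vit_config(pretrained = TRUE),
                                        bilstm_config(), fusion_config(),
                                        d_tab = 5)),
               "pretrained")
})

test_that("tiny encoder meets its shape contracts deterministically", {
  model <- build_model(tiny_model_config(6), seed = 11)
  withr::with_seed(41, {
    sq <- random_sequence(size = 32)
    emb <- vit_encode_frames(model, sq)
    expect_equal(dim(emb), c(5, 64))
    expect_true(all(is.finite(emb)))
    # identical frames give identical embeddings in eval mode
    sq2 <- sq
    sq2$frames <- rep(sq$frames[1], 5)
    emb2 <- vit_encode_frames(model, sq2)
    expect_equal(emb2[1, ], emb2[5, ])
    # eval-mode forward is bit-reproducible
    expect_identical(emb, vit_encode_frames(model, sq))
    out <- bilstm_temporal(model, emb)
    expect_equal(dim(out$tokens), c(5, 64))
    expect_length(out$pooled, 64)
    # single-frame sequence: pooled vector equals that frame's token
    one <- bilstm_temporal(model, emb[1, , drop = FALSE])
    expect_equal(one$pooled, as.numeric(one$tokens[1, ]))
    # reversing the frames changes the pooled vector (directionality)
    revd <- bilstm_temporal(model, emb[5:1, ])
    expect_gt(max(abs(revd$pooled - out$pooled)), 1e-6)
  })
})

test_that("full-size components produce the documented dimensions", {
  cfg <- model_config(vit_config(), bilstm_config(),
                      fusion_config("cross_attention"), d_tab = 10)
  model <- build_model(cfg, seed = 1)
  withr::with_seed(42, {
    sq <- random_sequence(size = 224)
    emb <- vit_encode_frames(model, sq)           # 768 per frame
    expect_equal(dim(emb), c(5, 768))
    out <- bilstm_temporal(model, emb)            # 256 per frame token
    expect_equal(dim(out$tokens), c(5, 256))
    expect_length(out$pooled, 256)
    fus <- cross_attention_fuse(model, rnorm(10), out$tokens)
    expect_length(fus$fused, 128)                 # fused width d_k
    pr <- classify(model, fus$fused)
    expect_length(pr, 2)                          # two classes
    expect_equal(sum(pr), 1, tolerance = 1e-12)
  })
  rm(model)
  gc(verbose = FALSE)
})

test_that("cross-attention weights are a proper attention distribution", {
  model <- build_model(tiny_model_config(6), seed = 3)
  withr::with_seed(43, {
    tokens <- matrix(rnorm(5 * 64), 5)
    tab <- rnorm(6)
    fus <- cross_attention_fuse(model, tab, tokens)
    expect_equal(rowSums(fus$weights), rep(1, 4), tolerance = 1e-12)
    expect_true(all(fus$weights >= 0 & fus$weights <= 1))
    # a single key/value token collapses the softmax: output is its value row
    one <- cross_attention_fuse(model, tab, tokens[2, , drop = FALSE])
    expect_equal(one$fused,
                 as.numeric(tokens[2, , drop = FALSE] %*% model$params$fus_Wv),
                 tolerance = 1e-12)
    expect_equal(as.numeric(one$weights), rep(1, 4))
    # all tokens identical: output equals the shared value row
    same <- tokens[rep(3, 5), ]
    fs <- cross_attention_fuse(model, tab, same)
    expect_equal(fs$fused,
                 as.numeric(same[1, , drop = FALSE] %*% model$params$fus_Wv),
                 tolerance = 1e-10)
    # jointly permuting keys and values leaves the output unchanged
    perm <- c(4, 1, 5, 3, 2)
    fp <- cross_attention_fuse(model, tab, tokens[perm, ])
    expect_equal(fp$fused, fus$fused, tolerance = 1e-6)
  })
})

test_that("single-token compatibility mode runs end to end", {
  samples <- random_samples(n = 3)
  model <- build_model(tiny_model_config(6, single_token = TRUE), seed = 5)
  fw <- model_forward(model, actimodal:::collate_batch(samples))
  expect_equal(rowSums(fw$probs), rep(1, 3), tolerance = 1e-9)
  # softmax over one token: every attention weight is exactly 1
  expect_equal(as.numeric(fw$attention), rep(1, 3 * 4))
})

test_that("concatenation fusion is linear and input-asymmetric", {
  model <- build_model(tiny_model_config(64, "simple_concat"), seed = 6)
  withr::with_seed(44, {
    pooled <- rnorm(64)
    tab <- rnorm(64)
    # zero tabular input: output is the image contribution plus bias
    f0 <- simple_concat_fuse(model, rep(0, 64), pooled)
    img_part <- as.numeric(matrix(pooled, 1) %*%
                             model$params$fus_W[65:128, ] + model$params$fus_b)
    expect_equal(f0, img_part, tolerance = 1e-12)
    expect_length(f0, 32)
    # generic weights distinguish the two slots
    expect_gt(max(abs(simple_concat_fuse(model, tab, pooled) -
                        simple_concat_fuse(model, pooled, tab))), 1e-6)
  })
})

test_that("weighted-sum fusion mixes through a sigmoid gate", {
  model <- build_model(tiny_model_config(6, "weighted_sum"), seed = 7)
  withr::with_seed(45, {
    tab <- rnorm(6)
    pooled <- rnorm(64)
    P <- model$params
    pt <- as.numeric(matrix(tab, 1) %*% P$fus_Wt + P$fus_bt)
    pi_ <- as.numeric(matrix(pooled, 1) %*% P$fus_Wi + P$fus_bi)
    # alpha = 0 (the init): exact equal mixture
    expect_equal(weighted_sum_fuse(model, tab, pooled), (pt + pi_) / 2,
                 tolerance = 1e-12)
    # saturated gate: output collapses to the tabular projection
    m2 <- model; m2$params$fus_alpha[1] <- 40
    expect_equal(weighted_sum_fuse(m2, tab, pooled), pt, tolerance = 1e-9)
    # the gate is live: finite difference in alpha is nonzero when the
    # modality projections differ
    mp <- model; mp$params$fus_alpha[1] <- 1e-4
    mm <- model; mm$params$fus_alpha[1] <- -1e-4
    d <- (weighted_sum_fuse(mp, tab, pooled) -
            weighted_sum_fuse(mm, tab, pooled)) / 2e-4
    expect_gt(max(abs(d)), 1e-3)
    expect_equal(d, 0.25 * (pt - pi_), tolerance = 1e-4)
  })
})

test_that("dual-stream fusion averages two independent heads", {
  model <- build_model(tiny_model_config(64, "dual_stream"), seed = 8)
  withr::with_seed(46, {
    tab <- rnorm(64)
    pooled <- rnorm(64)
    P <- model$params
    lt <- as.numeric(tanh(matrix(tab, 1) %*% P$ds_t1 + P$ds_t1b) %*%
                       P$ds_t2 + P$ds_t2b)
    li <- as.numeric(tanh(matrix(pooled, 1) %*% P$ds_i1 + P$ds_i1b) %*%
                       P$ds_i2 + P$ds_i2b)
    expect_equal(dual_stream_fuse(model, tab, pooled), (lt + li) / 2,
                 tolerance = 1e-12)
    # identical per-stream heads and inputs: output equals either stream
    m2 <- model
    m2$params$ds_i1 <- P$ds_t1; m2$params$ds_i1b <- P$ds_t1b
    m2$params$ds_i2 <- P$ds_t2; m2$params$ds_i2b <- P$ds_t2b
    expect_equal(dual_stream_fuse(m2, tab, tab), lt, tolerance = 1e-12)
    # a constant (uninformative) image stream shifts logits by a constant
    m3 <- model
    m3$params$ds_i1 <- P$ds_i1 * 0
    d1 <- dual_stream_fuse(m3, tab, pooled) - dual_stream_fuse(m3, tab, rnorm(64))
    expect_equal(d1, c(0, 0), tolerance = 1e-12)
  })
})

test_that("the classifier is a shift-invariant softmax with dropout only in training", {
  model <- build_model(tiny_model_config(6), seed = 9)
  withr::with_seed(47, {
    fused <- rnorm(32)
    m0 <- model
    m0$params$head_W[] <- 0
    m0$params$head_b[] <- 0
    expect_equal(classify(m0, fused), c(0.5, 0.5))
    p <- classify(model, fused)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # adding a constant to both logits leaves the probabilities unchanged
    m1 <- model
    m1$params$head_b <- m1$params$head_b + 3.7
    expect_equal(classify(m1, fused), p, tolerance = 1e-12)
    expect_error(classify(model, rnorm(10)), "d_k")
  })
})

test_that("a tiny-preset training step on batch 8 completes quickly", {
  samples <- random_samples(n = 8)
  model <- build_model(tiny_model_config(6), seed = 10)
  b <- actimodal:::collate_batch(samples)
  t0 <- proc.time()[["elapsed"]]
  set.seed(1)
  fw <- model_forward(model, b, train = TRUE)
  loss <- actimodal:::tp_focal_loss(fw$tape, fw$prob_node, b$labels,
                                    c(1, 1), 2)
  actimodal:::tape_backward(fw$tape, loss)
  expect_lt(proc.time()[["elapsed"]] - t0, 5)
  expect_true(is.finite(loss$value[1]))
  # eval-mode determinism of the full pipeline
  p1 <- model_forward(model, b)$probs
  p2 <- model_forward(model, b)$probs
  expect_identical(p1, p2)
})
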