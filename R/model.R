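#' Vision Transformer configuration
#'
#' @param image_size Input image side length (default 224).
#' @param patch_size Patch side length; must divide `image_size`.
#' @param depth Number of encoder layers (default 12).
#' @param heads Self-attention heads (default 12); must divide `embed_dim`.
#' @param embed_dim Token embedding width (default 768; this is also the
#'   per-frame feature dimension extracted from the class token of the
#'   final encoder layer).
#' @param pretrained If `TRUE`, initialisation from pretrained weights is
#'   requested; no weight files ship with the package, so this requires a
#'   user-supplied checkpoint and is off by default (random init).
#' @return A `vit_config` list.
#' @export
vit_config <- function(image_size = 224, patch_size = 16, depth = 12,
                       heads = 12, embed_dim = 768, pretrained = FALSE) {
  if (image_size %% patch_size != 0)
    stop("image_size must be divisible by patch_size")
  if (embed_dim %% heads != 0)
    stop("embed_dim must be divisible by heads")
  structure(list(image_size = as.integer(image_size),
                 patch_size = as.integer(patch_size),
                 depth = as.integer(depth), heads = as.integer(heads),
                 embed_dim = as.integer(embed_dim),
                 pretrained = isTRUE(pretrained)),
            class = "vit_config")
}

#' Tiny ViT preset for CPU-scale work
#'
#' 32x32 images, 8x8 patches, 2 layers, 4 heads, 64-dim embeddings.
#' @return A [vit_config()].
#' @export
vit_config_tiny <- function() vit_config(32, 8, 2, 4, 64)

#' Bidirectional LSTM configuration
#'
#' @param input_dim Per-frame input width (the ViT embedding dimension).
#' @param hidden Hidden state size per direction (default 128; per-frame
#'   token and pooled outputs then have dimension `2 * hidden`).
#' @param layers Stacked layers (default 2).
#' @return A `bilstm_config` list (always bidirectional).
#' @export
bilstm_config <- function(input_dim = 768, hidden = 128, layers = 2) {
  stopifnot(input_dim >= 1, hidden >= 1, layers >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden), layers = as.integer(layers),
                 bidirectional = TRUE),
            class = "bilstm_config")
}

#' Fusion head configuration
#'
#' @param kind One of `"cross_attention"`, `"simple_concat"`,
#'   `"weighted_sum"`, `"dual_stream"`.
#' @param d_k Fused representation width / attention key dimension
#'   (default 128).
#' @param heads Attention heads for cross-attention fusion (default 4;
#'   must divide `d_k`; set to 1 for the single-head literal form).
#' @param dropout Dropout rate on the fully connected classifier input
#'   during training (default 0.5).
#' @param single_token If `TRUE`, cross-attention uses the single pooled
#'   sequence vector as both key and value, in which case the softmax is
#'   over one token and the fusion returns the projected value exactly
#'   (compatibility mode; default `FALSE` attends over the per-frame
#'   tokens).
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(kind = c("cross_attention", "simple_concat",
                                   "weighted_sum", "dual_stream"),
                          d_k = 128, heads = 4, dropout = 0.5,
                          single_token = FALSE) {
  kind <- match.arg(kind)
  if (d_k %% heads != 0) stop("d_k must be divisible by fusion heads")
  stopifnot(dropout >= 0, dropout < 1)
  structure(list(kind = kind, d_k = as.integer(d_k),
                 heads = as.integer(heads), dropout = dropout,
                 single_token = isTRUE(single_token)),
            class = "fusion_config")
}

#' Full model configuration
#'
#' @param vit A [vit_config()].
#' @param lstm A [bilstm_config()]; its `input_dim` must equal the ViT
#'   embedding dimension.
#' @param fusion A [fusion_config()].
#' @param d_tab Number of clinical feature columns.
#' @param n_frames Frames per image sequence (default 5).
#' @return A `model_config` list.
#' @export
model_config <- function(vit = vit_config(), lstm = bilstm_config(),
                         fusion = fusion_config(), d_tab, n_frames = 5) {
  if (lstm$input_dim != vit$embed_dim)
    stop("lstm input_dim must equal vit embed_dim")
  stopifnot(d_tab >= 1, n_frames >= 1)
  structure(list(vit = vit, lstm = lstm, fusion = fusion,
                 d_tab = as.integer(d_tab), n_frames = as.integer(n_frames)),
            class = "model_config")
}

#' Tiny end-to-end model preset
#'
#' CPU-scale configuration used throughout the test suite: tiny ViT
#' ([vit_config_tiny()]), BiLSTM hidden 32 (64-dim tokens), fused width 32
#' with 4 fusion heads.
#'
#' @param d_tab Number of clinical feature columns.
#' @param fusion_kind Fusion strategy (default cross-attention).
#' @param single_token Passed to [fusion_config()].
#' @return A [model_config()].
#' @export
tiny_model_config <- function(d_tab, fusion_kind = "cross_attention",
                              single_token = FALSE) {
  model_config(vit = vit_config_tiny(),
               lstm = bilstm_config(input_dim = 64, hidden = 32, layers = 2),
               fusion = fusion_config(fusion_kind, d_k = 32, heads = 4,
                                      single_token = single_token),
               d_tab = d_tab)
}

rmat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

lstm_init <- function(input_dim, hidden) {
  s <- 1 / sqrt(hidden)
  b <- matrix(0, 1L, 4L * hidden)
  b[1L, hidden + seq_len(hidden)] <- 1  # forget-gate bias
  list(Wx = matrix(stats::runif(input_dim * 4 * hidden, -s, s), input_dim),
       Wh = matrix(stats::runif(hidden * 4 * hidden, -s, s), hidden),
       b = b)
}

#' Initialise model parameters
#'
#' Builds the full parameter set for the configured encoder and fusion
#' head: ViT patch/class/position embeddings and encoder layers, the
#' stacked bidirectional LSTM, the fusion projections and the classifier.
#' Weights use a small-variance normal (sd 0.02) as is conventional for
#' transformer training from scratch; LSTM weights use the usual
#' `U(-1/sqrt(H), 1/sqrt(H))` with forget-gate bias 1.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the initial weights.
#' @return Object of class `actimodal_model`: list with `params` (named
#'   matrices) and `cfg`.
#' @export
build_model <- function(cfg, seed = 42) {
  stopifnot(inherits(cfg, "model_config"))
  if (cfg$vit$pretrained)
    stop("no pretrained ViT checkpoint available; supply weights manually or use pretrained = FALSE")
  v <- cfg$vit
  np <- (v$image_size %/% v$patch_size)^2
  pdim <- 3L * v$patch_size^2
  E <- v$embed_dim
  H <- cfg$lstm$hidden
  tok_dim <- 2L * H
  d_k <- cfg$fusion$d_k
  d_tab <- cfg$d_tab
  P <- with_seed(seed, {
    P <- list(patch_W = rmat(pdim, E), patch_b = matrix(0, 1, E),
              cls = rmat(1, E), pos = rmat(np + 1L, E))
    for (l in seq_len(v$depth)) {
      nm <- sprintf("L%d_", l)
      P[[paste0(nm, "ln1_g")]] <- matrix(1, 1, E)
      P[[paste0(nm, "ln1_b")]] <- matrix(0, 1, E)
      P[[paste0(nm, "qkv_W")]] <- rmat(E, 3L * E)
      P[[paste0(nm, "qkv_b")]] <- matrix(0, 1, 3L * E)
      P[[paste0(nm, "att_W")]] <- rmat(E, E)
      P[[paste0(nm, "att_b")]] <- matrix(0, 1, E)
      P[[paste0(nm, "ln2_g")]] <- matrix(1, 1, E)
      P[[paste0(nm, "ln2_b")]] <- matrix(0, 1, E)
      P[[paste0(nm, "mlp1_W")]] <- rmat(E, 4L * E)
      P[[paste0(nm, "mlp1_b")]] <- matrix(0, 1, 4L * E)
      P[[paste0(nm, "mlp2_W")]] <- rmat(4L * E, E)
      P[[paste0(nm, "mlp2_b")]] <- matrix(0, 1, E)
    }
    P$lnf_g <- matrix(1, 1, E)
    P$lnf_b <- matrix(0, 1, E)
    for (l in seq_len(cfg$lstm$layers)) {
      ind <- if (l == 1L) E else tok_dim
      for (dir in c("f", "b")) {
        w <- lstm_init(ind, H)
        P[[sprintf("lstm%d%s_Wx", l, dir)]] <- w$Wx
        P[[sprintf("lstm%d%s_Wh", l, dir)]] <- w$Wh
        P[[sprintf("lstm%d%s_b", l, dir)]] <- w$b
      }
    }
    switch(cfg$fusion$kind,
      cross_attention = {
        P$fus_Wq <- rmat(d_tab, d_k)
        P$fus_Wk <- rmat(tok_dim, d_k)
        P$fus_Wv <- rmat(tok_dim, d_k)
      },
      simple_concat = {
        P$fus_W <- rmat(d_tab + tok_dim, d_k)
        P$fus_b <- matrix(0, 1, d_k)
      },
      weighted_sum = {
        P$fus_Wt <- rmat(d_tab, d_k); P$fus_bt <- matrix(0, 1, d_k)
        P$fus_Wi <- rmat(tok_dim, d_k); P$fus_bi <- matrix(0, 1, d_k)
        P$fus_alpha <- matrix(0, 1, 1)
      },
      dual_stream = {
        P$ds_t1 <- rmat(d_tab, d_k); P$ds_t1b <- matrix(0, 1, d_k)
        P$ds_t2 <- rmat(d_k, 2L); P$ds_t2b <- matrix(0, 1, 2)
        P$ds_i1 <- rmat(tok_dim, d_k); P$ds_i1b <- matrix(0, 1, d_k)
        P$ds_i2 <- rmat(d_k, 2L); P$ds_i2b <- matrix(0, 1, 2)
      })
    if (cfg$fusion$kind != "dual_stream") {
      P$head_W <- rmat(d_k, 2L)
      P$head_b <- matrix(0, 1, 2)
    }
    P
  })
  structure(list(params = P, cfg = cfg), class = "actimodal_model")
}

#' @export
print.actimodal_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<actimodal_model> %s fusion, ViT %dx%d/%d depth %d embed %d, BiLSTM %dx%d, d_k %d, %s parameters\n",
              x$cfg$fusion$kind, x$cfg$vit$image_size, x$cfg$vit$image_size,
              x$cfg$vit$patch_size, x$cfg$vit$depth, x$cfg$vit$embed_dim,
              x$cfg$lstm$layers, x$cfg$lstm$hidden, x$cfg$fusion$d_k,
              format(n_par, big.mark = ",")))
  invisible(x)
}

# ---- input preparation -----------------------------------------------------

# Flatten one frame (list of 1 or 3 gaf_image channels) into an
# n_patch x (3 * patch^2) matrix. Row = patch in row-major grid order;
# within a row: channel-major, column-major pixels within the patch.
frame_patches <- function(frame, patch_size) {
  chans <- if (length(frame) == 1L) rep(frame, 3L) else frame
  img1 <- chans[[1]]$matrix
  H <- nrow(img1)
  if (H %% patch_size != 0)
    stop(sprintf("image size %d not divisible by patch size %d", H, patch_size))
  g <- H %/% patch_size
  out <- matrix(0, g * g, 3L * patch_size^2)
  for (pr in seq_len(g)) {
    rr <- ((pr - 1L) * patch_size + 1L):(pr * patch_size)
    for (pc in seq_len(g)) {
      cc <- ((pc - 1L) * patch_size + 1L):(pc * patch_size)
      out[(pr - 1L) * g + pc, ] <-
        c(chans[[1]]$matrix[rr, cc], chans[[2]]$matrix[rr, cc],
          chans[[3]]$matrix[rr, cc])
    }
  }
  out
}

sequence_patches <- function(seq, patch_size) {
  do.call(rbind, lapply(seq$frames, frame_patches, patch_size = patch_size))
}

#' Assemble model-ready samples
#'
#' Joins encoded image sequences with standardised clinical features and
#' per-subject labels, pre-extracting ViT patches once.
#'
#' @param sequences List of `image_sequence` objects ([encode_cohort()]).
#' @param features Standardised feature matrix with subject-id rownames
#'   (the `features` element of [standardise_features()]).
#' @param labels Named integer vector of per-subject labels (names =
#'   subject ids).
#' @param vit_cfg The [vit_config()] the samples will be fed to.
#' @return List of samples: `subject_id`, `patches`, `tab`, `label`.
#' @export
build_samples <- function(sequences, features, labels, vit_cfg) {
  lapply(sequences, function(sq) {
    sid <- as.character(sq$subject_id)
    if (!sid %in% rownames(features))
      stop("no clinical features for subject ", sid)
    list(subject_id = sid,
         patches = sequence_patches(sq, vit_cfg$patch_size),
         tab = as.numeric(features[sid, ]),
         label = as.integer(labels[[sid]]))
  })
}

collate_batch <- function(samples) {
  list(patches = do.call(rbind, lapply(samples, `[[`, "patches")),
       tab = do.call(rbind, lapply(samples, `[[`, "tab")),
       labels = vapply(samples, `[[`, 0L, "label"),
       subject_id = vapply(samples, `[[`, "", "subject_id"))
}

# ---- forward pass ----------------------------------------------------------

vit_forward <- function(tp, P, X0, vcfg, n_frames_total) {
  np <- (vcfg$image_size %/% vcfg$patch_size)^2
  n_tok <- np + 1L
  x <- tp_add_rowvec(tp, tp_mm(tp, X0, P$patch_W), P$patch_b)
  x <- tp_prepend_cls(tp, x, P$cls, np)
  x <- tp_add_tiled(tp, x, P$pos, n_frames_total)
  for (l in seq_len(vcfg$depth)) {
    nm <- sprintf("L%d_", l)
    h <- tp_layernorm(tp, x, P[[paste0(nm, "ln1_g")]], P[[paste0(nm, "ln1_b")]])
    a <- tp_block_mhsa(tp, h, P[[paste0(nm, "qkv_W")]], P[[paste0(nm, "qkv_b")]],
                       P[[paste0(nm, "att_W")]], P[[paste0(nm, "att_b")]],
                       n_tok, vcfg$heads)
    x <- tp_add(tp, x, a)
    h2 <- tp_layernorm(tp, x, P[[paste0(nm, "ln2_g")]], P[[paste0(nm, "ln2_b")]])
    m <- tp_add_rowvec(tp, tp_mm(tp, h2, P[[paste0(nm, "mlp1_W")]]),
                       P[[paste0(nm, "mlp1_b")]])
    m <- tp_gelu(tp, m)
    m <- tp_add_rowvec(tp, tp_mm(tp, m, P[[paste0(nm, "mlp2_W")]]),
                       P[[paste0(nm, "mlp2_b")]])
    x <- tp_add(tp, x, m)
  }
  x <- tp_layernorm(tp, x, P$lnf_g, P$lnf_b)
  tp_rows(tp, x, seq(1L, by = n_tok, length.out = n_frames_total))
}

lstm_dir <- function(tp, xs, Wx, Wh, b, reverse = FALSE) {
  n <- length(xs)
  H <- nrow(Wh$value)
  B <- nrow(xs[[1]]$value)
  h <- tp_const(tp, matrix(0, B, H))
  cc <- tp_const(tp, matrix(0, B, H))
  hs <- vector("list", n)
  for (t in if (reverse) seq.int(n, 1L) else seq_len(n)) {
    gates <- tp_add_rowvec(tp, tp_add(tp, tp_mm(tp, xs[[t]], Wx),
                                      tp_mm(tp, h, Wh)), b)
    i_g <- tp_sigmoid(tp, tp_cols(tp, gates, seq_len(H)))
    f_g <- tp_sigmoid(tp, tp_cols(tp, gates, H + seq_len(H)))
    g_g <- tp_tanh(tp, tp_cols(tp, gates, 2L * H + seq_len(H)))
    o_g <- tp_sigmoid(tp, tp_cols(tp, gates, 3L * H + seq_len(H)))
    cc <- tp_add(tp, tp_mul(tp, f_g, cc), tp_mul(tp, i_g, g_g))
    h <- tp_mul(tp, o_g, tp_tanh(tp, cc))
    hs[[t]] <- h
  }
  list(hs = hs, last = h)
}

bilstm_forward <- function(tp, P, E, cfg, B) {
  nf <- cfg$n_frames
  xs <- lapply(seq_len(nf), function(t)
    tp_rows(tp, E, seq(t, by = nf, length.out = B)))
  inp <- xs
  for (l in seq_len(cfg$lstm$layers)) {
    fwd <- lstm_dir(tp, inp, P[[sprintf("lstm%df_Wx", l)]],
                    P[[sprintf("lstm%df_Wh", l)]], P[[sprintf("lstm%df_b", l)]])
    bwd <- lstm_dir(tp, inp, P[[sprintf("lstm%db_Wx", l)]],
                    P[[sprintf("lstm%db_Wh", l)]], P[[sprintf("lstm%db_b", l)]],
                    reverse = TRUE)
    inp <- lapply(seq_len(nf), function(t)
      tp_cbind2(tp, fwd$hs[[t]], bwd$hs[[t]]))
  }
  list(tokens = tp_rbind_list(tp, inp),        # (nf*B) x 2H, token-major
       pooled = tp_cbind2(tp, fwd$last, bwd$last))  # B x 2H
}

apply_dropout <- function(tp, a, rate, train) {
  if (!train || rate <= 0) return(a)
  mask <- matrix(stats::rbinom(length(a$value), 1L, 1 - rate) / (1 - rate),
                 nrow(a$value), ncol(a$value))
  tp_mul(tp, a, tp_const(tp, mask))
}

fusion_forward <- function(tp, P, tabn, lstm_out, fcfg, B, n_frames, train) {
  attn <- NULL
  if (fcfg$kind == "cross_attention") {
    Qn <- tp_mm(tp, tabn, P$fus_Wq)
    src <- if (fcfg$single_token) lstm_out$pooled else lstm_out$tokens
    n_tok <- if (fcfg$single_token) 1L else n_frames
    Kn <- tp_mm(tp, src, P$fus_Wk)
    Vn <- tp_mm(tp, src, P$fus_Wv)
    fused <- tp_cross_attn(tp, Qn, Kn, Vn, fcfg$heads, n_tok)
    attn <- fused$attn
  } else if (fcfg$kind == "simple_concat") {
    fused <- tp_add_rowvec(tp, tp_mm(tp, tp_cbind2(tp, tabn, lstm_out$pooled),
                                     P$fus_W), P$fus_b)
  } else if (fcfg$kind == "weighted_sum") {
    pt <- tp_add_rowvec(tp, tp_mm(tp, tabn, P$fus_Wt), P$fus_bt)
    pi_ <- tp_add_rowvec(tp, tp_mm(tp, lstm_out$pooled, P$fus_Wi), P$fus_bi)
    w <- tp_sigmoid(tp, P$fus_alpha)
    wbar <- tp_affine(tp, w, -1, 1)
    fused <- tp_add(tp, tp_mul_scalar(tp, pt, w), tp_mul_scalar(tp, pi_, wbar))
  } else {  # dual_stream: two per-modality heads, averaged logits
    ht <- tp_tanh(tp, tp_add_rowvec(tp, tp_mm(tp, tabn, P$ds_t1), P$ds_t1b))
    ht <- apply_dropout(tp, ht, fcfg$dropout, train)
    lt <- tp_add_rowvec(tp, tp_mm(tp, ht, P$ds_t2), P$ds_t2b)
    hi <- tp_tanh(tp, tp_add_rowvec(tp, tp_mm(tp, lstm_out$pooled, P$ds_i1),
                                    P$ds_i1b))
    hi <- apply_dropout(tp, hi, fcfg$dropout, train)
    li <- tp_add_rowvec(tp, tp_mm(tp, hi, P$ds_i2), P$ds_i2b)
    logits <- tp_affine(tp, tp_add(tp, lt, li), 0.5)
    return(list(logits = logits, fused = NULL, attn = NULL))
  }
  list(fused = fused, attn = attn)
}

#' Forward pass of the multimodal model
#'
#' Runs a batch through ViT frame encoding, BiLSTM temporal aggregation,
#' the configured fusion head, and the softmax classifier, on an autodiff
#' tape. In eval mode (`train = FALSE`, the default) the pass is
#' deterministic; in training mode dropout masks are drawn from the
#' current RNG state.
#'
#' @param model An [build_model()] result.
#' @param batch A collated batch: list with `patches`
#'   (`(B * n_frames * n_patch) x patch_dim` matrix) and `tab`
#'   (`B x d_tab` matrix). See [build_samples()].
#' @param train Enable dropout and gradient bookkeeping.
#' @return List: `probs` (`B x 2`, rows sum to 1; column 2 is the positive
#'   class), `logits`, `attention` (cross-attention weights,
#'   `B x (heads * n_tokens)`, or `NULL`), plus internal tape handles used
#'   by the trainer.
#' @export
model_forward <- function(model, batch, train = FALSE) {
  cfg <- model$cfg
  B <- nrow(batch$tab)
  tp <- tp_tape()
  P <- lapply(model$params, function(m) tp_leaf(tp, m, needs = train))
  X0 <- tp_const(tp, batch$patches)
  tabn <- tp_const(tp, batch$tab)
  E <- vit_forward(tp, P, X0, cfg$vit, B * cfg$n_frames)
  lstm_out <- bilstm_forward(tp, P, E, cfg, B)
  fus <- fusion_forward(tp, P, tabn, lstm_out, cfg$fusion, B, cfg$n_frames,
                        train)
  if (is.null(fus$logits)) {
    fd <- apply_dropout(tp, fus$fused, cfg$fusion$dropout, train)
    logits <- tp_add_rowvec(tp, tp_mm(tp, fd, P$head_W), P$head_b)
  } else {
    logits <- fus$logits
  }
  probs <- tp_softmax_rows(tp, logits)
  list(probs = probs$value, logits = logits$value, attention = fus$attn,
       tape = tp, param_nodes = P, prob_node = probs,
       pooled = lstm_out$pooled$value, tokens = lstm_out$tokens$value,
       fused = if (!is.null(fus$fused)) fus$fused$value else NULL)
}

#' Predict class probabilities for a set of samples
#'
#' @param model A trained or freshly built model.
#' @param samples Samples from [build_samples()].
#' @param batch_size Evaluation batch size (default 32).
#' @return Data frame with `subject_id`, `label`, `p_pos` (positive-class
#'   probability) and `pred` (argmax class).
#' @export
predict_model <- function(model, samples, batch_size = 32L) {
  out <- vector("list", 0L)
  i <- 1L
  while (i <= length(samples)) {
    j <- min(i + batch_size - 1L, length(samples))
    b <- collate_batch(samples[i:j])
    fw <- model_forward(model, b, train = FALSE)
    out[[length(out) + 1L]] <-
      data.frame(subject_id = b$subject_id, label = b$labels,
                 p_pos = fw$probs[, 2L],
                 pred = as.integer(fw$probs[, 2L] >= 0.5),
                 stringsAsFactors = FALSE)
    i <- j + 1L
  }
  do.call(rbind, out)
}

# ---- single-sample operation wrappers (inspection / testing API) ----------

eval_tape_single <- function(model, builder) {
  tp <- tp_tape()
  P <- lapply(model$params, function(m) tp_leaf(tp, m, needs = FALSE))
  builder(tp, P)
}

#' Encode one image sequence with the ViT backbone
#'
#' @param model An `actimodal_model`.
#' @param sequence An `image_sequence`.
#' @return `n_frames x embed_dim` matrix of class-token embeddings (one row
#'   per frame, from the final encoder layer).
#' @export
vit_encode_frames <- function(model, sequence) {
  v <- model$cfg$vit
  if (sequence$image_size != v$image_size)
    stop(sprintf("frame size %d does not match configured image_size %d",
                 sequence$image_size, v$image_size))
  X <- sequence_patches(sequence, v$patch_size)
  eval_tape_single(model, function(tp, P)
    vit_forward(tp, P, tp_const(tp, X), v, length(sequence$frames))$value)
}

#' Run the BiLSTM over a sequence of frame embeddings
#'
#' @param model An `actimodal_model`.
#' @param embeddings `n x embed_dim` matrix (one row per frame, in time
#'   order).
#' @return List: `tokens` (`n x 2*hidden`, the per-frame key/value token
#'   set) and `pooled` (length `2*hidden`; last forward state concatenated
#'   with last backward state).
#' @export
bilstm_temporal <- function(model, embeddings) {
  if (!nrow(embeddings)) stop("empty frame sequence")
  cfg <- model$cfg
  eval_tape_single(model, function(tp, P) {
    cfg2 <- cfg
    cfg2$n_frames <- nrow(embeddings)
    E <- tp_const(tp, embeddings)
    out <- bilstm_forward(tp, P, E, cfg2, 1L)
    list(tokens = out$tokens$value, pooled = as.numeric(out$pooled$value))
  })
}

fuse_check_kind <- function(model, kind) {
  if (model$cfg$fusion$kind != kind)
    stop(sprintf("model was built with fusion kind '%s', not '%s'",
                 model$cfg$fusion$kind, kind))
}

#' Cross-attention fusion of clinical features and frame tokens
#'
#' The clinical vector supplies the attention query; the frame tokens
#' supply keys and values. Output is `softmax(Q K' / sqrt(d_h)) V`
#' computed per head over the token set; with a single token the softmax
#' is trivial and the output equals the projected value row.
#'
#' @param model Model built with `fusion_config("cross_attention")`.
#' @param tab Numeric clinical feature vector (length `d_tab`).
#' @param tokens `n_tokens x 2*hidden` matrix of frame tokens.
#' @return List: `fused` (length `d_k`) and `weights`
#'   (`heads x n_tokens`; each row is non-negative and sums to 1).
#' @export
cross_attention_fuse <- function(model, tab, tokens) {
  fuse_check_kind(model, "cross_attention")
  fcfg <- model$cfg$fusion
  eval_tape_single(model, function(tp, P) {
    Qn <- tp_mm(tp, tp_const(tp, matrix(tab, 1L)), P$fus_Wq)
    src <- tp_const(tp, tokens)
    fused <- tp_cross_attn(tp, Qn, tp_mm(tp, src, P$fus_Wk),
                           tp_mm(tp, src, P$fus_Wv),
                           fcfg$heads, nrow(tokens))
    list(fused = as.numeric(fused$value),
         weights = matrix(fused$attn, fcfg$heads, nrow(tokens), byrow = TRUE))
  })
}

#' Concatenation fusion baseline
#'
#' Concatenates the clinical vector with the pooled image vector and maps
#' the result linearly to the fused width.
#'
#' @param model Model built with `fusion_config("simple_concat")`.
#' @param tab Clinical feature vector.
#' @param pooled Pooled image vector (length `2*hidden`).
#' @return Fused vector of length `d_k`.
#' @export
simple_concat_fuse <- function(model, tab, pooled) {
  fuse_check_kind(model, "simple_concat")
  as.numeric(sweep(matrix(c(tab, pooled), 1L) %*% model$params$fus_W, 2L,
                   as.numeric(model$params$fus_b), `+`))
}

#' Learnable weighted-sum fusion baseline
#'
#' Projects both modalities to the fused width and mixes them as
#' `sigmoid(alpha) * proj(tab) + (1 - sigmoid(alpha)) * proj(image)` with a
#' single learnable gate `alpha` (alpha = 0 gives an equal mixture).
#'
#' @inheritParams simple_concat_fuse
#' @param model Model built with `fusion_config("weighted_sum")`.
#' @return Fused vector of length `d_k`.
#' @export
weighted_sum_fuse <- function(model, tab, pooled) {
  fuse_check_kind(model, "weighted_sum")
  P <- model$params
  w <- 1 / (1 + exp(-P$fus_alpha[1L]))
  pt <- as.numeric(matrix(tab, 1L) %*% P$fus_Wt + P$fus_bt)
  pi_ <- as.numeric(matrix(pooled, 1L) %*% P$fus_Wi + P$fus_bi)
  w * pt + (1 - w) * pi_
}

#' Dual-stream fusion baseline
#'
#' Two independent per-modality MLP heads each produce class logits; the
#' final logits are their unweighted mean (so the combination commutes with
#' stream order).
#'
#' @inheritParams simple_concat_fuse
#' @param model Model built with `fusion_config("dual_stream")`.
#' @return Length-2 vector of class logits.
#' @export
dual_stream_fuse <- function(model, tab, pooled) {
  fuse_check_kind(model, "dual_stream")
  P <- model$params
  lt <- tanh(matrix(tab, 1L) %*% P$ds_t1 + P$ds_t1b) %*% P$ds_t2 + P$ds_t2b
  li <- tanh(matrix(pooled, 1L) %*% P$ds_i1 + P$ds_i1b) %*% P$ds_i2 + P$ds_i2b
  as.numeric((lt + li) / 2)
}

#' Classify a fused representation
#'
#' Softmax over the linear map of the fused vector. Dropout is applied
#' before the linear map only in training mode.
#'
#' @param model Model with a classifier head (any fusion kind except
#'   `dual_stream`, which emits logits directly).
#' @param fused Fused vector of length `d_k`.
#' @param train Apply dropout (draws from the current RNG state).
#' @return Length-2 probability vector summing to 1 (element 2 = positive
#'   class).
#' @export
classify <- function(model, fused, train = FALSE) {
  if (is.null(model$params$head_W))
    stop("model has no classifier head (dual_stream emits logits directly)")
  if (length(fused) != model$cfg$fusion$d_k)
    stop(sprintf("fused dimension %d != configured d_k %d", length(fused),
                 model$cfg$fusion$d_k))
  v <- matrix(fused, 1L)
  if (train && model$cfg$fusion$dropout > 0) {
    p <- model$cfg$fusion$dropout
    v <- v * stats::rbinom(length(v), 1L, 1 - p) / (1 - p)
  }
  as.numeric(softmax_rows(v %*% model$params$head_W + model$params$head_b))
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full configuration alongside the weights (and
#' training history, if any), so a loaded model is immediately usable for
#' prediction and its provenance is self-describing.
#'
#' @param model An `actimodal_model`.
#' @param path Checkpoint file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "actimodal_model"))
  saveRDS(list(format = "actimodal_checkpoint", version = 1L,
               package_version = as.character(utils::packageVersion("actimodal")),
               cfg = model$cfg, params = model$params,
               history = model$history, class_weights = model$class_weights),
          path)
}

#' @rdname save_model
#' @return `load_model` returns the restored `actimodal_model`.
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "actimodal_checkpoint"))
    stop("not an actimodal checkpoint: ", path)
  structure(list(params = ck$params, cfg = ck$cfg, history = ck$history,
                 class_weights = ck$class_weights),
            class = "actimodal_model")
}
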