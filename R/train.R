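#' Focal loss for binary class probabilities
#'
#' Mean over the batch of `-w_y * (1 - p_y)^gamma * log(p_y)`, where `p_y`
#' is the probability assigned to the true class and `w_y` a per-class
#' weight. With `gamma = 0` and unit weights this reduces to cross-entropy;
#' `gamma > 0` down-weights well-classified examples, concentrating the
#' gradient on hard cases under class imbalance.
#'
#' @param probs `n x 2` matrix of class probabilities (rows sum to 1),
#'   column 1 = class 0, column 2 = class 1.
#' @param labels Integer vector of 0/1 true classes.
#' @param weights Length-2 positive class weights (default unit).
#' @param gamma Focusing parameter, `>= 0` (default 2).
#' @param eps Probabilities below `eps` are clamped before the log
#'   (documented guard against `log(0)`).
#' @return Scalar loss.
#' @export
focal_loss <- function(probs, labels, weights = c(1, 1), gamma = 2,
                       eps = 1e-12) {
  probs <- as_mat(probs)
  stopifnot(ncol(probs) == 2L, length(labels) == nrow(probs),
            all(labels %in% 0:1), all(weights > 0), gamma >= 0)
  p <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  w <- weights[labels + 1L]
  mean(-w * (1 - p)^gamma * log(pmax(p, eps)))
}

#' Training configuration
#'
#' @param epochs Training epochs (default 20).
#' @param learning_rate Constant learning rate, no scheduler (default 1e-4).
#' @param batch_size Sequences per gradient step (default 8).
#' @param weight_decay Decoupled (AdamW-style) weight decay (default 1e-5).
#' @param dropout Dropout rate on fully connected layers (default 0.5);
#'   copied into the model's fusion config at training time.
#' @param seed RNG seed fixed before any stochastic operation (default 42).
#' @param focal_gamma Focal-loss focusing parameter (default 2).
#' @param class_weight_mode `"inverse"` (inverse class frequency,
#'   normalised to mean 1) or `"none"`.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 20, learning_rate = 1e-4, batch_size = 8,
                         weight_decay = 1e-5, dropout = 0.5, seed = 42,
                         focal_gamma = 2,
                         class_weight_mode = c("inverse", "none")) {
  class_weight_mode <- match.arg(class_weight_mode)
  stopifnot(epochs >= 1, learning_rate >= 0, batch_size >= 1,
            weight_decay >= 0, dropout >= 0, dropout < 1, focal_gamma >= 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, dropout = dropout,
                 seed = as.integer(seed), focal_gamma = focal_gamma,
                 class_weight_mode = class_weight_mode),
            class = "train_config")
}

#' Desk-scale training preset
#'
#' Companion to [tiny_model_config()]: the tiny randomly initialised model
#' has far fewer parameters than a full-size pretrained backbone, so it
#' trains with a larger constant learning rate (1e-3) over the same 20
#' epochs.
#'
#' @param ... Overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
tiny_train_config <- function(...) {
  args <- list(...)
  do.call(train_config, utils::modifyList(list(learning_rate = 1e-3), args))
}

class_weights <- function(labels, mode) {
  if (mode == "none") return(c(1, 1))
  n <- length(labels)
  cnt <- c(sum(labels == 0L), sum(labels == 1L))
  if (any(cnt == 0L)) return(c(1, 1))
  w <- n / (2 * cnt)
  w / mean(w)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, wd, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * ((st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps) +
              wd * params[[nm]])
  }
  list(params = params, state = st)
}

#' Train the multimodal model
#'
#' AdamW (Adam with decoupled weight decay) on the focal loss, constant
#' learning rate, per-epoch shuffling. Training and validation losses are
#' logged each epoch and the weights from the best validation epoch are
#' retained (when a validation set is given; otherwise the final weights).
#'
#' @param model A [build_model()] result.
#' @param train_samples,val_samples Sample lists from [build_samples()];
#'   `val_samples` may be `NULL`.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return The model with trained `params`, plus `history` (data.frame of
#'   per-epoch losses) and `class_weights` attached.
#' @export
train_model <- function(model, train_samples, val_samples = NULL,
                        cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), length(train_samples) >= 1)
  model$cfg$fusion$dropout <- cfg$dropout
  labels <- vapply(train_samples, `[[`, 0L, "label")
  w <- class_weights(labels, cfg$class_weight_mode)
  st <- adam_init(model$params)
  n <- length(train_samples)
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                     val_loss = NA_real_)
  best <- list(loss = Inf, params = model$params)
  set.seed(cfg$seed)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    i <- 1L
    while (i <= n) {
      j <- min(i + cfg$batch_size - 1L, n)
      b <- collate_batch(train_samples[ord[i:j]])
      fw <- model_forward(model, b, train = TRUE)
      loss <- tp_focal_loss(fw$tape, fw$prob_node, b$labels, w,
                            cfg$focal_gamma)
      lv <- loss$value[1L]
      if (!is.finite(lv))
        stop(sprintf("non-finite loss at epoch %d batch %d (lr %.3g); check inputs / learning rate",
                     ep, nb + 1L, cfg$learning_rate))
      tape_backward(fw$tape, loss)
      grads <- lapply(fw$param_nodes, function(nd) nd$grad)
      up <- adam_step(model$params, grads, st, cfg$learning_rate,
                      cfg$weight_decay)
      model$params <- up$params
      st <- up$state
      ep_loss <- ep_loss + lv
      nb <- nb + 1L
      i <- j + 1L
    }
    hist$train_loss[ep] <- ep_loss / nb
    if (length(val_samples)) {
      vb <- collate_batch(val_samples)
      vfw <- model_forward(model, vb, train = FALSE)
      hist$val_loss[ep] <- focal_loss(vfw$probs, vb$labels, w, cfg$focal_gamma)
      if (hist$val_loss[ep] < best$loss)
        best <- list(loss = hist$val_loss[ep], params = model$params)
    }
    if (verbose)
      message(sprintf("epoch %2d  train %.4f  val %s", ep, hist$train_loss[ep],
                      ifelse(is.na(hist$val_loss[ep]), "-",
                             sprintf("%.4f", hist$val_loss[ep]))))
  }
  if (length(val_samples) && is.finite(best$loss)) model$params <- best$params
  model$history <- hist
  model$class_weights <- w
  model
}
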