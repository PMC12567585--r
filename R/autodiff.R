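# Reverse-mode automatic differentiation on matrices.
#
# A tape records nodes in creation order; tape_backward() walks it in
# reverse, calling each node's backward() to push its gradient into the
# parents. Node values are plain numeric matrices. Ops only allocate a
# backward closure when some parent requires a gradient, so eval-mode
# forward passes carry almost no overhead. Composite blocks with many tiny
# intermediate products (multi-head self-attention, cross-attention, focal
# loss) are implemented as single fused nodes with hand-derived backward
# rules; all rules are checked against finite differences in the test
# suite.

tp_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 512L)
  e$k <- 0L
  e
}

tp_node <- function(tp, value, parents = NULL, backward = NULL,
                    needs = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- if (needs) backward else NULL
  nd$needs <- needs
  k <- tp$k + 1L
  if (k > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", k))
  tp$nodes[[k]] <- nd
  tp$k <- k
  nd
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

tp_leaf <- function(tp, value, needs = TRUE) {
  tp_node(tp, as_mat(value), needs = needs,
          backward = if (needs) function(nd) NULL)
}

tp_const <- function(tp, value) tp_leaf(tp, value, needs = FALSE)

tp_val <- function(nd) nd$value

acc_grad <- function(p, g) {
  if (isTRUE(p$needs))
    p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

needs_any <- function(...) {
  for (p in list(...)) if (isTRUE(p$needs)) return(TRUE)
  FALSE
}

tape_backward <- function(tp, loss) {
  loss$grad <- matrix(1, nrow(loss$value), ncol(loss$value))
  for (i in seq.int(tp$k, 1L)) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

# ---- primitive ops ---------------------------------------------------------

tp_mm <- function(tp, a, b) {
  v <- a$value %*% b$value
  tp_node(tp, v, needs = needs_any(a, b), backward = function(nd) {
    acc_grad(a, nd$grad %*% t(b$value))
    acc_grad(b, t(a$value) %*% nd$grad)
  })
}

tp_add <- function(tp, a, b) {
  tp_node(tp, a$value + b$value, needs = needs_any(a, b),
          backward = function(nd) {
            acc_grad(a, nd$grad)
            acc_grad(b, nd$grad)
          })
}

# add a 1 x d row vector to every row of a
tp_add_rowvec <- function(tp, a, b) {
  tp_node(tp, sweep(a$value, 2L, as.numeric(b$value), `+`),
          needs = needs_any(a, b), backward = function(nd) {
            acc_grad(a, nd$grad)
            acc_grad(b, matrix(colSums(nd$grad), 1L))
          })
}

tp_mul <- function(tp, a, b) {
  tp_node(tp, a$value * b$value, needs = needs_any(a, b),
          backward = function(nd) {
            acc_grad(a, nd$grad * b$value)
            acc_grad(b, nd$grad * a$value)
          })
}

# elementwise a * s where s is a 1x1 node (learnable scalar)
tp_mul_scalar <- function(tp, a, s) {
  sv <- s$value[1L]
  tp_node(tp, a$value * sv, needs = needs_any(a, s), backward = function(nd) {
    acc_grad(a, nd$grad * sv)
    acc_grad(s, matrix(sum(nd$grad * a$value), 1L, 1L))
  })
}

# mult * a + shift with numeric scalars
tp_affine <- function(tp, a, mult = 1, shift = 0) {
  tp_node(tp, mult * a$value + shift, needs = a$needs,
          backward = function(nd) acc_grad(a, mult * nd$grad))
}

tp_tanh <- function(tp, a) {
  v <- tanh(a$value)
  tp_node(tp, v, needs = a$needs,
          backward = function(nd) acc_grad(a, nd$grad * (1 - v^2)))
}

tp_sigmoid <- function(tp, a) {
  v <- 1 / (1 + exp(-a$value))
  tp_node(tp, v, needs = a$needs,
          backward = function(nd) acc_grad(a, nd$grad * v * (1 - v)))
}

tp_gelu <- function(tp, a) {
  x <- a$value
  ph <- stats::pnorm(x)
  tp_node(tp, x * ph, needs = a$needs, backward = function(nd)
    acc_grad(a, nd$grad * (ph + x * stats::dnorm(x))))
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

tp_softmax_rows <- function(tp, a) {
  v <- softmax_rows(a$value)
  tp_node(tp, v, needs = a$needs, backward = function(nd) {
    g <- nd$grad
    acc_grad(a, v * (g - rowSums(g * v)))
  })
}

tp_layernorm <- function(tp, a, gamma, beta, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$value)
  v <- sweep(sweep(xhat, 2L, gv, `*`), 2L, as.numeric(beta$value), `+`)
  tp_node(tp, v, needs = needs_any(a, gamma, beta), backward = function(nd) {
    g <- nd$grad
    acc_grad(gamma, matrix(colSums(g * xhat), 1L))
    acc_grad(beta, matrix(colSums(g), 1L))
    if (a$needs) {
      dxh <- sweep(g, 2L, gv, `*`)
      acc_grad(a, inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)))
    }
  })
}

tp_rows <- function(tp, a, idx) {
  tp_node(tp, a$value[idx, , drop = FALSE], needs = a$needs,
          backward = function(nd) {
            da <- matrix(0, nrow(a$value), ncol(a$value))
            da[idx, ] <- nd$grad
            acc_grad(a, da)
          })
}

tp_cols <- function(tp, a, idx) {
  tp_node(tp, a$value[, idx, drop = FALSE], needs = a$needs,
          backward = function(nd) {
            da <- matrix(0, nrow(a$value), ncol(a$value))
            da[, idx] <- nd$grad
            acc_grad(a, da)
          })
}

tp_cbind2 <- function(tp, a, b) {
  na <- ncol(a$value)
  tp_node(tp, cbind(a$value, b$value), needs = needs_any(a, b),
          backward = function(nd) {
            acc_grad(a, nd$grad[, seq_len(na), drop = FALSE])
            acc_grad(b, nd$grad[, -seq_len(na), drop = FALSE])
          })
}

tp_rbind_list <- function(tp, lst) {
  rows <- vapply(lst, function(n) nrow(n$value), 1L)
  ends <- cumsum(rows)
  needs <- any(vapply(lst, function(n) isTRUE(n$needs), TRUE))
  tp_node(tp, do.call(rbind, lapply(lst, tp_val)), needs = needs,
          backward = function(nd) {
            for (i in seq_along(lst)) {
              r <- (ends[i] - rows[i] + 1L):ends[i]
              acc_grad(lst[[i]], nd$grad[r, , drop = FALSE])
            }
          })
}

tp_mean_all <- function(tp, a) {
  n <- length(a$value)
  tp_node(tp, matrix(mean(a$value), 1L, 1L), needs = a$needs,
          backward = function(nd)
            acc_grad(a, matrix(nd$grad[1L] / n, nrow(a$value), ncol(a$value))))
}

# ---- fused blocks ----------------------------------------------------------

# Prepend a shared learnable class-token row to each frame block of
# n_patch rows. Input (F*n_patch) x d -> output (F*(n_patch+1)) x d.
tp_prepend_cls <- function(tp, a, cls, n_patch) {
  F <- nrow(a$value) %/% n_patch
  T <- n_patch + 1L
  cls_rows <- seq(1L, by = T, length.out = F)
  out <- matrix(0, F * T, ncol(a$value))
  out[cls_rows, ] <- matrix(cls$value, F, ncol(a$value), byrow = TRUE)
  out[-cls_rows, ] <- a$value
  tp_node(tp, out, needs = needs_any(a, cls), backward = function(nd) {
    acc_grad(cls, matrix(colSums(nd$grad[cls_rows, , drop = FALSE]), 1L))
    acc_grad(a, nd$grad[-cls_rows, , drop = FALSE])
  })
}

# Add a (T x d) positional table to each of n_rep consecutive T-row blocks.
tp_add_tiled <- function(tp, a, pos, n_rep) {
  T <- nrow(pos$value)
  tiled <- pos$value[rep(seq_len(T), n_rep), , drop = FALSE]
  tp_node(tp, a$value + tiled, needs = needs_any(a, pos),
          backward = function(nd) {
            acc_grad(a, nd$grad)
            if (pos$needs) {
              dp <- matrix(0, T, ncol(pos$value))
              grp <- rep(seq_len(T), n_rep)
              for (t in seq_len(T))
                dp[t, ] <- colSums(nd$grad[grp == t, , drop = FALSE])
              acc_grad(pos, dp)
            }
          })
}

# Multi-head self-attention over frame blocks of n_tok rows.
# x: (F*n_tok) x d; Wqkv: d x 3d; bqkv: 1 x 3d; Wo: d x d; bo: 1 x d.
tp_block_mhsa <- function(tp, x, Wqkv, bqkv, Wo, bo, n_tok, heads) {
  xv <- x$value
  d <- ncol(xv)
  dh <- d %/% heads
  F <- nrow(xv) %/% n_tok
  QKV <- sweep(xv %*% Wqkv$value, 2L, as.numeric(bqkv$value), `+`)
  Q <- QKV[, 1:d, drop = FALSE]
  K <- QKV[, d + 1:d, drop = FALSE]
  V <- QKV[, 2 * d + 1:d, drop = FALSE]
  O <- matrix(0, nrow(xv), d)
  A_cache <- vector("list", F * heads)
  sc <- 1 / sqrt(dh)
  for (f in seq_len(F)) {
    r <- ((f - 1L) * n_tok + 1L):(f * n_tok)
    for (j in seq_len(heads)) {
      cc <- ((j - 1L) * dh + 1L):(j * dh)
      A <- softmax_rows(Q[r, cc, drop = FALSE] %*%
                          t(K[r, cc, drop = FALSE]) * sc)
      O[r, cc] <- A %*% V[r, cc, drop = FALSE]
      A_cache[[(f - 1L) * heads + j]] <- A
    }
  }
  out <- sweep(O %*% Wo$value, 2L, as.numeric(bo$value), `+`)
  tp_node(tp, out, needs = needs_any(x, Wqkv, bqkv, Wo, bo),
          backward = function(nd) {
    g <- nd$grad
    acc_grad(Wo, t(O) %*% g)
    acc_grad(bo, matrix(colSums(g), 1L))
    dO <- g %*% t(Wo$value)
    dQKV <- matrix(0, nrow(xv), 3L * d)
    for (f in seq_len(F)) {
      r <- ((f - 1L) * n_tok + 1L):(f * n_tok)
      for (j in seq_len(heads)) {
        cc <- ((j - 1L) * dh + 1L):(j * dh)
        A <- A_cache[[(f - 1L) * heads + j]]
        dOf <- dO[r, cc, drop = FALSE]
        Vf <- V[r, cc, drop = FALSE]
        dA <- dOf %*% t(Vf)
        dS <- A * (dA - rowSums(dA * A))
        dQKV[r, cc] <- dS %*% K[r, cc, drop = FALSE] * sc
        dQKV[r, d + cc] <- t(dS) %*% Q[r, cc, drop = FALSE] * sc
        dQKV[r, 2L * d + cc] <- t(A) %*% dOf
      }
    }
    acc_grad(x, dQKV %*% t(Wqkv$value))
    acc_grad(Wqkv, t(xv) %*% dQKV)
    acc_grad(bqkv, matrix(colSums(dQKV), 1L))
  })
}

# Cross-modal attention: one query row per sample attends over that
# sample's n_tok key/value tokens, split across `heads` subspaces.
# Q: B x d_k; K, V: (n_tok*B) x d_k laid out token-major (row (t-1)*B + s).
# Attention weights are exposed on the node as $attn (B x (heads*n_tok)).
tp_cross_attn <- function(tp, Q, K, V, heads, n_tok) {
  Qv <- Q$value; Kv <- K$value; Vv <- V$value
  B <- nrow(Qv)
  d_k <- ncol(Qv)
  dh <- d_k %/% heads
  sc <- 1 / sqrt(dh)
  out <- matrix(0, B, d_k)
  attn <- matrix(0, B, heads * n_tok)
  for (s in seq_len(B)) {
    rk <- s + B * (seq_len(n_tok) - 1L)
    for (j in seq_len(heads)) {
      cc <- ((j - 1L) * dh + 1L):(j * dh)
      A <- softmax_rows(Qv[s, cc, drop = FALSE] %*%
                          t(Kv[rk, cc, drop = FALSE]) * sc)
      out[s, cc] <- A %*% Vv[rk, cc, drop = FALSE]
      attn[s, (j - 1L) * n_tok + seq_len(n_tok)] <- A
    }
  }
  nd <- tp_node(tp, out, needs = needs_any(Q, K, V), backward = function(nd) {
    g <- nd$grad
    dQ <- matrix(0, B, d_k)
    dK <- matrix(0, nrow(Kv), d_k)
    dV <- matrix(0, nrow(Vv), d_k)
    for (s in seq_len(B)) {
      rk <- s + B * (seq_len(n_tok) - 1L)
      for (j in seq_len(heads)) {
        cc <- ((j - 1L) * dh + 1L):(j * dh)
        A <- attn[s, (j - 1L) * n_tok + seq_len(n_tok), drop = FALSE]
        gf <- g[s, cc, drop = FALSE]
        dA <- gf %*% t(Vv[rk, cc, drop = FALSE])
        dS <- A * (dA - sum(dA * A))
        dQ[s, cc] <- dS %*% Kv[rk, cc, drop = FALSE] * sc
        dK[rk, cc] <- dK[rk, cc] + t(dS) %*% Qv[s, cc, drop = FALSE] * sc
        dV[rk, cc] <- dV[rk, cc] + t(A) %*% gf
      }
    }
    acc_grad(Q, dQ); acc_grad(K, dK); acc_grad(V, dV)
  })
  nd$attn <- attn
  nd
}

# Mean focal loss over a batch: mean_i -w_{y_i} (1 - p_i)^gamma log p_i,
# where p_i is the probability assigned to the true class. Probabilities
# are clamped to [eps, 1 - 1e-12] before the log for numerical safety;
# gradients are zeroed where the clamp is active.
tp_focal_loss <- function(tp, probs, labels, weights, gamma, eps = 1e-9) {
  n <- nrow(probs$value)
  sel <- cbind(seq_len(n), labels + 1L)
  p <- probs$value[sel]
  clamped <- p < eps | p > 1 - 1e-12
  pc <- pmin(1 - 1e-12, pmax(eps, p))
  w <- weights[labels + 1L]
  li <- -w * (1 - pc)^gamma * log(pc)
  tp_node(tp, matrix(mean(li), 1L, 1L), needs = probs$needs,
          backward = function(nd) {
    t1 <- if (gamma > 0) -gamma * (1 - pc)^(gamma - 1) * log(pc) else 0
    dp <- -w / n * (t1 + (1 - pc)^gamma / pc) * nd$grad[1L]
    dp[clamped] <- 0
    dP <- matrix(0, n, ncol(probs$value))
    dP[sel] <- dp
    acc_grad(probs, dP)
  })
}
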