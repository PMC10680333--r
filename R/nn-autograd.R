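# Reverse-mode automatic differentiation engine used by all four
# architectures. A tape records nodes in creation order; backward()
# walks the tape in reverse, each node distributing its gradient to its
# parents through a closure. Values are plain numeric matrices; batched
# sequence tensors use the (batch * time) x feature layout with row
# index (b - 1) * N + t.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 64L)
  e$n <- 0L
  e
}

ad_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

# leaf holding a weight matrix; gradients accumulate here
ad_leaf <- function(tape, value) ad_node(tape, value)

ad_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
}

# run the tape backwards from `root` (a scalar loss node)
ad_backward <- function(tape, root) {
  root$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

ad_matmul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_node(tape, av %*% bv, backward = function(g) {
    ad_accum(a, g %*% t(bv))
    ad_accum(b, crossprod(av, g))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, backward = function(g) {
    ad_accum(a, g)
    ad_accum(b, g)
  })
}

# broadcast a bias row vector over the rows of a matrix
ad_add_bias <- function(tape, a, bias) {
  v <- a$value + rep(bias$value, each = nrow(a$value))
  ad_node(tape, v, backward = function(g) {
    ad_accum(a, g)
    ad_accum(bias, colSums(g))
  })
}

ad_relu <- function(tape, a) {
  v <- a$value
  mask <- v > 0
  ad_node(tape, v * mask, backward = function(g) ad_accum(a, g * mask))
}

# inverted dropout; identity when not training or rate == 0
ad_dropout <- function(tape, a, rate, training) {
  if (!training || rate <= 0) return(a)
  keep <- 1 - rate
  mask <- (matrix(stats::runif(length(a$value)), nrow(a$value)) < keep) / keep
  ad_node(tape, a$value * mask, backward = function(g) ad_accum(a, g * mask))
}

# row-wise layer normalisation with learned gain/offset
ad_layernorm <- function(tape, x, gamma, beta, eps = 1e-6) {
  xv <- x$value
  D <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  v <- sweep(xhat, 2L, gamma$value, "*")
  v <- sweep(v, 2L, beta$value, "+")
  ad_node(tape, v, backward = function(g) {
    dgam <- colSums(g * xhat)
    dbet <- colSums(g)
    dxhat <- sweep(g, 2L, gamma$value, "*")
    s1 <- rowSums(dxhat)
    s2 <- rowSums(dxhat * xhat)
    dx <- (inv / D) * (D * dxhat - s1 - xhat * s2)
    ad_accum(x, dx)
    ad_accum(gamma, dgam)
    ad_accum(beta, dbet)
  })
}

# embedding lookup; token id 0 addresses the first row of the table
ad_embedding <- function(tape, E, ids) {
  rows <- as.integer(ids) + 1L
  Ev <- E$value
  ad_node(tape, Ev[rows, , drop = FALSE], backward = function(g) {
    agg <- rowsum(g, group = rows)
    dE <- matrix(0, nrow(Ev), ncol(Ev))
    dE[as.integer(rownames(agg)), ] <- agg
    ad_accum(E, dE)
  })
}

# (B*N) x d sequence tensor -> B x (N*d) matrix, features fastest
ad_flatten_seq <- function(tape, x, B, N) {
  d <- ncol(x$value)
  v <- t(matrix(t(x$value), d * N, B))
  ad_node(tape, v, backward = function(g) {
    ad_accum(x, t(matrix(t(g), d, N * B)))
  })
}

# mean binary cross-entropy on logits, restricted to columns col_keep
# (a logical vector over the label dimension)
ad_bce_mean <- function(tape, z, y, col_keep) {
  zv <- z$value[, col_keep, drop = FALSE]
  yv <- y[, col_keep, drop = FALSE]
  loss <- mean(pmax(zv, 0) - zv * yv + log1p(exp(-abs(zv))))
  ad_node(tape, loss, backward = function(g) {
    dz <- matrix(0, nrow(z$value), ncol(z$value))
    dz[, col_keep] <- (stats::plogis(zv) - yv) * (g / length(zv))
    ad_accum(z, dz)
  })
}

# Scaled-dot-product multi-head self-attention core. q, k, v are
# (B*N) x (h*dh) nodes; key_pad is a B x N logical matrix, TRUE where
# the position is padding (those keys are masked out). Returns the
# output node plus the post-softmax weights as a list indexed
# [[b]][[head]] of N x N matrices.
ad_attention <- function(tape, q, k, v, B, N, n_heads, head_dim, key_pad) {
  qv <- q$value; kv <- k$value; vv <- v$value
  scale <- 1 / sqrt(head_dim)
  out <- matrix(0, B * N, n_heads * head_dim)
  attn <- vector("list", B)
  head_cols <- lapply(seq_len(n_heads), function(h) {
    ((h - 1L) * head_dim + 1L):(h * head_dim)
  })
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    maskm <- matrix(-1e9 * key_pad[b, ], N, N, byrow = TRUE)
    ab <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- head_cols[[h]]
      S <- tcrossprod(qv[rows, cols, drop = FALSE],
                      kv[rows, cols, drop = FALSE]) * scale + maskm
      S <- S - S[cbind(seq_len(N), max.col(S, ties.method = "first"))]
      A <- exp(S)
      A <- A / .rowSums(A, N, N)
      ab[[h]] <- A
      out[rows, cols] <- A %*% vv[rows, cols, drop = FALSE]
    }
    attn[[b]] <- ab
  }
  node <- ad_node(tape, out, backward = function(g) {
    dq <- matrix(0, nrow(qv), ncol(qv))
    dk <- matrix(0, nrow(kv), ncol(kv))
    dv <- matrix(0, nrow(vv), ncol(vv))
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * N + 1L):(b * N)
      for (h in seq_len(n_heads)) {
        cols <- head_cols[[h]]
        A <- attn[[b]][[h]]
        G <- g[rows, cols, drop = FALSE]
        Vb <- vv[rows, cols, drop = FALSE]
        dA <- tcrossprod(G, Vb)
        dS <- A * (dA - rowSums(dA * A))
        dv[rows, cols] <- dv[rows, cols] + crossprod(A, G)
        dq[rows, cols] <- dq[rows, cols] +
          (dS %*% kv[rows, cols, drop = FALSE]) * scale
        dk[rows, cols] <- dk[rows, cols] +
          crossprod(dS, qv[rows, cols, drop = FALSE]) * scale
      }
    }
    ad_accum(q, dq)
    ad_accum(k, dk)
    ad_accum(v, dv)
  })
  list(node = node, attn = attn)
}

# One GRU layer over a (B*N) x d input tensor. Gate order z, r, h with
# the reset-after candidate (recurrent bias applied before the reset
# gate multiplies), so each layer carries 3 * (d*u + u*u + 2u)
# parameters. Returns (B*N) x u when return_sequences, else B x u.
ad_gru <- function(tape, x, W, U, b_in, b_rec, B, N, return_sequences = FALSE) {
  xv <- x$value
  u <- nrow(U$value)
  iz <- 1:u; ir <- (u + 1):(2 * u); ih <- (2 * u + 1):(3 * u)
  H <- matrix(0, B, u)
  st <- vector("list", N)
  seq_out <- if (return_sequences) matrix(0, B * N, u) else NULL
  for (t in seq_len(N)) {
    idx <- (seq_len(B) - 1L) * N + t
    Xt <- xv[idx, , drop = FALSE]
    gx <- sweep(Xt %*% W$value, 2L, b_in$value, "+")
    gh <- sweep(H %*% U$value, 2L, b_rec$value, "+")
    z <- stats::plogis(gx[, iz] + gh[, iz])
    r <- stats::plogis(gx[, ir] + gh[, ir])
    ghh <- gh[, ih]
    hh <- tanh(gx[, ih] + r * ghh)
    Hn <- z * H + (1 - z) * hh
    st[[t]] <- list(Xt = Xt, Hprev = H, z = z, r = r, hh = hh, ghh = ghh)
    H <- Hn
    if (return_sequences) seq_out[idx, ] <- H
  }
  value <- if (return_sequences) seq_out else H
  ad_node(tape, value, backward = function(g) {
    dW <- matrix(0, nrow(W$value), ncol(W$value))
    dU <- matrix(0, u, 3 * u)
    dbi <- numeric(3 * u)
    dbr <- numeric(3 * u)
    dx <- matrix(0, nrow(xv), ncol(xv))
    dH <- if (return_sequences) matrix(0, B, u) else g
    for (t in seq.int(N, 1L)) {
      idx <- (seq_len(B) - 1L) * N + t
      if (return_sequences) dH <- dH + g[idx, , drop = FALSE]
      s <- st[[t]]
      dz <- dH * (s$Hprev - s$hh)
      dhh <- dH * (1 - s$z)
      dHprev <- dH * s$z
      dhh_pre <- dhh * (1 - s$hh^2)
      dghh <- dhh_pre * s$r
      dr <- dhh_pre * s$ghh
      dz_pre <- dz * s$z * (1 - s$z)
      dr_pre <- dr * s$r * (1 - s$r)
      dgx <- cbind(dz_pre, dr_pre, dhh_pre)
      dgh <- cbind(dz_pre, dr_pre, dghh)
      dx[idx, ] <- dgx %*% t(W$value)
      dW <- dW + crossprod(s$Xt, dgx)
      dbi <- dbi + colSums(dgx)
      dHprev <- dHprev + dgh %*% t(U$value)
      dU <- dU + crossprod(s$Hprev, dgh)
      dbr <- dbr + colSums(dgh)
      dH <- dHprev
    }
    ad_accum(x, dx)
    ad_accum(W, dW)
    ad_accum(U, dU)
    ad_accum(b_in, dbi)
    ad_accum(b_rec, dbr)
  })
}

# index matrix for im2col on an N x d single-channel image
conv_patch_index <- function(N, d, kh, kw) {
  oh <- N - kh + 1L
  ow <- d - kw + 1L
  base <- as.vector(outer(seq_len(oh), (seq_len(ow) - 1L) * N, "+"))
  offs <- as.vector(outer(0:(kh - 1L), (0:(kw - 1L)) * N, "+"))
  list(idx = outer(base, offs, "+"), oh = oh, ow = ow)
}

# valid 2-D convolution (kh x kw kernel, F filters, relu) followed by a
# ph x pw max-pool (floor) and flatten, applied per sample of a
# (B*N) x d sequence tensor viewed as an N x d one-channel image.
ad_conv_relu_pool_flatten <- function(tape, x, K, bias, B, N, kh, kw,
                                      pool = c(2L, 2L)) {
  xv <- x$value
  d <- ncol(xv)
  pi_ <- conv_patch_index(N, d, kh, kw)
  oh <- pi_$oh; ow <- pi_$ow
  ph <- oh %/% pool[1]; pw <- ow %/% pool[2]
  nf <- ncol(K$value)
  # linear (column-major over oh) indices of the cells in each pool group
  grp <- vector("list", pool[1] * pool[2])
  gi <- 0L
  for (dj in 0:(pool[2] - 1L)) for (di in 0:(pool[1] - 1L)) {
    gi <- gi + 1L
    rows_i <- (seq_len(ph) - 1L) * pool[1] + 1L + di
    cols_j <- (seq_len(pw) - 1L) * pool[2] + 1L + dj
    grp[[gi]] <- as.vector(outer(rows_i, (cols_j - 1L) * oh, "+"))
  }
  ngrp <- length(grp)
  out <- matrix(0, B, ph * pw * nf)
  state <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    img <- xv[rows, , drop = FALSE]
    P <- matrix(img[pi_$idx], nrow(pi_$idx), ncol(pi_$idx))
    Z <- sweep(P %*% K$value, 2L, bias$value, "+")
    relu_mask <- Z > 0
    Z <- Z * relu_mask
    best <- Z[grp[[1]], , drop = FALSE]
    argg <- matrix(1L, ph * pw, nf)
    for (g2 in 2:ngrp) {
      cand <- Z[grp[[g2]], , drop = FALSE]
      better <- cand > best
      best[better] <- cand[better]
      argg[better] <- g2
    }
    out[b, ] <- as.vector(best)
    state[[b]] <- list(P = P, relu_mask = relu_mask, argg = argg)
  }
  ad_node(tape, out, backward = function(g) {
    dK <- matrix(0, nrow(K$value), ncol(K$value))
    db <- numeric(nf)
    dx <- matrix(0, nrow(xv), ncol(xv))
    for (b in seq_len(B)) {
      s <- state[[b]]
      gp <- matrix(g[b, ], ph * pw, nf)
      dZ <- matrix(0, oh * ow, nf)
      for (g2 in seq_len(ngrp)) {
        sel <- s$argg == g2
        if (!any(sel)) next
        rows_g <- grp[[g2]]
        # scatter pooled grads to the winning pre-pool cells
        tmp <- matrix(0, ph * pw, nf)
        tmp[sel] <- gp[sel]
        dZ[rows_g, ] <- dZ[rows_g, ] + tmp
      }
      dZ <- dZ * s$relu_mask
      dK <- dK + crossprod(s$P, dZ)
      db <- db + colSums(dZ)
      dP <- tcrossprod(dZ, K$value)
      dimg <- numeric(N * d)
      for (j in seq_len(ncol(pi_$idx))) {
        dimg[pi_$idx[, j]] <- dimg[pi_$idx[, j]] + dP[, j]
      }
      rows <- ((b - 1L) * N + 1L):(b * N)
      dx[rows, ] <- dx[rows, ] + matrix(dimg, N, d)
    }
    ad_accum(x, dx)
    ad_accum(K, dK)
    ad_accum(bias, db)
  })
}

# select rows of a node (e.g. the final time step of each sequence)
ad_select_rows <- function(tape, x, idx) {
  xv <- x$value
  ad_node(tape, xv[idx, , drop = FALSE], backward = function(g) {
    dx <- matrix(0, nrow(xv), ncol(xv))
    dx[idx, ] <- g
    ad_accum(x, dx)
  })
}

# Glorot-uniform initialiser (fan_in x fan_out dense kernels)
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# uniform(-0.05, 0.05) embedding initialiser
init_embedding <- function(n, d) {
  matrix(stats::runif(n * d, -0.05, 0.05), n, d)
}
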