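# Reverse-mode automatic differentiation on a linear tape, with the fused
# layer operations the segmentation network needs. Feature tensors are plain
# R arrays laid out (H, W, C, B); token matrices are (N x D). Index maps for
# im2col and the bilinear upsampling matrices are cached per shape.

.op_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  v <- .op_cache[[key]]
  if (is.null(v)) {
    v <- build()
    assign(key, v, envir = .op_cache)
  }
  v
}

# --- tape ---------------------------------------------------------------------

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", 256L)
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tape_push <- function(tp, val, parents, backward, name = NULL) {
  # force all promises first: evaluating `val` or `parents` may itself push
  # nested ops onto the tape, which must claim their slots before this one
  force(val); force(parents); force(backward)
  n <- tp$n + 1L
  if (n > length(tp$vals)) {
    length(tp$vals) <- 2L * length(tp$vals)
    length(tp$nodes) <- 2L * length(tp$nodes)
  }
  tp$vals[[n]] <- val
  tp$nodes[[n]] <- list(parents = parents, backward = backward, name = name)
  tp$n <- n
  n
}

t_leaf <- function(tp, val, name = NULL) tape_push(tp, val, integer(0), NULL, name)

t_val <- function(tp, id) {
  force(id)  # ids may be produced by nested op calls that push onto the tape
  tp$vals[[id]]
}

# Backpropagate from scalar node `root`; returns gradients of named leaves.
tape_backward <- function(tp, root) {
  grads <- vector("list", tp$n)
  grads[[root]] <- 1
  out <- list()
  for (id in root:1) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tp$nodes[[id]]
    if (!is.null(node$name))
      out[[node$name]] <- if (is.null(out[[node$name]])) g else out[[node$name]] + g
    if (is.null(node$backward)) next
    pg <- node$backward(g)
    for (j in seq_along(node$parents)) {
      p <- node$parents[j]
      if (is.null(pg[[j]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
    grads[[id]] <- NULL  # free early
  }
  out
}

# --- elementwise / linear algebra --------------------------------------------

t_add <- function(tp, a, b) {
  tape_push(tp, t_val(tp, a) + t_val(tp, b), c(a, b),
            function(g) list(g, g))
}

t_scale <- function(tp, a, s) {
  tape_push(tp, s * t_val(tp, a), a, function(g) list(s * g))
}

t_relu <- function(tp, a) {
  av <- t_val(tp, a)
  pos <- av > 0
  tape_push(tp, av * pos, a, function(g) list(g * pos))
}

t_matmul <- function(tp, a, b) {
  av <- t_val(tp, a); bv <- t_val(tp, b)
  tape_push(tp, av %*% bv, c(a, b),
            function(g) list(tcrossprod(g, bv), crossprod(av, g)))
}

# X (N x Din) %*% W (Din x Dout) + b (length Dout, broadcast over rows)
t_linear <- function(tp, x, w, b) {
  xv <- t_val(tp, x); wv <- t_val(tp, w); bv <- t_val(tp, b)
  y <- xv %*% wv
  y <- sweep(y, 2, bv, `+`)
  tape_push(tp, y, c(x, w, b),
            function(g) list(tcrossprod(g, wv), crossprod(xv, g), colSums(g)))
}

# Multiply each row of X (N x D) by w (length N); w is a constant.
t_rowscale_const <- function(tp, x, w) {
  xv <- t_val(tp, x)
  tape_push(tp, xv * w, x, function(g) list(g * w))
}

# --- normalization / attention -----------------------------------------------

t_layernorm <- function(tp, x, gamma, beta, eps = 1e-5) {
  xv <- t_val(tp, x); gv <- t_val(tp, gamma); bv <- t_val(tp, beta)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2, gv, `*`)
  y <- sweep(y, 2, bv, `+`)
  tape_push(tp, y, c(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- sweep(g, 2, gv, `*`)
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
    list(dx, dgamma, dbeta)
  })
}

# Attention logits A = Q K^T / sqrt(d_k) (+ lambda * B), lambda a learnable
# scalar node, B a constant rank-1 bias matrix.
t_attn_logits <- function(tp, q, k, lambda = NULL, B = NULL) {
  qv <- t_val(tp, q); kv <- t_val(tp, k)
  sc <- 1 / sqrt(ncol(kv))
  A <- tcrossprod(qv, kv) * sc
  if (!is.null(lambda)) {
    lv <- as.numeric(t_val(tp, lambda))
    A <- A + lv * B
    tape_push(tp, A, c(q, k, lambda), function(g) {
      list((g %*% kv) * sc, crossprod(g, qv) * sc, sum(g * B))
    })
  } else {
    tape_push(tp, A, c(q, k), function(g) {
      list((g %*% kv) * sc, crossprod(g, qv) * sc)
    })
  }
}

t_softmax_rows <- function(tp, a) {
  P <- softmax_rows(t_val(tp, a))
  tape_push(tp, P, a, function(g) {
    list(P * (g - rowSums(g * P)))
  })
}

# Mean binary cross-entropy between each softmaxed row of A and the binary
# token target (clamped); scalar node.
t_attn_bce <- function(tp, a, target) {
  Av <- t_val(tp, a)
  P <- softmax_rows(Av)
  Pc <- pmin(pmax(P, 1e-7), 1 - 1e-7)
  tg <- matrix(target, nrow(Av), ncol(Av), byrow = TRUE)
  loss <- mean(-(tg * log(Pc) + (1 - tg) * log(1 - Pc)))
  tape_push(tp, loss, a, function(g) {
    active <- (P > 1e-7) & (P < 1 - 1e-7)
    dP <- g * (-(tg / Pc) + (1 - tg) / (1 - Pc)) / length(P) * active
    list(P * (dP - rowSums(dP * P)))
  })
}

# --- convolution --------------------------------------------------------------

im2col_idx <- function(H, W, C, B, k, stride, pad) {
  key <- paste("i2c", H, W, C, B, k, stride, pad, sep = "_")
  cache_get(key, function() {
    Hp <- H + 2L * pad; Wp <- W + 2L * pad
    OH <- (Hp - k) %/% stride + 1L
    OW <- (Wp - k) %/% stride + 1L
    off_k <- as.vector(outer(outer(0:(k - 1L), Hp * (0:(k - 1L)), `+`),
                             Hp * Wp * (0:(C - 1L)), `+`))
    base_p <- as.vector(outer(stride * (0:(OH - 1L)), Hp * stride * (0:(OW - 1L)), `+`))
    idx1 <- outer(off_k, base_p, `+`) + 1L
    idx <- outer(as.vector(idx1), Hp * Wp * C * (0:(B - 1L)), `+`)
    dim(idx) <- c(length(off_k), length(base_p) * B)
    list(idx = idx, OH = OH, OW = OW, Hp = Hp, Wp = Wp)
  })
}

pad_array <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# 2D convolution, weights W (Cout x k*k*Cin), bias length Cout; optional
# fused ReLU activation.
t_conv2d <- function(tp, x, w, b, stride = 1L, pad = 1L, act = "linear") {
  xv <- t_val(tp, x); wv <- t_val(tp, w); bv <- t_val(tp, b)
  d <- dim(xv)
  k <- as.integer(sqrt(ncol(wv) / d[3]))
  info <- im2col_idx(d[1], d[2], d[3], d[4], k, as.integer(stride), as.integer(pad))
  xp <- pad_array(xv, pad)
  cols <- xp[as.vector(info$idx)]  # vector gather (a k-column idx matrix
                                   # would otherwise index by coordinates)
  dim(cols) <- dim(info$idx)
  Y <- wv %*% cols + bv
  P <- info$OH * info$OW
  pos <- if (act == "relu") Y > 0
  if (act == "relu") Y <- Y * pos
  dim(Y) <- c(nrow(wv), info$OH, info$OW, d[4])
  out <- aperm(Y, c(2, 3, 1, 4))
  tape_push(tp, out, c(x, w, b), function(g) {
    dY <- aperm(g, c(3, 1, 2, 4))
    if (!is.null(pos)) { dim(dY) <- dim(pos); dY <- dY * pos }
    dim(dY) <- c(nrow(wv), P * d[4])
    dW <- tcrossprod(dY, cols)
    db <- rowSums(dY)
    dcols <- crossprod(wv, dY)
    # col2im: accumulate per kernel offset (all channels/batches at once) in
    # channel-first layout, permuting back just once; dcols row order is
    # (di, dj, c) with di fastest
    OH <- info$OH; OW <- info$OW
    dxpc <- array(0, c(d[3], info$Hp, info$Wp, d[4]))
    for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
      rows <- seq.int(di + k * dj + 1L, by = k * k, length.out = d[3])
      blk <- dcols[rows, , drop = FALSE]
      dim(blk) <- c(d[3], OH, OW, d[4])
      ri <- di + stride * (0:(OH - 1L)) + 1L
      ci <- dj + stride * (0:(OW - 1L)) + 1L
      dxpc[, ri, ci, ] <- dxpc[, ri, ci, , drop = FALSE] + blk
    }
    dxc <- if (pad > 0L)
      dxpc[, pad + seq_len(d[1]), pad + seq_len(d[2]), , drop = FALSE]
    else dxpc
    dx <- aperm(dxc, c(2, 3, 1, 4))
    dim(dx) <- d
    list(dx, dW, db)
  })
}

# --- bilinear upsampling ------------------------------------------------------

upsample_matrix <- function(H) {
  key <- paste("up", H, sep = "_")
  cache_get(key, function() {
    U <- matrix(0, 2L * H, H)
    src <- pmin(pmax((seq_len(2L * H) - 0.5) / 2 - 0.5, 0), H - 1)
    i0 <- pmin(floor(src), H - 2)
    w <- src - i0
    for (i in seq_len(2L * H)) {
      U[i, i0[i] + 1] <- U[i, i0[i] + 1] + (1 - w[i])
      U[i, i0[i] + 2] <- U[i, i0[i] + 2] + w[i]
    }
    U
  })
}

apply_rows <- function(x, U) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1], prod(d[-1]))
  y <- U %*% m
  dim(y) <- c(nrow(U), d[-1])
  y
}

upsample2x_fwd <- function(xv) {
  d <- dim(xv)
  U1 <- upsample_matrix(d[1]); U2 <- upsample_matrix(d[2])
  y <- apply_rows(xv, U1)
  y <- aperm(y, c(2, 1, 3, 4))
  y <- apply_rows(y, U2)
  aperm(y, c(2, 1, 3, 4))
}

t_upsample2x <- function(tp, x) {
  xv <- t_val(tp, x)
  d <- dim(xv)
  U1 <- upsample_matrix(d[1]); U2 <- upsample_matrix(d[2])
  tape_push(tp, upsample2x_fwd(xv), x, function(g) {
    y <- apply_rows(g, t(U1))
    y <- aperm(y, c(2, 1, 3, 4))
    y <- apply_rows(y, t(U2))
    list(aperm(y, c(2, 1, 3, 4)))
  })
}

# --- layout ops ---------------------------------------------------------------

t_concat_c <- function(tp, ids) {
  vals <- lapply(ids, t_val, tp = tp)
  dims <- lapply(vals, dim)
  ch <- vapply(dims, `[`, numeric(1), 3)
  d1 <- dims[[1]]
  out <- array(0, c(d1[1], d1[2], sum(ch), d1[4]))
  at <- 0L
  for (i in seq_along(vals)) {
    out[, , at + seq_len(ch[i]), ] <- vals[[i]]
    at <- at + ch[i]
  }
  tape_push(tp, out, as.integer(ids), function(g) {
    at <- 0L
    lapply(seq_along(ids), function(i) {
      sl <- g[, , at + seq_len(ch[i]), , drop = FALSE]
      at <<- at + ch[i]
      sl
    })
  })
}

# Row-major token flattening: token r = (i-1)*s2 + j for grid cell (i, j).
tokens_perm <- function(s1, s2, C) {
  key <- paste("tokperm", s1, s2, C, sep = "_")
  cache_get(key, function() {
    # arr position (i, j, c) (column-major vector order: i fastest)
    i <- rep(seq_len(s1), times = s2 * C)
    j <- rep(rep(seq_len(s2), each = s1), times = C)
    cc <- rep(seq_len(C), each = s1 * s2)
    r <- (i - 1L) * s2 + j
    r + (cc - 1L) * (s1 * s2)  # index into as.vector(T) (N x C, col-major)
  })
}

# Extract sample b of a (s, s, C, B) array as a token matrix (N x C).
t_map_to_tokens <- function(tp, x, b) {
  xv <- t_val(tp, x)
  d <- dim(xv)
  perm <- tokens_perm(d[1], d[2], d[3])
  sl <- xv[, , , b]
  tv <- numeric(length(sl))
  tv[perm] <- as.vector(sl)
  T <- matrix(tv, d[1] * d[2], d[3])
  tape_push(tp, T, x, function(g) {
    dx <- array(0, d)
    dx[, , , b] <- array(as.vector(g)[perm], d[1:3])
    list(dx)
  })
}

# Stack per-sample token matrices (N x D) into a (s, s, D, B) feature map.
t_stack_tokens_to_map <- function(tp, ids, s1, s2) {
  vals <- lapply(ids, t_val, tp = tp)
  D <- ncol(vals[[1]])
  B <- length(ids)
  perm <- tokens_perm(s1, s2, D)
  out <- array(0, c(s1, s2, D, B))
  for (b in seq_len(B)) out[, , , b] <- array(as.vector(vals[[b]])[perm], c(s1, s2, D))
  N <- s1 * s2
  tape_push(tp, out, as.integer(ids), function(g) {
    # forward: arr_vec[p] = T_vec[perm[p]]  =>  dT_vec[perm[p]] += g_vec[p]
    lapply(seq_len(B), function(b) {
      sl <- as.vector(g[, , , b])
      tv <- numeric(length(sl))
      tv[perm] <- sl
      matrix(tv, N, D)
    })
  })
}

# --- losses -------------------------------------------------------------------

# Soft Dice loss on a probability array vs a binary truth array (constants).
t_dice_loss <- function(tp, p, truth, smooth = 1e-6) {
  pv <- t_val(tp, p)
  tv <- as.numeric(truth)
  sp <- sum(pv); st <- sum(tv); spt <- sum(pv * tv)
  denom <- sp + st + smooth
  loss <- 1 - (2 * spt + smooth) / denom
  tape_push(tp, loss, p, function(g) {
    dp <- -g * (2 * tv * denom - (2 * spt + smooth)) / denom^2
    dim(dp) <- dim(pv) %||% NULL
    list(dp)
  })
}

# Two-class softmax tumor probability from a logits array (H, W, 2, B).
t_softmax2_prob <- function(tp, z) {
  zv <- t_val(tp, z)
  d <- dim(zv)
  diff <- zv[, , 2, , drop = FALSE] - zv[, , 1, , drop = FALSE]
  p <- 1 / (1 + exp(-diff))
  dim(p) <- d[c(1, 2, 4)]
  tape_push(tp, p, z, function(g) {
    dd <- g * p * (1 - p)
    dz <- array(0, d)
    dz[, , 2, ] <- dd
    dz[, , 1, ] <- -dd
    list(dz)
  })
}
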