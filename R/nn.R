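# Compact 3D-CNN engine.
#
# Layers operate on arrays of shape (batch, V1, V2, V3, C); convolution is
# implemented as im2col + BLAS matrix multiply, which keeps both the forward
# and backward passes as dense GEMMs. Supported layers: conv3d (valid or
# same padding), elu, spatial_dropout (drops whole feature maps), gap
# (global average pooling), flatten, dense, dense_block (densely connected
# same-padded convolutions with channel concatenation). The final dense
# layer's logits feed a softmax cross-entropy head. Optimiser: Adam.

pad3d <- function(X, p) {
  if (p == 0) return(X)
  d <- dim(X)
  out <- array(0, dim = c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4] + 2 * p, d[5]))
  out[, p + seq_len(d[2]), p + seq_len(d[3]), p + seq_len(d[4]), ] <- X
  out
}

unpad3d <- function(X, p, d_orig) {
  if (p == 0) return(X)
  X[, p + seq_len(d_orig[2]), p + seq_len(d_orig[3]),
    p + seq_len(d_orig[4]), , drop = FALSE]
}

# columns ordered offset-major: for offset o (dx fastest) the C_in channels
im2col3d <- function(X, K) {
  d <- dim(X)  # B, V1, V2, V3, C
  Vo <- d[2:4] - K + 1
  B <- d[1]; C <- d[5]
  P <- prod(Vo)
  M <- matrix(0, B * P, K^3 * C)
  o <- 0L
  for (dz in 0:(K - 1)) for (dy in 0:(K - 1)) for (dx in 0:(K - 1)) {
    blk <- X[, dx + seq_len(Vo[1]), dy + seq_len(Vo[2]),
             dz + seq_len(Vo[3]), , drop = FALSE]
    dim(blk) <- c(B * P, C)
    M[, o * C + seq_len(C)] <- blk
    o <- o + 1L
  }
  list(M = M, Vo = Vo, B = B, C = C)
}

col2im3d <- function(dM, dimX, K) {
  Vo <- dimX[2:4] - K + 1
  B <- dimX[1]; C <- dimX[5]
  P <- prod(Vo)
  dX <- array(0, dim = dimX)
  o <- 0L
  for (dz in 0:(K - 1)) for (dy in 0:(K - 1)) for (dx in 0:(K - 1)) {
    blk <- dM[, o * C + seq_len(C), drop = FALSE]
    dim(blk) <- c(B, Vo[1], Vo[2], Vo[3], C)
    ix <- dx + seq_len(Vo[1]); iy <- dy + seq_len(Vo[2])
    iz <- dz + seq_len(Vo[3])
    dX[, ix, iy, iz, ] <- dX[, ix, iy, iz, , drop = FALSE] + blk
    o <- o + 1L
  }
  dX
}

# He-normal initialisation
init_conv <- function(K, c_in, filters) {
  fan_in <- K^3 * c_in
  list(W = matrix(stats::rnorm(fan_in * filters, sd = sqrt(2 / fan_in)),
                  fan_in, filters),
       b = numeric(filters))
}

init_dense <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)),
                  n_in, n_out),
       b = numeric(n_out))
}

layer_conv3d <- function(c_in, filters, K = 3L, padding = "valid") {
  c(list(type = "conv3d", K = as.integer(K), padding = padding,
         c_in = c_in, filters = filters),
    init_conv(K, c_in, filters))
}

layer_elu <- function() list(type = "elu")
layer_spatial_dropout <- function(rate) list(type = "spatial_dropout",
                                             rate = rate)
layer_gap <- function() list(type = "gap")
layer_flatten <- function() list(type = "flatten")
layer_dense <- function(n_in, n_out, activation = "linear") {
  c(list(type = "dense", n_in = n_in, n_out = n_out,
         activation = activation),
    init_dense(n_in, n_out))
}

# densely connected block: n_layers same-padded convs, each producing
# `growth` channels appended to the running feature stack
layer_dense_block <- function(c_in, growth, n_layers, K = 3L) {
  convs <- lapply(seq_len(n_layers) - 1L, function(l) {
    init_conv(K, c_in + l * growth, growth)
  })
  list(type = "dense_block", K = as.integer(K), c_in = c_in,
       growth = growth, n_layers = n_layers, convs = convs)
}

elu_fwd <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_bwd <- function(x, y, dy) dy * ifelse(x > 0, 1, y + 1)

concat_channels <- function(A, B) {
  da <- dim(A); db <- dim(B)
  out <- array(0, dim = c(da[1:4], da[5] + db[5]))
  out[, , , , seq_len(da[5])] <- A
  out[, , , , da[5] + seq_len(db[5])] <- B
  out
}

layer_forward <- function(layer, X, training) {
  switch(layer$type,
    conv3d = {
      d0 <- dim(X)
      p <- if (layer$padding == "same") (layer$K - 1L) %/% 2L else 0L
      Xp <- pad3d(X, p)
      ic <- im2col3d(Xp, layer$K)
      Y <- ic$M %*% layer$W
      Y <- Y + matrix(layer$b, nrow(Y), ncol(Y), byrow = TRUE)
      dim(Y) <- c(ic$B, ic$Vo, layer$filters)
      list(out = Y, cache = list(M = ic$M, dimXp = dim(Xp), d0 = d0, p = p))
    },
    elu = {
      Y <- elu_fwd(X)
      list(out = Y, cache = list(X = X, Y = Y))
    },
    spatial_dropout = {
      if (!training || layer$rate <= 0) {
        list(out = X, cache = NULL)
      } else {
        d <- dim(X)
        mask <- matrix(stats::rbinom(d[1] * d[5], 1, 1 - layer$rate),
                       d[1], d[5]) / (1 - layer$rate)
        Y <- X
        for (f in seq_len(d[5])) Y[, , , , f] <- Y[, , , , f] * mask[, f]
        list(out = Y, cache = list(mask = mask))
      }
    },
    gap = {
      d <- dim(X)
      S <- prod(d[2:4])
      Xr <- X; dim(Xr) <- c(d[1], S, d[5])
      Y <- matrix(0, d[1], d[5])
      for (f in seq_len(d[5])) Y[, f] <- rowMeans(Xr[, , f, drop = FALSE])
      list(out = Y, cache = list(d = d))
    },
    flatten = {
      d <- dim(X)
      Y <- X; dim(Y) <- c(d[1], prod(d[-1]))
      list(out = Y, cache = list(d = d))
    },
    dense = {
      Z <- X %*% layer$W
      Z <- Z + matrix(layer$b, nrow(Z), ncol(Z), byrow = TRUE)
      act <- layer$activation
      Y <- if (act == "elu") elu_fwd(Z) else Z
      list(out = Y, cache = list(X = X, Z = Z, Y = Y))
    },
    dense_block = {
      stack <- X
      caches <- vector("list", layer$n_layers)
      p <- (layer$K - 1L) %/% 2L
      for (l in seq_len(layer$n_layers)) {
        Xp <- pad3d(stack, p)
        ic <- im2col3d(Xp, layer$K)
        Z <- ic$M %*% layer$convs[[l]]$W
        Z <- Z + matrix(layer$convs[[l]]$b, nrow(Z), ncol(Z), byrow = TRUE)
        dim(Z) <- c(ic$B, ic$Vo, layer$growth)
        A <- elu_fwd(Z)
        caches[[l]] <- list(M = ic$M, dimXp = dim(Xp),
                            c_stack = dim(stack)[5], Z = Z, A = A)
        stack <- concat_channels(stack, A)
      }
      list(out = stack, cache = caches)
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dY) {
  switch(layer$type,
    conv3d = {
      d <- dim(dY)
      dYm <- dY; dim(dYm) <- c(prod(d[1:4]), d[5])
      dW <- crossprod(cache$M, dYm)
      db <- colSums(dYm)
      dM <- dYm %*% t(layer$W)
      dXp <- col2im3d(dM, cache$dimXp, layer$K)
      dX <- unpad3d(dXp, cache$p, cache$d0)
      list(dX = dX, grads = list(W = dW, b = db))
    },
    elu = list(dX = elu_bwd(cache$X, cache$Y, dY), grads = NULL),
    spatial_dropout = {
      if (is.null(cache)) {
        list(dX = dY, grads = NULL)
      } else {
        d <- dim(dY)
        dX <- dY
        for (f in seq_len(d[5])) {
          dX[, , , , f] <- dX[, , , , f] * cache$mask[, f]
        }
        list(dX = dX, grads = NULL)
      }
    },
    gap = {
      d <- cache$d
      S <- prod(d[2:4])
      dX <- array(0, dim = d)
      for (f in seq_len(d[5])) {
        dX[, , , , f] <- array(rep(dY[, f] / S, S), dim = d[1:4])
      }
      list(dX = dX, grads = NULL)
    },
    flatten = {
      dX <- dY; dim(dX) <- cache$d
      list(dX = dX, grads = NULL)
    },
    dense = {
      dZ <- if (layer$activation == "elu") {
        elu_bwd(cache$Z, cache$Y, dY)
      } else {
        dY
      }
      list(dX = dZ %*% t(layer$W),
           grads = list(W = crossprod(cache$X, dZ), b = colSums(dZ)))
    },
    dense_block = {
      dStack <- dY
      grads <- vector("list", layer$n_layers)
      for (l in rev(seq_len(layer$n_layers))) {
        cc <- cache[[l]]
        cs <- cc$c_stack
        dIn <- dStack[, , , , seq_len(cs), drop = FALSE]
        dA <- dStack[, , , , cs + seq_len(layer$growth), drop = FALSE]
        dZ <- elu_bwd(cc$Z, cc$A, dA)
        d <- dim(dZ)
        dZm <- dZ; dim(dZm) <- c(prod(d[1:4]), d[5])
        grads[[l]] <- list(W = crossprod(cc$M, dZm), b = colSums(dZm))
        dM <- dZm %*% t(layer$convs[[l]]$W)
        dXp <- col2im3d(dM, cc$dimXp, layer$K)
        p <- (layer$K - 1L) %/% 2L
        d0 <- dim(dIn)
        dStack <- dIn + unpad3d(dXp, p, d0)
      }
      list(dX = dStack, grads = list(convs = grads))
    },
    stop("unknown layer type: ", layer$type))
}

nn_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], X, training)
    X <- fw$out
    caches[[i]] <- fw$cache
  }
  list(logits = X, caches = caches)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# returns loss and gradient wrt logits for integer labels (1..n_classes)
softmax_xent <- function(logits, labels) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  picked <- P[cbind(seq_len(n), labels)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dZ <- P
  dZ[cbind(seq_len(n), labels)] <- dZ[cbind(seq_len(n), labels)] - 1
  list(loss = loss, dlogits = dZ / n, probs = P)
}

nn_backward <- function(layers, caches, dlogits) {
  grads <- vector("list", length(layers))
  dY <- dlogits
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], caches[[i]], dY)
    grads[i] <- list(bw$grads)  # plain [[<-]] would drop NULL entries
    dY <- bw$dX
  }
  grads
}

# --- gradient utilities ------------------------------------------------------

grad_sq_sum <- function(grads) {
  total <- 0
  for (g in grads) {
    if (is.null(g)) next
    if (!is.null(g$W)) total <- total + sum(g$W^2) + sum(g$b^2)
    if (!is.null(g$convs)) {
      for (cv in g$convs) total <- total + sum(cv$W^2) + sum(cv$b^2)
    }
  }
  total
}

# global-norm gradient clipping; a standard guard for small-batch training
clip_gradients <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  norm <- sqrt(grad_sq_sum(grads))
  if (norm <= max_norm) return(grads)
  scale <- max_norm / norm
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (!is.null(g$W)) {
      grads[[i]]$W <- g$W * scale
      grads[[i]]$b <- g$b * scale
    }
    if (!is.null(g$convs)) {
      for (k in seq_along(g$convs)) {
        grads[[i]]$convs[[k]]$W <- g$convs[[k]]$W * scale
        grads[[i]]$convs[[k]]$b <- g$convs[[k]]$b * scale
      }
    }
  }
  grads
}

# --- Adam --------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (l$type %in% c("conv3d", "dense")) {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    } else if (l$type == "dense_block") {
      list(convs = lapply(l$convs, function(cv) {
        list(mW = cv$W * 0, vW = cv$W * 0, mb = cv$b * 0, vb = cv$b * 0)
      }))
    } else {
      NULL
    }
  })
}

adam_step_param <- function(theta, g, m, v, lr, t,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

adam_update <- function(layers, grads, state, lr, t) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]; g <- grads[[i]]; s <- state[[i]]
    if (is.null(g)) next
    if (l$type %in% c("conv3d", "dense")) {
      uw <- adam_step_param(l$W, g$W, s$mW, s$vW, lr, t)
      ub <- adam_step_param(l$b, g$b, s$mb, s$vb, lr, t)
      layers[[i]]$W <- uw$theta; state[[i]]$mW <- uw$m; state[[i]]$vW <- uw$v
      layers[[i]]$b <- ub$theta; state[[i]]$mb <- ub$m; state[[i]]$vb <- ub$v
    } else if (l$type == "dense_block") {
      for (k in seq_along(l$convs)) {
        uw <- adam_step_param(l$convs[[k]]$W, g$convs[[k]]$W,
                              s$convs[[k]]$mW, s$convs[[k]]$vW, lr, t)
        ub <- adam_step_param(l$convs[[k]]$b, g$convs[[k]]$b,
                              s$convs[[k]]$mb, s$convs[[k]]$vb, lr, t)
        layers[[i]]$convs[[k]]$W <- uw$theta
        layers[[i]]$convs[[k]]$b <- ub$theta
        state[[i]]$convs[[k]]$mW <- uw$m; state[[i]]$convs[[k]]$vW <- uw$v
        state[[i]]$convs[[k]]$mb <- ub$m; state[[i]]$convs[[k]]$vb <- ub$v
      }
    }
  }
  list(layers = layers, state = state)
}

n_parameters <- function(layers) {
  sum(vapply(layers, function(l) {
    if (l$type %in% c("conv3d", "dense")) {
      length(l$W) + length(l$b)
    } else if (l$type == "dense_block") {
      sum(vapply(l$convs, function(cv) length(cv$W) + length(cv$b),
                 numeric(1)))
    } else {
      0
    }
  }, numeric(1)))
}
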