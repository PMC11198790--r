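# Minimal CNN training backend.
#
# Images are flattened row-major-in-R-sense: the per-image feature vector
# indexes spatial position (column-major within the H x W plane) fastest,
# then channel. A batch is a B x (H*W*C) matrix. Convolutions are "valid"
# (no padding, stride 1) and implemented as an im2col gather followed by
# one BLAS matrix multiply; max-pooling uses non-overlapping windows of
# size p (trailing remainder rows/columns are dropped). All gradients are
# exact (standard backpropagation); the optimizer is SGD with momentum.

# Gather indices for valid convolution: P x (k*k*C) matrix, where row p
# enumerates the flattened input indices feeding output position p.
conv_indices <- function(h, w, c, k) {
  ho <- h - k + 1L; wo <- w - k + 1L
  oi <- rep(seq_len(ho), times = wo)
  oj <- rep(seq_len(wo), each = ho)
  pos0 <- oi + (oj - 1L) * h
  ki <- rep(seq_len(k), times = k)
  kj <- rep(seq_len(k), each = k)
  ko <- (ki - 1L) + (kj - 1L) * h
  sp <- outer(pos0, ko, `+`)              # P x k^2
  idx <- matrix(0L, nrow(sp), k * k * c)
  for (ch in seq_len(c)) {
    idx[, ((ch - 1L) * k * k + 1L):(ch * k * k)] <- sp + (ch - 1L) * h * w
  }
  idx
}

# Gather indices for p x p max pooling: (p^2) x (Pout*C) matrix, column u
# enumerating the inputs feeding output unit u.
pool_indices <- function(h, w, c, p) {
  ho <- h %/% p; wo <- w %/% p
  oi <- rep(seq_len(ho), times = wo)
  oj <- rep(seq_len(wo), each = ho)
  pos0 <- ((oi - 1L) * p + 1L) + ((oj - 1L) * p) * h   # Pout
  ri <- rep(seq_len(p), times = p)
  rj <- rep(seq_len(p), each = p)
  off <- (ri - 1L) + (rj - 1L) * h
  base <- t(outer(pos0, off, `+`))        # p^2 x Pout
  pidx <- matrix(0L, p * p, ho * wo * c)
  for (ch in seq_len(c)) {
    pidx[, ((ch - 1L) * ho * wo + 1L):(ch * ho * wo)] <- base + (ch - 1L) * h * w
  }
  pidx
}

# Layer plan: sequence of conv (with clipped kernel) and feasible pool
# ops, tracking spatial dimensions; spatial size never drops below 1.
cnn_plan <- function(n_conv, kernel, filters, pool, input_shape) {
  h <- input_shape[1L]; w <- input_shape[2L]
  c <- if (length(input_shape) >= 3L) input_shape[3L] else 1L
  ops <- list()
  for (l in seq_len(n_conv)) {
    k_eff <- min(kernel, h, w)
    ho <- h - k_eff + 1L; wo <- w - k_eff + 1L
    ops[[length(ops) + 1L]] <- list(
      type = "conv", h = h, w = w, c = c, k = k_eff,
      ho = ho, wo = wo, f = filters,
      idx = conv_indices(h, w, c, k_eff))
    h <- ho; w <- wo; c <- filters
    if (pool >= 2L && h >= pool && w >= pool) {
      ho <- h %/% pool; wo <- w %/% pool
      ops[[length(ops) + 1L]] <- list(
        type = "pool", h = h, w = w, c = c, p = pool,
        ho = ho, wo = wo,
        pidx = pool_indices(h, w, c, pool))
      h <- ho; w <- wo
    }
  }
  list(ops = ops, out_dim = h * w * c, out_shape = c(h, w, c))
}

# Forward flops per image (multiply+add counted as 2) of the conv stack
# plus the dense head; used by the desk-scale compute guard.
plan_flops <- function(plan, n_classes) {
  fl <- 0
  for (op in plan$ops) {
    if (op$type == "conv") {
      fl <- fl + 2 * op$ho * op$wo * op$k^2 * op$c * op$f
    }
  }
  fl + 2 * plan$out_dim * n_classes
}

# Trainable parameter count (conv weights/biases plus the dense head).
plan_params <- function(plan, n_classes) {
  pa <- 0
  for (op in plan$ops) {
    if (op$type == "conv") pa <- pa + (op$k^2 * op$c + 1) * op$f
  }
  pa + (plan$out_dim + 1) * n_classes
}

cnn_init <- function(plan, n_classes, dropout) {
  conv <- lapply(plan$ops[vapply(plan$ops, function(o) o$type == "conv",
                                 logical(1L))], function(op) {
    fan_in <- op$k^2 * op$c
    list(W = matrix(stats::rnorm(fan_in * op$f, 0, sqrt(2 / fan_in)),
                    fan_in, op$f),
         b = numeric(op$f))
  })
  list(plan = plan, conv = conv,
       dense = list(W = matrix(stats::rnorm(plan$out_dim * n_classes, 0,
                                            sqrt(2 / plan$out_dim)),
                               plan$out_dim, n_classes),
                    b = numeric(n_classes)),
       dropout = dropout, n_classes = n_classes)
}

cnn_forward <- function(model, X, train = FALSE) {
  B <- nrow(X)
  A <- X
  caches <- vector("list", length(model$plan$ops))
  ci <- 0L
  for (oi in seq_along(model$plan$ops)) {
    op <- model$plan$ops[[oi]]
    if (op$type == "conv") {
      ci <- ci + 1L
      P <- op$ho * op$wo
      Y <- A[, as.vector(op$idx), drop = FALSE]
      dim(Y) <- c(B * P, op$k^2 * op$c)
      Z <- Y %*% model$conv[[ci]]$W
      Z <- Z + rep(model$conv[[ci]]$b, each = B * P)
      mask <- Z > 0
      Z[!mask] <- 0
      dim(Z) <- c(B, P * op$f)
      caches[[oi]] <- if (train) list(Y = Y, mask = mask) else NULL
      A <- Z
    } else {
      U <- op$ho * op$wo * op$c
      p2 <- op$p^2
      G <- A[, as.vector(op$pidx), drop = FALSE]
      dim(G) <- c(B, p2, U)
      M <- G[, 1L, , drop = FALSE]; dim(M) <- c(B, U)
      amax <- matrix(1L, B, U)
      for (r in seq_len(p2)[-1L]) {
        g <- G[, r, , drop = FALSE]; dim(g) <- c(B, U)
        upd <- g > M
        M[upd] <- g[upd]
        amax[upd] <- r
      }
      caches[[oi]] <- if (train) list(amax = amax, in_dim = op$h * op$w * op$c) else NULL
      A <- M
    }
  }
  drop_mask <- NULL
  if (train && model$dropout > 0) {
    drop_mask <- matrix(stats::rbinom(B * ncol(A), 1L, 1 - model$dropout) /
                          (1 - model$dropout), B, ncol(A))
    A <- A * drop_mask
  }
  logits <- A %*% model$dense$W
  logits <- logits + rep(model$dense$b, each = B)
  zmax <- apply(logits, 1L, max)
  ez <- exp(logits - zmax)
  probs <- ez / rowSums(ez)
  list(probs = probs, flat = A, caches = caches, drop_mask = drop_mask)
}

# Returns the per-parameter gradients for a batch under softmax
# cross-entropy loss; y is an integer class vector (1-based).
cnn_backward <- function(model, X, y, fw) {
  B <- nrow(X)
  probs <- fw$probs
  dlogits <- probs
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  dlogits <- dlogits / B
  gdense <- list(W = crossprod(fw$flat, dlogits), b = colSums(dlogits))
  dA <- tcrossprod(dlogits, model$dense$W)
  if (!is.null(fw$drop_mask)) dA <- dA * fw$drop_mask
  gconv <- vector("list", length(model$conv))
  ci <- sum(vapply(model$plan$ops, function(o) o$type == "conv", logical(1L)))
  for (oi in rev(seq_along(model$plan$ops))) {
    op <- model$plan$ops[[oi]]
    cache <- fw$caches[[oi]]
    if (op$type == "pool") {
      dPrev <- matrix(0, B, cache$in_dim)
      for (r in seq_len(op$p^2)) {
        sel <- cache$amax == r
        if (any(sel)) {
          contrib <- dA * sel
          cols <- op$pidx[r, ]
          dPrev[, cols] <- dPrev[, cols] + contrib
        }
      }
      dA <- dPrev
    } else {
      P <- op$ho * op$wo
      dZ <- dA
      dim(dZ) <- c(B * P, op$f)
      dZ <- dZ * cache$mask
      gconv[[ci]] <- list(W = crossprod(cache$Y, dZ), b = colSums(dZ))
      if (oi > 1L) {  # no input gradient needed at the first layer
        dY <- tcrossprod(dZ, model$conv[[ci]]$W)
        dPrev <- matrix(0, B, op$h * op$w * op$c)
        for (q in seq_len(ncol(op$idx))) {
          cols <- op$idx[, q]
          dPrev[, cols] <- dPrev[, cols] + matrix(dY[, q], B, P)
        }
        dA <- dPrev
      }
      ci <- ci - 1L
    }
  }
  list(conv = gconv, dense = gdense)
}

# Train with mini-batch SGD + momentum, early stopping on validation
# loss. Returns the best-validation-loss weights, the per-epoch history
# and a divergence flag (non-finite loss ends training immediately).
cnn_fit <- function(model, X, y, Xval, yval, epochs, batch_size, lr,
                    momentum, patience) {
  n <- nrow(X)
  batch_size <- max(1L, min(batch_size, n))
  vel <- list(conv = lapply(model$conv, function(l)
    list(W = l$W * 0, b = l$b * 0)),
    dense = list(W = model$dense$W * 0, b = model$dense$b * 0))
  best_loss <- Inf
  best <- list(conv = model$conv, dense = model$dense)
  wait <- 0L
  history <- data.frame(epoch = integer(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  diverged <- FALSE
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      bi <- perm[start:min(start + batch_size - 1L, n)]
      Xb <- X[bi, , drop = FALSE]
      fw <- cnn_forward(model, Xb, train = TRUE)
      if (any(!is.finite(fw$probs))) { diverged <- TRUE; break }
      gr <- cnn_backward(model, Xb, y[bi], fw)
      for (l in seq_along(model$conv)) {
        vel$conv[[l]]$W <- momentum * vel$conv[[l]]$W - lr * gr$conv[[l]]$W
        vel$conv[[l]]$b <- momentum * vel$conv[[l]]$b - lr * gr$conv[[l]]$b
        model$conv[[l]]$W <- model$conv[[l]]$W + vel$conv[[l]]$W
        model$conv[[l]]$b <- model$conv[[l]]$b + vel$conv[[l]]$b
      }
      vel$dense$W <- momentum * vel$dense$W - lr * gr$dense$W
      vel$dense$b <- momentum * vel$dense$b - lr * gr$dense$b
      model$dense$W <- model$dense$W + vel$dense$W
      model$dense$b <- model$dense$b + vel$dense$b
    }
    if (diverged) break
    vfw <- cnn_forward(model, Xval, train = FALSE)
    p <- vfw$probs[cbind(seq_len(nrow(Xval)), yval)]
    vloss <- -mean(log(pmax(p, 1e-12)))
    vacc <- mean(max.col(vfw$probs, ties.method = "first") == yval)
    if (!is.finite(vloss)) { diverged <- TRUE; break }
    history <- rbind(history, data.frame(epoch = ep, val_loss = vloss,
                                         val_acc = vacc))
    if (vloss < best_loss - 1e-8) {
      best_loss <- vloss
      best <- list(conv = model$conv, dense = model$dense)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  model$conv <- best$conv
  model$dense <- best$dense
  list(model = model, history = history, diverged = diverged,
       best_val_loss = best_loss)
}

cnn_predict <- function(model, X) {
  max.col(cnn_forward(model, X, train = FALSE)$probs, ties.method = "first")
}
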