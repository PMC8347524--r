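# Dual-head policy/value network.
#
# Three shared 3x3 "same"-padded convolutional layers (ReLU) over the
# 18 x L x L state encoding, followed by two heads: the policy head (1x1
# conv to one channel, flattened to L^2, softmax) and the value head
# (per-channel global average pooling, dense to a scalar, softplus so the
# output is strictly positive — it predicts the state's error from the
# native structure). Both heads are length-independent, so one parameter
# set serves any L.
#
# Convolutions are computed as im2col gathers followed by BLAS matrix
# multiplies; states are handled cell-major as L^2 x C matrices (cell
# k = i + (j-1)L). Training uses Adam on the summed value (squared error)
# and policy (cross-entropy) losses.

DEFAULT_CHANNELS <- c(32L, 64L, 128L)

.im2col_cache <- new.env(parent = emptyenv())

# neighbour index table for a 3x3 kernel on an L x L grid, cell-major.
# Entry (k, o) is the cell index of offset o (9 offsets, (di, dj) column-major
# over -1..1) relative to cell k, or L^2 + 1 for out-of-grid (zero padding).
im2col_index <- function(L) {
  key <- as.character(L)
  cached <- .im2col_cache[[key]]
  if (!is.null(cached)) return(cached)
  n <- L * L
  cell <- seq_len(n)
  i <- ((cell - 1L) %% L) + 1L
  j <- ((cell - 1L) %/% L) + 1L
  idx <- matrix(n + 1L, n, 9L)
  o <- 0L
  for (dj in -1:1) {
    for (di in -1:1) {
      o <- o + 1L
      ii <- i + di; jj <- j + dj
      ok <- ii >= 1L & ii <= L & jj >= 1L & jj <= L
      idx[ok, o] <- ii[ok] + (jj[ok] - 1L) * L
    }
  }
  .im2col_cache[[key]] <- idx
  idx
}

# gather: X is (B*n) x C with per-sample blocks of n rows; returns (B*n) x 9C
im2col_gather <- function(X, L, B) {
  n <- L * L
  C <- ncol(X)
  idx <- im2col_index(L)
  if (B > 1L) {
    offs <- rep((seq_len(B) - 1L) * n, each = n)
    pad <- B * n + 1L
    idx_b <- matrix(pad, B * n, 9L)
    for (o in 1:9) {
      v <- rep(idx[, o], times = B)
      inb <- v <= n
      w <- v + offs
      w[!inb] <- pad
      idx_b[, o] <- w
    }
    idx <- idx_b
  }
  Xp <- rbind(X, 0)
  out <- matrix(0, nrow(X), 9L * C)
  for (o in 1:9) out[, ((o - 1L) * C + 1L):(o * C)] <- Xp[idx[, o], , drop = FALSE]
  list(col = out, idx = idx)
}

# scatter-add the column-space gradient back onto the input grid
col2im_scatter <- function(dcol, idx, nrow_x, C) {
  dX <- matrix(0, nrow_x, C)
  for (o in 1:9) {
    v <- idx[, o]
    sel <- v <= nrow_x
    block <- dcol[sel, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
    dX[v[sel], ] <- dX[v[sel], ] + block
  }
  dX
}

#' Create a policy/value network
#'
#' @param channels Integer vector of the three shared convolution widths.
#' @param lr Adam learning rate.
#' @param seed Optional seed for weight initialization.
#' @return Object of class `pv_network` (parameters plus optimizer state).
#' @export
policy_value_network <- function(channels = DEFAULT_CHANNELS, lr = 0.001,
                                 seed = NULL) {
  stopifnot(length(channels) == 3L, all(channels >= 1L))
  if (!is.null(seed)) set.seed(seed)
  he <- function(fan_in, nout) {
    matrix(stats::rnorm(fan_in * nout, sd = sqrt(2 / fan_in)), fan_in, nout)
  }
  cin <- c(18L, channels[1:2])
  params <- list(
    W1 = he(9L * cin[1], channels[1]), b1 = rep(0, channels[1]),
    W2 = he(9L * cin[2], channels[2]), b2 = rep(0, channels[2]),
    W3 = he(9L * cin[3], channels[3]), b3 = rep(0, channels[3]),
    wp = he(channels[3], 1L), bp = 0,
    wv = he(channels[3], 1L), bv = 0.5)
  opt <- list(m = lapply(params, function(p) p * 0),
              v = lapply(params, function(p) p * 0),
              t = 0L)
  structure(list(params = params, opt = opt, channels = as.integer(channels),
                 lr = lr), class = "pv_network")
}

#' @export
print.pv_network <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("Policy/value network: conv channels %s, %d parameters, lr %g\n",
              paste(x$channels, collapse = "/"), np, x$lr))
  invisible(x)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
relu <- function(x) (x > 0) * x

# normalize the many accepted input forms to a (B*n) x 18 matrix
as_state_matrix <- function(x) {
  if (inherits(x, "folding_state")) return(encode_state_matrix(x))
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    if (d[1] != 18L || d[2] != d[3]) stop("state tensor must have shape 18 x L x L")
    return(matrix(aperm(x, c(2L, 3L, 1L)), d[2] * d[3], 18L))
  }
  if (is.matrix(x) && ncol(x) == 18L) return(x)
  stop("cannot interpret input as an 18-channel state encoding")
}

# full forward pass with caches (for backprop); X is (B*n) x 18
net_forward_raw <- function(net, X, L, B) {
  p <- net$params
  n <- L * L
  g1 <- im2col_gather(X, L, B)
  z1 <- sweep(g1$col %*% p$W1, 2L, p$b1, "+"); h1 <- relu(z1)
  g2 <- im2col_gather(h1, L, B)
  z2 <- sweep(g2$col %*% p$W2, 2L, p$b2, "+"); h2 <- relu(z2)
  g3 <- im2col_gather(h2, L, B)
  z3 <- sweep(g3$col %*% p$W3, 2L, p$b3, "+"); h3 <- relu(z3)
  # policy head: per-sample softmax over the n cells
  logit <- as.vector(h3 %*% p$wp + p$bp)
  lm <- matrix(logit, n, B)
  lm <- sweep(lm, 2L, apply(lm, 2L, max), "-")
  em <- exp(lm)
  policy <- sweep(em, 2L, colSums(em), "/")          # n x B
  # value head: per-channel global average -> dense -> softplus
  vpool <- rowsum(h3, rep(seq_len(B), each = n), reorder = FALSE) / n  # B x C3
  vpre <- as.vector(vpool %*% p$wv) + p$bv
  value <- softplus(vpre)
  list(policy = policy, value = value, caches = list(
    X = X, g1 = g1, z1 = z1, h1 = h1, g2 = g2, z2 = z2, h2 = h2,
    g3 = g3, z3 = z3, h3 = h3, vpool = vpool, vpre = vpre, L = L, B = B))
}

#' Evaluate the network
#'
#' @param net A [policy_value_network()].
#' @param x A `folding_state`, an `18 x L x L` array from [encode_state()],
#'   a cell-major `L^2 x 18` matrix, or a list of these (a batch; all must
#'   share one L).
#' @return List with `policy` (length-`L^2` probability vector, or `B x L^2`
#'   matrix for a batch; cell `k` is pair `(i, j)` with
#'   `k = i + (j-1)L`) and `value` (positive scalar or length-B vector).
#' @export
net_forward <- function(net, x) {
  stopifnot(inherits(net, "pv_network"))
  single <- !is.list(x) || inherits(x, "folding_state")
  xs <- if (single) list(x) else x
  mats <- lapply(xs, as_state_matrix)
  ns <- vapply(mats, nrow, 1L)
  if (length(unique(ns)) != 1L) stop("all states in a batch must share one L")
  L <- as.integer(sqrt(ns[1]))
  out <- net_forward_raw(net, do.call(rbind, mats), L, length(mats))
  if (single) {
    list(policy = as.vector(out$policy[, 1]), value = out$value[1])
  } else {
    list(policy = t(out$policy), value = out$value)
  }
}

#' Mask a raw policy to the action space and renormalize
#'
#' Keeps only the probabilities of currently legal pairs and rescales them to
#' sum to one; if every legal entry is zero the result is uniform over the
#' legal pairs.
#'
#' @param policy Numeric vector of length `L^2` (cell-major) or an `L x L`
#'   matrix.
#' @param space An `action_space`.
#' @param L Sequence length.
#' @return Named numeric vector, one probability per legal pair (names
#'   `"i-j"`), summing to 1.
#' @export
mask_and_normalize <- function(policy, space, L) {
  if (is.matrix(policy)) policy <- as.vector(policy)
  stopifnot(length(policy) == L * L)
  p <- space$legal
  if (nrow(p) == 0L) stop("cannot normalize a policy over an empty action space")
  vals <- policy[p[, 1] + (p[, 2] - 1L) * L]
  s <- sum(vals)
  out <- if (s <= 0) rep(1 / length(vals), length(vals)) else vals / s
  names(out) <- pair_keys(p)
  out
}

# ---- losses and training ----------------------------------------------

# batch: list of samples, each list(x, target_policy (length n), target_value)
batch_tensors <- function(batch) {
  mats <- lapply(batch, function(s) as_state_matrix(s$x))
  ns <- vapply(mats, nrow, 1L)
  if (length(unique(ns)) != 1L) stop("all samples in a batch must share one L")
  n <- ns[1]
  list(X = do.call(rbind, mats), L = as.integer(sqrt(n)), B = length(batch),
       TP = vapply(batch, function(s) as.numeric(s$target_policy), numeric(n)),
       tv = vapply(batch, function(s) s$target_value, numeric(1)))
}

#' Training losses on a batch
#'
#' The value head is scored by mean squared error against the target value
#' (the final episode error r), the policy head by cross-entropy against the
#' search-corrected policy; the total is their sum.
#'
#' @param net A [policy_value_network()].
#' @param batch List of samples, each a list with `x` (state encoding),
#'   `target_policy` (length `L^2`, sums to 1) and `target_value` (>= 0).
#' @return List `value_loss`, `policy_loss`, `total`.
#' @export
net_loss <- function(net, batch) {
  bt <- batch_tensors(batch)
  if (any(!is.finite(bt$TP)) || any(!is.finite(bt$tv))) stop("NaN in training targets")
  out <- net_forward_raw(net, bt$X, bt$L, bt$B)
  loss_from(out, bt)
}

loss_from <- function(out, bt) {
  value_loss <- mean((out$value - bt$tv)^2)
  pl <- pmax(out$policy, 1e-12)                       # n x B
  policy_loss <- mean(colSums(-bt$TP * log(pl)))
  list(value_loss = value_loss, policy_loss = policy_loss,
       total = value_loss + policy_loss)
}

#' One optimizer step on a batch
#'
#' Computes gradients of the summed loss by backpropagation and applies one
#' Adam update.
#'
#' @inheritParams net_loss
#' @return The updated network, with the pre-update losses attached as
#'   attribute `"loss"`.
#' @export
net_train_step <- function(net, batch) {
  bt <- batch_tensors(batch)
  out <- net_forward_raw(net, bt$X, bt$L, bt$B)
  loss <- loss_from(out, bt)
  cc <- out$caches
  p <- net$params
  n <- bt$L^2; B <- bt$B
  # value head gradient
  dvalue <- 2 * (out$value - bt$tv) / B               # length B
  dvpre <- dvalue * stats::plogis(cc$vpre)            # softplus'
  dwv <- crossprod(cc$vpool, dvpre); dbv <- sum(dvpre)
  dvpool <- tcrossprod(dvpre, p$wv)                   # B x C3
  # policy head gradient (softmax + CE): dlogit = (p - t) / B
  dlogit <- as.vector((out$policy - bt$TP) / B)
  dwp <- crossprod(cc$h3, dlogit); dbp <- sum(dlogit)
  # into the trunk (pooled value gradient spreads evenly over the n cells)
  dh3 <- dvpool[rep(seq_len(B), each = n), , drop = FALSE] / n +
    tcrossprod(dlogit, p$wp)
  dz3 <- dh3 * (cc$z3 > 0)
  dW3 <- crossprod(cc$g3$col, dz3); db3 <- colSums(dz3)
  dh2 <- col2im_scatter(tcrossprod(dz3, p$W3), cc$g3$idx, nrow(cc$h2), ncol(cc$h2))
  dz2 <- dh2 * (cc$z2 > 0)
  dW2 <- crossprod(cc$g2$col, dz2); db2 <- colSums(dz2)
  dh1 <- col2im_scatter(tcrossprod(dz2, p$W2), cc$g2$idx, nrow(cc$h1), ncol(cc$h1))
  dz1 <- dh1 * (cc$z1 > 0)
  dW1 <- crossprod(cc$g1$col, dz1); db1 <- colSums(dz1)
  grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3,
                wp = dwp, bp = dbp, wv = dwv, bv = dbv)
  net <- adam_update(net, grads)
  attr(net, "loss") <- loss
  net
}

adam_update <- function(net, grads, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  net$opt$t <- net$opt$t + 1L
  t <- net$opt$t
  lr <- net$lr
  for (nm in names(net$params)) {
    gr <- grads[[nm]]
    net$opt$m[[nm]] <- beta1 * net$opt$m[[nm]] + (1 - beta1) * gr
    net$opt$v[[nm]] <- beta2 * net$opt$v[[nm]] + (1 - beta2) * gr^2
    mhat <- net$opt$m[[nm]] / (1 - beta1^t)
    vhat <- net$opt$v[[nm]] / (1 - beta2^t)
    net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  net
}

#' Save / load a network checkpoint
#'
#' Checkpoints hold the parameters, optimizer state, architecture and the
#' current RNG state, so training can resume reproducibly.
#'
#' @param net A [policy_value_network()].
#' @param path Checkpoint file path.
#' @export
net_save <- function(net, path) {
  rng <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  saveRDS(list(net = net, rng_state = rng), path)
  invisible(path)
}

#' @rdname net_save
#' @param restore_rng Restore the saved RNG state (default FALSE).
#' @export
net_load <- function(path, restore_rng = FALSE) {
  ck <- readRDS(path)
  if (restore_rng && !is.null(ck$rng_state)) {
    assign(".Random.seed", ck$rng_state, envir = globalenv())
  }
  ck$net
}
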