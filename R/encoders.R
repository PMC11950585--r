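# Compact dense-network machinery used by the learned feature extractors.
# One hidden layer (tanh) feeding a linear or sigmoid output, trained by
# minibatch SGD with momentum. Sized for small grayscale images on CPU; the
# monitoring framework is encoder-agnostic, so these stand in for whatever
# production feature extractor a deployment uses.

dense2_init <- function(n_in, n_hidden, n_out) {
  list(
    W1 = matrix(rnorm(n_in * n_hidden, sd = 1 / sqrt(n_in)), n_in, n_hidden),
    b1 = rep(0, n_hidden),
    W2 = matrix(rnorm(n_hidden * n_out, sd = 1 / sqrt(n_hidden)),
                n_hidden, n_out),
    b2 = rep(0, n_out)
  )
}

dense2_forward <- function(net, X, out_act = c("linear", "sigmoid")) {
  out_act <- match.arg(out_act)
  H <- tanh(sweep(X %*% net$W1, 2L, net$b1, `+`))
  Z <- sweep(H %*% net$W2, 2L, net$b2, `+`)
  out <- if (out_act == "sigmoid") 1 / (1 + exp(-Z)) else Z
  list(H = H, Z = Z, out = out)
}

# dPre: gradient of the loss wrt the pre-activation output Z.
dense2_grad <- function(net, X, fwd, dPre) {
  gW2 <- crossprod(fwd$H, dPre)
  gb2 <- colSums(dPre)
  dH <- dPre %*% t(net$W2)
  dA <- dH * (1 - fwd$H^2)
  list(W1 = crossprod(X, dA), b1 = colSums(dA), W2 = gW2, b2 = gb2)
}

sgd_momentum_step <- function(net, vel, grad, lr, momentum = 0.9) {
  for (nm in names(grad)) {
    vel[[nm]] <- momentum * vel[[nm]] - lr * grad[[nm]]
    net[[nm]] <- net[[nm]] + vel[[nm]]
  }
  list(net = net, vel = vel)
}

zero_like <- function(net) lapply(net, function(w) w * 0)

train_autoencoder <- function(X, latent_dim, epochs, lr, batch_size = 32L) {
  n <- nrow(X)
  net <- dense2_init(ncol(X), latent_dim, ncol(X))
  vel <- zero_like(net)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      fwd <- dense2_forward(net, Xb, "sigmoid")
      err <- fwd$out - Xb
      ep_loss <- ep_loss + sum(err^2)
      dPre <- 2 * err * fwd$out * (1 - fwd$out) / length(err)
      g <- dense2_grad(net, Xb, fwd, dPre)
      upd <- sgd_momentum_step(net, vel, g, lr)
      net <- upd$net
      vel <- upd$vel
    }
    losses[ep] <- ep_loss / (n * ncol(X))
  }
  list(net = net, loss_trace = losses, out_act = "sigmoid")
}

train_bce <- function(X, y, latent_dim, epochs, lr, batch_size = 32L) {
  n <- nrow(X)
  net <- dense2_init(ncol(X), latent_dim, 1L)
  vel <- zero_like(net)
  losses <- numeric(epochs)
  eps <- 1e-12
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      fwd <- dense2_forward(net, Xb, "sigmoid")
      p <- pmin(pmax(fwd$out[, 1L], eps), 1 - eps)
      ep_loss <- ep_loss - sum(yb * log(p) + (1 - yb) * log(1 - p))
      dPre <- matrix((fwd$out[, 1L] - yb) / length(yb), ncol = 1L)
      g <- dense2_grad(net, Xb, fwd, dPre)
      upd <- sgd_momentum_step(net, vel, g, lr)
      net <- upd$net
      vel <- upd$vel
    }
    losses[ep] <- ep_loss / n
  }
  list(net = net, loss_trace = losses, out_act = "sigmoid")
}

# Pairwise margin ("contrastive") objective: same-label pairs are pulled
# together (loss d^2/2), different-label pairs pushed beyond `margin`
# (loss max(0, margin - d)^2 / 2) in the embedding space.
train_contrastive <- function(X, y, latent_dim, epochs, lr,
                              pairs_per_epoch = NULL, margin = 2,
                              batch_size = 64L) {
  n <- nrow(X)
  pairs_per_epoch <- pairs_per_epoch %||% (4L * n)
  net <- dense2_init(ncol(X), latent_dim, latent_dim)
  vel <- zero_like(net)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    i <- sample.int(n, pairs_per_epoch, replace = TRUE)
    j <- sample.int(n, pairs_per_epoch, replace = TRUE)
    same <- as.numeric(y[i] == y[j])
    ep_loss <- 0
    for (start in seq(1L, pairs_per_epoch, by = batch_size)) {
      sel <- start:min(start + batch_size - 1L, pairs_per_epoch)
      A <- X[i[sel], , drop = FALSE]
      B <- X[j[sel], , drop = FALSE]
      s <- same[sel]
      fa <- dense2_forward(net, A, "linear")
      fb <- dense2_forward(net, B, "linear")
      diff <- fa$out - fb$out
      d <- sqrt(rowSums(diff^2)) + 1e-12
      slack <- pmax(0, margin - d)
      ep_loss <- ep_loss + sum(s * d^2 / 2 + (1 - s) * slack^2 / 2)
      # dL/dzA per pair; dL/dzB is its negative.
      coef <- s - (1 - s) * slack / d
      dA <- diff * coef / length(sel)
      ga <- dense2_grad(net, A, fa, dA)
      gb <- dense2_grad(net, B, fb, -dA)
      g <- purrr::map2(ga, gb, `+`)
      upd <- sgd_momentum_step(net, vel, g, lr)
      net <- upd$net
      vel <- upd$vel
    }
    losses[ep] <- ep_loss / pairs_per_epoch
  }
  list(net = net, loss_trace = losses, out_act = "linear")
}
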