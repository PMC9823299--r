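# Minimal dense-network machinery: tanh MLPs with explicit backpropagation,
# Adam updates, masked MSE loss.  Everything operates on row-major sample
# matrices and is deterministic given the seed.

mlp_init <- function(sizes, seed = NULL) {
  build <- function() {
    layers <- vector("list", length(sizes) - 1L)
    for (l in seq_along(layers)) {
      fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
      sd <- sqrt(2 / (fan_in + fan_out))          # Glorot
      layers[[l]] <- list(
        w = matrix(stats::rnorm(fan_in * fan_out, 0, sd), fan_in, fan_out),
        b = numeric(fan_out))
    }
    layers
  }
  if (is.null(seed)) build() else local_seed(seed, build())
}

# forward pass; tanh on all layers except the last (linear output)
mlp_forward <- function(layers, x, keep = FALSE) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1]] <- x
  nl <- length(layers)
  for (l in seq_len(nl)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$w, 2, layers[[l]]$b, "+")
    acts[[l + 1L]] <- if (l < nl) tanh(z) else z
  }
  if (keep) acts else acts[[nl + 1L]]
}

# gradients for dL/d(output); returns list(grads, dx)
mlp_backward <- function(layers, acts, dout) {
  nl <- length(layers)
  grads <- vector("list", nl)
  delta <- dout
  for (l in rev(seq_len(nl))) {
    if (l < nl) delta <- delta * (1 - acts[[l + 1L]]^2)   # tanh'
    grads[[l]] <- list(w = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1L) delta <- delta %*% t(layers[[l]]$w)
  }
  list(grads = grads, dx = delta %*% t(layers[[1]]$w))
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mw = l$w * 0, vw = l$w * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    s <- state[[l]]; g <- grads[[l]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$w
    s$vw <- beta2 * s$vw + (1 - beta2) * g$w^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    layers[[l]]$w <- layers[[l]]$w - lr * (s$mw / c1) / (sqrt(s$vw / c2) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

# Generic masked-MSE autoencoder trainer shared by the graph-conditioned and
# naive models.  `cond` (optional) is concatenated to the latent code before
# decoding; `mask` zeroes padded entries out of the loss.  Learning rate
# halves when validation loss fails to improve for lr_patience epochs;
# training stops when lr < lr_floor, after early_stop non-improving epochs,
# or at max_epochs.  Returns the parameters at the best validation loss.
ae_fit <- function(x, cond = NULL, mask = NULL, enc_sizes, dec_sizes,
                   noise_percent = 0.05, lr = 1e-3, lr_patience = 10L,
                   lr_floor = 1e-8, early_stop = 30L, max_epochs = 200L,
                   batch_size = 1024L, val_fraction = 0.1, seed = 1L,
                   verbose = FALSE) {
  local_seed(seed, {
    n <- nrow(x)
    n_val <- max(1L, round(val_fraction * n))
    idx <- sample.int(n)
    val_i <- idx[seq_len(n_val)]; tr_i <- idx[-seq_len(n_val)]
    enc <- mlp_init(enc_sizes)
    dec <- mlp_init(dec_sizes)
    st_e <- adam_init(enc); st_d <- adam_init(dec)
    if (is.null(mask)) mask <- matrix(1, 1, ncol(x))
    msk <- function(i) if (nrow(mask) == 1L)
      mask[rep(1L, length(i)), , drop = FALSE] else mask[i, , drop = FALSE]
    recon <- function(i, noisy = FALSE) {
      z <- mlp_forward(enc, x[i, , drop = FALSE])
      if (noisy && noise_percent > 0)
        z <- z * (1 + noise_percent * stats::rnorm(length(z)))
      d_in <- if (is.null(cond)) z else cbind(cond[i, , drop = FALSE], z)
      mlp_forward(dec, d_in)
    }
    loss_of <- function(i) {
      r <- recon(i); m <- msk(i)
      sum(((r - x[i, , drop = FALSE]) * m)^2) / sum(m)
    }
    best <- list(enc = enc, dec = dec, val = Inf, epoch = 0L)
    log <- data.frame(epoch = integer(0), train = numeric(0),
                      val = numeric(0), lr = numeric(0))
    t_adam <- 0L
    since_best <- 0L; since_lr <- 0L
    for (epoch in seq_len(max_epochs)) {
      perm <- sample(tr_i)
      tr_loss <- 0; nb <- 0L
      for (start in seq(1L, length(perm), by = batch_size)) {
        i <- perm[start:min(start + batch_size - 1L, length(perm))]
        xb <- x[i, , drop = FALSE]
        a_e <- mlp_forward(enc, xb, keep = TRUE)
        z <- a_e[[length(a_e)]]
        if (noise_percent > 0) {
          eps_z <- 1 + noise_percent * stats::rnorm(length(z))
          zn <- z * eps_z
        } else zn <- z
        d_in <- if (is.null(cond)) zn else cbind(cond[i, , drop = FALSE], zn)
        a_d <- mlp_forward(dec, d_in, keep = TRUE)
        out <- a_d[[length(a_d)]]
        m <- msk(i)
        resid <- (out - xb) * m
        loss <- sum(resid^2) / sum(m)
        if (!is.finite(loss)) stop("training diverged (non-finite loss)")
        tr_loss <- tr_loss + loss; nb <- nb + 1L
        dout <- 2 * resid * m / sum(m)
        bw_d <- mlp_backward(dec, a_d, dout)
        dz <- bw_d$dx
        if (!is.null(cond)) dz <- dz[, -seq_len(ncol(cond)), drop = FALSE]
        if (noise_percent > 0) dz <- dz * eps_z
        bw_e <- mlp_backward(enc, a_e, dz)
        t_adam <- t_adam + 1L
        up <- adam_step(dec, bw_d$grads, st_d, lr, t_adam)
        dec <- up$layers; st_d <- up$state
        up <- adam_step(enc, bw_e$grads, st_e, lr, t_adam)
        enc <- up$layers; st_e <- up$state
      }
      val_loss <- loss_of(val_i)
      log <- rbind(log, data.frame(epoch = epoch, train = tr_loss / nb,
                                   val = val_loss, lr = lr))
      if (verbose)
        message(sprintf("epoch %3d  train %.3e  val %.3e  lr %.1e",
                        epoch, tr_loss / nb, val_loss, lr))
      if (val_loss < best$val - 1e-12) {
        best <- list(enc = enc, dec = dec, val = val_loss, epoch = epoch)
        since_best <- 0L; since_lr <- 0L
      } else {
        since_best <- since_best + 1L; since_lr <- since_lr + 1L
      }
      if (since_lr >= lr_patience) { lr <- lr / 2; since_lr <- 0L }
      if (lr < lr_floor || since_best >= early_stop) break
    }
    list(enc = best$enc, dec = best$dec, val_loss = best$val,
         best_epoch = best$epoch, log = log, val_idx = val_i,
         train_idx = tr_i)
  })
}
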