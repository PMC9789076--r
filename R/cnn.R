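# Small 2D encoder-decoder used by the "cnn" segmenter: two 3x3 conv
# layers, a 2x2 max-pool bottleneck with one 3x3 conv, nearest-neighbor
# upsampling, a skip concatenation, one 3x3 fusion conv and a 1x1
# classification head (3 classes). ~4k parameters with the default 8
# channels; trains on CPU in minutes. Convolution kernels live in src/.

cnn_init <- function(channels = 8L) {
  he <- function(k, cin, cout)
    matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
           k * k * cin, cout)
  C <- as.integer(channels)
  list(W1 = he(3, 1, C),      b1 = numeric(C),      k1 = 3L,
       W2 = he(3, C, C),      b2 = numeric(C),      k2 = 3L,
       W3 = he(3, C, 2 * C),  b3 = numeric(2 * C),  k3 = 3L,
       W4 = he(3, 3 * C, C),  b4 = numeric(C),      k4 = 3L,
       W5 = he(1, C, 3),      b5 = numeric(3),      k5 = 1L)
}

relu <- function(x) { x[x < 0] <- 0; x }

upsample2 <- function(x, H, W) {
  # nearest-neighbor 2x upsampling, cropped to (H, W)
  y <- x[rep(seq_len(dim(x)[1]), each = 2), rep(seq_len(dim(x)[2]), each = 2),
         , drop = FALSE]
  y[seq_len(H), seq_len(W), , drop = FALSE]
}

downsample2_sum_grad <- function(dy, Hp, Wp) {
  # adjoint of upsample2: sum gradients over each 2x2 replication block
  H <- dim(dy)[1]; W <- dim(dy)[2]; C <- dim(dy)[3]
  out <- array(0, dim = c(Hp, Wp, C))
  io <- (seq_len(H) + 1L) %/% 2L
  jo <- (seq_len(W) + 1L) %/% 2L
  for (c in seq_len(C)) {
    m <- rowsum(dy[, , c], io, reorder = TRUE)
    out[, , c] <- t(rowsum(t(m), jo, reorder = TRUE))
  }
  out
}

cnn_forward <- function(x, par) {
  H <- dim(x)[1]; W <- dim(x)[2]
  if (length(dim(x)) == 2L) dim(x) <- c(H, W, 1L)
  z1 <- conv2d_forward(x, par$W1, par$b1, par$k1);  h1 <- relu(z1)
  z2 <- conv2d_forward(h1, par$W2, par$b2, par$k2); h2 <- relu(z2)
  mp <- maxpool2_forward(h2)
  z3 <- conv2d_forward(mp$y, par$W3, par$b3, par$k3); h3 <- relu(z3)
  up <- upsample2(h3, H, W)
  cat24 <- array(c(h2, up), dim = c(H, W, dim(h2)[3] + dim(up)[3]))
  z4 <- conv2d_forward(cat24, par$W4, par$b4, par$k4); h4 <- relu(z4)
  logits <- conv2d_forward(h4, par$W5, par$b5, par$k5)
  list(logits = logits,
       cache = list(x = x, z1 = z1, h1 = h1, z2 = z2, h2 = h2, mp = mp,
                    z3 = z3, h3 = h3, cat24 = cat24, z4 = z4, h4 = h4,
                    H = H, W = W))
}

cnn_backward <- function(cache, dlogits, par) {
  H <- cache$H; W <- cache$W
  g5 <- conv2d_backward(cache$h4, par$W5, dlogits, par$k5)
  dh4 <- g5$dx * (cache$z4 > 0)
  g4 <- conv2d_backward(cache$cat24, par$W4, dh4, par$k4)
  C <- dim(cache$h2)[3]
  dh2_cat <- g4$dx[, , seq_len(C), drop = FALSE]
  dup <- g4$dx[, , C + seq_len(dim(cache$h3)[3]), drop = FALSE]
  dh3 <- downsample2_sum_grad(dup, dim(cache$h3)[1], dim(cache$h3)[2]) *
    (cache$z3 > 0)
  g3 <- conv2d_backward(cache$mp$y, par$W3, dh3, par$k3)
  dpool <- maxpool2_backward(cache$mp$idx, g3$dx, H, W)
  dh2 <- (dh2_cat + dpool) * (cache$z2 > 0)
  g2 <- conv2d_backward(cache$h1, par$W2, dh2, par$k2)
  dh1 <- g2$dx * (cache$z1 > 0)
  g1 <- conv2d_backward(cache$x, par$W1, dh1, par$k1)
  list(W1 = g1$dw, b1 = g1$db, W2 = g2$dw, b2 = g2$db,
       W3 = g3$dw, b3 = g3$db, W4 = g4$dw, b4 = g4$db,
       W5 = g5$dw, b5 = g5$db)
}

# weighted pixelwise softmax cross-entropy; labels are codes 0..2
cnn_loss_grad <- function(logits, labels, class_weights) {
  H <- dim(logits)[1]; W <- dim(logits)[2]
  lm <- matrix(logits, H * W, 3)
  lm <- lm - apply(lm, 1, max)
  p <- exp(lm); p <- p / rowSums(p)
  y <- as.vector(labels) + 1L
  wpx <- class_weights[y]
  wsum <- sum(wpx)
  nll <- -log(pmax(p[cbind(seq_along(y), y)], 1e-12))
  dp <- p
  dp[cbind(seq_along(y), y)] <- dp[cbind(seq_along(y), y)] - 1
  dp <- dp * (wpx / wsum)
  list(loss = sum(wpx * nll) / wsum,
       dlogits = array(dp, dim = c(H, W, 3)))
}

cnn_param_names <- function() c("W1", "b1", "W2", "b2", "W3", "b3",
                                "W4", "b4", "W5", "b5")

adam_init <- function(par) {
  nm <- cnn_param_names()
  list(m = lapply(par[nm], function(p) p * 0),
       v = lapply(par[nm], function(p) p * 0), t = 0)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in cnn_param_names()) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(par = par, state = state)
}
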