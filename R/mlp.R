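# Small fully-connected binary classifier used for the "mlp" algorithm:
# two sigmoid hidden layers (default 256 nodes each), sigmoid output,
# cross-entropy loss, Adam optimization (learning rate 0.001), inverted
# dropout with keep-probability 0.7 on the hidden activations during
# training (1.0 at inference). Inputs are standardized with training-set
# statistics.

sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_train <- function(x, y, hidden = c(256, 256), epochs = 200,
                      learning_rate = 1e-3, keep_prob = 0.7,
                      batch_size = 128, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sd, "/")
  n <- nrow(xs)
  sizes <- c(ncol(xs), hidden, 1L)
  nl <- length(sizes) - 1L

  with_seed(seed, {
    w <- vector("list", nl)
    b <- vector("list", nl)
    mw <- vector("list", nl)
    vw <- vector("list", nl)
    mb <- vector("list", nl)
    vb <- vector("list", nl)
    for (l in seq_len(nl)) {
      # Glorot-style init
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      w[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
      mw[[l]] <- matrix(0, sizes[l], sizes[l + 1])
      vw[[l]] <- matrix(0, sizes[l], sizes[l + 1])
      mb[[l]] <- rep(0, sizes[l + 1])
      vb[[l]] <- rep(0, sizes[l + 1])
    }
    beta1 <- 0.9
    beta2 <- 0.999
    eps <- 1e-8
    t <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        xb <- xs[idx, , drop = FALSE]
        yb <- y[idx]
        m <- length(idx)
        # forward with dropout on hidden activations
        acts <- vector("list", nl + 1)  # post-dropout activations
        raws <- vector("list", nl)      # pre-dropout sigmoid outputs
        drops <- vector("list", nl)
        acts[[1]] <- xb
        for (l in seq_len(nl)) {
          z <- sweep(acts[[l]] %*% w[[l]], 2, b[[l]], "+")
          a <- sigmoid(z)
          raws[[l]] <- a
          if (l < nl && keep_prob < 1) {
            dm <- matrix(
              stats::rbinom(length(a), 1, keep_prob) / keep_prob,
              nrow(a), ncol(a)
            )
            a <- a * dm
            drops[[l]] <- dm
          }
          acts[[l + 1]] <- a
        }
        # backward (cross-entropy + sigmoid output)
        delta <- (acts[[nl + 1]] - yb) / m
        t <- t + 1
        corr1 <- 1 - beta1^t
        corr2 <- 1 - beta2^t
        for (l in rev(seq_len(nl))) {
          gw <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            s <- raws[[l - 1]]
            delta <- delta %*% t(w[[l]])
            if (!is.null(drops[[l - 1]])) {
              delta <- delta * drops[[l - 1]]
            }
            delta <- delta * s * (1 - s)
          }
          mw[[l]] <- beta1 * mw[[l]] + (1 - beta1) * gw
          vw[[l]] <- beta2 * vw[[l]] + (1 - beta2) * gw^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          w[[l]] <- w[[l]] - learning_rate * (mw[[l]] / corr1) /
            (sqrt(vw[[l]] / corr2) + eps)
          b[[l]] <- b[[l]] - learning_rate * (mb[[l]] / corr1) /
            (sqrt(vb[[l]] / corr2) + eps)
        }
      }
    }
    structure(
      list(w = w, b = b, mu = mu, sd = sd, hidden = hidden,
           epochs = epochs, keep_prob = keep_prob),
      class = "phenotray_mlp"
    )
  })
}

mlp_predict <- function(model, x) {
  xs <- sweep(sweep(as.matrix(x), 2, model$mu), 2, model$sd, "/")
  a <- xs
  nl <- length(model$w)
  for (l in seq_len(nl)) {
    a <- sigmoid(sweep(a %*% model$w[[l]], 2, model$b[[l]], "+"))
  }
  as.vector(a)
}
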