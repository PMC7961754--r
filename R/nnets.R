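# Minimal neural networks written in base matrix algebra: a two-hidden-layer
# tanh MLP trained by conjugate gradients, a 1D CNN and a stacked
# bidirectional LSTM trained by full-batch Adam. Gradients are analytic and
# verified against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

xent_loss <- function(prob, y01) {
  -mean(log(pmax(prob[cbind(seq_along(y01), y01 + 1L)], 1e-12)))
}

init_mat <- function(nr, nc) {
  matrix(runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

## ---- MLP: p -> 20 tanh -> 20 tanh -> 1 sigmoid --------------------------

mlp_unpack <- function(theta, p, h) {
  i <- 0L
  take <- function(nr, nc) {
    m <- matrix(theta[i + seq_len(nr * nc)], nr, nc)
    i <<- i + nr * nc
    m
  }
  list(W1 = take(p, h), b1 = take(1, h), W2 = take(h, h), b2 = take(1, h),
       W3 = take(h, 1), b3 = take(1, 1))
}

mlp_loss_grad <- function(theta, X, y, p, h) {
  par <- mlp_unpack(theta, p, h)
  n <- nrow(X)
  A1 <- tanh(sweep(X %*% par$W1, 2, -par$b1))
  A2 <- tanh(sweep(A1 %*% par$W2, 2, -par$b2))
  z <- drop(A2 %*% par$W3) + par$b3[1]
  pr <- sigmoid(z)
  loss <- -mean(y * log(pmax(pr, 1e-12)) + (1 - y) * log(pmax(1 - pr,
                                                              1e-12)))
  dz <- matrix((pr - y) / n, n, 1)
  dW3 <- t(A2) %*% dz
  dA2 <- dz %*% t(par$W3) * (1 - A2^2)
  dW2 <- t(A1) %*% dA2
  dA1 <- dA2 %*% t(par$W2) * (1 - A1^2)
  dW1 <- t(X) %*% dA1
  grad <- c(dW1, colSums(dA1), dW2, colSums(dA2), dW3, sum(dz))
  list(loss = loss, grad = grad)
}

fit_mlp <- function(X, y, hidden = 20, epochs = 70, seed = 1) {
  p <- ncol(X)
  theta0 <- withr::with_seed(seed, {
    c(init_mat(p, hidden), numeric(hidden), init_mat(hidden, hidden),
      numeric(hidden), init_mat(hidden, 1), 0)
  })
  fit <- optim(theta0,
               fn = function(th) mlp_loss_grad(th, X, y, p, hidden)$loss,
               gr = function(th) mlp_loss_grad(th, X, y, p, hidden)$grad,
               method = "CG", control = list(maxit = epochs))
  list(theta = fit$par, p = p, hidden = hidden)
}

predict_mlp <- function(model, X) {
  par <- mlp_unpack(model$theta, model$p, model$hidden)
  A1 <- tanh(sweep(X %*% par$W1, 2, -par$b1))
  A2 <- tanh(sweep(A1 %*% par$W2, 2, -par$b2))
  as.numeric(sigmoid(drop(A2 %*% par$W3) + par$b3[1]) > 0.5)
}

## ---- Adam optimizer ------------------------------------------------------

adam_new <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- 1D CNN --------------------------------------------------------------
# conv1d(filters, kernel, stride 1) -> ReLU -> maxpool(pool, pool) ->
# dense(width, ReLU) -> dense(2, softmax)

cnn_init <- function(channels, len, filters = 64, kernel = 8, pool = 4,
                     dense = 1024, seed = 1) {
  t_out <- len - kernel + 1L
  t2 <- t_out %/% pool
  withr::with_seed(seed, list(
    W = init_mat(channels * kernel, filters), b = numeric(filters),
    W2 = init_mat(t2 * filters, dense), b2 = numeric(dense),
    W3 = init_mat(dense, 2), b3 = numeric(2)
  )) -> params
  list(params = params, channels = channels, len = len, filters = filters,
       kernel = kernel, pool = pool, t_out = t_out, t2 = t2, dense = dense)
}

# X: array N x channels x len -> im2col matrix (N * t_out) x (channels*kernel)
cnn_im2col <- function(X, kernel, t_out) {
  n <- dim(X)[1]; channels <- dim(X)[2]
  M <- matrix(0, n * t_out, channels * kernel)
  for (c in seq_len(channels)) {
    for (j in seq_len(kernel)) {
      M[, (c - 1L) * kernel + j] <- as.vector(X[, c, j:(j + t_out - 1L)])
    }
  }
  M
}

cnn_forward <- function(net, M, n) {
  p <- net$params
  Z <- sweep(M %*% p$W, 2, -p$b)              # (n*t_out) x filters
  R <- Z * (Z > 0)
  A <- array(R, c(n, net$t_out, net$filters))
  t2 <- net$t2; pool <- net$pool
  P <- array(-Inf, c(n, t2, net$filters))
  AM <- array(0L, c(n, t2, net$filters))      # argmax offset within window
  for (o in seq_len(pool)) {
    slice <- A[, (seq_len(t2) - 1L) * pool + o, , drop = FALSE]
    better <- slice > P
    P[better] <- slice[better]
    AM[better] <- o
  }
  Fl <- matrix(P, n, t2 * net$filters)
  H1 <- sweep(Fl %*% p$W2, 2, -p$b2)
  H1 <- H1 * (H1 > 0)
  logits <- sweep(H1 %*% p$W3, 2, -p$b3)
  list(Z = Z, AM = AM, Fl = Fl, H1 = H1, logits = logits,
       prob = softmax_rows(logits))
}

cnn_backward <- function(net, M, fw, y01, n) {
  p <- net$params
  Y <- matrix(0, n, 2); Y[cbind(seq_len(n), y01 + 1L)] <- 1
  dlogits <- (fw$prob - Y) / n
  dW3 <- t(fw$H1) %*% dlogits
  db3 <- colSums(dlogits)
  dH1 <- (dlogits %*% t(p$W3)) * (fw$H1 > 0)
  dW2 <- t(fw$Fl) %*% dH1
  db2 <- colSums(dH1)
  dFl <- dH1 %*% t(p$W2)
  dP <- array(dFl, c(n, net$t2, net$filters))
  dA <- array(0, c(n, net$t_out, net$filters))
  for (o in seq_len(net$pool)) {
    mask <- (fw$AM == o) * dP
    dA[, (seq_len(net$t2) - 1L) * net$pool + o, ] <-
      dA[, (seq_len(net$t2) - 1L) * net$pool + o, , drop = FALSE] + mask
  }
  dZ <- matrix(dA, n * net$t_out, net$filters) * (fw$Z > 0)
  list(W = t(M) %*% dZ, b = colSums(dZ), W2 = dW2, b2 = db2, W3 = dW3,
       b3 = db3)
}

fit_cnn <- function(X, y01, filters = 64, kernel = 8, pool = 4,
                    dense = 1024, lr = 5e-4, epochs = 50, seed = 1) {
  n <- dim(X)[1]
  net <- cnn_init(dim(X)[2], dim(X)[3], filters, kernel, pool, dense, seed)
  M <- cnn_im2col(X, net$kernel, net$t_out)
  st <- adam_new(net$params)
  for (e in seq_len(epochs)) {
    fw <- cnn_forward(net, M, n)
    gr <- cnn_backward(net, M, fw, y01, n)
    up <- adam_step(net$params, gr, st, lr)
    net$params <- up$params
    st <- up$state
  }
  net
}

predict_cnn <- function(net, X) {
  n <- dim(X)[1]
  M <- cnn_im2col(X, net$kernel, net$t_out)
  max.col(cnn_forward(net, M, n)$prob) - 1L
}

## ---- LSTM ----------------------------------------------------------------

lstm_init <- function(input, hidden) {
  Wx <- init_mat(input, 4L * hidden)
  Wh <- init_mat(hidden, 4L * hidden)
  b <- numeric(4L * hidden)
  b[hidden + seq_len(hidden)] <- 1       # forget-gate bias
  list(Wx = Wx, Wh = Wh, b = b)
}

# X: N x T x D. Returns H (N x T x Hd) and caches for backprop.
lstm_forward <- function(par, X) {
  n <- dim(X)[1]; T <- dim(X)[2]
  Hd <- nrow(par$Wh)
  H <- array(0, c(n, T, Hd))
  cache <- vector("list", T)
  h <- matrix(0, n, Hd); cc <- matrix(0, n, Hd)
  idx <- function(k) (k - 1L) * Hd + seq_len(Hd)
  for (t in seq_len(T)) {
    xt <- matrix(X[, t, ], n)
    zz <- sweep(xt %*% par$Wx + h %*% par$Wh, 2, -par$b)
    i <- sigmoid(zz[, idx(1)]); f <- sigmoid(zz[, idx(2)])
    o <- sigmoid(zz[, idx(3)]); g <- tanh(zz[, idx(4)])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    H[, t, ] <- h
    cache[[t]] <- list(xt = xt, i = i, f = f, o = o, g = g, c = cc,
                       c_prev = c_prev, tc = tc,
                       h_prev = if (t == 1L) matrix(0, n, Hd) else
                         H[, t - 1L, ])
  }
  list(H = H, cache = cache)
}

# dH: gradient wrt every timestep's output (N x T x Hd)
lstm_backward <- function(par, fw, dH) {
  n <- dim(dH)[1]; T <- dim(dH)[2]; Hd <- nrow(par$Wh)
  D <- nrow(par$Wx)
  dWx <- par$Wx * 0; dWh <- par$Wh * 0; db <- par$b * 0
  dX <- array(0, c(n, T, D))
  dh_next <- matrix(0, n, Hd); dc_next <- matrix(0, n, Hd)
  for (t in rev(seq_len(T))) {
    ca <- fw$cache[[t]]
    dh <- matrix(dH[, t, ], n) + dh_next
    do <- dh * ca$tc
    dc <- dh * ca$o * (1 - ca$tc^2) + dc_next
    di <- dc * ca$g
    df <- dc * ca$c_prev
    dg <- dc * ca$i
    dZ <- cbind(di * ca$i * (1 - ca$i), df * ca$f * (1 - ca$f),
                do * ca$o * (1 - ca$o), dg * (1 - ca$g^2))
    dWx <- dWx + t(ca$xt) %*% dZ
    dWh <- dWh + t(matrix(ca$h_prev, n)) %*% dZ
    db <- db + colSums(dZ)
    dh_next <- dZ %*% t(par$Wh)
    dc_next <- dc * ca$f
    dX[, t, ] <- dZ %*% t(par$Wx)
  }
  list(Wx = dWx, Wh = dWh, b = db, dX = dX)
}

rev_time <- function(X) X[, rev(seq_len(dim(X)[2])), , drop = FALSE]

# bidirectional layer: concatenated forward/backward outputs per timestep
bilstm_layer_forward <- function(parf, parb, X) {
  fwd <- lstm_forward(parf, X)
  bwd <- lstm_forward(parb, rev_time(X))
  H <- array(0, c(dim(X)[1], dim(X)[2], 2L * nrow(parf$Wh)))
  Hd <- nrow(parf$Wh)
  H[, , seq_len(Hd)] <- fwd$H
  H[, , Hd + seq_len(Hd)] <- rev_time(bwd$H)
  list(H = H, fwd = fwd, bwd = bwd)
}

bilstm_layer_backward <- function(parf, parb, layer, dH) {
  Hd <- nrow(parf$Wh)
  gf <- lstm_backward(parf, layer$fwd,
                      dH[, , seq_len(Hd), drop = FALSE])
  gb <- lstm_backward(parb, layer$bwd,
                      rev_time(dH[, , Hd + seq_len(Hd), drop = FALSE]))
  list(f = gf, b = gb, dX = gf$dX + rev_time(gb$dX))
}

bilstm_init <- function(channels, units1 = 64, units2 = 32, dense = 1024,
                        seed = 1) {
  withr::with_seed(seed, list(
    f1 = lstm_init(channels, units1), b1 = lstm_init(channels, units1),
    f2 = lstm_init(2L * units1, units2), b2 = lstm_init(2L * units1, units2),
    W2 = init_mat(2L * units2, dense), bd = numeric(dense),
    W3 = init_mat(dense, 2), b3 = numeric(2)
  ))
}

bilstm_forward <- function(par, X, drop_mask = NULL) {
  l1 <- bilstm_layer_forward(par$f1, par$b1, X)
  H1 <- l1$H
  if (!is.null(drop_mask)) H1 <- H1 * drop_mask$m1
  l2 <- bilstm_layer_forward(par$f2, par$b2, H1)
  n <- dim(X)[1]; T <- dim(X)[2]; Hd2 <- nrow(par$f2$Wh)
  hl <- cbind(matrix(l2$H[, T, seq_len(Hd2)], n),
              matrix(l2$H[, 1L, Hd2 + seq_len(Hd2)], n))
  if (!is.null(drop_mask)) hl <- hl * drop_mask$m2
  H1d <- sweep(hl %*% par$W2, 2, -par$bd)
  H1d <- H1d * (H1d > 0)
  logits <- sweep(H1d %*% par$W3, 2, -par$b3)
  list(l1 = l1, l2 = l2, H1 = H1, hl = hl, H1d = H1d,
       prob = softmax_rows(logits))
}

bilstm_backward <- function(par, X, fw, y01, drop_mask = NULL) {
  n <- dim(X)[1]; T <- dim(X)[2]
  Hd2 <- nrow(par$f2$Wh)
  Y <- matrix(0, n, 2); Y[cbind(seq_len(n), y01 + 1L)] <- 1
  dlogits <- (fw$prob - Y) / n
  dW3 <- t(fw$H1d) %*% dlogits
  db3 <- colSums(dlogits)
  dH1d <- (dlogits %*% t(par$W3)) * (fw$H1d > 0)
  dW2 <- t(fw$hl) %*% dH1d
  dbd <- colSums(dH1d)
  dhl <- dH1d %*% t(par$W2)
  if (!is.null(drop_mask)) dhl <- dhl * drop_mask$m2
  dH2 <- array(0, c(n, T, 2L * Hd2))
  dH2[, T, seq_len(Hd2)] <- dhl[, seq_len(Hd2)]
  dH2[, 1L, Hd2 + seq_len(Hd2)] <- dhl[, Hd2 + seq_len(Hd2)]
  g2 <- bilstm_layer_backward(par$f2, par$b2, fw$l2, dH2)
  dH1 <- g2$dX
  if (!is.null(drop_mask)) dH1 <- dH1 * drop_mask$m1
  g1 <- bilstm_layer_backward(par$f1, par$b1, fw$l1, dH1)
  list(f1 = g1$f[c("Wx", "Wh", "b")], b1 = g1$b[c("Wx", "Wh", "b")],
       f2 = g2$f[c("Wx", "Wh", "b")], b2 = g2$b[c("Wx", "Wh", "b")],
       W2 = dW2, bd = dbd, W3 = dW3, b3 = db3)
}

# flatten/unflatten nested parameter lists for a generic Adam loop
flatten_params <- function(par) {
  out <- list()
  for (nm in names(par)) {
    if (is.list(par[[nm]])) {
      for (sub in names(par[[nm]])) out[[paste(nm, sub, sep = ".")]] <-
          par[[nm]][[sub]]
    } else out[[nm]] <- par[[nm]]
  }
  out
}

unflatten_params <- function(flat, template) {
  for (nm in names(template)) {
    if (is.list(template[[nm]])) {
      for (sub in names(template[[nm]])) {
        template[[nm]][[sub]] <- flat[[paste(nm, sub, sep = ".")]]
      }
    } else template[[nm]] <- flat[[nm]]
  }
  template
}

fit_bilstm <- function(X, y01, units1 = 64, units2 = 32, dense = 1024,
                       lr = 5e-4, dropout = 0.2, epochs = 30, seed = 1) {
  par <- bilstm_init(dim(X)[3], units1, units2, dense, seed)
  flat <- flatten_params(par)
  st <- adam_new(flat)
  n <- dim(X)[1]; T <- dim(X)[2]
  withr::with_seed(seed + 1L, {
    for (e in seq_len(epochs)) {
      mask <- if (dropout > 0) {
        list(m1 = array(stats::rbinom(n * T * 2 * units1, 1, 1 - dropout) /
                          (1 - dropout), c(n, T, 2 * units1)),
             m2 = matrix(stats::rbinom(n * 2 * units2, 1, 1 - dropout) /
                           (1 - dropout), n, 2 * units2))
      } else NULL
      fw <- bilstm_forward(par, X, mask)
      gr <- bilstm_backward(par, X, fw, y01, mask)
      up <- adam_step(flat, flatten_params(gr), st, lr)
      flat <- up$params
      st <- up$state
      par <- unflatten_params(flat, par)
    }
  })
  par
}

predict_bilstm <- function(par, X) {
  max.col(bilstm_forward(par, X)$prob) - 1L
}

# X: N x C x L -> N x T x C time-major input for the recurrent nets
tensor_to_seq <- function(X) aperm(X, c(1, 3, 2))
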