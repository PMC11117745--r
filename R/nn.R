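# Minimal convolutional network engine: 3x3 same-padding convolutions via
# im2col (C++) + BLAS matmul, 2x2 max pooling, nearest-neighbour
# upsampling, softmax cross-entropy, and Adadelta with global
# gradient-norm clipping.  Feature maps are (H, W, C) arrays; conv
# weights are (9*Cin, Cout) matrices with rows ordered tap-major
# (channel fastest within a tap).

#' @useDynLib semprep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

im2col3 <- function(x) {
  d <- dim(x)
  cpp_im2col3(x, d[1], d[2], d[3])
}

col2im3 <- function(Xg, H, W, C) cpp_col2im3(Xg, H, W, C)

conv3_fwd <- function(x, W, b) {
  d <- dim(x)
  X <- im2col3(x)
  Y <- X %*% W
  Y <- sweep(Y, 2L, b, "+")
  list(y = array(Y, c(d[1], d[2], ncol(W))), X = X)
}

conv3_bwd <- function(dy, X, W, in_dim) {
  d <- dim(dy)
  dY <- matrix(dy, nrow = d[1] * d[2])
  dW <- crossprod(X, dY)
  db <- colSums(dY)
  dX <- tcrossprod(dY, W)
  dx <- col2im3(dX, in_dim[1], in_dim[2], in_dim[3])
  list(dx = dx, dW = dW, db = db)
}

conv1_fwd <- function(x, W, b) {
  d <- dim(x)
  X <- matrix(x, nrow = d[1] * d[2])
  Y <- sweep(X %*% W, 2L, b, "+")
  list(y = array(Y, c(d[1], d[2], ncol(W))), X = X)
}

conv1_bwd <- function(dy, X, W, in_dim) {
  d <- dim(dy)
  dY <- matrix(dy, nrow = d[1] * d[2])
  list(dx = array(tcrossprod(dY, W), in_dim),
       dW = crossprod(X, dY), db = colSums(dY))
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dy, x) dy * (x > 0)

pool2_fwd <- function(x) {
  d <- dim(x)
  oi <- seq(1L, d[1], 2L); ei <- oi + 1L
  oj <- seq(1L, d[2], 2L); ej <- oj + 1L
  s <- list(x[oi, oj, , drop = FALSE], x[ei, oj, , drop = FALSE],
            x[oi, ej, , drop = FALSE], x[ei, ej, , drop = FALSE])
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  list(y = y, slabs = s, in_dim = d)
}

pool2_bwd <- function(dy, cache) {
  d <- cache$in_dim
  y <- pmax(cache$slabs[[1]], cache$slabs[[2]],
            cache$slabs[[3]], cache$slabs[[4]])
  dx <- array(0, d)
  oi <- seq(1L, d[1], 2L); ei <- oi + 1L
  oj <- seq(1L, d[2], 2L); ej <- oj + 1L
  taken <- array(FALSE, dim(y))
  put <- list(list(oi, oj), list(ei, oj), list(oi, ej), list(ei, ej))
  for (k in 1:4) {
    m <- (cache$slabs[[k]] == y) & !taken
    taken <- taken | m
    dx[put[[k]][[1]], put[[k]][[2]], ] <- dy * m
  }
  dx
}

up2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

up2_bwd <- function(dy) {
  d <- dim(dy)
  oi <- seq(1L, d[1], 2L); ei <- oi + 1L
  oj <- seq(1L, d[2], 2L); ej <- oj + 1L
  dy[oi, oj, , drop = FALSE] + dy[ei, oj, , drop = FALSE] +
    dy[oi, ej, , drop = FALSE] + dy[ei, ej, , drop = FALSE]
}

softmax3 <- function(logits) {
  d <- dim(logits)
  L <- matrix(logits, nrow = d[1] * d[2])
  mx <- L[, 1L]
  for (k in 2:ncol(L)) mx <- pmax(mx, L[, k])
  E <- exp(L - mx)
  array(E / rowSums(E), d)
}

# Mean per-pixel categorical cross-entropy and its gradient w.r.t. logits.
# `labels` is an integer matrix of class codes 0..(K-1).
ce_loss_grad <- function(logits, labels) {
  d <- dim(logits)
  p <- softmax3(logits)
  P <- matrix(p, nrow = d[1] * d[2])
  idx <- cbind(seq_len(d[1] * d[2]), as.vector(labels) + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  G <- P
  G[idx] <- G[idx] - 1
  list(loss = loss, dlogits = array(G / (d[1] * d[2]), d))
}

# ---- Adadelta -------------------------------------------------------------

adadelta_state <- function(params) {
  list(Eg = lapply(params, function(p) p * 0),
       Ed = lapply(params, function(p) p * 0))
}

# Clip the global gradient norm, then apply one Adadelta update in place.
adadelta_update <- function(params, grads, state, rho = 0.9, eps = 1e-6,
                            clip = 1.0, lr = 1.0) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(clip) && gn > clip) grads <- lapply(grads, `*`, clip / gn)
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$Eg[[nm]] <- rho * state$Eg[[nm]] + (1 - rho) * g^2
    dx <- -sqrt(state$Ed[[nm]] + eps) / sqrt(state$Eg[[nm]] + eps) * g
    state$Ed[[nm]] <- rho * state$Ed[[nm]] + (1 - rho) * dx^2
    params[[nm]] <- params[[nm]] + lr * dx
  }
  list(params = params, state = state)
}

# ---- U-Net forward/backward ----------------------------------------------

# Widths per encoder level i: base * 2^(i-1); bottleneck doubles the
# deepest level.  `params` is a flat named list of arrays.
unet_init <- function(in_ch, n_classes, base_width, depth, seed = 1L) {
  set.seed(seed)
  he <- function(fan_in, nr, nc)
    matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  p <- list()
  w <- function(i) base_width * 2L^(i - 1L)
  cin <- in_ch
  for (i in seq_len(depth)) {
    p[[sprintf("enc%d.W1", i)]] <- he(9 * cin, 9 * cin, w(i))
    p[[sprintf("enc%d.b1", i)]] <- numeric(w(i))
    p[[sprintf("enc%d.W2", i)]] <- he(9 * w(i), 9 * w(i), w(i))
    p[[sprintf("enc%d.b2", i)]] <- numeric(w(i))
    cin <- w(i)
  }
  wb <- 2L * w(depth)
  p[["bott.W1"]] <- he(9 * w(depth), 9 * w(depth), wb)
  p[["bott.b1"]] <- numeric(wb)
  p[["bott.W2"]] <- he(9 * wb, 9 * wb, wb)
  p[["bott.b2"]] <- numeric(wb)
  cdeep <- wb
  for (i in rev(seq_len(depth))) {
    p[[sprintf("dec%d.Wu", i)]] <- he(9 * cdeep, 9 * cdeep, w(i))
    p[[sprintf("dec%d.bu", i)]] <- numeric(w(i))
    p[[sprintf("dec%d.W1", i)]] <- he(9 * 2 * w(i), 9 * 2 * w(i), w(i))
    p[[sprintf("dec%d.b1", i)]] <- numeric(w(i))
    p[[sprintf("dec%d.W2", i)]] <- he(9 * w(i), 9 * w(i), w(i))
    p[[sprintf("dec%d.b2", i)]] <- numeric(w(i))
    cdeep <- w(i)
  }
  p[["final.W"]] <- he(base_width, base_width, n_classes)
  p[["final.b"]] <- numeric(n_classes)
  p
}

unet_forward <- function(p, x, depth, want_cache = FALSE) {
  cache <- list(enc = vector("list", depth), dec = vector("list", depth))
  h <- x
  for (i in seq_len(depth)) {
    c1 <- conv3_fwd(h, p[[sprintf("enc%d.W1", i)]], p[[sprintf("enc%d.b1", i)]])
    a1 <- relu_fwd(c1$y)
    c2 <- conv3_fwd(a1, p[[sprintf("enc%d.W2", i)]], p[[sprintf("enc%d.b2", i)]])
    a2 <- relu_fwd(c2$y)
    pl <- pool2_fwd(a2)
    cache$enc[[i]] <- list(in_dim = dim(h), X1 = c1$X, z1 = c1$y,
                           a1_dim = dim(a1), X2 = c2$X, z2 = c2$y,
                           skip = a2, pool = pl)
    h <- pl$y
  }
  cb1 <- conv3_fwd(h, p[["bott.W1"]], p[["bott.b1"]])
  ab1 <- relu_fwd(cb1$y)
  cb2 <- conv3_fwd(ab1, p[["bott.W2"]], p[["bott.b2"]])
  ab2 <- relu_fwd(cb2$y)
  cache$bott <- list(in_dim = dim(h), X1 = cb1$X, z1 = cb1$y,
                     a1_dim = dim(ab1), X2 = cb2$X, z2 = cb2$y)
  h <- ab2
  for (i in rev(seq_len(depth))) {
    up <- up2_fwd(h)
    cu <- conv3_fwd(up, p[[sprintf("dec%d.Wu", i)]], p[[sprintf("dec%d.bu", i)]])
    au <- relu_fwd(cu$y)
    skip <- cache$enc[[i]]$skip
    ct <- array(c(au, skip), c(dim(au)[1], dim(au)[2],
                               dim(au)[3] + dim(skip)[3]))
    c1 <- conv3_fwd(ct, p[[sprintf("dec%d.W1", i)]], p[[sprintf("dec%d.b1", i)]])
    a1 <- relu_fwd(c1$y)
    c2 <- conv3_fwd(a1, p[[sprintf("dec%d.W2", i)]], p[[sprintf("dec%d.b2", i)]])
    a2 <- relu_fwd(c2$y)
    cache$dec[[i]] <- list(up_dim = dim(up), Xu = cu$X, zu = cu$y,
                           au_dim = dim(au), cat_dim = dim(ct), Xc = c1$X,
                           z1 = c1$y, a1_dim = dim(a1), X2 = c2$X,
                           z2 = c2$y, h_dim = dim(h))
    h <- a2
  }
  cf <- conv1_fwd(h, p[["final.W"]], p[["final.b"]])
  cache$final <- list(in_dim = dim(h), X = cf$X)
  if (want_cache) list(logits = cf$y, cache = cache) else cf$y
}

unet_backward <- function(p, cache, dlogits, depth) {
  g <- list()
  bf <- conv1_bwd(dlogits, cache$final$X, p[["final.W"]],
                  cache$final$in_dim)
  g[["final.W"]] <- bf$dW; g[["final.b"]] <- bf$db
  dh <- bf$dx
  for (i in seq_len(depth)) {
    cc <- cache$dec[[i]]
    d2 <- relu_bwd(dh, cc$z2)
    b2 <- conv3_bwd(d2, cc$X2, p[[sprintf("dec%d.W2", i)]], cc$a1_dim)
    g[[sprintf("dec%d.W2", i)]] <- b2$dW
    g[[sprintf("dec%d.b2", i)]] <- b2$db
    d1 <- relu_bwd(b2$dx, cc$z1)
    b1 <- conv3_bwd(d1, cc$Xc, p[[sprintf("dec%d.W1", i)]], cc$cat_dim)
    g[[sprintf("dec%d.W1", i)]] <- b1$dW
    g[[sprintf("dec%d.b1", i)]] <- b1$db
    cu_ch <- cc$au_dim[3]
    dau <- b1$dx[, , seq_len(cu_ch), drop = FALSE]
    dskip <- b1$dx[, , cu_ch + seq_len(cc$cat_dim[3] - cu_ch),
                   drop = FALSE]
    cache$enc[[i]]$dskip <- dskip
    du <- relu_bwd(dau, cc$zu)
    bu <- conv3_bwd(du, cc$Xu, p[[sprintf("dec%d.Wu", i)]], cc$up_dim)
    g[[sprintf("dec%d.Wu", i)]] <- bu$dW
    g[[sprintf("dec%d.bu", i)]] <- bu$db
    dh <- up2_bwd(bu$dx)
  }
  cb <- cache$bott
  d2 <- relu_bwd(dh, cb$z2)
  b2 <- conv3_bwd(d2, cb$X2, p[["bott.W2"]], cb$a1_dim)
  g[["bott.W2"]] <- b2$dW; g[["bott.b2"]] <- b2$db
  d1 <- relu_bwd(b2$dx, cb$z1)
  b1 <- conv3_bwd(d1, cb$X1, p[["bott.W1"]], cb$in_dim)
  g[["bott.W1"]] <- b1$dW; g[["bott.b1"]] <- b1$db
  dh <- b1$dx
  for (i in rev(seq_len(depth))) {
    ce <- cache$enc[[i]]
    dpool <- pool2_bwd(dh, ce$pool)
    dskip <- dpool + ce$dskip
    d2 <- relu_bwd(dskip, ce$z2)
    b2 <- conv3_bwd(d2, ce$X2, p[[sprintf("enc%d.W2", i)]], ce$a1_dim)
    g[[sprintf("enc%d.W2", i)]] <- b2$dW
    g[[sprintf("enc%d.b2", i)]] <- b2$db
    d1 <- relu_bwd(b2$dx, ce$z1)
    b1 <- conv3_bwd(d1, ce$X1, p[[sprintf("enc%d.W1", i)]], ce$in_dim)
    g[[sprintf("enc%d.W1", i)]] <- b1$dW
    g[[sprintf("enc%d.b1", i)]] <- b1$db
    dh <- b1$dx
  }
  g
}

unet_param_count <- function(p)
  sum(vapply(p, length, numeric(1)))

# Closed-form parameter count of the architecture unet_init() builds.
unet_count_formula <- function(in_ch, n_classes, base_width, depth) {
  w <- function(i) base_width * 2^(i - 1)
  total <- 0
  cin <- in_ch
  for (i in seq_len(depth)) {
    total <- total + 9 * cin * w(i) + w(i) + 9 * w(i)^2 + w(i)
    cin <- w(i)
  }
  wb <- 2 * w(depth)
  total <- total + 9 * w(depth) * wb + wb + 9 * wb^2 + wb
  cdeep <- wb
  for (i in rev(seq_len(depth))) {
    total <- total + 9 * cdeep * w(i) + w(i) +
      9 * 2 * w(i) * w(i) + w(i) + 9 * w(i)^2 + w(i)
    cdeep <- w(i)
  }
  total + base_width * n_classes + n_classes
}
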